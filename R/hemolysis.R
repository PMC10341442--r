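#' Hemolysis percentage from paired supernatant and suspension fits
#'
#' Hemolysis releases hemoglobin from ruptured cells into the surrounding
#' medium; its extent is the ratio of free (supernatant) to total (suspension)
#' hemoglobin:
#' \deqn{K = 100 \cdot \frac{d \cdot C_{tot}^{sup}}{C_{tot}^{susp}}\ \%,}
#' where each total \eqn{C_{tot} = C_{HbO_2} + C_{Hb} + C_{MetHb}} comes from an
#' [fit_spectrum()] unmixing fit and `d` is an optional dilution ratio (default 1,
#' i.e. no dilution correction). Under measurement noise K may exceed 100%; it
#' is never clipped silently.
#'
#' @param supernatant an `unmix_result` for the supernatant spectrum.
#' @param suspension an `unmix_result` for the suspension spectrum; must have
#'   been fitted at the same path length and have positive total heme.
#' @param dilution_ratio non-negative dimensionless factor applied to the
#'   supernatant concentration.
#' @return An object of class `hemolysis_result` with fields `k_pct`,
#'   `total_heme_supernatant`, `total_heme_suspension` (mmol/L) and
#'   `dilution_ratio`.
#' @examples
#' basis <- synth_basis()
#' pair <- make_hemolysis_pair(30, basis = basis, noise_sd = 0, seed = 1)
#' sup <- fit_spectrum(pair$supernatant, basis)
#' sus <- fit_spectrum(pair$suspension, basis)
#' hemolysis_pct(sup, sus)$k_pct   # 30
#' @export
hemolysis_pct <- function(supernatant, suspension, dilution_ratio = 1) {
  stopifnot(inherits(supernatant, "unmix_result"),
            inherits(suspension, "unmix_result"))
  if (!is_number(dilution_ratio) || dilution_ratio < 0)
    abort_rbc("dilution_ratio must be a non-negative number", "validation")
  if (abs(supernatant$path_length_cm - suspension$path_length_cm) > 1e-12)
    abort_rbc("supernatant and suspension were fitted at different path lengths",
              "validation")
  tot_sup <- total_heme(supernatant)
  tot_susp <- total_heme(suspension)
  if (tot_susp <= 0)
    abort_rbc("suspension total heme is zero; hemolysis is undefined",
              "undefined_hemolysis")
  structure(list(k_pct = 100 * dilution_ratio * tot_sup / tot_susp,
                 total_heme_supernatant = tot_sup,
                 total_heme_suspension = tot_susp,
                 dilution_ratio = dilution_ratio),
            class = "hemolysis_result")
}

#' @export
print.hemolysis_result <- function(x, ...) {
  cat(sprintf("<hemolysis_result> K = %.2f%%  (supernatant %.4g / suspension %.4g mmol/L, dilution %.3g)\n",
              x$k_pct, x$total_heme_supernatant, x$total_heme_suspension,
              x$dilution_ratio))
  invisible(x)
}
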