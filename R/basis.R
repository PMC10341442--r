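#' Extinction-coefficient basis for the three hemoglobin derivatives
#'
#' An `extinction_basis` holds molar absorptivity curves \eqn{\varepsilon(\lambda)}
#' for oxyhemoglobin (HbO2), deoxyhemoglobin (Hb) and methemoglobin (MetHb) on a
#' shared, strictly increasing wavelength grid. Units are L·mmol\eqn{^{-1}}·cm\eqn{^{-1}}
#' throughout, so that \eqn{\varepsilon \cdot C \cdot L} (C in mmol/L, path length L in cm)
#' is a dimensionless absorbance.
#'
#' @param wavelengths_nm strictly increasing numeric vector of wavelengths (nm).
#' @param eps_hbo2,eps_hb,eps_methb non-negative, finite absorptivities, one
#'   value per wavelength (L·mmol⁻¹·cm⁻¹).
#' @param source_label free-text provenance of the table.
#' @return An object of class `extinction_basis`: a list with fields
#'   `wavelengths_nm`, `eps_hbo2`, `eps_hb`, `eps_methb`, `source_label`.
#' @seealso [load_basis()], [synth_basis()], [resample_basis()]
#' @export
extinction_basis <- function(wavelengths_nm, eps_hbo2, eps_hb, eps_methb,
                             source_label = "unspecified") {
  wl <- as.numeric(wavelengths_nm)
  curves <- list(eps_hbo2 = as.numeric(eps_hbo2),
                 eps_hb = as.numeric(eps_hb),
                 eps_methb = as.numeric(eps_methb))
  if (length(wl) < 2L)
    abort_rbc("an extinction basis needs at least 2 wavelengths", "malformed_input")
  if (anyNA(wl) || any(!is.finite(wl)))
    abort_rbc("wavelengths must be finite numbers", "malformed_input")
  if (any(diff(wl) <= 0))
    abort_rbc("wavelengths must be strictly increasing (no duplicates)", "malformed_input")
  for (nm in names(curves)) {
    v <- curves[[nm]]
    if (length(v) != length(wl))
      abort_rbc(sprintf("%s must have one value per wavelength", nm), "malformed_input")
    if (anyNA(v) || any(!is.finite(v)))
      abort_rbc(sprintf("%s contains non-finite values", nm), "validation")
    if (any(v < 0))
      abort_rbc(sprintf("%s contains negative absorptivities", nm), "validation")
  }
  structure(c(list(wavelengths_nm = wl), curves,
              list(source_label = as.character(source_label)[1])),
            class = "extinction_basis")
}

#' @export
print.extinction_basis <- function(x, ...) {
  cat(sprintf("<extinction_basis> %d wavelengths, %.0f-%.0f nm\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm), max(x$wavelengths_nm)))
  cat("  source:", x$source_label, "\n")
  invisible(x)
}

#' Read an extinction-coefficient table from delimited text
#'
#' Expects a header `wavelength_nm,eps_hbo2,eps_hb,eps_methb` (comma- or
#' tab-separated, decimal point). Units are taken as given in the file
#' (L·mmol⁻¹·cm⁻¹ by package convention) and recorded in `source_label`.
#'
#' @param path path to the delimited text file.
#' @param source_label provenance string; defaults to the file name.
#' @return An [extinction_basis()].
#' @examples
#' path <- system.file("extdata", "extinction_synthetic_500_700nm.csv",
#'                     package = "rbcspectra")
#' basis <- load_basis(path)
#' @export
load_basis <- function(path, source_label = basename(path)) {
  if (!file.exists(path))
    abort_rbc(sprintf("basis file not found: %s", path), "malformed_input")
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.csv(path, sep = sep, check.names = TRUE)
  need <- c("wavelength_nm", "eps_hbo2", "eps_hb", "eps_methb")
  if (!all(need %in% names(tab)))
    abort_rbc(sprintf("basis file must have columns %s", paste(need, collapse = ", ")),
              "malformed_input")
  extinction_basis(tab$wavelength_nm, tab$eps_hbo2, tab$eps_hb, tab$eps_methb,
                   source_label = source_label)
}

#' Write an extinction basis to delimited text
#'
#' Inverse of [load_basis()]: writes the four-column comma-separated table that
#' `load_basis()` reads back bit-identically.
#'
#' @param basis an [extinction_basis()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "extinction_basis"))
  # %.17g is lossless for doubles, so load_basis() reads the table back
  # bit-identically
  num <- function(v) sprintf("%.17g", v)
  tab <- data.frame(wavelength_nm = num(basis$wavelengths_nm),
                    eps_hbo2 = num(basis$eps_hbo2),
                    eps_hb = num(basis$eps_hb),
                    eps_methb = num(basis$eps_methb))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample an extinction basis onto a new wavelength grid
#'
#' Linear interpolation of each absorptivity curve onto `grid`. Linear (not
#' spline) interpolation is used deliberately: it is monotone between knots and
#' cannot overshoot below zero, so non-negativity is preserved. Extrapolation
#' outside the basis support is refused.
#'
#' @param basis an [extinction_basis()].
#' @param grid strictly increasing numeric wavelengths (nm), all within
#'   `[min, max]` of the basis grid.
#' @return An [extinction_basis()] on `grid`.
#' @export
resample_basis <- function(basis, grid) {
  stopifnot(inherits(basis, "extinction_basis"))
  grid <- as.numeric(grid)
  if (length(grid) < 2L || any(diff(grid) <= 0))
    abort_rbc("target grid must be strictly increasing with >= 2 points", "malformed_input")
  rng <- range(basis$wavelengths_nm)
  if (min(grid) < rng[1] || max(grid) > rng[2])
    abort_rbc(sprintf(
      "target grid [%.6g, %.6g] nm extends outside basis support [%.6g, %.6g] nm",
      min(grid), max(grid), rng[1], rng[2]), "extrapolation")
  interp <- function(v) stats::approx(basis$wavelengths_nm, v, xout = grid,
                                      method = "linear", ties = "ordered")$y
  extinction_basis(grid, interp(basis$eps_hbo2), interp(basis$eps_hb),
                   interp(basis$eps_methb),
                   source_label = paste0(basis$source_label, " (resampled)"))
}

# Default Gaussian peak placement: HbO2 doublet at 542/577 nm, Hb single peak
# at 555 nm, MetHb at 630 nm -- the literature band positions in the visible.
default_peak_spec <- function() {
  list(
    hbo2  = list(c(542, 12, 13.0), c(577, 11, 14.0)),
    hb    = list(c(555, 22, 12.5)),
    methb = list(c(630, 18, 3.5), c(500, 30, 7.0))
  )
}

#' Synthesize an extinction basis from Gaussian peaks
#'
#' Builds smooth absorptivity curves as sums of Gaussian bumps on the 500–700 nm,
#' 1 nm grid. The defaults place the visible absorption bands of the three
#' derivatives at their literature positions: oxyhemoglobin at 542 and 577 nm,
#' deoxyhemoglobin at 555 nm, methemoglobin at 630 nm. The synthetic basis is a
#' deterministic function of `peak_spec` (no randomness) and is what the shipped
#' fixture `extinction_synthetic_500_700nm.csv` was generated from; it is a
#' synthetic stand-in, not a measured absorptivity table.
#'
#' @param peak_spec named list with elements `hbo2`, `hb`, `methb`; each a list
#'   of peaks `c(center_nm, width_nm, height)`. Centers must lie in
#'   \[500, 700\] nm; widths and heights must be positive.
#' @param wavelengths_nm wavelength grid (default 500–700 nm at 1 nm).
#' @return An [extinction_basis()].
#' @examples
#' b <- synth_basis()
#' b$wavelengths_nm[which.max(b$eps_hb)]   # 555
#' @export
synth_basis <- function(peak_spec = default_peak_spec(),
                        wavelengths_nm = seq(500, 700, by = 1)) {
  need <- c("hbo2", "hb", "methb")
  if (!is.list(peak_spec) || !all(need %in% names(peak_spec)))
    abort_rbc("peak_spec must be a named list with elements hbo2, hb, methb",
              "validation")
  wl <- as.numeric(wavelengths_nm)
  curve <- function(peaks, label) {
    if (length(peaks) == 0L)
      abort_rbc(sprintf("empty peak list for %s", label), "validation")
    y <- numeric(length(wl))
    for (p in peaks) {
      p <- as.numeric(p)
      if (length(p) != 3L || anyNA(p))
        abort_rbc("each peak must be c(center_nm, width_nm, height)", "validation")
      if (p[1] < 500 || p[1] > 700)
        abort_rbc(sprintf("peak center %.1f nm outside [500, 700]", p[1]), "validation")
      if (p[2] <= 0 || p[3] <= 0)
        abort_rbc("peak widths and heights must be positive", "validation")
      y <- y + p[3] * exp(-0.5 * ((wl - p[1]) / p[2])^2)
    }
    y
  }
  extinction_basis(wl,
                   curve(peak_spec$hbo2, "hbo2"),
                   curve(peak_spec$hb, "hb"),
                   curve(peak_spec$methb, "methb"),
                   source_label = "synthetic Gaussian-peak basis")
}
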