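#' Fit options for spectral unmixing
#'
#' @param fit_m fit the constant baseline offset M (AU)? M is unconstrained in
#'   sign: although it is interpreted as large-particle scattering, an
#'   unconstrained offset also absorbs cuvette/blank drift.
#' @param fit_s fit the Rayleigh scattering amplitude S (AU·nm⁴)? Constrained
#'   non-negative.
#' @param components which hemoglobin derivatives to include in the model;
#'   subset of `c("hbo2", "hb", "methb")`. Dropped components are reported as
#'   concentration 0 with SE `NA`.
#' @param lambda_ref internal reference wavelength (nm) for rescaling the
#'   \eqn{\lambda^{-4}} column: the raw nm⁻⁴ values are ~1e-11 and would destroy
#'   the conditioning of the normal equations, so the column used internally is
#'   \eqn{(\lambda_{ref}/\lambda)^4} and S is reported back in AU·nm⁴.
#' @param window wavelength window (nm) the spectrum is cropped to before
#'   fitting (cropped, never resampled).
#' @return A list of class `unmix_options`.
#' @export
fit_options <- function(fit_m = TRUE, fit_s = TRUE,
                        components = c("hbo2", "hb", "methb"),
                        lambda_ref = 550, window = c(500, 700)) {
  components <- match.arg(components, c("hbo2", "hb", "methb"), several.ok = TRUE)
  structure(list(fit_m = isTRUE(fit_m), fit_s = isTRUE(fit_s),
                 components = components, lambda_ref = lambda_ref,
                 window = as.numeric(window)),
            class = "unmix_options")
}

# Single source of truth for the five-term absorbance model
#   D(lambda) = eps_HbO2*C_HbO2*L + eps_Hb*C_Hb*L + eps_MetHb*C_MetHb*L + M + S/lambda^4.
# Returns the design matrix with columns named c_hbo2, c_hb, c_methb, m, s;
# the s column is (lambda_ref/lambda)^4, so its coefficient is S/lambda_ref^4.
eq4_design <- function(basis, path_length_cm, lambda_ref = 550,
                       components = c("hbo2", "hb", "methb"),
                       fit_m = TRUE, fit_s = TRUE) {
  wl <- basis$wavelengths_nm
  cols <- list()
  if ("hbo2" %in% components) cols$c_hbo2 <- basis$eps_hbo2 * path_length_cm
  if ("hb" %in% components) cols$c_hb <- basis$eps_hb * path_length_cm
  if ("methb" %in% components) cols$c_methb <- basis$eps_methb * path_length_cm
  if (fit_m) cols$m <- rep(1, length(wl))
  if (fit_s) cols$s <- (lambda_ref / wl)^4
  do.call(cbind, cols)
}

#' Evaluate the Beer–Lambert + scattering forward model
#'
#' Computes the noise-free theoretical absorbance
#' \deqn{D(\lambda) = \varepsilon_{HbO_2}(\lambda) C_{HbO_2} L +
#'   \varepsilon_{Hb}(\lambda) C_{Hb} L + \varepsilon_{MetHb}(\lambda) C_{MetHb} L
#'   + M + S/\lambda^4}
#' on the basis grid. This is the same design-matrix code path the fitter uses,
#' so forward simulation and inversion cannot drift apart.
#'
#' @param basis an [extinction_basis()] on the desired grid.
#' @param c_hbo2,c_hb,c_methb derivative concentrations (mmol/L), non-negative.
#' @param m constant baseline offset (AU), any sign.
#' @param s_au_nm4 Rayleigh amplitude S (AU·nm⁴), non-negative.
#' @param path_length_cm optical path length (cm); the measurement cell is a
#'   1 mm layer, hence the 0.1 cm default.
#' @return Numeric absorbance (AU) per basis wavelength.
#' @export
forward_absorbance <- function(basis, c_hbo2, c_hb, c_methb, m = 0, s_au_nm4 = 0,
                               path_length_cm = 0.1) {
  stopifnot(inherits(basis, "extinction_basis"))
  if (any(c(c_hbo2, c_hb, c_methb, s_au_nm4) < 0))
    abort_rbc("concentrations and S must be non-negative", "validation")
  lambda_ref <- 550
  X <- eq4_design(basis, path_length_cm, lambda_ref)
  drop(X %*% c(c_hbo2, c_hb, c_methb, m, s_au_nm4 / lambda_ref^4))
}

# Exact solution of min ||y - X b||^2 s.t. b[j] >= 0 for j in `constrained`,
# by enumeration of active sets. The model has at most 4 sign-constrained
# parameters, so all 2^k candidate faces are solved by QR; the global
# constrained minimizer is the feasible candidate with minimal SS (it is the
# unconstrained minimizer of its own face, hence among the candidates).
solve_signed_ls <- function(X, y, constrained, tol = 1e-10) {
  p <- ncol(X)
  k <- length(constrained)
  subsets <- lapply(0:(2^k - 1L), function(bits) constrained[bitwAnd(bits, 2^(seq_len(k) - 1L)) > 0])
  best <- NULL
  for (active in subsets) {
    free <- setdiff(seq_len(p), active)
    if (length(free) == 0L) {
      cand <- numeric(p); ss <- sum(y^2)
    } else {
      qrX <- qr(X[, free, drop = FALSE])
      if (qrX$rank < length(free)) next
      beta <- qr.coef(qrX, y)
      cand <- numeric(p); cand[free] <- beta
      ss <- sum((y - X[, free, drop = FALSE] %*% beta)^2)
    }
    feas <- intersect(free, constrained)
    if (length(feas) && any(cand[feas] < -tol)) next
    cand[constrained] <- pmax(cand[constrained], 0)
    if (is.null(best) || ss < best$ss - 1e-14) best <- list(beta = cand, ss = ss, active = active)
  }
  if (is.null(best))
    abort_rbc("no feasible least-squares solution found (design degenerate?)",
              "degenerate_fit")
  best
}

#' Unmix a measured spectrum into hemoglobin-derivative concentrations
#'
#' Least-squares fit of the five-parameter absorbance model (three derivative
#' concentrations, constant offset M, Rayleigh amplitude S) to a measured
#' spectrum. The model is linear in all five unknowns, so the fit is solved as
#' sign-constrained linear least squares — deterministic, with no starting
#' values or local minima. Concentrations and S are constrained non-negative;
#' M is free. Standard errors come from the curvature \eqn{\hat\sigma^2 (X^T X)^{-1}}
#' of the design restricted to the parameters not pinned at a bound; a pinned
#' parameter reports SE `NA`.
#'
#' @param spectrum an [new_spectrum()] object; its grid (after cropping to
#'   `options$window`) must equal the basis grid exactly.
#' @param basis an [extinction_basis()] resampled to the spectrum's grid
#'   (see [resample_basis()]).
#' @param path_length_cm optical path length in cm (default 0.1 cm = 1 mm layer).
#' @param options an [fit_options()] list.
#' @return An object of class `unmix_result` with fields `c_hbo2`, `c_hb`,
#'   `c_methb` (mmol/L), `m_offset` (AU), `s_rayleigh` (AU·nm⁴), matching
#'   `se_*` standard errors, `r_squared`, `residuals`, `fitted`,
#'   `path_length_cm`, `pinned` (names of parameters at the zero bound) and
#'   `options`.
#' @examples
#' basis <- synth_basis()
#' sp <- new_spectrum(basis$wavelengths_nm,
#'                    forward_absorbance(basis, 1.5, 0, 0))
#' fit <- fit_spectrum(sp, basis)
#' fit$c_hbo2   # 1.5
#' @export
fit_spectrum <- function(spectrum, basis, path_length_cm = 0.1,
                         options = fit_options()) {
  stopifnot(inherits(spectrum, "rbc_spectrum"), inherits(basis, "extinction_basis"))
  if (path_length_cm <= 0)
    abort_rbc("path_length_cm must be positive", "validation")
  sp <- crop_spectrum(spectrum, options$window)
  bwl <- basis$wavelengths_nm
  bkeep <- bwl >= options$window[1] & bwl <= options$window[2]
  bwl <- bwl[bkeep]
  if (length(bwl) != length(sp$wavelengths_nm) ||
      any(abs(bwl - sp$wavelengths_nm) > 1e-9))
    abort_rbc("spectrum and basis wavelength grids differ; resample the basis first",
              "alignment")
  cropped_basis <- extinction_basis(bwl, basis$eps_hbo2[bkeep], basis$eps_hb[bkeep],
                                    basis$eps_methb[bkeep], basis$source_label)
  X <- eq4_design(cropped_basis, path_length_cm, options$lambda_ref,
                  components = options$components,
                  fit_m = options$fit_m, fit_s = options$fit_s)
  y <- sp$absorbance
  if (length(y) < ncol(X))
    abort_rbc(sprintf("spectrum has %d points but the model has %d free parameters",
                      length(y), ncol(X)), "validation")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort_rbc(sprintf("design is rank-deficient; collinear column(s): %s",
                      paste(bad, collapse = ", ")), "degenerate_fit")
  }
  constrained <- which(colnames(X) != "m")
  sol <- solve_signed_ls(X, y, constrained)

  # SEs from the active-set-reduced design
  se <- rep(NA_real_, ncol(X))
  free <- setdiff(seq_len(ncol(X)), sol$active)
  dof <- length(y) - length(free)
  if (length(free) > 0L && dof > 0L) {
    XtX_inv <- chol2inv(chol(crossprod(X[, free, drop = FALSE])))
    se[free] <- sqrt(pmax(diag(XtX_inv), 0) * sol$ss / dof)
  }
  names(se) <- colnames(X)
  beta <- setNames(sol$beta, colnames(X))

  get <- function(nm, default = 0) if (nm %in% names(beta)) unname(beta[nm]) else default
  gse <- function(nm) if (nm %in% names(se)) unname(se[nm]) else NA_real_
  fitted <- drop(X %*% sol$beta)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - sol$ss / sstot else NA_real_
  sref4 <- options$lambda_ref^4
  structure(list(
    c_hbo2 = get("c_hbo2"), se_hbo2 = gse("c_hbo2"),
    c_hb = get("c_hb"), se_hb = gse("c_hb"),
    c_methb = get("c_methb"), se_methb = gse("c_methb"),
    m_offset = get("m", 0), se_m = gse("m"),
    s_rayleigh = get("s", 0) * sref4, se_s = gse("s") * sref4,
    r_squared = r2, ss_res = sol$ss,
    residuals = y - fitted, fitted = fitted,
    wavelengths_nm = sp$wavelengths_nm,
    path_length_cm = path_length_cm,
    pinned = colnames(X)[sol$active],
    meta = sp$meta, options = options,
    nonneg_constrained = TRUE), class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, digits = 4, ...) {
  pm <- function(v, s) {
    if (is.na(s)) sprintf("%.*g (at bound)", digits, v)
    else sprintf("%.*g ± %.*g", digits, v, 2, s)
  }
  cat("<unmix_result> concentrations (mmol/L), value ± SE\n")
  cat("  C_HbO2 :", pm(x$c_hbo2, x$se_hbo2), "\n")
  cat("  C_Hb   :", pm(x$c_hb, x$se_hb), "\n")
  cat("  C_MetHb:", pm(x$c_methb, x$se_methb), "\n")
  cat("  M      :", pm(x$m_offset, x$se_m), "AU\n")
  cat("  S      :", pm(x$s_rayleigh, x$se_s), "AU·nm⁴\n")
  cat(sprintf("  R² = %.5f\n", x$r_squared))
  invisible(x)
}

#' Total heme concentration of an unmixing fit
#'
#' Sum of the three fitted derivative concentrations (mmol/L).
#'
#' @param result an `unmix_result`.
#' @return Numeric scalar, mmol/L.
#' @export
total_heme <- function(result) {
  stopifnot(inherits(result, "unmix_result"))
  result$c_hbo2 + result$c_hb + result$c_methb
}

#' Hemoglobin-derivative percentages of total heme
#'
#' Converts fitted concentrations to percentages
#' \eqn{100 \cdot C_x / (C_{HbO_2} + C_{Hb} + C_{MetHb})}.
#'
#' @param result an `unmix_result`, or a numeric vector of three non-negative
#'   concentrations `(c_hbo2, c_hb, c_methb)`.
#' @return A list of class `hb_fractions` with `hbo2_pct`, `hb_pct`,
#'   `methb_pct`, summing to 100.
#' @export
fractions <- function(result) {
  if (inherits(result, "unmix_result")) {
    conc <- c(result$c_hbo2, result$c_hb, result$c_methb)
  } else {
    conc <- as.numeric(result)
    if (length(conc) != 3L || anyNA(conc))
      abort_rbc("fractions() needs an unmix_result or 3 concentrations", "validation")
  }
  if (any(conc < 0))
    abort_rbc("concentrations must be non-negative", "validation")
  tot <- sum(conc)
  if (tot <= 0)
    abort_rbc("total heme concentration is zero; fractions are undefined",
              "undefined_fraction")
  structure(list(hbo2_pct = 100 * conc[1] / tot,
                 hb_pct = 100 * conc[2] / tot,
                 methb_pct = 100 * conc[3] / tot),
            class = "hb_fractions")
}

#' @export
print.hb_fractions <- function(x, ...) {
  cat(sprintf("<hb_fractions> HbO2 %.2f%% | Hb %.2f%% | MetHb %.2f%%\n",
              x$hbo2_pct, x$hb_pct, x$methb_pct))
  invisible(x)
}

#' Unmix a batch of spectra into a tidy results table
#'
#' Runs [fit_spectrum()] and [fractions()] on each spectrum; per-spectrum
#' failures are recorded in the `error` column and do not abort the batch.
#' Rows are ordered by (tube, sts_pct, day).
#'
#' @param spectra a list of `rbc_spectrum` objects.
#' @inheritParams fit_spectrum
#' @return A [tibble::tibble()] with the metadata columns, fitted parameters
#'   and SEs, `r_squared`, derivative percentages, `ok` and `error`.
#' @export
batch_fit <- function(spectra, basis, path_length_cm = 0.1,
                      options = fit_options()) {
  if (length(spectra) == 0L) {
    return(tibble::tibble(sample_id = character(), day = integer(),
                          sts_pct = numeric(), tube = character(),
                          kind = character(), c_hbo2 = numeric(),
                          c_hb = numeric(), c_methb = numeric(),
                          m_offset = numeric(), s_rayleigh = numeric(),
                          r_squared = numeric(), hbo2_pct = numeric(),
                          hb_pct = numeric(), methb_pct = numeric(),
                          ok = logical(), error = character()))
  }
  rows <- lapply(spectra, function(sp) {
    m <- if (inherits(sp, "rbc_spectrum")) sp$meta else
      list(sample_id = NA_character_, day = NA_integer_, sts_pct = NA_real_,
           tube = NA_character_, kind = NA_character_)
    base <- tibble::tibble(sample_id = m$sample_id, day = m$day,
                           sts_pct = m$sts_pct, tube = m$tube, kind = m$kind)
    res <- tryCatch({
      fit <- fit_spectrum(sp, basis, path_length_cm, options)
      fr <- fractions(fit)
      cbind(base, tibble::tibble(
        c_hbo2 = fit$c_hbo2, c_hb = fit$c_hb, c_methb = fit$c_methb,
        m_offset = fit$m_offset, s_rayleigh = fit$s_rayleigh,
        r_squared = fit$r_squared,
        hbo2_pct = fr$hbo2_pct, hb_pct = fr$hb_pct, methb_pct = fr$methb_pct,
        ok = TRUE, error = NA_character_))
    }, error = function(e) {
      cbind(base, tibble::tibble(
        c_hbo2 = NA_real_, c_hb = NA_real_, c_methb = NA_real_,
        m_offset = NA_real_, s_rayleigh = NA_real_, r_squared = NA_real_,
        hbo2_pct = NA_real_, hb_pct = NA_real_, methb_pct = NA_real_,
        ok = FALSE, error = conditionMessage(e)))
    })
    res
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out[order(out$tube, out$sts_pct, out$day, na.last = TRUE), ]
}
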