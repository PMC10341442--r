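#' Deoxyhemoglobin kinetic series
#'
#' A per-condition time course of the deoxyhemoglobin percentage during storage:
#' mean Hb% per sampling day, optionally with per-day standard deviations used
#' as weights in [fit_cdf()].
#'
#' @param times storage days, non-negative and strictly increasing.
#' @param hb_pct mean deoxyhemoglobin percentage per time, each in \[0, 100\].
#' @param sd_pct optional standard deviation per time (percentage points).
#' @param sts_pct,tube condition labels carried along for reporting.
#' @return A list of class `kinetic_series`.
#' @export
kinetic_series <- function(times, hb_pct, sd_pct = NULL,
                           sts_pct = NA_real_, tube = NA_character_) {
  times <- as.numeric(times); hb_pct <- as.numeric(hb_pct)
  if (length(times) != length(hb_pct))
    abort_rbc("times and hb_pct must have equal length", "malformed_input")
  if (any(times < 0) || any(diff(times) <= 0))
    abort_rbc("times must be non-negative and strictly increasing", "malformed_input")
  if (any(!is.finite(hb_pct)) || any(hb_pct < 0) || any(hb_pct > 100))
    abort_rbc("hb_pct values must be finite and in [0, 100]", "validation")
  if (!is.null(sd_pct)) {
    sd_pct <- as.numeric(sd_pct)
    if (length(sd_pct) != length(times) || any(!is.finite(sd_pct)) || any(sd_pct <= 0))
      abort_rbc("sd_pct must be positive, one value per time", "validation")
  }
  structure(list(times = times, hb_pct = hb_pct, sd_pct = sd_pct,
                 condition = list(sts_pct = sts_pct, tube = tube)),
            class = "kinetic_series")
}

# Normal-CDF transition curve used throughout the kinetics module.
cdf_curve <- function(t, base, plateau, tm, sigma) {
  base + (plateau - base) * pnorm((t - tm) / sigma)
}

#' Fit a Normal-CDF transition model to a deoxyhemoglobin time course
#'
#' Least-squares fit of
#' \deqn{y(t) = base + (plateau - base)\,\Phi\!\left(\frac{t - t_m}{\sigma}\right)}
#' with \eqn{\Phi} the standard normal CDF, by Levenberg–Marquardt with box
#' bounds (0 ≤ base, plateau ≤ 100; σ > 0). When per-day standard deviations
#' are present the residuals are weighted by 1/sd². Initialization is
#' deterministic and data-driven: base = min(y), plateau = max(y), tm = the
#' linearly interpolated crossing of (base+plateau)/2, σ = span/4; a small
#' ladder of perturbed restarts is tried before declaring non-convergence.
#' Both asymptotes are fitted (with bounds), not pinned at the observed
#' extremes; which convention an external fitting tool used is unknowable from
#' reported values alone, so the fitted-asymptote convention is recorded in the
#' result.
#'
#' @param series a [kinetic_series()]; needs ≥4 time points and a non-flat
#'   response.
#' @param max_restarts number of perturbed restarts on non-convergence.
#' @return An object of class `cdf_fit`: `base_pct`, `plateau_pct`, `tm_days`,
#'   `sigma_days` with `se_*` standard errors, `rate_per_day` (= 1/tm), the
#'   derived `t50_abs_days` (absolute 50%-level crossing, `NA` when 50% lies
#'   outside (base, plateau)), `converged`, `r_squared` and the data.
#' @examples
#' s <- kinetic_series(c(0, 7, 14, 21, 29),
#'                     cdf_curve(c(0, 7, 14, 21, 29), 20, 85, 11, 3))
#' fit_cdf(s)$tm_days   # 11
#' @export
fit_cdf <- function(series, max_restarts = 8) {
  stopifnot(inherits(series, "kinetic_series"))
  t <- series$times; y <- series$hb_pct
  if (length(t) < 4L)
    abort_rbc("need at least 4 time points to fit the 4-parameter CDF model",
              "validation")
  if (diff(range(y)) < sqrt(.Machine$double.eps))
    abort_rbc("series is flat; the transition model is degenerate", "degenerate_series")
  w <- if (is.null(series$sd_pct)) rep(1, length(t)) else 1 / series$sd_pct^2
  span <- diff(range(t))
  base0 <- min(y); plat0 <- max(y)
  mid <- (base0 + plat0) / 2
  tm0 <- stats::approx(y, t, xout = mid, ties = "ordered")$y
  if (is.na(tm0)) tm0 <- mean(range(t))
  start0 <- c(base = base0, plateau = plat0, tm = tm0, sigma = span / 4)
  lower <- c(base = 0, plateau = 0, tm = min(t) - span, sigma = 1e-3)
  upper <- c(base = 100, plateau = 100, tm = max(t) + span, sigma = span * 2)

  dat <- data.frame(t = t, y = y)
  attempt <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(y ~ base + (plateau - base) * pnorm((t - tm) / sigma),
                        data = dat, start = as.list(start), weights = w,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  }
  wss <- function(p) sum(w * (y - cdf_curve(t, p[1], p[2], p[3], p[4]))^2)

  best <- attempt(start0)
  best_ss <- if (!is.null(best)) sum(w * residuals(best)^2) else Inf
  restart <- 0L
  # deterministic restart ladder: scale tm and sigma around the data span
  while (restart < max_restarts) {
    restart <- restart + 1L
    fr <- restart / (max_restarts + 1)
    st <- c(base = base0, plateau = plat0,
            tm = min(t) + fr * span,
            sigma = max(span * fr / 2, 0.5))
    f2 <- attempt(st)
    if (!is.null(f2)) {
      ss2 <- sum(w * residuals(f2)^2)
      if (ss2 < best_ss - 1e-12) { best <- f2; best_ss <- ss2 }
    }
  }

  # Profiled fallback for step-like optima where Levenberg-Marquardt cannot
  # build its model object (the tm/sigma gradient columns vanish as sigma
  # approaches the bound): scan (tm, sigma), solving the linear (base, plateau)
  # subproblem exactly, then polish all four parameters with bounded BFGS.
  profile_fit <- function() {
    grid_tm <- seq(min(t), max(t), length.out = 41)
    grid_sg <- exp(seq(log(lower[["sigma"]]), log(upper[["sigma"]]), length.out = 25))
    best_p <- NULL; best_pss <- Inf
    for (tm_i in grid_tm) for (sg_i in grid_sg) {
      phi <- pnorm((t - tm_i) / sg_i)
      Xl <- cbind(1 - phi, phi) * sqrt(w)
      cf <- tryCatch(qr.coef(qr(Xl), y * sqrt(w)), error = function(e) NULL)
      if (is.null(cf) || anyNA(cf)) next
      cf <- pmin(pmax(cf, 0), 100)
      if (cf[2] < cf[1]) next
      p <- c(cf[1], cf[2], tm_i, sg_i)
      ss <- wss(p)
      if (ss < best_pss) { best_p <- p; best_pss <- ss }
    }
    if (is.null(best_p)) return(NULL)
    opt <- stats::optim(best_p, wss, method = "L-BFGS-B",
                        lower = c(lower[["base"]], lower[["plateau"]],
                                  lower[["tm"]], lower[["sigma"]]),
                        upper = c(upper[["base"]], upper[["plateau"]],
                                  upper[["tm"]], upper[["sigma"]]),
                        hessian = TRUE,
                        control = list(maxit = 500, factr = 1e4))
    list(par = opt$par, ss = opt$value, hessian = opt$hessian)
  }

  # the profiled search is cheap and guards against local optima of the
  # Levenberg-Marquardt path, so it always runs
  fallback <- profile_fit()
  if (is.null(best) && is.null(fallback))
    abort_rbc("Normal-CDF fit failed to converge after bounded restarts",
              "non_convergence")
  if (!is.null(fallback) && fallback$ss < best_ss - 1e-12) {
    # try to polish the profiled optimum with LM for an exact covariance
    polished <- attempt(setNames(fallback$par, c("base", "plateau", "tm", "sigma")))
    if (!is.null(polished) && sum(w * residuals(polished)^2) <= fallback$ss + 1e-9) {
      best <- polished
      best_ss <- sum(w * residuals(polished)^2)
      fallback <- NULL
    }
  }

  if (!is.null(fallback) && fallback$ss < best_ss - 1e-12) {
    est <- setNames(fallback$par, c("base", "plateau", "tm", "sigma"))
    dof <- length(t) - 4L
    se <- rep(NA_real_, 4L)
    if (dof > 0L) {
      # Hessian of the weighted SS is 2 J'WJ near the optimum; invert where
      # the curvature is informative, report NA in degenerate directions
      covm <- tryCatch(solve(fallback$hessian / 2) * fallback$ss / dof,
                       error = function(e) NULL)
      if (!is.null(covm)) {
        dg <- diag(covm)
        se <- ifelse(dg > 0 & is.finite(dg), sqrt(pmax(dg, 0)), NA_real_)
      }
    }
    names(se) <- names(est)
  } else {
    est <- coef(best)
    se <- tryCatch(sqrt(diag(vcov(best))), error = function(e) rep(NA_real_, 4))
    names(se) <- names(est)
  }
  if (est[["plateau"]] < est[["base"]]) {
    abort_rbc("fitted transition is decreasing (plateau < base); model assumes a rising Hb course",
              "degenerate_series")
  }
  resid <- y - cdf_curve(t, est[["base"]], est[["plateau"]], est[["tm"]], est[["sigma"]])
  sstot <- sum(w * (y - sum(w * y) / sum(w))^2)
  r2 <- if (sstot > 0) 1 - sum(w * resid^2) / sstot else NA_real_
  tm <- est[["tm"]]
  t50 <- if (est[["base"]] < 50 && 50 < est[["plateau"]]) {
    tm + est[["sigma"]] * qnorm((50 - est[["base"]]) / (est[["plateau"]] - est[["base"]]))
  } else NA_real_
  structure(list(base_pct = est[["base"]], se_base = se[["base"]],
                 plateau_pct = est[["plateau"]], se_plateau = se[["plateau"]],
                 tm_days = tm, se_tm = se[["tm"]],
                 sigma_days = est[["sigma"]], se_sigma = se[["sigma"]],
                 rate_per_day = if (tm > 0) 1 / tm else NA_real_,
                 t50_abs_days = t50,
                 r_squared = r2, converged = TRUE,
                 asymptotes = "fitted (bounded), not pinned at observed extremes",
                 series = series),
            class = "cdf_fit")
}

#' @export
print.cdf_fit <- function(x, ...) {
  cat("<cdf_fit> y(t) = base + (plateau - base) * pnorm((t - tm)/sigma)\n")
  cat(sprintf("  base    = %.2f ± %.2f %%\n", x$base_pct, x$se_base))
  cat(sprintf("  plateau = %.2f ± %.2f %%\n", x$plateau_pct, x$se_plateau))
  cat(sprintf("  tm      = %.2f ± %.2f days\n", x$tm_days, x$se_tm))
  cat(sprintf("  sigma   = %.2f ± %.2f days\n", x$sigma_days, x$se_sigma))
  cat(sprintf("  rate    = %.2f / day   R² = %.4f\n", x$rate_per_day, x$r_squared))
  invisible(x)
}

#' Deoxyhemoglobin formation rate from a transition fit
#'
#' The formation rate is defined as the reciprocal transition time,
#' \eqn{1/t_m} (day⁻¹): with the transition times 11.0 and 17.7 days this gives
#' 0.09 and 0.06 day⁻¹ at two decimals. The alternative convention — the
#' maximum slope of the fitted CDF — is available as [rate_max_slope()].
#'
#' @param fit a `cdf_fit` (or a positive tm in days).
#' @param digits if non-NULL, round for reporting (the printed convention uses 2).
#' @return Rate in day⁻¹.
#' @examples
#' rate(11.0, digits = 2)   # 0.09
#' rate(17.7, digits = 2)   # 0.06
#' @export
rate <- function(fit, digits = NULL) {
  tm <- if (inherits(fit, "cdf_fit")) fit$tm_days else as.numeric(fit)
  if (!is_number(tm) || tm <= 0)
    abort_rbc("rate is undefined for non-positive transition time", "undefined_rate")
  r <- 1 / tm
  if (!is.null(digits)) round(r, digits) else r
}

#' Maximum-slope formation rate (secondary convention)
#'
#' The steepest slope of the fitted transition, attained at \eqn{t = t_m}:
#' \eqn{(plateau - base)\,\phi(0)/\sigma} in percentage points per day, divided
#' by 100 to express it as a fraction of total hemoglobin per day.
#'
#' @param fit a `cdf_fit`.
#' @return Rate in day⁻¹ (fraction of total heme per day).
#' @export
rate_max_slope <- function(fit) {
  stopifnot(inherits(fit, "cdf_fit"))
  (fit$plateau_pct - fit$base_pct) / 100 * dnorm(0) / fit$sigma_days
}

#' Time at which the fitted transition crosses a threshold level
#'
#' Analytic inversion of the fitted CDF:
#' \eqn{t = t_m + \sigma\,\Phi^{-1}\!\big((threshold - base)/(plateau - base)\big)}.
#'
#' @param fit a `cdf_fit`.
#' @param threshold_pct level in percent, strictly between the fitted base and
#'   plateau.
#' @return Time in days.
#' @export
time_to_threshold <- function(fit, threshold_pct) {
  stopifnot(inherits(fit, "cdf_fit"))
  if (!is_number(threshold_pct) ||
      threshold_pct <= fit$base_pct || threshold_pct >= fit$plateau_pct)
    abort_rbc(sprintf(
      "threshold %.3g%% is outside the fitted transition range (%.3g%%, %.3g%%)",
      threshold_pct, fit$base_pct, fit$plateau_pct), "unreachable_threshold")
  fit$tm_days + fit$sigma_days *
    qnorm((threshold_pct - fit$base_pct) / (fit$plateau_pct - fit$base_pct))
}
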