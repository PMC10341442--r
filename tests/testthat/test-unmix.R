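test_that("a pure-HbO2 noise-free spectrum is recovered exactly", {
  b <- fixture_basis
  sp <- new_spectrum(b$wavelengths_nm, 0.1 * b$eps_hbo2 * 1.5)
  fit <- fit_spectrum(sp, b, path_length_cm = 0.1)
  expect_equal(fit$c_hbo2, 1.5, tolerance = 1e-9)
  expect_equal(fit$c_hb, 0)
  expect_equal(fit$c_methb, 0)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("forward-inverse identity holds across random interior parameter sets", {
  set.seed(101)
  for (i in 1:25) {
    truth <- c(runif(3, 0.05, 2), runif(1, -0.1, 0.2), runif(1, 1e8, 5e9))
    sp <- new_spectrum(fixture_basis$wavelengths_nm,
                       forward_absorbance(fixture_basis, truth[1], truth[2],
                                          truth[3], truth[4], truth[5]))
    fit <- fit_spectrum(sp, fixture_basis)
    est <- c(fit$c_hbo2, fit$c_hb, fit$c_methb, fit$m_offset, fit$s_rayleigh)
    expect_lt(max(abs(est - truth) / pmax(abs(truth), 1e-12)), 1e-6)
  }
})

test_that("fitted concentrations scale linearly with the heme signal", {
  conc <- c(0.3, 0.2, 0.05)
  ab <- forward_absorbance(fixture_basis, conc[1], conc[2], conc[3], 0, 0)
  for (k in c(0.5, 2, 7)) {
    fit <- fit_spectrum(new_spectrum(fixture_basis$wavelengths_nm, k * ab),
                        fixture_basis)
    expect_equal(c(fit$c_hbo2, fit$c_hb, fit$c_methb), k * conc,
                 tolerance = 1e-8)
  }
})

test_that("constrained SSres is never below the unconstrained least squares", {
  b <- toy_basis()
  set.seed(7)
  opts <- fit_options(fit_m = FALSE, fit_s = FALSE,
                      components = c("hbo2", "hb"), window = c(500, 700))
  X <- cbind(b$eps_hbo2, b$eps_hb) * 0.1
  for (i in 1:30) {
    y <- drop(X %*% runif(2, -0.5, 1.5)) + rnorm(5, 0, 0.05)
    fit <- fit_spectrum(new_spectrum(b$wavelengths_nm, y), b, options = opts)
    ls <- lm.fit(X, y)
    ss_unc <- sum(ls$residuals^2)
    expect_gte(fit$ss_res, ss_unc - 1e-10)
    if (all(ls$coefficients >= 0))
      expect_equal(fit$ss_res, ss_unc, tolerance = 1e-10)
  }
})

test_that("the fitter agrees with pracma::lsqnonneg when all parameters are signed", {
  skip_if_not_installed("pracma")
  b <- toy_basis()
  opts <- fit_options(fit_m = FALSE, fit_s = TRUE, window = c(500, 700))
  set.seed(11)
  for (i in 1:20) {
    y <- runif(5, 0, 2)
    fit <- fit_spectrum(new_spectrum(b$wavelengths_nm, y), b, options = opts)
    X <- cbind(b$eps_hbo2 * 0.1, b$eps_hb * 0.1, b$eps_methb * 0.1,
               (550 / b$wavelengths_nm)^4)
    ref <- pracma::lsqnonneg(X, y)$x
    est <- c(fit$c_hbo2, fit$c_hb, fit$c_methb, fit$s_rayleigh / 550^4)
    expect_equal(est, ref, tolerance = 1e-7)
  }
})

test_that("rank-deficient designs and misaligned grids raise informative errors", {
  wl <- seq(500, 700, 10)
  eps <- exp(-0.5 * ((wl - 560) / 30)^2)
  dup <- extinction_basis(wl, eps, eps, 0.5 * eps + 0.1)
  sp <- new_spectrum(wl, eps * 0.05 + 0.01)
  err <- expect_error(fit_spectrum(sp, dup), class = "rbcspectra_degenerate_fit")
  expect_match(conditionMessage(err), "c_hb|c_hbo2")

  other <- new_spectrum(seq(505, 695, 10), rep(0.1, 20))
  expect_error(fit_spectrum(other, dup), class = "rbcspectra_alignment")
})

test_that("parameters pinned at the zero bound report SE NA, free ones a finite SE", {
  b <- fixture_basis
  # pure Hb signal: HbO2 and MetHb should pin at 0 under noise pushing negative
  set.seed(3)
  ab <- forward_absorbance(b, 0, 0.5, 0, 0.02, 0) + rnorm(201, 0, 0.002)
  fit <- fit_spectrum(new_spectrum(b$wavelengths_nm, ab), b)
  expect_true(is.finite(fit$se_hb))
  expect_true(is.finite(fit$se_m))
  for (nm in fit$pinned) {
    se <- switch(nm, c_hbo2 = fit$se_hbo2, c_hb = fit$se_hb,
                 c_methb = fit$se_methb, s = fit$se_s)
    expect_true(is.na(se))
  }
  out <- capture.output(print(fit))
  expect_true(any(grepl("±", out)))           # value ± SE reporting
  expect_true(any(grepl("R²", out)))
})

test_that("fractions normalises concentrations and rejects a zero total", {
  fr <- fractions(c(1, 1, 2))
  expect_equal(c(fr$hbo2_pct, fr$hb_pct, fr$methb_pct), c(25, 25, 50))
  fr1 <- fractions(c(3.7, 0, 0))
  expect_equal(c(fr1$hbo2_pct, fr1$hb_pct, fr1$methb_pct), c(100, 0, 0))
  expect_error(fractions(c(0, 0, 0)), class = "rbcspectra_undefined_fraction")
  expect_error(fractions(c(-1, 1, 1)), class = "rbcspectra_validation")
})

test_that("batch_fit isolates failures, orders rows, and recovers a monotone course", {
  b <- fixture_basis
  good <- make_reference_replicate(seed = 5, noise_sd = 0)
  bad <- new_spectrum(seq(505, 695, 5), rep(0.2, 39), sample_id = "bad",
                      day = 3, sts_pct = 0, tube = "closed", kind = "suspension")
  tab <- batch_fit(c(good, list(bad)), b)
  expect_identical(nrow(tab), 6L)
  expect_identical(sum(tab$ok), 5L)
  expect_identical(sum(!tab$ok), 1L)
  expect_false(is.na(tab$error[!tab$ok]))

  okt <- tab[tab$ok, ]
  expect_identical(okt$day, sort(okt$day))            # ordered by day
  expect_true(all(diff(okt$hb_pct[order(okt$day)]) >= -1e-6))  # CDF rise recovered
  expect_true(all(abs(okt$r_squared - 1) < 1e-10))

  empty <- batch_fit(list(), b)
  expect_identical(nrow(empty), 0L)
})
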