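test_that("make_trajectory follows the CDF + delayed-ramp model and sums to 100", {
  tr <- make_trajectory(trajectory_config())
  expect_identical(tr$day, c(0, 7, 14, 21, 29))
  expect_equal(tr$hb_pct[1], 20, tolerance = 0.02)       # day-0 Hb ~20%
  expect_equal(tr$hb_pct[5], 85, tolerance = 0.02)       # day-29 Hb ~85%
  expect_true(all(abs(tr$hbo2_pct + tr$hb_pct + tr$methb_pct - 100) < 1e-9))
  expect_true(all(tr$methb_pct == 0))

  flat <- make_trajectory(trajectory_config(hb_base_pct = 20, hb_plateau_pct = 20))
  expect_true(all(flat$hb_pct == 20))

  ramp <- make_trajectory(trajectory_config(hb_base_pct = 20, hb_plateau_pct = 20,
                                            methb_onset_day = 7,
                                            methb_final_pct = 25))
  expect_equal(ramp$methb_pct, c(0, 0, 25 * 7 / 22, 25 * 14 / 22, 25),
               tolerance = 1e-12)
})

test_that("configs implying negative HbO2 are rejected", {
  expect_error(trajectory_config(hb_base_pct = 60, hb_plateau_pct = 90,
                                 methb_final_pct = 40),
               class = "rbcspectra_config")
  expect_error(trajectory_config(days = c(0, 0, 7)), class = "rbcspectra_config")
  expect_error(trajectory_config(hb_sigma_days = 0), class = "rbcspectra_config")
})

test_that("make_spectrum is deterministic given a seed and leaves the session RNG alone", {
  a <- make_spectrum(c(20, 75, 5), 0.6, fixture_basis, noise_sd = 0.01, seed = 9)
  b <- make_spectrum(c(20, 75, 5), 0.6, fixture_basis, noise_sd = 0.01, seed = 9)
  expect_identical(a$absorbance, b$absorbance)
  c_ <- make_spectrum(c(20, 75, 5), 0.6, fixture_basis, noise_sd = 0.01, seed = 10)
  expect_false(identical(a$absorbance, c_$absorbance))

  set.seed(123); before <- rnorm(1)
  set.seed(123)
  invisible(make_spectrum(c(20, 75, 5), 0.6, fixture_basis, noise_sd = 0.01, seed = 9))
  expect_identical(rnorm(1), before)

  expect_error(make_spectrum(c(20, 75, 5), -1, fixture_basis),
               class = "rbcspectra_validation")
  expect_error(make_spectrum(c(20, 75, 15), 0.6, fixture_basis),
               class = "rbcspectra_validation")
})

test_that("forward model and fitter share one design: noise-free spectra invert exactly", {
  cfg <- trajectory_config(noise_sd_au = 0)
  tr <- make_trajectory(cfg)
  for (i in c(1, 3, 5)) {
    sp <- make_spectrum(c(tr$hbo2_pct[i], tr$hb_pct[i], tr$methb_pct[i]),
                        cfg$total_heme_mmol_l, fixture_basis,
                        m = cfg$scatter_m_au, s_au_nm4 = cfg$scatter_s_au_nm4)
    fit <- fit_spectrum(sp, fixture_basis)
    fr <- fractions(fit)
    expect_equal(fr$hb_pct, tr$hb_pct[i], tolerance = 1e-6)
    expect_equal(total_heme(fit), cfg$total_heme_mmol_l, tolerance = 1e-6)
    expect_equal(fit$m_offset, cfg$scatter_m_au, tolerance = 1e-6)
    expect_equal(fit$s_rayleigh, cfg$scatter_s_au_nm4,
                 tolerance = 1e-6 * cfg$scatter_s_au_nm4)
  }
})

test_that("fitted fractions are unbiased over noisy replicates", {
  truth <- c(20, 75, 5)
  est <- t(vapply(1:200, function(s) {
    sp <- make_spectrum(truth, 0.6, fixture_basis, m = 0.05, s_au_nm4 = 2e9,
                        noise_sd = 0.005, seed = s)
    fr <- fractions(fit_spectrum(sp, fixture_basis))
    c(fr$hbo2_pct, fr$hb_pct, fr$methb_pct)
  }, numeric(3)))
  expect_lt(max(abs(colMeans(est) - truth)), 0.5)
})

test_that("make_series renders the full 2x4x5 design with coherent metadata", {
  spectra <- make_series(default_study(seed = 7), fixture_basis)
  expect_length(spectra, 40L)
  meta <- do.call(rbind, lapply(spectra, function(s) as.data.frame(s$meta)))
  expect_identical(sort(unique(meta$sts_pct)), c(0, 30, 60, 100))
  expect_identical(sort(unique(meta$tube)), c("closed", "open"))
  expect_identical(sort(unique(meta$day)), c(0L, 7L, 14L, 21L, 29L))
  expect_true(all(meta$kind == "suspension"))

  again <- make_series(default_study(seed = 7), fixture_basis)
  expect_identical(lapply(spectra, `[[`, "absorbance"),
                   lapply(again, `[[`, "absorbance"))

  dup <- default_study()[c(1, 1)]
  names(dup) <- c("a", "b")
  expect_error(make_series(dup, fixture_basis), class = "rbcspectra_config")
})

test_that("an end-to-end pipeline on the closed 0% condition recovers tm", {
  spectra <- make_reference_replicate(seed = 1, noise_sd = 0.005)
  fit <- fit_replicate_tm(spectra)
  expect_lt(abs(fit$tm_days - 11), 1.5)
})

test_that("a flat open-tube course yields the degenerate-series error by design", {
  cfg <- trajectory_config(hb_base_pct = 20, hb_plateau_pct = 20,
                           noise_sd_au = 0, tube = "open")
  tr <- make_trajectory(cfg)
  spectra <- lapply(seq_len(nrow(tr)), function(i)
    make_spectrum(c(tr$hbo2_pct[i], tr$hb_pct[i], tr$methb_pct[i]),
                  cfg$total_heme_mmol_l, fixture_basis,
                  day = tr$day[i], tube = "open", sts_pct = 0))
  tab <- batch_fit(spectra, fixture_basis)
  expect_true(all(abs(tab$hb_pct - 20) < 1e-6))
  expect_error(fit_cdf(kinetic_series(tab$day, tab$hb_pct)),
               class = "rbcspectra_degenerate_series")
})

test_that("make_hemolysis_pair scales supernatant heme by the true K", {
  pair <- make_hemolysis_pair(25, suspension_total_heme = 0.8,
                              noise_sd = 0, seed = 2)
  sup <- fit_spectrum(pair$supernatant, fixture_basis)
  expect_equal(total_heme(sup), 0.2, tolerance = 1e-6)

  p0 <- make_hemolysis_pair(0, m = 0.02, s_au_nm4 = 5e8, noise_sd = 0, seed = 2)
  baseline <- forward_absorbance(fixture_basis, 0, 0, 0, 0.02, 5e8)
  expect_equal(p0$supernatant$absorbance, baseline, tolerance = 1e-12)
})
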