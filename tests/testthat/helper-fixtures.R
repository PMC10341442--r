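# Shared fixtures, built once per test run. Everything is generated in code;
# no stored binary data.

fixture_basis <- synth_basis()

# A small 5-point toy basis inside the fitting window, for oracle problems.
toy_basis <- function() {
  extinction_basis(
    wavelengths_nm = c(540, 555, 570, 600, 630),
    eps_hbo2 = c(12, 8, 13, 2, 0.5),
    eps_hb = c(8, 12.5, 7, 1.5, 0.8),
    eps_methb = c(3, 2.5, 2, 1.5, 3.4),
    source_label = "toy")
}

# Exhaustive lattice-search oracle for 2-parameter non-negative least squares:
# minimises ||y - X b||^2 over b in {0, step, ..., bmax}^2 without ever calling
# the package fitter.
lattice_nnls_2d <- function(X, y, bmax = 2, step = 1e-3) {
  stopifnot(ncol(X) == 2L)
  b <- seq(0, bmax, by = step)
  H <- crossprod(X)
  g <- crossprod(X, y)
  A <- H[1, 1] * b^2 - 2 * g[1] * b
  B <- H[2, 2] * b^2 - 2 * g[2] * b
  ss <- outer(A, B, "+") + 2 * H[1, 2] * outer(b, b)
  idx <- arrayInd(which.min(ss), dim(ss))
  c(b[idx[1]], b[idx[2]])
}

# Forward trajectory spectra for one noisy replicate of the reference
# storage course (base 20, plateau 85, tm 11 d, sigma 3 d; days 0..29).
make_reference_replicate <- function(seed, noise_sd = 0.005,
                                     basis = fixture_basis) {
  cfg <- trajectory_config(noise_sd_au = noise_sd, seed = seed)
  tr <- make_trajectory(cfg)
  lapply(seq_len(nrow(tr)), function(i)
    make_spectrum(c(tr$hbo2_pct[i], tr$hb_pct[i], tr$methb_pct[i]),
                  cfg$total_heme_mmol_l, basis,
                  m = cfg$scatter_m_au, s_au_nm4 = cfg$scatter_s_au_nm4,
                  noise_sd = noise_sd, seed = seed * 101L + i,
                  sample_id = sprintf("rep%d_d%d", seed, tr$day[i]),
                  day = tr$day[i], sts_pct = 0, tube = "closed"))
}

# Fit one replicate end to end: unmix every day, take Hb%, fit the CDF.
fit_replicate_tm <- function(spectra, basis = fixture_basis) {
  tab <- batch_fit(spectra, basis)
  stopifnot(all(tab$ok))
  tab <- tab[order(tab$day), ]
  fit_cdf(kinetic_series(tab$day, pmin(pmax(tab$hb_pct, 0), 100)))
  }
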