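#' Configuration for a synthetic storage trajectory
#'
#' Describes one storage condition (tube x storage-solution strength) as the
#' generator emulates it: the deoxyhemoglobin percentage follows a Normal-CDF
#' rise from `hb_base_pct` to `hb_plateau_pct` centred at `hb_tm_days`;
#' methemoglobin is zero until `methb_onset_day` and then ramps linearly to
#' `methb_final_pct` at the last sampling day; oxyhemoglobin is the remainder.
#' The default schedule samples days 0, 7, 14, 21 and 29, and the default
#' day-0 state (HbO2 ~80%, Hb ~20%, MetHb 0) matches the start-of-storage
#' normoxemic composition the trajectory model assumes.
#'
#' @param days sampling days (non-negative, strictly increasing).
#' @param hb_base_pct,hb_plateau_pct initial and final deoxyhemoglobin
#'   percentage (plateau ≥ base for a rising course; equal values give a flat
#'   trajectory).
#' @param hb_tm_days,hb_sigma_days transition midpoint and width (days) of the
#'   Normal-CDF rise.
#' @param methb_onset_day day methemoglobin first appears.
#' @param methb_final_pct methemoglobin percentage at the last sampling day
#'   (0 disables the ramp).
#' @param total_heme_mmol_l total heme concentration of the suspension
#'   (mmol/L); the default gives peak absorbances near 1 AU at a 1 mm path.
#' @param scatter_m_au constant scattering/offset baseline M (AU).
#' @param scatter_s_au_nm4 Rayleigh scattering amplitude S (AU·nm⁴).
#' @param noise_sd_au additive Gaussian absorbance noise SD (AU), homoscedastic
#'   across wavelength.
#' @param seed integer RNG seed for the condition.
#' @param sts_pct,tube condition labels (percent storage solution; closed/open).
#' @return A list of class `trajectory_config`.
#' @export
trajectory_config <- function(days = c(0, 7, 14, 21, 29),
                              hb_base_pct = 20, hb_plateau_pct = 85,
                              hb_tm_days = 11, hb_sigma_days = 3,
                              methb_onset_day = 7, methb_final_pct = 0,
                              total_heme_mmol_l = 0.6,
                              scatter_m_au = 0.05, scatter_s_au_nm4 = 2e9,
                              noise_sd_au = 0.005, seed = 1L,
                              sts_pct = 0, tube = "closed") {
  days <- as.numeric(days)
  if (length(days) < 1L || any(days < 0) || any(diff(days) <= 0))
    abort_rbc("days must be non-negative and strictly increasing", "config")
  if (hb_sigma_days <= 0)
    abort_rbc("hb_sigma_days must be positive", "config")
  if (hb_plateau_pct < hb_base_pct)
    abort_rbc("hb_plateau_pct must be >= hb_base_pct", "config")
  if (hb_base_pct < 0 || hb_plateau_pct > 100)
    abort_rbc("hb percentages must lie in [0, 100]", "config")
  if (methb_final_pct < 0 || methb_final_pct > 100)
    abort_rbc("methb_final_pct must lie in [0, 100]", "config")
  if (total_heme_mmol_l <= 0)
    abort_rbc("total_heme_mmol_l must be positive", "config")
  if (noise_sd_au < 0)
    abort_rbc("noise_sd_au must be non-negative", "config")
  if (!tube %in% c("closed", "open"))
    abort_rbc("tube must be 'closed' or 'open'", "config")
  cfg <- structure(list(days = days, hb_base_pct = hb_base_pct,
                        hb_plateau_pct = hb_plateau_pct, hb_tm_days = hb_tm_days,
                        hb_sigma_days = hb_sigma_days,
                        methb_onset_day = methb_onset_day,
                        methb_final_pct = methb_final_pct,
                        total_heme_mmol_l = total_heme_mmol_l,
                        scatter_m_au = scatter_m_au,
                        scatter_s_au_nm4 = scatter_s_au_nm4,
                        noise_sd_au = noise_sd_au, seed = as.integer(seed),
                        sts_pct = sts_pct, tube = tube),
                   class = "trajectory_config")
  # reject configs whose implied HbO2 goes negative on any sampling day
  tr <- make_trajectory(cfg)
  cfg
}

#' Per-day hemoglobin-derivative fractions implied by a trajectory config
#'
#' Evaluates the deterministic trajectory model:
#' Hb(t) = base + (plateau − base)·Φ((t − tm)/σ); MetHb(t) = 0 before onset,
#' then linear up to `methb_final_pct` at the last day; HbO2 = 100 − Hb − MetHb.
#' A config implying negative HbO2 on any sampling day is rejected.
#'
#' @param config a [trajectory_config()].
#' @return A [tibble::tibble()] with columns `day`, `hbo2_pct`, `hb_pct`,
#'   `methb_pct`; each row sums to 100.
#' @examples
#' make_trajectory(trajectory_config())
#' @export
make_trajectory <- function(config) {
  stopifnot(inherits(config, "trajectory_config") || is.list(config))
  t <- config$days
  hb <- cdf_curve(t, config$hb_base_pct, config$hb_plateau_pct,
                  config$hb_tm_days, config$hb_sigma_days)
  methb <- rep(0, length(t))
  if (config$methb_final_pct > 0) {
    t_end <- max(t)
    on <- config$methb_onset_day
    if (t_end > on) {
      ramp <- (t - on) / (t_end - on)
      methb <- config$methb_final_pct * pmax(0, pmin(1, ramp))
    }
  }
  hbo2 <- 100 - hb - methb
  if (any(hbo2 < -1e-9))
    abort_rbc(sprintf(
      "config implies negative HbO2 (%.2f%%) on day %g: Hb and MetHb exceed 100%%",
      min(hbo2), t[which.min(hbo2)]), "config")
  tibble::tibble(day = t, hbo2_pct = pmax(hbo2, 0), hb_pct = hb, methb_pct = methb)
}

#' Render a synthetic absorbance spectrum from derivative fractions
#'
#' Applies the same forward model the unmixing fit inverts
#' (see [forward_absorbance()]): per-derivative concentrations
#' \eqn{C_x = total\_heme \cdot fraction_x / 100}, plus the constant and
#' Rayleigh scattering baselines and seeded additive Gaussian noise.
#'
#' @param fr an `hb_fractions` object or numeric `c(hbo2_pct, hb_pct, methb_pct)`
#'   summing to 100.
#' @param total_heme total heme concentration (mmol/L), positive.
#' @param basis an [extinction_basis()] on the output grid.
#' @param path_length_cm optical path (cm).
#' @param m,s_au_nm4 scattering baseline parameters (AU; AU·nm⁴).
#' @param noise_sd additive absorbance noise SD (AU), ≥ 0.
#' @param seed integer seed for the noise; `NULL` uses the session RNG stream.
#' @param sample_id,day,sts_pct,tube,kind metadata stored on the spectrum.
#' @return An `rbc_spectrum` on the basis grid.
#' @export
make_spectrum <- function(fr, total_heme, basis, path_length_cm = 0.1,
                          m = 0, s_au_nm4 = 0, noise_sd = 0, seed = NULL,
                          sample_id = NA_character_, day = NA_integer_,
                          sts_pct = NA_real_, tube = NA_character_,
                          kind = "suspension") {
  if (inherits(fr, "hb_fractions")) fr <- c(fr$hbo2_pct, fr$hb_pct, fr$methb_pct)
  fr <- as.numeric(fr)
  if (length(fr) != 3L || any(fr < 0) || abs(sum(fr) - 100) > 1e-6)
    abort_rbc("fractions must be 3 non-negative percentages summing to 100",
              "validation")
  if (!is_number(total_heme) || total_heme < 0)
    abort_rbc("total_heme must be a non-negative number", "validation")
  if (noise_sd < 0)
    abort_rbc("noise_sd must be non-negative", "validation")
  conc <- total_heme * fr / 100
  ab <- forward_absorbance(basis, conc[1], conc[2], conc[3], m, s_au_nm4,
                           path_length_cm)
  if (noise_sd > 0) {
    noise <- with_seed_local(seed, rnorm(length(ab), 0, noise_sd))
    ab <- ab + noise
  }
  new_spectrum(basis$wavelengths_nm, ab, sample_id = sample_id, day = day,
               sts_pct = sts_pct, tube = tube, kind = kind)
}

#' Default synthetic study design
#'
#' Eight conditions emulating the storage experiment the trajectory model
#' targets: closed (hypoxemia/anoxemia) and open (normoxemia) tubes at storage-
#' solution strengths 0/30/60/100%, sampled on days 0/7/14/21/29. Closed-tube
#' deoxyhemoglobin transitions use midpoints 11, 15.2 and 17.7 days for 0, 30
#' and 60% StS; closed 100% StS and all open tubes stay flat at the ~20% day-0
#' level. Methemoglobin ramps from day 7 to 5% (60% StS) and 25% (100% StS) at
#' day 29.
#'
#' @param seed base integer seed; per-condition seeds are derived from it.
#' @param noise_sd_au absorbance noise SD shared by all conditions (AU).
#' @return A named list of [trajectory_config()]s keyed `"<tube>_<sts>"`.
#' @export
default_study <- function(seed = 1L, noise_sd_au = 0.005) {
  seed <- as.integer(seed)
  flat <- function(sts, tube, methb, sd_seed)
    trajectory_config(hb_base_pct = 20, hb_plateau_pct = 20, hb_tm_days = 11,
                      methb_final_pct = methb, noise_sd_au = noise_sd_au,
                      seed = sd_seed, sts_pct = sts, tube = tube)
  rising <- function(sts, tm, methb, sd_seed)
    trajectory_config(hb_tm_days = tm, methb_final_pct = methb,
                      noise_sd_au = noise_sd_au, seed = sd_seed,
                      sts_pct = sts, tube = "closed")
  list(
    closed_0   = rising(0, 11, 0, seed + 1L),
    closed_30  = rising(30, 15.2, 0, seed + 2L),
    closed_60  = rising(60, 17.7, 5, seed + 3L),
    closed_100 = flat(100, "closed", 25, seed + 4L),
    open_0     = flat(0, "open", 0, seed + 5L),
    open_30    = flat(30, "open", 0, seed + 6L),
    open_60    = flat(60, "open", 0, seed + 7L),
    open_100   = flat(100, "open", 0, seed + 8L)
  )
}

#' Generate suspension spectra for a whole study design
#'
#' One suspension spectrum per condition-day, with metadata populated so the
#' output feeds [batch_fit()] and then [fit_cdf()] end to end.
#'
#' @param study a named list of [trajectory_config()]s (see [default_study()]);
#'   duplicate condition keys or duplicate (tube, sts_pct) pairs are rejected.
#' @param basis an [extinction_basis()]; default [synth_basis()].
#' @param path_length_cm optical path (cm).
#' @return A list of `rbc_spectrum` objects.
#' @export
make_series <- function(study = default_study(), basis = synth_basis(),
                        path_length_cm = 0.1) {
  if (length(study) == 0L)
    abort_rbc("study must contain at least one condition", "config")
  keys <- names(study)
  if (is.null(keys) || anyDuplicated(keys))
    abort_rbc("study conditions must have unique names", "config")
  cond <- vapply(study, function(cf) paste(cf$tube, cf$sts_pct), "")
  if (anyDuplicated(cond))
    abort_rbc("duplicate (tube, sts_pct) condition in study", "config")
  out <- list()
  for (key in keys) {
    cf <- study[[key]]
    tr <- make_trajectory(cf)
    for (i in seq_len(nrow(tr))) {
      day_seed <- (cf$seed + 7919L * i) %% .Machine$integer.max
      sp <- make_spectrum(c(tr$hbo2_pct[i], tr$hb_pct[i], tr$methb_pct[i]),
                          cf$total_heme_mmol_l, basis, path_length_cm,
                          m = cf$scatter_m_au, s_au_nm4 = cf$scatter_s_au_nm4,
                          noise_sd = cf$noise_sd_au, seed = day_seed,
                          sample_id = sprintf("%s_d%02d", key, tr$day[i]),
                          day = tr$day[i], sts_pct = cf$sts_pct,
                          tube = cf$tube, kind = "suspension")
      out[[length(out) + 1L]] <- sp
    }
  }
  out
}

#' Generate a supernatant/suspension spectrum pair with known hemolysis
#'
#' The supernatant carries `k_true_pct`/100 of the suspension's total heme, so
#' a noise-free round trip through [fit_spectrum()] and [hemolysis_pct()]
#' recovers `k_true_pct` exactly.
#'
#' @param k_true_pct true hemolysis percentage, in \[0, 100\].
#' @param suspension_total_heme suspension total heme (mmol/L).
#' @param sup_fractions,susp_fractions derivative percentages of each
#'   compartment (numeric triplets summing to 100, or `hb_fractions`); the
#'   defaults put mostly deoxygenated heme in the cells and mostly oxygenated
#'   free heme in the supernatant, as at end of storage after reoxygenation
#'   of the lysate.
#' @param basis an [extinction_basis()].
#' @param path_length_cm optical path (cm).
#' @param m,s_au_nm4 scattering baseline shared by both spectra.
#' @param noise_sd absorbance noise SD (AU).
#' @param seed integer seed; the two spectra use derived sub-seeds.
#' @return A list with elements `supernatant` and `suspension`
#'   (`rbc_spectrum`s sharing a `sample_id`).
#' @export
make_hemolysis_pair <- function(k_true_pct, suspension_total_heme = 0.6,
                                sup_fractions = c(60, 35, 5),
                                susp_fractions = c(20, 75, 5),
                                basis = synth_basis(), path_length_cm = 0.1,
                                m = 0.02, s_au_nm4 = 5e8,
                                noise_sd = 0, seed = 1L) {
  if (!is_number(k_true_pct) || k_true_pct < 0 || k_true_pct > 100)
    abort_rbc("k_true_pct must lie in [0, 100]", "validation")
  seed <- as.integer(seed)
  sup_heme <- k_true_pct / 100 * suspension_total_heme
  id <- sprintf("pair_k%05.1f", k_true_pct)
  sup <- if (sup_heme > 0) {
    make_spectrum(sup_fractions, sup_heme, basis, path_length_cm, m, s_au_nm4,
                  noise_sd, seed = seed, sample_id = id, kind = "supernatant")
  } else {
    # zero free heme: baseline-only spectrum
    ab <- forward_absorbance(basis, 0, 0, 0, m, s_au_nm4, path_length_cm)
    if (noise_sd > 0)
      ab <- ab + with_seed_local(seed, rnorm(length(ab), 0, noise_sd))
    new_spectrum(basis$wavelengths_nm, ab, sample_id = id, kind = "supernatant")
  }
  susp <- make_spectrum(susp_fractions, suspension_total_heme, basis,
                        path_length_cm, m, s_au_nm4, noise_sd,
                        seed = (seed + 104729L) %% .Machine$integer.max,
                        sample_id = id, kind = "suspension")
  list(supernatant = sup, suspension = susp)
}
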