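#' Study-condition presets for the stretch-conditioning groups S0-S3
#'
#' Returns the group-level parameter values used throughout the package to
#' emulate engineered heart tissues cultured under static stretch (S0,
#' 0 mm/day post distension) up to intense progressive stretch (S3,
#' 0.32 mm/day). Values are the group means reported for the corresponding
#' measurements; entries the study did not report for a group are `NA`.
#'
#' Components per group:
#' \describe{
#'   \item{ephys}{`rmp_mV` (resting membrane potential), `amplitude_mV`
#'     (action-potential amplitude), `upstroke_Vps` (max dV/dt),
#'     `apd90_s` (duration at 90% repolarization; not reported numerically,
#'     plausible defaults are supplied).}
#'   \item{hypoxia}{`residual_pct` remaining twitch force after a 2-min
#'     cessation of medium agitation, and the matching exponential
#'     `decline_tau_s` (see [hypoxia_tau_for_residual()]).}
#'   \item{biomech}{`twitch_mN` and `actinin_cross_section_mm2` whose
#'     quotient is the specific force; `fs_diastolic_mN` / `fs_twitch_mN`
#'     (diastolic and twitch force at optimum preload of the isometric
#'     length-step protocol); `modulus_kPa` (passive elastic modulus).}
#'   \item{ffr}{mean twitch amplitude (mN) at 1-4 Hz pacing.}
#'   \item{morphology}{`sarcomere_um` striation period, `mean_length_um`,
#'     `mean_cross_section_um2`, `myocyte_fraction`, and `orientation_sd_deg`
#'     (alignment dispersion; synthetic-default where unreported).}
#'   \item{geometry}{`tissue_length_mm` and `actinin_cross_section_mm2`
#'     for the muscular-mass product.}
#' }
#'
#' @param group one of "S0", "S1", "S2", "S3"
#' @return a named list of preset components
#' @export
eht_preset <- function(group = c("S0", "S1", "S2", "S3")) {
  group <- match.arg(group)
  ephys <- switch(group,
    S0 = list(rmp_mV = -52.5, amplitude_mV = 68.3, upstroke_Vps = 7.79, apd90_s = 0.45),
    S3 = list(rmp_mV = -72.4, amplitude_mV = 99.7, upstroke_Vps = 13.47, apd90_s = 0.35),
    list(rmp_mV = NA_real_, amplitude_mV = NA_real_, upstroke_Vps = NA_real_, apd90_s = 0.4)
  )
  residual <- switch(group, S0 = 77.6, S3 = 64, NA_real_)
  hypoxia <- list(
    residual_pct = residual,
    decline_tau_s = if (is.na(residual)) NA_real_ else
      hypoxia_tau_for_residual(residual / 100)
  )
  biomech <- switch(group,
    S0 = list(twitch_mN = 0.55, actinin_cross_section_mm2 = 0.25,
              fs_diastolic_mN = 0.65, fs_twitch_mN = 1.99, modulus_kPa = 1.7),
    S3 = list(twitch_mN = 2.82, actinin_cross_section_mm2 = 0.25,
              fs_diastolic_mN = 1.20, fs_twitch_mN = 10.17, modulus_kPa = 4.5),
    list(twitch_mN = NA_real_, actinin_cross_section_mm2 = 0.25,
         fs_diastolic_mN = NA_real_, fs_twitch_mN = NA_real_, modulus_kPa = NA_real_)
  )
  ffr <- switch(group,
    S0 = c(`1` = 2.0, `2` = 1.8, `3` = 1.5, `4` = 1.3),
    S2 = c(`1` = 2.0, `2` = 2.3, `3` = 2.5, `4` = 2.4),
    S3 = c(`1` = 2.0, `2` = 2.3, `3` = 2.5, `4` = 2.4),
    c(`1` = 2.0, `2` = 2.0, `3` = 1.9, `4` = 1.8)
  )
  morphology <- switch(group,
    S0 = list(sarcomere_um = 1.87, mean_length_um = 50, mean_cross_section_um2 = 61,
              myocyte_fraction = 0.69, orientation_sd_deg = 25),
    S1 = list(sarcomere_um = NA_real_, mean_length_um = 50, mean_cross_section_um2 = 61,
              myocyte_fraction = 0.69, orientation_sd_deg = 20),
    S2 = list(sarcomere_um = NA_real_, mean_length_um = 100, mean_cross_section_um2 = 62.7,
              myocyte_fraction = 0.69, orientation_sd_deg = 14),
    S3 = list(sarcomere_um = 2.19, mean_length_um = 100, mean_cross_section_um2 = 62.7,
              myocyte_fraction = 0.69, orientation_sd_deg = 10)
  )
  geometry <- switch(group,
    S0 = list(tissue_length_mm = 14.4, actinin_cross_section_mm2 = 0.09),
    S3 = list(tissue_length_mm = 30, actinin_cross_section_mm2 = 0.09),
    list(tissue_length_mm = NA_real_, actinin_cross_section_mm2 = 0.09)
  )
  list(group = group, ephys = ephys, hypoxia = hypoxia, biomech = biomech,
       ffr = ffr, morphology = morphology, geometry = geometry)
}

#' Exponential decline constant matching a target residual force
#'
#' During a simulated cessation of medium agitation the generator multiplies
#' twitch amplitudes by \eqn{e^{-(t - start)/\tau}}. This helper returns the
#' \eqn{\tau} for which the amplitude at the end of the window equals
#' `residual_fraction` of its value at entry.
#'
#' @param residual_fraction force remaining at the end of the window, in (0, 1)
#' @param duration window length in seconds (default 120, i.e. 2 min)
#' @return decline time constant in seconds
#' @export
hypoxia_tau_for_residual <- function(residual_fraction, duration = 120) {
  if (residual_fraction <= 0 || residual_fraction >= 1)
    stop_eht("`residual_fraction` must be in (0, 1)")
  check_positive(duration, "duration")
  -duration / log(residual_fraction)
}
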