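#' Assemble an isometric length-force curve
#'
#' One row per acute length step of an organ-bath protocol. Systolic force is
#' defined as diastolic plus twitch amplitude (peak total force); relative
#' length and engineering strain are derived from the slack length.
#'
#' @param length_mm absolute tissue lengths, mm (monotone increasing)
#' @param diastolic_mN diastolic (passive) force per step, mN
#' @param twitch_mN twitch amplitude per step, mN
#' @param slack_length_mm unloaded slack length, mm
#' @return data frame of class `length_force_curve` with `length_mm`,
#'   `relative_length`, `strain`, `diastolic_mN`, `twitch_mN`, `systolic_mN`
#' @export
length_force_curve <- function(length_mm, diastolic_mN, twitch_mN,
                               slack_length_mm) {
  check_positive(slack_length_mm, "slack_length_mm")
  n <- length(length_mm)
  if (n != length(diastolic_mN) || n != length(twitch_mN))
    stop_eht("length step vectors must have equal length")
  if (is.unsorted(length_mm, strictly = TRUE))
    stop_eht("`length_mm` must be strictly increasing")
  structure(data.frame(
    length_mm = length_mm,
    relative_length = length_mm / slack_length_mm,
    strain = (length_mm - slack_length_mm) / slack_length_mm,
    diastolic_mN = diastolic_mN, twitch_mN = twitch_mN,
    systolic_mN = diastolic_mN + twitch_mN
  ), class = c("length_force_curve", "data.frame"))
}

#' Tissue geometry for stress normalization
#'
#' @param slack_length_mm unloaded length, mm
#' @param actinin_cross_section_mm2 alpha-actinin-positive cross-section, mm^2
#' @param tissue_cross_section_mm2 total tissue cross-section, mm^2 (defaults
#'   to the actinin-positive area)
#' @return list of class `tissue_geometry`
#' @export
tissue_geometry <- function(slack_length_mm = 10,
                            actinin_cross_section_mm2 = 0.25,
                            tissue_cross_section_mm2 = NULL) {
  check_positive(slack_length_mm, "slack_length_mm")
  check_positive(actinin_cross_section_mm2, "actinin_cross_section_mm2")
  tissue_cross_section_mm2 <- tissue_cross_section_mm2 %||% actinin_cross_section_mm2
  if (tissue_cross_section_mm2 < actinin_cross_section_mm2)
    stop_eht("actinin cross-section cannot exceed the tissue cross-section")
  structure(list(slack_length_mm = slack_length_mm,
                 actinin_cross_section_mm2 = actinin_cross_section_mm2,
                 tissue_cross_section_mm2 = tissue_cross_section_mm2),
            class = "tissue_geometry")
}

#' Frank-Starling analysis of a length-force curve
#'
#' Finds the optimum preload (the length step with maximal twitch amplitude)
#' and the ratio of systolic to diastolic force at that step. A diastolic
#' force below `dia_floor_frac` of the maximal systolic force makes the
#' ratio undefined (returned as `NA` with a warning) rather than divergent.
#'
#' @param curve a [length_force_curve()]
#' @param dia_floor_frac diastolic floor as a fraction of max systolic force
#' @return list with `optimum_length_mm`, `optimum_relative_length`,
#'   `max_twitch_mN`, `sys_dia_ratio`, and `ratio_by_step` (per-length ratios)
#' @export
frank_starling <- function(curve, dia_floor_frac = 0.01) {
  stopifnot(inherits(curve, "length_force_curve"))
  if (nrow(curve) < 3) stop_eht("need at least 3 length steps")
  i <- which.max(curve$twitch_mN)
  floor_mN <- dia_floor_frac * max(curve$systolic_mN)
  ratio <- if (curve$diastolic_mN[i] > floor_mN)
    curve$systolic_mN[i] / curve$diastolic_mN[i] else NA_real_
  if (is.na(ratio))
    warning("diastolic force at optimum preload below floor; ratio undefined",
            call. = FALSE)
  rb <- ifelse(curve$diastolic_mN > floor_mN,
               curve$systolic_mN / curve$diastolic_mN, NA_real_)
  list(optimum_length_mm = curve$length_mm[i],
       optimum_relative_length = curve$relative_length[i],
       max_twitch_mN = curve$twitch_mN[i],
       sys_dia_ratio = ratio,
       ratio_by_step = rb)
}

#' Passive elastic modulus from diastolic stress-strain
#'
#' Converts diastolic force to stress using the alpha-actinin-positive (or,
#' optionally, whole-tissue) cross-section -- 1 mN/mm^2 equals 1 kPa -- and
#' fits a least-squares line of stress versus engineering strain. By default
#' the fit uses all steps up to the optimum preload; `mode = "chord"` instead
#' returns the chord slope between the first and last point of the window.
#'
#' @param curve a [length_force_curve()]
#' @param geometry a [tissue_geometry()]
#' @param window "up_to_optimum" (default) or "all"
#' @param mode "fit" (least squares) or "chord"
#' @param use_total_cross_section normalize by the whole-tissue area instead
#'   of the actinin-positive area
#' @return list with `modulus_kPa`, `residual_kPa` (fit RMS residual), `n`
#' @export
elastic_modulus <- function(curve, geometry, window = c("up_to_optimum", "all"),
                            mode = c("fit", "chord"),
                            use_total_cross_section = FALSE) {
  stopifnot(inherits(curve, "length_force_curve"),
            inherits(geometry, "tissue_geometry"))
  window <- match.arg(window); mode <- match.arg(mode)
  area <- if (use_total_cross_section) geometry$tissue_cross_section_mm2
          else geometry$actinin_cross_section_mm2
  check_positive(area, "cross-section area")
  keep <- if (window == "up_to_optimum")
    seq_len(which.max(curve$twitch_mN)) else seq_len(nrow(curve))
  strain <- curve$strain[keep]
  stress <- curve$diastolic_mN[keep] / area   # kPa
  if (length(unique(strain)) < 2)
    stop_eht("degenerate fit: need at least two distinct strain values")
  if (mode == "chord") {
    k <- (stress[length(stress)] - stress[1]) / (strain[length(strain)] - strain[1])
    return(list(modulus_kPa = k, residual_kPa = NA_real_, n = length(strain)))
  }
  fit <- stats::lm(stress ~ strain)
  list(modulus_kPa = unname(stats::coef(fit)[2]),
       residual_kPa = sqrt(mean(stats::residuals(fit)^2)),
       n = length(strain))
}

#' Specific twitch force
#'
#' Twitch force normalized to the alpha-actinin-positive cross-section area.
#'
#' @param twitch_mN twitch amplitude, mN
#' @param geometry a [tissue_geometry()] (or a single area in mm^2)
#' @return specific force in mN/mm^2 (attribute `units`)
#' @examples
#' specific_force(2.82, tissue_geometry(actinin_cross_section_mm2 = 0.25))
#' @export
specific_force <- function(twitch_mN, geometry) {
  area <- if (inherits(geometry, "tissue_geometry"))
    geometry$actinin_cross_section_mm2 else geometry
  check_positive(area, "actinin_cross_section_mm2")
  check_nonneg(twitch_mN, "twitch_mN")
  structure(twitch_mN / area, units = "mN/mm^2")
}

#' Force-frequency relationship
#'
#' Normalizes mean twitch amplitudes at each pacing rate by the 1 Hz value
#' and classifies the relationship as positive, negative or flat from the
#' sign of the least-squares slope of normalized force against rate.
#'
#' @param forces_by_rate named numeric vector (names = pacing rate in Hz,
#'   values = mean twitch amplitude in mN); must contain a 1 Hz entry
#' @param flat_tol slope magnitude (fold per Hz) below which the FFR is
#'   called flat
#' @return list with `curve` (data frame `rate_Hz`, `force_mN`,
#'   `normalized`), `peak_rate_Hz`, `peak_fold`, `classification`
#' @export
ffr <- function(forces_by_rate, flat_tol = 0.01) {
  rates <- as.numeric(names(forces_by_rate))
  if (any(is.na(rates))) stop_eht("names of `forces_by_rate` must be rates in Hz")
  o <- order(rates); rates <- rates[o]; f <- unname(forces_by_rate[o])
  ref <- which(abs(rates - 1) < 1e-9)
  if (!length(ref)) stop_eht("missing 1 Hz reference entry")
  norm <- f / f[ref[1]]
  slope <- unname(stats::coef(stats::lm(norm ~ rates))[2])
  cls <- if (abs(slope) < flat_tol) "flat" else if (slope > 0) "positive" else "negative"
  i <- which.max(norm)
  list(curve = data.frame(rate_Hz = rates, force_mN = f, normalized = norm),
       peak_rate_Hz = rates[i], peak_fold = norm[i], classification = cls)
}

#' Fold response to an inotropic intervention
#'
#' Compares window means of twitch amplitude, relative relaxation rate and
#' contraction duration after versus before a drug application (e.g.
#' isoprenaline 1 umol/L), each normalized to its pre-treatment value.
#'
#' @param pre_beats,post_beats `beat_features` data frames from
#'   [detect_beats()] for the pre- and post-treatment windows
#' @return list of fold changes: `twitch_fold`, `relaxation_rate_fold`,
#'   `contraction_duration_fold`
#' @export
drug_response <- function(pre_beats, post_beats) {
  if (!nrow(pre_beats) || !nrow(post_beats))
    stop_eht("both beat windows must be non-empty")
  fold <- function(col) {
    pre <- mean(pre_beats[[col]], na.rm = TRUE)
    if (!is.finite(pre) || pre == 0)
      stop_eht("zero or undefined pre-treatment mean for `%s`", col)
    mean(post_beats[[col]], na.rm = TRUE) / pre
  }
  list(twitch_fold = fold("amplitude_mN"),
       relaxation_rate_fold = fold("relaxation_rate_per_s"),
       contraction_duration_fold = fold("contraction_duration_s"))
}
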