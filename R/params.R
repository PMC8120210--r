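#' Parameters for the synthetic twitch-force trace generator
#'
#' Bundles and validates everything [generate_force_trace()] needs. The
#' waveform model is a paced train of double-exponential (alpha-function)
#' twitch pulses on a diastolic baseline, with optional slow drift,
#' stretch-step events, a hypoxia (agitation-cessation) window, and additive
#' Gaussian noise.
#'
#' @param sampling_interval seconds between samples (default 0.002, i.e.
#'   500 Hz as used by biomimetic culture chambers).
#' @param duration total trace length in seconds.
#' @param pacing_rate stimulation rate in Hz; one twitch per pacing interval.
#' @param twitch_amplitude peak-minus-baseline force of a twitch, mN.
#' @param diastolic_force baseline passive force, mN.
#' @param rise_tau,decay_tau time constants (s) of the pulse
#'   \eqn{A (1 - e^{-t/\tau_r}) e^{-t/\tau_d}}, rescaled so its maximum equals
#'   `twitch_amplitude`.
#' @param noise_sd SD of additive Gaussian noise, mN.
#' @param drift_rate slow linear baseline drift, mN per hour.
#' @param stretch_events list of stretch steps; each element a list with
#'   fields `time` (s), `step_gain` (multiplicative twitch-amplitude factor
#'   immediately after the step), `diastolic_jump` (mN added to the baseline),
#'   `relaxation_tau` (s; both the extra gain and the jump relax toward a
#'   plateau with this constant) and optional `plateau_fraction` (fraction of
#'   the initial effect that persists, default 0.5).
#' @param hypoxia_window optional list with `start` (s), `duration` (s) and
#'   `decline_tau` (s): within the window twitch amplitudes are multiplied by
#'   \eqn{e^{-(t - start)/\tau}}; they recover afterwards.
#' @param rng_seed integer seed; identical seeds give bitwise-identical traces.
#' @return an object of class `trace_params`
#' @seealso [generate_force_trace()], [hypoxia_tau_for_residual()]
#' @export
trace_params <- function(sampling_interval = 0.002,
                         duration = 60,
                         pacing_rate = 1,
                         twitch_amplitude = 2,
                         diastolic_force = 1,
                         rise_tau = 0.05,
                         decay_tau = 0.1,
                         noise_sd = 0,
                         drift_rate = 0,
                         stretch_events = list(),
                         hypoxia_window = NULL,
                         rng_seed = 1L) {
  check_positive(sampling_interval, "sampling_interval")
  check_positive(duration, "duration")
  check_positive(pacing_rate, "pacing_rate")
  check_nonneg(twitch_amplitude, "twitch_amplitude")
  check_positive(rise_tau, "rise_tau")
  check_positive(decay_tau, "decay_tau")
  check_nonneg(noise_sd, "noise_sd")
  if (!is.finite(diastolic_force)) stop_eht("`diastolic_force` must be finite")
  for (ev in stretch_events) {
    if (is.null(ev$time) || is.null(ev$step_gain))
      stop_eht("each stretch event needs `time` and `step_gain`")
    ev$relaxation_tau <- ev$relaxation_tau %||% Inf
    if (ev$relaxation_tau <= 0) stop_eht("stretch event `relaxation_tau` must be > 0")
  }
  if (!is.null(hypoxia_window)) {
    if (is.null(hypoxia_window$start) || is.null(hypoxia_window$duration) ||
        is.null(hypoxia_window$decline_tau))
      stop_eht("`hypoxia_window` needs `start`, `duration` and `decline_tau`")
    check_positive(hypoxia_window$decline_tau, "hypoxia_window$decline_tau")
  }
  structure(list(
    sampling_interval = sampling_interval, duration = duration,
    pacing_rate = pacing_rate, twitch_amplitude = twitch_amplitude,
    diastolic_force = diastolic_force, rise_tau = rise_tau,
    decay_tau = decay_tau, noise_sd = noise_sd, drift_rate = drift_rate,
    stretch_events = stretch_events, hypoxia_window = hypoxia_window,
    rng_seed = as.integer(rng_seed)
  ), class = "trace_params")
}

#' Parameters for the synthetic three-channel tissue image generator
#'
#' Describes a 2D confocal-like field of elongated cells rendered into DAPI
#' (nuclei), WGA (membranes) and alpha-actinin (sarcomeric striations)
#' channels. Cells are placed without overlap on a jittered anisotropic grid
#' aligned with `orientation_mean`; per-cell axis angles are drawn from an
#' axial (mod 180 degrees) wrapped normal.
#'
#' @param n_cells number of cells to place.
#' @param pixel_size micrometres per pixel (default 0.1).
#' @param mean_cell_length,mean_cell_width mean cell axis extents, um.
#' @param length_cv,width_cv coefficients of variation of the cell axes.
#' @param orientation_mean mean axial orientation, degrees in [0, 180).
#' @param orientation_sd SD of the axial orientation noise, degrees.
#' @param myocyte_fraction probability that a cell is an (actinin-positive)
#'   myocyte, in [0, 1].
#' @param sarcomere_period striation period of the actinin channel, um.
#' @param nucleus_area_mean mean nucleus area, um^2; per-cell areas are
#'   jittered but kept at or above half the mean.
#' @param membrane_thickness WGA membrane ring thickness, um.
#' @param background_level baseline intensity added to every channel.
#' @param dapi_amp,wga_amp,actinin_amp channel signal amplitudes above
#'   background (arbitrary intensity units).
#' @param blur_sd Gaussian optical blur, um.
#' @param noise_sd SD of additive Gaussian noise per channel.
#' @param jitter_frac fraction of the free in-tile slack used for random
#'   placement jitter; lower values pack cells more regularly and tightly.
#' @param margin_px empty border, pixels.
#' @param rng_seed integer seed.
#' @return an object of class `image_params`
#' @seealso [generate_tissue_image()]
#' @export
image_params <- function(n_cells = 25,
                         pixel_size = 0.1,
                         mean_cell_length = 25,
                         mean_cell_width = 8,
                         length_cv = 0.1,
                         width_cv = 0.1,
                         orientation_mean = 0,
                         orientation_sd = 10,
                         myocyte_fraction = 0.69,
                         sarcomere_period = 2.19,
                         nucleus_area_mean = 30,
                         membrane_thickness = 0.4,
                         background_level = 5,
                         dapi_amp = 100,
                         wga_amp = 80,
                         actinin_amp = 120,
                         blur_sd = 0.15,
                         noise_sd = 0,
                         jitter_frac = 0.5,
                         margin_px = 4,
                         rng_seed = 1L) {
  check_positive(pixel_size, "pixel_size")
  check_positive(mean_cell_length, "mean_cell_length")
  check_positive(mean_cell_width, "mean_cell_width")
  check_positive(sarcomere_period, "sarcomere_period")
  check_positive(nucleus_area_mean, "nucleus_area_mean")
  check_nonneg(orientation_sd, "orientation_sd")
  check_nonneg(noise_sd, "noise_sd")
  if (myocyte_fraction < 0 || myocyte_fraction > 1)
    stop_eht("`myocyte_fraction` must be in [0, 1]")
  if (n_cells < 1) stop_eht("`n_cells` must be >= 1")
  structure(list(
    n_cells = as.integer(n_cells), pixel_size = pixel_size,
    mean_cell_length = mean_cell_length, mean_cell_width = mean_cell_width,
    length_cv = length_cv, width_cv = width_cv,
    orientation_mean = wrap_axial(orientation_mean),
    orientation_sd = orientation_sd,
    myocyte_fraction = myocyte_fraction, sarcomere_period = sarcomere_period,
    nucleus_area_mean = nucleus_area_mean,
    membrane_thickness = membrane_thickness,
    background_level = background_level, dapi_amp = dapi_amp,
    wga_amp = wga_amp, actinin_amp = actinin_amp, blur_sd = blur_sd,
    noise_sd = noise_sd, jitter_frac = jitter_frac,
    margin_px = as.integer(margin_px),
    rng_seed = as.integer(rng_seed)
  ), class = "image_params")
}
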