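#' Convert spring-post displacement to force
#'
#' Force developed by an engineered heart tissue mounted on an elastic spring
#' post follows from the measured displacement of the post tip and the
#' spring's compliance (default 71 mm/N).
#'
#' @param displacement_mm displacement in mm (vectorized); negative values
#'   indicate compression and are flagged in the result
#' @param compliance_mm_per_N spring compliance, mm/N; must be > 0
#' @return data frame with `force_mN` and logical `compression`
#' @examples
#' displacement_to_force(0.71)  # 10 mN at the default compliance
#' @export
displacement_to_force <- function(displacement_mm, compliance_mm_per_N = 71) {
  check_positive(compliance_mm_per_N, "compliance_mm_per_N")
  if (any(!is.finite(displacement_mm)))
    stop_eht("`displacement_mm` must be finite")
  force_mN <- displacement_mm / compliance_mm_per_N * 1000
  data.frame(displacement_mm = displacement_mm, force_mN = force_mN,
             compression = displacement_mm < 0)
}

#' Per-beat contractile features of a paced force trace
#'
#' Splits a uniformly sampled force recording into stimulation intervals and
#' extracts, per beat: diastolic force (minimum over a late-diastolic window
#' just before the next stimulus, by default the last 20% of the interval),
#' peak force, twitch amplitude (peak minus diastolic), time to peak,
#' relative relaxation rate (maximum downward slope after the peak divided by
#' the amplitude, 1/s) and contraction duration (time spent above diastolic
#' plus `duration_frac` of the amplitude). Beats whose amplitude falls below
#' a noise floor of `k_mad` times the MAD of the detrended signal are marked
#' `captured = FALSE`, supporting all-or-nothing capture analyses.
#'
#' @param trace a `force_trace` data frame (`time_s`, `force_mN`), e.g. from
#'   [generate_force_trace()] or [read_force_trace()]
#' @param pacing_rate stimulation rate, Hz; ignored if `stim_times` given
#' @param stim_times explicit stimulation timestamps, s
#' @param diastolic_frac fraction of the interval, before the next stimulus,
#'   used as the diastolic search window (default 0.2)
#' @param duration_frac amplitude fraction defining contraction duration
#'   (default 0.1)
#' @param k_mad non-capture threshold in MADs of the detrended trace
#' @param smooth_n odd Savitzky-Golay window (samples) applied before level
#'   and slope estimation; a quartic fit is used so smooth pulse extrema are
#'   preserved while noise is suppressed. 0 disables smoothing.
#' @return data frame of class `beat_features`, one row per stimulation
#'   interval: `beat`, `beat_time_s`, `diastolic_mN`, `peak_mN`,
#'   `amplitude_mN`, `time_to_peak_s`, `relaxation_rate_per_s`,
#'   `contraction_duration_s`, `captured`
#' @export
detect_beats <- function(trace, pacing_rate = NULL, stim_times = NULL,
                         diastolic_frac = 0.2, duration_frac = 0.1,
                         k_mad = 4, smooth_n = 25) {
  if (NROW(trace) < 2L) stop_eht("empty or degenerate trace")
  tt <- trace$time_s; ff <- trace$force_mN
  dt <- tt[2] - tt[1]
  if (is.null(stim_times)) stim_times <- attr(trace, "stim_times")
  if (is.null(stim_times)) {
    if (is.null(pacing_rate)) pacing_rate <- attr(trace, "pacing_rate")
    if (is.null(pacing_rate))
      stop_eht("provide `pacing_rate` or `stim_times`")
    stim_times <- seq(tt[1], tt[length(tt)], by = 1 / pacing_rate)
  }
  stim_times <- sort(stim_times)
  interval <- if (length(stim_times) > 1) stats::median(diff(stim_times))
              else tt[length(tt)] - stim_times
  if (interval < 4 * dt)
    stop_eht("pacing interval (%.4f s) too short for the sampling rate", interval)

  # noise floor from the MAD of the twice-differenced (detrended) signal
  noise_mad <- stats::mad(diff(ff, differences = 2)) / sqrt(6)
  floor_mN <- k_mad * noise_mad

  fs <- ff; fd <- ff
  margin <- 0
  if (smooth_n >= 7) {
    smooth_n <- min(smooth_n, max(7L, 2L * (floor(interval / dt / 6)) + 1L))
    smooth_n <- smooth_n + (smooth_n + 1L) %% 2L
    if (length(ff) > smooth_n) {
      # quartic fit preserves smooth pulse extrema; the diastolic level sits
      # on a flat segment, so a wider quadratic window suppresses more noise
      fs <- signal::sgolayfilt(ff, p = 4, n = smooth_n)
      n_dia <- min(2L * smooth_n + 1L,
                   2L * floor(0.3 * diastolic_frac * interval / dt) + 1L)
      fd <- if (n_dia >= 7 && length(ff) > n_dia)
        signal::sgolayfilt(ff, p = 2, n = n_dia) else fs
      # keep filter windows clear of the upstroke corner at the next stimulus
      margin <- (max(smooth_n, if (n_dia >= 7) n_dia else 0) %/% 2L + 1L) * dt
    }
  }
  slope <- c(NA, diff(fs, lag = 2) / (2 * dt), NA)

  n_samp <- length(tt)
  res <- lapply(seq_along(stim_times), function(k) {
    s <- stim_times[k]
    e <- s + interval
    i0 <- ceiling((s - tt[1]) / dt - 1e-9) + 1L
    i1 <- min(n_samp, floor((e - tt[1]) / dt - 1e-9) + 1L)
    if (i0 < 1L || i1 <= i0) return(NULL)
    seg <- i0:i1
    dw <- seg[tt[seg] >= e - diastolic_frac * interval & tt[seg] < e - margin]
    if (!length(dw)) dw <- seg[tt[seg] >= e - diastolic_frac * interval]
    if (!length(dw)) dw <- seg
    dia <- min(fd[dw])
    pk_i <- seg[which.max(fs[seg])]
    peak <- fs[pk_i]
    amp <- peak - dia
    captured <- amp > floor_mN & amp > 0
    ttp <- tt[pk_i] - s
    post <- seg[seg > pk_i]
    relax <- if (length(post) > 1 && amp > 0)
      max(-slope[post], na.rm = TRUE) / amp else NA_real_
    above <- fs[seg] >= dia + duration_frac * amp
    dur <- if (amp > 0) sum(above) * dt else NA_real_
    data.frame(beat = k, beat_time_s = s, diastolic_mN = dia, peak_mN = peak,
               amplitude_mN = amp, time_to_peak_s = ttp,
               relaxation_rate_per_s = relax, contraction_duration_s = dur,
               captured = captured)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || !nrow(out)) stop_eht("no complete stimulation interval in trace")
  class(out) <- c("beat_features", "data.frame")
  attr(out, "pacing_interval") <- interval
  attr(out, "noise_floor_mN") <- floor_mN
  out
}

#' Time-binned conditioning time course of twitch and diastolic force
#'
#' Averages per-beat twitch amplitude and diastolic force over fixed time
#' bins, for long-term conditioning records. Runs of consecutive
#' non-captured beats at least `gap_min_s` long (e.g. zero-force medium
#' changes) are treated as recording gaps and excluded from the bins.
#'
#' @param beats a `beat_features` data frame from [detect_beats()]
#' @param bin_s bin width in seconds
#' @param gap_min_s minimum duration of a non-captured run to count as a gap
#' @return data frame with `bin_start_s`, `n_beats`, `mean_twitch_mN`,
#'   `mean_diastolic_mN`; bins with no usable beats are kept with `NA` means
#' @export
conditioning_timecourse <- function(beats, bin_s, gap_min_s = 300) {
  stopifnot(nrow(beats) > 0)
  check_positive(bin_s, "bin_s")
  interval <- attr(beats, "pacing_interval") %||% stats::median(diff(beats$beat_time_s))
  gap_beats <- max(1L, ceiling(gap_min_s / interval))
  r <- rle(!beats$captured)
  drop <- rep(r$values & r$lengths >= gap_beats, r$lengths)
  use <- beats[!drop & beats$captured, , drop = FALSE]
  edges <- seq(0, max(beats$beat_time_s) + bin_s, by = bin_s)
  idx <- findInterval(use$beat_time_s, edges)
  all_bins <- seq_len(length(edges) - 1L)
  out <- data.frame(
    bin_start_s = edges[all_bins],
    n_beats = as.integer(tabulate(idx, nbins = length(all_bins))),
    mean_twitch_mN = vapply(all_bins, function(b)
      if (any(idx == b)) mean(use$amplitude_mN[idx == b]) else NA_real_, 0),
    mean_diastolic_mN = vapply(all_bins, function(b)
      if (any(idx == b)) mean(use$diastolic_mN[idx == b]) else NA_real_, 0))
  out[out$bin_start_s <= max(beats$beat_time_s), , drop = FALSE]
}

#' Acute and persistent response to a stretch step
#'
#' Compares window-mean twitch amplitudes and diastolic forces before and
#' after a distension event: the acute gain is the post/pre amplitude ratio
#' immediately after the step, the persistent gain the same ratio 24 h later,
#' and the diastolic jump the difference of window-mean diastolic forces.
#'
#' @param beats a `beat_features` data frame covering the event
#' @param event_time_s stretch event time, s
#' @param window_s width of the pre/post averaging windows, s
#' @param persist_at_s delay of the persistence window (default 86400 = 24 h)
#' @return list with `acute_gain`, `persistent_gain_24h`, `diastolic_jump_mN`
#' @export
stretch_step_response <- function(beats, event_time_s, window_s = 60,
                                  persist_at_s = 86400) {
  pick <- function(lo, hi, label) {
    w <- beats[beats$beat_time_s >= lo & beats$beat_time_s < hi &
                 beats$captured, , drop = FALSE]
    if (!nrow(w)) stop_eht("no captured beats in the %s window [%g, %g) s",
                           label, lo, hi)
    w
  }
  pre <- pick(event_time_s - window_s, event_time_s, "pre-event")
  post <- pick(event_time_s, event_time_s + window_s, "post-event")
  late <- pick(event_time_s + persist_at_s,
               event_time_s + persist_at_s + window_s, "24 h persistence")
  list(acute_gain = mean(post$amplitude_mN) / mean(pre$amplitude_mN),
       persistent_gain_24h = mean(late$amplitude_mN) / mean(pre$amplitude_mN),
       diastolic_jump_mN = mean(post$diastolic_mN) - mean(pre$diastolic_mN))
}

#' Residual force after a simulated hypoxia window
#'
#' Oxygen consumption of a beating tissue is estimated from the decline in
#' contractility during a cessation of medium agitation: the residual force
#' is the mean amplitude of the last `n_ref` beats inside the window as a
#' percentage of the mean amplitude of the `n_ref` beats immediately before
#' the cessation.
#'
#' @param beats a `beat_features` data frame
#' @param cessation_start_s start of the agitation-cessation window, s
#' @param duration_s window length, s (default 120)
#' @param n_ref number of beats averaged on each side (default 5)
#' @return residual force in percent
#' @export
hypoxia_residual <- function(beats, cessation_start_s, duration_s = 120,
                             n_ref = 5) {
  end <- cessation_start_s + duration_s
  if (end > max(beats$beat_time_s) + (attr(beats, "pacing_interval") %||% 0))
    stop_eht("hypoxia window ends at %g s, past the last detected beat", end)
  pre <- beats[beats$beat_time_s < cessation_start_s & beats$captured, ]
  inw <- beats[beats$beat_time_s >= cessation_start_s &
                 beats$beat_time_s < end & beats$captured, ]
  if (nrow(pre) < n_ref || nrow(inw) < n_ref)
    stop_eht("need at least %d captured beats before and inside the window", n_ref)
  ref <- mean(utils::tail(pre$amplitude_mN, n_ref))
  last <- mean(utils::tail(inw$amplitude_mN, n_ref))
  100 * last / ref
}

#' Stimulation threshold from an all-or-nothing capture table
#'
#' Given tested stimulation currents and whether each captured a contraction,
#' returns the smallest current with capture when the response is monotone.
#' Non-monotone tables are resolved as the midpoint of the ambiguous range
#' (smallest captured to largest non-captured current) with a warning.
#'
#' @param current_mA tested currents, mA
#' @param captured logical capture outcomes, same length
#' @return threshold in mA
#' @export
stimulation_threshold <- function(current_mA, captured) {
  if (length(current_mA) != length(captured))
    stop_eht("`current_mA` and `captured` must have equal length")
  o <- order(current_mA)
  cur <- current_mA[o]; cap <- as.logical(captured[o])
  if (all(cap) || !any(cap))
    stop_eht("threshold outside tested range (all %s captured)",
             if (all(cap)) "currents" else "currents non-")
  lo_yes <- min(cur[cap]); hi_no <- max(cur[!cap])
  if (hi_no < lo_yes) return(lo_yes)
  warning(sprintf(
    "non-monotone capture between %g and %g mA; threshold taken as midpoint",
    lo_yes, hi_no), call. = FALSE)
  (lo_yes + hi_no) / 2
}
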