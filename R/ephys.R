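#' Calcium-transient features per stimulation interval
#'
#' For each transient: the baseline \eqn{F_0} is the mean over a pre-upstroke
#' window (the late fraction of the preceding interval), the amplitude is
#' \eqn{(F_{peak} - F_0)/F_0}, durations are measured from upstroke onset
#' (crossing 10% of the amplitude) to 50% and 90% return toward baseline,
#' and the decay constant tau comes from a least-squares monoexponential fit
#' of the segment between the peak and 10% above baseline, reported with its
#' R^2. A transient whose decay cannot be fit has `tau = NA`.
#'
#' @param trace a `fluorescence_trace` data frame (`time_s`, `intensity`),
#'   e.g. from [generate_ca_transient()] or a two-column CSV
#' @param stim_times stimulation timestamps, s (defaults to the trace
#'   attribute)
#' @param onset_frac amplitude fraction defining upstroke onset (default 0.1)
#' @param baseline_frac late fraction of the interval averaged for F0
#' @param tau_from `"peak"` (default) fits from the peak; `"half"` fits from
#'   50% return, for traces with non-exponential early decay
#' @return data frame of class `ca_features`, one row per transient:
#'   `transient`, `f0`, `amplitude_dFF0`, `duration50_s`, `duration90_s`,
#'   `tau_s`, `fit_r2`
#' @export
ca_features <- function(trace, stim_times = NULL, onset_frac = 0.1,
                        baseline_frac = 0.1, tau_from = c("peak", "half")) {
  tau_from <- match.arg(tau_from)
  tt <- trace$time_s; ff <- trace$intensity
  if (length(tt) < 4) stop_eht("trace too short")
  stim_times <- stim_times %||% attr(trace, "stim_times")
  if (is.null(stim_times)) stop_eht("provide `stim_times`")
  stim_times <- sort(stim_times)
  interval <- if (length(stim_times) > 1) stats::median(diff(stim_times))
              else max(tt) - stim_times[1]

  rows <- lapply(seq_along(stim_times), function(k) {
    s <- stim_times[k]
    seg <- which(tt >= s & tt < s + interval)
    if (length(seg) < 4) return(NULL)
    # baseline from the window just before this upstroke (late previous cycle)
    bw <- which(tt >= s - baseline_frac * interval & tt < s)
    if (length(bw) < 2) bw <- utils::tail(seg, max(2L, round(length(seg) / 10)))
    f0 <- mean(ff[bw])
    if (f0 <= 0) return(NULL)
    pk_i <- seg[which.max(ff[seg])]
    peak <- ff[pk_i]
    amp_abs <- peak - f0
    if (amp_abs <= 0) return(NULL)
    onset <- cross_time(tt, ff, f0 + onset_frac * amp_abs, seg[1], +1L, rising = TRUE)
    t50 <- cross_time(tt, ff, f0 + 0.5 * amp_abs, pk_i, +1L, rising = FALSE)
    t90 <- cross_time(tt, ff, f0 + 0.1 * amp_abs, pk_i, +1L, rising = FALSE)

    start_i <- if (tau_from == "peak") pk_i else {
      i <- pk_i
      while (i < max(seg) && ff[i] > f0 + 0.5 * amp_abs) i <- i + 1L
      i
    }
    end_lvl <- f0 + 0.1 * amp_abs
    end_i <- start_i
    while (end_i < max(seg) && ff[end_i + 1L] > end_lvl) end_i <- end_i + 1L
    tau <- NA_real_; r2 <- NA_real_
    if (end_i - start_i >= 4) {
      td <- tt[start_i:end_i] - tt[start_i]
      yd <- ff[start_i:end_i]
      a0 <- max(yd[1] - f0, 1e-9)
      t0 <- max(td[length(td)] / log(max(a0 / max(yd[length(yd)] - f0, 1e-9), 1.1)),
                1e-6)
      fit <- tryCatch(
        minpack.lm::nlsLM(yd ~ C + A * exp(-td / tau),
                          start = list(C = f0, A = a0, tau = t0),
                          lower = c(0, 0, 1e-9),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- stats::coef(fit)
        if (cf[["tau"]] > 0 && cf[["A"]] > 0) {
          tau <- unname(cf[["tau"]])
          ss_res <- sum(stats::residuals(fit)^2)
          ss_tot <- sum((yd - mean(yd))^2)
          r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
        }
      }
    }
    data.frame(transient = k, f0 = f0, amplitude_dFF0 = amp_abs / f0,
               duration50_s = if (is.na(onset) || is.na(t50)) NA_real_ else t50 - onset,
               duration90_s = if (is.na(onset) || is.na(t90)) NA_real_ else t90 - onset,
               tau_s = tau, fit_r2 = r2)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop_eht("no complete transient in trace")
  class(out) <- c("ca_features", "data.frame")
  out
}

#' Action-potential features per stimulation interval
#'
#' For each action potential: the resting potential is the mean over a
#' diastolic window (late fraction of the interval), the amplitude the peak
#' minus resting value, the upstroke velocity the maximum central-difference
#' dV/dt during depolarization (reported in V/s), and APD90 the time from
#' upstroke onset (crossing `onset_frac` of the amplitude) to 90%
#' repolarization.
#'
#' @param trace a `voltage_trace` data frame (`time_s`, `voltage_mV`)
#' @param stim_times stimulation timestamps, s (defaults to the trace
#'   attribute)
#' @param onset_frac amplitude fraction defining upstroke onset
#' @param diastolic_frac late fraction of the interval averaged for the
#'   resting potential
#' @param min_amplitude_mV depolarizations smaller than this raise an error
#' @return data frame of class `ap_features`: `ap`, `resting_mV`,
#'   `amplitude_mV`, `upstroke_Vps`, `apd90_s`
#' @export
ap_features <- function(trace, stim_times = NULL, onset_frac = 0.1,
                        diastolic_frac = 0.2, min_amplitude_mV = 10) {
  tt <- trace$time_s; vv <- trace$voltage_mV
  if (length(tt) < 4) stop_eht("trace too short")
  dt <- tt[2] - tt[1]
  stim_times <- stim_times %||% attr(trace, "stim_times")
  if (is.null(stim_times)) stop_eht("provide `stim_times`")
  stim_times <- sort(stim_times)
  interval <- if (length(stim_times) > 1) stats::median(diff(stim_times))
              else max(tt) - stim_times[1]
  if (max(vv) - min(vv) < min_amplitude_mV)
    stop_eht("no depolarization detected (trace range %.1f mV)", max(vv) - min(vv))
  dvdt <- c(NA, diff(vv, lag = 2) / (2 * dt), NA) / 1000  # V/s

  rows <- lapply(seq_along(stim_times), function(k) {
    s <- stim_times[k]
    seg <- which(tt >= s & tt < s + interval)
    if (length(seg) < 4) return(NULL)
    rest_w <- seg[tt[seg] >= s + (1 - diastolic_frac) * interval]
    if (length(rest_w) < 2) rest_w <- utils::tail(seg, 2)
    rest <- mean(vv[rest_w])
    pk_i <- seg[which.max(vv[seg])]
    amp <- vv[pk_i] - rest
    if (amp < min_amplitude_mV) return(NULL)
    upstroke <- max(dvdt[seg[seg <= pk_i]], na.rm = TRUE)
    onset <- cross_time(tt, vv, rest + onset_frac * amp, seg[1], +1L, rising = TRUE)
    t90 <- cross_time(tt, vv, rest + 0.1 * amp, pk_i, +1L, rising = FALSE)
    data.frame(ap = k, resting_mV = rest, amplitude_mV = amp,
               upstroke_Vps = upstroke,
               apd90_s = if (is.na(onset) || is.na(t90)) NA_real_ else t90 - onset)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop_eht("no depolarization detected")
  class(out) <- c("ap_features", "data.frame")
  out
}
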