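#' Synthetic twitch-force recording with exact ground truth
#'
#' Renders a paced train of twitch pulses on a diastolic baseline according
#' to a [trace_params()] description. Each pulse is the alpha-function
#' \eqn{A (1 - e^{-t/\tau_r}) e^{-t/\tau_d}}, rescaled so its maximum equals
#' the configured twitch amplitude. Stretch-step events multiply subsequent
#' amplitudes by `step_gain` and add a diastolic jump, both relaxing
#' exponentially toward a persistent plateau; a hypoxia window multiplies
#' amplitudes by \eqn{e^{-(t-start)/\tau_{decline}}}. Gaussian noise is added
#' last, so the noiseless construction is exactly recoverable.
#'
#' @param params a [trace_params()] object
#' @return list with `trace` (a `force_trace` data frame: `time_s`,
#'   `force_mN`, with sampling metadata and stimulation times as attributes)
#'   and `truth` (a ground-truth table, one row per generated parameter)
#' @examples
#' ft <- generate_force_trace(trace_params(duration = 10, noise_sd = 0))
#' range(ft$trace$force_mN)
#' @export
generate_force_trace <- function(params) {
  stopifnot(inherits(params, "trace_params"))
  p <- params
  dt <- p$sampling_interval
  interval <- 1 / p$pacing_rate

  r <- p$rise_tau; d <- p$decay_tau
  t_peak <- r * log((r + d) / r)
  pmax <- (1 - exp(-t_peak / r)) * exp(-t_peak / d)
  support <- t_peak + d * log(1e3)
  if (support > interval)
    stop_eht(paste0("pacing interval (%.3f s) shorter than twitch pulse support ",
                    "(%.3f s); reduce rise_tau/decay_tau or the pacing rate"),
             interval, support)

  n <- max(2L, round(p$duration / dt))
  tt <- (seq_len(n) - 1L) * dt
  stim <- seq(0, p$duration - dt, by = interval)
  stim <- stim[stim < p$duration]

  # baseline with drift and stretch-event diastolic jumps
  base <- p$diastolic_force + p$drift_rate * tt / 3600
  gain_at <- function(times) {
    g <- rep(1, length(times))
    for (ev in p$stretch_events) {
      tau <- ev$relaxation_tau %||% Inf
      pf <- ev$plateau_fraction %||% 0.5
      on <- times >= ev$time
      rel <- exp(-(times[on] - ev$time) / tau)
      g[on] <- g[on] * (1 + (ev$step_gain - 1) * (pf + (1 - pf) * rel))
    }
    g
  }
  for (ev in p$stretch_events) {
    jump <- ev$diastolic_jump %||% 0
    if (jump != 0) {
      tau <- ev$relaxation_tau %||% Inf
      pf <- ev$plateau_fraction %||% 0.5
      on <- tt >= ev$time
      base[on] <- base[on] + jump * (pf + (1 - pf) * exp(-(tt[on] - ev$time) / tau))
    }
  }

  hyp_gain <- function(times) {
    g <- rep(1, length(times))
    hw <- p$hypoxia_window
    if (!is.null(hw)) {
      inside <- times >= hw$start & times < hw$start + hw$duration
      g[inside] <- exp(-(times[inside] - hw$start) / hw$decline_tau)
    }
    g
  }

  amp <- p$twitch_amplitude * gain_at(stim) * hyp_gain(stim)

  force <- base
  n_sup <- ceiling(support / dt)
  pulse_t <- (seq_len(n_sup) - 1L) * dt
  pulse <- (1 - exp(-pulse_t / r)) * exp(-pulse_t / d) / pmax
  for (k in seq_along(stim)) {
    i0 <- round(stim[k] / dt) + 1L
    idx <- i0:min(n, i0 + n_sup - 1L)
    force[idx] <- force[idx] + amp[k] * pulse[seq_along(idx)]
  }

  if (p$noise_sd > 0)
    force <- force + with_rng(p$rng_seed, stats::rnorm(n, 0, p$noise_sd))

  trace <- structure(
    data.frame(time_s = tt, force_mN = force),
    sampling_interval = dt, pacing_rate = p$pacing_rate,
    stim_times = stim, class = c("force_trace", "data.frame"))

  truth <- data.frame(
    entity = "trace",
    parameter = c("twitch_amplitude", "diastolic_force", "rise_tau",
                  "decay_tau", "pacing_rate", "drift_rate"),
    value = c(p$twitch_amplitude, p$diastolic_force, r, d, p$pacing_rate,
              p$drift_rate),
    units = c("mN", "mN", "s", "s", "Hz", "mN/h"),
    stringsAsFactors = FALSE)
  for (ev in p$stretch_events) {
    pf <- ev$plateau_fraction %||% 0.5
    tau <- ev$relaxation_tau %||% Inf
    g24 <- 1 + (ev$step_gain - 1) * (pf + (1 - pf) * exp(-86400 / tau))
    truth <- rbind(truth, data.frame(
      entity = sprintf("event_t%g", ev$time),
      parameter = c("acute_gain", "persistent_gain_24h", "diastolic_jump"),
      value = c(ev$step_gain, g24, ev$diastolic_jump %||% 0),
      units = c("fold", "fold", "mN")))
  }
  if (!is.null(p$hypoxia_window)) {
    hw <- p$hypoxia_window
    truth <- rbind(truth, data.frame(
      entity = "hypoxia", parameter = c("residual_pct", "decline_tau"),
      value = c(100 * exp(-hw$duration / hw$decline_tau), hw$decline_tau),
      units = c("%", "s")))
  }
  list(trace = trace, truth = truth)
}

#' Synthetic calcium-transient fluorescence trace
#'
#' Generates a paced Fluo-type fluorescence signal
#' \eqn{F(t) = F_0 (1 + a\,u(t))} where the upstroke \eqn{u} rises linearly
#' from 0 to 1 over `rise_time` and then decays exactly monoexponentially
#' with constant `tau`, so the peak is \eqn{F_0 (1 + a)} and the log of the
#' baseline-subtracted decay is linear with slope \eqn{-1/\tau}.
#'
#' @param amplitude peak \eqn{\Delta F / F_0} (dimensionless)
#' @param tau decay time constant, s
#' @param f0 baseline fluorescence (arbitrary units, > 0)
#' @param pacing_rate transients per second (default 0.5 so the decay
#'   completes well before the next stimulus)
#' @param duration trace length, s
#' @param rise_time upstroke duration, s
#' @param sampling_interval s (default 0.005, i.e. 200 Hz imaging)
#' @param noise_sd additive Gaussian noise SD, intensity units
#' @param rng_seed integer seed
#' @return list with `trace` (data frame `time_s`, `intensity`, stimulation
#'   times as attribute) and `truth`
#' @export
generate_ca_transient <- function(amplitude = 1.5, tau = 0.3, f0 = 100,
                                  pacing_rate = 0.5, duration = 20,
                                  rise_time = 0.05,
                                  sampling_interval = 0.005,
                                  noise_sd = 0, rng_seed = 1L) {
  check_positive(tau, "tau")
  if (f0 <= 0) stop_eht("baseline `f0` must be positive")
  check_positive(rise_time, "rise_time")
  check_positive(pacing_rate, "pacing_rate")
  n <- max(2L, round(duration / sampling_interval))
  tt <- (seq_len(n) - 1L) * sampling_interval
  interval <- 1 / pacing_rate
  s <- tt %% interval
  u <- ifelse(s < rise_time, s / rise_time, exp(-(s - rise_time) / tau))
  intensity <- f0 * (1 + amplitude * u)
  if (noise_sd > 0)
    intensity <- intensity + with_rng(rng_seed, stats::rnorm(n, 0, noise_sd))
  stim <- seq(0, duration - sampling_interval, by = interval)
  trace <- structure(data.frame(time_s = tt, intensity = intensity),
                     sampling_interval = sampling_interval,
                     stim_times = stim, f0 = f0,
                     class = c("fluorescence_trace", "data.frame"))
  truth <- data.frame(entity = "trace",
                      parameter = c("amplitude", "tau", "f0", "rise_time"),
                      value = c(amplitude, tau, f0, rise_time),
                      units = c("dF/F0", "s", "a.u.", "s"))
  list(trace = trace, truth = truth)
}

#' Synthetic intracellular action-potential train
#'
#' Each cycle has a linear upstroke with slope `upstroke_velocity` from the
#' resting potential to `rmp + amplitude`, followed by a raised-cosine
#' plateau-then-repolarization scaled so the trace crosses 90% repolarization
#' (`rmp + 0.1 * amplitude`) exactly `apd90` seconds after upstroke onset,
#' after which it sits exactly at the resting potential until the next
#' stimulus.
#'
#' @param rmp resting membrane potential, mV
#' @param amplitude action-potential amplitude (peak minus resting), mV; > 0
#' @param upstroke_velocity maximum dV/dt, V/s; > 0
#' @param apd90 duration at 90% repolarization measured from upstroke onset, s
#' @param pacing_rate Hz
#' @param duration trace length, s
#' @param sampling_interval s (default 2e-4, i.e. 5 kHz)
#' @param noise_sd additive Gaussian noise SD, mV
#' @param rng_seed integer seed
#' @return list with `trace` (data frame `time_s`, `voltage_mV`) and `truth`
#' @export
generate_action_potential <- function(rmp = -72.4, amplitude = 99.7,
                                      upstroke_velocity = 13.47,
                                      apd90 = 0.35, pacing_rate = 1,
                                      duration = 10,
                                      sampling_interval = 2e-4,
                                      noise_sd = 0, rng_seed = 1L) {
  check_positive(amplitude, "amplitude")
  check_positive(upstroke_velocity, "upstroke_velocity")
  check_positive(apd90, "apd90")
  interval <- 1 / pacing_rate
  if (apd90 >= interval)
    stop_eht("apd90 (%.3f s) must be shorter than the pacing interval (%.3f s)",
             apd90, interval)
  t_up <- amplitude / (1000 * upstroke_velocity)
  if (apd90 <= t_up)
    stop_eht("apd90 must exceed the upstroke duration (%.4f s)", t_up)
  # raised cosine 0.5*(1+cos(pi*x)) crosses 0.1 at x = acos(-0.8)/pi
  x90 <- acos(-0.8) / pi
  repol_dur <- (apd90 - t_up) / x90
  if (t_up + repol_dur >= interval)
    stop_eht("repolarization (%.3f s) does not fit in the pacing interval",
             t_up + repol_dur)
  n <- max(2L, round(duration / sampling_interval))
  tt <- (seq_len(n) - 1L) * sampling_interval
  s <- tt %% interval
  v <- rep(rmp, n)
  up <- s < t_up
  v[up] <- rmp + 1000 * upstroke_velocity * s[up]
  rp <- !up & s < t_up + repol_dur
  v[rp] <- rmp + amplitude * 0.5 * (1 + cos(pi * (s[rp] - t_up) / repol_dur))
  if (noise_sd > 0)
    v <- v + with_rng(rng_seed, stats::rnorm(n, 0, noise_sd))
  stim <- seq(0, duration - sampling_interval, by = interval)
  trace <- structure(data.frame(time_s = tt, voltage_mV = v),
                     sampling_interval = sampling_interval,
                     stim_times = stim,
                     class = c("voltage_trace", "data.frame"))
  truth <- data.frame(
    entity = "trace",
    parameter = c("rmp", "amplitude", "upstroke_velocity", "apd90", "peak"),
    value = c(rmp, amplitude, upstroke_velocity, apd90, rmp + amplitude),
    units = c("mV", "mV", "V/s", "s", "mV"))
  list(trace = trace, truth = truth)
}
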