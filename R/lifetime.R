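#' Options for transient-lifetime extraction
#'
#' The breakpoint construction fits one line to the initial rise after fuel
#' addition and one to the plateau after fuel consumption; their
#' intersection is the deactivation time. The exact fit windows are a
#' robustness choice: the rise line uses samples whose baseline-subtracted
#' value lies between `theta_lo` and `theta_hi` of the cycle amplitude, the
#' plateau line uses the last `plateau_frac` fraction of the cycle window.
#' A sample qualifying for both windows is assigned to the rise fit.
#'
#' @param theta_lo,theta_hi rise-fit amplitude band (defaults 10% and 60%).
#' @param plateau_frac trailing fraction of the window for the plateau fit
#'   (default 25%).
#' @param min_points minimum samples per fit (default 3).
#' @param noise_mult activation threshold: the cycle amplitude must exceed
#'   `noise_mult` times the robust noise estimate (default 3).
#' @param parallel_tol relative slope-difference threshold below which the
#'   two lines are declared parallel (no breakpoint).
#' @return a list of options for [transient_lifetime()].
#' @export
lifetime_opts <- function(theta_lo = 0.1, theta_hi = 0.6,
                          plateau_frac = 0.25, min_points = 3L,
                          noise_mult = 3, parallel_tol = 1e-9) {
  stopifnot(theta_lo > 0, theta_hi > theta_lo, theta_hi < 1,
            plateau_frac > 0, plateau_frac < 1, min_points >= 3)
  list(theta_lo = theta_lo, theta_hi = theta_hi,
       plateau_frac = plateau_frac, min_points = as.integer(min_points),
       noise_mult = noise_mult, parallel_tol = parallel_tol)
}

lifetime_error <- function(subclass, msg) {
  stop(structure(class = c(subclass, "lifetime_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# robust, scale-equivariant noise estimate from successive differences
robust_noise <- function(v) {
  d <- diff(v)
  if (length(d) < 2) return(0)
  stats::mad(d) / sqrt(2)
}

#' Transient lifetime of one activation-deactivation cycle
#'
#' Computes the lifetime of the transient active state as the time between
#' fuel addition and the deactivation breakpoint, the intersection of the
#' least-squares line through the initial signal rise and the line through
#' the plateau after fuel consumption.
#'
#' @param signal a [signal_trace()] covering `[t_d, window_end]`.
#' @param t_d fuel-dose time, min.
#' @param window_end end of the cycle window, min (default: end of trace).
#' @param opts a [lifetime_opts()] list.
#' @return an object of class `lifetime_result` with fields `t_d`, `t_star`
#'   (deactivation time), `tau` (lifetime, min), the two line fits (slope,
#'   intercept, number of points) and the cycle amplitude `delta_signal`.
#'
#' @section Errors: classed conditions `lifetime_no_activation` (amplitude
#'   below the noise floor), `lifetime_no_breakpoint` (parallel fits or an
#'   intersection outside the window), `lifetime_insufficient_data` (fewer
#'   than `min_points` samples in either fit window).
#' @export
transient_lifetime <- function(signal, t_d, window_end = NULL,
                               opts = lifetime_opts()) {
  stopifnot(inherits(signal, "signal_trace"))
  if (is.null(window_end)) window_end <- max(signal$time)
  sel <- signal$time >= t_d & signal$time <= window_end
  tt <- signal$time[sel]
  vv <- signal$value[sel]
  if (length(tt) < 8) {
    lifetime_error("lifetime_insufficient_data",
                   "fewer than 8 samples in the cycle window")
  }
  baseline <- vv[1]
  plateau_start <- window_end - opts$plateau_frac * (window_end - t_d)
  in_plateau <- tt >= plateau_start
  plateau_level <- mean(vv[in_plateau])
  amp <- plateau_level - baseline
  noise <- robust_noise(vv)
  if (!(amp > opts$noise_mult * noise) || amp <= 0) {
    lifetime_error("lifetime_no_activation",
                   "cycle amplitude does not exceed the noise floor")
  }
  rel <- (vv - baseline) / amp
  in_band <- rel >= opts$theta_lo & rel <= opts$theta_hi
  # the initial rise: in-band samples up to the first crossing of theta_hi
  # (noise spikes inside the band merely add points to the fit; samples
  # re-entering the band later, e.g. on a drifting plateau, are excluded)
  i_hi <- which(rel > opts$theta_hi)[1]
  limit <- if (is.na(i_hi)) length(tt) else i_hi - 1L
  rise_idx <- which(in_band[seq_len(limit)])
  if (length(rise_idx) == 0) {
    lifetime_error("lifetime_insufficient_data",
                   "no samples in the rise-fit amplitude band")
  }
  plat_idx <- setdiff(which(in_plateau), rise_idx)
  if (length(rise_idx) < opts$min_points || length(plat_idx) < opts$min_points) {
    lifetime_error("lifetime_insufficient_data",
                   "fewer than min_points samples in a fit window")
  }
  rise_fit <- stats::lm.fit(cbind(1, tt[rise_idx]), vv[rise_idx])$coefficients
  plat_fit <- stats::lm.fit(cbind(1, tt[plat_idx]), vv[plat_idx])$coefficients
  m1 <- rise_fit[2]; b1 <- rise_fit[1]
  m2 <- plat_fit[2]; b2 <- plat_fit[1]
  slope_scale <- max(abs(m1), abs(m2))
  if (slope_scale == 0 || abs(m1 - m2) < opts$parallel_tol * slope_scale) {
    lifetime_error("lifetime_no_breakpoint",
                   "rise and plateau fits are parallel")
  }
  t_star <- (b2 - b1) / (m1 - m2)
  if (!is.finite(t_star) || t_star <= t_d || t_star > window_end) {
    lifetime_error("lifetime_no_breakpoint",
                   "breakpoint falls outside the cycle window")
  }
  structure(list(t_d = t_d, t_star = unname(t_star),
                 tau = unname(t_star - t_d),
                 rise_slope = unname(m1), rise_intercept = unname(b1),
                 n_rise = length(rise_idx),
                 plateau_slope = unname(m2), plateau_intercept = unname(b2),
                 n_plateau = length(plat_idx),
                 delta_signal = unname(amp)),
            class = "lifetime_result")
}

#' @export
print.lifetime_result <- function(x, ...) {
  cat(sprintf(paste0("<lifetime_result> tau = %.2f min (dose %.1f -> ",
                     "breakpoint %.2f), amplitude %.3g\n"),
              x$tau, x$t_d, x$t_star, x$delta_signal))
  invisible(x)
}

#' Segment a repeatedly dosed trace into per-cycle windows
#'
#' Window `k` spans from dose `k` to dose `k+1` (the last window ends at the
#' end of the trace); each window carries the local baseline, the signal
#' value at its dose time.
#'
#' @param signal a [signal_trace()].
#' @param dose_times sorted, distinct dose times within the trace span.
#' @return data.frame with columns `cycle`, `t_d`, `window_end`, `baseline`.
#' @export
segment_cycles <- function(signal, dose_times) {
  stopifnot(inherits(signal, "signal_trace"))
  if (length(dose_times) == 0) stop("segment_cycles: no dose times")
  if (anyDuplicated(dose_times) || is.unsorted(dose_times, strictly = TRUE)) {
    stop("segment_cycles: dose times must be sorted and distinct")
  }
  if (min(dose_times) < min(signal$time) || max(dose_times) > max(signal$time)) {
    stop("segment_cycles: dose times must lie within the trace span")
  }
  ends <- c(dose_times[-1], max(signal$time))
  baseline <- vapply(dose_times, function(td) {
    signal$value[which.min(abs(signal$time - td))]
  }, numeric(1))
  data.frame(cycle = seq_along(dose_times), t_d = dose_times,
             window_end = ends, baseline = baseline)
}

#' Lifetimes of every cycle in a repeatedly dosed trace
#'
#' @param signal a [signal_trace()].
#' @param dose_times sorted dose times.
#' @param opts a [lifetime_opts()] list.
#' @return data.frame with one row per cycle: `cycle`, `t_d`, `tau`
#'   (NA where extraction failed), `delta_signal`, `error` (the failure
#'   class, or NA).
#' @export
cycle_lifetimes <- function(signal, dose_times, opts = lifetime_opts()) {
  win <- segment_cycles(signal, dose_times)
  res <- lapply(seq_len(nrow(win)), function(k) {
    r <- tryCatch(
      transient_lifetime(signal, win$t_d[k], win$window_end[k], opts),
      lifetime_error = function(e) e)
    if (inherits(r, "lifetime_result")) {
      data.frame(cycle = k, t_d = win$t_d[k], tau = r$tau,
                 delta_signal = r$delta_signal, error = NA_character_)
    } else {
      data.frame(cycle = k, t_d = win$t_d[k], tau = NA_real_,
                 delta_signal = NA_real_, error = class(r)[1])
    }
  })
  do.call(rbind, res)
}

#' Fatigue report: observed lifetimes against the ideal simulation
#'
#' Simulates the ideal, waste-free model (`K_W = Inf`) on the observed dose
#' schedule, extracts per-cycle lifetimes from both the observed signal and
#' the ideal prediction, and reports the per-cycle fatigue index
#' `f_k = (tau_k - tau_hat_k) / tau_hat_k`. Waste-driven fatigue shows as
#' positive, non-decreasing `f_k`; a cycle whose extraction fails is marked
#' missing, not fatal.
#'
#' @param observed a [signal_trace()] spanning the schedule.
#' @param ideal_params [kinetic_params()] for the ideal model; `K_W` is
#'   forced to `Inf`.
#' @param net the `reaction_network` (or a [condition()], from which it is
#'   built).
#' @param schedule list of [dose_event()]s that generated `observed`.
#' @param opts a [lifetime_opts()] list.
#' @param dt_out simulation output interval for the ideal model, min.
#' @return an object of class `fatigue_report`: data.frame `cycles` with
#'   `tau_obs`, `tau_ideal`, `fatigue_index`, `delta_signal_obs`, and a
#'   `fatigued` flag (any usable `f_k > 0.05` with a non-decreasing trend).
#' @export
fatigue_report <- function(observed, ideal_params, net, schedule,
                           opts = lifetime_opts(), dt_out = NULL) {
  stopifnot(inherits(observed, "signal_trace"))
  if (inherits(net, "circuit_condition")) {
    net <- build_network(ideal_params, net)
  }
  ideal_params <- update_params(ideal_params, K_W = Inf)
  if (is.null(dt_out)) {
    dt_out <- stats::median(diff(observed$time))
  }
  tr <- integrate_network(net, ideal_params, schedule = schedule,
                          t_end = max(observed$time), dt_out = dt_out,
                          t0 = min(observed$time))
  ideal_sig <- observables(tr, ideal_params, channel = observed$channel,
                           normalization = "raw")
  dose_times <- schedule_times(schedule)
  obs <- cycle_lifetimes(observed, dose_times, opts)
  ide <- cycle_lifetimes(ideal_sig, dose_times, opts)
  cycles <- data.frame(cycle = obs$cycle, t_d = obs$t_d,
                       tau_obs = obs$tau, tau_ideal = ide$tau,
                       fatigue_index = (obs$tau - ide$tau) / ide$tau,
                       delta_signal_obs = obs$delta_signal)
  f <- cycles$fatigue_index[!is.na(cycles$fatigue_index)]
  fatigued <- length(f) >= 2 && f[length(f)] > 0.05 &&
    stats::cor(seq_along(f), f, method = "spearman") > 0
  structure(list(cycles = cycles, fatigued = fatigued,
                 channel = observed$channel),
            class = "fatigue_report")
}

#' @export
print.fatigue_report <- function(x, ...) {
  cat("<fatigue_report> ", nrow(x$cycles), " cycles (", x$channel, "), ",
      if (x$fatigued) "fatigue detected" else "no fatigue detected",
      "\n", sep = "")
  print(x$cycles, row.names = FALSE)
  invisible(x)
}
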