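#' Impulsive fuel-dosing event
#'
#' A timed addition of a species (usually the fuel strand) to the running
#' reaction. The addition is instantaneous: the species concentration jumps
#' by `amount` and, if `dilution < 1`, every species is scaled by the
#' dilution factor (spike volumes are negligible by default).
#'
#' @param time dose time, min (>= 0).
#' @param species species name receiving the dose (default `"Fuel"`;
#'   trypsin-cycle fuel is `"FuelTry"`).
#' @param amount amount added, uM (>= 0). Exactly one of `amount` / `eq`.
#' @param eq amount in fuel equivalents; converted to uM at integration time
#'   through the network's reference concentration.
#' @param dilution multiplicative dilution factor in `(0, 1]` applied to all
#'   species at the dose time.
#' @return an object of class `dose_event`.
#' @export
dose_event <- function(time, species = "Fuel", amount = NULL, eq = NULL,
                       dilution = 1) {
  if (time < 0) stop("dose_event: time must be >= 0")
  if (is.null(amount) == is.null(eq)) {
    stop("dose_event: give exactly one of `amount` (uM) or `eq`")
  }
  if (!is.null(amount) && amount < 0) stop("dose_event: amount must be >= 0")
  if (!is.null(eq) && eq < 0) stop("dose_event: eq must be >= 0")
  if (dilution <= 0 || dilution > 1) {
    stop("dose_event: dilution must be in (0, 1]")
  }
  structure(list(time = time, species = species, amount = amount, eq = eq,
                 dilution = dilution),
            class = "dose_event")
}

#' A schedule of repeated fuel doses
#'
#' @param times dose times, min (sorted, distinct).
#' @param eq equivalents per dose (recycled).
#' @param species dosed species name.
#' @return list of [dose_event()]s.
#' @export
dose_schedule <- function(times, eq = 1, species = "Fuel") {
  eq <- rep_len(eq, length(times))
  mapply(function(t, e) dose_event(t, species = species, eq = e),
         times, eq, SIMPLIFY = FALSE)
}

schedule_times <- function(schedule) {
  vapply(schedule, `[[`, numeric(1), "time")
}

resolve_amount <- function(ev, net) {
  if (!is.null(ev$amount)) ev$amount else ev$eq * net$ref_conc
}

## Generate a fast rate evaluator for a fixed (network, params) pair.
## Parameter values are substituted as numeric literals and the descriptor
## interpretation is folded away, so both the ODE right-hand side and the
## SSA propensity loop run on plain arithmetic.
compile_rate_fn <- function(net, params) {
  sp <- net$species
  idx <- function(s) match(s, sp)
  lines <- character(0)
  # shared competitive-MM denominators
  groups <- list()
  for (r in net$reactions) {
    if (r$type == "competitive_mm") {
      term <- sprintf("y[%d]/%.17g", idx(r$substrate), params[[r$Km]])
      groups[[r$group]] <- c(groups[[r$group]], term)
    }
  }
  for (g in names(groups)) {
    lines <- c(lines, sprintf("den_%s <- 1 + %s", g,
                              paste(groups[[g]], collapse = " + ")))
  }
  waste_expr <- if (is.finite(params$K_W) && "Waste" %in% sp) {
    sprintf("wfac <- 1/(1 + y[%d]/%.17g)", idx("Waste"), params$K_W)
  } else "wfac <- 1"
  lines <- c(lines, waste_expr)
  rexprs <- vapply(net$reactions, function(r) {
    switch(r$type,
      mass_action = {
        terms <- vapply(names(r$reactants), function(s) {
          if (r$reactants[[s]] == 1) sprintf("y[%d]", idx(s))
          else sprintf("y[%d]^%d", idx(s), r$reactants[[s]])
        }, "")
        paste(c(sprintf("%.17g", params[[r$k]]), terms), collapse = " * ")
      },
      first_order = sprintf("%.17g * y[%d]", params[[r$k]], idx(r$species)),
      competitive_mm = {
        sat <- sprintf("(y[%d]/%.17g)/den_%s", idx(r$substrate),
                       params[[r$Km]], r$group)
        if (r$group %in% c("exoIII", "t7")) {
          vmax <- pool_vmax(r$group, r$L, net, params)
          sprintf("%.17g * wfac * %s", vmax, sat)
        } else {
          sprintf("%.17g * y[%d] * %s", params[[r$kcat]],
                  idx(r$enzyme_species), sat)
        }
      })
  }, "")
  body_txt <- paste(c("y <- pmax(y, 0)", lines,
                      sprintf("c(%s)", paste(rexprs, collapse = ",\n  "))),
                    collapse = "\n")
  f <- eval(parse(text = paste0("function(y) {\n", body_txt, "\n}")),
            envir = baseenv())
  compiler::cmpfun(f)
}

#' Integrate a reaction network with fuel-dosing events
#'
#' Stiff-capable ODE integration (deSolve, `lsoda`) split at dose times: at
#' each dose the state is updated instantaneously (`species += amount`, all
#' species scaled by the dilution factor) and integration restarts.
#' Non-negativity is controlled by solver tolerance, not clipping.
#'
#' @param net a `reaction_network`.
#' @param params a [kinetic_params()] object.
#' @param init named initial state, uM (defaults to the network's built-in
#'   initial state).
#' @param schedule list of [dose_event()]s, sorted by time.
#' @param t_end end of integration, min.
#' @param dt_out output sampling interval, min (default 0.5, the
#'   plate-reader cadence).
#' @param t0 start time, min.
#' @param rtol,atol solver tolerances (defaults 1e-8 and 1e-10 uM).
#' @param method deSolve method name.
#' @param hmax maximal internal step, min (default `20 * dt_out`; bounding
#'   the step keeps lsoda's dense output reliable across long flat
#'   plateaus).
#' @return an object of class `crn_trace`: time grid, state matrix
#'   (time x species, uM), dose times, and the generating network.
#' @export
integrate_network <- function(net, params, init = net$init, schedule = list(),
                              t_end, dt_out = 0.5, t0 = 0,
                              rtol = 1e-8, atol = 1e-10, method = "lsoda",
                              hmax = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  if (dt_out <= 0) stop("integrate_network: dt_out must be > 0")
  init <- init[net$species]
  if (anyNA(init)) stop("integrate_network: init must cover all species")
  if (any(init < 0)) stop("integrate_network: init must be non-negative")
  if (inherits(schedule, "dose_event")) schedule <- list(schedule)
  dt_times <- schedule_times(schedule)
  if (is.unsorted(dt_times, strictly = TRUE) && length(dt_times) > 1) {
    stop("integrate_network: schedule must be sorted by strictly increasing time")
  }
  if (length(dt_times) && (min(dt_times) < t0 || max(dt_times) >= t_end)) {
    stop("integrate_network: dose times must lie in [t0, t_end)")
  }

  rate_fn <- compile_rate_fn(net, params)
  N <- net$stoich
  storage.mode(N) <- "double"
  deriv <- function(t, y, p) list(as.vector(N %*% rate_fn(y)))

  grid <- seq(t0, t_end, by = dt_out)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  bounds <- c(t0, dt_times[dt_times > t0], t_end)

  y <- as.numeric(init)
  names(y) <- net$species
  out_t <- numeric(0)
  out_x <- NULL
  # apply any dose scheduled exactly at t0 before integrating
  for (ev in schedule[dt_times == t0]) {
    y[ev$species] <- y[ev$species] + resolve_amount(ev, net)
    y <- y * ev$dilution
  }
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    seg_t <- unique(c(a, grid[grid > a & grid < b], b))
    sol <- deSolve::ode(y = y, times = seg_t, func = deriv, parms = NULL,
                        method = method, rtol = rtol, atol = atol,
                        hmax = if (is.null(hmax)) 20 * dt_out else hmax)
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf(paste0("integrate_network: solver failure in segment ",
                          "[%.3f, %.3f] at state [%s]"), a, b,
                   paste(sprintf("%.3g", y), collapse = ", ")))
    }
    keep <- sol[, 1] %in% grid & !(sol[, 1] %in% out_t)
    out_t <- c(out_t, sol[keep, 1])
    out_x <- rbind(out_x, sol[keep, -1, drop = FALSE])
    y <- sol[nrow(sol), -1]
    names(y) <- net$species
    if (b < t_end) {
      for (ev in schedule[dt_times == b]) {
        y[ev$species] <- y[ev$species] + resolve_amount(ev, net)
        y <- y * ev$dilution
      }
    }
  }
  colnames(out_x) <- net$species
  structure(list(time = out_t, state = out_x,
                 dose_times = dt_times, network = net),
            class = "crn_trace")
}

#' @export
print.crn_trace <- function(x, ...) {
  cat("<crn_trace> ", x$network$circuit_id, ": ", length(x$time),
      " samples on [", min(x$time), ", ", max(x$time), "] min, ",
      ncol(x$state), " species\n", sep = "")
  invisible(x)
}

#' Conserved-moiety drift along a trajectory
#'
#' For each declared conserved moiety, the maximum relative deviation of
#' `v . x(t)` from its value at the start of each inter-dose segment
#' (conservation holds between, not across, dose events).
#'
#' @param trace a `crn_trace`.
#' @return named numeric vector of maximal relative deviations per moiety.
#' @export
trace_conservation <- function(trace) {
  net <- trace$network
  segs <- findInterval(trace$time, c(-Inf, trace$dose_times), left.open = TRUE)
  out <- vapply(net$moieties, function(v) {
    tot <- as.vector(trace$state[, names(v), drop = FALSE] %*% v)
    worst <- 0
    for (s in unique(segs)) {
      ti <- tot[segs == s]
      ref <- ti[1]
      if (ref > 0) worst <- max(worst, max(abs(ti - ref)) / ref)
    }
    worst
  }, numeric(1))
  out
}

#' Map a species trajectory to an optical observable
#'
#' The 520 nm fluorescence channel reports cleaved reporter
#' (`F0 + alpha_F * [RepCleaved]`); the 405 nm absorbance channel reports
#' p-nitroaniline (`A0 + eps_A * [pNA]`).
#'
#' @param trace a `crn_trace`.
#' @param params a [kinetic_params()] object (signal-mapping coefficients).
#' @param channel `"fluor520"` or `"abs405"`.
#' @param normalization `"raw"`, `"delta"` (subtract the value at the first
#'   dose time, the plotted quantity in kinetic assays) or `"minmax"`
#'   (rescale to `[0, 1]` over the trace).
#' @return an object of class `signal_trace`.
#' @export
observables <- function(trace, params, channel = c("fluor520", "abs405"),
                        normalization = c("raw", "delta", "minmax")) {
  channel <- match.arg(channel)
  normalization <- match.arg(normalization)
  sp <- switch(channel, fluor520 = "RepCleaved", abs405 = "pNA")
  if (!sp %in% colnames(trace$state)) {
    stop("observables: channel '", channel, "' needs species '", sp,
         "' which is absent from this network")
  }
  value <- switch(channel,
    fluor520 = params$F0 + params$alpha_F * trace$state[, sp],
    abs405 = params$A0 + params$eps_A * trace$state[, sp])
  value <- unname(value)
  if (normalization == "delta") {
    t_ref <- if (length(trace$dose_times)) trace$dose_times[1] else trace$time[1]
    i <- which.min(abs(trace$time - t_ref))
    value <- value - value[i]
  } else if (normalization == "minmax") {
    rng <- range(value)
    value <- if (diff(rng) > 0) (value - rng[1]) / diff(rng) else value * 0
  }
  signal_trace(time = trace$time, value = value, channel = channel,
               normalization = normalization, dose_times = trace$dose_times)
}

#' Construct a signal trace
#'
#' @param time time grid, min.
#' @param value observable values (same length as `time`).
#' @param channel `"fluor520"` or `"abs405"`.
#' @param normalization normalization tag.
#' @param dose_times fuel dose times, min.
#' @param condition_id optional label.
#' @return an object of class `signal_trace`.
#' @export
signal_trace <- function(time, value, channel = "fluor520",
                         normalization = "raw", dose_times = numeric(0),
                         condition_id = NA_character_) {
  if (length(time) != length(value)) {
    stop("signal_trace: time and value must have the same length")
  }
  structure(list(time = time, value = value, channel = channel,
                 normalization = normalization, dose_times = dose_times,
                 condition_id = condition_id),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat("<signal_trace> ", x$channel, " (", x$normalization, "): ",
      length(x$time), " samples on [", min(x$time), ", ", max(x$time),
      "] min\n", sep = "")
  invisible(x)
}
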