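#' Plate-reader noise model
#'
#' Statistical structure of the synthetic traces: i.i.d. additive Gaussian
#' noise scaled to the trace's dynamic range, optional linear baseline
#' drift, and an optional transient mixing-artifact dip after each dose
#' (`-mix_amp * exp(-(t - t_d)/mix_tau)`), emulating the dip seen when
#' glycerol-containing enzyme stocks are spiked into the well.
#'
#' @param sigma additive Gaussian SD as a fraction of the trace's dynamic
#'   range (default 0.02, a typical plate-reader noise floor).
#' @param drift baseline drift slope, signal units per min (default 0).
#' @param mix_amp mixing-artifact dip amplitude, signal units (default 0 =
#'   disabled).
#' @param mix_tau mixing-artifact decay time, min (must be > 0 when
#'   `mix_amp != 0`).
#' @param dt sampling interval, min (default 0.5).
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.02, drift = 0, mix_amp = 0, mix_tau = 5,
                        dt = 0.5) {
  if (sigma < 0) stop("noise_model: sigma must be >= 0")
  if (mix_amp != 0 && mix_tau <= 0) {
    stop("noise_model: mix_tau must be > 0 when mix_amp != 0")
  }
  if (dt <= 0) stop("noise_model: dt must be > 0")
  structure(list(sigma = sigma, drift = drift, mix_amp = mix_amp,
                 mix_tau = mix_tau, dt = dt),
            class = "noise_model")
}

#' Generate one synthetic plate-reader trace
#'
#' Simulates the circuit under the truth parameters (ideal or, with finite
#' `K_W`, waste-fatigued), maps the trajectory to the optical channel, and
#' overlays dose-locked mixing dips, baseline drift and Gaussian noise.
#'
#' @param truth [kinetic_params()] generating the data.
#' @param cond a [condition()].
#' @param schedule list of [dose_event()]s.
#' @param noise a [noise_model()].
#' @param seed RNG seed (fixed seeds give bit-identical output).
#' @param t_end simulation horizon, min.
#' @param channel observable channel (default by circuit).
#' @param t0 recording start, min.
#' @param condition_id label stored in the output trace.
#' @return list with `signal` (noisy [signal_trace()]), `clean` (noiseless
#'   signal) and `truth` (the underlying `crn_trace`).
#' @export
generate_trace <- function(truth, cond, schedule, noise = noise_model(),
                           seed = 1, t_end, channel = NULL, t0 = 0,
                           condition_id = NA_character_) {
  if (is.null(channel)) {
    channel <- if (grepl("^trypsin", cond$circuit_id)) "abs405" else "fluor520"
  }
  net <- build_network(truth, cond)
  tr <- integrate_network(net, truth, schedule = schedule, t_end = t_end,
                          dt_out = noise$dt, t0 = t0)
  clean <- observables(tr, truth, channel = channel, normalization = "raw")
  clean$condition_id <- condition_id
  value <- clean$value
  tt <- clean$time
  if (noise$mix_amp != 0) {
    for (td in schedule_times(schedule)) {
      after <- tt >= td
      value[after] <- value[after] -
        noise$mix_amp * exp(-(tt[after] - td) / noise$mix_tau)
    }
  }
  if (noise$drift != 0) value <- value + noise$drift * (tt - tt[1])
  dyn <- diff(range(clean$value))
  set.seed(seed)
  value <- value + stats::rnorm(length(value), 0, noise$sigma * dyn)
  noisy <- signal_trace(tt, value, channel = channel, normalization = "raw",
                        dose_times = clean$dose_times,
                        condition_id = condition_id)
  list(signal = noisy, clean = clean, truth = tr)
}

# dose-time grids from the published recyclability panels
RECYC_TIMES_DNAZYME <- c(15, 45.5, 76, 106, 137, 167.5, 219)
RECYC_TIMES_TRYPSIN <- c(15, 40, 71, 107, 144, 180.5, 216, 252.5, 288.5,
                         323.5, 365, 407, 449, 488.5, 530.5, 576.5, 624,
                         677, 765.5, 806, 884, 968.5, 1058.5, 1158.5, 1281.5)

SUITE_IDS <- c("fuel_titration", "enzyme_titration", "toehold_series",
               "recyclability", "trypsin_titration", "coupled_panel")

#' Preset experiment suites
#'
#' Assembles the conditions, schedules and truth parameters of one of the
#' preset panels, mirroring the published concentration grids: fuel
#' equivalents \{1, 2, 3\} (DNAzyme) and \{2, 3, 4\} (trypsin), Exo III loads
#' \{0.1, 0.25, 0.5\} and \{0.025, 0.05, 0.1\} U/uL, toe-holds \{0, 1, 2, 3\}
#' nt (Exo III) and \{0, 5, 7, 10, 12\} nt (T7), and the repeated-dosing time
#' grids of the recyclability panels.
#'
#' @param suite_id one of `"fuel_titration"`, `"enzyme_titration"`,
#'   `"toehold_series"`, `"recyclability"`, `"trypsin_titration"`,
#'   `"coupled_panel"`.
#' @param seed suite seed; trace `i` is generated with `seed + i`.
#' @param variant `"exoIII"` or `"t7"` flavor where both exist; the
#'   recyclability suite additionally accepts `"trypsin"` (25-dose panel).
#' @param truth optional [kinetic_params()] override.
#' @param noise optional [noise_model()] override (the coupled panel enables
#'   the mixing-artifact dip by default).
#' @return an object of class `experiment_design`.
#' @export
suite_design <- function(suite_id, seed = 1, variant = "exoIII",
                         truth = NULL, noise = NULL) {
  if (!suite_id %in% SUITE_IDS) {
    stop("suite_design: unknown suite id '", suite_id, "'")
  }
  exo_circuit <- if (variant == "t7") "dnazyme_t7" else "dnazyme_exoIII"
  enz <- if (variant == "t7") "t7" else "exoIII"
  mk <- function(id, cond, schedule, t_end, channels) {
    list(condition_id = id, cond = cond, schedule = schedule,
         t_end = t_end, channels = channels)
  }
  experiments <- switch(suite_id,
    fuel_titration = {
      lapply(c(1, 2, 3), function(eq) {
        mk(sprintf("fuel_%deq", eq), condition(exo_circuit),
           dose_schedule(15, eq = eq), 250, "fluor520")
      })
    },
    enzyme_titration = {
      loads <- if (variant == "t7") c(0.5, 0.6, 0.7) else c(0.1, 0.25, 0.5)
      lapply(loads, function(u) {
        mk(sprintf("%s_%g", enz, u),
           condition(exo_circuit,
                     enzymes = stats::setNames(u, enz)),
           dose_schedule(15, eq = 1), 400, "fluor520")
      })
    },
    toehold_series = {
      Ls <- if (variant == "t7") c(0, 5, 7, 10, 12) else c(0, 1, 2, 3)
      lapply(Ls, function(L) {
        mk(sprintf("toehold_%dnt", L),
           condition(exo_circuit, L_fuel = L),
           dose_schedule(15, eq = 1), 400, "fluor520")
      })
    },
    recyclability = {
      if (variant == "trypsin") {
        list(mk("recyc_trypsin",
                condition("trypsin_exoIII", enzymes = c(exoIII = 0.1)),
                dose_schedule(RECYC_TIMES_TRYPSIN, eq = 2,
                              species = "FuelTry"),
                1400, "abs405"))
      } else {
        list(mk("recyc_dnazyme",
                condition(exo_circuit,
                          enzymes = stats::setNames(1.5, enz)),
                dose_schedule(RECYC_TIMES_DNAZYME, eq = 1), 250,
                "fluor520"))
      }
    },
    trypsin_titration = {
      lapply(c(2, 3, 4), function(eq) {
        mk(sprintf("tryfuel_%deq", eq), condition("trypsin_exoIII"),
           dose_schedule(15, eq = eq, species = "FuelTry"), 300, "abs405")
      })
    },
    coupled_panel = {
      lapply(c(1, 2.5, 5), function(rep_c) {
        mk(sprintf("repC_%guM", rep_c),
           condition("coupled", totals = c(Rep = rep_c), L_tryfuel = 2),
           dose_schedule(30, eq = 2), 1100, c("fluor520", "abs405"))
      })
    }
  )
  circuit <- experiments[[1]]$cond$circuit_id
  if (is.null(truth)) truth <- default_params(circuit)
  if (is.null(noise)) {
    noise <- if (suite_id == "coupled_panel") {
      noise_model(sigma = 0.02, mix_amp = 0.05, mix_tau = 5)
    } else {
      noise_model(sigma = 0.02)
    }
  }
  structure(list(suite_id = suite_id, variant = variant,
                 experiments = experiments, truth = truth, noise = noise,
                 seed = seed),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design> ", x$suite_id, " (", x$variant, "): ",
      length(x$experiments), " condition(s), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a suite of synthetic traces and write it to disk
#'
#' Writes one tidy CSV per condition (columns `time_min`, `channel`,
#' `value`, `condition_id`) plus a JSON manifest recording the suite id,
#' seed, truth parameters, noise model, conditions and schedules.
#' [rebuild_suite()] regenerates every CSV byte-identically from the
#' manifest alone.
#'
#' @param design an [suite_design()] object.
#' @param dir output directory (created if missing).
#' @return invisibly, a list with `files` (CSV paths), `manifest` (path)
#'   and the per-condition generated traces.
#' @export
build_suite <- function(design, dir) {
  stopifnot(inherits(design, "experiment_design"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  traces <- list()
  for (i in seq_along(design$experiments)) {
    e <- design$experiments[[i]]
    sigs <- lapply(e$channels, function(ch) {
      generate_trace(design$truth, e$cond, e$schedule, noise = design$noise,
                     seed = design$seed + i, t_end = e$t_end, channel = ch,
                     condition_id = e$condition_id)$signal
    })
    f <- file.path(dir, paste0(e$condition_id, ".csv"))
    write_signal_csv(sigs, f)
    files <- c(files, f)
    traces[[e$condition_id]] <- sigs
  }
  manifest <- list(
    suite_id = design$suite_id,
    variant = design$variant,
    seed = design$seed,
    truth = jsonlite::parse_json(params_to_json(design$truth)),
    noise = unclass(design$noise),
    experiments = lapply(design$experiments, function(e) {
      list(condition_id = e$condition_id,
           condition = jsonlite::parse_json(condition_to_json(e$cond)),
           schedule = lapply(e$schedule, function(ev) {
             list(time = ev$time, species = ev$species,
                  amount = ev$amount, eq = ev$eq, dilution = ev$dilution)
           }),
           t_end = e$t_end,
           channels = as.list(e$channels),
           file = paste0(e$condition_id, ".csv"))
    })
  )
  mpath <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = I(17),
                              null = "null", pretty = TRUE), mpath)
  invisible(list(files = files, manifest = mpath, traces = traces))
}

#' Regenerate a suite from its manifest
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [build_suite()].
#' @param dir output directory.
#' @return as [build_suite()].
#' @export
rebuild_suite <- function(manifest_path, dir) {
  m <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  truth <- params_from_json(jsonlite::toJSON(m$truth, auto_unbox = TRUE,
                                             digits = I(17)))
  nm <- m$noise
  noise <- noise_model(sigma = nm$sigma, drift = nm$drift,
                       mix_amp = nm$mix_amp, mix_tau = nm$mix_tau,
                       dt = nm$dt)
  experiments <- lapply(m$experiments, function(e) {
    cond <- condition_from_json(jsonlite::toJSON(e$condition,
                                                 auto_unbox = TRUE,
                                                 digits = I(17)))
    schedule <- lapply(e$schedule, function(ev) {
      dose_event(time = ev$time, species = ev$species,
                 amount = ev$amount, eq = ev$eq, dilution = ev$dilution)
    })
    list(condition_id = e$condition_id, cond = cond, schedule = schedule,
         t_end = e$t_end, channels = unlist(e$channels))
  })
  design <- structure(list(suite_id = m$suite_id, variant = m$variant,
                           experiments = experiments, truth = truth,
                           noise = noise, seed = m$seed),
                      class = "experiment_design")
  build_suite(design, dir)
}
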