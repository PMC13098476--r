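#' Kinetic parameter set for the dissipative DNA circuits
#'
#' Bundles every rate constant, Michaelis constant, enzyme-unit conversion and
#' signal-mapping coefficient used by the three circuit models (DNAzyme cycle,
#' trypsin cycle, coupled network). Units follow plate-reader conventions:
#' concentrations in uM, time in minutes, enzyme loads in U/uL.
#'
#' @param k_hyb_dz bimolecular hybridization rate of fuel + protected DNAzyme
#'   strand, uM^-1 min^-1.
#' @param k_cat_rep,Km_rep DNAzyme turnover number (min^-1) and Michaelis
#'   constant (uM) for the fluorogenic reporter strand.
#' @param k_cat_inh,Km_inh DNAzyme turnover number and Michaelis constant for
#'   the inhibitor duplex (coupled network only).
#' @param c_exo,c_t7 enzyme-unit conversions, uM min^-1 per U uL^-1; the
#'   digestion Vmax is `c * U * phi(L)`.
#' @param Km_exo,Km_t7 digestion Michaelis constants, uM.
#' @param beta_exo,beta_t7 toe-hold attenuation coefficients, per nucleotide.
#' @param Lmax_exo,Lmax_t7 hard overhang cutoffs (nt) for the optional
#'   cutoff mode of [toehold_rate_factor()].
#' @param k_hyb_apt aptamer + trypsin-fuel hybridization rate, uM^-1 min^-1.
#' @param k_on_TA,k_off_TA trypsin-aptamer binding (uM^-1 min^-1) and
#'   unbinding (min^-1) rates.
#' @param k_disp direct displacement of the aptamer from the trypsin complex
#'   by fuel, uM^-1 min^-1 (0 disables the pathway).
#' @param k_cat_try,Km_try trypsin turnover (min^-1) and Michaelis constant
#'   (uM) on L-BAPNA.
#' @param alpha_F,F0 fluorescence gain (a.u. per uM cleaved reporter) and
#'   baseline (a.u.) of the 520 nm channel.
#' @param eps_A,A0 absorbance gain (AU per uM p-nitroaniline) and baseline
#'   (AU) of the 405 nm channel.
#' @param K_W waste inhibition constant, uM. `Inf` (default) is the ideal
#'   waste-free model; finite values scale the effective exonuclease load by
#'   `1 / (1 + [Waste]/K_W)` and produce fatigue across repeated doses.
#'
#' @return an object of class `kinetic_params` (a validated named list).
#' @seealso [default_params()] for circuit-calibrated defaults,
#'   [params_to_json()] / [params_from_json()] for serialization.
#' @export
kinetic_params <- function(k_hyb_dz = 0.5,
                           k_cat_rep = 0.08, Km_rep = 10,
                           k_cat_inh = 0.1, Km_inh = 1,
                           c_exo = 0.3, c_t7 = 0.16,
                           Km_exo = 0.2, Km_t7 = 0.2,
                           beta_exo = 0.5, beta_t7 = 0.09,
                           Lmax_exo = 4L, Lmax_t7 = 12L,
                           k_hyb_apt = 100,
                           k_on_TA = 20, k_off_TA = 0.02,
                           k_disp = 0,
                           k_cat_try = 150, Km_try = 900,
                           alpha_F = 2, F0 = 0,
                           eps_A = 0.0099, A0 = 0,
                           K_W = Inf) {
  p <- list(
    k_hyb_dz = k_hyb_dz,
    k_cat_rep = k_cat_rep, Km_rep = Km_rep,
    k_cat_inh = k_cat_inh, Km_inh = Km_inh,
    c_exo = c_exo, c_t7 = c_t7,
    Km_exo = Km_exo, Km_t7 = Km_t7,
    beta_exo = beta_exo, beta_t7 = beta_t7,
    Lmax_exo = as.integer(Lmax_exo), Lmax_t7 = as.integer(Lmax_t7),
    k_hyb_apt = k_hyb_apt,
    k_on_TA = k_on_TA, k_off_TA = k_off_TA,
    k_disp = k_disp,
    k_cat_try = k_cat_try, Km_try = Km_try,
    alpha_F = alpha_F, F0 = F0,
    eps_A = eps_A, A0 = A0,
    K_W = K_W
  )
  int_fields <- c("Lmax_exo", "Lmax_t7")
  for (nm in setdiff(names(p), int_fields)) p[[nm]] <- as.numeric(p[[nm]])
  class(p) <- "kinetic_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  pos <- c("k_hyb_dz", "k_cat_rep", "Km_rep", "k_cat_inh", "Km_inh",
           "c_exo", "c_t7", "Km_exo", "Km_t7", "k_hyb_apt",
           "k_on_TA", "k_off_TA", "k_cat_try", "Km_try", "alpha_F", "eps_A")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("kinetic_params: `", nm, "` must be a single positive number")
    }
  }
  if (p$k_disp < 0) stop("kinetic_params: `k_disp` must be >= 0")
  if (p$beta_exo < 0 || p$beta_t7 < 0) {
    stop("kinetic_params: toe-hold attenuation coefficients must be >= 0")
  }
  if (p$Lmax_exo < 1L || p$Lmax_t7 < 1L) {
    stop("kinetic_params: Lmax cutoffs must be positive integers")
  }
  if (!(is.infinite(p$K_W) || p$K_W > 0)) {
    stop("kinetic_params: `K_W` must be > 0 or Inf")
  }
  invisible(p)
}

#' Modify a subset of kinetic parameters
#'
#' @param params a [kinetic_params()] object.
#' @param ... named replacements, e.g. `update_params(p, c_exo = 0.5)`.
#' @return a revalidated `kinetic_params` object.
#' @export
update_params <- function(params, ...) {
  repl <- list(...)
  if (length(repl) == 0L) return(params)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown)) {
    stop("update_params: unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(repl)) params[[nm]] <- repl[[nm]]
  validate_params(params)
  params
}

#' Circuit-calibrated default parameter sets
#'
#' Synthetic truth parameters per circuit family, calibrated so that the
#' default experiment suites produce first-cycle transient lifetimes in the
#' tens-of-minutes range for the single cycles and the hours range for the
#' coupled network. These are plausible synthetic values for testing and
#' simulation studies, not measurements.
#'
#' @param circuit_id one of `"dnazyme_exoIII"`, `"dnazyme_t7"`,
#'   `"trypsin_exoIII"`, `"trypsin_t7"`, `"coupled"`.
#' @return a `kinetic_params` object.
#' @export
default_params <- function(circuit_id = c("dnazyme_exoIII", "dnazyme_t7",
                                          "trypsin_exoIII", "trypsin_t7",
                                          "coupled")) {
  circuit_id <- match.arg(circuit_id)
  switch(circuit_id,
    dnazyme_exoIII = kinetic_params(),
    dnazyme_t7     = kinetic_params(c_t7 = 0.16),
    # the trypsin fuel is a short 30-mer digested faster per enzyme unit;
    # k_disp > 0: the fuel also displaces the aptamer directly from the
    # trypsin complex, giving the immediate activation seen in plate-reader
    # traces (dissociation alone is too slow at high exonuclease loads)
    trypsin_exoIII = kinetic_params(c_exo = 2.6, k_disp = 5),
    trypsin_t7     = kinetic_params(c_exo = 2.6, c_t7 = 0.28, k_disp = 5),
    # coupled network: the doubly protected DNAzyme C1/C2 is a much weaker
    # catalyst, and inhibitor cleavage must be slow enough that reporter
    # competition for the DNAzyme active site modulates fuel release
    coupled        = kinetic_params(c_exo = 1.1, c_t7 = 0.3, k_disp = 5,
                                    k_cat_rep = 0.002, Km_rep = 1,
                                    k_cat_inh = 0.008, Km_inh = 1,
                                    Km_exo = 1)
  )
}

CIRCUIT_IDS <- c("dnazyme_exoIII", "dnazyme_t7",
                 "trypsin_exoIII", "trypsin_t7", "coupled")

#' Experimental condition for one circuit variant
#'
#' Describes one well: the circuit topology, the initial species totals, the
#' enzyme loads, and the fuel toe-hold lengths. Fuel is usually absent
#' initially and introduced by [dose_event()]s; amounts given in "eq." are
#' converted through `ref_conc` (the hybridization partner's total: the
#' protected DNAzyme strand for DNAzyme circuits, the aptamer for trypsin
#' circuits).
#'
#' @param circuit_id one of the five circuit variants.
#' @param totals named numeric vector of initial totals (uM) overriding the
#'   circuit defaults; recognised names depend on the circuit (see Details).
#' @param enzymes named numeric vector, entries `exoIII` and/or `t7`, U/uL.
#' @param L_fuel toe-hold length of the DNAzyme (or trypsin-cycle) fuel, nt.
#' @param L_tryfuel toe-hold length of the trypsin fuel in the coupled
#'   network, nt.
#' @param ref_conc reference concentration for "eq." conversion, uM; defaults
#'   to the circuit's hybridization partner total.
#'
#' @details Default totals mirror the published experiment layouts: DNAzyme
#' circuits use 2.5 uM protected strand and 2.5 uM reporter; trypsin circuits
#' use 0.1 uM trypsin, 1 uM aptamer (1:10 ratio) and 100 uM L-BAPNA; the
#' coupled network additionally carries a 2 uM inhibitor/trypsin-fuel duplex
#' and a 1 uM reporter C.
#'
#' @return an object of class `circuit_condition`.
#' @export
condition <- function(circuit_id, totals = NULL, enzymes = NULL,
                      L_fuel = 0L, L_tryfuel = 0L, ref_conc = NULL) {
  if (!is.character(circuit_id) || length(circuit_id) != 1L ||
      !(circuit_id %in% CIRCUIT_IDS)) {
    stop("condition: unknown circuit_id; must be one of ",
         paste(CIRCUIT_IDS, collapse = ", "))
  }
  base_totals <- switch(circuit_id,
    dnazyme_exoIII = ,
    dnazyme_t7 = c(S1 = 2.5, Rep = 2.5),
    trypsin_exoIII = ,
    trypsin_t7 = c(Try = 0.1, Apt = 1, LBAPNA = 100),
    coupled = c(S1 = 2.5, Rep = 1, Try = 0.02, Apt = 0.5, LBAPNA = 100,
                InhibDuplex = 1.5)
  )
  if (!is.null(totals)) {
    if (is.null(names(totals)) || any(names(totals) == "")) {
      stop("condition: `totals` must be a named numeric vector")
    }
    unknown <- setdiff(names(totals), names(base_totals))
    if (length(unknown)) {
      stop("condition: unknown species total(s) for ", circuit_id, ": ",
           paste(unknown, collapse = ", "))
    }
    base_totals[names(totals)] <- totals
  }
  if (any(base_totals < 0)) stop("condition: concentrations must be >= 0")

  base_enz <- c(exoIII = 0, t7 = 0)
  default_enz <- switch(circuit_id,
    dnazyme_exoIII = c(exoIII = 0.5),
    dnazyme_t7 = c(t7 = 0.5),
    trypsin_exoIII = c(exoIII = 0.05),
    trypsin_t7 = c(t7 = 0.6),
    coupled = c(exoIII = 0.025, t7 = 0.6)
  )
  base_enz[names(default_enz)] <- default_enz
  if (!is.null(enzymes)) {
    unknown <- setdiff(names(enzymes), names(base_enz))
    if (length(unknown)) {
      stop("condition: unknown enzyme(s): ", paste(unknown, collapse = ", "))
    }
    base_enz[names(enzymes)] <- enzymes
  }
  if (any(base_enz < 0)) stop("condition: enzyme loads must be >= 0")

  check_L <- function(L, nm) {
    if (length(L) != 1L || is.na(L) || L < 0 || L != round(L)) {
      stop("condition: `", nm, "` must be a non-negative integer")
    }
    as.integer(L)
  }
  L_fuel <- check_L(L_fuel, "L_fuel")
  L_tryfuel <- check_L(L_tryfuel, "L_tryfuel")

  if (is.null(ref_conc)) {
    ref_conc <- switch(circuit_id,
      dnazyme_exoIII = , dnazyme_t7 = , coupled = unname(base_totals["S1"]),
      trypsin_exoIII = , trypsin_t7 = unname(base_totals["Apt"])
    )
  }
  if (!is.numeric(ref_conc) || length(ref_conc) != 1L || ref_conc <= 0) {
    stop("condition: reference concentration must be a single positive number")
  }

  structure(list(circuit_id = circuit_id,
                 totals = base_totals,
                 enzymes = base_enz,
                 L_fuel = L_fuel,
                 L_tryfuel = L_tryfuel,
                 ref_conc = ref_conc),
            class = "circuit_condition")
}

#' @export
print.circuit_condition <- function(x, ...) {
  cat("<circuit_condition> ", x$circuit_id, "\n", sep = "")
  cat("  totals (uM):  ",
      paste(sprintf("%s=%g", names(x$totals), x$totals), collapse = ", "), "\n")
  cat("  enzymes (U/uL): ",
      paste(sprintf("%s=%g", names(x$enzymes), x$enzymes), collapse = ", "), "\n")
  cat("  toe-holds (nt): fuel=", x$L_fuel, ", trypsin fuel=", x$L_tryfuel,
      "; ref. conc = ", x$ref_conc, " uM\n", sep = "")
  invisible(x)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  v <- unlist(x)
  cat(paste(sprintf("  %-10s %g", names(v), v), collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize kinetic parameters or a condition to JSON
#'
#' Round-trips through [params_from_json()] / [condition_from_json()] at full
#' double precision.
#'
#' @param x a `kinetic_params` or `circuit_condition` object.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
params_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "kinetic_params"))
  obj <- unclass(x)
  obj$K_W <- if (is.infinite(obj$K_W)) "Inf" else obj$K_W
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname params_to_json
#' @param json a JSON string or path to a JSON file.
#' @export
params_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  if (identical(obj$K_W, "Inf")) obj$K_W <- Inf
  do.call(kinetic_params, obj)
}

#' @rdname params_to_json
#' @export
condition_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "circuit_condition"))
  obj <- list(circuit_id = x$circuit_id,
              totals = as.list(x$totals),
              enzymes = as.list(x$enzymes),
              L_fuel = x$L_fuel, L_tryfuel = x$L_tryfuel,
              ref_conc = x$ref_conc)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname params_to_json
#' @export
condition_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  condition(circuit_id = obj$circuit_id,
            totals = unlist(obj$totals),
            enzymes = unlist(obj$enzymes),
            L_fuel = obj$L_fuel,
            L_tryfuel = obj$L_tryfuel,
            ref_conc = obj$ref_conc)
}
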