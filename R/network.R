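#' Toe-hold rate factor for exonuclease digestion
#'
#' Double-strand-specific exonucleases initiate digestion at duplex ends;
#' single-stranded 3' (Exo III) or 5' (T7) overhangs ("toe-holds") slow or
#' block initiation. Exo III tolerates overhangs of up to about 4 nt, T7 up
#' to about 12 nt. The attenuation is modeled as `phi(L) = exp(-beta * L)`,
#' optionally truncated to zero beyond the enzyme's hard cutoff `Lmax`.
#'
#' @param L overhang length, nt (non-negative integer).
#' @param enzyme `"exoIII"` or `"t7"`.
#' @param params a [kinetic_params()] object supplying `beta_*` and `Lmax_*`.
#' @param mode `"exponential"` (default) or `"cutoff"`
#'   (`exp(-beta*L) * 1[L <= Lmax]`).
#' @return a dimensionless multiplier in `[0, 1]`; `phi(0) = 1`.
#' @export
toehold_rate_factor <- function(L, enzyme = c("exoIII", "t7"), params,
                                mode = c("exponential", "cutoff")) {
  enzyme <- match.arg(enzyme)
  mode <- match.arg(mode)
  if (any(L < 0) || any(L != round(L))) {
    stop("toehold_rate_factor: L must be a non-negative integer")
  }
  beta <- if (enzyme == "exoIII") params$beta_exo else params$beta_t7
  Lmax <- if (enzyme == "exoIII") params$Lmax_exo else params$Lmax_t7
  phi <- exp(-beta * L)
  if (mode == "cutoff") phi <- phi * as.numeric(L <= Lmax)
  phi
}

## ---- reaction-network construction -------------------------------------

new_reaction_network <- function(circuit_id, species, reactions, moieties,
                                 init, cond, toehold_mode) {
  stoich <- matrix(0L, nrow = length(species), ncol = length(reactions),
                   dimnames = list(species,
                                   vapply(reactions, `[[`, "", "name")))
  for (j in seq_along(reactions)) {
    st <- reactions[[j]]$stoich
    stoich[names(st), j] <- as.integer(st)
  }
  net <- structure(list(circuit_id = circuit_id,
                        species = species,
                        stoich = stoich,
                        reactions = reactions,
                        moieties = moieties,
                        init = init,
                        enzymes = cond$enzymes,
                        L_fuel = cond$L_fuel,
                        L_tryfuel = cond$L_tryfuel,
                        ref_conc = cond$ref_conc,
                        toehold_mode = toehold_mode),
                   class = "reaction_network")
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", x$circuit_id, ": ", length(x$species),
      " species, ", length(x$reactions), " reactions\n", sep = "")
  cat("  species: ", paste(x$species, collapse = ", "), "\n", sep = "")
  for (r in x$reactions) {
    cat("  ", r$name, " [", r$type, "]\n", sep = "")
  }
  invisible(x)
}

rxn <- function(name, type, stoich, ...) {
  c(list(name = name, type = type, stoich = stoich), list(...))
}

#' Build the dissipative DNAzyme cycle network
#'
#' Encodes the fuel-driven DNAzyme cycle: hybridization of the fuel strand
#' with the protected strand S1 forms the active duplex DNAzyme (Dz), which
#' cleaves the fluorogenic reporter; digestion of the fuel out of the duplex
#' by the exonuclease regenerates S1 and resets the system.
#'
#' Reactions: `S1 + Fuel -> Dz` (mass action, `k_hyb_dz`); `Rep ->
#' RepCleaved` catalyzed by Dz (Michaelis-Menten, competitive over all Dz
#' substrates); `Dz -> S1 + Waste` (exonuclease Michaelis-Menten with
#' `Vmax = c * U * phi(L_fuel)`). Conserved moieties: `S1 + Dz` and
#' `Rep + RepCleaved`.
#'
#' @param params a [kinetic_params()] object.
#' @param cond a [condition()] with `circuit_id` `"dnazyme_exoIII"` or
#'   `"dnazyme_t7"`.
#' @param toehold_mode passed to [toehold_rate_factor()].
#' @return a `reaction_network` object with an `init` state (fuel absent;
#'   dose it via [dose_event()]).
#' @export
build_dnazyme_cycle <- function(params, cond,
                                toehold_mode = c("exponential", "cutoff")) {
  toehold_mode <- match.arg(toehold_mode)
  if (!inherits(cond, "circuit_condition")) stop("`cond` must be a condition()")
  if (!cond$circuit_id %in% c("dnazyme_exoIII", "dnazyme_t7")) {
    stop("build_dnazyme_cycle: circuit_id must be dnazyme_exoIII or dnazyme_t7")
  }
  if (cond$ref_conc <= 0) stop("non-positive reference concentration")
  enzyme <- if (cond$circuit_id == "dnazyme_exoIII") "exoIII" else "t7"
  species <- c("S1", "Fuel", "Dz", "Rep", "RepCleaved", "Waste")
  reactions <- list(
    rxn("hybridization", "mass_action",
        c(S1 = -1, Fuel = -1, Dz = 1),
        reactants = c(S1 = 1, Fuel = 1), k = "k_hyb_dz"),
    rxn("reporter_cleavage", "competitive_mm",
        c(Rep = -1, RepCleaved = 1),
        group = "dz", enzyme_species = "Dz", substrate = "Rep",
        kcat = "k_cat_rep", Km = "Km_rep"),
    rxn("fuel_digestion", "competitive_mm",
        c(Dz = -1, S1 = 1, Waste = 1),
        group = enzyme, substrate = "Dz",
        Km = if (enzyme == "exoIII") "Km_exo" else "Km_t7",
        L = cond$L_fuel)
  )
  init <- stats::setNames(numeric(length(species)), species)
  init["S1"] <- cond$totals[["S1"]]
  init["Rep"] <- cond$totals[["Rep"]]
  moieties <- list(
    S1_total = c(S1 = 1, Dz = 1),
    Rep_total = c(Rep = 1, RepCleaved = 1)
  )
  new_reaction_network(cond$circuit_id, species, reactions, moieties, init,
                       cond, toehold_mode)
}

#' Build the aptamer-gated trypsin cycle network
#'
#' Trypsin is held inactive by a ssDNA aptamer; the trypsin fuel strand
#' hybridizes with the free aptamer (and, optionally, displaces it directly
#' from the complex), pulling the binding equilibrium toward free, active
#' trypsin, which cleaves the chromogenic substrate L-BAPNA to
#' p-nitroaniline. Exonuclease digestion of the aptamer/fuel duplex releases
#' the aptamer intact, which rebinds and silences trypsin.
#'
#' Conserved moieties: `Try + TryApt`, `Apt + TryApt + AptFuel`,
#' `LBAPNA + pNA`.
#'
#' @inheritParams build_dnazyme_cycle
#' @param cond a [condition()] with `circuit_id` `"trypsin_exoIII"` or
#'   `"trypsin_t7"`; the fuel toe-hold is taken from `cond$L_tryfuel`.
#' @return a `reaction_network`; initially all trypsin is aptamer-bound
#'   (`TryApt = min(Try_tot, Apt_tot)`).
#' @export
build_trypsin_cycle <- function(params, cond,
                                toehold_mode = c("exponential", "cutoff")) {
  toehold_mode <- match.arg(toehold_mode)
  if (!inherits(cond, "circuit_condition")) stop("`cond` must be a condition()")
  if (!cond$circuit_id %in% c("trypsin_exoIII", "trypsin_t7")) {
    stop("build_trypsin_cycle: circuit_id must be trypsin_exoIII or trypsin_t7")
  }
  if (cond$ref_conc <= 0) stop("non-positive reference concentration")
  enzyme <- if (cond$circuit_id == "trypsin_exoIII") "exoIII" else "t7"
  species <- c("TryApt", "Try", "Apt", "FuelTry", "AptFuel",
               "LBAPNA", "pNA", "Waste")
  reactions <- list(
    rxn("complex_dissociation", "first_order",
        c(TryApt = -1, Try = 1, Apt = 1),
        species = "TryApt", k = "k_off_TA"),
    rxn("complex_formation", "mass_action",
        c(Try = -1, Apt = -1, TryApt = 1),
        reactants = c(Try = 1, Apt = 1), k = "k_on_TA"),
    rxn("fuel_hybridization", "mass_action",
        c(Apt = -1, FuelTry = -1, AptFuel = 1),
        reactants = c(Apt = 1, FuelTry = 1), k = "k_hyb_apt"),
    rxn("fuel_displacement", "mass_action",
        c(TryApt = -1, FuelTry = -1, Try = 1, AptFuel = 1),
        reactants = c(TryApt = 1, FuelTry = 1), k = "k_disp"),
    rxn("bapna_cleavage", "competitive_mm",
        c(LBAPNA = -1, pNA = 1),
        group = "try", enzyme_species = "Try", substrate = "LBAPNA",
        kcat = "k_cat_try", Km = "Km_try"),
    rxn("fuel_digestion", "competitive_mm",
        c(AptFuel = -1, Apt = 1, Waste = 1),
        group = enzyme, substrate = "AptFuel",
        Km = if (enzyme == "exoIII") "Km_exo" else "Km_t7",
        L = cond$L_tryfuel)
  )
  init <- stats::setNames(numeric(length(species)), species)
  try_tot <- cond$totals[["Try"]]
  apt_tot <- cond$totals[["Apt"]]
  init["TryApt"] <- min(try_tot, apt_tot)
  init["Try"] <- try_tot - init["TryApt"]
  init["Apt"] <- apt_tot - init["TryApt"]
  init["LBAPNA"] <- cond$totals[["LBAPNA"]]
  moieties <- list(
    Try_total = c(Try = 1, TryApt = 1),
    Apt_total = c(Apt = 1, TryApt = 1, AptFuel = 1),
    Substrate_total = c(LBAPNA = 1, pNA = 1)
  )
  new_reaction_network(cond$circuit_id, species, reactions, moieties, init,
                       cond, toehold_mode)
}

#' Build the coupled unidirectional network
#'
#' Union of the DNAzyme and trypsin cycles, linked by the inhibitor/trypsin-
#' fuel duplex: the active DNAzyme cleaves the inhibitor strand (competing
#' with the reporter for the DNAzyme active site, shared competitive
#' Michaelis-Menten denominator), T7 digests the cleaved inhibitor and
#' releases the trypsin fuel, and Exo III dissipates both the DNAzyme fuel
#' (from the active duplex) and the trypsin fuel (from the aptamer/fuel
#' duplex) through a shared competitive denominator. The uncleaved inhibitor
#' duplex is protected at both ends and is not a T7 substrate.
#'
#' @inheritParams build_dnazyme_cycle
#' @param cond a [condition()] with `circuit_id = "coupled"`; both enzyme
#'   loads must be present (they may be zero to model control experiments).
#' @return a `reaction_network` with 15 species and 11 reactions.
#' @export
build_coupled_network <- function(params, cond,
                                  toehold_mode = c("exponential", "cutoff")) {
  toehold_mode <- match.arg(toehold_mode)
  if (!inherits(cond, "circuit_condition")) stop("`cond` must be a condition()")
  if (cond$circuit_id != "coupled") {
    stop("build_coupled_network: circuit_id must be 'coupled'")
  }
  if (anyNA(cond$enzymes[c("exoIII", "t7")])) {
    stop("build_coupled_network: missing enzyme load")
  }
  if (cond$ref_conc <= 0) stop("non-positive reference concentration")
  species <- c("S1", "Fuel", "Dz", "Rep", "RepCleaved",
               "InhibDuplex", "InhibDuplexCleaved", "FuelTry",
               "TryApt", "Try", "Apt", "AptFuel", "LBAPNA", "pNA", "Waste")
  reactions <- list(
    rxn("hybridization", "mass_action",
        c(S1 = -1, Fuel = -1, Dz = 1),
        reactants = c(S1 = 1, Fuel = 1), k = "k_hyb_dz"),
    rxn("reporter_cleavage", "competitive_mm",
        c(Rep = -1, RepCleaved = 1),
        group = "dz", enzyme_species = "Dz", substrate = "Rep",
        kcat = "k_cat_rep", Km = "Km_rep"),
    rxn("inhibitor_cleavage", "competitive_mm",
        c(InhibDuplex = -1, InhibDuplexCleaved = 1),
        group = "dz", enzyme_species = "Dz", substrate = "InhibDuplex",
        kcat = "k_cat_inh", Km = "Km_inh"),
    rxn("inhibitor_digestion", "competitive_mm",
        c(InhibDuplexCleaved = -1, FuelTry = 1, Waste = 1),
        group = "t7", substrate = "InhibDuplexCleaved", Km = "Km_t7",
        L = 0L),
    rxn("complex_dissociation", "first_order",
        c(TryApt = -1, Try = 1, Apt = 1),
        species = "TryApt", k = "k_off_TA"),
    rxn("complex_formation", "mass_action",
        c(Try = -1, Apt = -1, TryApt = 1),
        reactants = c(Try = 1, Apt = 1), k = "k_on_TA"),
    rxn("fuel_displacement", "mass_action",
        c(TryApt = -1, FuelTry = -1, Try = 1, AptFuel = 1),
        reactants = c(TryApt = 1, FuelTry = 1), k = "k_disp"),
    rxn("fuel_hybridization", "mass_action",
        c(Apt = -1, FuelTry = -1, AptFuel = 1),
        reactants = c(Apt = 1, FuelTry = 1), k = "k_hyb_apt"),
    rxn("bapna_cleavage", "competitive_mm",
        c(LBAPNA = -1, pNA = 1),
        group = "try", enzyme_species = "Try", substrate = "LBAPNA",
        kcat = "k_cat_try", Km = "Km_try"),
    rxn("dz_fuel_digestion", "competitive_mm",
        c(Dz = -1, S1 = 1, Waste = 1),
        group = "exoIII", substrate = "Dz", Km = "Km_exo",
        L = cond$L_fuel),
    rxn("try_fuel_digestion", "competitive_mm",
        c(AptFuel = -1, Apt = 1, Waste = 1),
        group = "exoIII", substrate = "AptFuel", Km = "Km_exo",
        L = cond$L_tryfuel)
  )
  init <- stats::setNames(numeric(length(species)), species)
  init["S1"] <- cond$totals[["S1"]]
  init["Rep"] <- cond$totals[["Rep"]]
  init["InhibDuplex"] <- cond$totals[["InhibDuplex"]]
  try_tot <- cond$totals[["Try"]]
  apt_tot <- cond$totals[["Apt"]]
  init["TryApt"] <- min(try_tot, apt_tot)
  init["Try"] <- try_tot - init["TryApt"]
  init["Apt"] <- apt_tot - init["TryApt"]
  init["LBAPNA"] <- cond$totals[["LBAPNA"]]
  moieties <- list(
    S1_total = c(S1 = 1, Dz = 1),
    Rep_total = c(Rep = 1, RepCleaved = 1),
    Try_total = c(Try = 1, TryApt = 1),
    Apt_total = c(Apt = 1, TryApt = 1, AptFuel = 1),
    Substrate_total = c(LBAPNA = 1, pNA = 1)
  )
  new_reaction_network("coupled", species, reactions, moieties, init,
                       cond, toehold_mode)
}

#' Build the network for a condition's circuit
#'
#' Dispatches to the circuit-specific builder according to
#' `cond$circuit_id`.
#'
#' @inheritParams build_dnazyme_cycle
#' @return a `reaction_network`.
#' @export
build_network <- function(params, cond,
                          toehold_mode = c("exponential", "cutoff")) {
  toehold_mode <- match.arg(toehold_mode)
  switch(cond$circuit_id,
    dnazyme_exoIII = , dnazyme_t7 =
      build_dnazyme_cycle(params, cond, toehold_mode),
    trypsin_exoIII = , trypsin_t7 =
      build_trypsin_cycle(params, cond, toehold_mode),
    coupled = build_coupled_network(params, cond, toehold_mode),
    stop("unknown circuit_id: ", cond$circuit_id)
  )
}

## ---- rate evaluation ----------------------------------------------------

# Effective Vmax of an enzyme pool (exoIII/t7), including the unit
# conversion, toe-hold attenuation and optional waste inhibition.
pool_vmax <- function(group, L, net, params) {
  if (group == "exoIII") {
    params$c_exo * net$enzymes[["exoIII"]] *
      toehold_rate_factor(L, "exoIII", params, net$toehold_mode)
  } else {
    params$c_t7 * net$enzymes[["t7"]] *
      toehold_rate_factor(L, "t7", params, net$toehold_mode)
  }
}

#' Evaluate all reaction rates at a state
#'
#' Mass-action rates are `k * prod(conc^order)`. Competitive
#' Michaelis-Menten groups share a denominator `1 + sum_j S_j/Km_j` over all
#' substrates of the same enzyme; rates are
#' `E_eff * kcat_i * (S_i/Km_i) / denom`, with `E_eff` the catalytic species
#' concentration (DNAzyme, trypsin) or the converted enzyme load
#' `c * U * phi(L)` for the exonuclease pools. Finite `K_W` scales the
#' exonuclease pools by `1/(1 + [Waste]/K_W)`.
#'
#' @param net a `reaction_network`.
#' @param conc named non-negative state vector, uM.
#' @param params a [kinetic_params()] object.
#' @return named numeric vector of reaction rates, uM/min.
#' @export
network_rates <- function(net, conc, params) {
  rx <- net$reactions
  n <- length(rx)
  rates <- numeric(n)
  # state is clipped at zero for rate evaluation only; the integrator keeps
  # the true state (non-negativity is enforced by tolerance, not clipping)
  cc <- pmax(conc[net$species], 0)
  # shared denominators per competitive group
  denom <- list(dz = 1, try = 1, exoIII = 1, t7 = 1)
  for (r in rx) {
    if (r$type == "competitive_mm") {
      denom[[r$group]] <- denom[[r$group]] +
        cc[[r$substrate]] / params[[r$Km]]
    }
  }
  waste_fac <- if (is.finite(params$K_W) && "Waste" %in% net$species) {
    1 / (1 + cc[["Waste"]] / params$K_W)
  } else 1
  for (j in seq_len(n)) {
    r <- rx[[j]]
    rates[j] <- switch(r$type,
      mass_action = {
        v <- params[[r$k]]
        for (s in names(r$reactants)) v <- v * cc[[s]]^r$reactants[[s]]
        v
      },
      first_order = params[[r$k]] * cc[[r$species]],
      competitive_mm = {
        sat <- (cc[[r$substrate]] / params[[r$Km]]) / denom[[r$group]]
        if (r$group %in% c("exoIII", "t7")) {
          pool_vmax(r$group, r$L, net, params) * waste_fac * sat
        } else {
          params[[r$kcat]] * cc[[r$enzyme_species]] * sat
        }
      },
      stop("unknown rate-law type: ", r$type)
    )
  }
  names(rates) <- colnames(net$stoich)
  rates
}

#' Conserved-moiety residuals of a network
#'
#' Each declared moiety vector `v` must lie in the left null space of the
#' stoichiometry matrix: `v %*% N = 0` exactly (integer arithmetic).
#'
#' @param net a `reaction_network`.
#' @return named numeric vector: `max |v . N|` per declared moiety.
#' @export
moiety_residuals <- function(net) {
  vapply(net$moieties, function(v) {
    full <- stats::setNames(numeric(length(net$species)), net$species)
    full[names(v)] <- v
    max(abs(as.vector(full %*% net$stoich)))
  }, numeric(1))
}
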