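#' Stochastic simulation oracle (exact SSA)
#'
#' Gillespie's direct method on the same reaction network used by the
#' deterministic model. Michaelis-Menten rate laws are used as mean-field
#' propensities: the propensity of reaction `j` at count state `n` is the
#' deterministic rate evaluated at concentration `n / volume_scale`, times
#' `volume_scale`. This is a documented approximation (enzyme-substrate
#' intermediates are not expanded); the deterministic model is the object
#' under test and the SSA serves as its independent large-copy-number check.
#'
#' @param net a `reaction_network`.
#' @param params a [kinetic_params()] object.
#' @param init named initial state, uM; fuel present at `t = 0` (dosing
#'   schedules are not supported in the stochastic oracle).
#' @param volume_scale copies per uM; choose it so that relevant copy
#'   numbers are >= ~1e3.
#' @param t_end,dt_out output grid, min.
#' @param n_runs number of trajectories (>= 1).
#' @param seed RNG seed (required; runs are reproducible).
#' @return list with `time`, `mean` and `sd` (species x time matrices
#'   transposed to time x species), and `n_runs`.
#' @export
ssa_simulate <- function(net, params, init = net$init, volume_scale,
                         t_end, dt_out = 0.5, n_runs = 1, seed) {
  stopifnot(inherits(net, "reaction_network"), n_runs >= 1)
  init <- init[net$species]
  if (anyNA(init)) stop("ssa_simulate: init must cover all species")
  x0 <- round(init * volume_scale)
  if (any(init > 0 & x0 == 0)) {
    stop("ssa_simulate: zero-copy initial state for a required species; ",
         "increase volume_scale")
  }
  set.seed(seed)
  rate_fn <- compile_rate_fn(net, params)
  N <- net$stoich
  storage.mode(N) <- "double"
  m <- ncol(N)
  Ncols <- lapply(seq_len(m), function(j) N[, j])
  rexp_ <- stats::rexp
  runif_ <- stats::runif
  grid <- seq(0, t_end, by = dt_out)
  G <- length(grid)
  S <- length(net$species)
  acc <- matrix(0, nrow = G, ncol = S)
  acc2 <- matrix(0, nrow = G, ncol = S)
  inv_v <- 1 / volume_scale

  for (run in seq_len(n_runs)) {
    x <- as.numeric(x0)
    t <- 0
    gi <- 1L
    out <- matrix(0, nrow = G, ncol = S)
    repeat {
      a <- rate_fn(x * inv_v) * volume_scale
      a[a < 0] <- 0
      a0 <- sum(a)
      if (a0 <= 0) {
        t_next <- Inf
      } else {
        t_next <- t + rexp_(1, a0)
      }
      while (gi <= G && grid[gi] <= t_next) {
        out[gi, ] <- x
        gi <- gi + 1L
      }
      if (gi > G || is.infinite(t_next)) break
      t <- t_next
      j <- 1L + sum(runif_(1) * a0 > cumsum(a))
      x <- x + Ncols[[j]]
    }
    acc <- acc + out
    acc2 <- acc2 + out * out
  }
  mean_x <- acc / n_runs * inv_v
  var_x <- pmax(acc2 / n_runs - (acc / n_runs)^2, 0)
  sd_x <- sqrt(var_x) * inv_v
  colnames(mean_x) <- colnames(sd_x) <- net$species
  list(time = grid, mean = mean_x, sd = sd_x, n_runs = n_runs)
}
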