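#' Simulation parameters for the lattice ecosystem
#'
#' Bundles the ecological parameters of one run. Defaults are the study
#' conditions used throughout: a 100 x 100 lattice, 500 predators and 2000
#' prey initially, predator reproduction probability `bX = 0.8`, prey
#' reproduction probability `bY = 0.1`, initial food reserve 1 decaying by
#' 0.1 per MCS (so an unfed predator starves after 10 MCS), and a prey
#' maximum age of 100 MCS.
#'
#' @param L lattice linear size (sites); the lattice is `L x L` with
#'   periodic boundaries.
#' @param n_pred0,n_prey0 initial number of predators / prey.
#' @param bX probability that a predation event also produces a predator
#'   offspring on the captured site.
#' @param bY probability that a prey-empty pairing produces a prey offspring
#'   rather than a move.
#' @param fX_init initial (and post-meal) predator food reserve,
#'   dimensionless.
#' @param metabolic_decay food lost per predator per MCS.
#' @param prey_max_age maximum prey age in MCS; older prey die at the
#'   end-of-MCS ageing sweep.
#' @param T_total number of MCS to run.
#' @param seed integer RNG seed for the run.
#' @return An object of class `pp_sim_params` (a validated list).
#' @export
sim_params <- function(L = 100, n_pred0 = 500, n_prey0 = 2000,
                       bX = 0.8, bY = 0.1, fX_init = 1,
                       metabolic_decay = 0.1, prey_max_age = 100,
                       T_total = 20000, seed = 1) {
  p <- list(L = as.integer(L), n_pred0 = as.integer(n_pred0),
            n_prey0 = as.integer(n_prey0), bX = bX, bY = bY,
            fX_init = fX_init, metabolic_decay = metabolic_decay,
            prey_max_age = as.integer(prey_max_age),
            T_total = as.integer(T_total), seed = as.integer(seed))
  if (p$L < 3) stop("L must be at least 3")
  if (p$bX < 0 || p$bX > 1 || p$bY < 0 || p$bY > 1)
    stop("reproduction probabilities must lie in [0, 1]")
  if (p$n_pred0 < 0 || p$n_prey0 < 0)
    stop("initial counts must be non-negative")
  if (p$n_pred0 + p$n_prey0 > p$L^2)
    stop("overfull lattice: n_pred0 + n_prey0 exceeds L^2")
  if (p$metabolic_decay <= 0) stop("metabolic_decay must be positive")
  if (p$prey_max_age < 1) stop("prey_max_age must be at least 1")
  if (p$T_total < 0) stop("T_total must be non-negative")
  structure(p, class = "pp_sim_params")
}

#' @export
print.pp_sim_params <- function(x, ...) {
  cat(sprintf("Lattice %d x %d, %d predators / %d prey initially\n",
              x$L, x$L, x$n_pred0, x$n_prey0))
  cat(sprintf("bX = %g, bY = %g, food %g - %g/MCS, prey max age %d\n",
              x$bX, x$bY, x$fX_init, x$metabolic_decay, x$prey_max_age))
  cat(sprintf("T_total = %d MCS, seed = %d\n", x$T_total, x$seed))
  invisible(x)
}
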