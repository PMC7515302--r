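# World state: an environment holding the L x L occupancy grid (0 empty,
# 1 prey, 2 predator) and aligned per-site attribute matrices. Predator
# food is valid where grid == 2, prey age where grid == 1. Coordinates are
# 1-based (row, col); wrap arithmetic is modulo L.

SP_EMPTY <- 0L
SP_PREY <- 1L
SP_PRED <- 2L

new_world <- function(L) {
  w <- new.env(parent = emptyenv())
  w$L <- as.integer(L)
  w$grid <- matrix(SP_EMPTY, L, L)
  w$food <- matrix(0, L, L)
  w$age <- matrix(0L, L, L)
  w$mcs_clock <- 0L
  class(w) <- "pp_world"
  w
}

#' Initialize a world with randomly placed individuals
#'
#' Places exactly `n_pred0` predators and `n_prey0` prey on distinct,
#' uniformly random sites of an `L x L` periodic lattice. Every predator
#' starts with food reserve `fX_init`; every prey starts at age 0. Consumes
#' the current R RNG stream (seed the run with [set.seed()] or via
#' [run_case()]).
#'
#' @param params a [sim_params()] object.
#' @return A `pp_world` environment with fields `grid`, `food`, `age`,
#'   `mcs_clock`.
#' @export
init_world <- function(params) {
  stopifnot(inherits(params, "pp_sim_params"))
  w <- new_world(params$L)
  n <- params$n_pred0 + params$n_prey0
  if (n > 0) {
    sites <- sample.int(params$L^2, n)
    pred_sites <- sites[seq_len(params$n_pred0)]
    prey_sites <- sites[params$n_pred0 + seq_len(params$n_prey0)]
    w$grid[pred_sites] <- SP_PRED
    w$food[pred_sites] <- params$fX_init
    w$grid[prey_sites] <- SP_PREY
    w$age[prey_sites] <- 0L
  }
  w
}

#' Population counts of a world
#'
#' @param world a `pp_world`.
#' @return Named integer vector `c(predators = , prey = )`.
#' @export
world_counts <- function(world) {
  c(predators = sum(world$grid == SP_PRED),
    prey = sum(world$grid == SP_PREY))
}

#' Export the occupancy grid
#'
#' @param world a `pp_world`.
#' @param path optional file path; when given, the grid is written as a
#'   headerless CSV matrix (0 = empty, 1 = prey, 2 = predator).
#' @return The integer occupancy matrix (invisibly when written to file).
#' @export
export_grid <- function(world, path = NULL) {
  g <- world$grid + 0L  # detach from the live world
  if (!is.null(path)) {
    utils::write.table(g, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    return(invisible(g))
  }
  g
}

#' @export
print.pp_world <- function(x, ...) {
  n <- world_counts(x)
  cat(sprintf("pp_world %d x %d at MCS %d: %d predators, %d prey\n",
              x$L, x$L, x$mcs_clock, n[["predators"]], n[["prey"]]))
  invisible(x)
}

# deep copy (worlds are environments, mutated in place by the engine)
clone_world <- function(world) {
  w <- new_world(world$L)
  w$grid[] <- world$grid
  w$food[] <- world$food
  w$age[] <- world$age
  w$mcs_clock <- world$mcs_clock
  w
}
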