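# Monte Carlo stepping: thin R wrappers over the C++ engine. One MCS is
# L*L sequential pairwise trials followed by one metabolism/ageing sweep;
# interactions mutate the lattice asynchronously (in real time).

#' The nine agent actions
#'
#' Actions 1..8 map bijectively onto the Moore offsets; action 9 is
#' stand-still.
#'
#' @return Named list: `names` (action labels in index order) and `offsets`
#'   (9 x 2 matrix of (drow, dcol)).
#' @export
pp_actions <- function() {
  list(names = c("up", "down", "left", "right", "up-left", "up-right",
                 "down-left", "down-right", "stand-still"),
       offsets = matrix(c(-1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L, -1L, -1L,
                          -1L, 1L, 1L, -1L, 1L, 1L, 0L, 0L),
                        ncol = 2, byrow = TRUE,
                        dimnames = list(NULL, c("drow", "dcol"))))
}

#' Event kinds recorded in the trial log
#'
#' @return Character vector indexed by the integer codes used in the
#'   `EventLog` matrices.
#' @export
event_kinds <- function() {
  c("move", "predation_birth", "predation_move", "prey_birth",
    "prey_move", "blocked", "noop")
}

# periodic (wrapped) Chebyshev distance between two sites
wrap_chebyshev <- function(p1, p2, L) {
  d <- abs(p1 - p2)
  d <- pmin(d, L - d)
  as.integer(max(d))
}

#' Apply one pairwise interaction rule
#'
#' Applies exactly one stochastic interaction rule to a site and one of its
#' Moore neighbours (under periodic wrap), mutating the world in place:
#' predator + empty moves the predator; predator + prey removes the prey,
#' restores the predator's food reserve and with probability `bX` places a
#' newborn predator on the captured site (otherwise the predator moves
#' there); prey + empty places a newborn prey with probability `bY`
#' (otherwise the prey moves). Any other pairing - an empty first site or
#' two agents that cannot interact - changes nothing.
#'
#' @param world a `pp_world` (mutated in place).
#' @param params a [sim_params()].
#' @param site,neighbor 1-based `(row, col)` coordinates; `neighbor` must
#'   be one of the 8 Moore neighbours of `site` under periodic wrap.
#' @return An event record: list with `kind` (see [event_kinds()]) and
#'   `sites` (2 x 2 matrix of the coordinates involved).
#' @export
interact <- function(world, params, site, neighbor) {
  if (wrap_chebyshev(site, neighbor, world$L) != 1L)
    stop("neighbor is not a Moore neighbour of site under periodic wrap")
  kind <- cpp_interact(world$grid, world$food, world$age,
                       params$bX, params$bY, params$fX_init,
                       site[1], site[2], neighbor[1], neighbor[2])
  list(kind = event_kinds()[kind],
       sites = rbind(site = as.integer(site),
                     neighbor = as.integer(neighbor)))
}

#' Metabolism and ageing sweep
#'
#' The end-of-MCS bookkeeping applied once per MCS after the `L*L` trials:
#' every predator's food reserve drops by `metabolic_decay` and predators
#' at (numerically) zero reserve starve; every prey ages by one MCS and
#' prey older than `prey_max_age` die. Mutates the world in place.
#'
#' @inheritParams interact
#' @return The world, invisibly.
#' @export
apply_metabolism_and_age <- function(world, params) {
  cpp_apply_metabolism(world$grid, world$food, world$age,
                       params$metabolic_decay, params$prey_max_age)
  invisible(world)
}

#' Run one Monte Carlo step
#'
#' Performs `L*L` sequential trials. Each trial picks a uniformly random
#' site; a non-learning occupant interacts with a uniformly random Moore
#' neighbour, while a learning agent (a species with a behaviour policy
#' attached) interacts with the site designated by its epsilon-greedy
#' action (stand-still is a no-op). After the trials the metabolism/ageing
#' sweep runs and the MCS clock advances by one.
#'
#' @param world a `pp_world` (mutated in place).
#' @param params a [sim_params()].
#' @param pred_policy,prey_policy optional folded behaviour policies from
#'   [fold_policy()]; `NULL` means the species acts by the base random
#'   rules.
#' @param collect_pred,collect_prey collect experience tuples for the
#'   learning species?
#' @param record_log keep the per-trial `EventLog`? (exactly `L*L` records
#'   per MCS).
#' @return List with `counts` (post-MCS populations), `log` (matrix with
#'   columns kind, r1, c1, r2, c2, or `NULL`), and `transitions` (per
#'   species: `s`/`s2` as `npix x n` code matrices with one column per
#'   experience tuple, plus `a`, `r`, `terminal` vectors; `NULL` when not
#'   collected).
#' @export
mcs_step <- function(world, params, pred_policy = NULL, prey_policy = NULL,
                     collect_pred = FALSE, collect_prey = FALSE,
                     record_log = FALSE) {
  res <- cpp_run_mcs(world$grid, world$food, world$age,
                     params$bX, params$bY, params$fX_init,
                     params$metabolic_decay, params$prey_max_age, 1L,
                     pred_policy, prey_policy,
                     collect_pred, collect_prey, record_log)
  world$mcs_clock <- world$mcs_clock + 1L
  log <- NULL
  if (record_log) {
    log <- res$log
    colnames(log) <- c("kind", "r1", "c1", "r2", "c2")
  }
  list(counts = c(predators = res$series[1, 1], prey = res$series[1, 2]),
       log = log,
       transitions = list(pred = res$trans_pred, prey = res$trans_prey))
}

#' Run many MCS of the pure (non-learning) lattice model
#'
#' Fast path for the baseline ecosystem: loops entirely in compiled code.
#'
#' @inheritParams mcs_step
#' @param n_mcs number of MCS to run.
#' @return Integer matrix with one row per completed MCS and columns
#'   `n_predators`, `n_prey` (truncated early only if both species reach
#'   total extinction).
#' @export
run_lattice <- function(world, params, n_mcs,
                        pred_policy = NULL, prey_policy = NULL) {
  res <- cpp_run_mcs(world$grid, world$food, world$age,
                     params$bX, params$bY, params$fX_init,
                     params$metabolic_decay, params$prey_max_age,
                     as.integer(n_mcs), pred_policy, prey_policy,
                     FALSE, FALSE, FALSE)
  world$mcs_clock <- world$mcs_clock + res$mcs_done
  out <- res$series[seq_len(res$mcs_done), , drop = FALSE]
  colnames(out) <- c("n_predators", "n_prey")
  out
}
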