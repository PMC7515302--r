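#' Run one simulation case
#'
#' Wires the lattice ecosystem, the perception/reward layer and the DQN
#' machinery according to a [case_config()] and runs it for
#' `sim$T_total` MCS. In `"evolve"` mode each learning species gets a fresh
#' Q-network, a population replay buffer, and the training cadence of its
#' [training_schedule()]: learning activates at `start_mcs`, the behaviour
#' policy is epsilon-greedy with the annealed exploration rate, one
#' gradient step runs per MCS once the buffer holds a minibatch, and the
#' Bellman target network plus the folded behaviour policy refresh every
#' `train_period` MCS. In `"apply_frozen"` mode both species act by the
#' base random rules for `random_phase_mcs` MCS, then the frozen networks
#' drive behaviour at exploration `eps_apply` with no parameter updates.
#'
#' The whole run consumes a single seeded RNG stream
#' (`set.seed(sim$seed)`), so repeated runs are bit-identical.
#'
#' @param config a [case_config()].
#' @param snapshot_mcs integer MCS values (0 = initial state) at which to
#'   keep a copy of the occupancy grid.
#' @param vr observation window size for learning agents.
#' @return A `pp_run`: list with `series` (data frame `mcs`,
#'   `n_predators`, `n_prey`, including the initial state at MCS 0),
#'   `extinction` (first MCS each species hit zero, `NA` if never),
#'   `snapshots`, `networks`, `loss` (per-species per-MCS training loss),
#'   `mcs_done`, and the `config`.
#' @export
run_case <- function(config, snapshot_mcs = integer(), vr = 9) {
  stopifnot(inherits(config, "pp_case"))
  sim <- config$sim
  Tt <- sim$T_total
  snapshot_mcs <- sort(unique(as.integer(snapshot_mcs)))
  if (length(snapshot_mcs) && any(snapshot_mcs < 0L | snapshot_mcs > Tt))
    stop("snapshot_mcs beyond the run horizon")

  set.seed(sim$seed)
  world <- init_world(sim)
  n0 <- world_counts(world)
  series <- matrix(0L, Tt, 2)
  snapshots <- list()
  if (0L %in% snapshot_mcs) snapshots[["0"]] <- export_grid(world)

  run_chunk <- function(n, pol_pred, pol_prey, cp, cy) {
    cpp_run_mcs(world$grid, world$food, world$age, sim$bX, sim$bY,
                sim$fX_init, sim$metabolic_decay, sim$prey_max_age,
                as.integer(n), pol_pred, pol_prey, cp, cy, FALSE)
  }

  sp <- list()
  if (config$mode == "evolve") {
    for (nm in c("pred", "prey")) {
      sch <- config[[paste0(nm, "_learning")]]
      if (!is.null(sch)) {
        net <- build_qnetwork(vr)
        sp[[nm]] <- list(sch = sch, net = net, target = qnet_clone(net),
                         buffer = replay_buffer(sch$replay_capacity, vr * vr,
                                                nm),
                         fold = NULL, loss = rep(NA_real_, Tt))
      }
    }
  }
  frozen_folds <- list(pred = NULL, prey = NULL)

  mcs <- 0L
  truncated <- FALSE
  while (mcs < Tt && !truncated) {
    if (config$mode == "apply_frozen") {
      in_random_phase <- mcs < config$random_phase_mcs
      if (!in_random_phase && is.null(frozen_folds$pred) &&
          is.null(frozen_folds$prey)) {
        for (nm in c("pred", "prey"))
          if (!is.null(config$frozen[[nm]]))
            frozen_folds[[nm]] <- fold_policy(config$frozen[[nm]],
                                              config$eps_apply)
      }
      bounds <- c(Tt, snapshot_mcs[snapshot_mcs > mcs],
                  if (in_random_phase) config$random_phase_mcs)
      chunk <- min(bounds) - mcs
      res <- run_chunk(chunk,
                       if (in_random_phase) NULL else frozen_folds$pred,
                       if (in_random_phase) NULL else frozen_folds$prey,
                       FALSE, FALSE)
      series[mcs + seq_len(res$mcs_done), ] <-
        res$series[seq_len(res$mcs_done), ]
      mcs <- mcs + res$mcs_done
      if (res$mcs_done < chunk) truncated <- TRUE
    } else {
      active <- names(sp)[vapply(sp, function(s) mcs >= s$sch$start_mcs,
                                 logical(1))]
      if (length(active) == 0) {
        bounds <- c(Tt, snapshot_mcs[snapshot_mcs > mcs],
                    unlist(lapply(sp, function(s)
                      if (s$sch$start_mcs > mcs) s$sch$start_mcs)))
        chunk <- min(bounds) - mcs
        res <- run_chunk(chunk, NULL, NULL, FALSE, FALSE)
        series[mcs + seq_len(res$mcs_done), ] <-
          res$series[seq_len(res$mcs_done), ]
        mcs <- mcs + res$mcs_done
        if (res$mcs_done < chunk) truncated <- TRUE
      } else {
        for (nm in active) {
          s <- sp[[nm]]
          steps <- mcs - s$sch$start_mcs
          eps <- epsilon_at(s$sch, steps)
          if (is.null(s$fold) || steps %% s$sch$train_period == 0L) {
            if (steps > 0L) qnet_copy_params(s$target, s$net)
            sp[[nm]]$fold <- fold_policy(s$net, eps)
          } else {
            sp[[nm]]$fold$eps <- eps
          }
        }
        res <- run_chunk(1L, sp$pred$fold, sp$prey$fold,
                         "pred" %in% active, "prey" %in% active)
        mcs <- mcs + 1L
        series[mcs, ] <- res$series[1, ]
        for (nm in active) {
          s <- sp[[nm]]
          record_experience(s$buffer,
                            if (nm == "pred") res$trans_pred else res$trans_prey)
          sw <- train_sweep(s$net, s$target, s$buffer, s$sch,
                            refresh_target = FALSE)
          sp[[nm]]$loss[mcs] <- sw$loss
        }
        if (res$series[1, 1] == 0L && res$series[1, 2] == 0L)
          truncated <- TRUE
      }
    }
    world$mcs_clock <- mcs
    if (mcs %in% snapshot_mcs)
      snapshots[[as.character(mcs)]] <- export_grid(world)
  }

  mcs_done <- mcs
  series_df <- data.frame(
    mcs = 0:mcs_done,
    n_predators = c(n0[["predators"]], series[seq_len(mcs_done), 1]),
    n_prey = c(n0[["prey"]], series[seq_len(mcs_done), 2]))
  first_zero <- function(x) {
    z <- which(x == 0L)
    if (length(z)) series_df$mcs[z[1]] else NA_integer_
  }
  networks <- if (config$mode == "evolve")
    list(pred = sp$pred$net, prey = sp$prey$net)
  else config$frozen
  structure(list(series = series_df,
                 extinction = list(predators = first_zero(series_df$n_predators),
                                   prey = first_zero(series_df$n_prey)),
                 snapshots = snapshots,
                 networks = networks,
                 loss = list(pred = sp$pred$loss, prey = sp$prey$loss),
                 mcs_done = mcs_done, truncated = truncated,
                 config = config, world = world),
            class = "pp_run")
}

#' @export
print.pp_run <- function(x, ...) {
  cat(sprintf("pp_run: %d MCS%s, final %d predators / %d prey\n",
              x$mcs_done, if (x$truncated) " (total extinction)" else "",
              utils::tail(x$series$n_predators, 1),
              utils::tail(x$series$n_prey, 1)))
  invisible(x)
}
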