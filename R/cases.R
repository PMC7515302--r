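#' Configuration of one simulation case
#'
#' One experiment wiring: which species learn, when they start, how often
#' they train, and whether networks evolve during the run (`"evolve"`) or
#' previously trained networks are applied frozen (`"apply_frozen"`). In
#' the frozen mode the ecosystem runs by the base random rules for
#' `random_phase_mcs` MCS, after which the frozen networks drive behaviour
#' at a fixed exploration rate `eps_apply` with no parameter updates.
#'
#' @param sim a [sim_params()].
#' @param pred_learning,prey_learning `NULL` (species does not learn) or a
#'   [training_schedule()] carrying `start_mcs` and `train_period`.
#' @param mode `"evolve"` or `"apply_frozen"`.
#' @param frozen for `apply_frozen`: list with optional `pred` and `prey`
#'   `pp_qnet`s to apply.
#' @param random_phase_mcs MCS of random behaviour before frozen networks
#'   take over.
#' @param eps_apply fixed exploration rate in frozen mode.
#' @return A `pp_case` list.
#' @export
case_config <- function(sim, pred_learning = NULL, prey_learning = NULL,
                        mode = c("evolve", "apply_frozen"), frozen = NULL,
                        random_phase_mcs = 1500, eps_apply = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "pp_sim_params"))
  for (sch in list(pred_learning, prey_learning))
    if (!is.null(sch) && !inherits(sch, "pp_schedule"))
      stop("learning specs must be training_schedule() objects or NULL")
  if (mode == "apply_frozen") {
    if (is.null(frozen) || (is.null(frozen$pred) && is.null(frozen$prey)))
      stop("apply_frozen mode requires at least one frozen network")
    for (net in frozen)
      if (!is.null(net) && !inherits(net, "pp_qnet"))
        stop("frozen networks must be pp_qnet objects")
    if (!is.null(pred_learning) || !is.null(prey_learning))
      stop("apply_frozen mode does not update networks; drop the learning specs")
  }
  structure(list(sim = sim, pred_learning = pred_learning,
                 prey_learning = prey_learning, mode = mode,
                 frozen = frozen,
                 random_phase_mcs = as.integer(random_phase_mcs),
                 eps_apply = eps_apply),
            class = "pp_case")
}

#' The eight standard learning / no-learning cases
#'
#' The case matrix studied with the default ecosystem: who learns, when
#' each species starts, and each species' training period (MCS).
#'
#' * case0 - no learning (baseline ecology)
#' * case1 - predators only (start 0, period 50)
#' * case2 - prey only (start 0, period 50)
#' * case3 - co-evolution (both start 0, period 50)
#' * case4 - predators start 0, prey start 500
#' * case5 - prey start 0, predators start 500
#' * case6 - predator period 50, prey period 100
#' * case7 - predator period 100, prey period 50
#'
#' @param sim a [sim_params()] shared by all cases.
#' @param ... further arguments (e.g. `eps_anneal_steps`) passed to every
#'   [training_schedule()].
#' @return Named list of eight `pp_case` objects.
#' @export
table_cases <- function(sim = sim_params(), ...) {
  sch <- function(start, period) training_schedule(start_mcs = start,
                                                   train_period = period, ...)
  list(
    case0 = case_config(sim),
    case1 = case_config(sim, pred_learning = sch(0, 50)),
    case2 = case_config(sim, prey_learning = sch(0, 50)),
    case3 = case_config(sim, pred_learning = sch(0, 50),
                        prey_learning = sch(0, 50)),
    case4 = case_config(sim, pred_learning = sch(0, 50),
                        prey_learning = sch(500, 50)),
    case5 = case_config(sim, pred_learning = sch(500, 50),
                        prey_learning = sch(0, 50)),
    case6 = case_config(sim, pred_learning = sch(0, 50),
                        prey_learning = sch(0, 100)),
    case7 = case_config(sim, pred_learning = sch(0, 100),
                        prey_learning = sch(0, 50)))
}
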