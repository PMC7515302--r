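#' Training schedule and hyperparameters for one species
#'
#' Collects everything that governs when and how a species learns.
#' Defaults follow the study conditions: discount `gamma = 0.95`, Adam
#' learning rate 0.01, minibatch size 32, training period 50 MCS, and an
#' epsilon-greedy behaviour policy annealed linearly from 1 to 0.05.
#'
#' The training cadence is: one gradient step per MCS once the replay
#' buffer holds a full minibatch, with the Bellman target network and the
#' folded behaviour policy refreshed every `train_period` MCS. Rewards are
#' divided by `reward_scale` before entering the Bellman target so that
#' targets stay within reach of the tanh-bounded Q-values.
#'
#' @param gamma discount factor in `[0, 1]`.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param train_period MCS between target-network / behaviour-policy
#'   refreshes.
#' @param updates_per_sweep gradient steps per training sweep.
#' @param start_mcs MCS at which this species begins learning.
#' @param eps_start,eps_end,eps_anneal_steps linear exploration schedule:
#'   epsilon falls from `eps_start` to `eps_end` over `eps_anneal_steps`
#'   MCS after `start_mcs`, then stays at `eps_end`.
#' @param reward_scale divisor applied to raw rewards before the target.
#' @param replay_capacity population replay memory size (transitions).
#' @param loss_type `"pseudo_huber"` (default, `sqrt(1+e^2)-1`) or
#'   `"squared"`.
#' @return A `pp_schedule` list.
#' @export
training_schedule <- function(gamma = 0.95, lr = 0.01, batch_size = 32,
                              train_period = 50, updates_per_sweep = 1,
                              start_mcs = 0, eps_start = 1, eps_end = 0.05,
                              eps_anneal_steps = 10000, reward_scale = 100,
                              replay_capacity = 10000,
                              loss_type = c("pseudo_huber", "squared")) {
  loss_type <- match.arg(loss_type)
  s <- list(gamma = gamma, lr = lr, batch_size = as.integer(batch_size),
            train_period = as.integer(train_period),
            updates_per_sweep = as.integer(updates_per_sweep),
            start_mcs = as.integer(start_mcs), eps_start = eps_start,
            eps_end = eps_end, eps_anneal_steps = as.integer(eps_anneal_steps),
            reward_scale = reward_scale,
            replay_capacity = as.integer(replay_capacity),
            loss_type = loss_type)
  if (s$gamma < 0 || s$gamma > 1) stop("gamma must lie in [0, 1]")
  if (s$eps_end > s$eps_start) stop("eps_end must not exceed eps_start")
  if (s$train_period < 1) stop("train_period must be >= 1")
  if (s$batch_size < 1) stop("batch_size must be >= 1")
  if (s$replay_capacity < s$batch_size)
    stop("replay_capacity must hold at least one minibatch")
  if (s$start_mcs < 0) stop("start_mcs must be >= 0")
  structure(s, class = "pp_schedule")
}

#' Exploration rate at a given training step
#'
#' Linear interpolation from `eps_start` to `eps_end` over
#' `eps_anneal_steps`, constant at `eps_end` thereafter.
#'
#' @param schedule a [training_schedule()].
#' @param steps_elapsed MCS elapsed since this species started learning.
#' @return Exploration probability.
#' @export
epsilon_at <- function(schedule, steps_elapsed) {
  frac <- pmin(1, pmax(0, steps_elapsed / schedule$eps_anneal_steps))
  schedule$eps_start + (schedule$eps_end - schedule$eps_start) * frac
}
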