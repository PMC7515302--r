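#' Bellman targets for a batch of transitions
#'
#' `y = r/reward_scale + gamma * max_a' Q(s', a'; theta_prev)` for
#' non-terminal transitions and `y = r/reward_scale` for terminal ones,
#' where `theta_prev` is the lagged target copy of the parameters.
#'
#' @param r raw rewards (vector).
#' @param s_next next observations (`B x vr^2` code matrix, `pp_obs`, or
#'   code vector for a single transition).
#' @param terminal 0/1 terminal flags.
#' @param target_net the lagged `pp_qnet`.
#' @param gamma discount factor.
#' @param reward_scale divisor applied to `r`.
#' @return Numeric vector of targets.
#' @export
bellman_target <- function(r, s_next, terminal, target_net, gamma,
                           reward_scale = 100) {
  q2 <- qnet_predict(target_net, s_next)
  maxq <- apply(q2, 1, max)
  r / reward_scale + gamma * (1 - as.numeric(terminal)) * maxq
}

#' Training loss between targets and predicted Q-values
#'
#' The pseudo-Huber penalty `mean(sqrt(1 + (y - q)^2) - 1)`: quadratic for
#' small residuals, asymptotically linear for large ones. A plain squared
#' error `mean((y - q)^2)` is selectable.
#'
#' @param y targets.
#' @param q predicted Q-values for the taken actions.
#' @param loss_type `"pseudo_huber"` or `"squared"`.
#' @return Scalar mean loss over the minibatch.
#' @export
qnet_loss <- function(y, q, loss_type = c("pseudo_huber", "squared")) {
  loss_type <- match.arg(loss_type)
  e <- y - q
  if (loss_type == "pseudo_huber") mean(sqrt(1 + e^2) - 1) else mean(e^2)
}

#' One training sweep of a species Q-network
#'
#' Performs `updates_per_sweep` Adam steps on minibatches sampled
#' uniformly from the replay memory, minimizing [qnet_loss()] against
#' [bellman_target()] targets built from `target_net`. If the buffer does
#' not yet hold a full minibatch the sweep is skipped (not an error). By
#' default the target parameters are refreshed to the updated parameters
#' at the end of the sweep; the experiment driver instead refreshes
#' targets on its own `train_period` cadence.
#'
#' @param net the live `pp_qnet` (mutated in place).
#' @param target_net the lagged target `pp_qnet`.
#' @param buffer a `pp_replay`.
#' @param schedule a [training_schedule()].
#' @param refresh_target copy the updated parameters into `target_net`
#'   when the sweep completes?
#' @return List with `skipped` (logical) and `loss` (mean minibatch loss
#'   over the sweep, `NA` if skipped).
#' @export
train_sweep <- function(net, target_net, buffer, schedule,
                        refresh_target = TRUE) {
  if (buffer_size(buffer) < schedule$batch_size)
    return(list(skipped = TRUE, loss = NA_real_))
  loss_code <- if (schedule$loss_type == "pseudo_huber") 0L else 1L
  losses <- numeric(schedule$updates_per_sweep)
  for (u in seq_len(schedule$updates_per_sweep)) {
    batch <- sample_transitions(buffer, schedule$batch_size)
    y <- bellman_target(batch$r, batch$s2, batch$terminal, target_net,
                        schedule$gamma, schedule$reward_scale)
    net$adam_t <- net$adam_t + 1L
    losses[u] <- cpp_qnet_train_step(net$params, net$adam_m, net$adam_v,
                                     net$adam_t, batch$s, batch$a, y,
                                     net$vr, schedule$lr, loss_code,
                                     QNET_BN_MOMENTUM)
  }
  if (refresh_target) qnet_copy_params(target_net, net)
  list(skipped = FALSE, loss = mean(losses))
}
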