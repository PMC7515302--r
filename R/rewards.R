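#' State reward of a predator
#'
#' Shell-shaped reward encouraging predators towards nearby prey: prey in
#' the first Chebyshev shell are worth 20 each, in the second shell 10 each,
#' and 1 each in any farther shell. If no prey is visible anywhere in the
#' window the reward is -10.
#'
#' @param shells a `pp_shells` from [shell_counts()] (or a list with a
#'   `prey` count vector).
#' @return Scalar reward.
#' @export
predator_reward <- function(shells) {
  n <- shells$prey
  if (sum(n) == 0) return(-10)
  coef <- c(20, 10, rep(1, max(0, length(n) - 2)))[seq_along(n)]
  sum(coef * n)
}

#' State reward of a prey
#'
#' Penalises nearby predators: -10 per predator in the first Chebyshev
#' shell and -1 per predator in the second; farther shells are ignored.
#' When no predator is visible anywhere in the window the reward is +10.
#'
#' @param shells a `pp_shells` from [shell_counts()] (or a list with a
#'   `pred` count vector).
#' @return Scalar reward.
#' @export
prey_reward <- function(shells) {
  n <- shells$pred
  if (sum(n) == 0) return(10)
  -10 * n[1] - if (length(n) >= 2) n[2] else 0
}
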