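# Independent oracles and scenario builders shared across the suite.
# Every oracle here is deliberately written by brute force / enumeration,
# not by calling the code paths it checks.

# Brute-force Chebyshev shell counting: plain double loop over window
# offsets, centre excluded.
brute_shell_counts <- function(window) {
  vr <- nrow(window)
  h <- vr %/% 2
  prey <- integer(h)
  pred <- integer(h)
  for (i in seq_len(vr)) {
    for (j in seq_len(vr)) {
      if (i == h + 1 && j == h + 1) next
      k <- max(abs(i - h - 1), abs(j - h - 1))
      if (window[i, j] == 1) prey[k] <- prey[k] + 1
      if (window[i, j] == 2) pred[k] <- pred[k] + 1
    }
  }
  list(prey = prey, pred = pred)
}

# Brute-force periodic window extraction by explicit modular arithmetic.
brute_window <- function(grid, pos, vr) {
  L <- nrow(grid)
  h <- vr %/% 2
  win <- matrix(0L, vr, vr)
  for (i in seq_len(vr)) {
    for (j in seq_len(vr)) {
      r <- ((pos[1] - 1 + i - h - 1) %% L) + 1
      c <- ((pos[2] - 1 + j - h - 1) %% L) + 1
      win[i, j] <- grid[r, c]
    }
  }
  win
}

# Periodic Chebyshev distance by explicit minimisation over image copies.
brute_wrap_chebyshev <- function(p1, p2, L) {
  best <- Inf
  for (dr in c(-L, 0, L)) {
    for (dc in c(-L, 0, L)) {
      best <- min(best, max(abs(p1[1] - (p2[1] + dr)),
                            abs(p1[2] - (p2[2] + dc))))
    }
  }
  best
}

# Tabular Q-value iteration on a small deterministic MDP.
# trans[s, a] = next state, rew[s, a] = immediate reward.
tabular_q_iteration <- function(trans, rew, gamma, iters = 2000) {
  ns <- nrow(trans)
  na <- ncol(trans)
  Q <- matrix(0, ns, na)
  for (it in seq_len(iters)) {
    V <- apply(Q, 1, max)
    Q <- rew + gamma * matrix(V[trans], ns, na)
  }
  Q
}

# Plain-R inference-mode forward pass of the Q-network, written
# independently of the compiled implementation (loops, no reshaping
# tricks). codes: row-major window codes of ONE observation.
r_qnet_forward <- function(params, codes, vr) {
  bn <- function(x, g, be, mu, va) g / sqrt(va + 1e-5) * (x - mu) + be
  relu <- function(x) pmax(x, 0)
  npix <- vr * vr
  H2 <- matrix(0, npix, ncol(params$W2))
  for (p in seq_len(npix)) {
    x <- c(codes[p] == 1, codes[p] == 2) + 0
    h1 <- relu(bn(drop(x %*% params$W1) + params$b1, params$g1, params$be1,
                  params$mu1, params$va1))
    H2[p, ] <- relu(bn(drop(h1 %*% params$W2) + params$b2, params$g2,
                       params$be2, params$mu2, params$va2))
  }
  f <- as.vector(t(H2))  # pixel-major, channel fastest
  h3 <- relu(bn(drop(f %*% params$W3) + params$b3, params$g3, params$be3,
                params$mu3, params$va3))
  tanh(drop(h3 %*% params$W4) + params$b4)
}

# A vr x vr observation window built from offset placements:
# offsets is a data frame with columns drow, dcol, code.
make_window <- function(vr, center_code = 2L, offsets = NULL) {
  h <- vr %/% 2
  win <- matrix(0L, vr, vr)
  win[h + 1, h + 1] <- as.integer(center_code)
  if (!is.null(offsets)) {
    for (i in seq_len(nrow(offsets))) {
      win[h + 1 + offsets$drow[i], h + 1 + offsets$dcol[i]] <-
        as.integer(offsets$code[i])
    }
  }
  win
}

# A hand-built behaviour policy (the folded-list form consumed by the
# engine) whose Q-values are constant per action: q = tanh(b4).
constant_policy <- function(b4, vr = 9, eps = 0, nh = 4) {
  npix <- vr * vr
  list(vr = as.integer(vr), base = numeric(nh), D1 = matrix(0, npix, nh),
       D2 = matrix(0, npix, nh), W4 = matrix(0, nh, length(b4)),
       b4 = as.numeric(b4), eps = eps)
}

# random small test world
random_world <- function(L, n_pred, n_prey, seed) {
  set.seed(seed)
  init_world(sim_params(L = L, n_pred0 = n_pred, n_prey0 = n_prey,
                        T_total = 0))
}
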