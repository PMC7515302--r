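test_that("the Q-network maps a window to bounded per-action values", {
  set.seed(31)
  net <- build_qnetwork(9)
  obs <- matrix(sample(0:2, 5 * 81, replace = TRUE), 5, 81)
  q <- qnet_predict(net, obs)
  expect_equal(dim(q), c(5L, 9L))
  expect_true(all(q > -1 & q < 1))

  # identical parameter seeds give identical networks
  set.seed(31)
  net2 <- build_qnetwork(9)
  expect_identical(net$params, net2$params)
  expect_identical(qnet_predict(net2, obs), q)
})

test_that("epsilon-greedy selection explores, exploits and breaks ties", {
  set.seed(32)
  net <- build_qnetwork(9)
  obs <- make_window(9, 2L)

  # eps = 1: uniform over the nine actions
  draws <- replicate(9000, select_action(net, obs, eps = 1))
  tab <- tabulate(draws, 9)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)

  # eps = 0 with one strictly maximal value: always that action
  net$params$W4[] <- 0
  net$params$b4 <- c(rep(0, 6), 0.5, 0, 0)
  expect_true(all(replicate(50, select_action(net, obs, eps = 0)) == 7))

  # eps = 0 with all values tied: uniform tie-breaking
  net$params$b4 <- rep(0, 9)
  draws <- replicate(9000, select_action(net, obs, eps = 0))
  tab <- tabulate(draws, 9)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("the exploration rate anneals linearly then stays at the floor", {
  sch <- training_schedule(eps_start = 1, eps_end = 0.05,
                           eps_anneal_steps = 10000)
  expect_equal(epsilon_at(sch, 0), 1)
  expect_equal(epsilon_at(sch, 10000), 0.05)
  expect_equal(epsilon_at(sch, 25000), 0.05)
  expect_equal(epsilon_at(sch, 5000), (1 + 0.05) / 2)
})

test_that("Bellman targets reduce correctly and match a by-hand forward", {
  set.seed(33)
  net <- build_qnetwork(3)
  s2 <- matrix(sample(0:2, 4 * 9, replace = TRUE), 4, 9)
  r <- c(20, -10, 0, 5)

  # gamma = 0: the scaled reward, whatever the next state
  expect_equal(bellman_target(r, s2, rep(0, 4), net, gamma = 0,
                              reward_scale = 100), r / 100)
  # terminal transitions: no bootstrap
  expect_equal(bellman_target(r, s2, rep(1, 4), net, gamma = 0.95,
                              reward_scale = 100), r / 100)
  # non-terminal: r/scale + gamma * max_a Q, against an independent
  # plain-R forward pass
  y <- bellman_target(r, s2, c(0, 0, 1, 0), net, gamma = 0.95,
                      reward_scale = 100)
  for (i in 1:4) {
    qi <- r_qnet_forward(net$params, s2[i, ], 3)
    yi <- r[i] / 100 + 0.95 * (if (i == 3) 0 else max(qi))
    expect_equal(y[i], yi, tolerance = 1e-10)
  }
})

test_that("the folded behaviour policy equals the inference forward pass", {
  set.seed(34)
  net <- build_qnetwork(9)
  # perturb BN statistics so the fold is non-trivial
  net$params$mu1 <- rnorm(32, 0, 0.1); net$params$va1 <- runif(32, 0.5, 2)
  net$params$mu3 <- rnorm(32, 0, 0.1); net$params$va3 <- runif(32, 0.5, 2)
  fold <- fold_policy(net, eps = 0)
  for (rep in 1:10) {
    codes <- sample(0:2, 81, replace = TRUE)
    expect_equal(predpreyRL:::cpp_policy_eval(fold, as.integer(codes)),
                 qnet_predict(net, matrix(codes, 1))[1, ], tolerance = 1e-10)
  }
})

test_that("the training loss has the stated shape", {
  expect_equal(qnet_loss(0.3, 0.3), 0)
  expect_equal(qnet_loss(1.7, 0.7), sqrt(2) - 1)
  e <- 1e5
  expect_equal(qnet_loss(e, 0) / e, 1, tolerance = 1e-4)  # asymptotically linear
  expect_equal(qnet_loss(c(1, 2), c(1, 1), loss_type = "squared"), 0.5)
})

test_that("analytic gradients match finite differences", {
  set.seed(35)
  net <- build_qnetwork(3)
  obs <- matrix(sample(0:2, 8 * 9, replace = TRUE), 8, 9)
  a <- sample(1:9, 8, replace = TRUE)
  y <- runif(8, -0.5, 0.5)
  lg <- predpreyRL:::cpp_qnet_loss_grads(net$params, obs, a, y, 3L, 0L)
  h <- 1e-6
  set.seed(36)
  for (nm in names(lg$grads)) {
    n_el <- length(net$params[[nm]])
    for (idx in sample(n_el, min(4, n_el))) {
      p_plus <- net$params
      p_plus[[nm]][idx] <- p_plus[[nm]][idx] + h
      p_minus <- net$params
      p_minus[[nm]][idx] <- p_minus[[nm]][idx] - h
      fd <- (predpreyRL:::cpp_qnet_batch_loss(p_plus, obs, a, y, 3L, 0L) -
             predpreyRL:::cpp_qnet_batch_loss(p_minus, obs, a, y, 3L, 0L)) /
        (2 * h)
      an <- lg$grads[[nm]][idx]
      expect_equal(an, fd, tolerance = 1e-3,
                   label = sprintf("grad %s[%d] analytic", nm, idx))
    }
  }
})

test_that("training contracts onto a singleton dataset", {
  set.seed(37)
  net <- build_qnetwork(3)
  target <- qnet_clone(net)
  buf <- replay_buffer(64, 9, "pred")
  s <- sample(0:2, 9, replace = TRUE)
  for (i in 1:64)
    record_experience(buf, list(s = s, a = 5L, r = 5, s2 = s, terminal = 1L))
  sch <- training_schedule(batch_size = 32, reward_scale = 100,
                           updates_per_sweep = 1)
  for (i in 1:400) sw <- train_sweep(net, target, buf, sch)
  expect_lt(sw$loss, 1e-4)
  # the fixed point Q(s, a) = y holds in the training regime (minibatch
  # BN statistics): the loss probed at the target is essentially zero
  probe <- matrix(rep(s, 32), 32, byrow = TRUE)
  expect_lt(predpreyRL:::cpp_qnet_batch_loss(net$params, probe, rep(5L, 32),
                                             rep(0.05, 32), 3L, 0L), 1e-5)
})

test_that("a zero learning rate leaves the parameters untouched", {
  set.seed(38)
  net <- build_qnetwork(3)
  target <- qnet_clone(net)
  before <- lapply(net$params, function(p) p * 1)
  buf <- replay_buffer(64, 9, "pred")
  for (i in 1:40)
    record_experience(buf, list(s = sample(0:2, 9, TRUE), a = 1L, r = 1,
                                s2 = sample(0:2, 9, TRUE), terminal = 0L))
  sch <- training_schedule(lr = 0, batch_size = 32)
  l1 <- train_sweep(net, target, buf, sch)$loss
  l2 <- train_sweep(net, target, buf, sch)$loss
  for (nm in c("W1", "W2", "W3", "W4", "g1", "g3", "be2", "b4"))
    expect_equal(net$params[[nm]], before[[nm]])
  expect_false(is.na(l1) || is.na(l2))
})

test_that("an underfilled buffer skips the sweep without error", {
  set.seed(39)
  net <- build_qnetwork(3)
  buf <- replay_buffer(64, 9, "prey")
  record_experience(buf, list(s = sample(0:2, 9, TRUE), a = 1L, r = 1,
                              s2 = sample(0:2, 9, TRUE), terminal = 0L))
  sw <- train_sweep(net, qnet_clone(net), buf, training_schedule())
  expect_true(sw$skipped)
  expect_true(is.na(sw$loss))
})

test_that("replay memory is a bounded species-routed FIFO", {
  buf <- replay_buffer(2, 9, "pred")
  for (i in 1:3)
    record_experience(buf, list(s = rep(i, 9), a = i, r = i, s2 = rep(i, 9),
                                terminal = 0L))
  expect_equal(buffer_size(buf), 2L)
  expect_setequal(buf$a[1:2], c(3L, 2L))  # the first insert was evicted
  expect_error(sample_transitions(buf, 3), "not enough")
  expect_error(record_experience(buf, list(s = rep(0, 4), a = 1L, r = 0,
                                           s2 = rep(0, 4), terminal = 0L)),
               "length")
})

test_that("each acting learner contributes exactly one stored transition", {
  # a single predator pinned by a stand-still policy: the number of stored
  # transitions must equal the number of trials that picked its site
  p <- sim_params(L = 6, n_pred0 = 0, n_prey0 = 0, fX_init = 100)
  w <- build_scenario(6, data.frame(row = 3, col = 4, species = "predator",
                                    food = 100))
  pol <- constant_policy(b4 = c(rep(0, 8), 1), eps = 0)
  set.seed(40)
  res <- mcs_step(w, p, pred_policy = pol, collect_pred = TRUE,
                  record_log = TRUE)
  hits <- sum(res$log[, "r1"] == 3 & res$log[, "c1"] == 4)
  expect_equal(length(res$transitions$pred$a), hits)
  expect_true(all(res$transitions$pred$a == 9L))
  buf <- replay_buffer(100, 81, "pred")
  record_experience(buf, res$transitions$pred)
  expect_equal(buffer_size(buf), hits)
})

test_that("a blocked action leaves the next observation unchanged", {
  # prey forced to step left into an occupied site: p(s|s,a) = 1 on failure
  p <- sim_params(L = 7, n_pred0 = 0, n_prey0 = 0, bY = 0)
  w <- build_scenario(7, data.frame(row = c(4, 4), col = c(4, 3),
                                    species = c("prey", "prey")))
  pol <- constant_policy(b4 = c(0, 0, 1, rep(0, 6)), vr = 7, eps = 0)
  set.seed(41)
  res <- mcs_step(w, p, prey_policy = pol, collect_prey = TRUE)
  tr <- res$transitions$prey
  expect_gt(length(tr$a), 0)
  h <- 3  # half window for vr = 7
  left_of_center <- h * 7 + h  # 1-based index of offset (0, -1)
  for (i in seq_along(tr$a)) {
    if (tr$s[left_of_center, i] != 0L) {
      expect_identical(tr$s2[, i], tr$s[, i])
    }
  }
})

test_that("targets stay within the representable tanh range after scaling", {
  # worst-case shell rewards over random windows, scaled by the default 100
  set.seed(42)
  sch <- training_schedule()
  worst <- 0
  for (rep in 1:200) {
    win <- matrix(sample(0:2, 81, TRUE), 9, 9)
    worst <- max(worst, abs(predator_reward(shell_counts(win))),
                 abs(prey_reward(shell_counts(win))))
  }
  bound <- worst / sch$reward_scale + sch$gamma
  expect_lt(worst / sch$reward_scale, 4)
  expect_true(bound < 5)  # pseudo-Huber keeps such residuals well-behaved
})

test_that("the greedy policy on a toy chain matches tabular Q-iteration", {
  # two observable states; action 4 (right) leads to the rewarding state,
  # every other action to the unrewarded one
  s_rew <- as.integer(t(make_window(3, 1L,
                                    data.frame(drow = -1, dcol = -1, code = 2))))
  s_poor <- as.integer(t(make_window(3, 1L)))
  states <- rbind(s_poor, s_rew)
  trans <- matrix(1L, 2, 9)
  trans[, 4] <- 2L
  rew <- matrix(0, 2, 9)
  rew[, 4] <- 1
  gamma <- 0.8
  q_tab <- tabular_q_iteration(trans, rew / 50, gamma)

  set.seed(43)
  net <- build_qnetwork(3)
  target <- qnet_clone(net)
  buf <- replay_buffer(400, 9, "pred")
  for (rep in 1:20)
    for (s in 1:2)
      for (a in 1:9)
        record_experience(buf, list(s = states[s, ], a = a, r = rew[s, a],
                                    s2 = states[trans[s, a], ],
                                    terminal = 0L))
  # wide minibatches keep the BN batch statistics close to the (tiny)
  # state distribution, so the inference-mode greedy policy is reliable
  sch <- training_schedule(gamma = gamma, batch_size = 128,
                           reward_scale = 50, lr = 0.005)
  for (i in 1:1200) train_sweep(net, target, buf, sch)
  q_net <- qnet_predict(net, states)
  expect_equal(unname(apply(q_net, 1, which.max)),
               unname(apply(q_tab, 1, which.max)))
  expect_equal(unname(apply(q_tab, 1, which.max)), c(4L, 4L))
})
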