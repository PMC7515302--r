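test_that("init_world places exactly the requested populations", {
  set.seed(1)
  w <- init_world(sim_params(L = 100, n_pred0 = 500, n_prey0 = 2000))
  expect_equal(sum(w$grid == 2), 500)
  expect_equal(sum(w$grid == 1), 2000)
  expect_equal(sum(w$grid == 0), 7500)
  expect_true(all(w$food[w$grid == 2] == 1))
  expect_true(all(w$age[w$grid == 1] == 0))

  w0 <- init_world(sim_params(L = 10, n_pred0 = 0, n_prey0 = 0))
  expect_true(all(w0$grid == 0))

  wf <- init_world(sim_params(L = 5, n_pred0 = 25, n_prey0 = 0))
  expect_equal(sum(wf$grid == 2), 25)
  expect_equal(sum(wf$grid == 0), 0)

  expect_error(sim_params(L = 5, n_pred0 = 20, n_prey0 = 6), "overfull")
})

test_that("interact applies each pairwise rule", {
  p <- sim_params(L = 5, n_pred0 = 0, n_prey0 = 0, bX = 1, bY = 1)

  # predator + empty: the predator moves
  w <- build_scenario(5, data.frame(row = 2, col = 2, species = "predator",
                                    food = 0.7))
  ev <- interact(w, p, c(2, 2), c(2, 3))
  expect_equal(ev$kind, "move")
  expect_equal(w$grid[2, 2], 0L)
  expect_equal(w$grid[2, 3], 2L)
  expect_equal(w$food[2, 3], 0.7)  # a plain move does not feed

  # predator + prey with bX = 1: offspring always born, parent stays
  w <- build_scenario(5, data.frame(row = c(2, 2), col = c(2, 3),
                                    species = c("predator", "prey")))
  ev <- interact(w, p, c(2, 2), c(2, 3))
  expect_equal(ev$kind, "predation_birth")
  expect_equal(w$grid[2, 2], 2L)
  expect_equal(w$grid[2, 3], 2L)
  expect_equal(w$food[2, 2], p$fX_init)  # meal restores the reserve
  expect_equal(w$food[2, 3], p$fX_init)  # newborn starts fresh

  # predator + prey with bX = 0: predation then move, food restored
  p0 <- sim_params(L = 5, n_pred0 = 0, n_prey0 = 0, bX = 0, bY = 0)
  w <- build_scenario(5, data.frame(row = c(2, 2), col = c(2, 3),
                                    species = c("predator", "prey"),
                                    food = c(0.3, NA)))
  ev <- interact(w, p0, c(2, 2), c(2, 3))
  expect_equal(ev$kind, "predation_move")
  expect_equal(w$grid[2, 2], 0L)
  expect_equal(w$grid[2, 3], 2L)
  expect_equal(w$food[2, 3], p0$fX_init)

  # prey + empty with bY = 1: newborn prey at age 0, parent stays
  w <- build_scenario(5, data.frame(row = 2, col = 2, species = "prey",
                                    age = 17))
  ev <- interact(w, p, c(2, 2), c(2, 3))
  expect_equal(ev$kind, "prey_birth")
  expect_equal(w$grid[2, 2], 1L)
  expect_equal(w$grid[2, 3], 1L)
  expect_equal(w$age[2, 3], 0L)
  expect_equal(w$age[2, 2], 17L)

  # prey + empty with bY = 0: the prey moves, keeping its age
  w <- build_scenario(5, data.frame(row = 2, col = 2, species = "prey",
                                    age = 17))
  ev <- interact(w, p0, c(2, 2), c(2, 3))
  expect_equal(ev$kind, "prey_move")
  expect_equal(w$age[2, 3], 17L)

  # failed pairings change nothing
  w <- build_scenario(5, data.frame(row = c(2, 2), col = c(2, 3),
                                    species = c("predator", "predator")))
  expect_equal(interact(w, p, c(2, 2), c(2, 3))$kind, "blocked")
  expect_equal(w$grid[2, 2], 2L)
  w <- build_scenario(5, data.frame(row = c(2, 2), col = c(2, 3),
                                    species = c("prey", "predator")))
  expect_equal(interact(w, p, c(2, 2), c(2, 3))$kind, "blocked")
  w <- build_scenario(5, data.frame(row = 2, col = 3, species = "prey"))
  expect_equal(interact(w, p, c(2, 2), c(2, 3))$kind, "noop")

  # non-neighbour pairs violate the contract
  w <- build_scenario(5, data.frame(row = 2, col = 2, species = "prey"))
  expect_error(interact(w, p, c(2, 2), c(2, 4)), "Moore")
})

test_that("sites on opposite edges are Moore-adjacent under periodic wrap", {
  p <- sim_params(L = 5, n_pred0 = 0, n_prey0 = 0)
  w <- build_scenario(5, data.frame(row = 1, col = 1, species = "predator"))
  expect_equal(brute_wrap_chebyshev(c(1, 1), c(5, 5), 5), 1)
  ev <- interact(w, p, c(1, 1), c(5, 5))
  expect_equal(ev$kind, "move")
  expect_equal(w$grid[5, 5], 2L)
})

test_that("reproduction frequencies match the Bernoulli rates", {
  n_rep <- 10000
  p <- sim_params(L = 5, n_pred0 = 0, n_prey0 = 0, bX = 0.8, bY = 0.1)
  set.seed(99)

  # prey + empty, bY = 0.1
  w <- build_scenario(5, data.frame(row = 2, col = 2, species = "prey"))
  births <- 0
  for (i in seq_len(n_rep)) {
    ev <- interact(w, p, c(2, 2), c(2, 3))
    if (ev$kind == "prey_birth") births <- births + 1
    w$grid[2, 3] <- 0L
    w$grid[2, 2] <- 1L
    w$age[2, 2] <- 0L
  }
  tol <- 4 * sqrt(0.1 * 0.9 / n_rep)
  expect_lt(abs(births / n_rep - 0.1), tol)

  # predator + prey, bX = 0.8
  w <- build_scenario(5, data.frame(row = c(2, 2), col = c(2, 3),
                                    species = c("predator", "prey")))
  births <- 0
  for (i in seq_len(n_rep)) {
    ev <- interact(w, p, c(2, 2), c(2, 3))
    if (ev$kind == "predation_birth") births <- births + 1
    w$grid[2, 2] <- 2L; w$food[2, 2] <- 1
    w$grid[2, 3] <- 1L; w$age[2, 3] <- 0L
  }
  tol <- 4 * sqrt(0.8 * 0.2 / n_rep)
  expect_lt(abs(births / n_rep - 0.8), tol)
})

test_that("an empty world is a fixed point and logs L^2 noop trials", {
  p <- sim_params(L = 6, n_pred0 = 0, n_prey0 = 0)
  w <- init_world(p)
  res <- mcs_step(w, p, record_log = TRUE)
  expect_equal(unname(res$counts), c(0L, 0L))
  expect_equal(nrow(res$log), 36L)
  expect_true(all(res$log[, "kind"] == which(event_kinds() == "noop")))
  expect_true(all(w$grid == 0L))
  expect_equal(w$mcs_clock, 1L)
})

test_that("a lone predator starves after exactly fX_init/decay MCS", {
  p <- sim_params(L = 5, n_pred0 = 0, n_prey0 = 0, fX_init = 1,
                  metabolic_decay = 0.1)
  set.seed(3)
  w <- build_scenario(5, data.frame(row = 3, col = 3, species = "predator",
                                    food = 1))
  alive_at <- integer(0)
  for (m in 1:12) {
    res <- mcs_step(w, p)
    if (res$counts[["predators"]] > 0) alive_at <- c(alive_at, m)
  }
  # ten decays of 0.1 exhaust a unit reserve: alive through MCS 9, gone at 10
  expect_equal(max(alive_at), 9L)
})

test_that("metabolism and ageing apply the boundary rules", {
  p <- sim_params(L = 5, n_pred0 = 0, n_prey0 = 0, metabolic_decay = 0.1,
                  prey_max_age = 100)
  w <- build_scenario(5, data.frame(
    row = c(1, 2, 3, 4), col = c(1, 1, 1, 1),
    species = c("predator", "predator", "prey", "prey"),
    food = c(1.0, 0.1, NA, NA), age = c(NA, NA, 100L, 42L)))
  apply_metabolism_and_age(w, p)
  expect_equal(w$food[1, 1], 0.9)        # 1.0 - 0.1
  expect_equal(w$grid[2, 1], 0L)         # 0.1 - 0.1 -> starved
  expect_equal(w$grid[3, 1], 0L)         # age 100 -> 101 > max
  expect_equal(w$age[4, 1], 43L)
  expect_equal(w$grid[4, 1], 1L)
})

test_that("population changes are fully explained by the event log", {
  # tiny decay and huge max age so only trial events change populations
  p <- sim_params(L = 8, n_pred0 = 10, n_prey0 = 20, bX = 0.8, bY = 0.3,
                  fX_init = 1000, metabolic_decay = 1e-6,
                  prey_max_age = 100000)
  set.seed(17)
  w <- init_world(p)
  for (m in 1:5) {
    before <- world_counts(w)
    res <- mcs_step(w, p, record_log = TRUE)
    kinds <- event_kinds()[res$log[, "kind"]]
    expect_equal(nrow(res$log), 64L)
    d_pred <- sum(kinds == "predation_birth")
    d_prey <- sum(kinds == "prey_birth") -
      sum(kinds %in% c("predation_birth", "predation_move"))
    expect_equal(res$counts[["predators"]], before[["predators"]] + d_pred)
    expect_equal(res$counts[["prey"]], before[["prey"]] + d_prey)
  }
})

test_that("without predators and bY = 0 the prey count never grows", {
  p <- sim_params(L = 10, n_pred0 = 0, n_prey0 = 30, bY = 0,
                  prey_max_age = 20)
  set.seed(5)
  w <- init_world(p)
  series <- run_lattice(w, p, 30)
  expect_true(all(diff(series[, "n_prey"]) <= 0))
  expect_true(all(series[, "n_predators"] == 0))
})

test_that("without prey all predators starve within fX_init/decay MCS", {
  p <- sim_params(L = 10, n_pred0 = 40, n_prey0 = 0, fX_init = 1,
                  metabolic_decay = 0.1)
  set.seed(6)
  w <- init_world(p)
  series <- run_lattice(w, p, ceiling(p$fX_init / p$metabolic_decay) + 1)
  expect_equal(series[ceiling(p$fX_init / p$metabolic_decay),
                      "n_predators"][[1]], 0L)
})

test_that("identical seeds give bit-identical trajectories and logs", {
  p <- sim_params(L = 12, n_pred0 = 15, n_prey0 = 40, T_total = 20)
  runs <- lapply(1:2, function(i) {
    set.seed(p$seed)
    w <- init_world(p)
    logs <- list()
    counts <- matrix(0L, 20, 2)
    for (m in 1:20) {
      res <- mcs_step(w, p, record_log = TRUE)
      logs[[m]] <- res$log
      counts[m, ] <- res$counts
    }
    list(logs = logs, counts = counts, grid = export_grid(w))
  })
  expect_identical(runs[[1]]$logs, runs[[2]]$logs)
  expect_identical(runs[[1]]$counts, runs[[2]]$counts)
  expect_identical(runs[[1]]$grid, runs[[2]]$grid)
})
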