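# Event loop: initialization, single exposure events, the new-belief
# sub-step, and whole-run contracts.

test_that("initial attitudes are uniform on [-1, 1]", {
  p <- model_params(n_agents = 10000L, n_steps = 1L, seed = 99L)
  set.seed(99)
  pop <- init_population(p)
  expect_length(pop$a1, 10000L)
  expect_false(any(pop$adopted))
  expect_true(all(abs(c(pop$a1, pop$a2, pop$a3)) <= 1))
  # moments of U(-1, 1): mean 0, variance 1/3
  expect_lt(abs(mean(pop$a1)), 3 * sqrt(1 / 3) / sqrt(10000))
  # KS statistic of a2 against U(-1, 1) below the 1% critical value
  ks <- suppressWarnings(stats::ks.test(pop$a2, "punif", -1, 1))
  expect_lt(unname(ks$statistic), 1.628 / sqrt(10000))

  p1 <- model_params(n_agents = 1L, n_steps = 1L, seed = 5L)
  set.seed(5)
  one <- init_population(p1)
  expect_length(one$a1, 1L)
  expect_false(one$adopted)
})

test_that("a corner-state agent is a stable point of the exposure step", {
  p <- model_params(n_agents = 1L, n_steps = 1L, k0 = -1L, za = 0.01)
  pop <- population(a1 = 1, a2 = -1)
  set.seed(1)
  for (i in 1:50) pop <- exposure_step(pop, p)
  expect_identical(pop$a1, 1)
  expect_identical(pop$a2, -1)
  expect_equal(pop$t, 50L)
})

test_that("zero attitudes feel no coherence pressure, only noise", {
  p <- model_params(n_agents = 1L, n_steps = 1L, k0 = 1L, za = 0.01)
  set.seed(2)
  for (i in 1:200) {
    pop <- exposure_step(population(a1 = 0, a2 = 0), p)
    expect_true(all(pop$a1 %in% c(0, 0.01, -0.01)))
    expect_true(all(pop$a2 %in% c(0, 0.01, -0.01)))
  }
})

test_that("a forced open-gate step reproduces the hand-computed update", {
  p <- model_params(n_agents = 1L, n_steps = 1L, k0 = 1L, za = 0.01)
  pop <- population(a1 = 0.4, a2 = 0.5)
  # draws: gates forced open (u = 0), both noise signs forced + (u < 0.5);
  # both attitudes use the pre-update coherence C = 0.4 * 0.5 * 1 = 0.2
  out <- exposure_step(pop, p, draws = list(idx = 1L, u = c(0, 0, 0, 0)))
  expect_equal(out$a1, 0.61)
  expect_equal(out$a2, 0.71)
})

test_that("one-step outcome frequencies match the exact enumeration", {
  p <- model_params(n_agents = 1L, n_steps = 1L, k0 = 1L, za = 0.01)
  start <- population(a1 = 0.4, a2 = 0.5)
  exact <- enumerate_onestep(0.4, 0.5, k0 = 1, rho = 1, za = 0.01)
  m <- 100000L
  set.seed(314)
  obs1 <- numeric(m); obs2 <- numeric(m)
  for (i in seq_len(m)) {
    pop <- exposure_step(start, p)
    obs1[i] <- pop$a1; obs2[i] <- pop$a2
  }
  for (side in list(list(o = obs1, e = exact$a1),
                    list(o = obs2, e = exact$a2))) {
    idx <- match_outcome(side$o, side$e$value)
    # every observed value is one of the enumerated outcomes
    expect_lt(max(abs(side$o - side$e$value[idx])), 1e-12)
    freq <- tabulate(idx, nbins = nrow(side$e)) / m
    se <- sqrt(side$e$prob * (1 - side$e$prob) / m)
    expect_true(all(abs(freq - side$e$prob) <= 4 * se))
  }
  # gates act independently: joint frequency of (both updated, both +noise)
  p_joint <- exact$a1$prob[2] * exact$a2$prob[2]
  f_joint <- mean(abs(obs1 - exact$a1$value[2]) < 1e-12 &
                  abs(obs2 - exact$a2$value[2]) < 1e-12)
  expect_lt(abs(f_joint - p_joint), 4 * sqrt(p_joint * (1 - p_joint) / m))
})

test_that("link-sign mirror symmetry holds trajectory-wise under a2 -> -a2", {
  n <- 20L; t_max <- 2000L
  p_neg <- model_params(n_agents = n, n_steps = t_max, k0 = -1L)
  p_pos <- model_params(n_agents = n, n_steps = t_max, k0 = +1L)
  set.seed(77)
  pop_a <- population(runif(n, -1, 1), runif(n, -1, 1))
  pop_b <- population(pop_a$a1, -pop_a$a2)
  # same random decisions; only the a2 noise-sign uniform is mirrored
  draws <- replicate(t_max, list(idx = sample.int(n, 1L), u = runif(4)),
                     simplify = FALSE)
  for (d in draws) {
    pop_a <- exposure_step(pop_a, p_neg, draws = d)
    d$u[4] <- 1 - d$u[4]
    pop_b <- exposure_step(pop_b, p_pos, draws = d)
  }
  expect_identical(pop_b$a1, pop_a$a1)
  expect_identical(pop_b$a2, -pop_a$a2)
})

test_that("consistent corner populations are invariant without noise", {
  for (k0 in c(-1L, 1L)) {
    p <- model_params(n_agents = 10L, n_steps = 1L, k0 = k0, za = 0)
    pop <- corner_population(10L, k0)
    ref <- pop
    set.seed(11)
    for (i in 1:200) pop <- exposure_step(pop, p)
    expect_identical(pop$a1, ref$a1)
    expect_identical(pop$a2, ref$a2)
  }
})

test_that("new-belief sub-step adopts only under dissonance relief", {
  p <- model_params(n_agents = 1L, n_steps = 1L, new_belief = TRUE,
                    k_nb = -1L)
  # reassuring event: nothing happens, regardless of the coin
  ag <- list(a1 = 0.5, a3 = 0.8, adopted = FALSE)
  out <- new_belief_substep(ag, c_event = 0.5, p,
                            draws = list(u_adopt = 0, u_nb = NULL))
  expect_identical(out, ag)
  # adoption would itself create dissonance: never adopted
  ag2 <- list(a1 = 1, a3 = 1, adopted = FALSE)
  set.seed(3)
  for (i in 1:100) {
    out2 <- new_belief_substep(ag2, c_event = -1, p)
    expect_false(out2$adopted)
  }
  # extreme adopter is frozen by the gates even under noise
  p0 <- model_params(n_agents = 1L, n_steps = 1L, new_belief = TRUE,
                     k_nb = -1L, za = 0.01)
  ag3 <- list(a1 = 1, a3 = -1, adopted = TRUE)
  set.seed(4)
  for (i in 1:100) {
    out3 <- new_belief_substep(ag3, c_event = -1, p0)
    expect_identical(out3, ag3)
  }
  # certain adoption when the relief is maximal
  ag4 <- list(a1 = 1, a3 = -1, adopted = FALSE)
  out4 <- new_belief_substep(ag4, c_event = -0.5, p,
                             draws = list(u_adopt = 0.999, u_nb = NULL))
  expect_true(out4$adopted)
  # adoption must go through the substep error check outside NB mode
  expect_error(new_belief_substep(ag4, -0.5, model_params(n_agents = 1)),
               "new_belief")
})

test_that("runs are bit-reproducible and leave the user's RNG untouched", {
  p <- tiny_params()
  set.seed(123); before <- runif(1)
  set.seed(123)
  tr1 <- run_simulation(p)
  after <- runif(1)
  tr2 <- run_simulation(p)
  expect_identical(tr1, tr2)
  expect_identical(before, after)  # ambient stream restored
  # a different seed gives a different trajectory
  p2 <- tiny_params(); p2$seed <- 43
  expect_false(identical(run_simulation(p2)$final$a1, tr1$final$a1))
})

test_that("run_simulation equals manually iterated exposure steps", {
  p <- model_params(n_agents = 10L, n_steps = 150L, snapshot_every = 50L,
                    seed = 9L, new_belief = TRUE)
  tr <- run_simulation(p)
  set.seed(9)
  pop <- init_population(p)
  for (i in seq_len(p$n_steps)) pop <- exposure_step(pop, p)
  expect_identical(pop$a1, tr$final$a1)
  expect_identical(pop$a2, tr$final$a2)
  expect_identical(pop$a3, tr$final$a3)
  expect_identical(pop$adopted, tr$final$adopted)
})

test_that("trajectory bookkeeping covers t = 0 and t = n_steps", {
  p <- model_params(n_agents = 5L, n_steps = 1L, seed = 2L)
  tr <- run_simulation(p)
  expect_identical(tr$times, c(0L, 1L))
  p2 <- model_params(n_agents = 5L, n_steps = 103L, snapshot_every = 25L,
                     seed = 2L)
  tr2 <- run_simulation(p2)
  expect_identical(tr2$times, c(0L, 25L, 50L, 75L, 100L, 103L))
  expect_true(all(diff(tr2$times) > 0))
  expect_equal(sum(tr2$exposure_counts), 103L)
})

test_that("attitudes stay in bounds and a3 is frozen for non-adopters", {
  p <- model_params(n_agents = 50L, n_steps = 5000L, snapshot_every = 1000L,
                    seed = 17L, new_belief = TRUE, k_nb = -1L)
  tr <- run_simulation(p)
  expect_lte(tr$max_abs_attitude, 1)
  for (s in tr$snapshots)
    expect_true(all(abs(c(s$a1, s$a2, s$a3)) <= 1))
  a3_0 <- tr$snapshots[[1]]$a3
  non <- !tr$final$adopted
  expect_identical(tr$final$a3[non], a3_0[non])
  expect_gt(sum(tr$final$adopted), 0)  # mechanism actually fires
  # adoption is permanent: the ratio never decreases over time
  adopt <- tr$metrics$adoption_ratio[tr$metrics$eps == p$epsilons[1]]
  expect_true(all(diff(adopt) >= 0))
})

test_that("uniform-rho mode runs and respects the same bounds", {
  p <- model_params(n_agents = 20L, n_steps = 2000L, rho_mode = "uniform",
                    snapshot_every = 500L, seed = 6L)
  tr <- run_simulation(p)
  expect_lte(tr$max_abs_attitude, 1)
  expect_identical(run_simulation(p)$final, tr$final)
})
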