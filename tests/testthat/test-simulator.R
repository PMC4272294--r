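test_that("wf_step handles degenerate frequencies exactly", {
  set.seed(1)
  expect_equal(wf_step(q = 0, N = 50, I = 3, E = 2, Q = 0), 0)
  expect_equal(wf_step(q = 1, N = 50, I = 3, E = 0, Q = 1), 1)
  expect_equal(wf_step(q = rep(0, 10), N = 5, I = rep(0, 10),
                       E = rep(0, 10), Q = 0), rep(0, 10))
  expect_error(wf_step(q = 1.5, N = 10, I = 0, E = 0, Q = 0.5), "'q'")
  expect_error(wf_step(q = 0.5, N = 10, I = 0, E = 0, Q = -1), "'Q'")
  expect_error(wf_step(q = 0.5, N = 10, I = 0, E = 11, Q = 0.5), "emigrant")
  expect_warning(out <- wf_step(q = 0.5, N = 1, I = 0, E = 1, Q = 0.5),
                 "empty")
  expect_equal(out, 0)
})

test_that("wf_step matches its conditional expectation", {
  # E[q'] = ((N - E) q + I Q) / (N - E + I), here (99*0.3 + 2*0.1)/101
  set.seed(11)
  n <- 1e5
  draws <- wf_step(q = rep(0.3, n), N = 100, I = rep(2L, n),
                   E = rep(1L, n), Q = 0.1)
  expected <- (99 * 0.3 + 2 * 0.1) / 101
  se <- stats::sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("transition_pmf enumerates exact small-pool distributions", {
  # pure drift, one diploid: Binomial(2, 0.5) / 2
  pmf <- transition_pmf(N = 1, q = 0.5, Q = 0, I = 0, E = 0)
  expect_equal(pmf$freq, c(0, 0.5, 1))
  expect_equal(pmf$prob, c(0.25, 0.5, 0.25))

  # absent everywhere: all mass at zero
  pmf <- transition_pmf(N = 5, q = 0, Q = 0, I = 2, E = 0)
  expect_equal(sum(pmf$prob[pmf$freq == 0]), 1)

  # migrant-only copies: Binomial(2, 0.5) over a pool of 4 copies
  pmf <- transition_pmf(N = 1, q = 0, Q = 0.5, I = 1, E = 0)
  expect_equal(pmf$freq, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(pmf$prob, c(0.25, 0.5, 0.25, 0, 0))

  # probabilities always sum to one
  for (cfg in list(c(10, 1, 2), c(16, 0, 0), c(4, 3, 5))) {
    pmf <- transition_pmf(N = cfg[1], q = 0.3, Q = 0.1,
                          I = cfg[3], E = cfg[2])
    expect_lt(abs(sum(pmf$prob) - 1), 1e-12)
  }
  expect_error(transition_pmf(N = 40, q = 0.5, Q = 0.5, I = 0, E = 0),
               "enumeration bound")
})

test_that("wf_step draws are distributed as the enumeration oracle", {
  set.seed(5)
  n <- 1e5
  cases <- list(list(N = 10, E = 1, I = 2, q = 0.3, Q = 0.1),
                list(N = 8, E = 0, I = 0, q = 0.5, Q = 0),
                list(N = 5, E = 2, I = 4, q = 0.1, Q = 0.6))
  for (cs in cases) {
    pool <- 2 * (cs$N - cs$E) + 2 * cs$I
    pmf <- transition_pmf(cs$N, cs$q, cs$Q, cs$I, cs$E)
    draws <- wf_step(rep(cs$q, n), cs$N, rep(cs$I, n), rep(cs$E, n), cs$Q)
    counts <- as.integer(round(draws * pool))
    expect_gt(gof_pvalue(counts, pmf, n), 0.001)
  }
})

test_that("founder draws are binomial in 2 N0 gametes", {
  expect_equal(founder_initialize(5, 0), 0)
  expect_equal(founder_initialize(5, 1), 1)
  set.seed(3)
  n <- 1e5
  q0 <- founder_initialize(5, 0.1, n = n)
  se_mean <- stats::sd(q0) / sqrt(n)
  expect_lt(abs(mean(q0) - 0.1), 3 * se_mean)
  # zero class: all 10 founder gametes miss the allele
  p0 <- 0.9^10
  se0 <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(q0 == 0) - p0), 3 * se0)
})

test_that("frequency zero is absorbing without migration", {
  ens <- simulate_ensemble(tiny_scenario(M = 0), tiny_settings(), T = 50)
  expect_equal(ens$mean_freq, rep(0, 51))
  expect_equal(ens$presence_prob, rep(0, 51))

  # started inside (0,1), replicates that hit zero stay there
  scn <- tiny_scenario(M = 0, q0 = 0.1)
  ens <- simulate_ensemble(scn, tiny_settings(n_reps = 100), T = 100,
                           keep_freq = TRUE)
  for (rep_i in 1:100) {
    z <- which(ens$freq[rep_i, ] == 0)
    if (length(z) > 0) expect_true(all(ens$freq[rep_i, z[1]:101] == 0))
  }
  expect_true(all(ens$freq >= 0 & ens$freq <= 1))
})

test_that("pure drift preserves the mean frequency (martingale)", {
  scn <- scenario(demography_params(100, 0, 100),
                  migration_params(0, 0), Q = 0, q0 = 0.5)
  ens <- simulate_ensemble(scn, sim_settings(n_reps = 1e4, seed = 9), T = 5,
                           keep_freq = TRUE)
  for (t in 1:5) {
    se <- stats::sd(ens$freq[, t + 1]) / sqrt(1e4)
    expect_lt(abs(ens$mean_freq[t + 1] - 0.5), 3 * se)
  }
})

test_that("ensembles are reproducible from the seed and internally consistent", {
  scn <- tiny_scenario(M = 0.5, Q = 0.1)
  a <- simulate_ensemble(scn, tiny_settings(seed = 123), T = 80)
  b <- simulate_ensemble(scn, tiny_settings(seed = 123), T = 80)
  expect_identical(a$mean_freq, b$mean_freq)
  expect_identical(a$presence_prob, b$presence_prob)

  # census equals the rounded logistic trajectory, shared by replicates
  traj <- logistic_trajectory(scn$demography, 80)
  expect_equal(a$size, traj$size)

  # no presence implies zero mean frequency, and all bounds hold
  expect_true(all(a$mean_freq[a$presence_prob == 0] == 0))
  expect_true(all(a$mean_freq >= 0 & a$mean_freq <= 1))
  expect_true(all(a$presence_prob >= 0 & a$presence_prob <= 1))
})

test_that("deterministic migration mode drives presence without randomness in counts", {
  scn <- tiny_scenario(M = 1, Q = 0.5, mode = "deterministic")
  a <- simulate_ensemble(scn, tiny_settings(seed = 4), T = 60)
  b <- simulate_ensemble(scn, tiny_settings(seed = 4), T = 60)
  expect_identical(a$mean_freq, b$mean_freq)
  expect_gt(a$presence_prob[61], 0.5)
})
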