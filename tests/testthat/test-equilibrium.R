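test_that("no-trend rule detects equilibrium on constructed series", {
  # constant series: every change is zero, equilibrium at generation 0
  expect_equal(detect_equilibrium(rep(1, 200)), 0L)

  # ramp 0..199 then 200 constant values: the first window holding at most
  # one signed change starts at generation 198
  s <- c(0:199, rep(199, 200))
  expect_equal(detect_equilibrium(s), 198L)

  # strictly increasing series never passes
  expect_true(is.na(detect_equilibrium(seq_len(150))))

  expect_error(detect_equilibrium(rep(1, 100)), "window")
})

test_that("detection is translation-invariant under a constant prefix", {
  set.seed(21)
  base <- cumsum(rnorm(400, 0.02)) + rnorm(400, sd = 0.3)
  t0 <- detect_equilibrium(base)
  for (k in c(5, 50)) {
    tk <- detect_equilibrium(c(rep(base[1], k), base))
    expect_lte(tk, t0 + k)
  }
})

test_that("equilibrium-phase means are exact on constructed ensembles", {
  fake_ens <- function(mean_freq, presence, n_reps = 100) {
    T <- length(mean_freq) - 1L
    structure(list(generations = 0:T, size = rep(50L, T + 1),
                   mean_freq = mean_freq, presence_prob = presence,
                   sd_freq = rep(0, T + 1), n_reps = n_reps),
              class = "trajectory_ensemble")
  }
  st <- sim_settings(n_reps = 100, trend_window = 100, post_eq_window = 200)

  # constant series: phase means equal the constants, equilibrium at 0
  eq <- summarize_equilibrium(fake_ens(rep(0.2, 301), rep(1, 301)), st)
  expect_equal(eq$t_eq, 0L)
  expect_equal(eq$q_bar_eq, 0.2)
  expect_equal(eq$P_eq, 1.0)

  # identically zero (no allele source): zero means
  eq <- summarize_equilibrium(fake_ens(rep(0, 301), rep(0, 301)), st)
  expect_equal(eq$q_bar_eq, 0)
  expect_equal(eq$P_eq, 0)
  expect_equal(eq$se_P, 0)

  # ramp then plateau: the phase covers generations 199..398, over which
  # the frequency series averages (0.5 * 1 + 199.5 * 199) / 200... computed
  # directly from the constructed series below
  mf <- c(0:199, rep(199, 300)) / 1000
  pp <- rep(1, 500)
  eq <- summarize_equilibrium(fake_ens(mf, pp), st)
  expect_equal(eq$t_eq, 198L)
  expect_equal(eq$q_bar_eq, mean(mf[200:399]))
  expect_equal(eq$P_eq, 1)

  # overall equilibrium is the max of the two per-series equilibria
  pres2 <- c(rep(0, 10), rep(0.5, 10), rep(1, 480))
  eq <- summarize_equilibrium(fake_ens(rep(0.2, 500), pres2), st)
  expect_equal(eq$t_eq_freq, 0L)
  expect_gt(eq$t_eq_pres, 0L)
  expect_equal(eq$t_eq, max(eq$t_eq_freq, eq$t_eq_pres))

  # too short for the phase
  expect_error(summarize_equilibrium(fake_ens(mf[1:350], pp[1:350]), st),
               "too short")
})

test_that("the driver extends simulation until the phase fits or errors", {
  scn <- tiny_scenario(M = 2, Q = 0.2)
  eq <- simulate_to_equilibrium(scn, tiny_settings(seed = 31))
  expect_s3_class(eq, "equilibrium_summary")
  expect_gte(eq$generations_run, eq$t_eq + 200)
  expect_true(eq$P_eq >= 0 && eq$P_eq <= 1)
  expect_true(eq$q_bar_eq >= 0 && eq$q_bar_eq <= 1)

  # M = 0, q0 = 0: series identically zero, equilibrium immediately
  eq0 <- simulate_to_equilibrium(tiny_scenario(M = 0), tiny_settings(seed = 1))
  expect_equal(eq0$t_eq, 0L)
  expect_equal(eq0$q_bar_eq, 0)
  expect_equal(eq0$P_eq, 0)

  # a hard cap short enough that a slowly growing population cannot settle
  scn_slow <- scenario(demography_params(5, 0.001, 5000),
                       migration_params(0.05), Q = 0.5)
  expect_error(
    simulate_to_equilibrium(scn_slow,
      sim_settings(n_reps = 50, max_generations = 350, seed = 2)),
    "no equilibrium")
})

test_that("high migration drives the equilibrium mean frequency to Q", {
  # deterministic prediction: with migration overwhelming drift the mean
  # frequency stabilizes at the source frequency
  scn <- scenario(demography_params(20, 0.1, 400), migration_params(30),
                  Q = 0.2)
  eq <- simulate_to_equilibrium(scn, sim_settings(n_reps = 500, seed = 41))
  expect_lt(abs(eq$q_bar_eq - 0.2), 3 * eq$se_q)
  expect_gt(eq$P_eq, 0.99)
})
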