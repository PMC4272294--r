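# Small scenario/settings builders shared across test files. Unit tests run
# on deliberately small populations and replicate counts; the full study
# protocol (1000 replicates, 0.1 migration grid) is exercised only by the
# table-reproduction tests.

tiny_scenario <- function(M = 1, Q = 0.2, N0 = 10, r = 0.1, K = 50,
                          m = 0.01, mode = "poisson", q0 = 0) {
  scenario(demography_params(N0, r, K), migration_params(M, m, mode),
           Q = Q, q0 = q0)
}

tiny_settings <- function(n_reps = 200, seed = 1, ...) {
  sim_settings(n_reps = n_reps, seed = seed, ...)
}

# Sweep built from a plain table of equilibrium summaries (no simulation),
# for threshold-extraction tests.
table_sweep <- function(M, q_bar_eq = NA_real_, P_eq = NA_real_,
                        Q = NULL, K = NULL) {
  scn <- if (is.null(Q)) NULL else
    tiny_scenario(M = 0, Q = Q, K = if (is.null(K)) 50 else K)
  sweep_result(data.frame(M = M, q_bar_eq = q_bar_eq, P_eq = P_eq),
               axis = "migration", scenario = scn)
}

# Chi-square goodness-of-fit of observed integer draws against an exact
# pmf, pooling low-expectation bins from the tails inward.
gof_pvalue <- function(observed_counts, pmf, n) {
  expected <- pmf$prob * n
  obs <- tabulate(observed_counts + 1L, nbins = nrow(pmf))
  keep <- expected >= 5
  # pool all low-expectation cells into one bin
  if (any(!keep)) {
    obs <- c(obs[keep], sum(obs[!keep]))
    expected <- c(expected[keep], sum(expected[!keep]))
  }
  stat <- sum((obs - expected)^2 / expected)
  stats::pchisq(stat, df = length(expected) - 1L, lower.tail = FALSE)
}
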