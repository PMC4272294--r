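# Internal simulation engine. Replicates are vectorized: one generation of
# the whole ensemble is a single set of binomial/Poisson draws, and all
# replicates share the deterministic logistic census trajectory (migration
# does not change the census size). State is carried between blocks so the
# equilibrium driver can extend a run without restarting it.

.engine_new <- function(scn, settings, founder = FALSE) {
  n <- settings$n_reps
  cap <- settings$max_generations
  q <- if (founder) founder_initialize(scn$demography$N0, scn$Q, n)
       else rep.int(scn$q0, n)
  st <- list(
    q = q, Nreal = as.numeric(scn$demography$N0), t = 0L,
    mig = migration_state(),
    size = integer(cap + 1L), mean_freq = numeric(cap + 1L),
    presence = numeric(cap + 1L), sd_freq = numeric(cap + 1L)
  )
  st$size[1L] <- scn$demography$N0
  st$mean_freq[1L] <- mean(q)
  st$presence[1L] <- mean(q > 0)
  st$sd_freq[1L] <- stats::sd(q)
  st
}

.engine_advance <- function(st, n_gen, scn, settings) {
  dem <- scn$demography
  mig <- scn$migration
  n <- settings$n_reps
  for (g in seq_len(n_gen)) {
    N <- round_half_up(st$Nreal)
    draw <- sample_migration(N, mig, n, st$mig)
    st$mig <- draw$state
    st$q <- wf_step(st$q, N, draw$I, draw$E, scn$Q)
    st$Nreal <- st$Nreal + dem$r * st$Nreal * (1 - st$Nreal / dem$K)
    st$t <- st$t + 1L
    i <- st$t + 1L
    st$size[i] <- round_half_up(st$Nreal)
    st$mean_freq[i] <- mean(st$q)
    st$presence[i] <- mean(st$q > 0)
    st$sd_freq[i] <- stats::sd(st$q)
  }
  st
}

.engine_ensemble <- function(st, scn, settings) {
  i <- seq_len(st$t + 1L)
  structure(list(
    generations = 0:st$t,
    size = st$size[i],
    mean_freq = st$mean_freq[i],
    presence_prob = st$presence[i],
    sd_freq = st$sd_freq[i],
    n_reps = settings$n_reps,
    seed = settings$seed,
    scenario = scn, settings = settings
  ), class = "trajectory_ensemble")
}

#' Simulate a replicate ensemble over a fixed horizon
#'
#' Runs `n_reps` independent replicate trajectories of the single-allele
#' model for `T` generations and records, per generation, the shared census
#' size, the across-replicate mean allele frequency, the fraction of
#' replicates in which the allele is present (frequency > 0), and the
#' across-replicate standard deviation of the frequency.
#'
#' @param scn A [scenario()].
#' @param settings A [sim_settings()]; `T` must not exceed
#'   `settings$max_generations`. If `settings$seed` is set the RNG is seeded,
#'   so identical inputs reproduce identical ensembles.
#' @param T Number of generations to simulate.
#' @param founder If `TRUE`, replicate initial frequencies are drawn by
#'   [founder_initialize()] instead of the fixed `scn$q0`.
#' @param keep_freq If `TRUE`, also return the full replicate-by-generation
#'   frequency matrix (`n_reps` rows, `T + 1` columns).
#'
#' @return An object of class `"trajectory_ensemble"`.
#' @export
#' @examples
#' scn <- scenario(demography_params(5, 0.1, 50), migration_params(1), Q = 0.2)
#' ens <- simulate_ensemble(scn, sim_settings(n_reps = 100, seed = 1), T = 20)
#' ens$presence_prob[21]
simulate_ensemble <- function(scn, settings, T, founder = FALSE,
                              keep_freq = FALSE) {
  stopifnot(inherits(scn, "scenario"), inherits(settings, "sim_settings"))
  if (T > settings$max_generations)
    stop("'T' exceeds settings$max_generations", call. = FALSE)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  st <- .engine_new(scn, settings, founder)
  freq <- if (keep_freq) matrix(NA_real_, settings$n_reps, T + 1L) else NULL
  if (keep_freq) freq[, 1L] <- st$q
  if (keep_freq && T > 0L) {
    for (g in seq_len(T)) {
      st <- .engine_advance(st, 1L, scn, settings)
      freq[, g + 1L] <- st$q
    }
  } else if (T > 0L) {
    st <- .engine_advance(st, as.integer(T), scn, settings)
  }
  out <- .engine_ensemble(st, scn, settings)
  out$freq <- freq
  out
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  T <- length(x$generations) - 1L
  cat(sprintf(
    "Trajectory ensemble: %d replicates, generations 0..%d\n", x$n_reps, T))
  cat(sprintf("  final census %d, mean frequency %.4f, presence %.3f\n",
              x$size[T + 1L], x$mean_freq[T + 1L], x$presence_prob[T + 1L]))
  invisible(x)
}

#' Export per-generation ensemble summaries
#'
#' @param x A `"trajectory_ensemble"`.
#' @param ... Unused.
#' @return A data frame with one row per generation.
#' @export
as.data.frame.trajectory_ensemble <- function(x, ...) {
  data.frame(generation = x$generations, size = x$size,
             mean_freq = x$mean_freq, presence_prob = x$presence_prob,
             sd_freq = x$sd_freq)
}
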