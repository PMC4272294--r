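#' Demographic parameters of the founded population
#'
#' Bundles the three parameters of the discrete logistic growth model
#' \eqn{N_{t+1} = N_t + r N_t (1 - N_t/K)}: the founder census size, the
#' per-generation growth rate and the carrying capacity.
#'
#' @param N0 Initial census size (individuals, integer >= 1).
#' @param r Per-generation logistic growth rate (dimensionless, >= 0).
#' @param K Carrying capacity (individuals, integer >= 1). `N0` must not
#'   exceed `K`: the framework models expanding, not contracting, founded
#'   populations.
#'
#' @return An object of class `"demography_params"`.
#' @export
#' @examples
#' demography_params(N0 = 5, r = 0.01, K = 200)
demography_params <- function(N0, r, K) {
  if (!is.numeric(N0) || length(N0) != 1L || is.na(N0) || N0 < 1 ||
      N0 != as.integer(N0))
    stop("'N0' must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K < 1 ||
      K != as.integer(K))
    stop("'K' must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0)
    stop("'r' must be a single number >= 0", call. = FALSE)
  if (N0 > K)
    stop("'N0' must not exceed the carrying capacity 'K'", call. = FALSE)
  structure(list(N0 = as.integer(N0), r = as.numeric(r), K = as.integer(K)),
            class = "demography_params")
}

#' Migration parameters
#'
#' Immigration into the founded population arrives at a mean rate of `M`
#' individuals per generation; back-migration removes a proportion `m` of
#' the founded population each generation (mean `m * N_t` emigrants).
#' Migrant counts are either Poisson-distributed (`mode = "poisson"`) or
#' emitted by a deterministic fractional accumulator whose long-run average
#' equals the mean rate exactly (`mode = "deterministic"`). Migration does
#' not change the census size, which follows the logistic trajectory.
#'
#' @param M Mean immigrants per generation (>= 0).
#' @param m Per-generation emigration proportion, in `[0, 1)`. Emigrants are
#'   effectively lost to the large static source population; `m` has no
#'   effect on the expected allele frequency and only a second-order effect
#'   on drift.
#' @param mode `"poisson"` (default) or `"deterministic"`.
#'
#' @return An object of class `"migration_params"`.
#' @export
#' @examples
#' migration_params(M = 1, m = 0.01)
migration_params <- function(M, m = 0.01, mode = c("poisson", "deterministic")) {
  mode <- match.arg(mode)
  if (!is.numeric(M) || length(M) != 1L || is.na(M) || M < 0)
    stop("'M' must be a single number >= 0", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 || m >= 1)
    stop("'m' must be a single number in [0, 1)", call. = FALSE)
  structure(list(M = as.numeric(M), m = as.numeric(m), mode = mode),
            class = "migration_params")
}

#' A single-allele founding scenario
#'
#' A scenario is one configuration of the model: the demography of the
#' founded population, the migration regime, the constant frequency `Q` of
#' the tracked allele in the (large, static) source population, and the
#' initial frequency `q0` in the founded population. The default `q0 = 0`
#' encodes the premise that the allele was lost in the founder event.
#'
#' @param demography A [demography_params()] object.
#' @param migration A [migration_params()] object.
#' @param Q Source-population allele frequency, in `[0, 1]`.
#' @param q0 Initial allele frequency in the founded population, in
#'   `[0, 1]`; default 0.
#'
#' @return An object of class `"scenario"`.
#' @export
#' @examples
#' scenario(demography_params(5, 0.01, 200), migration_params(1), Q = 0.2)
scenario <- function(demography, migration, Q, q0 = 0) {
  if (!inherits(demography, "demography_params"))
    stop("'demography' must be a demography_params object", call. = FALSE)
  if (!inherits(migration, "migration_params"))
    stop("'migration' must be a migration_params object", call. = FALSE)
  if (!is.numeric(Q) || length(Q) != 1L || is.na(Q) || Q < 0 || Q > 1)
    stop("'Q' must be a single number in [0, 1]", call. = FALSE)
  if (!is.numeric(q0) || length(q0) != 1L || is.na(q0) || q0 < 0 || q0 > 1)
    stop("'q0' must be a single number in [0, 1]", call. = FALSE)
  structure(list(demography = demography, migration = migration,
                 Q = as.numeric(Q), q0 = as.numeric(q0)),
            class = "scenario")
}

#' Simulation settings
#'
#' Replicate count, equilibrium-detection window, equilibrium-phase length,
#' the hard generation cap, and the RNG seed. The defaults are the protocol
#' used throughout: 1000 replicate simulations per scenario, equilibrium
#' defined as the first generation whose following 100 generations show no
#' trend, and a 200-generation equilibrium phase.
#'
#' @param n_reps Number of replicate simulations (>= 1); default 1000.
#' @param trend_window Number of consecutive one-generation changes examined
#'   by the no-trend rule (>= 2); default 100.
#' @param post_eq_window Length of the equilibrium phase in generations
#'   (>= 1); default 200.
#' @param max_generations Hard cap on the simulated horizon; must exceed
#'   `trend_window + post_eq_window`; default 5000.
#' @param seed Integer RNG seed, or `NULL` to leave the RNG state untouched.
#'
#' @return An object of class `"sim_settings"`.
#' @export
#' @examples
#' sim_settings(n_reps = 200, seed = 1)
sim_settings <- function(n_reps = 1000, trend_window = 100,
                         post_eq_window = 200, max_generations = 5000,
                         seed = NULL) {
  chk_int <- function(x, nm, min) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
        x != as.integer(x))
      stop(sprintf("'%s' must be a single integer >= %d", nm, min),
           call. = FALSE)
    as.integer(x)
  }
  n_reps <- chk_int(n_reps, "n_reps", 1L)
  trend_window <- chk_int(trend_window, "trend_window", 2L)
  post_eq_window <- chk_int(post_eq_window, "post_eq_window", 1L)
  max_generations <- chk_int(max_generations, "max_generations", 1L)
  if (max_generations <= trend_window + post_eq_window)
    stop("'max_generations' must exceed trend_window + post_eq_window",
         call. = FALSE)
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("'seed' must be a single integer or NULL", call. = FALSE)
    seed <- as.integer(seed)
  }
  structure(list(n_reps = n_reps, trend_window = trend_window,
                 post_eq_window = post_eq_window,
                 max_generations = max_generations, seed = seed),
            class = "sim_settings")
}

#' @export
print.demography_params <- function(x, ...) {
  cat(sprintf("Demography: N0 = %d, r = %g, K = %d\n", x$N0, x$r, x$K))
  invisible(x)
}

#' @export
print.migration_params <- function(x, ...) {
  cat(sprintf("Migration: M = %g immigrants/gen, m = %g (%s)\n",
              x$M, x$m, x$mode))
  invisible(x)
}

#' @export
print.scenario <- function(x, ...) {
  cat("Founding scenario\n")
  print(x$demography)
  print(x$migration)
  cat(sprintf("Source allele frequency Q = %g; initial frequency q0 = %g\n",
              x$Q, x$q0))
  invisible(x)
}

#' @export
print.sim_settings <- function(x, ...) {
  cat(sprintf(
    "Settings: %d replicates, trend window %d, equilibrium phase %d, cap %d%s\n",
    x$n_reps, x$trend_window, x$post_eq_window, x$max_generations,
    if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}
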