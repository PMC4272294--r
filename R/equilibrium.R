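#' Equilibrium generation by the no-trend rule
#'
#' A per-generation series is at equilibrium at generation `t` when the
#' `window` consecutive one-generation changes starting at `t` show no
#' trend: the number of positive changes and the number of negative changes
#' differ by at most one. Changes of exactly zero count as neither. The
#' smallest qualifying `t` is returned, or `NA` if no generation qualifies
#' within the series. This rule is deliberately conservative: it bounds the
#' time needed to reach equilibrium from above rather than pinpointing it.
#'
#' @param series Numeric per-generation series (element 1 is generation 0).
#' @param window Number of consecutive changes examined (default 100); the
#'   series must contain at least `window + 1` values.
#'
#' @return The equilibrium generation (0-based), or `NA_integer_` if not
#'   reached.
#' @export
#' @examples
#' detect_equilibrium(rep(1, 200))            # 0: all changes are zero
#' detect_equilibrium(seq_len(150), window = 100)  # NA: monotone trend
detect_equilibrium <- function(series, window = 100) {
  if (!is.numeric(series))
    stop("'series' must be numeric", call. = FALSE)
  window <- as.integer(window)
  d <- diff(series)
  if (length(d) < window)
    stop("'series' must contain at least window + 1 values", call. = FALSE)
  cpos <- c(0, cumsum(d > 0))
  cneg <- c(0, cumsum(d < 0))
  idx <- seq_len(length(d) - window + 1L)
  npos <- cpos[idx + window] - cpos[idx]
  nneg <- cneg[idx + window] - cneg[idx]
  ok <- which(abs(npos - nneg) <= 1L)
  if (length(ok) == 0L) NA_integer_ else ok[1L] - 1L
}

# Equilibrium indices of an ensemble's two summary series, plus whether the
# ensemble already extends through the full equilibrium phase.
.equilibrium_state <- function(ensemble, settings) {
  w <- settings$trend_window
  T <- length(ensemble$generations) - 1L
  if (T < w) return(list(reached = FALSE, complete = FALSE))
  tf <- detect_equilibrium(ensemble$mean_freq, w)
  tp <- detect_equilibrium(ensemble$presence_prob, w)
  if (is.na(tf) || is.na(tp)) return(list(reached = FALSE, complete = FALSE))
  teq <- max(tf, tp)
  list(reached = TRUE, complete = T >= teq + settings$post_eq_window,
       t_eq_freq = tf, t_eq_pres = tp, t_eq = teq)
}

#' Equilibrium-phase summary of an ensemble
#'
#' Applies the no-trend rule separately to the mean-frequency and
#' presence-probability series; the overall equilibrium generation is the
#' greater of the two, so that both statistics are stable. The
#' equilibrium-phase means `q_bar_eq` and `P_eq` are taken over the
#' `post_eq_window` generations following the equilibrium generation
#' (generations `t_eq + 1` to `t_eq + post_eq_window`).
#'
#' `se_P` is the binomial standard error `sqrt(P (1 - P) / n_reps)`;
#' `se_q` is the phase-averaged across-replicate standard deviation of the
#' frequency divided by `sqrt(n_reps)`.
#'
#' @param ensemble A `"trajectory_ensemble"` that extends at least
#'   `t_eq + post_eq_window` generations (use [simulate_to_equilibrium()] to
#'   produce one of guaranteed length).
#' @param settings The [sim_settings()] defining the trend window and the
#'   equilibrium-phase length.
#'
#' @return An object of class `"equilibrium_summary"` with elements
#'   `t_eq_freq`, `t_eq_pres`, `t_eq`, `q_bar_eq`, `P_eq`, `se_q`, `se_P`,
#'   `n_reps`.
#' @export
summarize_equilibrium <- function(ensemble, settings) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"),
            inherits(settings, "sim_settings"))
  es <- .equilibrium_state(ensemble, settings)
  if (!es$reached)
    stop("no equilibrium detected within the simulated horizon",
         call. = FALSE)
  if (!es$complete)
    stop("ensemble too short: the equilibrium phase extends past the ",
         "simulated horizon", call. = FALSE)
  ph <- es$t_eq + 1L + seq_len(settings$post_eq_window)  # gen t_eq+1 .. +post
  P_eq <- mean(ensemble$presence_prob[ph + 0L])
  q_bar <- mean(ensemble$mean_freq[ph + 0L])
  se_q <- mean(ensemble$sd_freq[ph + 0L]) / sqrt(ensemble$n_reps)
  se_P <- sqrt(P_eq * (1 - P_eq) / ensemble$n_reps)
  structure(list(t_eq_freq = es$t_eq_freq, t_eq_pres = es$t_eq_pres,
                 t_eq = es$t_eq, q_bar_eq = q_bar, P_eq = P_eq,
                 se_q = se_q, se_P = se_P, n_reps = ensemble$n_reps),
            class = "equilibrium_summary")
}

#' Simulate a scenario to equilibrium and summarize the equilibrium phase
#'
#' Runs the ensemble forward in blocks of `trend_window` generations,
#' re-testing the no-trend rule after each block, until the equilibrium
#' generation is found and the full equilibrium phase has been simulated,
#' or until `max_generations` is hit (in which case an explicit error names
#' the scenario rather than silently returning a non-equilibrium summary).
#'
#' @inheritParams simulate_ensemble
#' @param keep_ensemble If `TRUE`, attach the full per-generation ensemble
#'   summaries to the result as element `ensemble`.
#'
#' @return An `"equilibrium_summary"` (see [summarize_equilibrium()]), with
#'   the additional element `generations_run`.
#' @export
#' @examples
#' scn <- scenario(demography_params(20, 0.1, 100), migration_params(2), Q = 0.2)
#' simulate_to_equilibrium(scn, sim_settings(n_reps = 100, seed = 1))
simulate_to_equilibrium <- function(scn, settings, founder = FALSE,
                                    keep_ensemble = FALSE) {
  stopifnot(inherits(scn, "scenario"), inherits(settings, "sim_settings"))
  if (!is.null(settings$seed)) set.seed(settings$seed)
  st <- .engine_new(scn, settings, founder)
  w <- settings$trend_window
  first_block <- w + settings$post_eq_window
  repeat {
    block <- if (st$t == 0L) first_block else w
    block <- min(block, settings$max_generations - st$t)
    st <- .engine_advance(st, block, scn, settings)
    ens <- .engine_ensemble(st, scn, settings)
    es <- .equilibrium_state(ens, settings)
    if (es$reached && es$complete) break
    if (st$t >= settings$max_generations)
      stop(sprintf(
        paste0("no equilibrium within %d generations for scenario ",
               "N0=%d, r=%g, K=%d, M=%g, Q=%g"),
        settings$max_generations, scn$demography$N0, scn$demography$r,
        scn$demography$K, scn$migration$M, scn$Q), call. = FALSE)
  }
  out <- summarize_equilibrium(ens, settings)
  out$generations_run <- st$t
  if (keep_ensemble) out$ensemble <- ens
  out
}

#' @export
print.equilibrium_summary <- function(x, ...) {
  cat(sprintf(
    "Equilibrium at generation %d (freq %d, presence %d)\n",
    x$t_eq, x$t_eq_freq, x$t_eq_pres))
  cat(sprintf("  q_bar_eq = %.4f (se %.4f),  P_eq = %.3f (se %.3f)\n",
              x$q_bar_eq, x$se_q, x$P_eq, x$se_P))
  invisible(x)
}
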