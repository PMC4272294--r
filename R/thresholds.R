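#' Construct a sweep result
#'
#' Low-level constructor bundling a grid of equilibrium summaries into the
#' object consumed by the threshold extractors [find_M_Q()], [find_M_95()]
#' and [fit_alpha()]. [sweep_migration()] and [find_Q_c()] build these from
#' simulations; constructing one directly is useful for threshold extraction
#' from externally computed tables.
#'
#' @param table A data frame with one row per grid point, containing the
#'   grid column (`M` for a migration sweep, `Q` for a source-frequency
#'   sweep) and any of `q_bar_eq`, `P_eq`, `se_q`, `se_P`, `t_eq`, `failed`.
#' @param axis `"migration"` or `"source_frequency"`.
#' @param scenario The base [scenario()] (optional metadata).
#' @param settings The [sim_settings()] used (optional metadata).
#'
#' @return An object of class `"sweep_result"`.
#' @export
sweep_result <- function(table, axis = c("migration", "source_frequency"),
                         scenario = NULL, settings = NULL) {
  axis <- match.arg(axis)
  key <- if (axis == "migration") "M" else "Q"
  if (!is.data.frame(table) || !key %in% names(table))
    stop(sprintf("'table' must be a data frame with a '%s' column", key),
         call. = FALSE)
  g <- table[[key]]
  if (any(diff(g) <= 0))
    stop("grid values must be strictly increasing", call. = FALSE)
  if (!"failed" %in% names(table)) table$failed <- FALSE
  structure(list(axis = axis, grid = g, table = table,
                 scenario = scenario, settings = settings),
            class = "sweep_result")
}

# Per-grid-point seeds spawned deterministically from the root seed, so a
# sweep is reproducible and each point is an independent stream.
.spawn_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep.int(list(NULL), n))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}

.sweep_point <- function(scn, settings, seed) {
  s <- settings
  s$seed <- seed
  tryCatch({
    eq <- simulate_to_equilibrium(scn, s)
    data.frame(t_eq = eq$t_eq, q_bar_eq = eq$q_bar_eq, se_q = eq$se_q,
               P_eq = eq$P_eq, se_P = eq$se_P, failed = FALSE)
  }, error = function(e) {
    data.frame(t_eq = NA_integer_, q_bar_eq = NA_real_, se_q = NA_real_,
               P_eq = NA_real_, se_P = NA_real_, failed = TRUE)
  })
}

#' Sweep the migration rate across a grid
#'
#' Simulates the base scenario to equilibrium at each migration rate in
#' `grid`, with an independent per-point seed spawned from
#' `settings$seed`, and collects the equilibrium summaries. Points at which
#' no equilibrium is reached within `max_generations` are recorded with
#' `failed = TRUE` rather than aborting the sweep.
#'
#' @param base The base [scenario()]; its migration rate `M` is replaced by
#'   each grid value in turn.
#' @param grid Strictly increasing migration rates (>= 0).
#' @param settings A [sim_settings()].
#'
#' @return A `"sweep_result"` with `axis = "migration"`.
#' @export
#' @examples
#' scn <- scenario(demography_params(10, 0.1, 100), migration_params(0), Q = 0.2)
#' sw <- sweep_migration(scn, c(0, 0.5, 1), sim_settings(n_reps = 100, seed = 1))
#' sw$table
sweep_migration <- function(base, grid, settings) {
  stopifnot(inherits(base, "scenario"), inherits(settings, "sim_settings"))
  if (length(grid) == 0L || any(grid < 0) || any(diff(grid) <= 0))
    stop("'grid' must be non-empty, non-negative and strictly increasing",
         call. = FALSE)
  seeds <- .spawn_seeds(settings$seed, length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    scn <- base
    scn$migration$M <- grid[i]
    rows[[i]] <- .sweep_point(scn, settings, seeds[[i]])
  }
  tab <- cbind(data.frame(M = grid), do.call(rbind, rows))
  sweep_result(tab, axis = "migration", scenario = base, settings = settings)
}

.threshold_result <- function(kind, value, criterion, grid, se_P = NA_real_) {
  step <- if (length(grid) > 1L) min(diff(grid)) else NA_real_
  structure(list(kind = kind, value = value, attained = !is.na(value),
                 criterion = criterion, grid_step = step,
                 se_P_at_value = se_P),
            class = "threshold_result")
}

#' Migration threshold for recovery of the mean allele frequency (M_Q)
#'
#' The minimal migration rate on the sweep grid at which the
#' equilibrium-phase mean allele frequency has stabilized at the source
#' frequency: that grid point and the following four must all have
#' `q_bar_eq >= 0.95 Q`. A window truncated by the end of the grid does not
#' qualify, so the grid must extend at least four steps past any candidate
#' threshold.
#'
#' @param sweep A migration-axis `"sweep_result"` with at least 5 points.
#' @param Q Source allele frequency; defaults to the sweep scenario's `Q`.
#'
#' @return A `"threshold_result"` of kind `"M_Q"`; `value` is `NA` when not
#'   attained.
#' @export
find_M_Q <- function(sweep, Q = NULL) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (sweep$axis != "migration")
    stop("'sweep' must be a migration sweep", call. = FALSE)
  if (is.null(Q)) Q <- sweep$scenario$Q
  if (is.null(Q)) stop("'Q' must be supplied", call. = FALSE)
  n <- length(sweep$grid)
  if (n < 5L) stop("at least 5 grid points are required", call. = FALSE)
  ok <- !is.na(sweep$table$q_bar_eq) & sweep$table$q_bar_eq >= 0.95 * Q
  hit <- NA_real_
  for (i in seq_len(n - 4L)) {
    if (all(ok[i:(i + 4L)])) { hit <- sweep$grid[i]; break }
  }
  .threshold_result("M_Q", hit,
                    "5 consecutive grid points with q_bar_eq >= 0.95 Q",
                    sweep$grid)
}

#' Early-stopping scan for the frequency-recovery threshold
#'
#' Equivalent to `find_M_Q(sweep_migration(base, grid, settings))` — per-point
#' seeds are spawned identically, so the returned threshold is the same —
#' but the scan walks the grid left to right and stops as soon as five
#' consecutive points satisfy `q_bar_eq >= 0.95 Q`, roughly halving the cost
#' of threshold tabulation over wide grids.
#'
#' @inheritParams sweep_migration
#' @return A `"threshold_result"` of kind `"M_Q"`, with the simulated
#'   portion of the sweep attached as element `sweep`.
#' @export
scan_M_Q <- function(base, grid, settings) {
  stopifnot(inherits(base, "scenario"), inherits(settings, "sim_settings"))
  if (length(grid) < 5L || any(grid < 0) || any(diff(grid) <= 0))
    stop("'grid' must be strictly increasing, non-negative, length >= 5",
         call. = FALSE)
  seeds <- .spawn_seeds(settings$seed, length(grid))
  rows <- vector("list", length(grid))
  run <- 0L
  n_done <- 0L
  hit <- NA_real_
  for (i in seq_along(grid)) {
    scn <- base
    scn$migration$M <- grid[i]
    rows[[i]] <- .sweep_point(scn, settings, seeds[[i]])
    n_done <- i
    ok <- !is.na(rows[[i]]$q_bar_eq) &&
      rows[[i]]$q_bar_eq >= 0.95 * base$Q
    run <- if (ok) run + 1L else 0L
    if (run == 5L) { hit <- grid[i - 4L]; break }
  }
  tab <- cbind(data.frame(M = grid[seq_len(n_done)]),
               do.call(rbind, rows[seq_len(n_done)]))
  out <- .threshold_result("M_Q", hit,
                           "5 consecutive grid points with q_bar_eq >= 0.95 Q",
                           grid)
  out$sweep <- sweep_result(tab, axis = "migration", scenario = base,
                            settings = settings)
  out
}

#' Migration threshold for 95\% probability of allele presence (M_95)
#'
#' The minimal migration rate on the sweep grid whose equilibrium-phase
#' probability of allele presence is at least 0.95.
#'
#' @param sweep A migration-axis `"sweep_result"`.
#'
#' @return A `"threshold_result"` of kind `"M_95"`, carrying the Monte Carlo
#'   standard error of `P_eq` at the crossing point.
#' @export
find_M_95 <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (sweep$axis != "migration")
    stop("'sweep' must be a migration sweep", call. = FALSE)
  ok <- !is.na(sweep$table$P_eq) & sweep$table$P_eq >= 0.95
  i <- which(ok)
  if (length(i) == 0L)
    return(.threshold_result("M_95", NA_real_, "P_eq >= 0.95", sweep$grid))
  se <- if ("se_P" %in% names(sweep$table)) sweep$table$se_P[i[1L]]
        else NA_real_
  .threshold_result("M_95", sweep$grid[i[1L]], "P_eq >= 0.95", sweep$grid, se)
}

#' Cut-off source frequency for 95\% presence probability (Q_c)
#'
#' Sweeps the source-population allele frequency at a fixed migration rate
#' and returns the minimal grid frequency whose equilibrium-phase presence
#' probability reaches 0.95. Alleles at or above `Q_c` in the source are
#' expected (with 95\% confidence) to be present in the founded population
#' at migration-drift balance; alleles below it are not.
#'
#' @param base The base [scenario()].
#' @param M Migration rate at which to scan.
#' @param Q_grid Strictly increasing source frequencies in `(0, 1]`;
#'   default `seq(0.01, 0.2, by = 0.01)`.
#' @param settings A [sim_settings()].
#'
#' @return A `"threshold_result"` of kind `"Q_c"`, with the underlying
#'   source-frequency `"sweep_result"` attached as element `sweep`.
#' @export
find_Q_c <- function(base, M, Q_grid = seq(0.01, 0.2, by = 0.01), settings) {
  stopifnot(inherits(base, "scenario"), inherits(settings, "sim_settings"))
  if (length(Q_grid) == 0L || any(Q_grid <= 0) || any(Q_grid > 1) ||
      any(diff(Q_grid) <= 0))
    stop("'Q_grid' must be strictly increasing within (0, 1]", call. = FALSE)
  seeds <- .spawn_seeds(settings$seed, length(Q_grid))
  rows <- vector("list", length(Q_grid))
  for (i in seq_along(Q_grid)) {
    scn <- base
    scn$migration$M <- M
    scn$Q <- Q_grid[i]
    rows[[i]] <- .sweep_point(scn, settings, seeds[[i]])
  }
  tab <- cbind(data.frame(Q = Q_grid), do.call(rbind, rows))
  sw <- sweep_result(tab, axis = "source_frequency", scenario = base,
                     settings = settings)
  ok <- !is.na(tab$P_eq) & tab$P_eq >= 0.95
  i <- which(ok)
  value <- if (length(i) == 0L) NA_real_ else Q_grid[i[1L]]
  se <- if (length(i) == 0L) NA_real_ else tab$se_P[i[1L]]
  out <- .threshold_result("Q_c", value, "P_eq >= 0.95 at source frequency Q",
                           Q_grid, se)
  out$sweep <- sw
  out
}

#' Waiting-time approximation of the equilibrium mean allele frequency
#'
#' Copies of the allele arrive from the source at rate `2 M Q` per
#' generation, so the expected spacing between arrivals is `1 / (2 M Q)`;
#' an individual copy arriving in a population at carrying capacity is lost
#' after approximately `2 ln(2 K)` generations (diffusion result for a rare
#' allele). When arrivals are more frequent than losses the allele is
#' effectively always present and the mean frequency stabilizes at `Q`;
#' below that point the mean is reduced in proportion to the fraction of
#' time the allele is present:
#' \deqn{\bar{q}_{eq} \approx Q \min(1,\; \alpha\, 4 M Q \ln(2K))}
#' The scale parameter `alpha` (default 1) absorbs the roughness of the
#' approximation and can be fitted to simulated sweeps with [fit_alpha()].
#'
#' @param M Migration rate(s) (>= 0); vectorized.
#' @param Q Source allele frequency in `(0, 1]`.
#' @param K Carrying capacity (>= 1).
#' @param alpha Scale parameter (> 0), default 1.
#'
#' @return Approximate equilibrium mean frequency, same length as `M`.
#' @export
#' @examples
#' approx_mean_freq(M = c(0.1, 0.5, 2), Q = 0.2, K = 200)
approx_mean_freq <- function(M, Q, K, alpha = 1) {
  if (any(M < 0)) stop("'M' must be >= 0", call. = FALSE)
  if (Q <= 0 || Q > 1) stop("'Q' must be in (0, 1]", call. = FALSE)
  if (K < 1) stop("'K' must be >= 1", call. = FALSE)
  Q * pmin(1, alpha * 4 * M * Q * log(2 * K))
}

#' Fit the scale parameter of the waiting-time approximation
#'
#' Least-squares fit of `alpha` in the [approx_mean_freq()] model to a
#' simulated migration sweep's equilibrium mean frequencies. Only the
#' ramp (uncapped) region identifies `alpha`; points already at the cap
#' contribute no slope information, so the fit requires at least three grid
#' points clearly below the cap (`q_bar_eq < 0.95 Q`) and errors otherwise.
#'
#' @param sweep A migration-axis `"sweep_result"`.
#' @param Q Source allele frequency; defaults to the sweep scenario's `Q`.
#' @param K Carrying capacity; defaults to the sweep scenario's `K`.
#'
#' @return An object of class `"approx_fit"` with elements `alpha`,
#'   `rss` (residual sum of squares over all non-failed points) and
#'   `n_ramp` (points used to anchor the fit).
#' @export
fit_alpha <- function(sweep, Q = NULL, K = NULL) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (sweep$axis != "migration")
    stop("'sweep' must be a migration sweep", call. = FALSE)
  if (is.null(Q)) Q <- sweep$scenario$Q
  if (is.null(K)) K <- sweep$scenario$demography$K
  if (is.null(Q) || is.null(K))
    stop("'Q' and 'K' must be supplied", call. = FALSE)
  keep <- !is.na(sweep$table$q_bar_eq)
  M <- sweep$grid[keep]
  y <- sweep$table$q_bar_eq[keep]
  c0 <- 4 * Q * log(2 * K)
  ramp <- y < 0.95 * Q & M > 0
  if (sum(ramp) < 3L)
    stop("alpha is unidentifiable: fewer than 3 grid points below the cap",
         call. = FALSE)
  # slope through the origin on the ramp, then refine on the full
  # piecewise model; keep whichever minimizes the residual sum of squares
  a0 <- sum(M[ramp] * y[ramp]) / (Q * c0 * sum(M[ramp]^2))
  sse <- function(a) sum((y - Q * pmin(1, a * c0 * M))^2)
  opt <- stats::optimize(sse, interval = c(a0 / 10, a0 * 10), tol = 1e-12)
  alpha <- if (sse(a0) <= opt$objective) a0 else opt$minimum
  structure(list(alpha = alpha, rss = sse(alpha), n_ramp = sum(ramp)),
            class = "approx_fit")
}

#' @export
print.threshold_result <- function(x, ...) {
  val <- if (x$attained) format(x$value) else "not attained"
  cat(sprintf("%s = %s  (criterion: %s; grid step %s)\n",
              x$kind, val, x$criterion, format(x$grid_step)))
  invisible(x)
}

#' @export
print.approx_fit <- function(x, ...) {
  cat(sprintf("Fitted scale alpha = %.6g (rss %.3g, %d ramp points)\n",
              x$alpha, x$rss, x$n_ramp))
  invisible(x)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep over %s: %d grid points in [%g, %g]\n",
              x$axis, length(x$grid), min(x$grid), max(x$grid)))
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("...\n")
  invisible(x)
}
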