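#' Define a grid of founding scenarios
#'
#' The cross-product of the supplied demographic and genetic parameter
#' lists defines the scenario set for [run_grid()] and [run_recovery()].
#' All scenarios share the migration grid, the back-migration proportion,
#' the migration mode and the simulation settings.
#'
#' @param N0 Initial census sizes (one or more).
#' @param r Growth rates (one or more).
#' @param K Carrying capacities (one or more).
#' @param Q Source allele frequencies (one or more).
#' @param m_grid Migration-rate grid shared by all scenarios.
#' @param m Back-migration proportion (default 0.01).
#' @param mode Migration mode, `"poisson"` or `"deterministic"`.
#' @param settings A [sim_settings()].
#'
#' @return An object of class `"scenario_grid"`.
#' @export
#' @examples
#' scenario_grid(N0 = 5, r = 0.01, K = 200, Q = c(0.02, 0.2),
#'               m_grid = seq(0, 2, 0.5), settings = sim_settings(seed = 1))
scenario_grid <- function(N0, r, K, Q, m_grid, m = 0.01,
                          mode = c("poisson", "deterministic"),
                          settings = sim_settings()) {
  mode <- match.arg(mode)
  stopifnot(inherits(settings, "sim_settings"))
  for (nm in c("N0", "r", "K", "Q")) {
    v <- get(nm)
    if (length(v) == 0L || anyNA(v))
      stop(sprintf("'%s' must be a non-empty vector", nm), call. = FALSE)
  }
  if (length(m_grid) == 0L || any(m_grid < 0) || any(diff(m_grid) <= 0))
    stop("'m_grid' must be non-empty, non-negative, strictly increasing",
         call. = FALSE)
  structure(list(N0 = N0, r = r, K = K, Q = Q, m_grid = m_grid, m = m,
                 mode = mode, settings = settings),
            class = "scenario_grid")
}

.grid_combos <- function(grid, with_Q = TRUE) {
  if (with_Q)
    expand.grid(Q = grid$Q, K = grid$K, r = grid$r, N0 = grid$N0)[
      , c("N0", "r", "K", "Q")]
  else
    expand.grid(K = grid$K, r = grid$r, N0 = grid$N0)[, c("N0", "r", "K")]
}

.grid_manifest <- function(grid, kind, extra = list()) {
  c(list(
    kind = kind,
    package = "alleleflow",
    version = as.character(utils::packageVersion("alleleflow")),
    N0 = grid$N0, r = grid$r, K = grid$K, Q = grid$Q,
    m_grid = grid$m_grid, back_m = grid$m, mode = grid$mode,
    n_reps = grid$settings$n_reps,
    trend_window = grid$settings$trend_window,
    post_eq_window = grid$settings$post_eq_window,
    max_generations = grid$settings$max_generations,
    seed = grid$settings$seed
  ), extra)
}

.write_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
}

#' Run a scenario grid and tabulate migration thresholds
#'
#' For every `(N0, r, K, Q)` combination, sweeps the migration grid to
#' equilibrium and extracts `M_Q` and `M_95`. Writes a threshold table
#' (`thresholds.csv`), one sweep archive per scenario (under `sweeps/`) and
#' a machine-readable JSON manifest recording every parameter and seed, so
#' a run is reproducible from its manifest alone. Per-scenario failures are
#' recorded in the manifest and the table rather than aborting the grid.
#'
#' The default back-migration proportion `m = 0.01` is a package choice
#' (emigrants carry alleles at the founded population's own frequency, so
#' `m` does not move the expected frequency and has only a second-order
#' effect on drift); a message flags it on every run.
#'
#' @param grid A [scenario_grid()].
#' @param out Output directory (created if missing), or `NULL` to skip
#'   writing files.
#'
#' @return Invisibly, a list with the threshold `table` (one row per
#'   scenario: `N0, r, K, Q, M_Q, M_95, failed`), the per-scenario `sweeps`,
#'   and the `manifest`.
#' @export
run_grid <- function(grid, out = NULL) {
  stopifnot(inherits(grid, "scenario_grid"))
  message(sprintf("back-migration proportion m = %g (package default %s)",
                  grid$m, if (grid$m == 0.01) "in effect" else "overridden"))
  combos <- .grid_combos(grid)
  seeds <- .spawn_seeds(grid$settings$seed, nrow(combos))
  sweeps <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cm <- combos[i, ]
    base <- scenario(demography_params(cm$N0, cm$r, cm$K),
                     migration_params(0, grid$m, grid$mode), Q = cm$Q)
    s <- grid$settings
    s$seed <- seeds[[i]]
    sw <- sweep_migration(base, grid$m_grid, s)
    sweeps[[i]] <- sw
    # fewer than 5 grid points cannot host the 5-point M_Q window
    mq_val <- if (length(grid$m_grid) >= 5L) find_M_Q(sw)$value else NA_real_
    m95 <- find_M_95(sw)
    rows[[i]] <- data.frame(
      N0 = cm$N0, r = cm$r, K = cm$K, Q = cm$Q,
      M_Q = mq_val, M_95 = m95$value,
      failed = any(sw$table$failed))
  }
  table <- do.call(rbind, rows)
  manifest <- .grid_manifest(grid, "thresholds",
                             list(scenario_seeds = unlist(seeds),
                                  n_failed = sum(table$failed)))
  if (!is.null(out)) {
    dir.create(file.path(out, "sweeps"), recursive = TRUE,
               showWarnings = FALSE)
    .write_csv(table, file.path(out, "thresholds.csv"))
    for (i in seq_len(nrow(combos))) {
      cm <- combos[i, ]
      fn <- sprintf("sweep_N0%g_r%g_K%g_Q%g.csv", cm$N0, cm$r, cm$K, cm$Q)
      .write_csv(sweeps[[i]]$table, file.path(out, "sweeps", fn))
    }
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(table = table, sweeps = sweeps, manifest = manifest))
}

#' Cut-off frequencies and allelic-richness recovery over a scenario grid
#'
#' For every demographic combination `(N0, r, K)` and every migration rate
#' in `M_values`, scans the source-frequency grid for the cut-off `Q_c` and
#' converts it into expected allelic-richness recovery under each supplied
#' spectrum. When `Q_c` is not attained within the grid the recovery
#' proportion is reported as 0 and flagged.
#'
#' @param grid A [scenario_grid()] (its `Q` list is ignored; the
#'   source-frequency axis is scanned instead).
#' @param M_values Migration rates at which to derive cut-offs.
#' @param spectra A list of [spectrum_model()] and/or
#'   [empirical_spectrum()] objects.
#' @param out Output directory, or `NULL` to skip writing files.
#' @param Q_grid Source-frequency scan grid; default
#'   `seq(0.01, 0.2, by = 0.01)`.
#'
#' @return Invisibly, a list with the recovery `table` and the `manifest`.
#' @export
run_recovery <- function(grid, M_values, spectra, out = NULL,
                         Q_grid = seq(0.01, 0.2, by = 0.01)) {
  stopifnot(inherits(grid, "scenario_grid"))
  if (inherits(spectra, "spectrum_model") ||
      inherits(spectra, "empirical_spectrum")) spectra <- list(spectra)
  combos <- .grid_combos(grid, with_Q = FALSE)
  cases <- merge(combos, data.frame(M = M_values), by = NULL)
  seeds <- .spawn_seeds(grid$settings$seed, nrow(cases))
  rows <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    base <- scenario(demography_params(cs$N0, cs$r, cs$K),
                     migration_params(cs$M, grid$m, grid$mode), Q = Q_grid[1])
    s <- grid$settings
    s$seed <- seeds[[i]]
    qc <- find_Q_c(base, cs$M, Q_grid, s)
    row <- data.frame(N0 = cs$N0, r = cs$r, K = cs$K, M = cs$M,
                      Q_c = qc$value, attained = qc$attained)
    for (j in seq_along(spectra)) {
      sp <- spectra[[j]]
      if (qc$attained) {
        rep_j <- if (inherits(sp, "empirical_spectrum"))
          empirical_recovery(sp, qc$value) else recovery_report(qc$value, sp)
        above <- rep_j$expected_above
        prop <- rep_j$proportion
        th <- rep_j$theta
      } else {
        above <- 0; prop <- 0
        th <- if (inherits(sp, "empirical_spectrum")) NA_real_ else sp$theta
      }
      lab <- if (is.na(th)) sprintf("empirical%d", j)
             else sprintf("theta%g", th)
      row[[paste0("alleles_above_", lab)]] <- above
      row[[paste0("proportion_", lab)]] <- prop
    }
    rows[[i]] <- row
  }
  table <- do.call(rbind, rows)
  manifest <- .grid_manifest(grid, "recovery",
                             list(M_values = M_values, Q_grid = Q_grid,
                                  case_seeds = unlist(seeds)))
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    .write_csv(table, file.path(out, "recovery.csv"))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(table = table, manifest = manifest))
}
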