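#' Fractional accumulator state for deterministic migration
#'
#' Under the deterministic migration pattern the number of migrants per
#' generation is constant in the long-run-average sense: a fractional
#' accumulator carries the remainder of the mean rate between generations
#' and emits integer counts whose cumulative total over `G` generations
#' stays within one migrant of `G` times the mean rate. One state object
#' tracks immigration and emigration separately.
#'
#' @return An object of class `"migration_state"` with accumulators at zero.
#' @export
migration_state <- function() {
  structure(list(acc_in = 0, acc_out = 0), class = "migration_state")
}

.emit_count <- function(acc, rate) {
  acc <- acc + rate
  k <- floor(acc + 1e-9)  # guard against 0.9999... float representations
  list(count = as.integer(k), acc = acc - k)
}

#' Draw one generation of migrant counts
#'
#' Returns the number of immigrants `I` and emigrants `E` for one
#' generation, given the current rounded census size. In `"poisson"` mode
#' `I ~ Poisson(M)` and `E ~ min(Poisson(m N), N)` independently per
#' replicate; in `"deterministic"` mode both counts come from the fractional
#' accumulator in `state` and are shared by all replicates. Emigrant counts
#' are truncated at `N`: no more individuals can leave than exist.
#'
#' @param N Current rounded census size (>= 0).
#' @param mig A [migration_params()] object.
#' @param n Number of replicate draws (default 1).
#' @param state A [migration_state()], used (and advanced) only in
#'   deterministic mode.
#'
#' @return A list with integer vectors `I` and `E` of length `n` and the
#'   updated `state`.
#' @export
#' @examples
#' draw <- sample_migration(100, migration_params(M = 2.5, m = 0.01), n = 5)
#' draw$I
sample_migration <- function(N, mig, n = 1L, state = migration_state()) {
  if (!inherits(mig, "migration_params"))
    stop("'mig' must be a migration_params object", call. = FALSE)
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 0)
    stop("'N' must be a single number >= 0", call. = FALSE)
  n <- as.integer(n)
  if (mig$mode == "poisson") {
    I <- stats::rpois(n, mig$M)
    E <- pmin(stats::rpois(n, mig$m * N), as.integer(N))
  } else {
    ei <- .emit_count(state$acc_in, mig$M)
    ee <- .emit_count(state$acc_out, mig$m * N)
    state$acc_in <- ei$acc
    state$acc_out <- ee$acc
    I <- rep.int(ei$count, n)
    E <- rep.int(min(ee$count, as.integer(N)), n)
  }
  list(I = as.integer(I), E = as.integer(E), state = state)
}
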