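# Round half-up to the nearest integer (not banker's rounding): census sizes
# are delineated this way before any gamete or emigrant count is drawn.
round_half_up <- function(x) floor(x + 0.5)

#' Discrete logistic census trajectory
#'
#' Iterates \eqn{N_{t+1} = N_t + r N_t (1 - N_t/K)} from `N0` for `T`
#' generations. The recursion is maintained in floating point; rounding the
#' recursion itself would freeze growth whenever the per-generation increment
#' falls below 0.5 (e.g. `N0 = 5, r = 0.01` gives an increment of 0.0488),
#' so sizes are rounded half-up only at the point of use. Both the
#' real-valued and the rounded sequence are returned.
#'
#' @param dem A [demography_params()] object.
#' @param T Number of generations to project (>= 0).
#'
#' @return A data frame with columns `generation` (0..T), `size_real`
#'   (floating-point recursion) and `size` (rounded half-up).
#' @export
#' @examples
#' logistic_trajectory(demography_params(100, 0.1, 200), 3)
logistic_trajectory <- function(dem, T) {
  if (!inherits(dem, "demography_params"))
    stop("'dem' must be a demography_params object", call. = FALSE)
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T < 0)
    stop("'T' must be a single integer >= 0", call. = FALSE)
  T <- as.integer(T)
  n <- numeric(T + 1L)
  n[1L] <- dem$N0
  if (T > 0L) {
    for (t in seq_len(T)) {
      n[t + 1L] <- n[t] + dem$r * n[t] * (1 - n[t] / dem$K)
    }
  }
  data.frame(generation = 0:T, size_real = n, size = round_half_up(n))
}
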