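#' One Wright-Fisher generation with migration
#'
#' Advances the allele frequency by one generation. After `E` emigrants
#' leave and `I` immigrants arrive, the next-generation gene pool is built
#' by independent gamete draws: `X ~ Binomial(2 (N - E), q)` copies from the
#' resident pool and `Y ~ Binomial(2 I, Q)` copies carried by immigrants,
#' giving frequency `(X + Y) / (2 (N - E) + 2 I)`. If the post-migration
#' pool is empty the frequency is defined as 0 and a warning is raised; an
#' allele cannot persist in an empty pool.
#'
#' Vectorized over `q`, `I` and `E` (replicates share the census size `N`).
#'
#' @param q Current allele frequency (vector, each in `[0, 1]`).
#' @param N Current rounded census size (single value, >= 0).
#' @param I Immigrant counts (vector, >= 0).
#' @param E Emigrant counts (vector, `0 <= E <= N`).
#' @param Q Source-population allele frequency, in `[0, 1]`.
#'
#' @return Next-generation allele frequencies, same length as `q`.
#' @export
#' @examples
#' set.seed(1)
#' wf_step(q = 0.3, N = 100, I = 2, E = 1, Q = 0.1)
wf_step <- function(q, N, I, E, Q) {
  if (anyNA(q) || any(q < 0) || any(q > 1))
    stop("'q' must lie in [0, 1]", call. = FALSE)
  if (length(Q) != 1L || is.na(Q) || Q < 0 || Q > 1)
    stop("'Q' must be a single value in [0, 1]", call. = FALSE)
  if (length(N) != 1L || is.na(N) || N < 0)
    stop("'N' must be a single value >= 0", call. = FALSE)
  if (any(E > N))
    stop("emigrant count exceeds census size", call. = FALSE)
  R <- 2L * (as.integer(N) - as.integer(E))
  G <- 2L * as.integer(I)
  X <- stats::rbinom(length(q), R, q)
  Y <- stats::rbinom(length(q), G, Q)
  den <- R + G
  out <- (X + Y) / den
  empty <- den == 0L
  if (any(empty)) {
    warning("empty post-migration gene pool; frequency set to 0",
            call. = FALSE)
    out[empty] <- 0
  }
  out
}

#' One-generation founder event
#'
#' Draws the initial allele frequency of the founded population from the
#' source: `2 N0` founder gametes are sampled independently at frequency
#' `Q`, so `q0 = X / (2 N0)` with `X ~ Binomial(2 N0, Q)`. This replaces
#' the default premise `q0 = 0` (allele already lost at founding) by an
#' explicit founder draw.
#'
#' @param N0 Founder census size (integer >= 1).
#' @param Q Source-population allele frequency, in `[0, 1]`.
#' @param n Number of independent replicate draws (default 1).
#'
#' @return Numeric vector of length `n` of initial frequencies.
#' @export
#' @examples
#' set.seed(1)
#' founder_initialize(5, 0.1, n = 3)
founder_initialize <- function(N0, Q, n = 1L) {
  if (!is.numeric(N0) || length(N0) != 1L || is.na(N0) || N0 < 1)
    stop("'N0' must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(Q) || length(Q) != 1L || is.na(Q) || Q < 0 || Q > 1)
    stop("'Q' must be a single value in [0, 1]", call. = FALSE)
  stats::rbinom(as.integer(n), 2L * as.integer(N0), Q) / (2 * as.integer(N0))
}

#' Exact one-generation transition distribution
#'
#' Enumerates the exact probability mass function of the next-generation
#' allele frequency for one [wf_step()] configuration, by convolving the two
#' binomial gamete draws (resident pool and immigrant pool). Intended as an
#' independent oracle for small gene pools; refuses pools larger than 64
#' gene copies.
#'
#' @param N Census size (>= 0).
#' @param q Current allele frequency, in `[0, 1]`.
#' @param Q Source-population allele frequency, in `[0, 1]`.
#' @param I Immigrant count (>= 0).
#' @param E Emigrant count (`0 <= E <= N`).
#'
#' @return A data frame with columns `count` (copies of the allele), `freq`
#'   (count divided by pool size) and `prob`; probabilities sum to 1 within
#'   1e-12. For an empty pool, a single row with frequency 0 and
#'   probability 1.
#' @export
#' @examples
#' transition_pmf(N = 1, q = 0.5, Q = 0, I = 0, E = 0)
transition_pmf <- function(N, q, Q, I = 0L, E = 0L) {
  if (length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop("'q' must be a single value in [0, 1]", call. = FALSE)
  if (length(Q) != 1L || is.na(Q) || Q < 0 || Q > 1)
    stop("'Q' must be a single value in [0, 1]", call. = FALSE)
  if (E > N) stop("emigrant count exceeds census size", call. = FALSE)
  R <- 2L * (as.integer(N) - as.integer(E))
  G <- 2L * as.integer(I)
  if (R + G > 64L)
    stop("gene pool exceeds the enumeration bound of 64 copies",
         call. = FALSE)
  if (R + G == 0L)
    return(data.frame(count = 0L, freq = 0, prob = 1))
  px <- stats::dbinom(0:R, R, q)
  py <- stats::dbinom(0:G, G, Q)
  pz <- numeric(R + G + 1L)
  for (i in 0:R) pz[i + 0:G + 1L] <- pz[i + 0:G + 1L] + px[i + 1L] * py
  data.frame(count = 0:(R + G), freq = (0:(R + G)) / (R + G), prob = pz)
}
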