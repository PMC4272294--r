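#' Ewens allele frequency spectrum model
#'
#' The neutral-theory expected allele frequency spectrum of the source
#' population: the expected number of alleles with frequency in
#' `(x, x + dx)` is `phi(x) dx` with
#' \eqn{\phi(x) = \theta x^{-1} (1 - x)^{\theta - 1}}, where
#' \eqn{\theta = 4 N_{ev} \mu}, `N_ev` the variance effective size of the
#' source and `mu` the per-locus mutation rate per generation. Supply
#' `theta` directly, or `N_ev` and `mu` together.
#'
#' @param theta Scaled mutation rate (> 0), or `NULL` to derive it from
#'   `N_ev` and `mu`.
#' @param N_ev Variance effective population size of the source (optional;
#'   required by [recovery_report()] to set the smallest representable
#'   frequency).
#' @param mu Per-locus mutation rate per generation (optional).
#'
#' @return An object of class `"spectrum_model"`.
#' @export
#' @examples
#' spectrum_model(theta = 1, N_ev = 500)
#' spectrum_model(N_ev = 500, mu = 5e-4)  # theta = 1
spectrum_model <- function(theta = NULL, N_ev = NULL, mu = NULL) {
  if (is.null(theta)) {
    if (is.null(N_ev) || is.null(mu))
      stop("supply 'theta', or both 'N_ev' and 'mu'", call. = FALSE)
    theta <- 4 * N_ev * mu
  } else if (!is.null(N_ev) && !is.null(mu) &&
             abs(theta - 4 * N_ev * mu) > 1e-9) {
    stop("'theta' is inconsistent with 4 * N_ev * mu", call. = FALSE)
  }
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta <= 0)
    stop("'theta' must be a single number > 0", call. = FALSE)
  structure(list(theta = as.numeric(theta), N_ev = N_ev, mu = mu),
            class = "spectrum_model")
}

#' Expected allele density of the Ewens spectrum
#'
#' Evaluates \eqn{\phi(x) = \theta x^{-1} (1 - x)^{\theta - 1}}.
#'
#' @param x Allele frequency, strictly inside `(0, 1)`; vectorized.
#' @param spec A [spectrum_model()].
#'
#' @return `phi(x)`, same length as `x`.
#' @export
#' @examples
#' ewens_density(0.5, spectrum_model(theta = 1))  # 2
ewens_density <- function(x, spec) {
  stopifnot(inherits(spec, "spectrum_model"))
  if (any(x <= 0) || any(x >= 1))
    stop("'x' must lie strictly inside (0, 1)", call. = FALSE)
  spec$theta * x^(-1) * (1 - x)^(spec$theta - 1)
}

#' Expected number of alleles above a cut-off frequency
#'
#' Integrates the Ewens density from `Qc` to 1 with relative tolerance
#' 1e-8, giving the expected number of alleles whose source-population
#' frequency is at least the cut-off.
#'
#' @param Qc Cut-off frequency in `(0, 1]`.
#' @param spec A [spectrum_model()].
#'
#' @return A non-negative expected allele count.
#' @export
#' @examples
#' expected_alleles_above(0.2, spectrum_model(theta = 1))  # log(5)
expected_alleles_above <- function(Qc, spec) {
  stopifnot(inherits(spec, "spectrum_model"))
  if (length(Qc) != 1L || is.na(Qc) || Qc <= 0 || Qc > 1)
    stop("'Qc' must be a single value in (0, 1]", call. = FALSE)
  if (Qc == 1) return(0)
  stats::integrate(function(x) ewens_density(x, spec), Qc, 1,
                   rel.tol = 1e-8, subdivisions = 500L)$value
}

#' Expected allelic-richness recovery above a cut-off
#'
#' Converts a cut-off frequency `Q_c` into the expected number and
#' proportion of the source population's alleles that lie above the
#' cut-off, i.e. the allelic richness expected to be retained or recovered
#' by gene flow under the 95\% presence-probability criterion. The total
#' expected allele count integrates the spectrum from the smallest
#' frequency representable in the source, `x_min = 1 / (2 N_ev)` by
#' default.
#'
#' Note the proportions treat allele presence events as independent across
#' alleles; presence probabilities of different alleles at one locus are in
#' fact dependent, so reports are approximations of expected recovery.
#'
#' @param Qc Cut-off frequency in `(0, 1]`.
#' @param spec A [spectrum_model()]; `N_ev` must be set unless `x_min` is
#'   given.
#' @param x_min Lower integration bound for the total allele count;
#'   default `1 / (2 N_ev)`.
#'
#' @return An object of class `"recovery_report"` with elements `Q_c`,
#'   `expected_above`, `expected_total`, `proportion`, `theta`, `x_min`.
#' @export
#' @examples
#' recovery_report(0.2, spectrum_model(theta = 1, N_ev = 500))
recovery_report <- function(Qc, spec, x_min = NULL) {
  stopifnot(inherits(spec, "spectrum_model"))
  if (is.null(x_min)) {
    if (is.null(spec$N_ev))
      stop("'x_min' or spec$N_ev must be supplied", call. = FALSE)
    x_min <- 1 / (2 * spec$N_ev)
  }
  if (length(Qc) != 1L || is.na(Qc) || Qc <= 0 || Qc > 1)
    stop("'Qc' must be a single value in (0, 1]", call. = FALSE)
  total <- expected_alleles_above(x_min, spec)
  if (Qc < x_min) {
    warning("'Qc' below the smallest representable frequency; ",
            "proportion clipped to 1", call. = FALSE)
    above <- total
  } else {
    above <- expected_alleles_above(Qc, spec)
  }
  structure(list(Q_c = Qc, expected_above = above, expected_total = total,
                 proportion = above / total, theta = spec$theta,
                 x_min = x_min),
            class = "recovery_report")
}

#' Empirical allele frequency spectrum
#'
#' A tabulated spectrum: allele frequencies (strictly increasing, in
#' `(0, 1]`) and the observed or expected number of alleles at each. Use
#' when a genetic study of the source population supplies an actual
#' spectrum instead of the Ewens theoretical form; recovery proportions are
#' then derived directly from the table.
#'
#' @param frequency Strictly increasing frequencies in `(0, 1]`.
#' @param count Non-negative allele counts, one per frequency.
#'
#' @return An object of class `"empirical_spectrum"` (a data frame).
#' @export
#' @examples
#' empirical_spectrum(c(0.1, 0.3), c(3, 1))
empirical_spectrum <- function(frequency, count) {
  if (length(frequency) == 0L || length(frequency) != length(count))
    stop("'frequency' and 'count' must be non-empty and equal length",
         call. = FALSE)
  if (any(frequency <= 0) || any(frequency > 1) || any(diff(frequency) <= 0))
    stop("'frequency' must be strictly increasing within (0, 1]",
         call. = FALSE)
  if (any(count < 0) || anyNA(count))
    stop("'count' must be non-negative", call. = FALSE)
  structure(data.frame(frequency = frequency, count = count),
            class = c("empirical_spectrum", "data.frame"))
}

#' Read an empirical spectrum from a two-column CSV
#'
#' The file must have a header row and two columns: allele frequency and
#' allele count.
#'
#' @param path Path to the CSV file.
#' @return An [empirical_spectrum()].
#' @export
read_spectrum <- function(path) {
  tab <- utils::read.csv(path)
  if (ncol(tab) < 2L)
    stop("spectrum CSV must have two columns (frequency, count)",
         call. = FALSE)
  empirical_spectrum(tab[[1L]], tab[[2L]])
}

#' Recovery report from an empirical spectrum
#'
#' Counts the alleles tabulated at frequencies at or above the cut-off and
#' reports them as number and proportion of the full table.
#'
#' @param spectrum An [empirical_spectrum()].
#' @param Qc Cut-off frequency.
#'
#' @return A `"recovery_report"` (with `theta = NA`).
#' @export
#' @examples
#' empirical_recovery(empirical_spectrum(c(0.1, 0.3), c(3, 1)), Qc = 0.2)
empirical_recovery <- function(spectrum, Qc) {
  stopifnot(inherits(spectrum, "empirical_spectrum"))
  total <- sum(spectrum$count)
  if (total == 0)
    stop("total allele count is zero; proportion undefined", call. = FALSE)
  above <- sum(spectrum$count[spectrum$frequency >= Qc])
  structure(list(Q_c = Qc, expected_above = above, expected_total = total,
                 proportion = above / total, theta = NA_real_,
                 x_min = min(spectrum$frequency)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "Recovery at Q_c = %g: %.4g of %.4g expected alleles (proportion %.3f)\n",
    x$Q_c, x$expected_above, x$expected_total, x$proportion))
  cat("  (treats allele presence events as independent across alleles)\n")
  invisible(x)
}
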