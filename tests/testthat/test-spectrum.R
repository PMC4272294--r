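test_that("spectrum model ties theta to 4 N_ev mu", {
  expect_equal(spectrum_model(N_ev = 500, mu = 5e-4)$theta, 1)
  expect_equal(spectrum_model(theta = 2)$theta, 2)
  expect_error(spectrum_model(theta = 1, N_ev = 500, mu = 1e-3),
               "inconsistent")
  expect_error(spectrum_model(theta = 0), "'theta'")
  expect_error(spectrum_model(), "supply")
})

test_that("ewens density evaluates theta x^-1 (1-x)^(theta-1)", {
  # theta = 1: the (1-x)^0 factor vanishes, density is 1/x
  expect_equal(ewens_density(0.5, spectrum_model(theta = 1)), 2)
  expect_equal(ewens_density(0.1, spectrum_model(theta = 1)), 10)
  # theta = 2: 2 * (1/x) * (1-x)
  expect_equal(ewens_density(0.5, spectrum_model(theta = 2)), 2)
  expect_equal(ewens_density(0.2, spectrum_model(theta = 2)), 8)
  expect_error(ewens_density(0, spectrum_model(theta = 1)), "strictly")
  expect_error(ewens_density(1, spectrum_model(theta = 1)), "strictly")
})

test_that("integrated allele counts match closed forms to 1e-8", {
  # theta = 1: integral of 1/x from Qc to 1 is ln(1/Qc)
  expect_lt(abs(expected_alleles_above(0.2, spectrum_model(theta = 1)) -
                  log(5)), 1e-8)
  # theta = 2: integral of 2(1/x - 1) is 2[ln x - x]
  closed <- 2 * ((log(1) - 1) - (log(0.5) - 0.5))
  expect_lt(abs(expected_alleles_above(0.5, spectrum_model(theta = 2)) -
                  closed), 1e-8)
  # empty interval
  expect_equal(expected_alleles_above(1, spectrum_model(theta = 2)), 0)
  expect_error(expected_alleles_above(0, spectrum_model(theta = 1)), "'Qc'")
})

test_that("expected counts are non-increasing and continuous in the cut-off", {
  spec <- spectrum_model(theta = 1.5)
  qc <- seq(0.01, 0.99, by = 0.02)
  vals <- vapply(qc, expected_alleles_above, numeric(1), spec = spec)
  expect_true(all(diff(vals) < 0))
  expect_true(all(abs(diff(vals)) < ewens_density(0.01, spec) * 0.02))
})

test_that("recovery reports express the recoverable fraction of richness", {
  spec <- spectrum_model(theta = 1, N_ev = 500)
  rep1 <- recovery_report(0.2, spec)
  expect_lt(abs(rep1$proportion - log(5) / log(1000)), 1e-8)
  expect_lte(rep1$expected_above, rep1$expected_total)

  # cut-off at the smallest representable frequency: everything recovered
  expect_equal(recovery_report(1 / 1000, spec)$proportion, 1)
  # cut-off of 1: nothing recovered
  expect_equal(recovery_report(1, spec)$proportion, 0)
  # below the representable minimum: clipped with a warning
  expect_warning(r <- recovery_report(1e-5, spec), "clipped")
  expect_equal(r$proportion, 1)
  expect_error(recovery_report(0.2, spectrum_model(theta = 1)), "N_ev")
})

test_that("more rare alleles (higher theta) lower the recovered proportion", {
  props <- vapply(c(0.5, 1, 2, 4), function(th)
    recovery_report(0.1, spectrum_model(theta = th, N_ev = 500))$proportion,
    numeric(1))
  expect_true(all(diff(props) < 0))
})

test_that("empirical spectra are counted directly", {
  sp <- empirical_spectrum(c(0.1, 0.3), c(3, 1))
  expect_equal(empirical_recovery(sp, 0.2)$proportion, 0.25)
  expect_equal(empirical_recovery(sp, 0.05)$proportion, 1)
  expect_equal(empirical_recovery(sp, 0.5)$proportion, 0)
  # a frequency exactly at the cut-off counts as recovered
  expect_equal(empirical_recovery(sp, 0.3)$proportion, 0.25)

  expect_error(empirical_spectrum(c(0.3, 0.1), c(1, 1)), "increasing")
  expect_error(empirical_spectrum(c(0.1, 0.3), c(-1, 1)), "count")
  expect_error(empirical_recovery(empirical_spectrum(0.1, 0), 0.05),
               "zero")
})

test_that("spectrum CSV round-trips through read_spectrum", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(frequency = c(0.05, 0.25, 0.6),
                              count = c(10, 2, 1)),
                   path, row.names = FALSE)
  sp <- read_spectrum(path)
  expect_s3_class(sp, "empirical_spectrum")
  expect_equal(sp$frequency, c(0.05, 0.25, 0.6))
  expect_equal(empirical_recovery(sp, 0.2)$proportion, 3 / 13)
})
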