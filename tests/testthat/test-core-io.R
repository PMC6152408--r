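test_that("spectra parse from delimited text, sorted and validated", {
  s <- read_spectrum(c("300,0.0", "340,1.0", "400,0.1"), kind = "emission")
  expect_s3_class(s, "quench_spectrum")
  expect_equal(s$wavelength, c(300, 340, 400))
  expect_equal(s$value, c(0, 1, 0.1))

  # tab delimiter and header line are auto-detected; rows get sorted
  s2 <- read_spectrum(c("wavelength\tvalue", "400\t0.1", "300\t0.0",
                        "340\t1.0"))
  expect_equal(s2$wavelength, c(300, 340, 400))
  expect_equal(s2$value, c(0, 1, 0.1))

  expect_error(read_spectrum(c("300,0.0", "340,abc")), "line 2")
  expect_error(read_spectrum(c("300,0.0", "300,1.0", "340,1")), "duplicate")
})

test_that("spectrum writer round-trips values and metadata exactly", {
  s <- spectrum(c(300, 340.25, 400), c(0.1, exp(1), pi), kind = "emission",
                temperature = 297, ligand_conc = 1.5e-5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, f)
  txt <- readLines(f)
  expect_true(any(grepl("temperature_K: 297", txt)))
  back <- read_spectrum(f)
  expect_identical(back$wavelength, s$wavelength)
  expect_identical(back$value, s$value)
  expect_equal(back$meta$temperature, 297)
  expect_equal(back$meta$ligand_conc, 1.5e-5)
  expect_equal(back$kind, "emission")
})

test_that("spectrum invariants are enforced", {
  expect_error(spectrum(c(300, 300), c(1, 2)), "increasing")
  expect_error(spectrum(300, 1), "at least 2")
  expect_error(spectrum(c(300, 310), c(1, 2, 3)), "lengths differ")
  expect_error(spectrum(c(300, 310), c(-0.1, 1), kind = "absorbance"),
               ">= 0")
  expect_error(spectrum(c(300, 310), c(1, 2), kind = "synchronous"),
               "delta_lambda")
  expect_error(spectrum(c(300, 310), c(1, 2), kind = "emission",
                        delta_lambda = 60), "synchronous")
})

test_that("resampling interpolates linearly without extrapolation", {
  s <- spectrum(c(300, 400), c(0, 1), kind = "emission")
  expect_equal(resample(s, c(300, 350))$value, c(0, 0.5))
  # identity on the original grid, idempotent on its own output
  r <- resample(s, c(300, 325, 400))
  expect_equal(resample(s, s$wavelength)$value, s$value)
  expect_equal(resample(r, r$wavelength)$value, r$value)
  # constant spectra survive any grid exactly
  cs <- spectrum(seq(300, 400, 10), rep(2.5, 11), kind = "emission")
  expect_equal(resample(cs, seq(301.5, 398.5, 0.7))$value,
               rep(2.5, length(seq(301.5, 398.5, 0.7))))
  expect_error(resample(s, 250), "beyond")
  # kind and metadata travel with the resampled object
  syn <- spectrum(c(300, 400), c(0, 1), kind = "synchronous",
                  delta_lambda = 60)
  expect_equal(resample(syn, c(310, 390))$meta$delta_lambda, 60)
})

test_that("titration tables read with design validation", {
  concs <- c(0, 5, 7.5, 10, 15, 20, 25, 30) * 1e-6
  lines <- c("# temperature_K: 289", "# protein_conc_M: 5e-06",
             "ligand_conc_M,intensity",
             paste(format(concs, scientific = FALSE),
                   seq(1000, 650, length.out = 8), sep = ","))
  tr <- read_titration(lines)
  expect_length(tr$ligand_conc, 8)
  expect_equal(tr$temperature, 289)
  expect_false(tr$corrected)

  expect_error(read_titration(c("ligand_conc_M,intensity", "5e-6,900",
                                "1e-5,800", "2e-5,700")), "ligand-free")
  expect_error(read_titration(c("ligand_conc_M,intensity,a_ex",
                                "0,1000,0", "5e-6,900,0.01")), "both")
})

test_that("titration writer round-trips including absorbances", {
  tr <- titration_series(c(0, 5e-6, 1e-5, 2e-5), c(1000, 900, 810, 700),
                         temperature = 297, a_ex = c(0, 0.02, 0.04, 0.08),
                         a_em = c(0, 0.01, 0.02, 0.04))
  f <- withr::local_tempfile(fileext = ".csv")
  write_titration(tr, f)
  back <- read_titration(f)
  expect_identical(back$intensity, tr$intensity)
  expect_identical(back$a_ex, tr$a_ex)
  expect_identical(back$a_em, tr$a_em)
  expect_equal(back$temperature, 297)
})

test_that("titration invariants are enforced", {
  expect_error(titration_series(c(0, 2e-5, 1e-5), c(1, 1, 1), 297),
               "increasing")
  expect_error(titration_series(c(0, 1e-5), c(1000, 0), 297), "> 0")
  expect_error(titration_series(c(0, 1e-5), c(1000, 900), 297,
                                a_ex = c(0, 0.1)), "both")
})
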