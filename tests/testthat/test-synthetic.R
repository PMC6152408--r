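test_that("gaussian bands have the stated peak, width and symmetry", {
  grid <- seq(240, 440, by = 1)
  b <- gaussian_band(340, 40, 1000, grid)
  expect_equal(b$value[grid == 340], 1000)
  expect_equal(b$value[grid == 320], 500)
  expect_equal(b$value[grid == 360], 500)
  expect_equal(b$value, rev(b$value))  # grid symmetric about the centre
  expect_error(gaussian_band(340, 40, 1000, numeric(0)), "empty")
  expect_error(gaussian_band(340, -1, 1000, grid), "fwhm")
})

test_that("static titrations follow the closed-form binding law", {
  tr <- simulate_titration(ground_truth(kb = 1e5, n = 1, F0 = 1000),
                           ligand_concs = c(0, 1e-5))
  expect_equal(tr$intensity, c(1000, 500))  # Kb [Q] = 1 halves the signal

  # (F0 - F)/F = Kb [Q]^n identically when noise- and ife-free
  for (kb in c(1e3, 1e5)) for (n in c(0.9, 1.2)) {
    tr <- make_static_series(kb, n)
    q <- tr$ligand_conc[-1]
    lhs <- (tr$intensity[1] - tr$intensity[-1]) / tr$intensity[-1]
    expect_equal(lhs, kb * q^n, tolerance = 1e-12)
  }
  expect_error(simulate_titration(ground_truth(), ligand_concs = c(0, -1e-6)),
               "negative")
})

test_that("inner-filter attenuation is applied and recorded per point", {
  truth <- ground_truth(kb = 5e4, ife_ex = 4e3, ife_em = 2e3)
  tr <- simulate_titration(truth)
  expect_false(tr$corrected)
  q <- tr$ligand_conc
  expect_equal(tr$a_ex, 4e3 * q)
  expect_equal(tr$a_em, 2e3 * q)
  clean <- simulate_titration(ground_truth(kb = 5e4))
  expect_equal(tr$intensity,
               clean$intensity * 10^(-(tr$a_ex + tr$a_em) / 2))
  # correcting recovers the attenuation-free titration
  expect_equal(inner_filter_correct(tr)$intensity, clean$intensity)
})

test_that("generators are deterministic under the stored seed", {
  t1 <- simulate_titration(ground_truth(noise_sd = 5, seed = 42))
  t2 <- simulate_titration(ground_truth(noise_sd = 5, seed = 42))
  t3 <- simulate_titration(ground_truth(noise_sd = 5, seed = 43))
  expect_identical(t1$intensity, t2$intensity)
  expect_false(identical(t1$intensity, t3$intensity))
  # the generator does not disturb the caller's RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(simulate_titration(ground_truth(noise_sd = 5)))
  expect_identical(rnorm(1), before)
})

test_that("temperature series follow the Van't Hoff forward model", {
  ts <- simulate_temperature_series(ground_truth(delta_H = 0,
                                                 delta_S = 95))
  expect_equal(diff(unname(ts$kb)), c(0, 0))  # dH = 0: Kb independent of T

  ts2 <- simulate_temperature_series(ground_truth(delta_H = -50e3,
                                                  delta_S = -100))
  expect_true(all(diff(unname(ts2$kb)) < 0))  # exothermic: Kb falls with T
  expect_equal(unname(ts2$kb),
               exp(50e3 / (8.314 * c(289, 297, 307)) - 100 / 8.314))
  expect_length(ts2$titrations, 3)
  expect_equal(ts2$titrations[[2]]$temperature, 297)
  expect_error(simulate_temperature_series(ground_truth(),
                                           temperatures = 297), "2 temp")
  expect_error(simulate_temperature_series(ground_truth(),
                                           temperatures = c(297, 297)),
               "distinct")
})

test_that("synthetic CD spectra hit the target 208 nm ellipticity", {
  # anchors of the two-point helicity formula
  for (alpha in c(0, 1, 0.5861)) {
    cd <- simulate_cd(alpha)
    mre <- mean_residue_ellipticity(cd$value[cd$wavelength == 208])
    expect_equal(mre, -(4000 + 29000 * alpha), tolerance = 1e-12)
  }
  # 5 uM BSA (583 residues) in a 1 mm cell at 58.61% helix: about -61.2 mdeg
  cd <- simulate_cd(0.5861, protein_conc = 5e-6, n_residues = 583,
                    path_cm = 0.1)
  expect_equal(cd$value[cd$wavelength == 208], -61.2, tolerance = 1e-3)
  # helix-like shape: negative lobes with local minima near 208 and 222
  expect_true(all(cd$value <= 0))
  expect_error(simulate_cd(0.5, protein_conc = 0), "> 0")
})

test_that("absorbance simulation is Beer-Lambert linear", {
  grid <- seq(300, 400, by = 1)
  a0 <- simulate_absorbance(350, 50, 1.2e4, 0, grid)
  expect_true(all(a0$value == 0))
  a1 <- simulate_absorbance(350, 50, 1.2e4, 3e-5, grid)
  expect_equal(max(a1$value), 1.2e4 * 3e-5)
  a2 <- simulate_absorbance(350, 50, 1.2e4, 6e-5, grid)
  expect_equal(a2$value, 2 * a1$value)
})

test_that("simulate_study writes a loadable, self-consistent bundle", {
  dir <- withr::local_tempdir()
  truth <- ground_truth(kb = 7.8e4, n = 1.08)
  files <- simulate_study(dir, truth)
  expect_true(all(file.exists(unlist(files))))
  gt <- yaml::read_yaml(files$truth)
  expect_equal(gt$kb, 7.8e4)
  tr <- read_titration(files$titration_289)
  expect_equal(tr$temperature, 289)
  fit <- double_log_fit(local({ tr$corrected <- TRUE; tr }))
  expect_equal(fit$log_kb, log10(gt$kb_by_temperature[["289"]]),
               tolerance = 1e-9)
})
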