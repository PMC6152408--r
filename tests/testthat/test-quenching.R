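test_that("inner-filter correction applies the half-path factor", {
  mk <- function(f, aex, aem)
    titration_series(c(0, 5e-6, 1e-5, 2e-5), c(1000, f, f, f), 297,
                     a_ex = c(0, aex, aex, aex), a_em = c(0, aem, aem, aem))
  expect_equal(inner_filter_correct(mk(100, 0, 0))$intensity[2], 100)
  expect_equal(inner_filter_correct(mk(100, 0.1, 0.1))$intensity[2],
               100 * 10^0.1)
  expect_equal(inner_filter_correct(mk(50, 0.3, 0.1))$intensity[2],
               50 * 10^0.2)
  # absorbances are >= 0, so correction never decreases any intensity
  tr <- simulate_titration(ground_truth(ife_ex = 4e3, ife_em = 2e3))
  expect_true(all(inner_filter_correct(tr)$intensity >= tr$intensity))
  # preconditions
  plain <- titration_series(c(0, 5e-6), c(1000, 900), 297)
  expect_error(inner_filter_correct(plain), "a_ex")
  expect_error(inner_filter_correct(inner_filter_correct(tr)), "already")
})

test_that("Stern-Volmer regression recovers exact lines", {
  q <- c(0, 5, 7.5, 10, 15, 20, 25, 30) * 1e-6
  tr <- titration_series(q, 1000 / (1 + 2e4 * q), 297, corrected = TRUE)
  fit <- stern_volmer_fit(tr)
  expect_equal(fit$ksv, 2e4, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$kq, 2e12, tolerance = 1e-6)

  flat <- titration_series(q, rep(800, 8), 297, corrected = TRUE)
  expect_equal(stern_volmer_fit(flat)$ksv, 0, tolerance = 1e-8)

  dyn <- simulate_titration(ground_truth(model = "dynamic_sv", kb = 2.29e4),
                            temperature = 289)
  fit6 <- stern_volmer_fit(dyn)
  expect_equal(fit6$ksv, 2.29e4, tolerance = 1e-9)
  expect_equal(fit6$kq, 2.29e12, tolerance = 1e-5)
  expect_equal(fit6$temperature, 289)

  expect_error(stern_volmer_fit(
    titration_series(c(0, 1e-5, 2e-5), c(1000, 900, 800), 297,
                     corrected = TRUE)), ">= 3")
  # uncorrected series carrying absorbances are refused
  raw <- simulate_titration(ground_truth(ife_ex = 4e3, ife_em = 2e3))
  expect_error(stern_volmer_fit(raw), "inner-filter")
})

test_that("double-log fit recovers (log Kb, n) exactly on noise-free data", {
  for (kb in 10^(3:6)) for (n in c(0.8, 1.0, 1.3)) {
    fit <- double_log_fit(make_static_series(kb, n))
    expect_equal(fit$log_kb, log10(kb), tolerance = 1e-7)
    expect_equal(fit$n, n, tolerance = 1e-7)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("double-log fit reproduces a reference binding row round-trip", {
  ref <- bsa_binding_reference()
  row <- ref[ref$compound == 6 & ref$temperature_K == 289, ]
  tr <- make_static_series(10^row$log_kb, row$n, temperature = 289)
  fit <- double_log_fit(tr)
  expect_equal(fit$log_kb, row$log_kb, tolerance = 1e-7)
  expect_equal(fit$n, row$n, tolerance = 1e-7)
})

test_that("double-log fit tolerates realistic noise and drops bad points", {
  # 0.5% of F0 additive noise: the log-log intercept sits ~5 log units of
  # extrapolation from the sampled [Q] range, so its repeated-draw spread
  # is a few hundredths of a log unit; check it over a fixed seed panel
  devs <- vapply(1:20, function(s) {
    fit <- double_log_fit(simulate_titration(
      ground_truth(kb = 7.8e4, n = 1.08, noise_sd = 5, seed = s)))
    abs(fit$log_kb - log10(7.8e4))
  }, numeric(1))
  expect_lt(median(devs), 0.1)
  expect_lt(max(devs), 0.4)

  # a point with F >= F0 is dropped with a warning, fit still succeeds
  tr <- make_static_series(5e4, 1)
  tr$intensity[2] <- tr$intensity[1] * 1.01
  expect_warning(fit2 <- double_log_fit(tr), "dropped")
  expect_equal(fit2$n_points, 6)

  # stability: removing the highest-concentration point barely moves log Kb
  full <- double_log_fit(make_static_series(5e4, 1.1))
  short <- make_static_series(5e4, 1.1,
                              concs = default_ligand_concs()[1:7])
  expect_lt(abs(double_log_fit(short)$log_kb - full$log_kb), 0.01)
})

test_that("mechanism classification follows the Ksv-trend and kq rules", {
  temps <- c(289, 297, 307)
  static <- classify_mechanism(Map(fake_sv_fit, c(2.29, 2.11, 1.75) * 1e4,
                                   temps))
  expect_equal(static$label, "static")
  expect_true(any(grepl("decreases", static$reasons)))
  expect_true(any(grepl("diffusion limit", static$reasons)))

  dynamic <- classify_mechanism(Map(fake_sv_fit, c(1, 1.2, 1.4) * 1e4,
                                    temps, tau0 = 1e-5))  # kq = 5e8-1.4e9
  expect_equal(dynamic$label, "dynamic")

  conflict <- classify_mechanism(Map(fake_sv_fit, c(1, 1.2, 1.4) * 1e4,
                                     temps))  # increasing but kq ~ 1e12
  expect_equal(conflict$label, "ambiguous")
  expect_length(conflict$reasons, 2)

  expect_error(classify_mechanism(Map(fake_sv_fit, c(1e4, 2e4),
                                      c(297, 297))), "duplicate")
})

test_that("synchronous peak shifts are localised and labelled", {
  grid <- seq(250, 350, by = 1)
  mk <- function(center, amp = 1000, dl = 60)
    gaussian_band(center, 30, amp, grid, kind = "synchronous",
                  delta_lambda = dl)
  same <- synchronous_shift(list(mk(285), mk(285), mk(285)))
  expect_equal(same$net_shift, 0, tolerance = 1e-9)
  expect_equal(same$label, "unchanged")

  # +2 nm drift across the series at the Trp offset: a red shift
  red <- synchronous_shift(lapply(seq(285, 287, length.out = 5), mk))
  expect_equal(red$label, "red")
  expect_equal(red$net_shift, 2, tolerance = 0.1)

  # Tyr offset: centres fixed, amplitudes fall -> unchanged, quenched
  tyr <- synchronous_shift(lapply(c(1000, 850, 700, 550),
                                  function(a) mk(285, a, dl = 15)))
  expect_equal(tyr$label, "unchanged")

  expect_error(synchronous_shift(list(mk(285, dl = 60), mk(285, dl = 15))),
               "mixed")
  expect_error(synchronous_shift(list(
    gaussian_band(285, 30, 1, grid), mk(285))), "synchronous")
})

test_that("site-marker competition identifies the primary binding site", {
  ref <- site_marker_reference()
  base <- fake_binding_fit(ref$log_kb[ref$system == "alone"])
  warf <- fake_binding_fit(ref$log_kb[ref$system == "warfarin"])
  ibu <- fake_binding_fit(ref$log_kb[ref$system == "ibuprofen"])
  v <- competitive_site_assignment(base, warf, ibu)
  expect_true(all(v$competes))
  expect_equal(v$site, "site I")

  none <- competitive_site_assignment(base, base, base)
  expect_equal(none$site, "neither marker site")

  only2 <- competitive_site_assignment(base, base, ibu)
  expect_equal(only2$site, "site II")
})
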