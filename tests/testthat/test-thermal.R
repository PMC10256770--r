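test_that("fit_rate recovers the slope of noiseless linear logs exactly", {
  cool <- gen_temperature_log(-20, 0, -150, noise_sd = 0)
  fr <- fit_rate(cool)
  expect_equal(fr$magnitude, 20, tolerance = 1e-9)
  expect_equal(fr$mean_rate, -20, tolerance = 1e-9)
  expect_equal(fr$direction, "cooling")

  warm <- gen_temperature_log(72, -150, -25, noise_sd = 0)
  fw <- fit_rate(warm)
  expect_equal(fw$mean_rate, 72, tolerance = 1e-9)
  expect_equal(fw$direction, "warming")

  # the published mean rates are recovered from logs built at those slopes
  expect_equal(fit_rate(gen_temperature_log(-20.5, 0, -150,
                                            noise_sd = 0))$magnitude, 20.5,
               tolerance = 1e-9)
})

test_that("fit_rate errors when the log does not span the window", {
  shallow <- gen_temperature_log(-20, 0, -100, noise_sd = 0)  # stops above Tg
  expect_error(fit_rate(shallow), "cross")
})

test_that("an annealing plateau does not bias the window crossings", {
  lg <- gen_temperature_log(-40, 0, -150, noise_sd = 0,
                            anneal = list(T_C = -122, duration_min = 25))
  # crossing -128.3 happens after the 25-min hold at -122
  fr <- fit_rate(lg)
  expect_lt(fr$magnitude, 40)   # elapsed time includes the anneal
  expect_gt(fr$t_low_s, 25 * 60)
})

test_that("noisy 1-s logs recover the generating rate within 2% on average", {
  mags <- vapply(1:500, function(s)
    fit_rate(gen_temperature_log(72, -150, -25, noise_sd = 0.5,
                                 seed = s))$magnitude, numeric(1))
  expect_lt(abs(mean(mags) - 72) / 72, 0.02)
})

test_that("critical-rate checks pass strictly and report margins", {
  c1 <- check_against_critical(20.5, 2)
  expect_true(c1$pass)
  expect_equal(c1$margin, 10.25)
  c2 <- check_against_critical(72.0, 50)
  expect_true(c2$pass)
  expect_equal(c2$margin, 1.44)
  expect_false(check_against_critical(50, 50)$pass)
  expect_true(check_against_critical(-20.5, 2)$pass)   # signed rates allowed
  expect_error(check_against_critical(10, 0), "positive")
})

test_that("ice_fraction integrates constructed exotherms to their target", {
  flat <- gen_thermogram(0, noise_sd = 0)
  expect_equal(ice_fraction(flat), 0)

  half <- gen_thermogram(50, noise_sd = 0)
  expect_equal(ice_fraction(half), 50, tolerance = 0.2 / 50)

  small <- gen_thermogram(12.5, noise_sd = 0)
  expect_equal(ice_fraction(small), 12.5, tolerance = 0.2 / 12.5)
})

test_that("ice_fraction agrees with an independent trapezoid integration", {
  tg <- gen_thermogram(12.5, noise_sd = 0, baseline_offset = 0)
  manual <- trapz_oracle(tg$temp_C, tg$heatflow) / (tg$scan_rate / 60)
  expect_equal(ice_fraction(tg, flank_frac = 0.15),
               100 * manual / tg$latent_heat_ref, tolerance = 1e-3)
})

test_that("ice_fraction is invariant to constant and linear baselines", {
  tg <- gen_thermogram(30, noise_sd = 0)
  base <- ice_fraction(tg)
  shifted <- thermogram(tg$temp_C, tg$heatflow + 0.5, tg$scan_rate,
                        tg$direction, tg$latent_heat_ref)
  sloped <- thermogram(tg$temp_C, tg$heatflow + 0.01 * tg$temp_C,
                       tg$scan_rate, tg$direction, tg$latent_heat_ref)
  expect_equal(ice_fraction(shifted), base, tolerance = 1e-9)
  expect_equal(ice_fraction(sloped), base, tolerance = 1e-6)
})

test_that("thermogram rejects non-monotone scans", {
  expect_error(thermogram(c(-60, -40, -50), c(0, 0, 0), 5, "warming"),
               "increasing")
  expect_error(thermogram(c(-10, -40, -30), c(0, 0, 0), 5, "cooling"),
               "decreasing")
})

test_that("critical_rate log-interpolates the published fixture", {
  pts <- data.frame(rate = c(2, 4), ice_fraction = c(1, 0.1))
  cr <- critical_rate(pts, threshold = 0.5)
  expect_equal(cr$rate, 2 + 2 * log10(2), tolerance = 1e-9)  # 2.602
  expect_false(cr$extrapolated)

  # threshold equal to an observed fraction returns that rate exactly
  expect_equal(critical_rate(pts, threshold = 1)$rate, 2)

  expect_error(critical_rate(pts[1, , drop = FALSE]), "two")
  expect_error(critical_rate(data.frame(rate = c(2, 4),
                                        ice_fraction = c(0.1, 1))),
               "monotone")
})

test_that("critical_rate is monotone non-increasing in the threshold", {
  pts <- data.frame(rate = c(1, 2, 4, 8),
                    ice_fraction = c(20, 5, 0.8, 0.05))
  ths <- c(0.1, 0.3, 0.5, 1, 3, 10)
  rates <- vapply(ths, function(t) critical_rate(pts, t)$rate, numeric(1))
  expect_true(all(diff(rates) <= 1e-12))
  # out-of-range thresholds are flagged as extrapolations
  expect_true(critical_rate(pts, 0.01)$extrapolated)
  expect_true(critical_rate(pts, 50)$extrapolated)
})

test_that("the vitrification freezer program has the published span", {
  prog <- vitrification_program()
  expect_equal(program_duration(prog), 3.05 + 25 + 5.6 + 10)  # 43.65 min
  expect_equal(freezer_setpoints(prog, 0), 0)
  expect_equal(freezer_setpoints(prog, 20), -122)    # inside the anneal
  expect_equal(freezer_setpoints(prog, 43.65), -150)
  expect_equal(freezer_setpoints(prog, 3.05 / 2), -61)
  expect_error(freezer_setpoints(prog, 44), "span")
  expect_error(freezer_program(data.frame(start_C = c(0, -50),
                                          end_C = c(-100, -150),
                                          rate_C_min = c(-10, -10),
                                          hold_min = c(NA, NA))),
               "discontinuity")
})
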