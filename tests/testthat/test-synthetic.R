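test_that("every generator is a pure function of (config, seed)", {
  expect_identical(gen_temperature_log(-20.5, 0, -150, seed = 4),
                   gen_temperature_log(-20.5, 0, -150, seed = 4))
  expect_identical(gen_thermogram(25, seed = 4, noise_sd = 0.002),
                   gen_thermogram(25, seed = 4, noise_sd = 0.002))
  expect_identical(gen_ct_phantom(seed = 4), gen_ct_phantom(seed = 4))
  expect_identical(gen_nmp_timeseries("vs55", seed = 4),
                   gen_nmp_timeseries("vs55", seed = 4))
  expect_identical(gen_transplant_labs("nanowarmed", 3, seed = 4),
                   gen_transplant_labs("nanowarmed", 3, seed = 4))
  # different seeds differ
  expect_false(identical(gen_ct_phantom(seed = 4), gen_ct_phantom(seed = 5)))
  # generators do not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(gen_ct_phantom(seed = 4)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("temperature-log generator feeds the rate estimator consistently", {
  expect_equal(fit_rate(gen_temperature_log(-20, 0, -150,
                                            noise_sd = 0))$magnitude, 20,
               tolerance = 1e-9)
  expect_error(gen_temperature_log(0, 0, -150), "non-zero")
  expect_error(gen_temperature_log(20, 0, -150), "inconsistent")
})

test_that("thermogram generator hits its ice-fraction target by area", {
  expect_equal(ice_fraction(gen_thermogram(0)), 0)
  for (target in c(5, 12.5, 50, 95))
    expect_equal(ice_fraction(gen_thermogram(target, noise_sd = 0)), target,
                 tolerance = 0.005)
})

test_that("phantom scenarios classify as the study reports", {
  ph <- gen_ct_phantom(ct_phantom_regions("vmp_kidney"), seed = 11)
  hu <- calibrate_hu(ph$volume, ph$water_roi, ph$air_roi)
  rep <- classify_state(region_stats(hu, ph$labels,
                                     names = c("1" = "kidney", "2" = "fat")),
                        threshold_HU = 400)
  expect_equal(rep$state[rep$region == "kidney"], "vitrified")
  expect_equal(rep$state[rep$region == "fat"], "frozen")

  # nanoparticle-loaded kidney: all regions vitrified at a shifted threshold
  ph2 <- gen_ct_phantom(ct_phantom_regions("ionp_kidney"), seed = 12)
  hu2 <- calibrate_hu(ph2$volume, ph2$water_roi, ph2$air_roi)
  rep2 <- classify_state(region_stats(hu2, ph2$labels), threshold_HU = 520)
  expect_true(all(rep2$state == "vitrified"))
  expect_equal(nrow(rep2), 4)

  # overlap rejection
  bad <- list(list(label = 1L, name = "a", mean_HU = 0, sd_HU = 1,
                   box = roi_box(c(10, 20), c(10, 20), c(10, 20))),
              list(label = 2L, name = "b", mean_HU = 0, sd_HU = 1,
                   box = roi_box(c(15, 25), c(10, 20), c(10, 20))))
  expect_error(gen_ct_phantom(bad), "overlap")
})

test_that("degenerate NMP draws reproduce the group means exactly", {
  par0 <- nmp_group_params("nanowarmed")
  sd_cols <- grep("_sd$", names(par0))
  par0[sd_cols] <- 0
  s <- gen_nmp_timeseries("nanowarmed", n_kidneys = 1, seed = 1,
                          params = par0)
  m <- nmp_endpoint_metrics(s, mass = s$mass_g[1])
  expect_equal(m$resistance, 31.3)
  expect_equal(m$creatinine_clearance, par0$crcl_mean)
  expect_equal(m$ocr, par0$ocr_mean)
  expect_equal(m$glucose_consumption, par0$glucose_mean)
  expect_equal(m$lactate_production, par0$lactate_mean)
  expect_equal(m$cumulative_urine[length(m$cumulative_urine)],
               par0$urine40_mean)
})

test_that("NMP generator respects the physiologic pressure window", {
  s <- gen_nmp_timeseries("control", n_kidneys = 6, seed = 8)
  expect_true(all(s$pressure_mmHg >= 90 & s$pressure_mmHg <= 110))
  expect_equal(unique(s$time_min), seq(0, 40, 10))
})

test_that("VS55 resistance draws center on the published endpoint", {
  r <- vapply(1:300, function(s) {
    k <- gen_nmp_timeseries("vs55", n_kidneys = 1, seed = s)
    nmp_endpoint_metrics(k, k$mass_g[1])$resistance
  }, numeric(1))
  expect_lt(abs(mean(r) - 372), 3 * 131 / sqrt(300))
})

test_that("deterministic transplant trajectories hit the study landmarks", {
  nano <- gen_transplant_labs("nanowarmed", 4, seed = 3, sd_scale = 0)
  summ <- outcome_summary(nano)
  expect_true(all(summ$peak_day %in% 2:3))
  expect_true(all(summ$first_below_day >= 15 & summ$first_below_day <= 21))
  expect_true(all(summ$terminal >= 0.4 & summ$terminal <= 0.8))

  ctrl <- gen_transplant_labs("control", 3, seed = 3, sd_scale = 0)
  cs <- creatinine_summary(ctrl, animal_id = ctrl$animal_id[1])
  expect_equal(cs$first_below_day, -1)

  # weight: baseline ratio 1; nanowarmed shows a transient excess resolving
  nw <- normalize_weight(nano, animal_id = nano$animal_id[1])
  expect_equal(nw$weight_ratio[nw$day == -1], 1)
  expect_gt(max(nw$weight_ratio[nw$day %in% 3:8]) -
              nw$weight_ratio[nw$day == 12], 0.05)
})

test_that("all shipped scenarios run end-to-end with fixed seeds", {
  scen <- list_scenarios()
  expect_setequal(scen, c("cooling", "nanowarming", "dsc", "ct_vmp",
                          "ct_ionp", "nmp", "transplant"))
  out_dir <- withr::local_tempdir()
  for (s in scen) {
    res <- run_scenario(s, seed = 1, out_dir = out_dir)
    expect_true(length(res$results) > 0, label = s)
  }
  expect_gt(length(list.files(out_dir, pattern = "\\.csv$")), 7)

  # spot-check scientific content of two scenarios
  cool <- run_scenario("cooling", seed = 1)
  expect_true(cool$results$check$pass)
  expect_equal(cool$results$fit$magnitude, 20.5, tolerance = 0.05)
  dsc <- run_scenario("dsc", seed = 1)
  expect_false(dsc$results$critical$extrapolated)
  expect_true(dsc$results$critical$rate > 2 && dsc$results$critical$rate < 4)
})
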