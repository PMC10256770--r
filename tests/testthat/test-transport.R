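R_GAS <- 8.314462618

test_that("kk_fluxes matches hand evaluation of the flux laws", {
  m0 <- membrane_params()
  z <- kk_fluxes(0, 0, 0, 0, 0, m0)
  expect_equal(z$Jv, 0)
  expect_equal(z$Js, 0)

  # pure osmosis: sigma = 1, omega = 0, 1000 mM gradient at 277 K
  m1 <- membrane_params(sigma = 1, omega = 0)
  f <- kk_fluxes(0, 1000, 0, 0, 0, m1, T_K = 277)
  expect_equal(f$Js, 0)
  expect_equal(f$Jv, -1.5e-14 * R_GAS * 277 * 1000, tolerance = 1e-12)
  expect_equal(f$Jv, -3.45e-8, tolerance = 2e-3)

  # study parameters: independent one-liner for each term
  f2 <- kk_fluxes(0, 1000, 0, 0, 0, m0, T_K = 277)
  Jv_exp <- 1.5e-14 * (-0.1 * R_GAS * 277 * 1000)
  expect_equal(f2$Jv, Jv_exp)
  expect_equal(f2$Js, 7e-13 * R_GAS * 277 * 1000 + 0.9 * 500 * Jv_exp)
  expect_equal(7e-13 * R_GAS * 277 * 1000, 1.61e-6, tolerance = 2e-3)

  expect_error(kk_fluxes(0, -1, 0), "non-negative")
  expect_error(kk_fluxes(0, 1, 0, T_K = 0), "positive")
})

test_that("hydrostatic and impermeant terms enter Jv with the right sign", {
  m <- membrane_params(sigma = 0.5)
  # pressure pushes fluid into the tissue
  expect_gt(kk_fluxes(1000, 0, 0, 0, 0, m)$Jv, 0)
  # an impermeant-rich tissue draws fluid in
  expect_gt(kk_fluxes(0, 0, 0, 0, 500, m)$Jv, 0)
})

test_that("tissue equilibrates to a constant inlet concentration", {
  g <- krogh_geometry(n_axial = 3, tissue_radius = 8e-6)
  p <- build_protocol(list(seg_hold(5000, 1500)))
  h <- simulate_perfusion(p, g, dt = 10, hydrostatic = FALSE)
  expect_true(all(abs(h$c_extra[nrow(h$c_extra), ] - 5000) / 5000 < 0.01))
  expect_equal(h$final_mean_mM, 5000, tolerance = 0.01)
})

test_that("sigma=1, omega=0 volume settles at the Boyle-van't Hoff point", {
  m <- membrane_params(sigma = 1, omega = 0)
  g <- krogh_geometry(n_axial = 1, tissue_radius = 8e-6)
  p <- build_protocol(list(seg_hold(1000, 3000)))
  h <- simulate_perfusion(p, g, m, dt = 20, hydrostatic = FALSE,
                          c_imp_vasc = 300, c_imp_extra0 = 300)
  # no CPA can enter; V_eq/V0 = c_imp0 / (c_in + c_imp_vasc)
  expect_equal(h$c_extra[nrow(h$c_extra), 1], 0, tolerance = 1e-6)
  expect_equal(h$V_rel[nrow(h$V_rel), 1], 300 / 1300, tolerance = 1e-3)
})

test_that("solver trajectory matches a brute-force fine-step Euler oracle", {
  g <- krogh_geometry(n_axial = 1)
  m <- membrane_params()
  p <- build_protocol(list(seg_hold(3000, 30)))
  h <- simulate_perfusion(p, g, m, flow = 5, dt = 1, hydrostatic = FALSE)
  o <- euler_transport(3000, 30, g, m, flow_mL_min = 5, dt_s = 0.005,
                       sample_every = 12000)   # sample each minute
  ih <- match(round(o$t_min, 6), round(h$time, 6))
  expect_false(anyNA(ih))
  ref <- o$c_extra[-1]
  got <- h$c_extra[ih, 1][-1]
  expect_lt(max(abs(got - ref)) / max(abs(ref)), 0.005)
  expect_lt(max(abs(h$V_rel[ih, 1] - o$V_rel)), 0.005)
})

test_that("solute mass is conserved through arbitrary protocols", {
  for (seed in 1:6) {
    p <- random_protocol(seed)
    h <- simulate_perfusion(p, krogh_geometry(n_axial = 4), dt = 1)
    expect_lt(h$mass_balance_rel, 1e-6)
  }
})

test_that("tissue never exceeds the running-max inlet concentration", {
  for (seed in c(2, 5, 11)) {
    p <- random_protocol(seed)
    h <- simulate_perfusion(p, krogh_geometry(n_axial = 4), dt = 0.5,
                            hydrostatic = FALSE)
    run_max <- cummax(h$c_in)
    expect_true(all(h$c_extra <= pmax(run_max, 1e-9) * (1 + 1e-6)))
    expect_true(all(h$c_extra >= -1e-9))
  }
})

test_that("with sigma=0 and no pressure, halving omega halves early uptake", {
  g <- krogh_geometry(n_axial = 1)
  p <- build_protocol(list(seg_hold(4000, 2)))
  slope_for <- function(om) {
    m <- membrane_params(sigma = 0, omega = om, Lp = 1e-20)
    h <- simulate_perfusion(p, g, m, dt = 0.05, hydrostatic = FALSE)
    # early mean uptake slope, mM/min
    (h$mean_c_extra[21] - h$mean_c_extra[11]) / (h$time[21] - h$time[11])
  }
  s1 <- slope_for(7e-13)
  s2 <- slope_for(3.5e-13)
  expect_equal(s1 / s2, 2, tolerance = 0.01)
})

test_that("history sampling interval does not affect the solution", {
  p <- vmp_loading_protocol()
  h1 <- simulate_perfusion(p, krogh_geometry(), dt = 2)
  h2 <- simulate_perfusion(p, krogh_geometry(), dt = 1)
  expect_equal(h1$final_mean_mM, h2$final_mean_mM, tolerance = 1e-3)
})

test_that("equilibration_time finds the fractional approach to plateau", {
  g <- krogh_geometry(n_axial = 1, tissue_radius = 8e-6)
  p <- build_protocol(list(seg_hold(5000, 400)))
  # permeation-only compartment: exponential with tau = V0/(A omega R T)
  m <- membrane_params(Lp = 1e-25, sigma = 0)
  h <- simulate_perfusion(p, g, m, dt = 0.2, hydrostatic = FALSE)
  V0 <- pi * (8e-6^2 - 3.5e-6^2) * 1e-3
  A <- 2 * pi * 3.5e-6 * 1e-3
  tau_min <- V0 / (A * 7e-13 * R_GAS * 277.15) / 60
  t63 <- equilibration_time(h, 1 - exp(-1))
  expect_equal(t63, tau_min, tolerance = 0.02)

  # already at plateau
  h0 <- simulate_perfusion(p, g, m, dt = 1, c_extra0 = 5000,
                           hydrostatic = FALSE)
  expect_equal(equilibration_time(h0, 0.5), 0)

  # never reached on a short ramp-only history
  pr <- build_protocol(list(seg_ramp(0, 5000, 500)))
  hr <- simulate_perfusion(pr, g, m, dt = 0.5, hydrostatic = FALSE)
  expect_identical(equilibration_time(hr, 1.0), Inf)

  expect_error(equilibration_time(h, 0), "fraction")
  expect_error(equilibration_time(h, 1.5), "fraction")
})

test_that("compare_protocols credits the osmotic-equilibration hold", {
  g <- krogh_geometry(n_axial = 4)
  with_hold <- vmp_loading_protocol()
  without <- build_protocol(list(seg_flush(20), seg_ramp(0, 5000, 50),
                                 seg_step(8400, 25)), name = "no hold")
  rep <- compare_protocols(with_hold, without, g, dt = 1,
                           thresholds = c(500, 2000))
  expect_gte(rep$final_mean_mM[1], rep$final_mean_mM[2])
  # identical protocols give identical reports
  rep2 <- compare_protocols(with_hold, with_hold, g, dt = 1)
  expect_equal(rep2[1, -1], rep2[2, -1], ignore_attr = TRUE)
  # zero-duration protocol has zero exposure
  rep3 <- compare_protocols(build_protocol(list()), without, g, dt = 1)
  expect_equal(unlist(rep3[1, -1]), c(final_mean_mM = 0, exposure_2000 = 0,
                                      exposure_5000 = 0))
})
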