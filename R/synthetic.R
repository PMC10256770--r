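#' Synthetic temperature log
#'
#' Linear cooling/warming trajectory sampled at fixed cadence with additive
#' Gaussian probe noise, emulating a fiberoptic data-logger record. An
#' optional annealing plateau (as in the controlled-rate-freezer program) is
#' inserted when the trajectory reaches `anneal$T_C`, holding for
#' `anneal$duration_min` before the ramp resumes.
#'
#' @param rate ramp rate, C/min, signed (non-zero; sign must match the
#'   direction `T_start` to `T_end`).
#' @param T_start,T_end endpoint temperatures, C.
#' @param noise_sd probe noise SD, C.
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @param cadence_s sampling interval, s.
#' @param anneal optional `list(T_C =, duration_min =)` plateau.
#' @param probe probe label.
#' @return a [temperature_log()].
#' @export
gen_temperature_log <- function(rate, T_start, T_end, noise_sd = 0.5,
                                seed = 1, cadence_s = 1, anneal = NULL,
                                probe = "synthetic") {
  if (rate == 0) stop_msg("rate must be non-zero")
  if (noise_sd < 0) stop_msg("noise_sd must be non-negative")
  if (sign(rate) != sign(T_end - T_start))
    stop_msg("rate sign inconsistent with direction %g -> %g C",
             T_start, T_end)
  rs <- rate / 60                       # C/s
  ramp1_s <- (T_end - T_start) / rs
  hold_s <- 0; t_anneal <- NA_real_
  if (!is.null(anneal)) {
    between <- (anneal$T_C - T_start) / (T_end - T_start)
    if (between <= 0 || between >= 1)
      stop_msg("anneal temperature must lie strictly between the endpoints")
    t_anneal <- (anneal$T_C - T_start) / rs
    hold_s <- anneal$duration_min * 60
  }
  total_s <- ramp1_s + hold_s
  tt <- seq(0, ceiling(total_s), by = cadence_s)
  temp <- T_start + rs * tt
  if (hold_s > 0) {
    in_hold <- tt >= t_anneal & tt < t_anneal + hold_s
    temp[in_hold] <- anneal$T_C
    after <- tt >= t_anneal + hold_s
    temp[after] <- anneal$T_C + rs * (tt[after] - t_anneal - hold_s)
  }
  cl <- range(T_start, T_end)
  temp <- pmin(pmax(temp, cl[1]), cl[2])
  if (noise_sd > 0)
    temp <- with_seed(seed, temp + stats::rnorm(length(temp), 0, noise_sd))
  temp <- pmin(pmax(temp, -200), 50)
  temperature_log(tt, temp, probe = probe)
}

#' Synthetic DSC thermogram with a controlled crystallization event
#'
#' Builds a heat-flow scan consisting of a (possibly sloped) baseline plus a
#' Gaussian exo/endotherm whose integrated energy equals
#' `ice_fraction_target`% of the reference latent heat, so the expected
#' [ice_fraction()] of the result is the target by construction.
#'
#' @param ice_fraction_target target ice fraction, percent (0-100).
#' @param latent_heat_ref reference latent heat, J/g.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @param scan_rate scan rate magnitude, C/min.
#' @param direction scan direction.
#' @param T_range scan temperature range, C.
#' @param center,width Gaussian event center and SD, C.
#' @param baseline_offset,baseline_slope instrumental baseline, W/g and
#'   W/(g C).
#' @param noise_sd additive heat-flow noise SD, W/g.
#' @param step temperature step between scan points, C.
#' @return a [thermogram()].
#' @export
gen_thermogram <- function(ice_fraction_target, latent_heat_ref = 334,
                           seed = 1, scan_rate = 5,
                           direction = c("warming", "cooling"),
                           T_range = c(-60, -10), center = -35, width = 3,
                           baseline_offset = 0.02, baseline_slope = 0,
                           noise_sd = 0, step = 0.05) {
  direction <- match.arg(direction)
  if (ice_fraction_target < 0 || ice_fraction_target > 100)
    stop_msg("ice fraction target must be within [0, 100]")
  temps <- seq(min(T_range), max(T_range), by = step)
  if (direction == "cooling") temps <- rev(temps)
  energy <- ice_fraction_target / 100 * latent_heat_ref     # J/g
  amp <- energy * scan_rate / 60                            # (W/g) C total area
  hf <- baseline_offset + baseline_slope * temps +
    amp * stats::dnorm(temps, center, width)
  if (noise_sd > 0)
    hf <- with_seed(seed, hf + stats::rnorm(length(hf), 0, noise_sd))
  thermogram(temps, hf, scan_rate, direction, latent_heat_ref)
}

#' Region tables for the shipped micro-CT phantom scenarios
#'
#' `"vmp_kidney"`: a nanoparticle-free vitrified kidney (507 +/- 30 HU) with
#' adherent perihilar fat containing ice (267 +/- 104 HU). `"ionp_kidney"`: a
#' nanoparticle-loaded kidney where the iron oxide raises the radiodensity of
#' the surrounding solution, cortex, outer and inner medulla
#' (768/628/656/560 HU). Box placements are phantom conventions; the kidney
#' region of `"vmp_kidney"` holds 1e5 voxels.
#'
#' @param scenario scenario name.
#' @return list of region descriptors (`label`, `name`, `mean_HU`, `sd_HU`,
#'   `box`).
#' @export
ct_phantom_regions <- function(scenario = c("vmp_kidney", "ionp_kidney")) {
  scenario <- match.arg(scenario)
  reg <- function(label, name, mean_HU, sd_HU, box)
    list(label = label, name = name, mean_HU = mean_HU, sd_HU = sd_HU,
         box = box)
  if (scenario == "vmp_kidney")
    list(reg(1L, "kidney", 507, 30, roi_box(c(8, 57), c(8, 57), c(8, 47))),
         reg(2L, "fat", 267, 104, roi_box(c(8, 40), c(8, 40), c(50, 62))))
  else
    list(reg(1L, "solution", 768, 20, roi_box(c(8, 60), c(8, 16), c(8, 60))),
         reg(2L, "cortex", 628, 15, roi_box(c(8, 60), c(20, 32), c(8, 60))),
         reg(3L, "outer_medulla", 656, 20,
             roi_box(c(8, 60), c(36, 46), c(8, 60))),
         reg(4L, "inner_medulla", 560, 18,
             roi_box(c(8, 60), c(50, 58), c(8, 60))))
}

#' Synthetic micro-CT phantom
#'
#' Generates a raw-intensity voxel grid with per-region Gaussian radiodensity
#' (specified in HU) embedded in a noisy background, affinely mapped into an
#' arbitrary raw scanner scale, with optional water and air reference tubes
#' so the full HU calibration path is exercised end-to-end.
#'
#' @param regions region list as from [ct_phantom_regions()]; boxes must be
#'   pairwise disjoint and inside the grid.
#' @param dim grid dimensions (z, y, x).
#' @param voxel_size_mm isotropic voxel size, mm.
#' @param include_refs include water/air reference tubes (top-of-container
#'   corners).
#' @param seed RNG seed.
#' @param raw_gain,raw_offset affine map from HU to the raw scanner scale.
#' @param background_HU,background_sd background radiodensity, HU.
#' @param ref_sd reference-tube noise SD, HU.
#' @return list with `volume` (a [raw_volume()]), `labels` (integer array),
#'   `water_roi`, `air_roi`, and the `regions` table.
#' @export
gen_ct_phantom <- function(regions = ct_phantom_regions("vmp_kidney"),
                           dim = c(64, 64, 64), voxel_size_mm = 0.061,
                           include_refs = TRUE, seed = 1, raw_gain = 0.7,
                           raw_offset = 1024, background_HU = -100,
                           background_sd = 10, ref_sd = 1) {
  water_roi <- roi_box(c(1, 6), c(1, 6), c(1, 6))
  air_roi <- roi_box(c(1, 6), c(1, 6), c(dim[3] - 5, dim[3]))
  boxes <- lapply(regions, `[[`, "box")
  if (include_refs) boxes <- c(boxes, list(water_roi, air_roi))
  nb <- length(boxes)
  for (i in seq_len(nb)) {
    b <- boxes[[i]]
    if (b$z[2] > dim[1] || b$y[2] > dim[2] || b$x[2] > dim[3] ||
        any(c(b$z[1], b$y[1], b$x[1]) < 1))
      stop_msg("region box %d outside the grid", i)
    if (i < nb) for (j in (i + 1):nb)
      if (roi_overlap(b, boxes[[j]]))
        stop_msg("region boxes %d and %d overlap", i, j)
  }
  with_seed(seed, {
    hu <- array(stats::rnorm(prod(dim), background_HU, background_sd), dim)
    labels <- array(0L, dim)
    for (r in regions) {
      ix <- as.matrix(expand.grid(z = r$box$z[1]:r$box$z[2],
                                  y = r$box$y[1]:r$box$y[2],
                                  x = r$box$x[1]:r$box$x[2]))
      hu[ix] <- stats::rnorm(nrow(ix), r$mean_HU, r$sd_HU)
      labels[ix] <- r$label
    }
    if (include_refs) {
      wix <- as.matrix(expand.grid(z = water_roi$z[1]:water_roi$z[2],
                                   y = water_roi$y[1]:water_roi$y[2],
                                   x = water_roi$x[1]:water_roi$x[2]))
      aix <- as.matrix(expand.grid(z = air_roi$z[1]:air_roi$z[2],
                                   y = air_roi$y[1]:air_roi$y[2],
                                   x = air_roi$x[1]:air_roi$x[2]))
      hu[wix] <- stats::rnorm(nrow(wix), 0, ref_sd)
      hu[aix] <- stats::rnorm(nrow(aix), -1000, ref_sd)
    }
    raw <- raw_offset + raw_gain * hu
    list(volume = raw_volume(raw, voxel_size_mm), labels = labels,
         water_roi = if (include_refs) water_roi else NULL,
         air_roi = if (include_refs) air_roi else NULL,
         regions = data.frame(
           label = vapply(regions, `[[`, integer(1), "label"),
           region = vapply(regions, `[[`, character(1), "name"),
           mean_HU = vapply(regions, `[[`, numeric(1), "mean_HU"),
           sd_HU = vapply(regions, `[[`, numeric(1), "sd_HU")))
  })
}

#' Endpoint-metric distributions for the NMP study groups
#'
#' Minute-40 endpoint means and SDs per experimental group. The vascular
#' resistance values are the reported group endpoints
#' (mmHg/(mL/min/g)); the remaining metrics (urine output, creatinine
#' clearance, oxygen consumption, glucose consumption, lactate production,
#' venous pH) are *synthetic* plausible values chosen once to reproduce the
#' qualitative group ordering (fresh control best, VS55 worst), since only
#' the resistance endpoints are reported numerically.
#'
#' @param group one of `"control"`, `"cold_24h"`, `"vmp"`, `"nanowarmed"`,
#'   `"vs55"`; omit for the full table.
#' @return one-row (or full) data frame of means/SDs.
#' @export
nmp_group_params <- function(group = NULL) {
  tab <- data.frame(
    group = c("control", "cold_24h", "vmp", "nanowarmed", "vs55"),
    resistance_mean = c(18.8, 24.9, 27.5, 31.3, 372),
    resistance_sd = c(4.1, 2.6, 3.4, 3.6, 131),
    urine40_mean = c(4.0, 3.5, 3.2, 3.0, 0.4),
    urine40_sd = c(0.8, 0.7, 0.6, 0.6, 0.2),
    crcl_mean = c(0.80, 0.65, 0.55, 0.50, 0.05),
    crcl_sd = c(0.15, 0.12, 0.10, 0.10, 0.03),
    ocr_mean = c(1.00, 0.85, 0.80, 0.75, 0.20),
    ocr_sd = c(0.15, 0.12, 0.12, 0.12, 0.08),
    glucose_mean = c(1.50, 1.35, 1.30, 1.35, 0.30),
    glucose_sd = c(0.30, 0.25, 0.25, 0.30, 0.10),
    lactate_mean = c(0.40, 0.45, 0.50, 0.55, 0.90),
    lactate_sd = c(0.10, 0.10, 0.10, 0.12, 0.25),
    ph40_mean = c(7.38, 7.36, 7.35, 7.33, 7.10),
    ph40_sd = c(0.03, 0.03, 0.03, 0.04, 0.08))
  if (is.null(group)) return(tab)
  row <- tab[tab$group == group, ]
  if (!nrow(row)) stop_msg("unknown NMP group '%s'", group)
  row
}

#' Synthetic NMP perfusion time series
#'
#' Simulates perfusion records for `n_kidneys` organs of one experimental
#' group: samples at 10-min cadence over 40 min, arterial pressure held in
#' the physiologic 90-110 mmHg window, and minute-40 endpoint metrics drawn
#' from the group's Normal(mean, SD) distributions. Within-series values
#' interpolate smoothly toward the endpoint, and the series are constructed
#' by inverting the metric formulas, so the analysis pipeline
#' ([nmp_endpoint_metrics()]) recovers each kidney's drawn endpoints
#' exactly.
#'
#' @param group experimental group label (see [nmp_group_params()]).
#' @param n_kidneys number of organs.
#' @param seed RNG seed.
#' @param mass_g kidney mass, g.
#' @param params endpoint distribution row, defaulting to the group table.
#' @param cadence_min,duration_min sampling cadence and run length.
#' @return data frame, one row per kidney-sample, with the perfusion-record
#'   columns of [nmp_endpoint_metrics()] plus `kidney_id`, `group`,
#'   `mass_g`, electrolytes and venous pH.
#' @export
gen_nmp_timeseries <- function(group = "nanowarmed", n_kidneys = 4, seed = 1,
                               mass_g = 2, params = nmp_group_params(group),
                               cadence_min = 10, duration_min = 40) {
  if (n_kidneys < 1) stop_msg("n_kidneys must be >= 1")
  tt <- seq(0, duration_min, by = cadence_min)
  nt <- length(tt)
  frac <- tt / duration_min
  with_seed(seed, {
    out <- lapply(seq_len(n_kidneys), function(k) {
      draw <- function(mu, sd, lo = 1e-6) max(lo, stats::rnorm(1, mu, sd))
      r40 <- draw(params$resistance_mean, params$resistance_sd)
      urine40 <- draw(params$urine40_mean, params$urine40_sd, 0.01)
      crcl40 <- draw(params$crcl_mean, params$crcl_sd, 1e-4)
      ocr40 <- draw(params$ocr_mean, params$ocr_sd, 1e-4)
      glu40 <- draw(params$glucose_mean, params$glucose_sd, 1e-4)
      lac40 <- draw(params$lactate_mean, params$lactate_sd, 1e-4)
      ph40 <- stats::rnorm(1, params$ph40_mean, params$ph40_sd)

      pressure <- stats::runif(nt, 95, 105)
      resistance <- r40 * (1 + 0.15 * (1 - frac))
      flow <- pressure * mass_g / resistance
      ramp <- 0.7 + 0.3 * frac
      pO2_art <- rep(500, nt)
      pO2_ven <- pO2_art - ocr40 * ramp * mass_g * 1000 / (1.4 * flow)
      glucose_art <- rep(5.54, nt)
      glucose_ven <- glucose_art - glu40 * ramp * mass_g / flow
      lactate_art <- rep(0.30, nt)
      lactate_ven <- lactate_art + lac40 * ramp * mass_g / flow
      ph_ven <- ph40 - (ph40 - 7.10) * (1 - frac)^2
      w <- c(0, 0.22, 0.24, 0.26, 0.28)[seq_len(nt)]
      urine <- urine40 * w / sum(w)
      urine_flow <- urine / cadence_min
      perf_cr <- 50                        # 0.5 g/L supplemented creatinine
      u_cr <- ifelse(urine_flow > 0,
                     crcl40 * ramp * perf_cr / pmax(urine_flow, 1e-9), 0)
      data.frame(kidney_id = sprintf("%s_%02d", group, k), group = group,
                 time_min = tt, pressure_mmHg = pressure,
                 flow_mL_min = flow, pO2_art = pO2_art, pO2_ven = pO2_ven,
                 glucose_art = glucose_art, glucose_ven = glucose_ven,
                 lactate_art = lactate_art, lactate_ven = lactate_ven,
                 pH_ven = ph_ven, urine_mL = urine,
                 urine_cr_mg_dl = u_cr, perf_cr_mg_dl = perf_cr,
                 Na_mmol_L = stats::rnorm(nt, 140, 1),
                 K_mmol_L = stats::rnorm(nt, 4.5, 0.15),
                 Cl_mmol_L = stats::rnorm(nt, 102, 1),
                 mass_g = mass_g)
    })
    do.call(rbind, out)
  })
}

# smooth 0..1 excursion: ramps up from `onset` to `peak`, back down by
# `resolve`; zero outside
excursion <- function(day, onset, peak, resolve) {
  up <- pmin(1, pmax(0, (day - onset) / max(peak - onset, 0.5)))
  down <- pmin(1, pmax(0, (resolve - day) / max(resolve - peak, 0.5)))
  pmin(up, down)
}

#' Synthetic 30-day post-transplant laboratory trajectories
#'
#' Generates daily labs (day -1 baseline through day 30) for a transplant
#' cohort. Control recipients stay near-normal throughout. Nanowarmed
#' recipients show the initial-graft-dysfunction pattern: serum creatinine
#' rising to a peak on day 2-3, then declining exponentially to cross
#' 2.0 mg/dL around day 17-21 and settle at 0.4-0.8 mg/dL; correlated
#' hyperkalemia and partially compensated metabolic acidosis (low pH, HCO3,
#' pCO2) resolving by day 15; transiently elevated lactate; an ~10% excess
#' weight gain resolving by days 10-12; and a post-surgical hemoglobin dip
#' recovering in both groups. Trajectory shapes are piecewise
#' rise/exponential-decay constructions (an artifact choice; only the
#' landmarks are study-anchored).
#'
#' @param group `"control"` or `"nanowarmed"`.
#' @param n_animals number of recipients.
#' @param seed RNG seed.
#' @param storage_days per-animal graft storage durations (days); defaults
#'   to an even spread over 1-100 for nanowarmed grafts, 0 for control.
#' @param sd_scale multiplier on all between/within-animal noise (0 gives
#'   the deterministic landmark trajectories).
#' @return a [lab_series()].
#' @export
gen_transplant_labs <- function(group = c("nanowarmed", "control"),
                                n_animals = 5, seed = 1,
                                storage_days = NULL, sd_scale = 1) {
  group <- match.arg(group)
  if (n_animals < 1) stop_msg("n_animals must be >= 1")
  if (is.null(storage_days))
    storage_days <- if (group == "nanowarmed")
      rep(c(1, 25, 50, 75, 100), length.out = n_animals) else
        rep(0, n_animals)
  days <- -1:30
  with_seed(seed, {
    rows <- lapply(seq_len(n_animals), function(i) {
      nz <- function(sd) stats::rnorm(length(days), 0, sd * sd_scale)
      if (group == "control") {
        # terminal distribution anchored at the day-30 table values
        level <- 0.48 + stats::rnorm(1, 0, 0.15 * sd_scale)
        cr <- pmax(0.2, level + nz(0.06))
        k_exc <- 0; acid <- 0
      } else {
        base_cr <- 0.5
        peak_day <- sample(2:3, 1)
        peak <- max(2.5, 4.0 + stats::rnorm(1, 0, 0.5 * sd_scale))
        term <- min(max(0.62 + stats::rnorm(1, 0, 0.15 * sd_scale), 0.4), 0.8)
        cross <- sample(16:20, 1)
        # two-phase decline: log-linear shoulder from the peak to the
        # 2.0 mg/dL crossing, then fast exponential normalization
        k2 <- 0.45
        cr <- numeric(length(days))
        for (j in seq_along(days)) {
          d <- days[j]
          cr[j] <- if (d <= 0) base_cr
          else if (d <= peak_day)
            base_cr + (peak - base_cr) * d / peak_day
          else if (d < cross - 0.5)
            exp(log(peak) + (log(2.0) - log(peak)) *
                  (d - peak_day) / (cross - 0.5 - peak_day))
          else term + (2.0 - term) * exp(-k2 * (d - cross + 0.5))
        }
        cr <- pmax(0.2, cr + nz(0.05))
        cr[days == -1] <- base_cr + abs(stats::rnorm(1, 0, 0.05 * sd_scale))
        k_exc <- excursion(days, 0, peak_day, 15)
        acid <- excursion(days, 0, 3, 15)
      }
      lac_exc <- if (group == "nanowarmed") excursion(days, 0, 2, 9) else 0
      hgb_dip <- excursion(days, -1, 2, 12)
      wt_base <- 480 + stats::rnorm(1, 0, 15 * sd_scale)
      wt_gain <- 1 + 0.004 * (days + 1)
      wt_bump <- if (group == "nanowarmed")
        0.10 * excursion(days, 0, 5, 12) else 0
      data.frame(
        animal_id = sprintf("%s_%02d", group, i), group = group,
        storage_days = storage_days[i], day = days,
        creatinine = cr,
        potassium = pmax(3, 4.5 + 2.0 * k_exc + nz(0.15)),
        pH = 7.40 - 0.15 * acid + nz(0.02),
        hco3 = 25 - 7 * acid + nz(0.5),
        pco2 = 40 - 8 * acid + nz(1.5),
        lactate = pmax(0.3, 1.0 + 1.5 * lac_exc + nz(0.15)),
        hemoglobin = pmax(7, 13 - 2 * hgb_dip +
                            pmin(2, 0.08 * pmax(days, 0)) + nz(0.4)),
        weight = wt_base * (wt_gain + wt_bump) + nz(3))
    })
    lab_series(do.call(rbind, rows))
  })
}
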