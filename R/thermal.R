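#' Temperature logs and thermal landmarks
#'
#' A temperature log is the thermal history recorded by a fiberoptic probe at
#' ~1 s cadence during cooling into the glassy state or during rewarming.
#' The crystallization "zone of risk" is bounded by the melting temperature
#' `Tm` above and the glass transition temperature `Tg` below; for VMP in
#' kidney tissue these are -40.8 C and -128.3 C.
#'
#' @param time_s sample times, s (strictly increasing).
#' @param temp_C temperatures, C, within `[-200, 50]`.
#' @param probe probe label.
#' @return a `temperature_log` data frame.
#' @export
temperature_log <- function(time_s, temp_C, probe = "probe") {
  if (length(time_s) != length(temp_C))
    stop_msg("time and temperature must have equal length")
  if (any(diff(time_s) <= 0)) stop_msg("time must be strictly increasing")
  if (any(temp_C < -200 | temp_C > 50))
    stop_msg("temperatures outside [-200, 50] C")
  structure(data.frame(time_s = time_s, temp_C = temp_C),
            probe = probe, class = c("temperature_log", "data.frame"))
}

#' @rdname temperature_log
#' @export
thermal_landmarks <- function(Tg = -128.3, Tm = -40.8) {
  if (Tg >= Tm) stop_msg("require Tg < Tm")
  list(Tg = Tg, Tm = Tm)
}

first_crossing <- function(time_s, temp_C, bound, falling) {
  hit <- if (falling) temp_C <= bound else temp_C >= bound
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(time_s[1])
  # linear interpolation between the bracketing samples
  t0 <- time_s[i - 1L]; t1 <- time_s[i]
  y0 <- temp_C[i - 1L]; y1 <- temp_C[i]
  if (y1 == y0) return(t1)
  t0 + (bound - y0) / (y1 - y0) * (t1 - t0)
}

#' Mean and instantaneous cooling/warming rate across a temperature window
#'
#' The mean rate is the temperature span divided by the elapsed time between
#' the first crossings of `T_high` and `T_low` (crossing times interpolated
#' linearly between samples), signed negative for cooling and positive for
#' warming. The default window is the ice-formation risk zone `[Tm, Tg]`.
#' Instantaneous rates are central differences of a moving-average smoothed
#' series.
#'
#' @param log a [temperature_log()].
#' @param T_high,T_low window bounds, C (`T_low < T_high`).
#' @param smooth_window moving-average width (samples) for the instantaneous
#'   rate series.
#' @return list with `mean_rate` (signed, C/min), `magnitude`, `direction`
#'   (`"cooling"`/`"warming"`), crossing times (s), and `instantaneous`
#'   (data frame `time_s`, `rate_C_min`).
#' @export
fit_rate <- function(log, T_high = -40.8, T_low = -128.3, smooth_window = 5) {
  stopifnot(inherits(log, "temperature_log"))
  if (T_low >= T_high) stop_msg("require T_low < T_high")
  falling <- log$temp_C[nrow(log)] < log$temp_C[1]
  if (falling) {
    t_hi <- first_crossing(log$time_s, log$temp_C, T_high, TRUE)
    t_lo <- first_crossing(log$time_s, log$temp_C, T_low, TRUE)
  } else {
    t_lo <- first_crossing(log$time_s, log$temp_C, T_low, FALSE)
    t_hi <- first_crossing(log$time_s, log$temp_C, T_high, FALSE)
  }
  if (is.na(t_hi) || is.na(t_lo))
    stop_msg("log does not cross both %g and %g C", T_high, T_low)
  elapsed <- abs(t_lo - t_hi)
  if (elapsed <= 0) stop_msg("degenerate crossing interval")
  mag <- (T_high - T_low) / elapsed * 60
  sm <- stats::filter(log$temp_C, rep(1 / smooth_window, smooth_window),
                      sides = 2)
  ok <- which(!is.na(sm))
  inst <- data.frame(time_s = log$time_s[ok],
                     rate_C_min = c(NA, diff(as.numeric(sm[ok])) /
                                      diff(log$time_s[ok])) * 60)
  list(mean_rate = if (falling) -mag else mag, magnitude = mag,
       direction = if (falling) "cooling" else "warming",
       t_high_s = t_hi, t_low_s = t_lo, instantaneous = inst)
}

#' Check an achieved rate against a critical rate
#'
#' Pass requires the magnitude of the achieved rate to strictly exceed the
#' critical rate (CCR for cooling, CWR for warming).
#'
#' @param rate achieved rate, C/min (signed or magnitude).
#' @param critical critical rate, C/min (> 0).
#' @return list with `pass` and `margin` (`|rate|/critical`).
#' @export
check_against_critical <- function(rate, critical) {
  if (critical <= 0) stop_msg("critical rate must be positive")
  margin <- abs(rate) / critical
  list(pass = margin > 1, margin = margin)
}

#' DSC thermogram
#'
#' Heat flow vs temperature scan from differential scanning calorimetry, used
#' to quantify crystallization/melting events. The temperature sequence must
#' be monotone in the scan direction.
#'
#' @param temp_C scan temperatures, C.
#' @param heatflow heat flow, W/g.
#' @param scan_rate scan rate magnitude, C/min.
#' @param direction `"cooling"` or `"warming"`.
#' @param latent_heat_ref reference latent heat of fusion, J/g (pure water
#'   334 J/g by default).
#' @export
thermogram <- function(temp_C, heatflow, scan_rate, direction = c("warming",
                       "cooling"), latent_heat_ref = 334) {
  direction <- match.arg(direction)
  if (length(temp_C) != length(heatflow))
    stop_msg("temperature and heat flow must have equal length")
  d <- diff(temp_C)
  if (direction == "warming" && any(d <= 0))
    stop_msg("warming scan temperatures must be strictly increasing")
  if (direction == "cooling" && any(d >= 0))
    stop_msg("cooling scan temperatures must be strictly decreasing")
  if (scan_rate <= 0) stop_msg("scan rate must be positive")
  structure(list(temp_C = temp_C, heatflow = heatflow, scan_rate = scan_rate,
                 direction = direction, latent_heat_ref = latent_heat_ref),
            class = "thermogram")
}

#' Ice fraction from a DSC thermogram
#'
#' Baseline-corrects the scan (linear fit through the event-free flanks),
#' integrates the crystallization/melting event over temperature
#' (trapezoidal rule), converts to energy per gram by dividing by the scan
#' rate, and expresses it as a percentage of the reference latent heat,
#' clipped to `[0, 100]`. Adding any constant or linear baseline to the heat
#' flow leaves the result unchanged.
#'
#' @param tg a [thermogram()].
#' @param flank_frac fraction of the scan at each end treated as event-free
#'   baseline.
#' @return ice fraction, percent.
#' @export
ice_fraction <- function(tg, flank_frac = 0.15) {
  stopifnot(inherits(tg, "thermogram"))
  if (tg$latent_heat_ref <= 0) stop_msg("reference latent heat must be positive")
  n <- length(tg$temp_C)
  k <- max(2L, floor(n * flank_frac))
  idx <- c(seq_len(k), seq(n - k + 1L, n))
  base <- stats::lm.fit(cbind(1, tg$temp_C[idx]), tg$heatflow[idx])$coefficients
  corr <- tg$heatflow - (base[1] + base[2] * tg$temp_C)
  area <- abs(trapz(tg$temp_C, corr))          # (W/g) C
  energy <- area / (tg$scan_rate / 60)         # J/g
  min(100, max(0, 100 * energy / tg$latent_heat_ref))
}

#' Critical rate from ice-fraction measurements
#'
#' Given ice fractions measured at several cooling (or warming) rates, the
#' critical rate is where the ice fraction falls to a small threshold
#' (default 0.5%). Because the ice fraction decays roughly exponentially with
#' rate, interpolation is linear in `log10(ice fraction)` vs rate. If the
#' threshold lies outside the measured range the result is extrapolated and
#' flagged.
#'
#' @param points data frame (or 2-column matrix) with columns `rate` (C/min)
#'   and `ice_fraction` (%), at least two rows; ice fraction must be monotone
#'   non-increasing in rate.
#' @param threshold ice-fraction threshold, percent.
#' @return list with `rate` (C/min), `extrapolated`, `threshold`.
#' @export
critical_rate <- function(points, threshold = 0.5) {
  points <- as.data.frame(points)
  names(points)[1:2] <- c("rate", "ice_fraction")
  if (nrow(points) < 2L) stop_msg("need at least two (rate, ice fraction) points")
  points <- points[order(points$rate), ]
  if (any(diff(points$ice_fraction) > 0))
    stop_msg("ice fraction must be monotone non-increasing in rate")
  if (threshold <= 0) stop_msg("threshold must be positive")
  exact <- which(points$ice_fraction == threshold)
  if (length(exact))
    return(list(rate = points$rate[exact[1]], extrapolated = FALSE,
                threshold = threshold))
  if (any(points$ice_fraction <= 0))
    stop_msg("non-positive ice fractions cannot be log-interpolated")
  lf <- log10(points$ice_fraction)
  target <- log10(threshold)
  extrap <- target > max(lf) || target < min(lf)
  # piecewise-linear in (log10 fraction, rate); extrapolate on end slopes
  rate <- stats::approx(lf, points$rate, xout = target, rule = 1)$y
  if (is.na(rate)) {
    i <- if (target > max(lf)) order(lf)[c(length(lf) - 1L, length(lf))]
         else order(lf)[1:2]
    slope <- diff(points$rate[i]) / diff(lf[i])
    rate <- points$rate[i[1]] + slope * (target - lf[i[1]])
  }
  list(rate = rate, extrapolated = extrap, threshold = threshold)
}

#' Controlled-rate freezer program
#'
#' An ordered list of chamber setpoint segments, each either a linear ramp
#' (`rate` C/min, duration derived from the temperature span) or a hold
#' (`hold_min` minutes). [vitrification_program()] is the kidney
#' vitrification program: cool 0 to -122 C at -40 C/min, anneal 25 min just
#' above the glass transition, cool -122 to -150 C at -5 C/min, then hold
#' 10 min at the storage temperature.
#'
#' @param segments data frame with columns `start_C`, `end_C`, and either
#'   `rate_C_min` (ramps) or `hold_min` (holds, `start_C == end_C`).
#' @export
freezer_program <- function(segments) {
  segments <- as.data.frame(segments)
  need <- c("start_C", "end_C")
  if (!all(need %in% names(segments))) stop_msg("need start_C and end_C columns")
  if (is.null(segments$rate_C_min)) segments$rate_C_min <- NA_real_
  if (is.null(segments$hold_min)) segments$hold_min <- NA_real_
  dur <- ifelse(is.na(segments$rate_C_min),
                segments$hold_min,
                abs(segments$end_C - segments$start_C) /
                  abs(segments$rate_C_min))
  if (any(!is.finite(dur) | dur < 0)) stop_msg("invalid segment durations")
  for (i in seq_len(nrow(segments))) {
    if (is.na(segments$rate_C_min[i]) &&
        segments$start_C[i] != segments$end_C[i])
      stop_msg("hold segment %d must keep a constant setpoint", i)
    if (i > 1 && segments$start_C[i] != segments$end_C[i - 1])
      stop_msg("setpoint discontinuity between segments %d and %d", i - 1, i)
  }
  structure(list(segments = segments, duration = dur,
                 start = cumsum(c(0, dur))[seq_len(nrow(segments))]),
            class = "freezer_program")
}

#' @rdname freezer_program
#' @export
vitrification_program <- function() {
  freezer_program(data.frame(
    start_C = c(0, -122, -122, -150),
    end_C = c(-122, -122, -150, -150),
    rate_C_min = c(-40, NA, -5, NA),
    hold_min = c(NA, 25, NA, 10)))
}

#' @rdname freezer_program
#' @param prog a `freezer_program`.
#' @export
program_duration <- function(prog) {
  stopifnot(inherits(prog, "freezer_program"))
  sum(prog$duration)
}

#' Freezer setpoint at a given time
#'
#' Piecewise-linear chamber setpoint trajectory of a freezer program.
#'
#' @param prog a [freezer_program()].
#' @param t time(s) in minutes within the program span.
#' @return setpoint temperature(s), C.
#' @export
freezer_setpoints <- function(prog, t) {
  stopifnot(inherits(prog, "freezer_program"))
  tot <- program_duration(prog)
  if (any(t < 0 | t > tot)) stop_msg("time outside program span [0, %g] min", tot)
  idx <- pmin(findInterval(t, prog$start), nrow(prog$segments))
  frac <- ifelse(prog$duration[idx] > 0,
                 (t - prog$start[idx]) / prog$duration[idx], 0)
  prog$segments$start_C[idx] +
    frac * (prog$segments$end_C[idx] - prog$segments$start_C[idx])
}
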