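#' CPA perfusion protocol segments
#'
#' A perfusion protocol is an ordered sequence of segments, each describing how
#' the arterial cryoprotective-agent (CPA) concentration evolves over a span of
#' time together with the pressure and temperature setpoints of the perfusion
#' system. Five segment kinds are supported:
#'
#' * `flush` - carrier-only perfusion at a constant (usually zero) CPA
#'   concentration for a fixed duration.
#' * `ramp` - linear concentration change at a stated rate (mM/min, signed);
#'   the duration is derived as `|c_end - c_start| / |rate|`.
#' * `hold` - constant concentration for a fixed duration (osmotic
#'   equilibration pauses).
#' * `step` - an abrupt change to a new constant concentration held for a fixed
#'   duration; the discontinuity at the step boundary is intentional and the
#'   value applies on the half-open interval `[start, end)`.
#' * `ionp` - nanoparticle co-perfusion at constant CPA concentration and a
#'   fixed volumetric flow setpoint (mL/min); nanoparticles are treated as
#'   non-permeating and do not enter the membrane-transport model.
#'
#' An optional adjunct co-solute (e.g. mannitol during unloading) rides on the
#' same timeline: constant on non-ramp segments, linear on ramps. Its ramp rate
#' must be consistent with the segment duration derived from the CPA rate.
#'
#' @param duration span of the segment in minutes (not for `ramp`, where it is
#'   derived).
#' @param c,c_start,c_end CPA concentration in mM.
#' @param rate concentration ramp rate in mM/min, signed.
#' @param pressure perfusion pressure setpoint, mmHg.
#' @param temperature perfusate temperature, degrees C.
#' @param adjunct optional co-solute, a list with elements `name`, `c_start`,
#'   `c_end` (mM) and, for ramps, optionally `rate` (mM/min).
#' @param flow constant flow setpoint for `ionp` segments, mL/min.
#' @return a `protocol_segment` list.
#' @name protocol_segments
NULL

new_segment <- function(kind, c_start, c_end, rate = NA_real_,
                        duration = NA_real_, pressure = 40, temperature = 4,
                        adjunct = NULL, flow = NA_real_) {
  seg <- list(kind = kind, c_start = c_start, c_end = c_end, rate = rate,
              duration = duration, pressure = pressure,
              temperature = temperature, adjunct = adjunct, flow = flow)
  class(seg) <- "protocol_segment"
  seg
}

#' @rdname protocol_segments
#' @export
seg_flush <- function(duration, c = 0, pressure = 40, temperature = 4,
                      adjunct = NULL)
  new_segment("flush", c, c, duration = duration, pressure = pressure,
              temperature = temperature, adjunct = adjunct)

#' @rdname protocol_segments
#' @export
seg_ramp <- function(c_start, c_end, rate, pressure = 40, temperature = 4,
                     adjunct = NULL)
  new_segment("ramp", c_start, c_end, rate = rate, pressure = pressure,
              temperature = temperature, adjunct = adjunct)

#' @rdname protocol_segments
#' @export
seg_hold <- function(c, duration, pressure = 40, temperature = 4,
                     adjunct = NULL)
  new_segment("hold", c, c, duration = duration, pressure = pressure,
              temperature = temperature, adjunct = adjunct)

#' @rdname protocol_segments
#' @export
seg_step <- function(c, duration, pressure = 40, temperature = 4,
                     adjunct = NULL)
  new_segment("step", c, c, duration = duration, pressure = pressure,
              temperature = temperature, adjunct = adjunct)

#' @rdname protocol_segments
#' @export
seg_ionp <- function(c, duration = 4.5, flow = 0.5, pressure = 45,
                     temperature = 4, adjunct = NULL)
  new_segment("ionp", c, c, duration = duration, pressure = pressure,
              temperature = temperature, adjunct = adjunct, flow = flow)

#' Duration of a linear concentration ramp
#'
#' @param c_start,c_end endpoint concentrations, mM.
#' @param rate ramp rate, mM/min, signed; its sign must match the direction of
#'   the change and it must be non-zero.
#' @return ramp duration in minutes.
#' @examples
#' ramp_duration(4200, 0, -35) # 120
#' ramp_duration(0, 5000, 50)  # 100
#' @export
ramp_duration <- function(c_start, c_end, rate) {
  if (!is.finite(rate) || rate == 0)
    stop_msg("ramp rate must be non-zero and finite")
  if (c_start != c_end && sign(rate) != sign(c_end - c_start))
    stop_msg("ramp rate sign (%+g) inconsistent with direction %g -> %g mM",
             rate, c_start, c_end)
  abs(c_end - c_start) / abs(rate)
}

validate_segment <- function(seg, i) {
  k <- seg$kind
  if (!k %in% c("flush", "ramp", "hold", "step", "ionp"))
    stop_msg("segment %d: unknown kind '%s'", i, k)
  if (seg$pressure <= 0)
    stop_msg("segment %d: pressure setpoint must be positive", i)
  if (seg$temperature < -10 || seg$temperature > 40)
    stop_msg("segment %d: temperature %g outside [-10, 40] C", i,
             seg$temperature)
  if (k == "ramp") {
    d <- tryCatch(ramp_duration(seg$c_start, seg$c_end, seg$rate),
                  error = function(e)
                    stop_msg("segment %d: %s", i, conditionMessage(e)))
    if (!is.finite(d) || d <= 0)
      stop_msg("segment %d: derived ramp duration must be finite and positive",
               i)
    seg$duration <- d
  } else {
    if (seg$c_start != seg$c_end)
      stop_msg("segment %d: non-ramp segment must have c_start == c_end", i)
    if (!is.finite(seg$duration) || seg$duration < 0)
      stop_msg("segment %d: duration must be a finite non-negative number", i)
  }
  if (!is.null(seg$adjunct)) {
    a <- seg$adjunct
    if (is.null(a$name) || is.null(a$c_start) || is.null(a$c_end))
      stop_msg("segment %d: adjunct needs name, c_start and c_end", i)
    if (k == "ramp") {
      implied <- (a$c_end - a$c_start) / seg$duration
      if (!is.null(a$rate) && !is.na(a$rate) &&
          abs(a$rate - implied) > 1e-9 * max(1, abs(implied)))
        stop_msg("segment %d: adjunct rate %g inconsistent with duration-implied %g mM/min",
                 i, a$rate, implied)
      seg$adjunct$rate <- implied
    } else {
      if (a$c_start != a$c_end)
        stop_msg("segment %d: adjunct must be constant on non-ramp segments", i)
      seg$adjunct$rate <- 0
    }
  }
  seg
}

#' Build and validate a CPA perfusion protocol
#'
#' Assembles segments into a validated protocol. Ramp durations are derived
#' from their endpoints and rate. Adjacent segments must be
#' concentration-continuous unless the boundary involves an explicit `step`
#' segment, whose discontinuity is part of the design.
#'
#' @param segments list of [protocol_segments].
#' @param name protocol label.
#' @param cpa CPA cocktail label (e.g. `"VMP"`).
#' @param carrier carrier solution label (e.g. `"LM5-XZ"`).
#' @return a `cpa_protocol` object.
#' @export
build_protocol <- function(segments, name = "protocol", cpa = "VMP",
                           carrier = "LM5-XZ") {
  segments <- lapply(seq_along(segments), function(i)
    validate_segment(segments[[i]], i))
  n <- length(segments)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      a <- segments[[i]]; b <- segments[[i + 1L]]
      if (a$kind != "step" && b$kind != "step" && a$c_end != b$c_start)
        stop_msg(paste0("segments %d -> %d: concentration discontinuity ",
                        "(%g -> %g mM) not marked as a step"),
                 i, i + 1L, a$c_end, b$c_start)
    }
  }
  durs <- vapply(segments, `[[`, numeric(1), "duration")
  p <- list(name = name, cpa = cpa, carrier = carrier, segments = segments,
            start = cumsum(c(0, durs))[seq_len(max(n, 1L))],
            duration = durs)
  if (n == 0L) p$start <- numeric(0)
  class(p) <- "cpa_protocol"
  p
}

#' @export
print.cpa_protocol <- function(x, ...) {
  cat(sprintf("<cpa_protocol> %s (%s in %s), %d segments, %g min total\n",
              x$name, x$cpa, x$carrier, length(x$segments),
              total_duration(x)))
  for (i in seq_along(x$segments)) {
    s <- x$segments[[i]]
    cat(sprintf("  %2d %-6s %6g -> %6g mM  %6.2f min  %g mmHg  %g C%s\n",
                i, s$kind, s$c_start, s$c_end, s$duration, s$pressure,
                s$temperature,
                if (!is.null(s$adjunct))
                  sprintf("  +%s %g->%g mM", s$adjunct$name,
                          s$adjunct$c_start, s$adjunct$c_end) else ""))
  }
  invisible(x)
}

#' Total duration of a protocol
#'
#' Sum of all segment durations (derived ramp durations included), minutes.
#'
#' @param p a `cpa_protocol`.
#' @export
total_duration <- function(p) {
  stopifnot(inherits(p, "cpa_protocol"))
  sum(p$duration)
}

adjunct_names <- function(p)
  unique(unlist(lapply(p$segments, function(s) s$adjunct$name)))

#' Evaluate protocol concentrations at given times
#'
#' Piecewise evaluation of the CPA concentration (and each adjunct co-solute)
#' defined by a protocol. Ramps are linear; `step` segments take their own
#' value on the half-open interval `[start, end)` (right-continuous at the
#' step boundary). The final instant `t == total_duration(p)` evaluates to the
#' last segment's end value.
#'
#' @param p a `cpa_protocol`.
#' @param t vector of times in minutes, all within `[0, total_duration(p)]`.
#' @return data frame with columns `time_min`, `cpa_mM`, and one column per
#'   adjunct solute (mM).
#' @export
concentration_at <- function(p, t) {
  stopifnot(inherits(p, "cpa_protocol"))
  tot <- total_duration(p)
  if (any(t < 0 | t > tot))
    stop_msg("time outside [0, %g] min", tot)
  if (length(p$segments) == 0L)
    return(data.frame(time_min = t, cpa_mM = rep(0, length(t))))
  idx <- pmin(findInterval(t, p$start), length(p$segments))
  eval_one <- function(ti, i) {
    s <- p$segments[[i]]
    frac <- if (s$duration > 0) (ti - p$start[i]) / s$duration else 0
    cpa <- if (s$kind == "ramp") s$c_start + frac * (s$c_end - s$c_start)
           else s$c_start
    adj <- numeric(0)
    nm <- adjunct_names(p)
    if (length(nm)) {
      adj <- setNames(numeric(length(nm)), nm)
      if (!is.null(s$adjunct)) {
        a <- s$adjunct
        adj[a$name] <- if (s$kind == "ramp")
          a$c_start + frac * (a$c_end - a$c_start) else a$c_start
      }
    }
    c(cpa = cpa, adj)
  }
  vals <- do.call(rbind, Map(eval_one, t, idx))
  out <- data.frame(time_min = t, cpa_mM = unname(vals[, "cpa"]))
  nm <- adjunct_names(p)
  for (a in nm) out[[a]] <- unname(vals[, a])
  rownames(out) <- NULL
  out
}

#' Nanoparticle perfusion flow-rate quality control
#'
#' Prospective exclusion rule for nanoparticle-loaded organs: the perfusion
#' flow rate observed during unloading must exceed 45% of the flow rate
#' observed during loading (strict inequality), otherwise nanoparticle
#' aggregation is suspected and the organ is excluded.
#'
#' @param loading_flow observed flow during loading, mL/min (> 0).
#' @param unloading_flow observed flow during unloading, mL/min.
#' @param threshold ratio cutoff (default 0.45).
#' @return list with `pass` (logical), `ratio`, `threshold`.
#' @export
flow_qc <- function(loading_flow, unloading_flow, threshold = 0.45) {
  if (!is.finite(loading_flow) || loading_flow <= 0)
    stop_msg("loading flow must be positive")
  ratio <- unloading_flow / loading_flow
  list(pass = ratio > threshold, ratio = ratio, threshold = threshold)
}

#' Reference VMP loading and unloading protocols
#'
#' `vmp_loading_protocol()`: 20-min carrier flush, ramp 0 to 5000 mM at
#' 50 mM/min (100 min), 10-min hold at 5000 mM for osmotic equilibration, then
#' a 25-min step to full-strength VMP (8400 mM) at raised pressure
#' (40 to 60 mmHg) - 155 min in total. With `include_ionp = TRUE` an explicit
#' nanoparticle co-perfusion segment (4.5 min at 0.5 mL/min in full-strength
#' VMP) is appended; by default the co-perfusion is understood to overlap the
#' final minutes of the step and is not double-counted in the total.
#'
#' `vmp_unloading_protocol()`: 15-min hold at 4200 mM VMP with 300 mM mannitol
#' (cell-swelling control), ramp to 0 mM at -35 mM/min with the mannitol
#' ramping out at -2.5 mM/min (120 min), then a 30-min carrier flush -
#' 165 min in total at 40 mmHg, 0-4 C.
#'
#' @param include_ionp append the nanoparticle co-perfusion segment.
#' @param ionp_duration duration of that segment, minutes.
#' @return a `cpa_protocol`.
#' @export
vmp_loading_protocol <- function(include_ionp = FALSE, ionp_duration = 4.5) {
  segs <- list(
    seg_flush(20, pressure = 40, temperature = 4),
    seg_ramp(0, 5000, 50, pressure = 40, temperature = 4),
    seg_hold(5000, 10, pressure = 40, temperature = 4),
    seg_step(8400, 25, pressure = 60, temperature = 4)
  )
  if (include_ionp)
    segs <- c(segs, list(seg_ionp(8400, duration = ionp_duration)))
  build_protocol(segs, name = "VMP loading", cpa = "VMP", carrier = "LM5-XZ")
}

#' @rdname vmp_loading_protocol
#' @export
vmp_unloading_protocol <- function() {
  mann <- function(c0, c1) list(name = "mannitol", c_start = c0, c_end = c1)
  build_protocol(list(
    seg_hold(4200, 15, pressure = 40, temperature = 2,
             adjunct = mann(300, 300)),
    seg_ramp(4200, 0, -35, pressure = 40, temperature = 2,
             adjunct = mann(300, 0)),
    seg_flush(30, pressure = 40, temperature = 2)
  ), name = "VMP unloading", cpa = "VMP", carrier = "LM5-XZ")
}

#' Read or write a protocol as YAML
#'
#' The YAML form carries `name`, `cpa`, `carrier` and a `segments` list with
#' per-kind keys; reading re-validates through [build_protocol()] so the
#' round trip is lossless.
#'
#' @param p a `cpa_protocol`.
#' @param path file path.
#' @export
write_protocol_yaml <- function(p, path) {
  stopifnot(inherits(p, "cpa_protocol"))
  seg_list <- lapply(p$segments, function(s) {
    out <- list(kind = s$kind, c_start = s$c_start, c_end = s$c_end,
                pressure = s$pressure, temperature = s$temperature)
    if (s$kind == "ramp") out$rate <- s$rate else out$duration <- s$duration
    if (s$kind == "ionp") out$flow <- s$flow
    if (!is.null(s$adjunct))
      out$adjunct <- list(name = s$adjunct$name, c_start = s$adjunct$c_start,
                          c_end = s$adjunct$c_end)
    out
  })
  yaml::write_yaml(list(name = p$name, cpa = p$cpa, carrier = p$carrier,
                        segments = seg_list), path)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  segs <- lapply(y$segments, function(s) {
    adj <- s$adjunct
    switch(s$kind,
      flush = seg_flush(s$duration, c = s$c_start, pressure = s$pressure,
                        temperature = s$temperature, adjunct = adj),
      ramp = seg_ramp(s$c_start, s$c_end, s$rate, pressure = s$pressure,
                      temperature = s$temperature, adjunct = adj),
      hold = seg_hold(s$c_start, s$duration, pressure = s$pressure,
                      temperature = s$temperature, adjunct = adj),
      step = seg_step(s$c_start, s$duration, pressure = s$pressure,
                      temperature = s$temperature, adjunct = adj),
      ionp = seg_ionp(s$c_start, s$duration, flow = s$flow,
                      pressure = s$pressure, temperature = s$temperature,
                      adjunct = adj),
      stop_msg("unknown segment kind '%s' in %s", s$kind, path))
  })
  build_protocol(segs, name = y$name %||% "protocol", cpa = y$cpa %||% "CPA",
                 carrier = y$carrier %||% "carrier")
}
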