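# Independent oracles used to cross-check the implementation. These are
# deliberately written from the defining formulas, not by calling the
# package's own solvers.

# Brute-force explicit-Euler integration of a single Krogh unit with one
# axial segment: constant inlet concentration, donor-side convective term.
euler_transport <- function(c_in, duration_min, g, m, flow_mL_min,
                            c_imp_vasc = 300, c_imp_extra0 = 300,
                            delta_p = 0, T_K = 277.15, dt_s = 0.01,
                            sample_every = 1000) {
  R <- 8.314462618
  Vv <- pi * g$capillary_radius^2 * g$unit_length
  V0 <- pi * (g$tissue_radius^2 - g$capillary_radius^2) * g$unit_length
  A <- 2 * pi * g$capillary_radius * g$unit_length
  Q <- flow_mL_min / g$n_units * 1e-6 / 60
  cv <- 0; vr <- 1; ce <- 0
  nstep <- ceiling(duration_min * 60 / dt_s)
  out <- matrix(NA_real_, floor(nstep / sample_every) + 1L, 4)
  out[1, ] <- c(0, cv, vr, ce)
  row <- 2L
  for (k in seq_len(nstep)) {
    RT <- R * T_K
    Jv <- m$Lp * (delta_p - m$sigma * RT * (cv - ce) -
                    RT * (c_imp_vasc - c_imp_extra0 / vr))
    cbar <- if (Jv >= 0) cv else ce
    Js <- m$omega * RT * (cv - ce) + (1 - m$sigma) * cbar * Jv
    qo <- Q - Jv * A
    dcv <- (Q * c_in - qo * cv - Js * A) / Vv
    dvr <- Jv * A / V0
    dce <- (Js * A - ce * Jv * A) / (vr * V0)
    cv <- cv + dt_s * dcv
    vr <- vr + dt_s * dvr
    ce <- ce + dt_s * dce
    if (k %% sample_every == 0L) {
      out[row, ] <- c(k * dt_s / 60, cv, vr, ce)
      row <- row + 1L
    }
  }
  colnames(out) <- c("t_min", "c_vasc", "V_rel", "c_extra")
  as.data.frame(out[!is.na(out[, 1]), ])
}

# Exact two-sided Wilcoxon rank-sum p-value by enumeration of all
# group-label assignments.
wilcox_p_enum <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  ws <- apply(combs, 2, function(i) sum(r[i]))
  mu <- n1 * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu))
}

# Kendall tau by brute force over all pairs (tau-a; equals tau-b without
# ties).
kendall_tau_brute <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
  s / choose(n, 2)
}

# Independent trapezoid integration used to cross-check ice_fraction.
trapz_oracle <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Random but valid CPA protocol for property tests.
random_protocol <- function(seed) {
  set.seed(seed)
  segs <- list()
  c_now <- 0
  n <- sample(2:5, 1)
  for (i in seq_len(n)) {
    kind <- sample(c("flush", "ramp", "hold", "step"), 1)
    if (i == 1 && kind == "ramp" && c_now == 0 && runif(1) < 0.5)
      kind <- "flush"
    seg <- switch(kind,
      flush = { c_now <- 0; seg_flush(runif(1, 2, 10), c = 0) },
      ramp = {
        target <- runif(1, 0, 6000)
        if (abs(target - c_now) < 1) target <- c_now + 500
        rate <- sign(target - c_now) * runif(1, 50, 400)
        s <- seg_ramp(c_now, target, rate); c_now <- target; s
      },
      hold = seg_hold(c_now, runif(1, 2, 10)),
      step = { c_now <- runif(1, 0, 8400); seg_step(c_now, runif(1, 2, 10)) })
    segs <- c(segs, list(seg))
  }
  # a flush after a step is a discontinuity; route through build for validity
  for (i in seq_along(segs)[-1]) {
    if (segs[[i]]$kind == "flush" && segs[[i - 1]]$kind != "step" &&
        segs[[i - 1]]$c_end != 0)
      segs[[i]] <- seg_step(0, segs[[i]]$duration)
  }
  build_protocol(segs, name = sprintf("random_%d", seed))
}
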