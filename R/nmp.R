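#' Normothermic machine perfusion functional metrics
#'
#' During normothermic machine perfusion (NMP) the kidney is perfused at 37 C
#' with an oxygenated acellular Krebs-Henseleit perfusate at physiologic
#' pressure (90-110 mmHg), and hemodynamics plus venous/ureteral effluent
#' chemistry are sampled at 10-min intervals. These helpers compute the
#' standard per-organ functional metrics.
#'
#' `vascular_resistance()` is mass-normalized as pressure divided by flow per
#' gram, in mmHg/(mL/min/g) - note this convention means *multiplying* by
#' kidney mass, matching the field's "mmHg/mL/min x g" unit string.
#'
#' `substrate_flux()` converts an arteriovenous concentration difference
#' (mmol/L) times flow (mL/min) into umol/(min g); `sign = "consumption"`
#' (default) counts arterial minus venous (glucose), `"production"` venous
#' minus arterial (lactate).
#'
#' `creatinine_clearance()` is the classic UV/P clearance per organ.
#'
#' `oxygen_consumption()` uses dissolved oxygen only (the perfusate is
#' acellular): the arteriovenous pO2 difference times an oxygen solubility
#' coefficient (default 1.4 umol/(L mmHg) at 37 C, configurable) times flow.
#'
#' @param pressure arterial pressure, mmHg.
#' @param flow arterial flow, mL/min (> 0 for resistance).
#' @param mass kidney mass, g.
#' @return numeric metric value (see each description for units).
#' @name nmp_metrics
NULL

#' @rdname nmp_metrics
#' @export
vascular_resistance <- function(pressure, flow, mass) {
  if (any(mass <= 0)) stop_msg("kidney mass must be positive")
  if (any(flow <= 0)) stop_msg("flow must be positive (infinite resistance)")
  pressure / (flow / mass)
}

#' @rdname nmp_metrics
#' @param c_art,c_ven arterial/venous concentrations, mmol/L.
#' @param sign `"consumption"` (arterial minus venous) or `"production"`.
#' @export
substrate_flux <- function(c_art, c_ven, flow, mass,
                           sign = c("consumption", "production")) {
  sign <- match.arg(sign)
  if (any(mass <= 0)) stop_msg("kidney mass must be positive")
  d <- if (sign == "consumption") c_art - c_ven else c_ven - c_art
  d * flow / mass        # mmol/L * mL/min = umol/min
}

#' @rdname nmp_metrics
#' @param u_cr urine creatinine, mg/dL.
#' @param urine_flow urine flow, mL/min.
#' @param p_cr perfusate (arterial) creatinine, mg/dL (> 0).
#' @export
creatinine_clearance <- function(u_cr, urine_flow, p_cr) {
  if (any(p_cr <= 0)) stop_msg("perfusate creatinine must be positive")
  u_cr * urine_flow / p_cr
}

#' @rdname nmp_metrics
#' @param pO2_art,pO2_ven arterial/venous oxygen partial pressure, mmHg.
#' @param solubility oxygen solubility, umol/(L mmHg).
#' @export
oxygen_consumption <- function(pO2_art, pO2_ven, flow, mass,
                               solubility = 1.4) {
  if (any(mass <= 0)) stop_msg("kidney mass must be positive")
  if (any(solubility <= 0)) stop_msg("solubility must be positive")
  (pO2_art - pO2_ven) * solubility * (flow / 1000) / mass
}

#' Endpoint metrics from an NMP perfusion time series
#'
#' Computes the standard functional metrics from a perfusion record (one
#' kidney, samples at fixed cadence): cumulative urine output, and the
#' minute-`t_end` vascular resistance, creatinine clearance, oxygen
#' consumption, glucose consumption and lactate production.
#'
#' @param series data frame with columns `time_min`, `pressure_mmHg`,
#'   `flow_mL_min`, `pO2_art`, `pO2_ven`, `glucose_art`, `glucose_ven`,
#'   `lactate_art`, `lactate_ven`, `urine_mL` (per-interval increment),
#'   `urine_cr_mg_dl`, `perf_cr_mg_dl`.
#' @param mass kidney mass, g.
#' @param solubility oxygen solubility, umol/(L mmHg).
#' @return list of metrics; `cumulative_urine` is the full non-decreasing
#'   series.
#' @export
nmp_endpoint_metrics <- function(series, mass, solubility = 1.4) {
  need <- c("time_min", "pressure_mmHg", "flow_mL_min", "urine_mL")
  if (!all(need %in% names(series)))
    stop_msg("series missing columns: %s",
             paste(setdiff(need, names(series)), collapse = ", "))
  series <- series[order(series$time_min), ]
  last <- nrow(series)
  cadence <- if (last > 1) diff(series$time_min)[last - 1] else NA_real_
  urine_flow <- series$urine_mL[last] / cadence
  list(
    cumulative_urine = cumsum(series$urine_mL),
    resistance = vascular_resistance(series$pressure_mmHg[last],
                                     series$flow_mL_min[last], mass),
    creatinine_clearance = if (!is.null(series$urine_cr_mg_dl))
      creatinine_clearance(series$urine_cr_mg_dl[last], urine_flow,
                           series$perf_cr_mg_dl[last]) else NA_real_,
    ocr = if (!is.null(series$pO2_art))
      oxygen_consumption(series$pO2_art[last], series$pO2_ven[last],
                         series$flow_mL_min[last], mass, solubility)
      else NA_real_,
    glucose_consumption = if (!is.null(series$glucose_art))
      substrate_flux(series$glucose_art[last], series$glucose_ven[last],
                     series$flow_mL_min[last], mass) else NA_real_,
    lactate_production = if (!is.null(series$lactate_ven))
      substrate_flux(series$lactate_art[last], series$lactate_ven[last],
                     series$flow_mL_min[last], mass, sign = "production")
      else NA_real_,
    mass_g = mass)
}

# Games-Howell pairwise comparisons: Welch-type t statistics referred to the
# studentized-range distribution; the standard post hoc for unequal variances.
games_howell <- function(values, groups) {
  gl <- split(values, groups)
  k <- length(gl)
  nm <- names(gl)
  means <- vapply(gl, mean, numeric(1))
  vars <- vapply(gl, stats::var, numeric(1))
  ns <- vapply(gl, length, numeric(1))
  out <- NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se2 <- vars[i] / ns[i] + vars[j] / ns[j]
    df <- se2^2 / ((vars[i] / ns[i])^2 / (ns[i] - 1) +
                     (vars[j] / ns[j])^2 / (ns[j] - 1))
    tstat <- (means[i] - means[j]) / sqrt(se2)
    p <- stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    out <- rbind(out, data.frame(group1 = nm[i], group2 = nm[j],
                                 estimate = means[i] - means[j],
                                 statistic = tstat, df = df, p_adj = p))
  }
  rownames(out) <- NULL
  out
}

#' Group comparison with normality/variance gating
#'
#' Implements the decision tree used for NMP endpoint comparisons:
#' Shapiro-Wilk normality per group; if all groups are consistent with
#' normality, Levene's test gates between ANOVA with Tukey HSD post hoc
#' (equal variances) and Games-Howell (unequal variances); otherwise
#' Kruskal-Wallis with pairwise Wilcoxon rank-sum tests (Holm-adjusted).
#' With exactly two normal groups a t-test (pooled or Welch per the Levene
#' gate) is used directly.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @param alpha gate level for the Shapiro-Wilk and Levene tests.
#' @return an `nmp_group_test` list: `path` (one of `"anova_tukey"`,
#'   `"games_howell"`, `"kruskal_wallis"`, `"t_test"`, `"welch_t"`),
#'   `normal_p`, `levene_p`, `omnibus` (statistic + p), and `pairwise`
#'   (data frame with adjusted p-values).
#' @export
group_compare <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop_msg("need at least two groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L)) stop_msg("every group needs n >= 2")
  values <- unlist(groups, use.names = FALSE)
  gf <- factor(rep(names(groups), ns), levels = names(groups))
  k <- length(groups)

  normal_p <- vapply(groups, function(g) {
    if (length(unique(g)) < 3L || length(g) < 3L) return(1)
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  normal <- all(normal_p > alpha)

  if (!normal) {
    om <- stats::kruskal.test(values, gf)
    pw <- stats::pairwise.wilcox.test(values, gf, p.adjust.method = "holm",
                                      exact = FALSE)
    pmat <- pw$p.value
    pairs <- which(!is.na(pmat), arr.ind = TRUE)
    pairwise <- data.frame(group1 = colnames(pmat)[pairs[, 2]],
                           group2 = rownames(pmat)[pairs[, 1]],
                           p_adj = pmat[pairs])
    res <- list(path = "kruskal_wallis", normal_p = normal_p,
                levene_p = NA_real_,
                omnibus = list(statistic = unname(om$statistic),
                               p = om$p.value),
                pairwise = pairwise)
    class(res) <- "nmp_group_test"
    return(res)
  }

  lev <- car::leveneTest(values ~ gf)
  levene_p <- lev[["Pr(>F)"]][1]
  equal_var <- levene_p > alpha

  if (k == 2L) {
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = equal_var)
    res <- list(path = if (equal_var) "t_test" else "welch_t",
                normal_p = normal_p, levene_p = levene_p,
                omnibus = list(statistic = unname(tt$statistic),
                               p = tt$p.value),
                pairwise = data.frame(group1 = names(groups)[1],
                                      group2 = names(groups)[2],
                                      estimate = mean(groups[[1]]) -
                                        mean(groups[[2]]),
                                      p_adj = tt$p.value))
  } else if (equal_var) {
    fit <- stats::aov(values ~ gf)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$gf
    nms <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(group1 = vapply(nms, `[`, character(1), 1),
                           group2 = vapply(nms, `[`, character(1), 2),
                           estimate = tk[, "diff"], p_adj = tk[, "p adj"])
    rownames(pairwise) <- NULL
    res <- list(path = "anova_tukey", normal_p = normal_p,
                levene_p = levene_p,
                omnibus = list(statistic = an[["F value"]][1],
                               p = an[["Pr(>F)"]][1]),
                pairwise = pairwise)
  } else {
    fit <- stats::oneway.test(values ~ gf, var.equal = FALSE)
    res <- list(path = "games_howell", normal_p = normal_p,
                levene_p = levene_p,
                omnibus = list(statistic = unname(fit$statistic),
                               p = fit$p.value),
                pairwise = games_howell(values, gf))
  }
  class(res) <- "nmp_group_test"
  res
}

#' @export
print.nmp_group_test <- function(x, ...) {
  cat(sprintf("<nmp_group_test> path: %s, omnibus p = %.3g\n",
              x$path, x$omnibus$p))
  print(x$pairwise, digits = 3)
  invisible(x)
}
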