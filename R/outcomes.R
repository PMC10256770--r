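#' Post-transplant laboratory trajectories
#'
#' A transplant cohort is stored long-and-wide: one row per animal-day with a
#' baseline row at day -1 (pre-transplant) and daily follow-up through day
#' 30. Columns: `animal_id`, `group` (`"control"` or `"nanowarmed"`),
#' `storage_days` (cryogenic storage duration of the graft), `day`, and the
#' daily labs `creatinine` (mg/dL), `potassium` (mmol/L), `pH`, `hco3`
#' (mmol/L), `pco2` (mmHg), `lactate` (mmol/L), `hemoglobin` (g/dL) and
#' `weight` (g).
#'
#' @param df data frame as described.
#' @return validated `lab_series` data frame.
#' @export
lab_series <- function(df) {
  need <- c("animal_id", "group", "day")
  if (!all(need %in% names(df)))
    stop_msg("lab series needs columns: %s", paste(need, collapse = ", "))
  for (id in unique(df$animal_id)) {
    days <- df$day[df$animal_id == id]
    if (!(-1 %in% days)) stop_msg("animal %s missing day -1 baseline", id)
    if (any(diff(sort(days)) == 0)) stop_msg("animal %s has duplicate days", id)
  }
  df <- df[order(df$animal_id, df$day), ]
  rownames(df) <- NULL
  class(df) <- c("lab_series", "data.frame")
  df
}

one_animal <- function(s, animal_id = NULL) {
  if (!is.null(animal_id)) s <- s[s$animal_id == animal_id, ]
  if (!nrow(s)) stop_msg("no rows for that animal")
  s[order(s$day), ]
}

#' Summarize a post-transplant creatinine trajectory
#'
#' Extracts the landmarks used to grade initial graft dysfunction: the peak
#' serum creatinine and its day, the first day at or after the peak on which
#' the creatinine falls strictly below `threshold` (time to normalization;
#' `Inf` if never; no interpolation between days), and the terminal (last
#' observed) value.
#'
#' @param s a [lab_series()] (optionally filtered), or any data frame with
#'   `day` and `creatinine` columns for a single animal.
#' @param animal_id optional animal to select.
#' @param threshold recovery threshold, mg/dL.
#' @return list with `peak`, `peak_day`, `first_below_day`, `terminal`.
#' @export
creatinine_summary <- function(s, animal_id = NULL, threshold = 2.0) {
  s <- one_animal(s, animal_id)
  cr <- s$creatinine
  ok <- !is.na(cr)
  s <- s[ok, ]; cr <- cr[ok]
  if (!length(cr)) stop_msg("no creatinine values")
  ipk <- which.max(cr)
  below <- which(cr < threshold & seq_along(cr) >= ipk)
  list(peak = cr[ipk], peak_day = s$day[ipk],
       first_below_day = if (length(below)) s$day[below[1]] else Inf,
       terminal = cr[length(cr)])
}

#' Body weight normalized to the pre-transplant baseline
#'
#' Each day's weight divided by the day -1 (baseline) weight, so the baseline
#' ratio is exactly 1 and post-operative fluid shifts read as fractional
#' excursions.
#'
#' @param s single-animal rows of a [lab_series()] (or pass `animal_id`).
#' @param animal_id optional animal to select.
#' @return data frame with `day` and `weight_ratio`.
#' @export
normalize_weight <- function(s, animal_id = NULL) {
  s <- one_animal(s, animal_id)
  base <- s$weight[s$day == -1]
  if (!length(base) || is.na(base) || base <= 0)
    stop_msg("missing or invalid day -1 baseline weight")
  data.frame(day = s$day, weight_ratio = s$weight / base)
}

#' Compare two groups on one variable at one day
#'
#' Available-case two-group comparison of a daily lab at a given day. The
#' test defaults follow the per-variable mapping used for these trajectories:
#' t-test for `potassium` and `hemoglobin`, Wilcoxon rank-sum for everything
#' else; override with `test`.
#'
#' @param cohort a [lab_series()] containing both groups.
#' @param day day index.
#' @param variable lab column name.
#' @param test `"auto"`, `"wilcoxon"` or `"t"`.
#' @param groups the two group labels to compare.
#' @return list with `test`, `statistic`, `p`, `n1`, `n2`.
#' @export
longitudinal_compare <- function(cohort, day, variable,
                                 test = c("auto", "wilcoxon", "t"),
                                 groups = c("control", "nanowarmed")) {
  test <- match.arg(test)
  if (test == "auto")
    test <- if (variable %in% c("potassium", "hemoglobin")) "t" else "wilcoxon"
  if (!variable %in% names(cohort)) stop_msg("no column '%s'", variable)
  a <- cohort[[variable]][cohort$group == groups[1] & cohort$day == day]
  b <- cohort[[variable]][cohort$group == groups[2] & cohort$day == day]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop_msg("empty group for %s at day %s", variable, day)
  if (test == "t") {
    tt <- stats::t.test(a, b)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
         n1 = length(a), n2 = length(b))
  } else {
    wt <- stats::wilcox.test(a, b, exact = !any(duplicated(c(a, b))))
    list(test = "wilcoxon", statistic = unname(wt$statistic), p = wt$p.value,
         n1 = length(a), n2 = length(b))
  }
}

#' Correlation of storage duration with an outcome (Kendall)
#'
#' Kendall rank correlation between per-animal cryogenic storage duration and
#' a per-animal outcome (peak creatinine, time to normalization, terminal
#' creatinine, ...). Uses the exact null distribution for n <= 10 without
#' ties; constant inputs leave tau undefined and are flagged.
#'
#' @param storage_days numeric vector, one per animal.
#' @param outcome numeric vector, same length.
#' @return list with `tau`, `p`, `n`, `exact`, `defined`.
#' @export
storage_correlation <- function(storage_days, outcome) {
  ok <- !is.na(storage_days) & !is.na(outcome)
  x <- storage_days[ok]; y <- outcome[ok]
  n <- length(x)
  if (n < 3L) stop_msg("need at least 3 paired values")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(tau = NA_real_, p = NA_real_, n = n, exact = FALSE,
                defined = FALSE))
  has_ties <- any(duplicated(x)) || any(duplicated(y))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall",
                    exact = n <= 10 && !has_ties))
  list(tau = unname(ct$estimate), p = ct$p.value, n = n,
       exact = n <= 10 && !has_ties, defined = TRUE)
}

#' Per-animal outcome summary table
#'
#' Applies [creatinine_summary()] to every animal in a cohort, yielding the
#' per-animal landmark table used for storage-duration correlations. An
#' estimated GFR can be attached through `egfr`, a function of the animal's
#' rows (the formula is study-specific, so it is pluggable; the conventional
#' urinary UV/P clearance is available as [creatinine_clearance()]).
#'
#' @param cohort a [lab_series()].
#' @param threshold creatinine recovery threshold, mg/dL.
#' @param egfr optional `function(animal_rows)` returning mL/min.
#' @return data frame, one row per animal: `animal_id`, `group`,
#'   `storage_days`, `peak`, `peak_day`, `first_below_day`, `terminal`, and
#'   `egfr` when requested.
#' @export
outcome_summary <- function(cohort, threshold = 2.0, egfr = NULL) {
  ids <- unique(cohort$animal_id)
  rows <- lapply(ids, function(id) {
    s <- cohort[cohort$animal_id == id, ]
    cs <- creatinine_summary(s, threshold = threshold)
    data.frame(animal_id = id, group = s$group[1],
               storage_days = if ("storage_days" %in% names(s))
                 s$storage_days[1] else NA_real_,
               peak = cs$peak, peak_day = cs$peak_day,
               first_below_day = cs$first_below_day, terminal = cs$terminal,
               egfr = if (is.null(egfr)) NA_real_ else egfr(s))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
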