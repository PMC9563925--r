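#' Cohort contrast by Wilcoxon rank-sum test
#'
#' Compares patient and normal-donor enumerations per classification with a
#' two-tailed Wilcoxon rank-sum test (exact when sample sizes permit and there
#' are no ties). Results are ordered by p-value.
#'
#' @param enum_case,enum_control Stacked enumeration rows (`sample_id`,
#'   `classification`, `events_per_ml`).
#' @param classifications Classes to test (default: all present in the case
#'   arm).
#' @return data.frame: `classification`, `statistic` (W), `p_value`,
#'   `median_case`, `median_control`, ordered by p.
#' @export
compare_cohorts <- function(enum_case, enum_control, classifications = NULL) {
  if (!nrow(enum_case) || !nrow(enum_control)) {
    stop("both arms must be non-empty", call. = FALSE)
  }
  classifications <- classifications %||% unique(enum_case$classification)
  rows <- lapply(classifications, function(cl) {
    x <- enum_case$events_per_ml[enum_case$classification == cl]
    y <- enum_control$events_per_ml[enum_control$classification == cl]
    if (length(x) < 3 || length(y) < 3) {
      stop("need >= 3 samples per arm for '", cl, "'", call. = FALSE)
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y,
                                              alternative = "two.sided"))
    data.frame(classification = cl, statistic = unname(wt$statistic),
               p_value = wt$p.value, median_case = stats::median(x),
               median_control = stats::median(y), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value), , drop = FALSE]
}

#' Spearman correlation of an analyte with progression-free survival
#'
#' Two-tailed Spearman rank correlation between per-patient analyte levels
#' (events/mL, or kinetics deltas) and PFS in months. The default p-value uses
#' the t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of
#' freedom; an exact permutation p (all n! orderings via the exact null
#' distribution of the rank statistic) is available for small n.
#'
#' @param values Analyte values, one per patient.
#' @param pfs_months PFS values; pairs with NA in either are dropped.
#' @param method `"t"` (default) or `"exact"`.
#' @return List: `rho`, `p_value`, `n`. Constant inputs give NA with a message
#'   field.
#' @export
analyte_pfs_correlation <- function(values, pfs_months,
                                    method = c("t", "exact")) {
  method <- match.arg(method)
  ok <- is.finite(values) & is.finite(pfs_months)
  x <- values[ok]; y <- pfs_months[ok]
  n <- length(x)
  if (n < 4) stop("need >= 4 patients with the draw present", call. = FALSE)
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                message = "constant series"))
  }
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (method == "t") {
    if (abs(rho) >= 1) {
      0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                     exact = TRUE)$p.value)
  }
  list(rho = rho, p_value = min(p, 1), n = n)
}

#' Screen analytes against PFS
#'
#' Runs [analyte_pfs_correlation()] for every classification in an enumeration
#' table joined to survival records and keeps (flags) those with p <= `alpha`.
#'
#' @param enum Stacked enumeration rows with `patient_id`.
#' @param surv Survival table (`patient_id`, `pfs_months`).
#' @param alpha Screening level.
#' @param method p-value method.
#' @return data.frame ordered by p with a `significant` column.
#' @export
screen_pfs_analytes <- function(enum, surv, alpha = 0.05, method = "t") {
  cls <- unique(enum$classification)
  rows <- lapply(cls, function(cl) {
    e <- enum[enum$classification == cl, ]
    m <- merge(e, surv, by = "patient_id")
    m <- m[is.finite(m$pfs_months), ]
    if (nrow(m) < 4) return(NULL)
    r <- analyte_pfs_correlation(m$events_per_ml, m$pfs_months, method)
    data.frame(classification = cl, rho = r$rho, p_value = r$p_value,
               n = r$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(classification = character(0), rho = numeric(0),
                      p_value = numeric(0), n = integer(0),
                      significant = logical(0)))
  }
  out <- out[order(out$p_value), , drop = FALSE]
  out$significant <- !is.na(out$p_value) & out$p_value <= alpha
  out
}

#' Kaplan-Meier curves stratified at the analyte median
#'
#' Splits patients at the median analyte value -- the high group is strictly
#' above the median for enumeration levels (`rule = "gt"`), or at-or-above for
#' kinetics deltas (`rule = "geq"`) -- and computes the product-limit estimate
#' for each group and overall.
#'
#' @param values Analyte value per patient.
#' @param pfs_months,event_flag Survival input (event = progression observed).
#' @param rule Median tie rule: `"gt"` or `"geq"` for the high group.
#' @return List of class `stratified_km`: `threshold`, `group` (factor),
#'   `fit_overall`, `fit_groups` (`survival::survfit` objects), and `curves`
#'   (long data.frame of step functions: `group`, `time`, `surv`).
#' @export
km_stratify <- function(values, pfs_months, event_flag = NULL,
                        rule = c("gt", "geq")) {
  rule <- match.arg(rule)
  ok <- is.finite(values) & is.finite(pfs_months)
  v <- values[ok]; t <- pfs_months[ok]
  if (length(v) < 4) stop("need >= 4 patients", call. = FALSE)
  ev <- if (is.null(event_flag)) rep(1L, length(v)) else
    as.integer(event_flag[ok])
  thr <- stats::median(v)
  hi <- if (rule == "gt") v > thr else v >= thr
  if (all(hi) || !any(hi)) {
    warning("all analyte values on one side of the median: single group")
  }
  group <- factor(ifelse(hi, "high", "low"), levels = c("low", "high"))
  s <- survival::Surv(t, ev)
  fit_overall <- survival::survfit(s ~ 1)
  fit_groups <- if (length(unique(group)) > 1) {
    survival::survfit(s ~ group)
  } else NULL
  curves <- km_curves_df(fit_overall, fit_groups)
  structure(list(threshold = thr, group = group, fit_overall = fit_overall,
                 fit_groups = fit_groups, curves = curves),
            class = "stratified_km")
}

km_curves_df <- function(fit_overall, fit_groups) {
  mk <- function(fit, label) {
    data.frame(group = label,
               time = c(0, fit$time), surv = c(1, fit$surv),
               stringsAsFactors = FALSE)
  }
  out <- mk(fit_overall, "overall")
  if (!is.null(fit_groups)) {
    st <- fit_groups$strata
    labs <- sub("^group=", "", names(st))
    idx <- rep(seq_along(st), st)
    for (g in seq_along(st)) {
      sel <- idx == g
      out <- rbind(out, data.frame(group = labs[g],
                                   time = c(0, fit_groups$time[sel]),
                                   surv = c(1, fit_groups$surv[sel]),
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Draw-to-draw kinetics
#'
#' Change in events/mL between draws per patient (`draw2 - draw1`); patients
#' missing either draw are excluded and counted.
#'
#' @param draw1,draw2 Named numeric vectors (names = patient ids) or a
#'   data.frame with `patient_id`, `draw`, `events_per_ml`.
#' @param classification When a data.frame is given, the classification to use.
#' @return List: `delta` (named vector), `n_excluded`.
#' @export
kinetics <- function(draw1, draw2 = NULL, classification = NULL) {
  if (is.data.frame(draw1)) {
    df <- draw1
    if (!is.null(classification)) {
      df <- df[df$classification == classification, ]
    }
    d1 <- stats::setNames(df$events_per_ml[df$draw == 1],
                          df$patient_id[df$draw == 1])
    d2 <- stats::setNames(df$events_per_ml[df$draw == 2],
                          df$patient_id[df$draw == 2])
  } else {
    d1 <- draw1; d2 <- draw2
  }
  ids <- union(names(d1), names(d2))
  both <- intersect(names(d1)[is.finite(d1)], names(d2)[is.finite(d2)])
  delta <- d2[both] - d1[both]
  list(delta = delta, n_excluded = length(ids) - length(both))
}
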