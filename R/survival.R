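# Survival and association statistics shared by every stage:
# Kaplan-Meier curves, k-group log-rank tests, fixed-horizon ROC for the
# 5-year progression endpoint, Wilcoxon rank-sum contrasts, 2x2 chi-square,
# and immune-score x clinical-covariate stratified survival.

#' Kaplan-Meier curve
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i/n_i)`.  The
#' curve starts at 1, is non-increasing, and steps only at event times;
#' with no events it is identically 1.
#'
#' @param times Positive follow-up times.
#' @param events 0 (censored) / 1 (progressed) indicators.
#' @param label Optional group label stored on the curve.
#' @return A list of class `"survival_curve"`: `time`, `surv`, `n_risk`,
#'   `n_event`, `label`.
#' @export
km_estimate <- function(times, events, label = NA_character_) {
  if (length(times) == 0L) stop("empty input")
  stopifnot(all(times > 0), all(events %in% c(0, 1)),
            length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  out <- list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
              n_event = fit$n.event, label = label)
  class(out) <- "survival_curve"
  stopifnot(all(out$surv >= 0), all(out$surv <= 1),
            all(diff(out$surv) <= 1e-12))
  out
}

#' K-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square with
#' `df = groups - 1`.  Identical duplicated groups give a chi-square of
#' exactly 0.
#'
#' @param groups Group label per subject (>= 2 distinct values).
#' @param times,events Follow-up times and 0/1 event indicators.
#' @return List with `chisq`, `df`, `p`, and per-group `n`.
#' @export
logrank_test <- function(groups, times, events) {
  groups <- factor(groups)
  if (any(table(groups) == 0L) || nlevels(groups) < 2L)
    stop("need >= 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(droplevels(groups)) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = table(groups))
}

#' Fixed-horizon ROC for a prognostic score
#'
#' Binarizes the outcome at `horizon` months: progression at or before the
#' horizon is positive, follow-up beyond the horizon negative, and subjects
#' censored before the horizon are excluded (their count is reported).
#' AUC uses the rank (Mann-Whitney) formula with average-rank tie handling;
#' ROC points sweep all score thresholds.
#'
#' @param scores Numeric risk scores (higher = earlier progression).
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param horizon_months Positive horizon (60 = 5 years).
#' @return List with `auc`, `roc` (data.frame `threshold`, `tpr`, `fpr`),
#'   `n_used`, `n_excluded`.
#' @export
roc_horizon <- function(scores, times, events, horizon_months = 60) {
  stopifnot(horizon_months > 0, length(scores) == length(times))
  excluded <- times < horizon_months & events == 0
  s <- scores[!excluded]
  pos <- (times <= horizon_months & events == 1)[!excluded]
  if (sum(pos) == 0L || sum(!pos) == 0L)
    stop("a class is empty after excluding early-censored subjects")
  r <- rank(s)
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  roc <- data.frame(threshold = thr,
                    tpr = vapply(thr, function(t) mean(s[pos] >= t), 0),
                    fpr = vapply(thr, function(t) mean(s[!pos] >= t), 0))
  list(auc = auc, roc = roc, n_used = length(s), n_excluded = sum(excluded))
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum with average-tie ranks: exact enumeration when both
#' samples have fewer than 10 untied values, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return List with `statistic` (Mann-Whitney U for `x`) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  exact <- length(x) < 10L && length(y) < 10L &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Pearson chi-square for a 2x2 table
#'
#' `X^2 = N (ad - bc)^2 / (r1 r2 c1 c2)`, df = 1, without continuity
#' correction by default (Yates available via `yates = TRUE`).
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param yates Logical; apply the continuity correction.
#' @return List with `chisq`, `df`, `p`.
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in 2x2 table")
  ct <- stats::chisq.test(table, correct = yates)
  list(chisq = unname(ct$statistic), df = 1L, p = ct$p.value)
}

#' Survival stratified by immune-score group and a clinical covariate
#'
#' Crosses the high/low immune-score group with one covariate —
#' `hormone_therapy`, `radiation_therapy`, `n_status`, or `gleason_binary`
#' (Gleason dichotomized at <= 7 vs > 7) — optionally restricted to a
#' T-stage subset, and compares the resulting strata with a multi-group
#' log-rank test.  Samples with a missing covariate are excluded and
#' counted.
#'
#' @param clinical Clinical table.
#' @param is_group Named factor (`high`/`low`) from [optimal_cutpoint()].
#' @param covariate One of `"hormone_therapy"`, `"radiation_therapy"`,
#'   `"n_status"`, `"gleason_binary"`.
#' @param stage_filter Optional character vector of T stages to keep (e.g.
#'   `c("T3", "T4")`), applied before grouping.
#' @return A list of class `"stratified_comparison"`: `groups` (per-sample
#'   stratum), `n` (per-stratum counts), `chisq`, `df`, `p`, `curves`
#'   (per-stratum [km_estimate()] curves), `n_excluded_missing`.
#' @export
stratified_survival <- function(clinical, is_group,
                                covariate = c("hormone_therapy",
                                              "radiation_therapy",
                                              "n_status", "gleason_binary"),
                                stage_filter = NULL) {
  covariate <- match.arg(covariate)
  clin <- clinical[match(names(is_group), clinical$sample_id), ]
  keep <- !is.na(clin$sample_id)
  if (!is.null(stage_filter)) {
    keep <- keep & !is.na(clin$t_stage) &
      as.character(clin$t_stage) %in% stage_filter
    if (!any(keep)) stop("stage filter excluded all samples")
  }
  cov_vals <- switch(covariate,
    gleason_binary = ifelse(is.na(clin$gleason), NA,
                            ifelse(clin$gleason > 7, "Gleason>7", "Gleason<=7")),
    hormone_therapy = ifelse(is.na(clin$hormone_therapy), NA,
                             ifelse(clin$hormone_therapy == 1, "treated",
                                    "untreated")),
    radiation_therapy = ifelse(is.na(clin$radiation_therapy), NA,
                               ifelse(clin$radiation_therapy == 1, "treated",
                                      "untreated")),
    n_status = as.character(clin$n_status))
  n_missing <- sum(keep & is.na(cov_vals))
  keep <- keep & !is.na(cov_vals)
  if (n_missing > 0L)
    is_log("stratified_survival: excluded %d sample(s) with missing %s",
           n_missing, covariate)
  strata <- paste(ifelse(is_group[keep] == "high", "IS-high", "IS-low"),
                  cov_vals[keep], sep = "/")
  expected <- as.vector(outer(c("IS-high", "IS-low"),
                              sort(unique(cov_vals[keep])), paste, sep = "/"))
  empty <- setdiff(expected, unique(strata))
  if (length(empty))
    stop("empty stratum(s): ", paste(empty, collapse = ", "))
  lr <- logrank_test(strata, clin$pfs_time[keep], clin$pfs_event[keep])
  curves <- lapply(split(seq_along(strata), strata), function(idx)
    km_estimate(clin$pfs_time[keep][idx], clin$pfs_event[keep][idx],
                label = strata[idx[1L]]))
  out <- list(groups = stats::setNames(strata, clin$sample_id[keep]),
              n = table(strata), chisq = lr$chisq, df = lr$df, p = lr$p,
              curves = curves, n_excluded_missing = n_missing)
  class(out) <- "stratified_comparison"
  out
}
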