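# Diagnostic-accuracy statistics over site-distance records: category
# summaries, Spearman correlation, Welch t-tests, ROC for predicting a
# site-to-nerve distance > 10 mm, and the per-cutoff Se/Sp panel.

#' Per-category cohort summary
#'
#' Counts, percentages (one decimal, of the grand total), and mean / sample
#' SD / minimum of the distance per threshold category, plus the share of
#' capture sites (all categories below non-capture). A single-record category
#' has undefined sample SD; it is reported as 0 with `sd_defined = FALSE`.
#'
#' @param records data.frame with columns `distance_mm` and `category`
#'   (levels of [threshold_categories()]).
#' @return list of class `cohort_stats`: `by_category` (data.frame with
#'   `category`, `n`, `percent`, `mean_mm`, `sd_mm`, `sd_defined`, `min_mm`),
#'   `total`, `capture_share_percent`.
#' @export
summarize_categories <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("no records to summarize", call. = FALSE)
  lev <- threshold_categories()
  cat_f <- factor(as.character(records$category), levels = lev)
  n <- as.integer(table(cat_f))
  total <- nrow(records)
  stats_by <- lapply(lev, function(l) {
    d <- records$distance_mm[cat_f == l]
    if (length(d) == 0L) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(mean(d), if (length(d) > 1L) stats::sd(d) else 0,
      as.numeric(length(d) > 1L), min(d))
  })
  sm <- do.call(rbind, stats_by)
  by_category <- data.frame(
    category = lev, n = n,
    percent = round(100 * n / total, 1),
    mean_mm = sm[, 1], sd_mm = sm[, 2], sd_defined = sm[, 3] == 1,
    min_mm = sm[, 4]
  )
  capture_n <- sum(n[lev != "non-capture"])
  structure(
    list(by_category = by_category, total = total,
         capture_share_percent = round(100 * capture_n / total, 1)),
    class = "cohort_stats"
  )
}

#' Spearman rank correlation between threshold category and distance
#'
#' Mid-rank handling of the heavily tied 5-level ordinal predictor, with the
#' large-sample p-value (via [stats::cor.test()] with `exact = FALSE`).
#' Constant input leaves rho undefined and is flagged rather than silently
#' returning NA.
#'
#' @param ordinal_thresholds ordinal predictor (factor or integer ranks).
#' @param distances numeric distances (mm), same length (>= 3).
#' @return list: `rho`, `p_value`, `defined`.
#' @export
spearman_rho <- function(ordinal_thresholds, distances) {
  x <- as.numeric(ordinal_thresholds)
  y <- as.numeric(distances)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length inputs of at least 3 pairs", call. = FALSE)
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p_value = NA_real_, defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, defined = TRUE)
}

#' Welch two-sample t-test between two distance groups
#'
#' Unequal-variance, unpaired, two-sided (via [stats::t.test()]). Used for
#' the adjacent-category distance comparisons.
#'
#' @param group_a,group_b numeric vectors (each of length >= 2).
#' @return list: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    stop("both groups have zero variance; t-test undefined", call. = FALSE)
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Tie-corrected rank-sum AUC
#'
#' Area under the ROC curve by the Mann-Whitney estimator with mid-rank tie
#' correction: the probability that a random positive outranks a random
#' negative, counting ties as one half.
#'
#' @param predictor numeric (or ordered) predictor; higher predicts positive.
#' @param positive logical vector of class labels.
#' @return scalar AUC in `[0, 1]`.
#' @export
rank_sum_auc <- function(predictor, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(as.numeric(predictor))  # mid-ranks on ties
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity of each threshold cutoff
#'
#' For cutoffs `>10, >20, >30, >50 mA` (the last meaning non-capture at
#' maximum output): sensitivity is the probability that a remote site
#' (distance beyond the cutoff distance) shows a threshold beyond the pacing
#' cutoff, and specificity the probability that a close site does not.
#'
#' @param records data.frame with `distance_mm` and `category`.
#' @param distance_cutoff_mm distance defining the positive (remote) class.
#' @return data.frame: `cutoff`, `sensitivity`, `specificity` (proportions,
#'   3 decimals in printed reports; stored at full precision).
#' @export
build_table2 <- function(records, distance_cutoff_mm = 10) {
  cat_i <- as.integer(factor(as.character(records$category),
                             levels = threshold_categories()))
  pos <- records$distance_mm > distance_cutoff_mm
  cutoffs <- c(">10 mA", ">20 mA", ">30 mA", ">50 mA")
  se <- sp <- numeric(4L)
  for (k in 1:4) {
    beyond <- cat_i > k
    se[k] <- if (any(pos)) mean(beyond[pos]) else NA_real_
    sp[k] <- if (any(!pos)) mean(!beyond[!pos]) else NA_real_
  }
  data.frame(cutoff = cutoffs, sensitivity = se, specificity = sp)
}

#' ROC analysis of the threshold category predicting a remote site
#'
#' Positive class: distance beyond `distance_cutoff_mm`. Predictor: the
#' 5-level ordinal category index (non-capture ranked highest, i.e. most
#' nerve-remote). AUC by the tie-corrected rank-sum estimator; confidence
#' interval by nonparametric bootstrap percentiles over sites; Se/Sp at each
#' of the four cutoffs from the corresponding 2x2 tables.
#'
#' @param records data.frame with `distance_mm` and `category`.
#' @param distance_cutoff_mm positive-class distance cutoff (mm), default 10.
#' @param n_boot bootstrap replicates for the AUC CI (0 skips the CI).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level.
#' @return list of class `diagnostic_table`: `auc`, `auc_ci_low`,
#'   `auc_ci_high`, `distance_cutoff_mm`, `n_positive`, `n_negative`, and
#'   `by_cutoff` (the [build_table2()] data.frame).
#' @export
roc_analysis <- function(records, distance_cutoff_mm = 10, n_boot = 2000L,
                         seed = 1L, conf = 0.95) {
  cat_i <- as.integer(factor(as.character(records$category),
                             levels = threshold_categories()))
  pos <- records$distance_mm > distance_cutoff_mm
  if (all(pos) || all(!pos)) stop("both classes must be present", call. = FALSE)
  auc <- rank_sum_auc(cat_i, pos)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
    n <- length(pos)
    boot <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (all(pos[i]) || all(!pos[i])) return(NA_real_)
      rank_sum_auc(cat_i[i], pos[i])
    }, numeric(1))
    ci <- unname(stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                                 na.rm = TRUE))
  }
  structure(
    list(auc = auc, auc_ci_low = ci[1], auc_ci_high = ci[2],
         distance_cutoff_mm = distance_cutoff_mm,
         n_positive = sum(pos), n_negative = sum(!pos),
         by_cutoff = build_table2(records, distance_cutoff_mm)),
    class = "diagnostic_table"
  )
}

#' Full cohort statistics in one call
#'
#' Category summary, Spearman correlation, adjacent-category Welch t-tests
#' and the diagnostic panel, mirroring the reference study's analysis plan.
#'
#' @param records site-distance records.
#' @param distance_cutoff_mm ROC positive-class cutoff (mm).
#' @param n_boot bootstrap replicates for the AUC CI.
#' @param seed integer seed.
#' @return list: `summary` (a `cohort_stats`), `spearman`, `adjacent_tests`
#'   (data.frame of adjacent-category comparisons), `diagnostics`
#'   (a `diagnostic_table`).
#' @export
cohort_statistics <- function(records, distance_cutoff_mm = 10, n_boot = 0L,
                              seed = 1L) {
  lev <- threshold_categories()
  sm <- summarize_categories(records)
  sp <- spearman_rho(factor(records$category, levels = lev, ordered = TRUE),
                     records$distance_mm)
  pair_p <- vapply(1:4, function(k) {
    a <- records$distance_mm[records$category == lev[k]]
    b <- records$distance_mm[records$category == lev[k + 1]]
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    welch_t_test(a, b)$p_value
  }, numeric(1))
  list(
    summary = sm,
    spearman = sp,
    adjacent_tests = data.frame(
      comparison = paste(lev[1:4], "vs", lev[2:5]),
      p_value = pair_p
    ),
    diagnostics = roc_analysis(records, distance_cutoff_mm, n_boot = n_boot,
                               seed = seed)
  )
}
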