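# ROC machinery for steatosis grade prediction: Mann-Whitney AUROC,
# Youden-index cutoffs with Se/Sp/PPV/NPV, and DeLong variance/CI and the
# paired z-test for correlated AUROCs. Implemented from the estimators'
# definitions because the pipeline fixes specific conventions (midpoint
# candidate cutoffs, tie-breaks, unclipped CIs).

#' Steatosis grade from histological fat fraction
#'
#' Semi-quantitative grading by the proportion of liver tissue affected by
#' fat vacuoles: grade 0 below 5%, grade 1 for 5-33%, grade 2 for 33-66%,
#' grade 3 above 66%. The upper boundaries 33 and 66 belong to the lower
#' grade, consistent with the strict "> 66%" definition of grade 3.
#'
#' @param fat_fraction_percent fat fraction(s) in percent, within `[0, 100]`.
#' @return Integer grade(s) in 0-3.
#' @examples
#' grade_from_fraction(c(0, 4.9, 5, 33, 66, 70, 100))
#' @export
grade_from_fraction <- function(fat_fraction_percent) {
  f <- as.numeric(fat_fraction_percent)
  if (any(!is.finite(f)) || any(f < 0 | f > 100)) {
    stop("fat fraction must lie in [0, 100] percent", call. = FALSE)
  }
  ifelse(f < 5, 0L, ifelse(f <= 33, 1L, ifelse(f <= 66, 2L, 3L)))
}

#' Dichotomize a graded cohort
#'
#' Binary disease labels for a grade-threshold classification task:
#' positive iff `grade >= threshold_grade` (e.g. threshold 1 contrasts
#' grades 1-3 against grade 0; threshold 3 isolates grade 3).
#'
#' @param grades integer grades in 0-3, or a cohort `data.frame` with a
#'   `grade` column.
#' @param threshold_grade 1, 2 or 3.
#' @return Logical vector of positive labels, with attribute `degenerate`
#'   set to `TRUE` (plus a warning) when only one class results.
#' @export
dichotomize <- function(grades, threshold_grade) {
  if (is.data.frame(grades)) grades <- grades$grade
  if (!threshold_grade %in% 1:3) stop("threshold_grade must be 1, 2 or 3", call. = FALSE)
  if (any(!grades %in% 0:3)) {
    stop("grades must be integers in {0, 1, 2, 3}", call. = FALSE)
  }
  labels <- grades >= threshold_grade
  if (length(unique(labels)) < 2L) {
    warning("dichotomization is degenerate: only one class present")
    attr(labels, "degenerate") <- TRUE
  }
  labels
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  if (is.factor(labels) && nlevels(labels) == 2L) return(labels == levels(labels)[2])
  stop("labels must be logical, 0/1, or a two-level factor", call. = FALSE)
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Over all (positive, negative) subject pairs, the fraction with
#' `score_pos > score_neg`, ties counted 1/2. Equals the probability that a
#' random diseased subject scores above a random healthy one; invariant
#' under any strictly increasing transform of the scores.
#'
#' @param scores numeric scores, higher = more diseased.
#' @param labels positive-class labels (logical, 0/1 or two-level factor).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos < 1L || n_neg < 1L) {
    stop("need at least one positive and one negative subject", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Candidate thresholds: midpoints between adjacent distinct scores plus
# sentinels, so reported cutoffs are stable to infinitesimal perturbation.
candidate_cutoffs <- function(scores) {
  s <- sort(unique(scores))
  c(-Inf, if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2, Inf)
}

confusion_at <- function(scores, labels, cutoff) {
  pred <- scores >= cutoff
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  list(se = se, sp = sp,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Optimal cutoff by Youden's index
#'
#' Scans candidate thresholds (midpoints between adjacent distinct scores
#' plus infinite sentinels; positive prediction means `score >= cutoff`) and
#' returns the one maximising `J = Se + Sp - 1`. Ties are broken towards
#' higher sensitivity, then towards the lower cutoff.
#'
#' @inheritParams auroc
#' @return A list with `cutoff`, `j`, `se`, `sp`, `ppv`, `npv`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (sum(labels) < 1L || sum(!labels) < 1L) {
    stop("need at least one positive and one negative subject", call. = FALSE)
  }
  cands <- candidate_cutoffs(scores)
  best <- NULL
  for (ct in cands) {
    m <- confusion_at(scores, labels, ct)
    j <- m$se + m$sp - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
         (m$se > best$se + 1e-12 ||
          (abs(m$se - best$se) <= 1e-12 && ct < best$cutoff)))) {
      best <- c(list(cutoff = ct, j = j), m)
    }
  }
  best[c("cutoff", "j", "se", "sp", "ppv", "npv")]
}

# DeLong placement values: V10 per positive, V01 per negative.
placement_values <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong AUROC variance and 95% confidence interval
#'
#' Variance by the placement-value (structural components) estimator:
#' `var = var(V10)/m + var(V01)/n` for m positives and n negatives; the CI
#' is the normal approximation `auroc +/- 1.96 * sd`. Bounds are *not*
#' clipped to `[0, 1]` unless `clip = TRUE`, so near-perfect classifiers can
#' report upper bounds slightly above 1 as ROC software conventionally
#' prints them.
#'
#' @inheritParams auroc
#' @param clip clip the CI to `[0, 1]`?
#' @return A list with `auroc`, `var`, `ci95 = c(low, high)`, `n_pos`,
#'   `n_neg`.
#' @export
delong_ci <- function(scores, labels, clip = FALSE) {
  labels <- as_binary_labels(labels)
  m <- sum(labels); n <- sum(!labels)
  if (m < 2L || n < 2L) {
    stop("DeLong CI needs at least 2 subjects per class", call. = FALSE)
  }
  pv <- placement_values(scores, labels)
  v <- stats::var(pv$v10) / m + stats::var(pv$v01) / n
  half <- stats::qnorm(0.975) * sqrt(v)
  ci <- c(pv$auc - half, pv$auc + half)
  if (clip) ci <- pmin(pmax(ci, 0), 1)
  list(auroc = pv$auc, var = v, ci95 = ci, n_pos = m, n_neg = n)
}

#' Paired DeLong test for two correlated AUROCs
#'
#' Compares the AUROCs of two scores measured on the same subjects with the
#' same disease labels, using the covariance of the paired placement values;
#' returns the z statistic (score A minus score B) and the two-sided normal
#' p-value. When both scores are identical, `z = 0`, `p = 1`.
#'
#' @param scores_a,scores_b score vectors on the same subjects.
#' @inheritParams auroc
#' @return A list with `z`, `p`, `auroc_a`, `auroc_b`, `var_diff`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must have equal length", call. = FALSE)
  }
  m <- sum(labels); n <- sum(!labels)
  if (m < 2L || n < 2L) {
    stop("DeLong comparison needs at least 2 subjects per class", call. = FALSE)
  }
  pa <- placement_values(scores_a, labels)
  pb <- placement_values(scores_b, labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  z <- if (var_diff <= 0) {
    if (abs(diff) < 1e-15) 0 else sign(diff) * Inf
  } else diff / sqrt(var_diff)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), auroc_a = pa$auc,
       auroc_b = pb$auc, var_diff = var_diff)
}

#' Full ROC analysis of one score for one grade dichotomization
#'
#' Combines [dichotomize()], [auroc()], [delong_ci()] and [youden_cutoff()]
#' into one classification report (one row of a grade-prediction accuracy
#' table). Scores inversely related to disease (such as the raw liver
#' difference readout, which falls with lipid content) are handled with
#' `invert = TRUE`, which negates the scores for analysis and reports the
#' cutoff back on the original scale.
#'
#' @param cohort `data.frame` with a `grade` column and the score column.
#' @param score name of the score column.
#' @param threshold_grade dichotomization threshold (1, 2 or 3).
#' @param invert treat lower scores as more diseased?
#' @param clip_ci clip the DeLong CI to `[0, 1]`?
#' @return An object of class `steatosis_roc`.
#' @examples
#' cohort <- make_graded_cohort(seed = 7)
#' roc_grade(cohort, "score_linear", threshold_grade = 1)
#' @export
roc_grade <- function(cohort, score, threshold_grade, invert = FALSE,
                      clip_ci = FALSE) {
  if (!score %in% names(cohort)) stop("no score column '", score, "'", call. = FALSE)
  labels <- dichotomize(cohort, threshold_grade)
  s <- cohort[[score]]
  if (any(!is.finite(s))) stop("scores must be finite", call. = FALSE)
  if (invert) s <- -s
  dl <- delong_ci(s, labels, clip = clip_ci)
  yc <- youden_cutoff(s, labels)
  cutoff <- if (invert) -yc$cutoff else yc$cutoff
  structure(
    list(score = score, threshold_grade = threshold_grade, invert = invert,
         auroc = dl$auroc, ci95 = dl$ci95, var = dl$var,
         cutoff = cutoff, j = yc$j, se = yc$se, sp = yc$sp,
         ppv = yc$ppv, npv = yc$npv, n_pos = dl$n_pos, n_neg = dl$n_neg),
    class = "steatosis_roc"
  )
}

#' @export
print.steatosis_roc <- function(x, ...) {
  cat(sprintf(
    "ROC: %s, grades >= %d (n+ = %d) vs below (n- = %d)%s\n",
    x$score, x$threshold_grade, x$n_pos, x$n_neg,
    if (x$invert) " [score inverted]" else ""))
  cat(sprintf("  AUROC %.2f (95%% CI %.2f-%.2f)\n", x$auroc, x$ci95[1], x$ci95[2]))
  cat(sprintf("  cutoff %.4g  Se %.0f%%  Sp %.0f%%  PPV %.0f%%  NPV %.0f%%\n",
              x$cutoff, 100 * x$se, 100 * x$sp, 100 * x$ppv, 100 * x$npv))
  invisible(x)
}

#' Grade-prediction accuracy table
#'
#' Runs [roc_grade()] for each score and each grade dichotomization and
#' returns the stacked classification table (cutoff, AUROC with CI, Se, Sp,
#' PPV, NPV per row), the shape conventionally reported for steatosis
#' classifiers.
#'
#' @param cohort cohort `data.frame` with `grade` and score columns.
#' @param scores score column names; a name listed in `invert` is analysed
#'   with inverted orientation.
#' @param thresholds grade thresholds to test.
#' @param invert character vector of score names inversely related to
#'   disease.
#' @param clip_ci clip CIs to `[0, 1]`?
#' @return A `data.frame` with one row per (score, threshold).
#' @export
roc_table <- function(cohort, scores, thresholds = 1:3, invert = character(),
                      clip_ci = FALSE) {
  rows <- list()
  for (sc in scores) {
    for (th in thresholds) {
      r <- roc_grade(cohort, sc, th, invert = sc %in% invert, clip_ci = clip_ci)
      rows[[length(rows) + 1L]] <- data.frame(
        score = sc, threshold_grade = th, n_pos = r$n_pos, n_neg = r$n_neg,
        cutoff = r$cutoff, auroc = r$auroc,
        ci_low = r$ci95[1], ci_high = r$ci95[2],
        se = r$se, sp = r$sp, ppv = r$ppv, npv = r$npv)
    }
  }
  do.call(rbind, rows)
}
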