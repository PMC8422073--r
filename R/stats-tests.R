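#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data; the monotone-association
#' measure used to relate unmixing readouts to true lipid fractions and to
#' histology.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Normality-gated two-group comparison
#'
#' The routing rule used for all two-group readout comparisons: Shapiro-Wilk
#' on each group at `alpha`; if both groups pass, an unpaired two-sided
#' Student's t-test, otherwise a two-sided Mann-Whitney (Wilcoxon rank-sum)
#' test. Groups whose values are all identical cannot be tested for
#' normality and are routed to Mann-Whitney.
#'
#' @param a,b numeric samples, each of size >= 3.
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @return A list with `test` (`"t"` or `"mann-whitney"`), `p`, and the
#'   per-group Shapiro-Wilk p-values (`NA` where degenerate).
#' @export
group_compare <- function(a, b, alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1L) {
    # no variation anywhere: the samples are indistinguishable
    return(list(test = "mann-whitney", p = 1,
                shapiro_a = NA_real_, shapiro_b = NA_real_))
  }
  sw <- function(x) {
    if (length(unique(x)) < 2L || length(x) > 5000L) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  pa <- sw(a); pb <- sw(b)
  normal <- !is.na(pa) && !is.na(pb) && pa > alpha && pb > alpha
  if (normal) {
    p <- stats::t.test(a, b, var.equal = TRUE)$p.value
    list(test = "t", p = p, shapiro_a = pa, shapiro_b = pb)
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    list(test = "mann-whitney", p = p, shapiro_a = pa, shapiro_b = pb)
  }
}
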