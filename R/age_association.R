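# Age association of per-locus scores (or per-window methylation):
# rank/linear correlation with age, Benjamini-Hochberg adjustment, subset
# selection at the clock thresholds, and the quadratic global-trend fit.

#' Correlate every locus with donor age
#'
#' Spearman (midrank) or Pearson correlation per matrix row against age,
#' using pairwise-complete observations. Rows with fewer than `min_n`
#' complete pairs, or with a constant score vector, are skipped.
#' Two-sided p-values use the t approximation; for Spearman with n <= 7 an
#' exact permutation enumeration is used instead.
#'
#' @param mat Numeric matrix, loci (rows) x samples (columns).
#' @param ages Numeric vector of ages, aligned with the columns.
#' @param method `"spearman"` (scores) or `"pearson"` (window methylation).
#' @param min_n Minimum complete pairs per locus (default 3).
#' @return `data.table` with `locus`, `coefficient`, `p_value`, `p_adj`
#'   (Benjamini-Hochberg within the tested loci), `n`.
#' @export
correlate_with_age <- function(mat, ages, method = c("spearman", "pearson"),
                               min_n = 3L) {
  method <- match.arg(method)
  stopifnot(is.matrix(mat), ncol(mat) == length(ages))
  nr <- nrow(mat)
  res_coef <- rep(NA_real_, nr); res_p <- rep(NA_real_, nr); res_n <- rep(NA_integer_, nr)
  for (i in seq_len(nr)) {
    x <- mat[i, ]
    ok <- !is.na(x) & !is.na(ages)
    n <- sum(ok)
    if (n < min_n) next
    xi <- x[ok]; ai <- ages[ok]
    if (stats::sd(xi) == 0 || stats::sd(ai) == 0) next   # undefined coefficient
    if (method == "spearman") {
      xi <- rank(xi); ai2 <- rank(ai)
    } else ai2 <- ai
    r <- stats::cor(xi, ai2)
    res_coef[i] <- r
    res_p[i] <- correlation_p_value(r, n, method, xi, ai2)
    res_n[i] <- n
  }
  keep <- !is.na(res_coef)
  out <- data.table::data.table(locus = rownames(mat)[keep],
                                coefficient = res_coef[keep],
                                p_value = res_p[keep], n = res_n[keep])
  out$p_adj <- bh_adjust(out$p_value)
  data.table::setcolorder(out, c("locus", "coefficient", "p_value", "p_adj", "n"))
  out
}

correlation_p_value <- function(r, n, method, xr, ar) {
  if (method == "spearman" && n <= 7L) {
    # exact permutation null of the rank correlation (ties preserved)
    perms <- all_permutations(n)
    robs <- abs(r)
    rs <- apply(perms, 1L, function(idx) stats::cor(xr, ar[idx]))
    return(mean(abs(rs) >= robs - 1e-12))
  }
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-i]
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in \[0,1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Select age-correlated locus subsets at the clock thresholds
#'
#' Splits correlation records into the three subsets used downstream:
#' negatively correlated (`coefficient <= -cor_low`), positively correlated
#' (`coefficient >= cor_low`) and highly correlated
#' (`|coefficient| >= cor_high`), each additionally requiring
#' `p_adj < padj_max`.
#'
#' @param records Output of [correlate_with_age()].
#' @param cor_low Low threshold (default 0.25).
#' @param cor_high High threshold (default 0.5).
#' @param padj_max Adjusted-p cut-off (default 0.05).
#' @return List with character vectors `negative`, `positive`, `high` of
#'   locus keys, and a one-row `counts` table (total and per-subset counts).
#' @export
select_loci <- function(records, cor_low = 0.25, cor_high = 0.5, padj_max = 0.05) {
  sig <- !is.na(records$p_adj) & records$p_adj < padj_max
  negative <- records$locus[sig & records$coefficient <= -cor_low]
  positive <- records$locus[sig & records$coefficient >= cor_low]
  high <- records$locus[sig & abs(records$coefficient) >= cor_high]
  counts <- data.table::data.table(n_loci = nrow(records),
                                   n_negative = length(negative),
                                   n_positive = length(positive),
                                   n_high = length(high))
  list(negative = negative, positive = positive, high = high, counts = counts)
}

#' Global mean-score trend across age
#'
#' Per-sample mean score over a locus subset (NA-excluded) and its ordinary
#' least-squares quadratic fit against age. The quadratic captures the
#' characteristic fast-young/slow-old dynamics of global heterogeneity.
#'
#' @param mat Locus-by-sample score matrix.
#' @param subset Character vector of locus keys (rows) to average over.
#' @param ages Ages aligned with columns.
#' @return List with `means` (`data.table` of sample, age, mean score) and
#'   `fit` (intercept/linear/quadratic coefficients plus the residual sums
#'   of squares of the quadratic and the nested linear fit).
#' @export
mean_score_trend <- function(mat, subset, ages) {
  subset <- intersect(subset, rownames(mat))
  if (length(subset) == 0L) stop("subset is empty or disjoint from the matrix")
  sub <- mat[subset, , drop = FALSE]
  means <- colMeans(sub, na.rm = TRUE)
  keep <- is.finite(means)
  if (!all(keep)) means <- means[keep]
  a <- ages[keep]
  fit_q <- stats::lm(means ~ a + I(a^2))
  fit_l <- stats::lm(means ~ a)
  co <- stats::coef(fit_q)
  list(means = data.table::data.table(sample_id = colnames(mat)[keep],
                                      age = a, mean_score = means),
       fit = list(intercept = unname(co[1L]), linear = unname(co[2L]),
                  quadratic = unname(co[3L]),
                  rss_quadratic = sum(stats::resid(fit_q)^2),
                  rss_linear = sum(stats::resid(fit_l)^2)))
}
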