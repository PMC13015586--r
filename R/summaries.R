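#' One-way ANOVA from group summaries
#'
#' Recovers the one-way ANOVA F test from printed per-group means, SDs and
#' ns: between-group sum of squares from the group means about the grand
#' mean, within-group sum of squares from `sum((n_i - 1) * sd_i^2)`. Exact
#' when the summaries are exact; approximate to the summaries' printed
#' precision otherwise.
#'
#' @param groups Data frame with columns `label`, `n`, `mean`, `sd`
#'   (each n >= 2).
#' @return List `f`, `df` (between, within), `p`.
#' @export
anova_from_summaries <- function(groups) {
  stopifnot(all(c("n", "mean", "sd") %in% names(groups)), nrow(groups) >= 2)
  n <- groups$n
  if (any(n < 2)) stop("every group needs n >= 2")
  grand <- sum(n * groups$mean) / sum(n)
  ssb <- sum(n * (groups$mean - grand)^2)
  ssw <- sum((n - 1) * groups$sd^2)
  dfb <- nrow(groups) - 1
  dfw <- sum(n) - nrow(groups)
  if (ssw == 0) stop("zero within-group variance")
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, df = c(dfb, dfw), p = pf(f, dfb, dfw, lower.tail = FALSE))
}

#' Bonferroni-adjusted pairwise comparisons from summaries
#'
#' Pooled-variance two-sample t tests for every pair of groups, with raw
#' p-values multiplied by the number of pairs (capped at 1).
#'
#' @inheritParams anova_from_summaries
#' @return Data frame of pairs with `t`, `df`, `p_raw`, `p_adj`.
#' @export
bonferroni_pairwise_from_summaries <- function(groups) {
  stopifnot(nrow(groups) >= 2)
  pairs <- utils::combn(seq_len(nrow(groups)), 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(i) {
    a <- groups[pairs[1, i], ]
    b <- groups[pairs[2, i], ]
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    if (sp2 == 0) stop("zero pooled variance for pair ", i)
    t_stat <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
    p_raw <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
    data.frame(pair = paste(a$label, b$label, sep = " vs "), t = t_stat,
               df = df, p_raw = p_raw, p_adj = min(1, m * p_raw))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Pearson chi-square test of independence
#'
#' `sum((O - E)^2 / E)` with expected counts from the marginal products,
#' `df = (r - 1)(c - 1)`, no continuity correction.
#'
#' @param counts An r x c count matrix with positive row and column totals.
#' @return List `chisq`, `df`, `p`.
#' @export
chisq_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal total")
  }
  res <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(chisq = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Chi-square goodness of fit
#'
#' `sum((O - E)^2 / E)` against expected counts (uniform by default),
#' `df = k - 1`.
#'
#' @param counts Observed counts.
#' @param expected Optional expected counts (same total); defaults to uniform.
#' @return List `chisq`, `df`, `p`.
#' @export
chisq_gof <- function(counts, expected = NULL) {
  if (sum(counts) <= 0) stop("counts must be positive in total")
  if (is.null(expected)) expected <- rep(sum(counts) / length(counts),
                                         length(counts))
  if (any(expected <= 0)) stop("expected counts must be positive")
  res <- suppressWarnings(
    chisq.test(counts, p = expected / sum(expected))
  )
  list(chisq = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
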