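#' Z-score the columns of a matrix
#'
#' Centers each column and scales to unit sample SD; errors on constant
#' columns (naming them) rather than dividing by zero.
#'
#' @param x Numeric matrix or data frame of features.
#' @return The standardized matrix.
#' @export
zscore_columns <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  scale(x, center = TRUE, scale = sds)
}

#' Principal components of a standardized matrix
#'
#' Singular-value decomposition of the z-scored matrix with the n-1 variance
#' divisor; components ordered by decreasing variance with a deterministic
#' sign convention (the largest-magnitude loading of each component is made
#' positive). Trailing zero-variance components are allowed.
#'
#' @param x Standardized matrix (see [zscore_columns()]), n > ncol.
#' @return A `pca_result`: `loadings` (p x p), `scores` (n x p),
#'   `variance_fraction` (sums to 1), `sdev`.
#' @export
pca_fit <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= ncol(x)) stop("need more rows than columns")
  sv <- svd(x)
  loadings <- sv$v
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  sdev <- sv$d / sqrt(n - 1)
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(ncol(loadings))))
  colnames(scores) <- colnames(loadings)
  structure(list(loadings = loadings, scores = scores,
                 variance_fraction = sdev^2 / sum(sdev^2), sdev = sdev),
            class = "pca_result")
}

#' MANOVA with Pillai's trace
#'
#' Tests whether group centroids differ across the multivariate space of the
#' scores, using Pillai's trace and its standard F approximation.
#'
#' @param scores Numeric matrix (n x p).
#' @param labels Group labels, length n, >= 2 groups with n >= 2 each.
#' @return List with `pillai`, `f`, `df` (numerator, denominator), `p`.
#' @export
manova_pillai <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  if (any(table(labels) < 2)) stop("every group needs n >= 2")
  fit <- manova(as.matrix(scores) ~ labels)
  s <- summary(fit, test = "Pillai")$stats
  list(pillai = s[1, "Pillai"], f = s[1, "approx F"],
       df = c(s[1, "num Df"], s[1, "den Df"]), p = s[1, "Pr(>F)"])
}

#' One-way ANOVA with Tukey HSD post hocs for one component
#'
#' @param scores Numeric vector (one PC's scores).
#' @param labels Group labels.
#' @return List with `f`, `p`, and `tukey` (per-pair difference, studentized
#'   range adjusted p).
#' @export
anova_tukey <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  fit <- aov(scores ~ labels)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$labels
  list(f = s[1, "F value"], p = s[1, "Pr(>F)"],
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL))
}

#' Leave-one-out cross-validated linear discriminant analysis
#'
#' For each subject an LDA (shared covariance, priors proportional to
#' training-fold class frequencies) is trained on all other subjects and
#' predicts the held-out one; posterior rows sum to 1. Discriminant
#' coefficients are reported from the full-data fit.
#'
#' @param vectors Feature matrix (n x p).
#' @param labels Group labels, each group n >= 2.
#' @param equal_priors Use equal class priors instead of fold frequencies.
#' @return List with `predicted`, `posterior` (n x groups), `coefficients`
#'   (full-fit LD weights), `labels`.
#' @export
lda_loocv <- function(vectors, labels, equal_priors = FALSE) {
  vectors <- as.matrix(vectors)
  labels <- factor(labels)
  if (any(table(labels) < 2)) stop("every group needs n >= 2")
  prior_arg <- function(l) {
    if (equal_priors) rep(1 / nlevels(l), nlevels(l))
    else as.numeric(table(l) / length(l))
  }
  cv <- MASS::lda(vectors, grouping = labels, CV = TRUE,
                  prior = prior_arg(labels))
  full <- MASS::lda(vectors, grouping = labels, prior = prior_arg(labels))
  list(predicted = cv$class, posterior = cv$posterior,
       coefficients = full$scaling, labels = labels)
}

#' Confusion matrix and derived classification metrics
#'
#' Builds the predicted x actual count matrix and computes overall accuracy
#' (diagonal / n), per-group sensitivity (diagonal / actual column total) and
#' specificity (correctly rejected non-members / actual non-members).
#'
#' @param predicted,actual Equal-length label vectors (or pass a ready-made
#'   predicted x actual matrix as `confusion`).
#' @param confusion Optional square count matrix, predicted rows x actual
#'   columns, overriding `predicted`/`actual`.
#' @return A `classification_report`: `confusion`, `accuracy`, `sensitivity`,
#'   `specificity`, `kappa`, `n`.
#' @export
confusion_metrics <- function(predicted = NULL, actual = NULL,
                              confusion = NULL) {
  if (is.null(confusion)) {
    if (length(predicted) != length(actual)) stop("label length mismatch")
    lev <- union(levels(factor(actual)), levels(factor(predicted)))
    confusion <- table(factor(predicted, levels = lev),
                       factor(actual, levels = lev))
    confusion <- unclass(confusion)
  }
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix not square")
  n <- sum(confusion)
  acc <- sum(diag(confusion)) / n
  sens <- diag(confusion) / colSums(confusion)
  spec <- vapply(seq_len(ncol(confusion)), function(g) {
    fp <- sum(confusion[g, -g])
    tn <- sum(confusion[-g, -g])
    tn / (tn + fp)
  }, numeric(1))
  names(spec) <- colnames(confusion)
  structure(list(confusion = confusion, accuracy = acc, sensitivity = sens,
                 specificity = spec, kappa = cohens_kappa(confusion), n = n),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification: accuracy %.1f%%, kappa %.2f (n = %d)\n",
              100 * x$accuracy, x$kappa, x$n))
  print(x$confusion)
  invisible(x)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the row/column marginal products.
#'
#' @param confusion Square count matrix (predicted x actual).
#' @return Kappa, or `NA` with a warning when expected agreement is 1.
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix not square")
  n <- sum(confusion)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe >= 1) {
    warning("expected agreement is 1; kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' One-vs-all ROC with DeLong confidence intervals
#'
#' For each group, the group's posterior probability is scored against the
#' binary group-vs-rest label; the AUC comes from the Mann-Whitney statistic
#' (ties half-weighted) and its 95% CI from DeLong's method, truncated to
#' the unit interval.
#'
#' @param posterior Matrix n x groups of class posterior probabilities
#'   (columns named by group).
#' @param labels Actual labels.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame `group`, `auc`, `ci_lower`, `ci_upper`.
#' @export
roc_delong <- function(posterior, labels, conf_level = 0.95) {
  labels <- factor(labels)
  groups <- colnames(posterior)
  if (is.null(groups)) stop("posterior must have group column names")
  out <- lapply(groups, function(g) {
    y <- as.integer(labels == g)
    if (length(unique(y)) < 2) stop("group ", g, " missing one class")
    r <- pROC::roc(response = y, predictor = posterior[, g], quiet = TRUE,
                   direction = "<", levels = c(0, 1))
    ci <- suppressWarnings(pROC::ci.auc(r, conf.level = conf_level,
                                        method = "delong"))
    data.frame(group = g, auc = as.numeric(pROC::auc(r)),
               ci_lower = max(0, ci[1]), ci_upper = min(1, ci[3]))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Full classification stage
#'
#' Chains the published analysis: z-score the per-subject parameter vectors,
#' PCA, MANOVA on the scores, per-PC ANOVA + Tukey HSD, LOOCV LDA on the PC
#' scores, confusion metrics with Cohen's kappa, and one-vs-all DeLong ROC
#' from the held-out posteriors.
#'
#' @param vectors Per-subject parameter matrix (n x p).
#' @param labels Group labels.
#' @param equal_priors Passed to [lda_loocv()].
#' @return List with `pca`, `manova`, `tukey` (per PC), `lda`, `report`,
#'   `roc`.
#' @export
classify_groups <- function(vectors, labels, equal_priors = FALSE) {
  z <- zscore_columns(vectors)
  pca <- pca_fit(z)
  mv <- manova_pillai(pca$scores, labels)
  tukey <- lapply(seq_len(ncol(pca$scores)), function(j) {
    anova_tukey(pca$scores[, j], labels)
  })
  names(tukey) <- colnames(pca$scores)
  lda <- lda_loocv(pca$scores, labels, equal_priors = equal_priors)
  report <- confusion_metrics(lda$predicted, labels)
  roc <- roc_delong(lda$posterior, labels)
  list(pca = pca, manova = mv, tukey = tukey, lda = lda, report = report,
       roc = roc)
}
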