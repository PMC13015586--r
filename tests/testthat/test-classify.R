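test_that("z-scoring centers and scales; constant columns are refused", {
  set.seed(31)
  x <- matrix(rnorm(200, 5, 3), 50, 4,
              dimnames = list(NULL, paste0("c", 1:4)))
  z <- zscore_columns(x)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-12))
  x[, 2] <- 7
  expect_error(zscore_columns(x), "c2")
})

test_that("PCA matches a direct eigendecomposition of the correlation matrix", {
  set.seed(32)
  x <- MASS::mvrnorm(120, rep(0, 3),
                     matrix(c(2, .8, .2, .8, 1, .1, .2, .1, .5), 3))
  colnames(x) <- c("alpha", "gamma", "beta")
  z <- zscore_columns(x)
  p <- pca_fit(z)
  ev <- eigen(cor(x))
  expect_equal(p$sdev^2, ev$values, tolerance = 1e-8)
  expect_equal(sum(p$variance_fraction), 1)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  # loadings orthonormal and aligned with eigenvectors up to sign
  expect_equal(crossprod(p$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  for (j in 1:3) {
    expect_equal(abs(sum(p$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  }
  # scores are uncorrelated across components
  expect_lt(max(abs(cor(p$scores)[upper.tri(diag(3))])), 1e-10)

  # diagonal-covariance data: loadings are coordinate axes
  set.seed(33)
  xd <- cbind(rnorm(400, 0, 3), rnorm(400, 0, 1), rnorm(400, 0, 0.2))
  pd <- pca_fit(zscore_columns(xd))
  expect_equal(max(abs(pd$loadings)), 1, tolerance = 0.2)
})

test_that("Pillai MANOVA separates shifted groups and stays null under none", {
  set.seed(34)
  v_null <- replicate(20, {
    x <- MASS::mvrnorm(100, rep(0, 3), diag(3))
    g <- rep(letters[1:4], each = 25)
    manova_pillai(x, g)$pillai
  })
  expect_lt(median(v_null), 0.1)

  x <- MASS::mvrnorm(80, rep(0, 3), diag(3))
  g <- rep(c("a", "b"), each = 40)
  x[g == "b", 1] <- x[g == "b", 1] + 5
  expect_lt(manova_pillai(x, g)$p, 1e-3)

  # a shift on the last component only still registers
  x2 <- MASS::mvrnorm(60, rep(0, 3), diag(3))
  g2 <- rep(c("a", "b"), each = 30)
  x2[g2 == "b", 3] <- x2[g2 == "b", 3] + 2
  expect_gt(manova_pillai(x2, g2)$pillai, 0)
})

test_that("Tukey HSD matches a hand-computed worked example", {
  # classic 3-group example, computed from the studentized range distribution
  y <- c(18.2, 20.1, 17.6, 16.8, 18.8, 19.7,
         17.4, 18.7, 19.1, 16.4, 15.9, 18.4,
         15.2, 18.8, 17.7, 16.5, 15.9, 17.1)
  g <- rep(c("a", "b", "c"), each = 6)
  res <- anova_tukey(y, g)
  fit <- aov(y ~ factor(g))
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  means <- tapply(y, g, mean)
  hand <- sapply(list(c("b", "a"), c("c", "a"), c("c", "b")), function(pr) {
    q_obs <- abs(means[pr[1]] - means[pr[2]]) / sqrt(mse / 6)
    ptukey(q_obs, 3, 15, lower.tail = FALSE)
  })
  expect_equal(unname(res$tukey$p_adj), unname(hand), tolerance = 1e-6)

  # identical groups: equal means give F = 0 exactly
  y0 <- rep(c(1, 2, 3), times = 2)
  expect_equal(anova_tukey(y0, rep(c("a", "b"), each = 3))$f, 0)
  set.seed(35)
  nulls <- replicate(20, {
    yy <- rnorm(40)
    min(anova_tukey(yy, rep(c("a", "b"), 20))$tukey$p_adj)
  })
  expect_gt(median(nulls), 0.4)
  expect_error(anova_tukey(rnorm(10), rep("a", 10)), "2 groups")
})

test_that("LOOCV LDA: separable, chance-level, and normalized posteriors", {
  sep <- make_labeled_vectors(list(c(0, 0, 0), c(8, 8, 8), c(-8, 8, 0)),
                              list(diag(3) * .4), ns = c(10, 10, 10),
                              rng_seed = 36)
  r <- lda_loocv(as.matrix(sep[, -1]), sep$label)
  expect_equal(mean(r$predicted == sep$label), 1)
  expect_true(all(abs(rowSums(r$posterior) - 1) < 1e-10))
  expect_equal(dim(r$coefficients), c(3L, 2L))

  set.seed(37)
  null <- make_labeled_vectors(list(c(0, 0, 0), c(0, 0, 0)),
                               list(diag(3)), ns = c(60, 60), rng_seed = 38)
  perm <- sample(null$label)
  rp <- lda_loocv(as.matrix(null[, -1]), perm)
  acc <- mean(rp$predicted == perm)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 120))
})

test_that("confusion metrics and kappa reproduce the published matrix exactly", {
  cm <- published_confusion_matrix()
  rep <- confusion_metrics(confusion = cm)
  expect_equal(rep$accuracy, 0.82)
  expect_equal(round(rep$kappa, 2), 0.76)
  expect_equal(round(100 * rep$sensitivity[["NeverTUD"]], 1), 56.5)
  expect_equal(round(100 * rep$specificity[["NeverTUD"]], 1), 96.1)
  expect_equal(round(100 * rep$sensitivity[["FormerTUD"]], 1), 90.9)
  expect_equal(round(100 * rep$sensitivity[["CurrentTUD"]], 1), 80.8)
  expect_equal(round(100 * rep$sensitivity[["TUD_OUD"]], 1), 96.6)

  ident <- diag(5) * 10
  rep_i <- confusion_metrics(confusion = ident)
  expect_equal(rep_i$accuracy, 1)
  expect_equal(unname(rep_i$sensitivity), rep(1, 5))
  expect_equal(unname(rep_i$specificity), rep(1, 5))
  expect_equal(rep_i$kappa, 1)

  # independence-constructed table: kappa ~ 0
  marg <- c(20, 30, 50)
  indep <- outer(marg, marg) / 100
  expect_lt(abs(cohens_kappa(indep)), 1e-10)
  expect_warning(cohens_kappa(matrix(c(5, 0, 0, 0), 2)), "undefined")

  # metrics from label vectors agree with the matrix route
  pred <- c("a", "a", "b", "b", "b")
  act <- c("a", "b", "b", "b", "a")
  rep_v <- confusion_metrics(pred, act)
  expect_equal(rep_v$accuracy, 3 / 5)
  expect_error(confusion_metrics(pred, act[1:3]), "length mismatch")
})

test_that("DeLong AUC: separable, null, and bootstrap-consistent SE", {
  sep <- data.frame(score = c(rnorm(30, 5), rnorm(30, -5)),
                    y = rep(c("pos", "neg"), each = 30))
  post <- cbind(pos = stats::plogis(sep$score),
                neg = 1 - stats::plogis(sep$score))
  r <- roc_delong(post, sep$y)
  expect_equal(r$auc[r$group == "pos"], 1)

  set.seed(39)
  n <- 500
  y <- sample(c("a", "b"), n, replace = TRUE)
  post_null <- cbind(a = runif(n), b = runif(n))
  rn <- roc_delong(post_null, y)
  se_null <- sqrt((1 / 12) * (1 / sum(y == "a") + 1 / sum(y == "b")))
  expect_lt(abs(rn$auc[rn$group == "a"] - 0.5), 3 * se_null)

  # DeLong SE vs a bootstrap of the Mann-Whitney AUC
  set.seed(40)
  score <- c(rnorm(40, 1), rnorm(60, 0))
  yy <- rep(c(1, 0), c(40, 60))
  pr <- pROC::roc(yy, score, quiet = TRUE, direction = "<", levels = c(0, 1))
  ci <- pROC::ci.auc(pr, method = "delong")
  delong_se <- (ci[3] - ci[1]) / (2 * qnorm(0.975))
  boot <- replicate(2000, {
    idx1 <- sample(which(yy == 1), replace = TRUE)
    idx0 <- sample(which(yy == 0), replace = TRUE)
    s1 <- score[idx1]; s0 <- score[idx0]
    (mean(outer(s1, s0, ">")) + 0.5 * mean(outer(s1, s0, "==")))
  })
  expect_lt(abs(delong_se - sd(boot)) / sd(boot), 0.2)
})

test_that("pipeline accuracy grows with group separation", {
  accs <- sapply(c(0.5, 2, 6), function(d) {
    v <- make_labeled_vectors(
      list(c(0, 0, 0), c(d, 0, 0), c(0, d, 0), c(0, 0, d)),
      list(diag(3)), ns = rep(20, 4), rng_seed = 41)
    cls <- classify_groups(as.matrix(v[, -1]), v$label)
    cls$report$accuracy
  })
  expect_true(all(diff(accs) >= 0))
  expect_lt(accs[1], 0.6)
  expect_equal(accs[3], 1)
})
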