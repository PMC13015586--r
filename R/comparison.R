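#' Pointwise log-likelihood matrix of a fit
#'
#' Entry (s, n) is the log probability of the n-th evaluated (freely made)
#' choice under posterior draw s, with forced trials excluded as columns.
#' Row sums equal the likelihood part of the hierarchical log posterior at
#' the corresponding draw.
#'
#' @param fit An `hb_fit`.
#' @param thin Keep every `thin`-th draw (default 1 = all).
#' @return Matrix draws x evaluated choices, with a `cohort` attribute giving
#'   each column's cohort.
#' @export
pointwise_loglik <- function(fit, thin = 1L) {
  ind <- individual_draws(fit)
  if (thin > 1) ind <- ind[seq(1, nrow(ind), by = thin), , drop = FALSE]
  a <- fit$prep$arrays
  ll <- cpp_pointwise_loglik(model_code(fit$model_id), ind, fit$prep$offsets,
                             a$choice, a$prob, a$easy_mag, a$hard_mag,
                             a$random_assigned, a$payoff)
  # column -> cohort bookkeeping for per-cohort ELPD
  n_eval <- sapply(seq_len(nrow(fit$prep$subjects)), function(s) {
    o <- fit$prep$offsets
    sum(a$random_assigned[(o[s] + 1):o[s + 1]] == 0)
  })
  attr(ll, "cohort") <- rep(fit$prep$subjects$cohort, times = n_eval)
  attr(ll, "n_obs") <- ncol(ll)
  ll
}

# Zhang & Stephens (2009) posterior-mean fit of a generalized Pareto
# distribution to exceedances x > 0. Returns shape k and scale sigma for
# F(x) = 1 - (1 + k x / sigma)^(-1/k).
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) stop("too few tail samples for a generalized Pareto fit")
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  ks <- vapply(b, function(bi) mean(log1p(-bi * x)), numeric(1))
  L <- n * (log(-b / ks) - ks - 1)
  w <- 1 / vapply(seq_len(m), function(i) sum(exp(L - L[i])), numeric(1))
  b_hat <- sum(b * w)
  k <- mean(log1p(-b_hat * x))
  list(k = k, sigma = -k / b_hat)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Pareto-smooth one vector of log importance ratios; returns smoothed log
# weights and the tail shape khat.
psis_smooth <- function(lw) {
  s <- length(lw)
  m <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  ord <- order(lw)
  tail_ids <- ord[(s - m + 1):s]
  cutoff <- lw[ord[s - m]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  if (max(exceed) <= 0) return(list(lw = lw, khat = -Inf))
  fit <- gpd_fit(exceed[exceed > 0])
  p <- (seq_len(m) - 0.5) / m
  smoothed <- log(exp(cutoff) + qgpd(p, fit$k, fit$sigma))
  lw_max <- max(lw)
  lw[tail_ids[order(lw[tail_ids])]] <- pmin(smoothed, lw_max)
  list(lw = lw, khat = fit$k)
}

#' PSIS leave-one-out expected log predictive density
#'
#' Importance ratios 1/p(y_n | theta_s) are stabilized per observation by
#' replacing the largest 20% (or 3*sqrt(S), whichever is smaller) with
#' quantiles of a generalized Pareto distribution fitted to the tail, then
#' truncated at the raw maximum. The ELPD is the sum over observations of the
#' log smoothed-weighted predictive density; its SE comes from the pointwise
#' variance. Tail shapes above 0.7 are counted and warned about.
#'
#' @param ll Log-likelihood matrix (draws x observations), e.g. from
#'   [pointwise_loglik()]; needs >= 100 draws.
#' @return A `loo_result`: `elpd_loo`, `se`, `pointwise`, `pareto_k`,
#'   `n_bad_k`, `n_obs`.
#' @export
psis_loo <- function(ll) {
  if (nrow(ll) < 100) stop("need at least 100 draws for PSIS-LOO")
  n <- ncol(ll)
  pointwise <- numeric(n)
  khat <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i])
    lw <- sm$lw - logsumexp(sm$lw)
    pointwise[i] <- logsumexp(lw + ll[, i])
    khat[i] <- sm$khat
  }
  n_bad <- sum(khat > 0.7)
  if (n_bad > 0) {
    warning(n_bad, " observations with Pareto k > 0.7; ELPD may be unstable")
  }
  structure(list(elpd_loo = sum(pointwise),
                 se = sqrt(n * var(pointwise)),
                 pointwise = pointwise, pareto_k = khat, n_bad_k = n_bad,
                 n_obs = n),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd = %.1f (SE %.1f) over %d observations; %d k > 0.7\n",
              x$elpd_loo, x$se, x$n_obs, x$n_bad_k))
  invisible(x)
}

#' Per-cohort ELPD breakdown
#'
#' @param ll A matrix from [pointwise_loglik()] (carries cohort column labels).
#' @return Data frame of cohort, elpd, se, n_obs, plus a pooled row.
#' @export
elpd_by_cohort <- function(ll) {
  cohorts <- attr(ll, "cohort")
  if (is.null(cohorts)) stop("ll must come from pointwise_loglik()")
  rows <- lapply(unique(cohorts), function(co) {
    r <- psis_loo(ll[, cohorts == co, drop = FALSE])
    data.frame(cohort = co, elpd = r$elpd_loo, se = r$se, n_obs = r$n_obs)
  })
  pooled <- psis_loo(ll)
  rbind(do.call(rbind, rows),
        data.frame(cohort = "all", elpd = pooled$elpd_loo, se = pooled$se,
                   n_obs = pooled$n_obs))
}

# multivariate normal log density given mean and cholesky of covariance
dmvnorm_log <- function(x, mean, chol_cov) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  z <- backsolve(chol_cov, t(x) - mean, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(chol_cov))) -
    0.5 * ncol(x) * log(2 * pi)
}

#' Bridge-sampling estimate of the log marginal likelihood
#'
#' The optimal-bridge iterative estimator with a moment-matched multivariate
#' normal proposal. Each repetition splits the posterior draws at random into
#' a proposal-fitting half and an estimation half, draws fresh proposal
#' samples, and iterates the bridge identity to relative tolerance 1e-10
#' (at most 1000 iterations). The median and interquartile range over
#' repetitions are reported.
#'
#' @param draws Posterior draws on the unconstrained scale (matrix, one row
#'   per draw); any Jacobians must be inside `log_post`.
#' @param log_post Function: matrix of parameter rows -> vector of
#'   unnormalized log posterior densities.
#' @param n_reps Number of repetitions (default 10).
#' @param rng_seed Integer seed.
#' @return An `evidence_estimate`: per-repetition log marginal likelihoods,
#'   their median and IQR.
#' @export
bridge_evidence <- function(draws, log_post, n_reps = 10L, rng_seed = 1L) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 20) stop("too few draws for bridge sampling")
  set.seed(rng_seed)
  reps <- vapply(seq_len(n_reps), function(r) {
    idx <- sample.int(n, floor(n / 2))
    fit_half <- draws[idx, , drop = FALSE]
    est_half <- draws[-idx, , drop = FALSE]
    mu <- colMeans(fit_half)
    cov <- var(fit_half) + diag(1e-8, ncol(draws))
    ch <- chol(cov)
    n2 <- nrow(est_half)
    prop <- matrix(rnorm(n2 * ncol(draws)), n2) %*% ch +
      matrix(mu, n2, ncol(draws), byrow = TRUE)
    l1 <- log_post(est_half) - dmvnorm_log(est_half, mu, ch)
    l2 <- log_post(prop) - dmvnorm_log(prop, mu, ch)
    if (!all(is.finite(l1))) stop("non-finite posterior density at draws")
    l2[!is.finite(l2)] <- -Inf
    lstar <- stats::median(l1)
    n1 <- length(l1)
    s1 <- n1 / (n1 + n2)
    s2 <- n2 / (n1 + n2)
    r_cur <- 1
    for (it in seq_len(1000)) {
      num <- mean(exp(l2 - lstar) / (s1 * exp(l2 - lstar) + s2 * r_cur))
      den <- mean(1 / (s1 * exp(l1 - lstar) + s2 * r_cur))
      r_new <- num / den
      if (!is.finite(r_new) || r_new <= 0) {
        stop("bridge estimator failed to converge (iteration ", it, ")")
      }
      done <- abs(r_new - r_cur) / r_cur < 1e-10
      r_cur <- r_new
      if (done) break
    }
    log(r_cur) + lstar
  }, numeric(1))
  structure(list(reps = reps, median = stats::median(reps),
                 iqr = stats::IQR(reps), n_reps = n_reps),
            class = "evidence_estimate")
}

#' @export
print.evidence_estimate <- function(x, ...) {
  cat(sprintf("Bridge-sampling log evidence: median %.2f (IQR %.3f, %d reps)\n",
              x$median, x$iqr, x$n_reps))
  invisible(x)
}

#' Log marginal likelihood of a hierarchical fit
#'
#' Convenience wrapper running [bridge_evidence()] on a fit's unconstrained
#' draws with the fit's own log posterior as the target.
#'
#' @param fit An `hb_fit`.
#' @param n_reps,rng_seed Passed to [bridge_evidence()].
#' @return An `evidence_estimate` with the fit's `model_id` and observation
#'   count attached.
#' @export
model_evidence <- function(fit, n_reps = 10L, rng_seed = 1L) {
  d <- fit$draws
  flat <- matrix(d, nrow = dim(d)[1] * dim(d)[2])
  lp_fun <- function(m) {
    apply(m, 1, function(th) hier_lp(fit$spec, th, fit$prep,
                                     want_grad = FALSE)$lp)
  }
  ev <- bridge_evidence(flat, lp_fun, n_reps = n_reps, rng_seed = rng_seed)
  ev$model_id <- fit$model_id
  ev$n_obs <- sum(fit$prep$arrays$random_assigned == 0)
  ev
}

#' Rank models by evidence and by ELPD
#'
#' Orders models by median log marginal likelihood (greatest, i.e. least
#' negative, first) and separately by ELPD-LOO, flagging any disagreement
#' between the two criteria.
#'
#' @param evidences Named list of `evidence_estimate`s (one per model).
#' @param loos Named list of `loo_result`s on the same data (same names).
#' @return A `model_comparison` data frame with both rankings.
#' @export
compare_models <- function(evidences, loos) {
  models <- names(evidences)
  if (!identical(sort(models), sort(names(loos)))) {
    stop("evidence and LOO lists must cover the same models")
  }
  n_obs <- unique(c(sapply(evidences, function(e) e$n_obs %||% NA),
                    sapply(loos, function(l) l$n_obs)))
  n_obs <- n_obs[!is.na(n_obs)]
  if (length(n_obs) > 1) stop("models were not fitted to identical data")
  tab <- data.frame(
    model_id = models,
    evidence_median = sapply(evidences, function(e) e$median),
    evidence_iqr = sapply(evidences, function(e) e$iqr),
    elpd = sapply(loos, function(l) l$elpd_loo),
    elpd_se = sapply(loos, function(l) l$se),
    n_bad_k = sapply(loos, function(l) l$n_bad_k),
    row.names = NULL
  )
  tab$rank_evidence <- rank(-tab$evidence_median, ties.method = "first")
  tab$rank_elpd <- rank(-tab$elpd, ties.method = "first")
  tab <- tab[order(tab$rank_evidence), ]
  attr(tab, "criteria_agree") <- identical(tab$rank_evidence, tab$rank_elpd)
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
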