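fit_small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      study <- simulate_study(list(
        cohort_spec("A", 4, "reward_only", c(k = 1.2, beta = 2.5),
                    c(k = .3, beta = .6)),
        cohort_spec("B", 4, "reward_only", c(k = 1.8, beta = 1.5),
                    c(k = .3, beta = .6))), n_trials = 30, rng_seed = 21)
      fit <- sample_posterior(hierarchical_spec("reward_only"),
                              study$sessions, chains = 2, iter = 500,
                              warmup = 200, seed = 21)
      cache <<- list(study = study, fit = fit)
    }
    cache
  }
})

test_that("pointwise log-likelihoods are probabilities and sum to the fit's likelihood", {
  fs <- fit_small_study()
  ll <- pointwise_loglik(fs$fit)
  expect_true(all(ll <= 0))
  expect_equal(ncol(ll), sum(fs$study$sessions$random_assigned == 0))

  # row-sum identity against the hierarchical posterior's likelihood part
  d <- fs$fit$draws
  flat <- matrix(d, nrow = dim(d)[1] * dim(d)[2])
  for (i in c(1, 57, nrow(flat))) {
    parts <- log_posterior_density(fs$fit$spec, flat[i, ],
                                   fs$study$sessions)$parts
    expect_equal(sum(ll[i, ]), unname(parts["loglik"]), tolerance = 1e-8)
  }
})

test_that("a zero-temperature draw gives log(1/2) everywhere", {
  fs <- fit_small_study()
  a <- fs$fit$prep$arrays
  # constrained draws with a vanishing inverse temperature
  draws <- matrix(rep(c(1.2, 1e-12), 8), nrow = 1)
  ll <- effortrl:::cpp_pointwise_loglik(2L, draws, fs$fit$prep$offsets,
                                        a$choice, a$prob, a$easy_mag,
                                        a$hard_mag, a$random_assigned,
                                        a$payoff)
  expect_equal(as.vector(ll), rep(log(0.5), ncol(ll)), tolerance = 1e-6)
})

test_that("PSIS-LOO agrees with exact leave-one-out on a conjugate toy", {
  # Bernoulli with Beta prior: exact LOO predictive is Beta-Binomial
  set.seed(22)
  y <- rbinom(50, 1, 0.6)
  a0 <- 1; b0 <- 1
  th <- rbeta(4000, a0 + sum(y), b0 + sum(1 - y))
  ll <- vapply(y, function(yi) dbinom(yi, 1, th, log = TRUE),
               numeric(length(th)))
  r <- psis_loo(ll)
  exact <- sum(vapply(seq_along(y), function(i) {
    a <- a0 + sum(y[-i]); b <- b0 + sum(1 - y[-i])
    log(if (y[i] == 1) a / (a + b) else b / (a + b))
  }, numeric(1)))
  expect_lt(abs(r$elpd_loo - exact), 2 * r$se)
  expect_lte(r$elpd_loo, 0)
  expect_true(all(r$pareto_k < 0.7))
  expect_error(psis_loo(ll[1:50, ]), "at least 100 draws")
})

test_that("generalized Pareto tail fit recovers known shapes", {
  set.seed(23)
  for (k_true in c(0.2, 0.5)) {
    # inverse-CDF samples from GPD(sigma = 1, k)
    u <- runif(20000)
    x <- (u^(-k_true) - 1) / k_true
    f <- effortrl:::gpd_fit(x)
    expect_lt(abs(f$k - k_true), 0.05)
    expect_lt(abs(f$sigma - 1), 0.08)
  }
})

test_that("bridge sampling hits a closed-form marginal likelihood", {
  set.seed(24)
  n <- 30; s <- 1.5; t0 <- 2
  y <- rnorm(n, 1.2, s)
  post_var <- 1 / (1 / t0^2 + n / s^2)
  post_mean <- post_var * sum(y) / s^2
  Sigma <- diag(s^2, n) + t0^2
  analytic <- as.numeric(-0.5 * (n * log(2 * pi) +
    determinant(Sigma)$modulus + t(y) %*% solve(Sigma) %*% y))
  draws <- matrix(rnorm(4000, post_mean, sqrt(post_var)), ncol = 1)
  lp <- function(m) {
    vapply(m[, 1], function(th) sum(dnorm(y, th, s, log = TRUE)) +
             dnorm(th, 0, t0, log = TRUE), numeric(1))
  }
  ev <- bridge_evidence(draws, lp, n_reps = 10, rng_seed = 25)
  expect_lt(abs(ev$median - analytic), 0.05)
  expect_lt(ev$iqr, 0.5)
  expect_true(ev$median >= min(ev$reps) && ev$median <= max(ev$reps))

  # invariance to an affine reparameterization of the sampled space
  scale_f <- 37
  draws2 <- draws * scale_f
  lp2 <- function(m) lp(m / scale_f) - log(scale_f)
  ev2 <- bridge_evidence(draws2, lp2, n_reps = 10, rng_seed = 26)
  expect_lt(abs(ev2$median - ev$median), max(ev$iqr, ev2$iqr, 0.01))
})

test_that("model ranking orders by both criteria and validates inputs", {
  mk_ev <- function(med, n_obs) structure(
    list(reps = med, median = med, iqr = 0.1, n_reps = 1, n_obs = n_obs),
    class = "evidence_estimate")
  mk_loo <- function(elpd, n_obs) structure(
    list(elpd_loo = elpd, se = 1, pointwise = NULL, pareto_k = 0,
         n_bad_k = 0, n_obs = n_obs), class = "loo_result")
  cmp <- compare_models(list(a = mk_ev(-100, 50), b = mk_ev(-90, 50)),
                        list(a = mk_loo(-110, 50), b = mk_loo(-95, 50)))
  expect_equal(cmp$model_id, c("b", "a"))
  expect_true(attr(cmp, "criteria_agree"))

  single <- compare_models(list(a = mk_ev(-100, 50)),
                           list(a = mk_loo(-110, 50)))
  expect_equal(single$rank_evidence, 1L)
  expect_error(
    compare_models(list(a = mk_ev(-100, 50)), list(b = mk_loo(-95, 50))),
    "same models")
  expect_error(
    compare_models(list(a = mk_ev(-100, 50), b = mk_ev(-90, 99)),
                   list(a = mk_loo(-110, 50), b = mk_loo(-95, 50))),
    "identical data")
})

test_that("per-cohort ELPD partitions the pooled observations", {
  fs <- fit_small_study()
  ll <- pointwise_loglik(fs$fit)
  tab <- elpd_by_cohort(ll)
  expect_setequal(tab$cohort, c("A", "B", "all"))
  expect_equal(sum(tab$n_obs[tab$cohort != "all"]),
               tab$n_obs[tab$cohort == "all"])
  expect_equal(sum(tab$elpd[tab$cohort != "all"]),
               tab$elpd[tab$cohort == "all"], tolerance = 1e-8)
})
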