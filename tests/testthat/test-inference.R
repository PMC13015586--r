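test_that("constrain/unconstrain is a midpoint-symmetric bijection", {
  expect_equal(constrain_param(0, 0, 10), 5)
  expect_equal(constrain_param(unconstrain_param(0.37, 0, 1), 0, 1), 0.37,
               tolerance = 1e-10)
  expect_lt(abs(constrain_param(20, 0, 1) - 1), 1e-8)
  set.seed(1)
  x <- rnorm(50, 0, 3)
  expect_equal(unconstrain_param(constrain_param(x, 0, 100), 0, 100), x,
               tolerance = 1e-8)
  expect_error(unconstrain_param(0, 0, 1), "bounds")
})

test_that("log posterior decomposes additively and matches the analytic prior", {
  study <- simulate_study(list(
    cohort_spec("A", 3, "reward_only", c(k = 1, beta = 2),
                c(k = .2, beta = .4))), rng_seed = 2)
  spec <- hierarchical_spec("reward_only")
  set.seed(3)
  theta <- rnorm(2 * 2 + 3 * 2, 0, 0.7)
  r <- log_posterior_density(spec, theta, study$sessions)
  expect_equal(unname(sum(r$parts)), r$lp, tolerance = 1e-10)

  # likelihood part equals the sum of session_loglik at the implied params
  mu <- theta[1:2]; sigma <- exp(theta[3:4]); z <- matrix(theta[5:10], 3, 2,
                                                          byrow = TRUE)
  b <- param_bounds("reward_only")
  lls <- sapply(1:3, function(s) {
    pars <- constrain_param(mu + sigma * z[s, ], b["lower", ], b["upper", ])
    names(pars) <- c("k", "beta")
    id <- unique(study$sessions$subject_id)[s]
    session_loglik("reward_only", pars,
                   study$sessions[study$sessions$subject_id == id, ])$loglik
  })
  expect_equal(unname(r$parts["loglik"]), sum(lls), tolerance = 1e-8)

  # with every trial forced, only the analytic prior terms remain
  masked <- study$sessions
  masked$random_assigned <- 1
  r0 <- log_posterior_density(spec, theta, masked)
  expect_equal(unname(r0$parts["loglik"]), 0)
  m0 <- spec$prior_loc_mean
  hyper <- sum(dnorm(mu, m0, 1.5, log = TRUE)) +
    sum(log(2) + dnorm(sigma, 0, 1, log = TRUE))
  expect_equal(unname(r0$parts["hyperprior"]), hyper, tolerance = 1e-10)
  expect_equal(unname(r0$parts["individual_prior"]),
               sum(dnorm(z, log = TRUE)), tolerance = 1e-10)
  expect_equal(unname(r0$parts["jacobian"]), sum(theta[3:4]))
})

test_that("analytic gradient matches central finite differences", {
  study <- simulate_study(list(
    cohort_spec("A", 2, "tdrl", c(alpha = .4, gamma = .6, beta = 3),
                c(alpha = .1, gamma = .1, beta = .5)),
    cohort_spec("B", 2, "tdrl", c(alpha = .3, gamma = .5, beta = 2),
                c(alpha = .1, gamma = .1, beta = .5))), rng_seed = 4)
  spec <- hierarchical_spec("tdrl")
  npar <- 2 * 2 * 3 + 4 * 3
  set.seed(5)
  for (rep in 1:3) {
    theta <- rnorm(npar, 0, 0.6)
    r <- log_posterior_density(spec, theta, study$sessions, grad = TRUE)
    fd <- vapply(seq_len(npar), function(j) {
      e <- rep(0, npar); e[j] <- 1e-5
      (log_posterior_density(spec, theta + e, study$sessions)$lp -
         log_posterior_density(spec, theta - e, study$sessions)$lp) / 2e-5
    }, numeric(1))
    expect_lt(max(abs(r$grad - fd) / pmax(abs(fd), 1)), 1e-5)
  }
})

test_that("HMC recovers a known conjugate posterior", {
  # y ~ N(theta, s^2), theta ~ N(0, t^2): posterior is normal in closed form
  set.seed(6)
  s <- 1.5; t0 <- 2; n <- 25
  y <- rnorm(n, 1, s)
  post_var <- 1 / (1 / t0^2 + n / s^2)
  post_mean <- post_var * sum(y) / s^2
  lp_fun <- function(th) {
    list(lp = sum(dnorm(y, th, s, log = TRUE)) + dnorm(th, 0, t0, log = TRUE),
         grad = sum(y - th) / s^2 - th / t0^2)
  }
  draws <- c()
  for (ch in 1:2) {
    set.seed(100 + ch)
    res <- effortrl:::hmc_chain(lp_fun, rnorm(1), iter = 1500, warmup = 300,
                                target_accept = 0.8, max_leapfrog = 16)
    draws <- c(draws, res$draws[, 1])
  }
  # generous effective-sample allowance: 3 MC SEs at ESS >= 100
  expect_lt(abs(mean(draws) - post_mean), 3 * sqrt(post_var) / sqrt(100))
  expect_lt(abs(sd(draws) - sqrt(post_var)), 0.15 * sqrt(post_var))
})

test_that("split-Rhat matches a direct implementation and flags divergence", {
  set.seed(7)
  x <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(x), 1.01)
  expect_equal(split_rhat(x), oracle_split_rhat(x), tolerance = 1e-12)

  bad <- cbind(rnorm(200, 0), rnorm(200, 5))
  expect_gt(split_rhat(bad), 1.5)

  y <- matrix(rnorm(200), 100, 2)
  expect_equal(split_rhat(y), oracle_split_rhat(y), tolerance = 1e-12)
  expect_warning(split_rhat(matrix(1, 100, 2)), "undefined")
})

test_that("KDE posterior mode finds known modes", {
  expect_equal(extract_map(rep(3.3, 200)), 3.3)
  set.seed(8)
  x <- rbeta(50000, 2, 5) # mode (a-1)/(a+b-2) = 0.2
  expect_lt(abs(extract_map(x, 0, 1) - 0.2), 0.02)
  z <- rnorm(20000, 1.7, 0.4)
  expect_lt(abs(extract_map(z) - mean(z)), 2 * 0.4 / sqrt(20000) * 10)
  expect_error(extract_map(rnorm(50)), "100 draws")
})

test_that("HDI is the shortest mass interval", {
  set.seed(9)
  x <- rnorm(100000)
  ci <- hdi(x, 0.95)
  expect_lt(abs(ci[["lower"]] + 1.96), 0.05)
  expect_lt(abs(ci[["upper"]] - 1.96), 0.05)
  expect_equal(unname(hdi(x, 1)), c(min(x), max(x)))
  expect_equal(unname(hdi(rep(2, 50))), c(2, 2))
  # skewed case: HDI is shorter than the central interval
  g <- rgamma(50000, 2, 1)
  ci_h <- hdi(g, 0.9)
  ci_c <- quantile(g, c(0.05, 0.95))
  expect_lt(diff(unname(ci_h)), unname(ci_c[2] - ci_c[1]))
})

test_that("cohort difference report flags separation, not identity", {
  # hand-built fit skeleton with known cohort-location draws
  skeleton <- function(mu_a, mu_b) {
    nd <- length(mu_a)
    draws <- array(0, c(nd, 1, 2 * 2 * 2 + 0),
                   dimnames = list(NULL, "chain1",
                                   c("mu[A,k]", "mu[A,beta]", "mu[B,k]",
                                     "mu[B,beta]", "tau[A,k]", "tau[A,beta]",
                                     "tau[B,k]", "tau[B,beta]")))
    draws[, 1, "mu[A,k]"] <- mu_a
    draws[, 1, "mu[B,k]"] <- mu_b
    structure(list(
      spec = hierarchical_spec("reward_only"), model_id = "reward_only",
      prep = list(cohorts = c("A", "B"),
                  subjects = data.frame(subject_id = character(0),
                                        cohort = character(0)))),
      class = "hb_fit") -> fit
    fit$draws <- draws
    fit
  }
  set.seed(10)
  null_fit <- skeleton(rnorm(2000, 0, 0.5), rnorm(2000, 0, 0.5))
  rep0 <- cohort_difference_report(null_fit, "k")
  expect_false(rep0$excludes_zero)
  expect_false(rep0$credible)

  sep_fit <- skeleton(rnorm(2000, 1.5, 0.3), rnorm(2000, 0, 0.3))
  rep1 <- cohort_difference_report(sep_fit, "k")
  expect_true(rep1$excludes_zero)
  expect_true(rep1$credible)
  expect_error(cohort_difference_report(sep_fit, "nope"), "unknown parameter")
})

test_that("hierarchical shrinkage pulls individuals toward the cohort mean", {
  study <- simulate_study(list(
    cohort_spec("A", 12, "reward_only", c(k = 1.2, beta = 2.5),
                c(k = .4, beta = .8))), rng_seed = 11)
  fit <- sample_posterior(hierarchical_spec("reward_only"), study$sessions,
                          chains = 2, iter = 700, warmup = 250, seed = 11)
  maps <- map_table(fit)
  b <- param_bounds("reward_only")
  # per-subject maximum likelihood on the unconstrained scale
  mles <- t(sapply(unique(study$sessions$subject_id), function(id) {
    s <- study$sessions[study$sessions$subject_id == id, ]
    opt <- optim(c(0, 0), function(u) {
      pars <- constrain_param(u, b["lower", ], b["upper", ])
      names(pars) <- c("k", "beta")
      -session_loglik("reward_only", pars, s)$loglik
    })
    constrain_param(opt$par, b["lower", ], b["upper", ])
  }))
  pooled <- colMeans(maps[, c("k", "beta")])
  frac_between <- mean(sapply(1:12, function(i) {
    all((maps$k[i] - mles[i, 1]) * (pooled["k"] - mles[i, 1]) >= -1e-8,
        (maps$beta[i] - mles[i, 2]) * (pooled["beta"] - mles[i, 2]) >= -1e-8)
  }))
  expect_gte(frac_between, 0.8)
})
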