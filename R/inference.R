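#' Bounded/unbounded parameter transforms
#'
#' Scaled-logistic bijection between the real line and an open interval:
#' `constrain_param(x) = lo + (hi - lo) / (1 + exp(-x))`. Round trips are
#' exact to numerical precision; `unconstrain_param` rejects boundary values.
#'
#' @param x Unconstrained real value(s).
#' @param lower,upper Interval bounds.
#' @return The transformed value(s).
#' @export
constrain_param <- function(x, lower, upper) {
  lower + (upper - lower) * stats::plogis(x)
}

#' @rdname constrain_param
#' @param y Constrained value(s), strictly inside `(lower, upper)`.
#' @export
unconstrain_param <- function(y, lower, upper) {
  if (any(y <= lower) || any(y >= upper)) {
    stop("value on or outside the open bounds (", lower, ", ", upper, ")")
  }
  stats::qlogis((y - lower) / (upper - lower))
}

#' Hierarchical model specification
#'
#' Individual parameters are nested within cohort-level distributions on the
#' unconstrained (logistic) scale: cohort locations get Normal(`loc_mean`,
#' `loc_sd`) priors, cohort scales half-Normal(`scale_sd`), and individual
#' effects are non-centered standard normals. The default location centers
#' sit at plausible behavioral values rather than the interval midpoints
#' (learning rate and discount at 0.5, effort/probability weights at 1,
#' inverse temperature at 5): a Normal(0, 1.5) prior on the logistic scale of
#' (0, 100) would otherwise put the prior median inverse temperature at 50,
#' i.e. near-deterministic choice, which is not weakly informative in effect.
#'
#' @param model_id One of [model_ids()].
#' @param prior_loc_mean Optional named vector of prior centers on the
#'   constrained scale (defaults as above).
#' @param prior_loc_sd SD of the Normal prior on cohort locations
#'   (unconstrained scale).
#' @param prior_scale_sd Scale of the half-Normal prior on cohort scales.
#' @return A `hier_spec` list.
#' @export
hierarchical_spec <- function(model_id, prior_loc_mean = NULL,
                              prior_loc_sd = 1.5, prior_scale_sd = 1) {
  model_id <- match.arg(model_id, model_ids())
  b <- param_bounds(model_id)
  if (is.null(prior_loc_mean)) {
    prior_loc_mean <- c(k = 1, h = 1, alpha = 0.5, gamma = 0.5,
                        beta = 5)[param_names(model_id)]
  }
  prior_loc_mean <- prior_loc_mean[param_names(model_id)]
  if (anyNA(prior_loc_mean)) stop("prior_loc_mean must name every parameter")
  check_in_bounds(prior_loc_mean, b)
  structure(list(model_id = model_id, bounds = b,
                 prior_loc_mean = unconstrain_param(prior_loc_mean,
                                                    b["lower", ], b["upper", ]),
                 prior_loc_sd = prior_loc_sd, prior_scale_sd = prior_scale_sd),
            class = "hier_spec")
}

# Internal: session table -> concatenated arrays + subject/cohort bookkeeping.
prepare_sessions <- function(sessions) {
  subjects <- unique(sessions[, c("subject_id", "cohort")])
  rownames(subjects) <- NULL
  cohorts <- unique(subjects$cohort)
  ord <- order(match(sessions$subject_id, subjects$subject_id),
               sessions$trial_index)
  sessions <- sessions[ord, , drop = FALSE]
  a <- session_arrays(sessions)
  counts <- as.integer(table(factor(sessions$subject_id,
                                    levels = subjects$subject_id)))
  list(subjects = subjects, cohorts = cohorts,
       cohort_of_subj = match(subjects$cohort, cohorts) - 1L,
       offsets = c(0L, cumsum(counts)), arrays = a)
}

theta_names <- function(spec, prep) {
  pn <- param_names(spec$model_id)
  c(as.vector(t(outer(prep$cohorts, pn, function(co, p)
      sprintf("mu[%s,%s]", co, p)))),
    as.vector(t(outer(prep$cohorts, pn, function(co, p)
      sprintf("tau[%s,%s]", co, p)))),
    as.vector(t(outer(prep$subjects$subject_id, pn, function(s, p)
      sprintf("z[%s,%s]", s, p)))))
}

#' Hierarchical log posterior density
#'
#' Evaluates (and optionally differentiates) the joint unnormalized log
#' posterior at a full unconstrained parameter vector `theta`, laid out as
#' cohort locations `mu[c,j]`, log cohort scales `tau[c,j]`, then individual
#' standard-normal effects `z[s,j]` (subject-major). The returned `parts`
#' decompose the total into hyperprior, individual prior, data log-likelihood,
#' and the log-Jacobian of the scale transform.
#'
#' @param spec A [hierarchical_spec()].
#' @param theta Unconstrained parameter vector.
#' @param sessions Session table (may have zero rows for prior-only checks;
#'   subjects then come from `prep`).
#' @param grad Also return the analytic gradient?
#' @return List with `lp`, `parts`, and (if requested) `grad`.
#' @export
log_posterior_density <- function(spec, theta, sessions, grad = FALSE) {
  prep <- prepare_sessions(sessions)
  res <- hier_lp(spec, theta, prep, want_grad = grad)
  out <- list(lp = res$lp, parts = res$parts)
  if (grad) out$grad <- res$grad
  out
}

hier_lp <- function(spec, theta, prep, want_grad = TRUE) {
  a <- prep$arrays
  cpp_hier_lp(model_code(spec$model_id), theta, length(prep$cohorts),
              prep$cohort_of_subj, prep$offsets, a$choice, a$prob, a$easy_mag,
              a$hard_mag, a$random_assigned, a$payoff,
              spec$bounds["lower", ], spec$bounds["upper", ],
              spec$prior_loc_mean, spec$prior_loc_sd, spec$prior_scale_sd,
              want_grad)
}

#' Sample the hierarchical posterior by Hamiltonian Monte Carlo
#'
#' Gradient-based MCMC: per chain, leapfrog trajectories with a jittered
#' number of steps, dual-averaging step-size adaptation toward a target
#' acceptance rate, and a diagonal mass matrix estimated during warmup.
#' Warmup draws are discarded. Chain seeds derive deterministically from
#' `seed`. Convergence is summarized by split-Rhat over all parameters.
#'
#' @param spec A [hierarchical_spec()].
#' @param sessions A filtered session table.
#' @param chains Number of chains (default 4).
#' @param iter Total iterations per chain, including warmup (default 1000;
#'   the reference analysis scale of 10000/2000 is available by setting
#'   `iter`/`warmup` accordingly).
#' @param warmup Warmup iterations discarded from each chain (default 250).
#' @param seed Master integer seed.
#' @param target_accept Dual-averaging target acceptance rate.
#' @param max_leapfrog Upper bound of the jittered leapfrog step count.
#' @return An `hb_fit` object: raw draws (`iter - warmup` x `chains` x
#'   n_parameters), log-posterior draws, acceptance rates, a convergence
#'   report, and the prepared data needed by downstream stages.
#' @export
sample_posterior <- function(spec, sessions, chains = 4L, iter = 1000L,
                             warmup = 250L, seed = 1L, target_accept = 0.8,
                             max_leapfrog = 32L) {
  stopifnot(inherits(spec, "hier_spec"), nrow(sessions) > 0,
            chains >= 1, iter > warmup, warmup >= 20)
  prep <- prepare_sessions(sessions)
  pn <- param_names(spec$model_id)
  C <- length(prep$cohorts)
  S <- nrow(prep$subjects)
  J <- length(pn)
  npar <- 2L * C * J + S * J
  nm <- theta_names(spec, prep)
  keep <- iter - warmup

  draws <- array(NA_real_, c(keep, chains, npar),
                 dimnames = list(NULL, paste0("chain", seq_len(chains)), nm))
  lp_draws <- matrix(NA_real_, keep, chains)
  accept <- numeric(chains)

  mu0 <- spec$prior_loc_mean
  for (ch in seq_len(chains)) {
    set.seed(seed * 100L + ch)
    # layout is cohort-major: mu[c*J + j]
    theta <- c(rep(mu0, times = C) + rnorm(C * J, 0, 0.2),
               rnorm(C * J, log(0.3), 0.2),
               rnorm(S * J, 0, 0.2))
    lp_fun <- function(th) hier_lp(spec, th, prep)
    res <- hmc_chain(lp_fun, theta, iter, warmup, target_accept, max_leapfrog)
    draws[, ch, ] <- res$draws
    lp_draws[, ch] <- res$lp
    accept[ch] <- res$accept
  }

  rhat <- apply(draws, 3, function(m) split_rhat(m))
  report <- data.frame(parameter = nm, rhat = rhat,
                       flagged = !is.na(rhat) & rhat > 1.1)
  structure(list(spec = spec, model_id = spec$model_id, prep = prep,
                 draws = draws, lp = lp_draws, accept_rate = accept,
                 convergence = report, chains = chains, iter = iter,
                 warmup = warmup, seed = seed),
            class = "hb_fit")
}

#' @export
print.hb_fit <- function(x, ...) {
  cat("Hierarchical Bayesian fit:", x$model_id, "\n")
  cat(sprintf("  %d subjects in %d cohorts; %d chains x %d draws (+%d warmup)\n",
              nrow(x$prep$subjects), length(x$prep$cohorts), x$chains,
              x$iter - x$warmup, x$warmup))
  cat(sprintf("  mean acceptance %.2f; max split-Rhat %.3f (%d of %d > 1.1)\n",
              mean(x$accept_rate), max(x$convergence$rhat, na.rm = TRUE),
              sum(x$convergence$flagged), nrow(x$convergence)))
  invisible(x)
}

# One HMC chain over a generic target. lp_fun(theta) must return list(lp, grad).
# Dual averaging during warmup; diagonal mass matrix estimated from the middle
# warmup window.
hmc_chain <- function(lp_fun, theta, iter, warmup, target_accept,
                      max_leapfrog) {
  npar <- length(theta)
  inv_mass <- rep(1, npar)
  cur <- lp_fun(theta)
  if (!is.finite(cur$lp)) stop("non-finite log posterior at initialization")

  # dual-averaging state
  eps <- find_reasonable_eps(lp_fun, theta, cur, inv_mass)
  da_mu <- log(10 * eps)
  da_h <- 0; da_logeps_bar <- log(eps); da_count <- 0
  gamma0 <- 0.05; t0 <- 10; kappa <- 0.75

  adapt_end <- warmup
  win_lo <- max(2L, floor(warmup * 0.4))
  win_hi <- floor(warmup * 0.9)
  win <- matrix(NA_real_, max(win_hi - win_lo + 1L, 1L), npar)

  keep <- iter - warmup
  draws <- matrix(NA_real_, keep, npar)
  lp_out <- numeric(keep)
  n_acc <- 0

  for (it in seq_len(iter)) {
    p <- rnorm(npar, 0, sqrt(1 / inv_mass))
    h0 <- cur$lp - 0.5 * sum(p^2 * inv_mass)
    L <- sample(seq_len(max_leapfrog), 1)
    th <- theta
    g <- cur$grad
    lp_new <- cur$lp
    ok <- TRUE
    for (l in seq_len(L)) {
      p <- p + 0.5 * eps * g
      th <- th + eps * inv_mass * p
      prop <- lp_fun(th)
      if (!is.finite(prop$lp)) { ok <- FALSE; break }
      g <- prop$grad
      lp_new <- prop$lp
      p <- p + 0.5 * eps * g
    }
    a_prob <- if (!ok) 0 else min(1, exp(lp_new - 0.5 * sum(p^2 * inv_mass) - h0))
    if (ok && runif(1) < a_prob) {
      theta <- th
      cur <- prop
      if (it > warmup) n_acc <- n_acc + 1
    }
    if (it <= adapt_end) {
      # dual averaging update
      da_count <- da_count + 1
      frac <- 1 / (da_count + t0)
      da_h <- (1 - frac) * da_h + frac * (target_accept - a_prob)
      logeps <- da_mu - sqrt(da_count) / gamma0 * da_h
      w <- da_count^(-kappa)
      da_logeps_bar <- w * logeps + (1 - w) * da_logeps_bar
      eps <- exp(logeps)
      if (it >= win_lo && it <= win_hi) win[it - win_lo + 1L, ] <- theta
      if (it == win_hi) {
        v <- apply(win[seq_len(it - win_lo + 1L), , drop = FALSE], 2, var)
        inv_mass <- pmax(v, 1e-6)
        # restart step-size adaptation under the new metric
        eps <- exp(da_logeps_bar)
        da_mu <- log(10 * eps); da_h <- 0; da_count <- 0
        da_logeps_bar <- log(eps)
      }
      if (it == warmup) eps <- exp(da_logeps_bar)
    } else {
      draws[it - warmup, ] <- theta
      lp_out[it - warmup] <- cur$lp
    }
  }
  list(draws = draws, lp = lp_out, accept = n_acc / keep)
}

find_reasonable_eps <- function(lp_fun, theta, cur, inv_mass) {
  eps <- 0.1
  p <- rnorm(length(theta), 0, sqrt(1 / inv_mass))
  h0 <- cur$lp - 0.5 * sum(p^2 * inv_mass)
  step_lp <- function(eps) {
    p1 <- p + 0.5 * eps * cur$grad
    th <- theta + eps * inv_mass * p1
    prop <- lp_fun(th)
    if (!is.finite(prop$lp)) return(-Inf)
    p1 <- p1 + 0.5 * eps * prop$grad
    prop$lp - 0.5 * sum(p1^2 * inv_mass) - h0
  }
  d <- step_lp(eps)
  dir <- if (is.finite(d) && d > log(0.5)) 1 else -1
  for (i in 1:20) {
    eps <- eps * 2^dir
    d <- step_lp(eps)
    if ((dir == 1 && !(is.finite(d) && d > log(0.5))) ||
        (dir == -1 && (is.finite(d) && d > log(0.5)))) break
  }
  eps
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Splits each chain in half and computes the potential scale reduction
#' factor from the within- and between-chain variances of the split halves.
#'
#' @param x Matrix of draws, iterations x chains (>= 2 chains' worth after
#'   splitting, >= 4 draws).
#' @return Rhat, or `NA` (with a warning) if the within-chain variance is 0.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 draws per chain")
  half <- floor(n / 2)
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, var)
  W <- mean(vars)
  if (W == 0) {
    warning("zero within-chain variance; Rhat undefined")
    return(NA_real_)
  }
  B <- half * var(means)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Highest density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' draws.
#'
#' @param samples Numeric draws.
#' @param mass Probability mass in (0, 1].
#' @return Named vector `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  stopifnot(length(samples) > 0, mass > 0, mass <= 1)
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(k + 1):n] - x[seq_len(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

#' Posterior mode of a marginal by kernel density
#'
#' The per-parameter MAP is the mode of the 1-D marginal posterior on the
#' constrained scale, located by a Gaussian KDE with Silverman's bandwidth.
#'
#' @param draws Numeric vector of >= 100 retained draws (constant vectors are
#'   returned as-is).
#' @param lower,upper Optional bounds to clamp the result into.
#' @return The estimated mode.
#' @export
extract_map <- function(draws, lower = -Inf, upper = Inf) {
  if (length(draws) < 100) stop("need at least 100 draws for a KDE mode")
  if (max(draws) - min(draws) < 1e-12) return(draws[1])
  d <- density(draws, bw = "nrd0")
  m <- d$x[which.max(d$y)]
  min(max(m, lower), upper)
}

# Constrained individual-parameter draws, ndraws_total x (S*J),
# columns subject-major matching the C++ layout.
individual_draws <- function(fit) {
  pn <- param_names(fit$model_id)
  J <- length(pn)
  C <- length(fit$prep$cohorts)
  S <- nrow(fit$prep$subjects)
  d <- fit$draws
  flat <- matrix(aperm(d, c(1, 2, 3)), nrow = dim(d)[1] * dim(d)[2],
                 dimnames = list(NULL, dimnames(d)[[3]]))
  out <- matrix(NA_real_, nrow(flat), S * J)
  cn <- character(S * J)
  for (s in seq_len(S)) {
    c_idx <- fit$prep$cohort_of_subj[s] + 1L
    for (j in seq_len(J)) {
      mu <- flat[, (c_idx - 1) * J + j]
      sigma <- exp(flat[, C * J + (c_idx - 1) * J + j])
      z <- flat[, 2 * C * J + (s - 1) * J + j]
      out[, (s - 1) * J + j] <- constrain_param(
        mu + sigma * z, fit$spec$bounds["lower", j], fit$spec$bounds["upper", j])
      cn[(s - 1) * J + j] <- sprintf("%s|%s", fit$prep$subjects$subject_id[s],
                                     pn[j])
    }
  }
  colnames(out) <- cn
  out
}

# Constrained cohort-location draws for one parameter: ndraws x n_cohorts.
cohort_location_draws <- function(fit, parameter) {
  pn <- param_names(fit$model_id)
  j <- match(parameter, pn)
  if (is.na(j)) stop("unknown parameter: ", parameter)
  J <- length(pn)
  d <- fit$draws
  flat <- matrix(d, nrow = dim(d)[1] * dim(d)[2])
  cols <- sapply(seq_along(fit$prep$cohorts), function(c_idx) (c_idx - 1) * J + j)
  out <- constrain_param(flat[, cols, drop = FALSE],
                         fit$spec$bounds["lower", j],
                         fit$spec$bounds["upper", j])
  colnames(out) <- fit$prep$cohorts
  out
}

#' Per-subject MAP table
#'
#' KDE modes of each subject's marginal posteriors on the constrained scale.
#'
#' @param fit An `hb_fit`.
#' @return Data frame `subject_id`, `cohort`, one column per parameter.
#' @export
map_table <- function(fit) {
  pn <- param_names(fit$model_id)
  J <- length(pn)
  ind <- individual_draws(fit)
  S <- nrow(fit$prep$subjects)
  maps <- matrix(NA_real_, S, J, dimnames = list(NULL, pn))
  for (s in seq_len(S)) {
    for (j in seq_len(J)) {
      maps[s, j] <- extract_map(ind[, (s - 1) * J + j],
                                fit$spec$bounds["lower", j],
                                fit$spec$bounds["upper", j])
    }
  }
  cbind(fit$prep$subjects, as.data.frame(maps))
}

#' Pairwise cohort-difference HDI report
#'
#' For every cohort pair, the posterior of the difference of cohort-level
#' locations on the constrained scale, its 95% HDI, and a credibility flag:
#' the HDI excludes 0, or an HDI endpoint lies within `margin` (parameter
#' units) of 0.
#'
#' @param fit An `hb_fit`.
#' @param parameter Parameter name.
#' @param mass HDI mass (default 0.95).
#' @param margin Near-exclusion margin in parameter units (default 0.05).
#' @return Data frame of pairs with difference mean, HDI, and flags.
#' @export
cohort_difference_report <- function(fit, parameter, mass = 0.95,
                                     margin = 0.05) {
  loc <- cohort_location_draws(fit, parameter)
  cohorts <- colnames(loc)
  if (length(cohorts) < 2) stop("need at least 2 cohorts")
  pairs <- utils::combn(cohorts, 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    diff <- loc[, a] - loc[, b]
    ci <- hdi(diff, mass)
    excludes <- ci["lower"] > 0 || ci["upper"] < 0
    near <- !excludes && min(abs(ci)) <= margin
    data.frame(cohort_a = a, cohort_b = b, parameter = parameter,
               mean_diff = mean(diff), hdi_lower = ci[["lower"]],
               hdi_upper = ci[["upper"]], excludes_zero = excludes,
               credible = excludes || near)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
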