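#' Specify a synthetic cohort of agents
#'
#' A cohort is a labelled group of simulated subjects whose behavioral
#' parameters are drawn from truncated normal distributions inside the model's
#' bounds, and whose button-press completion success is Bernoulli per option.
#'
#' @param label Cohort label.
#' @param n_subjects Number of agents.
#' @param model_id Generating model, one of [model_ids()].
#' @param param_means Named vector of parameter means on the constrained scale.
#' @param param_sds Named vector of spreads (>= 0), same names.
#' @param completion_prob_easy,completion_prob_hard Probability of completing
#'   the button-press requirement for each option. Defaults of 1 reflect a task
#'   calibrated so completion failures are negligible.
#' @param random_assign_prob Fraction of trials forced to a uniformly random
#'   option (no free choice); defaults to 0.
#' @param dist Population shape for parameter heterogeneity: `"truncnorm"`
#'   (default; `param_sds` on the constrained scale, draws truncated to the
#'   bounds) or `"logitnorm"` (draws from the hierarchical model's own
#'   population form: normal on the unconstrained logistic scale, centered at
#'   the unconstrained image of `param_means`, with `param_sds` read as
#'   unconstrained-scale SDs). Use `"logitnorm"` for coverage studies, which
#'   are only meaningful under a well-specified population.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(label, n_subjects, model_id, param_means, param_sds,
                        completion_prob_easy = 1, completion_prob_hard = 1,
                        random_assign_prob = 0,
                        dist = c("truncnorm", "logitnorm")) {
  dist <- match.arg(dist)
  model_id <- match.arg(model_id, model_ids())
  b <- param_bounds(model_id)
  pn <- param_names(model_id)
  param_means <- param_means[pn]
  param_sds <- param_sds[pn]
  if (anyNA(param_means) || anyNA(param_sds)) {
    stop("param_means/param_sds must name every parameter of ", model_id)
  }
  check_in_bounds(param_means, b)
  if (any(param_sds < 0)) stop("param_sds must be >= 0")
  stopifnot(completion_prob_easy >= 0, completion_prob_easy <= 1,
            completion_prob_hard >= 0, completion_prob_hard <= 1,
            random_assign_prob >= 0, random_assign_prob <= 1)
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 model_id = model_id, param_means = param_means,
                 param_sds = param_sds, dist = dist,
                 completion_prob_easy = completion_prob_easy,
                 completion_prob_hard = completion_prob_hard,
                 random_assign_prob = random_assign_prob),
            class = "cohort_spec")
}

# truncated-normal draw by rejection inside (lo, hi); sd 0 returns the mean
rtruncnorm_bounded <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), mean, sd)
    ok <- x > lo & x < hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Draw agent parameters for a cohort
#'
#' @param spec A [cohort_spec()].
#' @param rng_seed Integer seed.
#' @param id_prefix Prefix for subject ids.
#' @return A data frame with `subject_id`, `cohort`, `model_id`, and one
#'   column per model parameter (true values on the constrained scale).
#' @export
draw_cohort_agents <- function(spec, rng_seed = NULL, id_prefix = spec$label) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  b <- param_bounds(spec$model_id)
  pars <- sapply(param_names(spec$model_id), function(p) {
    if (identical(spec$dist, "logitnorm")) {
      m_u <- unconstrain_param(spec$param_means[[p]], b["lower", p],
                               b["upper", p])
      constrain_param(rnorm(spec$n_subjects, m_u, spec$param_sds[[p]]),
                      b["lower", p], b["upper", p])
    } else {
      rtruncnorm_bounded(spec$n_subjects, spec$param_means[[p]],
                         spec$param_sds[[p]], b["lower", p], b["upper", p])
    }
  })
  pars <- matrix(pars, nrow = spec$n_subjects,
                 dimnames = list(NULL, param_names(spec$model_id)))
  cbind(
    data.frame(
      subject_id = sprintf("%s_%03d", id_prefix, seq_len(spec$n_subjects)),
      cohort = spec$label, model_id = spec$model_id,
      stringsAsFactors = FALSE
    ),
    as.data.frame(pars)
  )
}

#' Simulate one subject's EEfRT session
#'
#' Each trial: the choice is sampled from the agent's softmax choice
#' probability (TDRL agents update their Q-values online from realized
#' payoffs); with probability `random_assign_prob` the trial is instead a
#' forced uniform assignment; completion is Bernoulli given the chosen option;
#' a completed trial is rewarded with the trial's probability level; the
#' payoff is the chosen option's magnitude if rewarded, else 0.
#'
#' @param params Named parameter vector for the agent.
#' @param model_id Generating model.
#' @param trials A trial-spec data frame from [generate_trial_sequence()].
#' @param completion_probs Named vector `c(easy = , hard = )`.
#' @param random_assign_prob Forced-trial fraction.
#' @param subject_id,cohort Labels written into the session rows.
#' @param rng_seed Integer seed; the session is deterministic given the seed.
#' @return A session table (one row per trial).
#' @export
simulate_session <- function(params, model_id, trials,
                             completion_probs = c(easy = 1, hard = 1),
                             random_assign_prob = 0,
                             subject_id = "S001", cohort = "synthetic",
                             rng_seed = NULL) {
  model_id <- match.arg(model_id, model_ids())
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- nrow(trials)
  beta <- params[["beta"]]
  q <- q_init()
  choice <- character(n)
  random_assigned <- integer(n)
  completed <- integer(n)
  rewarded <- integer(n)
  payoff <- numeric(n)
  for (t in seq_len(n)) {
    if (model_id == "full_sv") {
      ve <- sv_full(trials$easy_magnitude[t], trials$prob_level[t],
                    trials$easy_effort[t], params[["k"]], params[["h"]])
      vh <- sv_full(trials$hard_magnitude[t], trials$prob_level[t],
                    trials$hard_effort[t], params[["k"]], params[["h"]])
    } else if (model_id == "reward_only") {
      ve <- sv_reward_only(trials$easy_magnitude[t], trials$easy_effort[t],
                           params[["k"]])
      vh <- sv_reward_only(trials$hard_magnitude[t], trials$hard_effort[t],
                           params[["k"]])
    } else {
      ve <- q["easy", 1]
      vh <- q["hard", 1]
    }
    forced <- runif(1) < random_assign_prob
    p_hard <- if (forced) 0.5 else softmax_prob(vh, ve, beta)
    ch <- if (runif(1) < p_hard) "hard" else "easy"
    choice[t] <- ch
    random_assigned[t] <- as.integer(forced)
    completed[t] <- rbinom(1, 1, completion_probs[[ch]])
    rewarded[t] <- if (completed[t]) rbinom(1, 1, trials$prob_level[t]) else 0L
    payoff[t] <- if (rewarded[t]) {
      if (ch == "hard") trials$hard_magnitude[t] else trials$easy_magnitude[t]
    } else 0
    if (model_id == "tdrl") {
      q <- tdrl_trial_update(q, ch, payoff[t], params[["alpha"]],
                             params[["gamma"]])$q
    }
  }
  data.frame(
    subject_id = subject_id, cohort = cohort,
    trial_index = trials$trial_index, prob_level = trials$prob_level,
    easy_magnitude = trials$easy_magnitude,
    hard_magnitude = trials$hard_magnitude,
    choice = choice, random_assigned = random_assigned,
    completed = completed, rewarded = rewarded, payoff = payoff,
    stringsAsFactors = FALSE
  )
}

#' Default synthetic study: four cohorts of TDRL agents
#'
#' Cohort sizes mirror a four-group tobacco/opioid study design (23/22/26/29
#' subjects). Parameter locations are plausible adult values with moderate
#' heterogeneity; differences across cohorts are modest, with the dual-use
#' cohort showing the steepest temporal discounting and the noisiest policy.
#'
#' @return A list of four [cohort_spec()] objects.
#' @export
default_study_cohorts <- function() {
  sds <- c(alpha = 0.10, gamma = 0.12, beta = 1.0)
  list(
    cohort_spec("NeverTUD", 23, "tdrl",
                c(alpha = 0.35, gamma = 0.70, beta = 5.0), sds),
    cohort_spec("FormerTUD", 22, "tdrl",
                c(alpha = 0.30, gamma = 0.45, beta = 2.5), sds),
    cohort_spec("CurrentTUD", 26, "tdrl",
                c(alpha = 0.38, gamma = 0.65, beta = 4.5), sds),
    cohort_spec("TUD_OUD", 29, "tdrl",
                c(alpha = 0.25, gamma = 0.55, beta = 2.0), sds)
  )
}

#' Recovery-benchmark cohorts
#'
#' Four identically distributed, broadly dispersed TDRL cohorts for
#' parameter-recovery studies: every agent's parameters are drawn from the
#' same wide truncated normals (learning rate 0.45 +/- 0.18, discount
#' 0.60 +/- 0.15, inverse temperature 4 +/- 2), so that recovery is judged on
#' individual variation rather than on cohort-mean geometry. Recovery studies
#' sample the plausible parameter range; the study-emulating defaults in
#' [default_study_cohorts()] intentionally vary much less and are not suited
#' to ranking individuals.
#'
#' @return A list of four [cohort_spec()] objects (20 agents each).
#' @export
recovery_study_cohorts <- function() {
  sds <- c(alpha = 0.18, gamma = 0.15, beta = 2.0)
  mns <- c(alpha = 0.45, gamma = 0.60, beta = 4.0)
  lapply(paste0("R", 1:4), function(l) cohort_spec(l, 20, "tdrl", mns, sds))
}

#' Simulate a whole multi-cohort study
#'
#' One session per agent, each with its own freshly generated trial sequence.
#'
#' @param cohorts List of [cohort_spec()] objects.
#' @param n_trials Trials per session (default 50).
#' @param rng_seed Master seed; all draws derive from it.
#' @return A list with `sessions` (session table for all agents) and `truth`
#'   (long table `subject_id`, `cohort`, `model_id`, `param_name`,
#'   `true_value`).
#' @export
simulate_study <- function(cohorts, n_trials = 50L, rng_seed = 1L) {
  if (!length(cohorts)) stop("at least one cohort required")
  set.seed(rng_seed)
  sessions <- list()
  truth <- list()
  for (spec in cohorts) {
    agents <- draw_cohort_agents(spec)
    pn <- param_names(spec$model_id)
    for (i in seq_len(nrow(agents))) {
      trials <- generate_trial_sequence(n_trials)
      pars <- unlist(agents[i, pn])
      sessions[[agents$subject_id[i]]] <- simulate_session(
        pars, spec$model_id, trials,
        completion_probs = c(easy = spec$completion_prob_easy,
                             hard = spec$completion_prob_hard),
        random_assign_prob = spec$random_assign_prob,
        subject_id = agents$subject_id[i], cohort = spec$label
      )
      truth[[agents$subject_id[i]]] <- data.frame(
        subject_id = agents$subject_id[i], cohort = spec$label,
        model_id = spec$model_id, param_name = pn,
        true_value = as.numeric(pars), stringsAsFactors = FALSE
      )
    }
  }
  list(sessions = do.call(rbind, c(sessions, make.row.names = FALSE)),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Labeled multivariate-normal parameter vectors
#'
#' Fixture generator for the classification stage: per-group three-vectors
#' (learning-rate, discount, temperature proxies) drawn from multivariate
#' normals with given means and covariances.
#'
#' @param group_means List of numeric vectors (equal length d).
#' @param group_covs List of d x d covariance matrices (recycled if one).
#' @param ns Integer vector of group sizes.
#' @param rng_seed Integer seed.
#' @param labels Optional group labels (default G1, G2, ...).
#' @return Data frame with a `label` column and `d` feature columns.
#' @export
make_labeled_vectors <- function(group_means, group_covs, ns, rng_seed = 1L,
                                 labels = NULL) {
  g <- length(group_means)
  if (length(group_covs) == 1) group_covs <- rep(group_covs, g)
  if (length(group_covs) != g || length(ns) != g) {
    stop("group_means, group_covs and ns must have equal length")
  }
  d <- length(group_means[[1]])
  for (i in seq_len(g)) {
    if (length(group_means[[i]]) != d || !all(dim(group_covs[[i]]) == d)) {
      stop("dimension mismatch between means and covariances")
    }
  }
  if (is.null(labels)) labels <- paste0("G", seq_len(g))
  set.seed(rng_seed)
  out <- lapply(seq_len(g), function(i) {
    x <- MASS::mvrnorm(ns[i], group_means[[i]], group_covs[[i]])
    x <- matrix(x, nrow = ns[i])
    df <- as.data.frame(x)
    names(df) <- paste0("v", seq_len(d))
    cbind(data.frame(label = labels[i], stringsAsFactors = FALSE), df)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
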