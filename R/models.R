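#' Subjective value of an option (full model)
#'
#' Reward magnitude scaled by the probability of payout raised to a weighting
#' exponent, minus an effort cost: `R * P^h - k * E`.
#'
#' @param reward Reward magnitude in dollars.
#' @param prob Reward probability.
#' @param effort Effort cost of the option (0.3 easy, 1.0 hard).
#' @param k Effort-discount weight in (0, 10).
#' @param h Probability weight in (0, 10).
#' @return Subjective value (vectorized over trials).
#' @export
sv_full <- function(reward, prob, effort, k, h) {
  check_in_bounds(c(k = k, h = h), param_bounds("full_sv")[, c("k", "h")])
  reward * prob^h - k * effort
}

#' Subjective value of an option (reward-only model)
#'
#' Reward magnitude minus an effort cost, ignoring probability: `R - k * E`.
#'
#' @inheritParams sv_full
#' @return Subjective value (vectorized over trials).
#' @export
sv_reward_only <- function(reward, effort, k) {
  check_in_bounds(c(k = k), param_bounds("reward_only")[, "k", drop = FALSE])
  reward - k * effort
}

#' Softmax choice probability
#'
#' Probability of choosing option 1 given two values and an inverse
#' temperature: `exp(b v1) / (exp(b v1) + exp(b v2))`, computed by subtracting
#' the larger value before exponentiating so it is stable for large `beta`.
#' `beta = 0` yields 0.5 regardless of the values.
#'
#' @param v1,v2 Values of the two options (vectorized).
#' @param beta Inverse temperature, >= 0.
#' @return Probability of option 1, in (0, 1).
#' @export
softmax_prob <- function(v1, v2, beta) {
  if (!all(is.finite(v1)) || !all(is.finite(v2)) || !all(is.finite(beta))) {
    stop("softmax_prob requires finite inputs")
  }
  if (any(beta < 0)) stop("beta must be >= 0")
  x1 <- beta * v1
  x2 <- beta * v2
  m <- pmax(x1, x2)
  e1 <- exp(x1 - m)
  e1 / (e1 + exp(x2 - m))
}

#' A fresh action-value state for the TDRL model
#'
#' Each action (easy, hard) owns a chain of three values over the within-trial
#' time points (options presented; action taken; outcome presented), all
#' initialized to 0 dollars.
#'
#' @return A 2 x 3 numeric matrix, rows `easy`/`hard`, columns `s1`..`s3`.
#' @export
q_init <- function() {
  matrix(0, 2, 3, dimnames = list(c("easy", "hard"), c("s1", "s2", "s3")))
}

#' One TDRL trial update
#'
#' Applies the temporal-difference update sequentially along the chosen
#' action's chain of three time points. The prediction error at point `i` is
#' `outcome_i + gamma * Q(s_{i+1}) - Q(s_i)`, where the outcome is 0 at the
#' first two points and the realized payoff at the third, and the successor
#' value beyond the third point is 0 (terminal). Each error updates its own
#' state value (`Q <- Q + alpha * delta`) before the next error is computed.
#' The unchosen action's chain is untouched.
#'
#' @param q A 2 x 3 Q-value matrix as from [q_init()].
#' @param action `"easy"` or `"hard"`.
#' @param outcome_payoff Realized payoff in dollars (0 if no reward).
#' @param alpha Learning rate in (0, 1).
#' @param gamma Temporal discount in (0, 1).
#' @return A list with the updated `q` and the three prediction errors
#'   `deltas`.
#' @export
tdrl_trial_update <- function(q, action, outcome_payoff, alpha, gamma) {
  check_in_bounds(c(alpha = alpha, gamma = gamma),
                  param_bounds("tdrl")[, c("alpha", "gamma")])
  a <- match.arg(action, c("easy", "hard"))
  d <- numeric(3)
  d[1] <- gamma * q[a, 2] - q[a, 1]
  q[a, 1] <- q[a, 1] + alpha * d[1]
  d[2] <- gamma * q[a, 3] - q[a, 2]
  q[a, 2] <- q[a, 2] + alpha * d[2]
  d[3] <- outcome_payoff - q[a, 3]
  q[a, 3] <- q[a, 3] + alpha * d[3]
  list(q = q, deltas = d)
}

check_in_bounds <- function(values, bounds) {
  bounds <- as.matrix(bounds)
  for (j in seq_along(values)) {
    if (!is.finite(values[j]) || values[j] <= bounds[1, j] ||
        values[j] >= bounds[2, j]) {
      stop(sprintf("parameter %s = %g outside open bounds (%g, %g)",
                   names(values)[j], values[j], bounds[1, j], bounds[2, j]))
    }
  }
  invisible(TRUE)
}

# Internal: one subject's rows -> the parallel vectors the C++ core expects.
session_arrays <- function(session) {
  list(
    choice = as.integer(session$choice == "hard"),
    prob = as.numeric(session$prob_level),
    easy_mag = as.numeric(session$easy_magnitude),
    hard_mag = as.numeric(session$hard_magnitude),
    random_assigned = as.integer(session$random_assigned),
    payoff = as.numeric(session$payoff)
  )
}

#' Log-likelihood of one subject's choices under a model
#'
#' For the subjective-value models, each freely made choice contributes the
#' log softmax probability of the chosen option's subjective value against the
#' alternative. For the TDRL model the choice probability comes from a softmax
#' over the two first-time-point Q-values, after which the trial's realized
#' payoff drives the Q update. Forced (random-assigned) trials are included in
#' the value updates but excluded from the log-likelihood sum.
#'
#' @param model_id One of [model_ids()].
#' @param params Named parameter vector (see [param_bounds()]); `beta = 0` is
#'   accepted for degenerate-policy checks.
#' @param session One subject's rows of a session table, in trial order.
#' @return A list with `loglik` and `n_evaluated` (likelihood-bearing trials).
#' @export
session_loglik <- function(model_id, params, session) {
  model_id <- match.arg(model_id, model_ids())
  if (nrow(session) == 0) stop("empty session")
  b <- param_bounds(model_id)
  params <- params[param_names(model_id)]
  if (anyNA(params)) stop("missing parameters for ", model_id)
  # beta = 0 allowed (degenerate temperature); others must be interior
  interior <- setdiff(param_names(model_id), "beta")
  check_in_bounds(params[interior], b[, interior, drop = FALSE])
  if (params[["beta"]] < 0 || params[["beta"]] >= b["upper", "beta"]) {
    stop("beta outside [0, 100)")
  }
  a <- session_arrays(session)
  res <- cpp_session_loglik(model_code(model_id), as.numeric(params),
                            a$choice, a$prob, a$easy_mag, a$hard_mag,
                            a$random_assigned, a$payoff)
  list(loglik = res$loglik, n_evaluated = res$n_evaluated)
}
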