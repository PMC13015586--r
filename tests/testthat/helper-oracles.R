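# Independent brute-force oracles, written directly from the model equations
# with none of the package's numerical shortcuts.

oracle_softmax <- function(v1, v2, beta) {
  exp(v1 * beta) / (exp(v1 * beta) + exp(v2 * beta))
}

# Plain-R trial-by-trial trace of a session log-likelihood.
oracle_session_loglik <- function(model_id, params, session) {
  ll <- 0
  n_eval <- 0L
  q <- matrix(0, 2, 3, dimnames = list(c("easy", "hard"), NULL))
  for (t in seq_len(nrow(session))) {
    row <- session[t, ]
    if (model_id == "full_sv") {
      ve <- row$easy_magnitude * row$prob_level^params[["h"]] -
        params[["k"]] * 0.3
      vh <- row$hard_magnitude * row$prob_level^params[["h"]] -
        params[["k"]] * 1.0
    } else if (model_id == "reward_only") {
      ve <- row$easy_magnitude - params[["k"]] * 0.3
      vh <- row$hard_magnitude - params[["k"]] * 1.0
    } else {
      ve <- q["easy", 1]
      vh <- q["hard", 1]
    }
    if (row$random_assigned == 0) {
      p_chosen <- if (row$choice == "hard") {
        oracle_softmax(vh, ve, params[["beta"]])
      } else {
        oracle_softmax(ve, vh, params[["beta"]])
      }
      ll <- ll + as.numeric(log(p_chosen))
      n_eval <- n_eval + 1L
    }
    if (model_id == "tdrl") {
      a <- row$choice
      d1 <- params[["gamma"]] * q[a, 2] - q[a, 1]
      q[a, 1] <- q[a, 1] + params[["alpha"]] * d1
      d2 <- params[["gamma"]] * q[a, 3] - q[a, 2]
      q[a, 2] <- q[a, 2] + params[["alpha"]] * d2
      d3 <- row$payoff - q[a, 3]
      q[a, 3] <- q[a, 3] + params[["alpha"]] * d3
    }
  }
  list(loglik = ll, n_evaluated = n_eval)
}

# Direct split-Rhat from the textbook formula.
oracle_split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  chains <- cbind(x[1:half, ], x[(n - half + 1):n, ])
  m <- ncol(chains)
  mbar <- colMeans(chains)
  B <- half / (m - 1) * sum((mbar - mean(mbar))^2)
  W <- mean(apply(chains, 2, var))
  sqrt(((half - 1) / half * W + B / half) / W)
}

# A tiny deterministic session table for serialization/filter tests.
toy_sessions <- function(n_subjects = 3, n_trials = 55, seed = 42) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    tr <- generate_trial_sequence(n_trials)
    simulate_session(c(k = 1, beta = 2), "reward_only", tr,
                     random_assign_prob = 0.1,
                     subject_id = sprintf("S%02d", i), cohort = "toy")
  }))
}
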