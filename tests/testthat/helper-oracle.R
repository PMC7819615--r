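# Independent oracles used across tests.
#
# oracle_response(): exhaustive path enumeration of the release/timeout
# distribution under the true-stimulus kernel — walks every evidence
# trajectory, branching on release, timeout and evidence steps, and sums
# complete-path probabilities.  Feasible on tiny lattices.
#
# oracle_Q(): expected outcome of STAY-then-follow-policy from a state,
# by direct recursive expectation over the subjective chain (timeout value
# from the belief posterior; belief-averaged evidence steps).  Independent
# of the backward-induction implementation, which computes all states in
# one sweep.

oracle_response <- function(mu, theta, R, L, delta, n, params, disc) {
  tb <- jbpomdp:::build_model_tables(params["sigma"], params["zeta"],
                                     params["phi"], disc)
  lat <- value_recursion(R, L, delta, n, params, disc, theta_true = theta,
                         tables = tb)
  Ktrue <- tb$kernels[, , jbpomdp:::kernel_index(mu, theta, tb$thetas)]
  h <- tb$hazard
  S <- disc$n_states
  prel <- numeric(disc$T)
  pto <- 0
  recurse <- function(t, j, prob) {
    if (prob <= 0) return()
    if (t == disc$T) { pto <<- pto + prob; return() }  # forced timeout
    pi_t <- lat$pi[t + 1, j]
    prel[t + 1] <<- prel[t + 1] + prob * (1 - pi_t)
    pstay <- prob * pi_t
    pto <<- pto + pstay * h[t + 1]
    surv <- pstay * (1 - h[t + 1])
    for (j2 in seq_len(S))
      if (Ktrue[j, j2] > 0) recurse(t + 1, j2, surv * Ktrue[j, j2])
  }
  recurse(0, disc$K + 1, 1)
  list(p_release = prel, p_timeout = pto)
}

oracle_Q <- function(R, L, delta, n, params, disc, theta_true) {
  tb <- jbpomdp:::build_model_tables(params["sigma"], params["zeta"],
                                     params["phi"], disc)
  lat <- value_recursion(R, L, delta, n, params, disc,
                         theta_true = theta_true, tables = tb)
  Vt <- R * tb$P1 + L * (1 - tb$P1)
  h <- tb$hazard
  S <- disc$n_states
  q_rec <- function(t, j) {
    val <- h[t + 1] * Vt[t + 1, j]
    cont <- 0
    for (j2 in seq_len(S)) {
      m <- tb$M[j, j2, t + 1]
      if (m > 0) {
        v2 <- if (t + 1 == disc$T) Vt[disc$T + 1, j2]
              else lat$pi[t + 2, j2] * q_rec(t + 1, j2)
        cont <- cont + m * v2
      }
    }
    val + (1 - h[t + 1]) * cont
  }
  Q <- matrix(NA_real_, disc$T, S)
  for (t in 0:(disc$T - 1)) for (j in seq_len(S)) Q[t + 1, j] <- q_rec(t, j)
  list(Q = Q, lat = lat)
}

# a small session fixture shared across tests (simulated once per run)
fixture_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sch <- jb_schedule("fluctuating_reward", seed = 42, n_test = 90L)
      cache <<- list(schedule = sch,
                     session = simulate_session(sch, jb_default_truth(),
                                                jb_disc(), seed = 43))
    }
    cache
  }
})

# random valid parameter draw within the optimisation box
random_params <- function() {
  jb_params(sigma = stats::runif(1, 0.05, 0.8),
            lambda_amb = stats::runif(1, 0, 0.4),
            lambda_ref = stats::runif(1, 0, 0.4),
            B = stats::runif(1, 0.1, 6),
            zeta = stats::runif(1, 0.5, 15),
            phi = stats::runif(1, 0.05, 2),
            beta0 = stats::runif(1, -2, 2),
            betaR = stats::runif(1, -0.5, 0.5),
            betaO = stats::runif(1, -0.1, 0.1),
            alphaR = stats::runif(1, 0, 1),
            gammaPE = stats::runif(1, 0, 0.95))
}
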