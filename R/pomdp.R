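#' Gamma-hazard timeout probabilities
#'
#' Per-bin probability that the trial subjectively times out, derived from a
#' gamma-distributed subjective stay time with shape `zeta` and scale `phi`:
#' `P_t;timeout = [F((t+1) dt) - F(t dt)] / [1 - F(t dt)]` for `t < T`, where
#' `F` is the gamma cdf.  An actual timeout is imposed at the end of the
#' trial by fiat, so the terminal entry is 1.
#'
#' @param zeta,phi Gamma shape and scale (> 0).
#' @param disc A [jb_disc()] discretisation.
#' @return Numeric vector of length `T + 1`: entries for `t = 0..T-1` from
#'   the hazard formula, last entry exactly 1.
#' @examples
#' h <- jb_hazard(8, 0.3, jb_disc())
#' h[length(h)]  # 1 by fiat
#' @export
jb_hazard <- function(zeta, phi, disc) {
  if (zeta <= 0 || phi <= 0) stop("zeta and phi must be > 0")
  t_edges <- (0:disc$T) * disc$dt
  # survivor function via the upper tail: [F(t+1)-F(t)]/[1-F(t)] = 1 - S(t+1)/S(t)
  # stays accurate when the cdf is within rounding of 1
  surv <- stats::pgamma(t_edges, shape = zeta, scale = phi, lower.tail = FALSE)
  h <- numeric(disc$T + 1)
  sat <- surv[1:disc$T] == 0
  if (any(sat)) {
    warning("gamma cdf numerically saturated before end of trial; hazard clipped to 1")
    h[1:disc$T][sat] <- 1
  }
  ok <- !sat
  h[1:disc$T][ok] <- 1 - surv[2:(disc$T + 1)][ok] / surv[1:disc$T][ok]
  h[1:disc$T] <- pmin(pmax(h[1:disc$T], 0), 1)
  h[disc$T + 1] <- 1
  h
}

#' Posterior log-odds that the stimulus is favourable
#'
#' Closed form of the evidence-accumulation equation: the log-odds of the
#' favourable direction after observing summed evidence `X_sum` at coherence
#' `theta` is the prior log-odds plus `2 * theta / sigma^2 * X_sum`.
#'
#' @param prior_odds Log prior odds of `mu = +1`.
#' @param theta Stimulus coherence.
#' @param sigma Observation noise sd (> 0).
#' @param X_sum Accumulated evidence.
#' @return The posterior log-odds (numeric).
#' @examples
#' log_posterior_odds(0, 0.16, 1, 2)  # 0.64
#' @export
log_posterior_odds <- function(prior_odds, theta, sigma, X_sum) {
  if (sigma <= 0) stop("sigma must be > 0")
  prior_odds + 2 * theta / sigma^2 * X_sum
}

# Default coherence support of the observer's prior: the test-block levels.
jb_thetas <- function() c(0.01, 0.02, 0.16)

#' Evidence transition kernel for a known stimulus
#'
#' Row-stochastic matrix over the evidence grid for one time bin given the
#' true stimulus `(mu, theta)`.  Per-bin increments are Gaussian with mean
#' `mu * theta * dt` and sd `sigma * sqrt(dt)`, binned to the grid; the
#' extreme bins absorb the tail mass so every row sums to 1.
#'
#' @param mu Stimulus direction, +1 (favourable) or -1.
#' @param theta Stimulus coherence.
#' @param sigma Observation noise sd.
#' @param disc A [jb_disc()] discretisation.
#' @return A `(2K+1) x (2K+1)` row-stochastic matrix; rows index the current
#'   evidence state, columns the next.
#' @export
evidence_transitions <- function(mu, theta, sigma, disc) {
  if (!mu %in% c(-1, 1)) stop("mu must be -1 or +1")
  chi <- disc_chi(disc, sigma)
  K <- disc$K
  m <- mu * theta * disc$dt
  s <- sigma * sqrt(disc$dt)
  j <- -K:K
  # breaks between target bins j' and j'+1 sit at increment (j' + 0.5 - j) * chi
  breaks <- outer(j, (-K:(K - 1)) + 0.5, function(from, to) (to - from) * chi)
  cdf <- stats::pnorm(breaks, mean = m, sd = s)
  n <- 2 * K
  P <- cbind(cdf[, 1], cdf[, 2:n] - cdf[, 1:(n - 1)], 1 - cdf[, n])
  dimnames(P) <- NULL
  P
}

#' Posterior belief over stimulus identity at a lattice state
#'
#' Posterior `P(mu, theta | t, X)` over the six `(direction, coherence)`
#' cells, from symmetric direction priors, a uniform prior over the three
#' test coherences, and the Gaussian marginal `X ~ N(mu * theta * t * dt,
#' sigma^2 * t * dt)`.  At `t = 0` the prior is returned exactly.
#'
#' @param t Time bin, `0..T`.
#' @param X Evidence value (a grid point, though any numeric is accepted).
#' @param sigma Observation noise sd.
#' @param disc A [jb_disc()] discretisation.
#' @param thetas Coherence support of the prior.
#' @return A `2 x length(thetas)` matrix of posterior masses; rows named
#'   `"mu=-1"`, `"mu=+1"`, columns by coherence.  Sums to 1.
#' @export
belief_posterior <- function(t, X, sigma, disc, thetas = jb_thetas()) {
  stopifnot(t >= 0, t <= disc$T)
  nt <- length(thetas)
  if (t == 0) {
    post <- matrix(1 / (2 * nt), 2, nt)
  } else {
    tau <- t * disc$dt
    logd <- sapply(thetas, function(th)
      c(stats::dnorm(X, -th * tau, sigma * sqrt(tau), log = TRUE),
        stats::dnorm(X, +th * tau, sigma * sqrt(tau), log = TRUE)))
    logd <- logd - max(logd)
    w <- exp(logd)
    post <- w / sum(w)
  }
  dimnames(post) <- list(c("mu=-1", "mu=+1"), paste0("theta=", thetas))
  post
}

# Belief tables for all (t, X): list with
#   P1:  (T+1) x S matrix of P(mu = +1 | t, X)
#   W:   S x (2*nt) x (T+1) array of posterior weights, cells ordered
#        (mu=-1, theta_1..nt, mu=+1, theta_1..nt)
belief_tables <- function(sigma, disc, thetas = jb_thetas()) {
  S <- disc$n_states
  grid <- disc_grid(disc, sigma)
  nt <- length(thetas)
  W <- array(NA_real_, c(S, 2 * nt, disc$T + 1))
  W[, , 1] <- 1 / (2 * nt)
  mus <- rep(c(-1, 1), each = nt)
  ths <- rep(thetas, 2)
  tau <- (1:disc$T) * disc$dt
  # log density of X = grid[x] under each (mu, theta) cell at each t > 0
  for (k in seq_len(2 * nt)) {
    W[, k, -1] <- stats::dnorm(matrix(grid, S, disc$T),
                               mean = matrix(mus[k] * ths[k] * tau, S, disc$T,
                                             byrow = TRUE),
                               sd = matrix(sigma * sqrt(tau), S, disc$T,
                                           byrow = TRUE), log = TRUE)
  }
  for (t in 2:(disc$T + 1)) {
    logd <- W[, , t]
    logd <- logd - logd[cbind(seq_len(S), max.col(logd))]
    w <- exp(logd)
    W[, , t] <- w / rowSums(w)
  }
  P1 <- t(apply(W, 3, function(w) rowSums(w[, (nt + 1):(2 * nt), drop = FALSE])))
  list(P1 = P1, W = W, thetas = thetas, grid = grid)
}

# All model tables needed by the recursions, for one sigma / zeta / phi.
#   kernels: S x S x (2*nt) evidence kernels, slice order matching belief W
#   M:       S x S x T belief-averaged subjective evidence kernels (t = 0..T-1)
#   hazard:  length T+1
build_model_tables <- function(sigma, zeta, phi, disc, thetas = jb_thetas()) {
  S <- disc$n_states
  nt <- length(thetas)
  bt <- belief_tables(sigma, disc, thetas)
  kernels <- array(NA_real_, c(S, S, 2 * nt))
  for (k in seq_len(nt)) {
    Kp <- evidence_transitions(+1, thetas[k], sigma, disc)
    kernels[, , nt + k] <- Kp
    kernels[, , k] <- Kp[S:1, S:1]   # mu = -1 kernel mirrors the +1 kernel
  }
  M <- cpp_mix_kernels(kernels, bt$W, disc$T)
  # hazard warnings are for direct callers; fitting objectives and simulators
  # probe degenerate (zeta, phi) routinely and handle the clipped hazard
  hz <- suppressWarnings(jb_hazard(zeta, phi, disc))
  list(kernels = kernels, M = M, P1 = bt$P1, W = bt$W, hazard = hz,
       thetas = thetas, grid = bt$grid, sigma = sigma, disc = disc)
}

# index of a (mu, theta) pair into the kernel/belief cell order
kernel_index <- function(mu, theta, thetas = jb_thetas()) {
  k <- match(theta, thetas)
  if (is.na(k)) stop("theta ", theta, " not in the observer's coherence support")
  if (mu == 1) length(thetas) + k else k
}

#' Subjective transition distribution from a lattice state
#'
#' Mixture of the evidence kernels over `(mu, theta)` weighted by the
#' posterior belief at `(t, X)`, scaled by the survival probability
#' `1 - P_t;timeout`, plus mass `P_t;timeout` on the timeout state.
#'
#' @param t Time bin, `0..T-1`.
#' @param X_index Index of the evidence state on the grid (1..2K+1).
#' @param tables Model tables from the lattice builder (internal); supply
#'   `params` and `disc` instead for a one-off call.
#' @param params,disc Used to build tables when `tables` is `NULL`.
#' @return A list with `p_timeout` (scalar) and `p_next` (length `2K+1`
#'   vector over next evidence states); masses sum to 1.
#' @export
subjective_transition <- function(t, X_index, params = NULL, disc = NULL,
                                  tables = NULL) {
  if (is.null(tables))
    tables <- build_model_tables(params["sigma"], params["zeta"], params["phi"], disc)
  disc <- tables$disc
  stopifnot(t >= 0, t < disc$T, X_index >= 1, X_index <= disc$n_states)
  h <- tables$hazard[t + 1]
  list(p_timeout = h, p_next = (1 - h) * tables$M[X_index, , t + 1])
}

#' Backward-induction values and policy for one trial
#'
#' Solves the Bellman recursion on the belief lattice for a trial with
#' offered reward `R`, threatened loss `L` (`<= 0`), bias `delta` and trial
#' index `n`.  `Q(s, GO) = 0` everywhere; `Q(s, STAY)` mixes the timeout
#' value `R * P(mu=+1|s) + L * P(mu=-1|s)` with the expected continuation
#' value under the policy
#' `pi(s, STAY) = lambda/2 + (1 - lambda) * plogis(B * (Q + delta - n * beta_n))`.
#' Decisions occur at bins `t = 0..T-1`; mass still holding at `t = T` times
#' out by fiat.  No discounting.
#'
#' @param R Offered reward (>= 0, GBP).
#' @param L Threatened loss (<= 0, GBP).
#' @param delta Trial bias.
#' @param n Trial index within the test block (enters as `-n * beta_n`).
#' @param params A [jb_params()] vector.
#' @param disc A [jb_disc()] discretisation.
#' @param theta_true True coherence of the trial; selects the lapse rate
#'   (ambiguous vs reference class) used throughout the trial's policy.
#' @param tables Optional precomputed model tables (internal reuse).
#' @return An object of class `"jb_lattice"`: list with `Q` (`(T+1) x S`;
#'   row `t = T` holds the forced-timeout value), `pi` (`T x S` stay
#'   probabilities), `V` (`(T+1) x S` state values), `V00` (value of the
#'   start state), `hazard`, `grid`, and the call ingredients.
#' @export
value_recursion <- function(R, L, delta, n, params, disc, theta_true = 0.01,
                            tables = NULL) {
  validate_params(params)
  if (R < 0 || L > 0) stop("need R >= 0 and L <= 0 (losses are negative)")
  if (is.null(tables))
    tables <- build_model_tables(params["sigma"], params["zeta"], params["phi"], disc)
  disc <- tables$disc
  S <- disc$n_states
  lam <- lapse_for_theta(params, theta_true)
  B <- unname(params["B"])
  drive <- delta - n * unname(params["beta_n"])
  h <- tables$hazard
  Vtime <- R * tables$P1 + L * (1 - tables$P1)  # (T+1) x S

  Q <- matrix(NA_real_, disc$T + 1, S)
  Pi <- matrix(NA_real_, disc$T, S)
  V <- matrix(NA_real_, disc$T + 1, S)
  Q[disc$T + 1, ] <- Vtime[disc$T + 1, ]   # forced timeout at t = T
  V[disc$T + 1, ] <- Vtime[disc$T + 1, ]
  for (t in (disc$T - 1):0) {
    q <- h[t + 1] * Vtime[t + 1, ] +
      (1 - h[t + 1]) * as.vector(tables$M[, , t + 1] %*% V[t + 2, ])
    p <- lam / 2 + (1 - lam) * stats::plogis(B * (q + drive))
    Q[t + 1, ] <- q
    Pi[t + 1, ] <- p
    V[t + 1, ] <- p * q    # pi * Q(STAY) + (1 - pi) * 0
  }
  structure(list(Q = Q, pi = Pi, V = V,
                 V00 = V[1, disc$K + 1],
                 hazard = h, grid = tables$grid,
                 R = R, L = L, delta = delta, n = n, lambda = lam,
                 disc = disc),
            class = "jb_lattice")
}

#' @export
print.jb_lattice <- function(x, ...) {
  cat("Belief lattice:", nrow(x$pi), "decision bins x", ncol(x$pi),
      "evidence states\n")
  cat(sprintf("  R = %.2f, L = %.2f, delta = %.3f, n = %d, lambda = %.3f\n",
              x$R, x$L, x$delta, x$n, x$lambda))
  cat(sprintf("  start-state value V00 = %.4f GBP\n", x$V00))
  invisible(x)
}

#' Analytic distribution over release bins and timeout
#'
#' Forward recursion of the remain probability under the *true* stimulus
#' kernel: starting from all mass at `(0, X = 0)`, at each decision bin the
#' policy releases with probability `1 - pi`, the survivors time out with
#' the hazard, and the rest diffuse under the true `(mu, theta)` kernel.
#' All mass still holding at `t = T` times out (the stay response).
#'
#' @inheritParams value_recursion
#' @param mu,theta True stimulus direction and coherence.
#' @return List of class `"jb_response_dist"` with `p_release` (length `T`)
#'   and `p_timeout` (scalar); the entries sum to 1.
#' @export
response_distribution <- function(mu, theta, R, L, delta, n, params, disc,
                                  tables = NULL) {
  if (is.null(tables))
    tables <- build_model_tables(params["sigma"], params["zeta"], params["phi"], disc)
  disc <- tables$disc
  lat <- value_recursion(R, L, delta, n, params, disc, theta_true = theta,
                         tables = tables)
  Ktrue <- tables$kernels[, , kernel_index(mu, theta, tables$thetas)]
  h <- tables$hazard
  S <- disc$n_states
  p <- numeric(S); p[disc$K + 1] <- 1
  p_release <- numeric(disc$T)
  p_timeout <- 0
  for (t in 0:(disc$T - 1)) {
    pi_t <- lat$pi[t + 1, ]
    p_release[t + 1] <- sum(p * (1 - pi_t))
    stay <- p * pi_t
    p_timeout <- p_timeout + h[t + 1] * sum(stay)
    p <- as.vector(crossprod(Ktrue, stay * (1 - h[t + 1])))
  }
  p_timeout <- p_timeout + sum(p)   # forced timeout at t = T
  structure(list(p_release = p_release, p_timeout = p_timeout,
                 mu = mu, theta = theta),
            class = "jb_response_dist")
}

#' @export
print.jb_response_dist <- function(x, ...) {
  cat(sprintf("Response distribution (mu = %+d, theta = %.2f):\n", x$mu, x$theta))
  cat(sprintf("  P(stay/timeout) = %.4f; P(release) by bin:\n", x$p_timeout))
  print(round(x$p_release, 4))
  invisible(x)
}

#' Mean timeout probability
#'
#' Summarises the gamma hazard into a single scalar: the mean of the per-bin
#' timeout probabilities over `t = 0..T` (including the forced terminal
#' bin).  Used downstream in place of `zeta` and `phi` for a more
#' interpretable measure of time-estimation quality.
#'
#' @param params A [jb_params()] vector (only `zeta`, `phi` are used).
#' @param disc A [jb_disc()] discretisation.
#' @return A scalar in `(0, 1]`.
#' @export
mean_timeout_probability <- function(params, disc) {
  mean(jb_hazard(params["zeta"], params["phi"], disc))
}
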