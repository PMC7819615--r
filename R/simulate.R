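#' Simulate test-block behaviour from the generative model
#'
#' For each test trial, samples an evidence trajectory on the lattice under
#' the true `(mu, theta)`, applies the fitted policy at each decision bin
#' (release with probability `1 - pi`), samples timeout from the gamma
#' hazard, and records the action, release bin and realised outcome.  The
#' experience state (average earning rate, weighted prediction errors,
#' previous outcome) is updated online with each outcome, so the bias
#' `delta` evolves exactly as in the likelihood.  Training blocks are
#' structural only and are not simulated.
#'
#' @param schedule A [jb_schedule()].
#' @param params A [jb_params()] vector (the generating parameters).
#' @param disc A [jb_disc()] discretisation.
#' @param seed Integer seed.
#' @return A data frame of class `"jb_session"` with one row per test trial:
#'   the schedule columns plus `action` (`"stay"`/`"go"`), `release_bin`
#'   (0-based bin, `NA` for stay) and `outcome` (GBP).  The per-trial
#'   experience trace is attached as attribute `"trace"`.
#' @export
simulate_session <- function(schedule, params, disc = jb_disc(), seed) {
  if (!missing(seed)) set.seed(seed)
  out <- simulate_trials(test_block(schedule), params, disc)
  class(out) <- c("jb_session", class(out))
  out
}

# core simulator over a prepared test-block trial table (uses the current
# RNG state; callers seed)
simulate_trials <- function(tr, params, disc) {
  validate_params(params)
  tables <- build_model_tables(params["sigma"], params["zeta"], params["phi"], disc)
  h <- tables$hazard
  S <- disc$n_states
  N <- nrow(tr)
  gam <- unname(params["gammaPE"]); alp <- unname(params["alphaR"])
  Rbar <- wpe <- wpe2 <- Oprev <- 0
  s1 <- s2 <- wsum <- 0

  action <- character(N); release_bin <- rep(NA_integer_, N)
  outcome <- numeric(N); V00 <- delta <- numeric(N)
  for (i in seq_len(N)) {
    delta[i] <- compose_delta(params, list(Rbar = Rbar, wPE = wpe,
                                           wPE2 = wpe2, O = Oprev))
    lat <- value_recursion(tr$R[i], tr$L[i], delta[i], tr$n[i], params, disc,
                           theta_true = tr$theta[i], tables = tables)
    V00[i] <- lat$V00
    Ktrue <- tables$kernels[, , kernel_index(tr$mu[i], tr$theta[i], tables$thetas)]
    j <- disc$K + 1L
    act <- "stay"; rbin <- NA_integer_
    for (t in 0:(disc$T - 1)) {
      if (stats::runif(1) > lat$pi[t + 1, j]) { act <- "go"; rbin <- t; break }
      if (stats::runif(1) < h[t + 1]) break   # timeout: de facto stay
      j <- sample.int(S, 1L, prob = Ktrue[j, ])
    }
    action[i] <- act
    release_bin[i] <- rbin
    outcome[i] <- if (act == "go") 0 else if (tr$mu[i] == 1) tr$R[i] else tr$L[i]

    pe <- outcome[i] - V00[i]
    s1 <- gam * s1 + pe; s2 <- gam * s2 + pe^2; wsum <- gam * wsum + 1
    wpe <- s1 / wsum; wpe2 <- s2 / wsum
    Rbar <- update_rbar(Rbar, outcome[i], alp)
    Oprev <- outcome[i]
  }
  out <- cbind(tr, action = action, release_bin = release_bin, outcome = outcome)
  attr(out, "trace") <- experience_trace(outcome, V00, params)
  out
}

#' Simulate many releases for one fixed stimulus
#'
#' Monte-Carlo counterpart of [response_distribution()]: repeatedly samples
#' the trajectory/policy/hazard for a single trial configuration and tallies
#' release bins and timeouts.  Used to verify simulator/analytic agreement.
#'
#' @inheritParams response_distribution
#' @param n_sims Number of simulated trials.
#' @param seed Integer seed.
#' @return A list with `counts` (length `T + 1`: releases per bin followed
#'   by the timeout count) and `freq` (the same, normalised).
#' @export
simulate_release_bins <- function(mu, theta, R, L, delta, n, params,
                                  disc = jb_disc(), n_sims = 10000, seed = 1) {
  set.seed(seed)
  tables <- build_model_tables(params["sigma"], params["zeta"], params["phi"], disc)
  lat <- value_recursion(R, L, delta, n, params, disc, theta_true = theta,
                         tables = tables)
  Ktrue <- tables$kernels[, , kernel_index(mu, theta, tables$thetas)]
  h <- tables$hazard
  S <- disc$n_states
  state <- rep(disc$K + 1L, n_sims)   # all mass starts at X = 0
  alive <- rep(TRUE, n_sims)
  result <- rep(disc$T, n_sims)       # T encodes stay/timeout
  for (t in 0:(disc$T - 1)) {
    idx <- which(alive)
    if (!length(idx)) break
    pi_t <- lat$pi[t + 1, state[idx]]
    go <- stats::runif(length(idx)) > pi_t
    result[idx[go]] <- t
    alive[idx[go]] <- FALSE
    idx <- idx[!go]
    if (!length(idx)) next
    tout <- stats::runif(length(idx)) < h[t + 1]
    alive[idx[tout]] <- FALSE          # result stays T (timeout)
    idx <- idx[!tout]
    if (!length(idx)) next
    # evidence step, grouped by current state for vectorised sampling
    # (group against a snapshot so freshly moved trials step only once)
    cur <- state[idx]
    for (j in unique(cur)) {
      sel <- idx[cur == j]
      state[sel] <- sample.int(S, length(sel), replace = TRUE, prob = Ktrue[j, ])
    }
  }
  counts <- tabulate(result + 1L, nbins = disc$T + 1L)
  list(counts = counts, freq = counts / n_sims)
}

#' Simulate a cohort of participants
#'
#' Draws per-participant generating parameters around group-level values,
#' simulates each participant's schedule and test-block behaviour, and
#' returns tidy session data plus the per-participant traces and true
#' parameters.  Conditions are assigned to match the study design (roughly
#' half fluctuating reward, half fluctuating loss).
#'
#' @param n_participants Number of participants.
#' @param group_params Group-level [jb_params()] around which individual
#'   parameters are drawn.
#' @param sd_scale Multiplier on the default between-participant spread
#'   (0 gives identical participants).
#' @param disc A [jb_disc()] discretisation.
#' @param seed Integer seed.
#' @param n_test Test-block length.
#' @return A list with `sessions` (one data frame, `participant` column
#'   added), `traces` (list of experience traces), `true_params` (matrix of
#'   generating parameters, one row per participant) and `schedules`.
#' @export
simulate_cohort <- function(n_participants, group_params = jb_default_truth(),
                            sd_scale = 1, disc = jb_disc(), seed = 1,
                            n_test = 180L) {
  set.seed(seed)
  conditions <- rep(c("fluctuating_reward", "fluctuating_loss"),
                    length.out = n_participants)
  seeds <- sample.int(.Machine$integer.max, 2 * n_participants)
  truth <- matrix(NA_real_, n_participants, length(param_names()),
                  dimnames = list(NULL, param_names()))
  sessions <- vector("list", n_participants)
  traces <- vector("list", n_participants)
  schedules <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    p <- draw_participant_params(group_params, sd_scale)
    truth[i, ] <- p
    sch <- jb_schedule(conditions[i], seed = seeds[2 * i - 1], n_test = n_test)
    ses <- simulate_session(sch, p, disc, seed = seeds[2 * i])
    traces[[i]] <- attr(ses, "trace")
    attr(ses, "trace") <- NULL
    ses <- cbind(participant = i, as.data.frame(ses))
    sessions[[i]] <- ses
    schedules[[i]] <- sch
  }
  list(sessions = do.call(rbind, sessions), traces = traces,
       true_params = truth, schedules = schedules)
}

#' Group-level generating parameters for simulation studies
#'
#' The study conditions used throughout the package's simulations: bias
#' weights at the fitted group means (baseline bias 0.711, earning-rate
#' weight -0.143, previous-outcome weight -0.018) and core parameters chosen
#' to give realistic task performance — discrimination noise `sigma = 0.15`
#' (reference coherence well above chance, ambiguous coherences near
#' chance), a subjective stay interval of mean 2.4 s (`zeta = 8`,
#' `phi = 0.3`, a moderate timeout probability), decision stochasticity low
#' enough that confidently favourable states are held through the trial
#' (`B = 3`; the per-bin policy compounds over 20 bins, so smaller values
#' collapse holding behaviour) and small lapse rates.
#'
#' @return A [jb_params()] vector.
#' @export
jb_default_truth <- function() {
  jb_params(sigma = 0.15, lambda_amb = 0.1, lambda_ref = 0.05, B = 3,
            zeta = 8, phi = 0.3, beta0 = 0.711, betaR = -0.143,
            betaO = 0, betaPE = 0, betaPE2 = 0, beta_n = 0,
            alphaR = 0.1, gammaPE = 0.5)
}

# draw one participant's parameters around the group values (log-normal for
# positive parameters, logit-ish clipping for rates, Gaussian for weights)
draw_participant_params <- function(gp, sd_scale = 1) {
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  ln <- function(m, s) m * exp(stats::rnorm(1, 0, s * sd_scale))
  p <- unclass(gp)
  p["sigma"] <- clip(ln(gp["sigma"], 0.3), 0.03, 1.5)
  p["lambda_amb"] <- clip(ln(gp["lambda_amb"], 0.4), 0.005, 0.4)
  p["lambda_ref"] <- clip(ln(gp["lambda_ref"], 0.4), 0.005, 0.4)
  p["B"] <- clip(ln(gp["B"], 0.3), 0.05, 8)
  p["zeta"] <- clip(ln(gp["zeta"], 0.25), 0.5, 20)
  p["phi"] <- clip(ln(gp["phi"], 0.25), 0.05, 4)
  p["beta0"] <- stats::rnorm(1, gp["beta0"], 0.35 * sd_scale)
  if (gp["betaR"] != 0)
    p["betaR"] <- clip(stats::rnorm(1, gp["betaR"], 0.05 * sd_scale), -1, 1)
  if (gp["betaO"] != 0)
    p["betaO"] <- clip(stats::rnorm(1, gp["betaO"], 0.01 * sd_scale), -0.5, 0.5)
  if (gp["betaPE"] != 0)
    p["betaPE"] <- stats::rnorm(1, gp["betaPE"], 0.05 * sd_scale)
  p["alphaR"] <- clip(ln(gp["alphaR"], 0.3), 0.01, 0.9)
  p["gammaPE"] <- clip(gp["gammaPE"] + stats::rnorm(1, 0, 0.1 * sd_scale), 0.05, 0.95)
  structure(p, class = "jb_params")
}

#' Simulate affect-grid reports with injected dependencies
#'
#' Synthetic stand-in for human affect reports: at each probe a latent
#' Gaussian valence and arousal are built as linear combinations of the
#' probe-time experience predictors (each standardised by its own
#' within-session sd, matching the downstream analysis), plus noise, then
#' discretised to the 9-level grid coded -4..+4.
#'
#' @param session A [simulate_session()] result (trace attached) or a
#'   session with a `trace` supplied separately.
#' @param schedule The [jb_schedule()] used.
#' @param coeffs List with numeric vectors `valence` and `arousal`; named
#'   entries among `intercept`, `wPE`, `wPE2`, `Rbar`, `O`,
#'   `potential_outcome`, `n` give the effect of each standardised predictor
#'   on the latent report.  Missing entries are 0.
#' @param noise_sd Latent noise sd (grid units).
#' @param seed Integer seed.
#' @param trace Experience trace (defaults to `attr(session, "trace")`).
#' @return A data frame: `trial_index`, `valence`, `arousal` (integer grid
#'   levels in -4..4), plus the standardised predictors used.
#' @export
simulate_affect <- function(session, schedule, coeffs = list(), noise_sd = 1,
                            seed = 1, trace = attr(session, "trace")) {
  set.seed(seed)
  if (is.null(trace)) stop("an experience trace is required")
  pred <- probe_predictor_frame(session, schedule, trace)
  latent <- function(cf) {
    cf <- cf[!is.na(cf)]
    v <- rep(if ("intercept" %in% names(cf)) cf[["intercept"]] else 0, nrow(pred))
    for (nm in setdiff(names(cf), "intercept")) {
      if (!nm %in% names(pred)) stop("unknown affect predictor: ", nm)
      v <- v + cf[[nm]] * pred[[nm]]
    }
    v
  }
  val <- latent(coeffs$valence %||% numeric()) + stats::rnorm(nrow(pred), 0, noise_sd)
  aro <- latent(coeffs$arousal %||% numeric()) + stats::rnorm(nrow(pred), 0, noise_sd)
  to_grid <- function(x) as.integer(pmin(4, pmax(-4, round(x))))
  cbind(data.frame(trial_index = pred$trial_index,
                   valence = to_grid(val), arousal = to_grid(aro)),
        pred[, setdiff(names(pred), "trial_index"), drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standardised probe-time predictors for one session: experience state
# immediately prior to each probe, divided by its own within-session sd.
# The baseline probe (after 0 trials) carries the neutral pre-task state and
# the first trial's stakes as the potential-outcome context.
probe_predictor_frame <- function(session, schedule, trace) {
  probes <- schedule$probe_after
  tr <- test_block(schedule)
  state_at <- function(k) {
    if (k == 0) c(Rbar = 0, wPE = 0, wPE2 = 0, O = 0)
    else c(Rbar = trace$Rbar[k], wPE = trace$wPE[k], wPE2 = trace$wPE2[k],
           O = trace$O[k])
  }
  st <- t(vapply(probes, state_at, numeric(4)))
  po <- vapply(probes, function(k) {
    k <- max(k, 1L)                      # baseline probe: first trial's context
    (tr$R[k] + tr$L[k]) / 2
  }, numeric(1))
  d <- data.frame(trial_index = probes, Rbar = st[, "Rbar"], wPE = st[, "wPE"],
                  wPE2 = st[, "wPE2"], O = st[, "O"], potential_outcome = po,
                  n = probes)
  for (nm in c("Rbar", "wPE", "wPE2", "O", "potential_outcome", "n")) {
    s <- stats::sd(d[[nm]])
    d[[nm]] <- if (is.na(s) || s == 0) d[[nm]] * 0 else d[[nm]] / s
  }
  d
}
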