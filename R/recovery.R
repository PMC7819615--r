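#' Parameter recovery study
#'
#' Simulates a cohort from known per-participant parameters, refits each
#' participant with [jb_fit()], and reports the correlation and bias between
#' true and recovered values for each free parameter, plus the mean timeout
#' probability (the interpretable summary of `zeta`/`phi`) and the fraction
#' of participants whose recovered bias weights have the correct sign.
#'
#' @param n_participants Number of simulated participants.
#' @param group_params Group-level generating parameters
#'   ([jb_default_truth()] by default).
#' @param spec The [jb_model_spec()] fitted to the simulated data (should
#'   normally match the generating structure).
#' @param n_trials Test-block length per participant.
#' @param n_starts Optimisation starts per fit.
#' @param disc A [jb_disc()] discretisation.
#' @param seed Integer seed.
#' @param sd_scale Between-participant spread multiplier (see
#'   [simulate_cohort()]).
#' @param control Optimiser control for [jb_fit()].
#' @return An object of class `"jb_recovery"`: list with `true` and
#'   `recovered` matrices (participant x quantity), `table` (per-quantity
#'   correlation, with a normal-approximation 95% CI, and mean bias) and
#'   `sign_agreement` (named vector, for the fitted bias weights).
#' @export
jb_recovery <- function(n_participants = 20, group_params = jb_default_truth(),
                        spec = jb_model_spec(baseline = TRUE, experience = "rbar"),
                        n_trials = 180L, n_starts = 10, disc = jb_disc(),
                        seed = 1, sd_scale = 1, control = list()) {
  cohort <- simulate_cohort(n_participants, group_params, sd_scale = sd_scale,
                            disc = disc, seed = seed, n_test = n_trials)
  sessions <- split(cohort$sessions, cohort$sessions$participant)
  fits <- lapply(seq_along(sessions), function(i)
    jb_fit(sessions[[i]], spec, disc, n_starts = n_starts, seed = seed + 7919 * i,
           control = control))

  quantities <- c(spec$free, "timeout_prob")
  truth <- matrix(NA_real_, n_participants, length(quantities),
                  dimnames = list(NULL, quantities))
  rec <- truth
  for (i in seq_len(n_participants)) {
    tp <- structure(cohort$true_params[i, ], class = "jb_params")
    truth[i, spec$free] <- cohort$true_params[i, spec$free]
    truth[i, "timeout_prob"] <- mean_timeout_probability(tp, disc)
    rec[i, spec$free] <- fits[[i]]$coefficients
    rec[i, "timeout_prob"] <- mean_timeout_probability(fits[[i]]$params, disc)
  }

  tab <- do.call(rbind, lapply(quantities, function(q) {
    r <- if (stats::sd(truth[, q]) > 0) stats::cor(truth[, q], rec[, q]) else NA_real_
    ci <- if (is.na(r) || abs(r) >= 1 || n_participants < 4) c(NA, NA) else {
      z <- atanh(r) + c(-1, 1) * 1.96 / sqrt(n_participants - 3)
      tanh(z)
    }
    data.frame(quantity = q, correlation = r, ci_lo = ci[1], ci_hi = ci[2],
               bias = mean(rec[, q] - truth[, q]))
  }))

  weights <- intersect(c("beta0", "betaR", "betaPE", "betaPE2", "betaO", "beta_n"),
                       spec$free)
  sign_agreement <- vapply(weights, function(w)
    mean(sign(rec[, w]) == sign(truth[, w])), numeric(1))

  structure(list(true = truth, recovered = rec, table = tab,
                 sign_agreement = sign_agreement, fits = fits,
                 spec = spec, n_trials = n_trials),
            class = "jb_recovery")
}

#' @export
print.jb_recovery <- function(x, ...) {
  cat("Parameter recovery:", nrow(x$true), "participants x", x$n_trials,
      "trials\n")
  print(transform(x$table, correlation = round(correlation, 3),
                  ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3),
                  bias = round(bias, 3)), row.names = FALSE)
  if (length(x$sign_agreement)) {
    cat("sign agreement of bias weights:\n")
    print(round(x$sign_agreement, 3))
  }
  invisible(x)
}
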