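#' Specify which parameters are free
#'
#' The six core parameters (`sigma`, `lambda_amb`, `lambda_ref`, `B`,
#' `zeta`, `phi`) are always fitted.  `baseline` adds the constant bias
#' `beta0`.  `experience` adds experience/time terms, each bringing its
#' dynamics parameter where one exists: `"rbar"` (`betaR` + `alphaR`),
#' `"wpe"` (`betaPE` + `gammaPE`), `"wpe2"` (`betaPE2` + `gammaPE`),
#' `"outcome"` (`betaO`), `"trials"` (`beta_n`).  Because the underlying
#' regressors are strongly correlated, at most one of
#' `{"wpe", "wpe2", "outcome"}` and at most one of `{"rbar", "trials"}` may
#' be entered — requesting more is an error, mirroring the stepwise
#' selection's hard constraint.
#'
#' @param baseline Include the constant bias `beta0`?
#' @param experience Character vector of experience/time terms (see above).
#' @return An object of class `"jb_model_spec"`.
#' @examples
#' jb_model_spec(baseline = TRUE, experience = "rbar")
#' @export
jb_model_spec <- function(baseline = TRUE, experience = character()) {
  experience <- unique(experience)
  bad <- setdiff(experience, c("rbar", "wpe", "wpe2", "outcome", "trials"))
  if (length(bad)) stop("unknown experience terms: ", paste(bad, collapse = ", "))
  if (sum(experience %in% c("wpe", "wpe2", "outcome")) > 1)
    stop("wpe, wpe2 and outcome are mutually exclusive (correlated predictors)")
  if (sum(experience %in% c("rbar", "trials")) > 1)
    stop("rbar and trials are mutually exclusive (correlated predictors)")
  free <- c("sigma", "lambda_amb", "lambda_ref", "B", "zeta", "phi")
  if (baseline) free <- c(free, "beta0")
  if ("rbar" %in% experience) free <- c(free, "betaR", "alphaR")
  if ("wpe" %in% experience) free <- c(free, "betaPE", "gammaPE")
  if ("wpe2" %in% experience) free <- c(free, "betaPE2", "gammaPE")
  if ("outcome" %in% experience) free <- c(free, "betaO")
  if ("trials" %in% experience) free <- c(free, "beta_n")
  structure(list(baseline = baseline, experience = experience, free = free),
            class = "jb_model_spec")
}

#' @export
print.jb_model_spec <- function(x, ...) {
  cat("Model spec: core",
      if (x$baseline) "+ baseline bias",
      if (length(x$experience)) paste("+", paste(x$experience, collapse = " + ")),
      sprintf("(%d free parameters)\n", length(x$free)))
  invisible(x)
}

# full parameter vector from the spec's free subset; everything else fixed:
# bias weights at 0, dynamics parameters at 0 (inert when their weight is 0)
spec_to_params <- function(spec, free_values) {
  p <- unclass(jb_params())
  p[c("beta0", "betaR", "betaPE", "betaPE2", "betaO", "beta_n")] <- 0
  p[c("alphaR", "gammaPE")] <- 0
  p[spec$free] <- free_values
  structure(p, class = "jb_params")
}

#' Fit the POMDP to one participant's session by maximum likelihood
#'
#' Minimises the session negative log-likelihood over the spec's free
#' parameters with multistart bounded local optimisation: `n_starts`
#' Latin-hypercube initialisations within the parameter box (the first start
#' is replaced by the package defaults), each refined with BOBYQA on a
#' unit-scaled box.  The experience/bias trace is recomputed inside the
#' objective, since it depends on the parameters.
#'
#' @param session A session data frame of test trials (columns `mu`,
#'   `theta`, `R`, `L`, `n`, `action`, `release_bin`, `outcome`).
#' @param spec A [jb_model_spec()].
#' @param disc A [jb_disc()] discretisation.
#' @param n_starts Number of optimisation starts.
#' @param seed Integer seed for the start draw.
#' @param bounds Parameter box, as from [jb_param_bounds()].
#' @param control List: `maxfun` (function evaluations per start),
#'   `rhobeg`, `rhoend` (BOBYQA trust-region radii on the unit box).
#' @return An object of class `"jb_fit"`; see [coef.jb_fit()],
#'   [logLik.jb_fit()], [predict.jb_fit()], [simulate.jb_fit()],
#'   [plot.jb_fit()].
#' @export
jb_fit <- function(session, spec = jb_model_spec(), disc = jb_disc(),
                   n_starts = 20, seed = 1, bounds = jb_param_bounds(),
                   control = list()) {
  stopifnot(inherits(spec, "jb_model_spec"), nrow(session) >= 1)
  maxfun <- control$maxfun %||% 500
  rhobeg <- control$rhobeg %||% 0.2
  rhoend <- control$rhoend %||% 1e-5

  free <- spec$free
  lo <- bounds$lower[free]; hi <- bounds$upper[free]
  p_free <- length(free)
  # positive scale parameters are searched on a log scale
  logpar <- free %in% c("sigma", "B", "zeta", "phi")
  lo[logpar] <- pmax(lo[logpar], c(sigma = 0.02, B = 0.05, zeta = 0.2,
                                   phi = 0.02)[free[logpar]])
  unscale <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    th <- lo + u * (hi - lo)
    th[logpar] <- exp(log(lo[logpar]) + u[logpar] * (log(hi[logpar]) - log(lo[logpar])))
    th
  }
  rescale <- function(th) {
    u <- (th - lo) / (hi - lo)
    u[logpar] <- (log(th[logpar]) - log(lo[logpar])) /
      (log(hi[logpar]) - log(lo[logpar]))
    pmin(pmax(u, 0.02), 0.98)
  }

  objective <- function(u) {
    params <- spec_to_params(spec, unscale(u))
    val <- tryCatch(suppressWarnings(session_nll(session, params, disc)$nll),
                    error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }

  set.seed(seed)
  starts <- lhs::randomLHS(n_starts, p_free)
  starts[1, ] <- rescale(unclass(jb_params())[free])

  run_bobyqa <- function(par, mf, rb, re) {
    tryCatch(
      suppressWarnings(
        minqa::bobyqa(par, objective, lower = rep(0, p_free),
                      upper = rep(1, p_free),
                      control = list(maxfun = mf, rhobeg = rb, rhoend = re,
                                     iprint = 0))),
      error = function(e) list(fval = Inf, par = par, ierr = -1L,
                               msg = conditionMessage(e)))
  }
  # stage 1: coarse exploration from every start
  mf1 <- max(50, round(maxfun * 0.4))
  runs <- lapply(seq_len(n_starts), function(s)
    run_bobyqa(starts[s, ], mf1, rhobeg, 5e-3))
  fvals <- vapply(runs, function(r) r$fval, numeric(1))
  if (all(!is.finite(fvals))) stop("all optimisation starts failed")
  # stage 2: refine the most promising local optima
  n_ref <- max(1L, min(n_starts, ceiling(n_starts / 3)))
  top <- order(fvals)[seq_len(n_ref)]
  for (s in top) {
    ref <- run_bobyqa(runs[[s]]$par, maxfun, 0.05, rhoend)
    if (ref$fval < runs[[s]]$fval) runs[[s]] <- ref
  }
  fvals <- vapply(runs, function(r) r$fval, numeric(1))
  best <- runs[[which.min(fvals)]]
  params <- spec_to_params(spec, unscale(best$par))
  nll <- best$fval
  k <- p_free
  N <- nrow(session)
  final <- suppressWarnings(session_nll(session, params, disc, want_dists = TRUE))

  structure(list(
    coefficients = unclass(params)[free],
    params = params,
    spec = spec,
    nll = nll,
    n_params = k,
    nobs = N,
    aic = 2 * k + 2 * nll,
    bic = k * log(N) + 2 * nll,
    starts = n_starts,
    start_nlls = fvals,
    # ierr 0: rho reached rhoend; ierr 1: evaluation budget exhausted after
    # refinement.  Both are normal terminations; anything else is a failure.
    converged = is.finite(nll) && (best$ierr %||% 0L) %in% c(0L, 1L),
    trace = final$trace,
    p_obs = final$p_obs,
    p_release = final$p_release,
    p_timeout = final$p_timeout,
    session = session,
    disc = disc,
    bounds = list(lower = lo, upper = hi),
    seed = seed),
    class = "jb_fit")
}

#' @export
print.jb_fit <- function(x, ...) {
  cat("Judgement-bias POMDP fit (", x$nobs, " trials, ",
      x$n_params, " free parameters, ", x$starts, " starts)\n", sep = "")
  print(round(x$coefficients, 4))
  cat(sprintf("nll = %.3f, AIC = %.2f, BIC = %.2f, converged: %s\n",
              x$nll, x$aic, x$bic, x$converged))
  invisible(x)
}

#' @export
summary.jb_fit <- function(object, ...) {
  res <- list(fit = object,
              stay_rate = mean(object$session$action == "stay"),
              mean_timeout = mean_timeout_probability(object$params, object$disc),
              start_spread = stats::quantile(object$start_nlls,
                                             c(0, 0.5, 1), na.rm = TRUE))
  class(res) <- "summary.jb_fit"
  res
}

#' @export
print.summary.jb_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("observed stay rate: %.3f\n", x$stay_rate))
  cat(sprintf("mean timeout probability (hazard summary): %.3f\n", x$mean_timeout))
  cat("nll across starts (min/median/max):",
      paste(round(x$start_spread, 3), collapse = " / "), "\n")
  invisible(x)
}

#' Extract fitted parameters
#'
#' @param object A [jb_fit()] result.
#' @param full If `TRUE`, the full 14-parameter vector (fixed entries at
#'   their constrained values); otherwise the free subset.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
coef.jb_fit <- function(object, full = FALSE, ...) {
  if (full) unclass(object$params) else object$coefficients
}

#' Log-likelihood of a fitted model
#'
#' @param object A [jb_fit()] result.
#' @param ... Unused.
#' @return A `"logLik"` object with `df` and `nobs` attributes, so
#'   [stats::AIC()] and [stats::BIC()] work directly.
#' @export
logLik.jb_fit <- function(object, ...) {
  structure(-object$nll, df = object$n_params, nobs = object$nobs,
            class = "logLik")
}

#' Predicted response distributions from a fit
#'
#' @param object A [jb_fit()] result.
#' @param newdata Optional new session data frame (defaults to the fitted
#'   session; note the experience trace is recomputed from `newdata`'s
#'   outcomes).
#' @param ... Unused.
#' @return A data frame with one row per trial: `p_stay` (probability of
#'   holding to the end), `expected_bin` (mean discretised reaction time,
#'   counting stay as bin `T`), and the observation probability `p_obs`.
#'   The full `T x N` release matrix is attached as attribute
#'   `"p_release"`.
#' @export
predict.jb_fit <- function(object, newdata = NULL, ...) {
  session <- newdata %||% object$session
  res <- session_nll(session, object$params, object$disc, want_dists = TRUE)
  T_bins <- object$disc$T
  ebin <- as.vector(crossprod(res$p_release, 0:(T_bins - 1))) +
    res$p_timeout * T_bins
  out <- data.frame(n = session$n, p_stay = res$p_timeout,
                    expected_bin = ebin, p_obs = res$p_obs)
  attr(out, "p_release") <- res$p_release
  out
}

#' Response residuals on the stay probability
#'
#' Observed stay indicator minus model stay probability, per trial.
#'
#' @param object A [jb_fit()] result.
#' @param ... Unused.
#' @return Numeric vector, one entry per trial.
#' @export
residuals.jb_fit <- function(object, ...) {
  as.numeric(object$session$action == "stay") - object$p_timeout
}

#' Simulate sessions from a fitted model
#'
#' Replays the fitted session's schedule through the generative model at the
#' fitted parameters.
#'
#' @param object A [jb_fit()] result.
#' @param nsim Number of simulated sessions.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` session data frames (traces attached).
#' @export
simulate.jb_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tr <- object$session[, c("block", "n", "mu", "theta", "R", "L", "condition")]
  lapply(seq_len(nsim), function(i) simulate_trials(tr, object$params, object$disc))
}

#' Observed vs predicted mean discretised reaction time
#'
#' One point per signed stimulus level (`mu * theta`): the observed mean
#' discretised reaction time (release bin; stay counted as the terminal
#' bin) against the model's expected bin.
#'
#' @param x A [jb_fit()] result.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the per-level summary data frame.
#' @export
plot.jb_fit <- function(x, ...) {
  ses <- x$session
  obs_bin <- ifelse(ses$action == "stay", x$disc$T, ses$release_bin)
  pred <- predict(x)
  lev <- ses$mu * ses$theta
  agg <- data.frame(level = sort(unique(lev)))
  agg$observed <- vapply(agg$level, function(l) mean(obs_bin[lev == l]), numeric(1))
  agg$predicted <- vapply(agg$level, function(l) mean(pred$expected_bin[lev == l]),
                          numeric(1))
  graphics::plot(agg$level, agg$observed, pch = 19, ylim = range(agg[, -1]),
                 xlab = "signed stimulus level (mu * theta)",
                 ylab = "mean discretised reaction time (bin)", ...)
  graphics::points(agg$level, agg$predicted, pch = 1, col = 2)
  graphics::legend("bottomleft", legend = c("observed", "model"),
                   pch = c(19, 1), col = c(1, 2), bty = "n")
  invisible(agg)
}
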