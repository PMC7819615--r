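#' Negative log-likelihood of one recorded trial
#'
#' A go response at release bin `t` contributes `-log p_release[t]`; a stay
#' (hold to the end / timeout) contributes `-log p_timeout`.  Probabilities
#' are floored at 1e-300 before the log.
#'
#' @param record A one-row data frame (or list) with `mu`, `theta`, `R`,
#'   `L`, `n`, `action`, `release_bin`.
#' @param delta The trial's bias.
#' @param params A [jb_params()] vector.
#' @param disc A [jb_disc()] discretisation.
#' @return The negative log-probability of the observation.
#' @export
trial_nll <- function(record, delta, params, disc = jb_disc()) {
  rd <- response_distribution(record$mu, record$theta, record$R, record$L,
                              delta, record$n, params, disc)
  p <- if (record$action == "stay") rd$p_timeout
       else rd$p_release[record$release_bin + 1]
  -log(max(p, 1e-300))
}

# prepare the per-trial vectors consumed by the C++ session evaluator
session_inputs <- function(session, params, disc, thetas = jb_thetas()) {
  need <- c("mu", "theta", "R", "L", "n", "action", "release_bin", "outcome")
  miss <- setdiff(need, names(session))
  if (length(miss)) stop("session is missing columns: ", paste(miss, collapse = ", "))
  kt <- match(session$theta, thetas)
  if (anyNA(kt)) stop("coherence outside the observer's support: ",
                      paste(unique(session$theta[is.na(kt)]), collapse = ", "))
  kid <- kt + ifelse(session$mu == 1, length(thetas), 0L)
  lam <- ifelse(session$theta <= 0.05, params["lambda_amb"], params["lambda_ref"])
  stay <- as.integer(session$action == "stay")
  rbin <- ifelse(stay == 1L, -1L, as.integer(session$release_bin))
  if (any(stay == 0L & (rbin < 0 | rbin >= disc$T)))
    stop("go trials must have release_bin in 0..T-1")
  list(kid = kid, lam = lam, stay = stay, rbin = rbin)
}

#' Session negative log-likelihood with experience dynamics
#'
#' Sums [trial_nll()] over a session's test trials, with the bias trace
#' `delta_n` recomputed online: each trial's start-state value feeds the
#' prediction error, which (with the realised outcomes) drives the
#' experience state for subsequent trials.  This is the objective minimised
#' by [jb_fit()]; the heavy recursions run in compiled code.
#'
#' @param session A session data frame (see [simulate_session()]).
#' @param params A [jb_params()] vector.
#' @param disc A [jb_disc()] discretisation.
#' @param tables Optional precomputed model tables (internal reuse).
#' @param want_dists If `TRUE`, also return the full per-trial release/
#'   timeout distributions.
#' @return A list: `nll`, `trace` (per-trial experience data frame),
#'   `p_obs` (per-trial observation probabilities); with `want_dists`,
#'   additionally `p_release` (`T x N`) and `p_timeout` (length `N`).
#' @export
session_nll <- function(session, params, disc = jb_disc(), tables = NULL,
                        want_dists = FALSE) {
  validate_params(params)
  if (is.null(tables))
    tables <- build_model_tables(params["sigma"], params["zeta"], params["phi"], disc)
  si <- session_inputs(session, params, disc, tables$thetas)
  res <- cpp_session_eval(tables$M, tables$kernels, tables$P1, tables$hazard,
                          session$R, session$L, as.integer(session$n), si$kid,
                          si$lam, si$stay, si$rbin, session$outcome,
                          unname(params["B"]), unname(params["beta0"]),
                          unname(params["betaR"]), unname(params["betaPE"]),
                          unname(params["betaPE2"]), unname(params["betaO"]),
                          unname(params["beta_n"]), unname(params["alphaR"]),
                          unname(params["gammaPE"]), want_dists)
  tracedf <- as.data.frame(res$trace)
  names(tracedf) <- c("delta", "V00", "PE", "Rbar", "wPE", "wPE2", "O")
  tracedf <- cbind(n = session$n, tracedf)
  out <- list(nll = res$nll, trace = tracedf, p_obs = res$p_obs)
  if (want_dists) {
    out$p_release <- res$p_release
    out$p_timeout <- res$p_timeout
  }
  out
}
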