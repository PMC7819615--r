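#' Within-task experience dynamics
#'
#' The decision bias on trial `n` is composed from experience accumulated on
#' trials `1..n-1`: the Rescorla-Wagner average earning rate `Rbar`, the
#' forgetting-weighted (normalised) average of signed prediction errors
#' `wPE`, the same weighting applied to squared prediction errors `wPE2`
#' (a measure of outcome unpredictability), and the previous outcome `O`.
#' These helpers implement the individual updates; [experience_trace()]
#' replays a whole outcome sequence.
#'
#' @name experience
NULL

#' Prediction error for one trial
#'
#' `PE_n = O_n - V00`, where `V00` is the value of the lattice start state
#' for the trial's stakes, i.e. the expected outcome prior to stimulus
#' presentation.
#'
#' @param O Realised outcome (GBP; 0 for a go response).
#' @param V00 Start-state value from [value_recursion()].
#' @return The prediction error (GBP).
#' @export
prediction_error <- function(O, V00) O - V00

#' Rescorla-Wagner update of the average earning rate
#'
#' @param Rbar_prev Previous average earning rate.
#' @param O Latest outcome.
#' @param alphaR Learning rate in `[0, 1]`.
#' @return Updated average earning rate.
#' @export
update_rbar <- function(Rbar_prev, O, alphaR) {
  if (alphaR < 0 || alphaR > 1) stop("alphaR must lie in [0, 1]")
  Rbar_prev + alphaR * (O - Rbar_prev)
}

#' Forgetting-weighted average of prediction errors
#'
#' `wPE_n = (1 - gamma) / (1 - gamma^n) * sum_i gamma^(n-i) PE_i` — a
#' *normalised* weighted average, so the weights sum to 1 for every `n`.
#' At `gamma = 0` only the latest PE survives; as `gamma -> 1` the
#' arithmetic mean is recovered (the limit is taken analytically).
#'
#' @param pe_history Numeric vector `PE_1..PE_n` in trial order.
#' @param gammaPE Forgetting factor in `[0, 1]`.
#' @return The weighted average; 0 for an empty history (pre-task state).
#' @export
update_wpe <- function(pe_history, gammaPE) {
  if (gammaPE < 0 || gammaPE > 1) stop("gammaPE must lie in [0, 1]")
  n <- length(pe_history)
  if (n == 0) return(0)
  if (gammaPE >= 1) return(mean(pe_history))
  w <- gammaPE^((n - 1):0)
  sum(w * pe_history) / sum(w)
}

#' Compose the trial-wise decision bias
#'
#' `delta_n = beta0 + betaR * Rbar + betaPE * wPE + betaPE2 * wPE2 +
#' betaO * O`, where the experience terms reflect trials `1..n-1`.  Weights
#' excluded by model selection are simply zero in `params`.
#'
#' @param params A [jb_params()] vector.
#' @param state A list (or one-row data frame) with elements `Rbar`, `wPE`,
#'   `wPE2`, `O` — the experience state after trial `n - 1`.
#' @return The bias `delta_n` (GBP).
#' @export
compose_delta <- function(params, state) {
  unname(params["beta0"] + params["betaR"] * state$Rbar +
           params["betaPE"] * state$wPE + params["betaPE2"] * state$wPE2 +
           params["betaO"] * state$O)
}

#' Replay an outcome sequence into an experience trace
#'
#' Given per-trial realised outcomes and start-state values, reproduces the
#' full experience trace: for each trial `n` the bias `delta_n` is composed
#' from the state after trial `n-1`, then `PE_n = O_n - V00_n` updates the
#' weighted prediction errors and `O_n` updates the average earning rate.
#' Initial conditions are the neutral pre-task state
#' (`Rbar = wPE = wPE2 = O = 0`).
#'
#' @param outcomes Numeric vector of realised outcomes `O_1..O_N` (GBP).
#' @param V00 Numeric vector of start-state values, same length.
#' @param params A [jb_params()] vector (uses the `beta*`, `alphaR`,
#'   `gammaPE` entries).
#' @return A data frame with one row per trial: `n`, `O`, `PE`, `Rbar`,
#'   `wPE`, `wPE2` (state *after* the trial's outcome) and `delta` (the bias
#'   that applied *on* the trial).
#' @export
experience_trace <- function(outcomes, V00, params) {
  N <- length(outcomes)
  stopifnot(length(V00) == N)
  gam <- unname(params["gammaPE"]); alp <- unname(params["alphaR"])
  Rbar <- wpe <- wpe2 <- Oprev <- 0
  s1 <- s2 <- wsum <- 0
  out <- data.frame(n = seq_len(N), O = outcomes, PE = NA_real_,
                    Rbar = NA_real_, wPE = NA_real_, wPE2 = NA_real_,
                    delta = NA_real_)
  for (i in seq_len(N)) {
    out$delta[i] <- compose_delta(params, list(Rbar = Rbar, wPE = wpe,
                                               wPE2 = wpe2, O = Oprev))
    pe <- prediction_error(outcomes[i], V00[i])
    s1 <- gam * s1 + pe
    s2 <- gam * s2 + pe^2
    wsum <- gam * wsum + 1
    wpe <- s1 / wsum
    wpe2 <- s2 / wsum
    Rbar <- update_rbar(Rbar, outcomes[i], alp)
    Oprev <- outcomes[i]
    out$PE[i] <- pe
    out$Rbar[i] <- Rbar
    out$wPE[i] <- wpe
    out$wPE2[i] <- wpe2
  }
  out
}
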