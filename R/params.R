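#' Model parameters
#'
#' Container for the fourteen fittable parameters of the judgement-bias POMDP.
#' Core parameters govern the psychometric function (`sigma`, `lambda_amb`,
#' `lambda_ref`), decision stochasticity (`B`) and interval timing
#' (`zeta`, `phi`: gamma shape/scale of the subjective stay time, so the
#' subjective interval has mean `zeta * phi` seconds).  The remaining
#' parameters compose the trial-wise decision bias
#' `delta = beta0 + betaR * Rbar + betaPE * wPE + betaPE2 * wPE2 + betaO * O`
#' and its experience dynamics (`alphaR` Rescorla-Wagner learning rate,
#' `gammaPE` forgetting factor), plus the trial-count term `beta_n` that
#' enters the policy as `delta - n * beta_n`.
#'
#' @param sigma Observation noise sd (> 0); higher = poorer discrimination.
#' @param lambda_amb,lambda_ref Lapse rates in `[0, 1]` for ambiguous
#'   (coherence 0.01/0.02/0.04) and reference (0.16/0.32) stimuli.
#' @param B Inverse temperature (>= 0).
#' @param zeta,phi Gamma shape and scale (> 0) of the subjective stay time.
#' @param beta0 Baseline bias towards the risky stay response (GBP).
#' @param betaR Weight of the average earning rate on the bias.
#' @param betaPE,betaPE2 Weights of the weighted (signed / squared)
#'   prediction error on the bias.
#' @param betaO Weight of the previous trial's outcome on the bias.
#' @param beta_n Trial-count coefficient.
#' @param alphaR Learning rate of the average earning rate, in `[0, 1]`.
#' @param gammaPE Forgetting factor of the weighted prediction errors, in
#'   `[0, 1]`.
#' @return A named numeric vector of class `"jb_params"`.
#' @examples
#' p <- jb_params(sigma = 0.15, beta0 = 0.7)
#' p["sigma"]
#' @export
jb_params <- function(sigma = 0.15, lambda_amb = 0.1, lambda_ref = 0.05,
                      B = 0.6, zeta = 8, phi = 0.3,
                      beta0 = 0, betaR = 0, betaPE = 0, betaPE2 = 0,
                      betaO = 0, beta_n = 0, alphaR = 0.1, gammaPE = 0.5) {
  p <- c(sigma = sigma, lambda_amb = lambda_amb, lambda_ref = lambda_ref,
         B = B, zeta = zeta, phi = phi, beta0 = beta0, betaR = betaR,
         betaPE = betaPE, betaPE2 = betaPE2, betaO = betaO,
         beta_n = beta_n, alphaR = alphaR, gammaPE = gammaPE)
  validate_params(p)
  structure(p, class = "jb_params")
}

param_names <- function() {
  c("sigma", "lambda_amb", "lambda_ref", "B", "zeta", "phi", "beta0",
    "betaR", "betaPE", "betaPE2", "betaO", "beta_n", "alphaR", "gammaPE")
}

validate_params <- function(p) {
  p <- unclass(p)
  stopifnot(identical(names(p), param_names()))
  if (!is.finite(p["sigma"]) || p["sigma"] <= 0) stop("sigma must be > 0")
  for (nm in c("lambda_amb", "lambda_ref", "alphaR", "gammaPE"))
    if (p[nm] < 0 || p[nm] > 1) stop(nm, " must lie in [0, 1]")
  if (p["B"] < 0) stop("B must be >= 0")
  if (p["zeta"] <= 0 || p["phi"] <= 0) stop("zeta and phi must be > 0")
  invisible(TRUE)
}

#' Optimisation bounds for the model parameters
#'
#' Box bounds used for multistart initialisation and bounded local search.
#' Parameters with a priori unbounded range (the `beta` weights) are boxed at
#' `+/- beta_box` for optimisation stability.
#'
#' @param beta_box Half-width of the box on the bias weights.
#' @return A list with numeric vectors `lower` and `upper`, named by
#'   parameter.
#' @export
jb_param_bounds <- function(beta_box = 10) {
  lower <- c(sigma = 0.02, lambda_amb = 0, lambda_ref = 0, B = 0,
             zeta = 0.2, phi = 0.02, beta0 = -beta_box, betaR = -beta_box,
             betaPE = -beta_box, betaPE2 = -beta_box, betaO = -beta_box,
             beta_n = -beta_box, alphaR = 0, gammaPE = 0)
  upper <- c(sigma = 2, lambda_amb = 1, lambda_ref = 1, B = 10,
             zeta = 25, phi = 5, beta0 = beta_box, betaR = beta_box,
             betaPE = beta_box, betaPE2 = beta_box, betaO = beta_box,
             beta_n = beta_box, alphaR = 1, gammaPE = 0.999)
  list(lower = lower, upper = upper)
}

#' @export
print.jb_params <- function(x, ...) {
  cat("Judgement-bias POMDP parameters:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

# lapse rate appropriate to a trial's true coherence class
lapse_for_theta <- function(params, theta) {
  if (theta <= 0.05) unname(params["lambda_amb"]) else unname(params["lambda_ref"])
}
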