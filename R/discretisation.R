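#' Time/evidence discretisation of the belief-state lattice
#'
#' The trial lasts 2 s.  Objective time is cut into `T` bins of width `dt`
#' seconds; accumulated evidence lives on a symmetric grid `X = j * chi`,
#' `j = -K..K`, whose extreme bins absorb tail transition mass.  Per-bin
#' observations are modelled as `N(mu * theta * dt, sigma^2 * dt)` so that
#' beliefs are invariant to the choice of `dt`; by default the evidence step
#' is tied to the observation noise, `chi = sigma * sqrt(dt) / 2`, i.e. half
#' a per-bin standard deviation.
#'
#' @param dt Bin width in seconds.  The number of bins is `T = 2 / dt` and
#'   must be an integer.
#' @param K Half-width of the evidence grid (grid has `2K + 1` states).
#' @param chi Evidence step size.  `NA` (default) means "tie to sigma":
#'   lattice builders substitute `sigma * sqrt(dt) / 2` at use time.
#' @return An object of class `"jb_disc"`: a list with elements `dt`, `T`,
#'   `K`, `chi`, `n_states` and `trial_s` (total trial duration, 2 s).
#' @examples
#' d <- jb_disc()
#' d$T * d$dt  # 2 seconds
#' @export
jb_disc <- function(dt = 0.1, K = 40, chi = NA_real_) {
  stopifnot(dt > 0, K >= 1)
  T_bins <- 2 / dt
  if (abs(T_bins - round(T_bins)) > 1e-9)
    stop("dt must divide the 2 s trial into an integer number of bins")
  structure(list(dt = dt, T = as.integer(round(T_bins)), K = as.integer(K),
                 chi = chi, n_states = 2L * as.integer(K) + 1L,
                 trial_s = 2), class = "jb_disc")
}

#' @export
print.jb_disc <- function(x, ...) {
  cat("Lattice discretisation: T =", x$T, "bins of", x$dt, "s;",
      x$n_states, "evidence states (K =", x$K, paste0("), chi = ",
      if (is.na(x$chi)) "sigma*sqrt(dt)/2" else x$chi), "\n")
  invisible(x)
}

# resolve the evidence step for a given observation noise
disc_chi <- function(disc, sigma) {
  if (is.na(disc$chi)) sigma * sqrt(disc$dt) / 2 else disc$chi
}

# grid of evidence values (GBP-free units of accumulated observation)
disc_grid <- function(disc, sigma) disc_chi(disc, sigma) * (-disc$K:disc$K)
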