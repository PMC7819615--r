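#' Generate a task schedule
#'
#' Builds one session of the go/stay judgement-bias task: three training
#' blocks of 24, 60 and 24 trials followed by a test block of `n_test`
#' trials.  Test-block coherences are 0.16, 0.02 and 0.01 with the ambiguous
#' levels (0.01, 0.02) on two thirds of trials; every `(theta, mu)` cell is
#' equal-sized and trial order is a seeded uniform permutation within block.
#' In the `"fluctuating_reward"` condition the offered reward follows a sine
#' with additive Gaussian noise (offset 10, amplitude 8, period 60 trials,
#' noise sd 1), affinely rescaled so the realised sequence spans exactly
#' GBP 0.87 to 19.16, while the loss is fixed at -10; in
#' `"fluctuating_loss"` the roles are swapped (losses are stored as negative
#' numbers).  Affect-grid probes occur at the start of the test block and
#' after every 10 test trials.
#'
#' @param condition `"fluctuating_reward"` or `"fluctuating_loss"`.
#' @param seed Integer seed; the schedule is fully reproducible.
#' @param n_test Number of test trials (default 180; must be divisible by 6
#'   and by the probe spacing).
#' @return An object of class `"jb_schedule"`: list with `trials` (data
#'   frame: `block`, `n` index within block, `mu`, `theta`, `R`, `L`,
#'   `condition`), `probe_after` (test-trial counts after which a probe
#'   occurs, including 0 for the baseline probe) and `condition`.
#' @examples
#' sch <- jb_schedule("fluctuating_reward", seed = 1)
#' range(subset(sch$trials, block == "test")$R)
#' @export
jb_schedule <- function(condition = c("fluctuating_reward", "fluctuating_loss"),
                        seed, n_test = 180L) {
  condition <- match.arg(condition)
  if (missing(seed)) stop("a seed is required")
  if (n_test %% 6 != 0) stop("n_test must be divisible by 6")
  set.seed(seed)

  block_thetas <- list(
    train1 = rep(0.32, 24),
    train2 = c(rep(0.04, 20), rep(0.32, 20), rep(0.16, 20)),
    train3 = rep(c(0.16, 0.02, 0.01), each = 8),
    test   = rep(c(0.16, 0.02, 0.01), each = n_test / 3))

  rows <- lapply(names(block_thetas), function(b) {
    th <- block_thetas[[b]]
    # balance direction within each coherence, then shuffle the block
    mu <- integer(length(th))
    for (g in split(seq_along(th), th)) mu[g] <- rep(c(-1L, 1L), length.out = length(g))
    d <- data.frame(block = b, n = seq_along(th), theta = th, mu = mu)
    d[sample.int(nrow(d)), c("block", "theta", "mu")]
  })
  trials <- do.call(rbind, rows)
  trials$n <- stats::ave(seq_len(nrow(trials)), trials$block, FUN = seq_along)
  rownames(trials) <- NULL

  fluct <- sine_stakes(n_test, lo = 0.87, hi = 19.16,
                       offset = 10, amplitude = 8, period = 60, noise_sd = 1)
  trials$R <- 10
  trials$L <- -10
  test_idx <- trials$block == "test"
  if (condition == "fluctuating_reward") {
    trials$R[test_idx] <- fluct
  } else {
    trials$L[test_idx] <- -fluct
  }
  trials$condition <- condition
  trials <- trials[, c("block", "n", "mu", "theta", "R", "L", "condition")]

  structure(list(trials = trials,
                 probe_after = seq(0L, n_test, by = 10L),
                 condition = condition),
            class = "jb_schedule")
}

# sine-plus-noise stakes, affinely rescaled to span [lo, hi] exactly
sine_stakes <- function(n, lo, hi, offset, amplitude, period, noise_sd) {
  raw <- offset + amplitude * sin(2 * pi * seq_len(n) / period) +
    stats::rnorm(n, 0, noise_sd)
  lo + (raw - min(raw)) * (hi - lo) / (max(raw) - min(raw))
}

#' @export
print.jb_schedule <- function(x, ...) {
  tb <- x$trials[x$trials$block == "test", ]
  cat("Judgement-bias session schedule (", x$condition, ")\n", sep = "")
  cat("  blocks:", paste(table(factor(x$trials$block,
      levels = c("train1", "train2", "train3", "test"))), collapse = "/"),
      "trials\n")
  cat(sprintf("  test-block stakes: R in [%.2f, %.2f], L in [%.2f, %.2f]\n",
              min(tb$R), max(tb$R), min(tb$L), max(tb$L)))
  cat("  affect probes after test trials:",
      paste(utils::head(x$probe_after, 4), collapse = ", "), "...\n")
  invisible(x)
}

# test-block trials as a plain data frame (the fitted portion of a session)
test_block <- function(schedule) {
  tr <- schedule$trials[schedule$trials$block == "test", ]
  rownames(tr) <- NULL
  tr
}
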