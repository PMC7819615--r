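disc <- jb_disc()

test_that("trial likelihood conserves over the observation space", {
  p <- jb_default_truth()
  rec <- list(mu = 1, theta = 0.02, R = 12, L = -10, n = 4)
  # sum over every possible observation (each release bin + stay) of the
  # trial likelihood equals one
  probs <- vapply(0:(disc$T - 1), function(b) {
    r <- c(rec, list(action = "go", release_bin = b))
    exp(-trial_nll(r, 0.5, p, disc))
  }, numeric(1))
  p_stay <- exp(-trial_nll(c(rec, list(action = "stay", release_bin = NA)),
                           0.5, p, disc))
  expect_equal(sum(probs) + p_stay, 1, tolerance = 1e-8)
})

test_that("session likelihood is additive over independent trial terms", {
  fx <- fixture_session()
  ses <- fx$session
  p <- jb_params(beta0 = 0.4, betaR = -0.1, alphaR = 0.2, B = 3)
  sn <- session_nll(ses, p, disc)
  expect_equal(sn$nll, sum(-log(sn$p_obs)), tolerance = 1e-10)
  # per-trial probabilities agree with one-off trial_nll at the trace deltas
  for (i in c(1, 20, 55)) {
    expect_equal(-log(sn$p_obs[i]),
                 trial_nll(ses[i, ], sn$trace$delta[i], p, disc),
                 tolerance = 1e-10)
  }
})

test_that("batched and sequential compiled paths agree exactly", {
  fx <- fixture_session()
  ses <- fx$session
  pb <- jb_params(beta0 = 0.4, betaR = -0.15, betaO = -0.02, alphaR = 0.25,
                  gammaPE = 0.6, B = 2.5)
  ps <- pb; ps["betaPE"] <- 1e-290   # forces the sequential branch, numerically nil
  a <- session_nll(ses, pb, disc, want_dists = TRUE)
  b <- session_nll(ses, ps, disc, want_dists = TRUE)
  expect_equal(a$nll, b$nll, tolerance = 1e-10)
  expect_equal(a$p_release, b$p_release, tolerance = 1e-12)
  expect_equal(a$p_timeout, b$p_timeout, tolerance = 1e-12)
  expect_equal(a$trace, b$trace, tolerance = 1e-12)
})

test_that("analytic response distributions match the compiled session path", {
  fx <- fixture_session()
  ses <- fx$session[1:12, ]
  p <- jb_params(beta0 = 0.3, betaPE = 0.05, gammaPE = 0.5, B = 3)
  sn <- session_nll(ses, p, disc, want_dists = TRUE)
  for (i in c(1, 7, 12)) {
    rd <- response_distribution(ses$mu[i], ses$theta[i], ses$R[i], ses$L[i],
                                sn$trace$delta[i], ses$n[i], p, disc)
    expect_equal(sn$p_release[, i], rd$p_release, tolerance = 1e-10)
    expect_equal(sn$p_timeout[i], rd$p_timeout, tolerance = 1e-10)
  }
})

test_that("zero-probability observations are floored, not infinite", {
  fx <- fixture_session()
  ses <- fx$session[1:5, ]
  # lapse-free saturated policy makes some observations essentially impossible
  p <- jb_params(sigma = 0.08, lambda_amb = 0, lambda_ref = 0, B = 60,
                 zeta = 30, phi = 2, beta0 = 5)
  sn <- suppressWarnings(session_nll(ses, p, disc))
  expect_true(is.finite(sn$nll))
})
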