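test_that("schedule invariants: counts, balance, stakes, probes", {
  for (cond in c("fluctuating_reward", "fluctuating_loss")) {
    sch <- jb_schedule(cond, seed = 3)
    tr <- sch$trials
    expect_equal(unname(table(tr$block)[c("train1", "train2", "train3", "test")]),
                 c(24L, 60L, 24L, 180L), ignore_attr = TRUE)
    tb <- tr[tr$block == "test", ]
    expect_equal(nrow(tb), 180)
    expect_setequal(unique(tb$theta), c(0.16, 0.02, 0.01))
    expect_equal(sum(tb$theta %in% c(0.01, 0.02)), 120)  # ambiguous two thirds
    cells <- table(tb$theta, tb$mu)
    expect_true(all(cells == 30))
    # every block balances direction within coherence
    for (b in unique(tr$block)) {
      blk <- tr[tr$block == b, ]
      expect_true(all(table(blk$theta, blk$mu) ==
                        table(blk$theta, blk$mu)[, 1]))
    }
    if (cond == "fluctuating_reward") {
      expect_equal(range(tb$R), c(0.87, 19.16), tolerance = 1e-9)
      expect_true(all(tb$L == -10))
    } else {
      expect_equal(range(-tb$L), c(0.87, 19.16), tolerance = 1e-9)
      expect_true(all(tb$R == 10))
    }
    expect_identical(sch$probe_after, seq(0L, 180L, by = 10L))
  }
  expect_error(jb_schedule("bogus", seed = 1))
})

test_that("schedules and simulations are seed-deterministic", {
  s1 <- jb_schedule("fluctuating_reward", seed = 9)
  s2 <- jb_schedule("fluctuating_reward", seed = 9)
  s3 <- jb_schedule("fluctuating_reward", seed = 10)
  expect_identical(s1$trials, s2$trials)
  expect_false(identical(s1$trials, s3$trials))

  p <- jb_default_truth()
  a <- simulate_session(s1, p, jb_disc(), seed = 5)
  b <- simulate_session(s1, p, jb_disc(), seed = 5)
  d <- simulate_session(s1, p, jb_disc(), seed = 6)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "trace"), attr(b, "trace"))
  expect_false(identical(as.data.frame(a), as.data.frame(d)))
})

test_that("simulated records respect the task contingencies", {
  fx <- fixture_session()
  ses <- fx$session
  go <- ses$action == "go"
  expect_true(all(ses$release_bin[go] %in% 0:19))
  expect_true(all(is.na(ses$release_bin[!go])))
  expect_true(all(ses$outcome[go] == 0))
  stay <- !go
  expect_equal(ses$outcome[stay],
               ifelse(ses$mu[stay] == 1, ses$R[stay], ses$L[stay]))
})

test_that("full lapse flattens the policy to one half", {
  p <- jb_params(lambda_amb = 1, lambda_ref = 1, beta0 = 2)
  lat_a <- value_recursion(15, -5, 2, 1, p, jb_disc(), theta_true = 0.01)
  lat_r <- value_recursion(15, -5, 2, 1, p, jb_disc(), theta_true = 0.16)
  expect_true(all(abs(lat_a$pi - 0.5) < 1e-12))
  expect_true(all(abs(lat_r$pi - 0.5) < 1e-12))
})

test_that("saturated policy stays on clearly favourable trials", {
  p <- jb_params(sigma = 0.08, lambda_amb = 0, lambda_ref = 0, B = 50,
                 zeta = 30, phi = 2, beta0 = 4)
  rd <- suppressWarnings(
    response_distribution(1, 0.16, 20, -1, 4, 1, p, jb_disc()))
  expect_gt(rd$p_timeout, 0.99)
})

test_that("affect generator: centre at null coefficients, monotone injection", {
  fx <- fixture_session()
  aff0 <- simulate_affect(fx$session, fx$schedule, coeffs = list(),
                          noise_sd = 0, seed = 1)
  expect_true(all(aff0$valence == 0L))
  expect_true(all(aff0$arousal == 0L))
  expect_equal(nrow(aff0), 10)  # 90-trial fixture: baseline + 9 probes

  aff <- simulate_affect(fx$session, fx$schedule,
                         coeffs = list(valence = c(wPE = 3)),
                         noise_sd = 0, seed = 1)
  # latent valence is strictly monotone in the standardised wPE predictor
  ord <- order(aff$wPE)
  expect_true(all(diff(aff$valence[ord]) >= 0))
  expect_true(all(aff$valence >= -4 & aff$valence <= 4))
  expect_error(simulate_affect(fx$session, fx$schedule,
                               coeffs = list(valence = c(nope = 1))))
})
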