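test_that("prediction error and earning-rate updates", {
  expect_identical(prediction_error(4, 4), 0)
  expect_identical(prediction_error(10, 4), 6)
  expect_lt(prediction_error(0, 2.5), 0)  # go response against positive value

  expect_identical(update_rbar(3, 10, 0), 3)
  expect_identical(update_rbar(3, 10, 1), 10)
  expect_identical(update_rbar(10, 0, 0.5), 5)
  expect_error(update_rbar(0, 1, 1.5))
})

test_that("weighted prediction error: normalised weights and limits", {
  pe <- c(2, -1, 4, 0.5)
  expect_identical(update_wpe(pe[1], 0.3), pe[1])     # n = 1, any gamma
  expect_identical(update_wpe(pe, 0), pe[4])          # gamma 0 keeps only last
  expect_equal(update_wpe(pe, 1), mean(pe))           # gamma -> 1: plain mean
  expect_equal(update_wpe(pe, 0.9999), mean(pe), tolerance = 1e-3)
  # direct evaluation of the normalised weighted average
  g <- 0.6
  w <- g^(3:0)
  expect_equal(update_wpe(pe, g), sum(w * pe) / sum(w))
  expect_equal(sum(w / sum(w)), 1)
  expect_identical(update_wpe(numeric(), 0.5), 0)     # pre-task state
})

test_that("bias composition is linear in the experience state", {
  p <- jb_params(beta0 = 0.711, betaR = -0.143)
  expect_equal(compose_delta(p, list(Rbar = 1, wPE = 0, wPE2 = 0, O = 0)), 0.568)
  p0 <- jb_params()
  expect_identical(compose_delta(p0, list(Rbar = 3, wPE = 2, wPE2 = 9, O = 5)), 0)
  pO <- jb_params(betaO = -0.018)
  d1 <- compose_delta(pO, list(Rbar = 0, wPE = 0, wPE2 = 0, O = 0))
  d2 <- compose_delta(pO, list(Rbar = 0, wPE = 0, wPE2 = 0, O = 10))
  expect_equal(d2 - d1, -0.18)
})

test_that("experience trace: causality, reproducibility, sign propagation", {
  p <- jb_params(beta0 = 0.5, betaR = -0.2, betaPE = 0.1, betaO = -0.02,
                 alphaR = 0.3, gammaPE = 0.6)
  set.seed(1)
  O <- round(runif(30, -10, 15), 2)
  V00 <- round(runif(30, 0, 5), 2)
  tr <- experience_trace(O, V00, p)

  # delta on trial n depends only on outcomes up to n - 1
  O2 <- O; O2[15] <- O2[15] + 7
  tr2 <- experience_trace(O2, V00, p)
  expect_identical(tr2$delta[1:15], tr$delta[1:15])
  expect_false(tr2$delta[16] == tr$delta[16])

  # replay is exact
  expect_identical(experience_trace(O, V00, p), tr)

  # with betaR < 0 and PEs held fixed, raising a past outcome cannot raise
  # any later delta
  pR <- jb_params(beta0 = 0.5, betaR = -0.2, alphaR = 0.3)
  trR <- experience_trace(O, V00, pR)
  O3 <- O; O3[5] <- O3[5] + 4
  trR2 <- experience_trace(O3, V00, pR)
  expect_true(all(trR2$delta[6:30] <= trR$delta[6:30] + 1e-12))

  # weights of the wPE average always sum to one: a constant PE history
  # gives that constant back at every n
  trc <- experience_trace(rep(3, 10), rep(0, 10), p)
  expect_equal(trc$wPE, rep(3, 10), tolerance = 1e-12)
})

test_that("compiled session trace matches the R replay", {
  fx <- fixture_session()
  ses <- fx$session
  p <- jb_params(beta0 = 0.4, betaR = -0.1, betaO = -0.02, alphaR = 0.2,
                 gammaPE = 0.5, B = 3)
  sn <- session_nll(ses, p, jb_disc())
  rep_tr <- experience_trace(ses$outcome, sn$trace$V00, p)
  expect_equal(sn$trace$delta, rep_tr$delta, tolerance = 1e-10)
  expect_equal(sn$trace$Rbar, rep_tr$Rbar, tolerance = 1e-10)
  expect_equal(sn$trace$wPE, rep_tr$wPE, tolerance = 1e-10)
  expect_equal(sn$trace$wPE2, rep_tr$wPE2, tolerance = 1e-10)
})
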