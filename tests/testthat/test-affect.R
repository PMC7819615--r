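test_that("sign-flip permutation test: exact cases and random agreement", {
  expect_identical(permutation_test_zero(rep(0, 8))$p, 1)

  r <- permutation_test_zero(rep(1, 10))
  expect_true(r$exact)
  expect_equal(r$p, 2 / 1024)

  # random flips approximate the exact enumeration
  set.seed(2)
  x <- rnorm(10, 0.4)
  exact <- permutation_test_zero(x)$p
  rand <- sapply(1:5, function(s) {
    n <- length(x)
    signs <- matrix(sample(c(-1, 1), n * 4000, replace = TRUE), 4000, n)
    (1 + sum(abs(signs %*% x) / n >= abs(mean(x)) - 1e-12)) / 4001
  })
  expect_lt(abs(mean(rand) - exact), 0.02)
  # the package's own random branch (n > 12) is a valid p-value near the
  # normal-theory answer for a clear effect
  y <- c(x, rnorm(4, 0.4))
  pr <- permutation_test_zero(y, n_perm = 4000, seed = 1)
  expect_false(pr$exact)
  expect_true(pr$p > 0 && pr$p <= 1)
  expect_error(permutation_test_zero(3))
})

test_that("parameter-affect GLM: LRT table and location invariance", {
  set.seed(5)
  n <- 24
  ft <- data.frame(participant = 1:n,
                   condition = rep(c("fluctuating_reward", "fluctuating_loss"),
                                   each = n / 2),
                   beta0 = rnorm(n), sigma = rlnorm(n, -2, 0.3),
                   timeout_prob = runif(n, 0.05, 0.3))
  am <- data.frame(participant = 1:n, valence = rnorm(n), arousal = rnorm(n))
  # inject a valence effect on beta0
  ft$beta0 <- ft$beta0 + 0.9 * am$valence

  tab <- glm_params_vs_affect(ft, am)
  expect_setequal(unique(tab$parameter), c("beta0", "sigma", "timeout_prob"))
  expect_true(all(tab$LRT >= 0))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  inj <- tab[tab$parameter == "beta0" & tab$predictor == "valence", ]
  expect_lt(inj$p, 0.01)
  full <- lm(beta0 ~ valence + arousal + condition, data = merge(ft, am))
  expect_gt(coef(full)["valence"], 0)

  # adding a constant to a predictor leaves every LRT unchanged
  am2 <- am; am2$valence <- am2$valence + 100
  tab2 <- glm_params_vs_affect(ft, am2)
  expect_equal(tab$LRT, tab2$LRT, tolerance = 1e-8)
})

test_that("affect GLMM: selection, LRTs, nesting and self-test", {
  set.seed(8)
  n_sub <- 16; n_probe <- 19
  mk <- function(inject_wpe = 0) {
    lapply(1:n_sub, function(i) {
      wPE <- rnorm(n_probe); O <- 0.8 * wPE + rnorm(n_probe, 0, 0.6)
      d <- data.frame(trial_index = seq(0, by = 10, length.out = n_probe),
                      Rbar = rnorm(n_probe), wPE = wPE,
                      wPE2 = rnorm(n_probe)^2, O = O,
                      potential_outcome = rnorm(n_probe),
                      n = seq(0, by = 10, length.out = n_probe) / 50)
      d$valence <- as.integer(pmin(4, pmax(-4, round(
        inject_wpe * d$wPE + rnorm(n_probe, 0, 1) + rnorm(1, 0, 0.5)))))
      d$arousal <- as.integer(pmin(4, pmax(-4, round(rnorm(n_probe)))))
      d
    })
  }
  probes <- probe_predictors(mk(inject_wpe = 1.2),
                             rep(c("fluctuating_reward", "fluctuating_loss"), 8))
  g <- affect_glmm(probes, "valence")
  expect_s3_class(g, "jb_glmm")
  # the injected wPE effect is chosen over its correlated rivals and detected
  expect_true("wPE" %in% g$chosen)
  expect_lt(g$lrt$p[g$lrt$term == "wPE"], 0.001)
  expect_true(all(g$lrt$LRT >= 0))

  # the arousal response with no injected structure yields valid LRTs
  ga <- affect_glmm(probes, "arousal")
  expect_true(all(ga$lrt$LRT >= 0))

  # a model tested against itself has zero deviance difference
  expect_equal(jbpomdp:::lrt_lme(g$model, g$model)$lrt, 0)
})

test_that("arousal-valence association mixed model", {
  set.seed(9)
  probes <- do.call(rbind, lapply(1:10, function(i)
    data.frame(participant = factor(i), valence = rnorm(15),
               arousal = rnorm(15))))
  indep <- arousal_valence_association(probes)
  expect_gte(indep$LRT, 0)
  expect_gt(indep$p, 0.001)

  probes$arousal <- probes$valence + rnorm(nrow(probes), 0, 0.05)
  dep <- arousal_valence_association(probes)
  expect_gt(dep$LRT, 100)
  expect_lt(dep$p, 1e-10)
})
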