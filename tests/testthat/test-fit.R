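test_that("model specs enforce the correlated-predictor exclusions", {
  s <- jb_model_spec(baseline = TRUE, experience = c("rbar", "wpe"))
  expect_setequal(s$free, c("sigma", "lambda_amb", "lambda_ref", "B", "zeta",
                            "phi", "beta0", "betaR", "alphaR", "betaPE",
                            "gammaPE"))
  expect_error(jb_model_spec(experience = c("wpe", "outcome")), "exclusive")
  expect_error(jb_model_spec(experience = c("wpe", "wpe2")), "exclusive")
  expect_error(jb_model_spec(experience = c("rbar", "trials")), "exclusive")
  expect_error(jb_model_spec(experience = "bogus"))
  expect_length(jb_model_spec(baseline = FALSE)$free, 6)
})

test_that("fitting recovers a usable optimum with information criteria", {
  fx <- fixture_session()
  ses <- fx$session
  spec <- jb_model_spec(baseline = TRUE)
  f <- jb_fit(ses, spec, jb_disc(), n_starts = 3, seed = 2,
              control = list(maxfun = 150))

  expect_s3_class(f, "jb_fit")
  expect_named(f$coefficients, spec$free)
  # the reported optimum is the best across starts
  expect_equal(f$nll, min(f$start_nlls))
  # information criteria satisfy their definitions
  expect_equal(f$aic, 2 * f$n_params + 2 * f$nll)
  expect_equal(f$bic, f$n_params * log(nrow(ses)) + 2 * f$nll)
  expect_equal(AIC(f), f$aic)
  expect_equal(BIC(f), f$bic)
  expect_equal(as.numeric(logLik(f)), -f$nll)

  # the fitted nll is reproduced by a fresh likelihood evaluation
  expect_equal(session_nll(ses, f$params, jb_disc())$nll, f$nll,
               tolerance = 1e-8)

  # near-idempotence: polishing the returned optimum with a fresh local
  # search from that point yields only a marginal improvement
  obj <- function(th) suppressWarnings(
    session_nll(ses, jbpomdp:::spec_to_params(spec, th), jb_disc())$nll)
  polish <- suppressWarnings(minqa::bobyqa(
    f$coefficients, obj, lower = f$bounds$lower, upper = f$bounds$upper,
    control = list(maxfun = 200, rhobeg = 1e-3, rhoend = 1e-7, iprint = 0)))
  expect_lt(f$nll - polish$fval, 0.05)
})

test_that("fit methods: coefficients, prediction, residuals, simulation, plot", {
  fx <- fixture_session()
  ses <- fx$session
  f <- jb_fit(ses, jb_model_spec(baseline = TRUE), jb_disc(), n_starts = 2,
              seed = 4, control = list(maxfun = 120))

  expect_length(coef(f, full = TRUE), 14)
  expect_identical(unname(coef(f, full = TRUE)[f$spec$free]),
                   unname(coef(f)))

  pr <- predict(f)
  expect_equal(nrow(pr), nrow(ses))
  expect_true(all(pr$p_stay >= 0 & pr$p_stay <= 1))
  expect_true(all(pr$expected_bin >= 0 & pr$expected_bin <= jb_disc()$T))
  expect_equal(colSums(attr(pr, "p_release")) + pr$p_stay,
               rep(1, nrow(ses)), tolerance = 1e-8, ignore_attr = TRUE)

  r <- residuals(f)
  expect_length(r, nrow(ses))
  expect_true(all(abs(r) <= 1))

  sims <- simulate(f, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), nrow(ses))
  expect_true(all(sims[[1]]$action %in% c("stay", "go")))

  expect_output(print(f), "POMDP fit")
  expect_output(print(summary(f)), "stay rate")
  pdf(NULL)
  agg <- plot(f)
  dev.off()
  expect_true(all(c("level", "observed", "predicted") %in% names(agg)))
})
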