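#' Sign-flip permutation test of a mean against zero
#'
#' Two-sided test that the mean of per-participant estimates is zero, under
#' the null of symmetric estimates: every sign assignment is equally
#' likely.  With 12 or fewer participants all `2^n` assignments are
#' enumerated and the p-value is the exact exceedance fraction of
#' `|mean|`; otherwise `n_perm` random assignments are drawn and the
#' add-one estimator `(1 + #exceed) / (1 + n_perm)` is used.
#'
#' @param estimates Numeric vector of per-participant estimates.
#' @param n_perm Number of random sign assignments when enumeration is
#'   infeasible.
#' @param seed Integer seed for the random branch.
#' @return A list: `p` (p-value), `mean` (observed mean), `exact` (logical),
#'   `n_used` (assignments evaluated).
#' @examples
#' permutation_test_zero(rep(1, 10))$p  # 2/1024
#' @export
permutation_test_zero <- function(estimates, n_perm = 10000, seed = 1) {
  n <- length(estimates)
  if (n < 2) stop("need at least 2 participants")
  obs <- abs(mean(estimates))
  if (all(estimates == 0)) return(list(p = 1, mean = 0, exact = TRUE, n_used = 2^n))
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm <- abs(signs %*% estimates) / n
    p <- mean(perm >= obs - 1e-12)
    list(p = p, mean = mean(estimates), exact = TRUE, n_used = 2^n)
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
    perm <- abs(signs %*% estimates) / n
    p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
    list(p = p, mean = mean(estimates), exact = FALSE, n_used = n_perm)
  }
}

# ML likelihood-ratio test between two nested lm fits
lrt_lm <- function(full, reduced) {
  lrt <- as.numeric(2 * (stats::logLik(full) - stats::logLik(reduced)))
  df <- attr(stats::logLik(full), "df") - attr(stats::logLik(reduced), "df")
  list(lrt = max(lrt, 0), df = df,
       p = stats::pchisq(max(lrt, 0), df, lower.tail = FALSE))
}

# ML likelihood-ratio test between two nested lme fits
lrt_lme <- function(full, reduced) {
  lrt <- as.numeric(2 * (stats::logLik(full) - stats::logLik(reduced)))
  df <- attr(stats::logLik(full), "df") - attr(stats::logLik(reduced), "df")
  list(lrt = max(lrt, 0), df = df,
       p = stats::pchisq(max(lrt, 0), df, lower.tail = FALSE))
}

#' Relate fitted parameters to mean reported affect
#'
#' For each fitted quantity (each free bias/psychometric parameter, with the
#' mean timeout probability in place of `zeta` and `phi`), fits the general
#' linear model `estimate ~ valence + arousal + condition` across
#' participants and reports the likelihood-ratio test for dropping each
#' affect predictor.
#'
#' @param fit_table A [jb_fit_cohort()] `table` (columns `participant`,
#'   `condition`, parameter estimates, `timeout_prob`).
#' @param affect_means Data frame: `participant`, `valence`, `arousal`
#'   (session means of the reported affect).
#' @param parameters Which columns of `fit_table` to analyse; defaults to
#'   every estimate column except `zeta` and `phi`.
#' @return A data frame: `parameter`, `predictor`, `LRT`, `p`.
#' @export
glm_params_vs_affect <- function(fit_table, affect_means, parameters = NULL) {
  d <- merge(fit_table, affect_means, by = "participant")
  if (nrow(d) < 4) stop("too few participants for the GLM")
  if (is.null(parameters))
    parameters <- setdiff(names(fit_table),
                          c("participant", "condition", "zeta", "phi"))
  use_cond <- length(unique(d$condition)) > 1
  rhs_full <- if (use_cond) "valence + arousal + condition" else "valence + arousal"
  if (stats::sd(d$valence) == 0 || stats::sd(d$arousal) == 0 ||
      abs(stats::cor(d$valence, d$arousal)) > 0.999)
    stop("collinear affect predictors: valence/arousal")
  out <- list()
  for (par in parameters) {
    full <- stats::lm(stats::reformulate(rhs_full, par), data = d)
    for (pred in c("arousal", "valence")) {
      reduced <- stats::update(full, stats::as.formula(paste(". ~ . -", pred)))
      tst <- lrt_lm(full, reduced)
      out[[length(out) + 1]] <- data.frame(parameter = par, predictor = pred,
                                           LRT = tst$lrt, p = tst$p)
    }
  }
  do.call(rbind, out)
}

#' Assemble probe-wise predictors across a cohort
#'
#' Binds each participant's standardised probe-time predictors (experience
#' state immediately prior to each probe, scaled by the participant's own
#' sd; potential outcome `(R + L) / 2`; trials completed) to their affect
#' reports.
#'
#' @param affect_list List of per-participant [simulate_affect()] frames
#'   (or equivalent: `trial_index`, `valence`, `arousal` plus predictors).
#' @param conditions Character vector of per-participant conditions.
#' @return A data frame with a `participant` factor and `condition` column,
#'   ready for [affect_glmm()].
#' @export
probe_predictors <- function(affect_list, conditions) {
  stopifnot(length(affect_list) == length(conditions))
  d <- do.call(rbind, lapply(seq_along(affect_list), function(i)
    cbind(participant = i, condition = unname(conditions[i]),
          affect_list[[i]])))
  d$participant <- factor(d$participant)
  d$condition <- factor(d$condition)
  d
}

#' Mixed-model analysis of probe-wise affect
#'
#' Gaussian linear mixed model of one affect response with a participant
#' random intercept (fitted by ML so deviances are comparable).  The
#' correlated experience predictors are never co-entered: one of
#' `{wPE, wPE2, O}` and one of `{Rbar, n}` are chosen by BIC across
#' single-predictor candidate models (each also containing the potential
#' outcome and condition), then the winning model gains condition
#' interactions.  Each term is assessed by a likelihood-ratio test from
#' nested ML refits; a significant experience-by-condition interaction is
#' followed by condition-split models with Benjamini-Hochberg adjustment
#' across that post-hoc family.
#'
#' @param probes A [probe_predictors()] frame.
#' @param response `"valence"` or `"arousal"`.
#' @param alpha Significance level used to trigger post-hoc splits.
#' @return An object of class `"jb_glmm"`: list with `response`, `chosen`
#'   (selected experience predictors), `model` (the full `nlme::lme` fit
#'   with interactions), `main_model` (the interaction-free fit whose
#'   coefficient table is reported as `fixed`), `lrt` (per-term LRT table:
#'   main effects tested against `main_model`, interactions against
#'   `model`), `bic_table` (candidate comparison) and `posthoc`
#'   (condition-split results or `NULL`).
#' @export
affect_glmm <- function(probes, response = c("valence", "arousal"),
                        alpha = 0.05) {
  response <- match.arg(response)
  d <- probes
  d$.y <- d[[response]]
  if (length(unique(d$participant)) < 2) stop("need >= 2 participants")
  ctrl <- nlme::lmeControl(opt = "optim", maxIter = 200, msMaxIter = 200,
                           returnObject = TRUE)
  fit <- function(rhs) {
    nlme::lme(stats::as.formula(paste(".y ~", rhs)), random = ~ 1 | participant,
              data = d, method = "ML", control = ctrl)
  }
  use_cond <- length(unique(d$condition)) > 1
  base_terms <- c("potential_outcome", if (use_cond) "condition")

  cand_bic <- vapply(c("wPE", "wPE2", "O", "Rbar", "n"), function(tm)
    stats::BIC(fit(paste(c(base_terms, tm), collapse = " + "))), numeric(1))
  bic_table <- data.frame(term = names(cand_bic), bic = unname(cand_bic))
  pick <- function(group) group[which.min(cand_bic[group])]
  e1 <- pick(c("wPE", "wPE2", "O"))
  e2 <- pick(c("Rbar", "n"))

  main <- c("potential_outcome", e1, e2, if (use_cond) "condition")
  inter <- if (use_cond) paste0(c("potential_outcome", e1), ":condition") else NULL
  rhs_full <- paste(c(main, inter), collapse = " + ")
  full <- fit(rhs_full)
  main_model <- fit(paste(main, collapse = " + "))

  # interactions are tested against the full model; main effects against the
  # interaction-free model (dropping a main effect while its factor
  # interaction remains would only reparameterise the same span)
  lrt_tab <- do.call(rbind, c(
    lapply(main, function(tm) {
      reduced <- fit(paste(setdiff(main, tm), collapse = " + "))
      tst <- lrt_lme(main_model, reduced)
      data.frame(term = tm, LRT = tst$lrt, df = tst$df, p = tst$p)
    }),
    lapply(inter, function(tm) {
      reduced <- fit(paste(setdiff(c(main, inter), tm), collapse = " + "))
      tst <- lrt_lme(full, reduced)
      data.frame(term = tm, LRT = tst$lrt, df = tst$df, p = tst$p)
    })))

  posthoc <- NULL
  sig_inter <- lrt_tab$term[grepl(":condition", lrt_tab$term) &
                              lrt_tab$p < alpha]
  if (length(sig_inter)) {
    vars <- sub(":condition", "", sig_inter)
    main_nc <- setdiff(main, "condition")
    ph <- list()
    for (cond in levels(d$condition)) {
      dc <- d[d$condition == cond, ]
      for (v in vars) {
        fullc <- nlme::lme(stats::as.formula(paste(".y ~", paste(main_nc, collapse = " + "))),
                           random = ~ 1 | participant, data = dc,
                           method = "ML", control = ctrl)
        redc <- nlme::lme(stats::as.formula(paste(".y ~", paste(setdiff(main_nc, v), collapse = " + "))),
                          random = ~ 1 | participant, data = dc,
                          method = "ML", control = ctrl)
        tst <- lrt_lme(fullc, redc)
        ph[[length(ph) + 1]] <- data.frame(condition = cond, term = v,
                                           LRT = tst$lrt, p = tst$p)
      }
    }
    posthoc <- do.call(rbind, ph)
    posthoc$p_fdr <- stats::p.adjust(posthoc$p, method = "BH")
  }

  structure(list(response = response, chosen = c(e1, e2), model = full,
                 main_model = main_model,
                 fixed = summary(main_model)$tTable, lrt = lrt_tab,
                 bic_table = bic_table, posthoc = posthoc),
            class = "jb_glmm")
}

#' @export
print.jb_glmm <- function(x, ...) {
  cat("Mixed model of reported", x$response, "| experience predictors:",
      paste(x$chosen, collapse = ", "), "\n")
  print(transform(x$lrt, LRT = round(LRT, 3), p = signif(p, 3)),
        row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat("post-hoc condition splits (FDR-adjusted):\n")
    print(transform(x$posthoc, LRT = round(LRT, 3), p = signif(p, 3),
                    p_fdr = signif(p_fdr, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Association between reported arousal and valence
#'
#' Single-predictor mixed model of valence on arousal with a participant
#' random intercept; returns the likelihood-ratio test for the association.
#'
#' @param probes A [probe_predictors()] frame.
#' @return A list: `LRT`, `df`, `p`, and the fitted `model`.
#' @export
arousal_valence_association <- function(probes) {
  ctrl <- nlme::lmeControl(opt = "optim", returnObject = TRUE)
  full <- nlme::lme(valence ~ arousal, random = ~ 1 | participant,
                    data = probes, method = "ML", control = ctrl)
  null <- nlme::lme(valence ~ 1, random = ~ 1 | participant,
                    data = probes, method = "ML", control = ctrl)
  tst <- lrt_lme(full, null)
  list(LRT = tst$lrt, df = tst$df, p = tst$p, model = full)
}
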