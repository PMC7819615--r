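#' Stepwise AIC/BIC model selection across participants
#'
#' Reproduces the stepwise construction of the bias model.  Step 0 fits the
#' six core parameters to every session.  Step 1 tests adding the baseline
#' bias `beta0`, kept if the group-summed BIC decreases.  Step 2 tests each
#' experience/time term singly on top of the step-1 winner (`rbar` with its
#' learning rate, `wpe`/`wpe2` with the forgetting factor, `outcome`,
#' `trials`); the best improving term from each correlated group
#' (`{wpe, wpe2, outcome}` and `{rbar, trials}`) is retained, and mutually
#' correlated terms are never co-entered.  The final candidate set (step-1
#' winner, each improving single addition, and the combination of group
#' winners) is compared on summed AIC and BIC; the BIC-best model is
#' selected and the AIC-best recorded.
#'
#' @param sessions A list of session data frames (one per participant), or
#'   a single data frame with a `participant` column.
#' @param disc A [jb_disc()] discretisation.
#' @param n_starts Optimisation starts per fit.
#' @param seed Integer seed.
#' @param control Optimiser control passed to [jb_fit()].
#' @return An object of class `"jb_selection"`: list with `selected` (the
#'   BIC-best [jb_model_spec()]), `aic_best` (label), `table` (per-candidate
#'   summed nll/AIC/BIC), and `fits` (per-participant fits of the selected
#'   model).
#' @export
jb_select <- function(sessions, disc = jb_disc(), n_starts = 5, seed = 1,
                      control = list()) {
  sessions <- as_session_list(sessions)
  fit_spec <- function(spec, seed_off) {
    lapply(seq_along(sessions), function(i)
      jb_fit(sessions[[i]], spec, disc, n_starts = n_starts,
             seed = seed + 1000 * seed_off + i, control = control))
  }
  crit <- function(fits) c(nll = sum(vapply(fits, `[[`, 0, "nll")),
                           aic = sum(vapply(fits, `[[`, 0, "aic")),
                           bic = sum(vapply(fits, `[[`, 0, "bic")))

  candidates <- list()
  fits_cache <- list()
  add_candidate <- function(label, spec, fits) {
    candidates[[label]] <<- c(list(spec = spec), as.list(crit(fits)))
    fits_cache[[label]] <<- fits
  }

  core_spec <- jb_model_spec(baseline = FALSE)
  core_fits <- fit_spec(core_spec, 0)
  add_candidate("core", core_spec, core_fits)

  base_spec <- jb_model_spec(baseline = TRUE)
  base_fits <- fit_spec(base_spec, 1)
  add_candidate("core+baseline", base_spec, base_fits)

  step1 <- if (candidates[["core+baseline"]]$bic < candidates[["core"]]$bic)
    "core+baseline" else "core"
  step1_spec <- candidates[[step1]]$spec
  step1_bic <- candidates[[step1]]$bic

  terms <- c("rbar", "wpe", "wpe2", "outcome", "trials")
  improving <- character()
  for (k in seq_along(terms)) {
    sp <- jb_model_spec(baseline = step1_spec$baseline, experience = terms[k])
    fits <- fit_spec(sp, 1 + k)
    add_candidate(paste0(step1, "+", terms[k]), sp, fits)
    if (candidates[[paste0(step1, "+", terms[k])]]$bic < step1_bic)
      improving <- c(improving, terms[k])
  }

  # combine the best improving term of each correlated group
  pick_best <- function(group) {
    g <- intersect(group, improving)
    if (!length(g)) return(NULL)
    bics <- vapply(g, function(tm) candidates[[paste0(step1, "+", tm)]]$bic,
                   numeric(1))
    g[which.min(bics)]
  }
  combo <- c(pick_best(c("wpe", "wpe2", "outcome")), pick_best(c("rbar", "trials")))
  if (length(combo) > 1) {
    sp <- jb_model_spec(baseline = step1_spec$baseline, experience = combo)
    fits <- fit_spec(sp, 99)
    add_candidate(paste0(step1, "+", paste(combo, collapse = "+")), sp, fits)
  }

  tab <- do.call(rbind, lapply(names(candidates), function(lb)
    data.frame(model = lb, n_free = length(candidates[[lb]]$spec$free),
               nll = candidates[[lb]]$nll, aic = candidates[[lb]]$aic,
               bic = candidates[[lb]]$bic)))
  sel_label <- tab$model[which.min(tab$bic)]
  structure(list(selected = candidates[[sel_label]]$spec,
                 selected_label = sel_label,
                 aic_best = tab$model[which.min(tab$aic)],
                 table = tab,
                 fits = fits_cache[[sel_label]]),
            class = "jb_selection")
}

#' @export
print.jb_selection <- function(x, ...) {
  cat("Stepwise model selection over", length(x$fits), "participants\n")
  print(transform(x$table, nll = round(nll, 2), aic = round(aic, 2),
                  bic = round(bic, 2)), row.names = FALSE)
  cat("BIC-best:", x$selected_label, "| AIC-best:", x$aic_best, "\n")
  invisible(x)
}

as_session_list <- function(sessions) {
  if (is.data.frame(sessions)) {
    if (!"participant" %in% names(sessions))
      stop("a single data frame needs a 'participant' column")
    sessions <- split(sessions, sessions$participant)
  }
  if (!length(sessions)) stop("at least one session is required")
  lapply(sessions, as.data.frame)
}

#' Per-participant fit table
#'
#' Fits one model spec to every session and assembles the tidy table used
#' by the affect analyses: one row per participant with the free-parameter
#' estimates and the mean timeout probability substituted for
#' `zeta`/`phi`.
#'
#' @inheritParams jb_select
#' @param spec A [jb_model_spec()] to fit to everyone.
#' @return A list with `fits` (per-participant [jb_fit()] objects) and
#'   `table` (data frame: `participant`, `condition`, one column per free
#'   parameter, and `timeout_prob`).
#' @export
jb_fit_cohort <- function(sessions, spec = jb_model_spec(), disc = jb_disc(),
                          n_starts = 10, seed = 1, control = list()) {
  sessions <- as_session_list(sessions)
  fits <- lapply(seq_along(sessions), function(i)
    jb_fit(sessions[[i]], spec, disc, n_starts = n_starts, seed = seed + i,
           control = control))
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    cond <- if ("condition" %in% names(sessions[[i]]))
      sessions[[i]]$condition[1] else NA_character_
    cbind(data.frame(participant = names(sessions)[i] %||% i, condition = cond),
          as.data.frame(as.list(f$coefficients)),
          timeout_prob = mean_timeout_probability(f$params, disc))
  }))
  rownames(tab) <- NULL
  list(fits = fits, table = tab)
}
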