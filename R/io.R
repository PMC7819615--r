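#' Write and read session CSVs
#'
#' Sessions are stored as tidy UTF-8 comma-separated files, one row per
#' trial: `participant`, `condition`, `block`, `n`, `mu`, `theta`, `R`,
#' `L`, `action`, `release_bin`, `outcome`.  Monetary values are GBP floats
#' with losses negative.  `read_sessions()` validates the schema (required
#' columns; test-block coherences in {0.16, 0.02, 0.01}; `release_bin` set
#' exactly for go responses; outcomes consistent with action and stimulus)
#' and reports the offending row on failure.  Unknown columns are preserved.
#' A column mapping (`c(file_column = "canonical_name")`) lets externally
#' deposited layouts be ingested without editing the file.
#'
#' @param sessions A data frame of trials with a `participant` column.
#' @param path File path.
#' @param mapping Optional named character vector renaming file columns to
#'   the canonical schema.
#' @return `read_sessions()`: a named list of per-participant session data
#'   frames.  `write_sessions()`: the path, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  utils::write.csv(sessions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    hit <- names(d) %in% names(mapping)
    names(d)[hit] <- unname(mapping[names(d)[hit]])
  }
  need <- c("participant", "condition", "n", "mu", "theta", "R", "L",
            "action", "release_bin", "outcome")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!"block" %in% names(d)) d$block <- "test"

  fail <- function(i, why) stop("schema error at row ", i, ": ", why)
  for (i in seq_len(nrow(d))) {
    r <- d[i, ]
    if (!r$action %in% c("stay", "go")) fail(i, "action must be stay/go")
    if (!r$mu %in% c(-1, 1)) fail(i, "mu must be -1 or +1")
    if (r$block == "test" && !r$theta %in% c(0.16, 0.02, 0.01))
      fail(i, paste("test-block coherence", r$theta, "not in {0.16, 0.02, 0.01}"))
    if (r$action == "stay" && !is.na(r$release_bin))
      fail(i, "stay response with a release_bin set")
    if (r$action == "go" && is.na(r$release_bin))
      fail(i, "go response without a release_bin")
    expected <- if (r$action == "go") 0 else if (r$mu == 1) r$R else r$L
    if (abs(r$outcome - expected) > 1e-6)
      fail(i, sprintf("outcome %.2f inconsistent with action/stimulus (expected %.2f)",
                      r$outcome, expected))
    if (r$R < 0 || r$L > 0) fail(i, "need R >= 0 and L <= 0")
  }
  split(d, d$participant)
}

#' Write and read affect-probe CSVs
#'
#' One row per probe: `participant`, `trial_index`, `valence`, `arousal`
#' (integer grid levels coded -4..+4).
#'
#' @param affect A data frame of probes with a `participant` column.
#' @param path File path.
#' @return `read_affect()`: the validated data frame; `write_affect()`: the
#'   path, invisibly.
#' @export
write_affect <- function(affect, path) {
  utils::write.csv(affect, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_affect
#' @export
read_affect <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "trial_index", "valence", "arousal")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  bad <- which(d$valence < -4 | d$valence > 4 | d$arousal < -4 | d$arousal > 4)
  if (length(bad)) stop("schema error at row ", bad[1],
                        ": affect levels must lie in -4..4")
  d
}

#' Pipeline configuration
#'
#' A serialisable bundle of every setting the pipeline needs; round-trips
#' losslessly through YAML or JSON.  All stage seeds derive
#' deterministically from the global `seed`.
#'
#' @param seed Global integer seed.
#' @param n_participants Cohort size for simulation.
#' @param n_test Test-block length.
#' @param dt,K Discretisation settings (see [jb_disc()]).
#' @param n_starts Optimisation starts per participant.
#' @param maxfun Function-evaluation budget per start.
#' @param select Run stepwise selection (`TRUE`) or fit `experience` +
#'   baseline directly.
#' @param experience Experience terms fitted when `select = FALSE`.
#' @param n_perm Permutation count.
#' @param alpha Significance level for post-hoc splits.
#' @param affect_coeffs Injected affect-generator coefficients (see
#'   [simulate_affect()]).
#' @param affect_noise_sd Latent affect noise sd.
#' @param sessions_csv Optional path to an existing session CSV (skips
#'   simulation).
#' @param out_dir Output directory.
#' @return A list of class `"jb_config"`.
#' @export
jb_config <- function(seed = 1, n_participants = 6, n_test = 180L,
                      dt = 0.1, K = 40, n_starts = 5, maxfun = 400,
                      select = FALSE, experience = "rbar", n_perm = 10000,
                      alpha = 0.05,
                      affect_coeffs = list(valence = c(wPE = 0.5,
                                                       potential_outcome = 0.3),
                                           arousal = c(n = -0.4)),
                      affect_noise_sd = 1, sessions_csv = NULL,
                      out_dir = "jbpomdp_out") {
  structure(as.list(environment()), class = "jb_config")
}

#' Save / load a pipeline configuration
#'
#' Format follows the file extension: `.json` uses JSON, anything else YAML.
#'
#' @param config A [jb_config()].
#' @param path File path.
#' @return `load_config()`: the configuration; `save_config()`: the path,
#'   invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  # named numeric vectors lose their names in YAML/JSON; store as maps
  x$affect_coeffs <- lapply(x$affect_coeffs, as.list)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  cfg <- do.call(jb_config, list())
  for (nm in names(x)) {
    v <- x[[nm]]
    if (nm == "affect_coeffs")
      v <- lapply(v, function(e) unlist(e))
    cfg[[nm]] <- v
  }
  # restore integer-ish types lost in serialisation
  cfg$n_test <- as.integer(cfg$n_test)
  cfg$sessions_csv <- if (is.null(x$sessions_csv)) NULL else x$sessions_csv
  cfg
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a cohort, fit every participant (stepwise selection or
#' a fixed spec), build the experience traces and probe predictors, run the
#' affect statistics, and write `sessions.csv`, `affect.csv`, `fits.csv`,
#' `trace.csv`, `selection_report.json`, `affect_report.json` and a
#' provenance log into the configured output directory.  Identical
#' configurations (including the seed) give byte-identical outputs.
#'
#' @param config A [jb_config()].
#' @return Invisibly, a list with the in-memory results (`fit_cohort`,
#'   `selection`, `glmms`, `perm`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "jb_config"))
  if (!is.null(config$sessions_csv) && !file.exists(config$sessions_csv))
    stop("input path does not exist: ", config$sessions_csv)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  disc <- jb_disc(dt = config$dt, K = config$K)
  ctl <- list(maxfun = config$maxfun)
  paths <- file.path(config$out_dir,
                     c(sessions = "sessions.csv", affect = "affect.csv",
                       fits = "fits.csv", trace = "trace.csv",
                       selection = "selection_report.json",
                       affect_report = "affect_report.json",
                       provenance = "provenance.json"))
  names(paths) <- c("sessions", "affect", "fits", "trace", "selection",
                    "affect_report", "provenance")

  stage_seed <- function(k) (config$seed * 113 + k * 10007) %% .Machine$integer.max

  # --- data: simulate or load -------------------------------------------
  if (is.null(config$sessions_csv)) {
    cohort <- simulate_cohort(config$n_participants, jb_default_truth(),
                              disc = disc, seed = stage_seed(1),
                              n_test = config$n_test)
    sessions <- split(cohort$sessions, cohort$sessions$participant)
    affect_list <- lapply(seq_along(sessions), function(i)
      simulate_affect(NULL, cohort$schedules[[i]], config$affect_coeffs,
                      config$affect_noise_sd, seed = stage_seed(100 + i),
                      trace = cohort$traces[[i]]))
    conditions <- vapply(sessions, function(s) s$condition[1], character(1))
    write_sessions(cohort$sessions, paths["sessions"])
    aff_all <- probe_predictors(affect_list, conditions)
    write_affect(aff_all[, c("participant", "trial_index", "valence", "arousal")],
                 paths["affect"])
  } else {
    sessions <- read_sessions(config$sessions_csv)
    conditions <- vapply(sessions, function(s) s$condition[1], character(1))
    affect_list <- NULL
    aff_all <- NULL
  }

  # --- fitting ----------------------------------------------------------
  test_sessions <- lapply(sessions, function(s) s[s$block == "test", ])
  selection <- NULL
  if (isTRUE(config$select)) {
    selection <- jb_select(test_sessions, disc, n_starts = config$n_starts,
                           seed = stage_seed(2), control = ctl)
    spec <- selection$selected
  } else {
    spec <- jb_model_spec(baseline = TRUE, experience = config$experience)
  }
  fc <- jb_fit_cohort(test_sessions, spec, disc, n_starts = config$n_starts,
                      seed = stage_seed(3), control = ctl)
  utils::write.csv(fc$table, paths["fits"], row.names = FALSE)
  traces <- do.call(rbind, lapply(seq_along(fc$fits), function(i)
    cbind(participant = i, fc$fits[[i]]$trace)))
  utils::write.csv(traces, paths["trace"], row.names = FALSE)

  sel_report <- if (is.null(selection)) {
    list(mode = "fixed_spec", spec = spec$free)
  } else {
    list(mode = "stepwise", selected = selection$selected_label,
         aic_best = selection$aic_best, table = selection$table)
  }
  jsonlite::write_json(sel_report, paths["selection"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")

  # --- statistics -------------------------------------------------------
  perm <- lapply(intersect(c("beta0", "betaR", "betaPE", "betaPE2", "betaO",
                             "beta_n"), spec$free), function(w)
    c(parameter = w,
      permutation_test_zero(fc$table[[w]], config$n_perm, stage_seed(4))[c("p", "mean")]))
  glmms <- NULL
  glm_tab <- NULL
  avl <- NULL
  if (!is.null(aff_all)) {
    glmms <- list(valence = affect_glmm(aff_all, "valence", config$alpha),
                  arousal = affect_glmm(aff_all, "arousal", config$alpha))
    affect_means <- stats::aggregate(cbind(valence, arousal) ~ participant,
                                     data = aff_all, FUN = mean)
    glm_tab <- glm_params_vs_affect(fc$table, affect_means)
    avl <- arousal_valence_association(aff_all)
  }
  report <- list(
    permutation = perm,
    glm_params_vs_affect = glm_tab,
    valence_lrt = if (!is.null(glmms)) glmms$valence$lrt,
    arousal_lrt = if (!is.null(glmms)) glmms$arousal$lrt,
    arousal_valence = if (!is.null(avl)) avl[c("LRT", "df", "p")])
  jsonlite::write_json(report, paths["affect_report"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", null = "null")

  prov <- list(seed = config$seed, n_participants = length(sessions),
               spec = spec$free, dt = config$dt, K = config$K,
               package_version = as.character(utils::packageVersion("jbpomdp")),
               r_version = R.version.string)
  jsonlite::write_json(prov, paths["provenance"], auto_unbox = TRUE, digits = NA)

  invisible(list(fit_cohort = fc, selection = selection, glmms = glmms,
                 glm_params = glm_tab, perm = perm, arousal_valence = avl,
                 paths = paths))
}
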