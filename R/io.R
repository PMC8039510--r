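# Readers, writers and the pipeline driver.
#
# Observation CSV dialect (comma-separated, UTF-8, dot decimal, header row):
#   subject_id, time_min, analyte, value, unit
# with analyte in {glucose, insulin, glucose_basal, insulin_basal}; glucose
# rows in mmol/L, insulin rows in pmol/L, no silent unit conversion. The
# basal rows carry the end-point basal measurements (one row per subject
# and analyte). Covariate CSV: subject_id, age_yr, weight_kg, height_cm,
# bmi_kg_m2, sex, cohort {ND, T2D}, test_type {IVGTT, IM-IVGTT}, dose_mmol.

OBS_COLUMNS <- c("subject_id", "time_min", "analyte", "value", "unit")

#' Write observation records
#'
#' @param subjects List of [subject_data()] objects.
#' @param path Output CSV path.
#' @export
write_observations <- function(subjects, path) {
  rows <- lapply(subjects, function(s) {
    rbind(
      data.frame(subject_id = s$subject_id, time_min = s$obs_times,
                 analyte = "glucose", value = s$obs_glucose, unit = "mmol/L"),
      data.frame(subject_id = s$subject_id, time_min = s$forcing$times,
                 analyte = "insulin", value = s$forcing$concentrations,
                 unit = "pmol/L"),
      data.frame(subject_id = s$subject_id, time_min = max(s$obs_times),
                 analyte = "glucose_basal", value = s$Gbasal, unit = "mmol/L"),
      data.frame(subject_id = s$subject_id, time_min = max(s$forcing$times),
                 analyte = "insulin_basal", value = s$Ibasal, unit = "pmol/L"))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read observation records
#'
#' Assembles [subject_data()] objects from the long-format observation CSV;
#' units are validated and never converted. The early-sample filter is NOT
#' applied here -- it is an explicit pipeline step.
#'
#' @param path Observation CSV path.
#' @param covariates Optional covariate table (data frame or CSV path)
#'   supplying dose, test type and covariates.
#' @return List of [subject_data()] objects.
#' @export
read_observations <- function(path, covariates = NULL) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  tb <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(OBS_COLUMNS %in% names(tb)))
    abort_parse(paste0("observation file must have columns ",
                       paste(OBS_COLUMNS, collapse = ", ")))
  exp_unit <- c(glucose = "mmol/L", glucose_basal = "mmol/L",
                insulin = "pmol/L", insulin_basal = "pmol/L")
  bad_analyte <- !tb$analyte %in% names(exp_unit)
  if (any(bad_analyte))
    abort_parse(sprintf("unknown analyte '%s' at row %d",
                        tb$analyte[which(bad_analyte)[1]], which(bad_analyte)[1]))
  bad_unit <- tb$unit != exp_unit[tb$analyte]
  if (any(bad_unit))
    abort_parse(sprintf(
      "unsupported unit '%s' for analyte '%s' at row %d (no conversion is attempted)",
      tb$unit[which(bad_unit)[1]], tb$analyte[which(bad_unit)[1]], which(bad_unit)[1]))

  cov_tb <- NULL
  if (!is.null(covariates)) {
    cov_tb <- if (is.character(covariates)) read_covariates(covariates) else covariates
  }
  ids <- unique(tb$subject_id)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    sub <- tb[tb$subject_id == id, , drop = FALSE]
    gl <- sub[sub$analyte == "glucose", , drop = FALSE]
    ins <- sub[sub$analyte == "insulin", , drop = FALSE]
    if (nrow(gl) == 0)
      abort_parse(sprintf("subject %s has no glucose rows", id))
    if (nrow(ins) < 2)
      abort_parse(sprintf("subject %s has fewer than 2 insulin rows", id))
    if (any(diff(gl$time_min) <= 0))
      abort_parse(sprintf("non-monotone glucose times for subject %s", id))
    if (any(diff(ins$time_min) <= 0))
      abort_parse(sprintf("non-monotone insulin times for subject %s", id))
    gb <- sub$value[sub$analyte == "glucose_basal"]
    ib <- sub$value[sub$analyte == "insulin_basal"]
    if (length(gb) != 1 || length(ib) != 1)
      abort_parse(sprintf("subject %s is missing basal rows (glucose_basal/insulin_basal)", id))
    test_type <- "IVGTT"; dose <- NA_real_; covrow <- list()
    if (!is.null(cov_tb)) {
      i <- match(id, cov_tb$subject_id)
      if (is.na(i))
        abort_parse(sprintf("subject %s absent from the covariate table", id))
      test_type <- cov_tb$test_type[i]
      dose <- cov_tb$dose_mmol[i]
      covrow <- list(age_yr = cov_tb$age_yr[i], weight_kg = cov_tb$weight_kg[i],
                     height_cm = cov_tb$height_cm[i],
                     bmi_kg_m2 = cov_tb$bmi_kg_m2[i], sex = cov_tb$sex[i],
                     T2D = as.numeric(cov_tb$cohort[i] == "T2D"),
                     IM = as.numeric(cov_tb$test_type[i] == "IM-IVGTT"))
    }
    out[[k]] <- subject_data(id, test_type, dose, gl$time_min, gl$value,
                             insulin_forcing(ins$time_min, ins$value, ib),
                             Gbasal = gb, Ibasal = ib, covariates = covrow)
  }
  out
}

COV_COLUMNS <- c("subject_id", "age_yr", "weight_kg", "height_cm", "bmi_kg_m2",
                 "sex", "cohort", "test_type", "dose_mmol")

#' Write a covariate table
#' @param table Covariate data frame.
#' @param path Output CSV path.
#' @export
write_covariates <- function(table, path) {
  tb <- table
  names(tb)[names(tb) == "cohort"] <- "cohort"
  miss <- setdiff(COV_COLUMNS, names(tb))
  if (length(miss))
    abort_invalid(paste0("covariate table lacks columns: ", paste(miss, collapse = ", ")))
  write.csv(tb[, COV_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a covariate table
#' @param path Covariate CSV path.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  tb <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(COV_COLUMNS, names(tb))
  if (length(miss))
    abort_parse(paste0("covariate file lacks columns: ", paste(miss, collapse = ", ")))
  bad <- !tb$cohort %in% c("ND", "T2D")
  if (any(bad))
    abort_parse(sprintf("unknown cohort '%s' at row %d", tb$cohort[which(bad)[1]],
                        which(bad)[1]))
  bad <- !tb$test_type %in% c("IVGTT", "IM-IVGTT")
  if (any(bad))
    abort_parse(sprintf("unknown test_type '%s' at row %d",
                        tb$test_type[which(bad)[1]], which(bad)[1]))
  tb
}

# ---- fit serialization -----------------------------------------------------

pop_to_list <- function(pop) {
  list(mu_log = as.list(pop$mu_log),
       Sigma_log = apply(pop$Sigma_log, 1, as.list),
       effects = lapply(pop$effects, function(e)
         list(parameter = e$parameter, covariate = e$covariate, kind = e$kind,
              reference = e$reference, coefficient = e$coefficient)),
       sigma_prop = pop$sigma_prop)
}

pop_from_list <- function(x) {
  S <- matrix(unlist(x$Sigma_log), 4, 4)
  population_params(unlist(x$mu_log), (S + t(S)) / 2,
                    effects = lapply(x$effects, function(e)
                      covariate_effect(e$parameter, e$covariate, e$kind,
                                       if (e$kind == "power_centered") e$reference else NA_real_,
                                       e$coefficient)),
                    sigma_prop = x$sigma_prop)
}

#' Serialize a fit to JSON
#'
#' @param fit An [em_fit()] result.
#' @param path Output path.
#' @param rse Optional [standard_errors()] result to embed.
#' @param stamp Optional metadata list (seed, config hash) to embed.
#' @export
write_fit_json <- function(fit, path, rse = NULL, stamp = NULL) {
  obj <- list(
    package = "mmpop", version = as.character(packageVersion("mmpop")),
    stamp = stamp,
    pop = pop_to_list(fit$pop),
    minus2LL = as.numeric(fit$minus2LL),
    minus2LL_mc_se = attr(fit$minus2LL, "mc_se"),
    converged = fit$converged, n_iterations = fit$n_iterations,
    subject_ids = fit$subject_ids,
    conditional_mean_log = apply(fit$conditional_mean_log, 1, as.list),
    rse_cv_percent = if (!is.null(rse)) as.list(rse$rse) else NULL,
    trace = fit$trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read a serialized fit
#'
#' Restores the population parameters and conditional means written by
#' [write_fit_json()] (trace and settings are restored as plain lists).
#'
#' @param path JSON path.
#' @return List with `pop`, `minus2LL`, `conditional_mean_log`, ...
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  cm <- do.call(rbind, lapply(x$conditional_mean_log, function(r) unlist(r)))
  rownames(cm) <- unlist(x$subject_ids)
  colnames(cm) <- MM_PARS
  list(pop = pop_from_list(x$pop),
       minus2LL = structure(x$minus2LL, mc_se = x$minus2LL_mc_se),
       converged = isTRUE(x$converged),
       conditional_mean_log = cm,
       rse_cv_percent = if (!is.null(x$rse_cv_percent)) unlist(x$rse_cv_percent),
       stamp = x$stamp, version = x$version)
}

# ---- pipeline driver -------------------------------------------------------

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_config(sprintf("config file not found: %s", config))
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        abort_config("yaml package required for YAML configs")
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  config
}

effects_from_config <- function(lst) {
  lapply(lst, function(e)
    covariate_effect(e$parameter, e$covariate, e$kind,
                     if (identical(e$kind, "power_centered")) e$reference else NA_real_,
                     if (is.null(e$coefficient)) 0 else e$coefficient))
}

settings_from_config <- function(cfg, seed) {
  args <- cfg$settings
  if (is.null(args)) args <- list()
  if (!is.null(seed)) args$seed <- seed
  do.call(fit_settings, args)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (virtual trial to CSV), `fit` (population fit to
#' JSON + conditional means/residuals CSV), `covariates` (screening plus
#' forward selection), `disposal` (per-subject disposal partition and group
#' summary), `report` (base-vs-final comparison from two fit JSONs). Every
#' JSON artifact is stamped with the seed, package version and a hash of the
#' configuration.
#'
#' @param config List or path to a JSON/YAML file with elements `command`,
#'   `paths` (named input/output paths), optional `settings`, `model`,
#'   `cohort`, `seed`.
#' @return Invisibly, a list of written artifact paths.
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  if (is.null(cfg$command)) abort_config("config must name a command")
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  paths <- cfg$paths
  stamp <- list(seed = seed, config_hash = config_hash(cfg),
                version = as.character(packageVersion("mmpop")))
  need <- function(p, what) {
    if (is.null(p)) abort_config(sprintf("config paths must include '%s'", what))
    p
  }
  outdir <- need(paths$out, "out")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)

  if (cfg$command == "simulate") {
    sp_args <- if (is.null(cfg$cohort)) list() else cfg$cohort
    sp_args$seed <- seed
    spec <- do.call(cohort_spec, sp_args)
    trial <- simulate_trial(spec)
    p1 <- file.path(outdir, "observations.csv")
    p2 <- file.path(outdir, "covariates.csv")
    p3 <- file.path(outdir, "truth.csv")
    write_observations(trial$subjects, p1)
    write_covariates(trial$covariates, p2)
    write.csv(trial$truth, p3, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(stamp, file.path(outdir, "stamp.json"), auto_unbox = TRUE)
    written <- c(p1, p2, p3, file.path(outdir, "stamp.json"))
  } else if (cfg$command == "fit") {
    subjects <- read_observations(need(paths$data, "data"),
                                  need(paths$covariates, "covariates"))
    subjects <- filter_dataset(subjects)
    spec <- if (is.null(cfg$model)) NULL else effects_from_config(cfg$model)
    settings <- settings_from_config(cfg, seed)
    fit <- em_fit(subjects, spec = spec, settings = settings)
    rse <- if (isTRUE(cfg$se)) standard_errors(fit, subjects, settings) else NULL
    pf <- file.path(outdir, "fit.json")
    write_fit_json(fit, pf, rse = rse, stamp = stamp)
    cm <- data.frame(subject_id = fit$subject_ids,
                     exp(fit$conditional_mean_log), row.names = NULL)
    pc <- file.path(outdir, "conditional_means.csv")
    write.csv(cm, pc, row.names = FALSE, quote = FALSE)
    pr <- file.path(outdir, "residuals.csv")
    write.csv(conditional_std_residuals(fit, subjects), pr, row.names = FALSE,
              quote = FALSE)
    written <- c(pf, pc, pr)
  } else if (cfg$command == "covariates") {
    subjects <- read_observations(need(paths$data, "data"),
                                  need(paths$covariates, "covariates"))
    subjects <- filter_dataset(subjects)
    settings <- settings_from_config(cfg, seed)
    cands <- effects_from_config(cfg$candidates)
    sel <- forward_select(subjects, cands, settings,
                          alpha = if (is.null(cfg$alpha)) 0.05 else cfg$alpha)
    ps <- file.path(outdir, "selection_steps.csv")
    write.csv(sel$steps, ps, row.names = FALSE)
    pf <- file.path(outdir, "final_fit.json")
    write_fit_json(sel$fit, pf, stamp = stamp)
    written <- c(ps, pf)
  } else if (cfg$command == "disposal") {
    subjects <- read_observations(need(paths$data, "data"),
                                  need(paths$covariates, "covariates"))
    fit <- read_fit_json(need(paths$fit, "fit"))
    include_im <- isTRUE(cfg$include_im)
    rows <- list()
    for (s in subjects) {
      if (!include_im && s$test_type != "IVGTT") next
      b <- fit$conditional_mean_log[s$subject_id, ]
      d <- disposal_integrals(exp(b), s)
      d$cohort <- if (isTRUE(s$covariates$T2D == 1)) "T2D" else "ND"
      d$basal_fraction <- basal_noninsulin_fraction(exp(b[["GEZI"]]),
                                                    exp(b[["SI"]]), s$Ibasal)
      rows[[length(rows) + 1]] <- d
    }
    if (!length(rows)) abort_data("no eligible subjects for disposal analysis")
    tab <- do.call(rbind, rows)
    pd <- file.path(outdir, "disposal.csv")
    write.csv(tab, pd, row.names = FALSE, quote = FALSE)
    summ <- cohort_fraction_summary(tab$fraction_NID, tab$cohort)
    rs <- if (length(unique(tab$cohort)) == 2) {
      rank_sum_test(tab$fraction_NID[tab$cohort == "ND"],
                    tab$fraction_NID[tab$cohort == "T2D"])
    } else NULL
    pj <- file.path(outdir, "disposal_summary.json")
    jsonlite::write_json(list(stamp = stamp, summary = summ, rank_sum = rs),
                         pj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(pd, pj)
  } else if (cfg$command == "report") {
    fb <- read_fit_json(need(paths$base, "base"))
    ff <- read_fit_json(need(paths$final, "final"))
    df_extra <- length(ff$pop$effects) - length(fb$pop$effects)
    rep <- list(stamp = stamp,
                base = c(pop_to_list(fb$pop), list(minus2LL = as.numeric(fb$minus2LL))),
                final = c(pop_to_list(ff$pop), list(minus2LL = as.numeric(ff$minus2LL))),
                lrt = if (df_extra >= 1)
                  lrt(as.numeric(fb$minus2LL), as.numeric(ff$minus2LL), df_extra,
                      tolerance = Inf))
    pr <- file.path(outdir, "report.json")
    jsonlite::write_json(rep, pr, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- pr
  } else {
    abort_config(sprintf("unknown command '%s'", cfg$command))
  }
  invisible(list(status = 0L, artifacts = written, stamp = stamp))
}
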