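#' Run the end-to-end pneumonitis study
#'
#' Orchestrates the full analysis: obtain a cohort (simulated phantoms or
#' NIfTI fixtures), compute per-patient dosimetric profiles, screen clinical
#' covariates univariately, fit the standardized adjusted logistic model for
#' every dosimetric parameter, score the models (AUC/AIC/BIC/IDI/NRI against
#' the reference parameter) and locate the ROC operating point of the
#' best-AUC parameter. Deterministic given (config, seed).
#'
#' Outputs written to `outputDir`: `profiles.csv`, `univariate.csv`,
#' `models.csv`, `comparison.csv`, `roc.json`, `config.yaml`, `run.log`
#' (and `cohort.csv`).
#'
#' @param outputDir output directory. If it already contains a `comparison.csv`
#'   and `force` is `FALSE`, the run refuses to overwrite.
#' @param mode `"simulate"` (default) or `"fixtures"`.
#' @param inputDir for `mode = "fixtures"`: directory holding `cohort.csv` and
#'   per-patient `<id>_ct.nii.gz` / `<id>_dose.nii.gz` / `<id>_lung.nii.gz`.
#' @param n,seed cohort size and master seed for `mode = "simulate"`.
#' @param endpoint `"grade2"` or `"grade3"`.
#' @param adjusters adjustment covariates for every model.
#' @param reference reference parameter for IDI/NRI.
#' @param phantom,outcome,lavCfg generator and segmentation configs.
#' @param cutoffsGy dose cutoffs (must be sorted ascending).
#' @param writeVolumes also write phantom NIfTI volumes (simulate mode).
#' @param force overwrite an existing bundle.
#' @param firth use the penalized fit on separation (small cohorts).
#' @return invisibly, a list with the bundle paths and the in-memory tables.
#' @export
runStudy <- function(outputDir, mode = c("simulate", "fixtures"),
                     inputDir = NULL, n = 100L, seed = 1L,
                     endpoint = c("grade2", "grade3"),
                     adjusters = c("chemotherapy", "ild"), reference = "MLD",
                     phantom = phantomConfig(), outcome = outcomeModelConfig(),
                     lavCfg = lavConfig(), cutoffsGy = c(2, 5, 10, 20, 30),
                     writeVolumes = FALSE, force = FALSE, firth = FALSE) {
  mode <- match.arg(mode)
  endpoint <- match.arg(endpoint)
  if (is.unsorted(cutoffsGy, strictly = TRUE))
    stop("cutoffsGy must be sorted strictly ascending", call. = FALSE)
  if (file.exists(file.path(outputDir, "comparison.csv")) && !force)
    stop("output directory already holds a bundle; use force = TRUE to redo",
         call. = FALSE)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character()
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    logLines <<- c(logLines, line)
  }
  written <- character()
  emit <- function(name) written <<- c(written, file.path(outputDir, name))

  stage <- "input"
  result <- tryCatch({
    note("run start: mode=%s endpoint=%s seed=%d", mode, endpoint, seed)
    if (mode == "simulate") {
      sim <- simulateCohort(n = n, masterSeed = seed, phantom = phantom,
                            outcome = outcome, lavCfg = lavCfg,
                            dir = if (writeVolumes) outputDir else NULL,
                            writeVolumes = writeVolumes)
      cohort <- sim$cohort; profiles <- sim$profiles
      note("simulated %d patients (%d events, %d retries)", n,
           sim$manifest$nEvents, sim$manifest$outcomeRetries)
    } else {
      if (is.null(inputDir)) stop("inputDir required in fixtures mode", call. = FALSE)
      cohort <- readCohortTable(file.path(inputDir, "cohort.csv"))
      ids <- records(cohort)$patient_id
      stage <- "profiles"
      rows <- lapply(ids, function(id) {
        ct <- readCtVolume(file.path(inputDir, paste0(id, "_ct.nii.gz")))
        dose <- readDoseVolume(file.path(inputDir, paste0(id, "_dose.nii.gz")))
        lung <- readMaskVolume(file.path(inputDir, paste0(id, "_lung.nii.gz")))
        profileValues(dosimetricProfile(ct, dose, lung, cfg = lavCfg,
                                        cutoffsGy = cutoffsGy))
      })
      profiles <- cbind(data.frame(patient_id = ids), as.data.frame(do.call(rbind, rows)))
    }
    utils::write.csv(profiles, file.path(outputDir, "profiles.csv"),
                     row.names = FALSE); emit("profiles.csv")
    writeCohortTable(cohort, file.path(outputDir, "cohort.csv")); emit("cohort.csv")

    stage <- "univariate"
    rec <- records(cohort)
    y <- deriveEndpoint(rec$rp_grade, if (endpoint == "grade2") 2 else 3)
    uniVars <- c(age = "continuous", sex = "categorical", stage = "categorical",
                 histology = "categorical", treatment_type = "categorical",
                 chemotherapy = "categorical", ild = "categorical",
                 smoking_pack_years = "continuous", bmi = "continuous")
    uni <- do.call(rbind, lapply(names(uniVars), function(v) {
      res <- univariateCompare(rec[[v]], y, type = uniVars[[v]])
      data.frame(variable = v, test = res$test, p_value = res$p)
    }))
    utils::write.csv(uni, file.path(outputDir, "univariate.csv"),
                     row.names = FALSE); emit("univariate.csv")

    stage <- "models"
    cmp <- compareParameters(profiles, cohort, endpoint = endpoint,
                             reference = reference, adjusters = adjusters,
                             parameters = profileParameterNames(cutoffsGy),
                             firth = firth)
    excl <- cmp$n_excluded[cmp$n_excluded > 0]
    if (length(excl))
      note("listwise exclusions (undefined MED/MLWED): %d parameter(s) affected",
           length(excl))
    models <- cmp[, c("parameter", "n", "n_excluded", "odds_ratio", "or_lo",
                      "or_hi", "p_value")]
    utils::write.csv(models, file.path(outputDir, "models.csv"),
                     row.names = FALSE); emit("models.csv")
    comparison <- cmp[, c("parameter", "auc", "aic", "bic", "idi", "nri",
                          "reference")]
    utils::write.csv(comparison, file.path(outputDir, "comparison.csv"),
                     row.names = FALSE); emit("comparison.csv")

    stage <- "roc"
    best <- comparison$parameter[which.max(comparison$auc)]
    xv <- profiles[[best]]
    keep <- is.finite(xv)
    op <- rocOperatingPoint(xv[keep], y[keep])
    roc <- c(list(parameter = best), op)
    jsonlite::write_json(roc, file.path(outputDir, "roc.json"),
                         auto_unbox = TRUE, digits = NA); emit("roc.json")

    stage <- "config"
    yaml::write_yaml(list(mode = mode, n = n, seed = seed, endpoint = endpoint,
                          adjusters = as.list(adjusters), reference = reference,
                          cutoffsGy = as.list(cutoffsGy),
                          lavThresholdHu = lavCfg@thresholdHu,
                          phantom = unclass(phantom), outcome = unclass(outcome)),
                     file.path(outputDir, "config.yaml")); emit("config.yaml")
    note("run complete: best parameter by AUC = %s (AUC %.3f)", best,
         max(comparison$auc))
    writeLines(logLines, file.path(outputDir, "run.log"))
    list(dir = outputDir, cohort = cohort, profiles = profiles,
         univariate = uni, models = models, comparison = comparison, roc = roc)
  }, error = function(e) {
    unlink(written)   # remove partial outputs
    stop(sprintf("study failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(result)
}

#' Render a human-readable study report
#'
#' Builds a Markdown summary from an existing bundle directory: cohort
#' composition, univariate screen, the per-parameter model table and the
#' five-measure comparison, naming the best parameter per measure and
#' flagging tied rows. Every number is read from the bundle files; nothing is
#' recomputed.
#'
#' @param dir bundle directory written by [runStudy()].
#' @param path optional output file; default `report.md` inside `dir`.
#' @return the report path, invisibly.
#' @export
renderReport <- function(dir, path = file.path(dir, "report.md")) {
  need <- c("comparison.csv", "models.csv", "univariate.csv", "cohort.csv", "roc.json")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("bundle is missing ", f, call. = FALSE)
  comparison <- utils::read.csv(file.path(dir, "comparison.csv"))
  if (!nrow(comparison)) stop("comparison table is empty", call. = FALSE)
  models <- utils::read.csv(file.path(dir, "models.csv"))
  uni <- utils::read.csv(file.path(dir, "univariate.csv"))
  cohort <- utils::read.csv(file.path(dir, "cohort.csv"))
  roc <- jsonlite::read_json(file.path(dir, "roc.json"), simplifyVector = TRUE)

  md <- c("# Radiation pneumonitis dosimetric comparison", "",
          sprintf("Patients: %d; RP grade distribution: %s", nrow(cohort),
                  paste(sprintf("G%d:%d", 0:5,
                                tabulate(factor(cohort$rp_grade, levels = 0:5),
                                         nbins = 6)), collapse = " ")), "",
          "## Univariate screen", "",
          "| variable | test | p |", "|---|---|---|",
          sprintf("| %s | %s | %.4g |", uni$variable, uni$test, uni$p_value), "",
          "## Best parameter per measure", "")
  bestBy <- c(auc = which.max(comparison$auc), aic = which.min(comparison$aic),
              bic = which.min(comparison$bic), idi = which.max(comparison$idi),
              nri = which.max(comparison$nri))
  md <- c(md, sprintf("- %s: **%s** (%.4g)", names(bestBy),
                      comparison$parameter[bestBy],
                      mapply(function(m, i) comparison[[m]][i], names(bestBy), bestBy)),
          "",
          sprintf("ROC operating point of %s: threshold %.4g, sensitivity %.3f, specificity %.3f",
                  roc$parameter, roc$threshold, roc$sensitivity, roc$specificity), "")

  key <- do.call(paste, c(comparison[c("auc", "aic", "bic", "idi", "nri")], sep = "|"))
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup))
    md <- c(md, sprintf("Tied rows (identical on all five measures): %s",
                        paste(comparison$parameter[dup], collapse = ", ")), "")

  md <- c(md, "## Model comparison", "",
          "| parameter | OR/SD | p | AUC | AIC | BIC | IDI | NRI |",
          "|---|---|---|---|---|---|---|---|",
          sprintf("| %s | %.3f | %.4g | %.3f | %.2f | %.2f | %.4f | %.4f |",
                  comparison$parameter, models$odds_ratio, models$p_value,
                  comparison$auc, comparison$aic, comparison$bic,
                  comparison$idi, comparison$nri))
  writeLines(md, path)
  invisible(path)
}
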