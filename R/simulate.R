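#' Simulate a phantom cohort with dosimetric profiles and outcomes
#'
#' For each patient a phantom CT / lung mask / dose grid is generated from a
#' counter-based per-patient seed (cohorts are stable under patient
#' reordering), the dosimetric profile is computed, clinical covariates are
#' drawn at the configured prevalences, and the pneumonitis event is drawn
#' from the logistic outcome model on the cohort z-score of the driving
#' dosimetric parameter. Events receive CTCAE grades 2-5 (12:13:1:1) and
#' non-events grades 0-1 (49:24). The generator never reads outcome labels
#' when constructing images or doses, so there is no leakage by construction.
#' A replicate with zero events or zero non-events is redrawn (outcome
#' uniforms only) up to `maxRetries` times; retries are recorded in the
#' manifest.
#'
#' @param n number of patients (>= 10; default 100).
#' @param masterSeed integer master seed.
#' @param phantom a [phantomConfig()].
#' @param outcome an [outcomeModelConfig()].
#' @param lavCfg [LavConfig-class] used for profiles (default free-breathing).
#' @param dir optional output directory; when given, per-patient NIfTI
#'   volumes (`<id>_ct.nii.gz`, `<id>_dose.nii.gz`, `<id>_lung.nii.gz`),
#'   `cohort.csv`, `profiles.csv` and `manifest.yaml` are written.
#' @param writeVolumes write the NIfTI volumes when `dir` is given (the CSVs
#'   and manifest are always written).
#' @param maxRetries outcome redraw cap for degenerate replicates.
#' @return list with `cohort` ([CohortTable-class]), `profiles` (data.frame,
#'   one row per patient: `patient_id` + every profile parameter), and
#'   `manifest` (list of configs, seeds and retry count).
#' @export
simulateCohort <- function(n = 100L, masterSeed = 1L,
                           phantom = phantomConfig(),
                           outcome = outcomeModelConfig(),
                           lavCfg = lavConfig(),
                           dir = NULL, writeVolumes = TRUE,
                           maxRetries = 5L) {
  if (n < 10L) stop("need at least 10 patients", call. = FALSE)
  ids <- sprintf("P%03d", seq_len(n))

  profRows <- vector("list", n)
  cov <- data.frame(patient_id = ids, age = NA_real_, sex = NA_character_,
                    stage = NA_integer_, histology = NA_character_,
                    treatment_type = NA_character_, chemotherapy = NA_integer_,
                    ild = NA_integer_, smoking_pack_years = NA_real_,
                    bmi = NA_real_, rp_grade = NA_integer_,
                    stringsAsFactors = FALSE)
  uOutcome <- numeric(n); uGrade <- numeric(n)
  volumes <- if (!is.null(dir) && writeVolumes) vector("list", n) else NULL

  for (i in seq_len(n)) {
    ph <- generatePhantom(phantom, seed = .patientSeed(masterSeed, i))
    prof <- dosimetricProfile(ph$ct, ph$dose, ph$lung, cfg = lavCfg)
    profRows[[i]] <- profileValues(prof)
    .withSeed(.patientSeed(masterSeed, i, stream = 1L), {
      cov$chemotherapy[i] <- stats::rbinom(1, 1, outcome$chemotherapyPrevalence)
      cov$ild[i] <- stats::rbinom(1, 1, outcome$ildPrevalence)
      cov$age[i] <- round(min(89, max(39, stats::rnorm(1, 71, 9))))
      cov$sex[i] <- if (stats::runif(1) < 0.82) "M" else "F"
      cov$stage[i] <- sample(1:4, 1, prob = c(0.25, 0.09, 0.51, 0.15))
      cov$histology[i] <- sample(c("SqCC", "Adenocarcinoma", "SCC", "NSCC",
                                   "Unknown", "Others"), 1,
                                 prob = c(0.33, 0.27, 0.15, 0.08, 0.14, 0.03))
      cov$treatment_type[i] <- if (stats::runif(1) < 0.95) "3DCRT" else "IMRT"
      cov$smoking_pack_years[i] <- round(min(180, max(0, stats::rnorm(1, 42, 32))))
      cov$bmi[i] <- round(min(28, max(15, stats::rnorm(1, 20.5, 2.5))), 1)
      uOutcome[i] <- stats::runif(1)
      uGrade[i] <- stats::runif(1)
    })
    if (!is.null(volumes)) volumes[[i]] <- ph
  }

  profiles <- cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE),
                    as.data.frame(do.call(rbind, profRows)))

  x <- profiles[[outcome$drivingParameter]]
  if (is.null(x)) stop("driving parameter not found in profiles", call. = FALSE)
  z <- (x - mean(x)) / stats::sd(x)
  lp <- outcome$intercept + outcome$coefPerSd * z +
    outcome$coefChemotherapy * cov$chemotherapy + outcome$coefIld * cov$ild
  pEvent <- stats::plogis(lp)

  retries <- 0L
  u <- uOutcome
  repeat {
    event <- u < pEvent
    if (any(event) && !all(event)) break
    retries <- retries + 1L
    if (retries > maxRetries)
      stop("degenerate replicate: could not draw both outcome classes", call. = FALSE)
    u <- .withSeed(.patientSeed(masterSeed, 0L, stream = 10L + retries),
                   stats::runif(n))
  }
  eventGradeCut <- cumsum(c(12, 13, 1, 1) / 27)
  noneGradeCut <- cumsum(c(49, 24) / 73)
  cov$rp_grade <- ifelse(event,
                         1L + findInterval(uGrade, eventGradeCut,
                                           left.open = TRUE) + 1L,
                         findInterval(uGrade, noneGradeCut, left.open = TRUE))

  cohort <- cohortTable(cov, provenance = "simulated")
  manifest <- list(n = n, masterSeed = masterSeed,
                   phantom = unclass(phantom)[!vapply(phantom, is.function, TRUE)],
                   outcome = unclass(outcome),
                   lavThresholdHu = lavCfg@thresholdHu,
                   outcomeRetries = retries,
                   nEvents = sum(event))

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeCohortTable(cohort, file.path(dir, "cohort.csv"))
    utils::write.csv(profiles, file.path(dir, "profiles.csv"), row.names = FALSE)
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
    if (writeVolumes) {
      for (i in seq_len(n)) {
        writeVolume(volumes[[i]]$ct, file.path(dir, paste0(ids[i], "_ct.nii.gz")))
        writeVolume(volumes[[i]]$dose, file.path(dir, paste0(ids[i], "_dose.nii.gz")))
        writeVolume(volumes[[i]]$lung, file.path(dir, paste0(ids[i], "_lung.nii.gz")))
      }
    }
  }
  list(cohort = cohort, profiles = profiles, manifest = manifest)
}
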