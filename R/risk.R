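#' Divide a dosimetric parameter by its sample standard deviation
#'
#' Standardization used before every logistic fit so that odds ratios are
#' per-SD and comparable across parameters with different units. Division
#' only, no centering (centering would change only the intercept; it is
#' available behind the `center` flag).
#'
#' @param values numeric vector with at least 2 distinct finite values.
#' @param center if `TRUE`, subtract the mean before dividing (full z-score).
#' @return rescaled vector with sample SD (n-1 denominator) equal to 1.
#' @export
standardizePerSd <- function(values, center = FALSE) {
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  s <- stats::sd(values)
  if (!isTRUE(s > 0))
    stop("zero variance: cannot standardize a constant parameter", call. = FALSE)
  if (center) (values - mean(values)) / s else values / s
}

## ---------------------------------------------------------------------------
## Logistic fit

.firthLogistic <- function(X, y, maxit = 100L, tol = 1e-6) {
  beta <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XtW <- t(X * w)
    info <- XtW %*% X
    ## hat diagonal of W^(1/2) X I^-1 X' W^(1/2)
    h <- rowSums((X %*% solve(info)) * (X * w))
    score <- as.vector(t(X) %*% (y - p + h * (0.5 - p)))
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(score)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  p <- stats::plogis(eta)
  info <- t(X * (p * (1 - p))) %*% X
  ll <- sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(info)$modulus[1]
  list(coefficients = beta, vcov = solve(info), logLik = ll, fitted = p)
}

#' Fit a covariate-adjusted logistic pneumonitis model
#'
#' Maximum-likelihood logistic regression of a binary endpoint on one
#' SD-standardized dosimetric parameter plus adjustment covariates
#' (chemotherapy and interstitial lung disease in the reference analysis).
#' Reports the per-SD odds ratio with Wald 95% CI and p-value, the maximized
#' log-likelihood and the exact AIC/BIC identities. Complete or
#' quasi-complete separation (a fitted probability within 1e-8 of 0 or 1
#' together with a diverging coefficient) is a flagged error; `firth = TRUE`
#' requests a Jeffreys-prior penalized refit instead.
#'
#' @param outcome logical or 0/1 vector; both classes must be present.
#' @param predictor numeric vector, the (standardized) dosimetric parameter,
#'   or `NULL` for an adjusters-only / intercept-only model.
#' @param adjusters data.frame (or NULL) of adjustment covariates.
#' @param parameter name recorded for the dosimetric term.
#' @param firth use the penalized fit on separation.
#' @return an [RpLogisticFit-class].
#' @export
fitRpModel <- function(outcome, predictor = NULL, adjusters = NULL,
                       parameter = "predictor", firth = FALSE) {
  y <- as.integer(outcome)
  if (any(!(y %in% 0:1))) stop("outcome must be binary", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome must contain both classes", call. = FALSE)
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(predictor)) {
    if (any(!is.finite(predictor))) stop("predictor must be finite", call. = FALSE)
    X <- cbind(X, structure(matrix(predictor), dimnames = list(NULL, parameter)))
  }
  if (!is.null(adjusters) && NCOL(adjusters) > 0) {
    A <- as.matrix(as.data.frame(adjusters))
    X <- cbind(X, A)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)

  fit <- stats::glm.fit(X, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  beta <- fit$coefficients
  p <- fit$fitted.values
  extremeFit <- any(p < 1e-8 | p > 1 - 1e-8)
  ## separation is fatal when it involves the coefficient being reported;
  ## a diverging *adjuster* (e.g. a rare binary covariate perfectly aligned
  ## with the outcome) leaves the dosimetric term estimable and is tolerated
  ## with a warning
  divergingTerm <- if (is.null(predictor)) max(abs(beta)) > 15
                   else abs(beta[parameter]) > 15
  separated <- extremeFit && divergingTerm
  method <- "mle"
  if (extremeFit && !separated && !firth)
    warning("quasi-complete separation on an adjustment covariate; its coefficient is unreliable",
            call. = FALSE)
  if (separated) {
    if (!firth)
      stop("complete or quasi-complete separation detected; refit with firth = TRUE",
           call. = FALSE)
    ff <- .firthLogistic(X, y)
    beta <- stats::setNames(ff$coefficients, colnames(X))
    p <- ff$fitted
    vc <- ff$vcov
    ll <- ff$logLik
    method <- "firth"
  } else {
    w <- p * (1 - p)
    vc <- solve(t(X * w) %*% X)
    ll <- sum(y * log(p) + (1 - y) * log1p(-p))
  }
  se <- stats::setNames(sqrt(diag(vc)), colnames(X))
  k <- ncol(X); n <- length(y)
  z975 <- stats::qnorm(0.975)
  if (!is.null(predictor)) {
    b <- beta[parameter]; s <- se[parameter]
    orr <- exp(b); ci <- exp(c(b - z975 * s, b + z975 * s))
    pv <- 2 * stats::pnorm(-abs(b / s))
  } else {
    orr <- NA_real_; ci <- c(NA_real_, NA_real_); pv <- NA_real_
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
  new("RpLogisticFit", coefficients = beta, se = se,
      oddsRatio = unname(orr), orCi = unname(ci), pValue = unname(pv),
      logLik = ll, k = as.integer(k), n = as.integer(n),
      aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
      fitted = unname(p), outcome = y, parameter = parameter, method = method)
}

setMethod("show", "RpLogisticFit", function(object) {
  cat(sprintf("RpLogisticFit (%s): %s on %d patients (%d events)\n",
              object@method, object@parameter, object@n, sum(object@outcome)))
  if (is.finite(object@oddsRatio))
    cat(sprintf("  OR per SD %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
                object@oddsRatio, object@orCi[1], object@orCi[2], object@pValue))
  cat(sprintf("  logLik %.3f, AIC %.3f, BIC %.3f\n",
              object@logLik, object@aic, object@bic))
})

#' Fitted event probabilities of a logistic fit
#' @param x an [RpLogisticFit-class].
#' @return numeric vector of fitted probabilities.
#' @export
fittedProbs <- function(x) x@fitted

## ---------------------------------------------------------------------------
## Discrimination measures

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a random event scores higher than a random non-event;
#' tied scores contribute 1/2.
#'
#' @param score numeric risk scores or fitted probabilities.
#' @param outcome logical or 0/1 vector; both classes required.
#' @return AUC in \[0, 1\].
#' @export
aucRank <- function(score, outcome) {
  y <- as.integer(outcome)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC requires both outcome classes", call. = FALSE)
  r <- rank(score)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.probsAndOutcome <- function(new, ref, outcome) {
  if (is(new, "RpLogisticFit") && is(ref, "RpLogisticFit")) {
    if (new@n != ref@n || !identical(new@outcome, ref@outcome))
      stop("model fits must be on the same patients and outcome", call. = FALSE)
    list(pn = new@fitted, pr = ref@fitted, y = new@outcome)
  } else {
    if (is.null(outcome)) stop("outcome required with numeric inputs", call. = FALSE)
    if (length(new) != length(ref) || length(new) != length(outcome))
      stop("mismatched cohorts: lengths differ", call. = FALSE)
    list(pn = as.numeric(new), pr = as.numeric(ref), y = as.integer(outcome))
  }
}

#' Integrated discrimination improvement
#'
#' Difference in discrimination slopes: (mean fitted probability in events
#' minus mean in non-events) for the new model, minus the same difference for
#' the reference model. Antisymmetric in (new, ref); 0 on self-comparison.
#'
#' @param new,ref [RpLogisticFit-class] objects on the same patients, or
#'   numeric fitted-probability vectors (then `outcome` is required).
#' @param outcome optional 0/1 vector when probabilities are passed directly.
#' @return IDI in \[-1, 1\].
#' @export
idi <- function(new, ref, outcome = NULL) {
  z <- .probsAndOutcome(new, ref, outcome)
  ev <- z$y == 1L
  if (!any(ev) || all(ev)) stop("both outcome classes required", call. = FALSE)
  (mean(z$pn[ev]) - mean(z$pn[!ev])) - (mean(z$pr[ev]) - mean(z$pr[!ev]))
}

#' Continuous (category-free) net reclassification improvement
#'
#' `[P(up | event) - P(down | event)] + [P(down | non-event) -
#' P(up | non-event)]`, where "up" means the new model assigns a strictly
#' higher risk than the reference; exact ties contribute 0. Range \[-2, 2\].
#'
#' @inheritParams idi
#' @return continuous NRI in \[-2, 2\].
#' @export
nriContinuous <- function(new, ref, outcome = NULL) {
  z <- .probsAndOutcome(new, ref, outcome)
  ev <- z$y == 1L
  if (!any(ev) || all(ev)) stop("both outcome classes required", call. = FALSE)
  s <- sign(z$pn - z$pr)
  mean(s[ev]) - mean(s[!ev])
}

## ---------------------------------------------------------------------------
## Univariate screen

#' Univariate comparison of a clinical factor between endpoint groups
#'
#' Continuous variables are compared with Wilcoxon's rank-sum test (exact when
#' both groups have <= 20 patients — by the standard distribution when there
#' are no ties, by full permutation enumeration when there are ties and the
#' enumeration is tractable — otherwise the tie-corrected normal
#' approximation). Categorical variables use Fisher's exact test (two-sided by
#' the minimum-likelihood rule, network enumeration for r x c tables).
#'
#' @param values vector of the clinical factor.
#' @param endpoint logical endpoint indicator, same length.
#' @param type `"auto"` (numeric -> continuous), `"continuous"` or
#'   `"categorical"`.
#' @return list with `test` ("wilcoxon" or "fisher"), `statistic` (Wilcoxon W
#'   or NA), `p`.
#' @export
univariateCompare <- function(values, endpoint,
                              type = c("auto", "continuous", "categorical")) {
  type <- match.arg(type)
  endpoint <- as.logical(endpoint)
  if (length(values) != length(endpoint)) stop("length mismatch", call. = FALSE)
  if (!any(endpoint) || all(endpoint))
    stop("one endpoint group is empty", call. = FALSE)
  if (type == "auto")
    type <- if (is.numeric(values)) "continuous" else "categorical"
  if (type == "continuous") {
    if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
    g1 <- values[endpoint]; g0 <- values[!endpoint]
    n1 <- length(g1); n0 <- length(g0)
    hasTies <- anyDuplicated(values) > 0L
    if (n1 <= 20L && n0 <= 20L && !hasTies) {
      wt <- stats::wilcox.test(g1, g0, exact = TRUE)
      return(list(test = "wilcoxon", statistic = unname(wt$statistic), p = wt$p.value))
    }
    if (n1 <= 20L && n0 <= 20L && choose(n1 + n0, n1) <= 2e5) {
      return(c(list(test = "wilcoxon"), .exactWilcoxonPerm(g1, g0)))
    }
    if (stats::sd(values) == 0)
      return(list(test = "wilcoxon", statistic = n1 * n0 / 2, p = 1))
    wt <- suppressWarnings(stats::wilcox.test(g1, g0, exact = FALSE, correct = FALSE))
    list(test = "wilcoxon", statistic = unname(wt$statistic), p = wt$p.value)
  } else {
    tab <- table(factor(values), factor(endpoint, levels = c(FALSE, TRUE)))
    if (nrow(tab) < 2L)   # constant covariate: no association testable
      return(list(test = "fisher", statistic = NA_real_, p = NA_real_))
    ft <- stats::fisher.test(tab, workspace = 2e6)
    list(test = "fisher", statistic = NA_real_, p = ft$p.value)
  }
}

## Exact two-sided rank-sum p by full enumeration of group assignments;
## handles ties via midranks. Two-sided rule: P(|W - E W| >= |w - E W|).
.exactWilcoxonPerm <- function(g1, g0) {
  vals <- c(g1, g0)
  n1 <- length(g1); n <- length(vals)
  r <- rank(vals)
  w <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  ws <- colSums(matrix(r[combs], nrow = n1))
  mu <- n1 * (n + 1) / 2
  p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
  list(statistic = w - n1 * (n1 + 1) / 2, p = p)  # statistic on the U scale
}

## ---------------------------------------------------------------------------
## ROC operating point

#' ROC operating point by Youden's J
#'
#' Scans the observed score values as candidate thresholds under the rule
#' "score >= threshold is positive" and returns the threshold maximizing
#' Youden's J = sensitivity + specificity - 1. Ties are broken toward higher
#' specificity, then toward the higher threshold. With all-identical scores
#' the operating point is degenerate (J = 0) and flagged.
#'
#' @param score numeric risk scores.
#' @param outcome logical or 0/1 vector; both classes required.
#' @return list: `threshold`, `sensitivity`, `specificity`, `youdenJ`,
#'   `degenerate`.
#' @export
rocOperatingPoint <- function(score, outcome) {
  y <- as.integer(outcome)
  if (!any(y == 1L) || !any(y == 0L))
    stop("both outcome classes required", call. = FALSE)
  cand <- sort(unique(score))
  sens <- vapply(cand, function(t) mean(score[y == 1L] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(score[y == 0L] < t), numeric(1))
  J <- sens + spec - 1
  best <- which(J == max(J))
  if (length(best) > 1L) best <- best[spec[best] == max(spec[best])]
  if (length(best) > 1L) best <- best[which.max(cand[best])]
  list(threshold = cand[best], sensitivity = sens[best], specificity = spec[best],
       youdenJ = J[best], degenerate = length(cand) == 1L)
}

## ---------------------------------------------------------------------------
## Parameter comparison

#' Compare dosimetric parameters as pneumonitis predictors
#'
#' Fits one SD-standardized, covariate-adjusted logistic model per dosimetric
#' parameter and scores each by AUC, AIC and BIC, plus IDI and continuous NRI
#' against the reference parameter's model (MLD by convention). The reference
#' model contains the same adjusters plus the reference parameter, so
#' comparisons isolate the dosimetric term. Patients with a missing value for
#' a parameter (e.g. MED when there is no LAV) are excluded listwise for that
#' parameter's row, with the exclusion count reported; the reference model is
#' refit on the same subset so IDI/NRI compare identical patients.
#'
#' @param profiles data.frame with a `patient_id` column and one column per
#'   dosimetric parameter (one row per patient).
#' @param cohort a [CohortTable-class].
#' @param endpoint `"grade2"` (symptomatic RP) or `"grade3"`.
#' @param reference reference parameter name for IDI/NRI (default `"MLD"`).
#' @param adjusters cohort columns used as adjustment covariates.
#' @param parameters which profile columns to compare; default every
#'   non-`patient_id` column.
#' @param firth pass-through to [fitRpModel()].
#' @return data.frame with one row per parameter: `parameter`, `n`,
#'   `n_excluded`, `odds_ratio`, `or_lo`, `or_hi`, `p_value`, `auc`, `aic`,
#'   `bic`, `idi`, `nri`, `reference`.
#' @export
compareParameters <- function(profiles, cohort, endpoint = c("grade2", "grade3"),
                              reference = "MLD",
                              adjusters = c("chemotherapy", "ild"),
                              parameters = NULL, firth = FALSE) {
  endpoint <- match.arg(endpoint)
  cutoff <- if (endpoint == "grade2") 2 else 3
  rec <- records(cohort)
  m <- match(profiles$patient_id, rec$patient_id)
  if (any(is.na(m)))
    stop("profiles contain patient ids absent from the cohort", call. = FALSE)
  rec <- rec[m, , drop = FALSE]
  y <- deriveEndpoint(rec$rp_grade, cutoff)
  adj <- rec[, adjusters, drop = FALSE]
  if (is.null(parameters)) {
    parameters <- setdiff(names(profiles), "patient_id")
    constant <- vapply(parameters, function(pn) {
      v <- profiles[[pn]][is.finite(profiles[[pn]])]
      length(v) < 2L || stats::sd(v) == 0
    }, logical(1))
    if (any(constant)) {
      warning("dropping constant parameter(s): ",
              paste(parameters[constant], collapse = ", "), call. = FALSE)
      parameters <- parameters[!constant]
    }
  }
  if (!(reference %in% parameters))
    stop(sprintf("reference parameter '%s' is not among the profile columns",
                 reference), call. = FALSE)

  rows <- lapply(parameters, function(pn) {
    xv <- profiles[[pn]]
    keep <- is.finite(xv)
    nEx <- sum(!keep)
    ys <- y[keep]; xs <- xv[keep]; as <- adj[keep, , drop = FALSE]
    ## an adjuster constant in the fitting subset carries no information and
    ## would make the design rank deficient
    as <- as[, vapply(as, function(col) stats::var(col) > 0, logical(1)),
             drop = FALSE]
    fit <- fitRpModel(ys, standardizePerSd(xs), adjusters = as,
                      parameter = pn, firth = firth)
    if (pn == reference) {
      idiV <- 0; nriV <- 0
    } else {
      refFit <- fitRpModel(ys, standardizePerSd(profiles[[reference]][keep]),
                           adjusters = as, parameter = reference, firth = firth)
      idiV <- idi(fit, refFit)
      nriV <- nriContinuous(fit, refFit)
    }
    data.frame(parameter = pn, n = fit@n, n_excluded = nEx,
               odds_ratio = fit@oddsRatio, or_lo = fit@orCi[1],
               or_hi = fit@orCi[2], p_value = fit@pValue,
               auc = aucRank(fit@fitted, ys), aic = fit@aic, bic = fit@bic,
               idi = idiV, nri = nriV, reference = reference)
  })
  out <- do.call(rbind, rows)
  attr(out, "endpoint") <- endpoint
  out
}
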