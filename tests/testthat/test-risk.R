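test_that("per-SD standardization divides by the n-1 sample SD", {
  x <- c(3, 9, 4, 7, 12)
  expect_equal(sd(standardizePerSd(x)), 1)
  expect_equal(standardizePerSd(c(0, 2)), c(0, sqrt(2)))
  expect_error(standardizePerSd(rep(4, 5)), "zero variance")
  # division only: the mean/SD ratio is preserved, centering is opt-in
  expect_equal(mean(standardizePerSd(x)), mean(x) / sd(x))
  expect_equal(mean(standardizePerSd(x, center = TRUE)), 0)
})

test_that("the intercept-only MLE is the event rate", {
  y <- c(rep(1, 27), rep(0, 73))
  fit <- fitRpModel(y)
  expect_equal(unname(fittedProbs(fit)), rep(0.27, 100), tolerance = 1e-9)
  expect_equal(fit@aic, 2 * 1 - 2 * fit@logLik)
  expect_equal(fit@bic, log(100) - 2 * fit@logLik)
})

test_that("AIC/BIC identities hold and differ by k(ln n - 2)", {
  set.seed(19)
  y <- rbinom(60, 1, 0.4)
  x <- rnorm(60) + y
  adj <- data.frame(a = rbinom(60, 1, 0.5))
  fit <- fitRpModel(y, x, adj, parameter = "x")
  expect_equal(fit@aic, 2 * fit@k - 2 * fit@logLik)
  expect_equal(fit@bic, fit@k * log(fit@n) - 2 * fit@logLik)
  expect_equal(fit@bic - fit@aic, fit@k * (log(fit@n) - 2))
})

test_that("tiny-sample coefficients maximize the exact likelihood", {
  y <- c(0, 0, 1, 0, 1, 1, 0, 1)
  x <- c(-1.2, -0.5, 0.3, 0.9, 1.4, 0.8, 0.1, 0.6)   # overlapping classes
  fit <- fitRpModel(y, x, parameter = "x")
  negLogLik <- function(b0, b1) {
    p <- plogis(b0 + b1 * x)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  # brute-force grid around the reported optimum
  b0g <- seq(fit@coefficients[1] - 0.5, fit@coefficients[1] + 0.5, length.out = 201)
  b1g <- seq(fit@coefficients[2] - 0.5, fit@coefficients[2] + 0.5, length.out = 201)
  grid <- outer(b0g, b1g, Vectorize(negLogLik))
  best <- which(grid == min(grid), arr.ind = TRUE)[1, ]
  expect_lt(abs(b0g[best[1]] - fit@coefficients[1]), 1e-2 + 0.5 / 100)
  expect_lt(abs(b1g[best[2]] - fit@coefficients[2]), 1e-2 + 0.5 / 100)
  expect_lte(-fit@logLik, min(grid) + 1e-6)
})

test_that("a null predictor stays within 3 SEs in nearly all fits", {
  set.seed(101)
  covered <- replicate(500, {
    y <- rbinom(200, 1, 0.5)
    if (length(unique(y)) < 2) return(TRUE)
    x <- rnorm(200)
    fit <- fitRpModel(y, x, parameter = "x")
    abs(fit@coefficients["x"]) < 3 * fit@se["x"]
  })
  expect_gte(mean(covered), 0.94)
})

test_that("separation on the dosimetric term errors unless Firth is requested", {
  y <- rep(c(0, 1), each = 10)
  x <- c(-(10:1) / 2, (1:10) / 2)   # completely separated with a 1-unit gap
  expect_error(suppressWarnings(fitRpModel(y, x, parameter = "x")), "separation")
  ff <- suppressWarnings(fitRpModel(y, x, parameter = "x", firth = TRUE))
  expect_identical(ff@method, "firth")
  expect_true(all(fittedProbs(ff) > 0 & fittedProbs(ff) < 1))
  expect_true(is.finite(ff@oddsRatio))
})

test_that("rank AUC follows the tie and separation conventions", {
  expect_equal(aucRank(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
  expect_equal(aucRank(rep(5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(aucRank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(aucRank(1:4, c(1, 1, 1, 1)), "both")
})

test_that("rank AUC equals brute-force pairwise concordance", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.4); if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.05), n, TRUE)   # many ties
    pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
    conc <- mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                        ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
    expect_equal(aucRank(s, y), conc)
  }
})

test_that("rank AUC agrees with pROC", {
  set.seed(29)
  y <- rbinom(80, 1, 0.3); y[1:2] <- c(0, 1)
  s <- rnorm(80) + y
  expect_equal(aucRank(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("IDI and continuous NRI follow their definitions", {
  y <- c(1, 1, 0, 0)
  pn <- c(0.9, 0.8, 0.2, 0.1)
  pr <- c(0.6, 0.5, 0.4, 0.3)
  expect_equal(idi(pn, pr, y), 0.5)           # (0.85-0.15) - (0.55-0.35)
  expect_equal(nriContinuous(pn, pr, y), 2)   # all events up, all non-events down
  expect_equal(idi(pr, pn, y), -0.5)          # antisymmetry
  expect_equal(nriContinuous(pr, pn, y), -2)
  expect_equal(idi(pn, pn, y), 0)
  expect_equal(nriContinuous(pn, pn, y), 0)
})

test_that("IDI and NRI stay inside their ranges on random instances", {
  set.seed(37)
  for (rep in 1:50) {
    n <- sample(6:60, 1)
    y <- rbinom(n, 1, 0.5); y[1:2] <- c(0, 1)
    pn <- runif(n); pr <- runif(n)
    expect_true(abs(idi(pn, pr, y)) <= 1)
    expect_true(abs(nriContinuous(pn, pr, y)) <= 2)
    expect_equal(idi(pn, pr, y), -idi(pr, pn, y))
    expect_equal(nriContinuous(pn, pr, y), -nriContinuous(pr, pn, y))
  }
})

test_that("mismatched cohorts are rejected", {
  expect_error(idi(c(0.1, 0.2), c(0.3, 0.4, 0.5), c(0, 1, 0)), "mismatch")
  y1 <- c(rep(0, 5), rep(1, 5)); y2 <- c(rep(1, 5), rep(0, 5))
  f1 <- fitRpModel(y1, rnorm(10), parameter = "x")
  f2 <- fitRpModel(y2, rnorm(10), parameter = "x")
  expect_error(idi(f1, f2), "same patients")
})

test_that("exact rank-sum and Fisher tests match enumeration", {
  # two literally identical groups: exact two-sided p = 1
  res <- univariateCompare(c(1, 2, 3, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$p, 1)
  # {1,2,3} vs {11,12,13}: the most extreme of the 20 assignments, p = 2/20
  res <- univariateCompare(c(1, 2, 3, 11, 12, 13), c(rep(TRUE, 3), rep(FALSE, 3)))
  expect_equal(res$p, 0.1)
  # Fisher on [[2,0],[0,2]]: p = 1/3 by hypergeometric enumeration
  res <- univariateCompare(c("a", "a", "b", "b"), c(TRUE, TRUE, FALSE, FALSE),
                           type = "categorical")
  expect_equal(res$test, "fisher")
  expect_equal(res$p, 1 / 3)
  expect_error(univariateCompare(1:4, rep(TRUE, 4)), "empty")
})

test_that("the ROC operating point maximizes Youden's J", {
  sep <- rocOperatingPoint(c(1, 2, 10, 11), c(0, 0, 1, 1))
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  op <- rocOperatingPoint(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(op$threshold, 3)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  dg <- rocOperatingPoint(rep(2, 6), c(0, 1, 0, 1, 0, 1))
  expect_true(dg$degenerate)
  expect_equal(dg$youdenJ, 0)
})

test_that("ROC threshold ties break toward higher specificity", {
  # J is maximal (0.5) at thresholds 2 and 3; threshold 3 has higher specificity
  s <- c(1, 2, 2, 3); y <- c(0, 0, 1, 1)
  op <- rocOperatingPoint(s, y)
  expect_equal(op$threshold, 3)
  expect_equal(op$specificity, 1)
})

test_that("model measures are invariant to affine predictor rescaling", {
  set.seed(53)
  y <- rbinom(80, 1, 0.35); y[1:2] <- c(0, 1)
  x <- rnorm(80, 10, 3) + y
  adj <- data.frame(chemotherapy = rbinom(80, 1, 0.4))
  f1 <- fitRpModel(y, x, adj, parameter = "x")
  f2 <- fitRpModel(y, 5 - 2 * x, adj, parameter = "x")
  expect_equal(f1@logLik, f2@logLik, tolerance = 1e-8)
  expect_equal(f1@aic, f2@aic, tolerance = 1e-8)
  expect_equal(fittedProbs(f1), fittedProbs(f2), tolerance = 1e-8)
  expect_equal(aucRank(fittedProbs(f1), y), aucRank(fittedProbs(f2), y))
  expect_equal(f1@pValue, f2@pValue, tolerance = 1e-7)
})

test_that("parameter comparison zeroes the reference row and ties affine twins", {
  set.seed(59)
  n <- 60
  profiles <- data.frame(patient_id = sprintf("P%02d", 1:n),
                         MLD = rnorm(n, 8, 3))
  profiles$V20 <- 10 + 2 * profiles$MLD + rnorm(n)
  profiles$V20_twin <- 3 - 0.5 * profiles$V20
  grade <- ifelse(runif(n) < plogis(-1 + 0.3 * scale(profiles$MLD)), 2, 0)
  if (length(unique(grade)) < 2) grade[1:2] <- c(0, 2)
  cohort <- cohortTable(data.frame(
    patient_id = profiles$patient_id, age = 70, sex = "M", stage = 3,
    histology = "SqCC", treatment_type = "3DCRT",
    chemotherapy = rbinom(n, 1, 0.4), ild = rbinom(n, 1, 0.06),
    smoking_pack_years = 40, bmi = 21, rp_grade = grade))
  cmp <- suppressWarnings(compareParameters(profiles, cohort, reference = "MLD"))
  refRow <- cmp[cmp$parameter == "MLD", ]
  expect_identical(refRow$idi, 0)
  expect_identical(refRow$nri, 0)
  a <- cmp[cmp$parameter == "V20", ]; b <- cmp[cmp$parameter == "V20_twin", ]
  for (m in c("auc", "aic", "bic", "idi", "nri"))
    expect_equal(a[[m]], b[[m]], tolerance = 1e-6)
  expect_error(suppressWarnings(
    compareParameters(profiles, cohort, reference = "MLWED")), "reference")
})
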