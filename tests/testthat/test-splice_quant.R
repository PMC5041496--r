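test_that("Psi estimates are junction-normalised with Beta intervals", {
  expect_equal(estimatePsi(20, 10, 2, 1)$psi, 0.5)
  expect_equal(estimatePsi(0, 7, 2, 1)$psi, 0)
  e <- estimatePsi(30, 10, 2, 1)
  expect_equal(e$psi, 0.6)
  ## oracle: Beta(15.5, 10.5) quantiles on the normalised counts
  expect_equal(e$ci_low, qbeta(0.025, 15.5, 10.5))
  expect_equal(e$ci_high, qbeta(0.975, 15.5, 10.5))
  expect_true(e$ci_low <= e$psi && e$psi <= e$ci_high)

  z <- estimatePsi(0, 0, 2, 1)
  expect_true(is.na(z$psi))
  expect_true(z$no_coverage)
})

test_that("Psi is invariant under scaling both counts", {
  set.seed(1)
  for (i in 1:20) {
    inc <- sample(1:200, 1); exc <- sample(1:200, 1)
    k <- sample(2:7, 1)
    expect_equal(estimatePsi(inc, exc, 2, 1)$psi,
                 estimatePsi(k * inc, k * exc, 2, 1)$psi)
  }
})

test_that("gel Psi applies background correction", {
  expect_equal(gelPsi(110, 110, 10), 0.5)
  expect_equal(gelPsi(210, 10, 10), 1.0)
  expect_equal(gelPsi(77, 43, 10), 0.67)
  expect_true(is.na(gelPsi(10, 10, 10)))
  expect_error(gelPsi(5, 20, 10), "background")
})

test_that("relative activity normalises to the HsMBNL1 change", {
  expect_equal(relativeActivity(0.44, 0.67, 0.19), (0.44 - 0.67) / (0.19 - 0.67))
  expect_equal(relativeActivity(0.19, 0.67, 0.19), 1.0)
  expect_equal(relativeActivity(0.67, 0.67, 0.19), 0.0)
  expect_true(is.na(relativeActivity(0.5, 0.4, 0.4)))
})

test_that("Bayes factor matches numerical integration and behaves at the ends", {
  expect_lt(bayesFactorTwoSample(10, 10, 10, 10, 1, 1), 1)
  bf0 <- bayesFactorTwoSample(0, 0, 0, 0, 1, 1)
  expect_equal(as.numeric(bf0), 1)
  expect_true(attr(bf0, "noInformation"))

  bf <- as.numeric(bayesFactorTwoSample(18, 2, 2, 18, 1, 1))
  ## oracle: 2-D numerical integration of the two marginal likelihoods
  m1 <- integrate(function(p) p^18 * (1 - p)^2, 0, 1)$value *
    integrate(function(p) p^2 * (1 - p)^18, 0, 1)$value
  m0 <- integrate(function(p) p^20 * (1 - p)^20, 0, 1)$value
  expect_equal(bf, m1 / m0, tolerance = 1e-8)
  expect_gt(bf, 5)
})

test_that("monotonicity Z uses the per-group variance floor and is antisymmetric", {
  expect_equal(monotonicityZ(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7)), 0)
  expect_equal(monotonicityZ(c(0.7, 0.7, 0.7), c(0.4, 0.4, 0.4)),
               0.3 / sqrt(2e-4 / 3), tolerance = 1e-12)
  a <- c(0.72, 0.64, 0.70); b <- c(0.41, 0.36, 0.44)
  expect_equal(monotonicityZ(a, b), -monotonicityZ(b, a))
  expect_true(is.na(monotonicityZ(0.5, c(0.4, 0.5))))
})

test_that("regulation calls gate on all three thresholds", {
  c1 <- callRegulation(0.3, 20, 4)
  expect_identical(as.character(c1$direction), "activated")
  expect_true(c1$significant)
  c2 <- callRegulation(0.3, 4.9, 4)
  expect_identical(as.character(c2$direction), "unaffected")
  c3 <- callRegulation(-0.15, 8, -2)
  expect_identical(as.character(c3$direction), "repressed")
  ## Z gate skipped for single-sample comparisons
  c4 <- callRegulation(0.3, 20, z = NULL)
  expect_true(c4$significant)
  ## undefined inputs fall back to unaffected with a flag
  c5 <- callRegulation(NA_real_, 20, 4)
  expect_identical(as.character(c5$direction), "unaffected")
  expect_true(c5$low_coverage)
})

test_that("raising thresholds never converts unaffected to significant", {
  set.seed(3)
  dpsi <- runif(100, -0.5, 0.5)
  bf <- exp(runif(100, -1, 5))
  z <- rnorm(100, 0, 3)
  base <- callRegulation(dpsi, bf, z)
  for (th in list(list(bf_min = 10, dpsi_min = 0.1, z_min = 1.5),
                  list(bf_min = 5, dpsi_min = 0.2, z_min = 1.5),
                  list(bf_min = 5, dpsi_min = 0.1, z_min = 3))) {
    strict <- callRegulation(dpsi, bf, z, th)
    expect_true(all(!strict$significant | base$significant))
  }
})

test_that("homolog agreement counts significant same-direction calls", {
  ref <- list(delta_psi = 0.4)
  hc <- data.frame(delta_psi = c(0.3, 0.2, -0.1, 0.05, 0.4),
                   significant = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  a <- homologAgreement(ref, hc)
  expect_equal(a$n_homologs_regulating, 4L)
  expect_equal(a$consistency_fraction, 3 / 4)
  expect_false(a$consistent_direction)

  allSig <- data.frame(delta_psi = rep(0.3, 5), significant = TRUE)
  a2 <- homologAgreement(ref, allSig)
  expect_equal(a2$n_homologs_regulating, 5L)
  expect_true(a2$consistent_direction)

  none <- data.frame(delta_psi = rep(0.3, 5), significant = FALSE)
  expect_equal(homologAgreement(ref, none)$n_homologs_regulating, 0L)
})

test_that("direction bias test is the exact two-sided binomial", {
  expect_equal(directionBiasTest(10, 0), 2 * 0.5^10)
  expect_equal(directionBiasTest(5, 5), 1)
  expect_equal(directionBiasTest(0, 1), 1)
})

test_that("rescue correlation is the squared Pearson correlation", {
  x <- seq(-0.5, 0.5, length.out = 10)
  expect_equal(rescueCorrelation(x, 0.5 * x)$r_squared, 1)
  ## 6 hand-listed pairs against the covariance definition
  a <- c(0.30, -0.12, 0.25, 0.05, -0.40, 0.18)
  b <- c(0.22, -0.02, 0.31, -0.04, -0.28, 0.10)
  num <- sum((a - mean(a)) * (b - mean(b)))
  r2 <- (num / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))^2
  expect_equal(rescueCorrelation(a, b)$r_squared, r2)
  expect_equal(rescueCorrelation(a, a)$r_squared, 1)
  expect_true(is.na(rescueCorrelation(a, rep(0.1, 6))$r_squared))
  expect_error(rescueCorrelation(c(1, 2), c(1, 2)), "3")
})

test_that("SpliceCounts validates assays and groups; compareGroups calls events", {
  st <- smallStudy()
  sc <- SpliceCounts(st$count_table, st$sample_sheet)
  expect_s4_class(sc, "SpliceCounts")
  expect_true(all(c("inclusion", "exclusion") %in%
                  names(SummarizedExperiment::assays(sc))))
  psi <- quantifyPsi(sc)
  expect_true(all(psi$psi >= 0 & psi$psi <= 1, na.rm = TRUE))
  expect_true(all(psi$ci_low <= psi$psi & psi$psi <= psi$ci_high,
                  na.rm = TRUE))

  calls <- compareGroups(sc, "WT", "DKO")
  expect_equal(nrow(calls), nrow(st$events))
  truth <- st$events$class != "unaffected"
  called <- calls$significant[match(st$events$event_id, calls$event_id)]
  expect_gte(sum(called & truth), 1)
  ## homolog single-sample comparison works without replicates
  hs <- compareGroups(sc, "Hs", "GFP")
  expect_true(all(is.na(hs$z)))
})
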