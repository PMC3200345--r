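test_that("LRT arithmetic, nesting checks and Bonferroni behave", {
  r <- lrt(-100, -100, npNull = 10, npAlt = 12)
  expect_equal(r@statistic, 0)
  expect_equal(r@pRaw, 1)
  expect_error(lrt(-100, -99, npNull = 12, npAlt = 10), "nested")
  expect_error(lrt(-99, -100, npNull = 10, npAlt = 12), "optimization")
  r2 <- lrt(-105.3, -100.1, npNull = 10, npAlt = 12, m = 5)
  expect_equal(r2@statistic, 10.4, tolerance = 1e-12)
  expect_equal(r2@pCorrected, min(1, 5 * r2@pRaw))
  expect_gte(r2@pCorrected, r2@pRaw)
})

test_that("chi-squared tails match independent formulations", {
  ## df = 1: normal-tail identity; general df: numerical integration
  s <- 6.7
  expect_equal(stats::pchisq(s, 1, lower.tail = FALSE), 2 * pnorm(-sqrt(s)),
               tolerance = 1e-12)
  dens <- function(x, k) x^(k / 2 - 1) * exp(-x / 2) /
    (2^(k / 2) * gamma(k / 2))
  for (k in c(2, 5, 36)) {
    tail <- integrate(dens, s, Inf, k = k, rel.tol = 1e-12)$value
    expect_equal(stats::pchisq(s, k, lower.tail = FALSE), tail,
                 tolerance = 1e-10)
  }
})

test_that("np accounting follows the codon-model convention", {
  set.seed(91)
  tr20 <- ape::rtopology(20, rooted = FALSE)
  tr20$edge.length <- rep(0.05, nrow(tr20$edge))
  specs <- table1Specs()
  expect_equal(branchModelNp(specs$m1, tr20), 39L)  # 37 lengths + kappa + 1
  expect_equal(branchModelNp(specs$m2, tr20), 75L)  # one omega per branch
  lt <- batSpeciesTree()                            # 18 taxa: 33 lengths
  expect_equal(branchModelNp(specs$m1, lt), 35L)
  expect_equal(branchModelNp(specs$m6, lt), 36L)    # + one extra omega
  expect_equal(branchModelNp(specs$m7, lt), 35L)    # the d,e omega is fixed
})

test_that("one-ratio fits recover omega and collapse correctly", {
  lt <- batSpeciesTree()
  cm <- codonModel(kappa = 2.5, omega = 0.03)
  sim <- simulateCodonAlignment(simulationRecipe(lt@tree, cm, 600L,
                                                 seed = 93))
  fit <- fitBranchModel(sim$alignment, lt, table1Specs()$m1)
  expect_gt(fit@omega[["w0"]], 0.015)
  expect_lt(fit@omega[["w0"]], 0.05)
  expect_gt(fit@kappa, 1.7); expect_lt(fit@kappa, 3.6)

  ## fixing omega at the MLE reproduces the one-ratio lnL exactly
  fixed <- branchModelSpec("fixed", list(".default" = unname(fit@omega[1])))
  fitF <- fitBranchModel(sim$alignment, lt, fixed)
  expect_equal(fitF@logLik, fit@logLik, tolerance = 1e-3)
  expect_equal(fitF@np, fit@np - 1L)
})

test_that("two-ratio fits separate foreground from background omega", {
  lt <- batSpeciesTree()
  cm <- codonModel(kappa = 2, omega = c(b = 0.5, c = 0.5, .default = 0.05))
  sim <- simulateCodonAlignment(simulationRecipe(lt, cm, 1500L, seed = 95))
  spec <- branchModelSpec("fg vs bg", list(b = "w1", c = "w1",
                                           .default = "w0"))
  fit <- fitBranchModel(sim$alignment, lt, spec)
  expect_gt(fit@omega[["w1"]], fit@omega[["w0"]])
  expect_lt(abs(fit@omega[["w0"]] - 0.05) / 0.05, 0.4)
  expect_gt(fit@omega[["w1"]], 0.2)
})

test_that("selection reports keep their structure when a fit fails", {
  lt <- batSpeciesTree()
  cm <- codonModel(kappa = 2, omega = 0.05)
  sim <- simulateCodonAlignment(simulationRecipe(lt@tree, cm, 80L,
                                                 seed = 97))
  specs <- list(m1 = table1Specs()$m1,
                bad = new("BranchModelSpec", name = "broken",
                          assign = list(z = "w1"), freeRatio = FALSE),
                m6 = table1Specs()$m6)
  rep <- selectionReport(sim$alignment, lt, specs = specs,
                         comparisons = list(c("m6", "m1"), c("bad", "m1")),
                         m = 2)
  expect_equal(nrow(rep$fits), 3L)
  expect_equal(nrow(rep$tests), 2L)
  expect_true(nzchar(rep$fits$error[2]))     # the broken row carries an error
  expect_false(is.na(rep$tests$statistic[1]))  # others still computed
  expect_true(is.na(rep$tests$statistic[2]))
})
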