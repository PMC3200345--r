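test_that("simulation is deterministic under a fixed seed", {
  tr <- batSpeciesTree(labeled = FALSE)
  m <- aaModel("HIVb", pInv = 0.2, gammaShape = 0.8)
  r <- simulationRecipe(tr, m, 120L, seed = 7)
  s1 <- simulateAlignment(r); s2 <- simulateAlignment(r)
  expect_identical(alignmentMatrix(s1$alignment),
                   alignmentMatrix(s2$alignment))
  expect_identical(s1$nodeStates, s2$nodeStates)
})

test_that("zero-length trees copy the root everywhere", {
  tr <- batSpeciesTree(labeled = FALSE)
  tr$edge.length[] <- 0
  sim <- simulateAlignment(simulationRecipe(tr, aaModel("WAG"), 30L,
                                            seed = 8))
  m <- alignmentMatrix(sim$alignment)
  expect_true(all(m == rep(m[1, ], each = nrow(m))))
})

test_that("branch substitution counts match the closed-form expectation", {
  ## unit-mean-rate generator: expected substitutions/site on a branch of
  ## length t is t; check a 3 sigma band at large n
  m <- aaModel("HIVb")
  tr <- ape::read.tree(text = "(A:0.2,B:0.001);")
  sim <- simulateAlignment(simulationRecipe(tr, m, 50000L, seed = 9),
                           mode = "gillespie")
  eA <- sum(sim$events$edge == which(sim$tree$edge[, 2] == 1))
  lam <- 0.2 * 50000
  expect_lt(abs(eA - lam), 3 * sqrt(lam))
  ## matrix and gillespie modes agree in distribution (difference rate)
  sim2 <- simulateAlignment(simulationRecipe(tr, m, 50000L, seed = 10))
  pdiff <- mean(alignmentMatrix(sim2$alignment)[1, ] !=
                  alignmentMatrix(sim2$alignment)[2, ])
  pdiffG <- mean(alignmentMatrix(sim$alignment)[1, ] !=
                   alignmentMatrix(sim$alignment)[2, ])
  expect_lt(abs(pdiff - pdiffG), 0.01)
})

test_that("forced parallel events are realized, inherited and recorded", {
  lt <- batSpeciesTree()
  m <- aaModel("HIVb")
  rec <- simulationRecipe(lt@tree, m, 50L, seed = 11)
  pair <- vapply(c("b", "c"), function(lb)
    parallevol:::.resolveLabeledEdge(rec@tree, lt, lb), integer(1))
  rec2 <- injectParallel(rec, pair, 20L, "M", "I")
  expect_equal(nrow(rec2@forcedEvents), 2L)
  expect_error(injectParallel(rec2, pair, 20L, "M", "L"), "collision")
  expect_error(injectParallel(rec, pair, 20L, "M", "M"), "change")
  expect_error(injectParallel(rec, pair, 999L, "M", "I"), "site")

  sim <- simulateAlignment(rec2)
  expect_equal(sort(sim$events$edge[sim$events$site == 20]),
               sort(unname(pair)))
  mat <- alignmentMatrix(sim$alignment)
  echolocators <- c(batClades()$yango, batClades()$rhino)
  expect_true(all(mat[echolocators, 20] == "I"))
  expect_true(all(mat[setdiff(rownames(mat), echolocators), 20] == "M"))
})

test_that("omega = 0 forbids nonsynonymous change", {
  lt <- batSpeciesTree(labeled = FALSE)
  tr <- lt; tr$edge.length <- tr$edge.length * 10
  cm <- codonModel(kappa = 2, omega = 0)
  sim <- simulateCodonAlignment(simulationRecipe(tr, cm, 150L, seed = 12))
  prot <- alignmentMatrix(translateAlignment(sim$alignment))
  expect_true(all(prot == rep(prot[1, ], each = nrow(prot))))
})

test_that("simulated codon divergence reflects the recipe omega", {
  ## two-taxon alignment: classify observed single-nucleotide differences
  ## as synonymous or nonsynonymous and compare with the generator's
  ## per-category flux computed directly from the rate matrix
  cm <- codonModel(kappa = 2, omega = 0.08)
  tr <- ape::read.tree(text = "(A:0.05,B:0.05);")
  sim <- simulateCodonAlignment(simulationRecipe(tr, cm, 30000L, seed = 13),
                                mode = "gillespie")
  code <- Biostrings::GENETIC_CODE
  ev <- sim$events
  syn <- code[ev$from] == code[ev$to]
  Q <- parallevol:::.buildQcodon(2, 0.08, cm@freq)
  key <- parallevol:::.codonPairs()
  flux <- Q[key$pairs] * cm@freq[key$pairs[, 1]]
  synShare <- sum(flux[key$isSynonymous]) / sum(flux)
  expect_lt(abs(mean(syn) - synShare), 0.02)
})

test_that("Brownian traits have the Brownian covariance and coupling", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  set.seed(14)
  xy <- replicate(2000, {
    v <- simulateTraits(tr, sigma2 = 1, root = 0)
    stats::setNames(v$trait, v$taxon)[c("A", "B")]
  })
  expect_lt(abs(cov(xy[1, ], xy[2, ]) - 1), 0.12)  # shared path length 1
  v0 <- simulateTraits(tr, sigma2 = 0, root = 3)
  expect_equal(v0$trait, rep(3, 3))
  vc <- simulateTraits(tr, sigma2 = 1e-12, root = 0, seed = 1,
                       coupling = list(beta = 2,
                                       counts = c(A = 1, B = 2, C = 3)))
  expect_equal(stats::setNames(vc$trait, vc$taxon)[c("A", "B", "C")],
               c(A = 2, B = 4, C = 6), tolerance = 1e-4)
})
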