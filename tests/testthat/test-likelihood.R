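test_that("per-site likelihoods equal exhaustive enumeration (AA, 3-4 taxa)", {
  m <- aaModel("HIVb")
  eig <- parallevol:::.eigsys(
    parallevol:::.buildQrev(m@exch, m@freq), m@freq)
  Pfun <- function(t) parallevol:::.pmat(eig, t)
  trees <- c("((A:0.2,B:0.35):0.1,C:0.4);",
             "((A:0.1,B:0.2):0.05,(C:0.3,D:0.15):0.1);")
  set.seed(4)
  for (nwk in trees) {
    tr <- ape::read.tree(text = nwk)
    aln <- randomAAln(tr$tip.label, 6, seed = nchar(nwk))
    ll <- siteLogLik(aln, tr, m)
    for (s in 1:6) {
      idx <- match(alignmentMatrix(aln)[, s], parallevol:::.AA_STATES)
      names(idx) <- taxa(aln)
      expect_equal(ll[s], log(bruteSiteLik(tr, Pfun, m@freq, idx)),
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})

test_that("site pattern probabilities sum to one on a nucleotide tree", {
  m <- parallevol:::ntModel("HKY", kappa = 2.5, freq = c(.35, .15, .2, .3))
  tr <- ape::read.tree(text = "((A:0.3,B:0.1):0.2,C:0.25);")
  tot <- 0
  for (a in parallevol:::.NT_STATES) for (b in parallevol:::.NT_STATES)
    for (cc in parallevol:::.NT_STATES) {
      aln <- phyloAlignment(c(A = a, B = b, C = cc), "NT")
      tot <- tot + exp(siteLogLik(aln, tr, m)[1])
    }
  expect_equal(unname(tot), 1, tolerance = 1e-10)
})

test_that("identical taxa on zero-length branches give lnL = log(pi)", {
  m <- aaModel("WAG")
  tr <- ape::read.tree(text = "(A:0,B:0);")
  ll <- siteLogLik(phyloAlignment(c(A = "W", B = "W"), "AA"), tr, m)
  expect_equal(as.numeric(ll), log(m@freq[["W"]]), tolerance = 1e-12)
})

test_that("likelihood is invariant under re-rooting (reversibility)", {
  m <- aaModel("HIVb", pInv = 0.2, gammaShape = 0.9)
  tr <- batSpeciesTree(labeled = FALSE)
  aln <- simulateAlignment(simulationRecipe(tr, m, 80L, seed = 31))$alignment
  l1 <- attr(siteLogLik(aln, tr, m), "logLik")
  l2 <- attr(siteLogLik(aln, ape::unroot(tr), m), "logLik")
  tr3 <- ape::root(ape::unroot(tr), outgroup = "Myotis_laniger",
                   resolve.root = TRUE)
  l3 <- attr(siteLogLik(aln, tr3, m), "logLik")
  expect_equal(l1, l2, tolerance = 1e-6)
  expect_equal(l1, l3, tolerance = 1e-6)
})

test_that("rate-mixture likelihood matches phangorn on a fixture", {
  ## independent implementation of HIVb+I+G+F as a cross-check oracle
  set.seed(12)
  tr <- ape::rtree(7)
  tr$edge.length <- tr$edge.length * 0.3
  aln <- randomAAln(tr$tip.label, 50, seed = 13)
  m <- aaModel("HIVb", pInv = 0.25, gammaShape = 0.6, nCat = 4)
  mine <- attr(siteLogLik(aln, tr, m), "logLik")
  pd <- phangorn::phyDat(alignmentMatrix(aln), type = "AA")
  ref <- phangorn::pml(tr, pd, model = "HIVb", bf = m@freq, inv = 0.25,
                       k = 4, shape = 0.6)$logLik
  expect_equal(mine, ref, tolerance = 1e-6)
})

test_that("branch-length fitting recovers truth and matches phangorn's optimum", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.2,(C:0.2,D:0.3):0.2);")
  m <- aaModel("HIVb")
  sim <- simulateAlignment(simulationRecipe(tr, m, 4000L, seed = 17))
  ft <- fitBranchLengths(sim$alignment, tr, m)
  expect_true(attr(ft, "converged"))
  ## recovered lengths within 20% of truth (internal edge is the sum of the
  ## two root edges under the unrooted convention)
  key <- parallevol:::.edgeKeys(tr)
  est <- tapply(ft$edge.length, key, sum)
  tru <- tapply(tr$edge.length, key, sum)
  expect_true(all(abs(est - tru) / tru < 0.2))

  ## same optimum as an established ML implementation
  pd <- phangorn::phyDat(alignmentMatrix(sim$alignment), type = "AA")
  ref <- phangorn::optim.pml(
    phangorn::pml(ape::unroot(tr), pd, model = "HIVb", bf = m@freq),
    optEdge = TRUE, control = phangorn::pml.control(trace = 0))
  expect_equal(attr(ft, "logLik"), ref$logLik, tolerance = 0.01)

  ## identical sequences drive lengths to the lower bound
  alnid <- phyloAlignment(c(A = "MKVL", B = "MKVL", C = "MKVL", D = "MKVL"),
                          "AA")
  f0 <- fitBranchLengths(alnid, tr, m)
  expect_lt(sum(f0$edge.length), 1e-5)
})

test_that("gamma shape and invariant proportion are recoverable", {
  tr <- batSpeciesTree(labeled = FALSE)
  tr$edge.length <- tr$edge.length * 6  # enough substitutions to inform rates
  m <- aaModel("HIVb", pInv = 0.3, gammaShape = 0.7)
  sim <- simulateAlignment(simulationRecipe(tr, m, 1500L, seed = 19))
  m0 <- aaModel("HIVb", pInv = 0.1, gammaShape = 1.5)
  ft <- fitBranchLengths(sim$alignment, tr, m0, optShape = TRUE,
                         optPinv = TRUE)
  mFit <- attr(ft, "model")
  expect_gt(mFit@pInv, 0.15); expect_lt(mFit@pInv, 0.45)
  expect_gt(mFit@gammaShape, 0.35); expect_lt(mFit@gammaShape, 1.4)
})

test_that("codon likelihood matches a matrix-exponential oracle", {
  cm <- codonModel(kappa = 3, omega = 0.2)
  tr <- ape::read.tree(text = "(A:0.3,B:0.2);")
  cs <- codonStates()
  Q <- parallevol:::.buildQcodon(3, 0.2, cm@freq)
  P <- expmP(Q, 0.5)
  for (pair in list(c("ATG", "ATA"), c("AAA", "AAA"), c("TGG", "TGT"))) {
    aln <- phyloAlignment(c(A = pair[1], B = pair[2]), "CODON")
    i <- match(pair[1], cs); j <- match(pair[2], cs)
    expect_equal(as.numeric(codonLogLik(aln, tr, cm)),
                 log(cm@freq[[i]] * P[i, j]), tolerance = 1e-9)
  }
  ## single codon, identical taxa, zero lengths -> log pi
  tr0 <- ape::read.tree(text = "(A:0,B:0);")
  aln0 <- phyloAlignment(c(A = "CCC", B = "CCC"), "CODON")
  expect_equal(as.numeric(codonLogLik(aln0, tr0, cm)),
               log(cm@freq[[match("CCC", cs)]]), tolerance = 1e-12)
})

test_that("codon likelihood collapses over branch classes with equal omega", {
  lt <- batSpeciesTree()
  cmFlat <- codonModel(kappa = 2, omega = 0.1)
  cmSplit <- codonModel(kappa = 2, omega = c(b = 0.1, c = 0.1,
                                             .default = 0.1))
  sim <- simulateCodonAlignment(simulationRecipe(lt@tree, cmFlat, 40L,
                                                 seed = 23))
  expect_equal(as.numeric(codonLogLik(sim$alignment, lt, cmSplit)),
               as.numeric(codonLogLik(sim$alignment, lt@tree, cmFlat)),
               tolerance = 1e-9)
})
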