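test_that("zero-length cherry pins the ancestor to the tip state", {
  tr <- ape::read.tree(text = "((A:0,B:0):0.1,C:0.3);")
  m <- aaModel("WAG")
  rec <- ancestralML(phyloAlignment(c(A = "M", B = "M", C = "M"), "AA"),
                     tr, m)
  cherry <- as.character(ape::getMRCA(tr, c("A", "B")))
  expect_gt(rec@posterior["M", 1, cherry], 0.999)
  expect_equal(unname(rec@best[cherry, 1]), "M")
})

test_that("marginal posteriors equal brute-force Bayes on a 3-taxon tree", {
  m <- parallevol:::ntModel("HKY", kappa = 2, freq = c(.3, .2, .3, .2))
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,C:0.4):0;")
  eig <- parallevol:::.eigsys(
    parallevol:::.buildQrev(m@exch, m@freq), m@freq)
  Pa <- parallevol:::.pmat(eig, 0.2); Pb <- parallevol:::.pmat(eig, 0.3)
  Pu <- parallevol:::.pmat(eig, 0.1); Pc <- parallevol:::.pmat(eig, 0.4)
  for (pat in list(c(1, 2, 1), c(3, 3, 4), c(2, 2, 2))) {
    aln <- phyloAlignment(c(A = parallevol:::.NT_STATES[pat[1]],
                            B = parallevol:::.NT_STATES[pat[2]],
                            C = parallevol:::.NT_STATES[pat[3]]), "NT")
    rec <- ancestralML(aln, tr, m)
    jo <- matrix(0, 4, 4)  # joint over (root, cherry ancestor)
    for (r in 1:4) for (u in 1:4)
      jo[r, u] <- m@freq[r] * Pc[r, pat[3]] * Pu[r, u] *
        Pa[u, pat[1]] * Pb[u, pat[2]]
    expect_equal(unname(rec@posterior[, 1, "4"]), rowSums(jo) / sum(jo),
                 tolerance = 1e-10)
    expect_equal(unname(rec@posterior[, 1, "5"]), colSums(jo) / sum(jo),
                 tolerance = 1e-10)
  }
})

test_that("posteriors normalize and an unrooted tree needs an outgroup", {
  m <- aaModel("HIVb", pInv = 0.2, gammaShape = 0.8)
  tr <- batSpeciesTree(labeled = FALSE)
  sim <- simulateAlignment(simulationRecipe(tr, m, 60L, seed = 41))
  rec <- ancestralML(sim$alignment, tr, m)
  expect_equal(colSums(rec@posterior[, , 1]), rep(1, 60), tolerance = 1e-9)
  expect_equal(colSums(rec@posterior[, , 10]), rep(1, 60), tolerance = 1e-9)
  expect_error(ancestralML(sim$alignment, ape::unroot(tr), m), "outgroup")
  rec2 <- ancestralML(sim$alignment, ape::unroot(tr), m,
                      outgroup = "Homo_sapiens")
  expect_s4_class(rec2, "AncestralReconstruction")
})

test_that("Fitch parsimony matches exhaustive minimum and the (A,A,B) example", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1);")  # basal trifurcation
  mp <- ancestralParsimony(phyloAlignment(c(A = "A", B = "A", C = "C"),
                                          "NT"), tr)
  expect_equal(mp@score, 1)
  expect_equal(parallevol:::.NT_STATES[mp@stateSets[, 1, 1]], "A")

  set.seed(9)
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  for (i in 1:20) {
    st <- sample(c("A", "C", "G", "T"), 4, TRUE)
    names(st) <- c("A", "B", "C", "D")
    aln <- phyloAlignment(matrix(st, 4, 1, dimnames = list(names(st))),
                          "NT")
    mp <- ancestralParsimony(aln, tr4)
    expect_equal(mp@score, bruteParsimony(tr4, st))
  }
})

test_that("ML reconstruction recovers simulated ancestral states", {
  m <- aaModel("HIVb")
  tr <- batSpeciesTree(labeled = FALSE)
  sim <- simulateAlignment(simulationRecipe(tr, m, 400L, seed = 53))
  ft <- fitBranchLengths(sim$alignment, tr, m)
  rec <- ancestralML(sim$alignment, ft, m)
  nodes <- rownames(rec@best)
  acc <- mean(rec@best == sim$nodeStates[nodes, ])
  expect_gte(acc, 0.95)
  expect_gt(mean(rec@meanPosterior), 0.99)

  ## ML and MP agree wherever ML is confident
  mp <- ancestralParsimony(sim$alignment, ft)
  conf <- apply(rec@posterior, c(2, 3), max) > 0.99
  agree <- rec@best == mp@best
  expect_gte(mean(agree[t(conf)]), 0.999)
})
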