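test_that("pair classification follows the parallel/convergent definitions", {
  ev <- function(edge, site, from, to)
    data.frame(edge = edge, site = site, from = from, to = to)
  ## parallel: same ancestral state, same derived state
  cls <- classifyPair(ev(1, 5, "M", "I"), ev(2, 5, "M", "I"))
  expect_equal(cls$class, "parallel")
  ## convergent: same derived, different ancestral
  cls <- classifyPair(ev(1, 5, "M", "I"), ev(2, 5, "L", "I"))
  expect_equal(cls$class, "convergent")
  ## divergent: different derived states
  cls <- classifyPair(ev(1, 5, "M", "I"), ev(2, 5, "M", "L"))
  expect_equal(cls$class, "divergent")
  ## symmetric in the branch arguments
  a <- ev(1, 1:3, c("M", "M", "A"), c("I", "I", "S"))
  b <- ev(2, 1:3, c("M", "L", "A"), c("I", "I", "T"))
  ab <- classifyPair(a, b); ba <- classifyPair(b, a)
  expect_equal(ab$class, ba$class)
  expect_equal(ab$class, c("parallel", "convergent", "divergent"))
  expect_error(classifyPair(ev(1, 1, "M", "I"), ev(1, 1, "M", "I")),
               "distinct")
})

test_that("substitution mapping emits one event per changed branch-site", {
  m <- aaModel("WAG")
  tr <- ape::read.tree(text = "((A:0,B:0):0.5,C:0.01);")
  aln <- phyloAlignment(c(A = "MMM", B = "MMM", C = "MMM"), "AA")
  rec <- ancestralML(aln, tr, m)
  expect_equal(nrow(mapSubstitutions(rec, aln)), 0L)

  aln2 <- phyloAlignment(c(A = "IMM", B = "IMM", C = "MMM"), "AA")
  rec2 <- ancestralML(aln2, tr, m)
  ev <- mapSubstitutions(rec2, aln2)
  cherryEdge <- which(rec2@tree$edge[, 2] ==
                        ape::getMRCA(rec2@tree, c("A", "B")))
  expect_true(any(ev$edge == cherryEdge & ev$site == 1 &
                    ev$from == "M" & ev$to == "I"))
})

test_that("event counts scale with branch length times sites", {
  m <- aaModel("HIVb")
  tr <- ape::read.tree(text = "(A:0.2,B:0.01);")
  sim <- simulateAlignment(simulationRecipe(tr, m, 20000L, seed = 71),
                           mode = "gillespie")
  ## expected events per site on a branch of length t is t (unit-rate Q)
  eA <- sum(sim$events$edge == which(sim$tree$edge[, 2] == 1))
  expect_lt(abs(eA - 0.2 * 20000) / sqrt(0.2 * 20000), 4)
})

test_that("Zhang-Kumar expectations match hand-computed sums", {
  ## tiny nucleotide system with posteriors chosen by hand
  m <- parallevol:::ntModel("HKY", kappa = 2, freq = c(.3, .2, .3, .2))
  tr <- ape::read.tree(text = "((A:0.15,B:0.2):0.05,(C:0.1,D:0.3):0.05):0;")
  aln <- phyloAlignment(c(A = "A", B = "C", C = "A", D = "G"), "NT")
  rec <- ancestralML(aln, tr, m)
  e1 <- which(rec@tree$edge[, 2] == 1)  # tip branches A and C
  e2 <- which(rec@tree$edge[, 2] == 3)
  zk <- zhangKumarTest(rec, m, c(e1, e2), aln = aln)

  Q <- parallevol:::.buildQrev(m@exch, m@freq)
  P1 <- expmP(Q, rec@tree$edge.length[e1])
  P2 <- expmP(Q, rec@tree$edge.length[e2])
  p1 <- rec@posterior[, 1, as.character(rec@tree$edge[e1, 1])]
  p2 <- rec@posterior[, 1, as.character(rec@tree$edge[e2, 1])]
  lamPar <- 0; lamCon <- 0
  for (x1 in 1:4) for (x2 in 1:4) for (y in 1:4) {
    if (y == x1 || y == x2) next
    term <- p1[x1] * p2[x2] * P1[x1, y] * P2[x2, y]
    if (x1 == x2) lamPar <- lamPar + term else lamCon <- lamCon + term
  }
  expect_equal(zk@expectedParallel, unname(lamPar), tolerance = 1e-8)
  expect_equal(zk@expectedConvergent, unname(lamCon), tolerance = 1e-8)
  ## Poisson tail closed form
  expect_equal(zk@pParallel,
               1 - stats::ppois(zk@observedParallel - 1, lamPar),
               tolerance = 1e-12)
})

test_that("Zhang-Kumar degenerate and monotonicity properties hold", {
  m <- aaModel("HIVb")
  lt <- batSpeciesTree()
  sim <- simulateAlignment(simulationRecipe(lt@tree, m, 50L, seed = 73))
  tr <- sim$tree
  rec <- ancestralML(sim$alignment, tr, m)
  pair <- vapply(c("b", "c"), function(lb)
    parallevol:::.resolveLabeledEdge(rec@tree, lt, lb), integer(1))

  ## zero-length branches give zero expectation and p = 1 at observed 0
  tr0 <- rec@tree
  tr0$edge.length[pair] <- 0
  rec0 <- rec; rec0@tree <- tr0
  zk0 <- zhangKumarTest(rec0, m, pair, aln = sim$alignment)
  expect_equal(zk0@expectedParallel, 0)
  expect_equal(zk0@pParallel, 1)

  ## expectations are monotone non-decreasing in branch length
  lams <- vapply(c(0.005, 0.02, 0.08), function(t1) {
    trx <- rec@tree; trx$edge.length[pair] <- t1
    recx <- rec; recx@tree <- trx
    zhangKumarTest(recx, m, pair, aln = sim$alignment)@expectedParallel
  }, numeric(1))
  expect_true(all(diff(lams) > 0))

  ## per-site both-substitute-to-s probabilities never exceed 1
  expect_lt(zk0@expectedParallel + zk0@expectedConvergent, 50)
  expect_error(zhangKumarTest(rec, m, c(pair[1], pair[1]), aln = sim$alignment))
})

test_that("the scan finds injected parallel sites and nothing under the null", {
  lt <- batSpeciesTree()
  m <- aaModel("HIVb")
  rec <- simulationRecipe(lt@tree, m, 300L, seed = 75)
  pair <- vapply(c("b", "c"), function(lb)
    parallevol:::.resolveLabeledEdge(rec@tree, lt, lb), integer(1))
  rec <- injectParallel(rec, pair, c(11L, 99L, 175L), "M", "I")
  sim <- simulateAlignment(rec)
  scan <- scanParallelSites(sim$alignment, lt, m, batLineagePairs(),
                            alpha = 0.01)
  expect_setequal(scan$site[scan$significant], c(11L, 99L, 175L))
  expect_lt(attr(scan, "pairs")$pParallel, 0.01)

  ## null alignments: no significant site
  nullHits <- vapply(1:3, function(i) {
    simN <- simulateAlignment(simulationRecipe(lt@tree, m, 300L,
                                               seed = 80 + i))
    sc <- scanParallelSites(simN$alignment, lt, m, batLineagePairs(),
                            alpha = 0.01)
    sum(sc$significant)
  }, numeric(1))
  expect_equal(sum(nullHits), 0)
})
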