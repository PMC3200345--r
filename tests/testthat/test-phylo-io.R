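test_that("alignment construction validates shape, alphabet and codons", {
  aln <- phyloAlignment(c(s1 = "ATGAAAGGG", s2 = "ATGAAAGGG"), "CODON")
  expect_equal(nSites(aln), 3L)
  expect_equal(taxa(aln), c("s1", "s2"))

  expect_error(phyloAlignment(c(a = "ACGT", b = "ACG"), "NT"),
               "alignment-shape")
  expect_error(phyloAlignment(c(a = "AJ", b = "AK"), "AA"), "illegal")
  expect_error(phyloAlignment(c(a = "ACGTA", b = "ACGTA"), "CODON"),
               "frame")
  expect_error(phyloAlignment(c("MK", "MR"), "AA"), "named")
})

test_that("FASTA round-trip preserves taxa, order and residues exactly", {
  set.seed(1)
  seqs <- vapply(1:5, function(i)
    paste(sample(c(parallevol:::.AA_STATES, "-"), 37, TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("tax", 5:1)  # non-alphabetical order must survive
  f <- tempfile(fileext = ".fasta")
  writeFastaAlignment(phyloAlignment(seqs, "AA"), f, width = 11)
  back <- readFastaAlignment(f, "AA")
  expect_identical(taxa(back), names(seqs))
  expect_identical(apply(alignmentMatrix(back), 1, paste0, collapse = ""),
                   seqs)
  ## second round trip is byte-identical
  f2 <- tempfile(fileext = ".fasta")
  writeFastaAlignment(back, f2, width = 11)
  expect_identical(readLines(f), readLines(f2))
})

test_that("translation matches the genetic code and rejects internal stops", {
  expect_equal(unname(alignmentMatrix(translateAlignment(
    phyloAlignment(c(x = "ATGAAA"), "CODON")))[1, ]), c("M", "K"))
  expect_error(translateAlignment(
    phyloAlignment(c(x = "ATGTAAAAG"), "NT")), "stop")
  ## random codons against an independent Biostrings translation
  set.seed(7)
  cods <- sample(codonStates(), 300, TRUE)
  aln <- phyloAlignment(c(s = paste(cods, collapse = "")), "CODON")
  mine <- paste(alignmentMatrix(translateAlignment(aln))[1, ], collapse = "")
  ref <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(paste(cods, collapse = ""))))
  expect_identical(mine, ref)
})

test_that("max pairwise distance matches brute force and is a p-distance", {
  a <- phyloAlignment(c(x = "MKVLMKVLMK", y = "MKVLMKVLMK"), "AA")
  expect_equal(as.numeric(maxPairwiseDistance(a)), 0)
  b <- phyloAlignment(c(x = "MKVLMKVLMK", y = "MRVLMKVLMS"), "AA")
  expect_equal(as.numeric(maxPairwiseDistance(b)), 0.2)

  aln <- randomAAln(paste0("t", 1:5), 60, seed = 2)
  m <- alignmentMatrix(aln)
  ref <- max(vapply(utils::combn(5, 2, simplify = FALSE), function(p)
    mean(m[p[1], ] != m[p[2], ]), numeric(1)))
  expect_equal(as.numeric(maxPairwiseDistance(aln)), ref)
  ## p-distance bounded by 1, symmetric by construction; poisson >= p
  expect_lte(as.numeric(maxPairwiseDistance(aln)), 1)
  expect_gte(as.numeric(maxPairwiseDistance(aln, "poisson")),
             as.numeric(maxPairwiseDistance(aln)))
  expect_error(maxPairwiseDistance(
    phyloAlignment(c(x = "--", y = "--"), "AA")), "undefined-distance")
})

test_that("newick I/O round-trips topology and lengths", {
  f <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- readNewickTree(f)
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(sum(tr$edge[, 1] == 4), 2L)  # root degree 2
  f2 <- tempfile(fileext = ".nwk")
  writeNewickTree(tr, f2)
  tr2 <- readNewickTree(f2)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2))), 0)
  expect_equal(tr2$edge.length, tr$edge.length)
  writeLines("((A:1,B:-1):1,C:2);", f)
  expect_error(readNewickTree(f), "negative")
})

test_that("branch labels attach to stem edges and survive YAML round trip", {
  lt <- batSpeciesTree()
  labs <- edgeLabels(lt)
  expect_setequal(unique(labs[nzchar(labs)]), c("a", "b", "c", "d", "e"))
  ## the edge labelled b is the stem above the Yangochiroptera MRCA
  e <- which(labs == "b")
  desc <- ape::extract.clade(lt@tree, lt@tree$edge[e, 2])$tip.label
  expect_setequal(desc, batClades()$yango)

  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(b = batClades()$yango,
                        tip = "Homo_sapiens"), yml)
  lt2 <- readBranchLabels(yml, lt@tree)
  expect_equal(which(edgeLabels(lt2) == "b"), e)
  tipEdge <- which(edgeLabels(lt2) == "tip")
  expect_equal(lt@tree$tip.label[lt@tree$edge[tipEdge, 2]], "Homo_sapiens")
  expect_error(labeledPhylo(lt@tree, list(x = "NoSuchBat")), "unknown taxa")
})

test_that("trait tables validate positivity and uniqueness", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(taxon = c("A", "B"), best_frequency_khz = c(60, 20),
                         source = c("audiogram", "call-frequency-inferred")),
              f, sep = "\t", row.names = FALSE, quote = FALSE)
  tb <- readTraitTable(f)
  expect_equal(tb$best_frequency_khz, c(60, 20))
  write.table(data.frame(taxon = c("A", "B"), best_frequency_khz = c(60, -2)),
              f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readTraitTable(f), "positive")
})
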