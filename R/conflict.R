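#' Per-site support for a gene tree over a species tree (d values)
#'
#' Branch lengths are fitted independently on each topology over the full
#' alignment; each site's d value is its log-likelihood under the gene tree
#' minus its log-likelihood under the species tree.  By construction the d
#' values sum to the difference of the two total log-likelihoods.
#'
#' @param aln a [PhyloAlignment-class].
#' @param geneTree,speciesTree two `phylo` topologies over the same taxa.
#' @param model substitution model used for both topologies.
#' @param fit refit branch lengths on each topology (default TRUE); if
#'   FALSE the trees' stored lengths are used as-is.
#' @param control passed to [fitBranchLengths()].
#' @return data.frame with columns `site`, `siteLabel`, `lnLGene`,
#'   `lnLSpecies`, `d`, sorted by site; attributes `lnLGene`,
#'   `lnLSpecies` (totals) and `trees` (the fitted trees).
#' @export
siteSupport <- function(aln, geneTree, speciesTree, model, fit = TRUE,
                        control = list()) {
  if (!setequal(geneTree$tip.label, speciesTree$tip.label))
    stop("taxon mismatch between the two trees")
  if (fit) {
    geneTree <- fitBranchLengths(aln, geneTree, model, control = control)
    speciesTree <- fitBranchLengths(aln, speciesTree, model,
                                    control = control)
  }
  llG <- siteLogLik(aln, geneTree, model)
  llS <- siteLogLik(aln, speciesTree, model)
  out <- data.frame(site = seq_len(nSites(aln)),
                    siteLabel = siteLabels(aln),
                    lnLGene = as.numeric(llG),
                    lnLSpecies = as.numeric(llS),
                    d = as.numeric(llG) - as.numeric(llS))
  attr(out, "lnLGene") <- attr(llG, "logLik")
  attr(out, "lnLSpecies") <- attr(llS, "logLik")
  attr(out, "trees") <- list(gene = geneTree, species = speciesTree)
  out
}

#' Greedy minimal site removal to flip topology preference
#'
#' Repeatedly removes the site with the largest d value (ties broken by
#' ascending site index), refitting branch lengths on both topologies after
#' each removal, until the species tree's total log-likelihood exceeds the
#' gene tree's.  If the species tree is already preferred the removal set is
#' empty.
#'
#' @inheritParams siteSupport
#' @param maxRemove stop with a failure diagnostic after this many removals.
#' @param preferTol numerical tolerance for the preference test: the species
#'   tree counts as preferred when `lnL_species > lnL_gene - preferTol`.
#'   When the conflicting splits collapse, the two topologies describe the
#'   same polytomy and the totals agree to optimizer precision; without a
#'   tolerance the comparison would be decided by rounding noise.
#' @return a [RemovalResult-class].
#' @export
minimalRemoval <- function(aln, geneTree, speciesTree, model,
                           maxRemove = 20L, preferTol = 1e-3,
                           control = list()) {
  removed <- integer(0)
  traceRows <- list()
  support0 <- NULL
  gT <- geneTree; sT <- speciesTree
  repeat {
    sub <- if (length(removed)) subsetSites(aln, removed, drop = TRUE)
           else aln
    supp <- siteSupport(sub, gT, sT, model, fit = TRUE, control = control)
    trees <- attr(supp, "trees")
    gT <- trees$gene; sT <- trees$species   # warm starts for the next round
    lnLG <- attr(supp, "lnLGene"); lnLS <- attr(supp, "lnLSpecies")
    if (is.null(support0)) support0 <- supp
    traceRows[[length(traceRows) + 1]] <-
      data.frame(step = length(removed), lnLGene = lnLG, lnLSpecies = lnLS)
    if (lnLS > lnLG - preferTol) {
      return(new("RemovalResult", removedSites = removed,
                 siteLabels = siteLabels(aln)[removed],
                 trace = do.call(rbind, traceRows), converged = TRUE,
                 support = support0))
    }
    if (length(removed) >= maxRemove || nSites(sub) <= 1) {
      warning("species tree not preferred after removing ", length(removed),
              " sites")
      return(new("RemovalResult", removedSites = removed,
                 siteLabels = siteLabels(aln)[removed],
                 trace = do.call(rbind, traceRows), converged = FALSE,
                 support = support0))
    }
    ## highest d on the current (reduced) alignment, mapped back to the
    ## original column index; ties by ascending original index
    origSites <- attr(sub, "origSites") %||% seq_len(nSites(aln))
    best <- which(supp$d == max(supp$d))
    removed <- c(removed, origSites[best[1]])
  }
}

#' Compare an observed topology against random labelled topologies
#'
#' Generates `nRandom` uniform random labelled topologies over the same
#' taxa, scores each (branch lengths refitted by maximum likelihood, or
#' Robinson-Foulds distance to a reference tree) and reports the empirical
#' probability `(r + 1) / (nRandom + 1)` that a random topology does at
#' least as well as the observed one.
#'
#' @inheritParams siteSupport
#' @param observedTree the tree under test.
#' @param nRandom number of random topologies (>= 100 recommended).
#' @param statistic `"lnl"` (fitted log-likelihood; higher is better) or
#'   `"rf"` (Robinson-Foulds distance to `referenceTree`; lower is better).
#' @param referenceTree required for `statistic = "rf"`.
#' @param seed integer seed for topology generation.
#' @return the empirical p value, with attributes `observed` (the observed
#'   statistic) and `null` (the random-topology statistics).
#' @export
randomTopologyTest <- function(aln, observedTree, model, nRandom = 100L,
                               statistic = c("lnl", "rf"),
                               referenceTree = NULL, seed = NULL,
                               control = list()) {
  statistic <- match.arg(statistic)
  n <- length(observedTree$tip.label)
  if (n < 4) stop("need at least 4 taxa")
  if (!is.null(seed)) set.seed(seed)
  if (statistic == "lnl") {
    obsFit <- fitBranchLengths(aln, observedTree, model, control = control)
    obs <- attr(obsFit, "logLik")
    null <- vapply(seq_len(nRandom), function(i) {
      rt <- ape::rtopology(n, rooted = FALSE,
                           tip.label = observedTree$tip.label)
      rt$edge.length <- rep(0.05, nrow(rt$edge))
      attr(fitBranchLengths(aln, rt, model, control = control), "logLik")
    }, numeric(1))
    r <- sum(null >= obs)
  } else {
    if (is.null(referenceTree)) stop("statistic 'rf' needs a referenceTree")
    obs <- as.numeric(phangorn::RF.dist(observedTree, referenceTree))
    null <- vapply(seq_len(nRandom), function(i) {
      rt <- ape::rtopology(n, rooted = FALSE,
                           tip.label = observedTree$tip.label)
      as.numeric(phangorn::RF.dist(rt, referenceTree))
    }, numeric(1))
    r <- sum(null <= obs)
  }
  structure((r + 1) / (nRandom + 1), observed = obs, null = null)
}
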