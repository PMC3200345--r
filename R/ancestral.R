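#' Marginal (empirical-Bayes) ancestral state reconstruction
#'
#' For every internal node and site, computes the posterior distribution of
#' the ancestral state given the tip data, the rooted tree and the model,
#' by combining rootward and tipward partial likelihoods at the node.  Rate
#' categories (+I, +G) are integrated out.  Under a reversible model the
#' marginals do not depend on where along the root split the root sits, but
#' a rooted topology is still required so "internal node" is well defined;
#' supply `outgroup` to root an unrooted tree.
#'
#' @inheritParams siteLogLik
#' @param outgroup optional tip name used to root an unrooted input tree.
#' @return an [AncestralReconstruction-class]; node ids follow `ape`
#'   numbering of the (possibly re-rooted) tree stored in the object.
#' @examples
#' tr <- ape::read.tree(text = "((A:0.01,B:0.01):0.01,C:0.05):0;")
#' aln <- phyloAlignment(c(A = "M", B = "M", C = "M"), "AA")
#' rec <- ancestralML(aln, tr, aaModel("WAG"))
#' @export
ancestralML <- function(aln, tree, model, outgroup = NULL) {
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup))
      stop("unrooted tree: supply 'outgroup' to place the root")
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  prep <- .prepareData(aln, tree, model)
  me <- .modelEig(model)
  res <- .patternLogLik(prep, model, me$eigList,
                        me$edgeClassOf(nrow(prep$ti$edge)), prep$ti$len,
                        wantUp = TRUE)
  ti <- prep$ti
  S <- length(prep$states)
  nInt <- ti$nNode - ti$nTip
  intNodes <- seq(ti$nTip + 1L, ti$nNode)
  rc <- res$rc
  K <- length(rc$rates)

  nSite <- nSites(aln)
  post <- array(0, c(S, nSite, nInt),
                dimnames = list(prep$states, NULL, intNodes))
  ## per-pattern site log-likelihood (the normalizer)
  patLL <- res$patternLogLik
  for (vi in seq_len(nInt)) {
    v <- intNodes[vi]
    ## numerator per state, in log space per category, summed with weights
    num <- matrix(0, S, prep$nPat)
    for (k in seq_len(K)) {
      pr <- res$cats[[k]]
      lsc <- pr$lscUp[, v] + pr$lscDown[, v] - patLL
      num <- num + rc$weights[k] * pr$upnode[, , v] * pr$down[, , v] *
        rep(exp(lsc), each = S)
    }
    if (rc$pInv > 0) {
      cs <- apply(prep$tipState, 2, function(col) {
        obs <- unique(col[col > 0])
        if (length(obs) == 1) obs else 0L
      })
      hit <- which(cs > 0)
      if (length(hit))
        num[cbind(cs[hit], hit)] <- num[cbind(cs[hit], hit)] +
          rc$pInv * model@freq[cs[hit]] * exp(-patLL[hit])
    }
    num <- sweep(num, 2, colSums(num), "/")
    post[, , vi] <- num[, prep$patOfSite]
  }
  bestIdx <- apply(post, c(2, 3), which.max)
  best <- matrix(prep$states[bestIdx], nSite, nInt)
  bestP <- apply(post, c(2, 3), max)
  meanPost <- colMeans(bestP)
  names(meanPost) <- intNodes
  best <- t(best)
  rownames(best) <- intNodes
  new("AncestralReconstruction", method = "ML", states = prep$states,
      best = best, posterior = post,
      stateSets = array(logical(0), c(0, 0, 0)),
      meanPosterior = meanPost, score = NA_real_, tree = ti$tree)
}

#' Fitch parsimony ancestral state sets
#'
#' Classic Fitch down-pass/up-pass on a rooted binary tree: returns the
#' most-parsimonious state set per internal node and site, the total
#' parsimony score, and a deterministic best-state matrix (first member of
#' each final set in alphabet order).  Gapped tips are treated as wildcards.
#'
#' @inheritParams ancestralML
#' @return an [AncestralReconstruction-class] with `method = "MP"`.
#' @export
ancestralParsimony <- function(aln, tree, outgroup = NULL) {
  ## unrooted input is fine for parsimony: the basal multifurcation acts as
  ## the root (Hartigan counts handle any arity); an outgroup may still be
  ## supplied to fix a binary root
  if (!ape::is.rooted(tree) && !is.null(outgroup))
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  states <- switch(alphabet(aln), AA = .AA_STATES, NT = .NT_STATES,
                   CODON = codonStates())
  ti <- .treeIndex(tree)
  m <- aln@chars[ti$tree$tip.label, , drop = FALSE]
  idx <- matrix(match(m, states), nrow(m), ncol(m))
  idx[is.na(idx)] <- 0L
  S <- length(states)
  nSite <- ncol(idx)
  nNode <- ti$nNode
  ## state sets as logical arrays S x nSite per node
  down <- vector("list", nNode)
  for (t in seq_len(ti$nTip)) {
    M <- matrix(FALSE, S, nSite)
    obs <- idx[t, ]
    M[cbind(obs[obs > 0], which(obs > 0))] <- TRUE
    M[, obs == 0] <- TRUE
    down[[t]] <- M
  }
  kids <- split(seq_len(nrow(ti$edge)), ti$edge[, 1])
  score <- numeric(nSite)
  binary <- TRUE
  for (e in seq_len(nrow(ti$edge))) {
    par <- ti$edge[e, 1]
    if (!is.null(down[[par]])) next
    ke <- kids[[as.character(par)]]
    if (length(ke) != 2) binary <- FALSE
    ## Hartigan down-pass: keep the states present in the largest number of
    ## child sets; each site costs (children - max count).  For binary
    ## nodes this is exactly Fitch (intersection, else union with cost 1).
    cnt <- Reduce(`+`, lapply(ke, function(k) down[[ti$edge[k, 2]]] * 1L))
    mx <- apply(cnt, 2, max)
    down[[par]] <- sweep(cnt, 2, mx, "==")
    score <- score + (length(ke) - mx)
  }
  ## up pass (Fitch final sets; binary trees only, the root is always exact)
  fin <- vector("list", nNode)
  fin[[ti$root]] <- down[[ti$root]]
  for (e in rev(seq_len(nrow(ti$edge)))) {
    par <- ti$edge[e, 1]; ch <- ti$edge[e, 2]
    if (ch <= ti$nTip) next
    ke <- kids[[as.character(ch)]]
    Fp <- fin[[par]]; D <- down[[ch]]
    if (length(ke) != 2) { fin[[ch]] <- D; next }
    a <- down[[ti$edge[ke[1], 2]]]; b <- down[[ti$edge[ke[2], 2]]]
    contained <- colSums(Fp & !D) == 0      # F_p subset of D
    interNonEmpty <- colSums(a & b) > 0
    M <- D
    caseB <- !contained & interNonEmpty
    M[, caseB] <- (D | (Fp & (a | b)))[, caseB]
    caseC <- !contained & !interNonEmpty
    M[, caseC] <- (D | Fp)[, caseC]
    M[, contained] <- Fp[, contained]
    fin[[ch]] <- M
  }
  intNodes <- seq(ti$nTip + 1L, nNode)
  sets <- array(FALSE, c(S, nSite, length(intNodes)),
                dimnames = list(states, NULL, intNodes))
  best <- matrix(NA_character_, length(intNodes), nSite,
                 dimnames = list(intNodes, NULL))
  for (vi in seq_along(intNodes)) {
    sets[, , vi] <- fin[[intNodes[vi]]]
    best[vi, ] <- states[apply(fin[[intNodes[vi]]], 2, which.max)]
  }
  new("AncestralReconstruction", method = "MP", states = states,
      best = best, posterior = array(numeric(0), c(0, 0, 0)),
      stateSets = sets, meanPosterior = numeric(0),
      score = sum(score), tree = ti$tree)
}
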