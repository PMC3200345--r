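## Core likelihood engine: Felsenstein pruning with +I and discrete-gamma
## mixtures for amino-acid/nucleotide models, and Goldman-Yang codon models
## with per-branch-class omega.  The C++ kernel (src/pruning.cpp) returns
## scaled partials; everything here combines categories in log space.

## prepare alignment + tree for pruning: pattern-compress columns and code
## tip states as integers (0 = gap/ambiguity)
.prepareData <- function(aln, tree, model) {
  states <- modelStates(model)
  if (!setequal(tree$tip.label, taxa(aln)))
    stop("taxon mismatch between tree and alignment")
  ti <- .treeIndex(tree)
  m <- aln@chars[ti$tree$tip.label, , drop = FALSE]
  idx <- matrix(match(m, states), nrow(m), ncol(m))
  idx[is.na(idx)] <- 0L
  key <- apply(idx, 2, paste, collapse = ",")
  firsts <- which(!duplicated(key))
  patOfSite <- match(key, key[firsts])
  tipState <- idx[, firsts, drop = FALSE]
  w <- as.numeric(tabulate(patOfSite, nbins = length(firsts)))
  ## invariant-category likelihood per pattern: freq mass of the states
  ## every (non-gap) tip is compatible with
  nPat <- ncol(tipState)
  linv <- numeric(nPat)
  for (s in seq_len(nPat)) {
    obs <- unique(tipState[, s])
    obs <- obs[obs > 0]
    linv[s] <- if (length(obs) == 0) 1
               else if (length(obs) == 1) model@freq[obs]
               else 0
  }
  list(ti = ti, tipState = tipState, patOfSite = patOfSite, weights = w,
       nPat = nPat, linv = linv, states = states)
}

## transition-matrix cube over all edges for one rate multiplier;
## eigList/edgeClass support per-edge generators (codon branch models)
.pcube <- function(eigList, edgeClass, tvec, rate = 1) {
  S <- nrow(eigList[[1]]$V)
  nE <- length(tvec)
  P <- array(0, c(S, S, nE))
  for (e in seq_len(nE))
    P[, , e] <- .pmat(eigList[[edgeClass[e]]], tvec[e] * rate)
  P
}

## log-sum-exp over the rows of a matrix of per-category log-likelihoods
.lse <- function(M) {
  mx <- apply(M, 1, max)
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(M - mx)))
  out[bad] <- -Inf
  out
}

## per-pattern log-likelihood for a mixture model given partial machinery
.patternLogLik <- function(prep, model, eigList, edgeClass, tvec,
                           wantUp = FALSE) {
  rc <- .rateCats(model)
  K <- length(rc$rates)
  cats <- vector("list", K)
  ll <- matrix(-Inf, prep$nPat, K)
  for (k in seq_len(K)) {
    P <- .pcube(eigList, edgeClass, tvec, rc$rates[k])
    pr <- .cpp_prune(prep$ti$edge, prep$ti$nTip, prep$ti$nNode, prep$ti$root,
                     prep$tipState, P, model@freq, wantUp)
    cats[[k]] <- pr
    ll[, k] <- pr$siteLogLik + log(rc$weights[k])
  }
  pat <- .lse(ll)
  if (rc$pInv > 0)
    pat <- .lse(cbind(pat, log(rc$pInv) + log(prep$linv)))
  list(patternLogLik = pat, cats = cats, rc = rc)
}

.modelEig <- function(model) {
  if (is(model, "MixtureModel")) {
    list(eigList = list(.eigsys(.buildQrev(model@exch, model@freq),
                                model@freq)),
         edgeClassOf = function(nE, labels = NULL) rep(1L, nE))
  } else stop("use .codonEig for codon models")
}

## --- public API ----------------------------------------------------------

#' Per-site log-likelihoods on a fixed tree
#'
#' Computes the log-likelihood of every alignment column under a reversible
#' substitution model by Felsenstein pruning, with invariant-sites and
#' discrete-gamma components mixed in log space.  The sum over sites is the
#' total log-likelihood (available as `attr(, "logLik")`).
#'
#' @param aln a [PhyloAlignment-class] whose taxa match the tree's tips.
#' @param tree a `phylo` with branch lengths (rooted or unrooted; for
#'   reversible models the likelihood does not depend on the root).
#' @param model an [AAModel-class] or [NTModel-class].
#' @return numeric vector, one log-likelihood per alignment column.
#' @examples
#' tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,C:0.2);")
#' aln <- phyloAlignment(c(A = "MKV", B = "MKV", C = "MRV"), "AA")
#' ll <- siteLogLik(aln, tr, aaModel("WAG"))
#' attr(ll, "logLik")
#' @export
siteLogLik <- function(aln, tree, model) {
  prep <- .prepareData(aln, tree, model)
  me <- .modelEig(model)
  res <- .patternLogLik(prep, model, me$eigList,
                        me$edgeClassOf(nrow(prep$ti$edge)), prep$ti$len)
  out <- res$patternLogLik[prep$patOfSite]
  names(out) <- siteLabels(aln)
  attr(out, "logLik") <- sum(res$patternLogLik * prep$weights)
  out
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Optimizes every branch length by cyclic 1-D Brent searches against
#' cached partial likelihoods from both sides of each edge (recomputed at
#' each sweep), until the total log-likelihood improves by less than `tol`.
#' Optionally the gamma shape and invariant proportion are optimized in
#' outer rounds.
#'
#' @inheritParams siteLogLik
#' @param optShape,optPinv also optimize the rate-heterogeneity parameters.
#' @param control list with elements `tol` (absolute lnL tolerance, default
#'   1e-6), `maxSweeps`, `minLen` (lower bound 1e-8), `maxLen`.
#' @return the tree with fitted branch lengths; attributes `logLik`,
#'   `model` (with updated rate parameters), `sweeps` and `converged`.
#' @export
fitBranchLengths <- function(aln, tree, model, optShape = FALSE,
                             optPinv = FALSE, control = list()) {
  ctrl <- modifyList(list(tol = 1e-6, maxSweeps = 50, minLen = 1e-8,
                          maxLen = 10), control)
  ## optimize on the unrooted tree: the two child edges of a rooted binary
  ## root are identifiable only through their sum, which makes cyclic
  ## updates oscillate; lengths are transferred back afterwards
  inputTree <- tree
  rootedBinary <- ape::is.rooted(tree) &&
    sum(tree$edge[, 1] == length(tree$tip.label) + 1L) == 2
  if (rootedBinary) tree <- ape::unroot(tree)
  prep <- .prepareData(aln, tree, model)
  me <- .modelEig(model)
  nE <- nrow(prep$ti$edge)
  edgeClass <- me$edgeClassOf(nE)
  tvec <- pmax(prep$ti$len, ctrl$minLen)
  if (is.null(tvec) || !length(tvec)) tvec <- rep(0.1, nE)

  sweepRes <- .branchSweeps(prep, model, me$eigList, edgeClass, tvec, ctrl)
  tvec <- sweepRes$tvec; lnL <- sweepRes$logLik

  if (optShape || optPinv) {
    for (round in 1:3) {
      par0 <- c(if (optShape) log(model@gammaShape) else NULL,
                if (optPinv) stats::qlogis(max(model@pInv, 1e-4)) else NULL)
      obj <- function(p) {
        m2 <- .updateRateParams(model, p, optShape, optPinv)
        me2 <- .modelEig(m2)
        -sum(.patternLogLik(prep, m2, me2$eigList, edgeClass,
                            tvec)$patternLogLik * prep$weights)
      }
      op <- stats::optim(par0, obj, method = "Nelder-Mead",
                         control = list(maxit = 100, reltol = 1e-8))
      model <- .updateRateParams(model, op$par, optShape, optPinv)
      me <- .modelEig(model)
      sweepRes <- .branchSweeps(prep, model, me$eigList, edgeClass, tvec, ctrl)
      improved <- sweepRes$logLik - lnL
      tvec <- sweepRes$tvec; lnL <- sweepRes$logLik
      if (improved < ctrl$tol) break
    }
  }

  post <- prep$ti$tree; post$edge.length <- tvec
  if (rootedBinary) {
    out <- .transferLengths(post, inputTree)
  } else {
    out <- tree
    out$edge.length <- tvec[.matchEdges(list(edge = post$edge),
                                        list(edge = out$edge))]
  }
  attr(out, "logLik") <- lnL
  attr(out, "model") <- model
  attr(out, "sweeps") <- sweepRes$sweeps
  attr(out, "converged") <- sweepRes$converged
  out
}

.updateRateParams <- function(model, p, optShape, optPinv) {
  i <- 1
  if (optShape) { model@gammaShape <- exp(p[i]); i <- i + 1 }
  if (optPinv) model@pInv <- stats::plogis(p[i])
  model
}

## cyclic per-edge Brent optimization; partials refreshed every sweep
.branchSweeps <- function(prep, model, eigList, edgeClass, tvec, ctrl) {
  nE <- length(tvec)
  rc <- .rateCats(model)
  K <- length(rc$rates)
  wts <- prep$weights
  logPinvTerm <- if (rc$pInv > 0) log(rc$pInv) + log(prep$linv) else NULL

  patternTotal <- function(llmat) {
    pat <- .lse(llmat)
    if (!is.null(logPinvTerm)) pat <- .lse(cbind(pat, logPinvTerm))
    sum(pat * wts)
  }

  evalFull <- function(tv, wantUp = FALSE) {
    res <- .patternLogLik(prep, model, eigList, edgeClass, tv, wantUp)
    list(lnL = sum(res$patternLogLik * wts), cats = res$cats)
  }

  cur <- evalFull(tvec, wantUp = TRUE)
  lnL <- cur$lnL
  best <- list(tvec = tvec, lnL = lnL)
  converged <- FALSE
  sweep <- 0
  while (sweep < ctrl$maxSweeps) {
    sweep <- sweep + 1
    cats <- cur$cats
    for (e in seq_len(nE)) {
      ch <- prep$ti$edge[e, 2]
      A <- lapply(cats, function(p) p$A[, , e, drop = FALSE][, , 1])
      D <- lapply(cats, function(p) p$down[, , ch, drop = FALSE][, , 1])
      lsc <- lapply(seq_len(K), function(k)
        cats[[k]]$lscA[, e] + cats[[k]]$lscDown[, ch])
      eig <- eigList[[edgeClass[e]]]
      obj <- function(logt) {
        t1 <- exp(logt)
        llmat <- matrix(-Inf, prep$nPat, K)
        for (k in seq_len(K)) {
          v <- .cpp_edge_lik(A[[k]], D[[k]], .pmat(eig, t1 * rc$rates[k]))
          llmat[, k] <- log(rc$weights[k]) + log(v) + lsc[[k]]
        }
        -patternTotal(llmat)
      }
      op <- stats::optimize(obj, c(log(ctrl$minLen), log(ctrl$maxLen)),
                            tol = 1e-7)
      if (-op$objective > -obj(log(tvec[e]))) tvec[e] <- exp(op$minimum)
    }
    cur <- evalFull(tvec, wantUp = TRUE)
    if (cur$lnL > best$lnL) best <- list(tvec = tvec, lnL = cur$lnL)
    if (abs(cur$lnL - lnL) < ctrl$tol) { converged <- TRUE; lnL <- cur$lnL; break }
    lnL <- cur$lnL
  }
  list(tvec = best$tvec, logLik = best$lnL, sweeps = sweep,
       converged = converged)
}
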