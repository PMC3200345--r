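#' Map substitutions onto branches from an ancestral reconstruction
#'
#' Compares best reconstructed states between the parent and child of every
#' branch (observed states at tips), emitting one event per branch x site
#' where they differ.  Gapped tip positions yield no event.  Edge indices in
#' the result refer to rows of `rec@tree$edge` (the postorder tree stored in
#' the reconstruction).
#'
#' @param rec an [AncestralReconstruction-class].
#' @param aln the alignment the reconstruction was built from.
#' @param posteriorThreshold if > 0 (ML reconstructions), events are only
#'   called where the best-state posterior at every internal node involved
#'   reaches this value.
#' @return data.frame with columns `edge`, `parentNode`, `childNode`,
#'   `site`, `siteLabel`, `from`, `to`.
#' @export
mapSubstitutions <- function(rec, aln, posteriorThreshold = 0) {
  tree <- rec@tree
  nTip <- length(tree$tip.label)
  m <- aln@chars[tree$tip.label, , drop = FALSE]
  nodeState <- function(v) {
    if (v <= nTip) m[v, ] else rec@best[as.character(v), ]
  }
  okPost <- function(v, sites) {
    if (posteriorThreshold <= 0 || v <= nTip || rec@method != "ML")
      return(rep(TRUE, length(sites)))
    vi <- match(as.character(v), dimnames(rec@posterior)[[3]])
    mx <- apply(rec@posterior[, sites, vi, drop = FALSE], 2, max)
    mx >= posteriorThreshold
  }
  out <- vector("list", nrow(tree$edge))
  labs <- siteLabels(aln)
  gapSet <- c(.GAP_CHARS, NA)
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    su <- nodeState(u); sv <- nodeState(v)
    ok <- !(su %in% gapSet) & !(sv %in% gapSet) &
      if (alphabet(aln) == "CODON") !grepl("[-?.N]", sv) else TRUE
    hit <- which(ok & su != sv)
    if (length(hit)) {
      keep <- okPost(u, hit) & okPost(v, hit)
      hit <- hit[keep]
    }
    if (length(hit))
      out[[e]] <- data.frame(edge = e, parentNode = u, childNode = v,
                             site = hit, siteLabel = labs[hit],
                             from = su[hit], to = sv[hit])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(edge = integer(), parentNode = integer(),
                      childNode = integer(), site = integer(),
                      siteLabel = integer(), from = character(),
                      to = character())
  rownames(res) <- NULL
  res
}

#' Classify sites shared by two branches as parallel, convergent or divergent
#'
#' A site where both branches substitute is *parallel* when both changes go
#' from the same ancestral state to the same derived state, *convergent*
#' when the derived states agree but the ancestral states differ, and
#' *divergent* when the derived states differ.  The classification is
#' symmetric in the two branches.
#'
#' @param events1,events2 event tables (rows of [mapSubstitutions()] output)
#'   for two distinct branches.
#' @return data.frame with columns `site`, `from1`, `to1`, `from2`, `to2`,
#'   `class`.
#' @export
classifyPair <- function(events1, events2) {
  if (nrow(events1) && nrow(events2) &&
      events1$edge[1] == events2$edge[1])
    stop("classifyPair needs two distinct branches")
  shared <- intersect(events1$site, events2$site)
  if (!length(shared))
    return(data.frame(site = integer(), from1 = character(),
                      to1 = character(), from2 = character(),
                      to2 = character(), class = character()))
  i1 <- match(shared, events1$site); i2 <- match(shared, events2$site)
  f1 <- events1$from[i1]; t1 <- events1$to[i1]
  f2 <- events2$from[i2]; t2 <- events2$to[i2]
  cls <- ifelse(t1 != t2, "divergent",
                ifelse(f1 == f2, "parallel", "convergent"))
  data.frame(site = shared, from1 = f1, to1 = t1, from2 = f2, to2 = t2,
             class = cls)
}

#' Zhang-Kumar test for excess parallel/convergent substitution
#'
#' For a pair of branches, computes the expected numbers of parallel and
#' convergent sites under the substitution model: per site, ancestral-state
#' posteriors at the two parent nodes are combined with the branches'
#' transition probabilities to give the probability that both branches
#' independently substitute to the same derived state (from the same
#' ancestral state for "parallel", from different ones for "convergent").
#' Summing over sites gives a Poisson mean; significance is the Poisson
#' upper tail P(X >= observed).
#'
#' @param rec an ML [AncestralReconstruction-class] on the fitted tree.
#' @param model the [AAModel-class]/[NTModel-class] used for the fit.
#' @param branchPair integer(2), edge rows of `rec@tree$edge`.
#' @param events optional precomputed [mapSubstitutions()] table.
#' @param aln alignment (needed when `events` is missing).
#' @param sites optional site subset to pool over (default: all sites).
#' @return a [ParallelTestResult-class].
#' @export
zhangKumarTest <- function(rec, model, branchPair, events = NULL,
                           aln = NULL, sites = NULL) {
  stopifnot(length(branchPair) == 2, branchPair[1] != branchPair[2])
  tree <- rec@tree
  if (is.null(events)) {
    if (is.null(aln)) stop("supply 'events' or 'aln'")
    events <- mapSubstitutions(rec, aln)
  }
  e1 <- branchPair[1]; e2 <- branchPair[2]
  ## branches must be comparable: neither ancestral to the other
  if (.isAncestorEdge(tree, e1, e2) || .isAncestorEdge(tree, e2, e1))
    stop("branches in a pair must not be on the same root-to-tip path")

  eig <- .modelEig(model)$eigList[[1]]
  P1 <- .pmatMixture(model, eig, tree$edge.length[e1])
  P2 <- .pmatMixture(model, eig, tree$edge.length[e2])
  S <- length(model@freq)

  C <- P1 %*% t(P2)                     # C[x1,x2] = sum_y P1[x1,y] P2[x2,y]
  aPar <- diag(C) - diag(P1) * diag(P2) # both leave x towards the same y != x
  ## convergent kernel: drop y = x1 and y = x2 from the shared-destination sum
  Kcon <- C - (diag(P1) %o% rep(1, S)) * t(P2) - sweep(P1, 2, diag(P2), "*")
  diag(Kcon) <- 0
  Kcon[Kcon < 0] <- 0

  nSite <- ncol(rec@best)
  useSites <- if (is.null(sites)) seq_len(nSite) else sites
  p1 <- .parentPosterior(rec, tree, e1, useSites)
  p2 <- .parentPosterior(rec, tree, e2, useSites)
  lamPar <- sum(colSums(p1 * p2 * aPar))
  lamCon <- sum(colSums(p1 * (Kcon %*% p2)))

  cls <- classifyPair(events[events$edge == e1, , drop = FALSE],
                      events[events$edge == e2, , drop = FALSE])
  cls <- cls[cls$site %in% useSites, , drop = FALSE]
  obsPar <- sum(cls$class == "parallel")
  obsCon <- sum(cls$class == "convergent")
  pPar <- stats::ppois(obsPar - 1, lamPar, lower.tail = FALSE)
  pCon <- stats::ppois(obsCon - 1, lamCon, lower.tail = FALSE)
  new("ParallelTestResult", pair = as.integer(branchPair),
      observedParallel = obsPar, observedConvergent = obsCon,
      expectedParallel = lamPar, expectedConvergent = lamCon,
      pParallel = pPar, pConvergent = pCon, sites = cls)
}

## posterior of the ancestral (parent) state of an edge, states x sites
.parentPosterior <- function(rec, tree, e, sites) {
  par <- tree$edge[e, 1]
  vi <- match(as.character(par), dimnames(rec@posterior)[[3]])
  if (is.na(vi)) stop("reconstruction lacks node ", par)
  out <- rec@posterior[, sites, vi, drop = FALSE]
  dim(out) <- dim(out)[1:2]
  out
}

.isAncestorEdge <- function(tree, e1, e2) {
  ## TRUE if edge e1's child is an ancestor of edge e2's child
  v <- tree$edge[e2, 2]
  target <- tree$edge[e1, 2]
  root <- length(tree$tip.label) + 1L
  repeat {
    e <- which(tree$edge[, 2] == v)
    if (!length(e)) return(FALSE)
    v <- tree$edge[e, 1]
    if (v == target) return(TRUE)
    if (v == root) return(root == target)
  }
}

#' Scan for significantly parallel sites between focal lineages
#'
#' Runs the full parallel-evolution analysis on one alignment: fits branch
#' lengths on the (species) tree, reconstructs ancestral sequences by
#' marginal ML, maps substitutions, and applies the Zhang-Kumar test to each
#' configured branch pair.  Sites classified parallel on a pair are reported
#' with that pair's pooled significance.
#'
#' @param aln a [PhyloAlignment-class].
#' @param tree a rooted `phylo` or [LabeledPhylo-class].
#' @param model an [AAModel-class]/[NTModel-class].
#' @param lineagePairs list of pairs; each pair is either integer edge rows
#'   (of the postorder reconstruction tree) or two branch-class labels of
#'   the [LabeledPhylo-class].
#' @param alpha significance threshold on the pooled per-pair Poisson test.
#' @param fit refit branch lengths before reconstructing (default TRUE).
#' @param control passed to [fitBranchLengths()].
#' @return data.frame of parallel sites (siteLabel, pair, states, observed,
#'   expected, p, significant), with attributes `pairs` (per-pair summary)
#'   and `reconstruction`.
#' @export
scanParallelSites <- function(aln, tree, model, lineagePairs, alpha = 0.01,
                              fit = TRUE, control = list()) {
  lt <- NULL
  if (is(tree, "LabeledPhylo")) { lt <- tree; tree <- tree@tree }
  if (fit) tree <- fitBranchLengths(aln, tree, model, control = control)
  rec <- ancestralML(aln, tree, model)
  events <- mapSubstitutions(rec, aln)
  rows <- list(); pairRows <- list()
  for (i in seq_along(lineagePairs)) {
    pr <- lineagePairs[[i]]
    edges <- if (is.character(pr)) {
      if (is.null(lt)) stop("label pairs need a LabeledPhylo tree")
      vapply(pr, function(lb) .resolveLabeledEdge(rec@tree, lt, lb),
             integer(1))
    } else as.integer(pr)
    zk <- zhangKumarTest(rec, model, edges, events = events)
    pname <- if (is.character(pr)) paste(pr, collapse = "x")
             else paste(edges, collapse = "x")
    sig <- zk@pParallel < alpha
    cls <- zk@sites
    par <- cls[cls$class == "parallel", , drop = FALSE]
    if (nrow(par))
      rows[[length(rows) + 1]] <- data.frame(
        site = par$site, siteLabel = siteLabels(aln)[par$site],
        pair = pname, from = par$from1, to = par$to1,
        observedParallel = zk@observedParallel,
        expectedParallel = zk@expectedParallel,
        p = zk@pParallel, significant = sig)
    pairRows[[i]] <- data.frame(
      pair = pname, edge1 = edges[1], edge2 = edges[2],
      observedParallel = zk@observedParallel,
      expectedParallel = zk@expectedParallel, pParallel = zk@pParallel,
      observedConvergent = zk@observedConvergent,
      expectedConvergent = zk@expectedConvergent,
      pConvergent = zk@pConvergent)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = integer(), siteLabel = integer(), pair = character(),
               from = character(), to = character(),
               observedParallel = numeric(), expectedParallel = numeric(),
               p = numeric(), significant = logical())
  attr(out, "pairs") <- do.call(rbind, pairRows)
  attr(out, "reconstruction") <- rec
  out
}

## find, on the reconstruction's postorder tree, the edge corresponding to a
## labelled branch of a LabeledPhylo (matched by the child clade's tip set)
.resolveLabeledEdge <- function(recTree, lt, label) {
  e <- which(lt@edgeLabels == label)
  if (length(e) != 1) stop("lineage label not found: ", label)
  child <- lt@tree$edge[e, 2]
  tips <- if (child <= length(lt@tree$tip.label)) {
    lt@tree$tip.label[child]
  } else {
    lt@tree$tip.label[unlist(ape::prop.part(lt@tree)[
      child - length(lt@tree$tip.label)])]
  }
  edgeAboveMRCA(recTree, tips)
}
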