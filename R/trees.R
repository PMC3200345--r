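#' Read and write Newick trees
#'
#' Thin wrappers around \pkg{ape} that validate branch lengths and keep
#' round-trips faithful to the printed precision.
#'
#' @param path file path.
#' @param tree a `phylo` object.
#' @return `readNewickTree()` a `phylo`; `writeNewickTree()` `path`,
#'   invisibly.
#' @export
readNewickTree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick in ", path)
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length in ", path)
  tr
}

#' @rdname readNewickTree
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Attach branch-class labels to a tree
#'
#' Branch classes (e.g. the `a`--`e` lineages used in the selection tests)
#' are attached per edge.  `labels` may be a character vector aligned to the
#' rows of `tree$edge`, or a named list of clade specifications: each entry
#' is a character vector of tip names, and the labelled edge is the stem
#' edge above their most recent common ancestor (a single tip name labels
#' its terminal edge).
#'
#' @param tree a `phylo`.
#' @param labels per-edge character vector, or named list of tip-name sets.
#' @return a [LabeledPhylo-class].
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' lt <- labeledPhylo(tr, list(x = c("A", "B"), y = "C"))
#' edgeLabels(lt)
#' @export
labeledPhylo <- function(tree, labels = NULL) {
  nE <- nrow(tree$edge)
  lab <- character(nE)
  if (is.character(labels) && length(labels) == nE) {
    lab <- labels
  } else if (is.list(labels)) {
    for (nm in names(labels)) {
      e <- edgeAboveMRCA(tree, labels[[nm]])
      if (nzchar(lab[e]))
        stop("edge already labelled '", lab[e], "' when assigning '", nm, "'")
      lab[e] <- nm
    }
  } else if (!is.null(labels)) {
    stop("labels must be a per-edge character vector or a named list")
  }
  new("LabeledPhylo", tree = tree, edgeLabels = lab)
}

#' Find the stem edge above a clade
#'
#' @param tree a `phylo`.
#' @param tips tip names (one tip gives its terminal edge).
#' @return the row index into `tree$edge` of the edge whose child is the MRCA
#'   of `tips`.
#' @export
edgeAboveMRCA <- function(tree, tips) {
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss)) stop("lineage label refers to unknown taxa: ",
                         paste(miss, collapse = ", "))
  node <- if (length(tips) == 1) match(tips, tree$tip.label)
          else ape::getMRCA(tree, tips)
  e <- which(tree$edge[, 2] == node)
  if (length(e) != 1)
    stop("no stem edge above clade (is it the root?): ",
         paste(tips, collapse = ", "))
  e
}

#' Read branch-class labels from a YAML file
#'
#' The YAML maps class symbols to tip-name lists, e.g.
#' \preformatted{
#' a: [Myotis_lucifugus, Pteropus_vampyrus]   # stem above their MRCA
#' b: [Myotis_lucifugus]                      # terminal branch
#' }
#'
#' @param path YAML file.
#' @param tree the `phylo` the labels refer to.
#' @return a [LabeledPhylo-class].
#' @export
readBranchLabels <- function(path, tree) {
  spec <- yaml::read_yaml(path)
  labeledPhylo(tree, lapply(spec, as.character))
}

## --- internal tree plumbing used by the likelihood engine ----------------

## postorder edge ordering plus convenience indices
.treeIndex <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tr$tip.label)
  nNode <- nTip + tr$Nnode
  root <- nTip + 1L
  list(tree = tr, edge = tr$edge, len = tr$edge.length, nTip = nTip,
       nNode = nNode, root = root)
}

## number of identifiable branch lengths (unrooted convention): a rooted
## binary root contributes only the sum of its two child edges
.nIdentifiableEdges <- function(tree) {
  nE <- nrow(tree$edge)
  root <- length(tree$tip.label) + 1L
  if (sum(tree$edge[, 1] == root) == 2) nE - 1L else nE
}

## map edge rows of one ordering to another (labels follow parent/child ids)
.matchEdges <- function(from, to) {
  key <- function(e) paste(e[, 1], e[, 2])
  match(key(to$edge), key(from$edge))
}

## carry per-edge labels across a reorder
.reorderLabels <- function(tree, labels, newTree) {
  idx <- .matchEdges(list(edge = tree$edge), list(edge = newTree$edge))
  labels[idx]
}

## split-based edge keys: each edge identified by the (orientation-free)
## bipartition of tips it induces, encoded as the lexicographically smaller
## side of the split
.edgeKeys <- function(tree) {
  nTip <- length(tree$tip.label)
  labs <- sort(tree$tip.label)
  below <- vector("list", nTip + tree$Nnode)
  for (t in seq_len(nTip)) below[[t]] <- tree$tip.label[t]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  vapply(tree$edge[, 2], function(v) {
    side <- sort(below[[v]])
    other <- setdiff(labs, side)
    a <- paste(side, collapse = "|"); b <- paste(other, collapse = "|")
    if (a < b) a else b
  }, character(1))
}

## copy fitted lengths from one tree onto another layout of the same
## (unrooted) topology; a rooted binary destination splits the merged root
## edge in proportion to its original two root-edge lengths
.transferLengths <- function(src, dst) {
  ks <- .edgeKeys(src); kd <- .edgeKeys(dst)
  out <- dst
  idx <- match(kd, ks)
  rootEdges <- which(is.na(idx) | duplicated(kd) | kd %in% kd[duplicated(kd)])
  plain <- setdiff(seq_along(kd), rootEdges)
  out$edge.length[plain] <- src$edge.length[idx[plain]]
  if (length(rootEdges)) {
    mergedKey <- unique(kd[rootEdges])
    stopifnot(length(mergedKey) == 1)
    tot <- src$edge.length[match(mergedKey, ks)]
    orig <- dst$edge.length[rootEdges]
    prop <- if (sum(orig) > 0) orig / sum(orig)
            else rep(1 / length(rootEdges), length(rootEdges))
    out$edge.length[rootEdges] <- tot * prop
  }
  out
}
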