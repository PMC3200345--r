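#' Count substitutions along a root-to-tip path
#'
#' Sums mapped substitution events over the unique path from an ancestral
#' node to a tip.  `lineageChangeCounts()` does this for every tip below
#' the ancestor.
#'
#' @param events a [mapSubstitutions()] table (edge indices refer to the
#'   reconstruction tree).
#' @param tree the reconstruction's tree (`rec@tree`).
#' @param rootNode internal node the paths start from (e.g. the bat stem
#'   ancestor).
#' @param tip tip name or index.
#' @return `countChanges()` an integer; `lineageChangeCounts()` a named
#'   integer vector over the descendant tips.
#' @export
countChanges <- function(events, tree, rootNode, tip) {
  if (is.character(tip)) tip <- match(tip, tree$tip.label)
  if (is.na(tip)) stop("unknown tip")
  path <- ape::nodepath(tree, rootNode, tip)
  ## every consecutive pair must be a parent -> child edge
  edges <- integer(length(path) - 1)
  for (i in seq_along(edges)) {
    e <- which(tree$edge[, 1] == path[i] & tree$edge[, 2] == path[i + 1])
    if (length(e) != 1)
      stop("tip ", tree$tip.label[tip], " is not a descendant of node ",
           rootNode)
    edges[i] <- e
  }
  sum(events$edge %in% edges)
}

#' @rdname countChanges
#' @export
lineageChangeCounts <- function(events, tree, rootNode) {
  nTip <- length(tree$tip.label)
  tips <- if (rootNode <= nTip) rootNode
          else intersect(seq_len(nTip),
                         .descendants(tree, rootNode))
  counts <- vapply(tips, function(tp)
    countChanges(events, tree, rootNode, tp), numeric(1))
  stats::setNames(as.integer(counts), tree$tip.label[tips])
}

.descendants <- function(tree, node) {
  out <- integer(0); stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ch <- tree$edge[tree$edge[, 1] == v, 2]
    out <- c(out, ch); stack <- c(stack, ch[ch > length(tree$tip.label)])
  }
  out
}

#' Phylogenetically independent contrasts
#'
#' Standardized contrasts under Brownian motion (Felsenstein's pruning
#' recursion, via \code{ape::pic}).  Soft polytomies are resolved with
#' zero-length branches; non-ultrametric trees are accepted but flagged
#' with a warning attribute.
#'
#' @param tree a `phylo` with positive branch durations.
#' @param trait named numeric vector over the tree's tips.
#' @return data.frame with columns `node`, `contrast` (standardized) and
#'   `variance` (the expected variance each contrast was scaled by).
#' @export
picContrasts <- function(tree, trait) {
  if (!all(tree$tip.label %in% names(trait)))
    stop("trait values missing for: ",
         paste(setdiff(tree$tip.label, names(trait)), collapse = ", "))
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  x <- trait[tree$tip.label]
  pc <- ape::pic(x, tree, scaled = TRUE, var.contrasts = TRUE)
  out <- data.frame(node = as.integer(rownames(pc)), contrast = pc[, 1],
                    variance = pc[, 2])
  rownames(out) <- NULL
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    attr(out, "nonUltrametric") <- TRUE
  out
}

#' Correlation of two traits through independent contrasts
#'
#' Computes standardized contrasts for both traits on the same tree and
#' correlates them through the origin (the standard practice for
#' contrasts, whose signs are arbitrary); the t test uses
#' `df = n_contrasts - 1`.
#'
#' @inheritParams picContrasts
#' @param x,y named numeric trait vectors over the tree's tips.
#' @return list with `R`, `p`, `df`, and the contrast pairs.
#' @export
picCorrelation <- function(tree, x, y) {
  cx <- picContrasts(tree, x)$contrast
  cy <- picContrasts(tree, y)$contrast
  n <- length(cx)
  sxx <- sum(cx^2); syy <- sum(cy^2); sxy <- sum(cx * cy)
  if (sxx == 0 || syy == 0) stop("undefined-correlation error: zero variance")
  R <- sxy / sqrt(sxx * syy)
  df <- n - 1
  t <- R * sqrt(df) / sqrt(max(1 - R^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df)
  list(R = R, p = p, df = df,
       contrasts = data.frame(x = cx, y = cy))
}

#' Ordinary Pearson correlation with t test
#'
#' Thin wrapper around \code{stats::cor.test} returning the pieces the
#' trait-association reports use.
#'
#' @param x,y numeric vectors (n >= 3, finite).
#' @return list with `R`, `p` and `n`.
#' @export
traitCorrelation <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) stop("need n >= 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation error: zero variance")
  ct <- stats::cor.test(x, y)
  list(R = unname(ct$estimate), p = ct$p.value, n = length(x))
}
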