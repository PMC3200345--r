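## Independent oracles used across the suite.  These deliberately avoid the
## package's pruning code path: likelihoods are computed by exhaustive
## enumeration over ancestral states, transition matrices by dense matrix
## exponentials, and PIC checks by generalized least squares on the
## Brownian covariance matrix.

## exhaustive likelihood of one site: sum over all internal-state
## assignments of pi_root * prod(P_edge[parent, child])
bruteSiteLik <- function(tree, Pfun, pi, tipStateIdx) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tr$tip.label)
  nNode <- nTip + tr$Nnode
  intNodes <- seq(nTip + 1L, nNode)
  S <- length(pi)
  Pedges <- lapply(seq_len(nrow(tr$edge)), function(e)
    Pfun(tr$edge.length[e]))
  grid <- do.call(expand.grid, rep(list(seq_len(S)), length(intNodes)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    assign <- integer(nNode)
    assign[seq_len(nTip)] <- tipStateIdx[tr$tip.label]
    assign[intNodes] <- as.integer(grid[g, ])
    p <- pi[assign[nTip + 1L]]
    for (e in seq_len(nrow(tr$edge)))
      p <- p * Pedges[[e]][assign[tr$edge[e, 1]], assign[tr$edge[e, 2]]]
    tot <- tot + p
  }
  tot
}

## exhaustive parsimony score of one site (minimum changes over all
## ancestral assignments, restricted to states seen at the tips)
bruteParsimony <- function(tree, tipStates) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tr$tip.label)
  nNode <- nTip + tr$Nnode
  intNodes <- seq(nTip + 1L, nNode)
  sts <- unique(unname(tipStates))
  grid <- do.call(expand.grid,
                  rep(list(sts), length(intNodes)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign <- character(nNode)
    assign[seq_len(nTip)] <- tipStates[tr$tip.label]
    assign[intNodes] <- as.character(unlist(grid[g, ]))
    ch <- sum(assign[tr$edge[, 1]] != assign[tr$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

## transition matrix by scaling-and-squaring matrix exponential
expmP <- function(Q, t) as.matrix(Matrix::expm(Q * t))

## GLS pieces on the Brownian covariance matrix
glsPieces <- function(tree, x) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  Ci <- solve(C)
  one <- rep(1, nrow(C))
  ahat <- as.numeric((t(one) %*% Ci %*% x) / (t(one) %*% Ci %*% one))
  r <- x - ahat
  list(ahat = ahat, quad = as.numeric(t(r) %*% Ci %*% r), resid = r,
       Ci = Ci)
}

## random ungapped amino-acid alignment helper
randomAAln <- function(taxa, n, seed) {
  set.seed(seed)
  m <- matrix(sample(parallevol:::.AA_STATES, length(taxa) * n, TRUE),
              length(taxa), n, dimnames = list(taxa, NULL))
  phyloAlignment(m, "AA")
}
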