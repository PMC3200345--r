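#' Build a simulation recipe
#'
#' The recipe fixes everything the simulators need; a given seed fully
#' determines the output.  The tree is stored in postorder, so edge indices
#' in `forcedEvents` (and in all reported truth) refer to rows of
#' `recipe@tree$edge`.
#'
#' @param tree a `phylo` with branch lengths, or a [LabeledPhylo-class]
#'   (labels are kept for per-class codon omegas).
#' @param model an [AAModel-class], [NTModel-class] or [CodonModel-class].
#' @param nSites alignment columns to simulate (codons for codon models).
#' @param seed integer; `NA` leaves the RNG state untouched.
#' @param forcedEvents data.frame(edge, site, from, to): at each listed
#'   branch the site deterministically substitutes `from -> to`; forced
#'   sites are otherwise held constant so the injected change is the only
#'   one at that column.
#' @return a [SimulationRecipe-class].
#' @export
simulationRecipe <- function(tree, model, nSites, seed = NA,
                             forcedEvents = NULL) {
  labels <- character(0)
  if (is(tree, "LabeledPhylo")) { labels <- tree@edgeLabels; tree <- tree@tree }
  ti <- .treeIndex(tree)
  if (length(labels)) labels <- .reorderLabels(tree, labels, ti$tree)
  if (is.null(forcedEvents))
    forcedEvents <- data.frame(edge = integer(), site = integer(),
                               from = character(), to = character())
  new("SimulationRecipe", tree = ti$tree, model = model,
      nSites = as.integer(nSites), seed = as.integer(seed),
      forcedEvents = forcedEvents, edgeLabels = labels)
}

#' Inject parallel substitutions into a recipe
#'
#' Adds forced events realizing the same `from -> to` change independently
#' on two branches at the given sites; descendants inherit the derived
#' state (no further events occur at forced sites).
#'
#' @param recipe a [SimulationRecipe-class].
#' @param branchPair integer(2) edge rows of `recipe@tree$edge`.
#' @param sites alignment columns to force.
#' @param from,to states in the model alphabet.
#' @return the augmented recipe.
#' @export
injectParallel <- function(recipe, branchPair, sites, from, to) {
  stopifnot(length(branchPair) == 2)
  clash <- intersect(sites, recipe@forcedEvents$site)
  if (length(clash))
    stop("site collision with existing forced events: ",
         paste(clash, collapse = ", "))
  add <- expand.grid(edge = as.integer(branchPair), site = as.integer(sites))
  add$from <- from; add$to <- to
  recipe@forcedEvents <- rbind(recipe@forcedEvents, add)
  validObject(recipe)
  recipe
}

#' Simulate an alignment along a tree with recorded truth
#'
#' The root sequence is drawn from the model's equilibrium frequencies and
#' evolved branch-wise.  `mode = "matrix"` samples each child state from
#' the exact transition probabilities (fast); `mode = "gillespie"` samples
#' the full substitution path so every individual event is recorded.  Site
#' rates follow the model's +I / discrete-gamma mixture.  Forced sites are
#' held invariant except for their forced events.
#'
#' @param recipe a [SimulationRecipe-class].
#' @param mode `"matrix"` or `"gillespie"`.
#' @return list with `alignment` (a [PhyloAlignment-class]), `nodeStates`
#'   (character matrix, all nodes x sites, rownames = node ids),
#'   `events` (data.frame edge, site, from, to; exhaustive under
#'   `"gillespie"`, forced events only under `"matrix"`), `siteRates`,
#'   and `tree` (the postorder tree).
#' @export
simulateAlignment <- function(recipe, mode = c("matrix", "gillespie")) {
  mode <- match.arg(mode)
  if (!is.na(recipe@seed)) set.seed(recipe@seed)
  model <- recipe@model
  states <- modelStates(model)
  S <- length(states)
  tree <- recipe@tree
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  nS <- recipe@nSites
  root <- nTip + 1L

  isCodon <- is(model, "CodonModel")
  eigs <- if (isCodon) .codonEig(model, recipe@edgeLabels, nrow(tree$edge))
          else { me <- .modelEig(model)
                 list(eigList = me$eigList,
                      edgeClass = rep(1L, nrow(tree$edge))) }
  Qs <- if (isCodon) {
    cls <- parallevol_codon_classes(model, recipe@edgeLabels,
                                    nrow(tree$edge))
    u <- unique(cls)
    list(Q = lapply(u, function(x)
      .buildQcodon(model@kappa, model@omegaMap[[x]], model@freq)),
      class = match(cls, u))
  } else {
    list(Q = list(.buildQrev(model@exch, model@freq)),
         class = rep(1L, nrow(tree$edge)))
  }

  rc <- .rateCats(model)
  rates <- numeric(nS)
  if (rc$pInv > 0 || length(rc$rates) > 1) {
    cat <- sample.int(length(rc$rates) + (rc$pInv > 0), nS, replace = TRUE,
                      prob = c(rc$weights, if (rc$pInv > 0) rc$pInv))
    rates <- c(rc$rates, 0)[cat]
  } else rates[] <- 1

  forced <- recipe@forcedEvents
  fsites <- unique(forced$site)
  nodeIdx <- matrix(0L, nNode, nS)
  nodeIdx[root, ] <- sample.int(S, nS, replace = TRUE, prob = model@freq)
  if (length(fsites))
    nodeIdx[root, fsites] <-
      match(forced$from[match(fsites, forced$site)], states)

  events <- forced[, c("edge", "site", "from", "to")]
  for (e in rev(seq_len(nrow(tree$edge)))) {  # preorder
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t1 <- tree$edge.length[e]
    cur <- nodeIdx[par, ]
    child <- cur  # default: inherit (rate 0 / forced sites)
    free <- setdiff(which(rates > 0), fsites)
    if (mode == "matrix") {
      for (r in unique(rates[free])) {
        P <- .pmat(eigs$eigList[[eigs$edgeClass[e]]], t1 * r)
        sel <- free[rates[free] == r]
        for (p in unique(cur[sel])) {
          idx <- sel[cur[sel] == p]
          child[idx] <- sample.int(S, length(idx), replace = TRUE,
                                   prob = P[p, ])
        }
      }
    } else {
      Q <- Qs$Q[[Qs$class[e]]]
      for (s in free) {
        x <- cur[s]; tleft <- t1 * rates[s]
        repeat {
          lam <- -Q[x, x]
          if (lam <= 0) break
          dt <- stats::rexp(1, lam)
          if (dt > tleft) break
          tleft <- tleft - dt
          y <- sample.int(S, 1, prob = pmax(Q[x, ], 0) *
                            (seq_len(S) != x))
          events <- rbind(events,
                          data.frame(edge = e, site = s,
                                     from = states[x], to = states[y]))
          x <- y
        }
        child[s] <- x
      }
    }
    fe <- forced[forced$edge == e, , drop = FALSE]
    if (nrow(fe)) child[fe$site] <- match(fe$to, states)
    nodeIdx[ch, ] <- child
  }

  chars <- matrix(states[nodeIdx[seq_len(nTip), ]], nTip, nS,
                  dimnames = list(tree$tip.label, NULL))
  nodeStates <- matrix(states[nodeIdx], nNode, nS,
                       dimnames = list(seq_len(nNode), NULL))
  aln <- phyloAlignment(chars,
                        alphabet = if (isCodon) "CODON"
                                   else if (is(model, "NTModel")) "NT"
                                   else "AA")
  rownames(events) <- NULL
  list(alignment = aln, nodeStates = nodeStates, events = events,
       siteRates = rates, tree = tree)
}

#' @rdname simulateAlignment
#' @details `simulateCodonAlignment()` is `simulateAlignment()` restricted
#'   to codon recipes (61 sense-codon states, per-branch-class omega).
#' @export
simulateCodonAlignment <- function(recipe, mode = c("matrix", "gillespie")) {
  if (!is(recipe@model, "CodonModel"))
    stop("recipe must carry a CodonModel")
  simulateAlignment(recipe, mode)
}

#' Simulate a Brownian-motion trait, optionally coupled to change counts
#'
#' Evolves a continuous trait by Brownian motion along the tree.  With
#' `coupling = list(beta, counts)` a linear term `beta * counts[tip]` is
#' added to each tip value, producing trait/substitution-count pairs with a
#' built-in association (as when hearing frequency tracks amino-acid
#' change).
#'
#' @param tree a `phylo` with branch lengths (durations).
#' @param sigma2 Brownian rate (variance per unit branch length), > 0.
#' @param root trait value at the root.
#' @param seed optional integer seed.
#' @param coupling optional list(beta = numeric, counts = named numeric by
#'   tip).
#' @return data.frame(taxon, trait, source), plus attribute `nodeValues`.
#' @export
simulateTraits <- function(tree, sigma2, root = 0, seed = NULL,
                           coupling = NULL) {
  stopifnot(sigma2 >= 0)
  if (!is.null(seed)) set.seed(seed)
  ti <- .treeIndex(tree)
  tr <- ti$tree
  nTip <- ti$nTip
  vals <- numeric(ti$nNode)
  vals[ti$root] <- root
  for (e in rev(seq_len(nrow(tr$edge)))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    vals[ch] <- vals[par] +
      stats::rnorm(1, 0, sqrt(sigma2 * tr$edge.length[e]))
  }
  tipVals <- stats::setNames(vals[seq_len(nTip)], tr$tip.label)
  if (!is.null(coupling)) {
    cnt <- coupling$counts[names(tipVals)]
    if (any(is.na(cnt))) stop("coupling counts missing for some tips")
    tipVals <- tipVals + coupling$beta * cnt
  }
  out <- data.frame(taxon = names(tipVals), trait = unname(tipVals),
                    source = "simulated")
  attr(out, "nodeValues") <- vals
  out
}
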