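#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib parallevol, .registration = TRUE
NULL

setOldClass("phylo")

## residue sets; codon states are built at load time from the standard code
.AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.NT_STATES <- c("A", "C", "G", "T")
.GAP_CHARS <- c("-", "?", ".", "X", "N", "*")

#' Multiple sequence alignment with a declared alphabet
#'
#' A thin S4 container for an aligned set of sequences.  Residues are stored
#' as a character matrix (taxa in rows); for codon alignments each cell holds
#' one in-frame codon (three letters).  `siteOffset` maps column 1 to a
#' reference coordinate so reported site labels can follow, e.g., human
#' protein numbering.
#'
#' @slot chars character matrix, taxa x sites.
#' @slot alphabet one of `"AA"`, `"NT"`, `"CODON"`.
#' @slot siteOffset integer added to `column - 1` to produce site labels.
#' @exportClass PhyloAlignment
setClass("PhyloAlignment",
  representation(chars = "matrix", alphabet = "character",
                 siteOffset = "integer"))

setValidity("PhyloAlignment", function(object) {
  msg <- character()
  if (!object@alphabet %in% c("AA", "NT", "CODON"))
    msg <- c(msg, "alphabet must be AA, NT or CODON")
  if (is.null(rownames(object@chars)))
    msg <- c(msg, "alignment rows must be named by taxon")
  if (anyDuplicated(rownames(object@chars)))
    msg <- c(msg, "duplicated taxon names")
  st <- switch(object@alphabet, AA = .AA_STATES, NT = .NT_STATES,
               CODON = codonStates())
  bad <- if (object@alphabet == "CODON") {
    v <- object@chars
    !(v %in% st | grepl(paste0("[", paste(.GAP_CHARS[1:4], collapse = ""), "N]"),
                        v))
  } else {
    !(object@chars %in% c(st, .GAP_CHARS))
  }
  if (any(bad))
    msg <- c(msg, sprintf("illegal character(s) for alphabet %s: %s",
                          object@alphabet,
                          paste(unique(object@chars[bad])[1:5], collapse = " ")))
  if (length(msg)) msg else TRUE
})

#' Phylogeny with labelled branch classes
#'
#' Wraps an `ape` \code{phylo} tree together with a character vector of
#' branch-class labels aligned to the rows of \code{tree$edge} (empty string
#' for background branches).  Labels name the lineage classes used by the
#' codon branch models and the parallel-site scans (e.g. the bat stem,
#' the Yangochiroptera and Rhinolophoidea ancestors).
#'
#' @slot tree a \code{phylo} object with branch lengths.
#' @slot edgeLabels character vector, one entry per edge row.
#' @exportClass LabeledPhylo
setClass("LabeledPhylo",
  representation(tree = "phylo", edgeLabels = "character"))

setValidity("LabeledPhylo", function(object) {
  if (length(object@edgeLabels) != nrow(object@tree$edge))
    return("edgeLabels must have one entry per edge")
  TRUE
})

#' Substitution models
#'
#' `AAModel` and `NTModel` share the reversible-matrix machinery: a symmetric
#' exchangeability matrix, equilibrium frequencies, an invariant-sites
#' proportion and a discrete-gamma shape.  `CodonModel` is a Goldman-Yang
#' model over the 61 sense codons with a transition/transversion ratio and a
#' map from branch-class label to dN/dS.
#'
#' @slot name model name (e.g. "HIVb", "WAG", "JC", "HKY").
#' @slot exch symmetric exchangeability matrix.
#' @slot freq equilibrium state frequencies (sum to 1).
#' @slot pInv proportion of invariant sites in `[0, 1)`.
#' @slot gammaShape gamma shape; `numeric(0)` disables rate heterogeneity.
#' @slot nCat number of discrete gamma categories.
#' @exportClass AAModel
setClass("SubstModel", representation("VIRTUAL",
  name = "character", freq = "numeric"))

setClass("MixtureModel", contains = "SubstModel", representation(
  exch = "matrix", pInv = "numeric", gammaShape = "numeric",
  nCat = "integer"))

setClass("AAModel", contains = "MixtureModel")

#' @rdname AAModel-class
#' @exportClass NTModel
setClass("NTModel", contains = "MixtureModel")

#' @rdname AAModel-class
#' @slot kappa transition/transversion rate ratio.
#' @slot omegaMap named numeric, branch-class label -> dN/dS; the entry
#'   named `".default"` covers unlabelled branches.
#' @exportClass CodonModel
setClass("CodonModel", contains = "SubstModel", representation(
  kappa = "numeric", omegaMap = "numeric"))

setValidity("MixtureModel", function(object) {
  msg <- character()
  if (abs(sum(object@freq) - 1) > 1e-8) msg <- c(msg, "freq must sum to 1")
  if (length(object@pInv) != 1 || object@pInv < 0 || object@pInv >= 1)
    msg <- c(msg, "pInv must lie in [0, 1)")
  if (length(object@gammaShape) == 1 && object@gammaShape <= 0)
    msg <- c(msg, "gammaShape must be > 0")
  if (length(msg)) msg else TRUE
})

setValidity("CodonModel", function(object) {
  msg <- character()
  if (object@kappa <= 0) msg <- c(msg, "kappa must be > 0")
  if (any(object@omegaMap < 0)) msg <- c(msg, "omega values must be >= 0")
  if (!".default" %in% names(object@omegaMap))
    msg <- c(msg, "omegaMap needs a '.default' entry")
  if (abs(sum(object@freq) - 1) > 1e-8) msg <- c(msg, "freq must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Ancestral character-state reconstruction
#'
#' Holds, for every internal node of a rooted tree, either marginal
#' empirical-Bayes posteriors over states (`method = "ML"`) or Fitch
#' parsimony state sets (`method = "MP"`), plus the best-state string per
#' node and per-node mean posterior of the best state.
#'
#' @slot method `"ML"` or `"MP"`.
#' @slot states the state alphabet.
#' @slot best character matrix, nodes x sites, best (or arbitrary MPR) state.
#' @slot posterior states x sites x nodes array of marginal posteriors (ML).
#' @slot stateSets states x sites x nodes logical array of Fitch sets (MP).
#' @slot meanPosterior named numeric, per-node mean posterior of best state.
#' @slot score total parsimony score (MP only).
#' @slot tree the rooted tree used.
#' @exportClass AncestralReconstruction
setClass("AncestralReconstruction", representation(
  method = "character", states = "character", best = "matrix",
  posterior = "array", stateSets = "array", meanPosterior = "numeric",
  score = "numeric", tree = "phylo"))

#' Codon branch-model specification and fit
#'
#' A `BranchModelSpec` maps branch-class labels to omega parameters: entries
#' of `assign` are either a parameter name (branches sharing a name share a
#' free omega) or a fixed numeric value.  `freeRatio = TRUE` gives every
#' branch its own omega.  A `BranchModelFit` records the ML estimates.
#'
#' @slot name model name, used in reports.
#' @slot assign named list, branch-class -> parameter name or fixed value;
#'   `".default"` covers unlabelled branches.
#' @slot freeRatio logical, one omega per branch.
#' @exportClass BranchModelSpec
setClass("BranchModelSpec", representation(
  name = "character", assign = "list", freeRatio = "logical"))

#' @rdname BranchModelSpec-class
#' @slot spec the specification that was fitted.
#' @slot kappa fitted transition/transversion ratio.
#' @slot omega fitted omega per parameter name (or per edge if free-ratio).
#' @slot logLik total log-likelihood.
#' @slot np number of free parameters (identifiable branch lengths + kappa +
#'   free omegas), matching CODEML's accounting.
#' @slot tree tree with fitted branch lengths.
#' @slot convergence diagnostics from the optimizer.
#' @exportClass BranchModelFit
setClass("BranchModelFit", representation(
  spec = "BranchModelSpec", kappa = "numeric", omega = "numeric",
  logLik = "numeric", np = "integer", tree = "phylo",
  convergence = "list"))

#' Likelihood-ratio test result
#'
#' @slot statistic 2 * (lnL_alt - lnL_null).
#' @slot df np_alt - np_null.
#' @slot pRaw chi-squared upper-tail p value.
#' @slot pCorrected Bonferroni-corrected p, `min(1, m * pRaw)`.
#' @slot m number of tests in the Bonferroni family.
#' @slot lnL numeric(2), null and alternative log-likelihoods.
#' @slot np integer(2), null and alternative parameter counts.
#' @slot comparison label such as "2 vs 1".
#' @exportClass LRTResult
setClass("LRTResult", representation(
  statistic = "numeric", df = "integer", pRaw = "numeric",
  pCorrected = "numeric", m = "integer", lnL = "numeric", np = "integer",
  comparison = "character"))

#' Greedy minimal site-removal result
#'
#' @slot removedSites alignment columns removed, in removal order.
#' @slot siteLabels offset-mapped labels of the removed sites.
#' @slot trace data.frame with the two total log-likelihoods after each
#'   removal step (step 0 = full alignment).
#' @slot converged TRUE if the species tree overtook the gene tree.
#' @slot support per-site support table on the full alignment.
#' @exportClass RemovalResult
setClass("RemovalResult", representation(
  removedSites = "integer", siteLabels = "integer", trace = "data.frame",
  converged = "logical", support = "data.frame"))

#' Zhang-Kumar parallel/convergent substitution test result
#'
#' @slot pair edge indices of the two branches compared.
#' @slot observedParallel,observedConvergent observed site counts.
#' @slot expectedParallel,expectedConvergent model expectations (Poisson
#'   means obtained by summing per-site probabilities).
#' @slot pParallel,pConvergent Poisson upper-tail probabilities
#'   P(X >= observed).
#' @slot sites per-site classification table.
#' @exportClass ParallelTestResult
setClass("ParallelTestResult", representation(
  pair = "integer", observedParallel = "numeric",
  observedConvergent = "numeric", expectedParallel = "numeric",
  expectedConvergent = "numeric", pParallel = "numeric",
  pConvergent = "numeric", sites = "data.frame"))

#' Simulation recipe
#'
#' Bundles everything the sequence simulators need: the tree, the model, the
#' number of sites, a seed, and an optional list of forced substitution
#' events (branch, site, from, to) used to inject parallel or conflicting
#' sites with known truth.
#'
#' @slot tree phylo with branch lengths.
#' @slot model an `AAModel`, `NTModel` or `CodonModel`.
#' @slot nSites number of alignment columns (codons for codon models).
#' @slot seed integer seed; `NA` leaves the RNG state alone.
#' @slot forcedEvents data.frame(edge, site, from, to) or empty.
#' @slot edgeLabels optional per-edge branch-class labels (codon models with
#'   per-class omega); empty character for none.
#' @exportClass SimulationRecipe
setClass("SimulationRecipe", representation(
  tree = "phylo", model = "SubstModel", nSites = "integer",
  seed = "integer", forcedEvents = "data.frame",
  edgeLabels = "character"))

setValidity("SimulationRecipe", function(object) {
  msg <- character()
  fe <- object@forcedEvents
  if (nrow(fe)) {
    if (!all(c("edge", "site", "from", "to") %in% names(fe)))
      msg <- c(msg, "forcedEvents needs columns edge, site, from, to")
    else {
      if (any(fe$edge < 1 | fe$edge > nrow(object@tree$edge)))
        msg <- c(msg, "forced event references a non-existent edge")
      if (any(fe$site < 1 | fe$site > object@nSites))
        msg <- c(msg, "forced event references a non-existent site")
      st <- modelStates(object@model)
      if (!all(c(fe$from, fe$to) %in% st))
        msg <- c(msg, "forced event state outside the model alphabet")
      if (any(fe$from == fe$to))
        msg <- c(msg, "forced events must change the state")
    }
  }
  if (object@nSites < 1) msg <- c(msg, "nSites must be >= 1")
  if (length(msg)) msg else TRUE
})
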