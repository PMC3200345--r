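#' Accessors for alignments, trees and models
#'
#' @param x an object.
#' @return `taxa()` the taxon names; `nSites()` the number of columns;
#'   `alphabet()` the alphabet string; `siteOffset()` the coordinate offset;
#'   `alignmentMatrix()` the raw character matrix; `siteLabels()` the
#'   offset-mapped column labels; `modelStates()` the state alphabet of a
#'   model; `edgeLabels()` the per-edge class labels of a [LabeledPhylo].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname accessors
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))
#' @rdname accessors
#' @export
setGeneric("siteOffset", function(x) standardGeneric("siteOffset"))
#' @rdname accessors
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))
#' @rdname accessors
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))
#' @rdname accessors
#' @export
setGeneric("modelStates", function(x) standardGeneric("modelStates"))
#' @rdname accessors
#' @export
setGeneric("edgeLabels", function(x) standardGeneric("edgeLabels"))

setMethod("taxa", "PhyloAlignment", function(x) rownames(x@chars))
setMethod("nSites", "PhyloAlignment", function(x) ncol(x@chars))
setMethod("alphabet", "PhyloAlignment", function(x) x@alphabet)
setMethod("siteOffset", "PhyloAlignment", function(x) x@siteOffset)
setMethod("alignmentMatrix", "PhyloAlignment", function(x) x@chars)
setMethod("siteLabels", "PhyloAlignment",
          function(x) seq_len(ncol(x@chars)) + x@siteOffset - 1L)

setMethod("modelStates", "AAModel", function(x) .AA_STATES)
setMethod("modelStates", "NTModel", function(x) .NT_STATES)
setMethod("modelStates", "CodonModel", function(x) codonStates())

setMethod("taxa", "LabeledPhylo", function(x) x@tree$tip.label)
setMethod("edgeLabels", "LabeledPhylo", function(x) x@edgeLabels)

setMethod("show", "PhyloAlignment", function(object) {
  cat(sprintf("PhyloAlignment: %d taxa x %d %s columns (site offset %d)\n",
              nrow(object@chars), ncol(object@chars), object@alphabet,
              object@siteOffset))
  cat("  taxa:", paste(utils::head(rownames(object@chars), 4), collapse = ", "),
      if (nrow(object@chars) > 4) "..." else "", "\n")
})

setMethod("show", "LabeledPhylo", function(object) {
  lab <- unique(object@edgeLabels[nzchar(object@edgeLabels)])
  cat(sprintf("LabeledPhylo: %d tips, %d edges, classes: %s\n",
              length(object@tree$tip.label), nrow(object@tree$edge),
              if (length(lab)) paste(lab, collapse = ", ") else "<none>"))
})

setMethod("show", "AAModel", function(object) {
  cat(sprintf("AAModel %s+%s%s%s\n", object@name,
              "F",
              if (object@pInv > 0) "+I" else "",
              if (length(object@gammaShape))
                sprintf("+G(%d cats, alpha=%.3g)", object@nCat,
                        object@gammaShape) else ""))
})

setMethod("show", "CodonModel", function(object) {
  cat(sprintf("CodonModel (Goldman-Yang): kappa=%.3g, omega: %s\n",
              object@kappa,
              paste(sprintf("%s=%.3g", names(object@omegaMap),
                            object@omegaMap), collapse = ", ")))
})

setMethod("show", "AncestralReconstruction", function(object) {
  cat(sprintf("AncestralReconstruction (%s): %d internal nodes x %d sites\n",
              object@method, nrow(object@best), ncol(object@best)))
  if (object@method == "ML")
    cat(sprintf("  mean posterior of best states: %.4f\n",
                mean(object@meanPosterior)))
  if (object@method == "MP")
    cat(sprintf("  parsimony score: %d\n", as.integer(object@score)))
})

setMethod("show", "BranchModelFit", function(object) {
  cat(sprintf("BranchModelFit '%s': lnL = %.3f, np = %d, kappa = %.3g\n",
              object@spec@name, object@logLik, object@np, object@kappa))
  cat("  omega:", paste(sprintf("%s=%.4g", names(object@omega), object@omega),
                        collapse = ", "), "\n")
})

setMethod("show", "LRTResult", function(object) {
  cat(sprintf("LRT %s: 2*dlnL = %.3f, df = %d, p = %.4g (Bonferroni m=%d: %.4g)\n",
              object@comparison, object@statistic, object@df, object@pRaw,
              object@m, object@pCorrected))
})

setMethod("show", "RemovalResult", function(object) {
  cat(sprintf("RemovalResult: %d site(s) removed (%s); species tree preferred: %s\n",
              length(object@removedSites),
              paste(object@siteLabels, collapse = ", "),
              object@converged))
})

setMethod("show", "ParallelTestResult", function(object) {
  cat(sprintf("ParallelTestResult (edges %d, %d):\n", object@pair[1],
              object@pair[2]))
  cat(sprintf("  parallel:   observed %g, expected %.4g, P(X>=obs) = %.4g\n",
              object@observedParallel, object@expectedParallel,
              object@pParallel))
  cat(sprintf("  convergent: observed %g, expected %.4g, P(X>=obs) = %.4g\n",
              object@observedConvergent, object@expectedConvergent,
              object@pConvergent))
})
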