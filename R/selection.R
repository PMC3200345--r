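## Codon branch models (CODEML-style) and likelihood-ratio tests.

## resolve per-edge branch-class labels against a codon model's omega map;
## classes without their own omega share the ".default" background value
parallevol_codon_classes <- function(model, labels, nE) {
  cls <- if (length(labels)) ifelse(nzchar(labels), labels, ".default")
         else rep(".default", nE)
  known <- cls %in% names(model@omegaMap)
  if (any(!known)) {
    if (!".default" %in% names(model@omegaMap))
      stop("no omega assigned for branch class(es): ",
           paste(unique(cls[!known]), collapse = ", "))
    cls[!known] <- ".default"
  }
  cls
}

## per-edge omega classes for a labelled tree; returns eigensystems for the
## distinct omega values and an edge -> eigensystem index
.codonEig <- function(model, labels, nE) {
  cls <- parallevol_codon_classes(model, labels, nE)
  ucls <- unique(cls)
  eigList <- lapply(ucls, function(u)
    .eigsys(.buildQcodon(model@kappa, model@omegaMap[[u]], model@freq),
            model@freq))
  list(eigList = eigList, edgeClass = match(cls, ucls))
}

#' Total log-likelihood of a codon alignment under a branch model
#'
#' Pruning over the 61 sense codons with a Goldman-Yang generator whose
#' dN/dS varies by branch class.
#'
#' @param aln a `"CODON"` [PhyloAlignment-class] (no stop codons).
#' @param tree a `phylo` or [LabeledPhylo-class]; labels select omega
#'   classes from the model's `omegaMap`.
#' @param model a [CodonModel-class].
#' @return total log-likelihood with attribute `siteLogLik` (per codon).
#' @export
codonLogLik <- function(aln, tree, model) {
  labels <- character(0)
  if (is(tree, "LabeledPhylo")) { labels <- tree@edgeLabels; tree <- tree@tree }
  if (alphabet(aln) != "CODON") stop("codonLogLik needs a CODON alignment")
  prep <- .prepareData(aln, tree, model)
  labPost <- if (length(labels))
    .reorderLabels(tree, labels, prep$ti$tree) else character(0)
  ce <- .codonEig(model, labPost, nrow(prep$ti$edge))
  res <- .patternLogLik(prep, model, ce$eigList, ce$edgeClass, prep$ti$len)
  out <- sum(res$patternLogLik * prep$weights)
  attr(out, "siteLogLik") <- res$patternLogLik[prep$patOfSite]
  out
}

#' Specify a codon branch model
#'
#' @param name model name used in reports.
#' @param assign named list mapping branch-class labels to either a
#'   parameter name (classes sharing a name share one free omega) or a
#'   fixed numeric value; the `".default"` entry covers unlabelled
#'   branches.  Ignored when `freeRatio = TRUE`.
#' @param freeRatio give every branch its own omega (expensive).
#' @return a [BranchModelSpec-class].
#' @examples
#' oneRatio <- branchModelSpec("one-ratio", list(".default" = "w0"))
#' twoRatio <- branchModelSpec("d,e vs rest",
#'   list(d = "w1", e = "w1", ".default" = "w0"))
#' fixedNeutral <- branchModelSpec("d,e neutral",
#'   list(d = 1, e = 1, ".default" = "w0"))
#' @export
branchModelSpec <- function(name, assign = list(".default" = "w0"),
                            freeRatio = FALSE) {
  if (!freeRatio && !".default" %in% names(assign))
    assign <- c(assign, list(".default" = "w0"))
  new("BranchModelSpec", name = name, assign = assign,
      freeRatio = freeRatio)
}

#' The seven branch models of the selection analysis
#'
#' Builds the standard ladder of branch models over the lineage classes
#' `a` (bat stem), `b` (Yangochiroptera stem), `c` (Rhinolophoidea stem),
#' `d` (Yinpterochiroptera stem) and `e` (Old World fruit bat stem): one
#' ratio, free ratio, a vs rest, {b,c} vs {d,e} vs each-other-branch-free
#' (and its shared-omega null), {d,e} vs rest, and {d,e} fixed at omega = 1.
#'
#' @return named list of [BranchModelSpec-class] objects.
#' @export
table1Specs <- function() {
  list(
    m1 = branchModelSpec("1 one ratio", list(".default" = "w0")),
    m2 = branchModelSpec("2 free ratio", freeRatio = TRUE),
    m3 = branchModelSpec("3 branch a vs rest",
                         list(a = "w1", ".default" = "w0")),
    m4 = branchModelSpec("4 bc vs de, others free",
                         list(b = "w1", c = "w1", d = "w2", e = "w2",
                              ".default" = ".each")),
    m5 = branchModelSpec("5 bc = de, others free",
                         list(b = "w1", c = "w1", d = "w1", e = "w1",
                              ".default" = ".each")),
    m6 = branchModelSpec("6 de vs rest",
                         list(d = "w1", e = "w1", ".default" = "w0")),
    m7 = branchModelSpec("7 de fixed at 1",
                         list(d = 1, e = 1, ".default" = "w0")))
}

## resolve a spec against the tree's edge labels: returns per-edge parameter
## id (0 = fixed), the fixed values, and the free-parameter names
.resolveSpec <- function(spec, labels, nE) {
  if (spec@freeRatio) {
    return(list(edgePar = seq_len(nE), fixed = numeric(0),
                parNames = paste0("w.edge", seq_len(nE))))
  }
  cls <- if (length(labels)) ifelse(nzchar(labels), labels, ".default")
         else rep(".default", nE)
  asg <- spec@assign
  miss <- setdiff(unique(cls), names(asg))
  if (length(miss)) {
    if (!".default" %in% names(asg))
      stop("spec does not cover branch class(es): ",
           paste(miss, collapse = ", "))
    cls[cls %in% miss] <- ".default"
  }
  entry <- asg[cls]
  ## ".each": every branch in that class gets its own parameter
  parKey <- vapply(seq_len(nE), function(e) {
    a <- entry[[e]]
    if (is.numeric(a)) sprintf(".fixed=%g", a)
    else if (identical(a, ".each")) paste0("w.edge", e)
    else as.character(a)
  }, character(1))
  isFixed <- grepl("^\\.fixed=", parKey)
  parNames <- unique(parKey[!isFixed])
  edgePar <- integer(nE)
  edgePar[!isFixed] <- match(parKey[!isFixed], parNames)
  fixedVal <- numeric(nE)
  fixedVal[isFixed] <- as.numeric(sub("^\\.fixed=", "", parKey[isFixed]))
  list(edgePar = edgePar, fixed = fixedVal, parNames = parNames)
}

#' Audit the parameter count of a branch model on a tree
#'
#' Returns the `np` a fit of `spec` on `tree` will report: identifiable
#' branch lengths (unrooted convention, `2n - 3` for a binary tree) plus
#' one for kappa plus the number of free omega parameters.  Useful for
#' checking degrees of freedom before running an expensive fit; e.g. a
#' one-ratio model on 20 taxa gives 37 + 1 + 1 = 39.
#'
#' @inheritParams fitBranchModel
#' @return integer parameter count.
#' @export
branchModelNp <- function(spec, tree) {
  labels <- character(0)
  if (is(tree, "LabeledPhylo")) { labels <- tree@edgeLabels; tree <- tree@tree }
  ur <- .unrootLabeled(tree, labels)
  rs <- .resolveSpec(spec, ur$labels, nrow(ur$tree$edge))
  .nIdentifiableEdges(ur$tree) + 1L + length(rs$parNames)
}

#' Fit a codon branch model by maximum likelihood
#'
#' Estimates kappa, the free omega parameters of the specification, and all
#' branch lengths.  Optimization alternates cyclic per-branch length (and,
#' for free-ratio models, per-branch omega) updates with Nelder-Mead moves
#' of the global parameters, until the log-likelihood is stable.  Internally
#' the tree is unrooted so the parameter count follows the usual codon-model
#' convention (2n - 3 branch lengths).
#'
#' @param aln a `"CODON"` [PhyloAlignment-class].
#' @param tree a [LabeledPhylo-class] (or plain `phylo` for one-ratio /
#'   free-ratio specs).
#' @param spec a [BranchModelSpec-class].
#' @param kappa,omegaStart starting values.
#' @param freq `"F3x4"` (default; position-specific nucleotide frequencies
#'   from the data), `"equal"`, or 61 numeric frequencies.
#' @param restarts number of seeded starting points (best fit kept).
#' @param control list: `tol` (lnL tolerance, 1e-6), `outerMax` (rounds),
#'   `minLen`, `maxLen`, `minOmega`, `maxOmega`.
#' @return a [BranchModelFit-class].
#' @export
fitBranchModel <- function(aln, tree, spec, kappa = 2, omegaStart = 0.1,
                           freq = "F3x4", restarts = 1, control = list()) {
  ctrl <- modifyList(list(tol = 1e-6, outerMax = 12, minLen = 1e-8,
                          maxLen = 20, minOmega = 1e-4, maxOmega = 20,
                          sweepsPerRound = 2), control)
  labels <- character(0)
  if (is(tree, "LabeledPhylo")) { labels <- tree@edgeLabels; tree <- tree@tree }
  ur <- .unrootLabeled(tree, labels)
  tree <- ur$tree; labels <- ur$labels
  model0 <- codonModel(kappa = kappa, omega = omegaStart, freq = freq,
                       data = aln)
  prep <- .prepareData(aln, tree, model0)
  nE <- nrow(prep$ti$edge)
  labPost <- if (length(labels)) .reorderLabels(tree, labels, prep$ti$tree)
             else character(0)
  rs <- .resolveSpec(spec, labPost, nE)
  nFree <- length(rs$parNames)

  best <- NULL
  for (r in seq_len(restarts)) {
    k0 <- kappa * if (r == 1) 1 else exp(stats::runif(1, -0.5, 0.5))
    w0 <- rep(omegaStart * if (r == 1) 1 else
                exp(stats::runif(1, -0.7, 0.7)), max(nFree, 1))
    fit <- .fitBranchModelOnce(prep, model0, rs, k0, w0, ctrl)
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }

  outTree <- tree
  post <- prep$ti$tree; post$edge.length <- best$tvec
  outTree$edge.length <- best$tvec[.matchEdges(list(edge = post$edge),
                                               list(edge = outTree$edge))]
  omega <- if (nFree) stats::setNames(best$omega[seq_len(nFree)],
                                      rs$parNames) else numeric(0)
  np <- .nIdentifiableEdges(tree) + 1L + as.integer(nFree)
  new("BranchModelFit", spec = spec, kappa = best$kappa, omega = omega,
      logLik = best$logLik, np = np, tree = outTree,
      convergence = list(rounds = best$rounds, converged = best$converged))
}

## one optimization run; omega vector is per free parameter
.fitBranchModelOnce <- function(prep, model0, rs, kappa, omega, ctrl) {
  nE <- length(prep$ti$len)
  tvec <- pmax(prep$ti$len, 1e-4)
  edgeOmega <- function(om) {
    w <- rs$fixed
    if (length(om)) w[rs$edgePar > 0] <- om[rs$edgePar[rs$edgePar > 0]]
    w
  }
  eigOf <- function(kap, wEdge) {
    uw <- unique(wEdge)
    eigList <- lapply(uw, function(w)
      .eigsys(.buildQcodon(kap, w, model0@freq), model0@freq))
    list(eigList = eigList, edgeClass = match(wEdge, uw))
  }
  fullLnL <- function(kap, wEdge, tv, wantUp = FALSE) {
    ce <- eigOf(kap, wEdge)
    res <- .patternLogLik(prep, model0, ce$eigList, ce$edgeClass, tv, wantUp)
    list(lnL = sum(res$patternLogLik * prep$weights), res = res, ce = ce)
  }

  freePerEdge <- length(rs$parNames) == nE && all(rs$edgePar == seq_len(nE))
  cur <- fullLnL(kappa, edgeOmega(omega), tvec, wantUp = TRUE)
  lnL <- cur$lnL
  converged <- FALSE
  round <- 0
  while (round < ctrl$outerMax) {
    round <- round + 1
    lnLStart <- lnL
    ## (1) per-edge updates against cached partials
    for (sweep in seq_len(ctrl$sweepsPerRound)) {
      wEdge <- edgeOmega(omega)
      cats <- cur$res$cats[[1]]
      for (e in seq_len(nE)) {
        ch <- prep$ti$edge[e, 2]
        A <- cats$A[, , e]; D <- cats$down[, , ch]
        lsc <- cats$lscA[, e] + cats$lscDown[, ch]
        if (freePerEdge) {
          obj <- function(p) {
            eg <- .eigsys(.buildQcodon(kappa, exp(p[2]), model0@freq),
                          model0@freq)
            v <- .cpp_edge_lik(A, D, .pmat(eg, exp(p[1])))
            -sum((log(v) + lsc) * prep$weights)
          }
          op <- stats::optim(c(log(tvec[e]), log(wEdge[e])), obj,
                             method = "Nelder-Mead",
                             control = list(maxit = 80, reltol = 1e-9))
          tvec[e] <- min(max(exp(op$par[1]), ctrl$minLen), ctrl$maxLen)
          omega[e] <- min(max(exp(op$par[2]), ctrl$minOmega), ctrl$maxOmega)
        } else {
          eg <- cur$ce$eigList[[cur$ce$edgeClass[e]]]
          obj <- function(logt) {
            v <- .cpp_edge_lik(A, D, .pmat(eg, exp(logt)))
            -sum((log(v) + lsc) * prep$weights)
          }
          op <- stats::optimize(obj, c(log(ctrl$minLen), log(ctrl$maxLen)),
                                tol = 1e-7)
          if (-op$objective > -obj(log(tvec[e]))) tvec[e] <- exp(op$minimum)
        }
      }
      cur <- fullLnL(kappa, edgeOmega(omega), tvec, wantUp = TRUE)
    }
    ## (2) global parameters (kappa + shared omegas) by Nelder-Mead
    if (!freePerEdge) {
      par0 <- c(log(kappa), if (length(omega)) log(omega))
      obj <- function(p) {
        kap <- exp(p[1])
        om <- if (length(p) > 1) exp(p[-1]) else numeric(0)
        -fullLnL(kap, edgeOmega(om), tvec)$lnL
      }
      op <- stats::optim(par0, obj, method = if (length(par0) > 1)
        "Nelder-Mead" else "Brent",
        lower = if (length(par0) == 1) log(1e-3) else -Inf,
        upper = if (length(par0) == 1) log(1e3) else Inf,
        control = list(maxit = 200, reltol = 1e-9))
      kappa <- exp(op$par[1])
      if (length(op$par) > 1) omega <- exp(op$par[-1])
    } else {
      op <- stats::optimize(function(lk)
        -fullLnL(exp(lk), edgeOmega(omega), tvec)$lnL,
        c(log(0.1), log(50)), tol = 1e-6)
      kappa <- exp(op$minimum)
    }
    cur <- fullLnL(kappa, edgeOmega(omega), tvec, wantUp = TRUE)
    lnL <- cur$lnL
    if (abs(lnL - lnLStart) < ctrl$tol) { converged <- TRUE; break }
  }
  list(kappa = kappa, omega = omega, tvec = tvec, logLik = lnL,
       rounds = round, converged = converged)
}

## unroot a tree while carrying per-edge class labels across; the merged
## root edge keeps whichever label the two old root edges had (conflict is
## an error)
.unrootLabeled <- function(tree, labels) {
  if (!ape::is.rooted(tree))
    return(list(tree = tree, labels = labels))
  ut <- ape::unroot(tree)
  if (!length(labels)) return(list(tree = ut, labels = character(0)))
  cladeOf <- function(tr, node) {
    nT <- length(tr$tip.label)
    if (node <= nT) tr$tip.label[node]
    else sort(ape::extract.clade(tr, node)$tip.label)
  }
  oldKey <- vapply(tree$edge[, 2], function(v)
    paste(cladeOf(tree, v), collapse = "|"), character(1))
  newLab <- character(nrow(ut$edge))
  for (e in which(nzchar(labels))) {
    key <- oldKey[e]
    hit <- which(vapply(ut$edge[, 2], function(v)
      paste(cladeOf(ut, v), collapse = "|"), character(1)) == key)
    if (length(hit) != 1) {
      ## stem collapsed into the merged root edge: find the complement clade
      allTips <- sort(tree$tip.label)
      comp <- paste(setdiff(allTips, strsplit(key, "\\|")[[1]]),
                    collapse = "|")
      hit <- which(vapply(ut$edge[, 2], function(v)
        paste(cladeOf(ut, v), collapse = "|"), character(1)) == comp)
    }
    if (length(hit) != 1)
      stop("cannot transfer label '", labels[e], "' across unrooting")
    if (nzchar(newLab[hit]) && newLab[hit] != labels[e])
      stop("conflicting labels on the merged root edge")
    newLab[hit] <- labels[e]
  }
  list(tree = ut, labels = newLab)
}

#' Likelihood-ratio test between nested branch models
#'
#' The statistic is `2 * (lnL_alt - lnL_null)`, compared to a chi-squared
#' distribution with `np_alt - np_null` degrees of freedom.  The Bonferroni
#' correction `min(1, m * p)` is reported alongside the raw p value, never
#' silently substituted.
#'
#' @param fitNull,fitAlt [BranchModelFit-class] objects, or bare numeric
#'   log-likelihoods (then supply `npNull`/`npAlt`).
#' @param m number of tests in the Bonferroni family.
#' @param npNull,npAlt parameter counts when passing bare log-likelihoods.
#' @param comparison label for reports (e.g. `"2 vs 1"`).
#' @return an [LRTResult-class].
#' @examples
#' lrt(-6673.677, -6658.124, npNull = 39, npAlt = 75, comparison = "2 vs 1")
#' @export
lrt <- function(fitNull, fitAlt, m = 1L, npNull = NULL, npAlt = NULL,
                comparison = "") {
  if (is(fitNull, "BranchModelFit")) {
    lnL0 <- fitNull@logLik; np0 <- fitNull@np
  } else { lnL0 <- as.numeric(fitNull); np0 <- npNull }
  if (is(fitAlt, "BranchModelFit")) {
    lnL1 <- fitAlt@logLik; np1 <- fitAlt@np
  } else { lnL1 <- as.numeric(fitAlt); np1 <- npAlt }
  if (is.null(np0) || is.null(np1)) stop("parameter counts required")
  if (np1 <= np0)
    stop("models not nested as given: np_alt (", np1,
         ") must exceed np_null (", np0, ")")
  stat <- 2 * (lnL1 - lnL0)
  if (stat < -1e-6)
    stop("optimization failure: alternative fit worse than null (2dlnL = ",
         format(stat), ")")
  stat <- max(stat, 0)
  df <- as.integer(np1 - np0)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  new("LRTResult", statistic = stat, df = df, pRaw = p,
      pCorrected = min(1, m * p), m = as.integer(m),
      lnL = c(null = lnL0, alt = lnL1), np = as.integer(c(np0, np1)),
      comparison = comparison)
}

#' Fit a ladder of branch models and run the standard comparisons
#'
#' Fits every specification (errors are captured per row, not fatal) and
#' evaluates the requested nested comparisons with Bonferroni correction
#' over the whole family.
#'
#' @inheritParams fitBranchModel
#' @param specs named list of [BranchModelSpec-class] (default
#'   [table1Specs()]).
#' @param comparisons list of `c(alt, null)` name pairs into `specs`.
#' @param m Bonferroni family size (default: number of comparisons).
#' @return list with elements `fits` (data.frame: model, omegas, lnL, np),
#'   `tests` (data.frame: comparison, statistic, df, pRaw, pCorrected) and
#'   `objects` (the fit objects).
#' @export
selectionReport <- function(aln, tree, specs = table1Specs(),
                            comparisons = list(c("m2", "m1"), c("m3", "m1"),
                                               c("m5", "m4"), c("m6", "m1"),
                                               c("m7", "m6")),
                            m = length(comparisons), kappa = 2,
                            omegaStart = 0.1, control = list()) {
  fits <- list()
  for (nm in names(specs)) {
    fits[[nm]] <- tryCatch(
      fitBranchModel(aln, tree, specs[[nm]], kappa = kappa,
                     omegaStart = omegaStart, control = control),
      error = function(e) e)
  }
  fitRows <- do.call(rbind, lapply(names(specs), function(nm) {
    f <- fits[[nm]]
    if (is(f, "error"))
      return(data.frame(model = specs[[nm]]@name, omega = NA, lnL = NA,
                        np = NA, error = conditionMessage(f)))
    data.frame(model = f@spec@name,
               omega = paste(sprintf("%s=%.4g", names(f@omega), f@omega),
                             collapse = " "),
               lnL = f@logLik, np = f@np, error = "")
  }))
  testRows <- do.call(rbind, lapply(comparisons, function(cp) {
    fa <- fits[[cp[1]]]; f0 <- fits[[cp[2]]]
    lab <- paste(sub("^m", "", cp[1]), "vs", sub("^m", "", cp[2]))
    if (is(fa, "error") || is(f0, "error"))
      return(data.frame(comparison = lab, statistic = NA, df = NA,
                        pRaw = NA, pCorrected = NA))
    tst <- tryCatch(lrt(f0, fa, m = m, comparison = lab),
                    error = function(e) NULL)
    if (is.null(tst))
      return(data.frame(comparison = lab, statistic = NA, df = NA,
                        pRaw = NA, pCorrected = NA))
    data.frame(comparison = lab, statistic = tst@statistic, df = tst@df,
               pRaw = tst@pRaw, pCorrected = tst@pCorrected)
  }))
  list(fits = fitRows, tests = testRows, objects = fits)
}
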