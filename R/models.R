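#' Sense codons of the standard genetic code
#'
#' @param code genetic code in `Biostrings::GENETIC_CODE` format.
#' @return the 61 sense codons, in the order used by codon alignments,
#'   models and simulators.
#' @export
codonStates <- function(code = Biostrings::GENETIC_CODE) {
  names(code)[code != "*"]
}

#' Empirical amino-acid substitution model
#'
#' Builds a reversible amino-acid model from one of the published empirical
#' exchangeability matrices shipped with \pkg{phangorn} (including the
#' HIV-derived HIVb/HIVw sets and general sets such as WAG, LG and JTT),
#' with optional invariant sites (+I), discrete-gamma rate heterogeneity
#' (+G) and observed frequencies (+F).
#'
#' @param name matrix name as known to \pkg{phangorn} (e.g. `"HIVb"`,
#'   `"WAG"`, `"LG"`, `"JTT"`).
#' @param freq `"model"` (the matrix's published frequencies), a numeric
#'   vector of 20 frequencies, or a [PhyloAlignment-class] from which
#'   observed frequencies are counted (+F).  Zero counts are floored at
#'   1e-4 and renormalized so the model stays reversible.
#' @param pInv proportion of invariant sites in `[0, 1)`.
#' @param gammaShape gamma shape parameter alpha (`NULL` disables +G).
#' @param nCat number of discrete gamma categories.
#' @return an [AAModel-class].
#' @examples
#' m <- aaModel("HIVb", pInv = 0.2, gammaShape = 0.8)
#' @export
aaModel <- function(name = "HIVb", freq = "model", pInv = 0,
                    gammaShape = NULL, nCat = 4L) {
  mods <- get(".aamodels", envir = asNamespace("phangorn"))
  if (!name %in% mods)
    stop("unknown amino-acid matrix '", name, "'; available: ",
         paste(mods, collapse = ", "))
  raw <- get(paste0(".", name), envir = asNamespace("phangorn"))
  exch <- matrix(0, 20, 20, dimnames = list(.AA_STATES, .AA_STATES))
  exch[lower.tri(exch)] <- raw$Q
  exch <- exch + t(exch)
  f <- .resolveFreq(freq, raw$bf, .AA_STATES)
  new("AAModel", name = name, exch = exch, freq = f, pInv = pInv,
      gammaShape = if (is.null(gammaShape)) numeric(0) else gammaShape,
      nCat = as.integer(nCat))
}

#' Nucleotide substitution model (JC69 / K80 / HKY85)
#'
#' @param name `"JC"` or `"HKY"` (with `kappa = 1` and equal frequencies HKY
#'   collapses to JC).
#' @param kappa transition/transversion rate ratio.
#' @param freq base frequencies (A, C, G, T) or an alignment (+F).
#' @inheritParams aaModel
#' @return an [NTModel-class].
#' @export
ntModel <- function(name = c("JC", "HKY"), kappa = 1, freq = rep(0.25, 4),
                    pInv = 0, gammaShape = NULL, nCat = 4L) {
  name <- match.arg(name)
  exch <- matrix(1, 4, 4, dimnames = list(.NT_STATES, .NT_STATES))
  diag(exch) <- 0
  if (name == "HKY") {
    exch["A", "G"] <- exch["G", "A"] <- kappa
    exch["C", "T"] <- exch["T", "C"] <- kappa
  }
  f <- .resolveFreq(freq, rep(0.25, 4), .NT_STATES)
  new("NTModel", name = name, exch = exch, freq = f, pInv = pInv,
      gammaShape = if (is.null(gammaShape)) numeric(0) else gammaShape,
      nCat = as.integer(nCat))
}

.resolveFreq <- function(freq, modelFreq, states) {
  if (is.character(freq) && identical(freq, "model")) {
    f <- as.numeric(modelFreq)
  } else if (is(freq, "PhyloAlignment")) {
    cnt <- table(factor(freq@chars[freq@chars %in% states], levels = states))
    f <- as.numeric(cnt)
    f <- pmax(f / sum(f), 1e-4)
  } else {
    f <- as.numeric(freq)
    if (length(f) != length(states)) stop("wrong frequency length")
  }
  f <- f / sum(f)
  names(f) <- states
  f
}

#' Goldman-Yang codon substitution model with per-branch-class dN/dS
#'
#' Instantaneous rates between sense codons differing at one position are
#' `pi_j`, times `kappa` for transitions, times the branch class's `omega`
#' for nonsynonymous changes.  Each class's generator is scaled to one
#' expected substitution per codon per unit branch length, matching CODEML's
#' convention for branch models.
#'
#' @param kappa transition/transversion rate ratio.
#' @param omega named numeric mapping branch-class labels to dN/dS; the
#'   `".default"` entry covers unlabelled branches.  A single unnamed value
#'   is taken as the one-ratio default.
#' @param freq `"F3x4"` with `data` a codon [PhyloAlignment-class] (codon
#'   frequencies from position-specific nucleotide frequencies), `"equal"`,
#'   or a numeric vector of 61 frequencies.
#' @param data codon alignment used for `"F3x4"`.
#' @param code genetic code (`Biostrings::GENETIC_CODE` format).
#' @return a [CodonModel-class].
#' @export
codonModel <- function(kappa = 2, omega = 0.1, freq = "equal", data = NULL,
                       code = Biostrings::GENETIC_CODE) {
  cs <- codonStates(code)
  if (is.null(names(omega))) {
    stopifnot(length(omega) == 1)
    omega <- c(".default" = unname(omega))
  } else if (!".default" %in% names(omega)) {
    omega <- c(omega, ".default" = unname(omega[[1]]))
  }
  if (is.numeric(freq)) {
    f <- freq / sum(freq)
  } else if (identical(freq, "equal")) {
    f <- rep(1 / length(cs), length(cs))
  } else if (identical(freq, "F3x4")) {
    if (is.null(data)) stop("freq = 'F3x4' needs a codon alignment in 'data'")
    f <- .f3x4(data, cs)
  } else stop("freq must be 'equal', 'F3x4' or a numeric vector")
  names(f) <- cs
  new("CodonModel", name = "GY94", kappa = kappa,
      omegaMap = omega, freq = f)
}

.f3x4 <- function(aln, cs) {
  stopifnot(alphabet(aln) == "CODON")
  cod <- aln@chars[aln@chars %in% cs]
  posf <- lapply(1:3, function(p) {
    nt <- substr(cod, p, p)
    f <- table(factor(nt, levels = .NT_STATES))
    pmax(as.numeric(f) / sum(f), 1e-4)
  })
  f <- vapply(cs, function(c3) {
    posf[[1]][match(substr(c3, 1, 1), .NT_STATES)] *
      posf[[2]][match(substr(c3, 2, 2), .NT_STATES)] *
      posf[[3]][match(substr(c3, 3, 3), .NT_STATES)]
  }, numeric(1))
  f / sum(f)
}

## --- rate matrices and transition probabilities --------------------------

## reversible generator from exchangeabilities and frequencies, scaled to
## one expected substitution per site per unit time
.buildQrev <- function(exch, freq) {
  Q <- exch * rep(freq, each = nrow(exch))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(freq * diag(Q))
  Q / rate
}

## Goldman-Yang generator for one omega value
.buildQcodon <- function(kappa, omega, freq, code = Biostrings::GENETIC_CODE) {
  cs <- codonStates(code)
  S <- length(cs)
  key <- .codonPairs(code)
  Q <- matrix(0, S, S, dimnames = list(cs, cs))
  rate <- rep(1, nrow(key$pairs))
  rate[key$isTransition] <- kappa
  rate[!key$isSynonymous] <- rate[!key$isSynonymous] * omega
  Q[key$pairs] <- rate * freq[key$pairs[, 2]]
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freq * diag(Q))
  Q / scale
}

## enumerate single-nucleotide codon neighbours once per session
.codonPairsCache <- new.env(parent = emptyenv())
.codonPairs <- function(code = Biostrings::GENETIC_CODE) {
  keyname <- paste(code, collapse = "")
  hit <- .codonPairsCache[[substr(keyname, 1, 32)]]
  if (!is.null(hit)) return(hit)
  cs <- codonStates(code)
  S <- length(cs)
  sp <- strsplit(cs, "")
  pairs <- NULL; isTs <- NULL; isSyn <- NULL
  purine <- c("A", "G")
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (i == j) next
    diffpos <- which(sp[[i]] != sp[[j]])
    if (length(diffpos) != 1) next
    a <- sp[[i]][diffpos]; b <- sp[[j]][diffpos]
    pairs <- rbind(pairs, c(i, j))
    isTs <- c(isTs, (a %in% purine) == (b %in% purine))
    isSyn <- c(isSyn, code[[cs[i]]] == code[[cs[j]]])
  }
  out <- list(pairs = pairs, isTransition = isTs, isSynonymous = isSyn)
  .codonPairsCache[[substr(keyname, 1, 32)]] <- out
  out
}

## eigen-system of a reversible generator (via the symmetrized matrix);
## returns V, values, Vi with Q = V diag(values) Vi
.eigsys <- function(Q, freq) {
  d <- sqrt(freq)
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(V = e$vectors / d, values = e$values, Vi = t(e$vectors * d))
}

.pmat <- function(eig, t) {
  P <- eig$V %*% (exp(eig$values * t) * eig$Vi)
  P[P < 0] <- 0
  P
}

## rate-category layout of a mixture model: gamma rates are rescaled by
## 1/(1 - pInv) so branch lengths stay in expected substitutions per site
.rateCats <- function(model) {
  if (!is(model, "MixtureModel"))
    return(list(rates = 1, weights = 1, pInv = 0))
  if (length(model@gammaShape)) {
    r <- phangorn::discrete.gamma(model@gammaShape, model@nCat)
    w <- rep(1 / model@nCat, model@nCat)
  } else {
    r <- 1; w <- 1
  }
  p <- model@pInv
  if (p > 0) {
    r <- r / (1 - p)
    w <- w * (1 - p)
  }
  list(rates = r, weights = w, pInv = p)
}

## mixture-averaged transition matrix over a branch of length t (includes
## the invariant category as an identity component)
.pmatMixture <- function(model, eig, t) {
  rc <- .rateCats(model)
  S <- length(model@freq)
  P <- matrix(0, S, S)
  for (k in seq_along(rc$rates))
    P <- P + rc$weights[k] * .pmat(eig, t * rc$rates[k])
  if (rc$pInv > 0) P <- P + rc$pInv * diag(S)
  P
}
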