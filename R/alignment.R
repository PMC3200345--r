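#' Construct an alignment from named sequences
#'
#' @param seqs named character vector of aligned sequences (one string per
#'   taxon), or a character matrix with one residue (or codon) per cell.
#' @param alphabet `"AA"`, `"NT"` or `"CODON"`.  With `"CODON"` the input
#'   nucleotide strings must have length divisible by 3 and are packed into
#'   codon columns.
#' @param siteOffset reference coordinate of column 1 (used for site labels).
#' @return a [PhyloAlignment-class].
#' @examples
#' aln <- phyloAlignment(c(s1 = "ATGAAA", s2 = "ATGAAG"), "CODON")
#' nSites(aln)  # 2 codon columns
#' @export
phyloAlignment <- function(seqs, alphabet = c("AA", "NT", "CODON"),
                           siteOffset = 1L) {
  alphabet <- match.arg(alphabet)
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    if (is.null(names(seqs))) stop("sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1)
      stop("alignment-shape error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    ch <- strsplit(toupper(seqs), "")
    m <- do.call(rbind, ch)
    rownames(m) <- names(seqs)
  }
  if (alphabet == "CODON" && all(nchar(m[1, ]) == 1L)) {
    if (ncol(m) %% 3 != 0)
      stop("frame error: length ", ncol(m), " not divisible by 3")
    idx <- seq(1, ncol(m), by = 3)
    m <- vapply(idx, function(i) paste0(m[, i], m[, i + 1], m[, i + 2]),
                character(nrow(m)))
    if (!is.matrix(m)) m <- matrix(m, nrow = 1)
    rownames(m) <- rownames(seqs) %||% names(seqs)
  }
  new("PhyloAlignment", chars = m, alphabet = alphabet,
      siteOffset = as.integer(siteOffset))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write FASTA alignments
#'
#' `readFastaAlignment()` parses a FASTA file into a [PhyloAlignment-class]
#' (taxa kept in file order); `writeFastaAlignment()` writes one back out.
#' Round-tripping preserves taxa, order and residues exactly.
#'
#' @param path file path.
#' @param alphabet,siteOffset see [phyloAlignment()].
#' @param aln a [PhyloAlignment-class].
#' @param width line width for output.
#' @return the alignment, or (for the writer) `path` invisibly.
#' @export
readFastaAlignment <- function(path, alphabet = c("AA", "NT", "CODON"),
                               siteOffset = 1L) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  phyloAlignment(seqs, alphabet, siteOffset)
}

#' @rdname readFastaAlignment
#' @export
writeFastaAlignment <- function(aln, path, width = 70L) {
  stopifnot(is(aln, "PhyloAlignment"))
  seqs <- apply(aln@chars, 1, paste0, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Translate an in-frame coding alignment to amino acids
#'
#' Codons are looked up in the standard genetic code (or a user-supplied
#' named vector in `Biostrings::GENETIC_CODE` format).  Internal stop codons
#' are a data error; codons containing gaps or N translate to `"-"`/`"X"`.
#'
#' @param aln a `"NT"` or `"CODON"` [PhyloAlignment-class].
#' @param code named character vector mapping codons to one-letter residues.
#' @return an `"AA"` alignment with the same taxa and a site offset of
#'   `(siteOffset(aln) + 2) / 3` rounded up.
#' @export
translateAlignment <- function(aln, code = Biostrings::GENETIC_CODE) {
  stopifnot(is(aln, "PhyloAlignment"))
  if (alphabet(aln) == "AA") stop("alignment is already amino acid")
  if (alphabet(aln) == "NT") {
    m <- aln@chars
    if (ncol(m) %% 3 != 0)
      stop("frame error: length ", ncol(m), " not divisible by 3")
    idx <- seq(1, ncol(m), by = 3)
    cod <- vapply(idx, function(i) paste0(m[, i], m[, i + 1], m[, i + 2]),
                  character(nrow(m)))
    if (!is.matrix(cod)) cod <- matrix(cod, nrow = 1)
    rownames(cod) <- rownames(m)
  } else {
    cod <- aln@chars
  }
  res <- matrix("-", nrow(cod), ncol(cod), dimnames = dimnames(cod))
  known <- cod %in% names(code)
  res[known] <- code[cod[known]]
  res[!known & !grepl("[-?.]", cod)] <- "X"
  internal <- res == "*" & col(res) < ncol(res)
  if (any(res == "*")) {
    if (any(internal))
      stop("data error: internal stop codon (e.g. taxon ",
           rownames(res)[which(internal, arr.ind = TRUE)[1, 1]], ")")
    stop("data error: stop codon in alignment")
  }
  phyloAlignment(res, "AA", siteOffset = (siteOffset(aln) + 2L) %/% 3L)
}

#' Largest pairwise sequence distance in an alignment
#'
#' Computes all pairwise distances under pairwise deletion (per-pair complete
#' columns) and returns the maximum.  The default is the raw p-distance; a
#' Poisson correction `-log(1 - p)` is available for amino acids.
#'
#' @param aln a [PhyloAlignment-class] with at least two taxa.
#' @param metric `"p"` (default) or `"poisson"`.
#' @return the maximum distance, with attributes `metric` and `pair`.
#' @export
maxPairwiseDistance <- function(aln, metric = c("p", "poisson")) {
  metric <- match.arg(metric)
  m <- aln@chars
  if (nrow(m) < 2) stop("need at least two taxa")
  gap <- if (alphabet(aln) == "CODON") {
    matrix(grepl("[-?.N]", m), nrow(m), ncol(m))
  } else {
    matrix(m %in% .GAP_CHARS, nrow(m), ncol(m))
  }
  best <- -Inf; pair <- c(NA, NA)
  for (i in seq_len(nrow(m) - 1)) {
    for (j in seq(i + 1, nrow(m))) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok))
        stop("undefined-distance error: taxa ", rownames(m)[i], " and ",
             rownames(m)[j], " share no ungapped columns")
      p <- mean(m[i, ok] != m[j, ok])
      d <- if (metric == "poisson") {
        if (p >= 1) Inf else -log(1 - p)
      } else p
      if (d > best) { best <- d; pair <- c(i, j) }
    }
  }
  structure(best, metric = metric, pair = rownames(m)[pair])
}

#' Subset alignment columns
#'
#' @param aln a [PhyloAlignment-class].
#' @param sites column indices to keep (or drop).
#' @param drop if TRUE, `sites` are removed instead of kept.
#' @return a [PhyloAlignment-class]; the site offset is preserved, so labels
#'   of kept sites stay meaningful only via `attr(, "origSites")`.
#' @export
subsetSites <- function(aln, sites, drop = FALSE) {
  keep <- if (drop) setdiff(seq_len(nSites(aln)), sites) else sites
  out <- new("PhyloAlignment", chars = aln@chars[, keep, drop = FALSE],
             alphabet = aln@alphabet, siteOffset = aln@siteOffset)
  attr(out, "origSites") <- keep
  out
}

#' Read a per-species trait table
#'
#' Expects a TSV with columns `taxon`, `best_frequency_khz` and optionally
#' `source` (`"audiogram"` or `"call-frequency-inferred"`).
#'
#' @param path file path.
#' @return a data.frame with validated positive frequencies.
#' @export
readTraitTable <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "best_frequency_khz") %in% names(tb)))
    stop("trait table needs columns 'taxon' and 'best_frequency_khz'")
  if (any(!is.finite(tb$best_frequency_khz) | tb$best_frequency_khz <= 0))
    stop("best hearing frequencies must be positive")
  if (anyDuplicated(tb$taxon)) stop("duplicated taxon in trait table")
  if (is.null(tb$source)) tb$source <- NA_character_
  tb
}
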