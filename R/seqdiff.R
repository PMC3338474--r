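## Codon-aware pairwise allele comparison: per-site synonymous/nonsynonymous
## classification and Grantham typing of the resulting amino acid changes.

.GENETIC_CODE <- Biostrings::GENETIC_CODE

.translateCodon <- function(codon) {
  aa <- .GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

.checkCds <- function(x, label) {
  x <- toupper(x)
  if (nchar(x) %% 3 != 0)
    stop(label, ": length not divisible by 3")
  chars <- strsplit(x, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop(label, ": unsupported character '", chars[bad[1]], "' at position ",
         bad[1], " (only unambiguous A/C/G/T codons are compared)")
  ncod <- nchar(x) / 3
  codons <- substring(x, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
  aas <- vapply(codons, .translateCodon, character(1))
  if (any(aas[-length(aas)] == "*"))
    stop(label, ": internal stop codon at codon ",
         which(aas[-length(aas)] == "*")[1])
  list(seq = x, codons = codons, aas = aas)
}

#' Count synonymous and nonsynonymous substitutions between two alleles
#'
#' Site-by-site comparison of two equal-length in-frame coding sequences
#' (an alignment is assumed: the sequences are allelic). A nucleotide
#' difference is nonsynonymous when exchanging that single site -- the other
#' two codon positions held at the first sequence's state -- changes the
#' encoded amino acid; codons carrying several differences contribute each
#' site classified under this convention, plus one amino-acid-change event
#' if the codon translations differ. Amino acid changes are classified
#' conservative/radical by Grantham distance. A terminal stop codon in both
#' sequences is excluded from counting.
#'
#' @param seq1,seq2 nucleotide coding sequences (character strings, equal
#'   length, length divisible by 3, unambiguous A/C/G/T).
#' @param gene label for the summary.
#' @param threshold Grantham conservative/radical threshold (default 100).
#' @param pathway if \code{"average"}, multi-hit codons are additionally
#'   scored by Nei-Gojobori-style averaging over the minimal mutational
#'   pathways (reported in \code{@changes} attributes); the default
#'   \code{"observed"} counts observed single-site exchanges only.
#' @return A \code{\linkS4class{SubstitutionSummary}}.
#' @examples
#' countSubstitutions("ATGAAACCC", "ATGAGACCC", gene = "toy")
#' @export
countSubstitutions <- function(seq1, seq2, gene = "gene", threshold = 100,
                               pathway = c("observed", "average")) {
  pathway <- match.arg(pathway)
  a <- .checkCds(seq1, "seq1")
  b <- .checkCds(seq2, "seq2")
  if (nchar(a$seq) != nchar(b$seq))
    stop("sequences must have equal length (allelic alignment assumed)")
  ncod <- length(a$codons)
  use <- seq_len(ncod)
  if (a$aas[ncod] == "*" && b$aas[ncod] == "*") use <- use[-ncod]
  nNon <- 0L; nSyn <- 0L; nAa <- 0L; nCons <- 0L; nRad <- 0L
  rows <- list()
  for (k in use) {
    c1 <- a$codons[k]; c2 <- b$codons[k]
    if (c1 == c2) next
    s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
    diffs <- which(s1 != s2)
    for (d in diffs) {
      swapped <- s1; swapped[d] <- s2[d]
      aaSwap <- .translateCodon(paste(swapped, collapse = ""))
      if (isTRUE(aaSwap == a$aas[[k]])) nSyn <- nSyn + 1L
      else nNon <- nNon + 1L
    }
    if (a$aas[k] != b$aas[k]) {
      nAa <- nAa + 1L
      cls <- classifySubstitution(a$aas[k], b$aas[k], threshold)
      if (cls == "conservative") nCons <- nCons + 1L else nRad <- nRad + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        codon = k, from = a$aas[k], to = b$aas[k], class = cls,
        grantham = granthamDistance(a$aas[k], b$aas[k]))
    }
  }
  changes <- if (length(rows)) do.call(rbind, rows)
             else data.frame(codon = integer(), from = character(),
                             to = character(), class = character(),
                             grantham = numeric())
  if (pathway == "average")
    attr(changes, "pathway") <- .pathwayAverage(a, b, use)
  new("SubstitutionSummary", gene = gene, nNonsynNt = nNon, nSynNt = nSyn,
      nAaChanges = nAa, nConservative = nCons, nRadical = nRad,
      changes = changes)
}

# Nei-Gojobori style pathway averaging for multi-hit codons: average the
# syn/nonsyn split over all orderings of the single-site steps, skipping
# pathways through stop codons.
.pathwayAverage <- function(a, b, use) {
  tot <- c(syn = 0, nonsyn = 0)
  for (k in use) {
    c1 <- strsplit(a$codons[k], "")[[1]]
    c2 <- strsplit(b$codons[k], "")[[1]]
    diffs <- which(c1 != c2)
    if (!length(diffs)) next
    perms <- if (length(diffs) == 1L) list(diffs) else {
      idx <- seq_along(diffs)
      prm <- list()
      permute <- function(v, acc) {
        if (!length(v)) { prm[[length(prm) + 1L]] <<- acc; return() }
        for (i in seq_along(v)) permute(v[-i], c(acc, v[i]))
      }
      permute(diffs, integer())
      prm
    }
    acc <- c(syn = 0, nonsyn = 0); nOK <- 0L
    for (pth in perms) {
      cur <- c1; step <- c(syn = 0, nonsyn = 0); ok <- TRUE
      for (d in pth) {
        prev <- .translateCodon(paste(cur, collapse = ""))
        cur[d] <- c2[d]
        nxt <- .translateCodon(paste(cur, collapse = ""))
        if (nxt == "*") { ok <- FALSE; break }
        if (prev == nxt) step["syn"] <- step["syn"] + 1
        else step["nonsyn"] <- step["nonsyn"] + 1
      }
      if (ok) { acc <- acc + step; nOK <- nOK + 1L }
    }
    if (nOK) tot <- tot + acc / nOK
  }
  tot
}
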