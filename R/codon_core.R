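## Goldman-Yang codon model machinery shared by the likelihood engine and
## the sequence simulator: sense-codon tables, F3x4 frequencies, rate-matrix
## construction, and alignment/tree encoding.

.senseCodons <- local({
  nts <- c("T", "C", "A", "G")
  all <- as.vector(outer(outer(nts, nts, paste0), nts,
                         function(ab, c) paste0(ab, c)))
  all <- sort(all)
  all[vapply(all, function(cd) Biostrings::GENETIC_CODE[[cd]] != "*",
             logical(1))]
})

.codonAA <- vapply(.senseCodons, function(cd) Biostrings::GENETIC_CODE[[cd]],
                   character(1))

# structural table of single-nucleotide codon exchanges: rows (i, j) with
# transition/transversion and synonymous/nonsynonymous flags
.codonPairs <- local({
  n <- length(.senseCodons)
  spl <- strsplit(.senseCodons, "")
  isTs <- function(x, y) (x %in% c("A", "G") && y %in% c("A", "G")) ||
    (x %in% c("C", "T") && y %in% c("C", "T"))
  ii <- integer(); jj <- integer(); ts <- logical(); ns <- logical()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- which(spl[[i]] != spl[[j]])
    if (length(d) != 1L) next
    ii <- c(ii, i); jj <- c(jj, j)
    ts <- c(ts, isTs(spl[[i]][d], spl[[j]][d]))
    ns <- c(ns, .codonAA[i] != .codonAA[j])
  }
  list(i = ii, j = jj, ts = ts, nonsyn = ns)
})

#' Goldman-Yang codon rate matrix
#'
#' 61x61 instantaneous rate matrix over sense codons: zero for
#' multi-nucleotide exchanges, target frequency pi_j times kappa for
#' transitions and omega for nonsynonymous exchanges; diagonal set so rows
#' sum to zero. With \code{normalize = TRUE} the matrix is scaled so the
#' mean substitution rate at stationarity, -sum(pi_i Q_ii), equals 1
#' (branch lengths then read as expected substitutions per codon).
#'
#' @param kappa transition/transversion rate ratio (>= 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param codonFreqs length-61 stationary codon frequencies (default
#'   uniform); must be non-negative and sum to 1.
#' @param normalize logical.
#' @return 61x61 matrix with codon dimnames.
#' @export
buildCodonRateMatrix <- function(kappa = 2, omega = 1, codonFreqs = NULL,
                                 normalize = TRUE) {
  n <- length(.senseCodons)
  if (is.null(codonFreqs)) codonFreqs <- rep(1 / n, n)
  if (length(codonFreqs) != n || any(codonFreqs < 0) ||
      abs(sum(codonFreqs) - 1) > 1e-6)
    stop("codonFreqs must be 61 non-negative values summing to 1")
  if (kappa < 0 || omega < 0) stop("kappa and omega must be >= 0")
  cp <- .codonPairs
  vals <- codonFreqs[cp$j] * ifelse(cp$ts, kappa, 1) *
    ifelse(cp$nonsyn, omega, 1)
  Q <- matrix(0, n, n, dimnames = list(.senseCodons, .senseCodons))
  Q[cbind(cp$i, cp$j)] <- vals
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    rate <- -sum(codonFreqs * diag(Q))
    if (rate > 0) Q <- Q / rate
  }
  Q
}

# mean substitution rate of the unnormalized GY matrix at stationarity
.codonRate <- function(kappa, omega, codonFreqs) {
  Q <- buildCodonRateMatrix(kappa, omega, codonFreqs, normalize = FALSE)
  -sum(codonFreqs * diag(Q))
}

#' F3x4 codon frequencies from an alignment
#'
#' Position-specific nucleotide frequencies multiplied across the three
#' codon positions, stop codons removed, renormalized (the standard F3x4
#' estimator).
#'
#' @param alignment named character vector (or \code{DNAStringSet}) of
#'   equal-length in-frame coding sequences; gaps/N ignored in the counts.
#' @return Length-61 named frequency vector over sense codons.
#' @export
codonFreqsF3x4 <- function(alignment) {
  if (is(alignment, "DNAStringSet"))
    alignment <- setNames(as.character(alignment), names(alignment))
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  ncol3 <- ncol(mat) %/% 3L
  posFreq <- matrix(0, 3, 4, dimnames = list(NULL, c("T", "C", "A", "G")))
  for (p in 1:3) {
    cols <- seq(p, by = 3L, length.out = ncol3)
    tab <- table(factor(mat[, cols], levels = c("T", "C", "A", "G")))
    tot <- sum(tab)
    posFreq[p, ] <- if (tot > 0) as.numeric(tab) / tot else rep(0.25, 4)
  }
  spl <- strsplit(.senseCodons, "")
  fr <- vapply(spl, function(s)
    posFreq[1, s[1]] * posFreq[2, s[2]] * posFreq[3, s[3]], numeric(1))
  if (sum(fr) <= 0) fr <- rep(1, length(fr))
  fr <- fr / sum(fr)
  names(fr) <- .senseCodons
  fr
}

# ---- alignment encoding ---------------------------------------------------

# encode an aligned set of CDS into 0-based codon states; -1 for codons
# containing gap/ambiguity. Rejects internal stop codons.
.encodeCodonAlignment <- function(alignment) {
  if (is(alignment, "DNAStringSet"))
    alignment <- setNames(as.character(alignment), names(alignment))
  alignment <- toupper(alignment)
  if (length(unique(nchar(alignment))) != 1L)
    stop("aligned sequences must have equal length")
  if (nchar(alignment[1]) %% 3 != 0)
    stop("alignment length must be divisible by 3")
  ncod <- nchar(alignment[1]) %/% 3L
  idx <- setNames(seq_along(.senseCodons) - 1L, .senseCodons)
  states <- matrix(-1L, nrow = length(alignment), ncol = ncod,
                   dimnames = list(names(alignment), NULL))
  for (r in seq_along(alignment)) {
    codons <- substring(alignment[r], 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
    known <- codons %in% .senseCodons
    stops <- !known & codons %in% c("TAA", "TAG", "TGA")
    if (any(stops)) {
      at <- which(stops)
      if (any(at < ncod))
        stop(names(alignment)[r], ": internal stop codon at codon ",
             at[at < ncod][1])
      known[at] <- FALSE            # terminal stop: treat as missing
    }
    states[r, known] <- idx[codons[known]]
  }
  states
}

# drop all-missing columns, compress to unique site patterns
.compressPatterns <- function(states) {
  keep <- colSums(states >= 0L) > 0L
  states <- states[, keep, drop = FALSE]
  key <- apply(states, 2L, paste, collapse = ",")
  uniq <- !duplicated(key)
  map <- match(key, key[uniq])
  list(patterns = states[, uniq, drop = FALSE],
       weights = as.numeric(table(factor(map, levels = seq_len(sum(uniq))))),
       map = map, siteKept = which(keep))
}

# ---- tree encoding --------------------------------------------------------

# postorder edge structure with tips matched to alignment rows; polytomies
# resolved with zero-length branches; unrooted for the reversible likelihood
.encodeTree <- function(tree, taxa, defaultBL = 0.1) {
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, taxa))
    stop("tree leaves must match alignment taxa")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(defaultBL,
                                                         nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (length(tree$tip.label) > 2L) tree <- ape::unroot(tree)
  po <- stats::reorder(tree, "postorder")
  ord <- match(taxa, po$tip.label)   # row r of states = taxon taxa[r]
  list(tree = po, edge = po$edge, edgeLen = po$edge.length,
       ntip = length(po$tip.label), nnode = po$Nnode,
       root = po$edge[nrow(po$edge), 1], tipOrder = ord)
}

# reorder state rows into the tree's tip numbering
.tipStatesForTree <- function(states, enc) {
  out <- states[match(enc$tree$tip.label, rownames(states)), , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

# per-pattern likelihoods for a list of omega classes (and optional tau
# multipliers) -- thin wrapper over the C++ pruning engine
.classLik <- function(omegas, kappa, codonFreqs, enc, tipStates, scale = 1,
                      taus = 1) {
  Qlist <- lapply(omegas, function(w)
    buildCodonRateMatrix(kappa, w, codonFreqs, normalize = FALSE) / scale)
  site_class_lik(Qlist, codonFreqs, tipStates, enc$edge, enc$edgeLen,
                 enc$ntip, enc$nnode, enc$root, as.numeric(taus))
}
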