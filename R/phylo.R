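## Distance-based gene trees and congruence against a species tree that may
## contain polytomies. Distances and neighbor-joining are delegated to ape;
## the polytomy-aware congruence test (split compatibility + greedy
## displaced-taxon search) is implemented here.

.asDNAbin <- function(alignment) {
  if (inherits(alignment, "DNAbin")) return(alignment)
  if (is(alignment, "DNAStringSet")) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  if (is.character(alignment)) {
    if (length(unique(nchar(alignment))) != 1L)
      stop("aligned sequences must have equal length")
    mat <- do.call(rbind, strsplit(tolower(alignment), ""))
    rownames(mat) <- names(alignment)
    return(ape::as.DNAbin(mat))
  }
  stop("unsupported alignment representation")
}

#' Pairwise distances from an alignment
#'
#' p-distance or Kimura two-parameter, with pairwise deletion of sites
#' containing gaps or ambiguity. K2P is the default (the classic
#' distance for this kind of analysis); a saturated pair, for which the K2P
#' logs are undefined, raises an error naming the pair.
#'
#' @param alignment named character vector, \code{DNAStringSet} or
#'   \code{DNAbin} of equal-length aligned sequences (>= 2 taxa).
#' @param model \code{"k2p"} or \code{"p_distance"}.
#' @return Symmetric distance matrix with taxon dimnames.
#' @export
pairwiseDistances <- function(alignment, model = c("k2p", "p_distance")) {
  model <- match.arg(model)
  dna <- .asDNAbin(alignment)
  if (NROW(dna) < 2L) stop("need at least 2 taxa")
  m <- ape::dist.dna(dna, model = if (model == "k2p") "K80" else "raw",
                     pairwise.deletion = TRUE, as.matrix = TRUE)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("saturated/undefined %s distance between '%s' and '%s'",
                 model, rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  m
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor-joining on a distance matrix (exact on additive
#' distances). Negative branch lengths are clamped to zero. With an
#' \code{outgroup}, the tree is additionally rooted on it.
#'
#' @param dm symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @param outgroup optional taxon label to root on.
#' @return An \code{ape} \code{phylo} (rooted if \code{outgroup} given).
#' @export
njTree <- function(dm, outgroup = NULL) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("need at least 3 taxa")
  if (any(!is.finite(dm)) || any(abs(dm - t(dm)) > 1e-8))
    stop("degenerate distance matrix")
  tr <- ape::nj(as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label)
      stop("outgroup '", outgroup, "' not among taxa")
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

# Non-trivial splits of an (un)rooted tree as sorted tip-label sets (the
# side not containing the reference ordering is irrelevant: compatibility
# below is side-symmetric).
.treeSplits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  eo <- stats::reorder(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  splits <- list()
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2]
    if (ch > ntip) {
      s <- sort(sets[[ch]])
      if (length(s) >= 2L && length(s) <= ntip - 2L)
        splits[[length(splits) + 1L]] <- s
    }
  }
  unique(splits)
}

# two splits (as one-side subsets of the same leaf set) are compatible iff
# one of the four side intersections is empty (Buneman)
.splitsCompatible <- function(s1, s2, leaves) {
  b1 <- setdiff(leaves, s1); b2 <- setdiff(leaves, s2)
  !length(intersect(s1, s2)) || !length(intersect(s1, b2)) ||
    !length(intersect(b1, s2)) || !length(intersect(b1, b2))
}

.countIncompatible <- function(geneSplits, speciesSplits, leaves) {
  sum(vapply(geneSplits, function(g)
    any(!vapply(speciesSplits, function(s)
      .splitsCompatible(g, s, leaves), logical(1))), logical(1)))
}

.restrictSplits <- function(splits, leaves) {
  out <- lapply(splits, function(s) intersect(s, leaves))
  out <- out[vapply(out, function(s)
    length(s) >= 2L && length(s) <= length(leaves) - 2L, logical(1))]
  unique(out)
}

#' Test gene-tree congruence with a (possibly polytomous) species tree
#'
#' The gene tree is congruent iff every non-trivial split it contains is
#' compatible with every split of the species tree; a polytomy in the
#' species tree therefore accepts any of its resolutions. \code{rfDistance}
#' counts the gene-tree splits incompatible with the species tree.
#' \code{displacedTaxa} is found by greedy leaf removal: repeatedly drop the
#' leaf (ties broken alphabetically) whose removal most reduces the
#' incompatible-split count, until the restriction is congruent.
#'
#' Branch lengths are ignored; only topology matters.
#'
#' @param geneTree,speciesTree \code{phylo} objects on the same leaf set.
#' @param gene label for the report.
#' @return A \code{\linkS4class{CongruenceReport}}.
#' @export
checkCongruence <- function(geneTree, speciesTree, gene = "gene") {
  leaves <- sort(geneTree$tip.label)
  if (!setequal(leaves, speciesTree$tip.label))
    stop("gene tree and species tree must share the same leaf set")
  gs <- .treeSplits(geneTree)
  ss <- .treeSplits(speciesTree)
  rf <- .countIncompatible(gs, ss, leaves)
  displaced <- character()
  if (rf > 0L) {
    remaining <- leaves
    g <- gs; s <- ss
    while (length(remaining) > 3L &&
           .countIncompatible(g, s, remaining) > 0L) {
      scores <- vapply(remaining, function(l) {
        keep <- setdiff(remaining, l)
        .countIncompatible(.restrictSplits(g, keep),
                           .restrictSplits(s, keep), keep)
      }, numeric(1))
      drop1 <- remaining[which.min(scores)]   # ties: first alphabetically
      displaced <- c(displaced, drop1)
      remaining <- setdiff(remaining, drop1)
      g <- .restrictSplits(g, remaining)
      s <- .restrictSplits(s, remaining)
    }
  }
  new("CongruenceReport", gene = gene, congruent = rf == 0L,
      displacedTaxa = displaced, rfDistance = as.integer(rf))
}
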