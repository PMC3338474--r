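## Grantham (1974) amino acid distances, computed from the published
## composition/polarity/volume properties and constants rather than typed in
## as a 190-entry table. D_ij = rho * sqrt(alpha*(c_i-c_j)^2 +
## beta*(p_i-p_j)^2 + gamma*(v_i-v_j)^2), alpha = 1.833, beta = 0.1018,
## gamma = 0.000399, rho = 50.723 (sets the mean distance to 100); entries
## rounded to integers as in the published table.

.granthamProps <- data.frame(
  aa = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
         "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
  c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
        0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
  p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
        6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
  v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
        136, 55, 96, 85, 56, 119, 54, 83, 105, 170))

.granthamMatrix <- local({
  pr <- .granthamProps
  n <- nrow(pr)
  m <- matrix(0, n, n, dimnames = list(pr$aa, pr$aa))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(1.833 * (pr$c[i] - pr$c[j])^2 +
              0.1018 * (pr$p[i] - pr$p[j])^2 +
              0.000399 * (pr$v[i] - pr$v[j])^2)
    m[i, j] <- round(50.723 * d)
  }
  m
})

#' Grantham distance between two amino acids
#'
#' @param aaFrom,aaTo single-letter amino acid codes (standard 20).
#' @return Integer Grantham distance (0 for identical residues).
#' @examples
#' granthamDistance("I", "L")  # 5
#' granthamDistance("C", "W")  # ~215, the most radical pair
#' @export
granthamDistance <- function(aaFrom, aaTo) {
  aaFrom <- toupper(aaFrom); aaTo <- toupper(aaTo)
  if (!aaFrom %in% rownames(.granthamMatrix) ||
      !aaTo %in% rownames(.granthamMatrix))
    stop("non-standard residue: ", aaFrom, "/", aaTo)
  unname(.granthamMatrix[aaFrom, aaTo])
}

#' Classify an amino acid replacement as conservative or radical
#'
#' Grantham distance at or below \code{threshold} (default 100) is
#' conservative. The threshold is a convention, not a property of the data;
#' it is exposed so sensitivity can be checked.
#'
#' @param aaFrom,aaTo single-letter amino acid codes; must differ.
#' @param threshold numeric, default 100.
#' @return \code{"conservative"} or \code{"radical"}.
#' @examples
#' classifySubstitution("I", "L")  # conservative
#' classifySubstitution("C", "W")  # radical
#' @export
classifySubstitution <- function(aaFrom, aaTo, threshold = 100) {
  if (toupper(aaFrom) == toupper(aaTo))
    stop("not a substitution: identical residues")
  if (granthamDistance(aaFrom, aaTo) <= threshold) "conservative" else "radical"
}
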