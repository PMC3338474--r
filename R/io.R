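## Readers/writers for the pipeline's plain-text dialects. Sequence and tree
## formats go through Biostrings and ape.

#' Read a marker genotype table
#'
#' TSV with columns name, chrom, pos_mb, donor_hap, recipient_hap,
#' congenic_hap.
#' @param path file path.
#' @return data.frame.
#' @export
readMarkerTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "chrom", "pos_mb", "donor_hap", "recipient_hap",
            "congenic_hap")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("marker table missing column(s): ", paste(missing, collapse = ", "))
  df
}

#' Read ancestry tracks (BED-like TSV)
#'
#' Columns: strain, chrom, start_mb, end_mb, subspecies. Intervals per
#' strain must be sorted and non-overlapping.
#' @param path file path.
#' @return data.frame.
#' @export
readAncestryTracks <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "chrom", "start_mb", "end_mb", "subspecies")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("ancestry track missing column(s): ", paste(missing, collapse = ", "))
  for (s in unique(df$strain)) {
    t1 <- df[df$strain == s, ]
    t1 <- t1[order(t1$start_mb), ]
    if (any(t1$end_mb[-nrow(t1)] > t1$start_mb[-1] + 1e-9))
      stop("overlapping intervals in track for strain ", s)
  }
  df
}

#' Read an assembly-gap table (chrom, start_mb, end_mb)
#' @param path file path.
#' @return data.frame.
#' @export
readGapTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (any(df$start_mb >= df$end_mb)) stop("gap with start >= end")
  df
}

#' Read a probe-level expression table (TSV)
#' @param path file path.
#' @return data.frame.
#' @export
readExpressionTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "start_mb", "end_mb", "gland", "sex",
            "intensity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("expression table missing column(s): ",
         paste(missing, collapse = ", "))
  badG <- !df$gland %in% c("parotid", "sublingual", "submandibular")
  if (any(badG)) stop("unknown gland label: ", df$gland[badG][1])
  if (any(df$intensity < 0)) stop("negative intensity")
  df
}

#' Read an aligned FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFastaAlignment <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeFastaAlignment <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(sequences)), path)
  invisible(path)
}

#' Write a transferred-segment report as JSON + BED-like segment file
#' @param report a \code{TransferredSegmentReport}.
#' @param jsonPath,bedPath output paths (NULL to skip).
#' @param chrom chromosome label for the BED lines.
#' @return invisibly, a list representation of the report.
#' @export
writeSegmentReport <- function(report, jsonPath = NULL, bedPath = NULL,
                               chrom = "chr7") {
  rep <- list(
    minimal_interval = report@minimalInterval,
    maximal_interval = report@maximalInterval,
    unbounded_left = report@unboundedLeft,
    crossover_intervals = report@crossoverIntervals,
    functional_size_mb = report@functionalSizeMb,
    ibd_masked_mb = report@ibdMaskedMb,
    notes = report@notes)
  if (!is.null(jsonPath))
    jsonlite::write_json(rep, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(bedPath)) {
    lines <- c(sprintf("%s\t%.3f\t%.3f\tminimal_segment", chrom,
                       report@minimalInterval[1], report@minimalInterval[2]),
               sprintf("%s\t%.3f\t%.3f\tmaximal_segment", chrom,
                       report@maximalInterval[1], report@maximalInterval[2]))
    writeLines(lines, bedPath)
  }
  invisible(rep)
}
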