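#' Read a reference genome FASTA
#'
#' Loads a FASTA into a named \code{DNAStringSet}, upper-casing bases.
#' Sequence names must be unique and sequences may contain only
#' A, C, G, T or N; the first offending position is reported otherwise.
#' Chromosome names are normalised to the unprefixed dialect ("chr1"
#' becomes "1").
#'
#' @param path FASTA file.
#' @return \code{Biostrings::DNAStringSet} keyed by chromosome label.
#' @export
readReference <- function(path) {
  # read as raw strings first so invalid characters can be located and
  # reported, then convert
  seqs <- Biostrings::readBStringSet(path)
  names(seqs) <- .normChrom(sub("\\s.*$", "", names(seqs)))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence names in ", path, ": ",
      paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  chr <- as.character(seqs)
  up <- toupper(chr)
  bad <- regexpr("[^ACGTN]", up)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("non-ACGTN character in sequence '", names(seqs)[i],
      "' at position ", bad[i])
  }
  out <- Biostrings::DNAStringSet(up)
  names(out) <- names(seqs)
  out
}

#' Write a reference to FASTA
#' @param reference named \code{DNAStringSet}.
#' @param path output FASTA file.
#' @return \code{path}, invisibly.
#' @export
writeReference <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

.checkChrom <- function(reference, chrom) {
  chrom <- .normChrom(chrom)
  missing <- setdiff(unique(chrom), names(reference))
  if (length(missing)) {
    stop("chromosome(s) not in reference: ", paste(missing, collapse = ", "))
  }
  chrom
}

#' Look up reference bases
#'
#' Vectorised 1-based single-base lookup; out-of-range positions are an
#' error.
#'
#' @param reference named \code{DNAStringSet} from \code{\link{readReference}}.
#' @param chrom chromosome label(s).
#' @param pos 1-based position(s).
#' @return character vector of bases.
#' @export
refBase <- function(reference, chrom, pos) {
  chrom <- .checkChrom(reference, chrom)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(as.integer(pos), n)
  len <- Biostrings::width(reference)[match(chrom, names(reference))]
  if (any(pos < 1L | pos > len)) {
    i <- which(pos < 1L | pos > len)[1L]
    stop("position out of range: ", chrom[i], ":", pos[i],
      " (contig length ", len[i], ")")
  }
  vapply(seq_len(n), function(i) {
    as.character(Biostrings::subseq(reference[[chrom[i]]], pos[i], pos[i]))
  }, character(1))
}
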