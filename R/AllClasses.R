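#' @import methods
NULL

AUTOSOMES <- as.character(1:22)
TRIO_ROLES <- c("father", "mother", "child")

## columns every TrioCallSet records table must carry, in canonical order
CORE_COLUMNS <- c(
  "chrom", "pos", "ref", "alt",
  "fatherGT", "motherGT", "childGT",
  "fatherRefDepth", "fatherAltDepth",
  "motherRefDepth", "motherAltDepth",
  "childRefDepth", "childAltDepth",
  "fatherGQ", "motherGQ", "childGQ"
)

.chromOrder <- function(chrom) match(chrom, AUTOSOMES)

.normChrom <- function(chrom) sub("^chr", "", as.character(chrom))

.variantKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' TrioCallSet: a pipeline's trio SNV call set
#'
#' Holds biallelic autosomal SNVs with per-role (father, mother, child)
#' genotype, reference/alternate allele depths and genotype quality.
#' Records are unique on (chrom, pos, ref, alt) and sorted by numeric
#' chromosome then position.  Chromosome labels are stored without a
#' "chr" prefix.
#'
#' @slot name pipeline label (e.g. "GATK").
#' @slot records data.frame with the columns listed under Details.
#' @slot provenance optional source file path.
#' @slot skipLog named integer vector counting records skipped or
#'   excluded while the object was built (e.g. multi-allelic sites).
#'
#' @details Required columns of \code{records}: \code{chrom}, \code{pos},
#' \code{ref}, \code{alt}, and per role \code{<role>GT} (character,
#' "0/0"/"0/1"/"1/1" or NA), \code{<role>RefDepth}/\code{<role>AltDepth}
#' (integer, NA when AD was absent) and \code{<role>GQ} (integer or NA).
#' Annotation columns (\code{gcContent}, \code{snvDensity},
#' \code{substClass}, \code{score}, \code{scoreReason},
#' \code{childHomAlt}) are optional and preserved by subsetting.
#'
#' @export
setClass("TrioCallSet",
  slots = c(
    name = "character",
    records = "data.frame",
    provenance = "character",
    skipLog = "integer"
  ),
  prototype = list(
    name = NA_character_,
    records = data.frame(),
    provenance = NA_character_,
    skipLog = integer()
  )
)

setValidity("TrioCallSet", function(object) {
  rec <- object@records
  if (length(object@name) != 1L) {
    return("'name' must be a single string")
  }
  if (nrow(rec) == 0L) {
    return(TRUE)
  }
  missing_cols <- setdiff(CORE_COLUMNS, names(rec))
  if (length(missing_cols)) {
    return(paste("missing record columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!all(rec$chrom %in% AUTOSOMES)) {
    return("chrom labels must be autosomes '1'..'22'")
  }
  if (!is.numeric(rec$pos) || any(rec$pos < 1)) {
    return("pos must be >= 1")
  }
  bad <- !(rec$ref %in% c("A", "C", "G", "T")) |
    !(rec$alt %in% c("A", "C", "G", "T")) | rec$ref == rec$alt
  if (any(bad)) {
    return("ref and alt must be distinct single bases in {A,C,G,T}")
  }
  depth_cols <- grep("Depth$", CORE_COLUMNS, value = TRUE)
  for (dc in depth_cols) {
    if (any(rec[[dc]] < 0, na.rm = TRUE)) {
      return(paste(dc, "contains negative depths"))
    }
  }
  key <- .variantKey(rec$chrom, rec$pos, rec$ref, rec$alt)
  if (anyDuplicated(key)) {
    return("duplicate (chrom, pos, ref, alt) keys")
  }
  ord <- order(.chromOrder(rec$chrom), rec$pos)
  if (!identical(ord, seq_len(nrow(rec)))) {
    return("records must be sorted by (chromosome, position)")
  }
  TRUE
})

#' Transition/transversion tally
#'
#' @slot nTransitions transition count.
#' @slot nTransversions transversion count.
#' @export
setClass("TiTvSummary",
  slots = c(nTransitions = "integer", nTransversions = "integer"),
  prototype = list(nTransitions = 0L, nTransversions = 0L)
)

setValidity("TiTvSummary", function(object) {
  if (length(object@nTransitions) != 1L || length(object@nTransversions) != 1L) {
    return("counts must be single integers")
  }
  if (object@nTransitions < 0L || object@nTransversions < 0L) {
    return("counts must be non-negative")
  }
  TRUE
})

#' Multi-pipeline call-set comparison report
#'
#' @slot setNames pipeline labels, in input order.
#' @slot exclusiveCounts named integer vector, one entry per Venn region
#'   (region names join set labels with "&"); entries sum to the union size.
#' @slot pairwiseOverlaps named integer vector of |A intersect B| per
#'   unordered pair.
#' @slot commonCount records present in every set.
#' @slot perChromCounts 22 x n matrix of per-autosome counts per set.
#' @slot overlapRates percent overlap with a known-variant catalog per set
#'   (length 0 when no catalog was supplied).
#' @export
setClass("ComparisonReport",
  slots = c(
    setNames = "character",
    exclusiveCounts = "integer",
    pairwiseOverlaps = "integer",
    commonCount = "integer",
    perChromCounts = "matrix",
    overlapRates = "numeric"
  )
)

setValidity("ComparisonReport", function(object) {
  if (length(object@setNames) < 2L) {
    return("a comparison needs at least two call sets")
  }
  if (any(object@pairwiseOverlaps < pmax(object@commonCount, 0L))) {
    return("common count exceeds a pairwise overlap")
  }
  TRUE
})

#' Configuration of the synthetic trio generator
#'
#' Defines the reference layout, planted variant counts, depth model and
#' seed of one simulated father-mother-child study.  Each chromosome is
#' laid out as the concatenation of \code{gcSegments}; segment lengths
#' must sum to \code{chromLength}.
#'
#' @slot nChrom number of synthetic autosomes (1..22).
#' @slot chromLength chromosome length in bp.
#' @slot gcSegments data.frame with columns \code{length} (bp) and
#'   \code{gc} (target G+C fraction in [0,1]).
#' @slot nInherited inherited SNVs planted per genome.
#' @slot nDenovo de novo SNVs planted (parents 0/0, child 0/1).
#' @slot tiFraction probability a planted substitution is a transition.
#' @slot meanDepth Poisson mean of per-sample read depth.
#' @slot seqError per-read sequencing error probability.
#' @slot spuriousRate fraction of candidate de novo calls that are
#'   injected genotype-error false positives.
#' @slot gqMargin additive GQ penalty applied to the child of spurious
#'   records.
#' @slot seed integer seed controlling all randomness.
#' @export
setClass("SyntheticTrioConfig",
  slots = c(
    nChrom = "integer",
    chromLength = "integer",
    gcSegments = "data.frame",
    nInherited = "integer",
    nDenovo = "integer",
    tiFraction = "numeric",
    meanDepth = "numeric",
    seqError = "numeric",
    spuriousRate = "numeric",
    gqMargin = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticTrioConfig", function(object) {
  if (object@nChrom < 1L || object@nChrom > 22L) {
    return("nChrom must be in 1..22")
  }
  seg <- object@gcSegments
  if (!all(c("length", "gc") %in% names(seg))) {
    return("gcSegments needs columns 'length' and 'gc'")
  }
  if (sum(seg$length) != object@chromLength) {
    return("gcSegments lengths must sum to chromLength")
  }
  if (any(seg$gc < 0 | seg$gc > 1)) {
    return("segment gc fractions must lie in [0,1]")
  }
  frac <- c(object@tiFraction, object@seqError, object@spuriousRate)
  if (any(frac < 0 | frac > 1)) {
    return("tiFraction, seqError and spuriousRate must lie in [0,1]")
  }
  if (any(c(object@nInherited, object@nDenovo, object@gqMargin) < 0L)) {
    return("counts and gqMargin must be non-negative")
  }
  if (object@meanDepth < 0) {
    return("meanDepth must be non-negative")
  }
  TRUE
})
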