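#' Compare 2-3 call sets by exact variant key
#'
#' Records are matched on (chrom, pos, ref, alt).  Computes every Venn
#' region count, all pairwise overlaps, the common (all-sets) count and
#' per-chromosome counts; optionally the overlap rate of each set
#' against a known-variant catalog.
#'
#' @param callsets list of 2-3 \linkS4class{TrioCallSet}s with distinct
#'   names.
#' @param catalog optional known-variant catalog (see
#'   \code{\link{overlapRate}}).
#' @return A \linkS4class{ComparisonReport}.
#' @export
intersectCallSets <- function(callsets, catalog = NULL) {
  if (!is.list(callsets) || length(callsets) < 2L || length(callsets) > 3L) {
    stop("need a list of 2 or 3 call sets")
  }
  nm <- vapply(callsets, callsetName, character(1))
  if (anyDuplicated(nm)) stop("call sets must have distinct names")
  keys <- lapply(callsets, variantKeys)
  universe <- unique(unlist(keys))
  member <- matrix(FALSE, nrow = length(universe), ncol = length(nm),
    dimnames = list(NULL, nm))
  for (j in seq_along(keys)) {
    member[, j] <- universe %in% keys[[j]]
  }

  ## Venn regions: every non-empty subset of sets
  regions <- integer()
  nset <- length(nm)
  for (size in seq_len(nset)) {
    for (combo in utils::combn(nset, size, simplify = FALSE)) {
      inside <- rowSums(member[, combo, drop = FALSE]) == size
      outside <- rowSums(member[, -combo, drop = FALSE]) == 0
      regions[paste(nm[combo], collapse = "&")] <- sum(inside & outside)
    }
  }
  pair <- integer()
  for (combo in utils::combn(nset, 2, simplify = FALSE)) {
    pair[paste(nm[combo], collapse = "&")] <-
      sum(rowSums(member[, combo, drop = FALSE]) == 2)
  }
  common <- if (length(universe)) sum(rowSums(member) == nset) else 0L

  perChrom <- vapply(callsets, chromosomalDistribution,
    integer(length(AUTOSOMES)))
  colnames(perChrom) <- nm

  rates <- numeric()
  if (!is.null(catalog)) {
    rates <- vapply(callsets, overlapRate, numeric(1), catalog = catalog)
    names(rates) <- nm
  }
  new("ComparisonReport",
    setNames = nm,
    exclusiveCounts = .asSkipLog(regions),
    pairwiseOverlaps = .asSkipLog(pair),
    commonCount = as.integer(common),
    perChromCounts = perChrom,
    overlapRates = rates)
}

#' Display a ComparisonReport
#' @param object a ComparisonReport.
#' @return invisible NULL.
#' @export
setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport over ", length(object@setNames), " call sets: ",
    paste(object@setNames, collapse = ", "), "\n", sep = "")
  cat("  common to all: ", object@commonCount, "\n", sep = "")
  for (nm in names(object@pairwiseOverlaps)) {
    cat("  overlap ", nm, ": ", object@pairwiseOverlaps[[nm]], "\n", sep = "")
  }
  if (length(object@overlapRates)) {
    cat("  catalog overlap rate: ",
      paste(names(object@overlapRates),
        sprintf("%d%%", round(object@overlapRates)),
        sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(NULL)
})

.catalogKeys <- function(catalog) {
  if (is(catalog, "TrioCallSet")) {
    variantKeys(catalog)
  } else if (is.data.frame(catalog)) {
    .variantKey(.normChrom(catalog$chrom), as.integer(catalog$pos),
      catalog$ref, catalog$alt)
  } else {
    as.character(catalog)
  }
}

#' Overlap rate of a call set against a known-variant catalog
#'
#' 100 x (records whose (chrom, pos, ref, alt) key appears in the
#' catalog) / (records in the set).  Monotone non-decreasing as the
#' catalog grows.
#'
#' @param callset a non-empty \linkS4class{TrioCallSet}.
#' @param catalog a \linkS4class{TrioCallSet}, a data.frame with chrom /
#'   pos / ref / alt columns, or a character vector of
#'   "chrom:pos:ref:alt" keys.
#' @return percent in [0, 100], full precision (round for display).
#' @export
overlapRate <- function(callset, catalog) {
  keys <- variantKeys(callset)
  if (length(keys) == 0L) {
    stop("overlap rate is undefined for an empty call set")
  }
  100 * sum(keys %in% .catalogKeys(catalog)) / length(keys)
}

#' Read a known-variant catalog from a VCF
#'
#' Extracts "chrom:pos:ref:alt" keys for all biallelic SNVs in a VCF
#' (e.g. a dbSNP extract); sample columns are not required.
#'
#' @param path VCF file.
#' @return character vector of variant keys.
#' @export
readCatalogVcf <- function(path) {
  v <- VariantAnnotation::readVcf(path, genome = "unknown")
  chrom <- .normChrom(as.character(GenomicRanges::seqnames(v)))
  pos <- GenomicRanges::start(v)
  refA <- as.character(VariantAnnotation::ref(v))
  altL <- VariantAnnotation::alt(v)
  nAlt <- S4Vectors::elementNROWS(altL)
  altA <- rep(NA_character_, length(nAlt))
  altA[nAlt == 1L] <- as.character(unlist(altL[nAlt == 1L]))
  keep <- nAlt == 1L & nchar(refA) == 1L & !is.na(altA) & nchar(altA) == 1L &
    refA %in% c("A", "C", "G", "T") & altA %in% c("A", "C", "G", "T")
  unique(.variantKey(chrom[keep], pos[keep], refA[keep], altA[keep]))
}

#' Per-autosome record counts
#'
#' @param callset a \linkS4class{TrioCallSet}.
#' @return named integer vector over all 22 autosomes (zeros included);
#'   sums to \code{length(callset)}.
#' @export
chromosomalDistribution <- function(callset) {
  rec <- records(callset)
  counts <- table(factor(rec$chrom, levels = AUTOSOMES))
  .asSkipLog(stats::setNames(as.integer(counts), AUTOSOMES))
}

#' Genotype-quality summary per trio role
#'
#' Five-number summary plus mean of the non-missing GQ values for each
#' role; missing values are counted, not imputed.
#'
#' @param callset a \linkS4class{TrioCallSet}.
#' @return data.frame with one row per role (father, mother, child) and
#'   columns n, nMissing, min, q25, median, q75, max, mean (NA for a
#'   role with no observed GQ).
#' @export
gqSummary <- function(callset) {
  rec <- records(callset)
  out <- lapply(TRIO_ROLES, function(role) {
    gq <- rec[[paste0(role, "GQ")]]
    if (is.null(gq)) gq <- integer()
    obs <- gq[!is.na(gq)]
    if (length(obs)) {
      q <- stats::quantile(obs, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      data.frame(role = role, n = length(obs), nMissing = sum(is.na(gq)),
        min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5],
        mean = mean(obs))
    } else {
      data.frame(role = role, n = 0L, nMissing = sum(is.na(gq)),
        min = NA_real_, q25 = NA_real_, median = NA_real_, q75 = NA_real_,
        max = NA_real_, mean = NA_real_)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
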