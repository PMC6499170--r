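## genotype normalisation: phased and unordered forms collapse to a
## canonical "a/b" with a <= b; anything not over alleles {0,1} is NA
.normGT <- function(gt) {
  gt <- gsub("|", "/", as.character(gt), fixed = TRUE)
  parts <- strsplit(gt, "/", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L || any(!p %in% c("0", "1"))) {
      return(NA_character_)
    }
    paste(sort(p), collapse = "/")
  }, character(1))
}

#' Extract candidate de novo SNVs from a trio call set
#'
#' Applies the Mendelian-violation pattern for a novel allele: both
#' parents homozygous reference (0/0) and the child carrying at least one
#' alternate allele (0/1 or 1/1).  Records with a missing genotype in any
#' role are excluded and counted in the skip log.  Child homozygous-alt
#' calls are admitted but flagged in a \code{childHomAlt} column so users
#' can exclude them.
#'
#' @param callset a \linkS4class{TrioCallSet} with genotypes for all
#'   three roles.
#' @return A \linkS4class{TrioCallSet} subset of the input (sorted,
#'   deduplicated by construction); idempotent.
#' @export
extractCandidateDnsnvs <- function(callset) {
  rec <- records(callset)
  if (nrow(rec) == 0L) {
    return(callset)
  }
  f <- .normGT(rec$fatherGT)
  m <- .normGT(rec$motherGT)
  s <- .normGT(rec$childGT)
  missing <- is.na(f) | is.na(m) | is.na(s)
  keep <- !missing & f == "0/0" & m == "0/0" & s %in% c("0/1", "1/1")
  out <- rec[keep, , drop = FALSE]
  if (nrow(out)) {
    out$childHomAlt <- .normGT(out$childGT) == "1/1"
  }
  log <- callset@skipLog
  nmiss <- sum(missing)
  if (nmiss > 0L) {
    log["missing_genotype"] <- nmiss +
      if ("missing_genotype" %in% names(log)) log[["missing_genotype"]] else 0L
  }
  x <- .withRecords(callset, out)
  x@skipLog <- .asSkipLog(log)
  x
}
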