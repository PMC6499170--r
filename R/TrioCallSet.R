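#' Construct a TrioCallSet
#'
#' Normalises chromosome labels ("chr1" and "1" dialects both accepted,
#' stored unprefixed), coerces column types, sorts records by numeric
#' chromosome then position, and validates the object.  Duplicate
#' (chrom, pos, ref, alt) keys are an error.
#'
#' @param name pipeline label.
#' @param records data.frame with the core columns documented in
#'   \linkS4class{TrioCallSet}; a zero-row or missing table yields an
#'   empty set.
#' @param provenance optional source path.
#' @param skipLog named integer vector of skip counts.
#' @return A \linkS4class{TrioCallSet}.
#' @examples
#' cs <- TrioCallSet("toy", exampleRecords(
#'   chrom = "1", pos = 100L, ref = "A", alt = "G",
#'   fatherGT = "0/0", motherGT = "0/0", childGT = "0/1"
#' ))
#' length(cs)
#' @export
TrioCallSet <- function(name, records = NULL, provenance = NA_character_,
                        skipLog = integer()) {
  if (is.null(records) || nrow(records) == 0L) {
    records <- emptyRecords()
  } else {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    records$chrom <- .normChrom(records$chrom)
    records$pos <- as.integer(records$pos)
    records$ref <- toupper(as.character(records$ref))
    records$alt <- toupper(as.character(records$alt))
    for (col in grep("(Depth|GQ)$", CORE_COLUMNS, value = TRUE)) {
      records[[col]] <- as.integer(records[[col]])
    }
    key <- .variantKey(records$chrom, records$pos, records$ref, records$alt)
    if (anyDuplicated(key)) {
      stop("duplicate variant keys in records: ",
        paste(unique(key[duplicated(key)]), collapse = ", "))
    }
    records <- records[order(.chromOrder(records$chrom), records$pos), ,
      drop = FALSE]
    rownames(records) <- NULL
  }
  new("TrioCallSet",
    name = as.character(name), records = records,
    provenance = as.character(provenance),
    skipLog = .asSkipLog(skipLog))
}

.asSkipLog <- function(x) stats::setNames(as.integer(x), names(x))

#' Empty records table with the canonical columns
#' @return zero-row data.frame with the core TrioCallSet columns.
#' @export
emptyRecords <- function() {
  data.frame(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    fatherGT = character(), motherGT = character(), childGT = character(),
    fatherRefDepth = integer(), fatherAltDepth = integer(),
    motherRefDepth = integer(), motherAltDepth = integer(),
    childRefDepth = integer(), childAltDepth = integer(),
    fatherGQ = integer(), motherGQ = integer(), childGQ = integer(),
    stringsAsFactors = FALSE
  )
}

#' Build a records table from (possibly recycled) field vectors
#'
#' Convenience constructor used in examples and tests: fills GT with
#' "0/0" (parents) / "0/1" (child), depths with 20/0 (parents) and 10/10
#' (child) and GQ with 99 unless overridden.
#'
#' @param chrom,pos,ref,alt variant coordinates and alleles.
#' @param ... any core column to override (e.g. \code{childGT = "1/1"}).
#' @return data.frame suitable for \code{\link{TrioCallSet}}.
#' @export
exampleRecords <- function(chrom, pos, ref, alt, ...) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  rec <- data.frame(
    chrom = rep_len(as.character(chrom), n), pos = rep_len(as.integer(pos), n),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    fatherGT = "0/0", motherGT = "0/0", childGT = "0/1",
    fatherRefDepth = 20L, fatherAltDepth = 0L,
    motherRefDepth = 20L, motherAltDepth = 0L,
    childRefDepth = 10L, childAltDepth = 10L,
    fatherGQ = 99L, motherGQ = 99L, childGQ = 99L,
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) {
    rec[[nm]] <- rep_len(dots[[nm]], n)
  }
  rec
}

#' @describeIn TrioCallSet-accessors pipeline label.
#' @export
setMethod("callsetName", "TrioCallSet", function(x) x@name)

#' Accessors for TrioCallSet and friends
#'
#' @param x a \linkS4class{TrioCallSet}.
#' @name TrioCallSet-accessors
#' @aliases records provenance skipLog variantKeys callsetName
NULL

#' @describeIn TrioCallSet-accessors records table (data.frame copy).
#' @export
setMethod("records", "TrioCallSet", function(x) x@records)

#' @describeIn TrioCallSet-accessors source path or NA.
#' @export
setMethod("provenance", "TrioCallSet", function(x) x@provenance)

#' @describeIn TrioCallSet-accessors named skip counts.
#' @export
setMethod("skipLog", "TrioCallSet", function(x) x@skipLog)

#' @describeIn TrioCallSet-accessors "chrom:pos:ref:alt" keys.
#' @export
setMethod("variantKeys", "TrioCallSet", function(x) {
  rec <- x@records
  if (nrow(rec) == 0L) return(character())
  .variantKey(rec$chrom, rec$pos, rec$ref, rec$alt)
})

#' @describeIn TrioCallSet-accessors number of records.
#' @export
setMethod("length", "TrioCallSet", function(x) nrow(x@records))

#' Subset a TrioCallSet by record index
#' @param x a TrioCallSet; @param i integer or logical index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "TrioCallSet", function(x, i, j, ..., drop = FALSE) {
  rec <- x@records[i, , drop = FALSE]
  rownames(rec) <- NULL
  methods::initialize(x, records = rec)
})

#' Compact display of a TrioCallSet
#' @param object a TrioCallSet.
#' @return invisible NULL.
#' @export
setMethod("show", "TrioCallSet", function(object) {
  rec <- object@records
  cat("TrioCallSet '", object@name, "': ", nrow(rec), " SNV record(s)\n",
    sep = "")
  if (nrow(rec)) {
    cat("  chromosomes: ", paste(unique(rec$chrom), collapse = ", "), "\n",
      sep = "")
    extra <- setdiff(names(rec), CORE_COLUMNS)
    if (length(extra)) {
      cat("  annotations: ", paste(extra, collapse = ", "), "\n", sep = "")
    }
  }
  if (length(object@skipLog)) {
    cat("  skipped: ",
      paste(names(object@skipLog), object@skipLog, sep = "=", collapse = ", "),
      "\n", sep = "")
  }
  invisible(NULL)
})

## replace the records table, preserving name/provenance; internal
.withRecords <- function(x, rec) {
  rownames(rec) <- NULL
  methods::initialize(x, records = rec)
}
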