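#' @import methods
#' @importFrom stats approx aggregate as.formula coef complete.cases cor lm
#'   median na.omit p.adjust pchisq pnorm predict pt quantile rbinom rnorm
#'   rpois runif sd setNames t.test var wilcox.test qnorm glm binomial
#' @importFrom utils head read.csv read.delim write.csv combn packageVersion
#' @useDynLib StackScreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Compound activity library
#'
#' Ordered collection of compound records: identifier, canonical SMILES,
#' potency (IC50 in nM, possibly censored or missing), the derived pIC50
#' and the compound's role in the screen (inhibitor, decoy or screening).
#' The \code{records} slot is a data.frame with one row per compound and at
#' least the columns \code{compound_id}, \code{smiles}, \code{ic50_nM},
#' \code{qualifier}, \code{pic50}, \code{role}; pIC50 is present exactly for
#' records whose qualifier is \code{"exact"} and satisfies
#' pIC50 = 9 - log10(IC50[nM]).
#'
#' @slot records data.frame of compound records.
#' @slot name single character, library name.
#' @slot metadata list of provenance information (raw row count, merged
#'   identifiers, skipped molecules, ...).
#' @export
setClass("CompoundLibrary",
  representation(records = "data.frame", name = "character", metadata = "list"),
  prototype(records = data.frame(), name = "library", metadata = list())
)

.validCompoundLibrary <- function(object) {
  msgs <- character()
  rec <- object@records
  req <- c("compound_id", "smiles", "ic50_nM", "qualifier", "pic50", "role")
  miss <- setdiff(req, colnames(rec))
  if (length(miss) > 0L) {
    msgs <- c(msgs, paste("missing record columns:", paste(miss, collapse = ", ")))
  } else if (nrow(rec) > 0L) {
    if (anyDuplicated(rec$compound_id)) {
      msgs <- c(msgs, "compound_id values must be unique")
    }
    if (!all(rec$qualifier %in% c("exact", "censored", "missing"))) {
      msgs <- c(msgs, "qualifier must be one of exact/censored/missing")
    }
    if (!all(rec$role %in% c("inhibitor", "decoy", "screening"))) {
      msgs <- c(msgs, "role must be one of inhibitor/decoy/screening")
    }
    ex <- rec$qualifier == "exact"
    if (any(ex & (is.na(rec$ic50_nM) | is.na(rec$pic50)))) {
      msgs <- c(msgs, "exact records must carry ic50_nM and pic50")
    }
    if (any(!ex & !is.na(rec$pic50))) {
      msgs <- c(msgs, "pIC50 must be absent unless qualifier is exact")
    }
    ok <- ex & !is.na(rec$ic50_nM)
    if (any(ok)) {
      if (any(rec$ic50_nM[ok] <= 0)) msgs <- c(msgs, "ic50_nM must be positive")
      dev <- abs(rec$pic50[ok] - (9 - log10(rec$ic50_nM[ok])))
      if (any(dev > 1e-9)) msgs <- c(msgs, "pIC50 inconsistent with ic50_nM")
    }
  }
  if (length(object@name) != 1L) msgs <- c(msgs, "name must be a single string")
  if (length(msgs) == 0L) TRUE else msgs
}
setValidity("CompoundLibrary", .validCompoundLibrary)

#' Construct a CompoundLibrary from a record data.frame
#'
#' @param records data.frame with columns \code{compound_id}, \code{smiles},
#'   \code{ic50_nM}, \code{qualifier}, \code{pic50}, \code{role} (extra
#'   columns are retained).
#' @param name library name.
#' @param metadata provenance list.
#' @return A \linkS4class{CompoundLibrary}.
#' @export
CompoundLibrary <- function(records, name = "library", metadata = list()) {
  new("CompoundLibrary", records = records, name = name, metadata = metadata)
}

#' Pattern-count fingerprint matrix
#'
#' Non-negative integer counts of pharmacophore fingerprint pattern tokens,
#' one row per compound, one column per pattern in the vocabulary (ordered by
#' first appearance, then lexicographically).
#'
#' @slot counts integer matrix, compounds x patterns, with dimnames.
#' @export
setClass("PatternCountMatrix", representation(counts = "matrix"))

setValidity("PatternCountMatrix", function(object) {
  m <- object@counts
  msgs <- character()
  if (is.null(rownames(m)) && nrow(m) > 0L) msgs <- c(msgs, "counts need rownames (compound ids)")
  if (length(m) > 0L && (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))) {
    msgs <- c(msgs, "counts must be non-negative integers")
  }
  if (length(msgs) == 0L) TRUE else msgs
})

#' Binary interaction-fingerprint matrix
#'
#' Presence/absence of a specific interaction type with a specific binding
#' site residue, one row per ligand. Column names are canonical feature keys
#' \code{"<residue>:<type>"}, sorted by residue number then interaction type.
#'
#' @slot fp binary (0/1) matrix, ligands x interaction features.
#' @slot reference named binary vector over the same features: the
#'   co-crystallised reference ligand fingerprint (may be empty).
#' @export
setClass("IFPMatrix", representation(fp = "matrix", reference = "numeric"))

setValidity("IFPMatrix", function(object) {
  m <- object@fp
  msgs <- character()
  if (length(m) > 0L && !all(m %in% c(0, 1))) msgs <- c(msgs, "fingerprint entries must be 0/1")
  if (length(object@reference) > 0L) {
    if (!identical(names(object@reference), colnames(m))) {
      msgs <- c(msgs, "reference fingerprint must share the feature universe")
    }
    if (!all(object@reference %in% c(0, 1))) msgs <- c(msgs, "reference entries must be 0/1")
  }
  if (length(msgs) == 0L) TRUE else msgs
})

#' @describeIn CompoundLibrary number of compounds
#' @param x,object a \code{CompoundLibrary}
#' @export
setMethod("length", "CompoundLibrary", function(x) nrow(x@records))

#' Library record accessors
#'
#' @param x a \linkS4class{CompoundLibrary}
#' @return \code{libraryRecords} returns the record data.frame;
#'   \code{libraryName} the library name; \code{libraryMetadata} the
#'   provenance list.
#' @export
libraryRecords <- function(x) {
  stopifnot(is(x, "CompoundLibrary"))
  x@records
}

#' @rdname libraryRecords
#' @export
libraryName <- function(x) x@name

#' @rdname libraryRecords
#' @export
libraryMetadata <- function(x) x@metadata

#' @describeIn PatternCountMatrix the count matrix
#' @param x a \code{PatternCountMatrix}
#' @export
patternCounts <- function(x) {
  stopifnot(is(x, "PatternCountMatrix"))
  x@counts
}

#' @describeIn PatternCountMatrix the ordered pattern vocabulary
#' @export
patternVocabulary <- function(x) colnames(patternCounts(x))

#' @describeIn IFPMatrix the binary fingerprint matrix
#' @param x an \code{IFPMatrix}
#' @export
ifpFingerprints <- function(x) {
  stopifnot(is(x, "IFPMatrix"))
  x@fp
}

#' @describeIn IFPMatrix the reference ligand fingerprint
#' @export
ifpReference <- function(x) x@reference

setMethod("show", "CompoundLibrary", function(object) {
  rec <- object@records
  cat("CompoundLibrary '", object@name, "' with ", nrow(rec), " compounds\n", sep = "")
  if (nrow(rec) > 0L) {
    cat("  qualifiers:",
        paste(sprintf("%s=%d", names(table(rec$qualifier)), table(rec$qualifier)),
              collapse = " "), "\n")
    cat("  roles:",
        paste(sprintf("%s=%d", names(table(rec$role)), table(rec$role)),
              collapse = " "), "\n")
  }
  invisible(object)
})

setMethod("show", "PatternCountMatrix", function(object) {
  cat("PatternCountMatrix:", nrow(object@counts), "compounds x",
      ncol(object@counts), "patterns\n")
  invisible(object)
})

setMethod("show", "IFPMatrix", function(object) {
  cat("IFPMatrix:", nrow(object@fp), "ligands x", ncol(object@fp),
      "interaction features;",
      if (length(object@reference)) "reference fingerprint attached" else "no reference",
      "\n")
  invisible(object)
})
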