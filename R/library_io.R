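## Activity-library ingestion: reading, duplicate merging, pIC50 conversion
## and activity labelling.

#' Convert IC50 (nM) to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the IC50 expressed in mol/L;
#' with the IC50 in nanomolar this is \code{9 - log10(ic50_nM)}, so an IC50
#' of 1000 nM corresponds to pIC50 = 6.
#'
#' @param ic50_nM positive numeric vector, IC50 in nM.
#' @return numeric vector of pIC50 values.
#' @export
#' @examples
#' toPIC50(1000)     # 6
#' fromPIC50(6.5)    # ~316.23 nM
toPIC50 <- function(ic50_nM) {
  ic50_nM <- as.numeric(ic50_nM)
  if (any(!is.finite(ic50_nM)) || any(ic50_nM <= 0)) {
    stop("IC50 values must be positive and finite")
  }
  9 - log10(ic50_nM)
}

#' @rdname toPIC50
#' @param pic50 numeric vector of pIC50 values.
#' @export
fromPIC50 <- function(pic50) 10^(9 - as.numeric(pic50))

## Multipliers taking the input concentration unit to nM.
.unitToNanomolar <- c(nM = 1, uM = 1e3, mM = 1e6, M = 1e9)

.parseQualifier <- function(q, value) {
  q <- trimws(as.character(q))
  out <- ifelse(is.na(value), "missing",
         ifelse(is.na(q) | q %in% c("", "=", "exact"), "exact", "censored"))
  bad <- !is.na(q) & !(q %in% c("", "=", "exact", "<", ">", "<=", ">=", "~", "censored", "missing"))
  if (any(bad)) stop("unrecognised potency qualifier: ", paste(unique(q[bad]), collapse = ", "))
  out[!is.na(q) & q == "missing"] <- "missing"
  out
}

#' Load and merge a compound activity library
#'
#' Reads a CSV/TSV activity table (compound id, SMILES, IC50 with optional
#' relation qualifier), canonicalises the SMILES, and merges duplicate
#' molecules (same canonical SMILES). Exact IC50 values of duplicates are
#' averaged arithmetically in concentration space before the log conversion
#' to pIC50; censored or missing potencies are never averaged with exact
#' ones — a merged record is exact only if all its source rows are exact,
#' otherwise it is censored (any censored source) or missing.
#'
#' @param path path to a delimited text file.
#' @param columns named list mapping the roles \code{id}, \code{smiles},
#'   \code{ic50}, \code{qualifier} to column names in the file (the
#'   qualifier column is optional).
#' @param sep field separator ("," or "\\t"); guessed from the file
#'   extension by default.
#' @param unit concentration unit of the IC50 column: \code{"nM"} (default),
#'   \code{"uM"}, \code{"mM"} or \code{"M"}.
#' @param name library name.
#' @param role role assigned to all records (default \code{"inhibitor"}).
#' @return A \linkS4class{CompoundLibrary}; metadata records the raw row
#'   count, merged row count, per-record source ids and any rejected rows.
#' @export
loadActivityLibrary <- function(path,
                                columns = list(id = "compound_id", smiles = "smiles",
                                               ic50 = "ic50", qualifier = "qualifier"),
                                sep = NULL, unit = c("nM", "uM", "mM", "M"),
                                name = basename(path), role = "inhibitor") {
  unit <- match.arg(unit)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("id", "smiles", "ic50")
  if (!all(req %in% names(columns)) || !all(unlist(columns[req]) %in% colnames(raw))) {
    stop("activity table must provide columns for id, smiles and ic50")
  }
  ic50_raw <- suppressWarnings(as.numeric(raw[[columns$ic50]]))
  qual_col <- if (!is.null(columns$qualifier) && columns$qualifier %in% colnames(raw)) {
    raw[[columns$qualifier]]
  } else rep(NA_character_, nrow(raw))
  qualifier <- .parseQualifier(qual_col, ic50_raw)
  bad_ic50 <- !is.na(ic50_raw) & ic50_raw <= 0
  if (any(bad_ic50)) {
    stop("non-positive IC50 in row(s): ", paste(which(bad_ic50), collapse = ", "))
  }
  ic50_nM <- ic50_raw * .unitToNanomolar[[unit]]

  can <- canonicalSmiles(raw[[columns$smiles]])
  rejected <- which(is.na(can))
  if (length(rejected) > 0L) {
    warning(length(rejected), " record(s) rejected: unparsable SMILES (rows ",
            paste(rejected, collapse = ", "), ")")
  }
  keep <- !is.na(can)
  df <- data.frame(compound_id = as.character(raw[[columns$id]])[keep],
                   smiles = can[keep], ic50_nM = ic50_nM[keep],
                   qualifier = qualifier[keep], stringsAsFactors = FALSE)

  merged <- mergeDuplicates(df)
  merged$pic50 <- ifelse(merged$qualifier == "exact", toPIC50_safe(merged$ic50_nM), NA_real_)
  merged$role <- role
  CompoundLibrary(
    records = merged, name = name,
    metadata = list(raw_rows = nrow(raw), merged_rows = nrow(merged),
                    rejected_rows = rejected, unit = unit)
  )
}

## toPIC50 that passes NA through (merged censored/missing records).
toPIC50_safe <- function(x) ifelse(is.na(x), NA_real_, 9 - log10(x))

## Merge rows sharing a canonical SMILES. Exact potencies are averaged in
## concentration space; a merged record is exact only if every source row is.
mergeDuplicates <- function(df) {
  split_idx <- split(seq_len(nrow(df)), factor(df$smiles, levels = unique(df$smiles)))
  rows <- lapply(split_idx, function(idx) {
    sub <- df[idx, , drop = FALSE]
    quals <- sub$qualifier
    if (all(quals == "exact")) {
      qual <- "exact"
      ic50 <- mean(sub$ic50_nM)
    } else if (any(quals == "censored")) {
      qual <- "censored"
      ic50 <- NA_real_
    } else {
      qual <- "missing"
      ic50 <- NA_real_
    }
    data.frame(compound_id = sub$compound_id[1L], smiles = sub$smiles[1L],
               ic50_nM = ic50, qualifier = qual,
               source_ids = paste(unique(sub$compound_id), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign binary activity labels
#'
#' Labels exact records active when pIC50 meets the threshold (default 6,
#' i.e. IC50 at or below 1000 nM). Censored and missing potencies are
#' labelled inactive under the default policy, or dropped.
#'
#' @param library a \linkS4class{CompoundLibrary}.
#' @param threshold_pic50 activity threshold on the pIC50 scale (default 6).
#' @param censored_policy \code{"inactive"} (default) or \code{"drop"}.
#' @return The library with a \code{label} column (1 active / 0 inactive)
#'   added to its records; original potencies untouched.
#' @export
assignActivityLabels <- function(library, threshold_pic50 = 6,
                                 censored_policy = c("inactive", "drop")) {
  censored_policy <- match.arg(censored_policy)
  stopifnot(is.finite(threshold_pic50))
  rec <- libraryRecords(library)
  inexact <- rec$qualifier != "exact"
  if (censored_policy == "drop") {
    rec <- rec[!inexact, , drop = FALSE]
    inexact <- rep(FALSE, nrow(rec))
  }
  rec$label <- ifelse(inexact, 0L, as.integer(rec$pic50 >= threshold_pic50))
  CompoundLibrary(rec, name = libraryName(library),
                  metadata = c(libraryMetadata(library),
                               list(label_threshold = threshold_pic50)))
}

#' Load a screening library
#'
#' Reads a screening library of molecules with no potency data, from a
#' SMILES table (\code{id<TAB>smiles}, optional \code{status} column for
#' approved/investigational filtering) or an SDF (V2000) file. Unreadable
#' molecules are skipped with a reported count.
#'
#' @param path file path.
#' @param format \code{"smiles-table"} or \code{"sdf"}.
#' @param name library name.
#' @return A \linkS4class{CompoundLibrary} with all roles \code{"screening"}.
#' @export
loadScreeningLibrary <- function(path, format = c("smiles-table", "sdf"),
                                 name = basename(path)) {
  format <- match.arg(format)
  if (format == "smiles-table") {
    info <- file.info(path)
    if (is.na(info$size) || info$size == 0L) {
      warning("empty screening library file: ", path)
      tab <- data.frame(id = character(), smiles = character())
    } else {
      tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
      if (!all(c("id", "smiles") %in% tolower(colnames(tab)))) {
        # headerless two-column dialect
        tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
        colnames(tab)[1:2] <- c("id", "smiles")
      }
      colnames(tab) <- tolower(colnames(tab))
    }
    ids <- as.character(tab$id)
    can <- canonicalSmiles(tab$smiles)
    skipped <- sum(is.na(can))
    status <- if ("status" %in% colnames(tab)) as.character(tab$status)[!is.na(can)] else NULL
    keep <- !is.na(can)
    rec <- data.frame(compound_id = ids[keep], smiles = can[keep],
                      ic50_nM = NA_real_, qualifier = "missing",
                      pic50 = NA_real_, role = "screening",
                      stringsAsFactors = FALSE)
    if (!is.null(status)) rec$status <- status
  } else {
    sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                       error = function(e) new("SDFset"))
    n_total <- length(sdfset)
    ok <- if (n_total > 0L) ChemmineR::validSDF(sdfset) else logical(0)
    sdfset <- sdfset[ok]
    skipped <- n_total - length(sdfset)
    smi <- if (length(sdfset) > 0L) {
      vapply(seq_along(sdfset), function(i) {
        tryCatch(trimws(sub("\t.*$", "",
          ChemmineOB::convertFormat("SDF", "CAN", source = ChemmineR::sdf2str(sdfset[[i]], sep = "\n")))),
          error = function(e) NA_character_)
      }, character(1))
    } else character(0)
    ids <- if (length(sdfset) > 0L) ChemmineR::sdfid(sdfset) else character(0)
    keep <- !is.na(smi)
    skipped <- skipped + sum(!keep)
    rec <- data.frame(compound_id = as.character(ids)[keep], smiles = smi[keep],
                      ic50_nM = NA_real_, qualifier = "missing",
                      pic50 = NA_real_, role = "screening",
                      stringsAsFactors = FALSE)
  }
  if (nrow(rec) == 0L && format == "smiles-table" && length(tab$id) > 0L) {
    warning("no parseable molecules in ", path)
  }
  if (exists("skipped") && skipped > 0L) {
    warning(skipped, " molecule(s) skipped while reading ", path)
  }
  if (nrow(rec) > 0L && anyDuplicated(rec$compound_id)) {
    rec <- rec[!duplicated(rec$compound_id), , drop = FALSE]
  }
  CompoundLibrary(rec, name = name,
                  metadata = list(skipped = if (exists("skipped")) skipped else 0L))
}
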