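## Scaffold analysis: most-central-ring (MCR) extraction, group statistics
## (Mann-Whitney, chi-square residuals, enrichment factors) and one-hot
## scaffold features.

## Minimal V2000 molblock writer for ring-system fragments.
.molblock <- function(elements, coords, bonds) {
  n_a <- length(elements); n_b <- nrow(bonds)
  head <- c("fragment", "  StackScreen", "",
            sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_a, n_b))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   coords[, 1], coords[, 2], coords[, 3], elements)
  bl <- if (n_b > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds[, 1], bonds[, 2], bonds[, 3])
  } else character(0)
  paste(c(head, atoms, bl, "M  END", "$$$$"), collapse = "\n")
}

## Ring perception on one ChemmineR SDF: returns a list of ring systems,
## each an integer vector of atom indices, plus the full bond table.
.ringSystems <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  atom_names <- rownames(ab)
  n <- nrow(ab)
  if (n == 0L) stop("empty molecule")
  bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, 1:2]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  # a bond is a ring bond iff it lies on some cycle, i.e. is not a bridge
  bridges <- igraph::bridges(g)
  ring_bond <- rep(TRUE, nrow(bonds))
  if (length(bridges) > 0L) {
    be <- igraph::ends(g, bridges)
    for (k in seq_len(nrow(be))) {
      ring_bond[(bonds$a1 == be[k, 1] & bonds$a2 == be[k, 2]) |
                (bonds$a1 == be[k, 2] & bonds$a2 == be[k, 1])] <- FALSE
    }
  }
  if (!any(ring_bond)) return(list(systems = list(), bonds = bonds, graph = g,
                                   atom_names = atom_names, atomblock = ab))
  rg <- igraph::subgraph_from_edges(
    g, which(ring_bond), delete.vertices = FALSE)
  comp <- igraph::components(rg)
  ring_atoms <- which(igraph::degree(rg) > 0)
  systems <- split(ring_atoms, comp$membership[ring_atoms])
  systems <- unname(systems[vapply(systems, length, 1L) >= 3L])
  list(systems = systems, bonds = bonds, graph = g,
       atom_names = atom_names, atomblock = ab)
}

## Canonical SMILES key of a ring-system fragment.
.ringSystemKey <- function(info, atoms) {
  ab <- info$atomblock
  elems <- sub("_.*$", "", info$atom_names[atoms])
  coords <- ab[atoms, 1:3, drop = FALSE]
  sel <- info$bonds$a1 %in% atoms & info$bonds$a2 %in% atoms
  bsub <- info$bonds[sel, , drop = FALSE]
  remap <- match(c(bsub$a1, bsub$a2), atoms)
  bonds <- cbind(remap[seq_len(nrow(bsub))],
                 remap[nrow(bsub) + seq_len(nrow(bsub))], bsub$order)
  mol <- .molblock(elems, coords, bonds)
  key <- tryCatch(
    trimws(sub("\t.*$", "", ChemmineOB::convertFormat("SDF", "CAN", source = mol))),
    error = function(e) ""
  )
  if (!nzchar(key)) key <- paste0(sort(elems), collapse = "")  # fallback key
  key
}

#' Extract the most central ring system of a molecule
#'
#' Documented stand-in for proprietary most-central-ring fragmentation:
#' fused/spiro ring systems form the nodes of a reduced graph whose
#' inter-node distances are shortest bond paths in the molecular graph; the
#' ring system with minimum eccentricity in that graph is returned as a
#' canonical SMILES key. Ties are broken by fewer atoms, then by the
#' lexicographically smaller key. Acyclic molecules return \code{NA}.
#'
#' @param smiles a single SMILES string.
#' @return canonical SMILES of the most central ring system, or \code{NA}
#'   for acyclic molecules.
#' @export
#' @examples
#' extractMostCentralRing("Cc1ccccc1")  # benzene key
#' extractMostCentralRing("CCCCCC")     # NA (acyclic)
extractMostCentralRing <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  sdfset <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                     error = function(e) NULL)
  if (is.null(sdfset) || length(sdfset) != 1L ||
      nrow(ChemmineR::atomblock(sdfset[[1]])) == 0L) {
    stop("invalid SMILES: ", smiles)
  }
  info <- .ringSystems(sdfset[[1]])
  systems <- info$systems
  if (length(systems) == 0L) return(NA_character_)
  if (length(systems) == 1L) return(.ringSystemKey(info, systems[[1]]))
  d_atom <- igraph::distances(info$graph)
  n_sys <- length(systems)
  d_sys <- matrix(0, n_sys, n_sys)
  for (i in seq_len(n_sys - 1L)) {
    for (j in (i + 1L):n_sys) {
      d_sys[i, j] <- d_sys[j, i] <-
        min(d_atom[systems[[i]], systems[[j]], drop = FALSE])
    }
  }
  ecc <- apply(d_sys, 1, max)
  cand <- which(ecc == min(ecc))
  if (length(cand) > 1L) {
    sizes <- vapply(systems[cand], length, 1L)
    cand <- cand[sizes == min(sizes)]
  }
  keys <- vapply(cand, function(i) .ringSystemKey(info, systems[[i]]), character(1))
  sort(keys)[1L]
}

#' Assign MCR scaffolds to a compound library
#'
#' Runs \code{\link{extractMostCentralRing}} over the library, or accepts an
#' externally supplied assignment table (compound_id, scaffold_id), which
#' overrides extraction (reference MCR implementations are proprietary, so
#' external assignments must be importable).
#'
#' @param library a \linkS4class{CompoundLibrary}.
#' @param external optional data.frame with columns \code{compound_id},
#'   \code{scaffold_id}.
#' @return data.frame with \code{compound_id}, \code{scaffold_id}
#'   (\code{NA} for acyclic molecules).
#' @export
scaffoldAssignments <- function(library, external = NULL) {
  rec <- libraryRecords(library)
  if (!is.null(external)) {
    stopifnot(all(c("compound_id", "scaffold_id") %in% colnames(external)))
    idx <- match(rec$compound_id, external$compound_id)
    return(data.frame(compound_id = rec$compound_id,
                      scaffold_id = as.character(external$scaffold_id)[idx],
                      stringsAsFactors = FALSE))
  }
  keys <- vapply(rec$smiles, function(s) {
    tryCatch(extractMostCentralRing(s), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  data.frame(compound_id = rec$compound_id, scaffold_id = keys,
             stringsAsFactors = FALSE)
}

#' Group scaffold assignments for analysis
#'
#' Applies a bioisostere merge map, then excludes groups below
#' \code{min_count} from the statistics (their compounds are retained,
#' flagged unscaffolded). Acyclic/unassigned compounds are always flagged
#' unscaffolded.
#'
#' @param assignments data.frame (compound_id, scaffold_id).
#' @param min_count minimum group size to enter the statistics (default 2,
#'   excluding singleton scaffolds).
#' @param merge_map named character vector mapping scaffold ids to merged
#'   group ids; referencing an unknown scaffold id is an error.
#' @return data.frame with \code{compound_id}, \code{scaffold_id},
#'   \code{group_id}, \code{analyzed} (logical).
#' @export
groupScaffolds <- function(assignments, min_count = 2L, merge_map = character(0)) {
  stopifnot(min_count >= 1L)
  group <- assignments$scaffold_id
  if (length(merge_map) > 0L) {
    unknown <- setdiff(names(merge_map), unique(na.omit(group)))
    if (length(unknown) > 0L) {
      stop("merge map references unknown scaffold id(s): ",
           paste(unknown, collapse = ", "))
    }
    hit <- group %in% names(merge_map)
    group[hit] <- unname(merge_map[group[hit]])
  }
  counts <- table(group)
  analyzed <- !is.na(group) & counts[group] >= min_count
  analyzed[is.na(analyzed)] <- FALSE
  data.frame(compound_id = assignments$compound_id,
             scaffold_id = assignments$scaffold_id,
             group_id = group, analyzed = as.logical(analyzed),
             stringsAsFactors = FALSE)
}

#' Scaffold enrichment factor
#'
#' Ratio of a scaffold's frequency among potent compounds to its frequency
#' in the whole analysed set: EF = (n_s_potent/N_potent)/(n_s/N).
#'
#' @param n_s_potent potent compounds carrying the scaffold.
#' @param N_potent all potent compounds.
#' @param n_s compounds carrying the scaffold.
#' @param N all compounds.
#' @return non-negative enrichment factor.
#' @export
enrichmentFactor <- function(n_s_potent, N_potent, n_s, N) {
  if (N_potent <= 0 || n_s <= 0 || N <= 0) {
    stop("enrichment factor requires positive N_potent, n_s and N")
  }
  (n_s_potent / N_potent) / (n_s / N)
}

#' Per-scaffold potency association statistics
#'
#' For each analysed scaffold group: size, potent count (pIC50 at or above
#' \code{potency_cutoff}), mean pIC50, Mann-Whitney U test of the group's
#' pIC50 distribution against all other analysed groups combined,
#' standardized residual of the group's potent cell in the groups x
#' {potent, weak} chi-square table, enrichment factor, and the relevance
#' flag of \code{\link{selectRelevantScaffolds}}.
#'
#' @param grouped output of \code{\link{groupScaffolds}}.
#' @param pic50 numeric pIC50 per compound, aligned with \code{grouped};
#'   compounds with missing pIC50 are excluded.
#' @param potency_cutoff potent/weak split on the pIC50 scale (default 6.5).
#' @param alpha Mann-Whitney significance level (default 0.05).
#' @param residual_cutoff standardized-residual significance cutoff (1.96).
#' @return list with \code{summary} (one row per analysed group),
#'   \code{chi_square} (full test object) and the inputs used.
#' @export
scaffoldSummaries <- function(grouped, pic50, potency_cutoff = 6.5,
                              alpha = 0.05, residual_cutoff = 1.96) {
  stopifnot(nrow(grouped) == length(pic50))
  keep <- grouped$analyzed & !is.na(pic50)
  g <- grouped$group_id[keep]
  p <- pic50[keep]
  if (length(unique(g)) < 2L) stop("need at least two analysed scaffold groups")
  potent <- p >= potency_cutoff
  N <- length(p); N_potent <- sum(potent)
  if (N_potent == 0L || N_potent == N) {
    stop("potency cutoff leaves an empty potent or weak class")
  }
  groups <- sort(unique(g))
  O <- t(vapply(groups, function(s) {
    c(potent = sum(potent[g == s]), weak = sum(!potent[g == s]))
  }, numeric(2)))
  rownames(O) <- groups
  chi <- chiSquareTable(O, residual_cutoff = residual_cutoff)
  rows <- lapply(groups, function(s) {
    inn <- p[g == s]; out <- p[g != s]
    mw <- mannWhitneyU(inn, out)
    data.frame(
      scaffold_id = s, n = length(inn), n_potent = sum(potent[g == s]),
      mean_pic50 = mean(inn), mean_out = mean(out),
      mw_U = mw$U, mw_p = mw$p,
      std_residual = chi$std_residual[s, "potent"],
      EF = enrichmentFactor(sum(potent[g == s]), N_potent, length(inn), N),
      stringsAsFactors = FALSE
    )
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  summary <- selectRelevantScaffolds(summary, alpha = alpha,
                                     residual_cutoff = residual_cutoff)
  list(summary = summary, chi_square = chi, N = N, N_potent = N_potent,
       potency_cutoff = potency_cutoff)
}

#' Flag scaffolds relevant for potency
#'
#' A scaffold is relevant when its enrichment factor exceeds 1 AND it shows
#' statistically higher potency via either route: Mann-Whitney p below
#' \code{alpha} with a higher in-group mean, or a standardized residual
#' above \code{residual_cutoff} in the potent column. Both routes are
#' recorded.
#'
#' @param summary data.frame with columns \code{EF}, \code{mw_p},
#'   \code{mean_pic50}, \code{mean_out}, \code{std_residual}.
#' @param alpha significance level (default 0.05).
#' @param residual_cutoff residual cutoff (default 1.96).
#' @return the summary with logical columns \code{sig_mw}, \code{sig_residual},
#'   \code{relevant} appended.
#' @export
selectRelevantScaffolds <- function(summary, alpha = 0.05, residual_cutoff = 1.96) {
  summary$sig_mw <- summary$mw_p < alpha & summary$mean_pic50 > summary$mean_out
  summary$sig_residual <- summary$std_residual > residual_cutoff
  summary$relevant <- summary$EF > 1 & (summary$sig_mw | summary$sig_residual)
  summary
}

#' One-hot encode relevant scaffolds
#'
#' Binary matrix with one column per relevant scaffold group; a cell is 1
#' iff the compound's group equals that scaffold. Compounds outside every
#' relevant scaffold (including acyclic molecules) get an all-zero row, so
#' row sums are always 0 or 1.
#'
#' @param grouped output of \code{\link{groupScaffolds}}.
#' @param relevant_ids scaffold group ids to encode; must be known groups.
#' @return binary matrix, compounds x relevant scaffolds, with dimnames.
#' @export
oneHotScaffolds <- function(grouped, relevant_ids) {
  known <- unique(na.omit(grouped$group_id))
  if (!all(relevant_ids %in% known)) {
    stop("unknown scaffold id(s): ",
         paste(setdiff(relevant_ids, known), collapse = ", "))
  }
  m <- vapply(relevant_ids, function(s) {
    as.numeric(!is.na(grouped$group_id) & grouped$group_id == s)
  }, numeric(nrow(grouped)))
  m <- matrix(m, nrow = nrow(grouped),
              dimnames = list(grouped$compound_id, relevant_ids))
  m
}
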