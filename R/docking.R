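## Post-docking analysis: interaction fingerprints from report tables,
## reference-ligand Tanimoto comparison, screening metrics on binding
## energies, consensus interaction-feature selection, and the MLP rescorer.

.interactionTypes <- c("hydrophobic", "hbond", "salt_bridge", "pi_stack",
                       "pi_cation", "halogen", "water_bridge")

.featureKey <- function(residue, type) paste0(residue, ":", type)

.sortFeatureKeys <- function(keys) {
  res <- sub(":.*$", "", keys)
  num <- as.integer(sub("^[A-Za-z]{3}", "", res))
  type <- sub("^.*:", "", keys)
  keys[order(num, type)]
}

#' Build a binary interaction-fingerprint matrix
#'
#' Converts an interaction report (ligand id, residue, interaction type)
#' into a ligands x features binary matrix. Duplicate records collapse to a
#' single bit; ligands listed in \code{ligand_ids} but absent from the
#' report get all-zero rows with a warning. The feature universe is the
#' union over the report and the reference ligand's interactions, and keys
#' are sorted by residue number then interaction type.
#'
#' @param interactions data.frame with columns \code{ligand_id},
#'   \code{residue} (3-letter code + number, e.g. "Glu161"), \code{type}
#'   (one of hydrophobic, hbond, salt_bridge, pi_stack, pi_cation, halogen,
#'   water_bridge).
#' @param reference optional data.frame (\code{residue}, \code{type}) of
#'   the co-crystallised reference ligand.
#' @param ligand_ids optional full ligand universe (e.g. every ligand in
#'   the energies table).
#' @return An \linkS4class{IFPMatrix}.
#' @export
buildIfpMatrix <- function(interactions, reference = NULL, ligand_ids = NULL) {
  stopifnot(all(c("ligand_id", "residue", "type") %in% colnames(interactions)))
  bad_type <- setdiff(unique(interactions$type), .interactionTypes)
  if (length(bad_type) > 0L) {
    stop("unknown interaction type(s): ", paste(bad_type, collapse = ", "),
         "; allowed: ", paste(.interactionTypes, collapse = ", "))
  }
  bad_res <- unique(c(interactions$residue,
                      if (!is.null(reference)) reference$residue))
  bad_res <- bad_res[!grepl("^[A-Za-z]{3}[0-9]+$", bad_res)]
  if (length(bad_res) > 0L) {
    stop("malformed residue label(s): ", paste(bad_res, collapse = ", "))
  }
  keys <- unique(.featureKey(interactions$residue, interactions$type))
  if (!is.null(reference)) {
    if (length(bad <- setdiff(unique(reference$type), .interactionTypes)) > 0L) {
      stop("unknown interaction type(s) in reference: ", paste(bad, collapse = ", "))
    }
    keys <- unique(c(keys, .featureKey(reference$residue, reference$type)))
  }
  keys <- .sortFeatureKeys(keys)
  ids <- unique(c(as.character(interactions$ligand_id), ligand_ids))
  if (!is.null(ligand_ids)) {
    missing <- setdiff(ligand_ids, unique(interactions$ligand_id))
    if (length(missing) > 0L) {
      warning(length(missing), " ligand(s) without interactions: all-zero rows")
    }
    ids <- ligand_ids
  }
  m <- matrix(0, length(ids), length(keys), dimnames = list(ids, keys))
  hit <- interactions$ligand_id %in% ids
  m[cbind(match(interactions$ligand_id[hit], ids),
          match(.featureKey(interactions$residue[hit], interactions$type[hit]),
                keys))] <- 1
  ref_vec <- setNames(numeric(length(keys)), keys)
  if (!is.null(reference)) {
    ref_vec[.featureKey(reference$residue, reference$type)] <- 1
  }
  new("IFPMatrix", fp = m, reference = if (is.null(reference)) numeric(0) else ref_vec)
}

#' Tanimoto similarity of every ligand to the reference fingerprint
#'
#' Per-ligand binary Tanimoto similarity to the reference (co-crystallised
#' ligand) fingerprint, with mean/median summaries per group (e.g. docking
#' method or activity class) for method comparison: the method whose poses
#' reproduce more reference interactions scores the higher median.
#'
#' @param ifp an \linkS4class{IFPMatrix} carrying a reference fingerprint
#'   (or pass \code{reference} explicitly).
#' @param groups factor/character labels per ligand.
#' @param reference optional binary vector over the same features.
#' @return list with \code{similarity} (named per-ligand vector) and
#'   \code{by_group} (data.frame of group mean/median).
#' @export
referenceSimilaritySummary <- function(ifp, groups, reference = NULL) {
  m <- ifpFingerprints(ifp)
  if (is.null(reference)) reference <- ifpReference(ifp)
  if (length(reference) == 0L) stop("no reference fingerprint available")
  stopifnot(length(reference) == ncol(m), length(groups) == nrow(m))
  sims <- vapply(seq_len(nrow(m)), function(i) {
    suppressWarnings(binaryTanimoto(m[i, ], reference))
  }, numeric(1))
  names(sims) <- rownames(m)
  by_group <- aggregate(sims, by = list(group = groups),
                        FUN = function(v) c(mean = mean(v), median = median(v)))
  by_group <- data.frame(group = by_group$group,
                         mean = by_group$x[, "mean"],
                         median = by_group$x[, "median"])
  list(similarity = sims, by_group = by_group)
}

#' Screening performance of docking energies
#'
#' Ranks compounds by score = -binding energy (strongest binder first) and
#' computes ROC AUC, semilog ROC AUC (\code{\link{logAuc}}), enrichment
#' factors in the top 1\% and 10\%, and two-sided Mann-Whitney and Welch t
#' tests on the active vs inactive energy distributions.
#'
#' @param energies data.frame with \code{ligand_id} and
#'   \code{binding_energy} (kcal/mol; more negative = stronger), optionally
#'   \code{method}.
#' @param labels named 0/1 vector (names = ligand ids) or vector aligned
#'   with the rows.
#' @return data.frame (one row per method) with \code{roc_auc},
#'   \code{log_auc}, \code{ef_1pct}, \code{ef_10pct}, \code{mannwhitney_p},
#'   \code{welch_t_p}.
#' @export
screeningPerformance <- function(energies, labels) {
  if (!is.null(names(labels))) {
    lab <- labels[as.character(energies$ligand_id)]
  } else lab <- labels
  lab <- as.integer(lab)
  if (is.null(energies$method)) energies$method <- "docking"
  rows <- lapply(split(seq_len(nrow(energies)), energies$method), function(idx) {
    sc <- -energies$binding_energy[idx]
    y <- lab[idx]
    if (length(unique(y)) < 2L) stop("both classes required per method")
    ef1 <- if (0.01 * length(y) >= 1) efAtFraction(sc, y, 0.01) else NA_real_
    mw <- mannWhitneyU(energies$binding_energy[idx][y == 1],
                       energies$binding_energy[idx][y == 0])
    tt <- t.test(energies$binding_energy[idx][y == 1],
                 energies$binding_energy[idx][y == 0])
    data.frame(method = energies$method[idx][1],
               roc_auc = rocAuc(sc, y), log_auc = logAuc(sc, y),
               ef_1pct = ef1, ef_10pct = efAtFraction(sc, y, 0.10),
               mannwhitney_p = mw$p, welch_t_p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Consensus interaction-feature selection
#'
#' Ranks interaction features by the chi-square statistic of feature
#' presence against ligand activity and, independently, by seeded
#' random-forest importance; retains the top \code{k} of each and selects
#' the intersection, ordered by chi-square rank. An empty intersection
#' falls back to the union with a provenance flag and warning.
#'
#' @param ifp an \linkS4class{IFPMatrix} (or binary matrix).
#' @param labels 0/1 labels aligned with the rows.
#' @param k per-method cut (default 10).
#' @param seed RNG seed for the forest.
#' @return list with \code{selected} (feature keys), \code{chi_rank},
#'   \code{forest_rank}, \code{fallback_union} (logical).
#' @export
consensusSelect <- function(ifp, labels, k = 10L, seed = 1L) {
  m <- if (is(ifp, "IFPMatrix")) ifpFingerprints(ifp) else as.matrix(ifp)
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  chi_stat <- vapply(seq_len(ncol(m)), function(j) {
    O <- table(factor(m[, j], levels = c(0, 1)), factor(y, levels = c(0, 1)))
    if (any(rowSums(O) == 0) || any(colSums(O) == 0)) return(0)
    chiSquareTable(O)$X2
  }, numeric(1))
  names(chi_stat) <- colnames(m)
  chi_rank <- names(sort(chi_stat, decreasing = TRUE))
  rf <- withSeed(seed, randomForest::randomForest(
    m, factor(y, levels = c(0, 1)), ntree = 500))
  imp <- randomForest::importance(rf)[, 1]
  forest_rank <- names(sort(imp, decreasing = TRUE))
  top_chi <- head(chi_rank, k)
  top_rf <- head(forest_rank, k)
  selected <- top_chi[top_chi %in% top_rf]
  fallback <- FALSE
  if (length(selected) == 0L) {
    warning("empty consensus; falling back to the union of both top-k sets")
    selected <- unique(c(top_chi, top_rf))
    fallback <- TRUE
  }
  list(selected = selected, chi_rank = chi_rank, forest_rank = forest_rank,
       chi_stat = chi_stat, forest_importance = imp, fallback_union = fallback)
}

#' Default MLP hyperparameter grid
#'
#' Exhaustive grid of learning rate {0.001, 0.01, 0.05, 0.1} x batch size
#' {8, 16, 32, 64} x dropout rate {0.1, 0.2, 0.3, 0.4}: 64 combinations.
#'
#' @return data.frame with columns \code{lr}, \code{batch}, \code{dropout}.
#' @export
mlpGrid <- function() {
  expand.grid(lr = c(0.001, 0.01, 0.05, 0.1), batch = c(8L, 16L, 32L, 64L),
              dropout = c(0.1, 0.2, 0.3, 0.4), KEEP.OUT.ATTRS = FALSE)
}

## Assemble the MLP input matrix: standardized energy first, then bits.
.mlpInputs <- function(energy, bits, energy_center = NULL, energy_scale = NULL) {
  if (is.null(energy_center)) energy_center <- mean(energy)
  if (is.null(energy_scale)) {
    energy_scale <- sd(energy)
    if (!is.finite(energy_scale) || energy_scale == 0) energy_scale <- 1
  }
  X <- cbind(energy = (energy - energy_center) / energy_scale, as.matrix(bits))
  attr(X, "energy_center") <- energy_center
  attr(X, "energy_scale") <- energy_scale
  X
}

#' Train the interaction-fingerprint MLP rescorer
#'
#' Fixed architecture input -> 32 (ReLU) -> dropout -> 16 (ReLU) -> dropout
#' -> 1 (sigmoid), trained with Adam on weighted binary cross-entropy
#' (positive-class weight = n_negative/n_positive). Gaussian noise of sd
#' 0.01 is injected into the standardized binding-energy input during
#' training only. Every grid combination is evaluated by stratified
#' 10-fold cross-validation (pooled out-of-fold probabilities); the best
#' combination by mean CV ROC AUC is refitted on the full data.
#'
#' @param energy numeric binding energies (kcal/mol).
#' @param bits binary matrix of selected interaction features.
#' @param labels 0/1 labels.
#' @param grid hyperparameter grid (default \code{\link{mlpGrid}}).
#' @param folds CV folds (default 10).
#' @param seed RNG seed.
#' @param epochs maximum epochs (default 200).
#' @param patience early-stopping patience on validation loss (default 20).
#' @param noise_sd train-time Gaussian noise sd on the energy input (0.01).
#' @return list with \code{cv} (per-combination mean CV AUC), \code{best}
#'   (chosen hyperparameters), \code{model} (weights + scalers), and
#'   \code{cv_auc} of the best combination.
#' @export
trainMLP <- function(energy, bits, labels, grid = mlpGrid(), folds = 10L,
                     seed = 1L, epochs = 200L, patience = 20L,
                     noise_sd = 0.01) {
  y <- as.integer(labels)
  bits <- as.matrix(bits)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  pos_weight <- sum(y == 0L) / sum(y == 1L)
  cv_auc <- numeric(nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    fold <- stratifiedFolds(y, folds, subSeed(seed, gidx))
    prob <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- fold != f
      Xtr <- .mlpInputs(energy[tr], bits[tr, , drop = FALSE])
      Xte <- .mlpInputs(energy[!tr], bits[!tr, , drop = FALSE],
                        attr(Xtr, "energy_center"), attr(Xtr, "energy_scale"))
      w <- withSeed(subSeed(seed, gidx * 100L + f), {
        mlp_fit(Xtr, y[tr], grid$lr[gidx], as.integer(grid$batch[gidx]),
                grid$dropout[gidx], as.integer(epochs), as.integer(patience),
                pos_weight, noise_sd, 0L, 0.1)
      })
      prob[!tr] <- as.numeric(mlp_forward(w, Xte))
    }
    cv_auc[gidx] <- rocAuc(prob, y)
  }
  best_idx <- which.max(cv_auc)
  Xall <- .mlpInputs(energy, bits)
  w_best <- withSeed(subSeed(seed, 999983L), {
    mlp_fit(Xall, y, grid$lr[best_idx], as.integer(grid$batch[best_idx]),
            grid$dropout[best_idx], as.integer(epochs), as.integer(patience),
            pos_weight, noise_sd, 0L, 0.1)
  })
  model <- list(weights = w_best,
                energy_center = attr(Xall, "energy_center"),
                energy_scale = attr(Xall, "energy_scale"),
                features = colnames(bits), pos_weight = pos_weight,
                hyper = grid[best_idx, , drop = FALSE])
  class(model) <- "stackscreenMLP"
  list(cv = cbind(grid, cv_auc = cv_auc), best = grid[best_idx, , drop = FALSE],
       cv_auc = cv_auc[best_idx], model = model)
}

#' Predict with a trained MLP rescorer
#'
#' Inference is deterministic: dropout and noise injection are train-time
#' only.
#'
#' @param object a \code{"stackscreenMLP"} model from \code{\link{trainMLP}}.
#' @param energy binding energies (kcal/mol).
#' @param bits binary matrix over the model's interaction features.
#' @param ... unused.
#' @return numeric probabilities in [0, 1].
#' @export
predictMLP <- function(object, energy, bits, ...) {
  bits <- as.matrix(bits)[, object$features, drop = FALSE]
  X <- .mlpInputs(energy, bits, object$energy_center, object$energy_scale)
  as.numeric(mlp_forward(object$weights, X))
}

#' First-layer weight importance of the MLP
#'
#' Importance of input j = mean over first-hidden-layer neurons of the
#' absolute incoming weight |w_ij|, reported sorted descending.
#'
#' @param model a \code{"stackscreenMLP"} model.
#' @return named numeric vector, sorted descending.
#' @export
mlpFeatureImportance <- function(model) {
  W1 <- model$weights$W1  # p x h1
  imp <- rowMeans(abs(W1))
  names(imp) <- c("energy", model$features)
  sort(imp, decreasing = TRUE)
}
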