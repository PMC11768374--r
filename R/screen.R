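## Repurposing cascade orchestration: applicability-domain gates, stacked
## predictions, meta gate, optional docking rescoring, and auditable
## per-stage reports.

#' Screening cascade configuration
#'
#' Default gate thresholds: meta-model probability 0.5, final MLP
#' probability 0.95, fingerprint similarity 0.8.
#'
#' @param meta_cutoff meta-model gate (default 0.5, strict >).
#' @param final_cutoff final-candidate MLP probability (default 0.95, >=).
#' @param similarity_cutoff fingerprint-similarity gate (default 0.8,
#'   strict >).
#' @param seed seed recorded in reports.
#' @return named list of thresholds.
#' @export
screeningConfig <- function(meta_cutoff = 0.5, final_cutoff = 0.95,
                            similarity_cutoff = 0.8, seed = 1L) {
  list(meta_cutoff = meta_cutoff, final_cutoff = final_cutoff,
       similarity_cutoff = similarity_cutoff, seed = as.integer(seed))
}

#' Train every stage of the repurposing pipeline
#'
#' Convenience orchestration over the stage-level functions: labels the
#' activity library, runs scaffold statistics on the exact-potency subset,
#' fits the QSAR regressors on selected descriptors, the fingerprint
#' classifiers on PCA component scores, the logistic meta-model on the
#' stacked outputs, and (when docking results are supplied) the
#' consensus-selected interaction features and the MLP rescorer. The
#' returned bundle plugs into \code{\link{runScreening}}.
#'
#' @param library an inhibitor \linkS4class{CompoundLibrary} (exact and
#'   inexact potencies).
#' @param fingerprint_lines exported fingerprint strings for the library
#'   compounds (same order as the records).
#' @param docking optional list with \code{energies}, \code{interactions},
#'   \code{labels} (named 0/1), \code{reference} (residue/type data.frame).
#' @param scaffold_assignments optional external assignment data.frame
#'   (compound_id, scaffold_id); MCR extraction is used when NULL.
#' @param threshold_pic50 activity-class threshold (default 6).
#' @param potency_cutoff potent/weak scaffold split (default 6.5).
#' @param k_features QSAR descriptors to retain (default 10).
#' @param classifier_seeds,meta_seeds split seeds for the classifier and
#'   meta evaluations.
#' @param mlp_grid hyperparameter grid for the MLP (default
#'   \code{\link{mlpGrid}}).
#' @param mlp_folds CV folds for the MLP grid search (default 10).
#' @param seed base RNG seed.
#' @return list of trained bundles (\code{qsar}, \code{flexo},
#'   \code{scaffold}, \code{meta}, \code{mlp}) plus per-stage evaluations.
#' @export
trainRepurposingModels <- function(library, fingerprint_lines, docking = NULL,
                                   scaffold_assignments = NULL,
                                   threshold_pic50 = 6, potency_cutoff = 6.5,
                                   k_features = 10L, classifier_seeds = 10L,
                                   meta_seeds = 10L, mlp_grid = mlpGrid(),
                                   mlp_folds = 10L, seed = 1L) {
  labeled <- assignActivityLabels(library, threshold_pic50)
  rec <- libraryRecords(labeled)

  ## scaffold statistics on the exact-potency subset
  asn <- scaffoldAssignments(labeled, external = scaffold_assignments)
  grouped <- groupScaffolds(asn, min_count = 2L)
  scaff <- scaffoldSummaries(grouped, rec$pic50, potency_cutoff = potency_cutoff)
  relevant <- scaff$summary$scaffold_id[scaff$summary$relevant]
  bits <- oneHotScaffolds(grouped, relevant)

  ## QSAR on exact records
  exact <- rec$qualifier == "exact"
  desc_all <- computeDescriptors(rec$smiles, rec$compound_id)
  Xe <- desc_all[rec$compound_id[exact], , drop = FALSE]
  sel <- selectFeatures(Xe, rec$pic50[exact], k = k_features, seed = seed)
  reg <- trainRegressors(Xe[, sel$selected, drop = FALSE], rec$pic50[exact],
                         seed = seed)
  qsar <- list(model = reg$models[[reg$best]], scaler = reg$scaler,
               features = sel$selected,
               X_train = Xe[reg$train, sel$selected, drop = FALSE],
               y_train = rec$pic50[exact][reg$train],
               evals = reg$evals, best = reg$best, selection = sel$report)

  ## fingerprint classification
  pcm <- parseFingerprintStrings(fingerprint_lines)
  red <- reduceToComponents(pcm)
  cls <- trainClassifiers(red$scores, rec$label, seeds = classifier_seeds,
                          base_seed = seed)
  flexo <- list(transform = red$transform, model = cls$final_model,
                train_counts = patternCounts(pcm), evals = cls$evals,
                best = cls$best, importance = cls$importance)

  ## stacked meta-model
  pred_pic50 <- predict(qsar$model, applyScaler(
    desc_all[, qsar$features, drop = FALSE], qsar$scaler))
  pred_proba <- predict(flexo$model, red$scores)
  mf <- metaFeatures(pred_pic50, pred_proba, bits)
  meta_fit <- fitMeta(mf$X, rec$label, seeds = meta_seeds, base_seed = seed)
  meta <- list(fit = meta_fit, bounds = mf$bounds, scaffold_ids = relevant)

  ## docking rescorer
  mlp <- NULL
  screening_metrics <- NULL
  if (!is.null(docking)) {
    ifp <- buildIfpMatrix(docking$interactions, reference = docking$reference,
                          ligand_ids = docking$energies$ligand_id)
    cons <- consensusSelect(ifp, docking$labels[rownames(ifpFingerprints(ifp))],
                            k = 10L, seed = seed)
    fp_sel <- ifpFingerprints(ifp)[, cons$selected, drop = FALSE]
    mlp_fit_out <- trainMLP(docking$energies$binding_energy, fp_sel,
                            docking$labels[rownames(fp_sel)],
                            grid = mlp_grid, folds = mlp_folds, seed = seed)
    mlp <- list(model = mlp_fit_out$model, consensus = cons,
                cv = mlp_fit_out$cv, cv_auc = mlp_fit_out$cv_auc)
    screening_metrics <- screeningPerformance(docking$energies, docking$labels)
  }
  list(qsar = qsar, flexo = flexo,
       scaffold = list(summary = scaff$summary, relevant = relevant,
                       grouped = grouped, chi_square = scaff$chi_square),
       meta = meta, mlp = mlp, screening_metrics = screening_metrics,
       labels = rec$label, seed = seed)
}

#' Run the repurposing screening cascade
#'
#' Applies the trained stages in the study's order: (1) QSAR applicability
#' domain (leverage and descriptor-range checks), (2) fingerprint
#' similarity to the training set above the similarity cutoff, (3)
#' meta-model probability above the meta cutoff, then (4), when docking
#' results are supplied, MLP rescoring with the final-candidate cutoff.
#' Compounds lacking docking rows stop at the meta stage with their status
#' recorded. Survivor counts per stage are returned and are monotone
#' non-increasing.
#'
#' @param library a screening \linkS4class{CompoundLibrary}.
#' @param models list of trained bundles: \code{qsar} (elements
#'   \code{model}, \code{scaler}, \code{features}, \code{X_train},
#'   \code{y_train}), \code{flexo} (\code{transform}, \code{model},
#'   \code{train_counts}), \code{meta} (\code{fit}, \code{bounds},
#'   \code{scaffold_ids}), and optionally \code{mlp} (\code{model}).
#' @param descriptors raw descriptor matrix for the library rows (computed
#'   with \code{\link{computeDescriptors}} when NULL).
#' @param fingerprints \linkS4class{PatternCountMatrix} for the library
#'   (pattern strings are an external export, so they must be supplied).
#' @param scaffold_groups data.frame (compound_id, group_id) for the
#'   library; compounds absent or NA carry all-zero scaffold bits.
#' @param docking optional list with \code{energies} (ligand_id,
#'   binding_energy, ...) and \code{interactions} (ligand_id, residue,
#'   type).
#' @param config a \code{\link{screeningConfig}}.
#' @return list with \code{predictions} (the per-compound stage table) and
#'   \code{stage_counts} (named survivor counts).
#' @export
runScreening <- function(library, models, descriptors = NULL,
                         fingerprints = NULL, scaffold_groups = NULL,
                         docking = NULL, config = screeningConfig()) {
  rec <- libraryRecords(library)
  n <- nrow(rec)
  if (n == 0L) {
    empty <- data.frame(compound_id = character(), ad_qsar_pass = logical(),
                        similarity_pass = logical(), pred_pic50 = numeric(),
                        pred_proba = numeric(), meta_proba = numeric(),
                        meta_pass = logical(), binding_energy = numeric(),
                        mlp_proba = numeric(), final_candidate = logical(),
                        rank = integer(), status = character(),
                        stringsAsFactors = FALSE)
    counts <- c(input = 0L, ad = 0L, similarity = 0L, meta = 0L, final = 0L)
    return(list(predictions = empty, stage_counts = counts, config = config))
  }
  if (is.null(fingerprints)) stop("fingerprints are required for the similarity stage")
  qs <- models$qsar
  if (is.null(descriptors)) {
    descriptors <- computeDescriptors(rec$smiles, rec$compound_id)
  }
  missing_desc <- setdiff(qs$features, colnames(descriptors))
  if (length(missing_desc) > 0L) {
    stop("descriptor schema mismatch at the QSAR stage: missing ",
         paste(missing_desc, collapse = ", "))
  }
  Xq <- as.matrix(descriptors)[, qs$features, drop = FALSE]

  ## stage 1: QSAR applicability domain (leverage + descriptor ranges)
  ad <- applicabilityDomain(qs$X_train, qs$y_train, Xq)
  ad_pass <- ad$in_domain

  ## stage 2: fingerprint similarity to the training set
  counts_m <- patternCounts(fingerprints)
  idx <- match(rec$compound_id, rownames(counts_m))
  if (anyNA(idx)) stop("fingerprint rows missing for some compounds")
  train_counts <- models$flexo$train_counts
  common <- intersect(colnames(counts_m), colnames(train_counts))
  pad <- function(m, vocab) {
    miss <- setdiff(vocab, colnames(m))
    if (length(miss) > 0L) {
      m <- cbind(m, matrix(0, nrow(m), length(miss),
                           dimnames = list(rownames(m), miss)))
    }
    m[, vocab, drop = FALSE]
  }
  vocab <- union(colnames(train_counts), colnames(counts_m))
  sim <- maxCountSimilarity(pad(counts_m[idx, , drop = FALSE], vocab),
                            pad(train_counts, vocab))
  sim_pass <- sim > config$similarity_cutoff

  ## stacked predictions
  Xq_scaled <- applyScaler(Xq, qs$scaler)
  pred_pic50 <- predict(qs$model, Xq_scaled)
  scores <- projectComponents(counts_m[idx, , drop = FALSE],
                              models$flexo$transform)
  pred_proba <- predict(models$flexo$model, scores)

  scaffold_ids <- models$meta$scaffold_ids
  bits <- matrix(0, n, length(scaffold_ids),
                 dimnames = list(rec$compound_id, scaffold_ids))
  if (!is.null(scaffold_groups) && length(scaffold_ids) > 0L) {
    gi <- match(rec$compound_id, scaffold_groups$compound_id)
    grp <- scaffold_groups$group_id[gi]
    for (s in scaffold_ids) bits[!is.na(grp) & grp == s, s] <- 1
  }
  mf <- metaFeatures(pred_pic50, pred_proba, bits, bounds = models$meta$bounds)
  meta_out <- predictMeta(models$meta$fit, mf$X, cutoff = config$meta_cutoff)
  meta_pass <- ad_pass & sim_pass & meta_out$pass

  ## stage 4: docking + MLP rescoring
  binding_energy <- rep(NA_real_, n)
  mlp_proba <- rep(NA_real_, n)
  status <- ifelse(!ad_pass, "failed_ad",
            ifelse(!sim_pass, "failed_similarity",
            ifelse(!meta_out$pass, "failed_meta", "passed_meta")))
  if (!is.null(docking) && !is.null(models$mlp)) {
    en <- docking$energies
    ei <- match(rec$compound_id, en$ligand_id)
    binding_energy <- en$binding_energy[ei]
    dockable <- meta_pass & !is.na(binding_energy)
    status[meta_pass & is.na(binding_energy)] <- "awaiting_docking"
    if (any(dockable)) {
      feats <- models$mlp$model$features
      ifp <- buildIfpMatrix(
        docking$interactions[docking$interactions$ligand_id %in%
                               rec$compound_id[dockable], , drop = FALSE],
        ligand_ids = rec$compound_id[dockable])
      fp <- ifpFingerprints(ifp)
      fp_sel <- matrix(0, sum(dockable), length(feats),
                       dimnames = list(rec$compound_id[dockable], feats))
      have <- intersect(feats, colnames(fp))
      fp_sel[, have] <- fp[, have]
      mlp_proba[dockable] <- predictMLP(models$mlp$model,
                                        binding_energy[dockable], fp_sel)
      status[dockable] <- ifelse(mlp_proba[dockable] >= config$final_cutoff,
                                 "final_candidate", "failed_mlp")
    }
  } else {
    status[meta_pass] <- "passed_meta"
  }
  final <- !is.na(mlp_proba) & mlp_proba >= config$final_cutoff & meta_pass

  rank <- rep(NA_integer_, n)
  if (any(final)) {
    ord <- order(-mlp_proba[final], binding_energy[final])
    rank[which(final)[ord]] <- seq_len(sum(final))
  }
  predictions <- data.frame(
    compound_id = rec$compound_id,
    ad_qsar_pass = ad_pass, similarity = sim, similarity_pass = sim_pass,
    pred_pic50 = pred_pic50, pred_proba = pred_proba,
    meta_proba = meta_out$probability, meta_pass = meta_pass,
    binding_energy = binding_energy, mlp_proba = mlp_proba,
    final_candidate = final, rank = rank, status = status,
    stringsAsFactors = FALSE)
  if (length(scaffold_ids) > 0L) {
    predictions <- cbind(predictions,
                         setNames(as.data.frame(bits),
                                  paste0("scaffold_", scaffold_ids)))
  }
  stage_counts <- c(input = n, ad = sum(ad_pass),
                    similarity = sum(ad_pass & sim_pass),
                    meta = sum(meta_pass), final = sum(final))
  list(predictions = predictions, stage_counts = stage_counts, config = config)
}

#' Write a screening report
#'
#' Writes the stage-prediction table as CSV plus a JSON report with the
#' per-stage survivor counts, every threshold, the seed, the package
#' version and a configuration hash (which changes iff a threshold
#' changes). Output is deterministic: no timestamps, fixed column order.
#'
#' @param screening output of \code{\link{runScreening}}.
#' @param path output directory (created if needed).
#' @param name file stem (default "screening_report").
#' @return invisibly, the paths written.
#' @export
writeReport <- function(screening, path, name = "screening_report") {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  csv_path <- file.path(path, paste0(name, ".csv"))
  json_path <- file.path(path, paste0(name, ".json"))
  write.csv(screening$predictions, csv_path, row.names = FALSE)
  cfg <- screening$config
  tmp <- tempfile()
  writeLines(jsonlite::toJSON(cfg[sort(names(cfg))], auto_unbox = TRUE), tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  report <- list(
    stage_counts = as.list(screening$stage_counts),
    config = cfg, config_hash = cfg_hash,
    package_version = as.character(utils::packageVersion("StackScreen")),
    n_final = sum(screening$predictions$final_candidate, na.rm = TRUE),
    failed_by_stage = as.list(table(screening$predictions$status)))
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), json_path)
  invisible(c(csv = csv_path, json = json_path))
}
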