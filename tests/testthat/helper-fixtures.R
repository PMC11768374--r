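## Shared test fixtures, computed lazily and cached for the whole run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache, inherits = FALSE)
}

## A small activity library with ground-truth scaffold families.
smallLibrary <- function() {
  cached("small_library", {
    genActivityLibrary(syntheticSpec(seed = 11L, n_compounds = 80L))
  })
}

## External scaffold assignments from the generator's ground truth.
truthAssignments <- function(library) {
  rec <- libraryRecords(library)
  data.frame(compound_id = rec$compound_id,
             scaffold_id = rec$scaffold_family,
             stringsAsFactors = FALSE)
}

## Descriptor matrix for the small library (slow: OpenBabel), cached.
smallDescriptors <- function() {
  cached("small_descriptors", {
    rec <- libraryRecords(smallLibrary())
    computeDescriptors(rec$smiles, rec$compound_id)
  })
}

## Remap synthetic docking ligand ids onto a library's compound ids, actives
## first, so energies/interactions/labels align with the given label vector.
remapDocking <- function(dk, compound_ids, labels) {
  ord_ids <- c(compound_ids[labels == 1], compound_ids[labels == 0])
  map <- setNames(ord_ids, dk$energies$ligand_id)
  dk$energies$ligand_id <- unname(map[dk$energies$ligand_id])
  dk$interactions$ligand_id <- unname(map[dk$interactions$ligand_id])
  names(dk$labels) <- unname(map[names(dk$labels)])
  dk
}

## A full trained pipeline bundle on a 192-compound synthetic study (cached:
## this is the expensive shared fixture).
cascadeModels <- function() {
  cached("cascade_models", {
    sp <- syntheticSpec(seed = 1L, n_compounds = 192L,
                        pattern_class_effect = 1.5, energy_gap = 2)
    lib <- genActivityLibrary(sp)
    rec <- libraryRecords(lib)
    lab <- libraryRecords(assignActivityLabels(lib, 6))$label
    fl <- genFlexophoreStrings(nrow(rec), sp, labels = lab,
                               ids = rec$compound_id)
    dk <- remapDocking(genDockingResults(sum(lab == 1), sum(lab == 0), sp),
                       rec$compound_id, lab)
    ext <- data.frame(compound_id = rec$compound_id,
                      scaffold_id = rec$scaffold_family,
                      stringsAsFactors = FALSE)
    ## a few random ligands legitimately draw no interactions -> zero rows
    models <- suppressWarnings(trainRepurposingModels(
      lib, fl$lines,
      docking = list(energies = dk$energies, interactions = dk$interactions,
                     labels = dk$labels, reference = dk$reference),
      scaffold_assignments = ext, classifier_seeds = 2L, meta_seeds = 3L,
      mlp_grid = data.frame(lr = 0.01, batch = 16L, dropout = 0.2),
      mlp_folds = 5L, seed = 1L))
    list(spec = sp, library = lib, labels = lab, models = models)
  })
}

## A fresh screening scenario for the cascade (cached): 60 unseen compounds
## whose ground truth is membership of the planted scaffold family.
cascadeScenario <- function() {
  cached("cascade_scenario", {
    sp2 <- syntheticSpec(seed = 1001L, n_compounds = 60L,
                         pattern_class_effect = 1.5, energy_gap = 2)
    rec2 <- libraryRecords(genActivityLibrary(sp2))
    truth <- as.integer(rec2$scaffold_family == "quinazoline")
    screen_rec <- data.frame(compound_id = paste0("DRUG", seq_len(nrow(rec2))),
                             smiles = rec2$smiles, ic50_nM = NA_real_,
                             qualifier = "missing", pic50 = NA_real_,
                             role = "screening", stringsAsFactors = FALSE)
    slib <- CompoundLibrary(screen_rec, name = "synthetic-screening")
    fl2 <- genFlexophoreStrings(nrow(screen_rec), sp2, labels = truth,
                                ids = screen_rec$compound_id)
    dk2 <- remapDocking(genDockingResults(sum(truth == 1), sum(truth == 0), sp2),
                        screen_rec$compound_id, truth)
    sg <- data.frame(compound_id = screen_rec$compound_id,
                     group_id = rec2$scaffold_family,
                     stringsAsFactors = FALSE)
    list(library = slib, truth = truth,
         fingerprints = parseFingerprintStrings(fl2$lines),
         docking = list(energies = dk2$energies,
                        interactions = dk2$interactions),
         scaffold_groups = sg)
  })
}

## Brute-force ROC AUC: pairwise comparisons with ties counting one half.
bruteForceAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

## Oracle Mann-Whitney U and exact two-sided p by enumerating every
## assignment of the pooled observations to the first group.
oracleMannWhitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  U_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, function(p, q) (p > q) + 0.5 * (p == q)))
  }
  U_obs <- U_of(seq_len(n1))
  mu <- n1 * n2 / 2
  all_idx <- combn(n1 + n2, n1)
  U_all <- apply(all_idx, 2, U_of)
  p <- mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-12)
  list(U = U_obs, p = p)
}

## Textbook chi-square on a contingency table.
oracleChiSquare <- function(O) {
  rs <- rowSums(O); cs <- colSums(O); N <- sum(O)
  E <- outer(rs, cs) / N
  X2 <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  list(X2 = X2, df = df, p = pchisq(X2, df, lower.tail = FALSE),
       std = (O - E) / sqrt(E))
}
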