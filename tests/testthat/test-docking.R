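test_that("IFP matrix construction canonicalises and sorts features", {
  inter <- data.frame(
    ligand_id = c("L1", "L1", "L1", "L2"),
    residue = c("Glu161", "Lys85", "Glu161", "Lys85"),
    type = c("hbond", "hydrophobic", "hbond", "hydrophobic"),  # duplicate row
    stringsAsFactors = FALSE)
  ref <- data.frame(residue = c("Lys85", "Tyr156"),
                    type = c("hydrophobic", "hbond"))
  expect_warning(
    ifp <- buildIfpMatrix(inter, reference = ref, ligand_ids = c("L1", "L2", "L3")),
    "without interactions")
  m <- ifpFingerprints(ifp)
  # sorted by residue number then type: Lys85 < Tyr156 < Glu161
  expect_identical(colnames(m),
                   c("Lys85:hydrophobic", "Tyr156:hbond", "Glu161:hbond"))
  expect_identical(rownames(m), c("L1", "L2", "L3"))
  expect_equal(unname(m["L1", ]), c(1, 0, 1))   # duplicates collapse to one bit
  expect_equal(unname(m["L3", ]), c(0, 0, 0))
  r <- ifpReference(ifp)
  expect_equal(unname(r), c(1, 1, 0))
  # malformed inputs are hard errors
  expect_error(buildIfpMatrix(transform(inter, type = "covalent")), "unknown interaction")
  expect_error(buildIfpMatrix(transform(inter, residue = "85Lys")), "malformed residue")
})

test_that("reference similarity summarises per group", {
  fp <- rbind(L1 = c(1, 1, 0), L2 = c(0, 0, 1), L3 = c(1, 1, 1))
  colnames(fp) <- c("A1:hbond", "B2:hbond", "C3:hbond")
  ifp <- new("IFPMatrix", fp = fp,
             reference = setNames(c(1, 1, 0), colnames(fp)))
  out <- referenceSimilaritySummary(ifp, groups = c("m1", "m2", "m1"))
  expect_equal(unname(out$similarity["L1"]), 1)
  expect_equal(unname(out$similarity["L2"]), 0)
  expect_equal(unname(out$similarity["L3"]), 2 / 3)
  m1 <- out$by_group[out$by_group$group == "m1", ]
  expect_equal(m1$mean, mean(c(1, 2 / 3)))
  expect_equal(m1$median, median(c(1, 2 / 3)))
})

test_that("screening performance computes the ranking metric suite", {
  sp <- syntheticSpec(seed = 6L, energy_gap = 2, energy_sd = 0.8)
  dk <- genDockingResults(60, 140, sp)
  perf <- screeningPerformance(dk$energies, dk$labels)
  expect_equal(nrow(perf), 1L)
  expect_gt(perf$roc_auc, 0.8)
  expect_gt(perf$log_auc, 0.14462)   # beats the chance diagonal
  expect_gt(perf$ef_10pct, 1)
  expect_lt(perf$mannwhitney_p, 1e-6)
  expect_lt(perf$welch_t_p, 1e-6)
  # EF at 1% is defined here (N = 200) and bounded by 1/alpha behaviour
  expect_gte(perf$ef_1pct, 0)
  # fewer than 100 compounds: EF at 1% is reported as NA
  small <- dk$energies[1:80, ]
  perf2 <- screeningPerformance(small, dk$labels[1:80])
  expect_true(is.na(perf2$ef_1pct))
  # two methods are reported on separate rows
  two <- rbind(dk$energies,
               transform(dk$energies, method = "VINA",
                         binding_energy = binding_energy + rnorm(200, 0, 0.1)))
  perf3 <- screeningPerformance(two, dk$labels)
  expect_setequal(perf3$method, c("AD4", "VINA"))
})

test_that("consensus selection recovers the planted interactions", {
  sp <- syntheticSpec(seed = 4L)
  dk <- genDockingResults(80, 120, sp, p_active = 0.85, p_inactive = 0.2)
  ifp <- suppressWarnings(buildIfpMatrix(dk$interactions, reference = dk$reference,
                                         ligand_ids = dk$energies$ligand_id))
  cons <- consensusSelect(ifp, dk$labels[rownames(ifpFingerprints(ifp))],
                          k = 10L, seed = 4L)
  planted_keys <- paste0(dk$reference$residue, ":", dk$reference$type)
  expect_true(all(planted_keys %in% cons$selected))
  expect_false(cons$fallback_union)
  # selected set is the ordered intersection of the two top-10 lists
  expect_true(all(cons$selected %in% head(cons$chi_rank, 10)))
  expect_true(all(cons$selected %in% head(cons$forest_rank, 10)))
  # deterministic under a fixed seed
  cons2 <- consensusSelect(ifp, dk$labels[rownames(ifpFingerprints(ifp))],
                           k = 10L, seed = 4L)
  expect_identical(cons$selected, cons2$selected)
})

test_that("the MLP grid enumerates 64 combinations", {
  g <- mlpGrid()
  expect_equal(nrow(g), 64L)
  expect_identical(sort(unique(g$lr)), c(0.001, 0.01, 0.05, 0.1))
  expect_identical(sort(unique(g$batch)), c(8L, 16L, 32L, 64L))
  expect_identical(sort(unique(g$dropout)), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(nrow(unique(g)), 64L)
})

test_that("MLP rescorer trains, beats energy alone and predicts deterministically", {
  sp <- syntheticSpec(seed = 8L, energy_gap = 1.2, energy_sd = 1.0)
  dk <- genDockingResults(70, 130, sp)
  ifp <- suppressWarnings(buildIfpMatrix(dk$interactions, reference = dk$reference,
                                         ligand_ids = dk$energies$ligand_id))
  y <- dk$labels[rownames(ifpFingerprints(ifp))]
  cons <- consensusSelect(ifp, y, k = 10L, seed = 8L)
  bits <- ifpFingerprints(ifp)[, cons$selected, drop = FALSE]
  grid <- mlpGrid()[c(2, 18, 39), ]           # small sub-grid for speed
  fit <- trainMLP(dk$energies$binding_energy, bits, y, grid = grid,
                  folds = 5L, seed = 8L)
  expect_equal(nrow(fit$cv), 3L)
  expect_true(all(fit$cv$cv_auc >= 0 & fit$cv$cv_auc <= 1))
  expect_equal(fit$cv_auc, max(fit$cv$cv_auc))
  energy_auc <- rocAuc(-dk$energies$binding_energy, y)
  expect_gt(fit$cv_auc, energy_auc)           # interactions add signal
  expect_gt(fit$cv_auc, 0.85)
  # inference is deterministic and bounded
  p1 <- predictMLP(fit$model, dk$energies$binding_energy, bits)
  p2 <- predictMLP(fit$model, dk$energies$binding_energy, bits)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_gt(rocAuc(p1, y), 0.85)
  # first-layer importance covers energy plus every selected feature
  imp <- mlpFeatureImportance(fit$model)
  expect_setequal(names(imp), c("energy", cons$selected))
  expect_true(all(diff(imp) <= 1e-12))        # sorted descending
  # the class weight is the negative/positive ratio
  expect_equal(fit$model$pos_weight, sum(y == 0) / sum(y == 1))
})
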