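test_that("screening config carries the study thresholds", {
  cfg <- screeningConfig()
  expect_equal(cfg$meta_cutoff, 0.5)
  expect_equal(cfg$final_cutoff, 0.95)
  expect_equal(cfg$similarity_cutoff, 0.8)
  cfg2 <- screeningConfig(similarity_cutoff = 0.3, seed = 7L)
  expect_equal(cfg2$similarity_cutoff, 0.3)
  expect_identical(cfg2$seed, 7L)
})

test_that("training orchestration wires every stage together", {
  tb <- cascadeModels()
  models <- tb$models
  expect_named(models,
               c("qsar", "flexo", "scaffold", "meta", "mlp",
                 "screening_metrics", "labels", "seed"))
  expect_true(models$qsar$best %in% c("MLR", "PLS", "SVM", "RF", "GB"))
  expect_length(models$qsar$features, 10L)
  expect_true(models$flexo$best %in% c("LR", "SVM", "RF", "GB", "KNN"))
  # planted scaffold is among the relevant set feeding the meta-model
  expect_true("quinazoline" %in% models$scaffold$relevant)
  # meta coefficients exist for both stacked predictions plus each scaffold bit
  expect_true(all(c("pred_pic50", "pred_proba") %in%
                    names(models$meta$fit$coefficients)))
  # docking stage trained and evaluated
  expect_s3_class(models$mlp$model, "stackscreenMLP")
  expect_gt(models$mlp$cv_auc, 0.8)
  expect_gt(models$screening_metrics$roc_auc, 0.8)
})

test_that("the cascade gates in order and counts survivors monotonically", {
  tb <- cascadeModels()
  sc <- cascadeScenario()
  out <- runScreening(sc$library, tb$models, fingerprints = sc$fingerprints,
                      scaffold_groups = sc$scaffold_groups,
                      docking = sc$docking,
                      config = screeningConfig(similarity_cutoff = 0.3))
  counts <- out$stage_counts
  expect_identical(names(counts), c("input", "ad", "similarity", "meta", "final"))
  expect_equal(unname(counts["input"]), 60L)
  expect_true(all(diff(counts) <= 0))          # non-increasing survivor counts
  pr <- out$predictions
  expect_equal(nrow(pr), 60L)
  # stage flags are internally consistent
  expect_identical(pr$meta_pass,
                   pr$ad_qsar_pass & pr$similarity_pass &
                     (pr$meta_proba > 0.5))
  # every final candidate passed every upstream gate, with full provenance
  fin <- pr[pr$final_candidate, ]
  expect_gt(nrow(fin), 0L)
  expect_true(all(fin$ad_qsar_pass & fin$similarity_pass & fin$meta_pass))
  expect_true(all(fin$mlp_proba >= 0.95))
  expect_true(all(!is.na(fin$binding_energy)))
  expect_identical(sort(fin$rank), seq_len(nrow(fin)))
  expect_true(all(fin$status == "final_candidate"))
  # non-candidates carry the stage at which they stopped
  expect_true(all(pr$status %in% c("failed_ad", "failed_similarity",
                                   "failed_meta", "awaiting_docking",
                                   "failed_mlp", "final_candidate")))
  # the screen enriches the planted class
  expect_gt(mean(sc$truth[pr$final_candidate]), mean(sc$truth))
})

test_that("compounds without docking rows halt at the meta stage", {
  tb <- cascadeModels()
  sc <- cascadeScenario()
  dk_partial <- sc$docking
  drop_ids <- sc$library@records$compound_id[1:30]
  dk_partial$energies <- dk_partial$energies[
    !dk_partial$energies$ligand_id %in% drop_ids, , drop = FALSE]
  out <- runScreening(sc$library, tb$models, fingerprints = sc$fingerprints,
                      scaffold_groups = sc$scaffold_groups,
                      docking = dk_partial,
                      config = screeningConfig(similarity_cutoff = 0.3))
  pr <- out$predictions
  stalled <- pr$compound_id %in% drop_ids & pr$meta_pass
  expect_true(all(pr$status[stalled] == "awaiting_docking"))
  expect_true(all(is.na(pr$mlp_proba[stalled])))
  expect_false(any(pr$final_candidate[stalled]))
})

test_that("an empty screening library yields an empty but well-formed result", {
  tb <- cascadeModels()
  empty <- CompoundLibrary(data.frame(
    compound_id = character(), smiles = character(), ic50_nM = numeric(),
    qualifier = character(), pic50 = numeric(), role = character(),
    stringsAsFactors = FALSE), name = "empty")
  out <- runScreening(empty, tb$models, fingerprints = NULL)
  expect_equal(unname(out$stage_counts), rep(0L, 5L))
  expect_equal(nrow(out$predictions), 0L)
})

test_that("reports are deterministic and hash their configuration", {
  tb <- cascadeModels()
  sc <- cascadeScenario()
  cfg <- screeningConfig(similarity_cutoff = 0.3)
  out1 <- runScreening(sc$library, tb$models, fingerprints = sc$fingerprints,
                       scaffold_groups = sc$scaffold_groups,
                       docking = sc$docking, config = cfg)
  out2 <- runScreening(sc$library, tb$models, fingerprints = sc$fingerprints,
                       scaffold_groups = sc$scaffold_groups,
                       docking = sc$docking, config = cfg)
  expect_identical(out1$predictions, out2$predictions)

  d1 <- file.path(tempfile(), "r1"); d2 <- file.path(tempfile(), "r2")
  p1 <- writeReport(out1, d1)
  p2 <- writeReport(out2, d2)
  expect_identical(readLines(p1["csv"]), readLines(p2["csv"]))
  expect_identical(readLines(p1["json"]), readLines(p2["json"]))
  rep1 <- jsonlite::fromJSON(p1["json"])
  expect_identical(as.integer(unlist(rep1$stage_counts)),
                   unname(out1$stage_counts))
  # changing a threshold changes the configuration hash
  out3 <- runScreening(sc$library, tb$models, fingerprints = sc$fingerprints,
                       scaffold_groups = sc$scaffold_groups,
                       docking = sc$docking,
                       config = screeningConfig(similarity_cutoff = 0.31))
  p3 <- writeReport(out3, file.path(tempfile(), "r3"))
  rep3 <- jsonlite::fromJSON(p3["json"])
  expect_false(identical(rep1$config_hash, rep3$config_hash))
})
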