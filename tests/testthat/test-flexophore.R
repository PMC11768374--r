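test_that("fingerprint parsing counts token multisets deterministically", {
  pcm <- parseFingerprintStrings(c("c1\tA;A;B", "c2\tB;C", "c3\tC;A"))
  m <- patternCounts(pcm)
  expect_identical(rownames(m), c("c1", "c2", "c3"))
  expect_identical(colnames(m), c("A", "B", "C"))   # first-appearance order
  expect_identical(unname(m["c1", ]), c(2L, 1L, 0L))
  expect_identical(unname(m["c2", ]), c(0L, 1L, 1L))
  expect_identical(patternVocabulary(pcm), c("A", "B", "C"))
  # custom delimiter
  m2 <- patternCounts(parseFingerprintStrings("x\tA|B|B", delimiter = "|"))
  expect_identical(unname(m2["x", ]), c(1L, 2L))
  # blank id is an error; empty token list is a zero row with a warning
  expect_error(parseFingerprintStrings("\tA;B"), "blank")
  expect_warning(p3 <- parseFingerprintStrings(c("c1\tA", "c2\t")), "empty")
  expect_identical(unname(patternCounts(p3)["c2", ]), 0L)
})

test_that("component reduction filters, standardizes and projects", {
  sp <- syntheticSpec(seed = 2L, n_patterns = 30L, pattern_class_effect = 1.2)
  fx <- genFlexophoreStrings(120, sp)
  pcm <- parseFingerprintStrings(fx$lines)
  red <- reduceToComponents(pcm, n_components = 10L)
  expect_equal(dim(red$scores), c(120L, 10L))
  expect_length(red$explained_variance_ratio, 10L)
  expect_true(all(diff(red$explained_variance_ratio) <= 1e-12))  # sorted
  expect_lte(sum(red$explained_variance_ratio), 1 + 1e-9)
  # projection of the training rows reproduces the training scores
  back <- projectComponents(patternCounts(pcm), red$transform)
  expect_equal(back, red$scores, tolerance = 1e-12)
  # unseen vocabulary columns are ignored, missing ones count zero
  q <- patternCounts(pcm)[1:2, 1:10, drop = FALSE]
  pj <- projectComponents(q, red$transform)
  expect_equal(dim(pj), c(2L, 10L))
  # a constant pattern never survives the variance filter
  m <- cbind(patternCounts(pcm), KONST = 1L)
  red2 <- reduceToComponents(m, n_components = 5L)
  expect_false("KONST" %in% red2$transform$patterns)
  # component cap warns when the vocabulary is too small
  expect_warning(reduceToComponents(m[, 1:3], n_components = 20L), "capped")
})

test_that("classifier families separate a strongly planted signal", {
  sp <- syntheticSpec(seed = 5L, n_patterns = 30L, pattern_class_effect = 2.0)
  fx <- genFlexophoreStrings(160, sp)
  pcm <- parseFingerprintStrings(fx$lines)
  red <- reduceToComponents(pcm, n_components = 10L)
  out <- trainClassifiers(red$scores, fx$labels, seeds = 2L, base_seed = 5L)
  expect_setequal(unique(out$evals$model), c("LR", "SVM", "RF", "GB", "KNN"))
  expect_setequal(unique(out$evals$partition), c("train", "cv", "test"))
  expect_equal(nrow(out$evals), 5L * 2L * 3L)
  expect_true(all(c("roc_auc", "bACC", "MCC") %in% colnames(out$evals)))
  # the winner generalises
  test_auc <- out$evals$roc_auc[out$evals$model == out$best &
                                  out$evals$partition == "test"]
  expect_gt(mean(test_auc), 0.85)
  # the final model predicts calibrated-range probabilities
  p <- predict(out$final_model, red$scores)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(rocAuc(p, fx$labels), 0.9)
  # forest importance covers every component
  expect_length(out$importance, ncol(red$scores))
  expect_error(trainClassifiers(red$scores, rep(1L, 160)), "both classes")
})

test_that("maximum count similarity gates by the generalized Tanimoto", {
  train <- rbind(a = c(2, 0, 1), b = c(0, 3, 0))
  q <- rbind(q1 = c(2, 0, 1),     # identical to a -> 1
             q2 = c(1, 1, 1),
             q3 = c(0, 0, 0))     # empty vs non-empty -> 0
  s <- maxCountSimilarity(q, train)
  expect_equal(s[1], 1)
  expect_equal(s[2], max(countSimilarity(c(1, 1, 1), c(2, 0, 1)),
                         countSimilarity(c(1, 1, 1), c(0, 3, 0))))
  expect_equal(s[3], 0)
  expect_error(maxCountSimilarity(q[, 1:2], train), "mismatch")
})
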