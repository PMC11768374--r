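test_that("descriptor computation yields a numeric finite panel", {
  X <- smallDescriptors()
  rec <- libraryRecords(smallLibrary())
  expect_identical(rownames(X), rec$compound_id)
  expect_true(all(is.finite(X)))
  expect_true(all(c("MW", "nHeavyAtoms", "nRingSystems") %in% colnames(X)))
  expect_gt(ncol(X), 15L)
  # molecular weight is positive and heavy atoms count as integers
  expect_true(all(X[, "MW"] > 0))
  expect_true(all(X[, "nHeavyAtoms"] == round(X[, "nHeavyAtoms"])))
  # unparsable molecules are rejected with a warning
  expect_warning(X2 <- computeDescriptors(c("CCO", "junk_smiles"), c("a", "b")),
                 "rejected")
  expect_identical(rownames(X2), "a")
})

test_that("three-stage selection drops constant, correlated and noise columns", {
  d <- genDescriptorDataset(250, 5, 25, seed = 7L)
  X <- d$X
  X <- cbind(X, CONST = rep(1, nrow(X)),          # stage-1 victim
             DUP01 = X[, "INF01"] + rnorm(nrow(X), 0, 1e-4))  # stage-2 victim
  sel <- selectFeatures(X, d$y, k = 10L, seed = 7L, ntree = 200L)
  expect_length(sel$selected, 10L)
  expect_true("CONST" %in% sel$report$variance_dropped)
  # exactly one of the duplicated pair survives
  expect_equal(sum(c("INF01", "DUP01") %in% sel$selected), 1L)
  expect_true(any(c("INF01", "DUP01") %in% sel$report$correlation_dropped))
  # RFE keeps at least 4 of the 5 planted informative columns
  kept_inf <- sum(sub("DUP01", "INF01", sel$selected) %in% d$informative)
  expect_gte(kept_inf, 4L)
  expect_error(selectFeatures(X[, 1:5], d$y, k = 10L), "survive")
})

test_that("regressor training evaluates five families and picks a sane best", {
  d <- genDescriptorDataset(150, 4, 4, seed = 2L, noise_sd = 0.5)
  out <- trainRegressors(d$X, d$y, seed = 2L)
  expect_setequal(out$evals$model, c("MLR", "PLS", "SVM", "RF", "GB"))
  expect_equal(nrow(out$evals), 5L)
  expect_true(all(c("train_r2", "test_r2", "q2_mean", "q2_sd",
                    "train_rmse", "test_rmse") %in% colnames(out$evals)))
  expect_true(out$best %in% out$evals$model)
  # a linear truth is fit well by the winner
  best_row <- out$evals[out$evals$model == out$best, ]
  expect_gt(best_row$test_r2, 0.7)
  expect_gt(best_row$q2_mean, 0.7)
  # determinism of the whole evaluation
  out2 <- trainRegressors(d$X, d$y, seed = 2L)
  expect_identical(out$evals, out2$evals)
  expect_error(trainRegressors(d$X, rep(1, 150)), "zero variance")
})

test_that("cross-validated Q2 is out-of-fold and penalises pure noise", {
  d <- genDescriptorDataset(120, 3, 2, seed = 13L, noise_sd = 0.3)
  q2 <- crossValidatedQ2("MLR", d$X, d$y, seed = 13L)
  expect_length(q2$q2, 5L)
  expect_equal(q2$mean, mean(q2$q2))
  expect_gt(q2$mean, 0.8)
  # on shuffled responses the out-of-fold Q2 collapses
  y_perm <- StackScreen:::withSeed(99L, sample(d$y))
  q2n <- crossValidatedQ2("MLR", d$X, y_perm, seed = 13L)
  expect_lt(q2n$mean, 0.3)
})

test_that("permutation importance ranks planted features above noise", {
  d <- genDescriptorDataset(150, 2, 4, seed = 21L, noise_sd = 0.3)
  scaler <- StackScreen:::fitScaler(d$X)
  Xs <- StackScreen:::applyScaler(d$X, scaler)
  mod <- StackScreen:::.fitRegressor("MLR", Xs, d$y)
  imp <- permutationImportance(mod, Xs, d$y, seed = 3L)
  expect_named(imp)
  expect_gt(min(imp[d$informative]), max(imp[setdiff(names(imp), d$informative)]))
  # deterministic under the same seed
  expect_identical(imp, permutationImportance(mod, Xs, d$y, seed = 3L))
})

test_that("partial dependence is the pointwise mean of the ICE curves", {
  d <- genDescriptorDataset(80, 3, 1, seed = 5L)
  mod <- StackScreen:::.fitRegressor("MLR", d$X, d$y)
  prof <- dependenceProfiles(mod, d$X, "INF01", grid_size = 15L)
  expect_length(prof$grid, 15L)
  expect_equal(dim(prof$ice), c(80L, 15L))
  expect_equal(prof$pdp, colMeans(prof$ice), tolerance = 1e-12)
  # for a linear model the PDP in one feature is a straight line
  slopes <- diff(prof$pdp) / diff(prof$grid)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-8)
  expect_error(dependenceProfiles(mod, d$X, "NOPE"), "unknown feature")
})

test_that("applicability domain flags leverage and range violations", {
  d <- genDescriptorDataset(100, 3, 2, seed = 9L)
  X <- d$X
  inside <- colMeans(X)                      # centroid: definitely in-domain
  outside <- apply(X, 2, max) * 10           # far outside every range
  Q <- rbind(inside, outside)
  ad <- applicabilityDomain(X, d$y, Q)
  expect_true(ad$in_domain[1])
  expect_false(ad$in_domain[2])
  expect_false(ad$in_range[2])
  expect_gt(ad$leverage_query[2], ad$h_star)
  # Williams-plot ingredients line up with the training fit
  expect_length(ad$studentized_residuals, 100L)
  expect_equal(dim(ad$pca_query), c(2L, 2L))
  # leverage trace identity: sum of training leverages = fitted parameters
  expect_equal(sum(ad$leverage_train), ncol(X) + 1, tolerance = 1e-8)
  expect_equal(ad$h_star, 3 * (ncol(X) + 1) / 100)
  # collinear descriptors are a hard error
  Xc <- cbind(X, DUP = X[, 1])
  expect_error(applicabilityDomain(Xc, d$y, cbind(Q, DUP = Q[, 1])), "singular")
})
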