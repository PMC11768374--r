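test_that("ROC AUC equals brute-force pair counting (property)", {
  set.seed(17)
  for (i in 1:1000) {
    n <- sample(10:200, 1)
    y <- c(0L, 1L, rbinom(n - 2L, 1L, 0.5))   # guarantee both classes
    sc <- if (i %% 3 == 0) sample(1:20, n, replace = TRUE) else rnorm(n)
    expect_equal(rocAuc(sc, y), bruteForceAuc(sc, y), tolerance = 1e-12)
  }
  expect_error(rocAuc(rnorm(5), rep(1L, 5)), "both classes")
})

test_that("logAUC hits its closed-form limits", {
  y <- rep(c(1L, 0L), c(20L, 980L))
  sc <- -seq_along(y)                  # perfect ranking: all actives first
  expect_equal(logAuc(sc, y), 1)
  # chance diagonal TPR = FPR via an explicit curve
  f <- seq(0, 1, length.out = 2001)
  diag_val <- logAuc(fpr = f, tpr = f)
  expect_equal(diag_val, 0.14458, tolerance = 1e-3)
  # a good-early ranker scores above the diagonal, a perfect one above both
  expect_gt(logAuc(sc, y), diag_val)
})

test_that("enrichment factor matches direct top-slice counting (property)", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(50:400, 1)
    y <- c(1L, 0L, rbinom(n - 2L, 1L, 0.2))
    sc <- rnorm(n)
    alpha <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    if (alpha * n < 1) next
    top_n <- ceiling(alpha * n)
    hits <- sum(y[order(sc, decreasing = TRUE)][seq_len(top_n)])
    expect_equal(efAtFraction(sc, y, alpha),
                 (hits / top_n) / (mean(y)), tolerance = 1e-12)
  }
  expect_error(efAtFraction(rnorm(10), rbinom(10, 1, 0.5), 0.01), "alpha")
})

test_that("classification metrics match their confusion-matrix identities", {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  p <- c(1, 1, 0, 1, 0, 0, 1, 0, 0, 0)
  m <- classificationMetrics(y, p)
  TP <- 3; FN <- 1; FP <- 1; TN <- 5
  expect_equal(unname(m["accuracy"]), (TP + TN) / 10)
  expect_equal(unname(m["sensitivity"]), TP / (TP + FN))
  expect_equal(unname(m["specificity"]), TN / (TN + FP))
  expect_equal(unname(m["bACC"]),
               mean(c(TP / (TP + FN), TN / (TN + FP))))
  prec <- TP / (TP + FP)
  rec <- TP / (TP + FN)
  expect_equal(unname(m["F1"]), 2 * prec * rec / (prec + rec))
  expect_equal(unname(m["MCC"]),
               (TP * TN - FP * FN) /
                 sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)))
  # perfect and inverted predictors bound the coefficient
  expect_equal(unname(classificationMetrics(y, y)["MCC"]), 1)
  expect_equal(unname(classificationMetrics(y, 1 - y)["MCC"]), -1)
  # degenerate single-class truth warns and yields NA
  expect_warning(m1 <- classificationMetrics(rep(1, 4), c(1, 1, 0, 1)),
                 "single-class")
  expect_true(is.na(m1["MCC"]))
})

test_that("rocAuc is consistent with classificationMetrics' AUC", {
  set.seed(4)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0L, 1L)
  sc <- rnorm(40)
  m <- suppressWarnings(classificationMetrics(y, as.integer(sc > 0), sc))
  expect_equal(unname(m["roc_auc"]), rocAuc(sc, y))
})

test_that("binary and count Tanimoto match set arithmetic (property)", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    a <- rbinom(n, 1, 0.4); b <- rbinom(n, 1, 0.4)
    A <- which(a == 1); B <- which(b == 1)
    if (length(union(A, B)) == 0) {
      expect_warning(s <- binaryTanimoto(a, b), "empty")
      expect_equal(s, 1)
    } else {
      expect_equal(binaryTanimoto(a, b),
                   length(intersect(A, B)) / length(union(A, B)),
                   tolerance = 1e-15)
    }
    ca <- rpois(n, 2); cb <- rpois(n, 2)
    if (sum(pmax(ca, cb)) > 0) {
      expect_equal(countSimilarity(ca, cb),
                   sum(pmin(ca, cb)) / sum(pmax(ca, cb)), tolerance = 1e-15)
    }
  }
  expect_error(binaryTanimoto(c(1, 0), c(1, 0, 1)), "length")
  expect_error(countSimilarity(c(a = 1, b = 2), c(b = 1, a = 2)), "vocabular")
})

test_that("similarity values are symmetric and bounded", {
  set.seed(61)
  a <- rpois(30, 1); b <- rpois(30, 3)
  expect_equal(countSimilarity(a, b), countSimilarity(b, a))
  expect_gte(countSimilarity(a, b), 0)
  expect_lte(countSimilarity(a, b), 1)
  expect_equal(countSimilarity(a, a), 1)
})
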