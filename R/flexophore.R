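## Pharmacophore fingerprint classification: parsing exported fingerprint
## strings into a pattern-count matrix, variance filter + standardization +
## PCA to 20 components, and the five classifier families evaluated across
## seeds.

#' Parse exported fingerprint strings
#'
#' One line per compound: compound id, a tab, and delimiter-separated
#' pattern tokens. Token multisets are counted per compound; columns are
#' ordered by first appearance for determinism. A blank id is an error; an
#' empty token list yields an all-zero row with a warning.
#'
#' @param lines character vector of fingerprint lines.
#' @param delimiter token delimiter (default ";").
#' @return A \linkS4class{PatternCountMatrix}.
#' @export
#' @examples
#' pcm <- parseFingerprintStrings(c("c1\tA;A;B", "c2\tB;C"))
#' patternCounts(pcm)
parseFingerprintStrings <- function(lines, delimiter = ";") {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, function(p) trimws(p[1]), character(1))
  if (any(is.na(ids) | !nzchar(ids))) {
    stop("blank compound id in line(s): ",
         paste(which(is.na(ids) | !nzchar(ids)), collapse = ", "))
  }
  token_lists <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(trimws(p[2]))) return(character(0))
    toks <- strsplit(p[2], delimiter, fixed = TRUE)[[1]]
    toks[nzchar(toks)]
  })
  empty <- vapply(token_lists, length, 1L) == 0L
  if (any(empty)) {
    warning("empty fingerprint for compound(s): ",
            paste(ids[empty], collapse = ", "))
  }
  vocab <- unique(unlist(token_lists))
  m <- matrix(0L, length(ids), length(vocab),
              dimnames = list(ids, vocab))
  for (i in seq_along(token_lists)) {
    if (length(token_lists[[i]]) == 0L) next
    tab <- table(token_lists[[i]])
    m[i, names(tab)] <- as.integer(tab)
  }
  new("PatternCountMatrix", counts = m)
}

#' Variance filter, standardization and PCA to component scores
#'
#' Removes patterns with variance below \code{var_thresh}, standardizes to
#' zero mean and unit variance, and projects onto the top
#' \code{n_components} principal components — every step fitted on the
#' training rows only. When fewer features survive the filter than
#' components requested, the component count is capped with a warning.
#'
#' @param pcm a \linkS4class{PatternCountMatrix} (or plain count matrix).
#' @param var_thresh variance threshold (default 0.01).
#' @param n_components number of components to retain (default 20).
#' @param fit_ids rownames (or logical/integer index) of the training
#'   subset; defaults to all rows.
#' @return list with \code{scores} (all rows x components),
#'   \code{explained_variance_ratio}, and \code{transform} (kept patterns,
#'   scaler and rotation) for projecting new compounds via
#'   \code{\link{projectComponents}}.
#' @export
reduceToComponents <- function(pcm, var_thresh = 0.01, n_components = 20L,
                               fit_ids = NULL) {
  m <- if (is(pcm, "PatternCountMatrix")) patternCounts(pcm) else as.matrix(pcm)
  if (is.null(fit_ids)) fit_ids <- seq_len(nrow(m))
  Xfit <- m[fit_ids, , drop = FALSE]
  if (nrow(Xfit) == 0L) stop("training subset is empty")
  vars <- apply(Xfit, 2, var)
  keep <- colnames(m)[vars >= var_thresh & is.finite(vars)]
  if (length(keep) == 0L) stop("no patterns survive the variance filter")
  if (length(keep) < n_components) {
    warning("only ", length(keep), " patterns survive filtering; components capped")
    n_components <- length(keep)
  }
  n_components <- min(n_components, nrow(Xfit) - 1L)
  scaler <- fitScaler(Xfit[, keep, drop = FALSE])
  Zfit <- applyScaler(Xfit[, keep, drop = FALSE], scaler)
  pca <- prcomp(Zfit, center = FALSE, scale. = FALSE)
  rot <- pca$rotation[, seq_len(n_components), drop = FALSE]
  evr <- pca$sdev^2 / sum(pca$sdev^2)
  transform <- list(patterns = keep, scaler = scaler, rotation = rot,
                    full_rotation = pca$rotation)
  scores <- projectComponents(m, transform)
  list(scores = scores, explained_variance_ratio = evr[seq_len(n_components)],
       transform = transform)
}

#' @rdname reduceToComponents
#' @param m count matrix over the same vocabulary (missing patterns count 0).
#' @param transform the fitted transform.
#' @export
projectComponents <- function(m, transform) {
  m <- as.matrix(m)
  missing <- setdiff(transform$patterns, colnames(m))
  if (length(missing) > 0L) {
    m <- cbind(m, matrix(0, nrow(m), length(missing),
                         dimnames = list(rownames(m), missing)))
  }
  Z <- applyScaler(m[, transform$patterns, drop = FALSE], transform$scaler)
  Z %*% transform$rotation
}

## ---- classifier registry -------------------------------------------------

.classifierFamilies <- c("LR", "SVM", "RF", "GB", "KNN")

.fitClassifier <- function(family, X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  fit <- switch(family,
    LR = suppressWarnings(
      glm(y ~ ., data = data.frame(y = y, X, check.names = FALSE),
          family = binomial())),
    SVM = e1071::svm(X, factor(y, levels = c(0, 1)), probability = TRUE),
    RF = randomForest::randomForest(X, factor(y, levels = c(0, 1))),
    GB = xgboost::xgboost(X, factor(y, levels = c(0, 1)), nrounds = 100,
                          learning_rate = 0.1, max_depth = 3,
                          verbosity = 0, nthreads = 1),
    KNN = caret::knn3(X, factor(y, levels = c(0, 1)), k = 5),
    stop("unknown classifier family: ", family)
  )
  structure(list(family = family, fit = fit, features = colnames(X)),
            class = "stackscreenClassifier")
}

#' @export
predict.stackscreenClassifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features)) X <- X[, object$features, drop = FALSE]
  switch(object$family,
    LR = unname(predict(object$fit, data.frame(X, check.names = FALSE),
                        type = "response")),
    SVM = {
      pr <- predict(object$fit, X, probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    },
    RF = unname(predict(object$fit, X, type = "prob")[, "1"]),
    GB = unname(predict(object$fit, X, type = "response")),
    KNN = unname(predict(object$fit, X, type = "prob")[, "1"])
  )
}

## Pooled out-of-fold probabilities for one family.
.cvProbabilities <- function(family, X, y, folds, seed) {
  fold <- stratifiedFolds(y, folds, seed)
  prob <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) stop("class absent from a training fold")
    mod <- withSeed(subSeed(seed, 100L + f), .fitClassifier(family, X[tr, , drop = FALSE], y[tr]))
    prob[!tr] <- predict(mod, X[!tr, , drop = FALSE])
  }
  prob
}

#' Train and evaluate the five classifier families across seeds
#'
#' Per seed: a stratified 80/20 split, five-fold cross-validation on the
#' training fold (pooled out-of-fold probabilities), and a fit on the full
#' training fold evaluated on both partitions. Families: logistic
#' regression, support vector machine (probability-enabled), random
#' forest, gradient boosting and k-nearest neighbours, with library
#' defaults. The best family has the highest mean CV ROC AUC, with mean CV
#' MCC as the tiebreak; the returned final model is that family refitted
#' on the complete dataset.
#'
#' @param X numeric feature matrix (component scores).
#' @param y 0/1 labels (both classes present).
#' @param seeds number of random split seeds (default 10).
#' @param folds CV folds (default 5).
#' @param base_seed base RNG seed from which split seeds derive.
#' @param threshold probability cutoff for label metrics (default 0.5).
#' @return list with \code{evals} (model x seed x partition metric rows),
#'   \code{best} (family), \code{final_model} (refit on all data),
#'   \code{importance} (forest Gini importance per component, when the
#'   forest is available).
#' @export
trainClassifiers <- function(X, y, seeds = 10L, folds = 5L, base_seed = 1L,
                             threshold = 0.5) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  rows <- list()
  for (s in seq_len(seeds)) {
    seed_s <- subSeed(base_seed, s)
    train <- stratifiedSplit(y, 0.8, seed_s)
    Xtr <- X[train, , drop = FALSE]; ytr <- y[train]
    Xte <- X[!train, , drop = FALSE]; yte <- y[!train]
    for (fam in .classifierFamilies) {
      cv_prob <- .cvProbabilities(fam, Xtr, ytr, folds, seed_s)
      mod <- withSeed(subSeed(seed_s, match(fam, .classifierFamilies)),
                      .fitClassifier(fam, Xtr, ytr))
      p_tr <- predict(mod, Xtr); p_te <- predict(mod, Xte)
      for (part in c("train", "cv", "test")) {
        pr <- switch(part, train = p_tr, cv = cv_prob, test = p_te)
        yy <- switch(part, train = ytr, cv = ytr, test = yte)
        met <- classificationMetrics(yy, as.integer(pr >= threshold), pr)
        rows[[length(rows) + 1L]] <- data.frame(
          model = fam, seed = s, partition = part, t(met),
          stringsAsFactors = FALSE)
      }
    }
  }
  evals <- do.call(rbind, rows)
  cv <- evals[evals$partition == "cv", ]
  agg <- aggregate(cbind(roc_auc, MCC) ~ model, data = cv, FUN = mean)
  agg <- agg[order(-agg$roc_auc, -agg$MCC), ]
  best <- agg$model[1L]
  final_model <- withSeed(base_seed, .fitClassifier(best, X, y))
  rf_imp <- NULL
  if (best == "RF") {
    rf_imp <- randomForest::importance(final_model$fit)[, 1]
  } else {
    rf_all <- withSeed(base_seed,
                       .fitClassifier("RF", X, y))
    rf_imp <- randomForest::importance(rf_all$fit)[, 1]
  }
  list(evals = evals, cv_summary = agg, best = best,
       final_model = final_model, importance = rf_imp)
}

#' Maximum fingerprint similarity to a training set
#'
#' For each query count vector, the maximum generalized Tanimoto similarity
#' (\code{\link{countSimilarity}}) to any training compound; used as the
#' fingerprint applicability-domain gate (default threshold 0.8).
#'
#' @param query,train count matrices over the same vocabulary.
#' @return numeric vector, one maximum similarity per query row.
#' @export
maxCountSimilarity <- function(query, train) {
  query <- as.matrix(query); train <- as.matrix(train)
  if (ncol(query) != ncol(train)) stop("vocabulary mismatch")
  vapply(seq_len(nrow(query)), function(i) {
    q <- query[i, ]
    max(vapply(seq_len(nrow(train)), function(j) {
      denom <- sum(pmax(q, train[j, ]))
      if (denom == 0) 1 else sum(pmin(q, train[j, ])) / denom
    }, numeric(1)))
  }, numeric(1))
}
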