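## Stacked logistic meta-model: QSAR-predicted pIC50, classifier
## probability and relevant-scaffold one-hot bits, combined by an
## L2-regularised logistic regression.

#' Min-max scaling to [-1, 1]
#'
#' x' = 2 (x - min)/(max - min) - 1, with min/max fitted on training
#' values. Queries outside the training range are clipped to +/- 1 with a
#' logged count.
#'
#' @param values numeric vector to scale.
#' @param fit_min,fit_max training minimum and maximum (\code{fit_max}
#'   must exceed \code{fit_min}).
#' @return numeric vector in [-1, 1]; attribute \code{"n_clipped"} counts
#'   clipped values.
#' @export
scaleToUnitInterval <- function(values, fit_min, fit_max) {
  if (!is.finite(fit_min) || !is.finite(fit_max) || fit_max <= fit_min) {
    stop("fit_max must exceed fit_min")
  }
  x <- 2 * (values - fit_min) / (fit_max - fit_min) - 1
  n_clip <- sum(x < -1 | x > 1)
  if (n_clip > 0) message(n_clip, " value(s) clipped to [-1, 1]")
  structure(pmin(1, pmax(-1, x)), n_clipped = n_clip)
}

#' Assemble meta-model features
#'
#' Two continuous inputs (predicted pIC50 and classifier probability),
#' min-max scaled to [-1, 1] with training bounds, plus the relevant
#' scaffold one-hot bits (left unscaled: already 0/1).
#'
#' @param pred_pic50,pred_proba numeric vectors.
#' @param scaffold_bits binary matrix (may have zero columns).
#' @param bounds optional list of training bounds (\code{pic50}, \code{proba}
#'   each c(min, max)); fitted from the data when NULL.
#' @return list with \code{X} (feature matrix) and \code{bounds}.
#' @export
metaFeatures <- function(pred_pic50, pred_proba, scaffold_bits, bounds = NULL) {
  scaffold_bits <- as.matrix(scaffold_bits)
  if (is.null(bounds)) {
    bounds <- list(pic50 = range(pred_pic50), proba = range(pred_proba))
  }
  X <- cbind(
    pred_pic50 = as.numeric(scaleToUnitInterval(pred_pic50, bounds$pic50[1], bounds$pic50[2])),
    pred_proba = as.numeric(scaleToUnitInterval(pred_proba, bounds$proba[1], bounds$proba[2]))
  )
  if (ncol(scaffold_bits) > 0L) X <- cbind(X, scaffold_bits)
  list(X = X, bounds = bounds)
}

#' Fit the L2-regularised logistic meta-model
#'
#' Ridge-penalised logistic regression (penalty strength fixed at the
#' conventional default, lambda = 1/n) on the stacked features, evaluated
#' with per-seed stratified 80/20 splits and five-fold CV ROC AUC.
#' Coefficients are exposed per feature for interpretation; the ridge
#' penalty keeps them finite even under complete separation.
#'
#' @param X meta-feature matrix (continuous features already in [-1, 1]).
#' @param y 0/1 labels.
#' @param seeds number of evaluation split seeds (default 10).
#' @param folds CV folds (default 5).
#' @param base_seed base RNG seed.
#' @return list with \code{model} (glmnet fit on all data), \code{lambda},
#'   \code{coefficients} (named, including intercept), \code{evals}
#'   (per-seed train/test/CV ROC AUC).
#' @export
fitMeta <- function(X, y, seeds = 10L, folds = 5L, base_seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  lambda <- 1 / length(y)
  fit_ridge <- function(Xf, yf) {
    glmnet::glmnet(Xf, yf, family = "binomial", alpha = 0,
                   lambda = lambda, standardize = FALSE)
  }
  rows <- list()
  for (s in seq_len(seeds)) {
    seed_s <- subSeed(base_seed, s)
    train <- stratifiedSplit(y, 0.8, seed_s)
    mod <- fit_ridge(X[train, , drop = FALSE], y[train])
    p_tr <- as.numeric(predict(mod, X[train, , drop = FALSE], type = "response"))
    p_te <- as.numeric(predict(mod, X[!train, , drop = FALSE], type = "response"))
    fold <- stratifiedFolds(y[train], folds, seed_s)
    cv_prob <- numeric(sum(train))
    Xtr <- X[train, , drop = FALSE]; ytr <- y[train]
    for (f in seq_len(folds)) {
      inn <- fold != f
      m_f <- fit_ridge(Xtr[inn, , drop = FALSE], ytr[inn])
      cv_prob[!inn] <- as.numeric(predict(m_f, Xtr[!inn, , drop = FALSE],
                                          type = "response"))
    }
    rows[[s]] <- data.frame(
      seed = s,
      train_auc = rocAuc(p_tr, y[train]),
      test_auc = rocAuc(p_te, y[!train]),
      cv_auc = rocAuc(cv_prob, ytr))
  }
  model <- fit_ridge(X, y)
  co <- as.numeric(coef(model))
  names(co) <- rownames(coef(model))
  list(model = model, lambda = lambda, coefficients = co,
       evals = do.call(rbind, rows), features = colnames(X))
}

#' Predict meta-model probabilities
#'
#' @param meta a fitted meta-model from \code{\link{fitMeta}}.
#' @param X feature matrix scaled with the training bounds (columns must
#'   match the training schema).
#' @param cutoff gate decision cutoff (default 0.5).
#' @return data.frame with \code{probability} in [0, 1] and logical
#'   \code{pass}.
#' @export
predictMeta <- function(meta, X, cutoff = 0.5) {
  X <- as.matrix(X)
  if (!identical(colnames(X), meta$features)) {
    stop("meta-feature schema mismatch: expected columns ",
         paste(meta$features, collapse = ", "))
  }
  p <- as.numeric(predict(meta$model, X, type = "response"))
  data.frame(probability = p, pass = p > cutoff)
}
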