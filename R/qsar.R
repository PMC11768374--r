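## Descriptor-based QSAR: descriptor panel, three-stage feature selection,
## five regression families with cross-validated metrics, interpretability
## (permutation importance, PDP/ICE) and a three-method applicability
## domain (leverage/Williams, PCA projection, descriptor ranges).

## Graph/constitutional descriptors for one molecule.
.graphDescriptors <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elems <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  bonds <- if (nrow(bb) > 0) {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else data.frame(a1 = integer(), a2 = integer(), order = integer())
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(bonds) > 0) g <- igraph::add_edges(g, t(as.matrix(bonds[, 1:2])))
  deg <- igraph::degree(g)
  d <- igraph::distances(g)
  finite_d <- d[is.finite(d) & d > 0]
  info <- .ringSystems(sdf)
  ring_atoms <- unique(unlist(info$systems))
  in_ring_bond <- if (nrow(bonds) > 0) {
    bonds$a1 %in% ring_atoms & bonds$a2 %in% ring_atoms
  } else logical(0)
  rot <- if (nrow(bonds) > 0) {
    sum(bonds$order == 1 & !in_ring_bond & deg[bonds$a1] > 1 & deg[bonds$a2] > 1)
  } else 0
  c(nHeavyAtoms = n, nBonds = nrow(bonds),
    nC = sum(elems == "C"), nN = sum(elems == "N"), nO = sum(elems == "O"),
    nS = sum(elems == "S"), nHalogen = sum(elems %in% c("F", "Cl", "Br", "I")),
    nRingAtoms = length(ring_atoms), nRingSystems = length(info$systems),
    fracRingAtoms = length(ring_atoms) / n,
    nRotatableBonds = rot,
    nDoubleBonds = sum(bonds$order == 2), nTripleBonds = sum(bonds$order == 3),
    meanDegree = mean(deg), maxDegree = max(deg),
    wienerIndex = sum(finite_d) / 2, zagrebM1 = sum(deg^2),
    graphDiameter = if (length(finite_d)) max(finite_d) else 0,
    graphRadius = if (length(finite_d)) {
      min(apply(d, 1, function(r) max(r[is.finite(r)])))
    } else 0)
}

#' Compute a molecular descriptor matrix
#'
#' Numeric descriptor panel combining OpenBabel property descriptors
#' (molecular weight, logP, molar refractivity, TPSA, H-bond donor and
#' acceptor counts, fluorine count) with graph and constitutional
#' descriptors computed from the molecular graph (atom/bond/ring counts,
#' rotatable bonds, degree statistics, Wiener and Zagreb indices, graph
#' diameter and radius). Columns containing any missing or non-numeric
#' value are dropped; invalid molecules are rejected with a warning.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional compound ids (rownames of the result).
#' @return numeric matrix, compounds x descriptors.
#' @export
computeDescriptors <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("CMP", seq_along(smiles))
  sdfset <- smilesToSDF(smiles, ids)
  skipped <- attr(sdfset, "skipped")
  if (length(skipped) > 0L) {
    warning(length(skipped), " molecule(s) rejected: ",
            paste(skipped, collapse = ", "))
  }
  if (length(sdfset) == 0L) stop("no valid molecules")
  pb <- ChemmineR::propOB(sdfset)
  num_cols <- c("MW", "logP", "MR", "TPSA", "HBA1", "HBA2", "HBD", "nF")
  num_cols <- intersect(num_cols, colnames(pb))
  P <- as.matrix(pb[, num_cols, drop = FALSE])
  G <- t(vapply(seq_along(sdfset), function(i) .graphDescriptors(sdfset[[i]]),
                numeric(19)))
  X <- cbind(P, G)
  rownames(X) <- ChemmineR::cid(sdfset)
  storage.mode(X) <- "double"
  ok <- apply(X, 2, function(col) all(is.finite(col)))
  X[, ok, drop = FALSE]
}

#' Three-stage descriptor selection
#'
#' Stage 1 removes columns with variance below \code{var_thresh}. Stage 2
#' greedily prunes correlated pairs: while any pair exceeds
#' \code{corr_thresh} in absolute Pearson correlation, the member of the
#' worst pair with the larger mean absolute correlation to all remaining
#' columns is dropped. Stage 3 runs recursive feature elimination with a
#' seeded random-forest regressor, removing the least important feature one
#' step at a time down to \code{k} features.
#'
#' @param X numeric descriptor matrix with column names.
#' @param y response vector aligned with rows of \code{X}.
#' @param var_thresh variance threshold (default 0.01).
#' @param corr_thresh correlation threshold (default 0.85).
#' @param k number of features to retain (default 10).
#' @param seed RNG seed for the forest.
#' @param ntree forest size used inside RFE (default 300).
#' @return list with \code{selected} (column names) and \code{report}
#'   (features dropped at each stage, in order).
#' @export
selectFeatures <- function(X, y, var_thresh = 0.01, corr_thresh = 0.85,
                           k = 10L, seed = 1L, ntree = 300L) {
  stopifnot(nrow(X) == length(y))
  vars <- apply(X, 2, var)
  drop_var <- colnames(X)[vars < var_thresh | !is.finite(vars)]
  X1 <- X[, setdiff(colnames(X), drop_var), drop = FALSE]
  drop_cor <- character(0)
  repeat {
    if (ncol(X1) < 2L) break
    C <- abs(cor(X1))
    diag(C) <- 0
    mx <- max(C)
    if (mx <= corr_thresh) break
    idx <- which(C == mx, arr.ind = TRUE)[1L, ]
    mean_abs <- colMeans(C)
    victim <- if (mean_abs[idx[1]] >= mean_abs[idx[2]]) idx[1] else idx[2]
    drop_cor <- c(drop_cor, colnames(X1)[victim])
    X1 <- X1[, -victim, drop = FALSE]
  }
  if (ncol(X1) < k) {
    stop("only ", ncol(X1), " features survive filtering; cannot select ", k)
  }
  drop_rfe <- character(0)
  Xr <- X1
  withSeed(seed, {
    while (ncol(Xr) > k) {
      rf <- randomForest::randomForest(Xr, y, ntree = ntree, importance = FALSE)
      imp <- randomForest::importance(rf)[, 1]
      worst <- names(which.min(imp))
      drop_rfe <- c(drop_rfe, worst)
      Xr <- Xr[, setdiff(colnames(Xr), worst), drop = FALSE]
    }
  })
  list(selected = colnames(Xr),
       report = list(variance_dropped = drop_var,
                     correlation_dropped = drop_cor,
                     rfe_dropped = drop_rfe))
}

## ---- regression model registry -------------------------------------------

.regressorFamilies <- c("MLR", "PLS", "SVM", "RF", "GB")

.fitRegressor <- function(family, X, y) {
  X <- as.matrix(X)
  fit <- switch(family,
    MLR = lm(y ~ ., data = data.frame(y = y, X, check.names = FALSE)),
    PLS = mixOmics::pls(X, y, ncomp = min(2L, ncol(X), nrow(X) - 1L),
                        scale = FALSE),
    SVM = e1071::svm(X, y),
    RF = randomForest::randomForest(X, y),
    GB = xgboost::xgboost(X, y, nrounds = 100, learning_rate = 0.1,
                          max_depth = 3, verbosity = 0, nthreads = 1),
    stop("unknown regression family: ", family)
  )
  structure(list(family = family, fit = fit, features = colnames(X)),
            class = "stackscreenRegressor")
}

#' @export
predict.stackscreenRegressor <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  switch(object$family,
    MLR = unname(predict(object$fit, data.frame(X, check.names = FALSE))),
    PLS = {
      pr <- predict(object$fit, X)
      unname(pr$predict[, 1, dim(pr$predict)[3]])
    },
    SVM = unname(predict(object$fit, X)),
    RF = unname(predict(object$fit, X)),
    GB = unname(predict(object$fit, X))
  )
}

#' Cross-validated Q2 of a regression family
#'
#' Five-fold (by default) out-of-fold coefficient of determination on the
#' training set; each fold re-fits the scaler and model on its in-fold
#' rows only. Reported as mean and standard deviation across folds.
#'
#' @param family one of \code{"MLR"}, \code{"PLS"}, \code{"SVM"},
#'   \code{"RF"}, \code{"GB"}.
#' @param X_train,y_train training data (unscaled).
#' @param folds number of folds (>= 2, default 5).
#' @param seed RNG seed for fold assignment and model fitting.
#' @return list with \code{mean}, \code{sd} and per-fold \code{q2}.
#' @export
crossValidatedQ2 <- function(family, X_train, y_train, folds = 5L, seed = 1L) {
  stopifnot(folds >= 2L)
  strata <- responseStrata(y_train)
  fold <- stratifiedFolds(strata, folds, seed)
  if (min(table(fold)) < 2L) stop("a fold has fewer than 2 samples")
  q2 <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    scaler <- fitScaler(X_train[tr, , drop = FALSE])
    Xtr <- applyScaler(X_train[tr, , drop = FALSE], scaler)
    Xte <- applyScaler(X_train[!tr, , drop = FALSE], scaler)
    mod <- withSeed(subSeed(seed, f), .fitRegressor(family, Xtr, y_train[tr]))
    rSquared(y_train[!tr], predict(mod, Xte))
  }, numeric(1))
  list(mean = mean(q2), sd = sd(q2), q2 = q2)
}

#' Train the five regression families
#'
#' One seeded 80/20 split stratified by response quantile; features are
#' standardized with training statistics only. Fits multiple linear
#' regression, partial least squares, support-vector, random-forest and
#' gradient-boosting regressors with library-default hyperparameters, and
#' evaluates R2/RMSE/MAE on both partitions plus five-fold cross-validated
#' Q2 on the training set. The best model has the highest mean Q2, with
#' test R2 as the tiebreak.
#'
#' @param X numeric feature matrix (already feature-selected).
#' @param y response (pIC50) vector; zero variance is an error.
#' @param split_ratio training fraction (default 0.8).
#' @param seed RNG seed.
#' @param folds CV folds for Q2 (default 5).
#' @param stratify stratify the split by response quantile (default TRUE).
#' @return list with \code{evals} (one row per family), \code{models}
#'   (fitted regressors on the training fold), \code{best} (family name),
#'   \code{scaler}, \code{train} (logical split vector).
#' @export
trainRegressors <- function(X, y, split_ratio = 0.8, seed = 1L, folds = 5L,
                            stratify = TRUE) {
  if (var(y) == 0) stop("response has zero variance")
  strata <- if (stratify) responseStrata(y) else rep(1L, length(y))
  train <- stratifiedSplit(strata, split_ratio, seed)
  scaler <- fitScaler(X[train, , drop = FALSE])
  Xtr <- applyScaler(X[train, , drop = FALSE], scaler)
  Xte <- applyScaler(X[!train, , drop = FALSE], scaler)
  ytr <- y[train]; yte <- y[!train]
  models <- list()
  rows <- lapply(.regressorFamilies, function(fam) {
    mod <- withSeed(subSeed(seed, match(fam, .regressorFamilies)),
                    .fitRegressor(fam, Xtr, ytr))
    models[[fam]] <<- mod
    p_tr <- predict(mod, Xtr); p_te <- predict(mod, Xte)
    q2 <- crossValidatedQ2(fam, X[train, , drop = FALSE], ytr,
                           folds = folds, seed = seed)
    data.frame(model = fam,
               train_r2 = rSquared(ytr, p_tr), test_r2 = rSquared(yte, p_te),
               train_rmse = rmse(ytr, p_tr), test_rmse = rmse(yte, p_te),
               train_mae = mae(ytr, p_tr), test_mae = mae(yte, p_te),
               q2_mean = q2$mean, q2_sd = q2$sd, stringsAsFactors = FALSE)
  })
  evals <- do.call(rbind, rows)
  ord <- order(-evals$q2_mean, -evals$test_r2)
  best <- evals$model[ord[1L]]
  list(evals = evals, models = models, best = best, scaler = scaler,
       train = train, seed = seed)
}

#' Permutation importance
#'
#' Mean decrease in R2 when a feature column is shuffled, averaged over
#' \code{n_repeats} seeded permutations.
#'
#' @param model a fitted regressor from \code{\link{trainRegressors}}.
#' @param X feature matrix (on the scale the model was fitted on).
#' @param y response vector.
#' @param n_repeats permutations per feature (default 10).
#' @param seed RNG seed.
#' @return named numeric vector of importances (one per feature).
#' @export
permutationImportance <- function(model, X, y, n_repeats = 10L, seed = 1L) {
  X <- as.matrix(X)
  base <- rSquared(y, predict(model, X))
  imp <- setNames(numeric(ncol(X)), colnames(X))
  withSeed(seed, {
    for (j in seq_len(ncol(X))) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[, j] <- X[sample(nrow(X)), j]
        base - rSquared(y, predict(model, Xp))
      }, numeric(1))
      imp[j] <- mean(drops)
    }
  })
  imp
}

#' Partial dependence and ICE profiles
#'
#' ICE curves clamp one feature to each grid value for every row and record
#' the model prediction; the partial dependence curve is the pointwise mean
#' of the ICE curves.
#'
#' @param model a fitted regressor.
#' @param X feature matrix.
#' @param feature feature name.
#' @param grid_size number of grid points across the feature's range.
#' @return list with \code{grid}, \code{pdp} (length grid_size) and
#'   \code{ice} (matrix rows x grid_size).
#' @export
dependenceProfiles <- function(model, X, feature, grid_size = 20L) {
  X <- as.matrix(X)
  if (!feature %in% colnames(X)) stop("unknown feature: ", feature)
  grid <- seq(min(X[, feature]), max(X[, feature]), length.out = grid_size)
  ice <- vapply(grid, function(v) {
    Xg <- X
    Xg[, feature] <- v
    predict(model, Xg)
  }, numeric(nrow(X)))
  ice <- matrix(ice, nrow = nrow(X))
  list(grid = grid, pdp = colMeans(ice), ice = ice)
}

#' Applicability domain report
#'
#' Three checks in the selected-descriptor space: (1) leverage
#' h = x (X'X)^-1 x' with an intercept column, against the Williams warning
#' leverage h* = 3 p / n (p = fitted parameters including the intercept),
#' with studentized residuals of the training regression for the Williams
#' plot; (2) projection of queries onto the first two principal components
#' of the standardized training space; (3) per-descriptor training
#' [min, max] range check. A query is in-domain when its leverage is at
#' most h* and every descriptor lies within the training range.
#'
#' @param X_train training descriptor matrix (selected descriptors).
#' @param y_train training response.
#' @param X_query query descriptor matrix over the same columns.
#' @return list with training and query leverages, \code{h_star},
#'   studentized residuals (training), PCA coordinates, descriptor ranges
#'   and \code{in_domain} flags for the queries.
#' @export
applicabilityDomain <- function(X_train, y_train, X_query) {
  X_train <- as.matrix(X_train)
  X_query <- as.matrix(X_query)[, colnames(X_train), drop = FALSE]
  n <- nrow(X_train)
  X1 <- cbind(1, X_train)
  XtX <- crossprod(X1)
  XtX_inv <- tryCatch(solve(XtX), error = function(e) {
    stop("singular descriptor cross-product; remove collinear descriptors")
  })
  h_train <- rowSums((X1 %*% XtX_inv) * X1)
  Q1 <- cbind(1, X_query)
  h_query <- rowSums((Q1 %*% XtX_inv) * Q1)
  p_fit <- ncol(X1)
  h_star <- 3 * p_fit / n
  fit <- lm(y ~ ., data = data.frame(y = y_train, X_train, check.names = FALSE))
  stud <- rstudent(fit)
  scaler <- fitScaler(X_train)
  pca <- prcomp(applyScaler(X_train, scaler), center = FALSE, scale. = FALSE)
  pc_train <- pca$x[, 1:2, drop = FALSE]
  pc_query <- (applyScaler(X_query, scaler) %*% pca$rotation)[, 1:2, drop = FALSE]
  ranges <- apply(X_train, 2, range)
  rownames(ranges) <- c("min", "max")
  in_range <- vapply(seq_len(nrow(X_query)), function(i) {
    all(X_query[i, ] >= ranges["min", ] & X_query[i, ] <= ranges["max", ])
  }, logical(1))
  list(leverage_train = h_train, leverage_query = h_query, h_star = h_star,
       studentized_residuals = stud, pca_train = pc_train, pca_query = pc_query,
       ranges = ranges, in_range = in_range,
       in_domain = (h_query <= h_star) & in_range)
}

#' @importFrom stats prcomp rstudent
NULL
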