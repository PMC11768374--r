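## Internal helpers shared across modules.

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a sub-seed from a base seed, kept within 32-bit integer range.
subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 31 * as.numeric(k)) %% 2147483647L)
}

#' Canonicalise SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form. Unparsable strings yield
#' \code{NA} so callers can reject the record with a warning.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES, \code{NA} where parsing
#'   failed.
#' @export
#' @examples
#' canonicalSmiles(c("C1=CC=CC=C1", "c1ccccc1"))  # same canonical form
canonicalSmiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", source = s)),
      error = function(e) ""
    )
    out <- trimws(sub("\t.*$", "", out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

## Parse SMILES into an ChemmineR SDFset; invalid entries are dropped and
## reported via the returned "skipped" attribute.
smilesToSDF <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("CMP", seq_along(smiles))
  keep <- logical(length(smiles))
  sdfs <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(smiles[[i]])),
      error = function(e) NULL
    )
    if (!is.null(sdf) && length(sdf) == 1L &&
        nrow(ChemmineR::atomblock(sdf[[1]])) > 0L) {
      keep[i] <- TRUE
      sdfs[[i]] <- sdf[[1]]
    }
  }
  if (!any(keep)) {
    out <- new("SDFset")
  } else {
    out <- new("SDFset", SDF = sdfs[keep], ID = ids[keep])
  }
  attr(out, "skipped") <- ids[!keep]
  out
}

## Stratified fold assignment: splits indices of each class evenly across
## `folds` folds, seeded. Returns an integer fold id per observation.
stratifiedFolds <- function(y, folds, seed) {
  y <- as.integer(as.factor(y))
  fold <- integer(length(y))
  withSeed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

## Stratified train/test split (classification labels or response quantile
## strata). Returns logical vector: TRUE = training row.
stratifiedSplit <- function(strata, train_fraction, seed) {
  train <- logical(length(strata))
  withSeed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      n_tr <- max(1L, round(length(idx) * train_fraction))
      if (length(idx) > 1L && n_tr == length(idx)) n_tr <- length(idx) - 1L
      train[sample(idx, n_tr)] <- TRUE
    }
  })
  train
}

## Quantile strata for a continuous response (used to stratify regression
## splits); constant responses collapse into a single stratum.
responseStrata <- function(y, n_strata = 4L) {
  qs <- unique(quantile(y, probs = seq(0, 1, length.out = n_strata + 1L)))
  if (length(qs) < 3L) return(rep(1L, length(y)))
  as.integer(cut(y, breaks = qs, include.lowest = TRUE))
}

## Column-wise standardiser fitted on training rows only.
fitScaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(center = mu, scale = sdv)
}

applyScaler <- function(X, scaler) {
  scale(X, center = scaler$center, scale = scaler$scale)[, , drop = FALSE]
}

## Coefficient of determination on observed vs predicted.
rSquared <- function(obs, pred) {
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  1 - ss_res / ss_tot
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))
mae <- function(obs, pred) mean(abs(obs - pred))
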