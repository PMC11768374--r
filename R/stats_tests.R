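## Rank and contingency statistics used by the scaffold-association and
## interaction-selection stages.

#' Mann-Whitney U test of an in-group against the pooled out-group
#'
#' Computes the U statistic of \code{in_group} (number of (in, out) pairs
#' with the in-group value larger, ties counting one half) and a two-sided
#' p value. An exact p is obtained by full enumeration of rank splits when
#' the smaller sample has at most 8 observations, there are no ties, and
#' the number of splits is tractable; otherwise the normal approximation
#' with tie and continuity corrections is used.
#'
#' @param in_group,out_group numeric vectors (both non-empty).
#' @param max_enumeration cap on the number of enumerated splits for the
#'   exact branch (default 2e5).
#' @return list with \code{U}, \code{p}, and \code{method}
#'   ("exact" or "normal-approx").
#' @export
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mannWhitneyU <- function(in_group, out_group, max_enumeration = 2e5) {
  if (length(in_group) == 0L || length(out_group) == 0L) {
    stop("both samples must be non-empty")
  }
  n1 <- length(in_group); n2 <- length(out_group)
  pooled <- c(in_group, out_group)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  n_splits <- choose(n1 + n2, min(n1, n2))
  if (!ties && min(n1, n2) <= 8L && n_splits <= max_enumeration) {
    p <- .mwExactP(r, n1, n2, U)
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  n <- n1 + n2
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal-approx"))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(U = U, p = min(1, 2 * pnorm(-z)), method = "normal-approx")
}

## Exact two-sided p: fraction of rank splits whose U deviates from n1*n2/2
## by at least as much as the observed U.
.mwExactP <- function(ranks, n1, n2, U_obs) {
  n <- n1 + n2
  m <- min(n1, n2)
  mu <- n1 * n2 / 2
  # U of group 1 and of group 2 are mirror images; enumerate the smaller one.
  splits <- combn(n, m)
  offset <- m * (m + 1) / 2
  U_all <- colSums(matrix(seq_len(n)[splits], nrow = m)) - offset
  dev_obs <- abs(U_obs - mu)
  mean(abs(U_all - mu) >= dev_obs - 1e-12)
}

#' Chi-square test of independence with standardized residuals
#'
#' Pearson chi-square on an r x c contingency table: X2 = sum (O-E)^2/E
#' with expected counts from the product of the margins, df = (r-1)(c-1),
#' and per-cell standardized residuals (O-E)/sqrt(E). Cells with
#' standardized residual beyond +/- 1.96 are flagged significant at the 95%
#' confidence level. The adjusted (Haberman) residual
#' (O-E)/sqrt(E(1-row/N)(1-col/N)) is available via \code{adjusted}.
#'
#' @param O matrix of observed counts (positive margins required).
#' @param adjusted also return Haberman-adjusted residuals.
#' @param residual_cutoff significance cutoff on the residuals (default 1.96).
#' @return list with \code{X2}, \code{df}, \code{p}, \code{expected},
#'   \code{std_residual}, \code{significant} (logical matrix), and
#'   optionally \code{adj_residual}.
#' @export
chiSquareTable <- function(O, adjusted = FALSE, residual_cutoff = 1.96) {
  O <- as.matrix(O)
  rs <- rowSums(O); cs <- colSums(O); N <- sum(O)
  if (any(rs == 0)) stop("zero row margin: ", paste(which(rs == 0), collapse = ", "))
  if (any(cs == 0)) stop("zero column margin: ", paste(which(cs == 0), collapse = ", "))
  E <- outer(rs, cs) / N
  X2 <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  std <- (O - E) / sqrt(E)
  out <- list(X2 = X2, df = df, p = pchisq(X2, df, lower.tail = FALSE),
              expected = E, std_residual = std,
              significant = abs(std) > residual_cutoff)
  if (adjusted) {
    out$adj_residual <- (O - E) / sqrt(E * outer(1 - rs / N, 1 - cs / N))
  }
  out
}
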