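# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
pinv_lstsq <- function(X, y, rtol = 1e-10) {
  # Minimum-norm least squares via SVD with a relative singular-value
  # cutoff, so rank-deficient designs (e.g. data projected into a
  # null-space) are handled without error.
  s <- svd(X)
  keep <- s$d > rtol * s$d[1]
  if (!any(keep)) return(rep(0, ncol(X)))
  s$v[, keep, drop = FALSE] %*%
    ((crossprod(s$u[, keep, drop = FALSE], y)) / s$d[keep])
}

#' @keywords internal
#' @noRd
unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

# Stratified k-fold assignment: within each class, indices are shuffled
# and dealt to folds round-robin, so fold class counts differ by at most 1.
#' @keywords internal
#' @noRd
stratified_folds <- function(labels, folds, seed) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < folds)) {
    bad <- names(counts)[counts < folds][1]
    stop(sprintf("class '%s' has fewer trials (%d) than folds (%d)",
                 bad, min(counts), folds))
  }
  fold <- integer(length(labels))
  set.seed(seed)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

# Deterministic alternating split used for cross-fitted projections.
#' @keywords internal
#' @noRd
alternating_halves <- function(n) {
  a <- seq(1, n, by = 2)
  list(a = a, b = setdiff(seq_len(n), a))
}

#' @keywords internal
#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x
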