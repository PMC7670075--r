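# Internal numerical helpers shared across modules.

# Row-wise sample variance of a numeric matrix (n-1 denominator).
# Two-pass (center first) to avoid cancellation on large offsets.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 columns to estimate a variance")
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1L)
}

col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows to estimate a variance")
  mu <- colMeans(x)
  colSums((t(t(x) - mu))^2) / (n - 1L)
}

# df-weighted pooled variance of two replicate groups (matrices, spots x reps)
pooled_parent_variance <- function(v1, n1, v2, n2) {
  ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
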