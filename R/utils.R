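# Internal helpers shared across modules.

# Row-major upper-triangle edge vector of a square matrix: values m[i, j]
# for i < j, ordered by row then column. This ordering is the package-wide
# edge convention; SC, FC and mask vectors must all use it.
edge_vector <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  t(m)[lower.tri(m)]
}

# (i, j) node-index pairs matching edge_vector() ordering.
edge_index <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) seq.int(k + 1L, n)), use.names = FALSE)
  cbind(i = i, j = j)
}

# Rebuild a symmetric zero-diagonal matrix from an edge vector.
edge_matrix <- function(v, n, labels = NULL) {
  idx <- edge_index(n)
  m <- matrix(0, n, n)
  m[idx] <- v
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

n_edges_of <- function(n) n * (n - 1L) / 2L

# Symmetric positive-semidefinite square root via eigendecomposition.
sqrtm_psd <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# Project a symmetric matrix to the nearest (in the eigenvalue-clipping
# sense) positive-semidefinite correlation-like matrix with unit diagonal.
project_correlation <- function(m, eps = 1e-8) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -eps) {
    diag(m) <- 1
    return(m)
  }
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out
}

check_square_symmetric <- function(m, name, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("`%s` must be a square matrix.", name), call. = FALSE)
  }
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    warning(sprintf("`%s` asymmetric (max |m - t(m)| = %.3g); symmetrized by averaging.",
                    name, asym), call. = FALSE)
  }
  (m + t(m)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
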