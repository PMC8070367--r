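#' Truncated SVD of a (sparse) feature matrix
#'
#' Computes the top-k right singular subspace of an n x d matrix without
#' mean-centering (the geometric features are sparse binary vectors and
#' centering would destroy sparsity). The decomposition is obtained exactly
#' from the symmetric eigendecomposition of the smaller Gram matrix
#' (X X' when n <= d, X'X otherwise), which is deterministic; `seed` is
#' recorded in the model for provenance. Component signs are fixed so each
#' component's largest-magnitude entry is positive.
#'
#' Fit on training rows only; transform held-out rows with the frozen model.
#'
#' @param x numeric or `Matrix` sparse n x d matrix.
#' @param k number of components, `1 <= k <= min(n, d)`.
#' @param seed integer, recorded in the model.
#' @return An [SvdModel-class].
#' @export
fitTruncatedSvd <- function(x, k, seed = 1L) {
  n <- nrow(x)
  d <- ncol(x)
  k <- as.integer(k)
  if (k < 1 || k > min(n, d)) stop("k out of range: need 1 <= k <= min(n, d)")
  if (n <= d) {
    G <- as.matrix(Matrix::tcrossprod(x))
    eig <- eigen(G, symmetric = TRUE)
    sv <- sqrt(pmax(eig$values[seq_len(k)], 0))
    if (any(sv < 1e-10))
      stop("k exceeds the numerical rank of the matrix")
    U <- eig$vectors[, seq_len(k), drop = FALSE]
    V <- as.matrix(Matrix::crossprod(x, U)) %*% diag(1 / sv, k)
  } else {
    G <- as.matrix(Matrix::crossprod(x))
    eig <- eigen(G, symmetric = TRUE)
    sv <- sqrt(pmax(eig$values[seq_len(k)], 0))
    if (any(sv < 1e-10))
      stop("k exceeds the numerical rank of the matrix")
    V <- eig$vectors[, seq_len(k), drop = FALSE]
  }
  comp <- t(V)
  for (j in seq_len(k)) {
    i <- which.max(abs(comp[j, ]))
    if (comp[j, i] < 0) comp[j, ] <- -comp[j, ]
  }
  new("SvdModel", components = comp, singularValues = sv, k = k,
      d = as.integer(d), seed = as.integer(seed))
}

#' Project feature vectors onto the truncated SVD basis
#'
#' `values = components %*% vec`: for training rows this equals the
#' corresponding row of U * Sigma up to the fixed sign convention.
#'
#' @param model an [SvdModel-class].
#' @param x a length-d vector, or an n x d matrix (rows transformed).
#' @return length-k vector, or n x k matrix.
#' @export
svdTransform <- function(model, x) {
  if (is.null(dim(x))) {
    if (length(x) != model@d)
      stop("length mismatch: expected ", model@d, " features")
    return(drop(model@components %*% x))
  }
  if (ncol(x) != model@d)
    stop("length mismatch: expected ", model@d, " features")
  as.matrix(x %*% t(model@components))
}

#' Truncate an SVD model to fewer components
#'
#' The top-k2 subspace of a rank-k model is its first k2 components, so a
#' single fit can serve several downstream component counts.
#'
#' @param model an [SvdModel-class].
#' @param k2 new component count, `1 <= k2 <= k`.
#' @return An [SvdModel-class] with `k2` components.
#' @export
svdTruncate <- function(model, k2) {
  k2 <- as.integer(k2)
  if (k2 < 1 || k2 > model@k) stop("k2 out of range")
  new("SvdModel", components = model@components[seq_len(k2), , drop = FALSE],
      singularValues = model@singularValues[seq_len(k2)], k = k2,
      d = model@d, seed = model@seed)
}
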