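# Dense linear-algebra helpers shared by the MFA and balancing code.
# All rank decisions go through one SVD-based routine so that the same
# `rank_tol` convention applies everywhere.

# Default numerical rank tolerance for an m x n matrix with singular values
# sv: max(dim) * eps * max(sv).  Returns the tolerance actually used.
.rank_tol <- function(M, sv, rank_tol = NULL) {
  if (!is.null(rank_tol)) return(rank_tol)
  if (length(sv) == 0L || max(sv) == 0) return(.Machine$double.eps)
  max(dim(M)) * .Machine$double.eps * max(sv)
}

# Numerical rank via SVD.
mat_rank <- function(M, rank_tol = NULL) {
  M <- as.matrix(M)
  if (nrow(M) == 0L || ncol(M) == 0L) return(0L)
  sv <- svd(M, nu = 0L, nv = 0L)$d
  sum(sv > .rank_tol(M, sv, rank_tol))
}

# Orthonormal basis of the (right) nullspace of M, as columns.
# Returns an n x d matrix (d = nullity); n x 0 when the kernel is trivial.
nullspace_basis <- function(M, rank_tol = NULL) {
  M <- as.matrix(M)
  n <- ncol(M)
  if (n == 0L) return(matrix(0, 0L, 0L))
  if (nrow(M) == 0L) return(diag(1, n))
  s <- svd(M, nu = 0L, nv = n)
  r <- sum(s$d > .rank_tol(M, s$d, rank_tol))
  if (r >= n) return(matrix(0, n, 0L))
  s$v[, seq.int(r + 1L, n), drop = FALSE]
}

# Moore-Penrose pseudoinverse via SVD with the shared rank tolerance.
pinv <- function(M, rank_tol = NULL) {
  M <- as.matrix(M)
  if (nrow(M) == 0L || ncol(M) == 0L) return(t(M))
  s <- svd(M)
  tol <- .rank_tol(M, s$d, rank_tol)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

# Indices of a maximal set of linearly independent rows of M, found by QR
# with column pivoting on t(M).  The returned order follows the pivoting.
independent_rows <- function(M, rank_tol = NULL) {
  M <- as.matrix(M)
  if (nrow(M) == 0L || ncol(M) == 0L) return(integer(0))
  qr_t <- qr(t(M), LAPACK = TRUE)
  d <- abs(diag(qr_t$qr))
  d <- d[seq_len(min(dim(M)))]
  r <- mat_rank(M, rank_tol)
  if (r == 0L) return(integer(0))
  qr_t$pivot[seq_len(r)]
}

# Minimum-norm least-squares solution of M x = y (x = pinv(M) %*% y).
lstsq_minnorm <- function(M, y, rank_tol = NULL) {
  drop(pinv(M, rank_tol) %*% y)
}
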