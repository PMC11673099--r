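# Fixed 32x32 block-sparse matrices for grid collocation: a block is stored
# (as a dense, zero-padded 32x32 payload) only if at least one element
# reaches the zero-block threshold epsilon; absent blocks reconstruct as
# exact zeros.

BS_BLOCK <- 32L

#' Build a block-sparse matrix from a dense matrix
#'
#' @param M dense numeric matrix
#' @param eps zero-block threshold: a 32x32 block is dropped iff all its
#'   elements are < eps in magnitude (default 1e-12). `eps = 0` stores every
#'   block, so reconstruction is exact.
#' @return object of class `mdft_bsm`
#' @export
block_sparse <- function(M, eps = 1e-12) {
  nr <- nrow(M); nc <- ncol(M)
  nbr <- (nr + BS_BLOCK - 1L) %/% BS_BLOCK
  nbc <- (nc + BS_BLOCK - 1L) %/% BS_BLOCK
  bi <- integer(0); bj <- integer(0); blocks <- list()
  for (i in seq_len(nbr)) {
    r0 <- (i - 1L) * BS_BLOCK + 1L
    r1 <- min(i * BS_BLOCK, nr)
    for (j in seq_len(nbc)) {
      c0 <- (j - 1L) * BS_BLOCK + 1L
      c1 <- min(j * BS_BLOCK, nc)
      blk <- M[r0:r1, c0:c1, drop = FALSE]
      if (eps == 0 || max(abs(blk)) >= eps) {
        pay <- matrix(0, BS_BLOCK, BS_BLOCK)
        pay[seq_len(r1 - r0 + 1L), seq_len(c1 - c0 + 1L)] <- blk
        bi <- c(bi, i); bj <- c(bj, j)
        blocks[[length(blocks) + 1L]] <- pay
      }
    }
  }
  structure(list(nrow = nr, ncol = nc, nbr = nbr, nbc = nbc,
                 bi = bi, bj = bj, blocks = blocks, eps = eps),
            class = "mdft_bsm")
}

#' @export
print.mdft_bsm <- function(x, ...) {
  cat("<mdft_bsm> ", x$nrow, " x ", x$ncol, ", ",
      length(x$blocks), "/", x$nbr * x$nbc, " blocks stored (eps ",
      format(x$eps), ")\n", sep = "")
  invisible(x)
}

#' Fraction of 32x32 blocks stored
#' @param A an `mdft_bsm`
#' @return numeric in [0, 1]
#' @export
bs_stored_fraction <- function(A) length(A$blocks) / (A$nbr * A$nbc)

#' Reconstruct the dense matrix
#' @param A an `mdft_bsm`
#' @return dense numeric matrix; absent blocks are exactly zero
#' @export
bs_dense <- function(A) {
  M <- matrix(0, A$nrow, A$ncol)
  for (k in seq_along(A$blocks)) {
    r0 <- (A$bi[k] - 1L) * BS_BLOCK + 1L
    r1 <- min(A$bi[k] * BS_BLOCK, A$nrow)
    c0 <- (A$bj[k] - 1L) * BS_BLOCK + 1L
    c1 <- min(A$bj[k] * BS_BLOCK, A$ncol)
    M[r0:r1, c0:c1] <- A$blocks[[k]][seq_len(r1 - r0 + 1L),
                                     seq_len(c1 - c0 + 1L)]
  }
  M
}

#' Block-sparse times dense multiplication
#'
#' Tiled product equal to `bs_dense(A) %*% B`; absent tiles contribute
#' exactly zero.
#'
#' @param A an `mdft_bsm` (m x k)
#' @param B dense numeric matrix (k x n)
#' @return dense numeric matrix m x n
#' @export
block_sparse_gemm <- function(A, B) {
  if (!is.matrix(B)) B <- as.matrix(B)
  if (A$ncol != nrow(B))
    stop("shape mismatch: ", A$ncol, " vs ", nrow(B), call. = FALSE)
  C <- matrix(0, A$nrow, ncol(B))
  for (k in seq_along(A$blocks)) {
    r0 <- (A$bi[k] - 1L) * BS_BLOCK + 1L
    r1 <- min(A$bi[k] * BS_BLOCK, A$nrow)
    c0 <- (A$bj[k] - 1L) * BS_BLOCK + 1L
    c1 <- min(A$bj[k] * BS_BLOCK, A$ncol)
    C[r0:r1, ] <- C[r0:r1, ] +
      A$blocks[[k]][seq_len(r1 - r0 + 1L), seq_len(c1 - c0 + 1L), drop = FALSE] %*%
      B[c0:c1, , drop = FALSE]
  }
  C
}

# rowSums(dense(A) * X) using only stored blocks; X is dense, same shape.
bs_hadamard_rowsum <- function(A, X) {
  out <- numeric(A$nrow)
  for (k in seq_along(A$blocks)) {
    r0 <- (A$bi[k] - 1L) * BS_BLOCK + 1L
    r1 <- min(A$bi[k] * BS_BLOCK, A$nrow)
    c0 <- (A$bj[k] - 1L) * BS_BLOCK + 1L
    c1 <- min(A$bj[k] * BS_BLOCK, A$ncol)
    out[r0:r1] <- out[r0:r1] + rowSums(
      A$blocks[[k]][seq_len(r1 - r0 + 1L), seq_len(c1 - c0 + 1L), drop = FALSE] *
        X[r0:r1, c0:c1, drop = FALSE])
  }
  out
}

# t(dense(A)) %*% (w * dense(B)) accumulated tile-by-tile over the stored
# blocks of A and B (which may differ); w is a per-row weight vector.
bs_crossprod_weighted <- function(A, w, B) {
  out <- matrix(0, A$ncol, B$ncol)
  # index B blocks by row-block for pairing
  bmap <- split(seq_along(B$blocks), B$bi)
  for (k in seq_along(A$blocks)) {
    i <- A$bi[k]
    bk <- bmap[[as.character(i)]]
    if (is.null(bk)) next
    r0 <- (i - 1L) * BS_BLOCK + 1L
    r1 <- min(i * BS_BLOCK, A$nrow)
    nr <- r1 - r0 + 1L
    ca0 <- (A$bj[k] - 1L) * BS_BLOCK + 1L
    ca1 <- min(A$bj[k] * BS_BLOCK, A$ncol)
    Ablk <- A$blocks[[k]][seq_len(nr), seq_len(ca1 - ca0 + 1L), drop = FALSE]
    wseg <- w[r0:r1]
    for (k2 in bk) {
      cb0 <- (B$bj[k2] - 1L) * BS_BLOCK + 1L
      cb1 <- min(B$bj[k2] * BS_BLOCK, B$ncol)
      Bblk <- B$blocks[[k2]][seq_len(nr), seq_len(cb1 - cb0 + 1L), drop = FALSE]
      out[ca0:ca1, cb0:cb1] <- out[ca0:ca1, cb0:cb1] +
        crossprod(Ablk, wseg * Bblk)
    }
  }
  out
}
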