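#' Robust principal component analysis (projection pursuit + MCD)
#'
#' Robust PCA in the ROBPCA style: (i) the data are reduced to their
#' affine span; (ii) a Stahel-Donoho outlyingness is computed over random
#' directions through point pairs, with coordinates robustly standardized
#' (median/MAD) first so the ranking is exactly invariant under shifts and
#' positive column scalings; (iii) the covariance of the `h` least
#' outlying points picks a k-dimensional subspace; (iv) [fast_mcd()] is
#' run on the data projected into that subspace.
#'
#' @param data numeric matrix (n x d).
#' @param k target dimension (1 <= k <= min(n - 1, d)).
#' @param alpha coverage fraction in `[0.5, 1]`; `h = floor(alpha * n)`
#'   clamped to the valid MCD range.  `alpha = 1` reproduces classical
#'   PCA.
#' @param seed integer RNG seed.
#' @param ndir number of random point-pair directions (default 250).
#' @param nsamp starting subsets passed to [fast_mcd()].
#' @return list of class `robpca` with `center` (length d), `loadings`
#'   (d x k, orthonormal, ordered by decreasing robust eigenvalue),
#'   `eigenvalues` (k), `scores` (n x k), `scatter` (k x k, diagonal in
#'   the loading basis), `support`, `h`, `alpha`, and `exact_fit`.
#' @export
robpca <- function(data, k, alpha = 0.75, seed = 1, ndir = 250, nsamp = 500) {
  data <- as.matrix(data)
  n <- nrow(data); d <- ncol(data)
  if (k < 1 || k > min(n - 1, d)) {
    stop(sprintf("k must lie in [1, %d]", min(n - 1, d)), call. = FALSE)
  }
  if (alpha < 0.5 || alpha > 1) stop("alpha must lie in [0.5, 1]", call. = FALSE)

  # (i) reduce to the affine span of the data; full-rank data keep their
  # original coordinates so that the per-column robust standardization
  # below makes the fit exactly equivariant under shifts and positive
  # column scalings
  med0 <- apply(data, 2, stats::median)
  Zc <- sweep(data, 2, med0)
  sv <- svd(Zc)
  tol <- max(dim(Zc)) * max(sv$d, 0) * .Machine$double.eps
  r <- sum(sv$d > tol)
  if (r == 0) stop("all observations coincide", call. = FALSE)
  if (k > r) {
    stop(sprintf("k = %d exceeds the data rank %d", k, r), call. = FALSE)
  }
  if (r == d) {
    V0 <- diag(d)
    Z <- Zc
  } else {
    V0 <- sv$v[, seq_len(r), drop = FALSE]
    Z <- Zc %*% V0                     # n x r coordinates in the span
  }

  h <- max(min(floor(alpha * n), n), mcd_h_range(n, k)[1])

  with_seed(seed, {
    # (ii) outlyingness on robustly standardized coordinates
    Zs <- Z
    for (j in seq_len(r)) {
      sj <- stats::mad(Z[, j])
      if (sj == 0) sj <- stats::sd(Z[, j])
      if (sj > 0) Zs[, j] <- (Z[, j] - stats::median(Z[, j])) / sj
    }
    outl <- rep(0, n)
    if (h < n) {
      pairs_i <- sample.int(n, ndir, replace = TRUE)
      pairs_j <- sample.int(n, ndir, replace = TRUE)
      D <- t(Zs[pairs_i, , drop = FALSE] - Zs[pairs_j, , drop = FALSE])
      len <- sqrt(colSums(D^2))
      ok <- len > tol
      if (!any(ok)) ok <- rep(TRUE, ncol(D))  # degenerate: keep axes below
      D <- sweep(D[, ok, drop = FALSE], 2, len[ok], "/")
      P <- Zs %*% D                     # n x ndirections projections
      med <- apply(P, 2, stats::median)
      mads <- apply(P, 2, stats::mad)
      for (jj in seq_len(ncol(P))) {
        dev <- abs(P[, jj] - med[jj])
        if (mads[jj] > 0) {
          outl <- pmax(outl, dev / mads[jj])
        } else if (any(dev > tol)) {
          # exact-fit direction: off-hyperplane points are maximally outlying
          outl[dev > tol] <- Inf
        }
      }
    }
    h0 <- order(outl)[seq_len(h)]

    # (iii) subspace spanned by the top-k eigenvectors of the h-subset
    sub <- Z[h0, , drop = FALSE]
    mu0 <- colMeans(sub)
    ev <- eigen(stats::cov(sub), symmetric = TRUE)
    Vk <- ev$vectors[, seq_len(k), drop = FALSE]
    S <- sweep(Z, 2, mu0) %*% Vk        # n x k projected data

    # (iv) MCD refinement inside the subspace
    mcd <- fast_mcd(S, h = h, seed = child_seed(seed, 7L), nsamp = nsamp)

    es <- eigen(mcd$scatter, symmetric = TRUE)
    rot <- es$vectors
    loadings <- V0 %*% Vk %*% rot       # d x k, orthonormal
    center <- med0 + as.numeric(V0 %*% (mu0 + Vk %*% mcd$center))
    scores <- sweep(data, 2, center) %*% loadings

    # support: least-outlying points that the subspace MCD also covers;
    # orthogonally displaced points are excluded by the outlyingness
    # step even though their in-plane projections look regular
    structure(
      list(center = center, loadings = loadings,
           eigenvalues = pmax(es$values, 0), scores = scores,
           scatter = diag(pmax(es$values, 0), nrow = k),
           support = intersect(sort(h0), mcd$support),
           h = h, alpha = alpha,
           exact_fit = isTRUE(mcd$exact_fit)),
      class = "robpca"
    )
  })
}

#' @export
print.robpca <- function(x, ...) {
  cat(sprintf("robust PCA: k = %d, h = %d, eigenvalues: %s\n",
              ncol(x$loadings), x$h,
              paste(signif(x$eigenvalues, 4), collapse = ", ")))
  invisible(x)
}
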