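#' Valid coverage range for MCD
#'
#' @param n number of observations.
#' @param d dimension.
#' @return integer vector `c(h_min, h_max)` with
#'   `h_min = ceiling((n + d + 1) / 2)`.
#' @export
mcd_h_range <- function(n, d) c(ceiling((n + d + 1) / 2), n)

check_h <- function(n, d, h) {
  rng <- mcd_h_range(n, d)
  if (h < rng[1] || h > rng[2]) {
    stop(sprintf("h = %d outside valid range [%d, %d] for n = %d, d = %d",
                 h, rng[1], rng[2], n, d), call. = FALSE)
  }
  as.integer(h)
}

new_rls <- function(center, scatter, support, h, consistency_applied,
                    exact_fit = FALSE) {
  structure(
    list(center = as.numeric(center),
         scatter = (scatter + t(scatter)) / 2,
         support = sort(as.integer(support)),
         h = as.integer(h),
         consistency_applied = consistency_applied,
         exact_fit = exact_fit),
    class = "robust_location_scatter"
  )
}

subset_det <- function(S) {
  d <- determinant(S, logarithm = TRUE)
  if (d$sign <= 0) -Inf else as.numeric(d$modulus)
}

# lean column-mean/covariance for small subsets
fast_moments <- function(Z) {
  m <- colMeans(Z)
  Zc <- Z - rep(m, each = nrow(Z))
  list(center = m, scatter = crossprod(Zc) / (nrow(Z) - 1))
}

# Cholesky factor or NULL when the scatter is (numerically) singular
chol_or_null <- function(S) {
  tryCatch(chol(S), error = function(e) NULL)
}

# One concentration step.  `R` is the Cholesky factor of the current
# scatter; keeps the h smallest Mahalanobis distances and recomputes
# moments.  logdet = -Inf flags a singular (exact-fit) subset.
c_step <- function(data, center, R, h) {
  dev <- t(data) - center
  d2 <- colSums(backsolve(R, dev, transpose = TRUE)^2)
  idx <- order(d2)[seq_len(h)]  # stable order(): deterministic under ties
  mom <- fast_moments(data[idx, , drop = FALSE])
  R2 <- chol_or_null(mom$scatter)
  list(center = mom$center, scatter = mom$scatter, chol = R2, support = idx,
       logdet = if (is.null(R2)) -Inf else 2 * sum(log(diag(R2))))
}

#' Exact minimum covariance determinant (enumeration oracle)
#'
#' Enumerates all `choose(n, h)` observation subsets and returns the mean
#' and covariance of the one whose covariance has minimal determinant.
#' Intended as a small-sample reference for [fast_mcd()]; refuses `n > 15`.
#' Ties are broken by the lexicographically smallest index set (the first
#' strict improvement wins during lexicographic enumeration).
#'
#' @param data numeric matrix or vector (n x d, n <= 15).
#' @param h coverage count.
#' @return a `robust_location_scatter` (no consistency correction: the
#'   oracle reports the raw subset moments).
#' @export
exact_mcd <- function(data, h) {
  data <- as.matrix(data)
  n <- nrow(data); d <- ncol(data)
  if (n > 15) stop("exact_mcd is an enumeration oracle; n must be <= 15",
                   call. = FALSE)
  h <- check_h(n, d, h)
  if (h == n) {
    return(new_rls(colMeans(data), stats::cov(data), seq_len(n), h, FALSE))
  }
  combos <- utils::combn(n, h)
  best_ld <- Inf; best_idx <- NULL
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    ld <- subset_det(stats::cov(data[idx, , drop = FALSE]))
    if (ld < best_ld) {  # strict: lexicographically first minimum kept
      best_ld <- ld
      best_idx <- idx
    }
  }
  sub <- data[best_idx, , drop = FALSE]
  new_rls(colMeans(sub), stats::cov(sub), best_idx, h, FALSE,
          exact_fit = !is.finite(best_ld))
}

#' FAST-MCD robust location and scatter
#'
#' Standard FAST-MCD: many random (d+1)-point starting subsets, two
#' concentration steps each, the best few iterated to convergence; the
#' determinant is non-increasing across concentration steps.  The raw
#' estimate is consistency-corrected and refined by one 0.975 chi-square
#' reweighting pass.  Fully deterministic given `seed`.
#'
#' @param data numeric matrix or vector (n x d, n > d).
#' @param h coverage count (`floor(alpha * n)` for coverage fraction
#'   alpha); `h = n` returns the classical mean and covariance.
#' @param seed integer RNG seed.
#' @param nsamp number of random starting subsets (default 500).
#' @param nkeep how many best candidates are iterated to convergence.
#' @return a `robust_location_scatter`; `support` holds the raw optimal
#'   h-subset, `center`/`scatter` the reweighted, consistency-corrected
#'   estimates.  Attribute `"raw"` carries the uncorrected subset moments.
#' @export
fast_mcd <- function(data, h, seed = 1, nsamp = 500, nkeep = 10) {
  data <- as.matrix(data)
  n <- nrow(data); d <- ncol(data)
  if (n <= d) stop("fast_mcd requires n > d", call. = FALSE)
  h <- check_h(n, d, h)
  if (h == n) {
    return(new_rls(colMeans(data), stats::cov(data), seq_len(n), h, FALSE))
  }

  with_seed(seed, {
    cands <- vector("list", nsamp)
    for (s in seq_len(nsamp)) {
      idx <- sample.int(n, d + 1)
      mom <- fast_moments(data[idx, , drop = FALSE])
      R <- chol_or_null(mom$scatter)
      # enlarge singular starting subsets until a proper covariance exists
      while (is.null(R) && length(idx) < n) {
        idx <- c(idx, sample(setdiff(seq_len(n), idx), 1))
        mom <- fast_moments(data[idx, , drop = FALSE])
        R <- chol_or_null(mom$scatter)
      }
      if (is.null(R)) { cands[[s]] <- list(logdet = Inf); next }
      cand <- list(center = mom$center, chol = R, logdet = Inf)
      for (it in 1:2) {
        nxt <- c_step(data, cand$center, cand$chol, h)
        cand <- nxt
        if (is.null(cand$chol)) break  # singular: exact-fit candidate
      }
      cands[[s]] <- cand
    }
    lds <- vapply(cands, function(cc) cc$logdet, numeric(1))
    keep <- order(lds)[seq_len(min(nkeep, length(cands)))]

    best <- NULL
    for (j in keep) {
      cand <- cands[[j]]
      repeat {
        if (is.null(cand$chol) || !is.finite(cand$logdet)) break
        nxt <- c_step(data, cand$center, cand$chol, h)
        stopifnot(nxt$logdet <= cand$logdet + 1e-8)  # C-step monotonicity
        done <- is.null(nxt$chol) || cand$logdet - nxt$logdet < 1e-12
        cand <- nxt
        if (done) break
      }
      if (is.null(best) || (cand$logdet %||% Inf) < best$logdet) best <- cand
    }

    if (identical(best$logdet, Inf) || is.null(best$support)) {
      stop("fast_mcd could not form a non-degenerate starting subset",
           call. = FALSE)
    }
    if (best$logdet == -Inf) {
      # exact fit: h points lie on a lower-dimensional affine subspace
      return(new_rls(best$center, best$scatter, best$support, h, FALSE,
                     exact_fit = TRUE))
    }

    c_raw <- mcd_consistency_factor(h / n, d)
    raw_center <- best$center
    raw_scatter <- best$scatter * c_raw

    d2 <- stats::mahalanobis(data, raw_center, raw_scatter)
    w <- d2 <= stats::qchisq(0.975, df = d)
    sub <- data[w, , drop = FALSE]
    rw_center <- colMeans(sub)
    rw_scatter <- stats::cov(sub) * mcd_consistency_factor(0.975, d)

    out <- new_rls(rw_center, rw_scatter, best$support, h, TRUE)
    attr(out, "raw") <- list(center = raw_center, scatter = raw_scatter)
    out$weights <- as.integer(w)
    out
  })
}

#' @export
print.robust_location_scatter <- function(x, ...) {
  cat(sprintf("robust location/scatter: d = %d, h = %d%s%s\n",
              length(x$center), x$h,
              if (x$consistency_applied) ", consistency-corrected" else "",
              if (isTRUE(x$exact_fit)) ", EXACT FIT" else ""))
  invisible(x)
}
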