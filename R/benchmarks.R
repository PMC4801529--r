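#' Multiple linear regression benchmark
#'
#' Ordinary least squares via the QR decomposition.
#'
#' @param X n x p predictor matrix (full column rank, n > p).
#' @param y response vector.
#' @return object of class `mlr_model` with `coefficients`, `intercept`,
#'   `fitted`, `residuals`.
#' @export
mlr_fit <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("MLR requires n > p", call. = FALSE)
  A <- cbind(`(Intercept)` = 1, X)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    stop("predictor matrix is rank deficient; consider PLS", call. = FALSE)
  }
  cf <- qr.coef(qrA, y)
  fitted <- as.numeric(A %*% cf)
  structure(
    list(coefficients = as.numeric(cf[-1]), intercept = unname(cf[1]),
         fitted = fitted, residuals = y - fitted,
         sensor_names = colnames(X)),
    class = "mlr_model"
  )
}

#' @export
predict.mlr_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  object$intercept + as.numeric(as.matrix(newdata) %*% object$coefficients)
}

#' Classical SIMPLS partial least squares benchmark
#'
#' Classical SIMPLS from the sample cross-covariance: weight vectors are
#' extracted from `cov(X, y)` with deflation through an orthonormal basis
#' of previous x-loadings.  At `k = p` on full-rank data the fit
#' reproduces ordinary least squares.
#'
#' @param X n x p predictor matrix.
#' @param y response vector.
#' @param k number of latent variables (`k <= min(n - 1, p)`).
#' @return object of class `simpls_model`.
#' @export
simpls_fit <- function(X, y, k) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (k < 1 || k > min(n - 1, p)) {
    stop(sprintf("k must lie in [1, %d]", min(n - 1, p)), call. = FALSE)
  }
  mu_x <- colMeans(X); mu_y <- mean(y)
  Sxx <- stats::cov(X)
  sxy <- as.numeric(stats::cov(X, y))
  W <- simpls_weights(Sxx, sxy, k)
  Stt <- crossprod(W, Sxx %*% W)
  q <- solve(Stt, as.numeric(crossprod(W, sxy)))
  b <- as.numeric(W %*% q)
  intercept <- mu_y - sum(mu_x * b)
  fitted <- intercept + as.numeric(X %*% b)
  structure(
    list(k = k, weights = W, coefficients = b, intercept = intercept,
         fitted = fitted, residuals = y - fitted,
         scores = sweep(X, 2, mu_x) %*% W,
         sensor_names = colnames(X)),
    class = "simpls_model"
  )
}

#' @export
predict.simpls_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  object$intercept + as.numeric(as.matrix(newdata) %*% object$coefficients)
}

#' RBF-kernel least squares support vector machine benchmark
#'
#' Solves the LSSVM training system
#' \deqn{\begin{pmatrix} 0 & \mathbf{1}^T \\ \mathbf{1} & K + I/\gamma
#'   \end{pmatrix} \begin{pmatrix} b \\ \boldsymbol\alpha \end{pmatrix} =
#'   \begin{pmatrix} 0 \\ y \end{pmatrix}}
#' with the radial kernel
#' `K_ij = exp(-||x_i - x_j||^2 / kernel_width)`; `kernel_width` is the
#' squared length-scale appearing in the exponent denominator.
#' Predictors are z-scored internally (training statistics stored), so
#' the width is on the scale of squared standardized distances
#' regardless of the raw sensor units.
#'
#' @param X n x p predictor matrix.
#' @param y response vector.
#' @param reg_gamma regularization parameter (> 0); larger values fit
#'   the training data more closely.
#' @param kernel_width squared RBF length-scale (> 0).
#' @return object of class `lssvm_model` with dual coefficients
#'   `alphas`, `bias`, and the stored training predictors.
#' @export
lssvm_fit <- function(X, y, reg_gamma, kernel_width) {
  if (reg_gamma <= 0 || kernel_width <= 0) {
    stop("reg_gamma and kernel_width must be positive", call. = FALSE)
  }
  X <- as.matrix(X)
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1  # single point / constant column
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  K <- exp(-as.matrix(stats::dist(Xs))^2 / kernel_width)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / reg_gamma))
  rhs <- c(0, y)
  if (n <= 60) {  # condition check is O(n^3); skip for larger systems
    cond <- kappa(A, exact = FALSE)
    if (cond > 1e12) {
      warning(sprintf("ill-conditioned LSSVM system (condition ~ %.2e)",
                      cond), call. = FALSE)
    }
  }
  sol <- solve(A, rhs)
  if (max(abs(A %*% sol - rhs)) > 1e-8 * max(1, sqrt(sum(y^2)))) {
    warning("LSSVM system solved with large residual", call. = FALSE)
  }
  structure(
    list(bias = sol[1], alphas = sol[-1], X_train = Xs,
         center = ctr, scale = scl,
         reg_gamma = reg_gamma, kernel_width = kernel_width),
    class = "lssvm_model"
  )
}

#' @export
predict.lssvm_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- object$X_train  # already standardized
  } else {
    newdata <- sweep(sweep(as.matrix(newdata), 2, object$center),
                     2, object$scale, "/")
  }
  # cross squared distances to the training points
  d2 <- outer(rowSums(newdata^2), rowSums(object$X_train^2), "+") -
    2 * newdata %*% t(object$X_train)
  Kx <- exp(-pmax(d2, 0) / object$kernel_width)
  as.numeric(Kx %*% object$alphas + object$bias)
}

#' Default LSSVM tuning grid
#'
#' 13 x 13 log-spaced grid: `reg_gamma` over 10^-2..10^6 and
#' `kernel_width` over 10^-2..10^4.
#'
#' @param n_gamma,n_width grid sizes.
#' @return list with numeric vectors `reg_gamma` and `kernel_width`.
#' @export
default_lssvm_grid <- function(n_gamma = 13, n_width = 13) {
  list(reg_gamma = 10^seq(-2, 6, length.out = n_gamma),
       kernel_width = 10^seq(-2, 4, length.out = n_width))
}

#' Tune the LSSVM by leave-one-out cross-validation
#'
#' Evaluates the LOOCV RMSECV at every point of a joint
#' (reg_gamma, kernel_width) grid and returns the argmin; ties go to the
#' smallest reg_gamma, then the smallest width.
#'
#' @param dataset an [etongue_dataset()].
#' @param grid list with `reg_gamma` and `kernel_width` vectors.
#' @param seed master seed (LSSVM itself is deterministic; kept for the
#'   common fitter interface).
#' @return list with `reg_gamma`, `kernel_width`, `rmsecv`, and the full
#'   `grid_rmsecv` table.
#' @export
tune_lssvm <- function(dataset, grid = default_lssvm_grid(), seed = 1) {
  if (!length(grid$reg_gamma) || !length(grid$kernel_width)) {
    stop("empty tuning grid", call. = FALSE)
  }
  combos <- expand.grid(reg_gamma = sort(grid$reg_gamma),
                        kernel_width = sort(grid$kernel_width))
  combos <- combos[order(combos$reg_gamma, combos$kernel_width), ]
  rms <- vapply(seq_len(nrow(combos)), function(j) {
    # extreme grid corners legitimately produce ill-conditioned systems;
    # their poor RMSECV removes them from contention without noise
    preds <- suppressWarnings(loocv_predictions(
      dataset, "lssvm",
      hyper = list(reg_gamma = combos$reg_gamma[j],
                   kernel_width = combos$kernel_width[j]),
      seed = seed
    ))
    weighted_rmse(dataset$y, preds)
  }, numeric(1))
  best <- which.min(rms)  # which.min: first minimum = smallest gamma/width
  list(reg_gamma = combos$reg_gamma[best],
       kernel_width = combos$kernel_width[best],
       rmsecv = rms[best],
       grid_rmsecv = cbind(combos, rmsecv = rms))
}

#' Evaluate a method by leave-one-out cross-validation
#'
#' LOOCV predictions via [loocv_predictions()], RMSECV via
#' [weighted_rmse()], and the cross-validated determination coefficient
#' `R2_CV` as the squared Pearson correlation between the response and
#' its held-out predictions (reported as 0 with a flag when the
#' predictions are constant).
#'
#' By default all case weights are 1 (the plain RMSECV).  For the robust
#' PLS the conventional headline is the robust RMSECV -- the same
#' quantity with detected outliers zero-weighted, since a robust model
#' refuses to fit contaminated samples by design; pass the robust fit's
#' `case_weights` to reproduce that convention (as [compare_methods()]
#' does).
#'
#' @param dataset an [etongue_dataset()].
#' @param method one of `"mlr"`, `"pls"`, `"lssvm"`, `"rpls"`.
#' @param hyperparams named list: `k` (pls/rpls), `alpha` (rpls),
#'   `reg_gamma`/`kernel_width` (lssvm).
#' @param seed master seed.
#' @param dataset_variant label recorded in the result
#'   (`"pre_screen"`/`"post_screen"`).
#' @param case_weights 0/1 weights applied to the CV errors and the
#'   `R2_CV` correlation (default all 1).
#' @return one-row data frame of class `benchmark_result`.
#' @export
evaluate_method <- function(dataset, method, hyperparams = list(), seed = 1,
                            dataset_variant = "pre_screen",
                            case_weights = NULL) {
  method <- match.arg(method, c("mlr", "pls", "lssvm", "rpls"))
  fitter <- switch(method, mlr = "mlr", pls = "simpls",
                   lssvm = "lssvm", rpls = "rsimpls")
  preds <- loocv_predictions(
    dataset, fitter,
    k = hyperparams[["k", exact = TRUE]] %||% 2,
    alpha = hyperparams[["alpha", exact = TRUE]] %||% 0.75,
    hyper = hyperparams, seed = seed
  )
  w <- case_weights %||% rep(1, dataset$n)
  rmsecv <- weighted_rmse(dataset$y, preds, w)
  keep <- w == 1
  degenerate <- stats::sd(preds[keep]) == 0
  r2 <- if (degenerate) 0 else stats::cor(dataset$y[keep], preds[keep])^2
  out <- data.frame(
    method = method,
    dataset_variant = dataset_variant,
    k = hyperparams[["k", exact = TRUE]] %||% NA_integer_,
    reg_gamma = hyperparams[["reg_gamma", exact = TRUE]] %||% NA_real_,
    kernel_width = hyperparams[["kernel_width", exact = TRUE]] %||% NA_real_,
    R2_CV = r2,
    RMSECV = rmsecv,
    degenerate_predictions = degenerate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("benchmark_result", class(out))
  out
}
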