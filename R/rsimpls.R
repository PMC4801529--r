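# SIMPLS weight extraction from a (cross-)covariance block.
# Sxx: p x p PSD, sxy: length-p cross-covariance with the response.
# Weights are unit-norm; loadings are deflated through an orthonormal
# basis of previous x-loadings (de Jong's scheme, univariate response).
simpls_weights <- function(Sxx, sxy, k) {
  p <- length(sxy)
  W <- matrix(0, p, k)
  B <- matrix(0, p, k)  # orthonormal loading basis used for deflation
  s <- sxy
  for (a in seq_len(k)) {
    ns <- sqrt(sum(s^2))
    if (ns < 1e-12 * (sqrt(sum(sxy^2)) + 1e-300)) {
      stop(sprintf(
        "cross-covariance exhausted after %d components (requested %d)",
        a - 1, k), call. = FALSE)
    }
    w <- s / ns
    v <- as.numeric(Sxx %*% w)
    if (a > 1) {
      Bp <- B[, seq_len(a - 1), drop = FALSE]
      v <- v - Bp %*% crossprod(Bp, v)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) {
      stop(sprintf("x-loadings degenerate at component %d", a), call. = FALSE)
    }
    B[, a] <- v / nv
    W[, a] <- w
    s <- s - B[, a] * sum(B[, a] * s)
  }
  W
}

# Robust (or classical, alpha = 1) center and scatter of the joint
# [X y] block, the moment input shared by all RSIMPLS fits.
joint_moments <- function(X, y, alpha, seed, ndir = 250, nsamp = 500) {
  Z <- cbind(X, y)
  n <- nrow(Z); dz <- ncol(Z)
  if (alpha >= 1) {
    return(list(center = colMeans(Z), scatter = stats::cov(Z),
                weights_init = rep(1L, n)))
  }
  k0 <- min(n - 1, dz)
  rp <- robpca(Z, k = k0, alpha = alpha, seed = seed, ndir = ndir,
               nsamp = nsamp)
  Sigma <- rp$loadings %*% (rp$eigenvalues * t(rp$loadings))
  w0 <- integer(n); w0[rp$support] <- 1L
  list(center = rp$center, scatter = Sigma, weights_init = w0)
}

# Extract a k-component PLS fit from joint moments and apply the
# reweighting pass.  Returns a full rpls_model.
rsimpls_from_moments <- function(X, y, k, mom, alpha, seed,
                                 sensor_names = colnames(X)) {
  n <- nrow(X); p <- ncol(X)
  mu_x <- unname(mom$center[seq_len(p)])
  mu_y <- unname(mom$center[p + 1])
  Sxx <- mom$scatter[seq_len(p), seq_len(p), drop = FALSE]
  sxy <- mom$scatter[seq_len(p), p + 1]
  syy <- mom$scatter[p + 1, p + 1]
  if (syy <= 0) stop("degenerate response variance", call. = FALSE)

  W <- simpls_weights(Sxx, sxy, k)
  Tt <- sweep(X, 2, mu_x) %*% W                  # scores about robust center
  Stt <- crossprod(W, Sxx %*% W)
  sty <- as.numeric(crossprod(W, sxy))
  q <- solve(Stt, sty)
  b <- as.numeric(W %*% q)
  intercept <- mu_y - sum(mu_x * b)
  r <- y - (intercept + as.numeric(X %*% b))

  if (alpha >= 1) {
    w <- rep(1L, n)
  } else {
    # robust residual scale implied by the robust joint scatter
    s0 <- sqrt(max(syy - sum(q * sty), 1e-12 * syy))
    sd_cut <- sd_cutoff(k)
    SD0 <- sqrt(pmax(stats::mahalanobis(Tt, rep(0, k), Stt), 0))
    # reweighted least squares, iterated twice: the second pass reuses
    # the (less noisy) weighted residual scale of the first refit
    s_cur <- s0
    w <- rep(1L, n)
    for (pass in 1:2) {
      w <- as.integer(abs(r) <= 2.5 * s_cur & SD0 <= sd_cut)
      if (sum(w) < k + 2) {
        # pathological reweighting: fall back to the robust support
        w <- mom$weights_init
      }
      keep <- w == 1L
      fit <- stats::lm.fit(cbind(1, Tt[keep, , drop = FALSE]), y[keep])
      cf <- fit$coefficients
      q <- cf[-1]
      b <- as.numeric(W %*% q)
      intercept <- cf[1] - sum(mu_x * b)
      r <- y - (intercept + as.numeric(X %*% b))
      s_cur <- sqrt(sum((r[keep])^2) / max(sum(keep) - k - 1, 1))
    }
  }

  nw <- sum(w)
  s <- sqrt(sum((r[w == 1L])^2) / max(nw - k - 1, 1))
  keep_scores <- Tt[w == 1L, , drop = FALSE]
  mu_t <- colMeans(keep_scores)
  Sig_t <- stats::cov(keep_scores)
  if (alpha < 1) Sig_t <- Sig_t * mcd_consistency_factor(0.975, k)

  structure(
    list(k = k, weights = W, x_center = mu_x,
         scores = Tt, score_center = mu_t, score_scatter = Sig_t,
         coefficients = b, intercept = intercept,
         fitted = intercept + as.numeric(X %*% b), residuals = r,
         residual_scale = s, case_weights = w,
         coverage = alpha, seed = seed,
         sensor_names = sensor_names %||% paste0("X", seq_len(p))),
    class = "rpls_model"
  )
}

#' Robust partial least squares regression (RSIMPLS style)
#'
#' Fits a univariate PLS regression from robust moments: a robust center
#' and scatter of the joint `[X y]` block are estimated by [robpca()]
#' (projection-pursuit + MCD), SIMPLS weight vectors are extracted from
#' the robust cross-covariance with loading deflation, and the score
#' regression is refined by one reweighting pass that zero-weights
#' samples with `|residual| > 2.5` robust residual scales or score
#' distance above the 0.975 chi-square cutoff.  `alpha = 1` forces the
#' classical path (all case weights 1, classical moments): this is the
#' "fraction of outliers set to zero" retrain mode used after outlier
#' exclusion.
#'
#' @param X n x p matrix of sensor responses (or an [etongue_dataset()],
#'   in which case `y` is taken from it).
#' @param y length-n response of panel bitterness means.
#' @param k number of latent variables, `k <= min(n - 1, p)`.
#' @param alpha coverage fraction in `[0.5, 1]`; default 0.75.
#' @param seed integer RNG seed for the robust moment estimation.
#' @param ndir,nsamp tuning of the robust moment step (see [robpca()]).
#' @return object of class `rpls_model`: latent weights, scores, robust
#'   score center/scatter, coefficients and intercept on the raw sensor
#'   scale, residual scale `residual_scale`, and 0/1 `case_weights`.
#' @export
rsimpls_fit <- function(X, y = NULL, k, alpha = 0.75, seed = 1,
                        ndir = 250, nsamp = 500) {
  if (inherits(X, "etongue_dataset")) { y <- X$y; X <- X$X }
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (k < 1 || k > min(n - 1, p)) {
    stop(sprintf("k must lie in [1, %d]", min(n - 1, p)), call. = FALSE)
  }
  if (alpha < 0.5 || alpha > 1) stop("alpha must lie in [0.5, 1]", call. = FALSE)
  if (stats::var(y) == 0) stop("degenerate response variance", call. = FALSE)
  mom <- joint_moments(X, y, alpha, seed, ndir = ndir, nsamp = nsamp)
  rsimpls_from_moments(X, y, k, mom, alpha, seed)
}

# Fit all component counts 1..k_max from a single robust moment
# estimate; used by the component-selection machinery where refitting
# the moments per k would be wasteful (the moments do not depend on k).
rsimpls_path <- function(X, y, k_max, alpha = 0.75, seed = 1,
                         ndir = 250, nsamp = 500) {
  mom <- joint_moments(X, y, alpha, seed, ndir = ndir, nsamp = nsamp)
  lapply(seq_len(k_max), function(k) {
    rsimpls_from_moments(X, y, k, mom, alpha, seed)
  })
}

#' Predict from a robust PLS model
#'
#' @param object an `rpls_model`.
#' @param newdata matrix with the same sensor columns as the training
#'   data (defaults to returning the fitted values).
#' @param ... unused.
#' @return numeric vector `intercept + newdata %*% coefficients`.
#' @export
predict.rpls_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(newdata), length(object$coefficients)), call. = FALSE)
  }
  object$intercept + as.numeric(newdata %*% object$coefficients)
}

#' @rdname predict.rpls_model
#' @param model an `rpls_model`.
#' @param X_new new sensor matrix.
#' @export
rpls_predict <- function(model, X_new) predict(model, X_new)

#' Express a fitted PLS model in original sensor units
#'
#' Collapses the latent-variable fit to one coefficient per sensor on the
#' raw (uncentered, unscaled) sensor scale plus an intercept absorbing
#' all centering, i.e. the familiar
#' `I = c_ZZ * ZZ + ... + c_AB * AB + intercept` calibration equation.
#'
#' @param model an `rpls_model` (or `simpls_model`/`mlr_model`).
#' @param sensor_names optional sensor names (default: from the model).
#' @return object of class `model_equation` with `coefficients`
#'   (named per sensor) and `intercept`.
#' @export
equation_original_form <- function(model, sensor_names = NULL) {
  cf <- model$coefficients
  names(cf) <- sensor_names %||% model$sensor_names %||%
    paste0("X", seq_along(cf))
  structure(list(coefficients = cf, intercept = model$intercept),
            class = "model_equation")
}

#' Evaluate a calibration equation on a sensor matrix
#'
#' @param eq a `model_equation`.
#' @param X sensor matrix with columns in the equation's sensor order.
#' @return predicted bitterness intensities.
#' @export
evaluate_equation <- function(eq, X) {
  eq$intercept + as.numeric(as.matrix(X) %*% eq$coefficients)
}

#' @export
print.model_equation <- function(x, ...) {
  terms <- sprintf("(%s) * %s", formatC(x$coefficients, format = "g", digits = 5),
                   names(x$coefficients))
  cat("I =", paste(terms, collapse = " + "), "+",
      formatC(x$intercept, format = "g", digits = 5), "\n")
  invisible(x)
}

#' @export
print.rpls_model <- function(x, ...) {
  cat(sprintf(
    "robust PLS model: k = %d latent variables, coverage alpha = %.2f\n",
    x$k, x$coverage))
  cat(sprintf("residual scale s = %.4f; %d/%d samples retained\n",
              x$residual_scale, sum(x$case_weights), length(x$case_weights)))
  print(equation_original_form(x))
  invisible(x)
}

#' Serialize a fitted robust PLS model to JSON
#'
#' Stores sensor names, coefficients, intercept, k, alpha and seed at
#' full precision, sufficient to reproduce predictions exactly.
#'
#' @param model an `rpls_model`.
#' @param path output file.
#' @export
write_rpls_model <- function(model, path) {
  doc <- list(
    class = "rpls_model",
    sensor_names = model$sensor_names,
    coefficients = model$coefficients,
    intercept = model$intercept,
    k = model$k,
    alpha = model$coverage,
    seed = model$seed,
    residual_scale = model$residual_scale,
    score_center = model$score_center,
    score_scatter = model$score_scatter,
    x_center = model$x_center,
    weights = model$weights
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a serialized robust PLS model
#'
#' @param path file written by [write_rpls_model()].
#' @return an `rpls_model` stub usable with [predict.rpls_model()] and
#'   [equation_original_form()].
#' @export
read_rpls_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(k = doc$k, weights = as.matrix(doc$weights),
         x_center = doc$x_center,
         score_center = doc$score_center,
         score_scatter = as.matrix(doc$score_scatter),
         coefficients = doc$coefficients, intercept = doc$intercept,
         residual_scale = doc$residual_scale,
         coverage = doc$alpha, seed = doc$seed,
         sensor_names = doc$sensor_names),
    class = "rpls_model"
  )
}
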