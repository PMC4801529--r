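#' Leave-one-out cross-validated predictions
#'
#' For each sample i, fits the supplied model on all samples except i and
#' predicts sample i.  Stochastic fitters are reseeded deterministically
#' per fold (`seed + fold index` through the package's child-seed rule),
#' so results are reproducible.
#'
#' @param dataset an [etongue_dataset()] (or list with `X`, `y`).
#' @param fitter one of `"rsimpls"`, `"mlr"`, `"simpls"`, `"lssvm"`, or a
#'   function `(X, y, seed)` returning an object with a `predict` method.
#' @param k number of latent variables (PLS fitters).
#' @param alpha coverage fraction (rsimpls).
#' @param hyper named list of extra hyperparameters (`reg_gamma`,
#'   `kernel_width` for lssvm).
#' @param seed master seed.
#' @return numeric vector of length n with the held-out predictions.
#' @export
loocv_predictions <- function(dataset, fitter, k = 2, alpha = 0.75,
                              hyper = list(), seed = 1) {
  X <- dataset$X; y <- dataset$y
  n <- length(y)
  if (n < 3) stop("LOOCV needs at least 3 samples", call. = FALSE)
  fit_fun <- resolve_fitter(fitter, k = k, alpha = alpha, hyper = hyper)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fold_seed <- child_seed(seed, i)
    fit <- tryCatch(
      fit_fun(X[-i, , drop = FALSE], y[-i], fold_seed),
      error = function(e) {
        stop(sprintf("fold %d (%s): %s", i,
                     if (is.character(fitter)) fitter else "custom",
                     conditionMessage(e)), call. = FALSE)
      }
    )
    preds[i] <- predict(fit, X[i, , drop = FALSE])
  }
  preds
}

resolve_fitter <- function(fitter, k, alpha, hyper) {
  if (is.function(fitter)) return(fitter)
  switch(
    match.arg(fitter, c("rsimpls", "mlr", "simpls", "lssvm")),
    rsimpls = function(X, y, seed) rsimpls_fit(X, y, k = k, alpha = alpha,
                                               seed = seed),
    mlr = function(X, y, seed) mlr_fit(X, y),
    simpls = function(X, y, seed) simpls_fit(X, y, k = k),
    lssvm = function(X, y, seed) {
      lssvm_fit(X, y,
                reg_gamma = hyper[["reg_gamma", exact = TRUE]] %||% 100,
                kernel_width = hyper[["kernel_width", exact = TRUE]] %||% ncol(X))
    }
  )
}

#' (Weighted) root-mean-square error
#'
#' `sqrt(sum(w * (y - yhat)^2) / sum(w))` with 0/1 case weights.  All-one
#' weights give the plain RMSE / RMSECV; zero-weighting detected outliers
#' gives the robust (R-) variants.
#'
#' @param y,yhat observed and predicted responses.
#' @param case_weights 0/1 weights (default all 1).
#' @return scalar RMSE.
#' @export
weighted_rmse <- function(y, yhat, case_weights = rep(1, length(y))) {
  if (length(y) != length(yhat) || length(y) != length(case_weights)) {
    stop("y, yhat and case_weights must have equal length", call. = FALSE)
  }
  if (!all(case_weights %in% c(0, 1))) {
    stop("case_weights must be 0 or 1", call. = FALSE)
  }
  sw <- sum(case_weights)
  if (sw == 0) stop("all case weights are zero", call. = FALSE)
  sqrt(sum(case_weights * (y - yhat)^2) / sw)
}

#' Robust component selection (RCS) statistic
#'
#' Blends the robust cross-validated error and the robust fit error for a
#' given number of latent variables:
#' \deqn{RCS_k = \sqrt{\gamma\, \mathrm{R\text{-}RMSECV}_k^2 +
#'   (1-\gamma)\, \mathrm{R\text{-}RMSE}_k^2}.}
#' `gamma = 1` keeps only the prediction-quality term, `gamma = 0` only
#' the goodness-of-fit term.
#'
#' @param gamma weight in `[0, 1]`.
#' @param r_rmsecv robust cross-validated RMSE (>= 0).
#' @param r_rmse robust fit RMSE (>= 0).
#' @return scalar RCS value.
#' @export
rcs_statistic <- function(gamma, r_rmsecv, r_rmse) {
  if (any(gamma < 0 | gamma > 1)) stop("gamma must lie in [0, 1]", call. = FALSE)
  if (any(r_rmsecv < 0) || any(r_rmse < 0)) {
    stop("error terms must be non-negative", call. = FALSE)
  }
  sqrt(gamma * r_rmsecv^2 + (1 - gamma) * r_rmse^2)
}

#' Select the number of latent variables by the RCS criterion
#'
#' Computes, for each k = 1..k_max, the robust fit error (R-RMSE), the
#' robust leave-one-out error (R-RMSECV) and the RCS statistic for each
#' requested gamma.  Case weights for the robust variants come from the
#' robust PLS fit at `k_max`, one common set for the whole curve (per-k
#' weights would let an underfitted model hide its own misfit samples
#' among the outliers).  The chosen k is the smallest k whose
#' relative RCS improvement from k to k + 1 (at gamma = 0.5) falls below
#' `plateau_tol` -- the point where the curve plateaus; the argmin-RCS k
#' is reported alongside.
#'
#' @param dataset an [etongue_dataset()].
#' @param k_max largest k considered (`<= min(n - 1, p)`).
#' @param gammas RCS weights to tabulate (default `c(0, 0.5, 1)`).
#' @param plateau_tol relative-improvement threshold (default 0.05).
#' @param alpha robust coverage fraction.
#' @param seed master seed.
#' @return object of class `selection_curve`: data frame `curve` with
#'   columns `gamma`, `k`, `r_rmse`, `r_rmsecv`, `rcs`; `chosen_k`;
#'   `argmin_k`.
#' @export
select_num_components <- function(dataset, k_max, gammas = c(0, 0.5, 1),
                                  plateau_tol = 0.05, alpha = 0.75,
                                  seed = 1) {
  X <- dataset$X; y <- dataset$y
  n <- length(y)
  if (k_max < 1) stop("k_max must be at least 1", call. = FALSE)
  k_max <- min(k_max, n - 1, ncol(X))

  # full-data fits for every k from one robust moment estimate
  fits <- rsimpls_path(X, y, k_max, alpha = alpha,
                       seed = child_seed(seed, 0L))

  # LOOCV: one robust moment estimate per fold, all k extracted from it
  cv_pred <- matrix(NA_real_, n, k_max)
  for (i in seq_len(n)) {
    fold <- rsimpls_path(X[-i, , drop = FALSE], y[-i], k_max,
                         alpha = alpha, seed = child_seed(seed, i))
    for (k in seq_len(k_max)) {
      cv_pred[i, k] <- predict(fold[[k]], X[i, , drop = FALSE])
    }
  }

  # one common outlier-weight set (from the fit at k_max) keeps the
  # curve comparable across k; per-k weights would let an underfitted
  # model mask its own misfit samples as outliers
  w <- fits[[k_max]]$case_weights
  rows <- list()
  r_rmse <- r_rmsecv <- numeric(k_max)
  for (k in seq_len(k_max)) {
    r_rmse[k] <- weighted_rmse(y, fits[[k]]$fitted, w)
    r_rmsecv[k] <- weighted_rmse(y, cv_pred[, k], w)
    for (g in gammas) {
      rows[[length(rows) + 1]] <- data.frame(
        gamma = g, k = k, r_rmse = r_rmse[k], r_rmsecv = r_rmsecv[k],
        rcs = rcs_statistic(g, r_rmsecv[k], r_rmse[k])
      )
    }
  }
  curve <- do.call(rbind, rows)

  rcs_half <- rcs_statistic(0.5, r_rmsecv, r_rmse)
  chosen_k <- k_max
  for (k in seq_len(k_max - 1)) {
    rel_imp <- (rcs_half[k] - rcs_half[k + 1]) / rcs_half[k]
    if (rel_imp < plateau_tol) { chosen_k <- k; break }
  }
  if (k_max == 1) chosen_k <- 1

  structure(
    list(curve = curve, chosen_k = chosen_k,
         argmin_k = which.min(rcs_half),
         plateau_tol = plateau_tol, alpha = alpha, seed = seed,
         cv_predictions = cv_pred, fits = fits),
    class = "selection_curve"
  )
}

#' @export
print.selection_curve <- function(x, ...) {
  cat(sprintf("latent-variable selection: chosen k = %d (argmin k = %d)\n",
              x$chosen_k, x$argmin_k))
  half <- x$curve[x$curve$gamma == 0.5, c("k", "r_rmse", "r_rmsecv", "rcs")]
  if (nrow(half)) print(half, row.names = FALSE)
  invisible(x)
}

#' Export a selection curve as CSV
#'
#' Columns `gamma`, `k`, `r_rmse`, `r_rmsecv`, `rcs`, one row per
#' (gamma, k); suitable for re-plotting the RCS-vs-components figure.
#'
#' @param sel a `selection_curve`.
#' @param path output path.
#' @export
write_selection_curve <- function(sel, path) {
  utils::write.csv(format(sel$curve, digits = 10, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
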