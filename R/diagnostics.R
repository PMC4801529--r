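#' Standardized residuals
#'
#' Residuals `r_i = y_i - yhat_i` scaled by
#' `s = sqrt(sum(r_i^2) / (n - p - 1))`, the residual scale with
#' `n - p - 1` degrees of freedom.
#'
#' @param y observed responses.
#' @param yhat fitted/predicted responses.
#' @param p number of predictors consumed by the model (`n > p + 1`).
#' @return list with `Sr` (standardized residuals), `s` (residual
#'   scale), and `exact_fit` (TRUE when all residuals vanish, in which
#'   case `Sr` is all zero).
#' @export
standardized_residuals <- function(y, yhat, p) {
  n <- length(y)
  if (length(yhat) != n) stop("y and yhat lengths differ", call. = FALSE)
  if (n <= p + 1) stop("need n > p + 1 for the residual scale", call. = FALSE)
  r <- y - yhat
  s <- sqrt(sum(r^2) / (n - p - 1))
  if (s == 0) {
    return(list(Sr = rep(0, n), s = 0, exact_fit = TRUE))
  }
  list(Sr = r / s, s = s, exact_fit = FALSE)
}

#' Score distances
#'
#' Mahalanobis-type distance of each sample's latent scores from the
#' robust score center:
#' `SD_i = sqrt((t_i - mu_t)' Sigma_t^{-1} (t_i - mu_t))`
#' (the rooted form, to pair with the rooted chi-square cutoff of
#' [sd_cutoff()]).
#'
#' @param scores n x k score matrix.
#' @param score_center robust score center (length k).
#' @param score_scatter robust k x k score scatter (positive definite).
#' @return numeric vector of score distances.
#' @export
score_distances <- function(scores, score_center, score_scatter) {
  scores <- as.matrix(scores)
  score_scatter <- as.matrix(score_scatter)
  ev <- eigen(score_scatter, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    stop("score scatter is singular; reduce the number of latent variables",
         call. = FALSE)
  }
  sqrt(pmax(stats::mahalanobis(scores, score_center, score_scatter), 0))
}

#' Score-distance cutoff
#'
#' The 0.975 chi-square quantile with k degrees of freedom, rooted to
#' match the rooted score distance.
#'
#' @param k number of latent variables (>= 1).
#' @return scalar cutoff `sqrt(qchisq(0.975, k))`.
#' @export
sd_cutoff <- function(k) {
  if (any(k < 1)) stop("k must be >= 1", call. = FALSE)
  sqrt(stats::qchisq(0.975, df = k))
}

#' Three-way outlier classification on the (SD, Sr) outlier map
#'
#' Each sample receives exactly one label: `good_leverage` when only the
#' score distance exceeds its cutoff (far in sensor space but consistent
#' with the calibration trend), `bad_leverage` when both the score
#' distance and the absolute standardized residual exceed their cutoffs,
#' `vertical` when only the residual cutoff is exceeded, and `regular`
#' otherwise.
#'
#' @param Sr standardized residuals.
#' @param SD score distances.
#' @param sr_cutoff residual cutoff (two-sided; default 2.5).
#' @param sd_cutoff score-distance cutoff (e.g. [sd_cutoff()] at the
#'   model's k).
#' @param ids optional sample identifiers.
#' @return object of class `etongue_diagnostics`: data frame `map` with
#'   columns `id`, `Sr`, `SD`, `label`, plus the cutoffs.
#' @export
classify_samples <- function(Sr, SD, sr_cutoff = 2.5, sd_cutoff, ids = NULL) {
  if (length(Sr) != length(SD)) stop("Sr and SD lengths differ", call. = FALSE)
  sr_out <- abs(Sr) > sr_cutoff
  sd_out <- SD > sd_cutoff
  label <- ifelse(sd_out & sr_out, "bad_leverage",
           ifelse(sd_out, "good_leverage",
           ifelse(sr_out, "vertical", "regular")))
  structure(
    list(map = data.frame(
           id = ids %||% as.character(seq_along(Sr)),
           Sr = Sr, SD = SD, label = label,
           stringsAsFactors = FALSE),
         sr_cutoff = sr_cutoff, sd_cutoff = sd_cutoff),
    class = "etongue_diagnostics"
  )
}

#' Outlier diagnostics for a fitted robust PLS model
#'
#' Convenience wrapper: standardized residuals from the model's fitted
#' values, score distances from the robust score center and scatter,
#' chi-square SD cutoff at the model's k, and the three-way
#' classification.
#'
#' The residual scale is the normal-consistent MAD of the residuals
#' (`1.4826 * mad`), the robust scale conventional for robust-PLS
#' outlier maps: the classical pooled `n - p - 1` scale is inflated by
#' the outliers' own residuals (masking moderate vertical outliers),
#' while a scale over only the retained samples is truncation-biased
#' downward and over-flags clean small-n data.  The pure formula
#' remains available as [standardized_residuals()].
#'
#' @param model an `rpls_model`.
#' @param dataset the training [etongue_dataset()].
#' @param sr_cutoff residual cutoff (default 2.5).
#' @return an `etongue_diagnostics` object.
#' @export
diagnose <- function(model, dataset, sr_cutoff = 2.5) {
  p <- ncol(dataset$X)
  r <- dataset$y - predict(model, dataset$X)
  s <- stats::mad(r)
  if (s == 0) {
    w <- model$case_weights %||% rep(1L, length(r))
    if (sum(w) <= p + 1) w <- rep(1L, length(r))
    s <- sqrt(sum(r[w == 1L]^2) / (sum(w) - p - 1))
  }
  Sr <- if (s == 0) rep(0, length(r)) else r / s
  SD <- score_distances(model$scores, model$score_center,
                        model$score_scatter)
  classify_samples(Sr, SD, sr_cutoff = sr_cutoff,
                   sd_cutoff = sd_cutoff(model$k), ids = dataset$ids)
}

#' @export
print.etongue_diagnostics <- function(x, ...) {
  tab <- table(factor(x$map$label, levels = c("regular", "good_leverage",
                                              "bad_leverage", "vertical")))
  cat(sprintf("outlier map: |Sr| cutoff %.2f, SD cutoff %.4f\n",
              x$sr_cutoff, x$sd_cutoff))
  print(tab)
  flagged <- x$map$id[x$map$label != "regular"]
  if (length(flagged)) cat("flagged:", paste(flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Samples excluded under the default screening policy
#'
#' Bad leverage and vertical outliers are excluded; good leverage points
#' are retained (they support the calibration trend).  Manual overrides
#' take precedence: ids in `manual_exclude` are always dropped (the
#' borderline-sample escape hatch), ids in `manual_include` always kept.
#'
#' @param diagnostics an `etongue_diagnostics`.
#' @param manual_exclude,manual_include character vectors of sample ids.
#' @return character vector of excluded sample ids.
#' @export
excluded_ids <- function(diagnostics, manual_exclude = character(),
                         manual_include = character()) {
  map <- diagnostics$map
  excl <- map$id[map$label %in% c("bad_leverage", "vertical")]
  excl <- union(excl, as.character(manual_exclude))
  setdiff(excl, as.character(manual_include))
}

#' Export an outlier map as CSV
#'
#' Columns `id`, `Sr`, `SD`, `label`; the cutoffs are recorded as
#' comment-style header columns `sr_cutoff`, `sd_cutoff` repeated per
#' row so the file is self-contained for re-plotting.
#'
#' @param diagnostics an `etongue_diagnostics`.
#' @param path output path.
#' @export
write_outlier_map <- function(diagnostics, path) {
  df <- diagnostics$map
  df$sr_cutoff <- diagnostics$sr_cutoff
  df$sd_cutoff <- diagnostics$sd_cutoff
  utils::write.csv(format(df, digits = 10, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot the outlier map (score distance vs standardized residual)
#'
#' @param x an `etongue_diagnostics`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.etongue_diagnostics <- function(x, ...) {
  map <- x$map
  graphics::plot(map$SD, map$Sr, xlab = "Score distance",
                 ylab = "Standardized residual",
                 pch = ifelse(map$label == "regular", 1, 19), ...)
  graphics::abline(h = c(-x$sr_cutoff, x$sr_cutoff), lty = 2)
  graphics::abline(v = x$sd_cutoff, lty = 2)
  off <- map$label != "regular"
  if (any(off)) {
    graphics::text(map$SD[off], map$Sr[off], map$id[off], pos = 3, cex = 0.7)
  }
  invisible(x)
}
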