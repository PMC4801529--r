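#' Iterative Grubbs screening of assessor bitterness scores
#'
#' Repeatedly applies the two-sided Grubbs test to a vector of assessor
#' scores, removing the single most extreme value while its test statistic
#' \eqn{G = \max_i |x_i - \bar x| / s} exceeds the critical value
#' \deqn{G_{crit}(N, \alpha) = \frac{N-1}{\sqrt N}
#'   \sqrt{\frac{t^2}{N - 2 + t^2}}, \quad
#'   t = t_{1 - \alpha/(2N),\; N-2},}
#' the standard two-sided critical point derived from the t distribution.
#' At least three scores are always retained (the statistic is undefined
#' below that), and a zero-variance vector is returned unchanged.
#'
#' @param scores numeric vector of assessor bitterness intensities
#'   (at least 3 values).
#' @param alpha two-sided significance level in (0, 0.5); default 0.05.
#' @return list with components `cleaned` (retained scores), `removed`
#'   (data frame with `index` into the original vector, `value`, and the
#'   Grubbs `G` at removal), and `alpha`.
#' @examples
#' grubbs_screen(c(8, 9, 10, 11, 50))$removed
#' @export
grubbs_screen <- function(scores, alpha = 0.05) {
  stopifnot_numeric(scores, "scores")
  if (length(scores) < 3) {
    stop("Grubbs screening needs at least 3 scores (insufficient replication)",
         call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)", call. = FALSE)

  keep <- seq_along(scores)
  removed <- data.frame(index = integer(), value = numeric(), G = numeric())
  repeat {
    x <- scores[keep]
    n <- length(x)
    if (n <= 3) break  # never screen below 3 retained scores
    s <- stats::sd(x)
    if (s == 0) break  # all equal: G undefined, nothing to remove
    dev <- abs(x - mean(x))
    G <- max(dev) / s
    if (G <= grubbs_critical(n, alpha)) break
    worst <- which.max(dev)  # ties: first (lowest index) removed
    removed <- rbind(removed, data.frame(
      index = keep[worst], value = x[worst], G = G
    ))
    keep <- keep[-worst]
  }
  list(cleaned = scores[keep], removed = removed, alpha = alpha)
}

#' Two-sided Grubbs critical value
#'
#' @param n number of observations (>= 3).
#' @param alpha two-sided significance level.
#' @return the critical value of the Grubbs statistic.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (n < 3) stop("Grubbs critical value requires n >= 3", call. = FALSE)
  t2 <- stats::qt(1 - alpha / (2 * n), df = n - 2)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Summarize assessor scores to a per-sample panel record
#'
#' Reduces a vector of assessor scores to the mean +/- sd form used for
#' panel reference tables (sample standard deviation, n - 1 denominator).
#'
#' @param scores numeric vector of assessor scores (non-empty).
#' @param sample_id optional sample identifier carried into the record.
#' @return data frame with `sample_id`, `mean_intensity`, `sd_intensity`,
#'   `n_assessors`, and `degenerate` (TRUE when only one score was given,
#'   in which case the sd is reported as 0 with a warning).
#' @export
summarize_panel <- function(scores, sample_id = NA_character_) {
  stopifnot_numeric(scores, "scores")
  if (length(scores) == 0) stop("scores must be non-empty", call. = FALSE)
  degenerate <- length(scores) == 1
  if (degenerate) {
    warning("single assessor score: sd reported as 0", call. = FALSE)
  }
  data.frame(
    sample_id = as.character(sample_id),
    mean_intensity = mean(scores),
    sd_intensity = if (degenerate) 0 else stats::sd(scores),
    n_assessors = length(scores),
    degenerate = degenerate,
    stringsAsFactors = FALSE
  )
}

#' Five-rank bitterness scale
#'
#' The rank scale used for reporting: five ordered intensity classes
#' I--V anchored by berberine hydrochloride reference solutions.  All
#' intervals are half-open `[lo, hi)` except rank V, which is closed at
#' both ends, so the ranks tile the full intensity range 0.5--5.5.
#'
#' @return data frame with columns `rank`, `lo`, `hi`, `closed_hi`,
#'   `description`, and `reference_mg_ml`.
#' @export
default_rank_scale <- function() {
  data.frame(
    rank = c("I", "II", "III", "IV", "V"),
    lo = c(0.5, 1.5, 2.5, 3.5, 4.5),
    hi = c(1.5, 2.5, 3.5, 4.5, 5.5),
    closed_hi = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    description = c("imperceptible", "slight", "moderate",
                    "high", "extreme"),
    reference_mg_ml = c(0, 0.01, 0.05, 0.1, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Map a bitterness intensity to its rank label
#'
#' @param intensity numeric vector of intensities in `[0.5, 5.5]`.
#' @param scale a rank scale as returned by [default_rank_scale()].
#' @return character vector of rank labels.
#' @export
rank_from_intensity <- function(intensity, scale = default_rank_scale()) {
  stopifnot_numeric(intensity, "intensity")
  vapply(intensity, function(v) {
    hit <- which((v >= scale$lo) &
                   (v < scale$hi | (scale$closed_hi & v <= scale$hi)))
    if (length(hit) != 1) {
      stop(sprintf("intensity %.4g is off the rank scale [0.5, 5.5]", v),
           call. = FALSE)
    }
    scale$rank[hit]
  }, character(1))
}

#' Read long-format assessor scores from CSV
#'
#' Expects a header row with columns `sample_id`, `assessor_id`, `score`.
#'
#' @param path CSV file path.
#' @return list of numeric score vectors, one per sample, named by
#'   `sample_id` in file order of first appearance.
#' @export
read_panel_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assessor_id", "score")
  if (!all(need %in% names(df))) {
    stop("panel CSV must have columns sample_id, assessor_id, score",
         call. = FALSE)
  }
  if (!is.numeric(df$score)) stop("score column must be numeric", call. = FALSE)
  ids <- unique(as.character(df$sample_id))
  out <- lapply(ids, function(id) df$score[as.character(df$sample_id) == id])
  names(out) <- ids
  out
}

#' Screen and summarize a set of panel score vectors
#'
#' Applies [grubbs_screen()] per sample, then [summarize_panel()], giving
#' a panel reference table (mean, sd, assessor count after screening).
#'
#' @param score_sets named list of numeric score vectors (as returned by
#'   [read_panel_scores()]).
#' @param alpha Grubbs significance level.
#' @return data frame of panel records, plus an attribute `"removed"`
#'   listing the screened-out scores per sample.
#' @export
screen_panel <- function(score_sets, alpha = 0.05) {
  recs <- vector("list", length(score_sets))
  removed <- list()
  for (i in seq_along(score_sets)) {
    id <- names(score_sets)[i] %||% as.character(i)
    scr <- grubbs_screen(score_sets[[i]], alpha = alpha)
    if (nrow(scr$removed) > 0) removed[[id]] <- scr$removed
    recs[[i]] <- summarize_panel(scr$cleaned, sample_id = id)
  }
  out <- do.call(rbind, recs)
  attr(out, "removed") <- removed
  out
}

#' Write panel records to CSV
#'
#' Columns: `sample_id`, `mean_intensity`, `sd_intensity`, `n_assessors`,
#' and any passthrough columns present (e.g. `pH`).
#'
#' @param records panel record data frame.
#' @param path output CSV path.
#' @export
write_panel_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
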