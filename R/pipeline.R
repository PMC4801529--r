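#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis.  All defaults are
#' overridable; the config is echoed into the report for provenance.
#'
#' @param dataset an [etongue_dataset()] (alternatively give
#'   `features_path`/`response_path`).
#' @param features_path,response_path CSV inputs (used when `dataset` is
#'   missing).
#' @param panel_scores named list of assessor score vectors; when given,
#'   Grubbs screening replaces the response by the screened panel means.
#' @param grubbs_alpha significance level of the panel screen.
#' @param alpha robust coverage fraction of the RPLS fit.
#' @param k fixed number of latent variables; `NULL` selects by RCS.
#' @param k_max largest k considered during selection.
#' @param gammas RCS weights tabulated.
#' @param plateau_tol plateau threshold of the selection rule.
#' @param sr_cutoff standardized-residual cutoff.
#' @param manual_exclude,manual_include manual overrides of the
#'   exclusion policy (sample ids).
#' @param lssvm_grid LSSVM tuning grid.
#' @param run_benchmarks compute the 4 x 2 method comparison (slowest
#'   stage; can be disabled for fit-only runs).
#' @param seed master seed for every stochastic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset = NULL, features_path = NULL,
                            response_path = NULL, panel_scores = NULL,
                            grubbs_alpha = 0.05, alpha = 0.75, k = NULL,
                            k_max = NULL, gammas = c(0, 0.5, 1),
                            plateau_tol = 0.05, sr_cutoff = 2.5,
                            manual_exclude = character(),
                            manual_include = character(),
                            lssvm_grid = default_lssvm_grid(),
                            run_benchmarks = TRUE, seed = 1) {
  structure(
    list(dataset = dataset, features_path = features_path,
         response_path = response_path, panel_scores = panel_scores,
         grubbs_alpha = grubbs_alpha, alpha = alpha, k = k, k_max = k_max,
         gammas = gammas, plateau_tol = plateau_tol, sr_cutoff = sr_cutoff,
         manual_exclude = as.character(manual_exclude),
         manual_include = as.character(manual_include),
         lssvm_grid = lssvm_grid, run_benchmarks = run_benchmarks,
         seed = seed),
    class = "pipeline_config"
  )
}

subset_dataset <- function(dataset, keep_ids) {
  keep <- dataset$ids %in% keep_ids
  etongue_dataset(dataset$X[keep, , drop = FALSE], dataset$y[keep],
                  dataset$ids[keep])
}

#' Number of samples retained after exclusion
#'
#' @param n_total total sample count.
#' @param excluded_ids distinct 1-based sample ids (integer or their
#'   character form) to exclude; must all lie in `1..n_total`.
#' @return `n_total - length(excluded_ids)`; warns when nothing remains.
#' @export
count_retained <- function(n_total, excluded_ids) {
  ids <- unique(as.integer(excluded_ids))
  if (length(ids) && (anyNA(ids) || any(ids < 1 | ids > n_total))) {
    stop("excluded ids must lie in 1..n_total", call. = FALSE)
  }
  left <- n_total - length(ids)
  if (left == 0) {
    warning("all samples excluded: estimator breakdown", call. = FALSE)
  }
  left
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[bitterpls] ", fmt), ...))
}

#' Benchmark the four methods before and after outlier screening
#'
#' Runs [evaluate_method()] for MLR, classical PLS, LSSVM and robust PLS
#' on the full dataset (`pre_screen`) and on the retained samples
#' (`post_screen`).  The number of latent variables is re-selected per
#' variant for the PLS-type methods and the LSSVM grid is re-tuned per
#' variant.
#'
#' @param dataset an [etongue_dataset()].
#' @param excluded_ids sample ids dropped in the post-screen variant.
#' @param hyperparams list: `alpha`, `k_max`, `gammas`, `plateau_tol`,
#'   `lssvm_grid` (all optional).
#' @param seed master seed.
#' @param verbose log stage progress to stderr.
#' @return data frame with 8 rows (4 methods x 2 variants).
#' @export
compare_methods <- function(dataset, excluded_ids = character(),
                            hyperparams = list(), seed = 1,
                            verbose = FALSE) {
  alpha <- hyperparams[["alpha", exact = TRUE]] %||% 0.75
  grid <- hyperparams[["lssvm_grid", exact = TRUE]] %||% default_lssvm_grid()
  variants <- list(
    pre_screen = dataset,
    post_screen = subset_dataset(dataset,
                                 setdiff(dataset$ids,
                                         as.character(excluded_ids)))
  )
  rows <- list()
  for (vn in names(variants)) {
    ds <- variants[[vn]]
    k_max <- min(hyperparams[["k_max", exact = TRUE]] %||% ds$p, ds$n - 2, ds$p)
    stage_log(verbose, "benchmarks (%s): selecting k (k_max = %d)", vn, k_max)
    sel <- select_num_components(
      ds, k_max = k_max, gammas = hyperparams[["gammas", exact = TRUE]] %||% c(0, 0.5, 1),
      plateau_tol = hyperparams[["plateau_tol", exact = TRUE]] %||% 0.05,
      alpha = alpha, seed = child_seed(seed, 11L)
    )
    # classical PLS: plain RMSECV over the same k range
    pls_rms <- vapply(seq_len(k_max), function(k) {
      weighted_rmse(ds$y, loocv_predictions(ds, "simpls", k = k,
                                            seed = child_seed(seed, 13L)))
    }, numeric(1))
    k_pls <- which.min(pls_rms)
    stage_log(verbose, "benchmarks (%s): tuning LSSVM", vn)
    tuned <- tune_lssvm(ds, grid = grid, seed = child_seed(seed, 17L))

    # robust PLS is reported with its conventional robust RMSECV:
    # detected outliers (from the full-data robust fit at the chosen k)
    # are zero-weighted, exactly as when quoting a robust RMSECV on a
    # dataset that still contains its outliers
    rfit <- rsimpls_fit(ds$X, ds$y, k = sel$chosen_k, alpha = alpha,
                        seed = child_seed(seed, 37L))
    rows[[length(rows) + 1]] <- evaluate_method(
      ds, "rpls", list(k = sel$chosen_k, alpha = alpha),
      seed = child_seed(seed, 19L), dataset_variant = vn,
      case_weights = if (alpha < 1) rfit$case_weights
    )
    rows[[length(rows) + 1]] <- evaluate_method(
      ds, "mlr", list(), seed = child_seed(seed, 23L), dataset_variant = vn
    )
    rows[[length(rows) + 1]] <- evaluate_method(
      ds, "pls", list(k = k_pls), seed = child_seed(seed, 29L),
      dataset_variant = vn
    )
    rows[[length(rows) + 1]] <- evaluate_method(
      ds, "lssvm", list(reg_gamma = tuned$reg_gamma,
                        kernel_width = tuned$kernel_width),
      seed = child_seed(seed, 31L), dataset_variant = vn
    )
  }
  do.call(rbind, rows)
}

#' Run the full bitterness-evaluation pipeline
#'
#' Stages, in order: (1) optional Grubbs screening of assessor panels;
#' (2) dataset assembly (from the supplied dataset or CSV paths);
#' (3) latent-variable selection by the RCS criterion; (4) robust PLS
#' fit at the chosen k; (5) outlier diagnostics (standardized residual
#' vs score distance) and three-way classification; (6) exclusion of
#' bad-leverage and vertical outliers (good leverage retained; manual
#' overrides applied); (7) retrain on the retained samples with the
#' outlier fraction set to zero (classical path, `alpha = 1`); (8) the
#' 4 x 2 method benchmark.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage progress and timings to stderr.
#' @return object of class `bitterness_report`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  seed <- config$seed

  # (1)-(2) inputs
  screened <- NULL
  if (!is.null(config$dataset)) {
    dataset <- config$dataset
  } else {
    if (is.null(config$features_path) || is.null(config$response_path)) {
      stop("pipeline needs either a dataset or feature/response paths",
           call. = FALSE)
    }
    dataset <- read_dataset(config$features_path, config$response_path)
  }
  if (!is.null(config$panel_scores)) {
    stage_log(verbose, "stage 1: Grubbs screening (alpha = %.3f)",
              config$grubbs_alpha)
    screened <- screen_panel(config$panel_scores, alpha = config$grubbs_alpha)
    idx <- match(dataset$ids, screened$sample_id)
    if (anyNA(idx)) {
      stop("panel scores missing for samples: ",
           paste(dataset$ids[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    dataset <- etongue_dataset(dataset$X, screened$mean_intensity[idx],
                               dataset$ids)
  }
  stage_log(verbose, "stage 2: dataset n = %d, p = %d", dataset$n, dataset$p)

  # (3) latent-variable selection; the default cap ~n/8 follows the
  # usual chemometrics guidance against over-parameterized PLS fits at
  # panel-study sample sizes
  k_max <- min(config$k_max %||% max(3, round(dataset$n / 8)),
               dataset$n - 2, dataset$p)
  selection <- NULL
  if (is.null(config$k)) {
    stage_log(verbose, "stage 3: RCS selection up to k_max = %d", k_max)
    selection <- select_num_components(
      dataset, k_max = k_max, gammas = config$gammas,
      plateau_tol = config$plateau_tol, alpha = config$alpha,
      seed = child_seed(seed, 1L)
    )
    k <- selection$chosen_k
  } else {
    k <- config$k
  }

  # (4) robust fit
  stage_log(verbose, "stage 4: robust PLS fit at k = %d", k)
  fit_pre <- rsimpls_fit(dataset$X, dataset$y, k = k, alpha = config$alpha,
                         seed = child_seed(seed, 2L))

  # (5) diagnostics
  stage_log(verbose, "stage 5: outlier diagnostics")
  diag_res <- diagnose(fit_pre, dataset, sr_cutoff = config$sr_cutoff)

  # (6) exclusion policy
  excl <- excluded_ids(diag_res, config$manual_exclude, config$manual_include)
  retained_ids <- setdiff(dataset$ids, excl)
  stage_log(verbose, "stage 6: excluding %d samples (%s); %d retained",
            length(excl), paste(excl, collapse = ", "), length(retained_ids))
  if (length(retained_ids) < dataset$p + 2) {
    stop("exclusion leaves too few samples to retrain", call. = FALSE)
  }

  # (7) retrain with the outlier fraction set to zero
  stage_log(verbose, "stage 7: retrain on retained samples (alpha = 1)")
  ds_post <- subset_dataset(dataset, retained_ids)
  fit_post <- rsimpls_fit(ds_post$X, ds_post$y, k = min(k, ds_post$n - 1),
                          alpha = 1, seed = child_seed(seed, 3L))

  # (8) benchmarks
  benchmarks <- NULL
  if (isTRUE(config$run_benchmarks)) {
    stage_log(verbose, "stage 8: 4 x 2 method benchmark")
    benchmarks <- compare_methods(
      dataset, excl,
      hyperparams = list(alpha = config$alpha, k_max = k_max,
                         gammas = config$gammas,
                         plateau_tol = config$plateau_tol,
                         lssvm_grid = config$lssvm_grid),
      seed = child_seed(seed, 4L), verbose = verbose
    )
  }

  # fit R2 follows the robust convention: correlation over the samples
  # the fit retained (for the classical retrain that is all of them)
  r2_fit <- function(fit, y) {
    keep <- (fit$case_weights %||% rep(1L, length(y))) == 1L
    if (stats::var(fit$fitted[keep]) == 0) 0 else
      stats::cor(y[keep], fit$fitted[keep])^2
  }
  report <- structure(
    list(
      selection = selection, chosen_k = k,
      fit_pre = fit_pre, fit_post = fit_post,
      equation_pre = equation_original_form(fit_pre),
      equation_post = equation_original_form(fit_post),
      r2_pre = r2_fit(fit_pre, dataset$y),
      r2_post = r2_fit(fit_post, ds_post$y),
      robust_rmse_pre = weighted_rmse(dataset$y, fit_pre$fitted,
                                      fit_pre$case_weights),
      diagnostics = diag_res,
      excluded_ids = excl,
      n_retained = count_retained(dataset$n,
                                  match(excl, dataset$ids)),
      benchmarks = benchmarks,
      dataset = dataset, dataset_post = ds_post,
      panel_screen = screened,
      config = config, seed = seed
    ),
    class = "bitterness_report"
  )
  stage_log(verbose, "pipeline finished in %.1f s",
            proc.time()[["elapsed"]] - t0)
  report
}

#' @export
print.bitterness_report <- function(x, ...) {
  cat("== e-tongue bitterness evaluation report ==\n")
  cat(sprintf("samples: %d (%d retained after screening)\n",
              x$dataset$n, x$n_retained))
  cat(sprintf("latent variables: k = %d\n", x$chosen_k))
  cat(sprintf("pre-screen robust fit: R2 = %.4f, weighted robust RMSE = %.4f\n",
              x$r2_pre, x$robust_rmse_pre))
  cat("pre-screen calibration equation:\n  ")
  print(x$equation_pre)
  cat(sprintf("excluded: %s\n",
              if (length(x$excluded_ids)) paste(x$excluded_ids, collapse = ", ")
              else "(none)"))
  cat("post-screen calibration equation (alpha = 1 retrain):\n  ")
  print(x$equation_post)
  if (!is.null(x$benchmarks)) {
    cat("benchmarks (LOOCV):\n")
    print(x$benchmarks[, c("method", "dataset_variant", "k", "R2_CV",
                           "RMSECV")], row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a pipeline report to a directory
#'
#' Emits deterministic text/CSV artifacts: `report.txt` (the printed
#' report and a config echo), `selection_curve.csv`, `outlier_map.csv`,
#' `benchmarks.csv`, and `model_equation.csv`.  Re-running the pipeline
#' with the same inputs, config and seed reproduces the files
#' byte-identically.
#'
#' @param report a `bitterness_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  echo <- vapply(setdiff(names(cfg), c("dataset", "panel_scores")),
                 function(nm) {
                   val <- cfg[[nm]]
                   if (is.null(val)) val <- "NULL"
                   sprintf("%s: %s", nm,
                           paste(format(unlist(val), digits = 10),
                                 collapse = ", "))
                 }, character(1))
  writeLines(c(utils::capture.output(print(report)), "",
               "-- config echo --", echo),
             file.path(dir, "report.txt"))

  if (!is.null(report$selection)) {
    write_selection_curve(report$selection,
                          file.path(dir, "selection_curve.csv"))
  }
  write_outlier_map(report$diagnostics, file.path(dir, "outlier_map.csv"))
  if (!is.null(report$benchmarks)) {
    utils::write.csv(format(report$benchmarks, digits = 10, trim = TRUE),
                     file.path(dir, "benchmarks.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  eq <- report$equation_pre
  utils::write.csv(
    data.frame(term = c(names(eq$coefficients), "(Intercept)"),
               coefficient = format(c(eq$coefficients, eq$intercept),
                                    digits = 12, trim = TRUE)),
    file.path(dir, "model_equation.csv"), row.names = FALSE, quote = FALSE
  )
  invisible(dir)
}
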