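#' Configuration for the synthetic e-tongue generator
#'
#' Describes an e-tongue calibration study with known ground truth: a
#' latent bitterness intensity drives all sensors linearly
#' (`sensor = baseline + loading * bitterness`), cross-sensitive
#' nuisance factors add correlated non-bitter matrix chemistry, each
#' sensor carries idiosyncratic noise, and the panel response is the
#' latent bitterness plus panel-mean noise.  Outliers of the three
#' canonical types can be planted on top.
#'
#' Defaults mirror the scale of a real seven-sensor potentiometric
#' array: baselines of order 10^3 response units, bitterness loadings of
#' order 10^2 per intensity unit (so fitted calibration coefficients
#' come out at the 1e-4..1e-3 magnitudes typical of raw-unit e-tongue
#' equations), latent bitterness uniform over the observed panel range
#' 0.63-4.78, and a panel-mean noise of 0.1 intensity units.
#'
#' @param n_samples number of decoction samples (default 35).
#' @param sensor_names sensor labels (default the seven-sensor array).
#' @param true_coefficients per-sensor bitterness loadings (response
#'   units per intensity unit).
#' @param sensor_baselines per-sensor offsets.
#' @param sensor_noise_sd idiosyncratic per-sensor noise sd.
#' @param n_nuisance number of cross-sensitive nuisance factors
#'   (at most `p - 1`); their loading directions are orthogonal to the
#'   bitterness fingerprint.
#' @param nuisance_sd base scale of the nuisance factors; the factor
#'   standard deviations taper as `nuisance_sd * seq(1.5, 0.75)`.
#' @param response_noise_sd sd of the panel-mean noise on the response.
#' @param bitterness_range range of the latent intensity.
#' @param contamination list of `list(type, fraction, magnitude)` with
#'   `type` one of `"good_leverage"`, `"bad_leverage"`, `"vertical"`;
#'   magnitudes are in multiples of the relevant clean sd (latent
#'   bitterness sd for leverage types, clean response-residual sd for
#'   vertical outliers).  Fractions must sum below 0.5.
#' @param n_assessors,panel_sd_range assessor-level panel simulation.
#' @param replicate_plan list with `n_cycles`, `drift`, `stabilization`,
#'   `noise_sd` for per-cycle replicate series.
#' @param seed master seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 35,
                             sensor_names = ETONGUE_SENSORS,
                             true_coefficients = c(120, -80, 150, 60,
                                                   200, -40, 90),
                             sensor_baselines = c(1800, 2100, 1500, 2400,
                                                  1900, 2200, 1700),
                             sensor_noise_sd = 100,
                             n_nuisance = 6,
                             nuisance_sd = 800,
                             response_noise_sd = 0.1,
                             bitterness_range = c(0.63, 4.78),
                             contamination = list(),
                             n_assessors = 10,
                             panel_sd_range = c(0.15, 0.9),
                             replicate_plan = list(n_cycles = 7, drift = 50,
                                                   stabilization = 3,
                                                   noise_sd = 0),
                             seed = 1) {
  p <- length(sensor_names)
  stopifnot(length(true_coefficients) == p, length(sensor_baselines) == p)
  if (sensor_noise_sd < 0 || response_noise_sd < 0 || nuisance_sd < 0) {
    stop("noise sds must be non-negative", call. = FALSE)
  }
  if (bitterness_range[1] < 0.5 || bitterness_range[2] > 5.5 ||
      diff(bitterness_range) <= 0) {
    stop("bitterness_range must be an interval within [0.5, 5.5]",
         call. = FALSE)
  }
  fracs <- vapply(contamination, function(cc) cc$fraction, numeric(1))
  if (length(fracs) && sum(fracs) >= 0.5) {
    stop("contamination fractions must sum below 0.5", call. = FALSE)
  }
  structure(
    list(n_samples = n_samples, sensor_names = sensor_names,
         true_coefficients = true_coefficients,
         sensor_baselines = sensor_baselines,
         sensor_noise_sd = sensor_noise_sd,
         n_nuisance = n_nuisance, nuisance_sd = nuisance_sd,
         response_noise_sd = response_noise_sd,
         bitterness_range = bitterness_range,
         contamination = contamination,
         n_assessors = n_assessors, panel_sd_range = panel_sd_range,
         replicate_plan = replicate_plan, seed = seed),
    class = "synthetic_config"
  )
}

#' Contamination plan mirroring a small observational study
#'
#' One good leverage point, three bad leverage points and two vertical
#' outliers -- roughly the 6-in-35 contamination pattern of a real
#' e-tongue bitterness panel -- at the stated magnitude.
#'
#' @param magnitude outlier magnitude in clean-sd multiples (default 10).
#' @param n reference sample count the fractions are quoted against.
#' @return contamination list for [synthetic_config()].
#' @export
study_contamination <- function(magnitude = 10, n = 35) {
  list(
    # half magnitude: leverage multiplies coefficient noise into the
    # residual, and a good leverage point must stay trend-consistent
    list(type = "good_leverage", fraction = 1 / n, magnitude = magnitude / 2),
    list(type = "bad_leverage", fraction = 3 / n, magnitude = magnitude),
    list(type = "vertical", fraction = 2 / n, magnitude = magnitude)
  )
}

#' Generate a synthetic e-tongue calibration dataset
#'
#' Draws the latent bitterness uniformly over the configured range,
#' builds clean sensors as baseline + loading * bitterness + nuisance +
#' noise, sets the response to bitterness + panel noise, then applies
#' the contamination plan: `vertical` outliers shift the response,
#' `bad_leverage` outliers shift the sensor vector along the bitterness
#' direction with the response held fixed (off the joint model
#' hyperplane), and `good_leverage` outliers are displaced along the
#' leading nuisance direction -- far out in sensor space but exactly on
#' the model hyperplane, so the response stays consistent.
#' Outlier counts are exact (`round(fraction * n)`); everything is
#' deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_etongue` with `dataset` (an
#'   [etongue_dataset()]) and `truth` (planted outlier ids and types,
#'   the analytic best-linear-predictor `coefficients` and `intercept`
#'   implied by the generative covariance, the latent intensities, and
#'   the clean residual sd).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  p <- length(config$sensor_names)
  l <- config$true_coefficients
  a <- config$sensor_baselines
  lo <- config$bitterness_range[1]; hi <- config$bitterness_range[2]
  var_b <- (hi - lo)^2 / 12

  counts <- vapply(config$contamination,
                   function(cc) round(cc$fraction * n), numeric(1))
  if (length(counts) && sum(counts) >= floor(n / 2)) {
    stop("contaminated count reaches the estimator breakdown point; refusing",
         call. = FALSE)
  }

  if (config$n_nuisance > p - 1) {
    stop("n_nuisance must be at most p - 1", call. = FALSE)
  }

  with_seed(config$seed, {
    b <- stats::runif(n, lo, hi)
    # Nuisance loading matrix: spans directions orthogonal to the
    # bitterness fingerprint l (interference that mimicked the bitterness
    # pattern would be indistinguishable from bitterness itself), with a
    # controlled variance spectrum and a seed-specific rotation.
    m <- config$n_nuisance
    if (m > 0) {
      B <- qr.Q(qr(cbind(l, diag(p))))[, 1 + seq_len(m), drop = FALSE]
      Qr <- qr.Q(qr(matrix(stats::rnorm(m * m), m)))
      sds <- config$nuisance_sd * seq(1.5, 0.75, length.out = m)
      M <- B %*% Qr %*% diag(sds, m)
    } else {
      M <- matrix(0, p, 1)
    }
    Z <- matrix(stats::rnorm(n * ncol(M)), nrow = n)
    E <- matrix(stats::rnorm(n * p, sd = config$sensor_noise_sd), nrow = n)
    X <- matrix(a, n, p, byrow = TRUE) + outer(b, l) + Z %*% t(M) + E
    y <- b + stats::rnorm(n, sd = config$response_noise_sd)

    # analytic best linear predictor implied by the generative
    # covariance; pseudo-inverse so the noiseless (rank-deficient) limit
    # yields the minimum-norm coefficients l / (l'l)
    Sxx <- var_b * tcrossprod(l) + tcrossprod(M) +
      diag(config$sensor_noise_sd^2, p)
    ev <- eigen(Sxx, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    beta <- as.numeric(ev$vectors[, pos, drop = FALSE] %*%
                         ((crossprod(ev$vectors[, pos, drop = FALSE],
                                     var_b * l)) / ev$values[pos]))
    mu_x <- a + l * (lo + hi) / 2
    intercept <- (lo + hi) / 2 - sum(beta * mu_x)
    resid_var <- config$response_noise_sd^2 + var_b * (1 - sum(beta * l))
    resid_sd <- sqrt(max(resid_var, 0))

    # plant outliers: exact counts, distinct indices, deterministic
    types <- rep(vapply(config$contamination, `[[`, character(1), "type"),
                 times = counts)
    mags <- rep(vapply(config$contamination, `[[`, numeric(1), "magnitude"),
                times = counts)
    out_idx <- if (length(types)) sample.int(n, length(types)) else integer()
    sd_b <- sqrt(var_b)
    for (j in seq_along(out_idx)) {
      i <- out_idx[j]
      sign_j <- sample(c(-1, 1), 1)
      if (types[j] == "vertical") {
        y[i] <- y[i] + sign_j * mags[j] * resid_sd
      } else if (types[j] == "bad_leverage") {
        X[i, ] <- X[i, ] + sign_j * mags[j] * sd_b * l
      } else {
        # good_leverage: displaced along the leading nuisance factor
        # (unusual non-bitter matrix chemistry, ordinary bitterness) --
        # far out in sensor space yet exactly on the model hyperplane,
        # so the response stays consistent.  Without nuisance factors,
        # fall back to an on-model extrapolation beyond the range.
        if (any(M != 0)) {
          X[i, ] <- X[i, ] + sign_j * mags[j] * M[, 1]
        } else {
          b_star <- hi + mags[j] * sd_b
          X[i, ] <- a + l * b_star +
            stats::rnorm(p, sd = config$sensor_noise_sd)
          y[i] <- b_star + stats::rnorm(1, sd = config$response_noise_sd)
          b[i] <- b_star
        }
      }
    }

    colnames(X) <- config$sensor_names
    rownames(X) <- as.character(seq_len(n))
    ds <- suppressWarnings(etongue_dataset(X, y))
    structure(
      list(dataset = ds,
           truth = list(
             coefficients = stats::setNames(beta, config$sensor_names),
             intercept = intercept,
             loadings = stats::setNames(l, config$sensor_names),
             baselines = stats::setNames(a, config$sensor_names),
             nuisance_loadings = M,
             latent_bitterness = b,
             clean_resid_sd = resid_sd,
             outlier_ids = as.character(out_idx),
             outlier_types = types),
           config = config),
      class = "synthetic_etongue"
    )
  })
}

#' @export
print.synthetic_etongue <- function(x, ...) {
  cat(sprintf("synthetic e-tongue study: n = %d, %d planted outliers\n",
              x$dataset$n, length(x$truth$outlier_ids)))
  if (length(x$truth$outlier_ids)) {
    cat(paste(sprintf("  %s (%s)", x$truth$outlier_ids,
                      x$truth$outlier_types), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Simulate assessor-level panel scores for one sample
#'
#' Gaussian assessor draws around the true intensity, clipped to the
#' 0.5-5.5 rank scale.
#'
#' @param true_intensity latent bitterness intensity.
#' @param n_assessors number of assessors (>= 1).
#' @param sd assessor score sd (>= 0).
#' @param seed RNG seed.
#' @return numeric vector of assessor scores.
#' @export
generate_panel_scores <- function(true_intensity, n_assessors, sd, seed = 1) {
  if (n_assessors < 1) stop("n_assessors must be >= 1", call. = FALSE)
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  with_seed(seed, {
    pmin(pmax(stats::rnorm(n_assessors, true_intensity, sd), 0.5), 5.5)
  })
}

#' Simulate a replicate acquisition series for one (sample, sensor)
#'
#' Early cycles carry an exponentially decaying stabilization drift;
#' cycles at and after the stabilization cycle equal the clean value
#' plus optional noise, so with zero noise the mean of the last four
#' cycles reproduces the clean value exactly.
#'
#' @param clean_value stabilized sensor response.
#' @param plan list with `n_cycles`, `drift`, `stabilization`,
#'   `noise_sd`.
#' @param seed RNG seed.
#' @return numeric vector of per-cycle final values.
#' @export
generate_replicate_series <- function(clean_value,
                                      plan = list(n_cycles = 7, drift = 50,
                                                  stabilization = 3,
                                                  noise_sd = 0),
                                      seed = 1) {
  nc <- plan$n_cycles
  if (nc < plan$stabilization) {
    stop("n_cycles must reach the stabilization cycle", call. = FALSE)
  }
  with_seed(seed, {
    cyc <- seq_len(nc)
    bias <- ifelse(cyc < plan$stabilization,
                   plan$drift * 2^(-(cyc - 1)), 0)
    noise <- if ((plan$noise_sd %||% 0) > 0) {
      stats::rnorm(nc, sd = plan$noise_sd)
    } else rep(0, nc)
    clean_value + bias + noise
  })
}

#' Emit a synthetic study as the CSV dialects the ingest modules read
#'
#' Writes four files into `dir`: `replicates.csv` (long-format per-cycle
#' series), `features.csv` (averaged wide-format sensor matrix),
#' `response.csv` (sample_id, bitterness), `panel_scores.csv`
#' (assessor-level long format) and `truth.csv` (planted outliers and
#' generating coefficients).
#'
#' @param sim a `synthetic_etongue` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_synthetic_csvs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  cfg <- sim$config

  long <- list()
  for (i in seq_len(ds$n)) {
    for (j in seq_len(ds$p)) {
      ser <- generate_replicate_series(
        ds$X[i, j], plan = cfg$replicate_plan,
        seed = child_seed(cfg$seed, i * 1000L + j)
      )
      long[[length(long) + 1]] <- data.frame(
        sample_id = ds$ids[i], sensor = colnames(ds$X)[j],
        cycle = seq_along(ser), value = ser, stringsAsFactors = FALSE
      )
    }
  }
  long <- do.call(rbind, long)
  utils::write.csv(format(long, digits = 12, trim = TRUE),
                   file.path(dir, "replicates.csv"),
                   row.names = FALSE, quote = FALSE)
  write_sensor_matrix(ds$X, file.path(dir, "features.csv"))
  utils::write.csv(
    data.frame(sample_id = ds$ids, bitterness = ds$y),
    file.path(dir, "response.csv"), row.names = FALSE, quote = FALSE
  )

  panel <- list()
  sds <- with_seed(child_seed(cfg$seed, 99L), {
    stats::runif(ds$n, cfg$panel_sd_range[1], cfg$panel_sd_range[2])
  })
  for (i in seq_len(ds$n)) {
    sc <- generate_panel_scores(sim$truth$latent_bitterness[i],
                                cfg$n_assessors, sds[i],
                                seed = child_seed(cfg$seed, 500L + i))
    panel[[i]] <- data.frame(
      sample_id = ds$ids[i], assessor_id = seq_along(sc), score = sc,
      stringsAsFactors = FALSE
    )
  }
  utils::write.csv(format(do.call(rbind, panel), digits = 12, trim = TRUE),
                   file.path(dir, "panel_scores.csv"),
                   row.names = FALSE, quote = FALSE)

  truth <- data.frame(
    sample_id = sim$truth$outlier_ids,
    type = sim$truth$outlier_types,
    stringsAsFactors = FALSE
  )
  utils::write.csv(truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
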