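#' Simulation configuration
#'
#' Study conditions for the synthetic-data generator. Defaults mirror the
#' recording geometry the pipeline targets — 17 posterior channels, 40
#' timepoints spanning -100..300 ms at 100 Hz, 80 trials per condition — with
#' the three object features injected as time-localized Gaussian gain bumps
#' whose default centers (87, 138, 206 ms for depth, retinal size and
#' real-world size) follow the processing order the pipeline is designed to
#' resolve. `width_ms` is the Gaussian standard deviation of the temporal
#' gain (default 15 ms, a ~35 ms FWHM transient typical of early evoked
#' components).
#'
#' @param n_conditions Number of stimulus conditions (>= 4).
#' @param n_trials_per_condition Trials per condition (>= 10, even).
#' @param n_channels Number of recording channels.
#' @param time_window_ms Epoch start/end in ms relative to stimulus onset;
#'   sample k maps to `time_window_ms[1] + k * 1000 / sample_rate_hz`.
#' @param sample_rate_hz Sampling rate.
#' @param feature_windows Data frame with columns `feature`, `center_ms`,
#'   `width_ms`, `amplitude` — one temporal injection window per feature.
#' @param noise_sd Per-trial, per-channel, per-timepoint Gaussian noise SD.
#' @param identity_amplitude Amplitude of an optional fixed per-condition
#'   identity pattern unrelated to any feature (0 = off, the default).
#' @param seed Integer seed; mandatory so a dataset is fully reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_conditions = 20,
                       n_trials_per_condition = 80,
                       n_channels = 17,
                       time_window_ms = c(-100, 300),
                       sample_rate_hz = 100,
                       feature_windows = default_feature_windows(),
                       noise_sd = 1,
                       identity_amplitude = 0,
                       seed) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("`seed` is mandatory in a simulation config.", call. = FALSE)
  }
  stopifnot(n_conditions >= 4,
            n_trials_per_condition >= 10,
            n_trials_per_condition %% 2 == 0,
            n_channels >= 1,
            length(time_window_ms) == 2, diff(time_window_ms) > 0,
            noise_sd >= 0, identity_amplitude >= 0)
  feature_windows <- tibble::as_tibble(feature_windows)
  stopifnot(all(c("feature", "center_ms", "width_ms", "amplitude") %in%
                  names(feature_windows)))
  if (any(feature_windows$width_ms <= 0)) {
    stop("feature window widths must be strictly positive.", call. = FALSE)
  }
  if (any(feature_windows$amplitude < 0)) {
    stop("feature amplitudes must be non-negative.", call. = FALSE)
  }
  n_time <- diff(time_window_ms) / 1000 * sample_rate_hz
  if (abs(n_time - round(n_time)) > 1e-9) {
    stop("epoch length times sample rate must give an integer sample count.",
         call. = FALSE)
  }
  structure(list(
    n_conditions = as.integer(n_conditions),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    n_channels = as.integer(n_channels),
    time_window_ms = time_window_ms,
    sample_rate_hz = sample_rate_hz,
    feature_windows = feature_windows,
    noise_sd = noise_sd,
    identity_amplitude = identity_amplitude,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_feature_windows <- function() {
  tibble::tibble(
    feature = c("real_world_depth", "retinal_size", "real_world_size"),
    center_ms = c(87, 138, 206),
    width_ms = 15,
    amplitude = 1
  )
}

#' Time axis of a simulation config
#' @param config A [sim_config()].
#' @return Numeric vector of sample times in ms.
#' @export
sim_time_axis <- function(config) {
  n_time <- as.integer(round(diff(config$time_window_ms) / 1000 * config$sample_rate_hz))
  config$time_window_ms[1] + (seq_len(n_time) - 1) * 1000 / config$sample_rate_hz
}

#' Draw latent condition features
#'
#' Real-world size is drawn log-uniform on the published rating range
#' (100-423 rating units) and retinal size independently log-uniform on
#' 50-600 px; the depth index is exactly size/retinal. Because depth is a
#' deterministic ratio, the three columns reproduce the qualitative
#' intercorrelation structure of the real feature set (size and depth
#' positively related, all three intercorrelated).
#'
#' @param n Number of conditions (>= 4).
#' @param seed Integer seed.
#' @param size_range,retinal_range Positive ranges for the log-uniform draws.
#' @return A [condition_set()] tibble.
#' @export
sample_latent_features <- function(n, seed,
                                   size_range = c(100, 423),
                                   retinal_range = c(50, 600)) {
  stopifnot(n >= 4, all(size_range > 0), all(retinal_range > 0))
  withr::with_seed(as.integer(seed), {
    size <- exp(stats::runif(n, log(size_range[1]), log(size_range[2])))
    retinal <- exp(stats::runif(n, log(retinal_range[1]), log(retinal_range[2])))
    condition_set(sprintf("cond_%03d", seq_len(n)), size, retinal)
  })
}

#' Labeled multichannel trial data
#'
#' @param data Numeric array, trials x channels x timepoints.
#' @param labels Condition id per trial.
#' @param time_ms Sample times in ms (strictly increasing).
#' @return An object of class `trial_array`.
#' @export
trial_array <- function(data, labels, time_ms) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  labels <- as.character(labels)
  stopifnot(length(labels) == dim(data)[1],
            length(time_ms) == dim(data)[3],
            all(diff(time_ms) > 0))
  structure(list(data = data, labels = labels, time_ms = as.numeric(time_ms)),
            class = "trial_array")
}

#' @export
print.trial_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_array> %d trials x %d channels x %d timepoints (%g..%g ms), %d conditions\n",
              d[1], d[2], d[3], min(x$time_ms), max(x$time_ms),
              length(unique(x$labels))))
  invisible(x)
}

#' Simulate multichannel trials with known feature geometry
#'
#' The noiseless signal for condition c at time t is
#' `sum_f amplitude_f * g_f(t) * u_f * z_f(c)`, where `g_f` is a unit-peak
#' Gaussian bump at (`center_ms`, `width_ms`), `u_f` a fixed random unit
#' channel direction and `z_f(c)` the standardized (z-scored) latent feature
#' value. Each trial adds i.i.d. Gaussian noise of SD `noise_sd`. A single
#' direction per feature scaled by the feature value makes the noiseless
#' pairwise pattern distance at the window center proportional to
#' `|z_f(c_i) - z_f(c_j)|`, i.e. exactly the geometry of an
#' absolute-difference hypothesis RDM, so injected feature geometry is
#' recoverable by the decoding + RSA pipeline.
#'
#' @param conditions A [condition_set()] whose feature columns are named in
#'   `config$feature_windows$feature`.
#' @param config A [sim_config()].
#' @return An object of class `synthetic_dataset`: `conditions`, `trials`
#'   (a [trial_array()]) and `ground_truth` (standardized latents `z`,
#'   channel directions `u`, temporal gains, time axis), sufficient to
#'   recompute the noiseless signal bit-exactly.
#' @export
simulate_trials <- function(conditions, config) {
  stopifnot(inherits(config, "sim_config"))
  conditions <- validate_condition_set(conditions)
  fw <- config$feature_windows
  miss <- setdiff(fw$feature, names(conditions))
  if (length(miss)) {
    stop("condition table lacks feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n_cond <- nrow(conditions)
  n_ch <- config$n_channels
  time_ms <- sim_time_axis(config)
  n_time <- length(time_ms)
  n_feat <- nrow(fw)

  z <- vapply(fw$feature, function(f) as.numeric(scale(conditions[[f]])), numeric(n_cond))
  gains <- vapply(seq_len(n_feat), function(k) {
    fw$amplitude[k] * exp(-0.5 * ((time_ms - fw$center_ms[k]) / fw$width_ms[k])^2)
  }, numeric(n_time))  # n_time x n_feat

  withr::with_seed(config$seed, {
    u <- vapply(seq_len(n_feat), function(k) {
      v <- stats::rnorm(n_ch)
      v / sqrt(sum(v^2))
    }, numeric(n_ch))  # n_ch x n_feat
    id_pat <- if (config$identity_amplitude > 0) {
      config$identity_amplitude * matrix(stats::rnorm(n_cond * n_ch), n_cond, n_ch)
    } else NULL

    # noiseless signal: cond x channel x time
    signal <- array(0, c(n_cond, n_ch, n_time))
    for (k in seq_len(n_feat)) {
      signal <- signal + outer(z[, k], outer(u[, k], gains[, k]))
    }
    if (!is.null(id_pat)) {
      onset <- which(time_ms >= 0)
      for (tt in onset) signal[, , tt] <- signal[, , tt] + id_pat
    }

    n_trials <- n_cond * config$n_trials_per_condition
    labels <- rep(conditions$id, each = config$n_trials_per_condition)
    cond_of_trial <- rep(seq_len(n_cond), each = config$n_trials_per_condition)
    data <- signal[cond_of_trial, , , drop = FALSE]
    if (config$noise_sd > 0) {
      data <- data + stats::rnorm(length(data), sd = config$noise_sd)
    }
  })

  structure(list(
    conditions = conditions,
    trials = trial_array(data, labels, time_ms),
    ground_truth = list(z = z, u = u, gains = gains, time_ms = time_ms,
                        feature_windows = fw, config = config)
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  print(x$trials)
  cat(sprintf("  injected features: %s\n",
              paste(sprintf("%s @ %g ms", x$ground_truth$feature_windows$feature,
                            x$ground_truth$feature_windows$center_ms),
                    collapse = ", ")))
  invisible(x)
}

#' Model-feature recipes
#'
#' A recipe names, per latent feature, the weight with which that feature is
#' embedded into a synthetic model feature space, plus the embedding size and
#' entry-wise noise. `recipe_early_layer()` weights retinal size and depth
#' (the low-level geometry available early in a feedforward hierarchy);
#' `recipe_late_layer()` weights real-world size (the higher-level,
#' semantically grounded dimension); `recipe_noise()` carries no feature at
#' all and is the null recipe.
#'
#' @param weights Named non-negative weights over
#'   `real_world_size`, `retinal_size`, `real_world_depth`.
#' @param n_dims Total embedding dimensions.
#' @param noise_sd Entry-wise Gaussian noise SD.
#' @param dissim_range Maximum correlation dissimilarity the carried mixture
#'   spans (1 - correlation of the most dissimilar pair before noise).
#' @return A list of class `model_recipe`.
#' @export
model_recipe <- function(weights, n_dims = 1024, noise_sd = 1,
                         dissim_range = 0.9) {
  all_feats <- c("real_world_size", "retinal_size", "real_world_depth")
  w <- stats::setNames(numeric(3), all_feats)
  stopifnot(all(names(weights) %in% all_feats), all(weights >= 0),
            dissim_range > 0, dissim_range < 2)
  w[names(weights)] <- weights
  structure(list(weights = w, n_dims = as.integer(n_dims),
                 noise_sd = noise_sd, dissim_range = dissim_range),
            class = "model_recipe")
}

#' @rdname model_recipe
#' @export
recipe_early_layer <- function(noise_sd = 1) {
  model_recipe(c(retinal_size = 1, real_world_depth = 1), noise_sd = noise_sd)
}

#' @rdname model_recipe
#' @export
recipe_late_layer <- function(noise_sd = 1) {
  model_recipe(c(real_world_size = 1), noise_sd = noise_sd)
}

#' @rdname model_recipe
#' @export
recipe_noise <- function(noise_sd = 1) {
  model_recipe(stats::setNames(numeric(0), character(0)), noise_sd = noise_sd)
}

#' Simulate a model feature matrix
#'
#' A recipe prescribes the representational geometry the model space should
#' carry: the weighted rank mixture of the named hypothesis RDMs, rescaled to
#' span `dissim_range` correlation-dissimilarity units. The target
#' correlation matrix (1 minus that dissimilarity, eigenvalue-clipped to the
#' nearest valid correlation structure) is realized by a Gaussian factor
#' model — `n_dims` i.i.d. latent draws through its Cholesky factor — so the
#' empirical 1 - Pearson RDM of the returned vectors matches the prescribed
#' mixture up to O(1/sqrt(n_dims)) sampling noise, plus entry-wise Gaussian
#' noise of SD `noise_sd`. Because the carried structure is *rank-linear* in
#' the hypothesis RDMs, partialling the named controls removes it exactly
#' (up to sampling noise): a feature the recipe does not carry is flagged at
#' the shuffle-null test's nominal rate. A recipe with no positive weight
#' yields a pure-noise matrix of the same width.
#'
#' @param conditions A [condition_set()].
#' @param recipe A [model_recipe()].
#' @param seed Integer seed.
#' @return Numeric matrix, one feature vector per condition, with the
#'   condition ids as rownames.
#' @export
simulate_model_features <- function(conditions, recipe, seed) {
  stopifnot(inherits(recipe, "model_recipe"))
  conditions <- validate_condition_set(conditions)
  n <- nrow(conditions)
  d <- recipe$n_dims
  active <- names(recipe$weights)[recipe$weights > 0]
  withr::with_seed(as.integer(seed), {
    if (length(active) == 0) {
      mat <- matrix(stats::rnorm(n * d, sd = max(recipe$noise_sd, 1)), n)
    } else {
      po <- pair_order(n)
      mix <- 0
      for (f in active) {
        v <- abs(outer(conditions[[f]], conditions[[f]], "-"))[po]
        rk <- rank(v, ties.method = "average")
        mix <- mix + recipe$weights[f] * (rk - 1) / (length(rk) - 1)
      }
      mix <- mix / max(mix)
      C <- matrix(1, n, n)
      C[po] <- 1 - recipe$dissim_range * mix
      C[po[, c(2, 1), drop = FALSE]] <- C[po]
      # make C positive definite by a uniform ridge shrink of the
      # off-diagonal, (C + bI)/(1 + b): linear in the mixture, so the
      # prescribed rank structure is preserved exactly
      e0 <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
      if (e0 < 1e-4) {
        b <- (1e-4 - e0) / (1 - 1e-4)
        C <- (C + b * diag(n)) / (1 + b)
      }
      mat <- t(chol(C)) %*% matrix(stats::rnorm(n * d), n, d)
      if (recipe$noise_sd > 0) {
        mat <- mat + stats::rnorm(length(mat), sd = recipe$noise_sd)
      }
    }
  })
  dimnames(mat) <- list(conditions$id, sprintf("f%04d", seq_len(ncol(mat))))
  mat
}

#' Simulate a multi-subject study
#'
#' One condition table is drawn from the seed; each pseudo-subject is an
#' independent noise realization of the same noiseless feature geometry
#' (subject s uses seed `seed + s`).
#'
#' @param config A [sim_config()]; its `seed` drives everything.
#' @param n_subjects Number of pseudo-subjects.
#' @return A list of class `synthetic_study`: `conditions`, `subjects` (list
#'   of `synthetic_dataset`), `config`.
#' @export
simulate_study <- function(config, n_subjects = 3) {
  stopifnot(inherits(config, "sim_config"), n_subjects >= 1)
  conditions <- sample_latent_features(config$n_conditions, config$seed)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    cfg_s <- config
    cfg_s$seed <- config$seed + s
    simulate_trials(conditions, cfg_s)
  })
  structure(list(conditions = conditions, subjects = subjects, config = config),
            class = "synthetic_study")
}
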