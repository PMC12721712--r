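#' Pipeline configuration
#'
#' Bundles the simulation, decoding and inference settings for
#' [run_rsa_pipeline()]. Every random stage consumes a seed derived from the
#' global `seed` (simulation: `seed`; subject s trials: `seed + s`; decoding
#' folds: `seed`; cluster permutations / bootstraps: `seed` plus a fixed
#' stage offset), so one integer replays the whole run.
#'
#' @param seed Global integer seed (mandatory).
#' @param n_subjects Number of pseudo-subjects to simulate.
#' @param sim A [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param decoding A [decoding_config()]; its seed defaults to `seed`.
#' @param n_permutations Cluster-test permutations (0 skips inference).
#' @param n_bootstrap Peak-latency bootstrap draws.
#' @param cluster_forming_p One-tailed cluster-forming threshold.
#' @param fallback_window_ms Peak search window used (with a notice) for a
#'   feature whose cluster test finds no significant cluster.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            n_subjects = 3,
                            sim = sim_config(seed = seed),
                            decoding = decoding_config(seed = seed),
                            n_permutations = 1000,
                            n_bootstrap = 1000,
                            cluster_forming_p = 0.05,
                            fallback_window_ms = c(0, Inf)) {
  if (missing(seed)) stop("`seed` is mandatory.", call. = FALSE)
  stopifnot(inherits(sim, "sim_config"), inherits(decoding, "decoding_config"),
            n_subjects >= 1, n_permutations >= 0, n_bootstrap >= 1)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 sim = sim, decoding = decoding,
                 n_permutations = as.integer(n_permutations),
                 n_bootstrap = as.integer(n_bootstrap),
                 cluster_forming_p = cluster_forming_p,
                 fallback_window_ms = fallback_window_ms),
            class = "pipeline_config")
}

#' Run the full simulate - decode - RSA - inference pipeline
#'
#' Simulates a multi-subject study, decodes every condition pair at every
#' timepoint into neural RDM stacks, builds the three hypothesis RDMs, runs
#' the mutually partialled RSA timecourses, cluster-based permutation tests,
#' bootstrap peak latencies within each feature's significant window, and
#' paired latency tests between features. With `n_permutations = 0` the
#' inference stage is skipped with an explicit notice. Optionally writes all
#' tabular artifacts plus a JSON manifest (settings, seeds, hashes) to
#' `out_dir`; rerunning with the same config reproduces the hashes.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for artifacts.
#' @return A list of class `rsa_pipeline_result` with elements `conditions`,
#'   `neural` (group [rdm_stack()]), `hypothesis`, `timecourses`,
#'   `cluster_tests`, `latencies`, `latency_tests`, `manifest`.
#' @export
run_rsa_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- simulate_study(config$sim, config$n_subjects)
  stacks <- lapply(seq_len(config$n_subjects), function(s) {
    neural_rdm_stack(study$subjects[[s]]$trials, config$decoding,
                     subject = sprintf("s%02d", s))
  })
  neural <- rdm_stack_bind(stacks)
  hyps <- build_hypothesis_rdms(study$conditions)
  tcs <- hyp_rsa_timecourses(neural, hyps)

  cluster_tests <- latencies <- latency_tests <- NULL
  if (config$n_permutations == 0) {
    message("n_permutations = 0: inference stage skipped.")
  } else {
    feats <- names(tcs)
    cluster_tests <- lapply(seq_along(feats), function(i) {
      cluster_permutation_test(tcs[[i]], n_permutations = config$n_permutations,
                               cluster_forming_p = config$cluster_forming_p,
                               seed = config$seed + 101L + i)
    })
    names(cluster_tests) <- feats
    latencies <- lapply(seq_along(feats), function(i) {
      f <- feats[i]
      window <- cluster_tests[[f]]
      if (!length(significant_window(window))) {
        message(sprintf(
          "no significant cluster for %s; peak search falls back to %g..%g ms.",
          f, max(config$fallback_window_ms[1], min(neural$time_ms)),
          min(config$fallback_window_ms[2], max(neural$time_ms))))
        window <- c(max(config$fallback_window_ms[1], min(neural$time_ms)),
                    min(config$fallback_window_ms[2], max(neural$time_ms)))
      }
      bootstrap_peak_latency(neural, hyps[[f]],
                             controls = hyps[setdiff(feats, f)],
                             window = window,
                             n_bootstrap = config$n_bootstrap,
                             seed = config$seed + 201L + 10L * i,
                             target_name = f)
    })
    names(latencies) <- feats
    pairs <- utils::combn(feats, 2, simplify = FALSE)
    latency_tests <- purrr::map_dfr(pairs, function(p) {
      dplyr::mutate(paired_latency_test(latencies[[p[1]]], latencies[[p[2]]]),
                    feature_a = p[1], feature_b = p[2], .before = 1)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("decodersa")),
    seed = config$seed,
    n_subjects = config$n_subjects,
    sim = config$sim[setdiff(names(config$sim), "feature_windows")],
    feature_windows = config$sim$feature_windows,
    decoding = unclass(config$decoding),
    n_permutations = config$n_permutations,
    n_bootstrap = config$n_bootstrap,
    cluster_forming_p = config$cluster_forming_p
  )
  out <- structure(list(conditions = study$conditions, neural = neural,
                        hypothesis = hyps, timecourses = tcs,
                        cluster_tests = cluster_tests, latencies = latencies,
                        latency_tests = latency_tests, manifest = manifest),
                   class = "rsa_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

#' @export
print.rsa_pipeline_result <- function(x, ...) {
  cat("<rsa_pipeline_result>\n")
  cat(sprintf("  %d conditions, %d subject(s), %d timepoints\n",
              nrow(x$conditions), dim(x$neural$values)[4],
              length(x$neural$time_ms)))
  if (!is.null(x$latencies)) {
    for (f in names(x$latencies)) {
      cat(sprintf("  %-18s peak %.1f ms +/- %.1f (SEM)\n", f,
                  x$latencies[[f]]$group_mean, x$latencies[[f]]$group_sem))
    }
  }
  invisible(x)
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_condition_table(result$conditions, file.path(out_dir, "conditions.csv"))
  tc <- purrr::map_dfr(result$timecourses, tidy, .id = "target")
  readr::write_csv(tc, file.path(out_dir, "timecourses.csv"))
  if (!is.null(result$cluster_tests)) {
    cl <- purrr::map_dfr(result$cluster_tests, tidy, .id = "target")
    readr::write_csv(cl, file.path(out_dir, "clusters.csv"))
    lat <- purrr::map_dfr(result$latencies, glance, .id = "target")
    readr::write_csv(lat, file.path(out_dir, "latencies.csv"))
    readr::write_csv(result$latency_tests, file.path(out_dir, "latency_tests.csv"))
  }
  manifest <- result$manifest
  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest$artifact_md5 <- as.list(tools::md5sum(files))
  names(manifest$artifact_md5) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a per-condition model feature matrix
#'
#' Reads a delimited table whose first column `id` names the condition and
#' whose remaining columns are feature dimensions, reordering rows to the
#' condition table's id order. Duplicate or missing ids are errors.
#'
#' @param path CSV/TSV path (delimiter inferred by extension).
#' @param conditions A [condition_set()] giving the required id order.
#' @return Numeric matrix with condition ids as rownames.
#' @export
read_feature_matrix <- function(path, conditions) {
  conditions <- validate_condition_set(conditions)
  d <- if (grepl("\\.tsv$", path)) readr::read_tsv(path, show_col_types = FALSE)
       else readr::read_csv(path, show_col_types = FALSE)
  if (!"id" %in% names(d)) stop("feature table needs an `id` column.", call. = FALSE)
  if (anyDuplicated(d$id)) {
    stop("duplicate condition id(s) in feature table: ",
         paste(unique(d$id[duplicated(d$id)]), collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(conditions$id, d$id)
  if (length(miss)) {
    stop("feature table is missing condition id(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(d[match(conditions$id, d$id), setdiff(names(d), "id")])
  if (!is.numeric(m)) stop("feature columns must be numeric.", call. = FALSE)
  rownames(m) <- conditions$id
  m
}

#' @rdname read_feature_matrix
#' @param x Numeric matrix with condition ids as rownames.
#' @export
write_feature_matrix <- function(x, path) {
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  d <- tibble::as_tibble(x)
  d <- dplyr::bind_cols(tibble::tibble(id = rownames(x)), d)
  readr::write_csv(d, path)
  invisible(x)
}
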