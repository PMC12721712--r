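#' Spearman correlation between two RDM vectors
#'
#' Spearman rho with average-rank ties. A zero-variance input yields `NaN`
#' with a warning (such timecourse cells are excluded from group tests).
#'
#' @param x,y `rdm_vector`s or numeric vectors of equal length (>= 3).
#' @return The correlation coefficient.
#' @export
spearman_rsa <- function(x, y) {
  x <- as_rdm_values(x); y <- as_rdm_values(y)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance RDM vector; Spearman correlation undefined.")
    return(NaN)
  }
  stats::cor(x, y, method = "spearman")
}

rank_avg <- function(x) rank(x, ties.method = "average")

check_controls <- function(C, labels) {
  q <- qr(cbind(1, C))
  if (q$rank < ncol(C) + 1L) {
    cc <- suppressWarnings(stats::cor(C))
    bad <- which(abs(cc) > 1 - 1e-12 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("collinear control RDMs: %s and %s.",
                   labels[bad[1, 1]], labels[bad[1, 2]]), call. = FALSE)
    }
    stop("control RDMs are collinear (rank-deficient design).", call. = FALSE)
  }
  q
}

#' Partial Spearman correlation between RDM vectors
#'
#' All vectors are rank-transformed (average ranks); both `x` and `y` are then
#' residualized on the ranked controls by least squares and the residuals are
#' correlated. With no controls this reduces exactly to [spearman_rsa()]. The
#' result equals the precision-matrix (inverse correlation) partial
#' correlation of the ranked variables.
#'
#' @param x,y `rdm_vector`s or numeric vectors.
#' @param controls List (possibly empty) of control vectors.
#' @return The partial correlation coefficient.
#' @export
partial_spearman_rsa <- function(x, y, controls = list()) {
  if (length(controls) == 0) return(spearman_rsa(x, y))
  x <- as_rdm_values(x); y <- as_rdm_values(y)
  C <- vapply(controls, as_rdm_values, numeric(length(x)))
  stopifnot(length(y) == length(x), length(x) > length(controls) + 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance RDM vector; partial Spearman undefined.")
    return(NaN)
  }
  labels <- names(controls) %||% paste0("control_", seq_along(controls))
  q <- check_controls(apply(C, 2, rank_avg), labels)
  rkx <- rank_avg(x); rky <- rank_avg(y)
  rx <- qr.resid(q, rkx)
  ry <- qr.resid(q, rky)
  # residual variance at numerical-noise level: fully explained by controls
  if (stats::sd(rx) < 1e-8 * stats::sd(rkx) ||
      stats::sd(ry) < 1e-8 * stats::sd(rky)) {
    warning("a vector is fully explained by the controls on one side; returning 0.")
    return(0)
  }
  stats::cor(rx, ry)
}

#' Time-resolved (partial) Spearman RSA
#'
#' Correlates each subject's neural RDM vector at each timepoint with the
#' target RDM vector, optionally partialling out control RDMs (e.g. each
#' hypothesis RDM against the neural stack while controlling the other two).
#'
#' @param neural An [rdm_stack()] (subjects x timepoints).
#' @param target An [rdm] sharing the stack's condition ids.
#' @param controls Named list of control [rdm]s (may be empty). The target
#'   may not appear among the controls, nor any control twice.
#' @param target_name Label stored with the result.
#' @return An object of class `rsa_timecourse`: `values` (subjects x
#'   timepoints matrix of coefficients), `time_ms`, `target`, `controls`.
#' @export
rsa_timecourse <- function(neural, target, controls = list(),
                           target_name = deparse(substitute(target))) {
  stopifnot(inherits(neural, "rdm_stack"), inherits(target, "rdm"))
  all_rdms <- c(list(target), controls)
  for (r in all_rdms) {
    if (!identical(r$ids, neural$ids)) {
      stop(sprintf(
        "condition ids differ between neural stack and an RDM (missing: %s; extra: %s).",
        paste(setdiff(neural$ids, r$ids), collapse = ", "),
        paste(setdiff(r$ids, neural$ids), collapse = ", ")), call. = FALSE)
    }
  }
  vt <- vectorize_upper(target)$values
  cv <- lapply(controls, function(r) vectorize_upper(r)$values)
  for (v in cv) {
    if (isTRUE(all.equal(v, vt, tolerance = 1e-12))) {
      stop("the target RDM may not appear among the controls.", call. = FALSE)
    }
  }
  if (length(cv) > 1) {
    for (a in seq_len(length(cv) - 1)) for (b in seq((a + 1), length(cv))) {
      if (isTRUE(all.equal(cv[[a]], cv[[b]], tolerance = 1e-12))) {
        stop("duplicated control RDMs.", call. = FALSE)
      }
    }
  }
  V <- stack_vectors(neural)
  n_subj <- dim(V)[3]; n_time <- dim(V)[2]
  values <- matrix(NA_real_, n_subj, n_time)
  ty <- rank_avg(vt)
  Cm <- if (length(cv)) vapply(cv, rank_avg, numeric(length(vt))) else NULL
  labels <- names(controls) %||% rep("control", length(controls))
  for (s in seq_len(n_subj)) {
    N <- apply(V[, , s, drop = FALSE][, , 1], 2, rank_avg)
    if (is.null(Cm)) {
      values[s, ] <- suppressWarnings(as.vector(stats::cor(N, ty)))
    } else {
      q <- check_controls(Cm, labels)
      ry <- qr.resid(q, ty)
      RN <- qr.resid(q, N)
      values[s, ] <- suppressWarnings(as.vector(stats::cor(RN, ry)))
    }
  }
  rownames(values) <- dimnames(neural$values)[[4]]
  structure(list(values = values, time_ms = neural$time_ms,
                 target = target_name,
                 controls = names(controls) %||% character(0)),
            class = "rsa_timecourse")
}

#' Hypothesis-RDM RSA timecourses with mutual partialling
#'
#' Convenience wrapper: one partial-Spearman timecourse per hypothesis RDM,
#' each controlling for the other two.
#'
#' @param neural An [rdm_stack()].
#' @param hyps A [build_hypothesis_rdms()] result.
#' @return Named list of three `rsa_timecourse`s.
#' @export
hyp_rsa_timecourses <- function(neural, hyps) {
  stopifnot(inherits(hyps, "hypothesis_rdms"))
  feats <- c("real_world_size", "retinal_size", "real_world_depth")
  out <- lapply(feats, function(f) {
    rsa_timecourse(neural, hyps[[f]], controls = hyps[setdiff(feats, f)],
                   target_name = f)
  })
  stats::setNames(out, feats)
}

#' @export
print.rsa_timecourse <- function(x, ...) {
  cat(sprintf("<rsa_timecourse> target = %s%s, %d subject(s), %d timepoints\n",
              x$target,
              if (length(x$controls)) paste0(" | ", paste(x$controls, collapse = ", ")) else "",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
tidy.rsa_timecourse <- function(x, ...) {
  tibble::tibble(
    subject = rep(rownames(x$values) %||% as.character(seq_len(nrow(x$values))),
                  times = ncol(x$values)),
    time_ms = rep(x$time_ms, each = nrow(x$values)),
    r = as.vector(x$values)
  )
}

#' @export
glance.rsa_timecourse <- function(x, ...) {
  m <- colMeans(x$values)
  tibble::tibble(target = x$target,
                 n_controls = length(x$controls),
                 n_subjects = nrow(x$values),
                 peak_time_ms = x$time_ms[which.max(m)],
                 peak_r = max(m))
}

find_clusters <- function(supra, tvals) {
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) {
    return(tibble::tibble(start_idx = integer(), end_idx = integer(),
                          stat = numeric()))
  }
  tibble::tibble(
    start_idx = starts[keep], end_idx = ends[keep],
    stat = vapply(keep, function(k) sum(tvals[starts[k]:ends[k]]), numeric(1))
  )
}

#' Cluster-based sign-flip permutation test on an RSA timecourse
#'
#' One-sample t-tests against zero per timepoint (one-tailed by default) form
#' clusters of contiguous supra-threshold timepoints; each cluster's statistic
#' is the sum of its t-values. The null distribution of the maximum cluster
#' statistic is built by randomly sign-flipping each subject's whole
#' timecourse (probability 1/2 per subject) `n_permutations` times; cluster
#' p-values use the (1 + count) / (1 + n) estimator and clusters with
#' p < 0.05 are flagged significant. Timepoints with zero across-subject
#' variance are excluded with a warning.
#'
#' @param tc An [rsa_timecourse()] (>= 2 subjects, >= 2 timepoints).
#' @param n_permutations Number of sign-flip permutations.
#' @param cluster_forming_p One-tailed cluster-forming p threshold
#'   (df = n_subjects - 1).
#' @param tail `"greater"` (the default, testing coefficients > 0).
#' @param seed Integer seed for the sign flips.
#' @return An object of class `cluster_test_result` with a `clusters` tibble
#'   (`start_ms`, `end_ms`, `stat`, `p_value`, `significant`), per-timepoint
#'   t-values and the settings used.
#' @export
cluster_permutation_test <- function(tc, n_permutations = 1000,
                                     cluster_forming_p = 0.05,
                                     tail = "greater", seed = 1) {
  stopifnot(inherits(tc, "rsa_timecourse"))
  tail <- match.arg(tail, "greater")
  X <- tc$values
  n <- nrow(X); n_time <- ncol(X)
  stopifnot(n >= 2, n_time >= 2)
  if (anyNA(X)) {
    warning("NaN coefficients present; treated as missing (excluded timepoints).")
  }
  sds <- apply(X, 2, stats::sd)
  excluded <- !is.finite(sds) | sds == 0
  if (any(excluded)) {
    warning(sprintf("%d timepoint(s) with zero across-subject variance excluded.",
                    sum(excluded)))
  }
  m <- colMeans(X)
  t_obs <- ifelse(excluded, -Inf, m / (sds / sqrt(n)))
  df <- n - 1
  thr <- stats::qt(1 - cluster_forming_p, df)
  obs <- find_clusters(t_obs > thr, t_obs)

  null_max <- numeric(n_permutations)
  if (n_permutations > 0) {
    ss <- colSums(X^2)
    withr::with_seed(seed, {
      Fm <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                   n_permutations, n)
    })
    Mp <- (Fm %*% X) / n
    Vp <- sweep(-n * Mp^2, 2, ss, "+") / (n - 1)
    Tp <- Mp / sqrt(pmax(Vp, 0) / n)
    Tp[, excluded] <- -Inf
    Tp[!is.finite(Tp)] <- -Inf
    for (b in seq_len(n_permutations)) {
      tv <- Tp[b, ]
      supra <- tv > thr
      if (!any(supra)) next
      r <- rle(supra)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      null_max[b] <- max(vapply(keep, function(k) sum(tv[starts[k]:ends[k]]),
                                numeric(1)))
    }
  }
  clusters <- obs
  clusters$start_ms <- tc$time_ms[clusters$start_idx]
  clusters$end_ms <- tc$time_ms[clusters$end_idx]
  clusters$p_value <- vapply(clusters$stat, function(s) {
    # tolerance: an identity sign-flip reproduces the observed statistic up
    # to floating-point noise and must count as >=
    (1 + sum(null_max >= s - 1e-9 * max(1, abs(s)))) / (1 + n_permutations)
  }, numeric(1))
  clusters$significant <- clusters$p_value < 0.05
  clusters <- clusters[c("start_ms", "end_ms", "start_idx", "end_idx",
                         "stat", "p_value", "significant")]
  structure(list(clusters = clusters, t = t_obs, threshold = thr,
                 n_permutations = n_permutations,
                 cluster_forming_p = cluster_forming_p, tail = tail,
                 time_ms = tc$time_ms, target = tc$target,
                 null_max = null_max),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> target = %s, %d permutation(s)\n",
              x$target, x$n_permutations))
  if (nrow(x$clusters)) print(x$clusters) else cat("  no supra-threshold clusters\n")
  invisible(x)
}

#' @export
tidy.cluster_test_result <- function(x, ...) x$clusters

#' Significant-window timepoint indices of a cluster test
#'
#' @param x A [cluster_permutation_test()] result.
#' @return Integer vector of timepoint indices in significant clusters
#'   (may be empty).
#' @export
significant_window <- function(x) {
  stopifnot(inherits(x, "cluster_test_result"))
  cl <- x$clusters[x$clusters$significant, , drop = FALSE]
  if (!nrow(cl)) return(integer(0))
  sort(unique(unlist(Map(seq, cl$start_idx, cl$end_idx))))
}

resolve_window <- function(window, time_ms) {
  if (inherits(window, "cluster_test_result")) {
    idx <- significant_window(window)
    if (!length(idx)) stop("no significant clusters: peak search window is empty.",
                           call. = FALSE)
    return(idx)
  }
  if (is.numeric(window) && length(window) == 2) {
    if (window[1] > max(time_ms) || window[2] < min(time_ms)) {
      stop("peak search window lies outside the time axis.", call. = FALSE)
    }
    idx <- which(time_ms >= window[1] & time_ms <= window[2])
    if (!length(idx)) stop("peak search window contains no timepoints.", call. = FALSE)
    return(idx)
  }
  stop("`window` must be a cluster_test_result or a length-2 ms range.",
       call. = FALSE)
}

#' Bootstrap peak-latency estimation
#'
#' Per subject and bootstrap draw, the n(n-1)/2 RDM cell entries are resampled
#' with replacement — the same resample indices applied to the neural, target
#' and control vectors — the partial-correlation timecourse is recomputed on
#' the pseudo-RDM, and the peak latency is the argmax within the search
#' window (earliest timepoint on ties). Each subject's latency is the mean of
#' its bootstrap distribution; the group summary is the mean +/- SEM of those
#' subject means. Subject s draws with seed `seed + s`.
#'
#' @param neural An [rdm_stack()].
#' @param target Target [rdm].
#' @param controls Named list of control [rdm]s.
#' @param window A [cluster_permutation_test()] result (the union of its
#'   significant clusters) or a length-2 ms range.
#' @param n_bootstrap Number of bootstrap draws (>= 1).
#' @param seed Integer seed.
#' @param target_name Label stored with the result.
#' @return An object of class `peak_latency_result`: per-subject bootstrap
#'   latency distributions, subject bootstrap-mean latencies, group mean and
#'   SEM, and the search window.
#' @export
bootstrap_peak_latency <- function(neural, target, controls = list(), window,
                                   n_bootstrap = 1000, seed = 1,
                                   target_name = deparse(substitute(target))) {
  stopifnot(inherits(neural, "rdm_stack"), n_bootstrap >= 1)
  idx <- resolve_window(window, neural$time_ms)
  vt <- vectorize_upper(target)$values
  cvs <- vapply(controls, function(r) vectorize_upper(r)$values, numeric(length(vt)))
  has_controls <- length(controls) > 0
  V <- stack_vectors(neural)
  n_subj <- dim(V)[3]
  m <- length(vt)
  lat <- matrix(NA_real_, n_subj, n_bootstrap)
  Cm <- if (has_controls) matrix(cvs, nrow = m) else matrix(0, m, 0)
  for (s in seq_len(n_subj)) {
    Vs <- V[, idx, s, drop = FALSE][, , 1, drop = FALSE]
    dim(Vs) <- c(m, length(idx))
    take <- withr::with_seed(seed + s, {
      matrix(sample.int(m, m * n_bootstrap, replace = TRUE), m, n_bootstrap)
    })
    peaks <- bootstrap_peaks_cpp(Vs, vt, Cm, take)
    lat[s, ] <- neural$time_ms[idx[peaks + 1L]]
  }
  subject_mean <- rowMeans(lat)
  names(subject_mean) <- dimnames(neural$values)[[4]]
  structure(list(
    latencies = lat, subject_mean = subject_mean,
    group_mean = mean(subject_mean),
    group_sem = stats::sd(subject_mean) / sqrt(n_subj),
    n_bootstrap = n_bootstrap,
    window_ms = range(neural$time_ms[idx]),
    window_idx = idx, target = target_name
  ), class = "peak_latency_result")
}

#' @export
print.peak_latency_result <- function(x, ...) {
  cat(sprintf("<peak_latency_result> target = %s: group mean %.1f ms +/- %.1f (SEM), window %g..%g ms, %d bootstraps\n",
              x$target, x$group_mean, x$group_sem,
              x$window_ms[1], x$window_ms[2], x$n_bootstrap))
  invisible(x)
}

#' @export
tidy.peak_latency_result <- function(x, ...) {
  tibble::tibble(
    subject = names(x$subject_mean) %||% as.character(seq_along(x$subject_mean)),
    latency_ms = unname(x$subject_mean)
  )
}

#' @export
glance.peak_latency_result <- function(x, ...) {
  tibble::tibble(target = x$target, group_mean_ms = x$group_mean,
                 group_sem_ms = x$group_sem, n_bootstrap = x$n_bootstrap,
                 window_start_ms = x$window_ms[1], window_end_ms = x$window_ms[2])
}

#' Paired t-test on bootstrap-mean peak latencies
#'
#' Two-tailed paired t-test on the per-subject bootstrap-mean latencies of
#' two features; df = n_subjects - 1. If every paired difference is an
#' identical non-zero constant the statistic diverges and the test reports
#' p = 0 with a warning; identical inputs give t = 0, p = 1.
#'
#' @param a,b [bootstrap_peak_latency()] results over the same subjects in
#'   the same order.
#' @return A tibble with `estimate` (mean latency difference a - b in ms),
#'   `t`, `df`, `p_value`.
#' @export
paired_latency_test <- function(a, b) {
  stopifnot(inherits(a, "peak_latency_result"), inherits(b, "peak_latency_result"))
  la <- a$subject_mean; lb <- b$subject_mean
  if (length(la) != length(lb) ||
      (!is.null(names(la)) && !is.null(names(lb)) && !identical(names(la), names(lb)))) {
    stop("latency results cover different subjects.", call. = FALSE)
  }
  d <- la - lb
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(estimate = 0, t = 0, df = n - 1, p_value = 1))
    }
    warning("zero variance of latency differences; t diverges, reporting p = 0.")
    return(tibble::tibble(estimate = mean(d), t = sign(mean(d)) * Inf,
                          df = n - 1, p_value = 0))
  }
  tt <- stats::t.test(la, lb, paired = TRUE)
  tibble::tibble(estimate = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value)
}

#' Shuffle-null partial-correlation test of a model RDM
#'
#' Computes the observed partial Spearman correlation between a model RDM
#' (network layer, word embedding, ...) and each hypothesis RDM, controlling
#' for the other two; the null shuffles the order of the model RDM's
#' upper-triangle cells `n_shuffles` times, recomputing all three partials
#' each time. A hypothesis is flagged significant iff its observed
#' correlation exceeds the 95th percentile of its null distribution
#' (one-sided criterion).
#'
#' @param model_rdm An [rdm] sharing ids with the hypothesis RDMs.
#' @param hyps A [build_hypothesis_rdms()] result.
#' @param n_shuffles Number of cell-order shuffles (>= 100).
#' @param seed Integer seed.
#' @return An object of class `bootstrap_null_result` whose `results` tibble
#'   has `hypothesis`, `observed`, `critical_95`, `p_value`, `significant`;
#'   the null distributions are kept in `$null`.
#' @export
model_hyp_partial_test <- function(model_rdm, hyps, n_shuffles = 1000, seed = 1) {
  stopifnot(inherits(model_rdm, "rdm"), inherits(hyps, "hypothesis_rdms"),
            n_shuffles >= 100)
  feats <- c("real_world_size", "retinal_size", "real_world_depth")
  if (!identical(model_rdm$ids, hyps[[feats[1]]]$ids)) {
    stop("model RDM and hypothesis RDMs must share condition ids.", call. = FALSE)
  }
  mv <- vectorize_upper(model_rdm)$values
  hv <- lapply(feats, function(f) vectorize_upper(hyps[[f]])$values)
  names(hv) <- feats
  m <- length(mv)
  mr <- rank_avg(mv)
  hr <- vapply(hv, rank_avg, numeric(m))
  # shuffling cell order then ranking == permuting the rank vector
  withr::with_seed(seed, {
    P <- vapply(seq_len(n_shuffles), function(b) mr[sample.int(m)], numeric(m))
  })
  observed <- numeric(3); names(observed) <- feats
  null <- matrix(NA_real_, n_shuffles, 3, dimnames = list(NULL, feats))
  for (f in feats) {
    others <- setdiff(feats, f)
    q <- check_controls(hr[, others, drop = FALSE], others)
    ry <- qr.resid(q, hr[, f])
    rx <- qr.resid(q, mr)
    # a model fully explained by the controls has no residual variance left
    if (stats::sd(rx) < 1e-8 * stats::sd(mr)) {
      observed[f] <- 0
    } else {
      obs_f <- suppressWarnings(stats::cor(rx, ry))
      observed[f] <- if (is.finite(obs_f)) obs_f else 0
    }
    RP <- qr.resid(q, P)
    null[, f] <- as.vector(stats::cor(RP, ry))
  }
  crit <- apply(null, 2, stats::quantile, probs = 0.95, names = FALSE)
  pv <- vapply(feats, function(f) {
    (1 + sum(null[, f] >= observed[f])) / (1 + n_shuffles)
  }, numeric(1))
  structure(list(
    results = tibble::tibble(hypothesis = feats, observed = unname(observed),
                             critical_95 = unname(crit), p_value = unname(pv),
                             significant = unname(observed > crit)),
    null = null, n_shuffles = n_shuffles
  ), class = "bootstrap_null_result")
}

#' @export
print.bootstrap_null_result <- function(x, ...) {
  cat(sprintf("<bootstrap_null_result> %d shuffles\n", x$n_shuffles))
  print(x$results)
  invisible(x)
}

#' @export
tidy.bootstrap_null_result <- function(x, ...) x$results

#' Commonality-analysis variance partitioning
#'
#' Decomposes the rank-regression R-squared of a neural RDM vector on up to
#' four regressor RDM vectors into unique and shared (commonality)
#' components: the R-squared of every non-empty regressor subset is computed
#' by least squares on rank-transformed vectors, and components are obtained
#' from the inclusion-exclusion identity "R2 of subset T = sum of components
#' whose regressor set intersects T". Components always sum exactly to the
#' full-model R-squared; individual commonalities can be negative (suppressor
#' structure) and are reported as such.
#'
#' @param neural_vec `rdm_vector` or numeric vector.
#' @param regressors Named list of 1-4 regressor vectors.
#' @return An object of class `variance_partition` whose `components` tibble
#'   has `component`, `regressors`, `r2`; `full_r2` holds the full-model
#'   R-squared.
#' @export
variance_partitioning <- function(neural_vec, regressors) {
  stopifnot(is.list(regressors), length(regressors) >= 1, length(regressors) <= 4)
  if (is.null(names(regressors)) || any(names(regressors) == "")) {
    stop("`regressors` must be a fully named list.", call. = FALSE)
  }
  y <- rank_avg(as_rdm_values(neural_vec))
  X <- vapply(regressors, function(r) rank_avg(as_rdm_values(r)), numeric(length(y)))
  k <- ncol(X)
  check_controls(X, colnames(X))
  tss <- sum((y - mean(y))^2)
  subsets <- lapply(seq_len(2^k - 1), function(code) which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0))
  r2 <- vapply(subsets, function(s) {
    q <- qr(cbind(1, X[, s, drop = FALSE]))
    1 - sum(qr.resid(q, y)^2) / tss
  }, numeric(1))
  M <- outer(seq_along(subsets), seq_along(subsets), Vectorize(function(ti, si) {
    as.numeric(length(intersect(subsets[[ti]], subsets[[si]])) > 0)
  }))
  comp <- solve(M, r2)
  labels <- vapply(subsets, function(s) {
    nm <- names(regressors)[s]
    if (length(s) == 1) paste0("unique_", nm) else paste0("common_", paste(nm, collapse = "_"))
  }, character(1))
  full <- r2[length(r2)]
  stopifnot(abs(sum(comp) - full) < 1e-8)
  structure(list(
    components = tibble::tibble(
      component = labels,
      regressors = vapply(subsets, function(s) paste(names(regressors)[s], collapse = ","),
                          character(1)),
      r2 = comp),
    full_r2 = full,
    subset_r2 = stats::setNames(r2, vapply(subsets, function(s)
      paste(names(regressors)[s], collapse = ","), character(1)))
  ), class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("<variance_partition> full R^2 = %.4f\n", x$full_r2))
  print(x$components)
  invisible(x)
}

#' @export
tidy.variance_partition <- function(x, ...) x$components

#' @export
glance.variance_partition <- function(x, ...) {
  tibble::tibble(full_r2 = x$full_r2, n_components = nrow(x$components))
}

#' Leave-one-subject-out noise ceiling
#'
#' Per timepoint: the upper bound is the mean over subjects of the Spearman
#' correlation between each subject's RDM vector and the all-subject mean
#' vector; the lower bound correlates each subject with the mean of the
#' remaining subjects.
#'
#' @param neural An [rdm_stack()] with >= 3 subjects.
#' @return A tibble with `time_ms`, `lower`, `upper`.
#' @export
noise_ceiling <- function(neural) {
  stopifnot(inherits(neural, "rdm_stack"))
  V <- stack_vectors(neural)
  n_subj <- dim(V)[3]
  if (n_subj < 3) stop("noise ceiling needs at least 3 subjects.", call. = FALSE)
  n_time <- dim(V)[2]
  lower <- upper <- numeric(n_time)
  for (t in seq_len(n_time)) {
    Vt <- V[, t, ]
    mall <- rowMeans(Vt)
    up <- lo <- numeric(n_subj)
    for (s in seq_len(n_subj)) {
      up[s] <- suppressWarnings(stats::cor(Vt[, s], mall, method = "spearman"))
      lo[s] <- suppressWarnings(stats::cor(Vt[, s], rowMeans(Vt[, -s, drop = FALSE]),
                                           method = "spearman"))
    }
    upper[t] <- mean(up); lower[t] <- mean(lo)
  }
  tibble::tibble(time_ms = neural$time_ms, lower = lower, upper = upper)
}
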