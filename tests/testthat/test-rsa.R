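test_that("spearman_rsa matches the rank-then-Pearson definition", {
  withr::with_seed(1, { x <- rnorm(50); y <- rnorm(50) })
  expect_equal(spearman_rsa(x, y), cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(spearman_rsa(x, exp(x)), 1)            # monotone transform
  expect_equal(spearman_rsa(x, -x), -1)               # order reversal
  expect_warning(r <- spearman_rsa(rep(1, 10), rnorm(10)), "zero-variance")
  expect_true(is.nan(r))
})

test_that("partial_spearman_rsa reduces to spearman with no controls and zeroes out shared variance", {
  withr::with_seed(2, { x <- rnorm(60); y <- rnorm(60); z <- rnorm(60) })
  expect_identical(partial_spearman_rsa(x, y), spearman_rsa(x, y))
  # y exactly equal to a control: coefficient 0
  expect_warning(p0 <- partial_spearman_rsa(x, y, list(ctrl = y)), "fully explained")
  expect_equal(p0, 0)
  # collinear controls are an error naming the pair
  expect_error(partial_spearman_rsa(x, y, list(a = z, b = 2 * z + 1)),
               "collinear.*a.*b")
})

test_that("partial_spearman_rsa equals the precision-matrix formula", {
  for (k in 1:40) {
    withr::with_seed(300 + k, {
      n <- 40 + (k %% 5) * 17
      x <- rnorm(n); y <- rnorm(n)
      nc <- 1 + (k %% 3)
      ctrls <- replicate(nc, rnorm(n) + 0.3 * x + 0.2 * y, simplify = FALSE)
    })
    got <- partial_spearman_rsa(x, y, ctrls)
    want <- precision_partial_cor(rank(x), rank(y), lapply(ctrls, rank))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("rsa_timecourse recovers injected geometry and validates inputs", {
  # size-only dataset at low noise (with zero noise decoding accuracy
  # saturates at 1 for every pair, flattening the RDM): timecourse maximum
  # inside the injected window
  cs <- sample_latent_features(10, seed = 23)
  fw <- data.frame(feature = "real_world_size", center_ms = 120,
                   width_ms = 15, amplitude = 2)
  cfg <- sim_config(n_conditions = 10, n_trials_per_condition = 20,
                    n_channels = 8, feature_windows = fw, noise_sd = 0.8, seed = 2)
  ds <- simulate_trials(cs, cfg)
  st <- neural_rdm_stack(ds$trials, decoding_config(seed = 1, n_repeats = 2))
  h <- build_hypothesis_rdms(cs)
  tc <- rsa_timecourse(st, h$real_world_size, target_name = "size")
  expect_identical(dim(tc$values), c(1L, 40L))
  pk <- tc$time_ms[which.max(tc$values[1, ])]
  expect_lte(abs(pk - 120), 20)

  # shuffled-id target: group-mean timecourse near zero
  withr::with_seed(5, perm <- sample(10))
  shuf <- rdm(h$real_world_size$values[perm, perm], ids = h$real_world_size$ids,
              kind = "abs_difference")
  tc_s <- rsa_timecourse(st, shuf, target_name = "shuffled")
  expect_lt(mean(abs(tc_s$values)), 0.25)

  # duplicated target among controls is an error
  expect_error(rsa_timecourse(st, h$real_world_size,
                              controls = list(dup = h$real_world_size)),
               "target RDM may not appear")
  expect_error(rsa_timecourse(st, h$real_world_size,
                              controls = list(a = h$retinal_size,
                                              b = h$retinal_size)),
               "duplicated control")
  # id mismatch lists the offending ids
  other <- random_symmetric_rdm(10, seed = 1)
  expect_error(rsa_timecourse(st, other), "cond_001")
})

test_that("cluster permutation test flags an injected window and respects the p floor", {
  # strong effect at samples 17-24 on top of noise
  withr::with_seed(42, X <- matrix(rnorm(10 * 40, 0, 0.2), 10, 40))
  X[, 17:24] <- X[, 17:24] + 1
  tc <- structure(list(values = X, time_ms = seq(-100, 290, by = 10),
                       target = "demo", controls = character(0)),
                  class = "rsa_timecourse")
  res <- cluster_permutation_test(tc, n_permutations = 500, seed = 3)
  sig <- res$clusters[res$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  main <- sig[which.max(sig$stat), ]
  expect_true(main$start_idx <= 17 && main$end_idx >= 24)
  # permutation p cannot undercut 1/(n_permutations + 1)
  expect_gte(min(res$clusters$p_value), 1 / 501)
  # all other flagged timepoints stay inside the injected window
  expect_true(all(unlist(Map(seq, sig$start_idx, sig$end_idx)) %in% 17:24))
})

test_that("cluster test excludes zero-variance timepoints with a warning", {
  withr::with_seed(4, X <- matrix(rnorm(8 * 12), 8, 12))
  X[, 5] <- 3  # identical across subjects
  tc <- structure(list(values = X, time_ms = seq_len(12) * 10,
                       target = "demo", controls = character(0)),
                  class = "rsa_timecourse")
  expect_warning(res <- cluster_permutation_test(tc, n_permutations = 100, seed = 1),
                 "zero across-subject variance")
  expect_false(5L %in% unlist(Map(seq, res$clusters$start_idx, res$clusters$end_idx)))
})

test_that("bootstrap peak latency is exact for a dominant unique maximum", {
  ids <- sprintf("c%d", 1:12)
  time_ms <- seq(0, 190, by = 10)
  target <- random_symmetric_rdm(12, seed = 8)
  tv <- vectorize_upper(target)$values
  # at the true peak the neural vector IS the target (rank correlation exactly
  # 1 under any resample); elsewhere a fixed corruption strictly lowers it
  corrupt <- 0.5 + abs(time_ms - 120) / 100
  corrupt[time_ms == 120] <- 0
  withr::with_seed(9, e <- rnorm(length(tv)))
  st <- stack_from_vectors(function(s, t) tv + corrupt[t] * e,
                           ids, time_ms, n_subjects = 2)
  res <- bootstrap_peak_latency(st, target, window = c(0, 190),
                                n_bootstrap = 60, seed = 2, target_name = "t")
  expect_true(all(res$latencies == 120))
  expect_equal(res$group_mean, 120)

  # exact tie between two timepoints resolves to the earliest
  st2 <- stack_from_vectors(function(s, t) (t %in% c(5, 9)) * tv,
                            ids, time_ms, n_subjects = 2)
  res2 <- bootstrap_peak_latency(st2, target, window = c(0, 190),
                                 n_bootstrap = 30, seed = 4, target_name = "t")
  expect_true(all(res2$latencies == time_ms[5]))

  # window outside the time axis errors
  expect_error(bootstrap_peak_latency(st, target, window = c(500, 600),
                                      n_bootstrap = 10, seed = 1),
               "outside the time axis")
})

test_that("paired latency tests match the textbook formula and handle degenerate cases", {
  make_res <- function(lat) {
    structure(list(latencies = matrix(lat, length(lat), 1),
                   subject_mean = lat, group_mean = mean(lat),
                   group_sem = sd(lat) / sqrt(length(lat)),
                   n_bootstrap = 1, window_ms = c(0, 100), window_idx = 1:2,
                   target = "x"), class = "peak_latency_result")
  }
  withr::with_seed(11, { la <- rnorm(8, 150, 20); lb <- rnorm(8, 120, 20) })
  out <- paired_latency_test(make_res(la), make_res(lb))
  d <- la - lb
  t_manual <- mean(d) / (sd(d) / sqrt(8))
  expect_equal(out$t, t_manual, tolerance = 1e-12)
  expect_equal(out$df, 7)
  expect_equal(out$p_value, 2 * pt(-abs(t_manual), 7), tolerance = 1e-12)

  same <- paired_latency_test(make_res(la), make_res(la))
  expect_equal(same$t, 0); expect_equal(same$p_value, 1)

  expect_warning(deg <- paired_latency_test(make_res(la), make_res(la - 30)),
                 "zero variance")
  expect_equal(deg$p_value, 0)
  expect_error(paired_latency_test(make_res(la), make_res(rnorm(5))),
               "different subjects")
})

test_that("model x hypothesis shuffle test flags the carried feature only", {
  cs <- sample_latent_features(20, seed = 31)
  h <- build_hypothesis_rdms(cs)
  res <- model_hyp_partial_test(h$real_world_size, h, n_shuffles = 500, seed = 5)
  tab <- res$results
  expect_true(tab$significant[tab$hypothesis == "real_world_size"])
  expect_gt(tab$observed[tab$hypothesis == "real_world_size"], 0.99)
  expect_true(all(abs(tab$observed[tab$hypothesis != "real_world_size"]) < 0.05))
})

test_that("variance partitioning matches an all-subsets R2 oracle", {
  withr::with_seed(6, {
    m <- 80
    a <- rnorm(m); b <- rnorm(m) + 0.5 * a; c_ <- rnorm(m)
    y <- a + 0.7 * b + 0.3 * c_ + rnorm(m)
  })
  vp <- variance_partitioning(y, list(a = a, b = b, c = c_))
  # oracle: subset R2s recomputed via lm() on ranks; components must satisfy
  # R2(T) = sum of components whose regressor set intersects T
  X <- cbind(a = rank(a), b = rank(b), c = rank(c_))
  yr <- rank(y)
  subsets <- unlist(lapply(1:3, function(k) combn(colnames(X), k, simplify = FALSE)),
                    recursive = FALSE)
  r2_lm <- vapply(subsets, function(s) {
    summary(lm(yr ~ X[, s, drop = FALSE]))$r.squared
  }, numeric(1))
  for (ti in seq_along(subsets)) {
    hits <- vapply(seq_len(nrow(vp$components)), function(si) {
      any(strsplit(vp$components$regressors[si], ",")[[1]] %in% subsets[[ti]])
    }, logical(1))
    expect_equal(sum(vp$components$r2[hits]), r2_lm[ti], tolerance = 1e-10)
  }
  expect_equal(sum(vp$components$r2), vp$full_r2, tolerance = 1e-12)
  expect_true(vp$full_r2 >= 0 && vp$full_r2 <= 1)
})

test_that("variance partitioning degenerate structures behave as defined", {
  # single regressor: unique component equals full R2
  withr::with_seed(7, { x <- rnorm(30); y <- x + rnorm(30) })
  vp1 <- variance_partitioning(y, list(x = x))
  expect_equal(vp1$components$r2, vp1$full_r2)
  # rank-orthogonal regressors: zero commonality, uniques equal marginals
  r1 <- c(1, 2, 3, 4); r2 <- c(2, 4, 1, 3)  # centered rank vectors, orthogonal
  yy <- c(1.2, 0.3, 2.5, 0.9)
  vp2 <- variance_partitioning(yy, list(p = r1, q = r2))
  common <- vp2$components$r2[vp2$components$component == "common_p_q"]
  expect_equal(common, 0, tolerance = 1e-10)
  u_p <- vp2$components$r2[vp2$components$component == "unique_p"]
  expect_equal(u_p, unname(vp2$subset_r2["p"]), tolerance = 1e-10)
  # collinear regressors are an error
  expect_error(variance_partitioning(y, list(a = x, b = 3 * x + 2)), "collinear")
})

test_that("noise ceiling bounds behave at the extremes and order correctly", {
  ids <- sprintf("c%d", 1:10)
  tv <- vectorize_upper(random_symmetric_rdm(10, seed = 3))$values
  # identical subjects: lower = upper = 1
  st_same <- stack_from_vectors(function(s, t) tv, ids, 1:4, n_subjects = 4)
  nc_same <- noise_ceiling(st_same)
  expect_equal(nc_same$lower, rep(1, 4))
  expect_equal(nc_same$upper, rep(1, 4))
  # independent-noise subjects: no shared structure. The lower (leave-one-out)
  # bound sits at zero; the upper bound keeps the ~1/sqrt(k) own-subject bias.
  withr::with_seed(31, {
    st_noise <- stack_from_vectors(function(s, t) rnorm(45), ids, 1:4, 10)
  })
  nc_noise <- noise_ceiling(st_noise)
  expect_lt(mean(abs(nc_noise$lower)), 0.15)
  expect_lt(mean(nc_noise$upper), 0.5)
  expect_true(all(nc_noise$lower <= nc_noise$upper))
  # shared signal + noise: the leave-one-out (lower) bound grows with subject
  # count as the left-out mean gets cleaner; lower stays below upper
  ceil_at <- function(k) {
    st <- stack_from_vectors(function(s, t) tv + rnorm(45, sd = 1),
                             ids, 1:3, n_subjects = k)
    nc <- noise_ceiling(st)
    c(lower = mean(nc$lower), upper = mean(nc$upper))
  }
  withr::with_seed(12, {
    c3 <- rowMeans(replicate(20, ceil_at(3)))
    c9 <- rowMeans(replicate(20, ceil_at(9)))
  })
  expect_gt(c9["lower"], c3["lower"])
  expect_lte(c3["lower"], c3["upper"])
  expect_error(noise_ceiling(stack_from_vectors(function(s, t) tv, ids, 1:3, 2)),
               "at least 3 subjects")
})
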