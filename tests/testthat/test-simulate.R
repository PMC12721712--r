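test_that("latent features reproduce the depth ratio and seed determinism", {
  cs <- sample_latent_features(50, seed = 7)
  expect_equal(cs$real_world_depth, cs$real_world_size / cs$retinal_size,
               tolerance = 1e-15)
  expect_identical(sample_latent_features(50, seed = 7), cs)
  expect_false(identical(sample_latent_features(50, seed = 8)$real_world_size,
                         cs$real_world_size))
  # published rating range respected
  expect_true(all(cs$real_world_size >= 100 & cs$real_world_size <= 423))
  # constant retinal size: size and depth RDM vectors rank-identical
  csc <- condition_set(cs$id, cs$real_world_size, rep(200, 50))
  h <- suppressWarnings(build_hypothesis_rdms(csc))  # flat retinal RDM warns
  expect_equal(h$intercorrelations["real_world_size", "real_world_depth"], 1)
})

test_that("mean size-depth RDM correlation is positive across seeds", {
  r <- vapply(1:60, function(s) {
    h <- build_hypothesis_rdms(sample_latent_features(20, seed = 7000 + s))
    h$intercorrelations["real_world_size", "real_world_depth"]
  }, numeric(1))
  expect_gt(mean(r), 0)
})

test_that("simulated trials realize |dz| pattern geometry at the bump center", {
  cs <- sample_latent_features(10, seed = 3)
  fw <- data.frame(feature = "real_world_size", center_ms = 100,
                   width_ms = 15, amplitude = 2)
  cfg <- sim_config(n_conditions = 10, n_trials_per_condition = 10,
                    n_channels = 6, feature_windows = fw, noise_sd = 0,
                    seed = 5)
  ds <- simulate_trials(cs, cfg)
  t0 <- which(ds$trials$time_ms == 100)
  # one noiseless trial per condition suffices (all trials identical)
  first <- match(cs$id, ds$trials$labels)
  pat <- ds$trials$data[first, , t0]
  z <- ds$ground_truth$z[, "real_world_size"]
  for (i in 1:9) for (j in (i + 1):10) {
    d_pat <- sqrt(sum((pat[i, ] - pat[j, ])^2))
    expect_equal(d_pat, 2 * abs(z[i] - z[j]), tolerance = 1e-10)
  }
})

test_that("same seed and config give a bit-identical dataset", {
  cs <- sample_latent_features(8, seed = 2)
  cfg <- sim_config(n_conditions = 8, n_trials_per_condition = 10,
                    n_channels = 5, noise_sd = 1, seed = 99)
  a <- simulate_trials(cs, cfg)
  b <- simulate_trials(cs, cfg)
  expect_identical(a$trials$data, b$trials$data)
  expect_identical(a$ground_truth$u, b$ground_truth$u)
})

test_that("disjoint feature windows localize their RDM geometry in time", {
  cs <- sample_latent_features(12, seed = 13)
  fw <- data.frame(feature = c("real_world_size", "retinal_size"),
                   center_ms = c(50, 200), width_ms = 12, amplitude = 1)
  cfg <- sim_config(n_conditions = 12, n_trials_per_condition = 10,
                    n_channels = 8, feature_windows = fw, noise_sd = 0, seed = 4)
  ds <- simulate_trials(cs, cfg)
  first <- match(cs$id, ds$trials$labels)
  h <- build_hypothesis_rdms(cs)
  # rank agreement with a feature RDM is scale-free, so on noiseless data it
  # is high anywhere that feature dominates; the time-localized quantity is
  # the covariance, which scales with the temporal gain and peaks at the
  # window center
  cov_with <- function(target_rdm, t) {
    pat <- ds$trials$data[first, , t]
    d <- as.matrix(dist(pat))
    cov(d[upper.tri(d)], target_rdm$values[upper.tri(target_rdm$values)])
  }
  tms <- ds$trials$time_ms
  cs_size <- vapply(seq_along(tms), function(t) cov_with(h$real_world_size, t), numeric(1))
  cs_ret <- vapply(seq_along(tms), function(t) cov_with(h$retinal_size, t), numeric(1))
  expect_true(abs(tms[which.max(cs_size)] - 50) <= 10)
  expect_true(abs(tms[which.max(cs_ret)] - 200) <= 10)
  # and inside each window the injected feature's rank agreement is at ceiling
  rank_agree <- function(target_rdm, t) {
    pat <- ds$trials$data[first, , t]
    d <- as.matrix(dist(pat))
    suppressWarnings(cor(d[upper.tri(d)],
                         target_rdm$values[upper.tri(target_rdm$values)],
                         method = "spearman"))
  }
  expect_gt(rank_agree(h$real_world_size, which(tms == 50)), 0.99)
  expect_gt(rank_agree(h$retinal_size, which(tms == 200)), 0.99)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(seed = 1, n_conditions = 3), "n_conditions")
  expect_error(sim_config(seed = 1, n_trials_per_condition = 15), "%%")
  fw <- data.frame(feature = "real_world_size", center_ms = 100,
                   width_ms = 0, amplitude = 1)
  expect_error(sim_config(seed = 1, feature_windows = fw), "width")
  expect_error(sim_config(n_conditions = 10), "seed")
})

test_that("model feature recipes carry the intended geometry", {
  cs <- sample_latent_features(20, seed = 17)
  h <- build_hypothesis_rdms(cs)
  # zero noise, size-only recipe: near-perfect rank agreement with size RDM
  fm <- simulate_model_features(cs, model_recipe(c(real_world_size = 1),
                                                 noise_sd = 0), seed = 1)
  r <- rdm_from_feature_vectors(cs$id, fm)
  expect_gte(cor(vectorize_upper(r)$values,
                 vectorize_upper(h$real_world_size)$values,
                 method = "spearman"), 0.99)
  # pure-noise recipe: all partial correlations near zero
  fm0 <- simulate_model_features(cs, recipe_noise(), seed = 2)
  r0 <- rdm_from_feature_vectors(cs$id, fm0)
  feats <- c("real_world_size", "retinal_size", "real_world_depth")
  for (f in feats) {
    pc <- partial_spearman_rsa(vectorize_upper(r0), vectorize_upper(h[[f]]),
                               h[setdiff(feats, f)])
    expect_lt(abs(pc), 0.2)
  }
  # determinism
  expect_identical(simulate_model_features(cs, recipe_early_layer(), seed = 9),
                   simulate_model_features(cs, recipe_early_layer(), seed = 9))
})

test_that("multi-subject studies share conditions but differ in noise", {
  cfg <- sim_config(n_conditions = 6, n_trials_per_condition = 10,
                    n_channels = 4, seed = 77)
  st <- simulate_study(cfg, n_subjects = 3)
  expect_length(st$subjects, 3)
  expect_identical(st$subjects[[1]]$conditions, st$subjects[[2]]$conditions)
  expect_false(identical(st$subjects[[1]]$trials$data, st$subjects[[2]]$trials$data))
  # noiseless signal identical across subjects (same ground-truth geometry)
  expect_identical(st$subjects[[1]]$ground_truth$z, st$subjects[[2]]$ground_truth$z)
})
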