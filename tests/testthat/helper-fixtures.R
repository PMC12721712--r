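# Shared fixture builders; everything is generated in code at test time.

random_symmetric_rdm <- function(n, seed = 1, kind = "abs_difference") {
  withr::with_seed(seed, {
    m <- matrix(runif(n * n), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
  })
  rdm(m, kind = kind)
}

# Stack whose subject/timepoint RDM vectors are supplied directly, bypassing
# decoding, for inference-level tests.
stack_from_vectors <- function(vec_fun, ids, time_ms, n_subjects) {
  n <- length(ids)
  # row-major (i < j) order, matching vectorize_upper()
  po <- do.call(rbind, lapply(seq_len(n - 1), function(i) cbind(i, (i + 1):n)))
  values <- array(0, c(n, n, length(time_ms), n_subjects),
                  dimnames = list(ids, ids, NULL, sprintf("s%02d", seq_len(n_subjects))))
  for (s in seq_len(n_subjects)) {
    for (t in seq_along(time_ms)) {
      v <- vec_fun(s, t)
      m <- matrix(0, n, n)
      m[po] <- v
      m[po[, c(2, 1), drop = FALSE]] <- v
      values[, , t, s] <- m
    }
  }
  rdm_stack(values, ids, time_ms, kind = "abs_difference")
}

# Gaussian two-class trial set: condition "a" centered at +mu/2, "b" at -mu/2
# along a random channel direction at every timepoint.
two_class_trials <- function(n_per = 80, n_ch = 8, n_time = 10, sep = 0, seed = 1) {
  withr::with_seed(seed, {
    u <- rnorm(n_ch); u <- u / sqrt(sum(u * u))
    data <- array(rnorm(2 * n_per * n_ch * n_time), c(2 * n_per, n_ch, n_time))
    shift <- outer(rep(c(+sep / 2, -sep / 2), each = n_per), u)
    for (t in seq_len(n_time)) data[, , t] <- data[, , t] + shift
  })
  trial_array(data, rep(c("a", "b"), each = n_per), seq_len(n_time))
}

# Brute-force partial correlation via the precision (inverse correlation)
# matrix of [x, y, controls].
precision_partial_cor <- function(x, y, controls) {
  R <- stats::cor(cbind(x, y, do.call(cbind, controls)))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}
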