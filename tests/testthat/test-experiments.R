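# Experiment drivers: settling, error distributions, density, ROC, outliers.

test_that("settling time follows the 95%-of-change definition", {
  # immediate jump settles at 0
  expect_equal(settling_time(c(8, 8, 10, 10), 8, 10, step_index = 3), 0)
  # linear ramp over 100 samples crosses the 95% level at 95
  ramp <- c(0, 0, seq(0, 1, length.out = 101))
  expect_equal(settling_time(ramp, 0, 1, step_index = 3), 95)
  # falling steps are direction-aware
  expect_equal(settling_time(c(10, 10, 8), 10, 8, step_index = 3), 0)
  # never settles
  expect_true(is.na(settling_time(rep(0, 50), 0, 1, step_index = 1)))
  expect_error(settling_time(1:10, 5, 5), "differ")
  expect_error(settling_time(1:10, 0, 1, step_index = 99), "outside")
})

test_that("CMM settles in about L/2 samples on a noiseless step", {
  L <- 31
  x <- c(rep(8, L), rep(10, 3 * L))
  trace <- stream_estimate(x, L, backend = "cmm")
  st <- settling_time(as.numeric(trace), 8, 10, step_index = L + 1)
  expect_equal(st, (L - 1) / 2)
  # and the oracle agrees with the incremental stream on the same input
  expect_equal(as.numeric(trace[L:length(x)]), sliding_median_oracle(x, L))
})

test_that("step experiment converges and flags degenerate steps", {
  sp <- step_spec(dist_normal(8, 2), dist_normal(10, 2), 630, 1260)
  res <- run_step_experiment(sp, L = 63, backend = "nm", n_reps = 200,
                             seed = 1)
  sm <- attr(res, "summary")
  expect_equal(sm$mean_final, 10, tolerance = 0.01)
  expect_true(all(res$settled))
  expect_identical(nrow(res), 200L)
  # same distribution on both sides: settling 0 by convention
  dg <- run_step_experiment(step_spec(dist_normal(5, 1), dist_normal(5, 1),
                                      200, 200),
                            L = 63, backend = "cmm", n_reps = 5, seed = 1)
  expect_true(all(dg$settling_time == 0))
})

test_that("experiment outputs are seed-reproducible", {
  sp <- step_spec(dist_normal(8, 2), dist_normal(10, 2), 315, 315)
  a <- run_step_experiment(sp, L = 63, backend = "nm", n_reps = 20, seed = 7)
  b <- run_step_experiment(sp, L = 63, backend = "nm", n_reps = 20, seed = 7)
  expect_identical(a$final_estimate, b$final_estimate)
  e1 <- error_distribution(dist_normal(0, 1), 63, "nm", n_reps = 20, seed = 7)
  e2 <- error_distribution(dist_normal(0, 1), 63, "nm", n_reps = 20, seed = 7)
  expect_identical(e1$errors, e2$errors)
})

test_that("error dispersion shrinks with buffer length and NM beats CMM", {
  d <- dist_normal(0, 1)
  Ls <- c(63, 127, 255)
  std_nm <- vapply(Ls, function(L)
    error_distribution(d, L, "nm", n_reps = 250, run_length = 20 * L,
                       seed = 5)$std, numeric(1))
  std_cmm <- vapply(Ls, function(L)
    error_distribution(d, L, "cmm", n_reps = 250, run_length = 20 * L,
                       seed = 6)$std, numeric(1))
  expect_true(all(diff(std_nm) < 0))
  expect_true(all(diff(std_cmm) < 0))
  expect_true(all(std_nm < std_cmm))
  # order-statistic scaling: std(CMM-63)/std(CMM-255) ~ sqrt(255/63)
  expect_equal(std_cmm[1] / std_cmm[3], 2, tolerance = 0.15)
})

test_that("buffer density concentrates around the median over time", {
  d <- buffer_density(dist_normal(0, 1), L = 63,
                      time_points = c(0, 630, 3150), n_reps = 60, seed = 3)
  expect_equal(rowSums(d$density), rep(1, 3), tolerance = 1e-9)
  expect_true(all(diff(d$iqr) < 0))
  # folded normal: late-time density mode sits at the median, not the mean
  df <- buffer_density(dist_folded_normal(1), L = 255,
                       time_points = c(0, 2550, 12750), n_reps = 60, seed = 4)
  centers <- (head(df$bin_edges, -1) + tail(df$bin_edges, -1)) / 2
  mode_late <- centers[which.max(df$density[3, ])]
  expect_lt(abs(mode_late - qnorm(0.75)), 0.05)
  expect_gt(abs(mode_late - sqrt(2 / pi)), 0.05)
})

test_that("an injected extreme outlier survives k steps with probability 2^-k", {
  set.seed(23)
  n_reps <- 1000
  surv <- matrix(FALSE, n_reps, 8)
  for (r in seq_len(n_reps)) {
    st <- nm_init(rnorm(15))
    for (w in 1:60) st <- nm_update(st, rnorm(1))
    st$values[15] <- 1e6                 # replace the max with an outlier
    for (k in 1:8) {
      st <- nm_update(st, rnorm(1))
      surv[r, k] <- 1e6 %in% st$values
    }
  }
  p_hat <- colMeans(surv)
  p_exp <- 0.5^(1:8)
  se <- sqrt(p_exp * (1 - p_exp) / n_reps)
  expect_true(all(abs(p_hat - p_exp) < 5 * se))
  # survival is a nested event: probabilities must be non-increasing
  expect_true(all(diff(p_hat) <= 0))
})

test_that("NM variance beats CMM at equal length on contaminated input", {
  r <- outlier_robustness(L = 63, n_reps = 120, seed = 11)
  expect_lt(r$var_nm, r$var_cmm)
  expect_equal(r$true_median, 0, tolerance = 1e-8)
  # degenerate mixture reduces to the plain iid comparison
  r0 <- outlier_robustness(outlier_prob = 0, L = 63, n_reps = 120, seed = 12)
  expect_lt(r0$var_nm, r0$var_cmm)
})

test_that("ROC: no change is chance level, large changes are separable", {
  r <- roc_small_change(c(0, 0.5), n_reps = 120, seed = 9)
  auc <- r$auc
  expect_equal(auc$auc[auc$delta == 0], c(0.5, 0.5), tolerance = 0.12)
  expect_true(all(auc$auc[auc$delta == 0.5] > 0.99))
  # curves are monotone from (0,0) to (1,1)
  cv <- r$curves[[1]]
  expect_true(all(diff(cv$fpr) <= 0))
  expect_equal(range(cv$fpr), c(0, 1))
  expect_equal(range(cv$tpr), c(0, 1))
})

test_that("settling scales with step amplitude for NM but not CMM", {
  tab <- settling_vs_amplitude(medians_after = c(1.21, 3.01, 20.50),
                               n_reps = 150, seed = 2)
  nm <- tab[tab$backend == "nm", ]
  cmm <- tab[tab$backend == "cmm", ]
  # CMM-511: consistent settling across amplitudes, near its buffer length
  expect_lt(diff(range(cmm$mean_settling)) / mean(cmm$mean_settling), 0.15)
  expect_equal(mean(cmm$mean_settling), 511, tolerance = 0.15)
  # NM-63: settling decreases with the size of the median step and is faster
  # than the equal-variance CMM-511 at every level
  expect_true(all(diff(nm$mean_settling) < 0))
  expect_true(all(nm$mean_settling < cmm$mean_settling))
  # large amplitude: the typical repetition settles within L to 2L steps
  # (the mean is inflated by a heavy right tail)
  sigma_of <- function(m) m / qnorm(0.75)
  sp <- step_spec(dist_folded_normal(sigma_of(qnorm(0.75))),
                  dist_folded_normal(sigma_of(20.5)), 630, 1260)
  big <- run_step_experiment(sp, L = 63, backend = "nm", n_reps = 300,
                             seed = 2)
  typical <- median(big$settling_time, na.rm = TRUE)
  expect_gte(typical, 63)
  expect_lte(typical, 126)
})
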