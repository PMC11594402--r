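# Simulation drivers characterising the estimators: settling time after a
# distribution step, steady-state error distributions, buffer density
# dynamics, ROC discrimination of small median changes, outlier robustness,
# and settling time versus step amplitude.

# independent per-repetition seeds derived from one master seed
rep_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

estimator_tag <- function(backend, L) paste0(toupper(backend), "-", L)

#' Settling time of an estimate trace after a step change
#'
#' The settling time is the first time, counted in samples from the step, at
#' which the estimate reaches 95% of the median change, i.e. crosses the
#' level `mu_f - 0.05 * (mu_f - mu_i)` (from below when the median rises,
#' from above when it falls).  First touch counts: trajectories are noisy and
#' may re-cross afterwards.
#'
#' @param trace per-sample estimate trace.
#' @param mu_i,mu_f true medians before and after the step (`mu_f != mu_i`).
#' @param step_index 1-based index of the first post-step sample in `trace`.
#' @return number of samples after the step at which the level is first
#'   touched (0 when the very first post-step estimate already crossed), or
#'   `NA` when the trace never settles.
#' @examples
#' settling_time(c(0, 0, seq(0, 1, length.out = 101)), 0, 1, step_index = 3)
#' @export
settling_time <- function(trace, mu_i, mu_f, step_index = 1L) {
  if (mu_f == mu_i) stop("mu_f must differ from mu_i")
  if (step_index < 1L || step_index > length(trace))
    stop("step_index outside the trace")
  level <- mu_f - 0.05 * (mu_f - mu_i)
  post <- trace[step_index:length(trace)]
  hit <- if (mu_f > mu_i) post >= level else post <= level
  k <- which(hit)
  if (!length(k)) return(NA_integer_)
  k[1L] - 1L
}

#' Repeat a distribution step experiment
#'
#' Streams many independent realisations of a step-change stimulus through an
#' estimator and records, per repetition, the settling time and the final
#' estimation error (last estimate minus the true post-step median).
#'
#' @param spec a [step_spec()]; its `seed` field is ignored in favour of
#'   per-repetition seeds derived from `seed`.
#' @param L odd buffer length.
#' @param backend `"nm"` or `"cmm"`.
#' @param n_reps number of independent repetitions.
#' @param seed master seed.
#' @return data.frame of class `step_experiment` with columns `rep`,
#'   `settling_time` (`NA` when not settled), `settled`, `final_estimate`,
#'   `final_error`; the attribute `summary` holds `mean_final`,
#'   `sd_final_error`, `mean_settling` (over settled repetitions),
#'   `sd_settling` and the configuration.  When the two distributions have
#'   the same median the settling time is 0 by convention.
#' @examples
#' sp <- step_spec(dist_normal(8, 2), dist_normal(10, 2), 630, 1260)
#' r <- run_step_experiment(sp, L = 63, backend = "nm", n_reps = 50, seed = 1)
#' attr(r, "summary")$mean_final  # close to 10
#' @export
run_step_experiment <- function(spec, L, backend = c("nm", "cmm"),
                                n_reps = 100L, seed = 1L) {
  stopifnot(inherits(spec, "step_spec"), n_reps >= 1)
  backend <- match.arg(backend)
  L <- check_buffer_length(L)
  mu_i <- dist_median(spec$dist_before)
  mu_f <- dist_median(spec$dist_after)
  degenerate <- mu_f == mu_i
  seeds <- rep_seeds(seed, n_reps)
  settle <- integer(n_reps)
  final <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    s <- gen_step_stream(step_spec(spec$dist_before, spec$dist_after,
                                   spec$n_before, spec$n_after,
                                   seed = seeds[r]))
    trace <- stream_estimate(s$samples, L = L, backend = backend)
    final[r] <- trace[length(trace)]
    settle[r] <- if (degenerate) 0L
      else settling_time(as.numeric(trace), mu_i, mu_f, s$step_index)
  }
  out <- data.frame(rep = seq_len(n_reps), settling_time = settle,
                    settled = !is.na(settle), final_estimate = final,
                    final_error = final - mu_f)
  attr(out, "summary") <- list(
    estimator = estimator_tag(backend, L),
    mu_i = mu_i, mu_f = mu_f,
    mean_final = mean(final),
    sd_final_error = sd(final - mu_f),
    mean_settling = mean(settle, na.rm = TRUE),
    sd_settling = sd(settle, na.rm = TRUE),
    n_not_settled = sum(is.na(settle)))
  class(out) <- c("step_experiment", "data.frame")
  out
}

#' Steady-state error distribution of an estimator
#'
#' Runs `n_reps` independent i.i.d. streams of `run_length` samples and
#' collects the final estimation error (last estimate minus the true median).
#' The default run length of `50 * L` samples lets the buffer concentration
#' play out so the spread measures the steady state.
#'
#' @param dist a [dist_spec].
#' @param L odd buffer length.
#' @param backend `"nm"` or `"cmm"`.
#' @param n_reps repetitions.
#' @param run_length samples per repetition (several `L` at least).
#' @param seed master seed.
#' @return list of class `error_distribution`: `errors` (length `n_reps`),
#'   `std`, `histogram` (a `graphics::hist` object, not plotted), and the
#'   configuration.
#' @examples
#' e <- error_distribution(dist_normal(0, 1), L = 63, backend = "nm",
#'                         n_reps = 100, seed = 1)
#' e$std
#' @export
error_distribution <- function(dist, L, backend = c("nm", "cmm"),
                               n_reps = 500L, run_length = 50L * L,
                               seed = 1L) {
  stopifnot(inherits(dist, "dist_spec"), n_reps >= 2)
  backend <- match.arg(backend)
  L <- check_buffer_length(L)
  if (run_length < 3L * L) stop("run_length must cover several buffer lengths")
  med <- dist_median(dist)
  seeds <- rep_seeds(seed, n_reps)
  errors <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seeds[r])
    x <- dist_sample(dist, run_length)
    trace <- stream_estimate(x, L = L, backend = backend)
    errors[r] <- trace[run_length] - med
  }
  structure(list(errors = errors, std = sd(errors),
                 histogram = hist(errors, breaks = "FD", plot = FALSE),
                 estimator = estimator_tag(backend, L),
                 dist = dist, run_length = run_length, n_reps = n_reps),
            class = "error_distribution")
}

#' @export
print.error_distribution <- function(x, ...) {
  cat("<error_distribution>", x$estimator, "on", dist_label(x$dist),
      "\n  reps =", x$n_reps, " run_length =", x$run_length,
      " std =", format(x$std), "\n")
  invisible(x)
}

#' Steady-state dispersion of an estimator on i.i.d. input
#'
#' Operationalises "steady state" by discarding the first `discard_mult * L`
#' estimates of each run and pooling the remaining estimates (up to
#' `run_mult * L`) across repetitions; the returned value is the standard
#' deviation of that pool around its mean.  This is the quantity behind the
#' equal-variance pairings (e.g. NM-63 against CMM-511) and the same-length
#' variance-ratio comparisons.
#'
#' @param dist a [dist_spec].
#' @param L odd buffer length.
#' @param backend `"nm"` or `"cmm"`.
#' @param n_reps independent repetitions.
#' @param run_mult,discard_mult run length and discarded warm-in, in buffer
#'   lengths (`discard_mult < run_mult`).
#' @param seed master seed.
#' @return the pooled standard deviation (signal units), with the pooled
#'   sample count as attribute `n_pooled`.
#' @examples
#' steady_state_std(dist_normal(0, 1), L = 63, backend = "nm",
#'                  n_reps = 20, seed = 1)
#' @export
steady_state_std <- function(dist, L, backend = c("nm", "cmm"),
                             n_reps = 200L, run_mult = 20L,
                             discard_mult = 10L, seed = 1L) {
  stopifnot(inherits(dist, "dist_spec"), n_reps >= 2,
            discard_mult >= 1, run_mult > discard_mult)
  backend <- match.arg(backend)
  L <- check_buffer_length(L)
  seeds <- rep_seeds(seed, n_reps)
  keep <- (discard_mult * L + 1L):(run_mult * L)
  pool <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seeds[r])
    x <- dist_sample(dist, run_mult * L)
    pool[[r]] <- as.numeric(stream_estimate(x, L = L, backend = backend)[keep])
  }
  pool <- unlist(pool)
  structure(sd(pool), n_pooled = length(pool))
}

#' Buffer density dynamics of the NM estimator
#'
#' Streams i.i.d. draws through the NM estimator and snapshots the full
#' buffer contents at chosen times after the buffer first fills, averaging
#' normalised histograms over repetitions.  This exposes the concentration
#' mechanism: the initially distribution-shaped buffer contracts around the
#' true median as extremes are discarded.
#'
#' @param dist a [dist_spec].
#' @param L odd buffer length (1023 for the full-scale characterisation).
#' @param time_points increasing sample counts measured from the moment the
#'   buffer is full (0 = just filled).
#' @param n_reps repetitions to average over.
#' @param n_bins histogram bins spanning the pooled snapshot range.
#' @param seed master seed.
#' @return list of class `density_matrix`: `time_points`, `bin_edges`
#'   (length `n_bins + 1`), `density` (matrix, one row per time point, rows
#'   summing to 1), `iqr` (mean inter-quartile width of the buffer contents
#'   at each time point) and `median_of_dist`.
#' @examples
#' d <- buffer_density(dist_normal(0, 1), L = 63,
#'                     time_points = c(0, 630, 3150), n_reps = 20, seed = 1)
#' d$iqr  # shrinks with time
#' @export
buffer_density <- function(dist, L = 1023L, time_points = c(0L, 10L, 50L) * L,
                           n_reps = 200L, n_bins = 61L, seed = 1L) {
  stopifnot(inherits(dist, "dist_spec"), n_reps >= 1,
            !is.unsorted(time_points, strictly = TRUE), all(time_points >= 0))
  L <- check_buffer_length(L)
  tp <- as.integer(time_points)
  n_t <- length(tp)
  run_length <- L + max(tp)
  seeds <- rep_seeds(seed, n_reps)
  snaps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seeds[r])
    x <- dist_sample(dist, run_length)
    est <- stream_estimate(x, L = L, backend = "nm", snapshot_at = L + tp)
    snaps[[r]] <- attr(est, "snapshots")       # L x n_t matrix
  }
  rng <- range(vapply(snaps, range, numeric(2)))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  dens <- matrix(0, nrow = n_t, ncol = n_bins)
  iqr <- numeric(n_t)
  for (j in seq_len(n_t)) {
    counts <- rep(0, n_bins)
    width <- 0
    for (r in seq_len(n_reps)) {
      b <- snaps[[r]][, j]
      counts <- counts + tabulate(findInterval(b, edges,
                                               rightmost.closed = TRUE),
                                  nbins = n_bins)
      q <- stats::quantile(b, c(0.25, 0.75), names = FALSE)
      width <- width + (q[2] - q[1])
    }
    dens[j, ] <- counts / sum(counts)
    iqr[j] <- width / n_reps
  }
  structure(list(time_points = tp, bin_edges = edges, density = dens,
                 iqr = iqr, median_of_dist = dist_median(dist),
                 estimator = estimator_tag("nm", L), dist = dist,
                 n_reps = n_reps),
            class = "density_matrix")
}

#' @export
print.density_matrix <- function(x, ...) {
  cat("<density_matrix>", x$estimator, "on", dist_label(x$dist), "\n")
  for (j in seq_along(x$time_points))
    cat(sprintf("  t = %6d : IQR of buffer contents = %.4f\n",
                x$time_points[j], x$iqr[j]))
  invisible(x)
}

# Mann-Whitney AUC: probability that a post-change estimate exceeds a
# pre-change one (ties count half)
mann_whitney_auc <- function(pre, post) {
  r <- rank(c(pre, post))
  n1 <- length(pre); n2 <- length(post)
  (sum(r[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2) / (n1 * n2)
}

#' ROC discrimination of small median changes
#'
#' For each relative median change `delta`, independent repetitions draw a
#' pre-change segment from `N(mu0, sd)` and a post-change segment from
#' `N(mu0 * (1 + delta), sd)`.  The estimator output at the end of each
#' segment forms the pre- and post-change estimate distributions; sweeping a
#' decision threshold over estimate values gives the ROC curve (TPR =
#' fraction of post-change estimates above the threshold, FPR = same for
#' pre-change) and the area under it (computed by the equivalent
#' Mann-Whitney rank statistic).
#'
#' @param delta_fracs relative median changes (e.g. `0.03` for 3%).
#' @param configs list of estimator configurations, each a list with
#'   `backend` and `L`.
#' @param n_reps repetitions per segment and delta.
#' @param mu0 pre-change median.
#' @param cv coefficient of variation of the signal (`sd = cv * mu0`).
#' @param pre_length,post_length segment lengths in samples, as multiples of
#'   `L` (pre must reach steady state; post must leave room to settle).
#' @param seed master seed.
#' @return list of class `roc_result`: `auc` — a data.frame with columns
#'   `delta`, `backend`, `L`, `estimator`, `auc` — and `curves`, a list (one
#'   entry per `auc` row) of data.frames with `threshold`, `fpr`, `tpr`.
#' @examples
#' r <- roc_small_change(c(0, 0.03), n_reps = 60, seed = 1)
#' r$auc
#' @export
roc_small_change <- function(delta_fracs,
                             configs = list(list(backend = "nm", L = 63),
                                            list(backend = "cmm", L = 63)),
                             n_reps = 400L, mu0 = 1, cv = 0.25,
                             pre_length = 50L, post_length = 30L,
                             seed = 1L) {
  stopifnot(all(delta_fracs >= 0), n_reps >= 10, mu0 > 0, cv > 0)
  rows <- list(); curves <- list(); k <- 0L
  for (cfg in configs) {
    L <- check_buffer_length(cfg$L)
    n_pre <- pre_length * L
    n_post <- post_length * L
    for (delta in delta_fracs) {
      seeds <- rep_seeds(seed, n_reps)   # same streams for every estimator
      pre <- numeric(n_reps); post <- numeric(n_reps)
      for (r in seq_len(n_reps)) {
        set.seed(seeds[r])
        x <- c(rnorm(n_pre, mu0, cv * mu0),
               rnorm(n_post, mu0 * (1 + delta), cv * mu0))
        trace <- stream_estimate(x, L = L, backend = cfg$backend)
        pre[r] <- trace[n_pre]
        post[r] <- trace[n_pre + n_post]
      }
      th <- sort(unique(c(pre, post, Inf)))
      curve <- data.frame(
        threshold = th,
        fpr = vapply(th, function(t) mean(pre >= t), numeric(1)),
        tpr = vapply(th, function(t) mean(post >= t), numeric(1)))
      k <- k + 1L
      rows[[k]] <- data.frame(delta = delta, backend = cfg$backend, L = L,
                              estimator = estimator_tag(cfg$backend, L),
                              auc = mann_whitney_auc(pre, post))
      curves[[k]] <- curve
    }
  }
  structure(list(auc = do.call(rbind, rows), curves = curves,
                 mu0 = mu0, cv = cv, n_reps = n_reps),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> reps =", x$n_reps, " mu0 =", x$mu0, " cv =", x$cv, "\n")
  print(x$auc, row.names = FALSE)
  invisible(x)
}

#' Outlier robustness: steady-state variance on a contaminated stream
#'
#' Streams an i.i.d. Gaussian mixture with an outlier component through NM
#' and CMM estimators of the same buffer length and compares their
#' steady-state variances: per repetition the first `discard_mult * L`
#' estimates are discarded and the rest pooled across repetitions, as in
#' [steady_state_std()].  Both estimators see the same streams.
#'
#' @param primary,outlier,outlier_prob mixture as in [gen_outlier_mixture()].
#' @param L odd buffer length (both estimators).
#' @param n_reps repetitions.
#' @param run_mult,discard_mult run length and discarded warm-in, in buffer
#'   lengths.
#' @param seed master seed.
#' @return list of class `outlier_robustness`: `var_nm`, `var_cmm`,
#'   `variance_ratio` (`var_cmm / var_nm`) and `true_median` (of the
#'   mixture).
#' @export
outlier_robustness <- function(primary = dist_normal(0, 1),
                               outlier = dist_normal(0, 10),
                               outlier_prob = 0.05, L = 63,
                               n_reps = 300L, run_mult = 20L,
                               discard_mult = 10L, seed = 1L) {
  L <- check_buffer_length(L)
  stopifnot(discard_mult >= 1, run_mult > discard_mult)
  seeds <- rep_seeds(seed, n_reps)
  keep <- (discard_mult * L + 1L):(run_mult * L)
  nm_pool <- vector("list", n_reps); cmm_pool <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    x <- gen_outlier_mixture(run_mult * L, primary, outlier, outlier_prob,
                             seed = seeds[r])
    nm_pool[[r]] <- as.numeric(stream_estimate(x, L, backend = "nm")[keep])
    cmm_pool[[r]] <- as.numeric(stream_estimate(x, L, backend = "cmm")[keep])
  }
  v_nm <- var(unlist(nm_pool)); v_cmm <- var(unlist(cmm_pool))
  spec <- if (outlier_prob > 0)
    dist_mixture(list(primary, outlier), c(1 - outlier_prob, outlier_prob))
  else primary
  structure(list(var_nm = v_nm, var_cmm = v_cmm,
                 variance_ratio = v_cmm / v_nm,
                 true_median = dist_median(spec),
                 L = L, n_reps = n_reps, run_mult = run_mult,
                 discard_mult = discard_mult),
            class = "outlier_robustness")
}

#' @export
print.outlier_robustness <- function(x, ...) {
  cat("<outlier_robustness> L =", x$L, " reps =", x$n_reps,
      "\n  var(CMM) =", format(x$var_cmm), " var(NM) =", format(x$var_nm),
      " ratio =", format(x$variance_ratio), "\n")
  invisible(x)
}

#' Settling time versus step amplitude on folded-normal input
#'
#' Generates step changes in the median of a folded-normal stream (the
#' distribution of `|x|` for Gaussian `x`, i.e. the shape seen by the noise
#' estimator) from a common pre-step median to each requested post-step
#' median, and reports mean and standard deviation of the settling time per
#' estimator configuration.
#'
#' @param medians_after post-step medians; the defaults are the
#'   characterisation levels 1.21 through 20.50 starting from 0.67.
#' @param median_before pre-step median.
#' @param configs list of estimator configurations (`backend`, `L`).
#' @param n_reps repetitions per amplitude and configuration.
#' @param pre_mult,post_mult segment lengths in buffer lengths.
#' @param seed master seed.
#' @return data.frame with columns `median_after`, `backend`, `L`,
#'   `estimator`, `mean_settling`, `sd_settling`, `n_not_settled`.
#' @export
settling_vs_amplitude <- function(medians_after = c(1.21, 1.81, 3.01, 4.82,
                                                    7.84, 12.66, 20.50),
                                  median_before = qnorm(0.75),
                                  configs = list(list(backend = "nm", L = 63),
                                                 list(backend = "cmm", L = 511)),
                                  n_reps = 200L, pre_mult = 10L,
                                  post_mult = 20L, seed = 1L) {
  stopifnot(all(medians_after > 0), median_before > 0)
  sigma_of <- function(med) med / qnorm(0.75)
  rows <- list(); k <- 0L
  for (cfg in configs) {
    L <- check_buffer_length(cfg$L)
    for (ma in medians_after) {
      sp <- step_spec(dist_folded_normal(sigma_of(median_before)),
                      dist_folded_normal(sigma_of(ma)),
                      n_before = pre_mult * L, n_after = post_mult * L)
      res <- run_step_experiment(sp, L = L, backend = cfg$backend,
                                 n_reps = n_reps, seed = seed)
      sm <- attr(res, "summary")
      k <- k + 1L
      rows[[k]] <- data.frame(median_after = ma, backend = cfg$backend,
                              L = L, estimator = estimator_tag(cfg$backend, L),
                              mean_settling = sm$mean_settling,
                              sd_settling = sm$sd_settling,
                              n_not_settled = sm$n_not_settled)
    }
  }
  do.call(rbind, rows)
}
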