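# Synthetic inputs with ground truth: distribution specs (normal, beta,
# folded normal, Gaussian mixture), step-change streams, spike-embedded noise,
# and outlier mixtures.  Everything is driven by an explicit seed.

#' Distribution specifications with exact quantile ground truth
#'
#' Small spec objects naming a sampling distribution together with its exact
#' median (from the quantile function), used by the generators and the
#' experiment drivers as ground truth.
#'
#' * `dist_normal(mean, sd)` — Gaussian.
#' * `dist_beta(shape1, shape2)` — Beta on (0, 1).
#' * `dist_folded_normal(sigma)` — `|X|` for `X ~ N(0, sigma^2)`; its median
#'   is `sigma * qnorm(0.75)` (0.6745 for `sigma = 1`), distinct from its mean
#'   `sigma * sqrt(2 / pi)` (0.7979).
#' * `dist_mixture(components, weights)` — finite mixture of the above; its
#'   median is found by root-solving the mixture CDF.
#'
#' @param mean,sd,shape1,shape2,sigma distribution parameters.
#' @param components list of distribution specs; `weights` positive weights
#'   summing to 1.
#' @param weights mixture weights.
#' @return an object of class `dist_spec`.
#' @examples
#' dist_median(dist_beta(1.5, 4))       # 0.2439
#' dist_median(dist_folded_normal(1))   # 0.6745
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
dist_normal <- function(mean = 0, sd = 1) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0)
  structure(list(family = "normal", mean = mean, sd = sd), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_beta <- function(shape1, shape2) {
  stopifnot(is.finite(shape1), is.finite(shape2), shape1 > 0, shape2 > 0)
  structure(list(family = "beta", shape1 = shape1, shape2 = shape2),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_folded_normal <- function(sigma = 1) {
  stopifnot(is.finite(sigma), sigma > 0)
  structure(list(family = "folded_normal", sigma = sigma), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_mixture <- function(components, weights) {
  stopifnot(is.list(components), length(components) == length(weights),
            all(vapply(components, inherits, logical(1), "dist_spec")),
            all(weights > 0))
  weights <- weights / sum(weights)
  structure(list(family = "mixture", components = components,
                 weights = weights), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec>", dist_label(x), " median =", format(dist_median(x)), "\n")
  invisible(x)
}

dist_label <- function(spec) {
  switch(spec$family,
    normal = sprintf("normal(%g, %g)", spec$mean, spec$sd),
    beta = sprintf("beta(%g, %g)", spec$shape1, spec$shape2),
    folded_normal = sprintf("folded_normal(%g)", spec$sigma),
    mixture = paste0("mixture[",
                     paste(vapply(spec$components, dist_label, character(1)),
                           collapse = ", "), "]"))
}

#' Sample, CDF and median of a distribution spec
#'
#' `dist_sample()` draws `n` i.i.d. values from the session RNG (seed it with
#' `set.seed()` for reproducibility).  `dist_cdf()` evaluates the CDF.
#' `dist_median()` returns the exact median: the closed-form quantile for the
#' basic families, a bracketed root of `CDF(x) = 1/2` for mixtures.
#'
#' @param spec a [dist_spec] object.
#' @param n number of draws.
#' @param q quantile points.
#' @param labels for mixtures, also return the component index of each draw
#'   (as attribute `component`), for diagnostics.
#' @return numeric vector (`dist_sample`, `dist_cdf`) or scalar
#'   (`dist_median`).
#' @export
dist_sample <- function(spec, n, labels = FALSE) {
  stopifnot(inherits(spec, "dist_spec"), n >= 0)
  switch(spec$family,
    normal = rnorm(n, spec$mean, spec$sd),
    beta = rbeta(n, spec$shape1, spec$shape2),
    folded_normal = abs(rnorm(n, 0, spec$sigma)),
    mixture = {
      k <- sample.int(length(spec$weights), n, replace = TRUE,
                      prob = spec$weights)
      out <- numeric(n)
      for (j in seq_along(spec$components)) {
        idx <- which(k == j)
        if (length(idx))
          out[idx] <- dist_sample(spec$components[[j]], length(idx))
      }
      if (labels) attr(out, "component") <- k
      out
    })
}

#' @rdname dist_sample
#' @export
dist_cdf <- function(spec, q) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    normal = pnorm(q, spec$mean, spec$sd),
    beta = pbeta(q, spec$shape1, spec$shape2),
    folded_normal = ifelse(q < 0, 0, 2 * pnorm(q / spec$sigma) - 1),
    mixture = {
      acc <- 0
      for (j in seq_along(spec$components))
        acc <- acc + spec$weights[j] * dist_cdf(spec$components[[j]], q)
      acc
    })
}

#' @rdname dist_sample
#' @export
dist_median <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    normal = spec$mean,
    beta = qbeta(0.5, spec$shape1, spec$shape2),
    folded_normal = spec$sigma * qnorm(0.75),
    mixture = {
      lo <- -1; hi <- 1
      while (dist_cdf(spec, lo) > 0.5) lo <- lo * 2
      while (dist_cdf(spec, hi) < 0.5) hi <- hi * 2
      uniroot(function(x) dist_cdf(spec, x) - 0.5, c(lo, hi),
              tol = 1e-10)$root
    })
}

# ---------------------------------------------------------------------------
# Step-change streams
# ---------------------------------------------------------------------------

#' Specify a distribution step change
#'
#' A stream that draws `n_before` samples from one distribution and then
#' switches to another for `n_after` samples — the stimulus used throughout
#' the settling-time and error-distribution experiments (e.g. `N(8, 2)` to
#' `N(10, 2)`).
#'
#' @param dist_before,dist_after [dist_spec] objects.
#' @param n_before,n_after positive sample counts.
#' @param seed integer seed making the stream reproducible.
#' @return an object of class `step_spec`.
#' @export
step_spec <- function(dist_before, dist_after, n_before, n_after, seed = 1L) {
  stopifnot(inherits(dist_before, "dist_spec"),
            inherits(dist_after, "dist_spec"),
            n_before > 0, n_after > 0)
  structure(list(dist_before = dist_before, dist_after = dist_after,
                 n_before = as.integer(n_before),
                 n_after = as.integer(n_after), seed = as.integer(seed)),
            class = "step_spec")
}

#' Generate a step-change stream with ground truth
#'
#' @param spec a [step_spec()].
#' @return list with `samples` (length `n_before + n_after`), `step_index`
#'   (1-based index of the first post-change sample),
#'   `true_median_before` and `true_median_after` (from the quantile
#'   functions).
#' @examples
#' s <- gen_step_stream(step_spec(dist_normal(8, 2), dist_normal(10, 2),
#'                                500, 500, seed = 42))
#' c(s$true_median_before, s$true_median_after)  # 8 10
#' @export
gen_step_stream <- function(spec) {
  stopifnot(inherits(spec, "step_spec"))
  set.seed(spec$seed)
  samples <- c(dist_sample(spec$dist_before, spec$n_before),
               dist_sample(spec$dist_after, spec$n_after))
  list(samples = samples,
       step_index = spec$n_before + 1L,
       true_median_before = dist_median(spec$dist_before),
       true_median_after = dist_median(spec$dist_after))
}

# ---------------------------------------------------------------------------
# Spike-embedded noise
# ---------------------------------------------------------------------------

#' Biphasic spike template
#'
#' Default extracellular-like action-potential shape: a sharp negative lobe
#' followed by a slower positive rebound, `width` samples long (default 36,
#' i.e. 1.2 ms at a nominal 30 kHz).  Normalised so the most extreme sample is
#' -1; scaling by `snr * noise_sigma` then plants a spike whose peak voltage
#' is `snr` noise standard deviations.
#'
#' @param width template length in samples.
#' @return numeric vector of length `width` with minimum exactly -1.
#' @export
biphasic_template <- function(width = 36L) {
  stopifnot(width >= 8)
  t <- seq_len(width) - 1
  w <- -exp(-((t - width * 0.28) / (width * 0.10))^2) +
    0.45 * exp(-((t - width * 0.62) / (width * 0.18))^2)
  w / abs(min(w))
}

#' Specify a spike-embedded noise signal
#'
#' Gaussian background noise `N(0, noise_sigma^2)` with spike templates
#' planted at random positions.  The SNR convention is the one used for
#' extracellular recordings: peak spike voltage divided by the noise standard
#' deviation, so each planted template is scaled to peak amplitude
#' `snr * noise_sigma` (negative-going for the default template).
#'
#' @param n_samples total length.
#' @param noise_sigma noise standard deviation (signal units).
#' @param snr positive peak-to-sigma ratio.
#' @param spike_rate expected spikes per 1000 samples.
#' @param template waveform shape (minimum -1); see [biphasic_template()].
#' @param seed integer seed.
#' @return an object of class `spike_train_spec`.
#' @export
spike_train_spec <- function(n_samples, noise_sigma = 1, snr = 8,
                             spike_rate = 2, template = biphasic_template(),
                             seed = 1L) {
  stopifnot(n_samples > 0, noise_sigma > 0, spike_rate >= 0,
            length(template) >= 2, min(template) < 0)
  if (!is.numeric(snr) || snr <= 0) stop("snr must be a positive number")
  structure(list(n_samples = as.integer(n_samples),
                 noise_sigma = noise_sigma, snr = snr,
                 spike_rate = spike_rate, template = template,
                 seed = as.integer(seed)),
            class = "spike_train_spec")
}

#' Generate a spike-embedded noise signal with ground truth
#'
#' @param spec a [spike_train_spec()].
#' @return list with `samples` and `events`, a data.frame with one row per
#'   planted spike: `index` (sample of the template's extreme, 1-based),
#'   `onset` (first template sample) and `amplitude` (peak, signal units).
#'   Planted spikes are separated by at least the template width.
#' @examples
#' sig <- gen_spiky_signal(spike_train_spec(20000, snr = 8, seed = 7))
#' nrow(sig$events)  # about 40 planted spikes
#' @export
gen_spiky_signal <- function(spec) {
  stopifnot(inherits(spec, "spike_train_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  w <- length(spec$template)
  samples <- rnorm(n, 0, spec$noise_sigma)
  n_spikes <- round(spec$spike_rate * n / 1000)
  onsets <- integer(0)
  if (n_spikes > 0) {
    # distribute the free slack uniformly between spikes so every gap is at
    # least the template width (exact placement, no rejection)
    lo <- w + 1L
    hi <- n - 2L * w
    slack <- (hi - lo) - n_spikes * w
    if (hi <= lo || slack < 0)
      stop("signal too short for ", n_spikes,
           " spikes with the required spacing; reduce spike_rate or the ",
           "template width")
    u <- sort(runif(n_spikes, 0, slack))
    onsets <- lo + as.integer(floor(u)) + (seq_len(n_spikes) - 1L) * w
  }
  amp <- spec$snr * spec$noise_sigma
  peak_off <- which.min(spec$template) - 1L
  for (o in onsets)
    samples[o:(o + w - 1L)] <- samples[o:(o + w - 1L)] + amp * spec$template
  events <- data.frame(index = onsets + peak_off, onset = onsets,
                       amplitude = rep(-amp, length(onsets)))
  list(samples = samples, events = events)
}

# ---------------------------------------------------------------------------
# Outlier mixtures
# ---------------------------------------------------------------------------

#' Generate an i.i.d. Gaussian mixture with an outlier component
#'
#' Draws from `(1 - p) * primary + p * outlier`, the stimulus for the
#' outlier-robustness comparison.  Component labels are kept for diagnostics.
#' Defaults: primary `N(0, 1)`, outliers `N(0, 10)`, `p = 0.05`.
#'
#' @param n number of samples.
#' @param primary,outlier [dist_spec] objects (typically [dist_normal()]).
#' @param outlier_prob outlier probability, `0 <= p < 0.5`.
#' @param seed integer seed.
#' @return numeric vector of samples with attributes `component` (1 =
#'   primary, 2 = outlier) and `spec` (the [dist_mixture()] actually sampled).
#' @export
gen_outlier_mixture <- function(n, primary = dist_normal(0, 1),
                                outlier = dist_normal(0, 10),
                                outlier_prob = 0.05, seed = 1L) {
  if (!is.numeric(outlier_prob) || outlier_prob < 0 || outlier_prob >= 0.5)
    stop("outlier_prob must satisfy 0 <= p < 0.5")
  set.seed(seed)
  if (outlier_prob == 0) {
    out <- dist_sample(primary, n)
    attr(out, "component") <- rep(1L, n)
    attr(out, "spec") <- primary
    return(out)
  }
  spec <- dist_mixture(list(primary, outlier),
                       c(1 - outlier_prob, outlier_prob))
  out <- dist_sample(spec, n, labels = TRUE)
  attr(out, "spec") <- spec
  out
}
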