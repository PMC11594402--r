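# Noise-sigma estimation from the median of the rectified signal and
# threshold-crossing spike detection.

# median{|x|} -> sigma conversion for Gaussian noise: the median of the
# half-normal distribution is sigma * qnorm(0.75) = 0.674490 * sigma.
HALF_NORMAL_MEDIAN <- qnorm(0.75)

#' Noise standard deviation from the median of the rectified signal
#'
#' For Gaussian background noise `x ~ N(0, sigma^2)` the rectified signal
#' `y = |x|` is half-normal with median `sigma * 0.675` (the constant is
#' `sqrt(2) * erfinv(1/2) = qnorm(0.75) = 0.674490`).  Inverting this gives a
#' robust sigma estimate that ignores sparse large excursions such as spikes:
#' `sigma = median(|x|) / 0.675`.
#'
#' @param med_abs median of the rectified signal (non-negative).
#' @return the implied noise standard deviation, `med_abs / 0.674490`.
#' @examples
#' sigma_from_median(0.6745)  # 1.0
#' @export
sigma_from_median <- function(med_abs) {
  if (any(!is.finite(med_abs)) || any(med_abs < 0))
    stop("med_abs must be non-negative and finite")
  med_abs / HALF_NORMAL_MEDIAN
}

#' Threshold-detection configuration
#'
#' @param K threshold in units of the estimated noise sigma (default 4, the
#'   usual setting for extracellular spike detection).
#' @param L odd buffer length of the streaming median estimator (default 63).
#' @param polarity which excursions count: `"negative"` (extracellular
#'   spikes are negative-going; threshold applied to `-x`), `"positive"`, or
#'   `"absolute"`.
#' @param refractory minimum number of samples between successive events
#'   (default 30, about 1 ms at 30 kHz).
#' @param backend streaming median backend, `"nm"` or `"cmm"`.
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(K = 4, L = 63, polarity = c("negative", "positive",
                                                         "absolute"),
                             refractory = 30L, backend = c("nm", "cmm")) {
  polarity <- match.arg(polarity)
  backend <- match.arg(backend)
  if (!is.numeric(K) || K <= 0) stop("K must be positive")
  if (refractory < 0) stop("refractory must be non-negative")
  structure(list(K = K, L = check_buffer_length(L), polarity = polarity,
                 refractory = as.integer(refractory), backend = backend),
            class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config> K =", x$K, " L =", x$L, " backend =", x$backend,
      " polarity =", x$polarity, " refractory =", x$refractory, "\n")
  invisible(x)
}

#' Streaming detection threshold
#'
#' Runs the configured streaming median over the *rectified* signal `|x|` and
#' converts each median estimate to a noise sigma via [sigma_from_median()];
#' element `k` is `K * sigma_hat_k`, the detection threshold in force after
#' consuming sample `k` (warm-up estimates included).  The threshold is
#' always returned as a non-negative magnitude; [detect_crossings()] applies
#' it on the side selected by the polarity.
#'
#' @param signal numeric signal.
#' @param cfg a [threshold_config()].
#' @return numeric vector of thresholds, same length as `signal`.
#' @examples
#' set.seed(1)
#' th <- streaming_threshold(rnorm(5000), threshold_config(K = 4, L = 63))
#' mean(th[1000:5000])  # close to 4
#' @export
streaming_threshold <- function(signal, cfg = threshold_config()) {
  stopifnot(inherits(cfg, "threshold_config"))
  med <- stream_estimate(abs(signal), L = cfg$L, backend = cfg$backend)
  cfg$K * sigma_from_median(as.numeric(med))
}

#' Detect threshold crossings
#'
#' An event opens when the polarity-transformed signal (`-x`, `x`, or `|x|`)
#' first exceeds the running threshold; the event is localised at the most
#' extreme sample before the signal re-crosses below the threshold, and its
#' `threshold` column records the threshold in force at the opening sample.
#' After an accepted event, further events are suppressed until `refractory`
#' samples have elapsed.
#'
#' @param signal numeric signal.
#' @param thresholds per-sample threshold magnitudes, same length as `signal`
#'   (e.g. from [streaming_threshold()]), or a single constant.
#' @param polarity `"negative"`, `"positive"` or `"absolute"`.
#' @param refractory minimum sample gap between events.
#' @return data.frame of class `spike_events` with columns `index` (1-based
#'   sample of the peak), `peak` (raw signal value there) and `threshold`.
#' @examples
#' detect_crossings(c(0, 0, -5, 0, 0), 4, polarity = "negative")
#' @export
detect_crossings <- function(signal, thresholds,
                             polarity = c("negative", "positive", "absolute"),
                             refractory = 0L) {
  polarity <- match.arg(polarity)
  if (length(thresholds) == 1L) thresholds <- rep(thresholds, length(signal))
  if (length(thresholds) != length(signal))
    stop("signal and thresholds must have the same length")
  if (refractory < 0) stop("refractory must be non-negative")
  y <- switch(polarity, negative = -signal, positive = signal,
              absolute = abs(signal))
  over <- y > thresholds
  idx <- integer(0); peak <- numeric(0); thr <- numeric(0)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  last_event <- -Inf
  for (j in which(r$values)) {
    s <- starts[j]; e <- ends[j]
    if (s - last_event <= refractory) next
    p <- s + which.max(y[s:e]) - 1L
    idx <- c(idx, p)
    peak <- c(peak, signal[p])
    thr <- c(thr, thresholds[s])
    last_event <- p
  }
  structure(data.frame(index = idx, peak = peak, threshold = thr),
            class = c("spike_events", "data.frame"))
}

#' One-call spike detection
#'
#' Convenience wrapper: compute the streaming threshold with
#' [streaming_threshold()] and extract events with [detect_crossings()].
#'
#' @inheritParams streaming_threshold
#' @return a `spike_events` data.frame (see [detect_crossings()]), with the
#'   per-sample thresholds attached as attribute `thresholds`.
#' @export
detect_spikes <- function(signal, cfg = threshold_config()) {
  th <- streaming_threshold(signal, cfg)
  ev <- detect_crossings(signal, th, polarity = cfg$polarity,
                         refractory = cfg$refractory)
  attr(ev, "thresholds") <- th
  ev
}
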