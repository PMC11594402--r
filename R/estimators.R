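# Streaming median estimators: the memory-less sorted-buffer estimator (NM),
# the classical moving median (CMM), a brute-force sliding-median oracle, the
# truth-table model of the hardware cell array, and the quartile cascade.

check_buffer_length <- function(L) {
  if (length(L) != 1L || !is.numeric(L) || is.na(L) || L < 3 || L %% 2 == 0)
    stop("buffer length L must be an odd integer >= 3, got ", deparse(L))
  as.integer(L)
}

check_sample <- function(x) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop("samples must be finite numbers; got ", deparse(x))
  as.numeric(x)
}

#' Create a memory-less streaming median (NM) state
#'
#' The NM estimator keeps an always-sorted buffer of fixed odd length
#' `L = 2m + 1`.  Its estimate is the central element.  Each incoming sample is
#' inserted at its sorted position; the sample dropped to keep the length
#' fixed is the *maximum* when the new sample falls below the centre and the
#' *minimum* when it falls above, so the buffer progressively concentrates
#' around the median.  When the new sample equals the central value it is
#' placed at the centre and a single alternating tie bit `S` decides which
#' extreme is dropped (an optional random mode draws the side instead).
#'
#' `nm_init()` builds a state from exactly `L` initial samples (the buffer is
#' their sorted order).  With fewer than `L` samples, or via `nm_new()`, a
#' warm-up state is returned: the partial buffer is kept sorted and the
#' estimate is its middle element (lower middle while the count is even).
#'
#' @param samples numeric vector of initial samples (finite).
#' @param L odd buffer length `>= 3`; defaults to `length(samples)`.
#' @param tie `"alternate"` for the deterministic alternating tie bit,
#'   `"random"` to draw the dropped side from the session RNG.
#' @return an object of class `nm_state` with fields `values` (sorted buffer),
#'   `L`, `tie_toggle` (0 = drop the last element at the next tie), `n_seen`,
#'   `estimate`, and `dropped` (the sample discarded by the last update).
#' @examples
#' s <- nm_init(c(3, 1, 2))
#' nm_estimate(s)        # 2
#' s <- nm_update(s, 0)  # 0 inserted at the front, 3 dropped
#' nm_estimate(s)        # 1
#' @seealso [nm_update()], [stream_estimate()]
#' @export
nm_init <- function(samples, L = length(samples), tie = c("alternate", "random")) {
  tie <- match.arg(tie)
  L <- check_buffer_length(L)
  samples <- vapply(samples, check_sample, numeric(1))
  if (length(samples) > L)
    stop("more initial samples (", length(samples), ") than buffer positions (", L, ")")
  v <- sort(samples)
  st <- structure(list(values = v, L = L, tie_toggle = 0L,
                       n_seen = length(v), tie = tie,
                       estimate = partial_middle(v), dropped = NA_real_),
                  class = "nm_state")
  st
}

#' @rdname nm_init
#' @export
nm_new <- function(L, tie = c("alternate", "random")) {
  nm_init(numeric(0), L = L, tie = match.arg(tie))
}

# middle of a sorted partial buffer; lower middle on even counts
partial_middle <- function(v) {
  k <- length(v)
  if (k == 0L) return(NA_real_)
  if (k %% 2 == 1L) v[(k + 1L) %/% 2L] else v[k %/% 2L]
}

#' Consume one sample with the NM estimator
#'
#' Applies the insertion and drop rules to a single sample and returns the
#' updated state.  During warm-up (fewer than `L` samples seen) the sample is
#' merged into the sorted partial buffer and nothing is dropped.
#'
#' @param state an `nm_state`.
#' @param x a finite numeric sample.  Non-finite values are rejected: the
#'   sorted-buffer invariant needs a total order.
#' @return the updated `nm_state`; the new estimate is `nm_estimate(state)`
#'   and the discarded sample is in `state$dropped`.
#' @export
nm_update <- function(state, x) {
  stopifnot(inherits(state, "nm_state"))
  x <- check_sample(x)
  v <- state$values
  L <- state$L
  if (length(v) < L) {                      # warm-up: grow the sorted buffer
    pos <- findInterval(x, v)
    v <- append(v, x, after = pos)
    state$values <- v
    state$n_seen <- state$n_seen + 1L
    state$estimate <- partial_middle(v)
    state$dropped <- NA_real_
    return(state)
  }
  m1 <- (L + 1L) %/% 2L                     # 1-based central position
  M <- v[m1]
  if (x < M) {
    dropped <- v[L]
    v <- v[-L]
    v <- append(v, x, after = findInterval(x, v))
  } else if (x > M) {
    dropped <- v[1L]
    v <- v[-1L]
    v <- append(v, x, after = findInterval(x, v))
  } else {
    drop_first <- if (state$tie == "random") runif(1) < 0.5 else state$tie_toggle == 1L
    if (state$tie == "alternate") state$tie_toggle <- 1L - state$tie_toggle
    if (drop_first) {
      dropped <- v[1L]
      v <- v[-1L]
    } else {
      dropped <- v[L]
      v <- v[-L]
    }
    v <- append(v, x, after = m1 - 1L)
  }
  state$values <- v
  state$n_seen <- state$n_seen + 1L
  state$estimate <- v[m1]
  state$dropped <- dropped
  state
}

#' @rdname nm_update
#' @export
nm_estimate <- function(state) state$estimate

#' @export
print.nm_state <- function(x, ...) {
  cat("<nm_state> L =", x$L, " samples seen =", x$n_seen,
      " estimate =", format(x$estimate), "\n")
  if (x$n_seen < x$L) cat("  (warm-up:", x$n_seen, "of", x$L, "positions filled)\n")
  invisible(x)
}

#' Classical moving median (CMM) state
#'
#' Keeps the last `L` samples in arrival order and reports the exact median of
#' the window.  Eviction is by age (the oldest sample leaves first), which is
#' the behaviour NM is compared against.  With fewer than `L` initial samples
#' the window grows until full; the reported median of a partial window is the
#' lower-middle order statistic, matching the NM warm-up convention.
#'
#' @inheritParams nm_init
#' @return an object of class `cmm_state` with fields `window` (arrival
#'   order), `L`, `n_seen`, `estimate`.
#' @seealso [cmm_update()], [sliding_median_oracle()]
#' @export
cmm_init <- function(samples, L = length(samples)) {
  L <- check_buffer_length(L)
  samples <- vapply(samples, check_sample, numeric(1))
  if (length(samples) > L)
    stop("more initial samples (", length(samples), ") than window positions (", L, ")")
  structure(list(window = samples, L = L, n_seen = length(samples),
                 estimate = partial_middle(sort(samples))),
            class = "cmm_state")
}

#' @rdname cmm_init
#' @export
cmm_new <- function(L) cmm_init(numeric(0), L = L)

#' Consume one sample with the classical moving median
#'
#' The oldest sample is evicted (once the window is full) and the new sample
#' appended; the estimate is the exact median of the current window.
#'
#' @param state a `cmm_state`.
#' @param x a finite numeric sample.
#' @return the updated `cmm_state`.
#' @export
cmm_update <- function(state, x) {
  stopifnot(inherits(state, "cmm_state"))
  x <- check_sample(x)
  w <- state$window
  if (length(w) >= state$L) w <- w[-1L]
  w <- c(w, x)
  state$window <- w
  state$n_seen <- state$n_seen + 1L
  state$estimate <- partial_middle(sort(w))
  state
}

#' @rdname cmm_update
#' @export
cmm_estimate <- function(state) state$estimate

#' @export
print.cmm_state <- function(x, ...) {
  cat("<cmm_state> L =", x$L, " samples seen =", x$n_seen,
      " estimate =", format(x$estimate), "\n")
  invisible(x)
}

#' Brute-force sliding-median oracle
#'
#' Reference implementation of the moving median: every trailing window of
#' length `L` is re-sorted from scratch.  Used as the independent check for
#' the incremental CMM implementation.
#'
#' @param signal numeric vector, `length(signal) >= L`.
#' @param L odd window length.
#' @return numeric vector of length `length(signal) - L + 1`; element `k` is
#'   the exact median of `signal[k:(k + L - 1)]`.
#' @examples
#' sliding_median_oracle(c(1, 9, 2, 8, 3), 3)  # 2 8 3
#' @export
sliding_median_oracle <- function(signal, L) {
  L <- check_buffer_length(L)
  n <- length(signal)
  if (n < L) stop("signal shorter than the window length")
  m1 <- (L + 1L) %/% 2L
  vapply(seq_len(n - L + 1L),
         function(k) sort(signal[k:(k + L - 1L)])[m1],
         numeric(1))
}

#' Stream a whole signal through an estimator
#'
#' Fast path for long signals: runs the compiled streaming loop and returns
#' the per-sample estimate trace, including the warm-up portion (middle of the
#' sorted partial buffer; lower middle on even counts).
#'
#' @param x numeric signal (finite values).
#' @param L odd buffer length.
#' @param backend `"nm"` (memory-less estimator) or `"cmm"` (moving median).
#' @param tie NM tie-bit mode, `"alternate"` (default) or `"random"` (draws
#'   from the session RNG, so it is governed by `set.seed()`).
#' @param snapshot_at optional increasing vector of 1-based sample counts
#'   (each `>= L`) at which the full NM buffer contents are recorded.
#' @param init optional sorted numeric vector of length `L` used as the
#'   starting buffer (NM only), e.g. to resume a stream.
#' @return numeric vector of estimates, one per sample.  For the NM backend
#'   the attributes `buffer` (final sorted buffer), `tie_toggle` and — when
#'   `snapshot_at` is given — `snapshots` (an `L` x `length(snapshot_at)`
#'   matrix, one column per snapshot) are attached.
#' @examples
#' set.seed(1)
#' x <- rnorm(2000)
#' est <- stream_estimate(x, L = 63, backend = "nm")
#' tail(est, 1)  # close to 0, the true median
#' @export
stream_estimate <- function(x, L, backend = c("nm", "cmm"),
                            tie = c("alternate", "random"),
                            snapshot_at = NULL, init = NULL) {
  backend <- match.arg(backend)
  tie <- match.arg(tie)
  L <- check_buffer_length(L)
  x <- as.numeric(x)
  if (backend == "cmm") {
    if (!is.null(snapshot_at) || !is.null(init))
      stop("snapshot_at/init are only supported by the nm backend")
    return(cmm_filter_cpp(x, L))
  }
  snap <- if (is.null(snapshot_at)) integer(0) else as.integer(snapshot_at)
  if (length(snap) && (is.unsorted(snap, strictly = TRUE) || any(snap < L)))
    stop("snapshot_at must be strictly increasing sample counts >= L")
  res <- nm_filter_cpp(x, L, random_tie = (tie == "random"),
                       snapshot_at = snap,
                       init = if (is.null(init)) NULL else as.numeric(init))
  est <- res$estimates
  attr(est, "buffer") <- res$buffer
  attr(est, "tie_toggle") <- res$tie_toggle
  if (length(snap)) attr(est, "snapshots") <- res$snapshots
  est
}

# ---------------------------------------------------------------------------
# Truth-table model of the hardware sorting cell array
# ---------------------------------------------------------------------------

#' Software model of the hardware sorting-cell array
#'
#' Models the register/comparator/multiplexer array of the hardware
#' realisation at truth-table level.  Each of the `L` cells holds a register
#' `R_i` and a comparator `C_i` which is 0 when `R_i <= X` and 1 when
#' `R_i > X`.  The central cell's full comparator exposes the mutually
#' exclusive signals `X < M`, `X = M`, `X > M`; on `X = M` the alternating bit
#' `S` selects whether the first (`S = 1`) or last (`S = 0`) register is
#' shifted out.  `hw_cell_step()` applies one clock step: every register takes
#' the value selected by its section's truth table (keep `R_i`, take `X`, take
#' `R_{i-1}`, or take `R_{i+1}`).  The result is the same buffer that
#' [nm_update()] produces for the same state, sample, and tie decision; the
#' two are verified against each other in lockstep.
#'
#' @param registers sorted numeric vector of odd length (the initial ordered
#'   buffer).
#' @param array an `hw_cell_array`.
#' @param x the new sample `X`.
#' @param S the tie bit in force for this step (0 or 1); only consulted when
#'   `X = M`.
#' @return `hw_init()` returns an `hw_cell_array`; `hw_cell_step()` the
#'   updated array; `hw_registers()` the register contents.
#' @examples
#' a <- hw_init(1:7)
#' a <- hw_cell_step(a, 2)
#' hw_registers(a)  # 1 2 2 3 4 5 6
#' @export
hw_init <- function(registers) {
  registers <- vapply(registers, check_sample, numeric(1))
  L <- check_buffer_length(length(registers))
  if (is.unsorted(registers)) stop("registers must be sorted non-decreasingly")
  structure(list(registers = registers, L = L), class = "hw_cell_array")
}

#' @rdname hw_init
#' @export
hw_cell_step <- function(array, x, S = 0L) {
  stopifnot(inherits(array, "hw_cell_array"))
  x <- check_sample(x)
  R <- array$registers
  L <- array$L
  cc <- (L + 1L) %/% 2L                 # central cell (1-based)
  M <- R[cc]
  Ci <- as.integer(R > x)               # C_i: R_i <= X -> 0; R_i > X -> 1
  new <- R
  if (x < M) {
    # right section: the only table entry is "take R_{i-1}" (shift right)
    idx <- (cc + 1L):L
    new[idx] <- R[idx - 1L]
    # central cell behaves like a left cell driven by C_{i-1}
    new[cc] <- if (Ci[cc - 1L] == 0L) x else R[cc - 1L]
    # left section: C_n = C_{i-1}; the first cell always receives C_n = 0
    left <- seq_len(cc - 1L)
    Cn <- c(0L, Ci[head(left, -1L)])
    Rprev <- c(NA_real_, R[head(left, -1L)])  # R_{i-1}; never selected at i = 1
    new[left] <- ifelse(Ci[left] == 0L, R[left],
                        ifelse(Cn == 0L, x, Rprev))
  } else if (x > M) {
    # left section shifts left
    idx <- seq_len(cc - 1L)
    new[idx] <- R[idx + 1L]
    # central cell behaves like a right cell driven by C_{i+1}
    new[cc] <- if (Ci[cc + 1L] == 1L) x else R[cc + 1L]
    # right section: C_n = C_{i+1}; the last cell always receives C_n = 1
    right <- (cc + 1L):L
    Cn <- c(Ci[tail(right, -1L)], 1L)
    new[right] <- ifelse(Ci[right] == 1L, R[right],
                         ifelse(Cn == 1L, x, R[right + 1L]))
  } else {
    new[cc] <- x
    if (S == 1L) {                      # drop the first value: left shifts left
      idx <- seq_len(cc - 1L)
      new[idx] <- R[idx + 1L]
    } else {                            # drop the last value: right shifts right
      idx <- (cc + 1L):L
      new[idx] <- R[idx - 1L]
    }
  }
  array$registers <- new
  array
}

#' @rdname hw_init
#' @export
hw_registers <- function(array) array$registers

#' @export
print.hw_cell_array <- function(x, ...) {
  cat("<hw_cell_array> L =", x$L, " median =",
      format(x$registers[(x$L + 1L) %/% 2L]), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Quartile cascade
# ---------------------------------------------------------------------------

#' Quartile cascade of three NM estimators
#'
#' Three instances of the same estimator: the primary tracks the median; the
#' `low` instance receives only samples below the primary's estimate and so
#' tracks the first quartile; the `high` instance receives samples above it
#' and tracks the third quartile.  A sample exactly equal to the primary
#' estimate is routed by the primary's tie bit (to `low` when the next tie
#' would drop the last element, to `high` otherwise).
#'
#' `quantile_cascade_run()` streams a whole signal: the primary warms up on
#' the first samples, and the sub-estimators warm up on the samples routed to
#' them.
#'
#' @param primary,low,high `nm_state` objects (typically the same `L`).
#' @param x a finite sample, or for `quantile_cascade_run()` the whole signal.
#' @param L buffer length for all three estimators.
#' @return `quantile_cascade_update()` returns the cascade with fields
#'   `primary`, `low`, `high` and `estimates = c(q25, q50, q75)`.
#'   `quantile_cascade_run()` returns a list with the final cascade and a
#'   three-column matrix `trace` (`q25`, `q50`, `q75` per sample; `NA` while
#'   the corresponding buffer is still empty).
#' @examples
#' set.seed(1)
#' res <- quantile_cascade_run(runif(5000), L = 63)
#' res$cascade$estimates  # approaches c(0.25, 0.5, 0.75)
#' @export
quantile_cascade_init <- function(primary, low, high) {
  stopifnot(inherits(primary, "nm_state"), inherits(low, "nm_state"),
            inherits(high, "nm_state"))
  structure(list(primary = primary, low = low, high = high,
                 estimates = c(q25 = nm_estimate(low),
                               q50 = nm_estimate(primary),
                               q75 = nm_estimate(high))),
            class = "quantile_cascade")
}

#' @rdname quantile_cascade_init
#' @export
quantile_cascade_update <- function(cascade, x) {
  stopifnot(inherits(cascade, "quantile_cascade"))
  x <- check_sample(x)
  side_toggle <- cascade$primary$tie_toggle   # S in force before the update
  cascade$primary <- nm_update(cascade$primary, x)
  est <- nm_estimate(cascade$primary)
  if (x < est) {
    cascade$low <- nm_update(cascade$low, x)
  } else if (x > est) {
    cascade$high <- nm_update(cascade$high, x)
  } else if (side_toggle == 0L) {
    cascade$low <- nm_update(cascade$low, x)
  } else {
    cascade$high <- nm_update(cascade$high, x)
  }
  cascade$estimates <- c(q25 = nm_estimate(cascade$low),
                         q50 = nm_estimate(cascade$primary),
                         q75 = nm_estimate(cascade$high))
  cascade
}

#' @rdname quantile_cascade_init
#' @export
quantile_cascade_run <- function(x, L) {
  L <- check_buffer_length(L)
  cas <- quantile_cascade_init(nm_new(L), nm_new(L), nm_new(L))
  n <- length(x)
  trace <- matrix(NA_real_, nrow = n, ncol = 3,
                  dimnames = list(NULL, c("q25", "q50", "q75")))
  for (i in seq_len(n)) {
    cas <- quantile_cascade_update(cas, x[i])
    trace[i, ] <- cas$estimates
  }
  list(cascade = cas, trace = trace)
}

#' @export
print.quantile_cascade <- function(x, ...) {
  cat("<quantile_cascade> q25 =", format(x$estimates[["q25"]]),
      " q50 =", format(x$estimates[["q50"]]),
      " q75 =", format(x$estimates[["q75"]]), "\n")
  invisible(x)
}
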