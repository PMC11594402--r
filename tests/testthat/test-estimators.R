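# NM and CMM estimators, the sliding-median oracle, the hardware cell-array
# model, and the quartile cascade.

test_that("nm_init sorts its samples and reports the central element", {
  expect_equal(nm_init(c(3, 1, 2))$values, c(1, 2, 3))
  expect_equal(nm_estimate(nm_init(c(3, 1, 2))), 2)
  expect_equal(nm_estimate(nm_init(rep(5, 5))), 5)
  expect_equal(nm_estimate(nm_init(1:7)), 4)
  expect_error(nm_init(1:4), "odd")
  expect_error(nm_init(numeric(0), L = 0), "odd")
  expect_error(nm_init(c(1, NA, 3)), "finite")
})

test_that("the insertion/drop rules reproduce the worked buffer example", {
  s <- nm_init(1:7)
  s <- nm_update(s, 2)                 # below the centre: max dropped
  expect_equal(s$values, c(1, 2, 2, 3, 4, 5, 6))
  expect_equal(nm_estimate(s), 3)
  expect_equal(s$dropped, 7)
  s <- nm_update(s, 4)                 # above the new centre: min dropped
  expect_equal(s$values, c(2, 2, 3, 4, 4, 5, 6))
  expect_equal(nm_estimate(s), 4)
  expect_equal(s$dropped, 1)
})

test_that("a sample below every element becomes the new minimum", {
  s <- nm_update(nm_init(1:3), 0)
  expect_equal(s$values, c(0, 1, 2))
  expect_equal(nm_estimate(s), 1)
})

test_that("ties at the centre alternate the dropped extreme", {
  s <- nm_init(1:3)
  expect_equal(s$tie_toggle, 0L)
  s <- nm_update(s, 2)                 # toggle 0: drop the last element
  expect_equal(s$values, c(1, 2, 2))
  expect_equal(s$tie_toggle, 1L)
  expect_equal(s$dropped, 3)
  s <- nm_update(s, 2)                 # toggle 1: drop the first element
  expect_equal(s$values, c(2, 2, 2))
  expect_equal(s$tie_toggle, 0L)
  expect_equal(s$dropped, 1)
})

test_that("warm-up grows a sorted partial buffer with lower-middle estimates", {
  s <- nm_new(5)
  s <- nm_update(s, 3)
  expect_equal(nm_estimate(s), 3)
  s <- nm_update(s, 1)                 # even count: lower middle
  expect_equal(nm_estimate(s), 1)
  s <- nm_update(s, 2)
  expect_equal(nm_estimate(s), 2)
  expect_equal(s$n_seen, 3L)
  s <- nm_update(nm_update(s, 10), 0)
  expect_equal(s$values, c(0, 1, 2, 3, 10))
  expect_identical(s$dropped, NA_real_)  # nothing dropped during warm-up
})

test_that("non-finite samples are rejected", {
  s <- nm_init(1:5)
  expect_error(nm_update(s, NaN), "finite")
  expect_error(nm_update(s, Inf), "finite")
  expect_error(stream_estimate(c(1, 2, NA, 4), 3), "position 3")
})

test_that("buffer stays sorted, fixed-length and bounded on random streams", {
  set.seed(42)
  for (L in c(5, 15, 63)) {
    x <- c(rnorm(5000), sample(-3:3, 2000, replace = TRUE))  # continuous + ties
    s <- nm_init(x[1:L])
    lo <- min(x[1:L]); hi <- max(x[1:L])
    for (i in (L + 1):(L + 500)) {       # exhaustive per-step checks (slow path)
      s <- nm_update(s, x[i])
      lo <- min(lo, x[i]); hi <- max(hi, x[i])
      expect_false(is.unsorted(s$values))
      expect_length(s$values, L)
      expect_true(nm_estimate(s) >= lo && nm_estimate(s) <= hi)
    }
    # bulk of the stream through the compiled path, checked at the end
    est <- stream_estimate(x, L)
    expect_sorted(attr(est, "buffer"))
    expect_true(all(est >= cummin(x) & est <= cummax(x)))
  }
})

test_that("compiled NM stream matches the single-step R updater (with ties)", {
  set.seed(7)
  x <- sample(0:9, 4000, replace = TRUE)   # integer stream exercises ties
  r <- nm_run_r(nm_new(15), x)
  cpp <- stream_estimate(x, 15)
  expect_equal(r$estimates, as.numeric(cpp))
  expect_equal(r$state$values, as.numeric(attr(cpp, "buffer")))
  expect_equal(r$state$tie_toggle, attr(cpp, "tie_toggle"))
})

test_that("cmm window semantics follow the worked example", {
  s <- cmm_init(c(5, 2, 3, 1, 4, 6, 7))   # oldest is 5; sorted 1..7
  s <- cmm_update(s, 2)
  expect_equal(sort(s$window), c(1, 2, 2, 3, 4, 6, 7))
  s0 <- cmm_init(7:1)                      # oldest is 7
  s0 <- cmm_update(s0, 2)                  # 7 evicted
  expect_equal(sort(s0$window), c(1, 2, 2, 3, 4, 5, 6))
  expect_equal(cmm_estimate(s0), 3)
  s0 <- cmm_update(s0, 0)                  # now the oldest is 6
  expect_false(6 %in% s0$window)
  v <- cmm_init(rep(4, 5))
  expect_equal(cmm_estimate(cmm_update(v, 4)), 4)
})

test_that("cmm stream equals the brute-force oracle and runmed", {
  set.seed(11)
  x <- rnorm(500)
  for (L in c(5, 31)) {
    o <- sliding_median_oracle(x, L)
    trace <- stream_estimate(x, L, backend = "cmm")
    expect_equal(as.numeric(trace[L:length(x)]), o)
    r <- cmm_run_r(cmm_new(L), x)
    expect_equal(r$estimates[L:length(x)], o)
    # independent cross-check: centred running median realigned to trailing
    half <- (L - 1) / 2
    rm <- stats::runmed(x, L)[(1 + half):(length(x) - half)]
    expect_equal(o, as.numeric(rm))
  }
  expect_error(sliding_median_oracle(x, 4), "odd")
  expect_equal(sliding_median_oracle(c(1, 9, 2, 8, 3), 3), c(2, 8, 3))
  expect_equal(sliding_median_oracle(rep(2, 10), 5), rep(2, 6))
})

test_that("hardware cell array reproduces the worked example and tie shifts", {
  a <- hw_init(1:7)
  a <- hw_cell_step(a, 2)
  expect_equal(hw_registers(a), c(1, 2, 2, 3, 4, 5, 6))
  a <- hw_cell_step(a, 4)
  expect_equal(hw_registers(a), c(2, 2, 3, 4, 4, 5, 6))
  # X = M: S selects which half shifts
  b0 <- hw_cell_step(hw_init(1:5), 3, S = 0L)   # drop last, right half shifts
  expect_equal(hw_registers(b0), c(1, 2, 3, 3, 4))
  b1 <- hw_cell_step(hw_init(1:5), 3, S = 1L)   # drop first, left half shifts
  expect_equal(hw_registers(b1), c(2, 3, 3, 4, 5))
  expect_error(hw_init(c(3, 1, 2)), "sorted")
})

test_that("hardware model tracks nm_update bit-identically in lockstep", {
  set.seed(13)
  L <- 15
  x <- sample(0:9, 10000, replace = TRUE)  # frequent ties
  s <- nm_init(x[1:L])
  a <- hw_init(s$values)
  for (i in (L + 1):length(x)) {
    S <- s$tie_toggle                      # share the tie decision sequence
    s <- nm_update(s, x[i])
    a <- hw_cell_step(a, x[i], S = S)
    if (!identical(as.numeric(s$values), as.numeric(hw_registers(a))))
      stop("lockstep divergence at step ", i)
  }
  expect_identical(as.numeric(s$values), as.numeric(hw_registers(a)))
})

test_that("quartile cascade recovers quartiles of stationary inputs", {
  # constant stream: every estimate collapses to the constant
  res <- quantile_cascade_run(rep(2.5, 400), L = 5)
  expect_equal(unname(res$cascade$estimates), rep(2.5, 3))
  # uniform(0,1): quartiles 0.25 / 0.50 / 0.75
  set.seed(17)
  res <- quantile_cascade_run(runif(30000), L = 63)
  expect_equal(unname(res$cascade$estimates), c(0.25, 0.5, 0.75),
               tolerance = 0.05)
  # symmetric N(0,1): q50 near 0, quartiles mirror each other
  set.seed(18)
  res <- quantile_cascade_run(rnorm(30000), L = 63)
  q <- res$cascade$estimates
  expect_lt(abs(q[["q50"]]), 0.1)
  expect_lt(abs(q[["q25"]] + q[["q75"]]), 0.2)
})
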