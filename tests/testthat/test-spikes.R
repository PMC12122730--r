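test_that("interspike intervals are successive differences", {
  expect_equal(isi(c(0.1, 0.3, 0.6)), c(0.2, 0.3))
  expect_length(isi(c(0.5)), 0)
  expect_length(isi(numeric(0)), 0)
  expect_equal(isi(seq(0, 1, by = 0.1)), rep(0.1, 10))
  st <- spike_train(c(0.1, 0.2), 0, 1, "u1")
  expect_equal(isi(st), 0.1)
})

test_that("interval histograms bin half-open and conserve counts", {
  h <- isih(c(0.002, 0.007), qty(5, "ms"), 0.25)
  expect_equal(h$counts[1:3], c(1, 1, 0))
  expect_equal(length(h$counts), 50)
  expect_equal(length(h$bin_edges), 51)

  h0 <- isih(numeric(0), qty(5, "ms"), 0.25)
  expect_true(all(h0$counts == 0))

  iv <- c(0.004, 0.005, 0.0049999, 0.25, 0.3)   # boundary and overflow cases
  h2 <- isih(iv, qty(5, "ms"), 0.25)
  expect_equal(sum(h2$counts), 3)               # >= t_max discarded
  expect_equal(h2$counts[1], 2)                 # [0, 5) ms
  expect_equal(h2$counts[2], 1)                 # 5 ms falls in [5, 10)
})

test_that("CV2 matches closed-form cases and errors on short input", {
  expect_equal(cv2(rep(0.05, 10)), 0)
  expect_equal(cv2(c(1, 3)), 1)                 # 2|3-1|/(3+1)
  expect_error(cv2(c(0.1)), "fewer than two")
})

test_that("CV2 of iid exponential intervals has expectation 1 (Monte Carlo oracle)", {
  set.seed(21)
  # oracle: E[2|X-Y|/(X+Y)] over iid exponential pairs, brute-force sampling
  x <- stats::rexp(200000); y <- stats::rexp(200000)
  oracle <- mean(2 * abs(x - y) / (x + y))
  expect_lt(abs(oracle - 1), 0.01)
  got <- cv2(stats::rexp(200000))
  expect_lt(abs(got - oracle), 0.02)
})

test_that("Poisson generation matches count statistics and is seed-stable", {
  st <- poisson_spiketrain(10, 100, seed = 42)
  expect_lt(abs(length(st$times) - 1000), 4 * sqrt(1000))
  expect_true(all(diff(st$times) > 0))
  expect_true(all(st$times >= 0 & st$times < 100))
  st2 <- poisson_spiketrain(10, 100, seed = 42)
  expect_identical(st$times, st2$times)
  # vanishing-rate limit produces (almost surely) no spikes
  expect_length(poisson_spiketrain(0.001, 10, seed = 1)$times, 0)
})

test_that("gamma(shape 1) intervals are exponential and CV scales as 1/sqrt(shape)", {
  g1 <- gamma_spiketrain(10, 1, 100, seed = 7)
  ref <- poisson_spiketrain(10, 100, seed = 8)
  ks <- stats::ks.test(isi(g1), isi(ref))
  expect_gt(ks$p.value, 0.01)
  g10 <- gamma_spiketrain(10, 10, 200, seed = 9)
  iv <- isi(g10)
  expect_lt(abs(stats::sd(iv) / mean(iv) - 1 / sqrt(10)), 0.05)
  # mean rate near target
  expect_lt(abs(length(g1$times) / 100 - 10), 1)
})

test_that("uniform dithering never increases the spike count and vanishes in the small-dither limit", {
  st <- poisson_spiketrain(20, 4, seed = 3)
  for (k in 1:5) {
    s <- surrogate_uniform_dither(st, qty(25, "ms"), seed = k)
    expect_lte(length(s$times), length(st$times))
    expect_true(all(s$times >= s$t_start & s$times < s$t_stop))
  }
  tiny <- surrogate_uniform_dither(st, 1e-12, seed = 1)
  expect_equal(tiny$times, st$times, tolerance = 1e-9)
})

test_that("uniform dithering loses at most the edge fraction on average", {
  st <- poisson_spiketrain(20, 4, seed = 13)
  d <- 0.025
  counts <- vapply(1:200, function(k)
    length(surrogate_uniform_dither(st, d, seed = 1000 + k)$times), numeric(1))
  # expected loss is bounded by the uniform edge-loss probability d/duration
  expect_gte(mean(counts),
             length(st$times) * (1 - d / (st$t_stop - st$t_start)) - 1)
})

test_that("trial shifting preserves the spike count and nearly the ISI multiset", {
  st <- poisson_spiketrain(20, 4, seed = 17)
  for (k in 1:10) {
    s <- surrogate_trial_shift(st, qty(30, "ms"), seed = k)
    expect_identical(length(s$times), length(st$times))
    # circular shift changes at most 2 elements of the interval multiset
    a <- round(sort(isi(st)), 9)
    b <- round(sort(isi(s)), 9)
    common <- length(a) - length(setdiff(a, b))
    expect_gte(common, length(a) - 2)
  }
  s1 <- surrogate_trial_shift(st, qty(30, "ms"), seed = 5)
  s2 <- surrogate_trial_shift(st, qty(30, "ms"), seed = 5)
  expect_identical(s1$times, s2$times)
})

test_that("pooled trial-shift ISIHs track the original distribution more closely than dithering", {
  set.seed(30)
  trains <- lapply(1:20, function(i) poisson_spiketrain(20, 4, seed = 300 + i))
  pooled_hist <- function(trs) {
    Reduce(`+`, lapply(trs, function(t) isih(isi(t), qty(5, "ms"), 0.25)$counts))
  }
  orig <- pooled_hist(trains)
  shift <- pooled_hist(lapply(seq_along(trains), function(i)
    surrogate_trial_shift(trains[[i]], qty(30, "ms"), seed = 600 + i)))
  dith <- pooled_hist(lapply(seq_along(trains), function(i)
    surrogate_uniform_dither(trains[[i]], qty(25, "ms"), seed = 900 + i)))
  err_shift <- sum(abs(shift - orig))
  err_dith <- sum(abs(dith - orig))
  expect_lt(err_shift, err_dith)
})

test_that("spike train construction validates ordering and window", {
  expect_error(spike_train(c(0.5, 0.2), 0, 1), "sorted|unsorted|times")
  expect_error(spike_train(c(1.5), 0, 1), "times")
})
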