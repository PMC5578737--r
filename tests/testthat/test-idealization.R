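test_that("noiseless steps are recovered exactly", {
  tr <- pwc_trace(c(0, 36.8), c(5000, 5000), rate = 1e4)  # step at t = 0.5 s
  id <- idealize(tr)
  expect_equal(nrow(id$segments), 2L)
  expect_equal(id$segments$start_s, c(0, 0.5))
  expect_equal(id$segments$level_pA, c(0, 36.8))
})

test_that("a constant noisy trace yields a single segment", {
  withr::with_seed(5, {
    tr <- channel_trace(rnorm(20000, 36.8, 2), meta_sym(duration_s = 2))
  })
  id <- idealize(tr)
  expect_equal(nrow(id$segments), 1L)
  expect_equal(id$segments$level_pA, 36.8, tolerance = 0.01)
})

test_that("idealizing a compliant piecewise-constant trace is idempotent", {
  tr <- pwc_trace(c(5, 22, 0, 36.8), c(2000, 1500, 3000, 2500))
  id1 <- idealize(tr)
  # re-idealize the reconstruction
  tr2 <- channel_trace(rep(id1$segments$level_pA,
                           round(id1$segments$duration_s * 1e4)),
                       tr$meta)
  id2 <- idealize(tr2)
  expect_equal(id2$segments, id1$segments)
  expect_equal(id1$segments$level_pA, c(5, 22, 0, 36.8))
})

test_that("increasing the penalty never increases the change-point count", {
  withr::with_seed(21, {
    x <- rep(c(0, 10, 3, 14, 0), each = 400) + rnorm(2000, 0, 2)
  })
  n_cp <- vapply(c(5, 20, 80, 320, 1280, 5120),
                 function(beta) length(tim23ephys:::.fpop_mean(x, beta)),
                 numeric(1))
  expect_true(all(diff(n_cp) <= 0))
})

test_that("penalized segmentation matches the exhaustive dynamic program", {
  withr::with_seed(33, {
    for (rep in 1:6) {
      n_cp_true <- sample(0:4, 1)
      cuts <- sort(sample(50:1950, n_cp_true))
      lens <- diff(c(0, cuts, 2000))
      levels <- cumsum(c(0, sample(c(-1, 1), n_cp_true, TRUE) *
                           stats::runif(n_cp_true, 8, 20)))
      x <- rep(levels, lens) + rnorm(2000, 0, 2)
      beta <- default_penalty(x)
      expect_identical(as.integer(tim23ephys:::.fpop_mean(x, beta)),
                       as.integer(dp_segment_oracle(x, beta)))
    }
  })
})

test_that("transitions of at least 60 pS are recovered against ground truth", {
  # two long-dwell flicker states, amplitudes 170 and 60 pS; at +80 mV and
  # sigma = 0.7 pA the smallest step (4.8 pA) has SNR ~ 7
  m <- channel_model(levels_pS = c(sub290 = 290, sub400 = 400, open = 460),
                     rate_matrix = matrix(c(0, 0, 50,
                                            0, 0, 50,
                                            1.3, 1.3, 0), 3, 3, byrow = TRUE),
                     noise_sd_pA = 0.7)
  prot <- recording_protocol(80, 50, sample_rate_Hz = 1e4)
  sim <- simulate_trace(m, prot, seed = 61)
  expect_gt(sim$truth$n_events, 200)
  id <- idealize(sim$trace)
  got <- id$segments$start_s[-1L]
  truth <- sim$truth$events$time_s
  hit <- vapply(truth, function(t0) any(abs(got - t0) <= 2e-3), logical(1))
  expect_gt(mean(hit), 0.95)
  # levels of long segments recovered to better than 1 pA
  long <- id$segments$duration_s > 5e-3
  lev_err <- vapply(which(long), function(i) {
    min(abs(id$segments$level_pA[i] - sim$truth$levels_pA))
  }, numeric(1))
  expect_lt(stats::median(lev_err), 1)
})

test_that("residual_sd recovers the injected noise and 0 for noiseless traces", {
  tr0 <- pwc_trace(c(0, 36.8, 10), c(3000, 4000, 3000))
  expect_equal(residual_sd(tr0, idealize(tr0)), 0)
  withr::with_seed(8, {
    sds <- vapply(1:4, function(i) {
      n_seg <- c(1, 3, 6, 12)[i]
      lv <- seq(0, 36.8, length.out = max(2, n_seg))[seq_len(n_seg)]
      tr <- pwc_trace(lv, rep(2000, n_seg), noise_sd = 2)
      residual_sd(tr, idealize(tr))
    }, numeric(1))
  })
  expect_true(all(abs(sds - 2) / 2 < 0.05))
  expect_lt(diff(range(sds)), 0.15)  # independent of segment count
})

test_that("degenerate inputs are rejected with named errors", {
  expect_error(idealize(channel_trace(rep(1, 5),
                                      meta_sym(duration_s = 5e-4, rate = 1e4))),
               class = "tim23_trace_too_short")
  tr <- pwc_trace(36.8, 8, rate = 1e4)
  expect_error(idealize(tr), class = "tim23_trace_too_short")
  expect_error(idealize_params(min_dwell_s = 0), class = "tim23_invalid_params")
  tr2 <- pwc_trace(c(0, 36.8), c(100, 100))
  id <- idealize(tr2)
  tr3 <- pwc_trace(c(0, 36.8), c(100, 100), voltage_mV = 100)
  expect_error(residual_sd(tr3, id), class = "tim23_meta_mismatch")
})
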