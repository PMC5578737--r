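test_that("variant defaults differ only in selectivity and activation", {
  wt <- default_model("wildtype")
  mut <- default_model("N150A")
  expect_equal(wt$flicker_amax, 50)
  expect_equal(mut$flicker_amax, 6)
  expect_identical(wt$levels_pS, mut$levels_pS)
  expect_identical(wt$rate_matrix, mut$rate_matrix)
  expect_equal(wt$v_half_mV, mut$v_half_mV)
  expect_equal(mut$pk_over_pcl / wt$pk_over_pcl, 0.33)
  expect_error(default_model("G153L"))
})

test_that("model reversal potential follows GHK under the recording buffers", {
  m <- default_model("wildtype")
  expect_equal(reversal_potential(m, meta_sym()), 0)
  # ideally cation-selective channel: Nernst potential of the 12.5x gradient,
  # (RT/F) ln 12.5 = 64.8925 mV at 298.15 K (evaluated independently)
  m_inf <- channel_model(pk_over_pcl = Inf)
  expect_equal(reversal_potential(m_inf, meta_asym()), 64.8925,
               tolerance = 1e-4)
  m1 <- channel_model(pk_over_pcl = 1)
  expect_equal(reversal_potential(m1, meta_asym()), 0)
})

test_that("a frozen open channel gives the ohmic constant-current trace", {
  sim <- simulate_trace(frozen_model(), recording_protocol(80, 0.05,
                                                           sample_rate_Hz = 1000),
                        initial_state = "open", seed = 1)
  expect_equal(unique(sim$trace$samples), 36.8)  # 0.460 nS x 80 mV
  expect_equal(sim$truth$n_events, 0L)
})

test_that("identical seeds give bit-identical traces", {
  m <- default_model("wildtype")
  prot <- recording_protocol(80, 0.5, substrate_uM = 2)
  a <- simulate_trace(m, prot, seed = 77)
  b <- simulate_trace(m, prot, seed = 77)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$truth$events, b$truth$events)
  c_ <- simulate_trace(m, prot, seed = 78)
  expect_false(identical(a$trace$samples, c_$trace$samples))
})

test_that("a symmetric two-state chain spends half its time open", {
  # at |V| = v_half the Boltzmann tie makes the closure rate equal the
  # reopening rate: k_open = k_close = 5/s
  m <- channel_model(levels_pS = c(closed = 0, open = 460),
                     rate_matrix = matrix(c(0, 5, 5, 0), 2, 2, byrow = TRUE))
  q <- effective_generator(m, m$v_half_mV)
  expect_equal(q["open", "closed"], q["closed", "open"])
  expect_equal(stationary_distribution(q), c(0.5, 0.5), ignore_attr = TRUE,
               tolerance = 1e-10)
  path <- simulate_state_path(m, m$v_half_mV, duration_s = 2000, seed = 9)
  occ <- path_occupancy(path, 2)
  expect_equal(occ[2], 0.5, tolerance = 0.03)
})

test_that("ground truth counts every state change and noiseless mean current matches occupancy", {
  m <- channel_model(noise_sd_pA = 0)
  prot <- recording_protocol(80, 120)
  sim <- simulate_trace(m, prot, seed = 13)
  expect_identical(sim$truth$n_events, length(sim$truth$times) - 1L)
  expect_identical(sim$truth$n_events, nrow(sim$truth$events))
  pi_ <- sim$truth$stationary
  expected_mean <- sum(pi_ * m$levels_pS) * 80 / 1000
  expect_equal(mean(sim$trace$samples), expected_mean, tolerance = 0.02)
})

test_that("substrate scaling reproduces the target event-frequency fold in stationarity", {
  for (variant in c("wildtype", "N150A")) {
    m <- default_model(variant)
    q0 <- effective_generator(m, 80, substrate_uM = 0)
    qs <- effective_generator(m, 80, substrate_uM = 1e4)  # saturating
    rate <- function(q) {
      pi_ <- stationary_distribution(q)
      sum(pi_ * -diag(q))
    }
    expect_equal(rate(qs) / rate(q0), m$flicker_amax, tolerance = 1e-3)
    # half-maximal concentration gives the Hill midpoint fold
    qh <- effective_generator(m, 80, substrate_uM = m$ec50_uM)
    expect_equal(rate(qh) / rate(q0), 1 + (m$flicker_amax - 1) / 2,
                 tolerance = 1e-3)
  }
})

test_that("unattainable event-frequency folds are rejected", {
  m <- channel_model(flicker_amax = 1e6)
  expect_error(effective_generator(m, 80, substrate_uM = 1e6),
               class = "tim23_invalid_model")
})

test_that("Tim50 presence shifts the closure midpoint by the configured offset", {
  m <- default_model("wildtype")
  po_at <- function(v, tim50) {
    q <- effective_generator(m, v, tim50_present = tim50)
    pi_ <- stationary_distribution(q)
    sum(pi_ * m$levels_pS) / max(m$levels_pS)
  }
  # without Tim50 the stationary Po crosses 1/2 near v_half; with Tim50 the
  # crossing moves down by |tim50_shift_mV|
  v_mid <- function(tim50) {
    vs <- seq(60, 180, by = 0.25)
    po <- vapply(vs, po_at, numeric(1), tim50 = tim50)
    vs[which.min(abs(po - 0.5))]
  }
  expect_equal(v_mid(FALSE) - v_mid(TRUE), abs(m$tim50_shift_mV),
               tolerance = 0.05)
})

test_that("simulated IV datasets cross zero at the GHK reversal potential", {
  meta <- meta_asym(duration_s = 5)
  volts <- seq(-60, 100, by = 20)

  # nonselective channel: zero crossing at 0 mV
  m1 <- channel_model(pk_over_pcl = 1, noise_sd_pA = 0)
  iv1 <- simulate_iv(m1, volts, meta, seed = 4)
  expect_equal(estimate_reversal(iv1)$u_rev_mV, 0, tolerance = 1e-9)

  # ohmic through the origin under symmetric buffers
  m0 <- frozen_model(noise_sd_pA = 0)
  iv0 <- simulate_iv(m0, volts, meta_sym(duration_s = 5), seed = 4)
  fit <- lm(mean_current_pA ~ voltage_mV, data = iv0$points)
  expect_equal(unname(coef(fit)), c(0, 0.460), tolerance = 1e-9)

  # x = 15 under the 12.5-fold gradient: 25.693 ln(3770/550) = 49.456 mV
  m15 <- channel_model(pk_over_pcl = 15, noise_sd_pA = 0)
  iv15 <- simulate_iv(m15, volts, meta, seed = 4)
  expect_equal(estimate_reversal(iv15)$u_rev_mV, 49.456, tolerance = 1e-3)

  expect_error(simulate_iv(m15, c(40, 0, 80), meta),
               class = "tim23_invalid_iv")
})
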