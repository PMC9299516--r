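test_that("delta F of a flat trace is exactly zero", {
  tr <- flat_traces(3, value = 100)
  d <- compute_delta_f(tr, default_protocol())
  expect_equal(d$delta_f, rep(0, 3))
})

test_that("delta F is peak minus baseline mean in raw units", {
  tr <- flat_traces(1, value = 100)
  tr[1, as.numeric(colnames(tr)) >= 12] <- 130
  d <- compute_delta_f(tr, default_protocol())
  expect_equal(d$delta_f, 30)
})

test_that("delta F is shift-invariant and scales linearly", {
  w <- quiet_well(n_cells = 10, seed = 6, noise_sd = 2)
  d0 <- compute_delta_f(w$traces, default_protocol())
  d_shift <- compute_delta_f(w$traces + 57, default_protocol())
  d_scale <- compute_delta_f(w$traces * 2.5, default_protocol())
  expect_equal(d_shift$delta_f, d0$delta_f)
  expect_equal(d_scale$delta_f, 2.5 * d0$delta_f)
})

test_that("one delta F value is emitted per cell and stimulus", {
  w <- quiet_well(n_cells = 7, seed = 2, stimulus_times = c(A = 10, B = 27))
  d <- compute_delta_f(w$traces, double_protocol())
  expect_equal(nrow(d), 7 * 2)
  expect_equal(sort(unique(d$stimulus)), c("A", "B"))
})

test_that("noise-free responder delta F recovers the planted amplitude", {
  # single stimulus: template peak falls exactly on a frame and the baseline
  # is exact, so recovery is exact
  w1 <- quiet_well(n_cells = 30, seed = 8)
  d1 <- compute_delta_f(w1$traces, default_protocol())
  expect_equal(d1$delta_f, w1$truth$amplitude_A)
  expect_true(all(d1$delta_f[w1$truth$amplitude_A == 0] == 0))

  # double stimulation: the first response has not fully decayed when the
  # second baseline is taken, leaving a small carry-over proportional to the
  # first amplitude; the re-baselining keeps it within 2% of amplitude_A
  w2 <- quiet_well(n_cells = 40, seed = 8, stimulus_times = c(A = 10, B = 27))
  d2 <- compute_delta_f(w2$traces, double_protocol())
  dA <- d2$delta_f[d2$stimulus == "A"]
  dB <- d2$delta_f[d2$stimulus == "B"]
  expect_equal(dA, w2$truth$amplitude_A)
  expect_true(all(abs(dB - w2$truth$amplitude_B) <=
                    0.02 * w2$truth$amplitude_A + 1e-9))
})

test_that("bleaching drift biases delta F by no more than the stated bound", {
  cfg <- sim_well_config(n_cells = 20, noise_sd = 0, bleach_rate = 0.002,
                         seed = 3)
  w <- simulate_well(cfg)
  d <- compute_delta_f(w$traces, default_protocol())
  err <- abs(d$delta_f - w$truth$amplitude_A)
  bound <- max(w$truth$baseline_level) * cfg$bleach_rate * cfg$duration
  expect_true(all(err <= bound))
})

test_that("a later stimulus is re-baselined against its own pre-window", {
  # sustained response to A would otherwise inflate delta F of B
  tr <- flat_traces(1, value = 100)
  t <- as.numeric(colnames(tr))
  tr[1, t >= 10] <- 160           # sustained A response, plateau 60
  tr[1, t >= 27] <- 160 + 25      # B adds 25 on top of the plateau
  d <- compute_delta_f(tr, double_protocol())
  expect_equal(d$delta_f[d$stimulus == "A"], 60)
  expect_equal(d$delta_f[d$stimulus == "B"], 25)
})

test_that("protocols with impossible windows are rejected", {
  expect_error(stimulation_protocol(c(A = 10), duration = 45,
                                    baseline_window = c(0, 12)),
               "baseline")
  expect_error(stimulation_protocol(c(A = 50), duration = 45), "end")
  tr <- flat_traces(1)[, 1:10, drop = FALSE]  # recording ends at 4.5 s
  expect_error(compute_delta_f(tr, default_protocol()), "no frames")
})

test_that("median baseline is robust to a baseline spike", {
  tr <- flat_traces(1, value = 100)
  tr[1, 3] <- 1000  # single-frame artifact during baseline
  d_mean <- compute_delta_f(tr, default_protocol(), baseline_stat = "mean")
  d_med <- compute_delta_f(tr, default_protocol(), baseline_stat = "median")
  expect_equal(d_med$delta_f, 0)
  expect_lt(d_mean$delta_f, 0)
})
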