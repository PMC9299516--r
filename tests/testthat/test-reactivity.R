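test_that("the noise-based threshold is mean + 3 SD, capped at 18", {
  # hand computation with the n-1 sample SD: {2, 6} -> 4 + 3 * 2.828
  th <- compute_threshold(c(2, 6))
  expect_equal(th$value, 4 + 3 * sqrt(8))
  expect_false(th$capped)

  # zero spread: threshold equals the mean
  th0 <- compute_threshold(c(4, 4, 4, 4))
  expect_equal(th0$value, 4)
  expect_equal(th0$control_sd, 0)
  expect_false(th0$capped)

  # naive value 25 exceeds the cap -> 18 exactly
  th_cap <- compute_threshold(c(5, 10, 15))
  expect_equal(th_cap$control_mean, 10)
  expect_equal(th_cap$control_sd, 5)
  expect_identical(th_cap$value, 18)
  expect_true(th_cap$capped)
})

test_that("threshold errors and the cap relation hold", {
  expect_error(compute_threshold(c(1)), "at least 2")
  expect_error(compute_threshold(c(1, 2), cap = -1), "cap")
  # removing the cap never decreases the threshold
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(10, mean = runif(1, 0, 20), sd = runif(1, 0, 10))
    capped <- compute_threshold(x)$value
    uncapped <- compute_threshold(x, cap = Inf)$value
    expect_lte(capped, 18)
    expect_gte(uncapped, capped)
  }
})

test_that("reactive calls use a strict inequality", {
  th <- compute_threshold(c(5, 10, 15))  # capped at 18
  calls <- classify(c(19, 18, 5, 17, 18.001, 30), th)
  expect_identical(calls$reactive, c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("the reactive fraction is the exact count ratio", {
  calls <- classify(c(rep(25, 3), rep(1, 7)), 18)
  fr <- fraction_reactive(calls)
  expect_equal(fr$n_cells, 10)
  expect_equal(fr$n_reactive, 3)
  expect_equal(fr$fraction_reactive, 0.3)
  all_r <- fraction_reactive(classify(rep(20, 5), 18))
  expect_equal(all_r$fraction_reactive, 1)
  expect_error(fraction_reactive(data.frame()), "no cells")
})

test_that("raising the threshold never increases the reactive count", {
  set.seed(42)
  dfv <- rnorm(200, 10, 8)
  prev <- Inf
  for (thr in seq(0, 40, by = 2)) {
    n <- sum(classify(dfv, thr)$reactive)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("classification matches a brute-force per-cell loop", {
  for (s in 1:20) {
    w <- quiet_well(n_cells = 25, seed = 300 + s, noise_sd = 2)
    d <- compute_delta_f(w$traces, default_protocol())
    th <- compute_threshold(rnorm(20, 5, 3), cap = 18)
    fr <- fraction_reactive(classify(d, th))
    expect_identical(fr$fraction_reactive,
                     brute_fraction(d$delta_f, th$value))
  }
})

test_that("replicate summaries average technical wells first and report SEM", {
  df <- data.frame(condition = "ctrl", replicate = 1:3,
                   fraction_reactive = c(0.2, 0.3, 0.4))
  s <- summarize_replicates(df)
  expect_equal(s$mean, 0.3)
  expect_equal(s$sem, sd(c(0.2, 0.3, 0.4)) / sqrt(3), tolerance = 1e-12)
  expect_equal(round(s$sem, 4), 0.0577)

  # identical replicates -> SEM 0; single replicate -> SEM undefined (NA)
  same <- summarize_replicates(data.frame(condition = "c", replicate = 1:3,
                                          fraction_reactive = 0.5))
  expect_equal(same$sem, 0)
  single <- summarize_replicates(data.frame(condition = "c", replicate = 1,
                                            fraction_reactive = 0.5))
  expect_true(is.na(single$sem))

  # technical wells within a biological replicate are averaged before SEM
  tech <- data.frame(condition = "c", replicate = c(1, 1, 2, 2),
                     fraction_reactive = c(0.0, 0.4, 0.3, 0.3))
  st <- summarize_replicates(tech)
  expect_equal(st$n_replicates, 2L)
  expect_equal(st$mean, 0.25)
  expect_equal(st$sem, sd(c(0.2, 0.3)) / sqrt(2))
})

test_that("double-stimulation overlap cross-tabulates matched cells", {
  calls_A <- data.frame(cell_id = 1:10, reactive = rep(TRUE, 10))
  calls_B <- data.frame(cell_id = 1:10, reactive = rep(FALSE, 10))
  ov <- double_stim_overlap(calls_A, calls_B)
  expect_equal(c(ov$fraction_both, ov$fraction_A_only, ov$fraction_B_only,
                 ov$fraction_neither), c(0, 1, 0, 0))
  expect_error(double_stim_overlap(calls_A, calls_B[1:5, ]), "same cells")
  # the four fractions always sum to 1
  set.seed(1)
  a <- data.frame(cell_id = 1:50, reactive = runif(50) < 0.5)
  b <- data.frame(cell_id = sample(1:50), reactive = runif(50) < 0.5)
  ov2 <- double_stim_overlap(a, b)
  expect_equal(ov2$fraction_both + ov2$fraction_A_only +
                 ov2$fraction_B_only + ov2$fraction_neither, 1)
})

test_that("independent calls factorise: P(both) is the product of marginals", {
  set.seed(7)
  n <- 20000
  pa <- 0.4; pb <- 0.3
  a <- data.frame(cell_id = 1:n, reactive = runif(n) < pa)
  b <- data.frame(cell_id = 1:n, reactive = runif(n) < pb)
  ov <- double_stim_overlap(a, b)
  se <- sqrt(pa * pb * (1 - pa * pb) / n)
  expect_lt(abs(ov$fraction_both - pa * pb), 3 * se)
})

test_that("condition comparisons behave at the null and under separation", {
  same <- data.frame(condition = rep(c("a", "b"), each = 3),
                     replicate = rep(1:3, 2),
                     fraction_reactive = rep(c(0.2, 0.3, 0.4), 2))
  expect_equal(compare_conditions(same, reference = "a")$p_value, 1)

  sep <- data.frame(condition = rep(c("a", "b"), each = 3),
                    replicate = rep(1:3, 2),
                    fraction_reactive = c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9))
  expect_error(compare_conditions(sep[1:4, ], reference = "a"), "replicates")
  p <- compare_conditions(sep, reference = "a")$p_value
  expect_lt(p, 0.05)
})

test_that("multi-condition designs use comparisons against the reference", {
  set.seed(13)
  df <- data.frame(
    condition = rep(c("ctrl", "low", "high"), each = 4),
    replicate = rep(1:4, 3),
    fraction_reactive = c(rnorm(4, 0.2, 0.03), rnorm(4, 0.2, 0.03),
                          rnorm(4, 0.8, 0.03)))
  res <- compare_conditions(df, reference = "ctrl")
  expect_equal(nrow(res), 2)
  p_high <- res$p_value[grepl("high", res$comparison)]
  p_low <- res$p_value[grepl("low", res$comparison)]
  expect_lt(p_high, 0.05)
  expect_gt(p_low, 0.05)
})

test_that("well thresholds use the in-well control stimulus or pooled controls", {
  df <- data.frame(
    well_id = rep(c("w1", "w2"), each = 4),
    cell_id = rep(1:4, 2),
    stimulus = c(rep("HBSS", 4), rep("A", 4)),
    delta_f = c(1, 2, 3, 2, 30, 40, 20, 25))
  wells <- data.frame(well_id = c("w1", "w2"), plate = "p1",
                      is_control = c(TRUE, FALSE))
  th <- well_thresholds(df, wells)
  expect_equal(th$w1$mode, "same_well")
  expect_equal(th$w1$value, mean(c(1, 2, 3, 2)) + 3 * sd(c(1, 2, 3, 2)))
  # w2 has no HBSS stimulus -> pooled control wells of the same plate
  expect_equal(th$w2$mode, "pooled_controls")
  expect_equal(th$w2$control_mean, 2)
  # no control anywhere -> actionable error
  wells_none <- data.frame(well_id = c("w1", "w2"), plate = "p1",
                           is_control = FALSE)
  df2 <- df[df$stimulus == "A", ]
  expect_error(well_thresholds(df2, wells_none), "control")
})
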