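test_that("trace simulator: no event sources gives a constant trace", {
  p <- trace_sim_params(n_frames = 50, event_rate_per_min = 0, noise_sd = 0,
                        bleach_rate = 0, baseline_f0 = 80)
  sim <- simulate_trace(p)
  expect_equal(sim$trace$samples, rep(80, 50))
  expect_equal(nrow(sim$events), 0L)
})

test_that("trace simulator is deterministic under its seed", {
  p <- trace_sim_params(seed = 99)
  a <- simulate_trace(p)
  b <- simulate_trace(p)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$events, b$events)
  c <- simulate_trace(trace_sim_params(seed = 100))
  expect_false(identical(a$trace$samples, c$trace$samples))
})

test_that("trace simulator rejects invalid parameters", {
  expect_error(trace_sim_params(n_frames = 1), "n_frames")
  expect_error(trace_sim_params(frame_rate_hz = 0), "frame_rate_hz")
  expect_error(trace_sim_params(burst_prob = 1.2), "burst_prob")
  expect_error(trace_sim_params(subpeaks_range = c(1, 3)), "subpeaks_range")
  expect_error(trace_sim_params(bleach_rate = 1), "bleach_rate")
})

test_that("noiseless transient peaks hit baseline_f0 * (1 + amplitude)", {
  p <- trace_sim_params(n_frames = 400, event_rate_per_min = 1.5,
                        amplitude_sd = 0, amplitude_mean = 0.6,
                        burst_prob = 0, noise_sd = 0, bleach_rate = 0,
                        baseline_f0 = 120, seed = 5)
  sim <- simulate_trace(p)
  expect_gt(nrow(sim$events), 0L)
  for (i in seq_len(nrow(sim$events))) {
    pk <- sim$events$peak_frames[[i]] + 1L
    if (max(pk) < 400) {   # fully observed events only
      peak_val <- max(sim$trace$samples[pk])
      # residual decay tails from preceding events can only add, and events
      # are spaced >= 4 decay time constants apart
      expect_gte(peak_val, 120 * 1.6 - 1e-9)
      expect_lte(peak_val, 120 * 1.6 * (1 + exp(-4) * 0.6))
    }
  }
})

test_that("ground-truth bursts keep inter-peak troughs above the offset band", {
  p <- trace_sim_params(n_frames = 500, burst_prob = 1, amplitude_sd = 0,
                        noise_sd = 0, bleach_rate = 0, seed = 8)
  sim <- simulate_trace(p)
  dff <- (sim$trace$samples - min(sim$trace$samples)) /
    min(sim$trace$samples)
  bursts <- sim$events[sim$events$is_burst, ]
  expect_gt(nrow(bursts), 0L)
  for (i in seq_len(nrow(bursts))) {
    pk <- bursts$peak_frames[[i]] + 1L
    if (length(pk) < 2L) next
    for (j in seq_len(length(pk) - 1L)) {
      trough <- min(dff[pk[j]:pk[j + 1L]])
      expect_gt(trough, 0.2)
    }
  }
})

test_that("recovery is accurate and precise in the high-SNR regime", {
  # at noise 0.01 the min-based F0 sits close enough to the true baseline
  # that the 0.1 threshold is ~7 sigma above the noise floor
  sims <- lapply(1:200, function(i) {
    simulate_trace(trace_sim_params(n_frames = 300, event_rate_per_min = 2,
                                    amplitude_mean = 0.5, noise_sd = 0.01,
                                    seed = 60000 + i))
  })
  dets <- lapply(sims, function(s) detect_transients(compute_dff(s$trace)))
  sc <- score_event_recovery(lapply(sims, `[[`, "events"), dets,
                             tol_frames = 2)
  expect_gte(sc$recall, 0.9)
  expect_gte(sc$precision, 0.9)
  expect_lte(abs(sc$amplitude_relative_bias), 0.10)
})

test_that("detection recovers most seeded events", {
  p <- trace_sim_params(n_frames = 330, event_rate_per_min = 1,
                        amplitude_mean = 0.5, noise_sd = 0.02, seed = 21)
  sim <- simulate_trace(p)
  expect_gte(nrow(sim$events), 5L)
  tr <- detect_transients(compute_dff(sim$trace))
  hits <- vapply(sim$events$onset_frame, function(o) {
    any(abs(tr$onset_frame - o) <= 2L)
  }, TRUE)
  expect_gte(sum(hits), nrow(sim$events) - 1L)
})

test_that("survival simulator honours the closed-form medians under the null", {
  p <- survival_sim_params(n_per_group = 500, seed = 31)
  rec <- simulate_survival(p)
  expect_equal(nrow(rec), 2000L)
  med_expected <- weibull_median(p$baseline_scale, p$shape)
  for (g in split(rec, interaction(rec$genotype, rec$induction))) {
    expect_equal(stats::median(g$day), med_expected, tolerance = 0.1)
  }
})

test_that("higher induction hazard shortens induced lifespans", {
  p <- survival_sim_params(n_per_group = 500, induction_hr = 3, seed = 32)
  rec <- simulate_survival(p)
  med <- tapply(rec$day, rec$induction, stats::median)
  expect_lt(med[["RU200"]], med[["RU0"]])
  # closed form: medians scale by hr^(-1/shape)
  expect_equal(med[["RU200"]] / med[["RU0"]], 3^(-1 / 4), tolerance = 0.1)
})

test_that("empirical hazard ratios track the specified ones", {
  p <- survival_sim_params(n_per_group = 500, genotype_hr = 0.6,
                           induction_hr = 2.5, seed = 33)
  rec <- simulate_survival(p)
  fit <- survival::coxph(
    survival::Surv(day, !censored) ~ genotype + induction,
    data = transform(rec,
                     genotype = factor(genotype, p$genotypes),
                     induction = factor(induction, p$inductions)))
  hr <- exp(stats::coef(fit))
  expect_equal(unname(hr[1]), 0.6, tolerance = 0.15)
  expect_equal(unname(hr[2]), 2.5, tolerance = 0.15 * 2.5)
})

test_that("censoring below all deaths censors every record", {
  p <- survival_sim_params(n_per_group = 50, censor_day = 1e-6, seed = 34)
  rec <- simulate_survival(p)
  expect_true(all(rec$censored))
  expect_true(all(rec$day == 1e-6))
})

test_that("survival simulator validates its parameters", {
  expect_error(survival_sim_params(n_per_group = 0), "n_per_group")
  expect_error(survival_sim_params(genotype_hr = 0), "hazard ratios")
  expect_error(survival_sim_params(genotypes = c("a", "a")), "distinct")
})

test_that("climbing simulator draws trinomial counts", {
  p <- climbing_sim_params(n_flies = 30, p_top = 1, p_middle = 0,
                           p_bottom = 0, n_trials = 5, seed = 41)
  d <- simulate_climbing(p)
  expect_true(all(d$n_top == 30 & d$n_middle == 0 & d$n_bottom == 0))

  expect_error(climbing_sim_params(n_flies = 0), "n_flies")
  expect_error(climbing_sim_params(p_top = 0.5, p_middle = 0.5,
                                   p_bottom = 0.5), "sum to 1")

  # per-bin frequencies converge at the binomial rate
  p <- climbing_sim_params(n_flies = 50, p_top = 0.2, p_middle = 0.5,
                           p_bottom = 0.3, n_trials = 400, seed = 42)
  d <- simulate_climbing(p)
  n_tot <- 50 * 400
  for (col in c("n_top", "n_middle", "n_bottom")) {
    prob <- c(n_top = 0.2, n_middle = 0.5, n_bottom = 0.3)[[col]]
    se <- sqrt(prob * (1 - prob) / n_tot)
    expect_lt(abs(sum(d[[col]]) / n_tot - prob), 4 * se)
  }
})

test_that("symmetric climbing bins give mean PI near 0.5", {
  p <- climbing_sim_params(n_flies = 50, n_trials = 1000, seed = 43)
  d <- simulate_climbing(p)
  pis <- performance_index(d)
  # PI = 0.5 + (X_top - X_bot)/(2 n); var = (p_t + p_b - (p_t - p_b)^2)/(4 n)
  mc_se <- sqrt((2 / 3) / (4 * 50) / 1000)
  expect_lt(abs(mean(pis) - 0.5), 3 * mc_se)
})

test_that("stack simulator produces the stated intensities and shifts", {
  p <- stack_sim_params(n_slices = 4, height = 16, width = 16,
                        roi_intensity = 90, background_intensity = 10,
                        noise_sd = 0, jitter_px = 0, seed = 51)
  sim <- simulate_stack(p)
  # all slices identical, ROI mean = roi + background
  expect_true(all(apply(sim$stack, 1, function(s) identical(s, sim$stack[1, , ]))))
  rq <- roi_mean_intensity(sim$stack, p$roi_mask)
  expect_equal(rq$overall_mean, 100)
  expect_true(all(sim$shifts$dy == 0 & sim$shifts$dx == 0))

  expect_error(stack_sim_params(roi_intensity = 5, background_intensity = 10),
               "background")
  expect_error(stack_sim_params(height = 8, width = 8,
                                roi_mask = matrix(TRUE, 4, 4)), "roi_mask")
})

test_that("registration recovers simulated jitter exactly at zero noise", {
  p <- stack_sim_params(n_slices = 6, height = 24, width = 24,
                        jitter_px = 3, noise_sd = 0, seed = 52)
  sim <- simulate_stack(p)
  reg <- register_frames(sim$stack, max_shift = 3)
  expect_identical(reg$shifts$dy, sim$shifts$dy)
  expect_identical(reg$shifts$dx, sim$shifts$dx)
})
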