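test_that("transition matrix is stochastic with the exact stationary law", {
  props <- c(N3 = 0.20, N2 = 0.475, N1 = 0.18, REM = 0.144)
  for (seff in c(0.5, 0.71, 0.9)) {
    P <- transition_matrix(seff, props)
    expect_equal(rowSums(P), rep(1, 5), ignore_attr = TRUE)
    expect_true(all(P >= 0))
    pi_s <- props[c("N1", "N2", "N3", "REM")] / sum(props)
    mu <- c(1 - seff, seff * pi_s)
    expect_equal(as.numeric(mu %*% P), mu, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  expect_error(transition_matrix(0.02, props), "infeasible")
})

test_that("simulated reference nights are reproducible and structured", {
  cfg <- cohort_config()
  a <- simulate_psg_hypnogram(cfg, 123)
  b <- simulate_psg_hypnogram(cfg, 123)
  expect_identical(a$psg$labels, b$psg$labels)
  expect_identical(a$ap_manual$t_start, b$ap_manual$t_start)
  expect_equal(a$psg$epoch_len, 30)
  expect_equal(a$psg$vocabulary, "FIVE")
  expect_equal(length(a$psg), cfg$trt_min * 2)
  # lights-off period sits inside the recording
  expect_gte(as.numeric(a$ap_manual$t_start), as.numeric(a$psg$start))
  expect_lte(as.numeric(a$ap_manual$t_end),
             as.numeric(hypnogram_end(a$psg)))
  # epochs outside lights-off are wake
  pre <- crop_to_period(a$psg, analysis_period(a$psg$start,
                                               a$ap_manual$t_start))
  expect_true(all(pre$labels == "W"))
})

test_that("generator hits its configured moments on a small cohort", {
  cfg <- cohort_config()
  res <- vapply(1:60, function(i) {
    nt <- simulate_psg_hypnogram(cfg, 7000 + i)
    s <- compute_summary(nt$psg, nt$ap_manual)
    hc <- crop_to_period(nt$psg, nt$ap_manual)
    n_sleep <- sum(hc$labels %in% c("N1", "N2", "N3", "REM"))
    c(s$seff_pct / 100, sum(hc$labels == "N3") / n_sleep, s$ap_min)
  }, numeric(3))
  expect_equal(mean(res[1, ]), 0.71, tolerance = 0.05)
  expect_equal(mean(res[2, ]), 0.20, tolerance = 0.04)
  expect_equal(mean(res[3, ]), 543, tolerance = 0.05)
})

test_that("a noiseless profile reproduces the reference stream", {
  cfg <- cohort_config(p_art = 0)
  ref <- simulate_psg_hypnogram(cfg, 55)
  dev <- simulate_device_hypnogram(ref$psg, ref$ap_manual,
                                   identity_profile(), seed = 1)
  expected <- crop_to_period(map_stages(ref$psg, "FOUR_DEFAULT"),
                             ref$ap_manual)
  expect_identical(dev$hypnogram$labels, expected$labels)
  expect_identical(dev$hypnogram$start, expected$start)
  expect_identical(dev$ap_auto$t_start, ref$ap_manual$t_start)
})

test_that("device corruption features behave as configured", {
  cfg <- cohort_config(p_art = 0)
  ref <- simulate_psg_hypnogram(cfg, 56)
  # clock lag shifts the claimed start
  lagged <- simulate_device_hypnogram(ref$psg, ref$ap_manual,
                                      identity_profile(lag_epochs = 4),
                                      seed = 2)
  expect_equal(as.numeric(difftime(lagged$hypnogram$start,
                                   ref$ap_manual$t_start, units = "secs")),
               120)
  ref4 <- map_stages(ref$psg, "FOUR_DEFAULT")
  al <- align_by_lag(ref4, lagged$hypnogram)
  expect_equal(al$lag_epochs, 4)
  expect_equal(al$concordance_at_lag, 1)
  # 60-s output halves the epoch count and upsamples back consistently
  dev60 <- simulate_device_hypnogram(ref$psg, ref$ap_manual,
                                     identity_profile(epoch_len = 60),
                                     seed = 3)
  expect_equal(dev60$hypnogram$epoch_len, 60)
  up <- upsample_to_30s(dev60$hypnogram)
  expect_equal(length(up), 2 * length(dev60$hypnogram))
  # ABSENT runs appear at high p_absent
  gappy <- simulate_device_hypnogram(ref$psg, ref$ap_manual,
                                     identity_profile(p_absent = 0.05),
                                     seed = 4)
  expect_gt(sum(gappy$hypnogram$labels == "ABSENT"), 0)
  # AP errors stretch the automatic period
  wide <- simulate_device_hypnogram(ref$psg, ref$ap_manual,
                                    identity_profile(ap_start_error_min = -30,
                                                     ap_end_error_min = 20),
                                    seed = 5)
  expect_gt(ap_minutes(wide$ap_auto), ap_minutes(ref$ap_manual))
})

test_that("run-length smoothing enforces the minimum run", {
  cfg <- cohort_config(p_art = 0)
  ref <- simulate_psg_hypnogram(cfg, 57)
  prof30 <- device_profile("wsa30", 30, device_profile_presets()$wsa$confusion,
                           smoothing_run = 3)
  dev30 <- simulate_device_hypnogram(ref$psg, ref$ap_manual, prof30,
                                     seed = 7)
  expect_true(all(rle(dev30$hypnogram$labels)$lengths >= 3))
})

test_that("cohorts are seed-deterministic with complete structure", {
  cfg <- cohort_config(n_subjects = 3)
  profs <- device_profile_presets()[c("wsa", "somnofy")]
  c1 <- simulate_cohort(cfg, profs, seed = 99)
  c2 <- simulate_cohort(cfg, profs, seed = 99)
  expect_length(c1, 3)
  for (i in 1:3) {
    expect_identical(c1[[i]]$psg$labels, c2[[i]]$psg$labels)
    expect_setequal(names(c1[[i]]$devices), c("wsa", "somnofy"))
    for (d in names(c1[[i]]$devices)) {
      expect_identical(c1[[i]]$devices[[d]]$hypnogram$labels,
                       c2[[i]]$devices[[d]]$hypnogram$labels)
    }
  }
  c3 <- simulate_cohort(cfg, profs, seed = 100)
  expect_false(identical(c1[[1]]$psg$labels, c3[[1]]$psg$labels))
})

test_that("EEG-enabled cohorts carry SWA summaries", {
  cfg <- cohort_config(n_subjects = 2, ap_min_mean = 60, ap_min_sd = 1,
                       trt_min = 70)
  coh <- simulate_cohort(cfg, list(ds = ds_coupling_profile()), seed = 5,
                         eeg = TRUE)
  for (nt in coh) {
    expect_s3_class(nt$swa, "swa_series")
    expect_true(is.finite(nt$mean_swa_nrem))
    expect_gt(nt$swa_multiplier, 0)
  }
})
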