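test_that("trial schedules have the exact block design", {
  s <- generate_trial_schedule(2, 120, seed = 7)
  expect_equal(nrow(s), 240)
  expect_equal(sum(s$compatibility == "compatible"), 160)
  expect_equal(sum(s$compatibility == "incompatible"), 80)
  # exact 2:1 within every block, for any block size divisible by 3
  for (tpb in c(12, 30, 120)) {
    s2 <- generate_trial_schedule(3, tpb, seed = 11)
    counts <- table(s2$block, s2$compatibility)
    expect_true(all(counts[, "compatible"] == 2 * counts[, "incompatible"]))
  }
  expect_true(all(s$rsi_ms >= 1400 & s$rsi_ms <= 1800))
  expect_true(all(s$flanker_onset_ms == -200))
  expect_true(all(s$response_deadline_ms == 450))
})

test_that("schedule generation is deterministic and validates input", {
  expect_identical(generate_trial_schedule(2, 60, seed = 3),
                   generate_trial_schedule(2, 60, seed = 3))
  expect_equal(nrow(generate_trial_schedule(0, 120, seed = 7)), 0)
  expect_error(generate_trial_schedule(-1, 120), "must be")
  expect_error(generate_trial_schedule(2, -5), "must be")
})

test_that("behavior follows the preset's reaction-time model", {
  p <- group_preset("ADD")
  s <- generate_trial_schedule(2, 120, seed = 1)

  # noise-free: every RT equals the condition mean, all responses correct
  p0 <- p
  p0$rt_within_sd[] <- 0
  subj <- draw_subjects(p0, n = 1, seed = 2)
  subj$accuracy_compatible <- 1
  subj$accuracy_incompatible <- 1
  b0 <- simulate_behavior(s, p0, seed = 3, subject = subj)
  comp <- s$compatibility == "compatible"
  expect_equal(unique(b0$rt_ms[comp]), subj$rt_mean_compatible)
  expect_equal(unique(b0$rt_ms[!comp]), subj$rt_mean_incompatible)
  expect_true(all(b0$correct))

  # determinism
  expect_identical(simulate_behavior(s, p, seed = 9),
                   simulate_behavior(s, p, seed = 9))

  # law of large numbers: grand means approach the preset's parameters
  subs <- draw_subjects(p, n = 150, seed = 4)
  rts <- vapply(seq_len(150), function(i) {
    b <- simulate_behavior(s, p, seed = 100 + i, subject = subs[i, ])
    c(mean(b$rt_ms[comp & b$correct]), mean(b$correct[comp]))
  }, numeric(2))
  expect_lt(abs(mean(rts[1, ], na.rm = TRUE) -
                  p$rt_mean["compatible"]), 15)
  expect_lt(abs(mean(rts[2, ]) - p$accuracy["compatible"]), 0.05)

  bad <- p
  bad$accuracy["compatible"] <- 1.4
  expect_error(simulate_behavior(s, bad, seed = 1), "\\[0, 1\\]")
  expect_error(simulate_behavior(s[0, ], p, seed = 1), "empty")
})

test_that("noise-free epochs are the exact sum of placed kernels", {
  p <- group_preset("ADD")
  p$rt_within_sd[] <- 0
  p$rt_cond_sd <- 0
  subj <- draw_subjects(p, n = 1, seed = 5)
  subj$c_jitter_sd <- 0
  subj$c_latency <- 530
  subj$c_amp_compatible <- 30
  # single fully deterministic template set (no subject amplitude factors)
  tpl <- list(
    a = component_template("S_N1t", 270, 50, -7, c(P9 = 1, Pz = 0.5),
                           "stimulus", 0),
    C = component_template("C", 0, 110, 1, c(Pz = 1, Cz = 0.5),
                           "estimated", 0)
  )
  s <- generate_trial_schedule(1, 6, seed = 6)
  b <- simulate_behavior(s, p, seed = 7, subject = subj)
  ep <- simulate_epochs(s, b, p, templates = tpl, seed = 8,
                        subject = subj, noise_level = 0)
  comp <- s$compatibility == "compatible"
  amp_c <- ifelse(comp, subj$c_amp_compatible, subj$c_amp_incompatible) /
    jride:::c_pipeline_gain()
  # conditions share RT here, so condition-centered coupling drops out;
  # at Pz (channel 6) the trial is exactly 0.5*N1t + 1*C
  for (i in c(1, 4)) {
    expected <- 0.5 * component_kernel(ep$time_ms, 270, 50, -7) +
      1 * component_kernel(ep$time_ms, subj$c_latency, 110, amp_c[i])
    expect_equal(ep$data[i, 6, ], expected, tolerance = 1e-12)
  }
  # P9 carries only the visual component
  expect_equal(ep$data[1, 7, ], component_kernel(ep$time_ms, 270, 50, -7),
               tolerance = 1e-12)
})

test_that("epoch simulation is deterministic and carries ground truth", {
  p <- group_preset("ADD")
  s <- generate_trial_schedule(1, 12, seed = 2)
  b <- simulate_behavior(s, p, seed = 3)
  e1 <- simulate_epochs(s, b, p, seed = 4)
  e2 <- simulate_epochs(s, b, p, seed = 4)
  expect_identical(e1$data, e2$data)
  expect_equal(nrow(e1$meta), 12)
  expect_true(all(is.finite(e1$truth$lc_true)))
  expect_equal(diff(e1$time_ms)[1], 1000 / 256)
  expect_lt(max(abs(diff(e1$time_ms) - 1000 / 256)), 1e-9)
})

test_that("latency jitter smears the conventional average", {
  # numerical oracle: the average under jitter is the kernel convolved
  # with the latency distribution, so its peak must shrink as jitter grows
  tm <- seq(-500, 1500, by = 1000 / 256)
  kern <- function(lat) component_kernel(tm, lat, 110, 30)
  set.seed(42)
  peaks <- vapply(c(0, 40, 80, 120), function(js) {
    lats <- 530 + rnorm(4000, 0, js)
    max(colMeans(t(vapply(lats, kern, numeric(length(tm))))))
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
  # same effect in the simulator itself (noise-free)
  zj <- zero_jitter_setup(c_amp = 35)
  avg0 <- colMeans(zj$epochs$data)[6, ]  # Pz
  subj <- zj$subject
  subj$c_jitter_sd <- 80
  epj <- simulate_epochs(zj$schedule, zj$behavior, zj$preset,
                         templates = default_templates(jitter_scale = 0),
                         seed = 7, subject = subj, noise_level = 0)
  avgj <- colMeans(epj$data)[6, ]
  # compare beyond the stimulus-locked components' support so only the
  # intermediate component contributes
  cw <- jride:::window_index(zj$epochs$time_ms, c(420, 900))
  expect_lt(max(avgj[cw]), max(avg0[cw]))
})

test_that("built-in presets match the study cohorts", {
  expect_equal(group_preset("ADD")$n_subjects, 25)
  expect_equal(group_preset("ADHD-C")$n_subjects, 34)
  expect_error(group_preset("ADHD-H"), "unknown preset")
  p <- group_preset("ADHD-C")
  expect_true(all(p$accuracy >= 0 & p$accuracy <= 1))
  expect_true(all(p$c_amp_sd >= 0))
})
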