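srate <- 256
dt <- 1000 / srate

test_that("component extraction realigns, medians, and windows trials", {
  tm <- -500 + (0:511) * dt
  base <- outer(c(1, 0.5, 0.2, 0, 0, 0, 0, 0, 0),
                component_kernel(tm, 100, 60, 10))
  # identical trials at zero lag reproduce the trial inside the window
  dat <- array(0, dim = c(3, 9, 512))
  for (i in 1:3) dat[i, , ] <- base
  out <- extract_component(dat, rep(0, 3), c(-100, 400), tm, srate,
                           ref_ms = 0, taper_fraction = 0)
  idx <- jride:::window_index(tm, c(-100, 400))
  expect_equal(out[, idx], base[, idx], tolerance = 1e-12)
  expect_true(all(out[, -idx] == 0))

  # trials shifted by known lags are realigned back onto the template
  lags_ms <- c(-40, 0, 28, -12, 60)
  dat2 <- array(0, dim = c(5, 9, 512))
  for (i in 1:5)
    dat2[i, , ] <- outer(c(1, 0.5, 0.2, rep(0, 6)),
                         component_kernel(tm, 100 + lags_ms[i], 60, 10))
  out2 <- extract_component(dat2, 100 + lags_ms, c(-100, 400), tm, srate,
                            ref_ms = 100, taper_fraction = 0)
  expect_lt(max(abs(out2[, idx] - base[, idx])), 0.05)

  # the median resists a grossly corrupted trial where a mean would not
  dat3 <- dat2
  dat3[3, , ] <- dat3[3, , ] + 500
  out3 <- extract_component(dat3, 100 + lags_ms, c(-100, 400), tm, srate,
                            ref_ms = 100, taper_fraction = 0)
  mean_based <- apply(dat3, c(2, 3), mean)
  expect_lt(max(abs(out3[, idx] - base[, idx])), 0.06)
  expect_gt(max(abs(mean_based[, idx] - base[, idx])), 50)

  expect_error(extract_component(dat, rep(NA_real_, 3), c(-100, 400), tm,
                                 srate, cluster = "C"),
               "all latencies missing for the C")
})

test_that("latency estimation matches an exhaustive brute-force search", {
  # oracle: independent R implementation of the same objective
  # (channel-summed lagged inner product, moving-average smoothing,
  # argmax with ties toward the smallest absolute lag)
  brute <- function(trial, tmpl, lmin, lmax, hw) {
    nz <- which(colSums(abs(tmpl)) > 0)
    lags <- lmin:lmax
    r <- vapply(lags, function(L) {
      s <- 0
      for (j in nz) {
        pos <- j + L
        if (pos >= 1 && pos <= ncol(trial))
          s <- s + sum(trial[, pos] * tmpl[, j])
      }
      s
    }, numeric(1))
    rs <- vapply(seq_along(r), function(i) {
      a <- max(1, i - hw); b <- min(length(r), i + hw)
      mean(r[a:b])
    }, numeric(1))
    best <- which(abs(rs - max(rs)) <= 1e-12)
    lags[best[which.min(abs(lags[best]))]]
  }
  set.seed(11)
  for (rep in 1:12) {
    n_s <- sample(32:64, 1)
    n_ch <- sample(2:4, 1)
    tmpl <- matrix(0, n_ch, n_s)
    ctr <- sample(12:(n_s - 12), 1)
    sup <- max(1, ctr - 8):min(n_s, ctr + 8)
    tmpl[, sup] <- matrix(rnorm(n_ch * length(sup)), n_ch)
    trial <- matrix(rnorm(n_ch * n_s), n_ch, n_s)
    lmin <- -8L; lmax <- 8L; hw <- 1L
    got <- jride:::cpp_best_lags(
      array(trial, dim = c(1, n_ch, n_s)), tmpl,
      min(sup) - 1L, max(sup) - 1L, 0, lmin, lmax, hw, TRUE)
    expect_equal(got[1], brute(trial, tmpl, lmin, lmax, hw))
  }
})

test_that("latency estimation recovers known shifts", {
  tm <- -500 + (0:511) * dt
  tmpl <- outer(c(1, 0.4, rep(0, 7)), component_kernel(tm, 200, 80, 10))
  shifted <- outer(c(1, 0.4, rep(0, 7)),
                   component_kernel(tm, 250, 80, 10))
  est <- estimate_c_latency(shifted, tmpl, c(-300, 300), srate)
  expect_lt(abs(est - 50), dt + 1e-9)
  expect_equal(estimate_c_latency(tmpl, tmpl, c(-300, 300), srate), 0)
  expect_error(estimate_c_latency(tmpl, tmpl * 0, c(-300, 300), srate),
               "zero template")
})

test_that("noisy shifted templates are recovered with r >= 0.8", {
  set.seed(21)
  tm <- -500 + (0:511) * dt
  topo <- c(1, 0.5, 0.3, rep(0, 6))
  n_tr <- 200
  shifts <- rnorm(n_tr, 0, 60)
  tmpl <- outer(topo, component_kernel(tm, 200, 80, 8))
  est <- vapply(seq_len(n_tr), function(i) {
    trial <- outer(topo, component_kernel(tm, 200 + shifts[i], 80, 8)) +
      matrix(rnorm(9 * 512, sd = 8), 9)  # SNR ~ 1 at the peak channel
    estimate_c_latency(trial, tmpl, c(-300, 300), srate)
  }, numeric(1))
  expect_gt(cor(shifts, est), 0.8)
})

test_that("zero-jitter decomposition reduces to the conventional average", {
  zj <- zero_jitter_setup(c_amp = 35, n_trials = 24)
  ep <- subset_trials(zj$epochs, zj$epochs$meta$compatibility ==
                        "compatible")
  avg <- colMeans(ep$data)
  dec <- suppressWarnings(ride_decompose(ep, ride_config(max_iter = 30)))
  pz <- 6
  # inside the central window, past the stimulus components' support,
  # the C cluster carries the average exactly
  iw <- jride:::window_index(ep$time_ms, c(240, 860))
  peak <- max(abs(avg[pz, ]))
  expect_lt(max(abs(dec$C[pz, iw] - avg[pz, iw])), 0.02 * peak)
  # reconstruction closes the loop
  rec <- reconstruct(dec)
  expect_lt(max(abs(rec - avg)), 0.05 * peak)
  # config is echoed and the latency bounds hold
  expect_identical(dec$config$c_window_ms, c(200, 900))
  expect_true(all(dec$lc >= 200 & dec$lc <= 900))
  expect_true(all(is.finite(dec$convergence_trace)))
})

test_that("decomposition separates jittered components and recovers latencies", {
  p <- group_preset("ADD")
  subj <- draw_subjects(p, n = 1, seed = 31)
  subj$c_amp_compatible <- 40
  subj$c_amp_incompatible <- 45
  ep <- sim_subject_epochs(p, subj, seed = 300, trials_per_block = 60)
  sel <- ep$meta$compatibility == "compatible" & ep$meta$correct
  sub <- subset_trials(ep, sel)
  sub <- bandpass_filter(sub)
  sub <- csd_transform(sub)
  sub <- epoch_and_baseline(sub)
  dec <- suppressWarnings(ride_decompose(sub, ride_config(max_iter = 10)))
  r <- cor(sub$truth$lc_true, dec$lc)
  expect_gt(r, 0.7)
  # converged or stopped at the cap, trace finite either way
  expect_true(all(is.finite(dec$convergence_trace)))
  if (dec$converged)
    expect_lt(tail(dec$convergence_trace, 1), dec$config$tol)
})

test_that("trials without a usable response are dropped from R only", {
  zj <- zero_jitter_setup(n_trials = 12)
  ep <- zj$epochs
  ep$meta$rt_ms[1:3] <- NA
  expect_message(
    dec <- suppressWarnings(ride_decompose(ep, ride_config(max_iter = 5))),
    "excluded from R")
  expect_equal(sum(is.finite(dec$lr)), nrow(ep$meta) - 3)
  expect_equal(length(dec$lc), nrow(ep$meta))
})
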