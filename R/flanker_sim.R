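#' Generate a flanker-task trial schedule
#'
#' Blocks of trials with an exact 2:1 compatible:incompatible split per
#' block (the 67%/33% design read as an exact ratio), pseudo-randomized
#' order, flankers preceding the target by 200 ms, 300 ms target duration,
#' a 450 ms response deadline and response-stimulus intervals drawn
#' uniformly from 1400-1800 ms.
#'
#' @param n_blocks number of blocks (default 2).
#' @param trials_per_block trials per block (default 120).
#' @param seed integer seed (optional).
#' @return data.frame with one row per trial: `trial_index`, `block`,
#'   `compatibility`, `target_direction`, `flanker_onset_ms`,
#'   `target_duration_ms`, `rsi_ms`, `response_deadline_ms`.
#' @export
generate_trial_schedule <- function(n_blocks = 2, trials_per_block = 120,
                                    seed = NULL) {
  stopifnot_scalar(n_blocks, "n_blocks", lower = 0)
  stopifnot_scalar(trials_per_block, "trials_per_block", lower = 0)
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  empty <- data.frame(trial_index = integer(), block = integer(),
                      compatibility = character(),
                      target_direction = character(),
                      flanker_onset_ms = numeric(),
                      target_duration_ms = numeric(), rsi_ms = numeric(),
                      response_deadline_ms = numeric(),
                      stringsAsFactors = FALSE)
  if (n_blocks == 0L || trials_per_block == 0L) return(empty)
  with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      n_inc <- round(trials_per_block / 3)
      n_comp <- trials_per_block - n_inc
      comp <- sample(c(rep("compatible", n_comp),
                       rep("incompatible", n_inc)))
      data.frame(
        block = b,
        compatibility = comp,
        target_direction = sample(c("left", "right"), trials_per_block,
                                  replace = TRUE),
        flanker_onset_ms = -200,
        target_duration_ms = 300,
        rsi_ms = runif(trials_per_block, 1400, 1800),
        response_deadline_ms = 450,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, blocks)
    out <- cbind(trial_index = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}

#' Simulate single-subject flanker behavior
#'
#' Reaction times follow a shifted lognormal per condition: the lognormal
#' part has mean (subject's condition mean - shift) and SD equal to the
#' condition's within-subject RT SD, so simulated within-subject variability
#' matches the preset by construction. Correctness is Bernoulli with the
#' subject's per-condition accuracy; responses slower than the deadline are
#' retained (the task signals them with a warning tone but they remain
#' valid responses).
#'
#' @param schedule a trial schedule from [generate_trial_schedule()].
#' @param preset a [group_preset()]; used both for validation and, when
#'   `subject` is NULL, to draw a single subject's parameters.
#' @param seed integer seed (optional).
#' @param subject optional single-row data.frame from [draw_subjects()].
#' @return data.frame with `trial_index`, `rt_ms` (NA for omissions) and
#'   `correct`.
#' @export
simulate_behavior <- function(schedule, preset, seed = NULL,
                              subject = NULL) {
  if (nrow(schedule) == 0L) stop("schedule is empty")
  if (any(preset$accuracy < 0 | preset$accuracy > 1) ||
      any(preset$omission_rate < 0 | preset$omission_rate > 1))
    stop("preset probabilities must lie in [0, 1]")
  with_seed(seed, {
    if (is.null(subject)) subject <- draw_subjects(preset, n = 1)
    n <- nrow(schedule)
    cond <- schedule$compatibility
    m <- ifelse(cond == "compatible", subject$rt_mean_compatible,
                subject$rt_mean_incompatible)
    s <- unname(preset$rt_within_sd[cond])
    acc <- ifelse(cond == "compatible", subject$accuracy_compatible,
                  subject$accuracy_incompatible)
    shift <- preset$rt_shift
    mu_ln <- pmax(m - shift, 30)
    if (all(s == 0)) {
      rt <- shift + mu_ln
    } else {
      sig2 <- log(1 + (s / mu_ln)^2)
      rt <- shift + exp(rnorm(n, log(mu_ln) - sig2 / 2, sqrt(sig2)))
    }
    correct <- rbinom(n, 1, acc) == 1
    if (preset$omission_rate > 0) {
      omit <- runif(n) < preset$omission_rate
      rt[omit] <- NA_real_
      correct[omit] <- FALSE
    }
    data.frame(trial_index = schedule$trial_index, rt_ms = rt,
               correct = correct, stringsAsFactors = FALSE)
  })
}

#' Epoch container
#'
#' Single-trial epochs with a uniform time axis, montage and per-trial
#' metadata; the common currency of the pipeline.
#'
#' @param data trial x channel x time array.
#' @param srate_hz sampling rate (Hz).
#' @param time_ms time axis (ms relative to target onset); must be uniform
#'   with step 1000/srate_hz.
#' @param channels montage data.frame from [default_montage()].
#' @param meta per-trial data.frame (subject, group, compatibility, rt_ms,
#'   correct, retained).
#' @param truth optional per-trial ground-truth latency table, carried only
#'   so that simulations can be scored; the decomposition never receives it.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, srate_hz, time_ms, channels, meta,
                      truth = NULL) {
  stopifnot(length(dim(data)) == 3L)
  if (any(!is.finite(data))) stop("epoch data must be finite")
  dt <- 1000 / srate_hz
  if (length(time_ms) != dim(data)[3] ||
      max(abs(diff(time_ms) - dt)) > 1e-6)
    stop("time_ms must be uniform with step 1000/srate_hz")
  if (nrow(meta) != dim(data)[1])
    stop("meta must have one row per trial")
  if (nrow(channels) != dim(data)[2])
    stop("channels must have one row per channel")
  if (is.null(meta$retained)) meta$retained <- TRUE
  structure(list(data = data, srate_hz = srate_hz, time_ms = time_ms,
                 channels = channels, meta = meta, truth = truth),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$srate_hz))
  cat(sprintf("  time %g..%g ms; %d retained\n", min(x$time_ms),
              max(x$time_ms), sum(x$meta$retained)))
  invisible(x)
}

#' Subset an epoch set by trial
#' @param epochs an [epoch_set()].
#' @param keep logical or integer trial index.
#' @return epoch_set with the selected trials.
#' @export
subset_trials <- function(epochs, keep) {
  idx <- if (is.logical(keep)) which(keep) else keep
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$srate_hz,
            epochs$time_ms, epochs$channels,
            epochs$meta[idx, , drop = FALSE],
            if (!is.null(epochs$truth)) epochs$truth[idx, , drop = FALSE])
}

# 1/f ("pink") noise via spectral shaping of white Gaussian noise,
# standardized to unit RMS; m independent columns of length n.
pink_noise <- function(n, m = 1) {
  w <- matrix(rnorm(n * m), n, m)
  f <- stats::mvfft(w)
  k <- c(1, seq_len(n - 1))
  k <- pmin(k, n - k + 1)  # two-sided frequency index
  x <- Re(stats::mvfft(f / sqrt(k), inverse = TRUE)) / n
  x <- sweep(x, 2, apply(x, 2, sd), "/")
  if (m == 1) drop(x) else x
}

# Background EEG for a block of trials: per trial, a handful of spatially
# smooth sources (spherical-Gaussian topographies at random orientations)
# carrying mixed pink + white traces (3:1 power), plus a small independent
# sensor-noise floor. Spatial smoothness matters: the surface Laplacian
# amplifies channel-independent noise far more than physiological,
# volume-conducted activity. Returns a trial x channel x sample array.
noise_block <- function(pos, n_tr, n_s, noise_level, n_sources = 8,
                        source_width = 0.8, sensor_frac = 0.05) {
  n_ch <- nrow(pos)
  m <- n_tr * n_sources
  # random source orientations for every trial at once
  v <- matrix(rnorm(3 * m), m, 3)
  v <- v / sqrt(rowSums(v^2))
  ang <- acos(pmin(pmax(v %*% t(pos), -1), 1))  # m x n_ch
  topo <- exp(-(ang / source_width)^2 / 2)
  sensor_rms <- sensor_frac * noise_level
  src_var <- noise_level^2 - sensor_rms^2
  # normalize so the average per-channel source variance equals src_var
  topo <- topo * sqrt(src_var / (sum(topo^2) / (n_tr * n_ch)))
  # traces: n_s x m, pink + white mixed
  traces <- sqrt(3 / 4) * pink_noise(n_s, m) +
    sqrt(1 / 4) * matrix(rnorm(n_s * m), n_s, m)
  out <- array(0, dim = c(n_tr, n_ch, n_s))
  for (i in seq_len(n_tr)) {
    cols <- (i - 1) * n_sources + seq_len(n_sources)
    out[i, , ] <- t(topo[cols, , drop = FALSE]) %*% t(traces[, cols,
                                                             drop = FALSE])
  }
  out + array(rnorm(n_tr * n_ch * n_s, 0, sensor_rms),
              dim = c(n_tr, n_ch, n_s))
}

#' Simulate single-trial EEG epochs for one subject
#'
#' Each trial is the sum of the component templates placed at their
#' per-trial latencies — stimulus-locked components at their nominal peak
#' plus Gaussian jitter, the intermediate C component at the subject's
#' latency plus reaction-time coupling plus jitter, the motor component at
#' the response — plus mixed 1/f and white noise (3:1 power ratio). The
#' true per-trial C latency is stored in `$truth` for scoring; the
#' decomposition itself never reads it.
#'
#' @param schedule trial schedule.
#' @param behavior matching behavior records.
#' @param preset a [group_preset()].
#' @param templates template list from [default_templates()].
#' @param seed integer seed (optional).
#' @param subject single-row data.frame from [draw_subjects()]; drawn from
#'   the preset when NULL.
#' @param montage montage data.frame.
#' @param srate_hz sampling rate (default 256).
#' @param tmin_ms,tmax_ms epoch limits relative to target onset.
#' @param noise_level per-channel noise RMS in microvolts; defaults to the
#'   preset's value.
#' @return an [epoch_set()].
#' @export
simulate_epochs <- function(schedule, behavior, preset,
                            templates = default_templates(), seed = NULL,
                            subject = NULL, montage = default_montage(),
                            srate_hz = 256, tmin_ms = -2000,
                            tmax_ms = 2000,
                            noise_level = preset$noise_level) {
  if (nrow(schedule) != nrow(behavior))
    stop("behavior must align with schedule")
  with_seed(seed, {
    if (is.null(subject)) subject <- draw_subjects(preset, n = 1)
    n_tr <- nrow(schedule)
    dt <- 1000 / srate_hz
    n_s <- round((tmax_ms - tmin_ms) / dt)
    time_ms <- tmin_ms + (seq_len(n_s) - 1) * dt
    n_ch <- nrow(montage)
    dat <- array(0, dim = c(n_tr, n_ch, n_s))
    cond <- schedule$compatibility
    rt <- behavior$rt_ms
    mean_rt <- mean(rt, na.rm = TRUE)
    truth <- data.frame(trial_index = schedule$trial_index,
                        lc_true = NA_real_, lr_true = rt)
    gain <- c_pipeline_gain()
    for (tp in templates) {
      w <- topo_on_montage(tp, montage)
      if (all(w == 0)) next
      # subject-level amplitude factor (mean-preserving lognormal)
      sfac <- if (tp$amp_cv > 0) {
        sig <- sqrt(log(1 + tp$amp_cv^2))
        exp(rnorm(1, -sig^2 / 2, sig))
      } else 1
      if (tp$locking == "stimulus") {
        lat <- tp$peak_ms +
          if (tp$jitter_sd_ms > 0) rnorm(n_tr, 0, tp$jitter_sd_ms) else 0
        amp <- sfac * template_amp(tp, cond)
      } else if (tp$locking == "estimated") {
        # right-skewed trial-to-trial latency jitter (zero-mean shifted
        # lognormal, left-bounded): late-latency decision components
        # straggle rightward but cannot precede the evidence, so the
        # conventional average smears asymmetrically away from early
        # fixed windows
        jit <- if (subject$c_jitter_sd > 0) {
          sig <- 0.75
          mu_ln <- subject$c_jitter_sd / sqrt(exp(sig^2) - 1)
          # median-zero: half the trials peak at the subject's latency or
          # earlier, so the realigned waveform centers on c_latency
          exp(rnorm(n_tr, log(mu_ln) - sig^2 / 2, sig)) -
            mu_ln * exp(-sig^2 / 2)
        } else 0
        # coupling is centered within condition: conditions differ in
        # speed, not in where the decision process sits relative to its
        # own typical reaction time
        rt0 <- ifelse(is.na(rt), ave(rt, cond, FUN = function(z)
          mean(z, na.rm = TRUE)), rt)
        lat <- subject$c_latency +
          preset$rt_coupling * (rt0 - ave(rt0, cond)) + jit
        amp <- ifelse(cond == "compatible", subject$c_amp_compatible,
                      subject$c_amp_incompatible) / gain
        truth$lc_true <- lat
      } else {
        lat <- rt + tp$peak_ms
        amp <- sfac * template_amp(tp, cond)
      }
      lat <- rep_len(lat, n_tr)
      amp <- rep_len(amp, n_tr)
      ok <- !is.na(lat)  # omissions carry no response-locked component
      if (!any(ok)) next
      # trial x sample kernel matrix in one vectorized sweep
      K <- matrix(0, n_tr, n_s)
      u <- outer(lat[ok], time_ms, function(l, t) (t - l) / tp$width_ms)
      K[ok, ] <- amp[ok] * kernel_shape(u)
      for (ci in which(w != 0))
        dat[, ci, ] <- dat[, ci, ] + w[ci] * K
    }
    if (noise_level > 0) {
      pos <- as.matrix(montage[, c("x", "y", "z")])
      pos <- pos / sqrt(rowSums(pos^2))
      dat <- dat + noise_block(pos, n_tr, n_s, noise_level)
    }
    meta <- data.frame(subject = subject$subject, group = subject$group,
                       compatibility = cond, rt_ms = rt,
                       correct = behavior$correct, retained = TRUE,
                       stringsAsFactors = FALSE)
    epoch_set(dat, srate_hz, time_ms, montage, meta, truth)
  })
}

#' Simulate behavior for a whole cohort
#'
#' Draws the cohort's subject parameters and simulates each subject's full
#' trial schedule and responses.
#'
#' @param preset a [group_preset()].
#' @param n number of subjects (defaults to the preset's cohort size).
#' @param seed integer seed.
#' @param n_blocks,trials_per_block schedule dimensions (defaults: the
#'   task's 2 x 120).
#' @return data.frame with one row per trial: `subject`, `group`,
#'   `condition`, `trial_index`, `rt_ms`, `correct`.
#' @export
cohort_behavior <- function(preset, n = preset$n_subjects, seed = NULL,
                            n_blocks = 2, trials_per_block = 120) {
  subs <- draw_subjects(preset, n = n, seed = child_seed(seed, 11))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sch <- generate_trial_schedule(n_blocks, trials_per_block,
                                   seed = child_seed(seed, 20 + 2 * i))
    b <- simulate_behavior(sch, preset, seed = child_seed(seed, 21 + 2 * i),
                           subject = subs[i, ])
    b$condition <- sch$compatibility
    b$subject <- i
    b$group <- preset$group
    out[[i]] <- b
  }
  do.call(rbind, out)[, c("subject", "group", "condition", "trial_index",
                          "rt_ms", "correct")]
}
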