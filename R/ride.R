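#' Decomposition configuration
#'
#' Windows, tolerances and iteration limits for the residue-iteration
#' decomposition. Windows follow the standard choice for this paradigm:
#' -200..600 ms around the target for the stimulus cluster, 200..900 ms for
#' the central cluster and +/-300 ms around the response for the motor
#' cluster; iteration stops when the component waveforms change by less
#' than `tol` (max absolute change normalized by their RMS) between two
#' successive iterations.
#'
#' @param s_window_ms stimulus-cluster window (ms relative to target).
#' @param c_window_ms central-cluster window (ms relative to target).
#' @param r_window_ms motor-cluster window (ms relative to the response).
#' @param tol convergence tolerance (default 1e-3).
#' @param max_iter maximum iterations (default 100).
#' @param c_latency_search_ms search range for the per-trial C latency,
#'   relative to the current estimate (default +/-300 ms).
#' @param taper_fraction cosine-taper fraction of the extraction window
#'   (Tukey alpha; default 0.1).
#' @param xcorr_smooth_ms moving-average width applied to the lag
#'   cross-correlation curve before the argmax (default 20 ms).
#' @param latency_prior_weight weight of the quadratic penalty pulling
#'   per-trial latency estimates toward their reaction-time-proportional
#'   prediction, applied to the SD-standardized correlation curve
#'   (maximum-a-posteriori estimation). A clear correlation peak overrides
#'   the prior; trials without usable component signal fall back toward
#'   the prediction instead of a noise-driven argmax. 0 disables it.
#' @return list of class `ride_config`.
#' @export
ride_config <- function(s_window_ms = c(-200, 600),
                        c_window_ms = c(200, 900),
                        r_window_ms = c(-300, 300), tol = 1e-3,
                        max_iter = 100,
                        c_latency_search_ms = c(-300, 300),
                        taper_fraction = 0.1, xcorr_smooth_ms = 20,
                        latency_prior_weight = 4) {
  if (s_window_ms[1] >= s_window_ms[2] || c_window_ms[1] >= c_window_ms[2] ||
      r_window_ms[1] >= r_window_ms[2])
    stop("windows must be nonempty increasing intervals")
  if (tol <= 0) stop("tol must be > 0")
  if (taper_fraction < 0 || taper_fraction >= 0.5)
    stop("taper_fraction must lie in [0, 0.5)")
  structure(list(s_window_ms = s_window_ms, c_window_ms = c_window_ms,
                 r_window_ms = r_window_ms, tol = tol,
                 max_iter = max_iter,
                 c_latency_search_ms = c_latency_search_ms,
                 taper_fraction = taper_fraction,
                 xcorr_smooth_ms = xcorr_smooth_ms,
                 latency_prior_weight = latency_prior_weight),
            class = "ride_config")
}

# Tukey (cosine-tapered) window over sample indices idx of total length n.
tukey_window <- function(n, alpha) {
  if (n == 1L) return(1)
  w <- rep(1, n)
  ntap <- floor(alpha * (n - 1) / 2)
  if (ntap > 0) {
    i <- seq_len(ntap)
    ramp <- 0.5 * (1 - cos(pi * i / (ntap + 1)))
    w[i] <- ramp
    w[n + 1 - i] <- ramp
  }
  w
}

#' Extract a component cluster as a latency-aligned median waveform
#'
#' Aligns every trial's residual to its latency, takes the per-timepoint,
#' per-channel median across trials, and applies a cosine-tapered window
#' over the requested interval (zero outside). The median makes the
#' estimate robust to occasional outlier trials.
#'
#' @param trial_residuals trial x channel x time array.
#' @param latencies_ms per-trial latencies (ms on the epoch time axis); NA
#'   excludes the trial.
#' @param window_ms extraction window (ms, on the epoch axis).
#' @param time_ms epoch time axis.
#' @param srate_hz sampling rate.
#' @param ref_ms the latency that maps to its own position in the output
#'   (default: median of `latencies_ms`); trials are shifted by
#'   (latency - ref).
#' @param taper_fraction Tukey alpha (default 0.1).
#' @param cluster name used in error messages.
#' @return channel x time waveform (zero outside the window).
#' @export
extract_component <- function(trial_residuals, latencies_ms, window_ms,
                              time_ms, srate_hz,
                              ref_ms = stats::median(latencies_ms,
                                                     na.rm = TRUE),
                              taper_fraction = 0.1, cluster = "component") {
  use <- is.finite(latencies_ms)
  if (!any(use))
    stop("all latencies missing for the ", cluster, " cluster")
  dt <- 1000 / srate_hz
  lags <- (latencies_ms - ref_ms) / dt
  lags[!use] <- 0
  med <- cpp_align_median(trial_residuals, lags, use)
  idx <- window_index(time_ms, window_ms)
  if (!length(idx))
    stop("window outside the epoch for the ", cluster, " cluster")
  out <- matrix(0, nrow(med), ncol(med))
  out[, idx] <- med[, idx, drop = FALSE] *
    rep(tukey_window(length(idx), taper_fraction), each = nrow(med))
  out
}

#' Estimate the latency of the central component in one trial
#'
#' Slides the current C template over the residual and returns the lag
#' maximizing the channel-summed cross-correlation within the search
#' interval; the lag curve is smoothed with a short moving average before
#' the argmax and ties are broken toward the smallest absolute lag.
#'
#' @param trial_residual channel x time matrix (one trial).
#' @param c_template channel x time template (same axes).
#' @param search_ms search interval around zero lag (default +/-300).
#' @param srate_hz sampling rate.
#' @param smooth_ms smoothing width (default 20 ms).
#' @return estimated lag in ms (grid-aligned).
#' @export
estimate_c_latency <- function(trial_residual, c_template,
                               search_ms = c(-300, 300), srate_hz,
                               smooth_ms = 20) {
  if (all(c_template == 0)) stop("zero template")
  dt <- 1000 / srate_hz
  dat <- array(0, dim = c(1, nrow(trial_residual), ncol(trial_residual)))
  dat[1, , ] <- trial_residual
  nz <- which(colSums(abs(c_template)) > 0)
  lag <- cpp_best_lags(dat, c_template, min(nz) - 1L, max(nz) - 1L,
                       0, as.integer(floor(search_ms[1] / dt)),
                       as.integer(ceiling(search_ms[2] / dt)),
                       as.integer(round(smooth_ms / dt / 2)), TRUE)
  lag[1] * dt
}

#' Residue iteration decomposition into S, C and R clusters
#'
#' Iteratively estimates three component clusters from single-trial
#' epochs: a stimulus-locked cluster (latency fixed at 0), a response-locked
#' cluster (latency = reaction time) and a central cluster whose per-trial
#' latency is estimated and refined by template cross-correlation. Each
#' cluster is obtained as the latency-aligned median of the residual after
#' subtracting the other two (each placed at its own per-trial latency).
#' The central cluster is initialized from the average aligned to
#' reaction-time-proportional initial latencies; iteration stops when the
#' concatenated waveforms change by less than `tol` (max absolute change /
#' RMS).
#'
#' Trials whose response falls outside the epoch (or is missing) are
#' excluded from the motor-cluster estimation but retained for S and C.
#' Only retained trials are used; ground-truth simulation latencies are
#' never consulted.
#'
#' @param epochs an [epoch_set()] (retained trials are used).
#' @param config a [ride_config()].
#' @param estimate_r estimate the motor cluster (default TRUE).
#' @return object of class `ride_result`: `S`, `C`, `R` channel x time
#'   waveforms, latencies `ls`, `lr`, `lc` (ms), reference latencies
#'   `ref_c`, `ref_r`, `n_iterations`, `converged`, `convergence_trace`,
#'   `time_ms`, `config`.
#' @export
ride_decompose <- function(epochs, config = ride_config(),
                           estimate_r = TRUE) {
  if (any(!is.finite(epochs$data))) stop("epoch data must be finite")
  keep <- epochs$meta$retained
  if (!all(keep)) epochs <- subset_trials(epochs, keep)
  d <- dim(epochs$data)
  n_tr <- d[1]
  if (n_tr < 1) stop("no retained trials")
  time_ms <- epochs$time_ms
  dt <- 1000 / epochs$srate_hz
  dat <- epochs$data
  rt <- epochs$meta$rt_ms
  all_true <- rep(TRUE, n_tr)

  # response-locked bookkeeping
  r_ok <- is.finite(rt) &
    (rt + config$r_window_ms[1]) >= min(time_ms) &
    (rt + config$r_window_ms[2]) <= max(time_ms)
  do_r <- estimate_r && any(r_ok)
  if (estimate_r && !all(r_ok) && any(r_ok))
    message(sum(!r_ok), " trial(s) excluded from R estimation ",
            "(response missing or outside the epoch)")
  lr <- ifelse(r_ok, rt, NA_real_)
  ref_r <- if (do_r) stats::median(lr, na.rm = TRUE) else NA_real_
  r_window_abs <- if (do_r) config$r_window_ms + ref_r else NULL

  # RT-proportional initial C latencies, clipped to the C window
  c_mid <- mean(config$c_window_ms)
  rt0 <- ifelse(is.finite(rt), rt, mean(rt, na.rm = TRUE))
  if (all(!is.finite(rt))) rt0 <- rep(0, n_tr)
  lc <- c_mid + (rt0 - mean(rt0))
  lc <- pmin(pmax(lc, config$c_window_ms[1]), config$c_window_ms[2])
  lc <- round(lc / dt) * dt
  # the C waveform is always expressed with its event at ref_c, the
  # grid-aligned median of the current latency estimates; ref_c is
  # refreshed whenever C is re-extracted so the waveform's position on the
  # epoch axis follows the estimated latencies
  ref_c <- round(stats::median(lc) / dt) * dt

  zero_cs <- matrix(0, d[2], d[3])
  S <- zero_cs
  R <- zero_cs
  # C initialized from the conventional average aligned to the initial
  # latencies; S and R start at zero, so with constant latencies the
  # central cluster keeps the full average inside its window.
  C <- extract_component(dat, lc, config$c_window_ms, time_ms,
                         epochs$srate_hz, ref_ms = ref_c,
                         taper_fraction = config$taper_fraction,
                         cluster = "C")
  lag_c <- function() (lc - ref_c) / dt

  lmin <- as.integer(floor(config$c_latency_search_ms[1] / dt))
  lmax <- as.integer(ceiling(config$c_latency_search_ms[2] / dt))
  smooth_hw <- as.integer(round(config$xcorr_smooth_ms / dt / 2))
  lc_prior <- lc  # RT-proportional predictions anchor the MAP estimate
  update_lc <- function(resid, C) {
    nzc <- which(colSums(abs(C)) > 0)
    dl <- cpp_best_lags(resid, C, min(nzc) - 1L, max(nzc) - 1L,
                        lag_c(), lmin, lmax, smooth_hw, all_true,
                        (lc_prior - ref_c) / dt,
                        config$latency_prior_weight,
                        (lmax - lmin) / 2)
    lc_new <- lc + dl * dt
    lc_new <- pmin(pmax(lc_new, config$c_window_ms[1]),
                   config$c_window_ms[2])
    round(lc_new / dt) * dt
  }
  # one Woody pass against the initial template before any subtraction, so
  # the first S extraction already removes C at usable latencies. The
  # across-trial mean is removed first: stimulus-locked components are
  # common to every trial and must not attract the alignment. The C
  # reference latency is frozen after this pass: re-deriving it from the
  # median estimate each iteration lets single-sample jumps translate
  # the whole waveform and masquerade as non-convergence.
  if (any(C != 0)) {
    davg <- colMeans(dat)
    dm <- dat - array(rep(davg, each = n_tr), dim(dat))
    lc <- update_lc(dm, C)
    ref_c <- round(stats::median(lc) / dt) * dt
    C <- extract_component(dat, lc, config$c_window_ms, time_ms,
                           epochs$srate_hz, ref_ms = ref_c,
                           taper_fraction = config$taper_fraction,
                           cluster = "C")
  }
  lag_r <- function() ifelse(is.finite(lr), (lr - ref_r) / dt, 0)

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    S_old <- S; C_old <- C; R_old <- R
    resid <- cpp_subtract_aligned(dat, C, lag_c(), all_true)
    if (do_r) resid <- cpp_subtract_aligned(resid, R, lag_r(), r_ok)
    S <- extract_component(resid, rep(0, n_tr), config$s_window_ms,
                           time_ms, epochs$srate_hz, ref_ms = 0,
                           taper_fraction = config$taper_fraction,
                           cluster = "S")
    if (do_r) {
      resid <- cpp_subtract_aligned(dat, S, rep(0, n_tr), all_true)
      resid <- cpp_subtract_aligned(resid, C, lag_c(), all_true)
      R <- extract_component(resid, lr, r_window_abs, time_ms,
                             epochs$srate_hz, ref_ms = ref_r,
                             taper_fraction = config$taper_fraction,
                             cluster = "R")
    }
    resid <- cpp_subtract_aligned(dat, S, rep(0, n_tr), all_true)
    if (do_r) resid <- cpp_subtract_aligned(resid, R, lag_r(), r_ok)
    C <- extract_component(resid, lc, config$c_window_ms, time_ms,
                           epochs$srate_hz, ref_ms = ref_c,
                           taper_fraction = config$taper_fraction,
                           cluster = "C")
    # re-estimate per-trial C latencies against the current template
    if (any(C != 0)) lc <- update_lc(resid, C)
    new <- c(S, C, R)
    delta <- max(abs(new - c(S_old, C_old, R_old)))
    scale <- rms(new)
    change <- if (scale > 0) delta / scale else 0
    trace <- c(trace, change)
    if (change < config$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("decomposition did not converge in ", config$max_iter,
            " iterations (last change ", signif(utils::tail(trace, 1), 3),
            ")")
  structure(list(S = S, C = C, R = R, ls = rep(0, n_tr), lr = lr, lc = lc,
                 ref_c = ref_c, ref_r = ref_r, n_iterations = iter,
                 converged = converged, convergence_trace = trace,
                 time_ms = time_ms, srate_hz = epochs$srate_hz,
                 channels = epochs$channels, config = config),
            class = "ride_result")
}

#' @export
print.ride_result <- function(x, ...) {
  cat(sprintf("<ride_result> %d channels x %d samples; %d trials\n",
              nrow(x$S), ncol(x$S), length(x$lc)))
  cat(sprintf("  %s after %d iteration(s); last change %.2g\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, utils::tail(x$convergence_trace, 1)))
  invisible(x)
}

#' Reconstruct the conventional average from a decomposition
#'
#' S plus the across-trial means of C and R placed back at their per-trial
#' latencies; a closure check — the reconstruction should approximate the
#' conventional trial average.
#'
#' @param result a `ride_result`.
#' @return channel x time matrix.
#' @export
reconstruct <- function(result) {
  dt <- 1000 / result$srate_hz
  out <- result$S
  lag_c <- (result$lc - result$ref_c) / dt
  out <- out + cpp_place_mean(result$C, lag_c, ncol(result$C))
  ok <- is.finite(result$lr)
  if (any(ok) && any(result$R != 0)) {
    lag_r <- (result$lr[ok] - result$ref_r) / dt
    out <- out + cpp_place_mean(result$R, lag_r, ncol(result$R))
  }
  out
}
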