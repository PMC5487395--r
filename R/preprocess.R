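#' Zero-phase band-pass filter
#'
#' Order-4 Butterworth band-pass applied forward and backward, giving zero
#' phase and a squared magnitude response that rolls off at about
#' 48 dB/octave beyond each corner.
#'
#' @param x an [epoch_set()], a channel x time matrix, or a vector.
#' @param srate_hz sampling rate; taken from the epoch set when given one.
#' @param low_hz,high_hz corner frequencies (defaults 0.5 and 20 Hz).
#' @return object of the same shape, filtered.
#' @export
bandpass_filter <- function(x, srate_hz = NULL, low_hz = 0.5,
                            high_hz = 20) {
  if (inherits(x, "epoch_set")) {
    srate_hz <- x$srate_hz
    d <- dim(x$data)
    flat <- matrix(aperm(x$data, c(3, 1, 2)), nrow = d[3])  # time x (trial*ch)
    flt <- bandpass_filter(t(flat), srate_hz, low_hz, high_hz)
    x$data <- aperm(array(t(flt), dim = c(d[3], d[1], d[2])), c(2, 3, 1))
    return(x)
  }
  stopifnot_scalar(srate_hz, "srate_hz", lower = 1e-9)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < srate_hz / 2))
    stop("need 0 < low_hz < high_hz < srate_hz/2")
  bt <- signal::butter(4, c(low_hz, high_hz) / (srate_hz / 2), type = "pass")
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else x
  # removing the DC offset first keeps the recursive passes transient-free
  # (the band-pass suppresses DC anyway)
  mu <- rowMeans(X)
  out <- cpp_filtfilt_rows(bt$b, bt$a, X - mu)
  if (vec) drop(out) else out
}

#' Epoch continuous data and apply baseline correction
#'
#' Given an epoch set, subtracts the per-trial, per-channel mean of the
#' baseline window. Given a continuous channel x time recording plus event
#' samples, cuts target-locked epochs first; events too close to the
#' recording edge are dropped with a warning.
#'
#' @param x an [epoch_set()] or a channel x time matrix.
#' @param events event sample indices (continuous input only).
#' @param srate_hz sampling rate (continuous input only).
#' @param tmin_ms,tmax_ms epoch limits relative to the event.
#' @param baseline length-2 window (ms) whose mean is subtracted; NULL
#'   skips the correction. The default -200..0 ms window precedes the
#'   target; -400..-200 (before flanker onset) is the documented
#'   alternative.
#' @param meta optional per-trial metadata for the continuous path.
#' @param channels optional montage for the continuous path.
#' @return an [epoch_set()].
#' @export
epoch_and_baseline <- function(x, events = NULL, srate_hz = NULL,
                               tmin_ms = -2000, tmax_ms = 2000,
                               baseline = c(-200, 0), meta = NULL,
                               channels = NULL) {
  if (!inherits(x, "epoch_set")) {
    if (is.null(events) || is.null(srate_hz))
      stop("continuous input needs 'events' and 'srate_hz'")
    dt <- 1000 / srate_hz
    n_s <- round((tmax_ms - tmin_ms) / dt)
    off <- round(tmin_ms / dt)
    n_ch <- nrow(x)
    ok <- events + off >= 1 & events + off + n_s - 1 <= ncol(x)
    if (any(!ok))
      warning(sum(!ok), " event(s) too close to the recording edge; dropped")
    events <- events[ok]
    dat <- array(0, dim = c(length(events), n_ch, n_s))
    for (i in seq_along(events))
      dat[i, , ] <- x[, events[i] + off + seq_len(n_s) - 1, drop = FALSE]
    time_ms <- tmin_ms + (seq_len(n_s) - 1) * dt
    if (is.null(channels))
      channels <- data.frame(label = paste0("ch", seq_len(n_ch)),
                             x = 0, y = 0, z = 1)
    if (is.null(meta))
      meta <- data.frame(subject = 1, group = NA, compatibility = NA,
                         rt_ms = NA, correct = TRUE,
                         retained = rep(TRUE, length(events)))
    meta <- meta[ok, , drop = FALSE]
    x <- epoch_set(dat, srate_hz, time_ms, channels, meta)
  }
  if (!is.null(baseline)) {
    if (baseline[1] < min(x$time_ms) || baseline[2] > max(x$time_ms) + 1e-9)
      stop("baseline window outside the epoch")
    idx <- window_index(x$time_ms, baseline)
    bl <- rowMeans(x$data[, , idx, drop = FALSE], dims = 2)
    x$data <- x$data - as.vector(bl)  # recycles over the time dimension
  }
  x
}

#' Artifact rejection criteria
#'
#' @param amp_max_uv,amp_min_uv absolute amplitude bounds (default +/-100).
#' @param lowactivity_uv flat-line threshold: minimum peak-to-peak activity
#'   (default 0.5).
#' @param lowactivity_window_ms flat-line window length (default 200 ms).
#' @return list of class `artifact_criteria`.
#' @export
artifact_criteria <- function(amp_max_uv = 100, amp_min_uv = -100,
                              lowactivity_uv = 0.5,
                              lowactivity_window_ms = 200) {
  if (amp_max_uv <= amp_min_uv) stop("amp_max_uv must exceed amp_min_uv")
  if (lowactivity_window_ms <= 0) stop("lowactivity_window_ms must be > 0")
  structure(list(amp_max_uv = amp_max_uv, amp_min_uv = amp_min_uv,
                 lowactivity_uv = lowactivity_uv,
                 lowactivity_window_ms = lowactivity_window_ms),
            class = "artifact_criteria")
}

#' Reject artifact trials
#'
#' A trial is rejected if any channel exceeds the amplitude bounds anywhere
#' in the epoch, or if any channel's peak-to-peak range stays below the
#' low-activity threshold within any sliding window of the configured
#' length (flat-line detection). Updates the `retained` flag; the rejection
#' counts are attached as the `"rejection"` attribute.
#'
#' @param epochs an [epoch_set()].
#' @param criteria an [artifact_criteria()].
#' @return the epoch set with `meta$retained` updated.
#' @export
reject_artifacts <- function(epochs, criteria = artifact_criteria()) {
  if (dim(epochs$data)[1] == 0L) stop("epochs are empty")
  d <- dim(epochs$data)
  w <- max(2L, round(criteria$lowactivity_window_ms / 1000 *
                       epochs$srate_hz))
  amp_bad <- logical(d[1])
  flat_bad <- logical(d[1])
  for (i in seq_len(d[1])) {
    tr <- epochs$data[i, , , drop = TRUE]
    if (is.null(dim(tr))) tr <- matrix(tr, nrow = 1)
    if (max(tr) > criteria$amp_max_uv || min(tr) < criteria$amp_min_uv) {
      amp_bad[i] <- TRUE
      next
    }
    for (ci in seq_len(d[2])) {
      if (cpp_min_window_range(tr[ci, ], w) < criteria$lowactivity_uv) {
        flat_bad[i] <- TRUE
        break
      }
    }
  }
  keep <- !(amp_bad | flat_bad)
  epochs$meta$retained <- epochs$meta$retained & keep
  if (!any(epochs$meta$retained))
    warning("no trials survive artifact rejection")
  attr(epochs, "rejection") <- c(amplitude = sum(amp_bad),
                                 flatline = sum(flat_bad),
                                 retained = sum(epochs$meta$retained))
  epochs
}
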