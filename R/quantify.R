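#' Component window registry
#'
#' The electrode/time windows in which each named component is quantified,
#' for the conventional average (`ERP`) and the three decomposition
#' clusters. The central-cluster P3 window is group dependent (520-540 ms
#' for the ADD cohort, 590-610 ms for the ADHD-C cohort, matching the
#' groups' observed peak latencies); for other cohorts pass
#' `c_p3_center_ms` to re-center it (peak +/- 10 ms). The motor-cluster
#' window is the subject's mean reaction time +/- 10 ms and is resolved at
#' quantification time via `rcluster_window()`.
#'
#' @param group `"ADD"` or `"ADHD-C"` (selects the C-cluster P3 window).
#' @param c_p3_center_ms optional explicit C-cluster P3 window center (ms).
#' @return data.frame: `component`, `source`, `electrodes`
#'   (comma-separated), `lo`, `hi` (ms; NA for the response-relative
#'   window).
#' @export
component_windows <- function(group = c("ADD", "ADHD-C"),
                              c_p3_center_ms = NULL) {
  if (is.null(c_p3_center_ms)) {
    group <- match.arg(group)
    c_p3_center_ms <- if (group == "ADD") 530 else 600
  }
  base <- data.frame(
    component = c("P1f", "N1f", "P1t", "N1t", "N2", "P3"),
    electrodes = c("P9,P10", "P9,P10", "P9,P10", "P9,P10", "FCz,Cz", "Pz"),
    lo = c(-95, -10, 115, 260, 280, 300),
    hi = c(-75, 10, 135, 280, 320, 320),
    stringsAsFactors = FALSE
  )
  erp <- cbind(base, source = "ERP")
  scl <- cbind(base[1:5, ], source = "S-cluster")
  ccl <- data.frame(
    component = c("N2", "P3"),
    electrodes = c("FCz,Fz", "Pz"),
    lo = c(370, c_p3_center_ms - 10),
    hi = c(390, c_p3_center_ms + 10),
    source = "C-cluster",
    stringsAsFactors = FALSE
  )
  rcl <- data.frame(component = "R", electrodes = "C3,C4", lo = NA,
                    hi = NA, source = "R-cluster",
                    stringsAsFactors = FALSE)
  out <- rbind(erp, scl, ccl, rcl)
  rownames(out) <- NULL
  out[, c("component", "source", "electrodes", "lo", "hi")]
}

#' Motor-cluster quantification window
#'
#' @param mean_rt_ms subject x condition mean correct reaction time (ms).
#' @param half_width_ms half-width (default 10 ms).
#' @return length-2 window (ms).
#' @export
rcluster_window <- function(mean_rt_ms, half_width_ms = 10) {
  c(mean_rt_ms - half_width_ms, mean_rt_ms + half_width_ms)
}

#' Mean amplitude in an electrode/time window
#'
#' Arithmetic mean over the samples of the half-open window \[lo, hi) at
#' each requested electrode.
#'
#' @param waveform channel x time matrix.
#' @param time_ms time axis.
#' @param channels montage data.frame (for electrode lookup).
#' @param window_ms length-2 window (ms).
#' @param electrodes character vector of labels.
#' @return named numeric vector, one value per electrode.
#' @export
mean_amplitude <- function(waveform, time_ms, channels, window_ms,
                           electrodes) {
  idx <- window_index(time_ms, window_ms)
  if (!length(idx)) stop("window outside the time axis")
  ci <- ch_index(channels, electrodes)
  out <- rowMeans(waveform[ci, idx, drop = FALSE])
  names(out) <- electrodes
  out
}

#' Validate electrode choices against the rest of the montage
#'
#' For each electrode, the per-subject window value is tested (paired
#' one-sample t) against the mean of all other electrodes; an electrode is
#' selected when the Bonferroni-style criterion p < alpha holds and the
#' sign of the difference matches the component polarity.
#'
#' @param subject_averages subject x channel matrix (column names are
#'   electrode labels).
#' @param polarity `"positive"` or `"negative"`.
#' @param alpha critical threshold (default 0.0007).
#' @return data.frame per electrode: `electrode`, `t`, `p`, `selected`.
#' @export
validate_electrode_selection <- function(subject_averages,
                                         polarity = c("positive",
                                                      "negative"),
                                         alpha = 0.0007) {
  polarity <- match.arg(polarity)
  X <- as.matrix(subject_averages)
  if (ncol(X) < 2) stop("need at least 2 channels")
  if (nrow(X) < 3) stop("need at least 3 subjects")
  n <- nrow(X)
  res <- lapply(seq_len(ncol(X)), function(e) {
    d <- X[, e] - rowMeans(X[, -e, drop = FALSE])
    tv <- mean(d) / (sd(d) / sqrt(n))
    p <- 2 * pt(-abs(tv), n - 1)
    sign_ok <- if (polarity == "positive") mean(d) > 0 else mean(d) < 0
    data.frame(electrode = colnames(X)[e], t = tv, p = p,
               selected = (p < alpha) && sign_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Signal-to-noise ratio of an averaged waveform
#'
#' RMS of the signal window divided by RMS of the noise (baseline) window,
#' per channel.
#'
#' @param waveform channel x time matrix (an average).
#' @param time_ms time axis.
#' @param signal_window,noise_window length-2 windows (ms).
#' @return numeric vector, one ratio per channel (Inf with a warning when
#'   the noise RMS is zero).
#' @export
compute_snr <- function(waveform, time_ms, signal_window,
                        noise_window = c(-200, 0)) {
  si <- window_index(time_ms, signal_window)
  ni <- window_index(time_ms, noise_window)
  if (!length(si) || !length(ni)) stop("window outside the time axis")
  s <- apply(waveform[, si, drop = FALSE], 1, rms)
  n <- apply(waveform[, ni, drop = FALSE], 1, rms)
  if (any(n == 0)) warning("zero noise RMS; returning Inf")
  s / n
}

# One subject x condition block of amplitude-table rows.
amplitude_rows <- function(subject, group, condition, component, source,
                           values) {
  data.frame(subject = subject, group = group, condition = condition,
             component = component, source = source,
             electrode = names(values), amplitude = unname(values),
             stringsAsFactors = FALSE)
}
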