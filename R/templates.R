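#' Component waveform kernel
#'
#' Smooth unimodal kernel used for all simulated components: a half-sine
#' over `peak_ms` +/- `width_ms` multiplied by a Gaussian taper, so the
#' kernel is compactly supported and differentiable at its edges.
#'
#' @param time_ms time axis (ms).
#' @param peak_ms peak latency (ms).
#' @param width_ms half-width of the support (ms); the effective FWHM is
#'   roughly 0.8 * width_ms.
#' @param amplitude signed peak amplitude.
#' @return numeric vector over `time_ms`.
#' @export
component_kernel <- function(time_ms, peak_ms, width_ms, amplitude = 1) {
  amplitude * kernel_shape((time_ms - peak_ms) / width_ms)
}

# unit kernel on the normalized axis u = (t - peak)/width
kernel_shape <- function(u) {
  ifelse(abs(u) <= 1, cos(pi * u / 2) * exp(-u^2 / (2 * 0.5^2)), 0)
}

#' Component template
#'
#' A generative component: kernel parameters, a per-channel topography, its
#' locking (stimulus onset, an estimated intermediate latency, or the
#' response), latency jitter SD and — for the intermediate component — the
#' slope coupling its latency to the trial's reaction time.
#'
#' @param name one of `"S_P1f"`, `"S_N1f"`, `"S_P1t"`, `"S_N1t"`, `"S_N2"`,
#'   `"C"`, `"R"`.
#' @param peak_ms peak latency relative to the locking marker (ms).
#' @param width_ms kernel half-width (ms).
#' @param amplitude peak amplitude in scalp microvolts; a named vector
#'   `c(compatible = , incompatible = )` gives condition-specific amplitudes.
#' @param topography named numeric vector of channel weights in \[-1, 1\].
#' @param locking `"stimulus"`, `"estimated"` or `"response"`.
#' @param jitter_sd_ms SD of the trial-to-trial latency jitter (ms).
#' @param rt_coupling slope of latency on (rt - mean rt); intermediate
#'   component only.
#' @param amp_cv between-subject coefficient of variation of the
#'   component's amplitude (lognormal, mean-preserving); 0 = identical
#'   across subjects.
#' @return object of class `component_template`.
#' @export
component_template <- function(name, peak_ms, width_ms, amplitude,
                               topography,
                               locking = c("stimulus", "estimated",
                                           "response"),
                               jitter_sd_ms = 0, rt_coupling = 0,
                               amp_cv = 0) {
  locking <- match.arg(locking)
  stopifnot_scalar(jitter_sd_ms, "jitter_sd_ms", lower = 0)
  if (any(!is.finite(topography)))
    stop("topography weights must be finite")
  structure(list(name = name, peak_ms = peak_ms, width_ms = width_ms,
                 amplitude = amplitude, topography = topography,
                 locking = locking, jitter_sd_ms = jitter_sd_ms,
                 rt_coupling = rt_coupling, amp_cv = amp_cv),
            class = "component_template")
}

#' Default flanker component templates
#'
#' The built-in generative model: flanker- and target-locked visual
#' components at P9/P10, a fronto-central conflict N2, a parietal
#' intermediate (P3-like) component whose amplitude and latency are supplied
#' per subject by the group preset, and a central motor component locked to
#' the response. Amplitudes are scalp microvolts before the current source
#' density transform.
#'
#' @param jitter_scale multiplies every stimulus-locked jitter SD (0 gives
#'   perfectly time-locked components).
#' @return named list of [component_template()] objects.
#' @export
default_templates <- function(jitter_scale = 1) {
  js <- function(x) x * jitter_scale
  list(
    S_P1f = component_template("S_P1f", -85, 45, 6,
      c(P9 = 1, P10 = 1, Oz = 0.6, Pz = 0.2), "stimulus", js(5),
      amp_cv = 0.4),
    S_N1f = component_template("S_N1f", 0, 50, -7,
      c(P9 = 1, P10 = 1, Oz = 0.5, Pz = 0.2), "stimulus", js(5),
      amp_cv = 0.4),
    S_P1t = component_template("S_P1t", 125, 45, 7,
      c(P9 = 1, P10 = 1, Oz = 0.6, Pz = 0.2), "stimulus", js(5),
      amp_cv = 0.4),
    S_N1t = component_template("S_N1t", 270, 50, -7,
      c(P9 = 1, P10 = 1, Oz = 0.5, Pz = 0.15), "stimulus", js(6),
      amp_cv = 0.4),
    S_N2 = component_template("S_N2", 300, 55,
      c(compatible = -5, incompatible = -8.5),
      c(FCz = 1, Cz = 0.9, Fz = 0.55, Pz = 0.1), "stimulus", js(8),
      amp_cv = 0.4),
    # early stimulus-locked parietal positivity: the classic P3 the fixed
    # 300-320 ms window quantifies; identical in both groups, large
    # inter-individual amplitude variability
    S_P3 = component_template("S_P3", 310, 80, 10,
      c(Pz = 1, Oz = 0.5, Cz = 0.5, P9 = 0.35, P10 = 0.35, FCz = 0.2),
      "stimulus", js(8), amp_cv = 0.5),
    C = component_template("C", 0, 110, 1,
      c(Pz = 1, Oz = 0.45, Cz = 0.5, FCz = 0.25, Fz = 0.15,
        P9 = 0.35, P10 = 0.35, C3 = 0.25, C4 = 0.25),
      "estimated", 0),
    R = component_template("R", 0, 55, 6,
      c(C3 = 0.95, C4 = 0.95, Cz = 0.6, FCz = 0.4), "response", js(4),
      amp_cv = 0.4)
  )
}

# Expand a template's named topography onto a montage (missing channels 0).
topo_on_montage <- function(template, channels) {
  w <- numeric(nrow(channels))
  idx <- match(names(template$topography), channels$label)
  keep <- !is.na(idx)
  w[idx[keep]] <- template$topography[keep]
  w
}

# Condition-specific amplitude lookup.
template_amp <- function(template, condition) {
  a <- template$amplitude
  if (length(a) == 1L) return(unname(rep(a, length(condition))))
  unname(a[as.character(condition)])
}
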