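#' Idealized unit-sphere electrode montage
#'
#' Returns electrode positions on the unit sphere for an idealized reduced
#' montage covering every electrode quantified by the analysis (P9/P10 for
#' the visual components, FCz/Cz/Fz for the N2, Pz for the P3, C3/C4 for the
#' motor cluster, plus Oz). Positions use inclination from the vertex and
#' azimuth (0 = right pre-auricular, 90 = nasion); coordinates are x right,
#' y anterior, z superior.
#'
#' @param channels character vector of labels to include (subset of the
#'   built-in layout).
#' @return data.frame with columns `label`, `x`, `y`, `z`.
#' @export
default_montage <- function(channels = c("Fz", "FCz", "Cz", "C3", "C4",
                                         "Pz", "P9", "P10", "Oz")) {
  layout <- data.frame(
    label = c("Fz", "FCz", "Cz", "C3", "C4", "Pz", "P9", "P10", "Oz"),
    incl  = c(46,   23,    0,    46,   46,   46,   112,  112,   92),
    az    = c(90,   90,    0,    180,  0,    270,  220,  320,   270),
    stringsAsFactors = FALSE
  )
  miss <- setdiff(channels, layout$label)
  if (length(miss))
    stop("unknown channel label(s): ", paste(miss, collapse = ", "))
  layout <- layout[match(channels, layout$label), ]
  ir <- layout$incl * pi / 180
  ar <- layout$az * pi / 180
  data.frame(
    label = layout$label,
    x = sin(ir) * cos(ar),
    y = sin(ir) * sin(ar),
    z = cos(ir),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

ch_index <- function(channels, labels) {
  idx <- match(labels, channels$label)
  if (anyNA(idx))
    stop("channel(s) not in montage: ",
         paste(labels[is.na(idx)], collapse = ", "))
  idx
}
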