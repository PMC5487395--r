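#' Spherical-spline CSD parameters
#'
#' @param spline_order_m spline stiffness m (default 4).
#' @param legendre_terms number of Legendre series terms (default 50).
#' @param regularization_lambda smoothing constant added to the diagonal of
#'   the interpolation matrix (default 1e-5).
#' @return list of class `csd_params`.
#' @export
csd_params <- function(spline_order_m = 4, legendre_terms = 50,
                       regularization_lambda = 1e-5) {
  if (spline_order_m < 2) stop("spline_order_m must be >= 2")
  if (legendre_terms < 10) stop("legendre_terms must be >= 10")
  if (regularization_lambda < 0)
    stop("regularization_lambda must be >= 0")
  structure(list(spline_order_m = spline_order_m,
                 legendre_terms = legendre_terms,
                 regularization_lambda = regularization_lambda),
            class = "csd_params")
}

# Legendre polynomials P_1..P_n at x via the Bonnet recurrence.
legendre_upto <- function(x, n) {
  out <- matrix(0, length(x), n)
  pm1 <- rep(1, length(x))  # P_0
  p <- x                    # P_1
  out[, 1] <- p
  for (k in 2:n) {
    pn <- ((2 * k - 1) * x * p - (k - 1) * pm1) / k
    out[, k] <- pn
    pm1 <- p
    p <- pn
  }
  out
}

# Perrin-style g and h kernels over cosine distances.
csd_g <- function(cosang, m, nterms) {
  n <- seq_len(nterms)
  P <- legendre_upto(cosang, nterms)
  drop(P %*% ((2 * n + 1) / (n * (n + 1))^m)) / (4 * pi)
}
csd_h <- function(cosang, m, nterms) {
  n <- seq_len(nterms)
  P <- legendre_upto(cosang, nterms)
  drop(P %*% ((2 * n + 1) / (n * (n + 1))^(m - 1))) / (4 * pi)
}

# Linear CSD operator for a montage: potentials (n_ch vector) -> surface
# Laplacian estimates, reference-free.
csd_matrix <- function(channels, params = csd_params()) {
  pos <- as.matrix(channels[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  n <- nrow(pos)
  if (n < 4) stop("CSD needs at least 4 channels")
  cosang <- tcrossprod(pos)
  cosang <- pmin(pmax(cosang, -1), 1)
  if (any(cosang[upper.tri(cosang)] > 1 - 1e-10))
    stop("duplicate channel positions")
  m <- params$spline_order_m
  nt <- params$legendre_terms
  G <- matrix(csd_g(as.vector(cosang), m, nt), n, n)
  H <- matrix(csd_h(as.vector(cosang), m, nt), n, n)
  Gi <- solve(G + diag(params$regularization_lambda, n))
  tc <- rowSums(Gi)
  sgi <- sum(tc)
  # spline coefficients c = Gi v - (sum(Gi v)/sgi) tc; CSD = H c
  H %*% (Gi - tcrossprod(tc) / sgi)
}

#' Current source density transform
#'
#' Spherical-spline surface Laplacian (stiffness m, truncated Legendre
#' series, regularized interpolation matrix) applied sample-wise. The
#' output is reference-free and proportional to uV/m^2 on the unit sphere;
#' any spatially uniform potential maps to zero.
#'
#' @param x an [epoch_set()] or a channel x time matrix.
#' @param channels montage data.frame (matrix input only).
#' @param params a [csd_params()].
#' @return same shape as the input, CSD-transformed.
#' @export
csd_transform <- function(x, channels = NULL, params = csd_params()) {
  if (inherits(x, "epoch_set")) {
    M <- csd_matrix(x$channels, params)
    d <- dim(x$data)
    flat <- matrix(aperm(x$data, c(2, 1, 3)), nrow = d[2])  # ch x (trial*time)
    flat <- M %*% flat
    x$data <- aperm(array(flat, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
    return(x)
  }
  if (is.null(channels)) stop("matrix input needs 'channels'")
  csd_matrix(channels, params) %*% x
}
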