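# Mixed-design ANOVA, post-hoc tests, within-subject RT variability and a
# Lilliefors-style normality check. The ANOVA is computed from sums of
# squares over orthonormal within-cell contrasts (the textbook split-plot
# partition), not delegated to a modeling package.

# Orthonormal contrast matrix (k x (k-1)) for a k-level factor.
orthonormal_contrasts <- function(k) {
  qr.Q(qr(cbind(rep(1, k), stats::contr.helmert(k))))[, -1, drop = FALSE]
}

#' Mixed-design ANOVA with Greenhouse-Geisser correction
#'
#' Split-plot ANOVA with one between-subject factor and one or two
#' within-subject factors, computed from sums of squares of orthonormal
#' within-cell contrast scores. Unequal group sizes are handled with
#' unweighted (Type-III-style) marginal means for the within effects.
#' Greenhouse-Geisser epsilon is estimated from the pooled covariance of
#' the contrast scores (Box's epsilon) and applied to every within-subject
#' test; for 2-level factors it equals 1 exactly. Effect sizes are partial
#' eta squared, SS_effect / (SS_effect + SS_error).
#'
#' @param data long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param within character vector (length 1 or 2) of within-subject factor
#'   columns; every subject must have every cell exactly once.
#' @param between name of the between-subject factor column.
#' @param subject name of the subject identifier column.
#' @return data.frame with one row per effect: `effect`, `df_num`,
#'   `df_den` (GG-adjusted), `F`, `p`, `epsilon_gg`, `partial_eta_sq`.
#' @export
mixed_anova <- function(data, dv = "amplitude", within = "condition",
                        between = "group", subject = "subject") {
  for (col in c(dv, within, between, subject))
    if (!col %in% names(data)) stop("column not found: ", col)
  data <- data[, c(subject, between, within, dv)]
  names(data) <- c(".s", ".g", paste0(".w", seq_along(within)), ".y")
  wcols <- paste0(".w", seq_along(within))
  lev <- lapply(wcols, function(w) sort(unique(as.character(data[[w]]))))
  k <- vapply(lev, length, 1L)
  cells <- do.call(expand.grid,
                   c(stats::setNames(lev, wcols),
                     list(stringsAsFactors = FALSE)))
  cell_id <- function(df) {
    id <- match(as.character(df[[wcols[1]]]), lev[[1]])
    if (length(wcols) > 1)
      id <- id + k[1] * (match(as.character(df[[wcols[2]]]), lev[[2]]) - 1)
    id
  }
  subj <- unique(data[, c(".s", ".g")])
  if (anyDuplicated(subj$.s))
    stop("subject assigned to more than one group")
  n <- nrow(subj)
  ncell <- prod(k)
  wide <- matrix(NA_real_, n, ncell)
  ri <- match(data$.s, subj$.s)
  ci <- cell_id(data)
  if (anyDuplicated(cbind(ri, ci)))
    stop("duplicate subject x cell observations")
  wide[cbind(ri, ci)] <- data$.y
  if (anyNA(wide)) {
    bad <- which(is.na(wide), arr.ind = TRUE)[1, ]
    stop(sprintf("missing cell: subject %s, cell %s",
                 subj$.s[bad[1]],
                 paste(unlist(cells[bad[2], ]), collapse = "/")))
  }
  grp <- factor(subj$.g)
  G <- nlevels(grp)
  ng <- as.vector(table(grp))
  if (any(ng < 2)) stop("each group needs at least 2 subjects")

  # contrast builders per factor: Q = effect, j = constant
  Qs <- lapply(k, orthonormal_contrasts)
  js <- lapply(k, function(kk) matrix(1 / sqrt(kk), kk, 1))
  kron_for <- function(use) {
    # cell index varies fastest in factor 1 -> kron(second, first)
    m <- if (use[1]) Qs[[1]] else js[[1]]
    if (length(k) > 1)
      m <- kronecker(if (use[2]) Qs[[2]] else js[[2]], m)
    m
  }

  effects <- list()
  add <- function(name, row) effects[[name]] <<- row

  # between-subject part: subject means scores
  z0 <- drop(wide %*% kron_for(rep(FALSE, length(k))))
  gm <- tapply(z0, grp, mean)
  ssb <- sum(ng * (gm - mean(z0))^2)
  sse0 <- sum((z0 - gm[grp])^2)
  f0 <- (ssb / (G - 1)) / (sse0 / (n - G))
  add(levels_name <- "group", data.frame(
    effect = "group", df_num = G - 1, df_den = n - G, F = f0,
    p = pf(f0, G - 1, n - G, lower.tail = FALSE), epsilon_gg = 1,
    partial_eta_sq = ssb / (ssb + sse0)))

  within_effect <- function(use, name) {
    M <- kron_for(use)
    d <- ncol(M)
    Z <- wide %*% M
    mg <- apply(Z, 2, function(col) tapply(col, grp, mean))
    mg <- matrix(mg, nrow = G)
    resid <- Z - mg[as.integer(grp), , drop = FALSE]
    sse <- sum(resid^2)
    df_err <- d * (n - G)
    # Box's epsilon from the pooled contrast-score covariance
    Sp <- crossprod(resid) / (n - G)
    eps <- if (d == 1) 1 else
      (sum(diag(Sp))^2) / (d * sum(Sp * Sp))
    eps <- min(1, max(eps, 1 / d))
    # main within effect: unweighted grand mean (Type III with unequal n)
    mbar <- colMeans(mg)
    neff <- G^2 / sum(1 / ng)
    ss_w <- neff * sum(mbar^2)
    f_w <- (ss_w / d) / (sse / df_err)
    # interaction with group: weighted between-group dispersion of scores
    zw <- colSums(mg * ng) / n
    ss_int <- sum(t((t(mg) - zw))^2 * ng)
    df_int <- d * (G - 1)
    f_int <- (ss_int / df_int) / (sse / df_err)
    add(name, data.frame(
      effect = name, df_num = d * eps, df_den = df_err * eps, F = f_w,
      p = pf(f_w, d * eps, df_err * eps, lower.tail = FALSE),
      epsilon_gg = eps, partial_eta_sq = ss_w / (ss_w + sse)))
    add(paste0("group:", name), data.frame(
      effect = paste0("group:", name), df_num = df_int * eps,
      df_den = df_err * eps, F = f_int,
      p = pf(f_int, df_int * eps, df_err * eps, lower.tail = FALSE),
      epsilon_gg = eps, partial_eta_sq = ss_int / (ss_int + sse)))
  }

  if (length(k) == 1) {
    within_effect(TRUE, within[1])
  } else {
    within_effect(c(TRUE, FALSE), within[1])
    within_effect(c(FALSE, TRUE), within[2])
    within_effect(c(TRUE, TRUE), paste(within, collapse = ":"))
  }
  out <- do.call(rbind, effects)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected post-hoc t test
#'
#' Two-sample (pooled-variance) or paired Student t; the p value is
#' multiplied by the number of comparisons and capped at 1.
#'
#' @param x,y numeric samples (per-subject values).
#' @param paired paired test (default FALSE).
#' @param n_comparisons Bonferroni denominator (default 1).
#' @return list with `t`, `df`, `p` (uncorrected) and `p_bonferroni`.
#' @export
posthoc_t <- function(x, y, paired = FALSE, n_comparisons = 1) {
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must match in length")
    d <- x - y
    if (sd(d) == 0) {
      if (all(d == 0)) return(list(t = 0, df = length(d) - 1, p = 1,
                                   p_bonferroni = 1))
      stop("zero variance in the paired differences")
    }
    tv <- mean(d) / (sd(d) / sqrt(length(d)))
    df <- length(d) - 1
  } else {
    vx <- var(x); vy <- var(y)
    if (vx == 0 && vy == 0) {
      if (mean(x) == mean(y)) return(list(t = 0,
                                          df = length(x) + length(y) - 2,
                                          p = 1, p_bonferroni = 1))
      stop("zero variance in both cells")
    }
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    tv <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  p <- 2 * pt(-abs(tv), df)
  list(t = tv, df = df, p = p,
       p_bonferroni = min(1, p * n_comparisons))
}

#' Within-subject reaction-time variability
#'
#' Sample SD of correct-trial reaction times per subject and condition.
#'
#' @param behavior data.frame with columns `subject`, `condition`, `rt_ms`,
#'   `correct`.
#' @return data.frame `subject`, `condition`, `rt_sd` (NA with a warning
#'   for cells with fewer than 2 correct trials).
#' @export
within_subject_rt_sd <- function(behavior) {
  b <- behavior[behavior$correct & is.finite(behavior$rt_ms), ]
  cells <- unique(behavior[, c("subject", "condition")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    v <- b$rt_ms[b$subject == cells$subject[i] &
                   b$condition == cells$condition[i]]
    s <- if (length(v) >= 2) sd(v) else NA_real_
    data.frame(subject = cells$subject[i], condition = cells$condition[i],
               rt_sd = s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (anyNA(out$rt_sd))
    warning("cell(s) with fewer than 2 correct trials: SD set to NA")
  out
}

#' Kolmogorov-Smirnov normality check (Lilliefors)
#'
#' One-sample K-S statistic of the data against a normal distribution with
#' estimated mean and SD; `z = D * sqrt(n)` and the Lilliefors-corrected p
#' value via the Dallal-Wilkinson approximation.
#'
#' @param values numeric sample (n >= 5, non-degenerate).
#' @return list with `D`, `z` and `p`.
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 5) stop("need at least 5 values")
  if (sd(values) == 0) stop("zero variance")
  x <- sort(values)
  p_hat <- pnorm(x, mean(x), sd(x))
  D <- max(pmax(seq_len(n) / n - p_hat, p_hat - (seq_len(n) - 1) / n))
  # Dallal-Wilkinson (1986) approximation to the Lilliefors p value
  if (n > 100) { Kd <- D * (n / 100)^0.49; nd <- 100 } else {
    Kd <- D; nd <- n
  }
  p <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
             2.99587 * Kd * sqrt(nd + 2.78019) - 0.122119 +
             0.974598 / sqrt(nd) + 1.67997 / nd)
  if (p > 0.1) {
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
    if (KK <= 0.302) p <- 1
    else if (KK <= 0.5) p <- 2.76773 - 19.828315 * KK + 80.709644 * KK^2 -
        138.55152 * KK^3 + 81.218052 * KK^4
    else if (KK <= 0.9) p <- -4.901232 + 40.662806 * KK - 97.490286 * KK^2 +
        94.029866 * KK^3 - 32.355711 * KK^4
    else if (KK <= 1.31) p <- 6.198765 - 19.558097 * KK + 23.186922 * KK^2 -
        12.234627 * KK^3 + 2.423045 * KK^4
    else p <- 0
  }
  list(D = D, z = D * sqrt(n), p = min(1, max(0, p)))
}
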