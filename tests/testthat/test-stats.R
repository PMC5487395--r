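# Long-format builder for a 2 (group) x 2 (condition) table.
make_table <- function(y, groups, subjects = seq_along(groups)) {
  data.frame(
    subject = rep(subjects, each = 2),
    group = rep(groups, each = 2),
    condition = rep(c("a", "b"), length(groups)),
    amplitude = as.vector(t(y))
  )
}

test_that("mixed ANOVA matches the hand-computed sums of squares", {
  # balanced 2x2 split-plot, 2 subjects per group: classical formulas
  y <- rbind(c(10, 12), c(11, 15), c(20, 26), c(19, 23))
  tab <- make_table(y, c("g1", "g1", "g2", "g2"))
  res <- mixed_anova(tab, dv = "amplitude", within = "condition",
                     between = "group", subject = "subject")

  n <- 4; k <- 2
  subj_mean <- rowMeans(y)
  grp <- c(1, 1, 2, 2)
  grand <- mean(y)
  gm <- tapply(subj_mean, grp, mean)
  ss_group <- k * sum(2 * (gm - grand)^2)
  ss_subj <- k * sum((subj_mean - gm[grp])^2)
  cond_mean <- colMeans(y)
  ss_cond <- n * sum((cond_mean - grand)^2)
  cell <- rbind(colMeans(y[1:2, ]), colMeans(y[3:4, ]))
  ss_int <- 2 * sum((cell - outer(gm, rep(1, 2)) -
                       outer(rep(1, 2), cond_mean) + grand)^2)
  ss_err <- sum(vapply(1:n, function(i)
    sum((y[i, ] - subj_mean[i] - (cell[grp[i], ] - gm[grp[i]]))^2),
    numeric(1)))

  f_group <- (ss_group / 1) / (ss_subj / 2)
  f_cond <- (ss_cond / 1) / (ss_err / 2)
  f_int <- (ss_int / 1) / (ss_err / 2)
  expect_equal(res$F[res$effect == "group"], f_group, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "condition"], f_cond, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "group:condition"], f_int,
               tolerance = 1e-10)
  expect_equal(res$partial_eta_sq[res$effect == "group"],
               ss_group / (ss_group + ss_subj), tolerance = 1e-10)
  # 2-level within factor: sphericity correction is inert
  expect_equal(res$epsilon_gg[res$effect == "condition"], 1)
})

test_that("mixed ANOVA agrees with the multivariate reference on unbalanced designs", {
  skip_if_not_installed("car")
  set.seed(13)
  for (rep in 1:4) {
    n1 <- sample(4:7, 1); n2 <- sample(5:9, 1)
    y <- matrix(rnorm((n1 + n2) * 2, mean = rep(c(0, 2), each = n1 + n2)),
                n1 + n2, 2)
    y[(n1 + 1):(n1 + n2), ] <- y[(n1 + 1):(n1 + n2), ] + 1.5
    grp <- factor(c(rep("g1", n1), rep("g2", n2)))
    tab <- make_table(y, as.character(grp))
    res <- mixed_anova(tab, dv = "amplitude", within = "condition",
                       between = "group", subject = "subject")
    mod <- lm(y ~ grp, contrasts = list(grp = "contr.sum"))
    idata <- data.frame(condition = factor(c("a", "b")))
    aov2 <- suppressWarnings(car::Anova(mod, idata = idata,
                                        idesign = ~condition, type = 3))
    s <- summary(aov2, multivariate = FALSE)$univariate.tests
    expect_equal(res$F[res$effect == "group"], s["grp", "F value"],
                 tolerance = 1e-8)
    expect_equal(res$F[res$effect == "condition"],
                 s["condition", "F value"], tolerance = 1e-8)
    expect_equal(res$F[res$effect == "group:condition"],
                 s["grp:condition", "F value"], tolerance = 1e-8)
    expect_equal(res$p[res$effect == "group"], s["grp", "Pr(>F)"],
                 tolerance = 1e-8)
  }
})

test_that("two within-subject factors partition correctly", {
  skip_if_not_installed("car")
  set.seed(14)
  n1 <- 5; n2 <- 6
  cells <- expand.grid(condition = c("a", "b"),
                       electrode = c("E1", "E2"))
  Y <- matrix(rnorm((n1 + n2) * 4), n1 + n2, 4)
  Y[, 2] <- Y[, 2] + 1
  grp <- c(rep("g1", n1), rep("g2", n2))
  tab <- do.call(rbind, lapply(seq_len(n1 + n2), function(i) {
    data.frame(subject = i, group = grp[i], condition = cells$condition,
               electrode = cells$electrode, amplitude = Y[i, ])
  }))
  res <- mixed_anova(tab, dv = "amplitude",
                     within = c("condition", "electrode"),
                     between = "group", subject = "subject")
  mod <- lm(Y ~ factor(grp), contrasts = list(`factor(grp)` = "contr.sum"))
  aov2 <- suppressWarnings(car::Anova(mod, idata = cells,
                                      idesign = ~condition * electrode,
                                      type = 3))
  s <- summary(aov2, multivariate = FALSE)$univariate.tests
  expect_equal(res$F[res$effect == "condition"],
               s["condition", "F value"], tolerance = 1e-8)
  expect_equal(res$F[res$effect == "electrode"],
               s["electrode", "F value"], tolerance = 1e-8)
  expect_equal(res$F[res$effect == "condition:electrode"],
               s["condition:electrode", "F value"], tolerance = 1e-8)
  expect_equal(res$F[res$effect == "group:condition"],
               s["factor(grp):condition", "F value"], tolerance = 1e-8)
})

test_that("null group effects give F near zero and errors are caught", {
  y <- rbind(c(10, 14), c(12, 16), c(10, 14), c(12, 16))
  tab <- make_table(y, c("g1", "g1", "g2", "g2"))
  res <- mixed_anova(tab)
  expect_lt(res$F[res$effect == "group"], 1e-20)
  tab_miss <- tab[-1, ]
  expect_error(mixed_anova(tab_miss), "missing cell")
  expect_error(mixed_anova(tab, dv = "nope"), "column not found")
})

test_that("effect size grows with the injected group effect", {
  set.seed(15)
  base <- matrix(rnorm(20 * 2), 20, 2)
  pes <- vapply(c(0, 1.5, 4), function(delta) {
    y <- base
    y[11:20, ] <- y[11:20, ] + delta
    tab <- make_table(y, rep(c("g1", "g2"), each = 10))
    res <- mixed_anova(tab)
    res$partial_eta_sq[res$effect == "group"]
  }, numeric(1))
  expect_true(all(diff(pes) > 0))
  expect_true(all(pes >= 0 & pes <= 1))
})

test_that("post-hoc t tests mirror the reference and cap Bonferroni p", {
  set.seed(16)
  x <- rnorm(12); y <- rnorm(14, 1)
  got <- posthoc_t(x, y, n_comparisons = 3)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_equal(got$p_bonferroni, min(1, ref$p.value * 3))
  expect_gte(got$p_bonferroni, got$p)

  xp <- rnorm(10); yp <- xp + rnorm(10, 0.5)
  gotp <- posthoc_t(xp, yp, paired = TRUE)
  refp <- t.test(xp, yp, paired = TRUE)
  expect_equal(gotp$t, unname(refp$statistic), tolerance = 1e-12)

  same <- c(1, 2, 3)
  expect_equal(posthoc_t(same, same, paired = TRUE)$t, 0)
  expect_equal(posthoc_t(same, same, paired = TRUE)$p, 1)
  expect_error(posthoc_t(c(1, 1), c(2, 2)), "zero variance")
  big <- posthoc_t(rnorm(5), rnorm(5), n_comparisons = 1000)
  expect_equal(big$p_bonferroni, 1)
})

test_that("within-subject RT variability is the cell-wise sample SD", {
  b <- data.frame(subject = c(1, 1, 1, 1, 2, 2),
                  condition = c("a", "a", "b", "b", "a", "a"),
                  rt_ms = c(300, 400, 500, 500, 350, 350),
                  correct = TRUE)
  out <- within_subject_rt_sd(b)
  expect_equal(out$rt_sd[out$subject == 1 & out$condition == "a"],
               70.71068, tolerance = 1e-5)
  expect_equal(out$rt_sd[out$subject == 1 & out$condition == "b"], 0)
  # a cell with fewer than 2 correct trials yields NA with a warning
  b2 <- b
  b2$correct[5] <- FALSE
  expect_warning(out2 <- within_subject_rt_sd(b2), "fewer than 2")
  expect_true(is.na(out2$rt_sd[out2$subject == 2]))
})

test_that("the normality check reproduces the Lilliefors statistic", {
  skip_if_not_installed("nortest")
  set.seed(17)
  for (x in list(rnorm(40), rexp(30), rnorm(150, 5, 2))) {
    got <- ks_normality(x)
    ref <- nortest::lillie.test(x)
    expect_equal(got$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(got$z, got$D * sqrt(length(x)))
  }
  # gross violation is detected
  expect_lt(ks_normality(c(rnorm(30), rep(25, 8)))$p, 0.01)
  # a clean normal sample at a fixed seed is not rejected
  set.seed(18)
  expect_gt(ks_normality(rnorm(80))$p, 0.1)
  expect_error(ks_normality(c(1, 2, 3)), "at least 5")
  expect_error(ks_normality(rep(2, 10)), "zero variance")
})
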