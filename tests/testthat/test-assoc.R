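test_that("one-way ANOVA matches hand computation and degenerate contracts", {
  a <- anova_oneway(c(1, 2, 1, 2), rep(c("g1", "g2"), each = 2))
  expect_equal(a$F, 0)
  expect_equal(a$p_value, 1)
  # groups (1,2,3) vs (4,5,6): SSB = 13.5, MSW = 1 -> F = 13.5
  a2 <- anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(a2$F, 13.5)
  expect_equal(a2$p_value, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_error(anova_oneway(1:3, c("a", "a", "a")), ">= 2 groups")
})

test_that("summary-based ANOVA equals the raw form on exact summaries", {
  set.seed(1)
  vals <- rnorm(60, rep(c(0, 0.5, 1.2), each = 20))
  grp <- rep(c("a", "b", "c"), each = 20)
  raw <- anova_oneway(vals, grp)
  s <- anova_from_summary(n = tapply(vals, grp, length),
                          mean = tapply(vals, grp, mean),
                          sd = tapply(vals, grp, sd))
  expect_equal(s$F, raw$F)
  expect_equal(s$p_value, raw$p_value)
})

test_that("Tukey HSD agrees with an independent studentized-range oracle", {
  set.seed(2)
  vals <- rnorm(45, rep(c(0, 1, 3), each = 15))
  grp <- rep(c("a", "b", "c"), each = 15)
  tk <- tukey_hsd(vals, grp)
  # oracle: direct ptukey computation from group summaries
  n <- tapply(vals, grp, length); m <- tapply(vals, grp, mean)
  s <- tapply(vals, grp, sd)
  df <- sum(n) - 3
  mse <- sum((n - 1) * s^2) / df
  for (r in seq_len(nrow(tk))) {
    i <- tk$group1[r]; j <- tk$group2[r]
    q <- abs(m[j] - m[i]) / sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
    expect_equal(tk$p_adj[r], unname(ptukey(q, 3, df, lower.tail = FALSE)),
                 tolerance = 1e-8)
  }
  # zero mean difference -> adjusted p = 1
  vals0 <- c(1, 2, 3, 1, 2, 3, 10, 11, 12)
  grp0 <- rep(c("a", "b", "c"), each = 3)
  tk0 <- tukey_hsd(vals0, grp0)
  expect_equal(tk0$p_adj[tk0$group1 == "a" & tk0$group2 == "b"], 1,
               tolerance = 1e-12)
  expect_error(tukey_hsd(1:5, rep("a", 5)), ">= 2 groups")
})

test_that("summary Tukey equals raw Tukey and is monotone in |diff|", {
  set.seed(3)
  vals <- rnorm(80, rep(c(0, 0.4, 1, 2), each = 20), 1.3)
  grp <- rep(c("a", "b", "c", "d"), each = 20)
  raw <- tukey_hsd(vals, grp)
  smry <- tukey_from_summary(labels = c("a", "b", "c", "d"),
                             n = tapply(vals, grp, length),
                             mean = tapply(vals, grp, mean),
                             sd = tapply(vals, grp, sd))
  key <- function(d) paste(d$group1, d$group2)
  smry <- smry[match(key(raw), key(smry)), ]
  expect_equal(smry$diff, raw$diff, tolerance = 1e-10)
  expect_equal(smry$p_adj, raw$p_adj, tolerance = 1e-8)

  # equal means -> all p = 1; p monotone nonincreasing in |diff|
  eq <- tukey_from_summary(c("a", "b"), c(10, 10), c(5, 5), c(1, 1))
  expect_equal(eq$p_adj, 1, tolerance = 1e-12)
  diffs <- seq(0, 3, by = 0.5)
  ps <- vapply(diffs, function(d)
    tukey_from_summary(c("a", "b"), c(20, 20), c(0, d), c(1, 1))$p_adj,
    numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(tukey_from_summary("a", 10, 1, 1), ">= 2")
  expect_error(tukey_from_summary(c("a", "b"), c(10, 10), c(0, 1), c(1, -1)),
               "sd")
})

test_that("Kruskal-Wallis matches hand ranking and is rank-invariant", {
  expect_equal(kruskal_wallis(rep(1, 6), rep(c("a", "b"), 3))$p_value, 1)
  # (1,2,3) vs (10,11,12): ranks 1-3 vs 4-6, H = 12/42 * 13.5 = 27/7
  kw <- kruskal_wallis(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)
  expect_equal(kw$p_value, pchisq(27 / 7, 1, lower.tail = FALSE))
  set.seed(4)
  v <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  expect_equal(kruskal_wallis(exp(v), g)$H, kruskal_wallis(v, g)$H)
})

test_that("chi-squared residuals satisfy the 2x2 identity and independence", {
  ind <- outer(c(30, 70), c(40, 60)) / 100   # exact independence
  r <- chi2_rxc(ind)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_true(all(abs(r$adjusted_residuals) < 1e-8))

  set.seed(5)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 30) + 1, 2)
    r2 <- chi2_rxc(tab)
    expect_equal(unname(r2$adjusted_residuals^2),
                 matrix(r2$statistic, 2, 2), tolerance = 1e-8)
  }
  expect_error(chi2_rxc(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(chi2_rxc(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("allele 2x2 association: OR, correction and errors", {
  r <- allele_assoc_2x2(30, 100, 30, 100)
  expect_equal(r$or, 1)
  expect_gt(r$p_value, 0.99)
  # cross-product by hand: (30*85)/(70*15) = 2.428...
  r2 <- allele_assoc_2x2(30, 100, 15, 100)
  expect_equal(round(r2$or, 2), 2.43)
  expect_equal(r2$log_or_se, sqrt(1 / 30 + 1 / 70 + 1 / 15 + 1 / 85))
  r3 <- allele_assoc_2x2(0, 50, 10, 50)
  expect_true(r3$corrected)
  expect_true(is.finite(r3$or) && r3$or > 0)
  expect_error(allele_assoc_2x2(5, 0, 3, 10), "zero allele total")
  expect_error(allele_assoc_2x2(15, 10, 3, 10), "exceeds")
})

test_that("fixed-effect meta-analysis pools by inverse variance", {
  one <- allele_assoc_2x2(40, 100, 25, 100)
  single <- meta_fixed(studies = list(one))
  expect_equal(single$log_or, one$log_or)
  expect_equal(single$se, one$log_or_se)

  twin <- meta_fixed(studies = list(one, one))
  expect_equal(twin$or, one$or)
  expect_equal(twin$se, one$log_or_se / sqrt(2))
  expect_equal(twin$Q, 0)

  # hand-computed weighted average
  b <- c(0.4, 0.9); s <- c(0.2, 0.3)
  m <- meta_fixed(b, s)
  w <- 1 / s^2
  expect_equal(m$log_or, sum(w * b) / sum(w))
  expect_equal(m$se, 1 / sqrt(sum(w)))
  expect_equal(m$Q, sum(w * (b - m$log_or)^2))
  # pooled estimate bounded by the study estimates
  set.seed(6)
  for (i in 1:20) {
    bi <- rnorm(3); si <- runif(3, 0.1, 0.5)
    mi <- meta_fixed(bi, si)
    expect_gte(mi$log_or, min(bi)); expect_lte(mi$log_or, max(bi))
  }
  expect_error(meta_fixed(c(1, 2), c(0.1, 0)), "positive SE")
})

test_that("adjusted logistic regression recovers effects and flags separation", {
  set.seed(7)
  n <- 2000
  g <- rbinom(n, 2, 0.3)
  sex <- rbinom(n, 1, 0.5); age <- rnorm(n, 50, 10)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * g + 0.3 * sex + 0.01 * (age - 50)))
  r <- logistic_adjusted(y, g, data.frame(sex = sex, age = age))
  expect_false(r$separation)
  expect_lt(abs(r$log_or - 0.5), 3 * r$se)

  # no-covariate binary-dosage fit equals the saturated cross-product OR
  tab <- c(a = 40, b = 60, c = 20, d = 80)  # cases/controls by carrier
  y2 <- rep(c(1, 1, 0, 0), tab)
  g2 <- rep(c(1, 0, 1, 0), tab)
  r2 <- logistic_adjusted(y2, g2)
  expect_equal(r2$or, (40 * 80) / (60 * 20), tolerance = 1e-6)

  # null coverage: coefficient within 3 SEs of zero nearly always
  ok <- 0
  for (s in 1:20) {
    set.seed(700 + s)
    gg <- rbinom(600, 2, 0.3)
    yy <- rbinom(600, 1, 0.4)
    rr <- logistic_adjusted(yy, gg)
    ok <- ok + (abs(rr$log_or) < 3 * rr$se)
  }
  expect_gte(ok, 19)

  # perfect separation flagged, no estimate
  ys <- c(rep(0, 20), rep(1, 20))
  gs <- c(rep(0, 20), rep(2, 20))
  rs <- logistic_adjusted(ys, gs)
  expect_true(rs$separation)
  expect_true(is.na(rs$or))
})

test_that("interaction GLM: null rate, recovery, degenerate dosage", {
  rej <- 0; R <- 200
  for (s in 1:R) {
    set.seed(1000 + s)
    ga <- rbinom(400, 2, 0.3); gb <- rbinom(400, 2, 0.4)
    y <- rbinom(400, 1, plogis(-0.5 + 0.2 * ga + 0.1 * gb))
    r <- glm_interaction(y, ga, gb)
    rej <- rej + (!is.na(r$p_value) && r$p_value < 0.05)
  }
  expect_lt(abs(rej / R - 0.05), 3 * sqrt(0.05 * 0.95 / R) + 1e-9)

  set.seed(8)
  ga <- rbinom(6000, 2, 0.3); gb <- rbinom(6000, 2, 0.4)
  y <- rbinom(6000, 1, plogis(-1 + 0.2 * ga + 0.1 * gb + 0.6 * ga * gb))
  r <- glm_interaction(y, ga, gb)
  expect_lt(abs(r$coef - 0.6), 3 * r$se)

  rd <- glm_interaction(rbinom(100, 1, 0.5), rbinom(100, 2, 0.3), rep(1, 100))
  expect_true(rd$dropped)
})
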