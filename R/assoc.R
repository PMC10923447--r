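# Inferential statistics used by the pipeline: one-way ANOVA and Tukey HSD
# (raw-data and summary-statistic forms), Kruskal-Wallis, r x c chi-squared
# with adjusted standardized residuals, allele-based 2x2 association with
# odds ratios, inverse-variance fixed-effect meta-analysis, and logistic
# models for covariate adjustment and gene-gene interaction.

#' One-way ANOVA
#'
#' @param values numeric vector.
#' @param groups group labels, >= 2 groups with n >= 2 each.
#' @return List with `F`, `df1`, `df2`, `p_value`. All values identical
#'   gives F = 0, p = 1.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_bad("need >= 2 groups")
  n <- tapply(values, groups, length)
  if (any(n < 2)) stop_bad("each group needs n >= 2")
  m <- tapply(values, groups, mean)
  gm <- mean(values)
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((values - m[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  if (ssw == 0 && ssb == 0) return(list(F = 0, df1 = df1, df2 = df2, p_value = 1))
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2, p_value = pf(F, df1, df2, lower.tail = FALSE))
}

#' One-way ANOVA from group summary statistics
#'
#' Equivalent to [anova_oneway()] when the summaries exactly describe the
#' raw data: between-group and within-group sums of squares are rebuilt
#' from per-group n, mean and sd.
#'
#' @param n,mean,sd per-group size, mean and standard deviation.
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
anova_from_summary <- function(n, mean, sd) {
  k <- length(n)
  if (k < 2) stop_bad("need >= 2 groups")
  if (any(n < 2)) stop_bad("all n must be >= 2")
  gm <- sum(n * mean) / sum(n)
  ssb <- sum(n * (mean - gm)^2)
  ssw <- sum((n - 1) * sd^2)
  df1 <- k - 1
  df2 <- sum(n) - k
  if (ssw == 0 && ssb == 0) return(list(F = 0, df1 = df1, df2 = df2, p_value = 1))
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2, p_value = pf(F, df1, df2, lower.tail = FALSE))
}

#' Tukey HSD on raw data
#'
#' All-pairs comparisons after one-way ANOVA with family-wise adjusted
#' p-values from the studentized range distribution (Tukey-Kramer standard
#' errors for unequal group sizes). This form delegates to
#' [stats::TukeyHSD()]; [tukey_from_summary()] is an independent
#' implementation from group summaries and the two agree on exactly
#' summarized data.
#'
#' @inheritParams anova_oneway
#' @return data.frame with `group1`, `group2`, `diff` (mean of `group2`
#'   minus mean of `group1`), `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_bad("need >= 2 groups")
  fit <- aov(values ~ groups, data = data.frame(values = values, groups = groups))
  tk <- TukeyHSD(fit)$groups
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  data.frame(group1 = pairs[, 2], group2 = pairs[, 1],
             diff = unname(tk[, "diff"]), p_adj = unname(tk[, "p adj"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tukey HSD from group summary statistics
#'
#' Reconstructs the Tukey-Kramer comparisons from per-group n, mean and
#' sd alone, with pooled mean square error
#' `MSE = sum((n_i - 1) s_i^2) / sum(n_i - 1)` and adjusted p-values from
#' the studentized range with `k` means and `N - k` degrees of freedom.
#' Identical in contract to [tukey_hsd()]; equal to it when the summaries
#' exactly describe the raw data.
#'
#' @param labels group labels.
#' @param n,mean,sd per-group size, mean and standard deviation.
#' @return data.frame as in [tukey_hsd()], plus `se` and `q`.
#' @export
tukey_from_summary <- function(labels, n, mean, sd) {
  k <- length(labels)
  stopifnot(length(n) == k, length(mean) == k, length(sd) == k)
  if (k < 2) stop_bad("need >= 2 groups")
  if (any(n < 2)) stop_bad("all n must be >= 2")
  if (any(sd < 0)) stop_bad("sd must be >= 0")
  df <- sum(n) - k
  mse <- sum((n - 1) * sd^2) / df
  idx <- which(upper.tri(diag(k)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  diff <- mean[j] - mean[i]
  se_q <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
  q <- ifelse(se_q == 0, 0, abs(diff) / se_q)
  p <- ifelse(q == 0, 1, ptukey(q, nmeans = k, df = df, lower.tail = FALSE))
  data.frame(group1 = labels[i], group2 = labels[j], diff = diff,
             se = se_q, q = q, p_adj = pmin(1, p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-squared reference distribution. All values
#' tied gives H = 0, p = 1.
#'
#' @inheritParams anova_oneway
#' @return List with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_bad("need >= 2 groups")
  if (length(unique(values)) == 1)
    return(list(H = 0, df = nlevels(groups) - 1, p_value = 1))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Pearson chi-squared test with adjusted standardized residuals
#'
#' For an r x c table of counts, tests independence (no continuity
#' correction by default) and reports the adjusted residual
#' `r_ij = (O_ij - E_ij) / sqrt(E_ij (1 - row_i/N) (1 - col_j/N))`,
#' approximately N(0,1) per cell under independence. On a 2x2 table each
#' squared adjusted residual equals the chi-squared statistic.
#'
#' @param observed matrix of non-negative integer counts.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return List with `statistic`, `df`, `p_value`, `expected`,
#'   `adjusted_residuals`.
#' @export
chi2_rxc <- function(observed, correct = FALSE) {
  observed <- as.matrix(observed)
  assert_counts(observed, "observed counts")
  if (sum(observed) < 1) stop_bad("grand total must be >= 1")
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
    stop_bad("zero row or column margin")
  ct <- suppressWarnings(chisq.test(observed, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected,
       adjusted_residuals = ct$stdres)
}

#' Allele-based 2x2 case-control association
#'
#' Compares risk-allele frequencies between two groups on the allele scale
#' (each individual contributes two alleles): Pearson chi-squared p-value
#' (no continuity correction) and the cross-product odds ratio with a
#' Haldane-Anscombe +0.5 correction applied to all cells iff any cell is
#' zero, so the OR and the SE of its log stay finite.
#'
#' @param risk_count_case,allele_total_case risk-allele count and total
#'   allele count in the case (or comparison) group.
#' @param risk_count_ctrl,allele_total_ctrl same for the reference group.
#' @return An `assoc_result` list: `or`, `log_or`, `log_or_se`, `p_value`,
#'   `counts`, `corrected`.
#' @export
allele_assoc_2x2 <- function(risk_count_case, allele_total_case,
                             risk_count_ctrl, allele_total_ctrl) {
  assert_counts(c(risk_count_case, allele_total_case,
                  risk_count_ctrl, allele_total_ctrl), "allele counts")
  if (allele_total_case == 0 || allele_total_ctrl == 0)
    stop_bad("zero allele total in one arm")
  if (risk_count_case > allele_total_case ||
      risk_count_ctrl > allele_total_ctrl)
    stop_bad("risk-allele count exceeds its total")
  a <- risk_count_case; b <- allele_total_case - a
  c <- risk_count_ctrl; d <- allele_total_ctrl - c
  tab <- matrix(c(a, c, b, d), 2)
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1 else
    suppressWarnings(chisq.test(tab, correct = FALSE))$p.value
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  structure(list(or = or, log_or = log(or), log_or_se = se, p_value = p,
                 counts = c(a_case = risk_count_case, b_case = allele_total_case - risk_count_case,
                            a_ctrl = risk_count_ctrl, b_ctrl = allele_total_ctrl - risk_count_ctrl),
                 corrected = corrected),
            class = "assoc_result")
}

#' Fixed-effect (inverse-variance) meta-analysis of log odds ratios
#'
#' Pools per-study log ORs with weights 1/SE^2; reports the pooled OR, its
#' SE, the two-sided Wald p-value, Cochran's Q and I^2.
#'
#' @param log_or,se numeric vectors (one entry per study), or alternatively
#'   `studies`, a list of `assoc_result` objects.
#' @param studies optional list of [allele_assoc_2x2()] results.
#' @return List with `log_or`, `se`, `or`, `p_value`, `Q`, `I2`, `k`.
#' @export
meta_fixed <- function(log_or = NULL, se = NULL, studies = NULL) {
  if (!is.null(studies)) {
    log_or <- vapply(studies, `[[`, numeric(1), "log_or")
    se <- vapply(studies, `[[`, numeric(1), "log_or_se")
  }
  if (!length(log_or) || length(log_or) != length(se))
    stop_bad("need matching log_or and se vectors with >= 1 study")
  if (any(!is.finite(log_or)) || any(!is.finite(se)) || any(se <= 0))
    stop_bad("all studies need finite log OR and positive SE")
  w <- 1 / se^2
  pooled <- sum(w * log_or) / sum(w)
  pse <- 1 / sqrt(sum(w))
  z <- pooled / pse
  Q <- sum(w * (log_or - pooled)^2)
  k <- length(log_or)
  I2 <- if (Q > 0 && k > 1) max(0, (Q - (k - 1)) / Q) * 100 else 0
  list(log_or = pooled, se = pse, or = exp(pooled),
       p_value = 2 * pnorm(-abs(z)), Q = Q, I2 = I2, k = k)
}

# shared logistic fit with separation detection
fit_logistic <- function(df, formula) {
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!sep) {
    se <- sqrt(diag(vcov(fit)))
    if (any(!is.finite(se)) || any(se > 50)) sep <- TRUE
  }
  list(fit = fit, separation = sep)
}

#' Covariate-adjusted logistic association of a genotype
#'
#' Logistic regression of the case/control outcome on the additive
#' genotype dosage (0/1/2) plus covariates, fit by IRLS; reports the Wald
#' per-allele OR and p-value. Perfect or quasi-separation is detected and
#' flagged, with no estimate returned.
#'
#' @param outcome 0/1 (or logical / two-level factor) case indicator.
#' @param dosage additive genotype dosage.
#' @param covariates optional data.frame (e.g. sex, age, smoking index).
#' @return List with `or`, `log_or`, `se`, `p_value`, `separation`, `n`.
#' @export
logistic_adjusted <- function(outcome, dosage, covariates = NULL) {
  y <- if (is.factor(outcome)) as.integer(outcome) - 1L else as.integer(outcome)
  df <- data.frame(.y = y, .g = as.numeric(dosage))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) <= ncol(df) + 1) stop_bad("n must exceed the parameter count")
  rhs <- paste(setdiff(names(df), ".y"), collapse = " + ")
  res <- fit_logistic(df, stats::as.formula(paste(".y ~", rhs)))
  if (res$separation)
    return(list(or = NA_real_, log_or = NA_real_, se = NA_real_,
                p_value = NA_real_, separation = TRUE, n = nrow(df)))
  b <- coef(res$fit)[".g"]
  se <- sqrt(vcov(res$fit)[".g", ".g"])
  list(or = unname(exp(b)), log_or = unname(b), se = unname(se),
       p_value = unname(2 * pnorm(-abs(b / se))), separation = FALSE,
       n = nrow(df))
}

#' Gene-gene interaction test in a logistic GLM
#'
#' Logistic model with both main dosage effects, their product, and
#' optional covariates; Wald test on the product coefficient. If one
#' dosage is constant the product term is dropped and flagged.
#'
#' @inheritParams logistic_adjusted
#' @param dosage_a,dosage_b additive dosages of the two variants.
#' @return List with `coef` (interaction log OR), `se`, `p_value`,
#'   `dropped` (TRUE if the product term was inestimable), `separation`.
#' @export
glm_interaction <- function(outcome, dosage_a, dosage_b, covariates = NULL) {
  y <- if (is.factor(outcome)) as.integer(outcome) - 1L else as.integer(outcome)
  df <- data.frame(.y = y, .ga = as.numeric(dosage_a),
                   .gb = as.numeric(dosage_b))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[complete.cases(df), , drop = FALSE]
  if (var(df$.ga) == 0 || var(df$.gb) == 0)
    return(list(coef = NA_real_, se = NA_real_, p_value = NA_real_,
                dropped = TRUE, separation = FALSE))
  rhs <- paste(c(".ga * .gb", setdiff(names(df), c(".y", ".ga", ".gb"))),
               collapse = " + ")
  res <- fit_logistic(df, stats::as.formula(paste(".y ~", rhs)))
  if (res$separation)
    return(list(coef = NA_real_, se = NA_real_, p_value = NA_real_,
                dropped = FALSE, separation = TRUE))
  b <- coef(res$fit)[".ga:.gb"]
  se <- sqrt(vcov(res$fit)[".ga:.gb", ".ga:.gb"])
  list(coef = unname(b), se = unname(se),
       p_value = unname(2 * pnorm(-abs(b / se))),
       dropped = FALSE, separation = FALSE)
}
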