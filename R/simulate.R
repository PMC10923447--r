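#' Simulation configuration
#'
#' Describes the stated world the generator draws from: cohorts with fixed
#' healthy/case sizes, biallelic variants with risk-allele frequencies and
#' optional within-block LD, and a latent phenotype mixture for the cases
#' in which cluster membership can be coupled to the genetic risk score.
#'
#' @param cohorts data.frame with `name`, `n_healthy`, `n_case`.
#' @param variants data.frame with `rsid`, `gene`, `p` (risk-allele
#'   frequency in \[0,1\]); optional `ld_block` (block id or `NA` for
#'   unlinked), `block_r2` (target pairwise r2 within the block) and
#'   `effect_weight` (relative contribution to the GRS-cluster coupling
#'   score, default 1 for all).
#' @param clusters data.frame of latent case components with `name`,
#'   `weight` (mixing proportion, summing to 1), `onset_mean`, `onset_sd`
#'   (age of asthma onset, years), `fev1_mean`, `fev1_sd` (%predicted
#'   FEV1), `delta` (log-odds coupling of membership to the centered GRS;
#'   positive enriches high-GRS cases), `female_p`, `atopy_p`, `eos_p`.
#' @param seed root seed; per-cohort child streams are derived from it so
#'   cohorts reproduce bit-identically when re-run independently.
#' @param mode `"planted"` uses the configured `delta`; `"null"` forces
#'   all couplings to zero so genotypes are independent of phenotype.
#' @param missing_rate uniform dosage missingness rate (default 0; only
#'   needed to exercise call-rate QC).
#' @return A `sim_config` list.
#' @export
sim_config <- function(cohorts, variants, clusters, seed = 1L,
                       mode = c("planted", "null"), missing_rate = 0) {
  mode <- match.arg(mode)
  cohorts <- as.data.frame(cohorts)
  variants <- as.data.frame(variants)
  clusters <- as.data.frame(clusters)
  stopifnot(all(c("name", "n_healthy", "n_case") %in% names(cohorts)),
            all(c("rsid", "gene", "p") %in% names(variants)),
            all(c("name", "weight", "onset_mean", "onset_sd",
                  "fev1_mean", "fev1_sd", "delta",
                  "female_p", "atopy_p", "eos_p") %in% names(clusters)))
  if (any(cohorts$n_healthy < 0) || any(cohorts$n_case < 0))
    stop_bad("cohort sizes must be >= 0")
  assert_prob(variants$p, "risk allele frequencies")
  assert_prob(c(clusters$weight, clusters$female_p, clusters$atopy_p,
                clusters$eos_p), "cluster probabilities")
  if (abs(sum(clusters$weight) - 1) > 1e-8)
    stop_bad("cluster weights must sum to 1")
  if (nrow(clusters) == 0 && any(cohorts$n_case > 0))
    stop_bad("a cohort with cases needs a non-empty cluster list")
  assert_prob(missing_rate, "missing_rate")
  if (is.null(variants$ld_block)) variants$ld_block <- NA
  if (is.null(variants$block_r2)) variants$block_r2 <- NA_real_
  if (is.null(variants$effect_weight)) variants$effect_weight <- 1
  structure(list(cohorts = cohorts, variants = variants,
                 clusters = clusters, seed = as.integer(seed),
                 mode = mode, missing_rate = missing_rate),
            class = "sim_config")
}

#' Default three-cohort configuration
#'
#' Three cohorts of the modeled sizes (565/537, 965/242 and 673/446
#' healthy/case), the packaged 12-SNP panel with its reference MAFs as
#' risk-allele frequencies, no within-gene LD by default, and four latent
#' case components echoing the canonical adult-asthma phenotype patterns:
#' a late-onset preserved-lung-function component coupled to high GRS, a
#' smoker component with airflow limitation, an early-onset atopic
#' component, and a late-onset component coupled to low GRS.
#'
#' @param seed root seed (default 1).
#' @param mode `"planted"` or `"null"`.
#' @return A `sim_config`.
#' @export
default_sim_config <- function(seed = 1L, mode = "planted") {
  pan <- default_panel()
  variants <- data.frame(rsid = pan$rsid, gene = pan$gene, p = pan$maf)
  cohorts <- data.frame(name = c("cohort1", "cohort2", "cohort3"),
                        n_healthy = c(565L, 965L, 673L),
                        n_case = c(537L, 242L, 446L))
  clusters <- data.frame(
    name = c("A", "B", "C", "D"),
    weight = c(0.30, 0.25, 0.23, 0.22),
    onset_mean = c(50, 48, 12, 60), onset_sd = c(13, 15, 8, 10),
    fev1_mean = c(94, 53, 81, 98), fev1_sd = c(15, 12, 17, 19),
    delta = c(0.4, 0, 0, -0.4),
    female_p = c(0.66, 0.44, 0.54, 0.56),
    atopy_p = c(0.63, 0.69, 0.85, 0.63),
    eos_p = c(0.39, 0.48, 0.48, 0.37))
  sim_config(cohorts, variants, clusters, seed = seed, mode = mode)
}

# P(Z1 < t1, Z2 < t2) for standard bivariate normal with correlation rho,
# by 1-D quadrature (avoids an external multivariate-normal dependency)
pbinorm <- function(t1, t2, rho) {
  if (abs(rho) >= 1 - 1e-12) return(pnorm(min(t1, t2)))
  integrate(function(z) pnorm((t2 - rho * z) / sqrt(1 - rho^2)) * dnorm(z),
            -Inf, t1, rel.tol = 1e-10)$value
}

# latent Gaussian correlation giving allele-indicator correlation r_target
# between Bernoulli(pa) and Bernoulli(pb) thresholds
calibrate_rho <- function(pa, pb, r_target) {
  if (r_target <= 0) return(0)
  ta <- qnorm(pa); tb <- qnorm(pb)
  f <- function(rho)
    (pbinorm(ta, tb, rho) - pa * pb) / sqrt(pa * (1 - pa) * pb * (1 - pb)) -
      r_target
  if (f(1 - 1e-9) < 0) return(1)   # target unattainable: cap at comonotone
  uniroot(f, c(0, 1 - 1e-9), tol = 1e-9)$root
}

#' Generate genotypes
#'
#' Unlinked variants are drawn binomial(2, p) per individual (HWE).
#' Variants sharing an `ld_block` are drawn from a shared latent Gaussian
#' factor per haplotype, thresholded to alleles, with the factor loading
#' calibrated so the expected pairwise dosage r2 tracks the block's
#' `block_r2`. Uses the current RNG state; callers set the seed (see
#' [gen_cohort()] for the per-cohort streams).
#'
#' @param config a `sim_config`.
#' @param n number of individuals.
#' @param prefix sample-id prefix.
#' @return Dosage matrix (n x K).
#' @export
gen_genotypes <- function(config, n, prefix = "S") {
  v <- config$variants
  assert_prob(v$p, "risk allele frequencies")
  K <- nrow(v)
  m <- matrix(NA_integer_, n, K,
              dimnames = list(sprintf("%s%04d", prefix, seq_len(n)), v$rsid))
  if (n == 0) return(m)
  unlinked <- is.na(v$ld_block)
  for (j in which(unlinked)) m[, j] <- rbinom(n, 2, v$p[j])
  for (b in unique(v$ld_block[!unlinked])) {
    idx <- which(!is.na(v$ld_block) & v$ld_block == b)
    if (length(idx) == 1) { m[, idx] <- rbinom(n, 2, v$p[idx]); next }
    r2 <- v$block_r2[idx[1]]
    assert_prob(r2, "block_r2")
    r_target <- sqrt(r2)
    # exchangeable factor model: pairwise latent correlation rho_lat,
    # calibrated on the first pair of the block
    rho_lat <- calibrate_rho(v$p[idx[1]], v$p[idx[2]], r_target)
    for (hap in 1:2) {
      f <- rnorm(n)
      z <- sqrt(rho_lat) * f +
        sqrt(1 - rho_lat) * matrix(rnorm(n * length(idx)), n)
      al <- sweep(z, 2, qnorm(v$p[idx]), `<`)
      m[, idx] <- (if (hap == 1) 0L else m[, idx]) + al
    }
  }
  if (config$missing_rate > 0)
    m[matrix(runif(n * K) < config$missing_rate, n, K)] <- NA_integer_
  storage.mode(m) <- "integer"
  m
}

#' Generate one synthetic cohort
#'
#' Healthy individuals receive genotypes plus covariates. In `"planted"`
#' mode each case's latent cluster is drawn with probability proportional
#' to `weight * exp(delta * S)`, where S is the case's centered,
#' effect-weighted risk-allele count — a logistic tilt that enriches
#' high-GRS cases in positive-`delta` clusters while keeping marginal
#' allele frequencies exact. Phenotypes are then drawn from
#' cluster-specific distributions. In `"null"` mode all couplings are zero
#' and genotypes are independent of phenotype.
#'
#' @param config a `sim_config`.
#' @param cohort cohort name or index (default 1).
#' @return A list of class `synthetic_cohort`: `genotypes` (dosage matrix,
#'   healthy then cases), `phenotypes` (data.frame), `truth` (per-case
#'   latent cluster label and the configured allele frequencies).
#' @export
gen_cohort <- function(config, cohort = 1L) {
  co <- config$cohorts
  i <- if (is.character(cohort)) match(cohort, co$name) else as.integer(cohort)
  if (is.na(i) || i < 1 || i > nrow(co)) stop_bad("unknown cohort: ", cohort)
  if (co$n_case[i] > 0 && nrow(config$clusters) == 0)
    stop_bad("cohort ", co$name[i], " has cases but the cluster list is empty")
  set.seed(child_seed(config$seed, i))
  n_h <- co$n_healthy[i]; n_c <- co$n_case[i]
  pfx <- sprintf("%s_", co$name[i])
  g_h <- gen_genotypes(config, n_h, prefix = paste0(pfx, "H"))
  g_c <- gen_genotypes(config, n_c, prefix = paste0(pfx, "C"))

  cl <- config$clusters
  delta <- if (config$mode == "null") rep(0, nrow(cl)) else cl$delta
  w <- config$variants$effect_weight
  p <- config$variants$p
  # centered effect-weighted allele count drives the membership tilt
  s <- as.numeric(g_c %*% w) - sum(2 * p * w)
  lab <- integer(n_c)
  if (n_c > 0) {
    lw <- outer(s, delta) + matrix(log(cl$weight), n_c, nrow(cl), byrow = TRUE)
    pr <- exp(lw - apply(lw, 1, max))
    pr <- pr / rowSums(pr)
    u <- runif(n_c)
    cum <- t(apply(pr, 1, cumsum))
    lab <- 1L + rowSums(cum < u)
  }

  draw_clip <- function(mu, sdv, lo, hi) pmin(hi, pmax(lo, rnorm(length(mu), mu, sdv)))
  onset <- draw_clip(cl$onset_mean[lab], cl$onset_sd[lab], 0, 87)
  fev1 <- draw_clip(cl$fev1_mean[lab], cl$fev1_sd[lab], 20, 140)
  age_case <- pmin(90, onset + rexp(n_c, 1 / 15))
  sex_case <- ifelse(runif(n_c) < cl$female_p[lab], "female", "male")
  atopy_case <- runif(n_c) < cl$atopy_p[lab]
  eos_case <- runif(n_c) < cl$eos_p[lab]

  age_h <- draw_clip(rep(50, n_h), rep(14, n_h), 20, 90)
  ph <- data.frame(
    sample_id = c(rownames(g_h), rownames(g_c)),
    cohort = co$name[i],
    status = rep(c("healthy", "asthma"), c(n_h, n_c)),
    sex = c(ifelse(runif(n_h) < 0.5, "female", "male"), sex_case),
    age = round(c(age_h, age_case), 1),
    onset_age = c(rep(NA_real_, n_h), round(onset, 1)),
    fev1pct = round(c(draw_clip(rep(97, n_h), rep(11, n_h), 50, 140), fev1), 1),
    fev1_fvc = round(pmin(95, pmax(30, 0.62 * c(rep(97, n_h), fev1) +
                                     rnorm(n_h + n_c, 12, 4))), 1),
    bmi = round(draw_clip(rep(23.5, n_h + n_c), rep(4, n_h + n_c), 14, 45), 1),
    smoking_status = sample(c("never", "ex", "current"), n_h + n_c,
                            replace = TRUE, prob = c(0.55, 0.3, 0.15)),
    atopy = c(runif(n_h) < 0.35, atopy_case),
    log_ige = round(rnorm(n_h + n_c, 2.2, 0.65), 2),
    eosinophilic = c(runif(n_h) < 0.15, eos_case),
    stringsAsFactors = FALSE)
  ph$smoking_index <- ifelse(ph$smoking_status == "never", 0,
                             round(pmax(0, rnorm(n_h + n_c, 300, 200))))
  truth <- data.frame(sample_id = ph$sample_id,
                      cluster = c(rep(NA_character_, n_h),
                                  cl$name[lab]),
                      stringsAsFactors = FALSE)
  structure(list(genotypes = rbind(g_h, g_c), phenotypes = ph, truth = truth,
                 true_freq = setNames(p, config$variants$rsid),
                 cohort = co$name[i], mode = config$mode),
            class = "synthetic_cohort")
}

#' Generate all configured cohorts
#'
#' @param config a `sim_config`.
#' @return Named list of `synthetic_cohort` objects, one per cohort, each
#'   generated from its own child RNG stream.
#' @export
simulate_cohorts <- function(config) {
  out <- lapply(seq_len(nrow(config$cohorts)), function(i)
    gen_cohort(config, i))
  names(out) <- config$cohorts$name
  out
}

#' Write a synthetic cohort to disk
#'
#' Genotypes as a TSV dosage matrix (and optionally VCF), phenotypes and
#' truth labels as TSV.
#'
#' @param dataset a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param vcf also write a VCF (needs a panel with `other_allele`).
#' @param panel panel used for VCF metadata; default [default_panel()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir, vcf = FALSE, panel = default_panel()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, dataset$cohort)
  write_dosage_tsv(dataset$genotypes, paste0(stem, "_dosage.tsv"))
  write.table(dataset$phenotypes, paste0(stem, "_phenotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$truth, paste0(stem, "_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (vcf) write_vcf(dataset$genotypes, panel, paste0(stem, ".vcf"))
  invisible(dir)
}
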