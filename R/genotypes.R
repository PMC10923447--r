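# Genotype container: a plain integer matrix, rows = samples, columns =
# variants, dimnames = (sample_ids, rsids), entries in {0, 1, 2, NA}
# counting copies of the risk allele.

check_genotypes <- function(genotypes) {
  if (!is.matrix(genotypes)) stop_bad("genotypes must be a matrix")
  if (is.null(rownames(genotypes)) || is.null(colnames(genotypes)))
    stop_bad("genotypes must carry sample ids (rownames) and rsids (colnames)")
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && (any(vals < 0) || any(vals > 2)))
    stop_bad("dosages must lie in {0, 1, 2} or be NA")
  invisible(genotypes)
}

#' Minor allele frequency from dosages
#'
#' Computes, per variant, f = (sum of dosages) / (2 * number of non-missing
#' samples) and folds it to the minor side, `min(f, 1 - f)`.
#'
#' @param genotypes dosage matrix (samples x variants).
#' @param rsid optional single variant; if given a scalar is returned.
#' @return Named numeric vector of MAFs (or a scalar for one `rsid`).
#' @export
compute_maf <- function(genotypes, rsid = NULL) {
  check_genotypes(genotypes)
  if (!is.null(rsid)) {
    if (!rsid %in% colnames(genotypes)) stop_bad("unknown variant: ", rsid)
    genotypes <- genotypes[, rsid, drop = FALSE]
  }
  n_ok <- colSums(!is.na(genotypes))
  if (any(n_ok == 0))
    stop_bad("all dosages missing for variant(s): ",
             paste(colnames(genotypes)[n_ok == 0], collapse = ", "))
  f <- colSums(genotypes, na.rm = TRUE) / (2 * n_ok)
  maf <- pmin(f, 1 - f)
  if (!is.null(rsid)) unname(maf) else maf
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the total probability of heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (computed by the standard stable recurrence over heterozygote counts).
#'
#' @param n_AA,n_AB,n_BB genotype counts (homozygote, heterozygote,
#'   homozygote).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  assert_counts(c(n_AA, n_AB, n_BB), "genotype counts")
  n <- n_AA + n_AB + n_BB
  if (n < 1) stop_bad("total genotype count must be >= 1")
  n_rare <- 2 * min(n_AA, n_BB) + n_AB
  if (n_rare == 0) return(1)          # monomorphic: single configuration
  # attainable heterozygote counts share the parity of the rare allele count
  hets <- seq.int(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  lp <- numeric(length(hets))
  # log conditional probability up to a constant:
  # P(h) proportional to 2^h / (nAA(h)! h! nBB(h)!)
  hom_rare <- (n_rare - hets) / 2
  hom_common <- n - hets - hom_rare
  lp <- hets * log(2) - lgamma(hom_rare + 1) - lgamma(hets + 1) -
    lgamma(hom_common + 1)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  obs <- which(hets == n_AB)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-10)]))
}

# genotype counts (AA = 0 risk alleles? counted on dosage scale:
# n0 = dosage 0, n1 = dosage 1, n2 = dosage 2) for one variant
geno_counts <- function(d) {
  d <- d[!is.na(d)]
  c(n0 = sum(d == 0), n1 = sum(d == 1), n2 = sum(d == 2))
}

#' Genotype quality control
#'
#' Removes samples with a call rate at or below `sample_call_min`, then
#' variants with a call rate at or below `variant_call_min`, MAF below
#' `maf_min`, or a Hardy-Weinberg exact-test p-value below `hwe_p_min`
#' (HWE evaluated in controls when `controls` is given, otherwise in all
#' samples). Thresholds follow the usual chip-QC conventions: keep
#' MAF >= 1%, HWE p >= 1e-6, call rates > 90%.
#'
#' @param genotypes dosage matrix.
#' @param maf_min minimum MAF kept (default 0.01).
#' @param hwe_p_min minimum HWE p kept (default 1e-6).
#' @param sample_call_min,variant_call_min call-rate thresholds; samples /
#'   variants with call rate strictly above the threshold are kept
#'   (default 0.9).
#' @param controls optional character vector of control sample ids in which
#'   HWE is evaluated.
#' @return The filtered dosage matrix with a `qc_report` attribute (see
#'   [qc_report()]).
#' @export
qc_genotypes <- function(genotypes, maf_min = 0.01, hwe_p_min = 1e-6,
                         sample_call_min = 0.9, variant_call_min = 0.9,
                         controls = NULL) {
  check_genotypes(genotypes)
  assert_prob(c(maf_min, sample_call_min, variant_call_min), "thresholds")
  scall <- rowMeans(!is.na(genotypes))
  drop_samples <- rownames(genotypes)[scall <= sample_call_min]
  g <- genotypes[scall > sample_call_min, , drop = FALSE]
  if (nrow(g) == 0) stop_bad("no samples survive call-rate QC")

  vcall <- colMeans(!is.na(g))
  maf <- vapply(seq_len(ncol(g)), function(j) {
    d <- g[, j]
    if (all(is.na(d))) return(NA_real_)
    f <- sum(d, na.rm = TRUE) / (2 * sum(!is.na(d)))
    min(f, 1 - f)
  }, numeric(1))
  hwe_src <- if (is.null(controls)) g else
    g[intersect(rownames(g), controls), , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    cc <- geno_counts(hwe_src[, j])
    if (sum(cc) == 0) return(NA_real_)
    hwe_exact_test(cc[1], cc[2], cc[3])
  }, numeric(1))

  keep <- vcall > variant_call_min & !is.na(maf) & maf >= maf_min &
    !is.na(hwe_p) & hwe_p >= hwe_p_min
  report <- data.frame(rsid = colnames(g), call_rate = vcall, maf = maf,
                       hwe_p = hwe_p, kept = keep, row.names = NULL)
  out <- g[, keep, drop = FALSE]
  if (ncol(out) == 0 || nrow(out) == 0)
    stop_bad("no variants survive QC")
  attr(out, "qc_report") <- list(dropped_samples = drop_samples,
                                 variants = report,
                                 thresholds = c(maf_min = maf_min,
                                                hwe_p_min = hwe_p_min,
                                                sample_call_min = sample_call_min,
                                                variant_call_min = variant_call_min))
  out
}

#' @rdname qc_genotypes
#' @param x a matrix returned by `qc_genotypes()`.
#' @export
qc_report <- function(x) attr(x, "qc_report")

#' Greedy LD pruning
#'
#' Scans variants in column order (the panel order: chromosome, position);
#' a variant is dropped if the squared Pearson correlation of its dosages
#' with any already-retained variant exceeds `r2_max` (composite LD from
#' unphased dosages). The surviving set therefore has all pairwise
#' r-squared at or below `r2_max`. Ties are resolved by keeping the
#' earlier variant. Monomorphic variants (zero variance) pass trivially.
#'
#' @param genotypes dosage matrix, >= 2 variants.
#' @param r2_max maximum pairwise r2 retained (default 0.5).
#' @return Character vector of retained rsids, with a `dropped` attribute
#'   naming each removed variant and the retained partner that removed it.
#' @export
ld_prune <- function(genotypes, r2_max = 0.5) {
  check_genotypes(genotypes)
  assert_prob(r2_max, "r2_max")
  if (ncol(genotypes) < 2) stop_bad("LD pruning needs at least 2 variants")
  all_na <- colSums(!is.na(genotypes)) == 0
  if (any(all_na))
    stop_bad("all dosages missing for variant(s): ",
             paste(colnames(genotypes)[all_na], collapse = ", "))
  rsids <- colnames(genotypes)
  kept <- character(0)
  dropped <- data.frame(rsid = character(0), because_of = character(0),
                        r2 = numeric(0))
  for (v in rsids) {
    dv <- genotypes[, v]
    hit <- NA_character_; hit_r2 <- NA_real_
    for (u in kept) {
      r <- suppressWarnings(stats::cor(dv, genotypes[, u],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_max) { hit <- u; hit_r2 <- r^2; break }
    }
    if (is.na(hit)) kept <- c(kept, v)
    else dropped <- rbind(dropped, data.frame(rsid = v, because_of = hit,
                                              r2 = hit_r2))
  }
  structure(kept, dropped = dropped)
}

#' Unweighted allele-count genetic risk score
#'
#' The GRS of individual i is the plain sum of risk-allele dosages over the
#' panel variants, `GRS_i = sum_k RA_ik`, an integer in 0..2K for a K-SNP
#' panel with complete data. Missing dosages contribute 0 under the default
#' `"zero"` policy (conservative, integer-preserving) and are counted in
#' `n_missing_loci`; the `"mean"` policy substitutes the variant's observed
#' mean dosage instead.
#'
#' @param genotypes dosage matrix oriented to the risk allele.
#' @param panel a `grs_panel`; all panel rsids must be present as columns.
#' @param missing_policy `"zero"` (default) or `"mean"`.
#' @return data.frame with `sample_id`, `grs`, `n_missing_loci`.
#' @export
compute_grs <- function(genotypes, panel,
                        missing_policy = c("zero", "mean")) {
  check_genotypes(genotypes)
  missing_policy <- match.arg(missing_policy)
  absent <- setdiff(panel$rsid, colnames(genotypes))
  if (length(absent))
    stop_bad("panel variant(s) absent from genotype matrix: ",
             paste(absent, collapse = ", "))
  g <- genotypes[, panel$rsid, drop = FALSE]
  n_miss <- rowSums(is.na(g))
  if (missing_policy == "mean") {
    mu <- colMeans(g, na.rm = TRUE)
    for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- mu[j]
    grs <- rowSums(g)
  } else {
    grs <- rowSums(g, na.rm = TRUE)
  }
  data.frame(sample_id = rownames(genotypes), grs = unname(grs),
             n_missing_loci = unname(n_miss), row.names = NULL,
             stringsAsFactors = FALSE)
}

## ---- file formats -------------------------------------------------------

#' Read / write a dosage matrix TSV
#'
#' Rows are individuals (first column `sample_id`), remaining columns are
#' rsids, values 0/1/2 with `NA` for missing.
#'
#' @param genotypes dosage matrix.
#' @param path file path.
#' @return `read_dosage_tsv()`: a dosage matrix; the writer returns `path`.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  check_genotypes(genotypes)
  df <- data.frame(sample_id = rownames(genotypes), genotypes,
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample_id
  check_genotypes(m)
}

#' Write genotypes as VCF
#'
#' One sample per individual, GT field only, 1-based positions taken from
#' the panel. The risk allele is written as ALT so that the ALT dosage in
#' the GT field equals the stored risk-allele dosage; the panel's
#' `other_allele` is REF. Strand harmonization is the caller's
#' responsibility.
#'
#' @param genotypes dosage matrix.
#' @param panel `grs_panel` covering all columns of `genotypes`.
#' @param path output path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, panel, path) {
  check_genotypes(genotypes)
  absent <- setdiff(colnames(genotypes), panel$rsid)
  if (length(absent)) stop_bad("variants not in panel: ",
                               paste(absent, collapse = ", "))
  pan <- as.data.frame(panel)[match(colnames(genotypes), panel$rsid), ]
  if (is.null(pan$other_allele)) stop_bad("panel needs an other_allele column")
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  body <- vapply(seq_len(ncol(genotypes)), function(j) {
    d <- genotypes[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(pan$chrom[j], pan$pos[j], pan$rsid[j], pan$other_allele[j],
            pan$risk_allele[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read risk-allele dosages from a VCF
#'
#' Parses GT fields with `VariantAnnotation::readVcf()` and orients each
#' variant's dosage to the panel's risk allele: if the risk allele is ALT
#' the ALT count is used, if it is REF the REF count is used, otherwise an
#' error names the variant.
#'
#' @param path VCF path.
#' @param panel `grs_panel`; only panel variants are returned, in panel order.
#' @return A dosage matrix (samples x variants).
#' @export
read_vcf <- function(path, panel) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop_bad("read_vcf() requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  ids <- rownames(gt)
  keep <- intersect(panel$rsid, ids)
  if (!length(keep)) stop_bad("no panel variants found in VCF")
  alt_count <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- x %in% c("0/0", "0/1", "1/0", "1/1", "0|0", "0|1", "1|0", "1|1")
    counted <- vapply(strsplit(gsub("\\|", "/", x[ok]), "/"),
                      function(a) sum(a == "1"), integer(1))
    out[ok] <- counted
    out
  }
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(VariantAnnotation::alt(vcf), function(a)
    as.character(a)[1], character(1))
  mats <- lapply(keep, function(v) {
    i <- match(v, ids)
    d <- alt_count(gt[i, ])
    p <- match(v, panel$rsid)
    if (panel$risk_allele[p] == alt[i]) d
    else if (panel$risk_allele[p] == ref[i]) 2L - d
    else stop_bad("risk allele of ", v, " matches neither REF nor ALT")
  })
  m <- do.call(cbind, mats)
  dimnames(m) <- list(colnames(gt), keep)
  m
}
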