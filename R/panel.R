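#' Construct a variant panel
#'
#' A variant panel is an ordered table of candidate SNPs with the metadata
#' the filter chain and the GRS need: identifier, location, gene, the risk
#' allele whose copies are counted, its molecular-consequence class,
#' reference minor allele frequency, and imputation quality. Panels carry a
#' provenance attribute recording each filter applied with its threshold
#' and the input/output variant counts.
#'
#' @param records data.frame with columns `rsid`, `chrom`, `pos`, `gene`,
#'   `risk_allele`, `consequence`, `maf`; optional `other_allele`,
#'   `imputation_r2`, `genotyped` (0/1, default 1).
#' @return An object of class `grs_panel` (a data.frame).
#' @export
variant_panel <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("rsid", "chrom", "pos", "gene", "risk_allele", "consequence", "maf")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop_bad("panel is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$rsid)) stop_bad("panel rsids must be unique")
  if (any(!is.na(records$maf) & (records$maf < 0 | records$maf > 0.5)))
    stop_bad("panel maf must lie in [0, 0.5]")
  if (is.null(records$imputation_r2)) records$imputation_r2 <- NA_real_
  if (is.null(records$genotyped)) records$genotyped <- 1L
  ord <- order(records$chrom, records$pos)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  structure(records, class = c("grs_panel", "data.frame"),
            provenance = list())
}

#' @export
print.grs_panel <- function(x, ...) {
  cat(sprintf("<grs_panel> %d variants at %d genes\n",
              nrow(x), length(unique(x$gene))))
  print.data.frame(x, ...)
  prov <- attr(x, "provenance")
  if (length(prov)) {
    cat("filters applied:\n")
    for (p in prov)
      cat(sprintf("  %s (threshold %s): %d -> %d\n",
                  p$stage, format(p$threshold), p$n_in, p$n_out))
  }
  invisible(x)
}

#' Filter provenance of a panel
#' @param panel a `grs_panel`.
#' @return List of applied filter stages with thresholds and counts.
#' @export
provenance <- function(panel) attr(panel, "provenance") %||% list()

add_provenance <- function(panel, stage, threshold, n_in, dropped) {
  prov <- attr(panel, "provenance") %||% list()
  prov[[length(prov) + 1L]] <- list(stage = stage, threshold = threshold,
                                    n_in = n_in, n_out = nrow(panel),
                                    dropped = dropped)
  attr(panel, "provenance") <- prov
  panel
}

subset_panel <- function(panel, keep) {
  prov <- attr(panel, "provenance")
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(panel), provenance = prov)
}

#' The packaged default 12-SNP ciliary-gene panel
#'
#' Twelve common biallelic SNPs with reported molecular consequences
#' (missense or 3'-UTR) at five primary-ciliary-dyskinesia genes
#' (CCDC164, DNAH5, DNAH11, TXNDC3, DYX1C1), the panel used for the
#' unweighted GRS (range 0-24). The `risk_allele` is the
#' molecular-consequence (variant) allele whose copies are counted,
#' regardless of whether it is the minor allele. Genomic positions other
#' than the two DNAH5 SNPs rs2277046 and rs1530496, the `other_allele`
#' column, and the reference MAFs of the ten SNPs without published
#' frequencies are synthetic placeholders used only for ordering, file
#' round-trips and simulation defaults.
#'
#' @return A `grs_panel` of 12 variants.
#' @export
default_panel <- function() {
  path <- system.file("extdata", "panel_default.tsv", package = "pcdgrs")
  read_panel(path)
}

#' Read / write a panel TSV
#'
#' @param path file path. Columns as in [variant_panel()]; `NA` allowed in
#'   `imputation_r2` for directly genotyped variants.
#' @return `read_panel()`: a `grs_panel`; `write_panel()`: `path`, invisibly.
#' @export
read_panel <- function(path) {
  variant_panel(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_panel
#' @param panel a `grs_panel`.
#' @export
write_panel <- function(panel, path) {
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' MAF filter: drop rare variants
#'
#' Retains variants whose reference minor allele frequency is at or above
#' `threshold` (boundary inclusive on the keep side). Records with a
#' missing MAF are rejected with a logged reason.
#'
#' @param panel a `grs_panel`.
#' @param threshold minimum MAF kept; default 0.1 (common variants only).
#' @return The filtered panel, provenance updated.
#' @export
filter_by_maf <- function(panel, threshold = 0.1) {
  assert_prob(threshold, "threshold")
  no_maf <- is.na(panel$maf)
  if (any(no_maf))
    message("rejecting ", sum(no_maf), " variant(s) with missing MAF: ",
            paste(panel$rsid[no_maf], collapse = ", "))
  keep <- !no_maf & panel$maf >= threshold
  out <- subset_panel(panel, keep)
  add_provenance(out, "maf", threshold, nrow(panel), panel$rsid[!keep])
}

#' Imputation-quality filter
#'
#' Directly genotyped variants always pass; imputed variants pass iff
#' their imputation r-squared is at least `r2_min`.
#'
#' @param panel a `grs_panel`.
#' @param r2_min minimum imputation r2 for imputed variants; default 0.3.
#' @return The filtered panel, provenance updated.
#' @export
filter_by_imputation <- function(panel, r2_min = 0.3) {
  assert_prob(r2_min, "r2_min")
  direct <- !is.na(panel$genotyped) & panel$genotyped == 1
  keep <- direct | (!is.na(panel$imputation_r2) & panel$imputation_r2 >= r2_min)
  out <- subset_panel(panel, keep)
  add_provenance(out, "imputation_r2", r2_min, nrow(panel), panel$rsid[!keep])
}

#' Apply the default filter chain
#'
#' MAF filter, then imputation-quality filter, then LD pruning against a
#' genotype matrix — the canonical order for panel curation.
#'
#' @param panel candidate `grs_panel`.
#' @param genotypes dosage matrix (see [compute_grs()]) used for LD pruning.
#' @param maf_min,r2_min,ld_r2_max thresholds; defaults 0.1, 0.3, 0.5.
#' @return The curated panel with full provenance.
#' @export
curate_panel <- function(panel, genotypes, maf_min = 0.1, r2_min = 0.3,
                         ld_r2_max = 0.5) {
  panel <- filter_by_maf(panel, maf_min)
  panel <- filter_by_imputation(panel, r2_min)
  keep <- ld_prune(genotypes[, panel$rsid, drop = FALSE], r2_max = ld_r2_max)
  out <- subset_panel(panel, panel$rsid %in% keep)
  add_provenance(out, "ld_prune", ld_r2_max, nrow(panel),
                 setdiff(panel$rsid, keep))
}
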