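# Published summary statistics of the three adult Japanese asthma cohorts
# the package models (cluster sizes, per-cluster GRS means/SDs, healthy
# GRS summaries, and counts for the combined GRS-Hi / GRS-Lo / GRS-average
# groups). These are report-level reference data: they let the
# summary-statistic methods (tukey_from_summary, chi2_rxc, pooled means)
# be exercised against printed values without subject-level data.

ref_table <- function(file) {
  read.delim(system.file("extdata", file, package = "pcdgrs"),
             stringsAsFactors = FALSE)
}

#' Reference cluster summaries of the modeled cohorts
#'
#' Per-cohort asthma clusters (labeled A.. by decreasing mean GRS) with
#' size, GRS mean and SD, and female count.
#'
#' @return data.frame with `cohort`, `cluster`, `n`, `grs_mean`,
#'   `grs_sd`, `female_n`.
#' @export
ref_cluster_summaries <- function() ref_table("ref_cluster_summaries.tsv")

#' Reference healthy-participant GRS summaries
#' @return data.frame with `cohort`, `n`, `grs_mean`, `grs_sd`.
#' @export
ref_healthy_summaries <- function() ref_table("ref_healthy_summaries.tsv")

#' Reference combined-group categorical counts
#'
#' Counts for the pooled GRS-Hi, GRS-Lo and GRS-average asthma groups
#' (group sizes and female/atopy/eosinophilic counts).
#'
#' @return data.frame with `variable`, `hi`, `lo`, `average`.
#' @export
ref_group_counts <- function() ref_table("ref_group_counts.tsv")

#' Size-weighted pooled mean
#'
#' The construction rule for combined-group continuous summaries: the
#' pooled mean equals the size-weighted mean of the component means.
#'
#' @param means,n component means and sizes.
#' @return The pooled mean.
#' @export
pooled_mean <- function(means, n) sum(n * means) / sum(n)
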