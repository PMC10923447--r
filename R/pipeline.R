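# Per-cohort orchestration: label fitted clusters by decreasing mean GRS,
# pick the GRS-extreme clusters by Tukey contrasts against healthy
# controls, pool extremes across cohorts into Hi / Lo / average groups,
# and contrast the extreme groups per SNP with cross-cohort meta-analysis.

#' Label clusters by decreasing mean GRS
#'
#' Sorts a fitted clustering's clusters by mean GRS (descending) and
#' assigns letters A, B, ...; ties are broken by cluster size (descending)
#' then by original cluster index. Relabeling never changes the partition.
#'
#' @param fit a [twostep_fit()] object.
#' @param grs numeric GRS per clustered sample (same order as
#'   `fit$assignments`).
#' @param healthy_grs optional GRS vector of the cohort's healthy
#'   controls, required downstream by [select_extreme_clusters()].
#' @param cohort cohort name carried into reports.
#' @return A `cohort_result` list: `labels` (letter per sample),
#'   `summary` (per-cluster letter, n, GRS mean/sd), `fit`, `grs`,
#'   `healthy_grs`, `cohort`.
#' @export
label_clusters <- function(fit, grs, healthy_grs = NULL, cohort = "cohort") {
  stopifnot(inherits(fit, "twostep_fit"), length(grs) == fit$n)
  means <- tapply(grs, fit$assignments, mean)
  sds <- tapply(grs, fit$assignments, sd)
  sizes <- fit$sizes
  ord <- order(-means, -sizes, as.integer(names(means)))
  letters_map <- setNames(LETTERS[seq_len(fit$k)], names(means)[ord])
  labels <- unname(letters_map[as.character(fit$assignments)])
  summary <- data.frame(cluster = LETTERS[seq_len(fit$k)],
                        n = sizes[as.integer(names(means)[ord])],
                        grs_mean = unname(means[ord]),
                        grs_sd = unname(sds[ord]),
                        row.names = NULL)
  structure(list(cohort = cohort, labels = labels, summary = summary,
                 fit = fit, grs = grs, healthy_grs = healthy_grs),
            class = "cohort_result")
}

#' Select GRS-extreme clusters by Tukey contrast against healthy controls
#'
#' Runs all-pairs Tukey HSD on the GRS over healthy controls plus the
#' lettered clusters; a cluster is "hi" if its healthy contrast has
#' adjusted p below `alpha` and its mean GRS is above the healthy mean,
#' "lo" if below, and "average" otherwise.
#'
#' @param cohort_result a [label_clusters()] result carrying `healthy_grs`.
#' @param alpha family-wise significance threshold (default 0.05).
#' @return The `cohort_result` augmented with `tukey` (healthy contrasts),
#'   `hi` and `lo` (letter sets).
#' @export
select_extreme_clusters <- function(cohort_result, alpha = 0.05) {
  hg <- cohort_result$healthy_grs
  if (is.null(hg) || !length(hg))
    stop_bad("no healthy control GRS present in cohort_result")
  values <- c(hg, cohort_result$grs)
  groups <- c(rep("healthy", length(hg)), cohort_result$labels)
  tk <- tukey_hsd(values, groups)
  vs_h <- tk[tk$group1 == "healthy" | tk$group2 == "healthy", ]
  vs_h$cluster <- ifelse(vs_h$group1 == "healthy", vs_h$group2, vs_h$group1)
  m_h <- mean(hg)
  cl_means <- setNames(cohort_result$summary$grs_mean,
                       cohort_result$summary$cluster)
  vs_h$direction <- ifelse(cl_means[vs_h$cluster] > m_h, "above", "below")
  sig <- vs_h$p_adj < alpha
  cohort_result$tukey <- vs_h[, c("cluster", "diff", "p_adj", "direction")]
  cohort_result$hi <- sort(vs_h$cluster[sig & vs_h$direction == "above"])
  cohort_result$lo <- sort(vs_h$cluster[sig & vs_h$direction == "below"])
  cohort_result$alpha <- alpha
  cohort_result
}

#' Pool extreme clusters across cohorts into Hi / Lo / average groups
#'
#' Group 1 pools the "hi" clusters of every cohort, Group 2 the "lo"
#' clusters, Group 3 all remaining clustered cases; the three groups
#' partition the clustered cases. Pooled continuous summaries are
#' size-weighted means of the cluster summaries.
#'
#' @param cohort_results list of [select_extreme_clusters()] results.
#' @return A `group_contrast` list: `membership` (data.frame sample-level
#'   cohort, cluster, group), `sizes`, `grs_mean` (pooled per group),
#'   `selection` (per-cohort hi/lo letter sets).
#' @export
combine_groups <- function(cohort_results) {
  if (!length(cohort_results)) stop_bad("need >= 1 cohort result")
  mem <- do.call(rbind, lapply(cohort_results, function(cr) {
    grp <- ifelse(cr$labels %in% cr$hi, "hi",
                  ifelse(cr$labels %in% cr$lo, "lo", "average"))
    data.frame(sample_id = names(cr$fit$assignments), cohort = cr$cohort,
               cluster = cr$labels, group = grp, grs = cr$grs,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(mem$sample_id)) stop_bad("overlapping cohort membership")
  sizes <- c(hi = sum(mem$group == "hi"), lo = sum(mem$group == "lo"),
             average = sum(mem$group == "average"))
  grs_mean <- tapply(mem$grs, factor(mem$group, c("hi", "lo", "average")), mean)
  structure(list(membership = mem, sizes = sizes, grs_mean = grs_mean,
                 selection = lapply(cohort_results, function(cr)
                   list(cohort = cr$cohort, hi = cr$hi, lo = cr$lo))),
            class = "group_contrast")
}

# allele counts of one variant in a sample subset
allele_counts <- function(genotypes, ids, rsid) {
  d <- genotypes[intersect(ids, rownames(genotypes)), rsid]
  d <- d[!is.na(d)]
  c(risk = sum(d), total = 2L * length(d))
}

#' Per-SNP contrasts between the GRS-extreme groups
#'
#' For every panel SNP and every cohort with both groups present, builds
#' the allele-based 2x2 table of the Lo group against the Hi group (Hi is
#' the reference, so OR > 1 means the risk allele is more frequent in the
#' Lo group) and pools the per-cohort log ORs by fixed-effect
#' meta-analysis. Additionally reports, per cohort, the contrasts of each
#' extreme group against the remaining clustered cases of that cohort
#' (`mode = "extreme_vs_rest"`) or against the cohort's healthy controls
#' (`mode = "vs_healthy"`).
#'
#' @param genotype_list named list (by cohort) of QC'd dosage matrices
#'   covering cases (and controls for `mode = "vs_healthy"`).
#' @param contrast a [combine_groups()] result.
#' @param panel `grs_panel` of the SNPs to test.
#' @param healthy_ids named list (by cohort) of healthy sample ids,
#'   required for `mode = "vs_healthy"`.
#' @param mode comparator for the per-group side tables.
#' @return The `group_contrast` filled with `per_snp` (data.frame: rsid,
#'   cohort log ORs/p, meta OR, meta p, Q, I2) and `per_group`
#'   (per-cohort Hi-vs-comparator and Lo-vs-comparator results).
#' @export
contrast_extremes <- function(genotype_list, contrast, panel,
                              healthy_ids = NULL,
                              mode = c("extreme_vs_rest", "vs_healthy")) {
  mode <- match.arg(mode)
  mem <- contrast$membership
  cohorts <- unique(mem$cohort)
  usable <- vapply(cohorts, function(co)
    any(mem$cohort == co & mem$group == "hi") &&
      any(mem$cohort == co & mem$group == "lo"), logical(1))
  if (any(!usable))
    warning("cohort(s) skipped in the Lo-vs-Hi contrast (empty extreme ",
            "group): ", paste(cohorts[!usable], collapse = ", "))
  per_snp <- lapply(panel$rsid, function(v) {
    studies <- list()
    for (co in cohorts[usable]) {
      g <- genotype_list[[co]]
      if (is.null(g) || !(v %in% colnames(g))) next
      hi_ids <- mem$sample_id[mem$cohort == co & mem$group == "hi"]
      lo_ids <- mem$sample_id[mem$cohort == co & mem$group == "lo"]
      ac_lo <- allele_counts(g, lo_ids, v)
      ac_hi <- allele_counts(g, hi_ids, v)
      if (ac_lo["total"] == 0 || ac_hi["total"] == 0) next
      studies[[co]] <- allele_assoc_2x2(ac_lo["risk"], ac_lo["total"],
                                        ac_hi["risk"], ac_hi["total"])
    }
    if (!length(studies)) return(NULL)
    mt <- meta_fixed(studies = studies)
    data.frame(rsid = v, n_cohorts = length(studies),
               meta_or = mt$or, meta_log_or = mt$log_or,
               meta_se = mt$se, meta_p = mt$p_value,
               Q = mt$Q, I2 = mt$I2, row.names = NULL)
  })
  contrast$per_snp <- do.call(rbind, per_snp)
  if (!is.null(contrast$per_snp)) {
    contrast$per_snp <- contrast$per_snp[order(contrast$per_snp$meta_p), ]
    rownames(contrast$per_snp) <- NULL
  }

  per_group <- list()
  for (co in cohorts) {
    g <- genotype_list[[co]]
    if (is.null(g)) next
    for (side in c("hi", "lo")) {
      ids <- mem$sample_id[mem$cohort == co & mem$group == side]
      if (!length(ids)) next
      comp <- if (mode == "vs_healthy") {
        if (is.null(healthy_ids[[co]]))
          stop_bad("mode 'vs_healthy' needs healthy_ids for ", co)
        healthy_ids[[co]]
      } else mem$sample_id[mem$cohort == co & mem$group != side]
      rows <- lapply(panel$rsid, function(v) {
        if (!(v %in% colnames(g))) return(NULL)
        ac_g <- allele_counts(g, ids, v)
        ac_c <- allele_counts(g, comp, v)
        if (ac_g["total"] == 0 || ac_c["total"] == 0) return(NULL)
        r <- allele_assoc_2x2(ac_g["risk"], ac_g["total"],
                              ac_c["risk"], ac_c["total"])
        data.frame(rsid = v, or = r$or, p_value = r$p_value)
      })
      per_group[[paste(co, side, sep = ".")]] <-
        do.call(rbind, rows)
    }
  }
  contrast$per_group <- per_group
  contrast$comparator <- mode
  contrast
}

#' Run the whole pipeline on a simulation configuration
#'
#' Simulates every configured cohort, computes the GRS, clusters the
#' cases on (GRS, %predicted FEV1, onset age), labels clusters by
#' decreasing GRS, selects GRS-extreme clusters against the cohort's
#' healthy controls, pools the extremes across cohorts and contrasts them
#' per SNP with meta-analysis. Deterministic given the configuration seed.
#'
#' @param config a [sim_config()].
#' @param panel `grs_panel` (default [default_panel()]).
#' @param out_dir optional directory; when given, assignment TSVs, report
#'   TSVs, a model JSON and a run manifest are written there.
#' @param alpha extreme-cluster significance threshold (default 0.05).
#' @param J_max clustering candidate maximum (default 15).
#' @param qc apply genotype QC before the contrast stage (default TRUE).
#' @return A list: `cohorts` (per-cohort `cohort_result`s), `contrast`
#'   (filled `group_contrast`), `grs` (per-cohort GRS tables), `datasets`.
#' @export
run_all <- function(config, panel = default_panel(), out_dir = NULL,
                    alpha = 0.05, J_max = 15, qc = TRUE) {
  datasets <- simulate_cohorts(config)
  cohort_results <- list()
  grs_tabs <- list()
  genotype_list <- list()
  healthy_ids <- list()
  for (co in names(datasets)) {
    ds <- datasets[[co]]
    g <- ds$genotypes
    ph <- ds$phenotypes
    controls <- ph$sample_id[ph$status == "healthy"]
    if (qc) g <- qc_genotypes(g, controls = controls)
    pan_co <- subset_panel(panel, panel$rsid %in% colnames(g))
    grs <- compute_grs(g, pan_co)
    grs$cohort <- co
    grs$status <- ph$status[match(grs$sample_id, ph$sample_id)]
    grs_tabs[[co]] <- grs
    genotype_list[[co]] <- g
    healthy_ids[[co]] <- intersect(controls, rownames(g))

    cases <- ph[ph$status == "asthma" & ph$sample_id %in% grs$sample_id, ]
    feat <- data.frame(grs = grs$grs[match(cases$sample_id, grs$sample_id)],
                       fev1pct = cases$fev1pct, onset_age = cases$onset_age,
                       row.names = cases$sample_id)
    cc <- complete.cases(feat)
    feat <- feat[cc, , drop = FALSE]
    fit <- twostep_fit(feat, J_max = J_max)
    cr <- label_clusters(fit, feat$grs,
                         healthy_grs = grs$grs[grs$status == "healthy"],
                         cohort = co)
    cohort_results[[co]] <- select_extreme_clusters(cr, alpha = alpha)
  }
  contrast <- combine_groups(cohort_results)
  contrast <- contrast_extremes(genotype_list, contrast, panel,
                                healthy_ids = healthy_ids)
  bundle <- list(cohorts = cohort_results, contrast = contrast,
                 grs = grs_tabs, datasets = datasets, config = config)
  if (!is.null(out_dir)) write_reports(bundle, out_dir)
  bundle
}

write_reports <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (co in names(bundle$cohorts)) {
    cr <- bundle$cohorts[[co]]
    write.table(data.frame(sample_id = names(cr$fit$assignments),
                           cluster = cr$labels),
                file.path(out_dir, paste0(co, "_assignments.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cr$summary,
                file.path(out_dir, paste0(co, "_cluster_summary.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cr$tukey,
                file.path(out_dir, paste0(co, "_tukey_vs_healthy.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(k = cr$fit$k, bic_trace = cr$fit$bic_trace,
           merge_dist = cr$fit$merge_dist[seq_len(
             min(length(cr$fit$merge_dist), 16))],
           hi = cr$hi, lo = cr$lo),
      file.path(out_dir, paste0(co, "_model.json")),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(bundle$contrast$per_snp))
    write.table(bundle$contrast$per_snp,
                file.path(out_dir, "meta_per_snp.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$contrast$membership,
              file.path(out_dir, "group_membership.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(package = "pcdgrs",
         version = as.character(packageVersion("pcdgrs")),
         seed = bundle$config$seed, mode = bundle$config$mode,
         group_sizes = as.list(bundle$contrast$sizes)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
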