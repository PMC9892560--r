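# Cross-tabulation of reversibility categories against epigenetic
# features: DMRs per gene, differential-peak overlap, CpG-island
# proximity, and Fisher enrichment tests, plus the machine-readable
# run report.

# category label per gene: ARR_up / ARR_down / ARI_up / ARI_down /
# unchanged (SAME_SIGN and NA reversibility fold into unchanged)
gene_categories <- function(calls) {
  ifelse(calls$reversibility %in% c("ARR", "ARI"),
         paste(calls$reversibility, calls$age_direction, sep = "_"),
         "unchanged")
}

#' Mean DMR count per gene category
#'
#' A DMR counts toward a gene when it overlaps the gene's (extended)
#' regulatory domain; the per-category mean is over all genes in the
#' category, so means below 1 are expected.
#'
#' @param dmrs DMR table (chrom/start/end).
#' @param domains Regulatory domains from [build_regulatory_domains()].
#' @param calls Reversibility calls from [call_arr_ari()].
#' @return List with `per_gene` (gene_id, category, n_dmr) and
#'   `per_category` (category, n_genes, mean_dmrs).
#' @export
dmrs_per_gene <- function(dmrs, domains, calls) {
  cat <- setNames(gene_categories(calls), calls$gene_id)
  n_dmr <- setNames(integer(nrow(domains)), domains$gene_id)
  if (nrow(dmrs) > 0) {
    dg <- GenomicRanges::GRanges(dmrs$chrom,
                                 IRanges::IRanges(dmrs$start + 1, dmrs$end))
    dom <- GenomicRanges::GRanges(domains$chrom,
                                  IRanges::IRanges(domains$ext_start + 1,
                                                   domains$ext_end))
    hits <- suppressWarnings(GenomicRanges::countOverlaps(dom, dg))
    n_dmr[] <- hits
  }
  per_gene <- data.frame(gene_id = domains$gene_id,
                         category = unname(cat[domains$gene_id]),
                         n_dmr = unname(n_dmr), stringsAsFactors = FALSE)
  per_gene$category[is.na(per_gene$category)] <- "unchanged"
  agg <- aggregate(n_dmr ~ category, per_gene, mean)
  sizes <- aggregate(gene_id ~ category, per_gene, length)
  per_category <- merge(sizes, agg, by = "category")
  names(per_category) <- c("category", "n_genes", "mean_dmrs")
  list(per_gene = per_gene, per_category = per_category)
}

#' Differential-peak overlap and per-distance peak counts by category
#'
#' Direction matching follows the figure-panel convention: up-regulated
#' genes are paired with age-accessible (LFC > 0) peaks and down-regulated
#' genes with age-inaccessible peaks; "unchanged" genes are matched
#' against either direction. Optionally restricts to reproducible genes
#' (per-gene effect SD below `max_effect_sd`).
#'
#' @param diff_peaks Differential table joined with positions (peak_id,
#'   chrom, summit, sig, lfc_mle).
#' @param associations peak-gene associations from
#'   [assign_peaks_to_genes()].
#' @param calls Reversibility calls.
#' @param genes Gene TSS models (chrom, start, name).
#' @param windows TSS-distance windows (default 10 kb / 100 kb / 1 Mb).
#' @param effect_sd Optional named per-gene SD used with
#'   `max_effect_sd`.
#' @param max_effect_sd Keep genes with effect_sd < this (default Inf).
#' @return List with `overlap_pct` (category, n_genes, pct_with_peak) and
#'   `mean_peaks` (category x window matrix of mean per-gene counts).
#' @export
peak_overlap_by_category <- function(diff_peaks, associations, calls, genes,
                                     windows = c(1e4, 1e5, 1e6),
                                     effect_sd = NULL,
                                     max_effect_sd = Inf) {
  cat <- setNames(gene_categories(calls), calls$gene_id)
  genes <- genes[genes$name %in% names(cat), , drop = FALSE]
  if (!is.null(effect_sd) && is.finite(max_effect_sd)) {
    keep <- names(effect_sd)[effect_sd < max_effect_sd]
    genes <- genes[genes$name %in% keep, , drop = FALSE]
  }
  gcat <- unname(cat[genes$name])
  dirmatch <- function(gene_cat) {
    want <- sub(".*_", "", gene_cat)  # up / down / "unchanged"
    sig <- diff_peaks$sig
    if (want == "up") sig & diff_peaks$lfc_mle > 0
    else if (want == "down") sig & diff_peaks$lfc_mle < 0
    else sig
  }
  cats <- c("ARR_up", "ARR_down", "ARI_up", "ARI_down", "unchanged")
  assoc_by_gene <- split(associations$peak_id, associations$gene_id)
  has_peak <- logical(nrow(genes))
  counts <- matrix(0, nrow(genes), length(windows))
  for (i in seq_len(nrow(genes))) {
    use <- dirmatch(gcat[i])
    pk <- diff_peaks[use, , drop = FALSE]
    ap <- assoc_by_gene[[genes$name[i]]]
    has_peak[i] <- length(intersect(ap, pk$peak_id)) > 0
    same <- pk$chrom == genes$chrom[i]
    if (any(same)) {
      d <- abs(pk$summit[same] - genes$start[i])
      counts[i, ] <- vapply(windows, function(w) sum(d <= w), 0)
    }
  }
  overlap <- do.call(rbind, lapply(cats, function(cc) {
    idx <- gcat == cc
    data.frame(category = cc, n_genes = sum(idx),
               pct_with_peak = if (any(idx)) 100 * mean(has_peak[idx]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  mean_peaks <- t(vapply(cats, function(cc) {
    idx <- gcat == cc
    if (any(idx)) colMeans(counts[idx, , drop = FALSE]) else rep(NA_real_, length(windows))
  }, numeric(length(windows))))
  colnames(mean_peaks) <- paste0("within_", windows)
  list(overlap_pct = overlap, mean_peaks = mean_peaks)
}

#' Fisher enrichment of a feature among a gene set
#'
#' 2x2 Fisher exact test of membership in `set_a` against carrying
#' `feature`, within `universe`. The reported odds ratio is the sample
#' cross-product ratio (ad/bc).
#'
#' @param set_a_genes,feature_genes Character vectors (subsets of
#'   universe).
#' @param universe Character vector of all genes considered.
#' @return List with table, odds_ratio, pvalue.
#' @export
category_enrichment_test <- function(set_a_genes, feature_genes, universe) {
  stopifnot(all(set_a_genes %in% universe), all(feature_genes %in% universe))
  in_a <- universe %in% set_a_genes
  in_f <- universe %in% feature_genes
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_f, c(TRUE, FALSE)))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(table = tab, odds_ratio = NA_real_, pvalue = 1))
  }
  orr <- (as.numeric(a) * d) / (as.numeric(b) * cc)
  p <- fisher.test(tab)$p.value
  list(table = tab, odds_ratio = orr, pvalue = p)
}

#' Run a battery of category-vs-feature enrichment tests
#'
#' @param category_sets Named list of gene-id vectors (e.g. ARI genes).
#' @param feature_sets Named list of gene-id vectors (e.g. DMR-bearing).
#' @param universe All gene ids.
#' @return Data frame category, feature, odds_ratio, pvalue, padj (BH).
#' @export
enrichment_battery <- function(category_sets, feature_sets, universe) {
  grid <- expand.grid(category = names(category_sets),
                      feature = names(feature_sets),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- category_enrichment_test(category_sets[[grid$category[i]]],
                                  feature_sets[[grid$feature[i]]], universe)
    data.frame(category = grid$category[i], feature = grid$feature[i],
               odds_ratio = r$odds_ratio, pvalue = r$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- p.adjust(out$pvalue, method = "BH")
  out
}

#' Assemble the machine-readable run report
#'
#' Collects whatever stage summaries are available into one JSON-ready
#' list; missing stages are marked absent rather than failing. When
#' simulation truth is supplied, a confusion matrix of called vs planted
#' reversibility classes is included.
#'
#' @param ... Named stage summaries (category_counts,
#'   reversibility_summary, concordance, stability, dmr_summary,
#'   atac_summary, integration, truth_comparison, ...).
#' @param path Optional path; when given the report is written as JSON.
#' @return The report list, invisibly when written.
#' @export
build_report <- function(..., path = NULL) {
  sections <- list(...)
  all_names <- c("category_counts", "reversibility_summary", "concordance",
                 "stability", "dmr_summary", "atac_summary", "integration",
                 "truth_comparison")
  report <- list()
  for (nm in union(all_names, names(sections))) {
    report[[nm]] <- if (!is.null(sections[[nm]])) sections[[nm]] else "absent"
  }
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    return(invisible(report))
  }
  report
}

#' Confusion matrix of called vs planted reversibility
#' @param calls Output of [call_arr_ari()].
#' @param truth Simulation truth table (gene_id, class).
#' @return Table of planted class x call.
#' @export
reversibility_confusion <- function(calls, truth) {
  m <- merge(calls, truth[, c("gene_id", "class")], by = "gene_id")
  call_lab <- ifelse(is.na(m$reversibility), "none", m$reversibility)
  table(planted = m$class, called = call_lab)
}
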