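# Peak processing, background-normalized differential accessibility,
# basal-plus-extension regulatory domains, peak-gene association,
# distance-binned peak counts, anchored pileups, and CpG-island proximity.

#' Merge peaks whose summits lie within a gap threshold
#'
#' Single-linkage clustering of summits per chromosome: any chain of
#' summits with consecutive gaps <= `gap` forms one cluster. The merged
#' summit is the midpoint of the cluster's summit span and the peak is
#' redefined as summit +/- `halfwidth` (default 1-kb peaks), clipped at 0.
#' Per-sample counts of merged members are summed when present. The
#' operation is idempotent: cluster midpoints are farther apart than
#' `gap`, so a second pass changes nothing.
#'
#' @param peaks Data frame with chrom and summit (and optionally count
#'   columns given via `count_cols`).
#' @param gap Maximum summit distance for merging (default 200).
#' @param halfwidth Half-width of the redefined peak (default 500; set
#'   250 for 500-bp total peaks).
#' @param count_cols Optional character vector of count columns to sum.
#' @return Data frame chrom, start, end, name, score, strand, summit,
#'   n_merged (+ summed count columns).
#' @export
merge_peaks <- function(peaks, gap = 200L, halfwidth = 500L,
                        count_cols = NULL) {
  stopifnot("summit" %in% names(peaks))
  o <- order(peaks$chrom, peaks$summit)
  pk <- peaks[o, , drop = FALSE]
  new_cluster <- c(TRUE, pk$chrom[-1] != pk$chrom[-nrow(pk)] |
                     diff(pk$summit) > gap)
  cl <- cumsum(new_cluster)
  agg <- function(f, x) as.vector(tapply(x, cl, f))
  summit <- as.integer(floor((agg(min, pk$summit) + agg(max, pk$summit)) / 2))
  out <- data.frame(chrom = agg(function(x) x[1], pk$chrom),
                    start = pmax(summit - halfwidth, 0L),
                    end = summit + halfwidth,
                    name = sprintf("merged%05d", seq_along(summit)),
                    score = 0L, strand = ".",
                    summit = summit,
                    n_merged = as.integer(agg(length, pk$summit)),
                    stringsAsFactors = FALSE)
  for (cc in count_cols) {
    out[[cc]] <- agg(sum, pk[[cc]])
  }
  out
}

#' Background-normalized differential accessibility
#'
#' For every peak, counts from the peak region and from its +/- 10 kb
#' background are stacked into one NB GLM with condition x region_type
#' terms and region-type-specific size factors. The interaction
#' coefficient is the peak's accessibility change beyond the local
#' background change; significance requires |LFC| > `lfc_min` (raw
#' coefficient) and BH-adjusted p < `padj_max`. Peaks whose background is
#' all-zero are refit on peak counts alone (size-factor normalization
#' only) and flagged.
#'
#' @param peak_counts,bg_counts Peak-by-sample integer matrices.
#' @param condition Factor ("young"/"aged"), one per sample.
#' @param lfc_min,padj_max Significance thresholds (defaults 1 and 0.05).
#' @param prior_scale Optional fixed shrinkage prior scale.
#' @return Data frame peak_id, lfc (moderated), lfc_mle, se, svalue,
#'   pvalue, padj, sig, bg_fallback.
#' @export
differential_accessibility <- function(peak_counts, bg_counts, condition,
                                       lfc_min = 1, padj_max = 0.05,
                                       prior_scale = NULL) {
  stopifnot(identical(dim(peak_counts), dim(bg_counts)),
            length(condition) == ncol(peak_counts))
  condition <- factor(condition, levels = c("young", "aged"))
  fallback <- rowSums(bg_counts) == 0
  counts <- cbind(bg_counts, peak_counts)
  ns <- ncol(peak_counts)
  region <- factor(rep(c("background", "peak"), each = ns),
                   levels = c("background", "peak"))
  cond2 <- factor(rep(as.character(condition), 2), levels = levels(condition))
  X <- model.matrix(~ region * cond2)
  colnames(X) <- c("(Intercept)", "regionpeak", "condaged", "regionpeak:condaged")
  sf <- c(estimate_size_factors(bg_counts),
          estimate_size_factors(peak_counts))
  disp <- estimate_dispersions(counts, X, sf)
  fit <- fit_nb_glm(counts, X, sf, disp)
  me <- moderate_effects(fit, "regionpeak:condaged", prior_scale = prior_scale)
  out <- data.frame(peak_id = rownames(peak_counts),
                    lfc = me$lfc_moderated, lfc_mle = me$lfc_mle,
                    se = me$se, svalue = me$svalue,
                    pvalue = me$pvalue, padj = me$padj,
                    bg_fallback = fallback, stringsAsFactors = FALSE)
  if (any(fallback)) {
    # no usable background: model the peak counts directly
    Xp <- model.matrix(~ condition)
    colnames(Xp) <- c("(Intercept)", "condaged")
    sub <- peak_counts[fallback, , drop = FALSE]
    sfp <- estimate_size_factors(peak_counts)
    dispp <- estimate_dispersions(peak_counts, Xp, sfp)[fallback]
    fitp <- fit_nb_glm(sub, Xp, sfp[colnames(sub)], dispp)
    wt <- wald_test(fitp, "condaged")
    idx <- match(wt$gene_id, out$peak_id)
    out$lfc_mle[idx] <- wt$estimate
    out$lfc[idx] <- wt$estimate
    out$se[idx] <- wt$se
    out$pvalue[idx] <- wt$pvalue
    out$padj <- p.adjust(out$pvalue, method = "BH")
  }
  out$sig <- !is.na(out$padj) & abs(out$lfc_mle) > lfc_min & out$padj < padj_max
  out
}

#' Build basal-plus-extension gene regulatory domains
#'
#' Basal domain: strand-aware 5 kb upstream to 1 kb downstream of the
#' TSS. Extension: each side grows to at most `extension` bp from the
#' TSS, stopping at any other gene's basal domain; extensions never enter
#' another basal domain. Genes with byte-identical basal intervals
#' (duplicate TSS on the same strand footprint) share their extension.
#' Coordinates are clipped at 0 and at `chrom_sizes` when given.
#'
#' @param genes Data frame chrom, start (TSS, 0-based), strand, name.
#' @param basal_up,basal_down Basal distances (defaults 5000 / 1000).
#' @param extension Maximum extension from the TSS (default 1e6).
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return Data frame gene_id, chrom, tss, strand, basal_start, basal_end,
#'   ext_start, ext_end.
#' @export
build_regulatory_domains <- function(genes, basal_up = 5000L,
                                     basal_down = 1000L,
                                     extension = 1e6,
                                     chrom_sizes = NULL) {
  stopifnot(all(c("chrom", "start", "strand", "name") %in% names(genes)))
  tss <- genes$start
  plus <- genes$strand != "-"
  b_start <- ifelse(plus, tss - basal_up, tss - basal_down)
  b_end <- ifelse(plus, tss + basal_down, tss + basal_up)
  b_start <- pmax(b_start, 0)
  n <- nrow(genes)
  ext_start <- pmax(tss - extension, 0)
  ext_end <- tss + extension
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[genes$chrom]
    b_end <- pmin(b_end, lim)
    ext_end <- pmin(ext_end, lim)
  }
  for (i in seq_len(n)) {
    same <- which(genes$chrom == genes$chrom[i])
    same <- setdiff(same, i)
    # identical basal intervals do not block each other
    same <- same[!(b_start[same] == b_start[i] & b_end[same] == b_end[i])]
    if (length(same) == 0) next
    # left: blockers whose basal intersects the candidate extension
    cs <- ext_start[i]
    blk <- same[b_end[same] > cs & b_start[same] < b_start[i]]
    if (length(blk)) {
      ext_start[i] <- max(cs, max(pmin(b_end[blk], b_start[i])))
    }
    ce <- ext_end[i]
    blk <- same[b_start[same] < ce & b_end[same] > b_end[i]]
    if (length(blk)) {
      ext_end[i] <- min(ce, min(pmax(b_start[blk], b_end[i])))
    }
  }
  ext_start <- pmin(ext_start, b_start)
  ext_end <- pmax(ext_end, b_end)
  data.frame(gene_id = genes$name, chrom = genes$chrom, tss = tss,
             strand = genes$strand,
             basal_start = as.numeric(b_start), basal_end = as.numeric(b_end),
             ext_start = as.numeric(ext_start), ext_end = as.numeric(ext_end),
             stringsAsFactors = FALSE)
}

#' Associate peaks with genes via regulatory-domain overlap
#'
#' A peak is associated with every gene whose extended domain it overlaps
#' by at least 1 bp (many-to-many).
#'
#' @param peaks Data frame chrom/start/end/name.
#' @param domains Output of [build_regulatory_domains()].
#' @return Data frame peak_id, gene_id.
#' @export
assign_peaks_to_genes <- function(peaks, domains) {
  if (nrow(peaks) == 0 || nrow(domains) == 0) {
    return(data.frame(peak_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1, peaks$end))
  dm <- GenomicRanges::GRanges(domains$chrom,
                               IRanges::IRanges(domains$ext_start + 1,
                                                domains$ext_end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(pk, dm))
  data.frame(peak_id = peaks$name[S4Vectors::queryHits(hits)],
             gene_id = domains$gene_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Count significant peaks per gene within TSS-distance windows
#'
#' @param diff_peaks Differential table (from
#'   [differential_accessibility()]) joined with peak positions: needs
#'   peak_id, chrom, summit, sig, lfc.
#' @param genes Data frame chrom, start (TSS), name.
#' @param windows Distance cutoffs in bp (default 10 kb, 100 kb, 1 Mb).
#' @param direction Optional "up" or "down" to count only peaks whose
#'   accessibility moves that way with age.
#' @return Matrix genes x windows of peak counts (|summit - TSS| <= w).
#' @export
peaks_per_gene_by_distance <- function(diff_peaks, genes,
                                       windows = c(1e4, 1e5, 1e6),
                                       direction = NULL) {
  use <- diff_peaks$sig
  if (!is.null(direction)) {
    use <- use & if (direction == "up") diff_peaks$lfc_mle > 0 else diff_peaks$lfc_mle < 0
  }
  pk <- diff_peaks[use, , drop = FALSE]
  out <- matrix(0L, nrow(genes), length(windows),
                dimnames = list(genes$name, paste0("within_", windows)))
  if (nrow(pk) == 0) return(out)
  for (i in seq_len(nrow(genes))) {
    same <- pk$chrom == genes$chrom[i]
    if (!any(same)) next
    d <- abs(pk$summit[same] - genes$start[i])
    out[i, ] <- vapply(windows, function(w) sum(d <= w), 0L)
  }
  out
}

#' Mean coverage profile around anchor midpoints
#'
#' Library-size (CPM-style) normalized mean coverage per condition at
#' each offset in [-flank, +flank] around anchor interval midpoints.
#' Anchors whose window runs off the covered chromosome are skipped (count
#' reported via message).
#'
#' @param coverages Named list of bedGraph data frames (one per sample).
#' @param conditions Character vector, condition per sample.
#' @param anchors Data frame chrom/start/end.
#' @param flank Half-window in bp (default 2000).
#' @return Matrix (2*flank+1) x conditions of mean normalized coverage;
#'   rownames are offsets.
#' @export
pileup <- function(coverages, conditions, anchors, flank = 2000L) {
  stopifnot(length(coverages) == length(conditions))
  conds <- unique(conditions)
  offsets <- -flank:flank
  out <- matrix(0, length(offsets), length(conds),
                dimnames = list(offsets, conds))
  n_used <- setNames(numeric(length(conds)), conds)
  skipped <- 0
  for (i in seq_along(coverages)) {
    bg <- coverages[[i]]
    # per-chromosome dense vectors (synthetic chromosomes are small)
    chroms <- unique(bg$chrom)
    vecs <- lapply(chroms, function(ch) {
      sub <- bg[bg$chrom == ch, , drop = FALSE]
      v <- numeric(max(sub$end))
      for (j in seq_len(nrow(sub))) {
        v[(sub$start[j] + 1):sub$end[j]] <- sub$value[j]
      }
      v
    })
    names(vecs) <- chroms
    libsize <- sum(bg$value * (bg$end - bg$start))
    if (libsize == 0) next
    prof <- numeric(length(offsets))
    n_anch <- 0
    for (a in seq_len(nrow(anchors))) {
      v <- vecs[[anchors$chrom[a]]]
      if (is.null(v)) { skipped <- skipped + 1; next }
      mid <- (anchors$start[a] + anchors$end[a]) %/% 2
      lo <- mid - flank + 1; hi <- mid + flank + 1
      if (lo < 1 || hi > length(v)) { skipped <- skipped + 1; next }
      prof <- prof + v[lo:hi]
      n_anch <- n_anch + 1
    }
    if (n_anch == 0) next
    prof <- prof / n_anch / libsize * 1e6
    ci <- match(conditions[i], conds)
    out[, ci] <- out[, ci] + prof
    n_used[ci] <- n_used[ci] + 1
  }
  if (skipped > 0) message(skipped, " anchor window(s) off-chromosome, skipped")
  for (ci in seq_along(conds)) {
    if (n_used[ci] > 0) out[, ci] <- out[, ci] / n_used[ci]
  }
  out
}

#' CpG-island proximity of gene TSSs
#'
#' A gene is flagged when a CpG island overlaps its TSS or lies within
#' `max_dist` bp of it (distance from the TSS to the nearest island base).
#'
#' @param genes Data frame chrom, start (TSS), name.
#' @param islands Data frame chrom/start/end (0-based half-open).
#' @param max_dist Maximum distance in bp (default 5000).
#' @return Data frame gene_id, cgi_distance, has_cgi; the percentage over
#'   the set is attached as attribute `pct`.
#' @export
cpg_island_proximity <- function(genes, islands, max_dist = 5000L) {
  n <- nrow(genes)
  dist <- rep(Inf, n)
  for (i in seq_len(n)) {
    same <- islands$chrom == genes$chrom[i]
    if (!any(same)) next
    s <- islands$start[same]; e <- islands$end[same]
    tss <- genes$start[i]
    d <- ifelse(tss < s, s - tss, ifelse(tss >= e, tss - (e - 1), 0))
    dist[i] <- min(d)
  }
  out <- data.frame(gene_id = genes$name, cgi_distance = dist,
                    has_cgi = dist <= max_dist, stringsAsFactors = FALSE)
  attr(out, "pct") <- 100 * mean(out$has_cgi)
  out
}
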