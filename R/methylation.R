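# Windowed differential-methylation calling: fixed 100-bp genome tiles
# with >= 4 CpGs, per-replicate window proportions tested by beta
# regression on condition, BH adjustment, and the hard reporting filters
# |delta| >= 0.40 and adjusted p < 0.01.

#' Pool CpG calls from both strands onto the forward-strand position
#'
#' A CpG dyad is covered on both strands; the reverse-strand cytosine sits
#' one base to the right of the forward-strand one. Calls are pooled per
#' dyad by shifting minus-strand records left by 1 and summing counts.
#'
#' @param track Methylation data frame (chrom, pos0, strand,
#'   count_methylated, count_total).
#' @return Pooled track with strand "+" only.
#' @export
pool_cpg_strands <- function(track) {
  if (nrow(track) == 0) {
    return(data.frame(chrom = character(), pos0 = integer(),
                      strand = character(), count_methylated = integer(),
                      count_total = integer(), stringsAsFactors = FALSE))
  }
  pos <- ifelse(track$strand == "-", track$pos0 - 1L, track$pos0)
  key <- paste(track$chrom, pos)
  agg_m <- rowsum(track$count_methylated, key)
  agg_t <- rowsum(track$count_total, key)
  first <- !duplicated(key)
  ord <- match(rownames(agg_m), key)
  out <- data.frame(chrom = track$chrom[ord], pos0 = pos[ord], strand = "+",
                    count_methylated = as.integer(agg_m[, 1]),
                    count_total = as.integer(agg_t[, 1]),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos0), , drop = FALSE]
}

#' Tile the genome into candidate methylation windows
#'
#' Fixed, non-overlapping windows of `window` bp aligned to coordinate 0.
#' A window is a candidate iff the union of CpG positions across all
#' tracks contains at least `min_cpg` distinct sites.
#'
#' @param tracks List of methylation data frames (any strand mix; strands
#'   are pooled per dyad first).
#' @param window Window width in bp (default 100).
#' @param min_cpg Minimum distinct CpG sites per window (default 4).
#' @return Data frame chrom, start, end, n_cpg (0-based half-open).
#' @export
tile_windows <- function(tracks, window = 100L, min_cpg = 4L) {
  if (length(tracks) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer()))
  }
  pooled <- lapply(tracks, pool_cpg_strands)
  allpos <- unique(do.call(rbind, lapply(pooled, function(t) {
    data.frame(chrom = t$chrom, pos0 = t$pos0, stringsAsFactors = FALSE)
  })))
  if (nrow(allpos) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer()))
  }
  tile <- allpos$pos0 %/% window
  key <- paste(allpos$chrom, tile)
  cnt <- table(key)
  keep <- names(cnt)[cnt >= min_cpg]
  if (length(keep) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer()))
  }
  parts <- strsplit(keep, " ")
  chrom <- vapply(parts, `[`, "", 1)
  t0 <- as.integer(vapply(parts, `[`, "", 2))
  out <- data.frame(chrom = chrom, start = t0 * window,
                    end = t0 * window + window,
                    n_cpg = as.integer(cnt[keep]), stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Beta regression of proportions on a binary condition: logit link for the
# mean, common precision phi, maximum likelihood via L-BFGS-B, Wald p for
# the condition coefficient from the numeric Hessian.
.beta_regression <- function(y, cond) {
  y <- pmin(pmax(y, 1e-6), 1 - 1e-6)
  m0 <- mean(y[cond == 0]); m1 <- mean(y[cond == 1])
  m0 <- min(max(m0, 1e-3), 1 - 1e-3); m1 <- min(max(m1, 1e-3), 1 - 1e-3)
  v <- var(y)
  phi0 <- if (is.finite(v) && v > 1e-6) {
    max(mean(y) * (1 - mean(y)) / v - 1, 2)
  } else 50
  par0 <- c(stats::qlogis(m0), stats::qlogis(m1) - stats::qlogis(m0),
            log(min(phi0, 2000)))
  nll <- function(p) {
    mu <- stats::plogis(p[1] + p[2] * cond)
    phi <- exp(p[3])
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  fit <- tryCatch(
    optim(par0, nll, method = "L-BFGS-B",
          lower = c(-12, -24, log(0.5)), upper = c(12, 24, log(1e4)),
          hessian = TRUE),
    error = function(e) NULL)
  if (is.null(fit)) return(c(est = NA_real_, p = NA_real_))
  se <- tryCatch(sqrt(diag(solve(fit$hessian)))[2], error = function(e) NA_real_)
  if (!is.finite(se) || se <= 0) return(c(est = fit$par[2], p = NA_real_))
  z <- fit$par[2] / se
  c(est = fit$par[2], p = 2 * pnorm(-abs(z)))
}

#' Test candidate windows for differential methylation
#'
#' Per replicate, the window's CpG counts are pooled and converted to a
#' proportion with +0.5/+1 pseudo-counts (beta likelihood is undefined at
#' 0 and 1). Proportions are regressed on condition by beta regression;
#' delta is the difference of condition-pooled proportions (aged - young).
#' Replicates with zero coverage in a window are dropped; windows with
#' fewer than 2 usable replicates in either condition are left untested
#' (NA p).
#'
#' @param windows Candidate windows from [tile_windows()].
#' @param tracks List of methylation tracks (one per replicate).
#' @param conditions Character vector ("young"/"aged"), one per track.
#' @return `windows` with columns prop_young, prop_aged, delta, pvalue.
#' @export
test_windows <- function(windows, tracks, conditions) {
  stopifnot(length(tracks) == length(conditions),
            all(conditions %in% c("young", "aged")))
  if (nrow(windows) == 0) {
    windows$prop_young <- windows$prop_aged <- windows$delta <-
      windows$pvalue <- numeric(0)
    return(windows)
  }
  width <- windows$end[1] - windows$start[1]
  wkey <- paste(windows$chrom, windows$start %/% width)
  nw <- nrow(windows)
  nt <- length(tracks)
  meth <- matrix(0, nw, nt)
  tot <- matrix(0, nw, nt)
  for (i in seq_len(nt)) {
    t <- pool_cpg_strands(tracks[[i]])
    key <- paste(t$chrom, t$pos0 %/% width)
    mm <- rowsum(t$count_methylated, key)
    tt <- rowsum(t$count_total, key)
    idx <- match(wkey, rownames(mm))
    hit <- !is.na(idx)
    meth[hit, i] <- mm[idx[hit], 1]
    tot[hit, i] <- tt[idx[hit], 1]
  }
  is_aged <- conditions == "aged"
  pool_m_y <- rowSums(meth[, !is_aged, drop = FALSE])
  pool_t_y <- rowSums(tot[, !is_aged, drop = FALSE])
  pool_m_a <- rowSums(meth[, is_aged, drop = FALSE])
  pool_t_a <- rowSums(tot[, is_aged, drop = FALSE])
  windows$prop_young <- (pool_m_y + 0.5) / (pool_t_y + 1)
  windows$prop_aged <- (pool_m_a + 0.5) / (pool_t_a + 1)
  windows$delta <- windows$prop_aged - windows$prop_young
  pvals <- rep(NA_real_, nw)
  for (w in seq_len(nw)) {
    use <- tot[w, ] > 0
    if (sum(use & !is_aged) < 2 || sum(use & is_aged) < 2) next
    y <- (meth[w, use] + 0.5) / (tot[w, use] + 1)
    res <- .beta_regression(y, as.integer(is_aged[use]))
    pvals[w] <- res[["p"]]
  }
  windows$pvalue <- pvals
  windows
}

#' Call differentially methylated regions
#'
#' BH adjustment over all tested windows, then the hard reporting rules:
#' |delta| >= `delta_min` (default 0.40) and adjusted p < `padj_max`
#' (default 0.01). Direction is gain iff delta > 0 (aged more methylated).
#' Adjacent significant windows are reported separately unless
#' `merge_adjacent` is TRUE.
#'
#' @param windows Tested windows from [test_windows()].
#' @param delta_min Minimum |methylation proportion difference|.
#' @param padj_max Maximum BH-adjusted p (strict inequality).
#' @param merge_adjacent Merge touching DMR windows into regions.
#' @return Data frame of DMRs: window columns + padj + direction.
#' @export
call_dmrs <- function(windows, delta_min = 0.40, padj_max = 0.01,
                      merge_adjacent = FALSE) {
  tested <- !is.na(windows$pvalue)
  windows$padj <- NA_real_
  windows$padj[tested] <- p.adjust(windows$pvalue[tested], method = "BH")
  keep <- tested & abs(windows$delta) >= delta_min & windows$padj < padj_max
  dmrs <- windows[keep, , drop = FALSE]
  dmrs$direction <- ifelse(dmrs$delta > 0, "gain", "loss")
  rownames(dmrs) <- NULL
  if (merge_adjacent && nrow(dmrs) > 1) {
    dmrs <- dmrs[order(dmrs$chrom, dmrs$start), ]
    new_run <- c(TRUE, dmrs$chrom[-1] != dmrs$chrom[-nrow(dmrs)] |
                   dmrs$start[-1] != dmrs$end[-nrow(dmrs)] |
                   dmrs$direction[-1] != dmrs$direction[-nrow(dmrs)])
    run <- cumsum(new_run)
    dmrs <- do.call(rbind, lapply(split(dmrs, run), function(d) {
      data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end),
                 n_cpg = sum(d$n_cpg), prop_young = mean(d$prop_young),
                 prop_aged = mean(d$prop_aged), delta = mean(d$delta),
                 pvalue = min(d$pvalue), padj = min(d$padj),
                 direction = d$direction[1], stringsAsFactors = FALSE)
    }))
    rownames(dmrs) <- NULL
  }
  dmrs
}

#' Gain/loss proportions among called DMRs
#' @param dmrs DMR table from [call_dmrs()].
#' @return Named vector pct_gain/pct_loss (NA when empty).
#' @export
summarize_gain_loss <- function(dmrs) {
  if (nrow(dmrs) == 0) {
    return(c(pct_gain = NA_real_, pct_loss = NA_real_))
  }
  g <- mean(dmrs$direction == "gain") * 100
  c(pct_gain = g, pct_loss = 100 - g)
}

#' Annotate DMRs with candidate cis-regulatory element classes
#'
#' A DMR is assigned a cCRE class when any cCRE lies within `max_dist` bp
#' (interval gap, overlap = 0). Ties are resolved by the precedence
#' PLS > ELS > other; DMRs with no cCRE in range are "other".
#'
#' @param dmrs DMR table.
#' @param ccres Data frame chrom/start/end/name where name is the class
#'   (PLS, ELS, or anything else).
#' @param max_dist Maximum gap in bp (default 300).
#' @return `dmrs` with an added `ccre_class` column.
#' @export
annotate_dmrs <- function(dmrs, ccres, max_dist = 300L) {
  cls <- rep("other", nrow(dmrs))
  prec <- c("PLS", "ELS")
  for (i in seq_len(nrow(dmrs))) {
    same <- ccres$chrom == dmrs$chrom[i]
    if (!any(same)) next
    cc <- ccres[same, , drop = FALSE]
    gap <- pmax(cc$start - dmrs$end[i], dmrs$start[i] - cc$end, 0)
    near <- cc$name[gap <= max_dist]
    if (length(near) == 0) next
    hit <- prec[prec %in% near]
    cls[i] <- if (length(hit)) hit[1] else "other"
  }
  dmrs$ccre_class <- cls
  dmrs
}

#' Write DMRs as BED6 (score = -log10 padj, name = direction)
#' @param dmrs DMR table.
#' @param path Output path.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                    name = dmrs$direction,
                    score = round(-log10(pmax(dmrs$padj, 1e-300)), 3),
                    strand = ".")
  write_bed(bed, path)
}
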