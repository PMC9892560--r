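# Shared fixtures and brute-force oracles used across test files.

# small factorial design: reps per age x time cell, cycling batches
make_design <- function(reps = 3, n_batches = 2) {
  grid <- expand.grid(time = c("T0", "T21"), age = c("young", "aged"),
                      stringsAsFactors = FALSE)
  df <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(sample_id = sprintf("%s_%s_r%d", grid$age[i], grid$time[i],
                                   seq_len(reps)),
               age = grid$age[i], time = grid$time[i],
               batch = sprintf("b%d", ((seq_len(reps) - 1) %% n_batches) + 1),
               stringsAsFactors = FALSE)
  }))
  validate_design(df)
}

# exact-replicate count matrix with the given age x time cell means;
# `ballast` constant genes anchor median-of-ratios size factors at 1 so
# planted effects are not absorbed by normalization
counts_from_means <- function(means, reps = 3, n_genes = 1, ballast = 0) {
  # means: named c(young_T0, young_T21, aged_T0, aged_T21)
  design <- make_design(reps, n_batches = 1)
  key <- paste(design$age, design$time, sep = "_")
  m <- matrix(rep(means[key], n_genes), n_genes, nrow(design), byrow = TRUE)
  if (ballast > 0) {
    m <- rbind(m, matrix(rep(300L + 7L * seq_len(ballast),
                             times = nrow(design)), ballast, nrow(design)))
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(sprintf("g%d", seq_len(nrow(m))), design$sample_id)
  list(counts = m, design = design,
       effect_genes = sprintf("g%d", seq_len(n_genes)))
}

# brute-force median-of-ratios size factors
oracle_size_factors <- function(counts) {
  use <- apply(counts > 0, 1, all)
  lc <- log(counts[use, , drop = FALSE])
  ref <- rowMeans(lc)
  sf <- apply(lc, 2, function(col) exp(median(col - ref)))
  sf / exp(mean(log(sf)))
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force basal-plus-extension domains (per-bp reasoning at small scale)
oracle_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                           extension = 1e6) {
  tss <- genes$start
  plus <- genes$strand != "-"
  b_start <- pmax(ifelse(plus, tss - basal_up, tss - basal_down), 0)
  b_end <- ifelse(plus, tss + basal_down, tss + basal_up)
  n <- nrow(genes)
  out <- data.frame(gene_id = genes$name, basal_start = b_start,
                    basal_end = b_end, ext_start = NA_real_,
                    ext_end = NA_real_)
  for (i in seq_len(n)) {
    others <- setdiff(which(genes$chrom == genes$chrom[i]), i)
    others <- others[!(b_start[others] == b_start[i] &
                       b_end[others] == b_end[i])]
    # left boundary: the rightmost blocking basal edge inside the window
    blk <- others[b_end[others] > max(tss[i] - extension, 0) &
                  b_start[others] < b_start[i]]
    lo <- max(tss[i] - extension, 0)
    if (length(blk)) lo <- max(lo, max(pmin(b_end[blk], b_start[i])))
    hi <- tss[i] + extension
    blk <- others[b_start[others] < hi & b_end[others] > b_end[i]]
    if (length(blk)) hi <- min(hi, min(pmax(b_start[blk], b_end[i])))
    out$ext_start[i] <- min(lo, b_start[i])
    out$ext_end[i] <- max(hi, b_end[i])
  }
  out
}

# brute-force interval overlap assignment
oracle_assign <- function(peaks, domains) {
  res <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(domains))) {
      if (peaks$chrom[i] == domains$chrom[j] &&
          peaks$start[i] < domains$ext_end[j] &&
          peaks$end[i] > domains$ext_start[j]) {
        res[[length(res) + 1]] <- data.frame(peak_id = peaks$name[i],
                                             gene_id = domains$gene_id[j])
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(peak_id = character(), gene_id = character()))
  }
  do.call(rbind, res)
}

# brute-force single-linkage summit merge
oracle_merge <- function(summits, gap = 200) {
  summits <- sort(summits)
  cl <- cumsum(c(TRUE, diff(summits) > gap))
  sapply(split(summits, cl), function(s) floor((min(s) + max(s)) / 2))
}

sort_assoc <- function(a) {
  a <- a[order(a$peak_id, a$gene_id), ]
  rownames(a) <- NULL
  a
}
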