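test_that("summit merging follows the 200-bp single-linkage rule", {
  # summits 1100 and 1250 -> one peak, summit 1175, interval [675, 1675)
  p <- merge_peaks(data.frame(chrom = "chr1", summit = c(1100L, 1250L)))
  expect_equal(nrow(p), 1)
  expect_equal(p$summit, 1175)
  expect_equal(c(p$start, p$end), c(675, 1675))
  # single summit 5000 -> [4500, 5500)
  p2 <- merge_peaks(data.frame(chrom = "chr1", summit = 5000L))
  expect_equal(c(p2$start, p2$end), c(4500, 5500))
  # chain 1100, 1280, 1460 links transitively -> one cluster, summit 1280
  p3 <- merge_peaks(data.frame(chrom = "chr1", summit = c(1100L, 1280L, 1460L)))
  expect_equal(nrow(p3), 1)
  expect_equal(p3$summit, 1280)
  # counts of merged members are summed
  p4 <- merge_peaks(data.frame(chrom = "chr1", summit = c(1100L, 1250L, 3000L),
                               c1 = c(5, 7, 9)), count_cols = "c1")
  expect_equal(p4$c1, c(12, 9))
})

test_that("summit merging is idempotent and equals the brute-force oracle", {
  set.seed(101)
  for (i in 1:5) {
    s <- sort(sample(100000, 60))
    pk <- data.frame(chrom = sample(c("chr1", "chr2"), 60, TRUE), summit = s)
    m1 <- merge_peaks(pk)
    m2 <- merge_peaks(m1)
    expect_equal(m1$summit, m2$summit)
    expect_equal(nrow(m1), nrow(m2))
    for (ch in unique(pk$chrom)) {
      expect_equal(m1$summit[m1$chrom == ch],
                   unname(oracle_merge(pk$summit[pk$chrom == ch])))
    }
  }
})

test_that("background-normalized accessibility honors its contracts", {
  set.seed(102)
  n <- 80
  diff_idx <- 1:20  # the rest are stable ballast anchoring size factors
  cond <- factor(rep(c("young", "aged"), each = 2), c("young", "aged"))
  base_pk <- 150 + 5 * seq_len(n); base_bg <- 60 + 2 * seq_len(n)
  mk <- function(pk_mult_aged, bg_mult_aged) {
    pm <- ifelse(seq_len(n) %in% diff_idx, pk_mult_aged, 1)
    bm <- ifelse(seq_len(n) %in% diff_idx, bg_mult_aged, 1)
    mu_pk <- base_pk %o% rep(1, 4)
    mu_bg <- base_bg %o% rep(1, 4)
    mu_pk[, cond == "aged"] <- mu_pk[, cond == "aged"] * pm
    mu_bg[, cond == "aged"] <- mu_bg[, cond == "aged"] * bm
    list(pk = matrix(as.integer(round(mu_pk)), n, 4,
                     dimnames = list(sprintf("p%d", 1:n), paste0("s", 1:4))),
         bg = matrix(as.integer(round(mu_bg)), n, 4,
                     dimnames = list(sprintf("p%d", 1:n), paste0("s", 1:4))))
  }
  # peak and background double together -> interaction LFC 0
  both <- mk(2, 2)
  da <- differential_accessibility(both$pk, both$bg, cond, prior_scale = 1e6)
  expect_equal(da$lfc_mle[diff_idx], rep(0, 20), tolerance = 1e-6)
  # peak doubles, background constant -> LFC 1 (saturated evaluation)
  only <- mk(2, 1)
  da2 <- differential_accessibility(only$pk, only$bg, cond, prior_scale = 1e6)
  expect_equal(da2$lfc_mle[diff_idx], rep(1, 20), tolerance = 1e-6)
})

test_that("the stacked interaction equals a grid-search MLE on a tiny instance", {
  set.seed(103)
  cond <- factor(rep(c("young", "aged"), each = 2), c("young", "aged"))
  pk <- matrix(rnbinom(4 * 30, mu = 150, size = 20), 30, 4,
               dimnames = list(sprintf("p%d", 1:30), paste0("s", 1:4)))
  bg <- matrix(rnbinom(4 * 30, mu = 60, size = 20), 30, 4,
               dimnames = list(sprintf("p%d", 1:30), paste0("s", 1:4)))
  da <- differential_accessibility(pk, bg, cond, prior_scale = 1e6)
  # independent oracle: direct maximization of the stacked NB likelihood
  # with the same size factors and dispersion, bypassing IRLS
  sf_bg <- estimate_size_factors(bg); sf_pk <- estimate_size_factors(pk)
  i <- 7
  y <- c(bg[i, ], pk[i, ])
  sf <- c(sf_bg, sf_pk)
  is_pk <- rep(c(0, 1), each = 4)
  is_ag <- rep(as.integer(cond == "aged"), 2)
  cnts <- rbind(bg, pk[1, , drop = FALSE])  # dispersion context as fitted
  X <- cbind(1, is_pk, is_ag, is_pk * is_ag)
  counts_all <- cbind(bg, pk)
  Xfull <- model.matrix(~ rep(c("bg", "pk"), each = 4) * rep(cond, 2))
  disp <- estimate_dispersions(counts_all, Xfull, sf)[i]
  nll <- function(b) {
    mu <- sf * exp(X %*% b * log(2))
    -sum(dnbinom(y, size = 1 / disp, mu = mu, log = TRUE))
  }
  opt <- optim(rep(0, 4), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  expect_equal(da$lfc_mle[i], opt$par[4], tolerance = 1e-3)
})

test_that("all-zero backgrounds fall back to peak-only normalization", {
  set.seed(104)
  cond <- factor(rep(c("young", "aged"), each = 2), c("young", "aged"))
  pk <- matrix(rnbinom(4 * 20, mu = 150, size = 20), 20, 4,
               dimnames = list(sprintf("p%d", 1:20), paste0("s", 1:4)))
  bg <- matrix(rnbinom(4 * 20, mu = 60, size = 20), 20, 4,
               dimnames = list(sprintf("p%d", 1:20), paste0("s", 1:4)))
  bg[3, ] <- 0L
  da <- differential_accessibility(pk, bg, cond, prior_scale = 1e6)
  expect_true(da$bg_fallback[3])
  expect_false(any(da$bg_fallback[-3]))
  expect_true(is.finite(da$lfc_mle[3]))
})

test_that("regulatory domains implement basal-plus-extension exactly", {
  # isolated + strand gene, TSS 2,000,000
  g <- data.frame(chrom = "chr1", start = 2000000L, end = 2000001L,
                  name = "g1", score = 0L, strand = "+")
  d <- build_regulatory_domains(g)
  expect_equal(c(d$basal_start, d$basal_end), c(1995000, 2001000))
  expect_equal(c(d$ext_start, d$ext_end), c(1000000, 3000000))
  # minus-strand gene mirrors the basal domain
  g2 <- g; g2$strand <- "-"
  d2 <- build_regulatory_domains(g2)
  expect_equal(c(d2$basal_start, d2$basal_end), c(1999000, 2005000))
  # neighbor basal domains clip the extension
  g3 <- data.frame(chrom = "chr1", start = c(2000000L, 2400000L),
                   end = c(2000001L, 2400001L), name = c("a", "b"),
                   score = 0L, strand = "+")
  d3 <- build_regulatory_domains(g3)
  expect_equal(d3$ext_end[1], d3$basal_start[2])
  expect_equal(d3$ext_start[2], d3$basal_end[1])
  # duplicate TSS: both kept with identical domains
  g4 <- data.frame(chrom = "chr1", start = 2000000L, end = 2000001L,
                   name = c("a", "b"), score = 0L, strand = "+")
  d4 <- build_regulatory_domains(rbind(g4))
  expect_equal(d4$ext_start[1], d4$ext_start[2])
  expect_equal(d4$ext_end[1], d4$ext_end[2])
})

test_that("random gene sets match the brute-force domain oracle", {
  set.seed(105)
  for (i in 1:5) {
    n <- 12
    g <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                    start = sample(3000000, n),
                    name = sprintf("g%02d", 1:n), score = 0L,
                    strand = sample(c("+", "-"), n, TRUE))
    g$end <- g$start + 1L
    d <- build_regulatory_domains(g)
    o <- oracle_domains(g)
    expect_equal(d$ext_start, o$ext_start)
    expect_equal(d$ext_end, o$ext_end)
  }
})

test_that("peak-gene assignment equals the brute-force overlap oracle", {
  set.seed(106)
  g <- data.frame(chrom = sample(c("chr1", "chr2"), 20, TRUE),
                  start = sample(5000000, 20),
                  name = sprintf("g%02d", 1:20), score = 0L,
                  strand = sample(c("+", "-"), 20, TRUE))
  g$end <- g$start + 1L
  dom <- build_regulatory_domains(g)
  pk <- data.frame(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                   start = sample(5000000, 100))
  pk$end <- pk$start + 1000L
  pk$name <- sprintf("p%03d", 1:100)
  a <- sort_assoc(assign_peaks_to_genes(pk, dom))
  b <- sort_assoc(oracle_assign(pk, dom))
  expect_equal(a, b)
  # a peak beyond 1 Mb of every TSS is unassociated
  far <- data.frame(chrom = "chr9", start = 1L, end = 1001L, name = "far")
  expect_equal(nrow(assign_peaks_to_genes(far, dom)), 0)
})

test_that("distance-binned peak counts are correct and nested", {
  genes <- data.frame(chrom = "chr1", start = 1000000L, name = "g1")
  dp <- data.frame(peak_id = sprintf("p%d", 1:3), chrom = "chr1",
                   summit = 1000000L + c(5000L, 50000L, 500000L),
                   sig = TRUE, lfc_mle = c(2, 2, -2))
  cnt <- peaks_per_gene_by_distance(dp, genes)
  expect_equal(unname(cnt[1, ]), c(1, 2, 3))
  up <- peaks_per_gene_by_distance(dp, genes, direction = "up")
  expect_equal(unname(up[1, ]), c(1, 2, 2))
  none <- peaks_per_gene_by_distance(dp[dp$sig == FALSE, , drop = FALSE], genes)
  expect_equal(unname(none[1, ]), c(0, 0, 0))
  # nested monotonicity on random data
  set.seed(107)
  genes2 <- data.frame(chrom = "chr1", start = sample(2000000, 10),
                       name = sprintf("g%d", 1:10))
  dp2 <- data.frame(peak_id = sprintf("p%d", 1:50), chrom = "chr1",
                    summit = sample(2000000, 50), sig = TRUE,
                    lfc_mle = rnorm(50))
  cnt2 <- peaks_per_gene_by_distance(dp2, genes2)
  expect_true(all(cnt2[, 1] <= cnt2[, 2]))
  expect_true(all(cnt2[, 2] <= cnt2[, 3]))
})

test_that("pileups are flat on uniform coverage and depth-invariant", {
  bg <- data.frame(chrom = "chrA", start = seq(0L, 19900L, 100L),
                   end = seq(100L, 20000L, 100L), value = 2)
  anchors <- data.frame(chrom = "chrA", start = c(5000L, 9000L),
                        end = c(5100L, 9100L))
  p <- pileup(list(a = bg), "young", anchors, flank = 1000)
  expect_equal(length(unique(p[, "young"])), 1)
  # doubling depth leaves the normalized profile unchanged
  bg2 <- bg; bg2$value <- 4
  p2 <- pileup(list(a = bg2), "young", anchors, flank = 1000)
  expect_equal(p, p2)
  # planted symmetric signal peaks at offset zero
  sig <- bg
  sig$value[sig$start >= 4900 & sig$end <= 5200] <- 20
  sig$value[sig$start >= 8900 & sig$end <= 9200] <- 20
  p3 <- pileup(list(a = sig), "young", anchors, flank = 1000)
  expect_equal(p3["0", "young"], max(p3[, "young"]))
  expect_lt(p3["-900", "young"], p3["0", "young"])
  # off-chromosome anchors are skipped with a note
  far <- rbind(anchors, data.frame(chrom = "chrA", start = 19950L, end = 19960L))
  expect_message(pileup(list(a = bg), "young", far, flank = 1000), "skipped")
})

test_that("CpG-island proximity applies the 5-kb boundary exactly", {
  genes <- data.frame(chrom = "chr1",
                      start = c(100000L, 200000L, 300000L, 400000L),
                      name = c("span", "near", "far", "none"))
  islands <- data.frame(chrom = "chr1",
                        start = c(99900L, 194702L, 294700L),
                        end = c(100200L, 195002L, 295000L))
  # island spans TSS -> 0; last base 4999 bp upstream -> true;
  # last base 5001 bp upstream -> false; no island on record -> false
  res <- cpg_island_proximity(genes, islands)
  expect_equal(res$has_cgi, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$cgi_distance[1:3], c(0, 4999, 5001))
  expect_equal(attr(res, "pct"), 50)
})
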