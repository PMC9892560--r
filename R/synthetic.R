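# Synthetic-data generator with planted ground truth for every layer the
# pipeline consumes: factorial transplant RNA-seq counts, paired
# exon/intron counts, clustered-CpG methylomes, and TSS-anchored ATAC
# peak landscapes. One RNG stream per layer, derived from the master seed
# by fixed offsets, so layers are independently reproducible.

GENE_CLASSES <- c("NULL", "AGE_REVERSIBLE", "AGE_IRREVERSIBLE",
                  "ENGRAFT_ONLY", "NICHE_ONLY")

.layer_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 7L))
}

#' Build a simulation configuration
#'
#' Defaults describe the reference simulation used throughout the test
#' suite: 2000 genes, 3 replicates per age-by-time cell, 2 batches, planted
#' age effects of 1-3 log2 units with random sign, a mean-dispersion trend
#' alpha = a0 + a1/mu, and moderate batch and library-size variation.
#'
#' @param n_genes Number of genes.
#' @param replicates_per_group Replicates per age-by-time cell (>= 2).
#' @param n_batches Number of batches (>= 1), balanced across groups.
#' @param class_proportions Named fractions over the planted gene classes
#'   NULL, AGE_REVERSIBLE, AGE_IRREVERSIBLE, ENGRAFT_ONLY, NICHE_ONLY; must
#'   sum to 1.
#' @param effect_size_range Range of |planted effect| in log2 units.
#' @param batch_sd SD (log2) of per-gene additive batch effects.
#' @param dispersion_params c(a0, a1) of the trend alpha = a0 + a1/mu.
#' @param baseline_log2 c(mean, sd) of the log2 baseline expression.
#' @param library_size_range Range of per-sample library-size factors.
#' @param seed Master seed; fully determines all layers.
#' @param exon_intron,methylome,atac Optional lists overriding layer
#'   defaults (see the configuration vignette).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       replicates_per_group = 3,
                       n_batches = 2,
                       class_proportions = c("NULL" = 0.70,
                                             AGE_REVERSIBLE = 0.10,
                                             AGE_IRREVERSIBLE = 0.10,
                                             ENGRAFT_ONLY = 0.05,
                                             NICHE_ONLY = 0.05),
                       effect_size_range = c(1, 3),
                       batch_sd = 0.3,
                       dispersion_params = c(a0 = 0.05, a1 = 5),
                       baseline_log2 = c(mean = 5, sd = 2),
                       library_size_range = c(0.7, 1.4),
                       seed = 1,
                       exon_intron = list(),
                       methylome = list(),
                       atac = list()) {
  miss <- setdiff(GENE_CLASSES, names(class_proportions))
  if (length(miss)) {
    class_proportions[miss] <- 0
  }
  unknown <- setdiff(names(class_proportions), GENE_CLASSES)
  if (length(unknown)) stop("unknown gene class(es): ", paste(unknown, collapse = ", "))
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class proportions must sum to 1 (got ", sum(class_proportions), ")")
  }
  if (any(class_proportions < 0)) stop("class proportions must be >= 0")
  if (n_genes < 1 || replicates_per_group < 1 || n_batches < 1) {
    stop("n_genes, replicates_per_group and n_batches must be >= 1")
  }
  if (replicates_per_group < 2) {
    stop("replicates_per_group must be >= 2 for an identifiable model")
  }
  ei <- utils::modifyList(list(
    transcription_fraction = 0.10, stability_fraction = 0.10,
    intron_ratio = 0.15), exon_intron)
  meth <- utils::modifyList(list(
    chrom = "chrS", chrom_length = 200000L, n_dmrs = 40,
    dmr_delta = 0.5, coverage_mean = 20, replicates = 3,
    bg_cluster_rate = 1 / 2000, cpg_per_cluster_mean = 5,
    logit_noise_sd = 0.1), methylome)
  at <- utils::modifyList(list(
    n_genes = 200, chrom = "chrA", gene_spacing = 100000L,
    peaks_per_gene_mean = 3, frac_differential = 0.10, diff_lfc = 1.5,
    samples_per_condition = 2, peak_mean = 100, bg_mean = 30,
    dispersion = 0.05, near_exp_mean = 5e4, far_fraction = 0.15,
    enrich_pattern = FALSE), atac)
  structure(list(n_genes = as.integer(n_genes),
                 replicates_per_group = as.integer(replicates_per_group),
                 n_batches = as.integer(n_batches),
                 class_proportions = class_proportions[GENE_CLASSES],
                 effect_size_range = effect_size_range,
                 batch_sd = batch_sd,
                 dispersion_params = dispersion_params,
                 baseline_log2 = baseline_log2,
                 library_size_range = library_size_range,
                 seed = as.integer(seed),
                 exon_intron = ei, methylome = meth, atac = at),
            class = "sim_config")
}

# deterministic largest-remainder apportionment of genes to classes
.apportion <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  base
}

.sample_table <- function(cfg) {
  groups <- expand.grid(time = c("T0", "T21"), age = c("young", "aged"),
                        stringsAsFactors = FALSE)
  reps <- cfg$replicates_per_group
  df <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    data.frame(sample_id = sprintf("%s_%s_r%d", groups$age[i], groups$time[i],
                                   seq_len(reps)),
               age = groups$age[i], time = groups$time[i],
               batch = sprintf("b%d", ((seq_len(reps) - 1) %% cfg$n_batches) + 1),
               stringsAsFactors = FALSE)
  }))
  validate_design(df)
}

#' Simulate the four-group heterochronic-transplant count matrix
#'
#' Counts are negative-binomial with log2 mean = baseline + beta_age*age +
#' beta_time*time + beta_interaction*age*time + beta_batch, scaled by a
#' per-sample library factor. Planted classes: AGE_REVERSIBLE genes have
#' beta_interaction = -beta_age exactly (a young niche fully reverts the
#' age effect); AGE_IRREVERSIBLE genes have beta_interaction = 0;
#' ENGRAFT_ONLY and NICHE_ONLY perturb only beta_time / beta_interaction.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts` (integer matrix), `design` (data frame) and
#'   `truth` (per-gene class and log2 coefficients).
#' @export
simulate_transplant_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.layer_seed(cfg$seed, 101))
  n <- cfg$n_genes
  nclass <- .apportion(n, cfg$class_proportions)
  cls <- rep(names(nclass), nclass)
  r <- cfg$effect_size_range
  amp <- function(k) runif(k, r[1], r[2]) * sample(c(-1, 1), k, replace = TRUE)
  beta_age <- beta_time <- beta_int <- numeric(n)
  i_rev <- which(cls == "AGE_REVERSIBLE")
  i_irr <- which(cls == "AGE_IRREVERSIBLE")
  i_eng <- which(cls == "ENGRAFT_ONLY")
  i_nic <- which(cls == "NICHE_ONLY")
  beta_age[i_rev] <- amp(length(i_rev))
  beta_int[i_rev] <- -beta_age[i_rev]
  beta_age[i_irr] <- amp(length(i_irr))
  beta_time[i_eng] <- amp(length(i_eng))
  beta_int[i_nic] <- amp(length(i_nic))
  beta_batch <- matrix(0, n, cfg$n_batches)
  if (cfg$n_batches > 1) {
    beta_batch[, -1] <- rnorm(n * (cfg$n_batches - 1), 0, cfg$batch_sd)
  }
  base <- rnorm(n, cfg$baseline_log2[["mean"]], cfg$baseline_log2[["sd"]])
  design <- .sample_table(cfg)
  ns <- nrow(design)
  libf <- runif(ns, cfg$library_size_range[1], cfg$library_size_range[2])
  a0 <- cfg$dispersion_params[["a0"]]; a1 <- cfg$dispersion_params[["a1"]]
  alpha <- a0 + a1 / pmax(2^base, 1e-3)
  age_i <- as.integer(design$age == "aged")
  time_i <- as.integer(design$time == "T21")
  batch_i <- as.integer(design$batch)
  log2mu <- outer(base, rep(1, ns)) +
    outer(beta_age, age_i) + outer(beta_time, time_i) +
    outer(beta_int, age_i * time_i) +
    beta_batch[, batch_i, drop = FALSE]
  mu <- sweep(2^log2mu, 2, libf, "*")
  counts <- matrix(rnbinom(n * ns, mu = mu, size = rep(1 / alpha, ns)),
                   n, ns)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sprintf("gene%04d", seq_len(n)), design$sample_id)
  truth <- data.frame(gene_id = rownames(counts), class = cls,
                      beta_age = beta_age, beta_time = beta_time,
                      beta_interaction = beta_int,
                      stringsAsFactors = FALSE)
  if (cfg$n_batches > 1) {
    bb <- beta_batch[, -1, drop = FALSE]
    colnames(bb) <- sprintf("beta_batch_b%d", 2:cfg$n_batches)
    truth <- cbind(truth, bb)
  }
  list(counts = counts, design = design, truth = truth,
       library_factors = setNames(libf, design$sample_id))
}

#' Simulate paired exonic/intronic counts
#'
#' Intronic abundance tracks the transcription rate; exonic abundance is
#' transcription times an mRNA-stability factor. Planted TRANSCRIPTION
#' genes shift both layers with age; planted STABILITY genes shift the
#' exonic layer only (a pure stability change).
#'
#' @param cfg A [sim_config()]; layer parameters under `cfg$exon_intron`.
#' @return List with `exonic` and `intronic` count matrices, `design`, and
#'   `truth` (beta_transcription_age, beta_stability_age, class).
#' @export
simulate_exon_intron_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.layer_seed(cfg$seed, 202))
  n <- cfg$n_genes
  ei <- cfg$exon_intron
  props <- c("NULL" = 1 - ei$transcription_fraction - ei$stability_fraction,
             TRANSCRIPTION = ei$transcription_fraction,
             STABILITY = ei$stability_fraction)
  if (props[["NULL"]] < 0) stop("exon/intron class fractions exceed 1")
  nclass <- .apportion(n, props)
  cls <- rep(names(nclass), nclass)
  r <- cfg$effect_size_range
  amp <- function(k) runif(k, r[1], r[2]) * sample(c(-1, 1), k, replace = TRUE)
  beta_tx <- beta_st <- numeric(n)
  beta_tx[cls == "TRANSCRIPTION"] <- amp(sum(cls == "TRANSCRIPTION"))
  beta_st[cls == "STABILITY"] <- amp(sum(cls == "STABILITY"))
  base <- rnorm(n, cfg$baseline_log2[["mean"]], cfg$baseline_log2[["sd"]])
  design <- .sample_table(cfg)
  ns <- nrow(design)
  libf_ex <- runif(ns, cfg$library_size_range[1], cfg$library_size_range[2])
  libf_in <- runif(ns, cfg$library_size_range[1], cfg$library_size_range[2])
  a0 <- cfg$dispersion_params[["a0"]]; a1 <- cfg$dispersion_params[["a1"]]
  age_i <- as.integer(design$age == "aged")
  log2_tx <- outer(base, rep(1, ns)) + outer(beta_tx, age_i)
  mu_in <- sweep(2^log2_tx * ei$intron_ratio, 2, libf_in, "*")
  mu_ex <- sweep(2^(log2_tx + outer(beta_st, age_i)), 2, libf_ex, "*")
  # one biological dispersion per gene, shared by both read types: the
  # same replicate libraries underlie the exonic and intronic counts
  alpha_in <- alpha_ex <- a0 + a1 / pmax(2^base, 1e-3)
  gn <- sprintf("gene%04d", seq_len(n))
  intronic <- matrix(rnbinom(n * ns, mu = mu_in, size = rep(1 / alpha_in, ns)),
                     n, ns, dimnames = list(gn, design$sample_id))
  exonic <- matrix(rnbinom(n * ns, mu = mu_ex, size = rep(1 / alpha_ex, ns)),
                   n, ns, dimnames = list(gn, design$sample_id))
  storage.mode(intronic) <- "integer"
  storage.mode(exonic) <- "integer" 
  truth <- data.frame(gene_id = gn, class = cls,
                      beta_transcription_age = beta_tx,
                      beta_stability_age = beta_st,
                      stringsAsFactors = FALSE)
  list(exonic = exonic, intronic = intronic, design = design, truth = truth)
}

#' Simulate replicate bisulfite methylomes with planted DMRs
#'
#' CpG sites arise from a clustered point process along one synthetic
#' chromosome; each 100-bp tile has a baseline methylation proportion, and
#' planted DMR tiles (each guaranteed >= 4 CpGs) shift the aged proportion
#' by +/- `dmr_delta`. Per-CpG coverage is Poisson and methylated counts
#' are binomial around the tile proportion with mild replicate-level logit
#' noise. CpGs with zero coverage are not emitted (unobserved sites).
#'
#' @param cfg A [sim_config()]; layer parameters under `cfg$methylome`.
#' @return List with `tracks` (data frame list; attributes condition and
#'   replicate), `track_info` (data frame), and `truth` (planted windows).
#' @export
simulate_methylome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  mm <- cfg$methylome
  set.seed(.layer_seed(cfg$seed, 303))
  if (mm$n_dmrs > 0 && mm$dmr_delta < 0.4) {
    warning("planted DMR delta ", mm$dmr_delta,
            " is below the caller's 40% filter; truth not discoverable")
  }
  n_tiles <- mm$chrom_length %/% 100L
  dmr_tiles <- if (mm$n_dmrs > 0) {
    sort(sample.int(n_tiles, mm$n_dmrs) - 1L)
  } else integer(0)
  # DMR CpGs: at least 4 per planted tile
  dmr_pos <- unlist(lapply(dmr_tiles, function(t0) {
    k <- 4 + rpois(1, 2)
    t0 * 100L + sort(sample.int(100L, min(k, 50L)))  - 1L
  }))
  # background clusters
  n_cl <- rpois(1, mm$chrom_length * mm$bg_cluster_rate)
  centers <- sort(sample.int(mm$chrom_length, max(n_cl, 1)))
  bg_pos <- unlist(lapply(centers, function(cen) {
    k <- 1 + rpois(1, mm$cpg_per_cluster_mean)
    unique(pmin(pmax(cen + round(rnorm(k, 0, 30)), 0L), mm$chrom_length - 1L))
  }))
  pos <- sort(unique(c(dmr_pos, bg_pos)))
  tile_of <- pos %/% 100L
  tiles <- sort(unique(tile_of))
  # baseline proportion per tile; DMR tiles get young/aged pair with the
  # planted shift, clamped inside (0.03, 0.97)
  p_base <- setNames(pmin(pmax(stats::rbeta(length(tiles), 2, 2), 0.05), 0.95),
                     tiles)
  direction <- sample(c("gain", "loss"), length(dmr_tiles), replace = TRUE)
  p_young <- p_base[as.character(dmr_tiles)]
  d <- mm$dmr_delta
  p_young[direction == "gain"] <- runif(sum(direction == "gain"), 0.03, 0.97 - d)
  p_young[direction == "loss"] <- runif(sum(direction == "loss"), 0.03 + d, 0.97)
  p_aged <- p_young + ifelse(direction == "gain", d, -d)
  prop_young <- p_base[as.character(tile_of)]
  prop_aged <- prop_young
  if (length(dmr_tiles)) {
    m <- match(tile_of, dmr_tiles)
    hit <- !is.na(m)
    prop_young[hit] <- p_young[m[hit]]
    prop_aged[hit] <- p_aged[m[hit]]
  }
  mk_track <- function(cond, rep_i) {
    p <- if (cond == "young") prop_young else prop_aged
    p_rep <- stats::plogis(stats::qlogis(pmin(pmax(p, 1e-4), 1 - 1e-4)) +
                           rnorm(length(p), 0, mm$logit_noise_sd))
    cov <- rpois(length(pos), mm$coverage_mean)
    meth <- rbinom(length(pos), cov, p_rep)
    keep <- cov > 0
    data.frame(chrom = rep(mm$chrom, sum(keep)), pos0 = pos[keep],
               strand = rep("+", sum(keep)), context = rep("CpG", sum(keep)),
               count_methylated = meth[keep],
               count_total = cov[keep], stringsAsFactors = FALSE)
  }
  info <- expand.grid(replicate = seq_len(mm$replicates),
                      condition = c("young", "aged"),
                      stringsAsFactors = FALSE)[, c("condition", "replicate")]
  tracks <- lapply(seq_len(nrow(info)), function(i) {
    mk_track(info$condition[i], info$replicate[i])
  })
  names(tracks) <- sprintf("%s_r%d", info$condition, info$replicate)
  truth <- data.frame(chrom = rep(mm$chrom, length(dmr_tiles)),
                      start = dmr_tiles * 100L,
                      end = dmr_tiles * 100L + 100L,
                      is_dmr = rep(TRUE, length(dmr_tiles)),
                      delta = ifelse(direction == "gain", d, -d),
                      direction = direction,
                      stringsAsFactors = FALSE)
  list(tracks = tracks, track_info = info, truth = truth)
}

#' Simulate a TSS-anchored ATAC peak landscape
#'
#' Gene TSSs are placed along a synthetic chromosome; peaks are placed at
#' sampled signed distances from TSSs (1-kb peaks, summit centered), with
#' NB counts for the peak and for a stable +/- 10 kb background region in
#' each sample. A configurable fraction of peaks carries a planted
#' accessibility log2 fold change in aged samples. With
#' `atac$enrich_pattern = TRUE`, genes are also assigned reversibility
#' categories and extra age-accessible peaks are planted within 10 kb of
#' upregulated-irreversible (ARI_up) genes.
#'
#' @param cfg A [sim_config()]; layer parameters under `cfg$atac`.
#' @return List with `peaks` (data frame incl. summit), `peak_counts` and
#'   `bg_counts` matrices, `condition` factor, `genes` (BED6-style TSS
#'   models), and `truth` (per-peak true LFC and anchor gene; per-gene
#'   category when enrichment is on).
#' @export
simulate_atac_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  at <- cfg$atac
  set.seed(.layer_seed(cfg$seed, 404))
  ng <- at$n_genes
  tss <- as.integer(2e6 + (seq_len(ng) - 1) * at$gene_spacing +
                    round(runif(ng, -2e4, 2e4)))
  tries <- 0
  while (anyDuplicated(tss) && tries < 20) {
    dup <- which(duplicated(tss))
    tss[dup] <- tss[dup] + as.integer(round(runif(length(dup), -2e4, 2e4)))
    tries <- tries + 1
  }
  if (tries > 0) message("resolved ", tries, " TSS collision round(s) by re-sampling")
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  gene_id <- sprintf("g%03d", seq_len(ng))
  genes <- data.frame(chrom = at$chrom, start = tss, end = tss + 1L,
                      name = gene_id, score = 0L, strand = strand,
                      stringsAsFactors = FALSE)
  gene_cat <- rep(NA_character_, ng)
  if (isTRUE(at$enrich_pattern)) {
    cats <- c("ARR_up", "ARR_down", "ARI_up", "ARI_down", "unchanged")
    gene_cat <- sample(cats, ng, replace = TRUE,
                       prob = c(0.1, 0.1, 0.1, 0.1, 0.6))
  }
  npk <- rpois(ng, at$peaks_per_gene_mean)
  anchor <- rep(seq_len(ng), npk)
  n_peaks <- length(anchor)
  far <- runif(n_peaks) < at$far_fraction
  dist <- integer(n_peaks)
  dist[!far] <- as.integer(round(rexp(sum(!far), 1 / at$near_exp_mean)) *
                           sample(c(-1L, 1L), sum(!far), replace = TRUE))
  dist[far] <- as.integer(round(runif(sum(far), -1.5e6, 1.5e6)))
  summit <- pmax(tss[anchor] + dist, 501L)
  is_diff <- runif(n_peaks) < at$frac_differential
  lfc <- ifelse(is_diff,
                at$diff_lfc * sample(c(-1, 1), n_peaks, replace = TRUE), 0)
  if (isTRUE(at$enrich_pattern)) {
    # plant extra age-accessible peaks within 10 kb of ARI_up genes
    ari_up <- which(gene_cat == "ARI_up")
    extra_anchor <- rep(ari_up, each = 2)
    extra_summit <- pmax(tss[extra_anchor] +
                         as.integer(round(runif(length(extra_anchor), -9000, 9000))),
                         501L)
    anchor <- c(anchor, extra_anchor)
    summit <- c(summit, extra_summit)
    lfc <- c(lfc, rep(at$diff_lfc, length(extra_anchor)))
    n_peaks <- length(anchor)
  }
  o <- order(summit)
  anchor <- anchor[o]; summit <- summit[o]; lfc <- lfc[o]
  peak_id <- sprintf("peak%05d", seq_len(n_peaks))
  peaks <- data.frame(chrom = at$chrom, start = summit - 500L,
                      end = summit + 500L, name = peak_id, score = 0L,
                      strand = ".", summit = summit,
                      stringsAsFactors = FALSE)
  spc <- at$samples_per_condition
  condition <- factor(rep(c("young", "aged"), each = spc),
                      levels = c("young", "aged"))
  sample_id <- sprintf("%s_a%d", condition, rep(seq_len(spc), 2))
  libf <- runif(length(condition), 0.8, 1.2)
  base_pk <- at$peak_mean * 2^rnorm(n_peaks, 0, 0.5)
  base_bg <- at$bg_mean * 2^rnorm(n_peaks, 0, 0.3)
  aged_i <- as.integer(condition == "aged")
  mu_pk <- sweep(base_pk * 2^outer(lfc, aged_i), 2, libf, "*")
  mu_bg <- sweep(outer(base_bg, rep(1, length(condition))), 2, libf, "*")
  size <- 1 / at$dispersion
  peak_counts <- matrix(rnbinom(length(mu_pk), mu = mu_pk, size = size),
                        n_peaks, length(condition),
                        dimnames = list(peak_id, sample_id))
  bg_counts <- matrix(rnbinom(length(mu_bg), mu = mu_bg, size = size),
                      n_peaks, length(condition),
                      dimnames = list(peak_id, sample_id))
  storage.mode(peak_counts) <- "integer"
  storage.mode(bg_counts) <- "integer" 
  truth_peaks <- data.frame(peak_id = peak_id, true_lfc = lfc,
                            anchor_gene = gene_id[anchor],
                            tss_distance = summit - tss[anchor],
                            stringsAsFactors = FALSE)
  truth_genes <- data.frame(gene_id = gene_id, category = gene_cat,
                            stringsAsFactors = FALSE)
  list(peaks = peaks, peak_counts = peak_counts, bg_counts = bg_counts,
       condition = condition, genes = genes,
       truth = list(peaks = truth_peaks, genes = truth_genes))
}

#' Run every simulation layer
#' @param cfg A [sim_config()].
#' @return Named list with `rna`, `exon_intron`, `methylome`, `atac`.
#' @export
simulate_all <- function(cfg) {
  list(rna = simulate_transplant_counts(cfg),
       exon_intron = simulate_exon_intron_counts(cfg),
       methylome = simulate_methylome(cfg),
       atac = simulate_atac_landscape(cfg))
}

#' Write a complete fixture bundle to disk
#'
#' Runs all simulation layers and writes every file in the pipeline's
#' standard on-disk formats plus truth tables and a checksum manifest.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Data frame manifest (file, md5), invisibly written to
#'   `manifest.tsv` as well.
#' @export
write_fixture_bundle <- function(cfg, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  sim <- simulate_all(cfg)
  fp <- function(x) file.path(outdir, x)
  write_counts(sim$rna$counts, fp("counts.tsv"))
  write_design(sim$rna$design, fp("design.tsv"))
  .write_tsv(sim$rna$truth, fp("truth_genes.tsv"))
  write_counts(sim$exon_intron$exonic, fp("exonic.tsv"))
  write_counts(sim$exon_intron$intronic, fp("intronic.tsv"))
  .write_tsv(sim$exon_intron$truth, fp("truth_exon_intron.tsv"))
  for (nm in names(sim$methylome$tracks)) {
    write_methylation(sim$methylome$tracks[[nm]],
                      fp(sprintf("meth_%s.tsv", nm)))
  }
  .write_tsv(sim$methylome$truth, fp("truth_dmrs.tsv"))
  write_bed(sim$atac$peaks, fp("peaks.bed"))
  write_counts(sim$atac$peak_counts, fp("peak_counts.tsv"))
  write_counts(sim$atac$bg_counts, fp("bg_counts.tsv"))
  write_bed(sim$atac$genes, fp("genes_tss.bed"))
  .write_tsv(sim$atac$truth$peaks, fp("truth_peaks.tsv"))
  .write_tsv(sim$atac$truth$genes, fp("truth_atac_genes.tsv"))
  files <- sort(setdiff(list.files(outdir), "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outdir, files))),
                         stringsAsFactors = FALSE)
  .write_tsv(manifest, fp("manifest.tsv"))
  manifest
}
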