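# Effect decomposition for the 2x2 heterochronic-transplant design and
# ARR/ARI reversibility classification.
#
# The gene-wise model is count ~ time + age + time:age (+ batch when more
# than one batch is present), with treatment coding anchored at
# young/T0. Under that coding:
#   age coefficient          = AgedT0  - YoungT0   (the age effect)
#   time coefficient         = YoungT21 - YoungT0  (the engraftment effect)
#   interaction coefficient  = (AgedT21 - AgedT0) - (YoungT21 - YoungT0)
# i.e. the interaction is the niche effect: the aged cells' response to
# transplantation beyond what engraftment alone explains.

#' Threshold profiles for effect calling
#'
#' `strict` is s-value < 0.05 with |moderated LFC| > 1. `permissive` is
#' s-value < 0.15 with |moderated LFC| > 1 plus a batch-LFC filter
#' (default: |batch LFC| > 0.5) applied when calling reversibility.
#'
#' @param name "strict" or "permissive", or pass all fields for a custom
#'   profile.
#' @param lfc_min Minimum |moderated LFC| (log2, strict inequality).
#' @param s_max Maximum s-value (strict inequality).
#' @param batch_rule One of "none", "abs_above", "abs_below".
#' @param batch_lfc Threshold for the batch rule.
#' @return A `threshold_profile` list.
#' @export
threshold_profile <- function(name = c("strict", "permissive", "custom"),
                              lfc_min = NULL, s_max = NULL,
                              batch_rule = NULL, batch_lfc = 0.5) {
  name <- match.arg(name)
  defaults <- switch(name,
    strict = list(lfc_min = 1, s_max = 0.05, batch_rule = "none"),
    permissive = list(lfc_min = 1, s_max = 0.15, batch_rule = "abs_above"),
    custom = list(lfc_min = 1, s_max = 0.05, batch_rule = "none"))
  p <- list(name = name,
            lfc_min = if (is.null(lfc_min)) defaults$lfc_min else lfc_min,
            s_max = if (is.null(s_max)) defaults$s_max else s_max,
            batch_rule = if (is.null(batch_rule)) defaults$batch_rule else batch_rule,
            batch_lfc = batch_lfc)
  stopifnot(p$lfc_min > 0, p$s_max > 0, p$s_max < 1,
            p$batch_rule %in% c("none", "abs_above", "abs_below"))
  class(p) <- "threshold_profile"
  p
}

#' Decompose age, engraftment, niche and batch effects per gene
#'
#' Fits the gene-wise negative-binomial model count ~ time + age +
#' time:age (+ batch when the design has more than one batch level) and
#' reports each named effect as a moderated (empirical-Bayes shrunken)
#' log2 fold change with s-value, plus the raw Wald p and BH-adjusted p.
#' The interaction coefficient is reported as the niche effect.
#'
#' @param counts Gene-by-sample integer count matrix.
#' @param design Sample design (see [read_design()]); all four age-by-time
#'   cells must be populated.
#' @param min_count Genes whose total count is below this are dropped.
#' @param prior_scale Optional fixed shrinkage prior scale.
#' @return A `gene_effect_table` data frame: one row per retained gene,
#'   columns `<effect>_<stat>` for effect in age/engraftment/niche/batch
#'   and stat in lfc (moderated), mle, se, svalue, pvalue, padj; plus
#'   `residual_sd`, the gene's residual SD of log2 normalized counts
#'   (a per-gene reproducibility measure).
#' @export
decompose_effects <- function(counts, design, min_count = 10,
                              prior_scale = NULL) {
  design <- validate_design(design, counts)
  cells <- table(design$age, design$time)
  if (any(cells == 0)) {
    stop("missing factorial cell(s); the decomposition is unidentifiable")
  }
  keep <- rowSums(counts) >= min_count
  counts <- counts[keep, , drop = FALSE]
  use_batch <- nlevels(droplevels(design$batch)) > 1
  fml <- if (use_batch) ~ time + age + time:age + batch else ~ time + age + time:age
  X <- model.matrix(fml, data = droplevels(design))
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, X, sf)
  fit <- fit_nb_glm(counts, X, sf, disp)
  effects <- list(age = "ageaged", engraftment = "timeT21",
                  niche = "timeT21:ageaged")
  out <- data.frame(gene_id = rownames(counts), stringsAsFactors = FALSE)
  for (eff in names(effects)) {
    me <- moderate_effects(fit, effects[[eff]], prior_scale = prior_scale)
    out[[paste0(eff, "_lfc")]] <- me$lfc_moderated
    out[[paste0(eff, "_mle")]] <- me$lfc_mle
    out[[paste0(eff, "_se")]] <- me$se
    out[[paste0(eff, "_svalue")]] <- me$svalue
    out[[paste0(eff, "_pvalue")]] <- me$pvalue
    out[[paste0(eff, "_padj")]] <- me$padj
  }
  if (use_batch) {
    bcols <- grep("^batch", colnames(X), value = TRUE)
    bmods <- lapply(bcols, function(bc) moderate_effects(fit, bc,
                                                         prior_scale = prior_scale))
    # report the largest-magnitude batch effect per gene; the batch-LFC
    # filter acts on the raw (unshrunken) coefficient: it is a
    # heterogeneity gate, not an effect of interest
    bl <- matrix(sapply(bmods, function(m) m$lfc_moderated), ncol = length(bcols))
    bm <- matrix(sapply(bmods, function(m) m$lfc_mle), ncol = length(bcols))
    bs <- matrix(sapply(bmods, function(m) m$svalue), ncol = length(bcols))
    pick <- max.col(abs(bm), ties.method = "first")
    idx <- cbind(seq_len(nrow(out)), pick)
    out$batch_lfc <- bm[idx]
    out$batch_lfc_moderated <- bl[idx]
    out$batch_svalue <- bs[idx]
  } else {
    out$batch_lfc <- NA_real_
    out$batch_lfc_moderated <- NA_real_
    out$batch_svalue <- NA_real_
  }
  # residual sd of log2 normalized counts around the four group means
  norm <- sweep(counts, 2, sf, "/")
  l2 <- log2(norm + 1)
  grp <- interaction(design$age, design$time)
  resid <- l2
  for (g in levels(grp)) {
    idx <- which(grp == g)
    resid[, idx] <- l2[, idx, drop = FALSE] -
      rowMeans(l2[, idx, drop = FALSE])
  }
  out$residual_sd <- apply(resid, 1, sd)
  attr(out, "converged") <- fit$converged
  class(out) <- c("gene_effect_table", "data.frame")
  out
}

.passes <- function(lfc, sval, profile) {
  !is.na(lfc) & !is.na(sval) &
    abs(lfc) > profile$lfc_min & sval < profile$s_max
}

#' Classify per-gene effect categories
#'
#' A gene shows an AGE / ENGRAFT / NICHE effect iff the corresponding
#' |moderated LFC| exceeds `lfc_min` (strictly) and its s-value is below
#' `s_max` (strictly). Genes are tallied over the seven non-empty
#' combinations plus "unchanged".
#'
#' @param effects A `gene_effect_table`.
#' @param profile A [threshold_profile()].
#' @return List with `labels` (data frame gene_id, has_age, has_engraft,
#'   has_niche, category) and `counts` (named vector over combinations).
#' @export
classify_effect_categories <- function(effects, profile = threshold_profile("strict")) {
  has_age <- .passes(effects$age_lfc, effects$age_svalue, profile)
  has_eng <- .passes(effects$engraftment_lfc, effects$engraftment_svalue, profile)
  has_nic <- .passes(effects$niche_lfc, effects$niche_svalue, profile)
  cat_str <- ifelse(!has_age & !has_eng & !has_nic, "unchanged",
                    paste0(ifelse(has_age, "AGE+", ""),
                           ifelse(has_eng, "ENGRAFT+", ""),
                           ifelse(has_nic, "NICHE+", "")))
  cat_str <- sub("\\+$", "", cat_str)
  labels <- data.frame(gene_id = effects$gene_id,
                       has_age = has_age, has_engraft = has_eng,
                       has_niche = has_nic, category = cat_str,
                       stringsAsFactors = FALSE)
  combos <- c("AGE", "ENGRAFT", "NICHE", "AGE+ENGRAFT", "AGE+NICHE",
              "ENGRAFT+NICHE", "AGE+ENGRAFT+NICHE", "unchanged")
  counts <- setNames(integer(length(combos)), combos)
  tab <- table(cat_str)
  counts[names(tab)] <- as.integer(tab)
  list(labels = labels, counts = counts)
}

#' Call ARR / ARI reversibility labels
#'
#' Among genes with an age effect: a significant niche effect of opposite
#' sign makes the gene Age-Related Reversible (ARR); no significant niche
#' effect makes it Age-Related Irreversible (ARI); a significant niche
#' effect of the same sign is reported separately as SAME_SIGN. A
#' profile's batch rule (permissive profile: |batch LFC| > 0.5) restricts
#' which age genes are eligible for a reversibility call; ineligible genes
#' get NA.
#'
#' @param labels Output of [classify_effect_categories()] (the list or its
#'   `labels` element).
#' @param effects The `gene_effect_table` used for classification.
#' @param profile The [threshold_profile()] used.
#' @return Data frame gene_id, category, reversibility (ARR / ARI /
#'   SAME_SIGN / NA), age_direction (up / down / NA).
#' @export
call_arr_ari <- function(labels, effects, profile = threshold_profile("strict")) {
  if (is.list(labels) && !is.data.frame(labels) && !is.null(labels$labels)) {
    labels <- labels$labels
  }
  stopifnot(identical(labels$gene_id, effects$gene_id))
  rev <- rep(NA_character_, nrow(labels))
  dir <- rep(NA_character_, nrow(labels))
  eligible <- labels$has_age
  if (profile$batch_rule == "abs_above") {
    eligible <- eligible & !is.na(effects$batch_lfc) &
      abs(effects$batch_lfc) > profile$batch_lfc
  } else if (profile$batch_rule == "abs_below") {
    eligible <- eligible & !is.na(effects$batch_lfc) &
      abs(effects$batch_lfc) < profile$batch_lfc
  }
  age_sign <- sign(effects$age_lfc)
  niche_sign <- sign(effects$niche_lfc)
  opp <- labels$has_niche & niche_sign == -age_sign
  same <- labels$has_niche & niche_sign == age_sign
  rev[eligible & opp] <- "ARR"
  rev[eligible & !labels$has_niche] <- "ARI"
  rev[eligible & same] <- "SAME_SIGN"
  dir[eligible] <- ifelse(age_sign[eligible] > 0, "up", "down")
  data.frame(gene_id = labels$gene_id, category = labels$category,
             reversibility = rev, age_direction = dir,
             stringsAsFactors = FALSE)
}

#' Fraction of reversible genes
#' @param n_arr,n_ari Counts of ARR and ARI genes.
#' @return Percentage ARR / (ARR + ARI), or NA when both are zero.
#' @export
reversibility_fraction <- function(n_arr, n_ari) {
  if (n_arr + n_ari == 0) return(NA_real_)
  100 * n_arr / (n_arr + n_ari)
}

#' Summarize reversibility fractions overall and by age direction
#'
#' @param calls Output of [call_arr_ari()].
#' @return Data frame with rows overall/up/down: n_arr, n_ari,
#'   pct_reversible (= 100 * ARR / (ARR + ARI); NA when no age-affected
#'   genes fall in a stratum).
#' @export
reversibility_summary <- function(calls) {
  strata <- list(overall = rep(TRUE, nrow(calls)),
                 up = calls$age_direction %in% "up",
                 down = calls$age_direction %in% "down")
  rows <- lapply(names(strata), function(s) {
    sub <- calls[strata[[s]], , drop = FALSE]
    n_arr <- sum(sub$reversibility %in% "ARR")
    n_ari <- sum(sub$reversibility %in% "ARI")
    data.frame(stratum = s, n_arr = n_arr, n_ari = n_ari,
               n_same_sign = sum(sub$reversibility %in% "SAME_SIGN"),
               pct_reversible = reversibility_fraction(n_arr, n_ari),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Concordance between two effect vectors
#'
#' Pearson correlation and least-squares slope of y on x over a gene
#' subset; used for niche-vs-age (anti-correlation expected when genes are
#' reversible) and for cross-dataset LFC concordance (positive expected).
#'
#' @param lfc_x,lfc_y Paired effect vectors (log2).
#' @param subset Logical or integer subset of genes to use (default all).
#' @return List with r, slope, n (NA when fewer than 3 finite pairs or
#'   degenerate variance).
#' @export
effect_concordance <- function(lfc_x, lfc_y, subset = NULL) {
  stopifnot(length(lfc_x) == length(lfc_y))
  if (!is.null(subset)) {
    lfc_x <- lfc_x[subset]; lfc_y <- lfc_y[subset]
  }
  ok <- is.finite(lfc_x) & is.finite(lfc_y)
  x <- lfc_x[ok]; y <- lfc_y[ok]
  if (length(x) < 3) return(list(r = NA_real_, slope = NA_real_, n = length(x)))
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, slope = NA_real_, n = length(x)))
  }
  list(r = cor(x, y), slope = unname(coef(lm(y ~ x))[2]), n = length(x))
}
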