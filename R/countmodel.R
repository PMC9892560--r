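# Shared negative-binomial machinery: size factors, dispersion, gene-wise
# GLM fits, Wald tests, and empirical-Bayes LFC moderation with s-values.
# All user-facing log fold changes are log2; fitting is on the natural-log
# scale internally.

LOG2 <- log(2)
DISPERSION_FLOOR <- 1e-8

#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed against the gene-wise geometric-mean
#' pseudo-reference, restricted to genes expressed in every sample. Factors
#' are rescaled so their geometric mean is exactly 1. When no gene is
#' nonzero in all samples the function falls back to total-count scaling
#' with a warning.
#'
#' @param counts Gene-by-sample count matrix.
#' @return Positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1)
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) {
    warning("no gene is nonzero in every sample; using total-count scaling")
    sf <- colSums(counts)
    if (any(sf == 0)) stop("sample with zero total count")
  } else {
    lc <- log(counts[use, , drop = FALSE])
    ref <- rowMeans(lc)
    sf <- exp(apply(lc - ref, 2, median))
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

# Cox-Reid adjusted profile log-likelihood for the dispersion of one
# gene, given fitted means mu (the adjustment penalizes the df consumed
# by the mean model and removes most of the ML downward bias).
.cr_loglik <- function(alpha, y, mu, X) {
  ll <- sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  w <- mu / (1 + alpha * mu)
  XtWX <- crossprod(X * sqrt(w))
  ll - 0.5 * determinant(XtWX, logarithm = TRUE)$modulus
}

#' Per-gene dispersion estimates with empirical-Bayes trend shrinkage
#'
#' Gene-wise dispersions are estimated by maximizing the Cox-Reid
#' adjusted profile likelihood given fitted means from a Poisson GLM of
#' the same design, then shrunk on the log scale toward a fitted
#' mean-dispersion trend alpha(mu) = a0 + a1/mu. The shrinkage weight is
#' precision-based: the sampling variance of a log-dispersion estimate at
#' the model's residual degrees of freedom is traded against the robustly
#' estimated gene-level scatter around the trend, as in standard
#' RNA-seq practice. Dispersions are floored at 1e-8; all-zero genes get
#' NA and are excluded downstream.
#'
#' @param counts Gene-by-sample count matrix.
#' @param design_matrix Model matrix (rows = samples).
#' @param size_factors Per-sample size factors.
#' @param min_prior_var Floor on the gene-level log-dispersion scatter
#'   retained after subtracting sampling noise (default 0.25).
#' @return Numeric vector of dispersions (NA for all-zero genes).
#' @export
estimate_dispersions <- function(counts, design_matrix, size_factors,
                                 min_prior_var = 0.25) {
  stopifnot(ncol(counts) == nrow(design_matrix),
            length(size_factors) == ncol(counts))
  m <- ncol(counts); p <- qr(design_matrix)$rank
  if (m - p < 2) {
    stop("need >= 2 residual degrees of freedom for dispersion estimation")
  }
  n_genes <- nrow(counts)
  off <- log(size_factors)
  alpha_hat <- rep(NA_real_, n_genes)
  mu_bar <- rowMeans(sweep(counts, 2, size_factors, "/"))
  for (g in seq_len(n_genes)) {
    y <- counts[g, ]
    if (all(y == 0)) next
    pf <- tryCatch(
      suppressWarnings(stats::glm.fit(design_matrix, y, offset = off,
                                      family = stats::poisson())),
      error = function(e) NULL)
    if (is.null(pf)) next
    mu <- pmax(pf$fitted.values, 1e-8)
    opt <- tryCatch(
      optimize(function(la) -.cr_loglik(exp(la), y, mu, design_matrix),
               c(log(1e-8), log(30))),
      error = function(e) NULL)
    if (!is.null(opt)) alpha_hat[g] <- exp(opt$minimum)
  }
  ok <- !is.na(alpha_hat) & mu_bar > 0
  if (sum(ok) < 10) return(pmax(alpha_hat, DISPERSION_FLOOR))
  # mean-dispersion trend alpha = a0 + a1/mu; gene-wise CR-ML estimates
  # are mean-unbiased, so the trend is fitted mean-targeting
  # (unweighted), iterating with trimming of far outliers
  use <- ok & alpha_hat > 1e-6
  a0 <- 0.05; a1 <- 5
  if (sum(use) >= 10) {
    keep <- use
    for (it in 1:3) {
      tf <- lm(alpha_hat[keep] ~ I(1 / mu_bar[keep]))
      a0 <- max(coef(tf)[1], 1e-4); a1 <- max(coef(tf)[2], 0)
      ratio <- alpha_hat / (a0 + a1 / pmax(mu_bar, 1e-8))
      keep <- use & ratio > 1e-4 & ratio < 15
    }
  }
  trend <- a0 + a1 / pmax(mu_bar, 1e-8)
  # precision-weighted log-scale shrinkage toward the trend
  v_samp <- trigamma((m - p) / 2)
  lr <- log(pmax(alpha_hat, 1e-8)) - log(trend)
  s_robust <- stats::mad(lr[ok], na.rm = TRUE)
  v_prior <- max(s_robust^2 - v_samp, min_prior_var)
  w <- v_prior / (v_prior + v_samp)
  alpha <- exp(w * log(pmax(alpha_hat, 1e-8)) + (1 - w) * log(trend))
  alpha[!ok] <- alpha_hat[!ok]
  # zero observed variance carries no overdispersion signal: floor, not trend
  zero_var <- apply(sweep(counts, 2, size_factors, "/"), 1, var) == 0
  alpha[zero_var & !is.na(alpha)] <- DISPERSION_FLOOR
  pmax(alpha, DISPERSION_FLOOR)
}

.check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix not full rank; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit gene-wise negative-binomial GLMs
#'
#' One NB GLM (log link, fixed gene-wise dispersion, log size-factor
#' offsets) per gene, fitted by iteratively reweighted least squares via
#' the negative-binomial family. Coefficients and standard errors are
#' reported in log2 units.
#'
#' @param counts Gene-by-sample count matrix.
#' @param design_matrix Full-rank model matrix (rows = samples).
#' @param size_factors Per-sample size factors.
#' @param dispersions Per-gene dispersion alpha (NA genes are skipped).
#' @return An object of class `nb_fit`: list with `beta` and `se` matrices
#'   (genes x coefficients, log2), `dispersion`, `converged`, `loglik`.
#' @export
fit_nb_glm <- function(counts, design_matrix, size_factors, dispersions) {
  stopifnot(nrow(design_matrix) == ncol(counts),
            length(dispersions) == nrow(counts))
  .check_full_rank(design_matrix)
  p <- ncol(design_matrix)
  n_genes <- nrow(counts)
  beta <- matrix(NA_real_, n_genes, p,
                 dimnames = list(rownames(counts), colnames(design_matrix)))
  se <- beta
  vcov_arr <- array(NA_real_, c(p, p, n_genes))
  converged <- logical(n_genes)
  loglik <- rep(NA_real_, n_genes)
  off <- log(size_factors)
  for (g in seq_len(n_genes)) {
    a <- dispersions[g]
    if (is.na(a)) next
    theta <- 1 / max(a, DISPERSION_FLOOR)
    y <- counts[g, ]
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(
        design_matrix, y, offset = off,
        family = MASS::negative.binomial(theta = theta, link = "log"),
        control = list(maxit = 100, epsilon = 1e-10))),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- fit$coefficients
    if (anyNA(cf) || fit$rank < p) next
    # covariance from the weighted least-squares information at convergence,
    # honoring QR column pivoting as summary.glm does
    p1 <- seq_len(fit$rank)
    covu <- tryCatch(chol2inv(fit$qr$qr[p1, p1, drop = FALSE]),
                     error = function(e) NULL)
    if (is.null(covu)) next
    piv <- fit$qr$pivot[p1]
    cov_ul <- matrix(NA_real_, p, p)
    cov_ul[piv, piv] <- covu
    ses <- sqrt(pmax(diag(cov_ul), 0))
    beta[g, ] <- cf / LOG2
    se[g, ] <- ses / LOG2
    vcov_arr[, , g] <- cov_ul / LOG2^2
    # runaway coefficients (a factorial cell with no counts) are not
    # estimable; exclude them from downstream inference
    estimable <- all(abs(cf / LOG2) < 12) && all(ses / LOG2 < 8)
    converged[g] <- isTRUE(fit$converged) && estimable
    mu <- fit$fitted.values
    loglik[g] <- sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
  }
  structure(list(beta = beta, se = se, vcov = vcov_arr,
                 dispersion = dispersions,
                 converged = converged, loglik = loglik,
                 design_matrix = design_matrix),
            class = "nb_fit")
}

.contrast_vector <- function(fit, contrast) {
  cn <- colnames(fit$beta)
  if (is.character(contrast)) {
    stopifnot(length(contrast) == 1)
    if (!contrast %in% cn) stop("unknown coefficient: ", contrast)
    v <- as.numeric(cn == contrast)
  } else {
    stopifnot(length(contrast) == length(cn))
    v <- as.numeric(contrast)
  }
  v
}

#' Extract a contrast (log2 estimate and SE) from an `nb_fit`
#' @param fit An `nb_fit`.
#' @param contrast Coefficient name or numeric contrast vector.
#' @return Data frame with gene_id, estimate, se, converged.
#' @export
contrast_estimates <- function(fit, contrast) {
  v <- .contrast_vector(fit, contrast)
  est <- drop(fit$beta %*% v)
  se <- apply(fit$vcov, 3, function(S) sqrt(max(drop(t(v) %*% S %*% v), 0)))
  data.frame(gene_id = rownames(fit$beta), estimate = est, se = se,
             converged = fit$converged, stringsAsFactors = FALSE)
}

#' Wald tests for a contrast
#'
#' Two-sided Wald p-values with Benjamini-Hochberg adjustment over all
#' testable genes. The reference distribution is t with the model's
#' residual degrees of freedom (falling back to normal when they are
#' exhausted), which keeps small-replicate designs from being
#' anticonservative.
#'
#' @param fit An `nb_fit`.
#' @param contrast Coefficient name or contrast vector.
#' @return Data frame gene_id, estimate, se, pvalue, padj.
#' @export
wald_test <- function(fit, contrast) {
  ce <- contrast_estimates(fit, contrast)
  z <- ce$estimate / ce$se
  df <- nrow(fit$design_matrix) - qr(fit$design_matrix)$rank
  ce$pvalue <- if (df >= 1) 2 * stats::pt(-abs(z), df = df) else 2 * pnorm(-abs(z))
  ce$padj <- p.adjust(ce$pvalue, method = "BH")
  ce
}

# Posterior summaries under a Cauchy(0, tau) prior with a normal
# likelihood approximation b ~ N(beta, se^2). The integration grid per
# gene is the union of nodes placed on the likelihood scale (b + se*z)
# and on the prior scale (tau*z), so neither a sharp likelihood nor a
# sharp prior is under-resolved; trapezoidal quadrature on the merged
# grid. Returns mean, sd, and P(beta < 0) per gene.
.cauchy_posterior <- function(b, s, tau) {
  z <- seq(-8, 8, by = 0.1)
  zp <- tau * seq(-50, 50, by = 0.25)
  n <- length(b)
  pm <- psd <- pneg <- numeric(n)
  for (i in seq_len(n)) {
    grid <- sort(unique(c(b[i] + s[i] * z, zp)))
    f <- stats::dnorm(b[i], grid, s[i]) * stats::dcauchy(grid, 0, tau)
    dw <- diff(grid)
    w <- c(dw, 0) / 2 + c(0, dw) / 2
    fw <- f * w
    norm <- sum(fw)
    m1 <- sum(fw * grid) / norm
    m2 <- sum(fw * grid^2) / norm
    pm[i] <- m1
    psd[i] <- sqrt(max(m2 - m1^2, 1e-12))
    pneg[i] <- sum(fw[grid < 0]) / norm
  }
  list(mean = pm, sd = psd, pneg = pneg)
}

# Prior scale from a two-group marginal ML fit: b ~ pi0 N(0, se^2) +
# pi1 N(0, tau^2 + se^2). The fitted slab scale tau measures the rms
# size of the nonzero effects themselves, decoupled from how rare they
# are (a single global moment like mean(b^2 - se^2) would conflate
# fraction and size and over-shrink when effects are sparse; a
# heavy-tailed slab would be unidentifiable, its tail covering large
# effects at any scale). When the fitted effect fraction is negligible
# the scale falls back to its floor, so effect-free data gets maximal
# shrinkage.
.slab_prior_scale <- function(b, s, floor = 0.05) {
  nll <- function(p) {
    pi0 <- stats::plogis(p[1])
    slab <- stats::dnorm(b, 0, sqrt(exp(2 * p[2]) + s^2))
    -sum(log(pmax(pi0 * stats::dnorm(b, 0, s) + (1 - pi0) * slab, 1e-300)))
  }
  opt <- optim(c(0, 0), nll, method = "L-BFGS-B",
               lower = c(-6, log(floor)), upper = c(6, log(10)))
  pi1 <- 1 - stats::plogis(opt$par[1])
  # adopt the slab only when it improves on the no-effect model beyond
  # chance (likelihood-ratio against the spike-only fit, 2 df, p < 0.01)
  nll0 <- -sum(stats::dnorm(b, 0, s, log = TRUE))
  lrt_ok <- 2 * (nll0 - opt$value) > stats::qchisq(0.99, df = 2)
  if (!lrt_ok || pi1 < 0.01) floor else max(exp(opt$par[2]), floor)
}

#' Empirical-Bayes moderation of log fold changes with s-values
#'
#' A zero-centered heavy-tailed Cauchy prior is placed on the true log2
#' effect. Its scale is the slab scale of a two-group (spike plus
#' Cauchy-slab) marginal maximum-likelihood fit across genes under the
#' normal approximation beta_hat ~ N(beta, se^2), so the shrinkage
#' strength of real effects does not depend on how rare they are. Heavy
#' tails give adaptive shrinkage: estimates consistent with noise shrink
#' strongly toward zero while clearly nonzero effects keep nearly their
#' full size. The posterior mean is the moderated LFC. When
#' `prior_scale` is supplied the prior is instead the normal
#' N(0, prior_scale^2), whose posterior is the familiar conjugate form.
#'
#' The local false-sign rate (lfsr) of a gene is the posterior
#' probability that the sign of its effect is wrong (an estimate of
#' exactly 0 has lfsr 0.5). The s-value is the running mean of lfsr over
#' all genes at or below a gene's lfsr — the estimated rate of false
#' sign among effects called at that threshold.
#'
#' @param fit An `nb_fit` (only converged genes are moderated).
#' @param contrast Coefficient name or contrast vector.
#' @param prior_scale Optional fixed normal prior sd (log2); when given
#'   the conjugate normal prior replaces the Cauchy.
#' @return Data frame gene_id, lfc_mle, lfc_moderated, se (posterior sd),
#'   lfsr, svalue, pvalue, padj; class `shrunken_effect`.
#' @export
moderate_effects <- function(fit, contrast, prior_scale = NULL) {
  wt <- wald_test(fit, contrast)
  ok <- wt$converged & is.finite(wt$estimate) & is.finite(wt$se) & wt$se > 0
  b <- wt$estimate[ok]; s <- wt$se[ok]
  if (is.null(prior_scale)) {
    if (sum(ok) < 50) {
      warning("fewer than 50 genes; using default prior scale 1")
      tau <- 1
    } else {
      tau <- .slab_prior_scale(b, s)
    }
    post <- .cauchy_posterior(b, s, tau)
    post_mean <- post$mean
    post_sd <- post$sd
    lfsr <- pmin(post$pneg, 1 - post$pneg)
  } else {
    tau <- prior_scale
    shrinkf <- tau^2 / (tau^2 + s^2)
    post_mean <- shrinkf * b
    post_sd <- sqrt(shrinkf) * s
    lfsr <- pnorm(-abs(post_mean) / post_sd)
  }
  # s-value: mean lfsr over all genes at least as confident (ashr-style)
  o <- order(lfsr)
  sval <- numeric(length(lfsr))
  sval[o] <- cummean(lfsr[o])
  out <- data.frame(gene_id = wt$gene_id,
                    lfc_mle = wt$estimate,
                    lfc_moderated = NA_real_, se = NA_real_,
                    lfsr = NA_real_, svalue = NA_real_,
                    pvalue = wt$pvalue, padj = wt$padj,
                    stringsAsFactors = FALSE)
  out$lfc_moderated[ok] <- post_mean
  out$se[ok] <- post_sd
  out$lfsr[ok] <- lfsr
  out$svalue[ok] <- sval
  attr(out, "prior_scale") <- tau
  class(out) <- c("shrunken_effect", "data.frame")
  out
}

cummean <- function(x) cumsum(x) / seq_along(x)

#' Write an effect table as TSV
#' @param effects A `shrunken_effect` (or any data frame).
#' @param path Output path.
#' @param contrast Contrast label stored in the table.
#' @export
write_effects <- function(effects, path, contrast = "effect") {
  df <- cbind(contrast = contrast, as.data.frame(effects))
  .write_tsv(df, path)
}
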