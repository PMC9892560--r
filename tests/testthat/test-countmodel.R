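test_that("size factors match the median-of-ratios definition", {
  # identical columns -> all factors 1
  m <- matrix(rep(c(5L, 10L, 20L), 3), 3, 3)
  expect_equal(unname(estimate_size_factors(m)), rep(1, 3))
  # column2 = 2 x column1 -> (1/sqrt(2), sqrt(2))
  m2 <- cbind(s1 = c(10L, 30L, 50L), s2 = c(20L, 60L, 100L))
  expect_equal(unname(estimate_size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  # random matrix equals the brute-force oracle
  set.seed(11)
  m3 <- matrix(rnbinom(300, mu = 50, size = 5), 50, 6)
  expect_equal(unname(estimate_size_factors(m3)), unname(oracle_size_factors(m3)))
  # geometric mean is 1
  expect_equal(exp(mean(log(estimate_size_factors(m3)))), 1)
})

test_that("size factors fall back to total counts when no gene is always nonzero", {
  m <- cbind(s1 = c(0L, 10L), s2 = c(10L, 0L))
  expect_warning(sf <- estimate_size_factors(m), "total-count")
  expect_equal(unname(sf), c(1, 1))
})

test_that("dispersion estimation recovers the data-generating dispersion", {
  set.seed(21)
  X <- model.matrix(~ g, data.frame(g = factor(rep(1:4, each = 3))))
  sf <- rep(1, 12)
  # Poisson data -> near-zero dispersion
  cp <- matrix(rpois(500 * 12, 100), 500, 12)
  expect_lte(median(estimate_dispersions(cp, X, sf)), 0.01)
  # NB alpha = 0.5 -> recovered within [0.3, 0.8]
  cn <- matrix(rnbinom(500 * 12, mu = 100, size = 2), 500, 12)
  med <- median(estimate_dispersions(cn, X, sf))
  expect_gt(med, 0.3)
  expect_lt(med, 0.8)
  # constant gene sits at the floor
  cc <- rbind(matrix(rnbinom(50 * 12, mu = 100, size = 2), 50, 12),
              matrix(64L, 1, 12))
  d <- estimate_dispersions(cc, X, sf)
  expect_lt(d[51], 1e-6)
  # all-zero gene flagged NA
  cz <- rbind(cn[1:20, ], matrix(0L, 1, 12))
  expect_true(is.na(estimate_dispersions(cz, X, sf)[21]))
})

test_that("NB GLM reproduces closed-form fits", {
  # intercept-only, all counts 64 -> beta0 = 6 log2
  X <- matrix(1, 8, 1, dimnames = list(NULL, "(Intercept)"))
  cnt <- matrix(64L, 1, 8, dimnames = list("g1", paste0("s", 1:8)))
  fit <- fit_nb_glm(cnt, X, rep(1, 8), 0.1)
  expect_equal(unname(fit$beta[1, 1]), 6, tolerance = 1e-8)
  # saturated 2x2 with exact replicate means (100, 200, 150, 600):
  # age = log2(1.5), time = 1, interaction = 1
  cm <- counts_from_means(c(young_T0 = 100, young_T21 = 200,
                            aged_T0 = 150, aged_T21 = 600), reps = 3)
  X2 <- model.matrix(~ time + age + time:age, cm$design)
  fit2 <- fit_nb_glm(cm$counts, X2, rep(1, ncol(cm$counts)), 0.1)
  expect_equal(unname(fit2$beta[1, "ageaged"]), log2(1.5), tolerance = 1e-6)
  expect_equal(unname(fit2$beta[1, "timeT21"]), 1, tolerance = 1e-6)
  expect_equal(unname(fit2$beta[1, "timeT21:ageaged"]), 1, tolerance = 1e-6)
})

test_that("NB GLM equals the brute-force likelihood maximizer on a tiny instance", {
  set.seed(31)
  y <- matrix(rnbinom(8, mu = 40, size = 10), 1, 8,
              dimnames = list("g1", paste0("s", 1:8)))
  sf <- runif(8, 0.8, 1.2)
  X <- matrix(1, 8, 1, dimnames = list(NULL, "(Intercept)"))
  alpha <- 0.1
  fit <- fit_nb_glm(y, X, sf, alpha)
  nll <- function(b2) {
    -sum(dnbinom(y[1, ], size = 1 / alpha, mu = sf * 2^b2, log = TRUE))
  }
  grid <- seq(2, 9, by = 1e-3)
  best <- grid[which.min(vapply(grid, nll, 0))]
  refine <- seq(best - 2e-3, best + 2e-3, by = 1e-6)
  best <- refine[which.min(vapply(refine, nll, 0))]
  expect_equal(unname(fit$beta[1, 1]), best, tolerance = 1e-4)
})

test_that("design-matrix rank deficiency is reported with the collinear column", {
  X <- cbind("(Intercept)" = 1, a = rep(0:1, 4), dup = rep(0:1, 4))
  cnt <- matrix(10L, 1, 8)
  expect_error(fit_nb_glm(cnt, X, rep(1, 8), 0.1), "dup")
})

test_that("Wald tests behave at reference points and BH matches the oracle", {
  mk_fit <- function(beta, se, n = 400) {
    p <- 1
    v <- array(se^2, c(1, 1, length(beta)))
    structure(list(beta = matrix(beta, ncol = 1,
                                 dimnames = list(sprintf("g%d", seq_along(beta)),
                                                 "b")),
                   se = matrix(se, ncol = 1), vcov = v,
                   dispersion = rep(0.1, length(beta)),
                   converged = rep(TRUE, length(beta)),
                   loglik = rep(0, length(beta)),
                   design_matrix = matrix(1, n, 1)),
              class = "nb_fit")
  }
  # beta = 0 -> p = 1
  f0 <- mk_fit(0, 0.5)
  expect_equal(wald_test(f0, "b")$pvalue, 1)
  # beta/se = 1.96 at large residual df -> p ~ 0.05
  f1 <- mk_fit(1.96 * 0.3, rep(0.3, 1), n = 1000)
  expect_equal(wald_test(f1, "b")$pvalue, 0.05, tolerance = 0.01)
  # BH equals the step-up oracle on a random p-vector
  set.seed(41)
  beta <- rnorm(200, 0, 0.6)
  f2 <- mk_fit(beta, rep(0.3, 200), n = 1000)
  wt <- wald_test(f2, "b")
  expect_equal(wt$padj, oracle_bh(wt$pvalue))
})

test_that("moderation follows the conjugate closed form under a fixed normal prior", {
  mk_fit <- function(beta, se) {
    structure(list(beta = matrix(beta, ncol = 1,
                                 dimnames = list(sprintf("g%d", seq_along(beta)), "b")),
                   se = matrix(se, ncol = 1),
                   vcov = array(se^2, c(1, 1, length(beta))),
                   dispersion = rep(0.1, length(beta)),
                   converged = rep(TRUE, length(beta)),
                   loglik = rep(0, length(beta)),
                   design_matrix = matrix(1, 100, 1)),
              class = "nb_fit")
  }
  # prior N(0,1), beta_hat = 2, SE = 1 -> posterior mean 1, sd 1/sqrt(2),
  # lfsr = Phi(-sqrt(2))
  f <- mk_fit(c(2, 0, rep(0.3, 58)), rep(1, 60))
  me <- moderate_effects(f, "b", prior_scale = 1)
  expect_equal(me$lfc_moderated[1], 1, tolerance = 1e-9)
  expect_equal(me$se[1], sqrt(0.5), tolerance = 1e-9)
  expect_equal(me$lfsr[1], pnorm(-sqrt(2)), tolerance = 1e-9)
  # beta_hat = 0 -> symmetric posterior -> lfsr = 0.5
  expect_equal(me$lfsr[2], 0.5)
  # flat-prior limit: moderated -> MLE
  me_flat <- moderate_effects(f, "b", prior_scale = 1e6)
  expect_equal(me_flat$lfc_moderated[1], 2, tolerance = 1e-4)
})

test_that("shrinkage contracts hold under the estimated heavy-tailed prior", {
  set.seed(51)
  n <- 300
  beta_true <- c(rep(0, 240), runif(60, 1, 3) * sample(c(-1, 1), 60, TRUE))
  se <- runif(n, 0.2, 0.6)
  bhat <- rnorm(n, beta_true, se)
  f <- structure(list(beta = matrix(bhat, ncol = 1,
                                    dimnames = list(sprintf("g%d", 1:n), "b")),
                      se = matrix(se, ncol = 1),
                      vcov = array(NA_real_, c(1, 1, n)),
                      dispersion = rep(0.1, n),
                      converged = rep(TRUE, n), loglik = rep(0, n),
                      design_matrix = matrix(1, 12, 1)),
                 class = "nb_fit")
  f$vcov[1, 1, ] <- se^2
  me <- moderate_effects(f, "b")
  # every moderated effect is no larger in magnitude than its MLE
  expect_true(all(abs(me$lfc_moderated) <= abs(me$lfc_mle) + 1e-12))
  # signs are never flipped by shrinkage
  expect_true(all(sign(me$lfc_moderated) == sign(me$lfc_mle) |
                  me$lfc_moderated == 0))
  # s-values live in [0,1], are monotone in lfsr rank, and never exceed lfsr
  expect_true(all(me$svalue >= 0 & me$svalue <= 1))
  o <- order(me$lfsr)
  expect_true(all(diff(me$svalue[o]) >= -1e-12))
  expect_true(all(me$svalue <= me$lfsr + 1e-12))
})

test_that("non-estimable fits are excluded from moderation", {
  set.seed(61)
  # one gene with an empty aged x T21 cell drives a runaway coefficient
  cm <- counts_from_means(c(young_T0 = 50, young_T21 = 50,
                            aged_T0 = 50, aged_T21 = 0), reps = 3,
                          n_genes = 1)
  X <- model.matrix(~ time + age + time:age, cm$design)
  fit <- fit_nb_glm(cm$counts, X, rep(1, ncol(cm$counts)), 0.1)
  expect_false(fit$converged[1])
})
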