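test_that("log_cpm follows its formula and invariances", {
  # library size 1e6 - 1 plus prior 2*0.5 makes the denominator 1e6 exactly
  m <- matrix(c(0, 1e6 - 1, 10, 2e6 - 10), 2, 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  lc <- log_cpm(m, prior_count = 0.5)
  expect_equal(lc["gA", "s1"], -1.0)

  # proportional columns give identical log-CPM
  m2 <- tiny_counts()
  m2 <- cbind(m2, double_col = m2[, 1] * 2)
  lc2 <- log_cpm(m2, prior_count = 0)  # no zeros in this fixture
  expect_equal(lc2[, 1], lc2[, "double_col"], ignore_attr = TRUE)

  z <- matrix(c(0, 5, 5, 5), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(log_cpm(z, prior_count = 0), "prior_count")
  z0 <- z; z0[, 1] <- 0
  expect_error(log_cpm(z0), "zero library size.*x")
})

test_that("fit_lm matches closed-form OLS and is weight-scale invariant", {
  withr::with_seed(31, {
    y <- matrix(rnorm(15 * 12, 5), 15, 12,
                dimnames = list(sprintf("g%02d", 1:15), sprintf("s%02d", 1:12)))
  })
  design <- build_design(rep(c("WT", "HIGH"), each = 6))
  fit <- fit_lm(y, design)
  means_diff <- rowMeans(y[, 7:12]) - rowMeans(y[, 1:6])
  expect_equal(unname(fit$coefficients[, "groupHIGH"]), unname(means_diff))

  w <- matrix(runif(length(y), 0.5, 2), nrow(y))
  f1 <- fit_lm(y, design, w)
  f2 <- fit_lm(y, design, 2 * w)
  expect_equal(f1$coefficients, f2$coefficients)
  expect_equal(f1$sigma2, f2$sigma2)

  # equal group means -> zero group coefficient
  y0 <- y; y0[1, ] <- rep(c(1, 2, 3, 4, 5, 6), 2)
  expect_equal(unname(fit_lm(y0, design)$coefficients[1, "groupHIGH"]), 0)

  bad <- cbind(design, dup = design[, "groupHIGH"])
  expect_error(fit_lm(y, bad), "rank deficient")
})

test_that("voom_weights reproduces the flat and planted-trend limits", {
  design <- build_design(rep(c("WT", "HIGH"), each = 15))
  withr::with_seed(41, {
    flat <- matrix(rnorm(200 * 30, mean = rep(seq(2, 10, length.out = 200), 30)),
                   200, 30,
                   dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:30)))
  })
  w <- voom_weights(flat, design)
  expect_true(all(is.finite(w) & w > 0))
  expect_lt(max(w) / min(w), 1.25)  # constant within ~10% of each other

  # planted decreasing sd(mean) trend -> monotone decreasing fitted trend
  withr::with_seed(42, {
    mu <- rep(seq(2, 10, length.out = 300), 30)
    trend_sd <- (mu / 2)^(-1 / 2)
    noisy <- matrix(rnorm(300 * 30, mean = mu, sd = trend_sd), 300, 30,
                    dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:30)))
  })
  wt <- voom_weights(noisy, design)
  amean <- rowMeans(noisy)
  # precision should rise with mean under this trend
  expect_gt(cor(amean, rowMeans(wt), method = "spearman"), 0.9)

  # duplicated gene row gets identical weights
  dup <- rbind(flat, dupgene = flat[1, ])
  wd <- voom_weights(dup, design)
  expect_equal(unname(wd["dupgene", ]), unname(wd[1, ]))
})

test_that("ebayes recovers both shrinkage limits", {
  design <- build_design(rep(c("WT", "HIGH"), each = 10))
  withr::with_seed(43, {
    y <- matrix(rnorm(400 * 20, sd = 1), 400, 20,
                dimnames = list(sprintf("g%03d", 1:400), sprintf("s%02d", 1:20)))
  })
  fit <- fit_lm(y, design)
  de <- suppressWarnings(ebayes(fit))  # homoscedastic fixture: pooling fallback
  expect_true(all(de$p >= 0 & de$p <= 1))
  expect_true(all(de$q >= de$p - 1e-12))  # BH never decreases the minimum...
  # q is non-decreasing along the p-sorted order
  expect_true(all(diff(de$q[order(de$p)]) >= -1e-12))

  # d0 -> Inf limit: equal gene variances collapse to pooled inference
  prior <- suppressWarnings(
    crbnsplice:::estimate_variance_prior(rep(2, 50), df = 18))
  expect_identical(prior$df_prior, Inf)

  # d0 = 0-ish: extremely heterogeneous variances keep t close to ordinary t
  t_ord <- fit$coefficients[, "groupHIGH"] /
    (sqrt(fit$sigma2) * fit$stdev_unscaled[, "groupHIGH"])
  expect_gt(cor(de$t, t_ord[de$gene]), 0.95)
})

test_that("moderated p-values are calibrated and order-invariant", {
  design <- build_design(rep(c("WT", "HIGH"), each = 10))
  withr::with_seed(44, {
    y <- matrix(rnorm(2000 * 20), 2000, 20,
                dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%02d", 1:20)))
  })
  fit <- fit_lm(y, design)
  de <- suppressWarnings(ebayes(fit))  # homoscedastic fixture: pooling fallback
  expect_gt(ks.test(de$p, "punif")$p.value, 0.01)
  frac <- mean(de$p < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)

  perm <- sample(nrow(y))
  de_perm <- suppressWarnings(ebayes(fit_lm(y[perm, ], design)))
  expect_equal(de_perm[order(de_perm$gene), ]$p, de[order(de$gene), ]$p)
})

test_that("the full DE pipeline agrees with the limma-voom oracle", {
  skip_if_not_installed("limma")
  sc <- planted_scenario(seed = 71, active = c(TF001 = 1.5),
                         n_samples = 60, n_genes = 800, n_cohorts = 1)
  co <- sc$cohorts[[1]]
  labels <- unname(co$truth$group)
  de <- de_analysis(co$counts, labels)

  design <- build_design(labels)
  v <- limma::voom(co$counts, design,
                   lib.size = colSums(co$counts), span = 0.5)
  lf <- limma::eBayes(limma::lmFit(v, design))
  tt <- limma::topTable(lf, coef = "groupHIGH", number = Inf, sort.by = "none")

  idx <- match(de$gene, rownames(tt))
  # same normalization differs only in voom's prior-count handling;
  # effect estimates and statistics must agree tightly
  expect_gt(cor(de$logFC, tt$logFC[idx]), 0.995)
  expect_gt(cor(de$t, tt$t[idx]), 0.99)
  both_sig <- mean((de$q < 0.05) == (tt$adj.P.Val[idx] < 0.05))
  expect_gt(both_sig, 0.95)
})

test_that("bh_fdr matches the hand-computed example and the oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  withr::with_seed(45, {
    for (i in 1:20) {
      p <- runif(50)
      expect_equal(bh_fdr(p), oracle_bh(p))
      expect_equal(bh_fdr(p), p.adjust(p, "BH"))
    }
  })
})
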