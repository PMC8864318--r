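test_that("enrichment_score reproduces the hand-computed walks", {
  stats <- c(a = 3, b = 2, c = 1, d = 0.5)
  # full universe: all hits, running sum peaks at 1
  expect_equal(enrichment_score(stats, names(stats))$es, 1.0)
  # top two genes, weight 1: peak after the leading hits = 3/5 + 2/5
  top <- enrichment_score(stats, c("a", "b"))
  expect_equal(top$es, 1.0)
  expect_equal(top$running, c(3 / 5, 1, 1 / 2, 0))
  # bottom two genes: deepest point just before the first hit
  bottom <- enrichment_score(stats, c("c", "d"))
  expect_equal(bottom$es, -1.0)
  expect_equal(bottom$running, c(-1 / 2, -1, -1 / 3, 0))
  expect_error(enrichment_score(stats, "zz"), "no overlap")
  expect_error(enrichment_score(stats, "a", weight_exponent = -1),
               "non-negative")
})

test_that("enrichment_score matches the brute-force oracle on random instances", {
  withr::with_seed(55, {
    for (i in 1:200) {
      n <- sample(5:50, 1)
      stats <- setNames(rnorm(n), sprintf("g%03d", sample.int(999, n)))
      set <- sample(names(stats), sample.int(min(10, n), 1))
      alpha <- sample(c(0, 0.5, 1, 1.5), 1)
      expect_equal(enrichment_score(stats, set, alpha)$es,
                   unname(oracle_es(stats, set, alpha)),
                   tolerance = 1e-12)
    }
  })
})

test_that("weight 0 depends only on rank order; ES stays within [-1, 1]", {
  withr::with_seed(56, {
    for (i in 1:50) {
      stats <- setNames(rnorm(30), sprintf("g%02d", 1:30))
      set <- sample(names(stats), 6)
      es0 <- enrichment_score(stats, set, weight_exponent = 0)$es
      mono <- exp(stats) + 5  # strictly increasing transform
      expect_equal(enrichment_score(mono, set, 0)$es, es0)
      es1 <- enrichment_score(stats, set, 1)$es
      expect_lte(abs(es1), 1)
      expect_lte(abs(es0), 1)
    }
  })
})

test_that("the fast permutation ES path agrees with the exported walk", {
  withr::with_seed(57, {
    stats <- setNames(rnorm(100), sprintf("g%03d", 1:100))
    ranked <- crbnsplice:::rank_genes(stats)
    absw <- abs(ranked)
    for (i in 1:100) {
      pos <- sample.int(100, sample(2:10, 1))
      es_fast <- crbnsplice:::es_from_positions(pos, absw, 100)
      es_full <- enrichment_score(stats, names(ranked)[pos])$es
      expect_equal(es_fast, es_full, tolerance = 1e-12)
    }
  })
})

test_that("gsea_significance is deterministic and finds a planted set", {
  withr::with_seed(58, {
    stats <- setNames(c(rnorm(20, 4, 0.5), rnorm(180)), sprintf("g%03d", 1:200))
  })
  sets <- list(planted = sprintf("g%03d", 1:20),
               random = sprintf("g%03d", seq(10, 200, by = 10)))
  a <- gsea_significance(stats, sets, n_perm = 500, seed = 9)
  b <- gsea_significance(stats, sets, n_perm = 500, seed = 9)
  expect_identical(a, b)
  expect_lt(a$q[a$set == "planted"], 0.05)
  expect_gt(a$nes[a$set == "planted"], 1)
  expect_error(gsea_significance(stats, sets, n_perm = 50, seed = 1), "100")
  expect_error(gsea_significance(stats, sets, n_perm = 500), "seed")
  expect_warning(
    gsea_significance(stats, c(sets, list(off = "zzz")), n_perm = 100, seed = 1),
    "skipped")
})

test_that("nominal permutation p is near-uniform for random sets", {
  withr::with_seed(59, {
    stats <- setNames(rnorm(500), sprintf("g%04d", 1:500))
    sets <- lapply(1:150, function(i) sample(names(stats), 20))
  })
  names(sets) <- sprintf("R%03d", seq_along(sets))
  res <- gsea_significance(stats, sets, n_perm = 500, seed = 10)
  frac <- mean(res$p < 0.05)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.10)
})

test_that("gsva_scores direction, invariances and the kernel CDF oracle", {
  withr::with_seed(60, {
    x <- matrix(rnorm(60 * 8, 5), 60, 8,
                dimnames = list(sprintf("g%02d", 1:60), sprintf("s%d", 1:8)))
  })
  # members at the top of sample 1 and the bottom of sample 2
  x[1:10, 1] <- x[1:10, 1] + 10
  x[1:10, 2] <- x[1:10, 2] - 10
  sets <- list(S = rownames(x)[1:10])
  sc <- gsva_scores(x, sets)
  expect_gt(sc["S", 1], 0)
  expect_lt(sc["S", 2], 0)
  expect_true(all(abs(sc) <= 1))

  # duplicate sample columns score identically
  xd <- cbind(x, s9 = x[, 1])
  scd <- gsva_scores(xd, sets)
  expect_equal(scd["S", "s9"], scd["S", "s1"])

  # shuffling gene rows leaves scores unchanged
  perm <- withr::with_seed(61, sample(nrow(x)))
  expect_equal(gsva_scores(x[perm, ], sets), sc)

  expect_error(gsva_scores(x[, 1:2], sets), ">= 3 samples")
  expect_warning(gsva_scores(x, list(S = rownames(x)[1:5], none = "zz")),
                 "skipped")

  # compiled Gaussian-kernel CDF equals the plain-R definition
  bw <- pmax(apply(x, 1, sd) / 4, 1e-8)
  expect_equal(crbnsplice:::kcdf_gauss(x, bw), oracle_kcdf(x, bw),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("gsva separates a planted pathway effect across groups", {
  gs <- sim_gene_sets(3, 40, 1000, seed = 63)
  cfg <- sim_config(n_cohorts = 1, n_samples = 100, n_genes = 1000,
                    prevalence_high = 0.5,
                    pathway_effects = c(PATHWAY001 = 1.5), seed = 64)
  co <- simulate_cohorts(cfg, gene_sets = gs)[[1]]
  sc <- gsva_scores(log_cpm(co$counts), gs)
  high <- co$truth$group == "HIGH"
  auc_num <- sum(rank(sc["PATHWAY001", ])[high]) -
    sum(high) * (sum(high) + 1) / 2
  auc <- auc_num / (sum(high) * sum(!high))
  expect_gte(auc, 0.9)
})
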