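test_that("LD pruning keeps independent variants and drops correlated ones", {
  withr::with_seed(1, {
    d <- matrix(rbinom(200 * 4, 2, 0.4), ncol = 4)
  })
  G <- make_gm(d)
  expect_equal(suppressMessages(ld_prune(G, r2_max = 0.99))$keep_index, 1:4)

  d2 <- cbind(d[, 1], d[, 1], d[, 3])  # first two perfectly correlated
  colnames(d2) <- paste0("v", 1:3)
  kept <- suppressMessages(ld_prune(make_gm(d2), r2_max = 0.02))
  expect_true(1 %in% kept$keep_index)
  expect_false(2 %in% kept$keep_index)

  # monomorphic variant: undefined correlation treated as zero, retained
  d3 <- cbind(d[, 1:2], rep(1, 200))
  colnames(d3) <- c("v1", "v2", "mono")
  expect_true(3 %in% suppressMessages(
    ld_prune(make_gm(d3), r2_max = 0.02))$keep_index)
})

test_that("pruning a 20-variant chain matches the brute-force greedy oracle", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      base <- matrix(rbinom(100 * 5, 2, 0.4), ncol = 5)
      d <- base[, sample(5, 20, replace = TRUE)] +
        matrix(rbinom(100 * 20, 2, 0.05), ncol = 20)
      d <- pmin(d, 2)
      colnames(d) <- paste0("v", 1:20)
    })
    G <- make_gm(d)
    kept <- suppressMessages(ld_prune(G, r2_max = 0.2, window = 10L))
    expect_equal(kept$keep_index, prune_oracle(d, 0.2, 10L))
  }
})

test_that("pruned set is invariant to appending uncorrelated variants", {
  withr::with_seed(2, {
    d <- matrix(rbinom(300 * 6, 2, 0.3), ncol = 6)
    extra <- matrix(rbinom(300 * 2, 2, 0.3), ncol = 2)
  })
  colnames(d) <- paste0("v", 1:6)
  colnames(extra) <- paste0("x", 1:2)
  k1 <- suppressMessages(ld_prune(make_gm(d), r2_max = 0.9))
  k2 <- suppressMessages(ld_prune(make_gm(cbind(d, extra)), r2_max = 0.9))
  expect_true(all(k1$id %in% k2$id))
})

test_that("PCA projection reproduces reference scores for duplicated samples", {
  withr::with_seed(3, {
    d <- matrix(rbinom(80 * 100, 2, 0.35), nrow = 80)
  })
  colnames(d) <- paste0("v", seq_len(ncol(d)))
  G <- make_gm(d)
  pca <- genotype_pca(G, G, n_pc = 5L)
  expect_equal(unname(pca$query_scores), unname(pca$ref_scores),
               tolerance = 1e-8)
  expect_error(genotype_pca(G, G, n_pc = 0L), "n_pc")
})

test_that("PC1 separates two populations at Fst 0.2", {
  cfg <- sim_config(fst = rep(0.2, 4), n_ref_per_pop = 100L, n_snps = 2000L,
                    n_cpgs = 10L, n_true_meqtls = 2L,
                    n_true_exposure_cpgs = 2L, n_exposure_snps = 2L,
                    n_cell_ref_cpgs = 5L, seed = 17L)
  p <- simulate_reference_panel(cfg)
  two <- p$labels %in% c("AFR", "EUR")
  G2 <- genotype_matrix(p$G$dosage[two, ], p$G$variants)
  pca <- genotype_pca(G2, G2, n_pc = 2L)
  pc1 <- pca$ref_scores[, 1]
  lab <- p$labels[two]
  expect_true(max(pc1[lab == "AFR"]) < min(pc1[lab == "EUR"]) ||
                min(pc1[lab == "AFR"]) > max(pc1[lab == "EUR"]))
})

test_that("supervised admixture EM recovers pure and mixed ancestry", {
  # Fst 0.2: well-differentiated populations, so the per-sample MLE spread
  # stays within the asserted recovery bounds at 2000 independent SNPs
  cfg <- sim_config(fst = rep(0.2, 4), n_ref_per_pop = 50L, n_snps = 2000L,
                    ld_r = 0, n_cpgs = 10L, n_true_meqtls = 2L,
                    n_true_exposure_cpgs = 2L, n_exposure_snps = 2L,
                    n_cell_ref_cpgs = 5L, seed = 23L)
  p <- simulate_reference_panel(cfg)
  n <- 40L
  # pure population 2
  props <- matrix(rep(c(0, 1, 0, 0), each = n), nrow = n)
  G <- simulate_admixed_cohort(p$freqs, props, cfg, p$layout, seed = 24L)
  # generous iteration cap: EM slows near the simplex boundary
  q <- supervised_admixture(G, p$freqs, max_iter = 10000L)
  expect_true(all(q[, 2] > 0.95))
  expect_equal(unname(rowSums(q)), rep(1, n), tolerance = 1e-6)

  # 50/50 two-population mixture
  props2 <- matrix(rep(c(0.5, 0.5, 0, 0), each = n), nrow = n)
  G2 <- simulate_admixed_cohort(p$freqs, props2, cfg, p$layout, seed = 25L)
  q2 <- supervised_admixture(G2, p$freqs, max_iter = 10000L)
  expect_lt(max(abs(colMeans(q2) - c(0.5, 0.5, 0, 0))), 0.05)

  # K = 1 degenerates to q = 1
  q1 <- suppressWarnings(supervised_admixture(G, p$freqs[1, , drop = FALSE]))
  expect_equal(unname(q1[, 1]), rep(1, n))

  # EM log-likelihood is non-decreasing
  trace <- attr(q, "loglik_trace")
  expect_true(all(diff(trace) > -1e-6))
})

test_that("centroid-distance flags admixed samples but not in-cluster queries", {
  withr::with_seed(31, {
    centers <- rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0), c(0, 0, 20))
    ref <- do.call(rbind, lapply(1:4, function(k)
      sweep(matrix(rnorm(100 * 3), ncol = 3), 2, centers[k, ], "+")))
    labels <- rep(c("AFR", "EUR", "EAS", "SAS"), each = 100)
  })
  # a query at a centroid is not flagged; a midpoint query is
  q <- rbind(centers[1, ], (centers[1, ] + centers[2, ]) / 2)
  res <- detect_admixed(q, ref, labels)
  expect_false(res$admixed[1])
  expect_true(res$admixed[2])

  # queries duplicating reference samples: only the extreme ~1% tail can
  # exceed the 99th-percentile radius
  res2 <- detect_admixed(ref, ref, labels)
  expect_lt(mean(res2$admixed), 0.02)

  expect_error(detect_admixed(q, ref[1:3, ], c("A", "A", "B")),
               ">= 2 reference samples")
})

test_that("KNN classification votes, copies labels at k=1, and breaks ties", {
  withr::with_seed(37, {
    train <- rbind(matrix(rnorm(40, 0), ncol = 2),
                   matrix(rnorm(40, 8), ncol = 2))
    labels <- rep(c("A", "B"), each = 20)
  })
  res <- knn_classify(train[1, , drop = FALSE], train, labels, k = 5L)
  expect_equal(res$label, "A")
  expect_equal(res$A, 5L)
  expect_equal(res$B, 0L)

  res1 <- knn_classify(train[25, , drop = FALSE], train, labels, k = 1L)
  expect_equal(res1$label, "B")

  expect_error(knn_classify(train[1, , drop = FALSE], train, labels, k = 100L),
               "exceeds")

  # exact two-way tie: nearer class wins
  train_tie <- rbind(c(-1, 0), c(-2, 0), c(1.5, 0), c(2.5, 0))
  res_tie <- knn_classify(matrix(c(0, 0), 1), train_tie,
                          c("L", "L", "R", "R"), k = 4L)
  expect_equal(res_tie$label, "L")
})

test_that("full ancestry stage labels dominant-ancestry samples correctly", {
  cfg <- sim_config(n_ref_per_pop = 100L, n_snps = 2000L, n_cpgs = 10L,
                    n_true_meqtls = 2L, n_true_exposure_cpgs = 2L,
                    n_exposure_snps = 2L, n_cell_ref_cpgs = 5L, seed = 43L)
  p <- simulate_reference_panel(cfg)
  pr <- simulate_admixture_props(cfg, 150L, seed = 44L)
  G <- simulate_admixed_cohort(p$freqs, pr$props, cfg, p$layout, seed = 45L)
  config <- pipeline_config(seed = 43L)
  res <- suppressWarnings(suppressMessages(
    run_ancestry(p$G, p$labels, G, config)))
  strong_afr <- pr$props[, 1] >= 0.8
  expect_gt(mean(res$label[strong_afr] == "AFR"), 0.9)
})
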