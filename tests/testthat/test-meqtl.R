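test_that("Hardy-Weinberg test matches hand-computed chi-squared values", {
  expect_equal(hwe_test(25, 50, 25), 1)
  # (50, 0, 50): p-hat = 0.5, expected (25, 50, 25), chi2 = 25+50+25 = 100
  expect_equal(hwe_test(50, 0, 50), pchisq(100, 1, lower.tail = FALSE))
  expect_lt(hwe_test(50, 0, 50), 1e-21)
  expect_equal(hwe_test(100, 0, 0), 1)  # monomorphic convention
  expect_error(hwe_test(-1, 0, 1), ">= 0")
  expect_error(hwe_test(0, 0, 0), "> 0")
})

test_that("genotype QC applies MAF, missingness and HWE rules at boundaries", {
  n <- 100L
  d <- cbind(
    maf04  = c(rep(1, 8), rep(0, 92)),            # MAF 0.04: removed
    maf05  = c(rep(1, 10), rep(0, 90)),           # MAF 0.05: kept
    miss06 = c(rep(NA, 6), rbinom(94, 2, 0.4)),   # 6% missing: removed
    hwe_bad = rep(c(0, 2), each = 50),            # (50, 0, 50): removed
    ok = rbinom(n, 2, 0.4))
  G <- make_gm(d)
  out <- suppressMessages(genotype_qc(G))
  expect_setequal(out$variants$id, c("maf05", "ok"))
})

test_that("cis pairing is inclusive at the window boundary and chromosome-safe", {
  cpgs <- data.frame(id = "cg1", chrom = "chr1", pos = 1000000L)
  vars <- data.frame(id = c("in", "edge", "out", "otherchr"),
                     chrom = c("chr1", "chr1", "chr1", "chr2"),
                     pos = c(1100000L, 1500000L, 1500001L, 1000000L))
  p <- cis_pairs(cpgs, vars, window = 500000)
  expect_setequal(p$variant, c("in", "edge"))
})

test_that("per-pair regression recovers planted effects and flags degenerates", {
  withr::with_seed(11, {
    n <- 400L
    g <- rbinom(n, 2, 0.3)
    C <- data.frame(age = rnorm(n))
    m1 <- 0.4 * g + 0.2 * C$age + rnorm(n)
    m2 <- rnorm(n)
    M <- cbind(cg1 = m1, cg2 = m2)
    rownames(M) <- paste0("s", 1:n)
  })
  G <- make_gm(cbind(v1 = g, mono = rep(2, n)))
  pairs <- data.frame(variant = c("v1", "mono"), cpg = c("cg1", "cg2"))
  res <- fit_meqtl(M, G, C, pairs)
  expect_lt(abs(res$beta[1] - 0.4), 3 * res$se[1])
  expect_equal(res$p[2], 1)
  expect_true(res$degenerate[2])

  # oracle: per-pair estimate equals the joint-OLS coefficient
  fit <- coef(summary(lm(m1 ~ g + C$age)))["g", ]
  expect_equal(res$beta[1], unname(fit["Estimate"]), tolerance = 1e-10)
  expect_equal(res$se[1], unname(fit["Std. Error"]), tolerance = 1e-10)
})

test_that("duplicating every sample shrinks the SE by about sqrt(2)", {
  withr::with_seed(12, {
    n <- 1000L
    g <- rbinom(n, 2, 0.3)
    m <- 0.3 * g + rnorm(n)
  })
  M1 <- matrix(m, dimnames = list(NULL, "cg1"))
  res1 <- fit_meqtl(M1, make_gm(matrix(g, dimnames = list(NULL, "v1"))),
                    NULL, data.frame(variant = "v1", cpg = "cg1"))
  M2 <- matrix(c(m, m), dimnames = list(NULL, "cg1"))
  res2 <- fit_meqtl(M2, make_gm(matrix(c(g, g), dimnames = list(NULL, "v1"))),
                    NULL, data.frame(variant = "v1", cpg = "cg1"))
  expect_lt(abs(res2$se / res1$se - 1 / sqrt(2)), 0.05 / sqrt(2))
})

test_that("BH adjustment matches the hand-applied step-up and an independent oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")

  for (seed in 1:20) {
    withr::with_seed(seed, p <- runif(sample(5:200, 1)))
    q <- bh_fdr(p)
    expect_equal(q, step_up_oracle(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) > -1e-12))  # monotone in sorted p
  }
})

test_that("clumping assigns indices greedily by p with the position tie rule", {
  withr::with_seed(13, {
    n <- 200L
    base <- matrix(rbinom(n * 5, 2, 0.4), ncol = 5)
    d <- base[, c(1, 1, 2, 3, 3, 3, 4, 5)] +
      matrix(rbinom(n * 8, 2, 0.03), ncol = 8)
    d <- pmin(d, 2)
    colnames(d) <- paste0("v", 1:8)
  })
  G <- make_gm(d)
  withr::with_seed(14, {
    recs <- data.frame(variant = colnames(d), cpg = "cg1",
                       p = runif(8, 1e-8, 1e-3))
  })
  out <- clump(recs, G, r2_min = 0.1)
  r2 <- cor(d)^2
  expect_equal(out$clump_id,
               clump_oracle(recs$p, G$variants$pos, r2))
  # exactly one index per clump; every member correlates with its index
  for (cl in unique(out$clump_id)) {
    members <- which(out$clump_id == cl)
    idx <- members[out$is_index[members]]
    expect_length(idx, 1L)
    for (mb in setdiff(members, idx))
      expect_gt(r2[idx, mb], 0.1)
  }

  # all-independent variants each become their own index
  withr::with_seed(15, ind <- matrix(rbinom(500 * 4, 2, 0.4), ncol = 4))
  colnames(ind) <- paste0("w", 1:4)
  recs2 <- data.frame(variant = colnames(ind), cpg = "cg1",
                      p = c(1e-5, 1e-6, 1e-7, 1e-4))
  out2 <- clump(recs2, make_gm(ind), r2_min = 0.1)
  expect_true(all(out2$is_index))

  # perfect correlation: smaller p becomes the index
  dup <- cbind(a = ind[, 1], b = ind[, 1])
  recs3 <- data.frame(variant = c("a", "b"), cpg = "cg1", p = c(1e-10, 1e-5))
  out3 <- clump(recs3, make_gm(dup), r2_min = 0.1)
  expect_equal(out3$clump_id, c(1L, 1L))
  expect_equal(out3$is_index, c(TRUE, FALSE))
})

test_that("nearest-gene mapping matches a brute-force oracle with the tie rule", {
  genes <- data.frame(gene = c("G1", "G2", "G3"), chrom = "chr1",
                      start = c(100L, 1000L, 5000L),
                      end = c(500L, 2000L, 6000L))
  inside <- nearest_gene(data.frame(id = "x", chrom = "chr1", pos = 1500L),
                         genes)
  expect_equal(inside$gene, "G2")
  expect_equal(inside$region, "genic")

  # equidistant between G2 (ends 2000) and G3 (starts 5000): midpoint 3500
  tie <- nearest_gene(data.frame(id = "t", chrom = "chr1", pos = 3500L),
                      genes)
  expect_equal(tie$gene, "G2")
  expect_equal(tie$region, "intergenic")

  none <- nearest_gene(data.frame(id = "n", chrom = "chrX", pos = 100L),
                       genes)
  expect_true(is.na(none$gene))

  withr::with_seed(16, {
    g10 <- data.frame(gene = paste0("g", 1:10), chrom = "chr2",
                      start = sort(sample.int(1e6, 10)))
    g10$end <- g10$start + sample(1000:20000, 10)
    pts <- data.frame(id = paste0("p", 1:100), chrom = "chr2",
                      pos = sample.int(1.2e6, 100))
  })
  res <- nearest_gene(pts, g10)
  for (r in seq_len(nrow(pts))) {
    d <- pmax(g10$start - pts$pos[r], pts$pos[r] - g10$end, 0)
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[which.min(g10$start[best])]
    expect_equal(res$gene[r], g10$gene[best])
    expect_equal(res$distance[r], min(d))
  }
})
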