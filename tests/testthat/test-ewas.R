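make_meth <- function(vals, chrom = "chr1", pos = NULL) {
  if (is.null(pos)) pos <- seq_len(ncol(vals)) * 1000L
  probes <- data.frame(id = colnames(vals), chrom = chrom, pos = pos)
  methylation_matrix(vals, probes, value_kind = "m")
}

test_that("probe filters apply the detection and SNP-proximity rules", {
  withr::with_seed(1, {
    vals <- matrix(rnorm(5 * 4), 5, 4,
                   dimnames = list(paste0("s", 1:5), paste0("cg", 1:4)))
  })
  M <- make_meth(vals, pos = c(1000L, 2000L, 3000L, 4000L))
  det <- matrix(1e-20, 5, 4, dimnames = dimnames(vals))
  det[2, 1] <- 1e-11  # one failing sample drops the whole CpG
  snps <- data.frame(id = c("rs1", "rs2"), chrom = "chr1",
                     pos = c(2010L, 3011L))  # +10 inclusive, +11 kept
  out <- suppressMessages(filter_probes(M, det, snps))
  expect_setequal(colnames(out$values), c("cg3", "cg4"))

  # identity when nothing fails
  out2 <- suppressMessages(filter_probes(M, matrix(1e-20, 5, 4,
                                                   dimnames = dimnames(vals)),
                                         snps[0, ]))
  expect_equal(out2$values, M$values)
})

test_that("control-probe PCs recover planted structure deterministically", {
  withr::with_seed(2, {
    t1 <- rnorm(60)
    rank1 <- outer(t1, runif(15, 0.5, 1))
  })
  s <- control_probe_pcs(rank1, n_pc = 1L)
  expect_gt(attr(s, "var_explained")[1], 1 - 1e-10)
  expect_error(control_probe_pcs(rank1, n_pc = 5L), "rank")

  withr::with_seed(3, {
    f1 <- scale(rnorm(80))[, 1]
    f2 <- scale(residuals(lm(rnorm(80) ~ f1)))[, 1]  # orthogonal factors
    l1 <- runif(30, 0.8, 1.2)
    l2 <- residuals(lm(rnorm(30) ~ l1))              # orthogonal loadings
    ctrl <- 2 * outer(f1, l1) + outer(f2, l2) +
      matrix(rnorm(80 * 30, 0, 0.02), 80)
    perm <- sample(80)
  })
  sc <- control_probe_pcs(ctrl, n_pc = 2L)
  expect_gt(abs(cor(sc[, 1], f1)), 0.99)
  expect_gt(abs(cor(sc[, 2], f2)), 0.99)

  # permutation equivariance
  sc_perm <- control_probe_pcs(ctrl[perm, ], n_pc = 2L)
  expect_equal(unname(sc_perm), unname(sc[perm, ]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("cell deconvolution is exact on pure and 50/50 profiles", {
  withr::with_seed(4, {
    P <- matrix(rnorm(200 * 6, 0, 2), 200, 6,
                dimnames = list(paste0("cg", 1:200), paste0("cell", 1:6)))
  })
  w_pure <- estimate_cell_proportions(P[, 3], P)
  expect_equal(unname(w_pure[1, ]), c(0, 0, 1, 0, 0, 0), tolerance = 1e-6)
  w_mix <- estimate_cell_proportions(0.5 * P[, 1] + 0.5 * P[, 2], P)
  expect_equal(unname(w_mix[1, ]), c(0.5, 0.5, 0, 0, 0, 0), tolerance = 1e-6)
  expect_error(estimate_cell_proportions(P[, 1], cbind(P[, 1:3], P[, 3])),
               "singular")
})

test_that("cell deconvolution RMSE under noise stays below 0.05", {
  withr::with_seed(5, {
    P <- matrix(rnorm(200 * 6, 0, 2), 200, 6,
                dimnames = list(paste0("cg", 1:200), paste0("cell", 1:6)))
    n <- 60L
    W <- meqtlmr:::rdirichlet_mat(n, c(6, 4, 2, 2, 3, 15))
    M <- W %*% t(P) + matrix(rnorm(n * 200, 0, 0.3), n)
  })
  What <- estimate_cell_proportions(M, P)
  expect_lt(sqrt(mean((What - W)^2)), 0.05)
})

test_that("residual PCs capture planted batch structure orthogonal to covariates", {
  withr::with_seed(6, {
    n <- 100L
    covs <- data.frame(age = rnorm(n), wbc = rnorm(n))
    batch <- rnorm(n)
    loadings <- rnorm(400, 0, 1)
    M <- outer(covs$age, rnorm(400, 0, 0.5)) + outer(batch, loadings) +
      matrix(rnorm(n * 400, 0, 0.3), n)
  })
  colnames(M) <- paste0("cg", 1:400)
  s <- residual_pcs(M, covs, n_pc = 2L)
  expect_gt(abs(cor(s[, 1], batch)), 0.95)

  # covariates fully explaining M leave near-zero scores
  M0 <- outer(covs$age, rnorm(400))
  colnames(M0) <- paste0("cg", 1:400)
  s0 <- residual_pcs(M0, covs, n_pc = 2L)
  expect_lt(max(abs(s0)), 1e-8)

  expect_error(residual_pcs(M, cbind(covs, age2 = covs$age * 1), 2L),
               "collinear")
})

test_that("the exposure regression recovers planted effects and matches a normal-equations oracle", {
  withr::with_seed(7, {
    n <- 400L
    Y <- rbinom(n, 1, 0.4)
    C <- data.frame(age = rnorm(n), tob = rbinom(n, 1, 0.5))
    M <- outer(Y, c(0.5, 0)) + matrix(rnorm(n * 2), n)
  })
  colnames(M) <- c("cg1", "cg2")
  res <- fit_ewas(M, Y, C)
  expect_lt(abs(res$beta[1] - 0.5), 3 * res$se[1])

  # oracle: explicit normal equations on a small instance
  withr::with_seed(8, {
    ns <- 20L
    Ys <- rbinom(ns, 1, 0.5)
    Cs <- data.frame(a = rnorm(ns))
    Ms <- matrix(rnorm(ns * 3), ns, dimnames = list(NULL, paste0("cg", 1:3)))
  })
  res_s <- fit_ewas(Ms, Ys, Cs)
  X <- cbind(1, Ys, Cs$a)
  XtXi <- solve(t(X) %*% X)
  for (j in 1:3) {
    bhat <- XtXi %*% t(X) %*% Ms[, j]
    rss <- sum((Ms[, j] - X %*% bhat)^2)
    se <- sqrt(rss / (ns - 3) * XtXi[2, 2])
    expect_equal(res_s$beta[j], bhat[2], tolerance = 1e-8)
    expect_equal(res_s$se[j], se, tolerance = 1e-8)
  }

  # a covariate orthogonal to both Y and M leaves the estimate unchanged
  base <- fit_ewas(Ms, Ys, Cs)
  Z <- residuals(lm(rnorm(ns) ~ X + Ms))
  with_z <- fit_ewas(Ms, Ys, cbind(Cs, z = Z))
  expect_equal(with_z$beta, base$beta, tolerance = 1e-10)

  expect_error(fit_ewas(Ms, rep(1, ns), Cs), "zero variance")
})

test_that("fixed-effects meta-analysis matches closed forms and limits", {
  r <- function(cpg, beta, se) data.frame(cpg = cpg, beta = beta, se = se,
                                          p = 0.5, n = 100)
  m1 <- meta_fixed(r("cg1", 0.3, 0.1), r("cg1", 0.3, 0.1))
  expect_equal(m1$beta, 0.3)
  expect_equal(m1$se, 0.1 / sqrt(2))

  m2 <- meta_fixed(r("cg1", 1, 1), r("cg1", 0, 1))
  expect_equal(m2$beta, 0.5)
  expect_equal(m2$se, 1 / sqrt(2))

  m3 <- meta_fixed(r("cg1", 0.4, 0.05), r("cg1", -2, 1e6))
  expect_equal(m3$beta, 0.4, tolerance = 1e-6)
  expect_equal(m3$se, 0.05, tolerance = 1e-6)

  expect_error(meta_fixed(r("cg1", 1, 1), r("cg2", 1, 1)), "no shared")
  expect_error(meta_fixed(r("cg1", 1, 0), r("cg1", 1, 1)), "positive")
})

test_that("meta-analysis agrees with an independent fixed-effects oracle", {
  withr::with_seed(9, {
    k <- 50L
    b1 <- rnorm(k); b2 <- rnorm(k)
    s1 <- runif(k, 0.05, 0.5); s2 <- runif(k, 0.05, 0.5)
  })
  r1 <- data.frame(cpg = paste0("cg", 1:k), beta = b1, se = s1, p = 0.5, n = 1)
  r2 <- data.frame(cpg = paste0("cg", 1:k), beta = b2, se = s2, p = 0.5, n = 1)
  m <- meta_fixed(r1, r2)
  m <- m[match(r1$cpg, m$cpg), ]
  for (j in c(1, 17, 42)) {
    fe <- metafor::rma(yi = c(b1[j], b2[j]), sei = c(s1[j], s2[j]),
                       method = "FE")
    expect_equal(m$beta[j], as.numeric(fe$beta), tolerance = 1e-10)
    expect_equal(m$se[j], fe$se, tolerance = 1e-10)
  }
  # weighted-average oracle across all records
  w1 <- 1 / s1^2; w2 <- 1 / s2^2
  expect_equal(m$beta, (w1 * b1 + w2 * b2) / (w1 + w2), tolerance = 1e-12)
})

test_that("candidate selection thresholds and direction counts behave", {
  meta <- data.frame(cpg = paste0("cg", 1:4), beta = c(1, -1, 2, -2),
                     se = 1, p = c(1e-5, 2e-5, 0.5, 0.9), cohort = "META")
  sel <- suppressMessages(select_candidates(meta, 1e-4))
  expect_equal(sel$cpg, c("cg1", "cg2"))
  expect_equal(attr(sel, "n_hyper"), 1L)
  expect_equal(attr(sel, "n_hypo"), 1L)
  expect_equal(nrow(suppressMessages(select_candidates(meta, 1e-10))), 0L)
  expect_equal(nrow(suppressMessages(select_candidates(meta, 1))), 4L)
})

test_that("genomic inflation is calibrated at the null and monotone under inflation", {
  expect_equal(genomic_lambda(rep(0.5, 11)), 1)
  withr::with_seed(10, p <- runif(10000))
  expect_lt(abs(genomic_lambda(p) - 1), 0.05)
  expect_gt(genomic_lambda(p / 10), genomic_lambda(p))
  expect_error(genomic_lambda(c(0.5, 0)), "\\(0, 1\\]")
})
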