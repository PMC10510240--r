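#' Greedy LD pruning
#'
#' Left-to-right scan: a variant is dropped when its squared dosage
#' correlation with any retained variant within the trailing window exceeds
#' `r2_max`. Monomorphic variants have undefined correlation, are treated
#' as r2 = 0 and retained.
#'
#' @param G a [genotype_matrix()]
#' @param r2_max squared-correlation ceiling
#' @param window variant-count window (comparisons are made against
#'   retained variants at most `window` positions back)
#' @return the retained subset of `G$variants` (with a `keep_index` column)
#' @export
ld_prune <- function(G, r2_max = 0.02, window = 100L) {
  d <- G$dosage
  m <- ncol(d)
  if (m < 2L) stop("need at least 2 variants to prune", call. = FALSE)
  keep <- integer(0)
  for (j in seq_len(m)) {
    in_window <- keep[keep >= j - window]
    drop <- FALSE
    if (length(in_window)) {
      r <- suppressWarnings(
        stats::cor(d[, j], d[, in_window, drop = FALSE],
                   use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0  # monomorphic or no overlap: undefined, treat as 0
      if (any(r^2 > r2_max)) drop <- TRUE
    }
    if (!drop) keep <- c(keep, j)
  }
  log_filter(sprintf("ld_prune r2<=%g", r2_max), m, length(keep))
  out <- G$variants[keep, , drop = FALSE]
  out$keep_index <- keep
  rownames(out) <- NULL
  out
}

#' Reference-anchored genotype PCA
#'
#' Variants are centred and scaled by the reference panel's allele
#' frequency (PLINK-style scaling `sqrt(2p(1-p))`); the reference is
#' decomposed by SVD and query samples are projected onto the reference
#' loadings.
#'
#' @param G_ref,G_query [genotype_matrix()] objects over a shared variant
#'   set (missing dosages are mean-imputed from the reference frequency)
#' @param n_pc number of components (must be >= 1)
#' @return list with `ref_scores`, `query_scores` (samples x n_pc),
#'   `loadings`, and the variant ids used
#' @export
genotype_pca <- function(G_ref, G_query, n_pc = 10L) {
  if (n_pc < 1L) stop("n_pc must be >= 1", call. = FALSE)
  shared <- intersect(G_ref$variants$id, G_query$variants$id)
  if (!length(shared)) stop("no shared variants", call. = FALSE)
  Xr <- G_ref$dosage[, match(shared, G_ref$variants$id), drop = FALSE]
  Xq <- G_query$dosage[, match(shared, G_query$variants$id), drop = FALSE]
  p_hat <- colMeans(Xr, na.rm = TRUE) / 2
  ok <- p_hat > 0 & p_hat < 1
  if (any(!ok)) {
    warning(sum(!ok), " zero-variance variant(s) dropped before PCA",
            call. = FALSE)
    Xr <- Xr[, ok, drop = FALSE]; Xq <- Xq[, ok, drop = FALSE]
    p_hat <- p_hat[ok]; shared <- shared[ok]
  }
  ctr <- 2 * p_hat
  scl <- sqrt(2 * p_hat * (1 - p_hat))
  std <- function(X) {
    for (j in seq_len(ncol(X))) {
      xj <- X[, j]
      xj[is.na(xj)] <- ctr[j]
      X[, j] <- (xj - ctr[j]) / scl[j]
    }
    X
  }
  Zr <- std(Xr); Zq <- std(Xq)
  n_pc <- min(n_pc, min(dim(Zr)))
  sv <- svd(Zr, nu = n_pc, nv = n_pc)
  ref_scores <- sv$u %*% diag(sv$d[seq_len(n_pc)], n_pc)
  query_scores <- Zq %*% sv$v
  colnames(ref_scores) <- colnames(query_scores) <- paste0("PC", seq_len(n_pc))
  rownames(ref_scores) <- rownames(Xr)
  rownames(query_scores) <- rownames(Xq)
  list(ref_scores = ref_scores, query_scores = query_scores,
       loadings = sv$v, variant_ids = shared, center = ctr, scale = scl)
}

#' Supervised admixture-proportion estimation
#'
#' Maximizes, per sample, the binomial admixture log-likelihood
#' `sum_j [ g_j log(sum_k q_k p_kj) + (2 - g_j) log(sum_k q_k (1 - p_kj)) ]`
#' over the K-simplex by EM, with reference population allele frequencies
#' held fixed. The log-likelihood is non-decreasing across iterations.
#'
#' @param G_query a [genotype_matrix()]
#' @param ref_freqs K x variants matrix of population allele frequencies
#'   (clamped to `[1e-6, 1 - 1e-6]`); columns must be named by variant id
#' @param max_iter,tol EM controls; convergence when every sample's
#'   log-likelihood gain falls below `tol`
#' @return samples x K matrix of proportions on the simplex, with an
#'   attribute `loglik` (final per-sample log-likelihood)
#' @export
supervised_admixture <- function(G_query, ref_freqs, max_iter = 1000L,
                                 tol = 1e-6) {
  K <- nrow(ref_freqs)
  shared <- intersect(G_query$variants$id, colnames(ref_freqs))
  if (!length(shared)) stop("no shared variants", call. = FALSE)
  G <- G_query$dosage[, match(shared, G_query$variants$id), drop = FALSE]
  P <- clamp(ref_freqs[, shared, drop = FALSE], 1e-6, 1 - 1e-6)
  n <- nrow(G); m <- ncol(G)
  obs <- !is.na(G)
  G0 <- ifelse(obs, G, 0)
  G2 <- ifelse(obs, 2 - G, 0)
  n_obs <- rowSums(obs)
  Q <- matrix(1 / K, n, K, dimnames = list(rownames(G), rownames(ref_freqs)))
  ll <- function(Q) {
    QP <- Q %*% P
    QN <- Q %*% (1 - P)
    rowSums(G0 * log(QP) + G2 * log(QN))
  }
  ll_old <- ll(Q)
  ll_trace <- sum(ll_old)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    QP <- Q %*% P
    QN <- Q %*% (1 - P)
    Qnew <- Q
    for (k in seq_len(K)) {
      ak <- sweep(1 / QP, 2L, P[k, ], "*") * Q[, k]
      bk <- sweep(1 / QN, 2L, 1 - P[k, ], "*") * Q[, k]
      Qnew[, k] <- rowSums(G0 * ak + G2 * bk) / (2 * n_obs)
    }
    Q <- Qnew / rowSums(Qnew)
    ll_new <- ll(Q)
    ll_trace <- c(ll_trace, sum(ll_new))
    if (max(ll_new - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll_new
  }
  if (!converged)
    warning("admixture EM did not converge in ", max_iter,
            " iterations; best iterate returned", call. = FALSE)
  attr(Q, "loglik") <- ll(Q)
  attr(Q, "loglik_trace") <- ll_trace
  Q
}

#' Flag samples with admixed ancestry by centroid distance
#'
#' Class centroids are computed from labelled reference scores on PC1-PC3;
#' a query sample is flagged when its distance to every class centroid
#' exceeds that class's 99th percentile of within-class reference
#' distances (a data-driven radius, no magic constant).
#'
#' @param query_scores,ref_scores score matrices with at least 3 PCs
#' @param ref_labels reference class labels (>= 2 samples per class)
#' @param probs quantile defining each class's radius
#' @return data.frame with `min_distance`, `nearest` class, and `admixed`
#'   flag per query sample
#' @export
detect_admixed <- function(query_scores, ref_scores, ref_labels,
                           probs = 0.99) {
  q3 <- as.matrix(query_scores)[, 1:3, drop = FALSE]
  r3 <- as.matrix(ref_scores)[, 1:3, drop = FALSE]
  classes <- sort(unique(ref_labels))
  cnt <- table(ref_labels)
  if (any(cnt < 2L))
    stop("need >= 2 reference samples per class", call. = FALSE)
  centroids <- t(vapply(classes, function(cl)
    colMeans(r3[ref_labels == cl, , drop = FALSE]), numeric(3L)))
  cutoffs <- vapply(classes, function(cl) {
    d <- sqrt(rowSums(sweep(r3[ref_labels == cl, , drop = FALSE], 2L,
                            centroids[cl, ])^2))
    stats::quantile(d, probs, names = FALSE)
  }, numeric(1L))
  dmat <- vapply(classes, function(cl)
    sqrt(rowSums(sweep(q3, 2L, centroids[cl, ])^2)), numeric(nrow(q3)))
  dmat <- matrix(dmat, nrow = nrow(q3), dimnames = list(rownames(q3), classes))
  nearest <- classes[max.col(-dmat, ties.method = "first")]
  min_d <- dmat[cbind(seq_len(nrow(dmat)), match(nearest, classes))]
  outside_all <- rowSums(sweep(dmat, 2L, cutoffs, ">")) == length(classes)
  data.frame(sample_id = rownames(q3) %||% as.character(seq_len(nrow(q3))),
             min_distance = min_d, nearest = nearest,
             admixed = outside_all, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' K-nearest-neighbour ancestry classification
#'
#' Features (10 PCs + K admixture proportions) are standardized to the
#' training mean and SD; each query takes a majority vote over its k
#' Euclidean nearest training neighbours. A vote tie is broken in favour
#' of the tied label with the smallest mean neighbour distance.
#'
#' @param query,training feature matrices with identical columns
#' @param train_labels training class labels
#' @param k neighbours (must not exceed the training size)
#' @return data.frame of per-sample `label` plus per-class vote counts
#' @export
knn_classify <- function(query, training, train_labels, k = 20L) {
  query <- as.matrix(query); training <- as.matrix(training)
  if (k > nrow(training))
    stop("k exceeds training size", call. = FALSE)
  mu <- colMeans(training)
  sd_ <- apply(training, 2L, stats::sd)
  sd_[sd_ == 0] <- 1
  Zt <- sweep(sweep(training, 2L, mu), 2L, sd_, "/")
  Zq <- sweep(sweep(query, 2L, mu), 2L, sd_, "/")
  # squared Euclidean distances query x training
  d2 <- outer(rowSums(Zq^2), rowSums(Zt^2), "+") - 2 * Zq %*% t(Zt)
  d2 <- pmax(d2, 0)
  classes <- sort(unique(train_labels))
  votes <- matrix(0L, nrow(query), length(classes),
                  dimnames = list(rownames(query), classes))
  label <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    nb <- order(d2[i, ])[seq_len(k)]
    tab <- table(factor(train_labels[nb], levels = classes))
    votes[i, ] <- as.integer(tab)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      mean_d <- vapply(top, function(cl)
        mean(sqrt(d2[i, nb[train_labels[nb] == cl]])), numeric(1L))
      top <- top[which.min(mean_d)]
    }
    label[i] <- top
  }
  out <- data.frame(sample_id = rownames(query) %||%
                      as.character(seq_len(nrow(query))),
                    label = label, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(votes))
}

#' Run the full ancestry-assignment stage
#'
#' LD-prunes the reference, runs reference-anchored PCA, estimates
#' supervised admixture proportions for reference and query samples,
#' flags admixed queries by centroid distance, builds a training set of
#' the labelled reference groups plus a seeded random draw of 20 flagged
#' admixed queries, and classifies the remaining queries by KNN on the
#' 10 PC + K proportion feature space.
#'
#' @param G_ref reference [genotype_matrix()]
#' @param ref_labels per-sample reference population labels
#' @param G_query query [genotype_matrix()]
#' @param config a [pipeline_config()]
#' @param n_admixed_train admixed queries drawn into the training set
#' @return data.frame per query sample: sample_id, PC1..PC10, per-population
#'   proportions, min centroid distance, admixed flag, ancestry label
#' @export
run_ancestry <- function(G_ref, ref_labels, G_query, config = pipeline_config(),
                         n_admixed_train = 20L) {
  stage_log("ancestry", "LD pruning reference panel")
  kept <- ld_prune(G_ref, r2_max = config$prune_r2)
  sub <- function(G, ids) {
    idx <- match(ids, G$variants$id)
    idx <- idx[!is.na(idx)]
    genotype_matrix(G$dosage[, idx, drop = FALSE],
                    G$variants[idx, , drop = FALSE])
  }
  Gr <- sub(G_ref, kept$id)
  Gq <- sub(G_query, kept$id)

  pca <- genotype_pca(Gr, Gq, n_pc = 10L)
  pops <- sort(unique(ref_labels))
  freqs <- t(vapply(pops, function(pl)
    colMeans(Gr$dosage[ref_labels == pl, , drop = FALSE], na.rm = TRUE) / 2,
    numeric(ncol(Gr$dosage))))
  colnames(freqs) <- Gr$variants$id
  q_ref <- supervised_admixture(Gr, freqs)
  q_query <- supervised_admixture(Gq, freqs)

  adm <- detect_admixed(pca$query_scores, pca$ref_scores, ref_labels)
  feats_ref <- cbind(pca$ref_scores, q_ref)
  feats_query <- cbind(pca$query_scores, q_query)

  train_feats <- feats_ref
  train_labels <- ref_labels
  admixed_idx <- which(adm$admixed)
  train_admixed <- integer(0)
  if (length(admixed_idx)) {
    n_draw <- min(n_admixed_train, length(admixed_idx))
    train_admixed <- with_seed(config$seed + 909L,
                               sort(sample(admixed_idx, n_draw)))
    train_feats <- rbind(train_feats, feats_query[train_admixed, , drop = FALSE])
    train_labels <- c(train_labels, rep("ADMIXED", length(train_admixed)))
  }
  test_idx <- setdiff(seq_len(nrow(feats_query)), train_admixed)
  label <- character(nrow(feats_query))
  label[train_admixed] <- "ADMIXED"
  if (length(test_idx)) {
    cls <- knn_classify(feats_query[test_idx, , drop = FALSE], train_feats,
                        train_labels, k = config$knn_k)
    label[test_idx] <- cls$label
  }
  stage_log("ancestry", sprintf("%d query samples labelled (%d flagged admixed)",
                                nrow(feats_query), sum(adm$admixed)))
  data.frame(sample_id = rownames(Gq$dosage),
             as.data.frame(pca$query_scores),
             as.data.frame(q_query),
             min_distance = adm$min_distance,
             admixed = adm$admixed, label = label,
             stringsAsFactors = FALSE, check.names = FALSE)
}
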