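# Independent brute-force oracles, kept deliberately separate from the
# package implementations they check.

# greedy left-to-right LD pruning as a plain double loop
prune_oracle <- function(d, r2_max, window) {
  keep <- integer(0)
  for (j in seq_len(ncol(d))) {
    drop <- FALSE
    for (i in keep) {
      if (j - i > window) next
      r <- suppressWarnings(cor(d[, i], d[, j]))
      if (!is.na(r) && r^2 > r2_max) { drop <- TRUE; break }
    }
    if (!drop) keep <- c(keep, j)
  }
  keep
}

# greedy clumping: repeatedly seed a clump at the smallest-p free variant
clump_oracle <- function(p, pos, r2, r2_min = 0.1) {
  assigned <- rep(NA_integer_, length(p))
  cl <- 0L
  repeat {
    free <- which(is.na(assigned))
    if (!length(free)) break
    lead <- free[order(p[free], pos[free])][1L]
    cl <- cl + 1L
    assigned[lead] <- cl
    others <- setdiff(which(is.na(assigned)), lead)
    assigned[others[r2[lead, others] > r2_min]] <- cl
  }
  assigned
}

# Benjamini-Hochberg step-up applied literally to the sorted p-values
step_up_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}

# one-sided (enrichment) Fisher p as an explicit hypergeometric tail sum
hyper_tail_oracle <- function(a, M, T_, R) {
  x <- max(0, M + R - T_):min(M, R)
  sum(dhyper(x[x >= a], M, T_ - M, R))
}

# nearest-gene by linear scan with the lower-coordinate tie rule
nearest_oracle <- function(pos, genes) {
  d <- pmax(genes$start - pos, pos - genes$end, 0)
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[which.min(genes$start[best])]
  list(gene = genes$gene[best], distance = min(d))
}
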