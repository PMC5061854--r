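# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths and the libraries it
# delegates to, computing each quantity from first principles.

# average ranks computed by explicit tie-averaging
oracle_ranks <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    below <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- below + (ties + 1) / 2
  }
  r
}

# Spearman rho from scratch: product-moment of tie-averaged ranks
oracle_spearman_rho <- function(x, y) {
  rx <- oracle_ranks(x); ry <- oracle_ranks(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# mean C-score by explicit pair loop
oracle_cscore <- function(mat, normalized = FALSE) {
  mat <- (mat > 0) * 1
  nr <- nrow(mat)
  vals <- c()
  for (i in seq_len(nr - 1)) for (j in (i + 1):nr) {
    Ri <- sum(mat[i, ]); Rj <- sum(mat[j, ])
    S <- sum(mat[i, ] == 1 & mat[j, ] == 1)
    v <- (Ri - S) * (Rj - S)
    if (normalized) {
      if (Ri * Rj == 0) next
      v <- v / (Ri * Rj)
    }
    vals <- c(vals, v)
  }
  mean(vals)
}

# Newman modularity from the edge list and a membership vector
oracle_modularity <- function(edges, membership) {
  m <- nrow(edges)
  nodes <- names(membership)
  deg <- setNames(numeric(length(nodes)), nodes)
  for (k in seq_len(m)) {
    deg[edges[k, 1]] <- deg[edges[k, 1]] + 1
    deg[edges[k, 2]] <- deg[edges[k, 2]] + 1
  }
  q <- 0
  for (k in seq_len(m)) {
    if (membership[edges[k, 1]] == membership[edges[k, 2]]) q <- q + 1 / m
  }
  for (cl in unique(membership)) {
    dc <- sum(deg[membership == cl])
    q <- q - (dc / (2 * m))^2
  }
  q
}

# dominant right-singular vector by power iteration on crossprod(z)
oracle_eigengene <- function(z, iters = 2000) {
  A <- t(z) %*% z
  v <- rep(1, ncol(z)) / sqrt(ncol(z))
  for (i in seq_len(iters)) {
    v2 <- A %*% v
    v <- v2 / sqrt(sum(v2^2))
  }
  as.numeric(v)
}

# single categorical-term PERMANOVA R2 by explicit sums-of-squares
# decomposition of squared distances (Total and Within-group)
oracle_permanova_r2 <- function(dmat, groups) {
  n <- nrow(dmat)
  sst <- sum(dmat[upper.tri(dmat)]^2) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- dmat[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  (sst - ssw) / sst
}

# exhaustive fixed-column-totals null: every binary matrix with the given
# column sums (rows equiprobable within each column), plus the exact
# mean/sd of the mean C-score over that uniform ensemble
oracle_null_ensemble <- function(mat) {
  nr <- nrow(mat); cs <- colSums(mat)
  per_col <- lapply(cs, function(k) {
    if (k == 0) return(list(integer(0)))
    combos <- combn(nr, k)
    lapply(seq_len(ncol(combos)), function(i) combos[, i])
  })
  grids <- expand.grid(lapply(per_col, seq_along))
  mats <- lapply(seq_len(nrow(grids)), function(g) {
    m <- matrix(0L, nr, length(cs))
    for (j in seq_along(cs)) m[per_col[[j]][[grids[g, j]]], j] <- 1L
    m
  })
  scores <- vapply(mats, oracle_cscore, numeric(1))
  list(matrices = mats, scores = scores, mean = mean(scores),
       sd = sqrt(mean((scores - mean(scores))^2)))
}

# adjusted Rand index between two labelings
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sc <- function(x) sum(choose(x, 2))
  si <- sc(rowSums(tab)); sj <- sc(colSums(tab))
  sall <- choose(sum(tab), 2)
  e <- si * sj / sall
  (sc(tab) - e) / ((si + sj) / 2 - e)
}

# reduced-size synthetic design shared by recovery tests
recovery_design <- function(n_samples = 30L) {
  synthetic_design(n_samples = n_samples, n_core = 60L, n_satellite = 240L,
                   n_modules = 4L, module_size_range = c(10L, 10L))
}

# design with all planted effects switched off (exchangeable null)
null_design <- function(n_samples = 20L, n_core = 30L, n_satellite = 60L) {
  synthetic_design(n_samples = n_samples, n_core = n_core,
                   n_satellite = n_satellite, n_modules = 0L,
                   beta_range = c(0, 0), core_idio_sd = 0,
                   contamination_multiplier = 1, depth = 1000L)
}
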