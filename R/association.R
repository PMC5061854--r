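#' Spearman rank correlation with small-sample exact p
#'
#' Average-rank tie handling. The two-sided p-value uses the t approximation
#' for n > 9 and exact enumeration of all n! permutations for n <= 9 (valid
#' with ties, unlike the classical null tables).
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @return list(rho, p); both NA when either vector is constant.
#' @export
spearman_assoc <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need at least 4 paired observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p = NA_real_))
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9) {
    perms <- all_permutations(n)
    # rho for every permutation of y's ranks against x's ranks
    num <- matrix(ry[perms], nrow = nrow(perms)) %*% rx -
      n * mean(rx) * mean(ry)
    den <- (n - 1) * sd(rx) * sd(ry)
    rho_null <- as.numeric(num / den)
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p <- min(1, p)
  }
  list(rho = rho, p = p)
}

# all n! permutations of 1..n as a matrix (rows = permutations); n <= 9
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    rows <- (k - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1)
  }
  out
}

#' All-pairs Spearman correlations filtered into a co-occurrence edge set
#'
#' Computes Spearman rho for every unordered OTU pair (t-approximation
#' p-values) and retains pairs with |rho| at or above the configured
#' threshold and p below the p-threshold (defaults 0.6 and 0.001). The
#' absolute-value gate keeps negative associations — sign is carried as an
#' edge attribute. OTUs below the prevalence filter (present in fewer than
#' `prevalence_min_fraction` of samples) are removed first to stabilise the
#' rank correlations.
#'
#' @param table an [abundance_table()], typically restricted to core OTUs
#'   (see [core_otus()]).
#' @param config a [benthonet_config()].
#' @param adjust_p apply Benjamini-Hochberg correction before the p gate
#'   (off by default; the stated gate is the raw p < 0.001).
#' @return data.frame of class `edge_table`: otu_a, otu_b (a < b), rho, p,
#'   sign; with attributes `n_otus_tested` and `full_rho` (the unfiltered
#'   correlation matrix).
#' @export
edge_table <- function(table, config = benthonet_config(),
                       adjust_p = FALSE) {
  m <- unclass(table)
  n_samp <- ncol(m)
  prev <- rowSums(m > 0) / n_samp
  keep <- prev >= config$prevalence_min_fraction
  if (sum(keep) < 2) {
    warning("fewer than 2 OTUs pass the prevalence filter; no edges")
    return(empty_edge_table(0))
  }
  m <- m[keep, , drop = FALSE]
  message(sprintf("association: %d of %d OTUs pass prevalence >= %.0f%%",
                  nrow(m), length(keep),
                  100 * config$prevalence_min_fraction))
  ranks <- t(apply(m, 1, rank))
  rho <- cor(t(ranks))
  # two-sided t approximation, vectorised over the pair matrix
  r2 <- pmin(rho^2, 1 - 1e-15)
  tstat <- abs(rho) * sqrt((n_samp - 2) / (1 - r2))
  p <- 2 * pt(tstat, df = n_samp - 2, lower.tail = FALSE)
  pair <- which(upper.tri(rho), arr.ind = TRUE)
  pr <- p[pair]
  if (adjust_p) pr <- p.adjust(pr, method = "BH")
  ok <- !is.na(rho[pair]) & abs(rho[pair]) >= config$rho_edge_threshold &
    pr < config$p_edge_threshold
  a <- rownames(m)[pair[ok, 1]]
  b <- rownames(m)[pair[ok, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- data.frame(otu_a = a, otu_b = b,
                      rho = rho[pair][ok], p = pr[ok],
                      sign = ifelse(rho[pair][ok] >= 0, "positive",
                                    "negative"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$otu_a, edges$otu_b), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "n_otus_tested") <- nrow(m)
  attr(edges, "full_rho") <- rho
  attr(edges, "tested_otus") <- rownames(m)
  class(edges) <- c("edge_table", "data.frame")
  edges
}

empty_edge_table <- function(n_tested) {
  edges <- data.frame(otu_a = character(), otu_b = character(),
                      rho = numeric(), p = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
  attr(edges, "n_otus_tested") <- n_tested
  class(edges) <- c("edge_table", "data.frame")
  edges
}
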