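#' Checkerboard units for one species pair
#'
#' C_ij = (R_i - S_ij)(R_j - S_ij) where R are the two species' occupancies
#' (row totals) and S_ij the number of sites where both are present. High
#' values indicate segregation (checkerboard patterns); 0 means the pair
#' co-occurs wherever possible.
#'
#' @param a,b binary presence vectors over the same sites.
#' @return number of checkerboard units.
#' @export
cscore_pair <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  s <- sum(a > 0 & b > 0)
  (sum(a > 0) - s) * (sum(b > 0) - s)
}

#' Mean checkerboard C-score of a presence/absence matrix
#'
#' Mean of C_ij over all unordered species (row) pairs. The normalized
#' variant divides each pair's units by R_i x R_j before averaging, giving a
#' scale in [0, 1]; pairs where R_i x R_j = 0 are skipped.
#'
#' @param mat binary matrix, rows = species, columns = sites.
#' @param normalized logical.
#' @return mean C-score.
#' @export
mean_cscore <- function(mat, normalized = FALSE) {
  mat <- (unclass(mat) > 0) * 1
  if (nrow(mat) < 2) stop("need at least 2 species (rows)")
  S <- tcrossprod(mat)
  R <- rowSums(mat)
  C <- (matrix(R, nrow(mat), nrow(mat)) - S) *
    (matrix(R, nrow(mat), nrow(mat), byrow = TRUE) - S)
  up <- upper.tri(C)
  if (normalized) {
    RR <- tcrossprod(R, R)
    ok <- up & RR > 0
    return(mean(C[ok] / RR[ok]))
  }
  mean(C[up])
}

#' Generate one null presence/absence matrix
#'
#' Three algorithms: `fixed_site_frequencies` (default; each site/column
#' keeps its total number of presences, reassigned to species equiprobably
#' without replacement), `fixed_occupancies` (each species/row keeps its
#' total), and `swap` (both margins preserved by random 2x2 checkerboard
#' submatrix swaps with burn-in).
#'
#' @param mat binary matrix (rows = species, columns = sites).
#' @param algorithm null algorithm.
#' @param n_swaps number of attempted swaps for `"swap"` (default
#'   `10 * sum(mat)`).
#' @return a binary matrix with the promised margins.
#' @export
generate_null <- function(mat,
                          algorithm = c("fixed_site_frequencies",
                                        "fixed_occupancies", "swap"),
                          n_swaps = NULL) {
  algorithm <- match.arg(algorithm)
  mat <- (unclass(mat) > 0) * 1L
  nr <- nrow(mat); nc <- ncol(mat)
  if (algorithm == "fixed_site_frequencies") {
    out <- matrix(0L, nr, nc, dimnames = dimnames(mat))
    cs <- colSums(mat)
    for (j in seq_len(nc)) {
      if (cs[j] > 0) out[sample.int(nr, cs[j]), j] <- 1L
    }
    return(out)
  }
  if (algorithm == "fixed_occupancies") {
    out <- matrix(0L, nr, nc, dimnames = dimnames(mat))
    rs <- rowSums(mat)
    for (i in seq_len(nr)) {
      if (rs[i] > 0) out[i, sample.int(nc, rs[i])] <- 1L
    }
    return(out)
  }
  # swap: 2x2 checkerboard exchanges preserve both margins
  out <- mat
  if (is.null(n_swaps)) n_swaps <- max(1000L, 10L * sum(mat))
  swapped <- FALSE
  rows <- sample.int(nr, 2 * n_swaps, replace = TRUE)
  rows2 <- sample.int(nr, 2 * n_swaps, replace = TRUE)
  cols <- sample.int(nc, 2 * n_swaps, replace = TRUE)
  cols2 <- sample.int(nc, 2 * n_swaps, replace = TRUE)
  for (k in seq_len(n_swaps)) {
    i1 <- rows[k]; i2 <- rows2[k]
    j1 <- cols[k]; j2 <- cols2[k]
    if (i1 == i2 || j1 == j2) next
    a <- out[i1, j1]; b <- out[i1, j2]; c <- out[i2, j1]; d <- out[i2, j2]
    if (a == d && b == c && a != b) {
      out[i1, j1] <- b; out[i1, j2] <- a; out[i2, j1] <- d; out[i2, j2] <- c
      swapped <- TRUE
    }
  }
  if (!swapped) warning("no swappable 2x2 submatrix found; matrix unchanged")
  out
}

#' C-score standardized effect size against a null-model ensemble
#'
#' Compares the observed mean C-score with `n_null` null matrices. The
#' standardized effect size SES = (observed - null mean) / null sd; positive
#' values indicate more segregation (less co-occurrence) than expected by
#' chance, and |SES| <= 2 is the random band. One-tailed p-values use the
#' add-one estimator p = (1 + #null >= obs) / (1 + n_null), so p is never 0.
#'
#' @param table counts or presence/absence matrix (rows = OTUs).
#' @param n_null number of null matrices (>= 100; conventional default 5000).
#' @param algorithm null algorithm, see [generate_null()].
#' @param seed integer seed for the null stream.
#' @return object of class `nullmodel_report`: observed and normalized
#'   C-score, null mean/sd, ses, p_greater, p_less, n_null, algorithm, seed.
#' @export
ses_cscore <- function(table, n_null = 5000,
                       algorithm = c("fixed_site_frequencies",
                                     "fixed_occupancies", "swap"),
                       seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (n_null < 100) stop("n_null must be at least 100")
  mat <- presence_matrix(table)
  obs <- mean_cscore(mat)
  obs_norm <- mean_cscore(mat, normalized = TRUE)
  set.seed(seed)
  null_scores <- vapply(seq_len(n_null), function(i)
    mean_cscore(generate_null(mat, algorithm)), numeric(1))
  mu <- mean(null_scores)
  sdev <- sd(null_scores)
  ses <- if (sdev == 0) NA_real_ else (obs - mu) / sdev
  if (sdev == 0)
    warning("null distribution is degenerate (sd = 0); SES undefined")
  structure(list(observed = obs, observed_norm = obs_norm,
                 null_mean = mu, null_sd = sdev, ses = ses,
                 p_greater = (1 + sum(null_scores >= obs)) / (1 + n_null),
                 p_less = (1 + sum(null_scores <= obs)) / (1 + n_null),
                 n_null = n_null, algorithm = algorithm, seed = seed),
            class = "nullmodel_report")
}

#' @export
print.nullmodel_report <- function(x, ...) {
  cat(sprintf(
    "C-score null-model report (%s, %d null matrices, seed %d)\n",
    x$algorithm, x$n_null, x$seed))
  cat(sprintf("  observed %.4f (normalized %.4f); null %.4f +/- %.4f\n",
              x$observed, x$observed_norm, x$null_mean, x$null_sd))
  cat(sprintf("  SES = %.3f; p(greater) = %.4g, p(less) = %.4g\n",
              x$ses, x$p_greater, x$p_less))
  invisible(x)
}
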