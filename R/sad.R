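#' Per-OTU dispersion index
#'
#' For one OTU's counts across samples: occurrence (number of samples with
#' count > 0), mean abundance and unbiased variance over ALL samples (zeros
#' included), the variance-to-mean ratio (VMR; 1 under a Poisson
#' distribution), and the dispersion statistic VMR x occurrence that is
#' compared against chi-square confidence limits.
#'
#' @param x integer vector of counts across samples (length >= 2).
#' @return named list: occurrence, mean, vmr, dispersion_stat.
#' @export
dispersion_index <- function(x) {
  if (length(x) < 2) stop("need counts from at least 2 samples")
  occ <- sum(x > 0)
  m <- mean(x)
  vmr <- if (m == 0) 0 else var(x) / m
  list(occurrence = occ, mean = m, vmr = vmr, dispersion_stat = vmr * occ)
}

#' Chi-square confidence limits for the dispersion statistic
#'
#' @param occurrence per-OTU occurrence (samples with count > 0).
#' @param n_samples total number of samples (needed for the
#'   `n_samples_minus_1` convention).
#' @param quantiles lower/upper quantiles of the band (default central 95%).
#' @param df_convention how degrees of freedom are derived: `"occurrence"`
#'   (default, literal to the statistic VMR x occurrence),
#'   `"occurrence_minus_1"`, or `"n_samples_minus_1"` (the classical
#'   index-of-dispersion test).
#' @return c(lower, upper) chi-square quantiles, or c(NA, NA) when the
#'   implied df falls below 1 (such OTUs are forced satellite).
#' @export
chi2_limits <- function(occurrence, n_samples = NULL,
                        quantiles = c(0.025, 0.975),
                        df_convention = c("occurrence", "occurrence_minus_1",
                                          "n_samples_minus_1")) {
  df_convention <- match.arg(df_convention)
  df <- switch(df_convention,
               occurrence = occurrence,
               occurrence_minus_1 = occurrence - 1,
               n_samples_minus_1 = {
                 if (is.null(n_samples))
                   stop("n_samples required for this df convention")
                 n_samples - 1
               })
  if (any(df < 1)) {
    lims <- cbind(lower = rep(NA_real_, length(df)),
                  upper = rep(NA_real_, length(df)))
    ok <- df >= 1
    lims[ok, 1] <- qchisq(quantiles[1], df[ok])
    lims[ok, 2] <- qchisq(quantiles[2], df[ok])
    if (length(df) == 1) return(c(lower = lims[1, 1], upper = lims[1, 2]))
    return(lims)
  }
  if (length(df) == 1)
    return(c(lower = qchisq(quantiles[1], df), upper = qchisq(quantiles[2], df)))
  cbind(lower = qchisq(quantiles[1], df), upper = qchisq(quantiles[2], df))
}

#' Partition the species abundance distribution into core and satellite OTUs
#'
#' An OTU is "core" when its dispersion statistic (VMR x occurrence) exceeds
#' the upper chi-square confidence limit — i.e. it is more aggregated across
#' samples than a Poisson (randomly dispersed) taxon. Everything else,
#' including underdispersed OTUs below the lower limit, is "satellite".
#' Best run on a rarefied table; uneven column sums are flagged.
#'
#' @param table an [abundance_table()].
#' @param config a [benthonet_config()] (chi-square band and df convention).
#' @return object of class `sad_partition`: a data.frame `records` with
#'   columns otu_id, occurrence, mean, vmr, dispersion_stat, chi2_lower,
#'   chi2_upper, class; plus counts n_core, n_satellite and the core read
#'   fraction.
#' @export
partition_sad <- function(table, config = benthonet_config()) {
  m <- unclass(table)
  n <- ncol(m)
  if (length(unique(colSums(m))) > 1)
    message("column sums are unequal; consider rarefying before partitioning")
  occ <- rowSums(m > 0)
  mu <- rowMeans(m)
  v <- rowSums((m - mu)^2) / (n - 1)
  vmr <- ifelse(mu == 0, 0, v / mu)
  stat <- vmr * occ
  lims <- chi2_limits(occ, n_samples = n,
                      quantiles = c(config$chi2_lower, config$chi2_upper),
                      df_convention = config$df_convention)
  if (is.null(dim(lims))) lims <- matrix(lims, nrow = 1)
  cls <- ifelse(!is.na(lims[, 2]) & stat > lims[, 2], "core", "satellite")
  if (any(occ == 0))
    warning(sprintf("%d all-zero OTU(s) classified satellite", sum(occ == 0)))
  rec <- data.frame(otu_id = rownames(m), occurrence = occ, mean = mu,
                    vmr = vmr, dispersion_stat = stat,
                    chi2_lower = lims[, 1], chi2_upper = lims[, 2],
                    class = cls, row.names = NULL,
                    stringsAsFactors = FALSE)
  core_reads <- sum(m[cls == "core", , drop = FALSE])
  structure(list(records = rec,
                 n_core = sum(cls == "core"),
                 n_satellite = sum(cls == "satellite"),
                 core_read_fraction = core_reads / sum(m),
                 quantiles = c(config$chi2_lower, config$chi2_upper),
                 df_convention = config$df_convention,
                 n_samples = n),
            class = "sad_partition")
}

#' @export
print.sad_partition <- function(x, ...) {
  cat(sprintf(
    "sad_partition: %d core / %d satellite OTUs (%.1f%% core, %.1f%% of reads)\n",
    x$n_core, x$n_satellite,
    100 * x$n_core / (x$n_core + x$n_satellite),
    100 * x$core_read_fraction))
  invisible(x)
}

#' Core OTU identifiers of a partition
#' @param partition a `sad_partition`.
#' @return character vector of core OTU ids.
#' @export
core_otus <- function(partition) {
  partition$records$otu_id[partition$records$class == "core"]
}

#' Abundance-occupancy relationship
#'
#' Spearman correlation between log mean abundance and occurrence across all
#' OTUs — the classical positive macro-ecological trend. Mean abundances of
#' zero are handled by a pseudocount.
#'
#' @param partition a `sad_partition`.
#' @param pseudocount added to mean abundance before log.
#' @return list(rho, p), both NA when occurrence is constant.
#' @export
abundance_occupancy_stats <- function(partition, pseudocount = 1e-6) {
  rec <- partition$records
  if (nrow(rec) < 3) stop("need at least 3 OTUs")
  if (length(unique(rec$occurrence)) == 1 ||
      length(unique(rec$mean)) == 1)
    return(list(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(
    cor.test(log(rec$mean + pseudocount), rec$occurrence,
             method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Taxonomic breakdown of core and satellite reads
#'
#' Read-weighted relative abundance of each taxon (at the requested rank,
#' class by default) within the core and satellite groups; minor taxa below
#' `min_fraction` are pooled into "Other". Fractions sum to 1 per group.
#'
#' @param table an [abundance_table()].
#' @param partition a `sad_partition` on the same table.
#' @param taxonomy taxonomy data.frame ([read_taxonomy()]); OTUs without an
#'   entry become "Unclassified".
#' @param level taxonomy column to aggregate at (default "class").
#' @param min_fraction pooling cutoff for minor taxa (default 0.05).
#' @return data.frame: group, taxon, fraction.
#' @export
taxonomy_breakdown <- function(table, partition, taxonomy, level = "class",
                               min_fraction = 0.05) {
  m <- unclass(table)
  rec <- partition$records
  lev <- setNames(rep("Unclassified", nrow(m)), rownames(m))
  if (level %in% names(taxonomy)) {
    hit <- intersect(rownames(m), taxonomy$otu_id)
    lev[hit] <- taxonomy[[level]][match(hit, taxonomy$otu_id)]
  } else stop("taxonomy has no column '", level, "'")
  out <- do.call(rbind, lapply(c("core", "satellite"), function(g) {
    ids <- rec$otu_id[rec$class == g]
    if (length(ids) == 0) return(NULL)
    reads <- rowSums(m[ids, , drop = FALSE])
    agg <- tapply(reads, lev[ids], sum)
    frac <- agg / sum(agg)
    pooled <- names(frac)[frac < min_fraction]
    if (length(pooled) > 1) {
      other <- sum(frac[pooled])
      frac <- c(frac[!names(frac) %in% pooled], Other = other)
    }
    data.frame(group = g, taxon = names(frac), fraction = as.numeric(frac),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}
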