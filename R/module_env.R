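#' Module eigengene by singular value decomposition
#'
#' OTU profiles are standardized (zero mean, unit variance across samples;
#' constant rows dropped) and the eigengene is the first right-singular
#' vector of the standardized OTU x sample matrix — a unit-norm per-sample
#' summary of the module's abundance profile. Its sign is oriented to
#' correlate positively with the module's mean standardized profile, and
#' the variance explained is the first squared singular value over the
#' total.
#'
#' @param table an [abundance_table()] (or matrix) restricted to one
#'   module's OTUs; needs >= 2 non-constant OTUs and >= 3 samples.
#' @return list of class `eigengene`: `scores` (named per-sample vector,
#'   unit norm), `variance_explained`, `n_otus`.
#' @export
module_eigengene <- function(table) {
  m <- unclass(table)
  if (ncol(m) < 3) stop("need at least 3 samples")
  keep <- apply(m, 1, sd) > 0
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2) stop("fewer than 2 non-constant OTU profiles")
  z <- t(scale(t(m)))
  sv <- svd(z)
  e <- sv$v[, 1]
  if (cor(e, colMeans(z)) < 0) e <- -e
  list(scores = setNames(e, colnames(m)),
       variance_explained = sv$d[1]^2 / sum(sv$d^2),
       n_otus = nrow(m))
}

#' Eigengenes for every detected module
#'
#' @param table full [abundance_table()].
#' @param net a `cooccurrence_network` with modules detected.
#' @param min_otus skip modules smaller than this (default 2).
#' @return named list of [module_eigengene()] results, one per module id.
#' @export
module_eigengenes <- function(table, net, min_otus = 2) {
  if (is.null(net$modules)) stop("run detect_modules() first")
  ids <- split(names(net$modules), net$modules)
  ids <- ids[vapply(ids, length, integer(1)) >= min_otus]
  out <- lapply(ids, function(members) {
    members <- intersect(members, rownames(table))
    tryCatch(module_eigengene(unclass(table)[members, , drop = FALSE]),
             error = function(e) NULL)
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Correlate module eigengenes with environmental variables
#'
#' Pearson correlations (Spearman selectable) between each module eigengene
#' and each transformed environmental variable, over complete-case samples.
#' Default transforms log-transform salinity and fluoranthene and square the
#' F/P ratio.
#'
#' @param eigengenes output of [module_eigengenes()].
#' @param metadata sample metadata (rows matched by sample_id to eigengene
#'   names).
#' @param variables which metadata columns to correlate.
#' @param transforms named transform map (see [benthonet_config()]).
#' @param method "pearson" or "spearman".
#' @return data.frame: module, variable, r, p.
#' @export
correlate_env <- function(eigengenes, metadata,
                          variables = c("salinity", "temperature",
                                        "latitude", "psd", "toc",
                                        "fluoranthene"),
                          transforms = default_transforms(),
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  out <- list()
  for (mod in names(eigengenes)) {
    e <- eigengenes[[mod]]$scores
    idx <- match(names(e), metadata$sample_id)
    for (v in variables) {
      if (!v %in% names(metadata)) next
      x <- apply_transform(metadata[[v]][idx], transforms[[v]])
      ok <- !is.na(x) & !is.na(e)
      r <- p <- NA_real_
      if (sum(ok) >= 4 && sd(x[ok]) > 0) {
        ct <- suppressWarnings(cor.test(e[ok], x[ok], method = method,
                                        exact = FALSE))
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1]] <- data.frame(module = mod, variable = v,
                                           r = r, p = p)
    }
  }
  do.call(rbind, out)
}

#' PERMANOVA variance partitioning of community composition
#'
#' Sequential (ordered-term) permutational multivariate ANOVA on a distance
#' matrix, via vegan's adonis2: pseudo-F per term and p-values by free
#' permutation of sample labels. Samples with missing predictors are
#' dropped (complete cases), and terms left constant after filtering are
#' dropped with a warning.
#'
#' @param d a `dist` or symmetric distance matrix over samples.
#' @param metadata data.frame with `sample_id` and the predictor columns.
#' @param terms ordered character vector of predictor names.
#' @param n_perm number of permutations (field-standard default 1000).
#' @param seed integer seed.
#' @param transforms transform map applied to predictors before fitting.
#' @return data.frame of class `permanova_result`: term, df, R2, F, p, with
#'   Residual and Total rows; attribute `n` = samples used.
#' @export
permanova <- function(d, metadata, terms, n_perm = 1000, seed = 1L,
                      transforms = default_transforms()) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix must be symmetric")
  ids <- rownames(dm)
  if (is.null(ids)) ids <- metadata$sample_id[seq_len(nrow(dm))]
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  for (v in terms)
    md[[v]] <- apply_transform(md[[v]], transforms[[v]])
  ok <- complete.cases(md[, terms, drop = FALSE])
  md <- md[ok, , drop = FALSE]
  dm <- dm[ok, ok]
  message(sprintf("PERMANOVA on %d complete-case samples", sum(ok)))
  drop <- vapply(terms, function(v) length(unique(md[[v]])) <= 1,
                 logical(1))
  if (any(drop)) {
    warning("dropping constant term(s): ",
            paste(terms[drop], collapse = ", "))
    terms <- terms[!drop]
  }
  if (length(terms) == 0) stop("no non-constant terms left")
  form <- stats::as.formula(paste("as.dist(dm) ~",
                                  paste(terms, collapse = " + ")))
  set.seed(seed)
  fit <- vegan::adonis2(form, data = md, permutations = n_perm,
                        by = "terms")
  res <- data.frame(term = rownames(fit), df = fit$Df, R2 = fit$R2,
                    F = fit$F, p = fit$`Pr(>F)`, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "n") <- sum(ok)
  attr(res, "n_perm") <- n_perm
  class(res) <- c("permanova_result", "data.frame")
  res
}

#' Bray-Curtis community distance
#'
#' Community dissimilarity between samples on (ideally rarefied) counts.
#'
#' @param table an [abundance_table()].
#' @return a `dist` over samples.
#' @export
community_distance <- function(table) {
  vegan::vegdist(t(unclass(table)), method = "bray")
}
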