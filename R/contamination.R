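#' Sum of the 9 guideline-covered PAH compounds
#'
#' Arithmetic sum of fluoranthene, pyrene, anthracene, benz[a]anthracene,
#' benzo[a]pyrene, chrysene, dibenz[a,h]anthracene, fluorene and
#' phenanthrene, the nine compounds for which sediment quality guidelines
#' exist. Benzo[g,h,i]perylene and indeno[1,2,3,c-d]pyrene are excluded.
#'
#' @param profile named numeric vector (or 1-row data.frame) of PAH
#'   concentrations in ug/kg DW; names must cover [pah9_compounds()].
#' @return the sum, or NA when any of the 9 compounds is missing.
#' @export
pah9_sum <- function(profile) {
  profile <- unlist(profile)
  need <- pah9_compounds()
  if (!all(need %in% names(profile)) || anyNA(profile[need])) {
    message("PAH9 sum: missing compound(s): ",
            paste(setdiff(need, names(profile)[!is.na(profile)]),
                  collapse = ", "))
    return(NA_real_)
  }
  sum(profile[need])
}

#' Diagnostic PAH source ratios
#'
#' P/A = phenanthrene/anthracene and F/P = fluoranthene/pyrene discriminate
#' combustion-derived (pyrogenic) from fuel-derived (petrogenic) PAH inputs:
#' P/A < 10 together with F/P > 1 indicates a pyrogenic source, P/A > 10
#' with F/P < 1 a petrogenic one; any other combination is indeterminate.
#'
#' @param profile named numeric vector of PAH concentrations.
#' @return list(pa, fp, source) where source is "pyrogenic", "petrogenic"
#'   or "indeterminate"; ratios are NA when a denominator is 0 or missing.
#' @export
diagnostic_ratios <- function(profile) {
  profile <- unlist(profile)
  g <- function(x) if (x %in% names(profile)) profile[[x]] else NA_real_
  pa <- if (!is.na(g("anthracene")) && g("anthracene") > 0)
    g("phenanthrene") / g("anthracene") else NA_real_
  fp <- if (!is.na(g("pyrene")) && g("pyrene") > 0)
    g("fluoranthene") / g("pyrene") else NA_real_
  source <- "indeterminate"
  if (!is.na(pa) && !is.na(fp)) {
    if (pa < 10 && fp > 1) source <- "pyrogenic"
    else if (pa > 10 && fp < 1) source <- "petrogenic"
  }
  list(pa = pa, fp = fp, source = source)
}

#' Sediment quality guideline table
#'
#' Guideline threshold concentrations (ug/kg DW) per compound for the PEL
#' (probable effect level), ERL (effect range low) and T50 (50% toxicity)
#' guidelines. Values are user-supplied; the package hard-codes none.
#'
#' @param ... named numeric vectors, one per guideline, each named by
#'   compound (covering [pah9_compounds()]).
#' @return named list of guideline vectors with class `sqg_table`.
#' @export
sqg_table <- function(...) {
  g <- list(...)
  if (length(g) == 0) return(structure(list(), class = "sqg_table"))
  for (nm in names(g)) {
    if (any(g[[nm]] <= 0, na.rm = TRUE))
      stop("guideline '", nm, "' has non-positive thresholds")
  }
  structure(g, class = "sqg_table")
}

#' Guideline exceedance flags
#'
#' Compares a sample's 9-PAH sum with each guideline's own 9-compound sum.
#' Exceedance is strict (`>`); a sum exactly at the threshold does not
#' exceed. Guidelines missing any of the 9 compounds yield NA.
#'
#' @param pah9 the sample's 9-PAH sum ([pah9_sum()]).
#' @param sqg an [sqg_table()].
#' @return named logical vector, one flag per guideline (NA when
#'   incomputable).
#' @export
guideline_exceedance <- function(pah9, sqg) {
  if (length(sqg) == 0) return(setNames(logical(0), character(0)))
  vapply(sqg, function(thr) {
    s <- pah9_sum(thr)
    if (is.na(s) || is.na(pah9)) NA else pah9 > s
  }, logical(1))
}

#' Classify sites as contaminated or pristine by hierarchical clustering
#'
#' Within each region independently, samples with complete 11-PAH vectors
#' are clustered by hierarchical agglomerative classification (Ward linkage
#' on Euclidean distances of log10(x+1)-transformed concentrations by
#' default) and the tree is cut at k = 2; the cluster with the higher mean
#' 9-PAH sum is labeled "contaminated". Samples with incomplete PAH data get
#' label NA.
#'
#' @param metadata sample metadata data.frame with `sample_id`, the 11 PAH
#'   columns and optionally a `region` column (used as the independent
#'   partition when `by_region = TRUE`).
#' @param config a [benthonet_config()] (linkage and transform knobs).
#' @param by_region cluster each region separately (default TRUE when a
#'   region column is present).
#' @return object of class `contamination_call`: data.frame `calls`
#'   (sample_id, region, cluster, label, pah9, pa, fp, source) plus the
#'   per-region hclust trees.
#' @export
classify_sites_hac <- function(metadata, config = benthonet_config(),
                               by_region = "region" %in% names(metadata)) {
  comp <- pah_compounds()
  miss <- setdiff(comp, names(metadata))
  if (length(miss) > 0)
    stop("metadata lacks PAH column(s): ", paste(miss, collapse = ", "))
  region <- if (by_region) metadata$region else rep("all", nrow(metadata))
  pah <- as.matrix(metadata[, comp])
  complete <- complete.cases(pah)
  calls <- data.frame(sample_id = metadata$sample_id, region = region,
                      cluster = NA_integer_, label = NA_character_,
                      stringsAsFactors = FALSE)
  calls$pah9 <- apply(pah, 1, pah9_sum)
  rat <- apply(pah, 1, function(p) unlist(diagnostic_ratios(p)[c("pa", "fp")]))
  calls$pa <- as.numeric(rat["pa", ])
  calls$fp <- as.numeric(rat["fp", ])
  calls$source <- apply(pah, 1, function(p) diagnostic_ratios(p)$source)
  trees <- list()
  for (r in unique(region)) {
    idx <- which(region == r & complete)
    if (length(idx) < 4)
      stop("region '", r, "' has fewer than 4 samples with complete PAH data")
    x <- pah[idx, , drop = FALSE]
    if (config$hac_transform == "log10p1") x <- log10(x + 1)
    if (all(dist(x) == 0))
      stop("no separation: all PAH profiles identical in region '", r, "'")
    hc <- hclust(dist(x), method = config$hac_linkage)
    cl <- cutree(hc, k = 2)
    m1 <- mean(calls$pah9[idx][cl == 1], na.rm = TRUE)
    m2 <- mean(calls$pah9[idx][cl == 2], na.rm = TRUE)
    hi <- if (m1 >= m2) 1 else 2
    calls$cluster[idx] <- cl
    calls$label[idx] <- ifelse(cl == hi, "contaminated", "pristine")
    trees[[r]] <- hc
  }
  structure(list(calls = calls, trees = trees,
                 linkage = config$hac_linkage,
                 transform = config$hac_transform),
            class = "contamination_call")
}

#' @export
print.contamination_call <- function(x, ...) {
  tab <- table(x$calls$label, useNA = "ifany")
  cat("contamination_call:",
      paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Export an HAC dendrogram as Newick text
#'
#' @param call a `contamination_call`.
#' @param region which region's tree.
#' @param path output file.
#' @export
write_dendrogram <- function(call, region, path) {
  phy <- ape::as.phylo(call$trees[[region]])
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Two-group Wilcoxon-Mann-Whitney comparison
#'
#' Two-sided rank-sum test; exact enumeration when both groups have n <= 8
#' and no ties, otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y numeric vectors (each n >= 2), e.g. the 9-PAH sums of
#'   contaminated vs. pristine samples.
#' @return list(u, p): the Mann-Whitney U statistic (for `x`) and two-sided
#'   p-value.
#' @export
compare_groups_ranksum <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations")
  exact <- length(x) <= 8 && length(y) <= 8 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Group collinear variables and choose proxies
#'
#' Builds a graph over variables with edges where |Spearman rho| meets the
#' threshold (complete-case pairwise); connected components form collinear
#' groups, represented by a single proxy each — by default the member with
#' the highest mean |rho| to the rest of its group. Explicit overrides
#' mirror field practice (fluoranthene standing for the 10 other
#' PAHs, salinity for latitude and temperature).
#'
#' @param metadata data.frame of samples x variables (non-numeric columns
#'   ignored).
#' @param variables which columns to consider (default: all numeric).
#' @param threshold |Spearman rho| grouping threshold (default 0.75).
#' @param proxies character vector of variable names forced to be their
#'   group's proxy.
#' @return list of class `collinearity_groups`: `groups` (list of character
#'   vectors), `proxies` (one name per group), `rho` (the correlation
#'   matrix).
#' @export
collinearity_proxies <- function(metadata, variables = NULL,
                                 threshold = 0.75, proxies = NULL) {
  num <- vapply(metadata, is.numeric, logical(1))
  vars <- if (is.null(variables)) names(metadata)[num] else variables
  x <- metadata[, vars, drop = FALSE]
  const <- vapply(x, function(v) length(unique(v[!is.na(v)])) <= 1,
                  logical(1))
  if (any(const)) {
    warning("excluding constant variable(s): ",
            paste(vars[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
    vars <- vars[!const]
  }
  if (sum(complete.cases(x)) < 3) stop("need at least 3 complete cases")
  if (ncol(x) == 1) {
    return(structure(list(groups = list(vars), proxies = vars,
                          rho = matrix(1, 1, 1, dimnames = list(vars, vars)),
                          threshold = threshold),
                     class = "collinearity_groups"))
  }
  rho <- suppressWarnings(
    cor(x, method = "spearman", use = "pairwise.complete.obs"))
  adj <- abs(rho) >= threshold
  diag(adj) <- FALSE
  adj[is.na(adj)] <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(vars, comp)
  names(groups) <- NULL
  chosen <- vapply(groups, function(gr) {
    forced <- intersect(proxies, gr)
    if (length(forced) > 0) return(forced[1])
    if (length(gr) == 1) return(gr)
    score <- vapply(gr, function(v)
      mean(abs(rho[v, setdiff(gr, v)])), numeric(1))
    gr[which.max(score)]
  }, character(1))
  structure(list(groups = groups, proxies = chosen, rho = rho,
                 threshold = threshold),
            class = "collinearity_groups")
}
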