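#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis pipeline in one validated
#' object. Defaults are the standard analysis settings: edge retention at Spearman
#' |rho| >= 0.6 with p < 0.001, 5000 null matrices under the
#' site-frequency-preserving algorithm, the central 95% chi-square band for
#' the dispersion-index test, a 0.75 collinearity grouping threshold and 1000
#' PERMANOVA permutations.
#'
#' @param rho_edge_threshold minimum |Spearman rho| for a retained edge.
#' @param p_edge_threshold maximum p-value for a retained edge.
#' @param prevalence_min_fraction OTUs must be present in at least this
#'   fraction of samples to enter the association step.
#' @param n_null_matrices number of null matrices for the C-score test.
#' @param null_algorithm one of `"fixed_site_frequencies"` (column totals
#'   preserved, rows equiprobable), `"fixed_occupancies"` (row totals
#'   preserved) or `"swap"` (both margins preserved by checkerboard swaps).
#' @param chi2_lower,chi2_upper quantiles of the chi-square band used to
#'   classify dispersion statistics.
#' @param df_convention degrees of freedom for the chi-square limits:
#'   `"occurrence"` (default), `"occurrence_minus_1"` or `"n_samples_minus_1"`.
#' @param collinearity_threshold |Spearman rho| at or above which variables
#'   are grouped as collinear.
#' @param permutations number of PERMANOVA permutations.
#' @param random_seed master seed recorded in all outputs.
#' @param transforms named list mapping metadata variable names to transform
#'   functions or the strings `"log10"`, `"log1p"`, `"sqrt"`, `"square"`,
#'   `"identity"`. Defaults apply log10 to salinity and fluoranthene and a
#'   square transform to the F/P ratio.
#' @param sqg sediment quality guideline table (see [sqg_table()]), or `NULL`.
#' @param hac_linkage hclust agglomeration method for site classification.
#' @param hac_transform transform applied to PAH concentrations before
#'   clustering (`"log10p1"` or `"identity"`).
#'
#' @return an object of class `benthonet_config` (a validated list).
#' @export
benthonet_config <- function(rho_edge_threshold = 0.6,
                             p_edge_threshold = 0.001,
                             prevalence_min_fraction = 0.25,
                             n_null_matrices = 5000,
                             null_algorithm = c("fixed_site_frequencies",
                                                "fixed_occupancies", "swap"),
                             chi2_lower = 0.025,
                             chi2_upper = 0.975,
                             df_convention = c("occurrence",
                                               "occurrence_minus_1",
                                               "n_samples_minus_1"),
                             collinearity_threshold = 0.75,
                             permutations = 1000,
                             random_seed = 1L,
                             transforms = default_transforms(),
                             sqg = NULL,
                             hac_linkage = "ward.D2",
                             hac_transform = c("log10p1", "identity")) {
  null_algorithm <- match.arg(null_algorithm)
  df_convention <- match.arg(df_convention)
  hac_transform <- match.arg(hac_transform)
  stopifnot(is.numeric(rho_edge_threshold), length(rho_edge_threshold) == 1)
  if (rho_edge_threshold < 0 || rho_edge_threshold > 1)
    stop("rho_edge_threshold must lie in [0, 1]")
  if (p_edge_threshold <= 0 || p_edge_threshold > 1)
    stop("p_edge_threshold must lie in (0, 1]")
  if (prevalence_min_fraction < 0 || prevalence_min_fraction > 1)
    stop("prevalence_min_fraction must lie in [0, 1]")
  if (chi2_lower < 0 || chi2_upper > 1 || chi2_lower > chi2_upper)
    stop("chi-square quantiles must satisfy 0 <= lower <= upper <= 1")
  if (collinearity_threshold <= 0 || collinearity_threshold > 1)
    stop("collinearity_threshold must lie in (0, 1]")
  if (n_null_matrices < 1) stop("n_null_matrices must be positive")
  if (permutations < 1) stop("permutations must be positive")
  structure(list(
    rho_edge_threshold = rho_edge_threshold,
    p_edge_threshold = p_edge_threshold,
    prevalence_min_fraction = prevalence_min_fraction,
    n_null_matrices = as.integer(n_null_matrices),
    null_algorithm = null_algorithm,
    chi2_lower = chi2_lower,
    chi2_upper = chi2_upper,
    df_convention = df_convention,
    collinearity_threshold = collinearity_threshold,
    permutations = as.integer(permutations),
    random_seed = as.integer(random_seed),
    transforms = transforms,
    sqg = sqg,
    hac_linkage = hac_linkage,
    hac_transform = hac_transform
  ), class = "benthonet_config")
}

#' Default variable transforms for environment correlations
#'
#' Salinity and fluoranthene are log-transformed and the F/P diagnostic ratio
#' is squared, to improve linearity and homoscedasticity with the community
#' responses; all other variables are left untouched.
#'
#' @return named list of transform specifications.
#' @export
default_transforms <- function() {
  list(salinity = "log10", fluoranthene = "log10", fp_ratio = "square")
}

#' @export
print.benthonet_config <- function(x, ...) {
  cat("benthonet pipeline configuration\n")
  cat(sprintf("  edge gate: |rho| >= %g, p < %g (prevalence >= %g)\n",
              x$rho_edge_threshold, x$p_edge_threshold,
              x$prevalence_min_fraction))
  cat(sprintf("  null model: %s, %d matrices\n", x$null_algorithm,
              x$n_null_matrices))
  cat(sprintf("  chi-square band: (%g, %g), df = %s\n", x$chi2_lower,
              x$chi2_upper, x$df_convention))
  cat(sprintf("  collinearity threshold: %g; permutations: %d; seed: %d\n",
              x$collinearity_threshold, x$permutations, x$random_seed))
  invisible(x)
}

apply_transform <- function(x, spec) {
  if (is.null(spec)) return(x)
  if (is.function(spec)) return(spec(x))
  switch(spec,
         log10 = log10(x),
         log1p = log1p(x),
         log10p1 = log10(x + 1),
         sqrt = sqrt(x),
         square = x^2,
         identity = x,
         stop("unknown transform: ", spec))
}
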