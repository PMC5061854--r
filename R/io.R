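#' Construct and validate an OTU abundance table
#'
#' The pipeline's central object: a non-negative integer count matrix with
#' OTUs as rows and samples as columns. Identifiers must be unique and at
#' least 2 OTUs and 2 samples are required for any downstream analysis.
#'
#' @param counts numeric matrix of non-negative counts, OTUs x samples, with
#'   row and column names.
#' @return the validated matrix with class `abundance_table`.
#' @export
abundance_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry OTU row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is.numeric(counts))
    stop("counts must be numeric")
  bad <- which(is.na(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or missing count at OTU '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("abundance table needs at least 2 OTUs and 2 samples")
  storage.mode(counts) <- "double"
  class(counts) <- c("abundance_table", "matrix", "array")
  counts
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d OTUs x %d samples, %s reads\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Read an OTU abundance table from TSV/CSV
#'
#' Internally tables are OTU-rows x sample-columns; files in the transposed
#' convention (samples as rows) are accepted via `orientation`.
#'
#' @param path path to a tab- or comma-separated file with row and column
#'   labels. The delimiter is inferred from the extension (`.csv` = comma).
#' @param orientation `"otus_as_rows"` (default) or `"samples_as_rows"`.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path,
                                 orientation = c("otus_as_rows",
                                                 "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                   check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df, 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric cell at row '%s', column '%s' of %s",
                 rownames(df)[bad[1, 1]], colnames(df)[bad[1, 2]], path))
  }
  if (orientation == "samples_as_rows") m <- t(m)
  tab <- abundance_table(m)
  message(sprintf("read %d OTUs x %d samples (%d reads) from %s",
                  nrow(tab), ncol(tab), sum(tab), path))
  tab
}

#' Write an abundance table to TSV
#'
#' @param table an [abundance_table()].
#' @param path output path.
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(otu_id = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU taxonomy table
#'
#' Expects columns `otu_id`, `domain`, and optional ranked lineage columns
#' (e.g. phylum, class). Missing ranks and domains become "Unclassified".
#'
#' @param path TSV path.
#' @return data.frame with at least columns otu_id, domain.
#' @export
read_taxonomy <- function(path) {
  tax <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("otu_id", "domain") %in% names(tax)))
    stop("taxonomy table needs columns 'otu_id' and 'domain'")
  if (anyDuplicated(tax$otu_id)) stop("duplicate otu_id in taxonomy table")
  tax[is.na(tax)] <- "Unclassified"
  tax$domain[!tax$domain %in% c("Bacteria", "Archaea", "Eukarya")] <-
    "Unclassified"
  tax
}

#' Read a sample metadata table
#'
#' Expects a TSV with a `sample_id` column plus environmental variables
#' (salinity, temperature, latitude, psd, toc, optional region and
#' a_priori_label) and the 11 per-compound PAH concentrations in ug/kg dry
#' weight. Missing values stay `NA` and are propagated; model fits later use
#' complete cases only.
#'
#' @param path TSV path.
#' @return data.frame keyed by sample_id.
#' @export
read_metadata <- function(path) {
  meta <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE, comment.char = "")
  if (!"sample_id" %in% names(meta))
    stop("metadata needs a 'sample_id' column")
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  pah <- intersect(pah_compounds(), names(meta))
  for (p in pah) {
    if (any(meta[[p]] < 0, na.rm = TRUE))
      stop("negative PAH concentration in column ", p)
  }
  meta
}

#' Write sample metadata to TSV
#' @param meta metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The 11 PAH compounds tracked by the pipeline
#'
#' @return character vector of compound names (snake_case).
#' @export
pah_compounds <- function() {
  c("fluoranthene", "fluorene", "pyrene", "anthracene",
    "benz_a_anthracene", "benzo_a_pyrene", "benzo_ghi_perylene",
    "chrysene", "dibenz_ah_anthracene", "indeno_123cd_pyrene",
    "phenanthrene")
}

#' The 9 PAH compounds covered by sediment quality guidelines
#'
#' The guideline sum excludes benzo[g,h,i]perylene and
#' indeno[1,2,3,c-d]pyrene, for which no guideline values exist.
#'
#' @return character vector of 9 compound names.
#' @export
pah9_compounds <- function() {
  setdiff(pah_compounds(), c("benzo_ghi_perylene", "indeno_123cd_pyrene"))
}

#' Rarefy samples to even depth
#'
#' Random subsampling without replacement to a fixed depth per sample.
#' Samples whose total is below `depth` are dropped with a warning. The same
#' seed always yields the same subsample.
#'
#' @param table an [abundance_table()].
#' @param depth target reads per sample.
#' @param seed integer seed.
#' @return rarefied [abundance_table()] whose retained columns each sum to
#'   `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  totals <- colSums(table)
  keep <- totals >= depth
  if (!all(keep))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(colnames(table)[!keep], collapse = ", ")))
  if (sum(keep) < 2) stop("fewer than 2 samples reach the rarefaction depth")
  m <- unclass(table)[, keep, drop = FALSE]
  set.seed(seed)
  out <- apply(m, 2, function(x) {
    if (sum(x) == depth) return(x)
    reads <- rep.int(seq_along(x), x)
    picked <- sample(reads, depth, replace = FALSE)
    tabulate(picked, nbins = length(x))
  })
  rownames(out) <- rownames(m)
  abundance_table(out)
}

#' Convert counts to a presence/absence matrix
#'
#' @param table an [abundance_table()] or numeric matrix.
#' @return binary 0/1 matrix (rows = OTUs/species, columns = samples/sites).
#' @export
presence_matrix <- function(table) {
  m <- (unclass(table) > 0) * 1L
  dimnames(m) <- dimnames(table)
  m
}

#' Export a co-occurrence network
#'
#' GraphML output carries node attributes (domain, core/satellite class,
#' module id, degree) and edge attributes (rho, p, sign) so the network can
#' be laid out in external viewers (e.g. Gephi). The edge-list TSV has
#' columns otu_a, otu_b, rho, p, sign.
#'
#' @param net a `cooccurrence_network` (see [build_network()]).
#' @param path output path.
#' @param format `"graphml"` or `"edge_list_tsv"`.
#' @export
write_network <- function(net, path, format = c("graphml", "edge_list_tsv")) {
  format <- match.arg(format)
  if (nrow(net$edges) == 0) warning("writing an empty network to ", path)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    write.table(net$edges[, c("otu_a", "otu_b", "rho", "p", "sign")],
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network back from GraphML
#' @param path GraphML file.
#' @return igraph graph object.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
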