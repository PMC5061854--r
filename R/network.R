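#' Assemble a co-occurrence network from a filtered edge table
#'
#' Nodes are the OTUs with at least one retained edge (isolated OTUs are
#' excluded); node attributes carry domain and class-level taxonomy, edge
#' attributes carry rho, p and sign. Duplicated unordered pairs are
#' collapsed with a warning.
#'
#' @param edges an [edge_table()] (or data.frame with otu_a, otu_b, rho, p,
#'   sign).
#' @param taxonomy optional taxonomy data.frame; unresolvable OTUs become
#'   "Unclassified".
#' @return object of class `cooccurrence_network`: the igraph `graph`, the
#'   `edges` data.frame, `nodes` data.frame (otu_id, domain, class, degree),
#'   and per-domain node fractions.
#' @export
build_network <- function(edges, taxonomy = NULL) {
  if (nrow(edges) == 0) {
    warning("empty edge list: returning an empty network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = g,
                          edges = as.data.frame(edges),
                          nodes = data.frame(otu_id = character(),
                                             domain = character(),
                                             class = character(),
                                             degree = integer()),
                          domain_fractions = numeric(0),
                          modules = NULL),
                     class = "cooccurrence_network"))
  }
  key <- paste(pmin(edges$otu_a, edges$otu_b),
               pmax(edges$otu_a, edges$otu_b))
  if (anyDuplicated(key)) {
    warning("duplicate edge pair(s) collapsed")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("otu_a", "otu_b", "rho", "p", "sign")], directed = FALSE)
  ids <- igraph::V(g)$name
  dom <- cls <- rep("Unclassified", length(ids))
  if (!is.null(taxonomy)) {
    hit <- match(ids, taxonomy$otu_id)
    dom[!is.na(hit)] <- taxonomy$domain[hit[!is.na(hit)]]
    if ("class" %in% names(taxonomy))
      cls[!is.na(hit)] <- taxonomy$class[hit[!is.na(hit)]]
  }
  igraph::V(g)$domain <- dom
  igraph::V(g)$class <- cls
  deg <- igraph::degree(g)
  igraph::V(g)$degree <- deg
  nodes <- data.frame(otu_id = ids, domain = dom, class = cls,
                      degree = as.integer(deg), stringsAsFactors = FALSE)
  message(sprintf("network: %d nodes, %d edges", length(ids), nrow(edges)))
  structure(list(graph = g, edges = as.data.frame(edges), nodes = nodes,
                 domain_fractions = table(dom) / length(ids),
                 modules = NULL),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (length(x$domain_fractions))
    cat("  domains:",
        paste(sprintf("%s %.0f%%", names(x$domain_fractions),
                      100 * as.numeric(x$domain_fractions)),
              collapse = ", "), "\n")
  invisible(x)
}

#' Detect network modules by modularity maximisation
#'
#' Louvain-style greedy modularity optimisation on the unweighted graph,
#' ignoring edge signs (correlation strength and direction play no role in
#' the partition). Deterministic for a given seed; modules are renumbered by
#' decreasing size.
#'
#' @param net a `cooccurrence_network`.
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed.
#' @return the network with `modules` set: named integer vector of module
#'   ids per node (also stored as a node attribute), plus `modularity`.
#' @export
detect_modules <- function(net, resolution = 1.0, seed = 1L) {
  if (igraph::ecount(net$graph) < 1) stop("network has no edges")
  g <- igraph::delete_edge_attr(net$graph, "rho")
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  renum <- setNames(seq_along(sizes), names(sizes))
  memb <- renum[as.character(memb)]
  names(memb) <- igraph::V(net$graph)$name
  net$modules <- memb
  igraph::V(net$graph)$module <- as.integer(memb)
  net$modularity <- igraph::modularity(net$graph, memb)
  net$nodes$module <- as.integer(memb[net$nodes$otu_id])
  net
}

#' Topological summary of a co-occurrence network
#'
#' Average degree (2E/N), average local clustering coefficient (nodes with
#' degree < 2 contribute 0), average shortest path over the largest
#' connected component, modularity Q of the detected (or component)
#' partition, and a descriptive scale-free diagnostic: slope and R-squared
#' of the log-log degree-distribution regression.
#'
#' @param net a `cooccurrence_network` (run [detect_modules()] first to get
#'   modularity of the detected partition; otherwise connected components
#'   are used).
#' @return object of class `topology_summary` (a list of indices).
#' @export
network_topology <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n < 2 || e == 0) {
    return(structure(list(n_nodes = n, n_edges = e, average_degree = NA,
                          average_clustering = NA, modularity = NA,
                          average_path = NA, powerlaw_slope = NA,
                          powerlaw_r2 = NA), class = "topology_summary"))
  }
  avg_deg <- 2 * e / n
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  loc[is.nan(loc)] <- 0
  memb <- net$modules
  if (is.null(memb)) memb <- igraph::components(g)$membership
  q <- igraph::modularity(g, memb)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  apl <- igraph::mean_distance(sub, directed = FALSE)
  deg <- igraph::degree(g)
  dd <- table(deg[deg > 0])
  slope <- r2 <- NA_real_
  if (length(dd) >= 3) {
    fit <- stats::lm(log10(as.numeric(dd)) ~ log10(as.numeric(names(dd))))
    slope <- unname(coef(fit)[2])
    r2 <- summary(fit)$r.squared
  }
  structure(list(n_nodes = n, n_edges = e, average_degree = avg_deg,
                 average_clustering = mean(loc), modularity = q,
                 average_path = apl, powerlaw_slope = slope,
                 powerlaw_r2 = r2),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0("topology: %d nodes, %d edges | <k> = %.2f, ",
                     "<C> = %.3f, Q = %.3f, <path> = %.2f\n"),
              x$n_nodes, x$n_edges, x$average_degree, x$average_clustering,
              x$modularity, x$average_path))
  invisible(x)
}

#' Compare contaminated vs. pristine co-occurrence networks
#'
#' Splits the sample set by contamination label, rebuilds the edge table and
#' network independently within each group from the same (core) OTU set, and
#' compares their topology. Per-node degree and local clustering
#' distributions are compared by two-sided rank-sum tests.
#'
#' @param table an [abundance_table()] restricted to the OTU set of interest
#'   (typically core OTUs).
#' @param labels named character vector (by sample id) or vector aligned to
#'   columns, with values "contaminated"/"pristine" (NA samples dropped).
#' @param config a [benthonet_config()].
#' @param taxonomy optional taxonomy for node attributes.
#' @param seed seed for module detection.
#' @return object of class `network_comparison`: per-group
#'   `topology_summary`, the two networks, and a data.frame of node-level
#'   rank-sum p-values (degree, clustering).
#' @export
split_and_compare <- function(table, labels, config = benthonet_config(),
                              taxonomy = NULL, seed = 1L) {
  if (!is.null(names(labels))) labels <- labels[colnames(table)]
  keep <- !is.na(labels)
  groups <- c("pristine", "contaminated")
  nets <- topo <- setNames(vector("list", 2), groups)
  stats_node <- setNames(vector("list", 2), groups)
  for (grp in groups) {
    cols <- which(keep & labels == grp)
    if (length(cols) < 4)
      stop("group '", grp, "' has fewer than 4 samples")
    sub <- abundance_table(unclass(table)[, cols, drop = FALSE])
    ed <- suppressMessages(edge_table(sub, config))
    net <- suppressMessages(suppressWarnings(build_network(ed, taxonomy)))
    if (nrow(net$edges) > 0) net <- detect_modules(net, seed = seed)
    nets[[grp]] <- net
    topo[[grp]] <- network_topology(net)
    if (nrow(net$nodes) > 0) {
      loc <- igraph::transitivity(net$graph, type = "local",
                                  isolates = "zero")
      loc[is.nan(loc)] <- 0
      stats_node[[grp]] <- data.frame(degree = net$nodes$degree,
                                      clustering = loc)
    }
  }
  cmp <- data.frame(metric = c("degree", "clustering"),
                    p = c(NA_real_, NA_real_))
  if (!is.null(stats_node$pristine) && !is.null(stats_node$contaminated) &&
      nrow(stats_node$pristine) > 0 && nrow(stats_node$contaminated) > 0) {
    for (i in 1:2) {
      met <- cmp$metric[i]
      x <- stats_node$pristine[[met]]
      y <- stats_node$contaminated[[met]]
      if (length(unique(c(x, y))) > 1)
        cmp$p[i] <- suppressWarnings(
          wilcox.test(x, y, exact = FALSE)$p.value)
    }
  } else {
    warning("a group yields an empty network; comparison is NA")
  }
  structure(list(networks = nets, topology = topo, node_tests = cmp),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  for (g in names(x$topology)) {
    cat(sprintf("%-12s", g)); print(x$topology[[g]])
  }
  print(x$node_tests)
  invisible(x)
}
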