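mk_edges <- function(pairs, rho = 0.9) {
  data.frame(otu_a = pairs[, 1], otu_b = pairs[, 2], rho = rho,
             p = 1e-6, sign = ifelse(rho >= 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

test_that("network assembly builds the right graph and deduplicates", {
  tri <- mk_edges(cbind(c("a", "b", "a"), c("b", "c", "c")))
  net <- suppressMessages(build_network(tri))
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$nodes$degree == 2))

  dup <- rbind(tri, tri[1, ])
  expect_warning(net2 <- suppressMessages(build_network(dup)), "duplicate")
  expect_equal(nrow(net2$edges), 3)

  expect_warning(empty <- suppressMessages(
    build_network(tri[integer(0), ])), "empty")
  expect_equal(nrow(empty$nodes), 0)

  # isolated OTUs never enter; node count = OTUs with >= 1 edge
  fx <- fixture_small()
  core <- names(fx$truth$otu_class)[fx$truth$otu_class == "core"]
  ct <- abundance_table(unclass(fx$table)[core, ])
  ed <- suppressMessages(edge_table(ct))
  net3 <- suppressMessages(build_network(ed, fx$taxonomy))
  expect_equal(sort(net3$nodes$otu_id),
               sort(unique(c(ed$otu_a, ed$otu_b))))
  expect_true(all(net3$nodes$domain %in%
                    c("Bacteria", "Archaea", "Eukarya", "Unclassified")))
})

test_that("topology indices match hand enumeration on canonical graphs", {
  tri <- mk_edges(cbind(c("a", "b", "a"), c("b", "c", "c")))
  net <- suppressMessages(build_network(tri))
  t1 <- network_topology(net)
  expect_equal(t1$average_degree, 2)
  expect_equal(t1$average_clustering, 1)
  expect_equal(t1$average_path, 1)
  expect_lt(abs(t1$modularity), 1e-9)

  path <- mk_edges(cbind(c("a", "b"), c("b", "c")))
  t2 <- network_topology(suppressMessages(build_network(path)))
  expect_equal(t2$average_clustering, 0)
  expect_equal(t2$average_path, 4 / 3)
  expect_equal(t2$average_degree, 4 / 3)

  two_tri <- mk_edges(cbind(c("a", "b", "a", "x", "y", "x"),
                            c("b", "c", "c", "y", "z", "z")))
  nt <- suppressMessages(build_network(two_tri))
  t3 <- network_topology(nt)  # component partition when no modules set
  expect_equal(t3$modularity, 0.5)
})

test_that("modularity of the detected partition equals the Newman oracle", {
  set.seed(61)
  for (i in 1:8) {
    n <- sample(6:12, 1)
    pairs <- t(combn(letters[1:n], 2))
    keep <- runif(nrow(pairs)) < 0.4
    if (sum(keep) < 2) next
    ed <- mk_edges(pairs[keep, , drop = FALSE])
    net <- suppressMessages(build_network(ed))
    net <- detect_modules(net, seed = 7)
    memb <- net$modules
    expect_equal(net$modularity,
                 oracle_modularity(as.matrix(ed[, 1:2]), memb),
                 tolerance = 1e-9)
  }
})

test_that("module detection recovers disconnected components and planted modules", {
  two_tri <- mk_edges(cbind(c("a", "b", "a", "x", "y", "x"),
                            c("b", "c", "c", "y", "z", "z")))
  net <- detect_modules(suppressMessages(build_network(two_tri)), seed = 1)
  expect_equal(length(unique(net$modules)), 2)
  expect_equal(length(unique(net$modules[c("a", "b", "c")])), 1)
  # modules renumbered by decreasing size
  plus <- mk_edges(cbind(c("a", "b", "a", "x"), c("b", "c", "c", "y")))
  net2 <- detect_modules(suppressMessages(build_network(plus)), seed = 1)
  sizes <- table(net2$modules)
  expect_true(all(diff(as.numeric(sizes)) <= 0))
  # single edge: degenerate but consistent
  one <- mk_edges(cbind("a", "b"))
  net3 <- detect_modules(suppressMessages(build_network(one)), seed = 1)
  expect_equal(net3$modularity,
               oracle_modularity(as.matrix(one[, 1:2]), net3$modules),
               tolerance = 1e-9)
})

test_that("planted module recovery reaches high adjusted Rand index", {
  des <- recovery_design()
  aris <- vapply(1:30, function(s) {
    sim <- simulate_community(des, seed = s)
    part <- suppressMessages(suppressWarnings(partition_sad(sim$table)))
    ct <- abundance_table(unclass(sim$table)[core_otus(part), ])
    ed <- suppressMessages(edge_table(ct))
    net <- detect_modules(suppressMessages(build_network(ed)), seed = s)
    planted <- sim$truth$module[names(net$modules)]
    keep <- planted > 0
    if (sum(keep) < 10) return(NA_real_)
    oracle_ari(planted[keep], net$modules[keep])
  }, numeric(1))
  expect_gte(median(aris, na.rm = TRUE), 0.8)
})

test_that("detected modularity falls toward zero as random-graph density grows", {
  set.seed(62)
  qs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(p) {
    mean(vapply(1:5, function(i) {
      g <- igraph::sample_gnp(30, p)
      el <- igraph::as_edgelist(g)
      el <- matrix(paste0("n", el), ncol = 2)
      ed <- mk_edges(el)
      net <- detect_modules(suppressMessages(build_network(ed)), seed = i)
      net$modularity
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(qs) < 0))
})

test_that("contaminated networks are sparser and less clustered than pristine", {
  des <- recovery_design()
  res <- vapply(1:30, function(s) {
    sim <- simulate_community(des, seed = 200 + s)
    part <- suppressMessages(suppressWarnings(partition_sad(sim$table)))
    ct <- abundance_table(unclass(sim$table)[core_otus(part), ])
    lab <- setNames(sim$metadata$a_priori_label, sim$metadata$sample_id)
    cmpr <- suppressMessages(suppressWarnings(
      split_and_compare(ct, lab, taxonomy = sim$taxonomy)))
    # an edgeless contaminated network has degree/clustering 0
    met <- function(t, what) if (is.na(t[[what]])) 0 else t[[what]]
    c(met(cmpr$topology$contaminated, "average_degree") <
        met(cmpr$topology$pristine, "average_degree"),
      met(cmpr$topology$contaminated, "average_clustering") <
        met(cmpr$topology$pristine, "average_clustering"))
  }, logical(2))
  expect_gte(mean(res[1, ]), 0.9)
  expect_gte(mean(res[2, ]), 0.9)
})

test_that("self-comparison of identical groups shows no significant difference", {
  sim <- simulate_community(recovery_design(), seed = 77)
  part <- suppressMessages(suppressWarnings(partition_sad(sim$table)))
  ct <- abundance_table(unclass(sim$table)[core_otus(part), ])
  m <- unclass(ct)
  dup <- cbind(m, m)
  colnames(dup) <- c(paste0(colnames(m), "_p"), paste0(colnames(m), "_c"))
  lab <- setNames(rep(c("pristine", "contaminated"), each = ncol(m)),
                  colnames(dup))
  cmpr <- suppressMessages(suppressWarnings(
    split_and_compare(abundance_table(dup), lab)))
  expect_equal(cmpr$topology$pristine$average_degree,
               cmpr$topology$contaminated$average_degree)
  expect_true(all(cmpr$node_tests$p > 0.9, na.rm = TRUE))
})
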