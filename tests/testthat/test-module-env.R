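test_that("eigengene of a rank-1 module explains all variance", {
  base <- c(1, 3, 2, 5, 4, 6, 8, 7)
  m <- rbind(a = base, b = 2 * base, c = 10 * base + 3)
  colnames(m) <- paste0("s", 1:8)
  eg <- module_eigengene(m)
  expect_equal(eg$variance_explained, 1, tolerance = 1e-12)
  expect_equal(sum(eg$scores^2), 1, tolerance = 1e-12)
  # eigengene is the (unit-norm) standardized shared profile
  z <- (base - mean(base)) / sd(base)
  expect_equal(abs(cor(eg$scores, z)), 1, tolerance = 1e-12)
  expect_gt(cor(eg$scores, z), 0)  # sign oriented with the mean profile
})

test_that("two orthogonal profile groups split the variance evenly", {
  s1 <- c(1, -1, 1, -1, 1, -1, 1, -1)
  s2 <- c(1, 1, -1, -1, 1, 1, -1, -1)
  m <- rbind(a = s1, b = s1, c = s2, d = s2) + 5
  colnames(m) <- paste0("s", 1:8)
  eg <- module_eigengene(m)
  expect_equal(eg$variance_explained, 0.5, tolerance = 1e-9)
})

test_that("eigengene matches an independent power-iteration oracle", {
  fx <- fixture_small()
  mod <- fx$truth$module
  members <- names(mod)[mod == 1]
  m <- unclass(fx$table)[members, ]
  eg <- module_eigengene(m)
  z <- t(scale(t(m[apply(m, 1, sd) > 0, ])))
  v <- oracle_eigengene(z)
  expect_gt(abs(sum(eg$scores * v)), 1 - 1e-9)
  # invariance (up to sign) to OTU order and profile rescaling
  eg2 <- module_eigengene(m[rev(seq_len(nrow(m))), ])
  expect_equal(abs(sum(eg$scores * eg2$scores)), 1, tolerance = 1e-9)
  m3 <- m; m3[1, ] <- m3[1, ] * 100
  eg3 <- module_eigengene(m3)
  expect_equal(abs(sum(eg$scores * eg3$scores)), 1, tolerance = 1e-9)
  # constant rows are dropped; too few survivors is an error
  bad <- rbind(a = rep(3, 8), b = rep(1, 8), c = 1:8)
  colnames(bad) <- paste0("s", 1:8)
  expect_error(module_eigengene(bad), "non-constant")
})

test_that("eigengene-environment correlation is exact on a planted variable", {
  set.seed(71)
  e <- rnorm(10)
  eg <- list("1" = list(scores = setNames(e / sqrt(sum(e^2)),
                                          paste0("s", 1:10)),
                        variance_explained = 1, n_otus = 3))
  md <- data.frame(sample_id = paste0("s", 1:10), myvar = e,
                   flat = rep(1, 10))
  ec <- correlate_env(eg, md, variables = c("myvar", "flat"),
                      transforms = list())
  expect_equal(ec$r[ec$variable == "myvar"], 1, tolerance = 1e-9)
  expect_true(is.na(ec$r[ec$variable == "flat"]))
})

test_that("the PAH-sensitive module's eigengene tracks fluoranthene negatively", {
  des <- recovery_design()
  res <- vapply(1:50, function(s) {
    sim <- simulate_community(des, seed = s)
    part <- suppressMessages(suppressWarnings(partition_sad(sim$table)))
    ct <- abundance_table(unclass(sim$table)[core_otus(part), ])
    ed <- suppressMessages(edge_table(ct))
    net <- detect_modules(suppressMessages(build_network(ed)), seed = s)
    pm <- names(sim$truth$module)[
      sim$truth$module == sim$truth$pah_sensitive_module]
    innet <- intersect(pm, names(net$modules))
    if (length(innet) < 2) return(NA)
    hit <- names(which.max(table(net$modules[innet])))
    eg <- module_eigengenes(ct, net)
    ec <- correlate_env(eg, sim$metadata, variables = "fluoranthene")
    row <- ec[ec$module == hit, ]
    row$r[1] < 0 && row$p[1] < 0.05
  }, logical(1))
  expect_gte(mean(res, na.rm = TRUE), 0.9)
})

test_that("shuffled metadata gives uniform eigengene correlation p-values", {
  sim <- simulate_community(recovery_design(), seed = 23)
  part <- suppressMessages(suppressWarnings(partition_sad(sim$table)))
  ct <- abundance_table(unclass(sim$table)[core_otus(part), ])
  ed <- suppressMessages(edge_table(ct))
  net <- detect_modules(suppressMessages(build_network(ed)), seed = 1)
  eg <- module_eigengenes(ct, net)[1]
  set.seed(24)
  pv <- vapply(1:300, function(i) {
    md <- sim$metadata
    md$fluoranthene <- sample(md$fluoranthene)
    correlate_env(eg, md, variables = "fluoranthene")$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("single-term PERMANOVA R2 matches the sums-of-squares oracle", {
  set.seed(72)
  for (i in 1:5) {
    n <- 8
    grp <- rep(c("A", "B"), each = n / 2)
    m <- matrix(rpois(12 * n, 8), 12, n,
                dimnames = list(paste0("o", 1:12), paste0("s", 1:n)))
    m[1:6, grp == "B"] <- m[1:6, grp == "B"] + rpois(6 * sum(grp == "B"), 6)
    d <- as.matrix(community_distance(abundance_table(m)))
    md <- data.frame(sample_id = colnames(m), grp = grp)
    fit <- suppressMessages(permanova(d, md, "grp", n_perm = 99, seed = i,
                                      transforms = list()))
    expect_equal(fit$R2[fit$term == "grp"],
                 oracle_permanova_r2(d, grp), tolerance = 1e-9)
    expect_equal(sum(fit$R2[fit$term != "Total"]), 1, tolerance = 1e-9)
  }
})

test_that("PERMANOVA p-values are calibrated and detect planted structure", {
  # separated clusters: p bottoms out at 1/(n_perm + 1)
  set.seed(73)
  m <- matrix(rpois(10 * 12, 5), 10, 12,
              dimnames = list(paste0("o", 1:10), paste0("s", 1:12)))
  m[, 7:12] <- m[, 7:12] + 60
  d <- as.matrix(community_distance(abundance_table(m)))
  md <- data.frame(sample_id = colnames(m), grp = rep(c("A", "B"), each = 6))
  fit <- suppressMessages(permanova(d, md, "grp", n_perm = 199, seed = 1,
                                    transforms = list()))
  # the group-swap permutation ties the observed pseudo-F, so the floor is
  # at most 2/(n_perm + 1)
  expect_lte(fit$p[fit$term == "grp"], 2 / 200)

  # all-equal distances: no structure to explain
  deq <- matrix(1, 12, 12, dimnames = list(colnames(m), colnames(m)))
  diag(deq) <- 0
  fit2 <- suppressMessages(permanova(deq, md, "grp", n_perm = 99, seed = 1,
                                     transforms = list()))
  expect_lt(fit2$R2[fit2$term == "grp"], 0.12)

  # validation and complete-case handling
  asym <- d; asym[1, 2] <- asym[1, 2] + 1
  expect_error(permanova(asym, md, "grp"), "symmetric")
  md2 <- md; md2$grp[1] <- NA; md2$cst <- 1
  expect_warning(
    fit3 <- suppressMessages(permanova(d, md2, c("grp", "cst"),
                                       n_perm = 99, transforms = list())),
    "constant")
  expect_equal(attr(fit3, "n"), 11)
})

test_that("core community responds more to the salinity proxy than the satellite community", {
  des <- recovery_design()
  wins <- vapply(1:20, function(s) {
    sim <- simulate_community(des, seed = 400 + s)
    part <- suppressMessages(suppressWarnings(partition_sad(sim$table)))
    rec <- part$records
    core <- rec$otu_id[rec$class == "core"]
    sat <- rec$otu_id[rec$class == "satellite"]
    r2 <- vapply(list(core, sat), function(ids) {
      d <- as.matrix(community_distance(
        abundance_table(unclass(sim$table)[ids, ])))
      fit <- suppressMessages(permanova(d, sim$metadata, "salinity",
                                        n_perm = 49, seed = s))
      fit$R2[fit$term == "salinity"]
    }, numeric(1))
    r2[1] > r2[2]
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
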