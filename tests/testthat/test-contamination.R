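test_that("9-PAH sum covers exactly the guideline compounds", {
  prof <- setNames(rep(1, 9), pah9_compounds())
  expect_equal(pah9_sum(prof), 9)
  expect_equal(pah9_sum(prof * 0), 0)
  # the two excluded compounds must not contribute, however large
  full <- c(prof, benzo_ghi_perylene = 1e6, indeno_123cd_pyrene = 1e6)
  expect_equal(pah9_sum(full), 9)
  # missing compound -> NA
  expect_true(is.na(suppressMessages(pah9_sum(prof[-1]))))
  # permutation invariance and additivity across profiles
  expect_equal(pah9_sum(rev(full)), 9)
  p2 <- setNames(runif(9, 1, 5), pah9_compounds())
  expect_equal(pah9_sum(prof + p2), pah9_sum(prof) + pah9_sum(p2))
})

test_that("diagnostic ratios classify pyrogenic vs petrogenic sources", {
  r <- diagnostic_ratios(c(phenanthrene = 50, anthracene = 10,
                           fluoranthene = 30, pyrene = 20))
  expect_equal(r$pa, 5)
  expect_equal(r$fp, 1.5)
  expect_equal(r$source, "pyrogenic")

  r2 <- diagnostic_ratios(c(phenanthrene = 100, anthracene = 5,
                            fluoranthene = 10, pyrene = 20))
  expect_equal(r2$pa, 20)
  expect_equal(r2$fp, 0.5)
  expect_equal(r2$source, "petrogenic")

  r3 <- diagnostic_ratios(c(phenanthrene = 50, anthracene = 0,
                            fluoranthene = 30, pyrene = 20))
  expect_true(is.na(r3$pa))
  expect_equal(r3$source, "indeterminate")
})

test_that("guideline exceedance is strict and NA-safe", {
  sqg <- sqg_table(PEL = setNames(rep(5 / 9, 9), pah9_compounds()),
                   ERL = setNames(rep(10 / 9, 9), pah9_compounds()))
  flags <- guideline_exceedance(10, sqg)
  expect_true(flags[["PEL"]])
  expect_false(flags[["ERL"]])  # sum equals threshold: strict >
  incomplete <- sqg_table(T50 = c(fluoranthene = 1))
  expect_true(is.na(suppressMessages(guideline_exceedance(10, incomplete))))
  expect_length(guideline_exceedance(10, sqg_table()), 0)
})

test_that("HAC classification separates well-separated PAH groups", {
  set.seed(11)
  n <- 10
  mk <- function(level) {
    m <- sapply(pah_compounds(), function(cp)
      level * runif(n / 2, 0.9, 1.1))
    m
  }
  pah <- rbind(mk(1), mk(1000))
  meta <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     as.data.frame(pah), stringsAsFactors = FALSE)
  call <- classify_sites_hac(meta)
  expect_equal(call$calls$label, rep(c("pristine", "contaminated"),
                                     each = n / 2))
  # invariant to sample order
  perm <- sample(n)
  call2 <- classify_sites_hac(meta[perm, ])
  expect_equal(call2$calls$label, call$calls$label[perm])
  # invariant to uniform rescaling (log transform)
  meta10 <- meta
  meta10[, pah_compounds()] <- meta10[, pah_compounds()] * 10
  expect_equal(classify_sites_hac(meta10)$calls$label, call$calls$label)
  # dendrogram exports as newick
  f <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(call, "all", f)
  expect_match(readLines(f), "^\\(")
})

test_that("HAC handles a singleton cluster and rejects identical profiles", {
  base <- setNames(rep(10, 11), pah_compounds())
  pah <- rbind(matrix(rep(base, 4), 4, byrow = TRUE),
               base * 100)
  colnames(pah) <- pah_compounds()
  meta <- data.frame(sample_id = paste0("s", 1:5), as.data.frame(pah))
  call <- classify_sites_hac(meta)
  expect_equal(call$calls$label, c(rep("pristine", 4), "contaminated"))
  allsame <- meta
  allsame[5, pah_compounds()] <- base
  expect_error(classify_sites_hac(allsame), "no separation")
})

test_that("HAC labels recover the planted contamination state on synthetic data", {
  des <- synthetic_design()
  acc <- vapply(1:50, function(s) {
    sim <- simulate_metadata(des, seed = s)
    call <- classify_sites_hac(sim$metadata)
    truth <- ifelse(sim$truth$contaminated, "contaminated", "pristine")
    mean(call$calls$label == truth)
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
})

test_that("rank-sum comparison matches exact enumeration and the null is uniform", {
  r <- compare_groups_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$u), 0)
  expect_equal(r$p, 0.1)  # 2/20 orderings as extreme
  same <- compare_groups_ranksum(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p, 0.95)
  expect_error(compare_groups_ranksum(1, c(1, 2)), "at least 2")
  # power at a 3-sigma shift
  set.seed(21)
  sig <- vapply(1:100, function(i)
    compare_groups_ranksum(rnorm(21), rnorm(21, 3))$p < 0.001, logical(1))
  expect_gte(mean(sig), 0.99)
  # exchangeable null: p uniform (KS over 500 replicates)
  set.seed(22)
  pv <- vapply(1:500, function(i)
    compare_groups_ranksum(rnorm(15), rnorm(15))$p, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("collinearity grouping finds components and honors proxy overrides", {
  set.seed(31)
  x <- rnorm(30)
  meta <- data.frame(sample_id = paste0("s", 1:30),
                     x = x, y = 2 * x, z = rnorm(30), w = rnorm(30))
  gr <- collinearity_proxies(meta, variables = c("x", "y", "z", "w"))
  sets <- lapply(gr$groups, sort)
  expect_true(list(c("x", "y")) %in% sets ||
                any(vapply(sets, identical, logical(1), c("x", "y"))))
  expect_true(all(c("z", "w") %in% unlist(sets[lengths(sets) == 1])))

  sim <- simulate_metadata(synthetic_design(), seed = 3)
  grp <- collinearity_proxies(sim$metadata, variables = pah_compounds(),
                              proxies = "fluoranthene")
  expect_length(grp$groups, 1)
  expect_equal(unname(grp$proxies), "fluoranthene")

  const <- data.frame(sample_id = paste0("s", 1:10), a = rnorm(10), b = 1)
  expect_warning(collinearity_proxies(const, variables = c("a", "b")),
                 "constant")
})
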