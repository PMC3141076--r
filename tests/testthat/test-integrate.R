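ranked10 <- sprintf("g%02d", 1:10)

test_that("running-sum enrichment matches hand-computed prefix sums", {
  ## targets at the top: five +1/5 steps reach ES = 1
  top <- ks_enrichment(ranked10, ranked10[1:5])
  expect_equal(top$ES, 1)
  expect_equal(top$running_sum[5], 1)
  expect_equal(top$running_sum[10], 0)          # conservation
  expect_setequal(top$leading_edge, ranked10[1:5])

  ## targets at the bottom: ES = 0, minimum -1
  bottom <- ks_enrichment(ranked10, ranked10[6:10])
  expect_equal(bottom$ES, 0)
  expect_equal(bottom$ES_min, -1)

  ## alternating targets: steps of +-0.2, max 0.2
  alt <- ks_enrichment(ranked10, ranked10[c(1, 3, 5, 7, 9)])
  expect_equal(alt$ES, 0.2)

  expect_error(ks_enrichment(ranked10, "absent"), "no target")
  expect_error(ks_enrichment(ranked10, ranked10), "degenerate")
  expect_error(ks_enrichment(c("a", "a", "b"), "a"), "duplicate")
})

test_that("the running sum always returns to zero and ES ignores non-target labels", {
  set.seed(9)
  for (k in 1:30) {
    N <- sample(5:60, 1)
    Nh <- sample(seq_len(N - 1), 1)
    ids <- sprintf("x%03d", sample.int(500, N))
    targets <- sample(ids, Nh)
    e <- ks_enrichment(ids, targets)
    expect_equal(e$running_sum[N], 0, tolerance = 1e-12)
    ## relabeling non-targets leaves ES unchanged
    ids2 <- ids
    ids2[!(ids %in% targets)] <- sprintf("y%03d", seq_len(N - Nh))
    expect_equal(ks_enrichment(ids2, targets)$ES, e$ES)
    ## vectorized subset evaluation agrees with the walk
    expect_equal(choreseq:::es_from_positions(N, sort(e$hit_ranks)), e$ES)
  }
})

test_that("the enrichment score agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(3)
  for (k in 1:20) {
    N <- sample(20:100, 1)
    Nh <- sample(3:10, 1)
    ids <- sprintf("g%03d", 1:N)
    targets <- sample(ids[1:floor(N / 2)], Nh)   # biased to the top
    ours <- ks_enrichment(ids, targets)$ES
    ## unweighted statistic (gseaParam = 0) on a strictly decreasing stat
    stats <- setNames(seq(N, 1), ids)
    ref <- fgsea::calcGseaStat(stats, selectedStats = which(ids %in% targets),
                               gseaParam = 0, returnAllExtremes = TRUE)
    expect_equal(ours, max(ref$tops), tolerance = 1e-12)
  }
})

test_that("exact and permutation p-values agree on small cases", {
  top <- ks_enrichment(ranked10, ranked10[1:5])
  sig <- ks_significance(top, n_perm = 20000, seed = 2)
  expect_equal(sig$p_exact, 1 / 252)   # only one of C(10,5) placements
  se <- sqrt(sig$p_exact * (1 - sig$p_exact) / 20000)
  expect_lt(abs(sig$p_perm - sig$p_exact), 3 * se + 1 / 20001)

  ## moderately enriched case: exact within MC error of permutation
  mid <- ks_enrichment(ranked10, ranked10[c(1, 2, 6)])
  s2 <- ks_significance(mid, n_perm = 20000, seed = 7)
  se2 <- sqrt(s2$p_exact * (1 - s2$p_exact) / 20000)
  expect_lt(abs(s2$p_perm - s2$p_exact), 4 * se2 + 1 / 20001)

  expect_warning(ks_significance(top, n_perm = 50, seed = 1), "coarse")
})

test_that("direction splits intersect targets with significant DE genes", {
  res <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    log2fc = c(2, -2, 3, 0.1),
                    t = c(8, -8, 9, 0.2), pvalue = c(1e-5, 1e-5, 1e-6, 0.8),
                    ppde = c(0.99, 0.99, 0.99, 0.05))
  sp <- split_targets_by_direction(c("g1", "g2"), res)
  expect_equal(sp$n_up, 1L)
  expect_equal(sp$n_down, 1L)
  expect_equal(sp$frac_up, 0.5)
  none <- split_targets_by_direction("g4", res)
  expect_equal(c(none$n_up, none$n_down), c(0L, 0L))
})

test_that("hypergeometric ORA gives exact point-mass p-values and valid BH", {
  universe <- sprintf("u%02d", 1:20)
  sets <- list(hit5 = universe[1:5], miss = universe[16:20])
  ora <- ora_hypergeometric(universe[1:5], sets, universe)
  expect_equal(ora$pvalue[ora$set == "hit5"], 1 / choose(20, 5))
  expect_equal(ora$pvalue[ora$set == "miss"], 1)

  ## BH values are monotone after sorting by p and never below p
  set.seed(4)
  big_universe <- sprintf("u%03d", 1:200)
  many <- lapply(1:25, function(i) sample(big_universe, sample(5:40, 1)))
  names(many) <- paste0("s", 1:25)
  ora2 <- ora_hypergeometric(sample(big_universe, 30), many, big_universe)
  expect_true(all(diff(ora2$fdr[order(ora2$pvalue)]) >= -1e-12))
  expect_true(all(ora2$fdr >= ora2$pvalue - 1e-12))

  expect_error(ora_hypergeometric("x", sets, character()), "universe")
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("onlyname\tdesc", bad)
  expect_error(read_gmt(bad), "line 1")
})
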