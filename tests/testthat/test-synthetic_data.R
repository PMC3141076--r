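small_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, genome_size = 1e5, n_chrom = 1, n_genes = 8,
               n_sites = 5, n_chip_tags = 5000, n_input_tags = 5000)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

test_that("the whole simulation is byte-identical under a fixed seed", {
  a <- simulate_experiment(small_cfg(seed = 11))
  b <- simulate_experiment(small_cfg(seed = 11))
  expect_identical(a$genome, b$genome)
  expect_identical(a$genes, b$genes)
  expect_identical(a$sites, b$sites)
  expect_identical(a$chip, b$chip)
  expect_identical(a$expression$matrix, b$expression$matrix)
})

test_that("background GC content matches the configured value", {
  cfg <- simulation_config(seed = 3, genome_size = 2e5, n_chrom = 1,
                           n_genes = 0, gc = 0.3)
  gg <- make_genome_and_genes(cfg)
  expect_equal(nrow(gg$genes), 0L)
  n_gc <- sum(strsplit(gg$genome[[1]], "")[[1]] %in% c("G", "C"))
  L <- nchar(gg$genome[[1]])
  ci <- qbinom(c(0.005, 0.995), L, 0.3)
  expect_gte(n_gc, ci[1]); expect_lte(n_gc, ci[2])
})

test_that("planted sites are written into the genome verbatim", {
  cfg <- small_cfg(seed = 7, n_sites = 8)
  gg <- make_genome_and_genes(cfg)
  el <- "CACGTGGCCGGCGCGTG"
  pl <- plant_binding_sites(gg$genome, gg$genes, el, cfg)
  expect_equal(nrow(pl$sites), 8L)
  for (i in seq_len(8L)) {
    s <- pl$sites[i, ]
    sub <- substr(pl$genome[[s$chrom]], s$start + 1L, s$end)
    expect_identical(sub, s$sequence)
    ## the planted sequence is the element or its reverse complement
    expect_true(sub == el || sub == revcomp(el))
  }
  ## zero sites leaves the genome untouched
  cfg0 <- small_cfg(seed = 7, n_sites = 0)
  pl0 <- plant_binding_sites(gg$genome, gg$genes, el, cfg0)
  expect_identical(pl0$genome, gg$genome)
  expect_equal(nrow(pl0$sites), 0L)
})

test_that("a degenerate placement distribution puts every site at its offset", {
  cfg <- small_cfg(seed = 5, n_sites = 4, tss_offset_mean = -1000,
                   tss_offset_sd = 0, intergenic_fraction = 0)
  gg <- make_genome_and_genes(cfg)
  pl <- plant_binding_sites(gg$genome, gg$genes, "CACGTG", cfg)
  tss <- setNames(tss_of(gg$genes), gg$genes$gene_id)
  strand <- setNames(gg$genes$strand, gg$genes$gene_id)
  for (i in seq_len(nrow(pl$sites))) {
    s <- pl$sites[i, ]
    expected <- if (strand[s$linked_gene_id] == "+") tss[s$linked_gene_id] - 1000
                else tss[s$linked_gene_id] + 1000
    expect_equal(s$center, as.integer(expected))
  }
})

test_that("without enrichment, ChIP and input tag positions are exchangeable", {
  cfg <- small_cfg(seed = 1, n_sites = 0, n_chip_tags = 2000,
                   n_input_tags = 2000)
  gg <- make_genome_and_genes(simulation_config(seed = 1, genome_size = 1e5,
                                                n_chrom = 1, n_genes = 0))
  rejections <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    cfg$seed <- 1000L + s
    tg <- simulate_tags(gg$genome, data.frame(), cfg)
    p <- suppressWarnings(ks.test(tg$chip$start, tg$input$start))$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 5L)   # non-significant in >= 95% of seeds
})

test_that("site-derived ChIP coverage peaks at the site center", {
  cfg <- simulation_config(seed = 2, genome_size = 1e5, n_chrom = 1,
                           n_genes = 4, n_sites = 1, n_chip_tags = 10000,
                           n_input_tags = 1000, chip_efficiency = 0.9,
                           intergenic_fraction = 0)
  gg <- make_genome_and_genes(cfg)
  pl <- plant_binding_sites(gg$genome, gg$genes, "CACGTG", cfg)
  tg <- simulate_tags(pl$genome, pl$sites, cfg)
  cov <- build_coverage(tg$chip, cfg$fragment_length,
                        setNames(nchar(pl$genome), names(pl$genome)))
  modal <- which.max(cov$cov[[1]]) - 1L
  expect_lte(abs(modal - pl$sites$center[1]), 50L)
})

test_that("expression simulation honors effect size and direction structure", {
  ids <- sprintf("g%03d", 1:200)
  bound <- ids[1:20]

  ## strong effects force all bound genes into the top |log2FC| decile
  cfg <- small_cfg(seed = 9, effect_size = 4, noise_sd = 0.1,
                   frac_independent_de = 0)
  ex <- simulate_expression(ids, bound, cfg)
  lfc <- compute_fold_changes(ex$matrix, ex$condition)
  top <- names(sort(abs(lfc), decreasing = TRUE))[1:20]
  expect_setequal(top, bound)

  ## fraction_up = 1 makes every bound gene up-regulated
  cfg_up <- small_cfg(seed = 9, fraction_up = 1)
  ex_up <- simulate_expression(ids, bound, cfg_up)
  expect_true(all(ex_up$truth$direction[ex_up$truth$bound] == 1L))

  ## effect 0: none responsive; downstream DE false-positive rate ~ alpha
  cfg0 <- small_cfg(seed = 9, effect_size = 0, frac_independent_de = 0)
  ex0 <- simulate_expression(ids, bound, cfg0)
  expect_true(all(!ex0$truth$responsive))
  de0 <- moderated_t_ppde(ex0$matrix, ex0$condition, nu0 = 0)
  fpr <- mean(de0$pvalue < 0.05)
  ci <- qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(fpr, ci[1]); expect_lte(fpr, ci[2])

  expect_error(simulate_expression(ids, bound, small_cfg(n_replicates = 1)),
               "replicates")
  expect_error(simulate_expression(ids, c("nope"), small_cfg()), "absent")
})
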