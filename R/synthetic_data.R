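## Synthetic ChIP-seq + expression experiment with planted ground truth.
##
## The generator emulates the structure the downstream analysis assumes:
## a toy genome with non-overlapping multi-exon genes, ChoRE-like motif
## instances planted near a subset of TSSs, ChIP tags drawn as a mixture of
## uniform background and site-derived fragments (midpoints Normal around
## the site center), an input library that is pure background, and a
## two-condition expression matrix in which roughly half of the bound genes
## respond upward and half downward.
##
## Every operation derives its own RNG stream from `config$seed`, so each
## stage is reproducible independently of call order.

#' Simulation configuration
#'
#' Builds the configuration list used by every generator function, with
#' defaults chosen to mimic a small but realistic two-condition ChIP-seq +
#' microarray experiment: a 1 Mb genome, 20 planted sites, 100k ChIP and
#' 100k input tags of which 10% of ChIP tags are site-derived, 200 bp
#' fragments sequenced as 36 nt tags, and six biological replicates per
#' glucose condition with a two-fold (1 log2 unit) shift for responsive
#' genes, half up and half down.
#'
#' @param seed integer seed; mandatory, all randomness derives from it.
#' @param genome_size total genome length in bp.
#' @param n_chrom number of chromosomes (equal sizes).
#' @param gc genome GC fraction for the iid background sequence.
#' @param n_genes number of non-overlapping genes to place.
#' @param n_sites number of planted binding sites.
#' @param fragment_length sonication fragment length in bp.
#' @param read_length sequenced tag length in bp.
#' @param n_chip_tags,n_input_tags library sizes.
#' @param chip_efficiency fraction of ChIP tags that are site-derived.
#' @param tss_offset_mean,tss_offset_sd Normal distribution (bp) of the
#'   signed site-center-to-TSS distance for gene-linked sites (negative =
#'   upstream in the gene's orientation).
#' @param intergenic_fraction fraction of sites placed uniformly at random
#'   with no linked gene.
#' @param n_replicates replicates per expression condition.
#' @param effect_size log2 expression shift of responsive genes.
#' @param fraction_up probability a bound gene responds upward.
#' @param noise_sd replicate log2 noise standard deviation.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log2
#'   intensity.
#' @param frac_independent_de fraction of unbound genes that are
#'   glucose-responsive through other regulators (random direction).
#' @param condition_names names of the two conditions, used in column
#'   headers of the expression matrix.
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(seed,
                              genome_size = 1e6, n_chrom = 2, gc = 0.5,
                              n_genes = 60, n_sites = 20,
                              fragment_length = 200, read_length = 36,
                              n_chip_tags = 1e5, n_input_tags = 1e5,
                              chip_efficiency = 0.10,
                              tss_offset_mean = -200, tss_offset_sd = 500,
                              intergenic_fraction = 0.1,
                              n_replicates = 6, effect_size = 1,
                              fraction_up = 0.5, noise_sd = 0.3,
                              baseline_mean = 8, baseline_sd = 1,
                              frac_independent_de = 0.05,
                              condition_names = c("lowglc", "highglc")) {
  if (missing(seed)) fail("simulation_config(): seed is mandatory")
  cfg <- list(seed = as.integer(seed), genome_size = genome_size,
              n_chrom = n_chrom, gc = gc, n_genes = n_genes,
              n_sites = n_sites, fragment_length = fragment_length,
              read_length = read_length, n_chip_tags = n_chip_tags,
              n_input_tags = n_input_tags, chip_efficiency = chip_efficiency,
              tss_offset_mean = tss_offset_mean,
              tss_offset_sd = tss_offset_sd,
              intergenic_fraction = intergenic_fraction,
              n_replicates = n_replicates, effect_size = effect_size,
              fraction_up = fraction_up, noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              frac_independent_de = frac_independent_de,
              condition_names = condition_names)
  stopifnot(cfg$genome_size > 0, cfg$n_chrom >= 1, cfg$n_genes >= 0,
            cfg$n_sites >= 0, cfg$fragment_length >= cfg$read_length,
            cfg$chip_efficiency >= 0, cfg$chip_efficiency <= 1,
            cfg$fraction_up >= 0, cfg$fraction_up <= 1,
            cfg$intergenic_fraction >= 0, cfg$intergenic_fraction <= 1,
            cfg$gc > 0, cfg$gc < 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a toy genome and non-overlapping gene models
#'
#' Background sequence is iid with the configured GC content. Genes have 2-5
#' exons, random strand, and (for ~90% of genes) a CDS nested inside the
#' transcript; genes are separated by at least 2 kb.
#'
#' @param config a [simulation_config()].
#' @return `list(genome = <named character vector>, genes = <gene models>)`.
#' @export
make_genome_and_genes <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  chrom_len <- rep(floor(config$genome_size / config$n_chrom), config$n_chrom)
  chrom_names <- paste0("chr", seq_len(config$n_chrom))
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  genome <- vapply(chrom_len, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE, prob = p), collapse = "")
  }, "")
  names(genome) <- chrom_names

  if (config$n_genes == 0L) {
    genes <- gene_models(character(), character(), character(), integer(),
                         integer(), list(), list())[0, ]
    return(list(genome = genome, genes = genes))
  }

  min_gap <- 2000L
  placed <- lapply(chrom_names, function(x) matrix(integer(), ncol = 2))
  names(placed) <- chrom_names
  rows <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    len <- sample(2000:8000, 1L)
    ok <- FALSE
    for (try in seq_len(200L)) {
      ci <- sample(config$n_chrom, 1L)
      L <- chrom_len[ci]
      if (L < len + 2L * min_gap) next
      s <- sample.int(L - len - 2L * min_gap, 1L) + min_gap
      e <- s + len
      iv <- placed[[ci]]
      if (nrow(iv) == 0L || all(e + min_gap <= iv[, 1L] | s >= iv[, 2L] + min_gap)) {
        placed[[ci]] <- rbind(iv, c(s, e))
        ok <- TRUE
        break
      }
    }
    if (!ok)
      fail("could not place %d non-overlapping genes; increase genome_size",
           config$n_genes)
    n_ex <- sample(2:5, 1L)
    n_seg <- 2L * n_ex - 1L
    w <- stats::runif(n_seg) + 0.2
    seg <- pmax(60L, floor(w / sum(w) * len))
    seg[n_seg] <- len - sum(seg[-n_seg])
    bounds <- s + c(0L, cumsum(seg))
    ex_s <- bounds[seq(1L, n_seg, by = 2L)]
    ex_e <- bounds[seq(2L, n_seg + 1L, by = 2L)]
    coding <- stats::runif(1) < 0.9
    cds_s <- if (coding) s + sample(30:200, 1L) else NA_integer_
    cds_e <- if (coding) e - sample(30:200, 1L) else NA_integer_
    rows[[g]] <- list(chrom = chrom_names[ci], strand = sample(c("+", "-"), 1L),
                      s = s, e = e, ex_s = ex_s, ex_e = ex_e,
                      cds_s = cds_s, cds_e = cds_e)
  }
  genes <- gene_models(
    sprintf("gene%03d", seq_len(config$n_genes)),
    vapply(rows, `[[`, "", "chrom"), vapply(rows, `[[`, "", "strand"),
    vapply(rows, `[[`, 0L, "s"), vapply(rows, `[[`, 0L, "e"),
    lapply(rows, `[[`, "ex_s"), lapply(rows, `[[`, "ex_e"),
    cds_start = vapply(rows, `[[`, 0L, "cds_s"),
    cds_end = vapply(rows, `[[`, 0L, "cds_e")
  )
  list(genome = genome, genes = genes)
}

## sample one realization of an IUPAC consensus (literal for ACGT letters)
sample_consensus <- function(consensus) {
  cols <- iupac_columns(consensus)
  paste(vapply(cols, function(b) b[sample.int(length(b), 1L)], ""), collapse = "")
}

#' Plant binding sites into a genome
#'
#' Each site's sequence is sampled from the supplied PWM (or realized from a
#' literal/IUPAC consensus string) and written into the genome sequence,
#' on a random strand. A fraction of sites is linked to genes (one gene at
#' most one site) with the site center at a Normal signed offset from the
#' TSS in the gene's orientation; the rest are placed uniformly (intergenic,
#' no linked gene). Sites are resampled if they would overrun a chromosome
#' or fall within two fragment lengths of an already-placed site; after 200
#' failed retries placement is an error.
#'
#' @param genome named character vector of chromosome sequences.
#' @param genes gene-model `data.frame`.
#' @param motif a `pwm` object (see [consensus_to_pwm()]) or a consensus
#'   string (IUPAC codes allowed; ACGT letters are planted literally).
#' @param config a [simulation_config()].
#' @return `list(genome = <modified genome>, sites = <data.frame>)`; the
#'   site table has columns `site_id`, `chrom`, `start`, `end`, `center`,
#'   `strand`, `sequence` (plus-strand genomic substring), `linked_gene_id`
#'   (`NA` for intergenic sites) and `occupancy`.
#' @export
plant_binding_sites <- function(genome, genes, motif, config) {
  set.seed(derive_seed(config$seed, 2L))
  n <- config$n_sites
  width <- if (inherits(motif, "pwm")) motif$width else nchar(motif)
  stopifnot(width >= 1L)
  empty <- data.frame(site_id = character(), chrom = character(),
                      start = integer(), end = integer(), center = integer(),
                      strand = character(), sequence = character(),
                      linked_gene_id = character(), occupancy = numeric(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(list(genome = genome, sites = empty))

  len <- chrom_lengths(genome)
  n_linked <- round(n * (1 - config$intergenic_fraction))
  if (n_linked > nrow(genes)) {
    fail("n_sites (%d linked) exceeds available genes (%d)", n_linked,
         nrow(genes))
  }
  linked_genes <- if (n_linked > 0L) sample(genes$gene_id, n_linked) else character()
  tss <- stats::setNames(tss_of(genes), genes$gene_id)
  gstrand <- stats::setNames(genes$strand, genes$gene_id)
  gchrom <- stats::setNames(genes$chrom, genes$gene_id)
  min_sep <- 2L * config$fragment_length

  sites <- empty
  for (i in seq_len(n)) {
    gene <- if (i <= n_linked) linked_genes[i] else NA_character_
    ok <- FALSE
    for (try in seq_len(200L)) {
      if (!is.na(gene)) {
        d <- round(stats::rnorm(1, config$tss_offset_mean, config$tss_offset_sd))
        center <- if (gstrand[gene] == "+") tss[gene] + d else tss[gene] - d
        chrom <- gchrom[gene]
      } else {
        chrom <- sample(names(genome), 1L, prob = len)
        center <- sample.int(len[chrom], 1L) - 1L
      }
      start <- as.integer(center - floor(width / 2))
      end <- start + width
      if (start < 0L || end > len[chrom]) next
      prev <- sites[sites$chrom == chrom, , drop = FALSE]
      if (nrow(prev) > 0L && any(abs(prev$center - center) < min_sep)) next
      ok <- TRUE
      break
    }
    if (!ok) fail("failed to place site %d after 200 retries", i)
    inst <- if (inherits(motif, "pwm")) sample_pwm(motif) else sample_consensus(motif)
    strand <- sample(c("+", "-"), 1L)
    planted <- if (strand == "+") inst else revcomp(inst)
    substr(genome[[chrom]], start + 1L, end) <- planted
    sites <- rbind(sites, data.frame(
      site_id = sprintf("site%03d", i), chrom = chrom, start = start,
      end = end, center = as.integer(center), strand = strand,
      sequence = planted, linked_gene_id = gene, occupancy = 1,
      stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(sites))) {
    stopifnot(substr(genome[[sites$chrom[i]]], sites$start[i] + 1L,
                     sites$end[i]) == sites$sequence[i])
  }
  list(genome = genome, sites = sites)
}

## draw one sequence from a PWM's column distributions
sample_pwm <- function(pwm) {
  paste(apply(pwm$mat, 2L, function(p) sample(DNA_BASES, 1L, prob = p)),
        collapse = "")
}

#' Simulate ChIP and input tag libraries
#'
#' Input fragments have midpoints uniform over the genome; ChIP fragments
#' are a mixture of the same background and site-derived fragments whose
#' midpoints are Normal(site center, fragment_length/4), sites chosen
#' proportional to occupancy. Each fragment is reported as a single
#' `read_length` tag from its 5' end on a Bernoulli(0.5) strand. Midpoints
#' are clamped so fragments stay within chromosome bounds.
#'
#' @param genome named character vector of chromosome sequences.
#' @param sites planted-site `data.frame` from [plant_binding_sites()]
#'   (may have zero rows).
#' @param config a [simulation_config()].
#' @return `list(chip = <tags>, input = <tags>)`, tag `data.frame`s as from
#'   [read_tags()].
#' @export
simulate_tags <- function(genome, sites, config) {
  set.seed(derive_seed(config$seed, 3L))
  len <- chrom_lengths(genome)
  frag <- as.integer(config$fragment_length)
  half <- floor(frag / 2)
  rl <- as.integer(config$read_length)

  frag_to_tags <- function(chrom, mid) {
    n <- length(mid)
    if (n == 0L) {
      return(data.frame(chrom = character(), start = integer(),
                        strand = character(), read_length = integer()))
    }
    mid <- pmin(pmax(mid, half), len[chrom] - (frag - half))
    fs <- as.integer(mid - half)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    start <- ifelse(strand == "+", fs, fs + frag - rl)
    data.frame(chrom = chrom, start = as.integer(start), strand = strand,
               read_length = rl, stringsAsFactors = FALSE)
  }

  draw_background <- function(n) {
    if (n == 0L) {
      return(frag_to_tags(character(), integer()))
    }
    ci <- sample(names(len), n, replace = TRUE, prob = len)
    mid <- floor(stats::runif(n) * len[ci])
    frag_to_tags(ci, mid)
  }

  input <- draw_background(as.integer(config$n_input_tags))

  n_chip <- as.integer(config$n_chip_tags)
  eff <- if (nrow(sites) > 0L) config$chip_efficiency else 0
  n_site <- stats::rbinom(1L, n_chip, eff)
  chip_bg <- draw_background(n_chip - n_site)
  if (n_site > 0L) {
    si <- sample.int(nrow(sites), n_site, replace = TRUE,
                     prob = sites$occupancy)
    mid <- round(stats::rnorm(n_site, sites$center[si], frag / 4))
    chip_site <- frag_to_tags(sites$chrom[si], mid)
    chip <- rbind(chip_bg, chip_site)
  } else {
    chip <- chip_bg
  }
  ## shuffle so tag order carries no information about origin
  chip <- chip[sample.int(nrow(chip)), , drop = FALSE]
  rownames(chip) <- NULL
  list(chip = chip, input = input)
}

#' Simulate a two-condition replicate expression matrix
#'
#' Per-gene log2 intensities are Normal(mu_g, noise_sd). Each bound gene is
#' responsive: with probability `fraction_up` its condition-2 mean shifts by
#' `+effect_size`, otherwise by `-effect_size`. A fraction
#' `frac_independent_de` of unbound genes is responsive in a random
#' direction (regulation through other factors); the remaining genes are
#' null.
#'
#' @param genes gene-model `data.frame` or character vector of gene ids.
#' @param bound_gene_ids character vector, subset of the gene ids.
#' @param config a [simulation_config()].
#' @return list with `matrix` (genes x 2*n_replicates log2 intensities,
#'   columns named `<condition>_r<i>`), `condition` (factor of length
#'   ncol), and `truth` (`data.frame`: `gene_id`, `bound`, `responsive`,
#'   `direction` in {-1,0,1}, `true_lfc`).
#' @export
simulate_expression <- function(genes, bound_gene_ids, config) {
  set.seed(derive_seed(config$seed, 4L))
  ids <- if (is.data.frame(genes)) genes$gene_id else as.character(genes)
  if (!all(bound_gene_ids %in% ids))
    fail("bound_gene_ids contains ids absent from the gene list")
  if (config$n_replicates < 2L)
    fail("at least 2 replicates per condition are required (variance undefined)")
  n <- length(ids)
  nr <- config$n_replicates
  bound <- ids %in% bound_gene_ids
  direction <- integer(n)
  direction[bound] <- ifelse(stats::runif(sum(bound)) < config$fraction_up, 1L, -1L)
  indep <- !bound & stats::runif(n) < config$frac_independent_de
  direction[indep] <- sample(c(-1L, 1L), sum(indep), replace = TRUE)
  true_lfc <- direction * config$effect_size

  mu <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  m1 <- matrix(stats::rnorm(n * nr, mu, config$noise_sd), n, nr)
  m2 <- matrix(stats::rnorm(n * nr, mu + true_lfc, config$noise_sd), n, nr)
  mat <- cbind(m1, m2)
  rownames(mat) <- ids
  colnames(mat) <- c(paste0(config$condition_names[1], "_r", seq_len(nr)),
                     paste0(config$condition_names[2], "_r", seq_len(nr)))
  condition <- factor(rep(config$condition_names, each = nr),
                      levels = config$condition_names)
  truth <- data.frame(gene_id = ids, bound = bound,
                      responsive = true_lfc != 0, direction = direction,
                      true_lfc = true_lfc, stringsAsFactors = FALSE)
  list(matrix = mat, condition = condition, truth = truth)
}

#' Run the whole simulation and (optionally) write the experiment bundle
#'
#' Convenience wrapper: genome + genes, planted sites (default: the
#' ChoRE-like element `CACGTGGCCGGCGCGTG`), ChIP/input tag libraries, and an
#' expression matrix whose responsive genes are exactly the site-linked
#' genes. When `out_dir` is given, writes `genome.fa`, `genes.bed`,
#' `chip.bed`, `input.bed`, `expression.tsv`, and the machine-readable
#' ground truth (`sites.tsv`, `bound_genes.tsv`) plus `config.yaml`.
#'
#' @param config a [simulation_config()].
#' @param motif consensus string or `pwm` to plant.
#' @param out_dir optional output directory.
#' @return list with `genome`, `genes`, `sites`, `chip`, `input`,
#'   `expression` (as from [simulate_expression()]), and `bound_genes`.
#' @export
simulate_experiment <- function(config, motif = "CACGTGGCCGGCGCGTG",
                                out_dir = NULL) {
  gg <- make_genome_and_genes(config)
  pl <- plant_binding_sites(gg$genome, gg$genes, motif, config)
  tg <- simulate_tags(pl$genome, pl$sites, config)
  bound <- pl$sites$linked_gene_id[!is.na(pl$sites$linked_gene_id)]
  expr <- simulate_expression(gg$genes, bound, config)
  out <- list(genome = pl$genome, genes = gg$genes, sites = pl$sites,
              chip = tg$chip, input = tg$input, expression = expr,
              bound_genes = bound)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genome_fasta(out$genome, file.path(out_dir, "genome.fa"))
    write_gene_models_bed12(out$genes, file.path(out_dir, "genes.bed"))
    write_tags(out$chip, file.path(out_dir, "chip.bed"), name = "chip")
    write_tags(out$input, file.path(out_dir, "input.bed"), name = "input")
    write_expression_tsv(expr$matrix, file.path(out_dir, "expression.tsv"))
    utils::write.table(out$sites, file.path(out_dir, "sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(bound, file.path(out_dir, "bound_genes.tsv"))
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  }
  out
}
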