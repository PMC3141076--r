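## End-to-end orchestration: simulate (optional) -> coverage -> peaks ->
## annotation -> motif scan + ChoRE pairs + discovery -> DE ranking ->
## running-sum KS integration. Stages communicate only through files when
## an output directory is used; every output directory carries the config
## and its hash so a rerun with the same config is byte-identical.

#' Pipeline configuration
#'
#' Either supplies input file paths (`genome`, `genes`, `chip`, `input`,
#' `expression`) or a `simulation` block (a [simulation_config()]), plus
#' stage parameters.
#'
#' @param simulation a [simulation_config()], or `NULL` when real input
#'   files are given.
#' @param paths named list of input paths (`genome`, `genes`, `chip`,
#'   `input`, `expression`) when not simulating.
#' @param extension_length tag extension for coverage (defaults to the
#'   simulated fragment length, else 200).
#' @param min_height,min_ratio,merge_gap peak-calling parameters.
#' @param motif_consensus IUPAC consensus scanned in peaks (the bipartite
#'   ChoRE-like element).
#' @param ebox_consensus half-site consensus for ChoRE pair detection.
#' @param scan_alpha,site_alpha,spacer motif-scanning parameters.
#' @param discover_width,discover_n_starts ZOOPS-EM parameters (set
#'   `discover_width = 0` to skip discovery).
#' @param nu0 moderated-t prior degrees of freedom.
#' @param ppde_cutoff significance cutoff for the DE gene lists.
#' @param rank_key ranking used for the KS walk (`"ppde"`,
#'   `"fold_change"`, `"abs_t"`).
#' @param n_perm KS permutation count.
#' @param seed global seed (defaults to the simulation seed when
#'   simulating).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, paths = NULL,
                            extension_length = NULL,
                            min_height = 8, min_ratio = 5, merge_gap = 100,
                            motif_consensus = "CABGTGNNCNGNGNSTG",
                            ebox_consensus = "CAYGNG",
                            scan_alpha = 0.001, site_alpha = 0.005,
                            spacer = 5,
                            discover_width = 17, discover_n_starts = 10,
                            nu0 = 4, ppde_cutoff = 0.95,
                            rank_key = "ppde", n_perm = 10000,
                            seed = NULL) {
  if (is.null(simulation) && is.null(paths))
    fail("provide a simulation config or input paths")
  if (is.null(seed))
    seed <- if (!is.null(simulation)) simulation$seed else 1L
  if (is.null(extension_length))
    extension_length <- if (!is.null(simulation)) simulation$fragment_length else 200L
  structure(list(simulation = simulation, paths = paths,
                 extension_length = extension_length,
                 min_height = min_height, min_ratio = min_ratio,
                 merge_gap = merge_gap, motif_consensus = motif_consensus,
                 ebox_consensus = ebox_consensus, scan_alpha = scan_alpha,
                 site_alpha = site_alpha, spacer = spacer,
                 discover_width = discover_width,
                 discover_n_starts = discover_n_starts,
                 nu0 = nu0, ppde_cutoff = ppde_cutoff, rank_key = rank_key,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()]; a `simulation:`
#' block is passed to [simulation_config()] (its `seed` is mandatory).
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation)) do.call(simulation_config, y$simulation)
  args <- y[setdiff(names(y), "simulation")]
  do.call(pipeline_config, c(list(simulation = sim), args))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Executes simulate (if configured) -> coverage -> peak calling ->
#' annotation -> motif scan, ChoRE pairs and (optionally) ZOOPS-EM
#' discovery on the peak sequences -> moderated-t/PPDE ranking -> KS
#' enrichment of peak-proximal genes in the ranked list. When `out_dir` is
#' given, writes `peaks.bed`, `annotations.tsv`, `motif_hits.tsv`,
#' `chore_pairs.tsv`, `de_results.tsv`, `enrichment.tsv`,
#' `running_sum.tsv`, `summary.json` and `summary.txt`; every run writes
#' `config.yaml` and records the config hash and seed in the JSON summary.
#'
#' @param config a `pipeline_config`.
#' @param out_dir optional output directory.
#' @return list with `data` (inputs used), `peaks`, `annotations`,
#'   `peak_summary`, `motif_scan`, `chore_pairs`, `discovery`,
#'   `de_results`, `de_split`, `enrichment`, `significance`, `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stage <- "load-inputs"
  result <- tryCatch({
    if (!is.null(config$simulation)) {
      stage <- "simulate"
      data <- simulate_experiment(config$simulation)
      genome <- data$genome; genes <- data$genes
      chip_tags <- data$chip; input_tags <- data$input
      expr <- data$expression$matrix
      cond <- data$expression$condition
    } else {
      p <- config$paths
      genome <- read_genome_fasta(p$genome)
      genes <- read_gene_models(p$genes)
      chip_tags <- read_tags(p$chip, genome)
      input_tags <- read_tags(p$input, genome)
      e <- read_expression_tsv(p$expression)
      expr <- e$matrix; cond <- e$condition
      data <- list(genome = genome, genes = genes, sites = NULL)
    }

    stage <- "coverage"
    clen <- chrom_lengths(genome)
    chip_cov <- build_coverage(chip_tags, config$extension_length, clen)
    input_cov <- build_coverage(input_tags, config$extension_length, clen)

    stage <- "callpeaks"
    peaks <- call_peaks(chip_cov, input_cov, config$min_height,
                        config$min_ratio, merge_gap = config$merge_gap)
    peak_summary <- summarize_peaks(peaks)

    stage <- "annotate"
    ann <- annotate_peaks(peaks, genes)

    stage <- "motifscan"
    pseq <- peak_sequences(genome, peaks, pad = 50)
    motif_pwm <- consensus_to_pwm(config$motif_consensus, pseudocount = 0.01)
    scan <- if (length(pseq) > 0L)
      scan_sequences(pseq, motif_pwm, config$scan_alpha) else NULL
    ebox_pwm <- consensus_to_pwm(config$ebox_consensus, pseudocount = 0.01)
    pairs <- if (length(pseq) > 0L)
      find_chore_pairs(pseq, ebox_pwm, config$spacer, config$site_alpha)
      else NULL

    stage <- "motifdiscover"
    discovery <- NULL
    if (config$discover_width > 0L && length(pseq) >= 5L &&
        all(nchar(pseq) > config$discover_width)) {
      discovery <- discover_motif_em(pseq, config$discover_width,
                                     n_starts = config$discover_n_starts,
                                     seed = config$seed)
    }

    stage <- "rank"
    de <- moderated_t_ppde(expr, cond, nu0 = config$nu0)
    de <- rank_genes(de, key = config$rank_key)

    stage <- "enrich"
    targets <- unique(ann$gene_id[!is.na(ann$gene_id)])
    enr <- NULL; sig <- NULL; split <- NULL
    n_targets_in_list <- length(intersect(targets, de$gene_id))
    if (n_targets_in_list > 0L && n_targets_in_list < nrow(de)) {
      enr <- ks_enrichment(de$gene_id, targets)
      sig <- ks_significance(enr, n_perm = config$n_perm, seed = config$seed)
      split <- split_targets_by_direction(targets, de, config$ppde_cutoff)
    }

    list(data = data, peaks = peaks, annotations = ann,
         peak_summary = peak_summary, motif_scan = scan,
         chore_pairs = pairs, discovery = discovery, de_results = de,
         de_split = split, enrichment = enr, significance = sig)
  }, error = function(e) {
    fail("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })

  cf <- category_fractions(result$annotations)
  summary <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_chip_tags = nrow(if (!is.null(config$simulation)) result$data$chip else data.frame()),
    n_peaks = result$peak_summary$count,
    mean_peak_width = result$peak_summary$mean_width,
    median_peak_width = result$peak_summary$median_width,
    category_fractions = as.list(cf),
    frac_peaks_with_motif = if (!is.null(result$motif_scan))
      result$motif_scan$frac_with_hit else NA,
    frac_peaks_with_chore_pair = if (!is.null(result$chore_pairs))
      mean(result$peaks$peak_id %in% result$chore_pairs$seq_id) else NA,
    n_genes_ranked = nrow(result$de_results),
    n_de_genes = sum(result$de_results$ppde >= config$ppde_cutoff),
    n_targets = if (!is.null(result$enrichment)) result$enrichment$Nh else 0L,
    n_bound_de_up = if (!is.null(result$de_split)) result$de_split$n_up else NA,
    n_bound_de_down = if (!is.null(result$de_split)) result$de_split$n_down else NA,
    ks_es = if (!is.null(result$enrichment)) result$enrichment$ES else NA,
    ks_p_perm = if (!is.null(result$significance)) result$significance$p_perm else NA
  )
  result$summary <- summary

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"),
                     file.path(out_dir, "config.yaml"))
    write_peaks_bed(result$peaks, file.path(out_dir, "peaks.bed"))
    utils::write.table(result$annotations, file.path(out_dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(result$motif_scan))
      utils::write.table(result$motif_scan$hits,
                         file.path(out_dir, "motif_hits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(result$chore_pairs))
      utils::write.table(result$chore_pairs,
                         file.path(out_dir, "chore_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(result$discovery))
      write_meme(result$discovery$pwm, file.path(out_dir, "discovered_motif.meme"),
                 name = "discovered")
    write_de_tsv(result$de_results, file.path(out_dir, "de_results.tsv"))
    if (!is.null(result$enrichment))
      write_enrichment_tsv(result$enrichment, result$significance,
                           file.path(out_dir, "running_sum.tsv"),
                           file.path(out_dir, "enrichment.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(format_pipeline_summary(summary), file.path(out_dir, "summary.txt"))
  }
  result
}

format_pipeline_summary <- function(s) {
  fr <- unlist(s$category_fractions)
  c(sprintf("seed: %d  config: %s", s$seed, s$config_hash),
    sprintf("peaks: %d (mean width %s bp, median %s bp)", s$n_peaks,
            format(s$mean_peak_width, digits = 4),
            format(s$median_peak_width, digits = 4)),
    sprintf("category fractions: %s",
            paste(sprintf("%s=%.2f", names(fr), fr), collapse = " ")),
    sprintf("peaks with motif: %s; with ChoRE pair: %s",
            format(s$frac_peaks_with_motif, digits = 3),
            format(s$frac_peaks_with_chore_pair, digits = 3)),
    sprintf("genes ranked: %d; significant (PPDE): %d", s$n_genes_ranked,
            s$n_de_genes),
    sprintf("bound & regulated: %s up / %s down of %d targets",
            format(s$n_bound_de_up), format(s$n_bound_de_down), s$n_targets),
    sprintf("KS enrichment: ES = %s, p_perm = %s",
            format(s$ks_es, digits = 4), format(s$ks_p_perm, digits = 4)))
}
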