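## Running-sum Kolmogorov-Smirnov enrichment of binding targets within a
## ranked expression list (the unweighted, classic GSEA-style statistic),
## its permutation and exact significance, the up/down split of bound
## differentially expressed genes, and hypergeometric over-representation
## of gene sets.
##
## Walking the ranked list, a target ("hit") adds +1/Nh and a non-target
## ("miss") adds -1/(N-Nh); the running sum therefore ends exactly at 0 and
## its maximum over prefixes is the enrichment score ES in [0, 1].

#' Running-sum KS enrichment of a target set in a ranked list
#'
#' @param ranked_list character vector of gene ids, best rank first.
#' @param target_set character vector of target gene ids; the intersection
#'   with `ranked_list` must be non-empty and strictly smaller than the
#'   whole list.
#' @return list of class `ks_enrichment`: `N`, `Nh`, `running_sum`
#'   (length N), `ES` (max prefix sum), `ES_min`, `argmax` (rank of the
#'   maximum), `leading_edge` (targets at or before the argmax),
#'   `hit_ranks`.
#' @export
ks_enrichment <- function(ranked_list, target_set) {
  if (anyDuplicated(ranked_list)) fail("ranked_list contains duplicate ids")
  N <- length(ranked_list)
  is_hit <- ranked_list %in% target_set
  Nh <- sum(is_hit)
  if (Nh == 0L) fail("no target gene appears in the ranked list")
  if (Nh == N) fail("target set covers the whole ranked list (degenerate)")
  steps <- ifelse(is_hit, 1 / Nh, -1 / (N - Nh))
  rs <- cumsum(steps)
  argmax <- which.max(rs)
  structure(list(N = N, Nh = Nh, running_sum = rs, ES = max(rs),
                 ES_min = min(rs), argmax = argmax,
                 leading_edge = ranked_list[seq_len(argmax)][is_hit[seq_len(argmax)]],
                 hit_ranks = which(is_hit)),
            class = "ks_enrichment")
}

## ES for target positions given as rank indices; `positions` may be a
## matrix (one permutation per row) for vectorized evaluation.
es_from_positions <- function(N, positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1L)
  Nh <- ncol(positions)
  hit_step <- 1 / Nh + 1 / (N - Nh)
  ## running sum at sorted hit position p_k equals
  ## k * hit_step - p_k / (N - Nh); the max over prefixes is attained at a
  ## hit position (the sum only increases there)
  sorted <- t(apply(positions, 1L, sort))
  if (Nh == 1L) sorted <- matrix(sorted, ncol = 1L)
  k <- matrix(seq_len(Nh), nrow(sorted), Nh, byrow = TRUE)
  vals <- k * hit_step - sorted / (N - Nh)
  apply(vals, 1L, max)
}

#' Significance of a KS enrichment score
#'
#' Permutation p-value: target placements are drawn uniformly over rank
#' subsets of size `Nh` (equivalent to permuting gene labels), and the
#' add-one estimator `p = (1 + #{ES* >= ES}) / (1 + n_perm)` is reported.
#' When `choose(N, Nh)` does not exceed `exact_limit`, the exact p-value
#' over all placements is computed as well.
#'
#' @param result a `ks_enrichment`.
#' @param n_perm number of permutations (a warning is issued below 100).
#' @param seed RNG seed for the permutations.
#' @param exact_limit compute the exact p when `choose(N, Nh)` is at most
#'   this.
#' @return list with `p_perm`, `p_exact` (`NA` when infeasible), `n_perm`,
#'   `es_observed`.
#' @export
ks_significance <- function(result, n_perm = 1000, seed = 1,
                            exact_limit = 1e6) {
  stopifnot(inherits(result, "ks_enrichment"))
  if (n_perm < 100) warning("fewer than 100 permutations; p_perm is coarse")
  N <- result$N; Nh <- result$Nh
  es_obs <- result$ES
  set.seed(as.integer(seed))
  perm <- matrix(0L, n_perm, Nh)
  for (b in seq_len(n_perm)) perm[b, ] <- sample.int(N, Nh)
  es_perm <- es_from_positions(N, perm)
  p_perm <- (1 + sum(es_perm >= es_obs - 1e-12)) / (1 + n_perm)
  p_exact <- NA_real_
  if (choose(N, Nh) <= exact_limit) {
    all_pos <- t(utils::combn(N, Nh))
    es_all <- es_from_positions(N, all_pos)
    p_exact <- mean(es_all >= es_obs - 1e-12)
  }
  list(p_perm = p_perm, p_exact = p_exact, n_perm = n_perm,
       es_observed = es_obs)
}

#' Split binding targets by direction of differential expression
#'
#' Intersects the target genes with the significant DE genes and
#' partitions by the sign of the log2 fold change.
#'
#' @param target_genes character vector of bound gene ids.
#' @param de_results output of [moderated_t_ppde()].
#' @param ppde_cutoff,p_cutoff passed to [de_gene_list()].
#' @return list with `n_up`, `n_down`, `frac_up`, `up`, `down`.
#' @export
split_targets_by_direction <- function(target_genes, de_results,
                                       ppde_cutoff = 0.95, p_cutoff = NULL) {
  de <- de_gene_list(de_results, ppde_cutoff, p_cutoff)
  up <- intersect(target_genes, de$up)
  down <- intersect(target_genes, de$down)
  n <- length(up) + length(down)
  list(n_up = length(up), n_down = length(down),
       frac_up = if (n > 0) length(up) / n else NA_real_,
       up = up, down = down)
}

#' Hypergeometric over-representation of gene sets
#'
#' One-sided upper-tail hypergeometric test of the target list against each
#' gene set (intersected with the universe), with Benjamini-Hochberg FDR
#' across sets.
#'
#' @param target_genes character vector (must be a subset of `universe`).
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all considered gene ids.
#' @return `data.frame` sorted by p: `set`, `set_size`, `overlap`,
#'   `expected`, `pvalue`, `fdr`.
#' @export
ora_hypergeometric <- function(target_genes, gene_sets, universe) {
  if (length(universe) == 0L) fail("empty universe")
  universe <- unique(universe)
  if (!all(target_genes %in% universe))
    fail("target_genes must be a subset of the universe")
  targets <- unique(target_genes)
  n_t <- length(targets); n_u <- length(universe)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(s, targets))
    K <- length(s)
    p <- stats::phyper(k - 1, K, n_u - K, n_t, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k,
               expected = n_t * K / n_u, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$pvalue, out$set), ]
  rownames(out) <- NULL
  out
}

#' Read / write gene sets in GMT format
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) fail("line %d: GMT lines need name, description, >=1 gene",
                     which(bad)[1L])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @param gene_sets named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write the enrichment running-sum profile and report
#'
#' @param result a `ks_enrichment`.
#' @param sig optional output of [ks_significance()].
#' @param profile_path TSV of `rank`, `running_sum`.
#' @param report_path TSV with one row of summary statistics.
#' @return invisibly, `NULL`.
#' @export
write_enrichment_tsv <- function(result, sig = NULL, profile_path,
                                 report_path) {
  utils::write.table(
    data.frame(rank = seq_len(result$N), running_sum = result$running_sum),
    profile_path, sep = "\t", quote = FALSE, row.names = FALSE)
  rep_df <- data.frame(N = result$N, Nh = result$Nh, ES = result$ES,
                       ES_min = result$ES_min,
                       p_perm = if (is.null(sig)) NA else sig$p_perm,
                       p_exact = if (is.null(sig)) NA else sig$p_exact)
  utils::write.table(rep_df, report_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
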