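## Two-condition differential-expression ranking: log2 fold change, a
## moderated t statistic with an explicit variance prior, and a PPDE-like
## posterior probability of differential expression obtained from a
## beta-uniform mixture (BUM) fitted to the p-value distribution by EM.
##
## The variance shrinkage is s~^2 = (nu0 * s0^2 + d * s^2) / (nu0 + d)
## with d the per-gene residual degrees of freedom; t = log2FC /
## (s~ * sqrt(1/n1 + 1/n2)), two-sided p from a t distribution with
## nu0 + d df. With nu0 = 0 this reduces exactly to the ordinary pooled
## two-sample t-test.

#' Read / write an expression matrix TSV
#'
#' Rows are genes; columns are samples named `<condition>_r<i>` so that the
#' condition factor can be recovered from the header.
#'
#' @param path TSV path.
#' @return list with `matrix` (numeric, rownames = gene ids) and
#'   `condition` (factor in column order, first-seen level first).
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  cond <- sub("_r[0-9]+$", "", colnames(mat))
  list(matrix = mat, condition = factor(cond, levels = unique(cond)))
}

#' @rdname read_expression_tsv
#' @param mat numeric matrix (rownames = gene ids, colnames =
#'   `<condition>_r<i>`).
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

condition_split <- function(condition) {
  condition <- as.factor(condition)
  lev <- levels(condition)
  if (length(lev) != 2L) fail("exactly two conditions are required")
  list(c1 = which(condition == lev[1L]), c2 = which(condition == lev[2L]),
       levels = lev)
}

#' Per-gene log2 fold changes
#'
#' Difference of condition means on the log2 scale (condition 2 minus
#' condition 1, conditions in factor-level order). Genes with all values
#' missing in either condition are excluded with a warning.
#'
#' @param mat log2 expression matrix (genes x samples).
#' @param condition two-level factor over the columns.
#' @return named numeric vector of log2 fold changes.
#' @export
compute_fold_changes <- function(mat, condition) {
  cs <- condition_split(condition)
  m1 <- rowMeans(mat[, cs$c1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(mat[, cs$c2, drop = FALSE], na.rm = TRUE)
  lfc <- m2 - m1
  bad <- !is.finite(lfc)
  if (any(bad)) {
    warning(sprintf("%d gene(s) with no finite values in a condition excluded",
                    sum(bad)))
    lfc <- lfc[!bad]
  }
  lfc
}

## EM fit of the beta-uniform mixture f(p) = lambda + (1-lambda) a p^(a-1)
fit_bum <- function(p, lambda0 = 0.5, a0 = 0.5, tol = 1e-8, max_iter = 500) {
  p <- pmin(pmax(p, 1e-12), 1)
  lambda <- lambda0; a <- a0
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    beta_dens <- a * p^(a - 1)
    denom <- lambda + (1 - lambda) * beta_dens
    z <- (1 - lambda) * beta_dens / denom     # posterior non-null
    ll <- sum(log(denom))
    if (ll - ll_old < tol && iter > 1L) break
    ll_old <- ll
    lambda <- 1 - mean(z)
    sz <- sum(z)
    a <- if (sz > 0) min(max(-sz / sum(z * log(p)), 1e-4), 1) else 1
    lambda <- min(max(lambda, 1e-6), 1 - 1e-6)
  }
  ## Under a global null the likelihood is flat along the a = 1 ridge, so
  ## the raw mixing weight lambda is not identified there; the density of
  ## the fitted mixture at p = 1, lambda + (1 - lambda) * a, is the
  ## identifiable (upper-bound) estimate of the null-gene fraction and is
  ## reported as pi0.
  list(lambda = lambda, a = a, pi0 = lambda + (1 - lambda) * a,
       loglik = ll, n_iter = iter)
}

#' Moderated t statistics and PPDE posteriors
#'
#' Computes, per gene, the log2 fold change, a moderated t with the prior
#' `(nu0, s0^2)` blended into the pooled residual variance, a two-sided
#' p-value on `nu0 + d` degrees of freedom, and the posterior probability
#' of differential expression (PPDE) under a beta-uniform mixture fitted to
#' all p-values: `PPDE_i = (1-lambda) a p_i^(a-1) / (lambda +
#' (1-lambda) a p_i^(a-1))`.
#'
#' Genes with fewer than 2 observed replicates in either condition are
#' dropped.
#'
#' @param mat log2 expression matrix (genes x samples).
#' @param condition two-level factor over the columns.
#' @param nu0 prior degrees of freedom (0 recovers the ordinary pooled
#'   two-sample t exactly).
#' @param s02 prior variance; `NULL` uses the median per-gene pooled
#'   variance.
#' @return `data.frame` (one row per gene, ranked by PPDE): `gene_id`,
#'   `log2fc`, `t`, `df`, `pvalue`, `ppde`, `rank`; the BUM fit is attached
#'   as `attr(, "bum")`.
#' @export
moderated_t_ppde <- function(mat, condition, nu0 = 4, s02 = NULL) {
  cs <- condition_split(condition)
  n1 <- rowSums(!is.na(mat[, cs$c1, drop = FALSE]))
  n2 <- rowSums(!is.na(mat[, cs$c2, drop = FALSE]))
  keep <- n1 >= 2L & n2 >= 2L
  if (!all(keep)) {
    warning(sprintf("%d gene(s) with <2 observed replicates dropped",
                    sum(!keep)))
    mat <- mat[keep, , drop = FALSE]
    n1 <- n1[keep]; n2 <- n2[keep]
  }
  m1 <- rowMeans(mat[, cs$c1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(mat[, cs$c2, drop = FALSE], na.rm = TRUE)
  v1 <- apply(mat[, cs$c1, drop = FALSE], 1L, stats::var, na.rm = TRUE)
  v2 <- apply(mat[, cs$c2, drop = FALSE], 1L, stats::var, na.rm = TRUE)
  d <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d
  if (is.null(s02)) s02 <- stats::median(s2)
  if (nu0 == 0 && all(s2 == 0))
    fail("all residual variances are zero; use a nonzero prior (nu0 > 0)")
  s2_mod <- (nu0 * s02 + d * s2) / (nu0 + d)
  lfc <- m2 - m1
  tstat <- lfc / sqrt(s2_mod * (1 / n1 + 1 / n2))
  pval <- 2 * stats::pt(abs(tstat), df = nu0 + d, lower.tail = FALSE)
  bum <- fit_bum(pval)
  pc <- pmin(pmax(pval, 1e-12), 1)
  beta_dens <- bum$a * pc^(bum$a - 1)
  ppde <- (1 - bum$lambda) * beta_dens / (bum$lambda + (1 - bum$lambda) * beta_dens)
  res <- data.frame(gene_id = rownames(mat), log2fc = lfc, t = tstat,
                    df = nu0 + d, pvalue = pval, ppde = ppde,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res <- rank_genes(res, key = "ppde")
  attr(res, "bum") <- bum
  res
}

#' Rank genes by a differential-expression key
#'
#' Descending order of the key; ties broken by |log2FC| (descending), then
#' lexicographic gene id — fully deterministic regardless of input order.
#'
#' @param results `data.frame` with `gene_id`, `log2fc` and the key column.
#' @param key `"ppde"`, `"fold_change"` (ranks by signed log2FC, most
#'   up-regulated first) or `"abs_t"`.
#' @return the results with a `rank` column (1 = top), sorted by rank.
#' @export
rank_genes <- function(results, key = c("ppde", "fold_change", "abs_t")) {
  key <- match.arg(key)
  kv <- switch(key,
               ppde = results$ppde,
               fold_change = results$log2fc,
               abs_t = abs(results$t))
  o <- order(-kv, -abs(results$log2fc), results$gene_id)
  results <- results[o, , drop = FALSE]
  results$rank <- seq_len(nrow(results))
  rownames(results) <- NULL
  results
}

#' Significant gene lists, split by direction
#'
#' @param results output of [moderated_t_ppde()].
#' @param ppde_cutoff call a gene responsive when `ppde >= ppde_cutoff`
#'   (default 0.95); set to `NULL` to use `p_cutoff` instead.
#' @param p_cutoff p-value cutoff, used when `ppde_cutoff` is `NULL`.
#' @return list with character vectors `up` and `down`.
#' @export
de_gene_list <- function(results, ppde_cutoff = 0.95, p_cutoff = NULL) {
  sig <- if (!is.null(ppde_cutoff)) {
    results$ppde >= ppde_cutoff
  } else {
    if (is.null(p_cutoff)) fail("provide ppde_cutoff or p_cutoff")
    results$pvalue <= p_cutoff
  }
  list(up = results$gene_id[sig & results$log2fc > 0],
       down = results$gene_id[sig & results$log2fc < 0])
}

#' Write a differential-expression results TSV
#'
#' @param results output of [moderated_t_ppde()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
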