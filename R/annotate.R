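## Peak-to-gene annotation: nearest TSS within a window, signed distances
## (negative = upstream of the TSS in the gene's orientation), and genomic
## feature categorization of each peak summit.
##
## The summit, not the peak span, determines both the distance and the
## category. Single-label categories follow the precedence
##   proximal_promoter > distal_promoter > utr5 > utr3 > exon >
##   intron_1_2 > intron_other > intergenic
## while the multi-label set records every feature the summit overlaps
## across all genes (so multi-label fractions may sum to more than 1).

PEAK_CATEGORIES <- c("proximal_promoter", "distal_promoter", "utr5", "utr3",
                     "exon", "intron_1_2", "intron_other", "intergenic")

## signed summit-to-TSS distance in the gene's orientation
signed_tss_distance <- function(summit, tss, strand) {
  ifelse(strand == "+", summit - tss, tss - summit)
}

#' Assign the nearest gene (by TSS) to each peak
#'
#' The assigned gene is the one whose TSS is closest to the peak summit,
#' provided the absolute distance is below `max_distance` (strictly).
#' Distances are signed in the gene's orientation: negative = upstream of
#' the TSS. Equidistant ties go to the lexicographically smaller gene id.
#'
#' @param peaks peak `data.frame` from [call_peaks()].
#' @param genes gene-model `data.frame`.
#' @param max_distance maximum |distance| in bp (default 20 kb).
#' @return `data.frame` with `peak_id`, `gene_id` (`NA` if none in range),
#'   `distance` (signed bp, `NA` if unassigned).
#' @export
assign_nearest_gene <- function(peaks, genes, max_distance = 20000) {
  tss <- tss_of(genes)
  out <- data.frame(peak_id = peaks$peak_id, gene_id = NA_character_,
                    distance = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    g <- which(genes$chrom == peaks$chrom[i])
    if (length(g) == 0L) next
    d <- signed_tss_distance(peaks$summit[i], tss[g], genes$strand[g])
    ok <- abs(d) < max_distance
    if (!any(ok)) next
    g <- g[ok]; d <- d[ok]
    o <- order(abs(d), genes$gene_id[g])
    out$gene_id[i] <- genes$gene_id[g[o[1L]]]
    out$distance[i] <- as.integer(d[o[1L]])
  }
  out
}

## all feature labels a single summit position overlaps for one gene
summit_features_for_gene <- function(summit, gene, proximal_bp = 2000,
                                     distal_bp = 5000) {
  labs <- character()
  tss <- if (gene$strand == "+") gene$tx_start else gene$tx_end - 1L
  d <- signed_tss_distance(summit, tss, gene$strand)
  if (d >= -proximal_bp && d < 0) labs <- c(labs, "proximal_promoter")
  if (d >= -distal_bp && d < -proximal_bp) labs <- c(labs, "distal_promoter")
  if (summit >= gene$tx_start && summit < gene$tx_end) {
    es <- gene$exon_starts[[1L]]; ee <- gene$exon_ends[[1L]]
    in_exon <- any(summit >= es & summit < ee)
    coding <- !is.na(gene$cds_start)
    if (in_exon) {
      if (coding) {
        before_cds <- summit < gene$cds_start
        after_cds <- summit >= gene$cds_end
        utr5 <- (gene$strand == "+" && before_cds) ||
                (gene$strand == "-" && after_cds)
        utr3 <- (gene$strand == "+" && after_cds) ||
                (gene$strand == "-" && before_cds)
        labs <- c(labs, if (utr5) "utr5" else if (utr3) "utr3" else "exon")
      } else {
        labs <- c(labs, "exon")
      }
    } else {
      ## which intron, in transcription order (1-based)
      k <- max(which(summit >= ee))      # intron after exon k (genomic order)
      n_introns <- length(es) - 1L
      idx <- if (gene$strand == "+") k else n_introns - k + 1L
      labs <- c(labs, if (idx <= 2L) "intron_1_2" else "intron_other")
    }
  }
  labs
}

#' Categorize peaks by genomic feature
#'
#' For each peak summit, computes the multi-label feature set over all
#' genes on the same chromosome and derives the single category by
#' precedence. Promoter windows are strand-aware: proximal = within 2 kb
#' upstream of the TSS, distal = 2-5 kb upstream.
#'
#' @param peaks peak `data.frame`.
#' @param genes gene-model `data.frame`.
#' @param proximal_bp,distal_bp strand-aware upstream windows (bp) defining
#'   the proximal and distal promoter. The published convention of "within
#'   2 kb upstream" and a wider "promoter" window can be explored by
#'   varying these; the defaults use 2 kb / 5 kb.
#' @return `data.frame` with `peak_id`, `category` (factor over all
#'   categories) and `multilabels` (comma-joined feature labels, empty for
#'   intergenic).
#' @export
categorize_peaks <- function(peaks, genes, proximal_bp = 2000,
                             distal_bp = 5000) {
  cats <- character(nrow(peaks)); multis <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    g <- which(genes$chrom == peaks$chrom[i])
    labs <- character()
    for (j in g) {
      labs <- c(labs, summit_features_for_gene(peaks$summit[i], genes[j, ],
                                               proximal_bp, distal_bp))
    }
    labs <- unique(labs)
    cats[i] <- if (length(labs) == 0L) "intergenic" else
      PEAK_CATEGORIES[min(match(labs, PEAK_CATEGORIES))]
    multis[i] <- paste(labs, collapse = ",")
  }
  data.frame(peak_id = peaks$peak_id,
             category = factor(cats, levels = PEAK_CATEGORIES),
             multilabels = multis, stringsAsFactors = FALSE)
}

#' Full peak annotation table
#'
#' Combines [assign_nearest_gene()] and [categorize_peaks()].
#'
#' @inheritParams assign_nearest_gene
#' @return `data.frame` with `peak_id`, `gene_id`, `distance`, `category`,
#'   `multilabels`.
#' @export
annotate_peaks <- function(peaks, genes, max_distance = 20000) {
  cbind(assign_nearest_gene(peaks, genes, max_distance),
        categorize_peaks(peaks, genes)[, c("category", "multilabels")])
}

#' Category fractions (single-label scheme)
#'
#' @param annotations output of [annotate_peaks()] or [categorize_peaks()].
#' @return named numeric vector of fractions summing to 1 (empty input:
#'   all zero).
#' @export
category_fractions <- function(annotations) {
  tab <- table(annotations$category)
  n <- sum(tab)
  if (n == 0L) return(stats::setNames(rep(0, length(PEAK_CATEGORIES)),
                                      PEAK_CATEGORIES))
  as.numeric(tab) / n -> fr
  stats::setNames(fr, names(tab))
}

#' Histogram of signed summit-to-TSS distances
#'
#' Counts assigned peaks in half-open bins over `[-window, +window)`;
#' unassigned peaks are excluded.
#'
#' @param annotations output of [annotate_peaks()] or
#'   [assign_nearest_gene()].
#' @param window half-width in bp.
#' @param bin_width bin width in bp; must divide `window`.
#' @return `data.frame` with `bin_start`, `bin_end`, `count`.
#' @export
tss_distance_profile <- function(annotations, window = 20000, bin_width = 1000) {
  if (window %% bin_width != 0) fail("bin_width must divide window")
  edges <- seq(-window, window, by = bin_width)
  d <- annotations$distance[!is.na(annotations$distance)]
  d <- d[d >= -window & d < window]
  idx <- floor((d + window) / bin_width) + 1L
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(bin_start = utils::head(edges, -1L), bin_end = edges[-1L],
             count = counts)
}
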