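## Readers/writers for the standard formats the pipeline touches, plus the
## shared coordinate and TSS conventions every other stage builds on.
##
## Conventions (used everywhere in this package):
##   * intervals are 0-based half-open, as in BED;
##   * the TSS of a plus-strand gene is tx_start, of a minus-strand gene
##     tx_end - 1 (the last transcribed base);
##   * tags are never deduplicated on input.

# ---------------------------------------------------------------------------
# Genome sequences
# ---------------------------------------------------------------------------

#' Read a genome from a FASTA file
#'
#' Returns a named character vector of uppercase chromosome sequences over
#' `{A,C,G,T,N}`. Chromosome names must be unique; any other letter is an
#' error.
#'
#' @param path path to a FASTA file.
#' @return named character vector (one element per chromosome) with
#'   attribute-free uppercase sequences; chromosome lengths are
#'   `nchar()` of the elements.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  genome <- toupper(as.character(ss))
  names(genome) <- sub("\\s.*$", "", names(ss))
  validate_genome(genome)
}

#' Write a genome to FASTA
#'
#' @param genome named character vector as returned by [read_genome_fasta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  validate_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path, width = 70L)
  invisible(path)
}

validate_genome <- function(genome) {
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    fail("genome chromosome names must be present and unique")
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad))
    fail("chromosome '%s' contains characters outside {A,C,G,T,N}",
         names(genome)[bad][1L])
  genome
}

chrom_lengths <- function(genome) {
  stats::setNames(nchar(genome), names(genome))
}

# ---------------------------------------------------------------------------
# Gene models
# ---------------------------------------------------------------------------

#' Gene models: constructor and validation
#'
#' A gene-model table has one row per gene with columns `gene_id`, `chrom`,
#' `strand` (`+`/`-`), `tx_start`, `tx_end` (0-based half-open),
#' `cds_start`, `cds_end` (`NA` for non-coding genes) and list-columns
#' `exon_starts`, `exon_ends` (integer vectors, 0-based half-open, sorted,
#' disjoint; the first exon starts at `tx_start`, the last ends at `tx_end`).
#'
#' @param gene_id,chrom,strand,tx_start,tx_end,cds_start,cds_end per-gene
#'   scalars (vectors of equal length).
#' @param exon_starts,exon_ends lists of integer vectors, one per gene.
#' @return validated `data.frame` of gene models.
#' @export
gene_models <- function(gene_id, chrom, strand, tx_start, tx_end,
                        exon_starts, exon_ends,
                        cds_start = NA_integer_, cds_end = NA_integer_) {
  gm <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    strand = as.character(strand),
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    cds_start = as.integer(rep_len(cds_start, length(gene_id))),
    cds_end = as.integer(rep_len(cds_end, length(gene_id))),
    stringsAsFactors = FALSE
  )
  gm$exon_starts <- lapply(exon_starts, as.integer)
  gm$exon_ends <- lapply(exon_ends, as.integer)
  validate_gene_models(gm)
}

#' @rdname gene_models
#' @param gm a gene-model `data.frame`.
#' @export
validate_gene_models <- function(gm) {
  if (anyDuplicated(gm$gene_id))
    fail("duplicate gene_id '%s'", gm$gene_id[duplicated(gm$gene_id)][1L])
  if (!all(gm$strand %in% c("+", "-")))
    fail("strand must be '+' or '-' (gene '%s')",
         gm$gene_id[!gm$strand %in% c("+", "-")][1L])
  for (i in seq_len(nrow(gm))) {
    id <- gm$gene_id[i]
    if (gm$tx_start[i] >= gm$tx_end[i])
      fail("gene '%s': tx_start must be < tx_end", id)
    es <- gm$exon_starts[[i]]; ee <- gm$exon_ends[[i]]
    if (length(es) == 0L || length(es) != length(ee))
      fail("gene '%s': exon_starts/exon_ends empty or of unequal length", id)
    if (any(es >= ee)) fail("gene '%s': empty or inverted exon", id)
    if (is.unsorted(es, strictly = TRUE))
      fail("gene '%s': exons not sorted", id)
    if (length(es) > 1L && any(es[-1L] < ee[-length(ee)]))
      fail("gene '%s': overlapping exons", id)
    if (es[1L] != gm$tx_start[i] || ee[length(ee)] != gm$tx_end[i])
      fail("gene '%s': exons must span [tx_start, tx_end)", id)
    if (any(es < gm$tx_start[i]) || any(ee > gm$tx_end[i]))
      fail("gene '%s': exon outside transcript bounds", id)
    if (!is.na(gm$cds_start[i])) {
      if (is.na(gm$cds_end[i]) || gm$cds_start[i] >= gm$cds_end[i])
        fail("gene '%s': invalid CDS bounds", id)
      if (gm$cds_start[i] < gm$tx_start[i] || gm$cds_end[i] > gm$tx_end[i])
        fail("gene '%s': CDS outside transcript bounds", id)
    }
  }
  gm
}

#' Read gene models from BED12 or GFF3
#'
#' The format is chosen by extension (`.bed` vs `.gff`/`.gff3`) unless
#' `format` is given. The BED12 dialect is standard (blockStarts relative to
#' chromStart; thickStart == thickEnd means non-coding). The GFF3 dialect
#' expects `gene` features with `ID=`, and `exon`/`CDS` features with
#' `Parent=` pointing at the gene ID; GFF3 coordinates (1-based closed) are
#' converted to 0-based half-open on input.
#'
#' Malformed lines raise an error naming the line number; invariant
#' violations (e.g. overlapping exons) raise an error naming the gene.
#'
#' @param path input file.
#' @param format `"bed12"`, `"gff3"` or `NULL` (guess from extension).
#' @return gene-model `data.frame` in file order (see [gene_models()]).
#' @export
read_gene_models <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed12"
  }
  switch(format,
    bed12 = read_gene_models_bed12(path),
    gff3 = read_gene_models_gff3(path),
    fail("unknown gene-model format '%s'", format)
  )
}

read_gene_models_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(gene_models(character(), character(), character(), integer(),
                       integer(), list(), list())[0, ])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fld <- lengths(fields)
  if (any(n_fld < 12L))
    fail("line %d: expected 12 tab-separated BED12 fields, found %d",
         which(n_fld < 12L)[1L], n_fld[n_fld < 12L][1L])
  f <- function(k) vapply(fields, `[[`, "", k)
  chrom <- f(1); start <- suppressWarnings(as.integer(f(2)))
  end <- suppressWarnings(as.integer(f(3))); id <- f(4); strand <- f(6)
  thick_s <- suppressWarnings(as.integer(f(7)))
  thick_e <- suppressWarnings(as.integer(f(8)))
  if (anyNA(start) || anyNA(end) || anyNA(thick_s) || anyNA(thick_e))
    fail("line %d: non-integer coordinate field",
         which(is.na(start) | is.na(end) | is.na(thick_s) | is.na(thick_e))[1L])
  n_blocks <- suppressWarnings(as.integer(f(10)))
  parse_csv <- function(s, line) {
    v <- suppressWarnings(as.integer(strsplit(sub(",$", "", s), ",")[[1]]))
    if (anyNA(v)) fail("line %d: malformed block list '%s'", line, s)
    v
  }
  ex_s <- vector("list", length(lines)); ex_e <- ex_s
  for (i in seq_along(lines)) {
    sizes <- parse_csv(f(11)[i], i); offs <- parse_csv(f(12)[i], i)
    if (length(sizes) != n_blocks[i] || length(offs) != n_blocks[i])
      fail("line %d: blockCount disagrees with block lists", i)
    ex_s[[i]] <- start[i] + offs
    ex_e[[i]] <- start[i] + offs + sizes
  }
  coding <- thick_s < thick_e
  gene_models(id, chrom, strand, start, end, ex_s, ex_e,
              cds_start = ifelse(coding, thick_s, NA_integer_),
              cds_end = ifelse(coding, thick_e, NA_integer_))
}

read_gene_models_gff3 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep); lines <- lines[keep]
  if (length(lines) == 0L) {
    return(gene_models(character(), character(), character(), integer(),
                       integer(), list(), list())[0, ])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) != 9L
  if (any(bad)) fail("line %d: expected 9 GFF3 columns", lineno[bad][1L])
  f <- function(k) vapply(fields, `[[`, "", k)
  type <- f(3)
  start1 <- suppressWarnings(as.integer(f(4)))
  end1 <- suppressWarnings(as.integer(f(5)))
  if (anyNA(start1) || anyNA(end1))
    fail("line %d: non-integer coordinate", lineno[is.na(start1) | is.na(end1)][1L])
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
  }
  attrs <- f(9)
  ids <- attr_get(attrs, "ID"); parents <- attr_get(attrs, "Parent")
  gi <- which(type == "gene")
  if (any(is.na(ids[gi])))
    fail("line %d: gene feature without ID attribute", lineno[gi[is.na(ids[gi])]][1L])
  out <- vector("list", length(gi))
  for (k in seq_along(gi)) {
    i <- gi[k]; id <- ids[i]
    child <- which(parents == id)
    exo <- child[type[child] == "exon"]
    cds <- child[type[child] == "CDS"]
    if (length(exo) == 0L)
      fail("gene '%s': no exon features", id)
    es <- sort(start1[exo] - 1L); ee <- sort(end1[exo])
    out[[k]] <- list(
      id = id, chrom = f(1)[i], strand = f(7)[i],
      tx_start = start1[i] - 1L, tx_end = end1[i],
      ex_s = es, ex_e = ee,
      cds_s = if (length(cds)) min(start1[cds]) - 1L else NA_integer_,
      cds_e = if (length(cds)) max(end1[cds]) else NA_integer_
    )
  }
  gene_models(
    vapply(out, `[[`, "", "id"), vapply(out, `[[`, "", "chrom"),
    vapply(out, `[[`, "", "strand"),
    vapply(out, `[[`, 0L, "tx_start"), vapply(out, `[[`, 0L, "tx_end"),
    lapply(out, `[[`, "ex_s"), lapply(out, `[[`, "ex_e"),
    cds_start = vapply(out, `[[`, 0L, "cds_s"),
    cds_end = vapply(out, `[[`, 0L, "cds_e")
  )
}

#' Write gene models as BED12
#'
#' Inverse of [read_gene_models()] for the BED12 dialect: a
#' write-then-read round trip reproduces identical records.
#'
#' @param gm gene-model `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed12 <- function(gm, path) {
  validate_gene_models(gm)
  lines <- vapply(seq_len(nrow(gm)), function(i) {
    es <- gm$exon_starts[[i]]; ee <- gm$exon_ends[[i]]
    coding <- !is.na(gm$cds_start[i])
    paste(
      gm$chrom[i], gm$tx_start[i], gm$tx_end[i], gm$gene_id[i], 0L,
      gm$strand[i],
      if (coding) gm$cds_start[i] else gm$tx_start[i],
      if (coding) gm$cds_end[i] else gm$tx_start[i],
      "0", length(es),
      paste0(paste(ee - es, collapse = ","), ","),
      paste0(paste(es - gm$tx_start[i], collapse = ","), ","),
      sep = "\t"
    )
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Transcription start site of each gene
#'
#' `tx_start` for plus-strand genes, `tx_end - 1` (the last base, 0-based)
#' for minus-strand genes.
#'
#' @param gm gene-model `data.frame`.
#' @return integer vector of 0-based TSS positions, one per gene.
#' @export
tss_of <- function(gm) {
  ifelse(gm$strand == "+", gm$tx_start, gm$tx_end - 1L)
}

# ---------------------------------------------------------------------------
# Tag alignments
# ---------------------------------------------------------------------------

#' Read mapped sequence tags from a BED6 file
#'
#' Tags are short mapped reads: `chrom`, `start` (0-based), `strand`, and a
#' read length taken from `end - start`. The BED score column is ignored.
#' Duplicate identical lines are retained — the pipeline does not
#' deduplicate tags (only multi-mapping reads are assumed removed upstream,
#' which is the caller's concern, not this reader's).
#'
#' @param path BED6 file of tags.
#' @param genome optional genome (named character vector) or named vector of
#'   chromosome lengths; when given, tags on unknown chromosomes or
#'   overrunning a chromosome end are an error.
#' @param dedup collapse tags with identical chrom/start/strand/length to a
#'   single copy. Off by default: upstream processing is assumed to have
#'   removed multi-mapping reads only, and whether PCR duplicates should
#'   also be collapsed is left to the caller.
#' @return `data.frame` with columns `chrom`, `start`, `strand`,
#'   `read_length`, in file order.
#' @export
read_tags <- function(path, genome = NULL, dedup = FALSE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), read_length = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 6L
  if (any(bad)) fail("line %d: expected 6 BED columns", which(bad)[1L])
  f <- function(k) vapply(fields, `[[`, "", k)
  start <- suppressWarnings(as.integer(f(2)))
  end <- suppressWarnings(as.integer(f(3)))
  if (anyNA(start) || anyNA(end))
    fail("line %d: non-integer coordinate", which(is.na(start) | is.na(end))[1L])
  tags <- data.frame(chrom = f(1), start = start, strand = f(6),
                     read_length = end - start, stringsAsFactors = FALSE)
  if (!all(tags$strand %in% c("+", "-")))
    fail("line %d: strand must be '+' or '-'",
         which(!tags$strand %in% c("+", "-"))[1L])
  if (any(tags$start < 0L))
    fail("line %d: negative start", which(tags$start < 0L)[1L])
  if (!is.null(genome)) {
    len <- if (is.character(genome)) chrom_lengths(genome) else genome
    unk <- !(tags$chrom %in% names(len))
    if (any(unk))
      fail("line %d: unknown chromosome '%s'", which(unk)[1L],
           tags$chrom[unk][1L])
    over <- tags$start + tags$read_length > len[tags$chrom]
    if (any(over))
      fail("line %d: tag overruns end of chromosome '%s'",
           which(over)[1L], tags$chrom[over][1L])
  }
  if (dedup) {
    tags <- tags[!duplicated(tags), , drop = FALSE]
    rownames(tags) <- NULL
  }
  message(sprintf("read %d tags on %d chromosome(s) from %s",
                  nrow(tags), length(unique(tags$chrom)), path))
  tags
}

#' Write tags as BED6
#'
#' @param tags tag `data.frame` as from [read_tags()].
#' @param path output path.
#' @param name name stem for the BED name column.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path, name = "tag") {
  lines <- paste(tags$chrom, tags$start, tags$start + tags$read_length,
                 paste0(name, seq_len(nrow(tags))), 0L, tags$strand,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
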