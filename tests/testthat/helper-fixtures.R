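## Shared fixtures and independent brute-force oracles. Everything here is
## built in code at test time; oracles deliberately use explicit per-base /
## per-pair loops so they share no code path with the implementation.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## coverage_track built directly from per-bp vectors (bypasses build_coverage)
make_track <- function(cov_list, n_tags, extension = 200L) {
  structure(list(cov = lapply(cov_list, as.integer),
                 extension = as.integer(extension), n_tags = n_tags),
            class = "coverage_track")
}

## Brute-force peak caller: per-base predicate loop, explicit run collection
## and merging. Independent oracle for call_peaks().
oracle_call_peaks <- function(chip, input, min_height = 8, min_ratio = 5,
                              pseudocount = 1, merge_gap = 100) {
  scale <- if (input$n_tags > 0) chip$n_tags / input$n_tags else 1
  rows <- list()
  for (chrom in names(chip$cov)) {
    cc <- chip$cov[[chrom]]
    ic <- input$cov[[chrom]]
    ok <- logical(length(cc))
    for (i in seq_along(cc)) {
      den <- max(ic[i] * scale, pseudocount)
      ok[i] <- (cc[i] >= min_height) && (cc[i] / den >= min_ratio)
    }
    runs <- list()
    i <- 1L
    while (i <= length(ok)) {
      if (ok[i]) {
        j <- i
        while (j < length(ok) && ok[j + 1L]) j <- j + 1L
        runs[[length(runs) + 1L]] <- c(i, j)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
    merged <- list()
    for (r in runs) {
      if (length(merged) > 0L &&
          r[1L] - merged[[length(merged)]][2L] - 1L <= merge_gap) {
        merged[[length(merged)]][2L] <- r[2L]
      } else {
        merged[[length(merged) + 1L]] <- r
      }
    }
    for (r in merged) {
      summit <- NA_integer_
      height <- -Inf
      for (i in r[1L]:r[2L]) {
        if (cc[i] > height) {
          height <- cc[i]
          summit <- i - 1L
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = r[1L] - 1L, end = r[2L],
        summit = summit, height = height, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), summit = integer(),
                      height = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(match(out$chrom, names(chip$cov)), out$start), , drop = FALSE]
}

## random coverage pair with occasional enriched blocks, for fuzzing
fuzz_tracks <- function() {
  L <- sample(200:2000, 1L)
  cc <- rpois(L, 2)
  for (k in seq_len(sample(0:4, 1L))) {
    w <- sample(5:120, 1L)
    s <- sample.int(L - w, 1L)
    cc[s:(s + w)] <- cc[s:(s + w)] + sample(5:30, 1L)
  }
  ic <- rpois(L, sample(c(0.5, 1, 2), 1L))
  list(chip = make_track(list(chrA = cc), n_tags = sample(1000:5000, 1L)),
       input = make_track(list(chrA = ic), n_tags = sample(1000:5000, 1L)))
}

## a coding plus-strand gene with 4 exons, used by the annotation truth table
toy_coding_gene <- function(gene_id = "gA", chrom = "chr1", strand = "+",
                            offset = 0L) {
  gene_models(gene_id, chrom, strand,
              tx_start = 10000L + offset, tx_end = 16000L + offset,
              exon_starts = list(c(10000L, 11500L, 12500L, 14000L) + offset),
              exon_ends = list(c(11000L, 12000L, 13000L, 16000L) + offset),
              cds_start = 10500L + offset, cds_end = 15500L + offset)
}

## peaks table with given summits on one chromosome (spans are +-10 bp)
peaks_at <- function(summits, chrom = "chr1") {
  summits <- as.integer(summits)
  data.frame(peak_id = sprintf("p%02d", seq_along(summits)), chrom = chrom,
             start = summits - 10L, end = summits + 10L, summit = summits,
             height = 10, ratio = 10, width = 20L, stringsAsFactors = FALSE)
}

## sequences of length `len` each embedding `el` at a random offset
embed_motif_seqs <- function(n, len, el) {
  w <- nchar(el)
  vapply(seq_len(n), function(i) {
    pos <- sample(0:(len - w), 1L)
    paste0(rand_dna(pos), el, rand_dna(len - w - pos))
  }, "")
}

## random letter-probability matrix as a pwm
random_pwm <- function(width) {
  m <- matrix(rgamma(4L * width, 1), 4L)
  m <- sweep(m, 2L, colSums(m), "/")
  choreseq:::new_pwm(m)
}
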