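## Tag-extension coverage and threshold peak calling.
##
## Tags are extended to the sonication fragment length in their strand
## direction and piled up per base; peaks are maximal runs where ChIP
## coverage reaches `min_height` AND the per-base ratio of ChIP to scaled
## input reaches `min_ratio` (the two stringency thresholds applied
## jointly), with nearby runs merged.

#' Build an extended-fragment coverage track
#'
#' Each plus-strand tag contributes 1 to `[start, start + extension)`; each
#' minus-strand tag to `[start + read_length - extension,
#' start + read_length)`. Intervals are clipped at chromosome bounds.
#'
#' @param tags tag `data.frame` (`chrom`, `start`, `strand`, `read_length`).
#' @param extension_length fragment extension in bp; must be >= the read
#'   length.
#' @param chrom_len named integer vector of chromosome lengths.
#' @return object of class `coverage_track`: list with `cov` (named list of
#'   per-bp integer vectors), `extension`, `n_tags`.
#' @export
build_coverage <- function(tags, extension_length, chrom_len) {
  if (any(extension_length < tags$read_length))
    fail("extension_length (%d) must be >= read length", extension_length)
  ext <- as.integer(extension_length)
  cov <- lapply(chrom_len, function(L) integer(L))
  for (chrom in names(chrom_len)) {
    t <- tags[tags$chrom == chrom, , drop = FALSE]
    L <- chrom_len[[chrom]]
    if (nrow(t) == 0L || L == 0L) next
    s <- ifelse(t$strand == "+", t$start, t$start + t$read_length - ext)
    e <- s + ext
    s <- pmax(s, 0L); e <- pmin(e, L)
    keep <- s < e
    s <- s[keep]; e <- e[keep]
    ## difference-array accumulation, O(tags + L)
    d <- integer(L + 1L)
    ts <- tabulate(s + 1L, nbins = L + 1L)
    te <- tabulate(e + 1L, nbins = L + 1L)
    cov[[chrom]] <- cumsum(ts - te)[seq_len(L)]
  }
  structure(list(cov = cov, extension = ext, n_tags = nrow(tags)),
            class = "coverage_track")
}

#' Call peaks from ChIP and input coverage
#'
#' Input coverage is scaled to the ChIP library size (`scale = ChIP tag
#' count / input tag count`). A base qualifies when ChIP coverage >=
#' `min_height` and ChIP / max(scaled input, pseudocount) >= `min_ratio`.
#' Maximal runs of qualifying bases separated by at most `merge_gap` bp are
#' merged into one peak. The summit is the leftmost base of maximal ChIP
#' coverage within the peak; `height` is the coverage there; `ratio` is
#' height over the maximum of scaled input within the peak (floored at the
#' pseudocount).
#'
#' Defaults follow the stringent setting of requiring at least 8
#' overlapping reads and a five-fold excess of ChIP over input.
#'
#' @param chip,input `coverage_track`s over identical chromosomes.
#' @param min_height minimum ChIP coverage (tags) at every peak base.
#' @param min_ratio minimum per-base ChIP/scaled-input ratio.
#' @param pseudocount floor for the scaled input in the ratio denominator.
#' @param merge_gap runs separated by <= this many bp are merged.
#' @return `data.frame` of peaks sorted by coordinate: `peak_id`, `chrom`,
#'   `start`, `end`, `summit`, `height`, `ratio`, `width`.
#' @export
call_peaks <- function(chip, input, min_height = 8, min_ratio = 5,
                       pseudocount = 1, merge_gap = 100) {
  if (!identical(names(chip$cov), names(input$cov)))
    fail("ChIP and input tracks cover different chromosomes")
  scale <- if (input$n_tags > 0) chip$n_tags / input$n_tags else 1
  out <- list()
  for (chrom in names(chip$cov)) {
    cc <- chip$cov[[chrom]]
    ic <- input$cov[[chrom]]
    if (length(cc) != length(ic))
      fail("chromosome '%s': track lengths differ", chrom)
    denom <- pmax(ic * scale, pseudocount)
    ok <- cc >= min_height & cc / denom >= min_ratio
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    rs <- starts[r$values]; re <- ends[r$values]  # 1-based inclusive runs
    ## merge runs with gaps <= merge_gap
    if (length(rs) > 1L) {
      gap <- rs[-1L] - re[-length(re)] - 1L
      new_group <- c(TRUE, gap > merge_gap)
      grp <- cumsum(new_group)
      rs <- tapply(rs, grp, min)
      re <- tapply(re, grp, max)
    }
    for (k in seq_along(rs)) {
      seg <- cc[rs[k]:re[k]]
      summit <- rs[k] - 1L + which.max(seg) - 1L     # 0-based
      height <- max(seg)
      ratio <- height / max(pmax(denom[rs[k]:re[k]], pseudocount))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = rs[k] - 1L, end = re[k],
        summit = as.integer(summit), height = height, ratio = ratio,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(peak_id = character(), chrom = character(),
                      start = integer(), end = integer(), summit = integer(),
                      height = numeric(), ratio = numeric(),
                      width = integer(), stringsAsFactors = FALSE))
  }
  peaks <- do.call(rbind, out)
  peaks <- peaks[order(match(peaks$chrom, names(chip$cov)), peaks$start), ]
  peaks <- data.frame(peak_id = sprintf("peak%04d", seq_len(nrow(peaks))),
                      peaks, stringsAsFactors = FALSE)
  peaks$width <- peaks$end - peaks$start
  rownames(peaks) <- NULL
  peaks
}

#' Summarize a peak set
#'
#' @param peaks peak `data.frame` from [call_peaks()].
#' @param breaks width-histogram breaks passed to [hist()].
#' @return list with `count`, `mean_width`, `median_width` (both `NA` when
#'   there are no peaks), and `width_histogram` (counts named by bin).
#' @export
summarize_peaks <- function(peaks, breaks = c(0, 100, 200, 400, 800, 1600, Inf)) {
  if (nrow(peaks) == 0L) {
    return(list(count = 0L, mean_width = NA_real_, median_width = NA_real_,
                width_histogram = integer(0)))
  }
  h <- hist(peaks$width, breaks = breaks, plot = FALSE, right = FALSE)
  list(count = nrow(peaks),
       mean_width = mean(peaks$width),
       median_width = stats::median(peaks$width),
       width_histogram = stats::setNames(h$counts,
         paste0("[", utils::head(breaks, -1), ",", breaks[-1], ")")))
}

#' Write peaks as BED6+3
#'
#' Columns: chrom, start, end, peak_id, height (score), strand (`.`),
#' summit, ratio, width.
#'
#' @param peaks peak `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  lines <- paste(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                 peaks$height, ".", peaks$summit,
                 formatC(peaks$ratio, digits = 4, format = "g"),
                 peaks$width, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Export a coverage track as bedGraph
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$cov)) {
    v <- track$cov[[chrom]]
    if (length(v) == 0L) next
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    keep <- r$values != 0L
    if (any(keep))
      writeLines(paste(chrom, s[keep], e[keep], r$values[keep], sep = "\t"), con)
  }
  invisible(path)
}
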