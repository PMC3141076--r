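## PWM construction and scoring, exact score-distribution p-values,
## double-strand scanning, bipartite ChoRE (tandem E-box) detection, and
## ZOOPS expectation-maximization motif discovery.
##
## Two scores are carried per window:
##   * the normalized score sum_i p_i(b_i) / sum_i max_b p_i(b) in [0,1],
##     which maps any consensus window to exactly 1 (the convention behind
##     "perfect E-box, PWM score = 1");
##   * the log2-odds score sum_i log2(p_i(b_i)/bg(b_i)), used for p-values
##     and for ranking ChoRE half-sites.

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_columns <- function(consensus) {
  letters <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  bad <- !(letters %in% names(IUPAC_MAP))
  if (any(bad)) fail("non-IUPAC character '%s' in consensus", letters[bad][1L])
  IUPAC_MAP[letters]
}

#' Build a PWM from an IUPAC consensus string
#'
#' Each column is uniform over the bases the IUPAC code allows, smoothed by
#' a pseudocount: `p(b) = (1[b allowed]/n_allowed + pseudocount) /
#' (1 + 4 pseudocount)`. With `pseudocount = 0` the column is exactly the
#' uniform distribution over the allowed bases (and disallowed bases have
#' probability 0).
#'
#' @param consensus IUPAC string, e.g. `"CABGTG"` or `"CAYGNG"`.
#' @param pseudocount per-base smoothing (default 0: literal consensus).
#' @param background length-4 background distribution over A,C,G,T.
#' @return object of class `pwm`: list with `mat` (4 x width, rows
#'   A,C,G,T, columns summing to 1), `width`, `pseudocount`, `background`.
#' @export
consensus_to_pwm <- function(consensus, pseudocount = 0,
                             background = rep(0.25, 4)) {
  cols <- iupac_columns(consensus)
  mat <- vapply(cols, function(allowed) {
    p <- (as.numeric(DNA_BASES %in% allowed) / length(allowed) + pseudocount) /
      (1 + 4 * pseudocount)
    p
  }, numeric(4))
  mat <- matrix(mat, nrow = 4, dimnames = list(DNA_BASES, NULL))
  new_pwm(mat, pseudocount, background)
}

new_pwm <- function(mat, pseudocount = 0, background = rep(0.25, 4)) {
  stopifnot(nrow(mat) == 4, all(mat >= 0),
            all(abs(colSums(mat) - 1) < 1e-9),
            length(background) == 4, abs(sum(background) - 1) < 1e-9)
  rownames(mat) <- DNA_BASES
  structure(list(mat = mat, width = ncol(mat), pseudocount = pseudocount,
                 background = stats::setNames(as.numeric(background),
                                              DNA_BASES)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM of width %d (pseudocount %g), consensus %s\n",
              x$width, x$pseudocount, pwm_consensus(x)))
  print(round(x$mat, 3))
  invisible(x)
}

#' Per-column argmax consensus of a PWM
#'
#' @param pwm a `pwm` object.
#' @return character string of length `pwm$width` (ties: first of A,C,G,T).
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$mat, 2L, which.max)], collapse = "")
}

#' Normalized PWM score of windows
#'
#' `sum_i p_i(b_i) / sum_i max_b p_i(b)`, so every per-column argmax window
#' scores exactly 1. Windows containing `N` score `NA` (skipped in scans).
#'
#' @param pwm a `pwm`.
#' @param windows character vector of sequences of length `pwm$width`.
#' @return numeric vector of scores in `[0, 1]` (or `NA`).
#' @export
normalized_score <- function(pwm, windows) {
  stopifnot(all(nchar(windows) == pwm$width))
  mx <- sum(apply(pwm$mat, 2L, max))
  vapply(windows, function(w) {
    idx <- seq_to_int(w)
    if (anyNA(idx)) return(NA_real_)
    sum(pwm$mat[cbind(idx, seq_len(pwm$width))]) / mx
  }, numeric(1), USE.NAMES = FALSE)
}

#' Log2-odds PWM score of windows
#'
#' @inheritParams normalized_score
#' @return numeric vector (can be `-Inf` with a 0-pseudocount PWM).
#' @export
log_odds_score <- function(pwm, windows) {
  stopifnot(all(nchar(windows) == pwm$width))
  lo <- log2(pwm$mat) - log2(matrix(pwm$background, 4, pwm$width))
  vapply(windows, function(w) {
    idx <- seq_to_int(w)
    if (anyNA(idx)) return(NA_real_)
    sum(lo[cbind(idx, seq_len(pwm$width))])
  }, numeric(1), USE.NAMES = FALSE)
}

## per-column score contributions for a score kind
pwm_column_scores <- function(pwm, score_kind) {
  if (score_kind == "normalized") {
    mx <- sum(apply(pwm$mat, 2L, max))
    pwm$mat / mx
  } else {
    log2(pwm$mat) - log2(matrix(pwm$background, 4, pwm$width))
  }
}

#' Exact background score distribution of a PWM
#'
#' Enumerates all `4^width` windows, scores each, and weights by the iid
#' background probability — the exact null distribution of the window
#' score. Intended for widths <= 10; see [score_distribution_dp()] for a
#' grid-convolution alternative for wide motifs.
#'
#' @param pwm a `pwm`.
#' @param score_kind `"normalized"` or `"log_odds"`.
#' @return `data.frame` with unique `score` (ascending) and `prob`,
#'   summing to 1.
#' @export
score_distribution_enum <- function(pwm, score_kind = c("normalized", "log_odds")) {
  score_kind <- match.arg(score_kind)
  w <- pwm$width
  if (w > 10L) fail("enumeration limited to width <= 10; use the DP method")
  cs <- pwm_column_scores(pwm, score_kind)
  idx <- as.matrix(expand.grid(rep(list(1:4), w)))    # 4^w windows
  score <- numeric(nrow(idx)); lp <- numeric(nrow(idx))
  logbg <- log(pwm$background)
  for (j in seq_len(w)) {
    score <- score + cs[cbind(idx[, j], j)]
    lp <- lp + logbg[idx[, j]]
  }
  agg <- tapply(exp(lp), round(score, 12), sum)
  data.frame(score = as.numeric(names(agg)), prob = as.numeric(agg))
}

#' Background score distribution by discretized convolution
#'
#' Dynamic-programming alternative to full enumeration: per-column score
#' contributions are rounded to a grid of resolution `grid` and the
#' distributions convolved column by column. Exact up to the grid
#' resolution, with cost linear in width.
#'
#' @inheritParams score_distribution_enum
#' @param grid score grid resolution.
#' @return `data.frame` with `score` (ascending) and `prob`.
#' @export
score_distribution_dp <- function(pwm, score_kind = c("normalized", "log_odds"),
                                  grid = 1e-4) {
  score_kind <- match.arg(score_kind)
  cs <- pwm_column_scores(pwm, score_kind)
  if (any(!is.finite(cs))) {
    ## -Inf log-odds (zero-probability base): clamp far below every finite
    ## score so such windows can never cross any threshold of interest
    cs[!is.finite(cs)] <- min(cs[is.finite(cs)], 0) - 30
  }
  ki <- round(cs / grid)
  cur <- c(1)                                     # distribution over offsets
  cur_lo <- 0L
  for (j in seq_len(pwm$width)) {
    kj <- ki[, j]
    new_lo <- cur_lo + min(kj)
    new_hi <- cur_lo + length(cur) - 1L + max(kj)
    nxt <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      sh <- (cur_lo + kj[b]) - new_lo
      idx <- seq_along(cur) + sh
      nxt[idx] <- nxt[idx] + cur * pwm$background[b]
    }
    cur <- nxt; cur_lo <- new_lo
  }
  keep <- cur > 0
  data.frame(score = (cur_lo + which(keep) - 1L) * grid, prob = cur[keep])
}

#' Exact p-value threshold for PWM scores
#'
#' The smallest attainable score `t` with `P_bg(score >= t) <= alpha`,
#' computed from the exact background score distribution (full enumeration
#' for width <= `enum_max_width`, discretized convolution otherwise).
#'
#' @param pwm a `pwm`.
#' @param alpha significance level in `(0, 1]`.
#' @param score_kind `"normalized"` or `"log_odds"`.
#' @param method `"auto"`, `"enum"`, or `"dp"`.
#' @param enum_max_width widths up to this use enumeration under `"auto"`.
#' @return list with `threshold`, `exceedance` (exact
#'   `P(score >= threshold)`), and the `distribution` used.
#' @export
pvalue_threshold <- function(pwm, alpha, score_kind = c("normalized", "log_odds"),
                             method = c("auto", "enum", "dp"),
                             enum_max_width = 10L) {
  score_kind <- match.arg(score_kind)
  method <- match.arg(method)
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha <= 1))
    fail("alpha must be in (0, 1]")
  if (method == "auto") method <- if (pwm$width <= enum_max_width) "enum" else "dp"
  dist <- switch(method,
                 enum = score_distribution_enum(pwm, score_kind),
                 dp = score_distribution_dp(pwm, score_kind))
  ## survival function at each attainable score (descending cumulative)
  surv <- rev(cumsum(rev(dist$prob)))
  ok <- which(surv <= alpha + 1e-12)
  if (length(ok) == 0L) {
    ## not even the maximum score is rare enough; threshold just above max
    return(list(threshold = max(dist$score) + 1e-9, exceedance = 0,
                distribution = dist))
  }
  t <- dist$score[min(ok)]
  list(threshold = t, exceedance = surv[min(ok)], distribution = dist)
}

## score every window of every sequence on the + representation.
## Returns per-sequence numeric vectors (NA where the window contains N).
window_scores <- function(sequences, pwm, score_kind) {
  cs <- pwm_column_scores(pwm, score_kind)
  w <- pwm$width
  lapply(sequences, function(s) {
    idx <- seq_to_int(s)
    n <- length(idx) - w + 1L
    if (n < 1L) return(numeric(0))
    sc <- numeric(n)
    na <- logical(n)
    for (j in seq_len(w)) {
      bj <- idx[seq_len(n) + j - 1L]
      na <- na | is.na(bj)
      contrib <- cs[cbind(bj, j)]
      contrib[is.na(contrib)] <- 0
      sc <- sc + contrib
    }
    sc[na] <- NA_real_
    sc
  })
}

#' Scan sequences with a PWM on both strands
#'
#' Windows on the forward strand and on the reverse complement are scored;
#' windows at or above the exact p-value threshold for `alpha` are hits.
#' Hit offsets always refer to the forward strand (0-based start of the
#' window). Overlapping hits are allowed; windows containing `N` are
#' skipped.
#'
#' @param sequences named character vector of sequences (names become
#'   `seq_id`; unnamed input gets `seq1`, `seq2`, ...).
#' @param pwm a `pwm`.
#' @param alpha per-window significance level defining the hit threshold.
#' @param score_kind score used for thresholding (default `"normalized"`).
#' @return list with `hits` (`data.frame`: `seq_id`, `offset`, `strand`,
#'   `score`, `log_odds`, `pvalue`), `counts` (named per-sequence hit
#'   counts), `frac_with_hit`, and `threshold`.
#' @export
scan_sequences <- function(sequences, pwm, alpha = 0.001,
                           score_kind = c("normalized", "log_odds")) {
  score_kind <- match.arg(score_kind)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  thr <- pvalue_threshold(pwm, alpha, score_kind)
  dist <- thr$distribution
  surv <- rev(cumsum(rev(dist$prob)))
  pval_of <- function(s) surv[findInterval(s - 1e-12, dist$score) + 1L]

  fwd <- window_scores(sequences, pwm, score_kind)
  rcseq <- revcomp(sequences)
  rev_ <- window_scores(rcseq, pwm, score_kind)
  w <- pwm$width
  rows <- list()
  for (i in seq_along(sequences)) {
    L <- nchar(sequences[[i]])
    for (str in c("+", "-")) {
      sc <- if (str == "+") fwd[[i]] else rev_[[i]]
      hit <- which(!is.na(sc) & sc >= thr$threshold - 1e-12)
      if (length(hit) == 0L) next
      off <- if (str == "+") hit - 1L else L - w - (hit - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = names(sequences)[i], offset = as.integer(off), strand = str,
        score = sc[hit], stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(), offset = integer(), strand = character(),
               score = numeric(), stringsAsFactors = FALSE)
  if (nrow(hits) > 0L) {
    hits <- hits[order(match(hits$seq_id, names(sequences)), hits$offset,
                       hits$strand), ]
    rownames(hits) <- NULL
    windows <- substring(sequences[hits$seq_id], hits$offset + 1L,
                         hits$offset + w)
    windows[hits$strand == "-"] <- revcomp(windows[hits$strand == "-"])
    hits$log_odds <- log_odds_score(pwm, windows)
    hits$pvalue <- pval_of(hits$score)
  } else {
    hits$log_odds <- numeric(0); hits$pvalue <- numeric(0)
  }
  counts <- stats::setNames(integer(length(sequences)), names(sequences))
  if (nrow(hits) > 0L) {
    tab <- table(factor(hits$seq_id, levels = names(sequences)))
    counts[] <- as.integer(tab)
  }
  list(hits = hits, counts = counts,
       frac_with_hit = mean(counts >= 1L), threshold = thr$threshold)
}

#' Detect bipartite ChoRE-like pairs (tandem E-boxes with a fixed spacer)
#'
#' A carbohydrate response element is two E-box-like hexamers separated by
#' a fixed spacer (default 5 nt, the spacing the element strictly
#' requires). Half-site hits of `ebox_pwm` are collected on both strands of
#' the sequence; a pair is two half-site positions whose inner gap is
#' exactly `spacer`. The element is searched in both orientations of the
#' sequence (`orientation` `+`/`-`); pairs found at the same position in
#' both orientations (the element is quasi-palindromic) are reported once,
#' keeping the orientation with the higher combined score, `+` on ties.
#'
#' @param sequences named character vector.
#' @param ebox_pwm half-site `pwm` of width 6 (e.g.
#'   `consensus_to_pwm("CAYGNG")`).
#' @param spacer required inner gap in nt between the two half-sites.
#' @param site_alpha per-half-site significance level.
#' @return `data.frame` with `seq_id`, `start` (0-based start of the first
#'   half-site on the forward strand), `spacer`, `orientation`,
#'   `strand1`, `strand2` (strand of each half-site hit within that
#'   orientation), `combined_log_odds`.
#' @export
find_chore_pairs <- function(sequences, ebox_pwm, spacer = 5,
                             site_alpha = 0.005) {
  stopifnot(ebox_pwm$width == 6L)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  w <- 6L
  scan <- scan_sequences(sequences, ebox_pwm, site_alpha)
  pairs_one_orientation <- function(hits, seq_id, L, orientation) {
    h <- hits[hits$seq_id == seq_id, , drop = FALSE]
    if (orientation == "-" && nrow(h) > 0L) {
      ## map hit offsets into reverse-complement coordinates
      h$offset <- L - w - h$offset
      h$strand <- ifelse(h$strand == "+", "-", "+")
    }
    if (nrow(h) < 2L) return(NULL)
    ## best hit per offset (a palindromic window can hit on both strands)
    h <- h[order(h$offset, -h$log_odds), ]
    h <- h[!duplicated(h$offset), ]
    first <- match(h$offset + w + spacer, h$offset)
    k <- which(!is.na(first))
    if (length(k) == 0L) return(NULL)
    start_rc <- h$offset[k]                     # in this orientation's coords
    start_fwd <- if (orientation == "+") start_rc else L - (start_rc + 2L * w + spacer)
    data.frame(seq_id = seq_id, start = as.integer(start_fwd),
               spacer = spacer, orientation = orientation,
               strand1 = h$strand[k], strand2 = h$strand[first[k]],
               combined_log_odds = h$log_odds[k] + h$log_odds[first[k]],
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_along(sequences)) {
    id <- names(sequences)[i]
    L <- nchar(sequences[[i]])
    pp <- pairs_one_orientation(scan$hits, id, L, "+")
    pm <- pairs_one_orientation(scan$hits, id, L, "-")
    both <- rbind(pp, pm)
    if (is.null(both) || nrow(both) == 0L) next
    ## dedupe identical element positions across orientations
    both <- both[order(both$start, -both$combined_log_odds,
                       both$orientation != "+"), ]
    both <- both[!duplicated(both$start), ]
    out[[length(out) + 1L]] <- both
  }
  if (length(out) == 0L) {
    return(data.frame(seq_id = character(), start = integer(),
                      spacer = integer(), orientation = character(),
                      strand1 = character(), strand2 = character(),
                      combined_log_odds = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---------------------------------------------------------------------------
# ZOOPS-EM de novo motif discovery
# ---------------------------------------------------------------------------

#' De novo motif discovery by ZOOPS expectation-maximization
#'
#' Fits the zero-or-one-occurrence-per-sequence model: each sequence
#' contains a site of width `width` with probability `gamma` (estimated),
#' at an offset uniform over valid positions, emitted by the PWM; all
#' other positions are iid background. The E-step computes per-offset site
#' posteriors, the M-step re-estimates the letter probabilities (with
#' pseudocount) and `gamma`. `n_starts` runs are seeded from randomly
#' chosen data windows; the best final log-likelihood wins. The
#' observed-data log-likelihood is non-decreasing across iterations (a
#' standard EM guarantee, asserted in the test suite).
#'
#' @param sequences character vector (>= 5 sequences, each longer than
#'   `width`); ambiguous bases are not supported here.
#' @param width motif width.
#' @param n_starts number of random restarts.
#' @param seed RNG seed.
#' @param max_iter maximum EM iterations per start.
#' @param tol stop when the log-likelihood improves by less than this.
#' @param pseudocount M-step letter pseudocount.
#' @return list with `pwm`, `site_posterior` (per-sequence probability of
#'   containing a site), `best_offset` (0-based MAP offset per sequence),
#'   `gamma`, `loglik_trace` (of the best start), `loglik`,
#'   `relative_entropy` (bits, summed over columns vs background),
#'   `converged`.
#' @export
discover_motif_em <- function(sequences, width, n_starts = 10, seed = 1,
                              max_iter = 200, tol = 1e-6,
                              pseudocount = 0.01) {
  if (length(sequences) < 5L) fail("need at least 5 sequences")
  if (any(nchar(sequences) <= width)) fail("every sequence must be longer than width")
  set.seed(as.integer(seed))
  seqs <- lapply(sequences, seq_to_int)
  if (any(vapply(seqs, anyNA, TRUE))) fail("sequences must be over {A,C,G,T}")
  n_off <- vapply(seqs, length, 0L) - width + 1L
  bg <- tabulate(unlist(seqs), 4L); bg <- bg / sum(bg)
  log_bg <- log(bg)
  ## per-sequence background log-likelihood (constant across iterations)
  bg_ll <- vapply(seqs, function(s) sum(log_bg[s]), 0)

  e_step_site_ll <- function(log_ratio) {
    ## log P(seq | site at offset o) - log P(seq | background), all offsets
    lapply(seq_along(seqs), function(i) {
      s <- seqs[[i]]; n <- n_off[i]
      v <- numeric(n)
      for (j in seq_len(width)) v <- v + log_ratio[cbind(s[seq_len(n) + j - 1L], j)]
      v
    })
  }

  run_em <- function(mat, gamma) {
    ll_trace <- numeric(0)
    converged <- FALSE
    z <- NULL
    for (iter in seq_len(max_iter)) {
      log_ratio <- log(mat) - matrix(log_bg, 4, width)
      site_ll <- e_step_site_ll(log_ratio)
      ## P(seq) = (1-gamma) P_bg + gamma * mean_o P_bg * exp(ratio_o)
      z <- vector("list", length(seqs))
      ll <- 0
      for (i2 in seq_along(seqs)) {
        r <- site_ll[[i2]]
        m <- max(r, 0)
        site_term <- gamma / n_off[i2] * exp(r - m)
        none_term <- (1 - gamma) * exp(-m)
        denom <- none_term + sum(site_term)
        z[[i2]] <- site_term / denom
        ll <- ll + bg_ll[i2] + m + log(denom)
      }
      ll_trace <- c(ll_trace, ll)
      if (iter > 1L && ll - ll_trace[iter - 1L] < tol) {
        converged <- TRUE
        break
      }
      ## M-step
      counts <- matrix(pseudocount, 4, width)
      for (i2 in seq_along(seqs)) {
        s <- seqs[[i2]]; zz <- z[[i2]]
        nz <- which(zz > 1e-12)
        for (o2 in nz) {
          win2 <- s[o2:(o2 + width - 1L)]
          counts[cbind(win2, seq_len(width))] <-
            counts[cbind(win2, seq_len(width))] + zz[o2]
        }
      }
      mat <- sweep(counts, 2L, colSums(counts), "/")
      gamma <- min(max(mean(vapply(z, sum, 0)), 1e-6), 1 - 1e-6)
    }
    list(mat = mat, gamma = gamma, z = z, ll = ll_trace[length(ll_trace)],
         ll_trace = ll_trace, converged = converged)
  }

  ## shift a PWM left/right, padding vacated columns with background
  shift_mat <- function(mat, by) {
    pad <- matrix(bg, 4, abs(by))
    if (by > 0) cbind(mat[, -seq_len(by), drop = FALSE], pad)
    else cbind(pad, mat[, seq_len(width + by), drop = FALSE])
  }

  run_one <- function(seed_seq_idx) {
    ## initialize the PWM from a random data window, smoothed
    o <- sample.int(n_off[seed_seq_idx], 1L)
    win <- seqs[[seed_seq_idx]][o:(o + width - 1L)]
    mat <- matrix(0.1 / 3, 4, width)
    mat[cbind(win, seq_len(width))] <- 0.9
    cur <- run_em(mat, 0.5)
    ## phase-shift refinement: EM can lock onto a shifted register of the
    ## true site; restarting from column-shifted models escapes it. The
    ## shifted restart is accepted only if its converged likelihood is
    ## strictly better; the reported trace is that of the final EM run.
    repeat {
      improved <- FALSE
      for (by in c(-3L, -2L, -1L, 1L, 2L, 3L)) {
        cand <- run_em(shift_mat(cur$mat, by), cur$gamma)
        if (cand$ll > cur$ll + 1e-9) {
          cur <- cand
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    cur
  }

  seed_idx <- sample.int(length(seqs), n_starts, replace = TRUE)
  runs <- lapply(seed_idx, run_one)
  best <- runs[[which.max(vapply(runs, `[[`, 0, "ll"))]]
  if (!best$converged)
    warning("EM did not converge within max_iter; returning best iterate")
  pwm <- new_pwm(best$mat, pseudocount, bg)
  site_post <- vapply(best$z, sum, 0)
  best_off <- vapply(best$z, function(zz) which.max(zz) - 1L, 0L)
  rel_ent <- sum(best$mat * (log2(best$mat) -
                             matrix(log2(bg), 4, width)))
  list(pwm = pwm, site_posterior = site_post, best_offset = best_off,
       gamma = best$gamma, loglik_trace = best$ll_trace, loglik = best$ll,
       relative_entropy = rel_ent, converged = best$converged)
}

# ---------------------------------------------------------------------------
# MEME minimal text format, peak sequences
# ---------------------------------------------------------------------------

#' Write a PWM in MEME minimal text format
#'
#' @param pwm a `pwm`.
#' @param path output path.
#' @param name motif name.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwm, path, name = "motif1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               sprintf("Background letter frequencies"),
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       pwm$background[1], pwm$background[2],
                       pwm$background[3], pwm$background[4]), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       pwm$width)), con)
  for (j in seq_len(pwm$width))
    writeLines(sprintf(" %.6f %.6f %.6f %.6f", pwm$mat[1, j], pwm$mat[2, j],
                       pwm$mat[3, j], pwm$mat[4, j]), con)
  invisible(path)
}

#' Read the first motif from a MEME minimal text file
#'
#' @param path MEME minimal format file.
#' @return a `pwm` (background taken from the file if present, else
#'   uniform).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) > 0L && bgl[1L] < length(lines)) {
    tok <- strsplit(trimws(lines[bgl[1L] + 1L]), "\\s+")[[1]]
    bg <- as.numeric(tok[c(2, 4, 6, 8)])
  }
  hdr <- grep("^letter-probability matrix", lines)
  if (length(hdr) == 0L) fail("no letter-probability matrix in '%s'", path)
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr[1L]]))
  rows <- lines[(hdr[1L] + 1L):(hdr[1L] + w)]
  mat <- t(vapply(rows, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                  numeric(4)))
  mat <- t(mat)  # 4 x w
  dimnames(mat) <- NULL
  mat <- sweep(mat, 2L, colSums(mat), "/")
  new_pwm(mat, background = bg)
}

#' Extract peak sequences from the genome
#'
#' @param genome named character vector of chromosome sequences.
#' @param peaks peak `data.frame`.
#' @param pad bp added on each side of the peak.
#' @return named character vector (names = peak ids).
#' @export
peak_sequences <- function(genome, peaks, pad = 0) {
  len <- chrom_lengths(genome)
  s <- pmax(peaks$start - pad, 0L)
  e <- pmin(peaks$end + pad, len[peaks$chrom])
  out <- substring(genome[peaks$chrom], s + 1L, e)
  stats::setNames(out, peaks$peak_id)
}
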