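test_that("IUPAC consensus columns are uniform over the allowed bases", {
  pwm <- consensus_to_pwm("CACGTG")
  expect_equal(unname(pwm$mat["C", 1]), 1)
  expect_true(all(colSums(pwm$mat) == 1))

  ## B = C/G/T
  pb <- consensus_to_pwm("CABGTG")
  expect_equal(unname(pb$mat[, 3]), c(0, 1, 1, 1) / 3)

  pn <- consensus_to_pwm("N")
  expect_equal(unname(pn$mat[, 1]), rep(0.25, 4))

  expect_error(consensus_to_pwm("CAXGTG"), "non-IUPAC")
})

test_that("normalized scores anchor the consensus at exactly 1", {
  pwm <- consensus_to_pwm("CACGTG")
  expect_equal(normalized_score(pwm, "CACGTG"), 1)
  expect_equal(normalized_score(pwm, "GTGACA"), 0)   # no position matches
  expect_equal(normalized_score(pwm, "TGTGCA"), 1 / 6)  # only position 4 (G)
  expect_true(is.na(normalized_score(pwm, "CACGTN")))

  ## ties: every argmax window scores 1
  tie <- choreseq:::new_pwm(matrix(c(0.5, 0.5, 0, 0), 4, 2))
  expect_equal(normalized_score(tie, "AA"), 1)
  expect_equal(normalized_score(tie, "CC"), 1)

  ## invariance under a base permutation applied to both PWM and window
  set.seed(2)
  for (k in 1:10) {
    pwm <- random_pwm(6)
    win <- rand_dna(6)
    perm <- sample(4)
    pwm2 <- choreseq:::new_pwm(pwm$mat[perm, ])
    win2 <- paste(c("A", "C", "G", "T")[match(
      match(strsplit(win, "")[[1]], c("A", "C", "G", "T")), perm)],
      collapse = "")
    expect_equal(normalized_score(pwm2, win2), normalized_score(pwm, win))
  }
})

test_that("exact thresholds isolate the consensus at alpha = 4^-width", {
  pwm <- consensus_to_pwm("CACGTG")
  th <- pvalue_threshold(pwm, alpha = 1 / 4096)
  expect_equal(th$threshold, 1)
  expect_equal(th$exceedance, 4^-6)

  ## alpha = 1 admits the minimum attainable score
  th1 <- pvalue_threshold(pwm, alpha = 1)
  expect_equal(th1$threshold, min(th1$distribution$score))
  expect_equal(th1$exceedance, 1)

  expect_error(pvalue_threshold(pwm, alpha = 0), "alpha")

  ## DP convolution reproduces enumeration to grid resolution
  set.seed(5)
  for (k in 1:10) {
    pwm <- random_pwm(sample(4:8, 1))
    alpha <- runif(1, 1e-4, 0.05)
    te <- pvalue_threshold(pwm, alpha, method = "enum")
    td <- pvalue_threshold(pwm, alpha, method = "dp")
    ## grid rounding accumulates at most grid/2 per column
    expect_lt(abs(te$threshold - td$threshold), pwm$width * 1e-4)
  }
})

test_that("scanning finds hits on both strands with mirrored coordinates", {
  pwm <- consensus_to_pwm("CACGTC")   # non-palindromic
  s <- paste0("AAAAAA", revcomp("CACGTC"), "AAAAAA")
  scan <- scan_sequences(c(x = s), pwm, alpha = 1 / 4096)
  expect_equal(nrow(scan$hits), 1L)
  expect_equal(scan$hits$strand, "-")
  expect_equal(scan$hits$offset, 6L)

  ## no spurious hits in a degenerate sequence
  none <- scan_sequences(c(x = strrep("A", 50)), pwm, alpha = 1 / 4096)
  expect_equal(nrow(none$hits), 0L)
  expect_equal(unname(none$counts), 0L)

  ## scanning the reverse complement mirrors offsets and swaps strands
  set.seed(8)
  seq1 <- rand_dna(80)
  pwm2 <- random_pwm(6)
  a <- scan_sequences(c(x = seq1), pwm2, alpha = 0.02)
  b <- scan_sequences(c(x = revcomp(seq1)), pwm2, alpha = 0.02)
  expect_equal(nrow(a$hits), nrow(b$hits))
  mirrored <- sort(80 - 6 - b$hits$offset)
  expect_equal(sort(a$hits$offset), mirrored)
  expect_equal(sort(a$hits$score), sort(b$hits$score))
})

test_that("ChoRE pairs require the exact spacer and are strand-symmetric", {
  ebox <- consensus_to_pwm("CAYGNG", pseudocount = 0.01)
  el <- "CACGTGGCCGGCGCGTG"   # perfect E-box, 5 nt spacer, imperfect E-box
  pos <- paste0("TTATTA", el, "ATTATT")
  pr <- find_chore_pairs(c(x = pos), ebox, spacer = 5, site_alpha = 0.005)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$start, 6L)
  expect_equal(pr$spacer, 5L)

  ## stretching or shrinking the spacer by 1 nt abolishes the pair
  el4 <- "CACGTGGCCGCGCGTG"      # 4 nt spacer
  el6 <- "CACGTGGCCGGACGCGTG"    # 6 nt spacer
  expect_equal(nrow(find_chore_pairs(c(x = paste0("TTATTA", el4, "ATTATT")),
                                     ebox, 5, 0.005)), 0L)
  expect_equal(nrow(find_chore_pairs(c(x = paste0("TTATTA", el6, "ATTATT")),
                                     ebox, 5, 0.005)), 0L)

  ## the reverse complement carries exactly one pair at the mirrored start
  rc <- revcomp(pos)
  prc <- find_chore_pairs(c(x = rc), ebox, spacer = 5, site_alpha = 0.005)
  expect_equal(nrow(prc), 1L)
  expect_equal(prc$start, nchar(pos) - 6L - nchar(el))
  expect_equal(prc$combined_log_odds, pr$combined_log_odds)
})

test_that("ZOOPS-EM recovers a planted element and is seed-deterministic", {
  set.seed(31)
  el <- "CACGTGGCCGGCGCGTG"
  seqs <- embed_motif_seqs(30, 90, el)
  res <- discover_motif_em(seqs, 17, n_starts = 6, seed = 4)
  cons <- pwm_consensus(res$pwm)
  matches <- sum(strsplit(cons, "")[[1]] == strsplit(el, "")[[1]])
  expect_gte(matches, 15)
  expect_true(all(diff(res$loglik_trace) > -1e-8))
  expect_gt(res$gamma, 0.8)

  res2 <- discover_motif_em(seqs, 17, n_starts = 6, seed = 4)
  expect_identical(res$pwm$mat, res2$pwm$mat)
  expect_identical(res$loglik, res2$loglik)

  ## pure background yields a much less informative motif
  bg_seqs <- vapply(1:30, function(i) rand_dna(90), "")
  null_res <- discover_motif_em(bg_seqs, 17, n_starts = 6, seed = 4)
  expect_lt(null_res$relative_entropy, res$relative_entropy)

  expect_error(discover_motif_em(seqs[1:3], 17), "at least 5")
})

test_that("MEME minimal format round-trips a PWM", {
  pwm <- consensus_to_pwm("CABGTG", pseudocount = 0.01,
                          background = c(0.3, 0.2, 0.2, 0.3))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwm, path, name = "chbm1")
  back <- read_meme(path)
  expect_equal(back$mat, pwm$mat, tolerance = 1e-5)
  expect_equal(unname(back$background), c(0.3, 0.2, 0.2, 0.3))
})

test_that("peak sequences are extracted with padding and clipping", {
  genome <- c(chr1 = paste0(strrep("A", 30), "CACGTG", strrep("T", 30)))
  pk <- data.frame(peak_id = "p1", chrom = "chr1", start = 30L, end = 36L,
                   summit = 33L)
  expect_equal(unname(peak_sequences(genome, pk)), "CACGTG")
  padded <- peak_sequences(genome, pk, pad = 100)   # clipped at both ends
  expect_equal(unname(nchar(padded)), 66L)
})
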