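test_that("nearest-gene assignment follows the signed-distance convention", {
  genes <- gene_models("gA", "chr1", "+", 5000L, 9000L,
                       exon_starts = list(c(5000L, 7000L)),
                       exon_ends = list(c(6000L, 9000L)))
  ann <- assign_nearest_gene(peaks_at(1000L), genes)
  expect_equal(ann$gene_id, "gA")
  expect_equal(ann$distance, -4000L)   # upstream of a + TSS is negative

  ## beyond the 20 kb window: unassigned
  far <- assign_nearest_gene(peaks_at(35000L), genes)
  expect_true(is.na(far$gene_id))

  ## equidistant tie goes to the lexicographically smaller id
  two <- gene_models(c("gB", "gAa"), "chr1", c("+", "-"),
                     tx_start = c(2000L, 0L), tx_end = c(3000L, 1001L),
                     exon_starts = list(2000L, 0L),
                     exon_ends = list(3000L, 1001L))
  tie <- assign_nearest_gene(peaks_at(1500L), two)
  expect_equal(tie$gene_id, "gAa")     # both TSSs 500 bp away
})

test_that("assign_nearest_gene agrees with a brute-force all-pairs scan", {
  set.seed(13)
  for (case in 1:25) {
    n <- sample(3:12, 1)
    starts <- sort(sample(seq(0, 2e5, by = 100), n))
    genes <- gene_models(sprintf("g%02d", seq_len(n)), "chr1",
                         sample(c("+", "-"), n, replace = TRUE),
                         tx_start = starts, tx_end = starts + 1000L,
                         exon_starts = as.list(starts),
                         exon_ends = as.list(starts + 1000L))
    summits <- sample(seq(0, 2.2e5, by = 7), 20)
    got <- assign_nearest_gene(peaks_at(summits), genes)
    tss <- tss_of(genes)
    for (i in seq_along(summits)) {
      best <- NA_character_; bestd <- NA_integer_
      for (j in seq_len(n)) {
        d <- if (genes$strand[j] == "+") summits[i] - tss[j] else tss[j] - summits[i]
        if (abs(d) >= 20000) next
        if (is.na(best) || abs(d) < abs(bestd) ||
            (abs(d) == abs(bestd) && genes$gene_id[j] < best)) {
          best <- genes$gene_id[j]; bestd <- as.integer(d)
        }
      }
      expect_identical(got$gene_id[i], best)
      expect_equal(got$distance[i], bestd)
    }
  }
})

test_that("summit categorization reproduces the hand-built truth table", {
  gplus <- toy_coding_gene("gA", strand = "+")
  ## exons [10000,11000) [11500,12000) [12500,13000) [14000,16000),
  ## CDS [10500, 15500)
  cases <- list(
    list(summit = 9000L, want = "proximal_promoter"),   # 1 kb upstream
    list(summit = 6000L, want = "distal_promoter"),     # 4 kb upstream
    list(summit = 10200L, want = "utr5"),               # exonic, pre-CDS
    list(summit = 15800L, want = "utr3"),               # exonic, post-CDS
    list(summit = 10800L, want = "exon"),               # CDS exon
    list(summit = 11200L, want = "intron_1_2"),         # intron 1
    list(summit = 12200L, want = "intron_1_2"),         # intron 2
    list(summit = 13500L, want = "intron_other"),       # intron 3
    list(summit = 50000L, want = "intergenic")
  )
  for (cs in cases) {
    got <- categorize_peaks(peaks_at(cs$summit), gplus)
    expect_equal(as.character(got$category), cs$want,
                 label = sprintf("summit %d", cs$summit))
  }

  ## minus-strand gene: promoter flips to the right, intron order reverses
  gminus <- toy_coding_gene("gB", strand = "-")
  expect_equal(as.character(categorize_peaks(peaks_at(17000L), gminus)$category),
               "proximal_promoter")
  expect_equal(as.character(categorize_peaks(peaks_at(19500L), gminus)$category),
               "distal_promoter")
  expect_equal(as.character(categorize_peaks(peaks_at(13500L), gminus)$category),
               "intron_1_2")    # first intron in transcription order
  expect_equal(as.character(categorize_peaks(peaks_at(11200L), gminus)$category),
               "intron_other")
})

test_that("multi-label sets record every overlapped feature across genes", {
  ## promoter of one gene inside the intron of another
  g1 <- toy_coding_gene("g1", strand = "+")                  # tx [10000,16000)
  g2 <- toy_coding_gene("g2", strand = "+", offset = 4300L)  # TSS 14300
  genes <- rbind(g1, g2)
  got <- categorize_peaks(peaks_at(13500L), genes)   # intron3 of g1, prox of g2
  labs <- strsplit(got$multilabels, ",")[[1]]
  expect_setequal(labs, c("intron_other", "proximal_promoter"))
  expect_equal(as.character(got$category), "proximal_promoter")  # precedence

  ## single-label fractions sum to 1
  ann <- categorize_peaks(peaks_at(c(9000L, 11200L, 50000L)), g1)
  expect_equal(sum(category_fractions(ann)), 1)
})

test_that("TSS distance profiles bin signed distances half-open", {
  ann <- data.frame(peak_id = c("p1", "p2", "p3"),
                    gene_id = c("g", "g", NA),
                    distance = c(0L, -1L, NA))
  prof <- tss_distance_profile(ann, window = 2000, bin_width = 1000)
  expect_equal(sum(prof$count), 2L)
  expect_equal(prof$count[prof$bin_start == 0], 1L)      # 0 in [0,1000)
  expect_equal(prof$count[prof$bin_start == -1000], 1L)  # -1 in [-1000,0)

  empty <- tss_distance_profile(ann[0, ], window = 2000, bin_width = 500)
  expect_true(all(empty$count == 0L))
  expect_error(tss_distance_profile(ann, window = 2000, bin_width = 300),
               "divide")
})
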