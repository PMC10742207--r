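test_that("repeat scanner reproduces the hand-enumerated cases", {
  t1 <- detect_repeat_tracts("TGATGATGATGA")
  expect_equal(nrow(t1), 1)
  expect_equal(t1$occurrences, 4)
  expect_equal(c(t1$start, t1$end), c(0L, 12L))

  expect_equal(nrow(detect_repeat_tracts("TGATGATGA")), 0) # 3 < threshold

  t3 <- detect_repeat_tracts("TGATCATGATCA") # alternating units, zero gaps
  expect_equal(t3$occurrences, 4)

  # leading unit separated by a 6 bp gap (> tolerance 5) restarts the chain
  t4 <- detect_repeat_tracts("TGACCCCCCTGATGATGATGA")
  expect_equal(nrow(t4), 1)
  expect_equal(t4$occurrences, 4)
  expect_equal(c(t4$start, t4$end), c(9L, 21L))

  # a 5 bp gap is tolerated
  t5 <- detect_repeat_tracts("TGACCCCCTGATGATGA")
  expect_equal(t5$occurrences, 4)
  expect_equal(c(t5$start, t5$end), c(0L, 17L))

  # N never matches
  expect_equal(nrow(detect_repeat_tracts("TGNTGATGATGATGA")),
               nrow(detect_repeat_tracts("CCCTGATGATGATGA")))
})

test_that("scanner configuration validates its invariants", {
  expect_error(scanner_config(patterns = "TGAA"), "3 bp")
  expect_error(scanner_config(threshold = 0), "threshold")
  expect_error(scanner_config(gap_tolerance = -1), "gap_tolerance")
})

test_that("scanner equals the brute-force chaining oracle on random DNA", {
  set.seed(101)
  for (i in 1:400) {
    s <- rand_seq(200)
    cfg <- scanner_config(gap_tolerance = sample(0:6, 1),
                          threshold = sample(2:5, 1))
    got <- detect_repeat_tracts(s, cfg)
    want <- oracle_repeat_tracts(s, cfg$patterns, cfg$gap_tolerance,
                                 cfg$threshold)
    expect_equal(got[, c("start", "end", "occurrences")], want)
  }
})

test_that("every emitted tract satisfies the gap and threshold invariants", {
  set.seed(55)
  for (i in 1:100) {
    cfg <- scanner_config(gap_tolerance = sample(0:8, 1),
                          threshold = sample(2:6, 1))
    tr <- detect_repeat_tracts(rand_seq(300), cfg)
    for (k in seq_len(nrow(tr))) {
      expect_gte(tr$occurrences[k], cfg$threshold)
      u <- tr$unit_positions[[k]]
      if (length(u) > 1) {
        expect_true(all(diff(u) - 3 <= cfg$gap_tolerance))
      }
      expect_gte(tr$end[k] - tr$start[k], 3 * tr$occurrences[k])
    }
  }
})

test_that("tract counts mirror on the reverse complement", {
  revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  set.seed(77)
  for (i in 1:200) {
    s <- rand_seq(150)
    a <- detect_repeat_tracts(s)
    b <- detect_repeat_tracts(revcomp(s))
    expect_equal(nrow(a), nrow(b))
    if (nrow(a)) {
      expect_equal(sort(a$occurrences), sort(b$occurrences))
      # spans mirror: [s, e) -> [L - e, L - s)
      expect_equal(sort(150L - a$end), sort(b$start))
    }
  }
})

test_that("central window extraction follows the left-bias and clip rules", {
  genome <- Biostrings::DNAStringSet(c(chr1 = rand_seq(500)))
  whole <- extract_central_window(genomic_intervals("chr1", 0, 100),
                                  genome, 100)
  expect_equal(whole, as.character(Biostrings::subseq(genome[[1]], 1, 100)))
  # odd-length peak: left bias keeps [0, 100)
  odd <- extract_central_window(genomic_intervals("chr1", 0, 101),
                                genome, 100)
  expect_equal(odd, whole)
  # short peak clips to the peak with a warning
  expect_warning(
    short <- extract_central_window(genomic_intervals("chr1", 40, 60),
                                    genome, 100),
    "clipped")
  expect_equal(nchar(short), 20)
  expect_error(
    extract_central_window(genomic_intervals("chrZ", 0, 10), genome),
    "chrZ")
})

test_that("IUPAC motif scan matches the exhaustive oracle", {
  hit <- scan_motif("AATGACGTCAAA", "TGACGTCA")
  expect_equal(hit$offset, 2L)
  expect_equal(nrow(hit), 1) # palindrome counted once
  expect_equal(scan_motif("TGACATCA", "TGANNTCA")$offset, 0L)
  expect_error(scan_motif("ACGT", "TGAXTCA"), "non-IUPAC")
  set.seed(31)
  for (i in 1:60) {
    s <- rand_seq(200)
    m <- sample(c("TGACGTCA", "TGANNTCA", "TGAGTCA", "CANNTG"), 1)
    got <- scan_motif(s, m)
    want <- oracle_scan_motif(s, m)
    expect_equal(got$offset, want$offset)
  }
})

test_that("motif classes partition with canonical precedence", {
  res <- classify_by_motif(c(
    "CCCCTGACGTCACCCC",   # canonical (which also matches TGANNTCA)
    "CCCCTGACATCACCCC",   # variant only
    "CCCCTGAGTCACCCCC",   # AP1 only
    "CCCCCCCCCCCCCCCC"))  # none
  expect_equal(res$flags$class,
               c("canonical_TGACGTCA", "variant_TGANNTCA", "AP1_TGAGTCA",
                 "none"))
  expect_false(res$flags$has_variant[1]) # canonical excluded from variant
  expect_equal(unname(res$counts), c(1L, 1L, 1L, 1L))
})

test_that("planted motif classes are recovered exactly by classification", {
  cfg <- small_sim_config(seed = 33)
  set.seed(cfg$seed)
  gg <- gen_genome_and_genes(cfg)
  pk <- gen_peaks_with_sequences(cfg, gg$genome, gg$genes)
  win <- extract_central_window(pk$peaks, pk$genome, 100)
  got <- classify_by_motif(win)$flags$class
  want <- c(canonical = "canonical_TGACGTCA", variant = "variant_TGANNTCA",
            ap1 = "AP1_TGAGTCA", none = "none")[pk$truth$motif_class]
  expect_equal(got, unname(want))
  # planted tracts are recovered at the planted unit counts
  sc <- scanner_config()
  n_units <- vapply(win, function(s) {
    tr <- detect_repeat_tracts(s, sc)
    if (nrow(tr)) max(tr$occurrences) else 0L
  }, integer(1), USE.NAMES = FALSE)
  planted <- !is.na(pk$truth$tract_units)
  expect_equal(n_units[planted], pk$truth$tract_units[planted])
  expect_true(all(n_units[!planted] == 0))
})

test_that("repeat fraction and its Welch test behave at the edges", {
  with_tract <- replicate(10, paste0(rand_seq(20), "TGATGATGATGA",
                                     rand_seq(20)))
  expect_equal(repeat_fraction(with_tract)$fraction, 1.0)
  rf <- repeat_fraction(with_tract, with_tract)
  expect_equal(rf$t_statistic, 0)
  expect_warning(repeat_fraction(with_tract, with_tract[1]), "skipped")
})

test_that("planted tract prevalences separate and the Welch t is exact", {
  set.seed(404)
  mk <- function(n, prev) {
    vapply(seq_len(n), function(i) {
      if (i <= round(n * prev)) {
        paste0(rand_seq(30), "TGATGATGATGATGA", rand_seq(30))
      } else {
        s <- rand_seq(75)
        while (nrow(detect_repeat_tracts(s)) > 0) s <- rand_seq(75)
        s
      }
    }, character(1))
  }
  a <- mk(300, 0.30)
  b <- mk(300, 0.10)
  rf <- repeat_fraction(a, b)
  expect_equal(rf$fraction, 0.30)
  expect_equal(rf$fraction_other, 0.10)
  # closed-form Welch t on the binary indicators
  x <- rf$indicator; y <- rf$indicator_other
  tt <- (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(rf$t_statistic, tt, tolerance = 1e-12)
  expect_lt(rf$p_value, 1e-6)
})

test_that("tract count is monotone in threshold and gap tolerance", {
  set.seed(202)
  seqs <- replicate(150, rand_seq(200))
  n_tracts <- function(s, gap, thr) {
    nrow(detect_repeat_tracts(s, scanner_config(gap_tolerance = gap,
                                                threshold = thr)))
  }
  for (s in seqs[1:50]) {
    by_thr <- vapply(3:6, function(t) n_tracts(s, 5, t), integer(1))
    expect_true(all(diff(by_thr) <= 0))
    by_gap <- vapply(0:8, function(g) n_tracts(s, g, 4), integer(1))
    expect_true(all(diff(by_gap) >= 0))
  }
})
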