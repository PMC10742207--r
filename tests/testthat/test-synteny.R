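identity_chain <- function(chrom = "chr1", size = 100000L,
                           q_chrom = chrom) {
  list(score = size, t_chrom = chrom, t_size = size, t_strand = "+",
       t_start = 0L, t_end = size, q_chrom = q_chrom, q_size = size,
       q_strand = "+", q_start = 0L, q_end = size,
       blocks = data.frame(size = size, dt = 0L, dq = 0L))
}

test_that("chain files round-trip and are validated on read", {
  tf <- withr::local_tempfile()
  write_chain(list(identity_chain()), tf)
  ch <- read_chain(tf)
  expect_equal(length(ch), 1)
  expect_equal(nrow(ch[[1]]$blocks), 1)
  expect_equal(ch[[1]]$t_end, 100000L)

  two_block <- list(score = 300, t_chrom = "chr1", t_size = 1000L,
                    t_strand = "+", t_start = 0L, t_end = 400L,
                    q_chrom = "chrB", q_size = 1000L, q_strand = "+",
                    q_start = 0L, q_end = 400L,
                    blocks = data.frame(size = c(100L, 200L),
                                        dt = c(100L, 0L),
                                        dq = c(100L, 0L)))
  write_chain(list(two_block), tf)
  expect_equal(nrow(read_chain(tf)[[1]]$blocks), 2)

  # truncated file (no terminal size-only line)
  writeLines(c("chain 100 chr1 1000 + 0 300 chrB 1000 + 0 300",
               "100 100 100"), tf)
  expect_error(read_chain(tf), "truncated|terminal")

  # header span inconsistent with blocks
  writeLines(c("chain 100 chr1 1000 + 0 500 chrB 1000 + 0 300",
               "100 100 100", "100", ""), tf)
  expect_error(read_chain(tf), "span")
})

test_that("identity-chain liftover is the identity map", {
  chains <- list(identity_chain(size = 1000000L))
  set.seed(61)
  iv <- rand_interval_set(200, chroms = "chr1", max_pos = 900000,
                          max_len = 5000)
  lifted <- liftover_intervals(iv, chains)
  expect_true(all(lifted$mapped))
  expect_equal(lifted$m_start, iv$start)
  expect_equal(lifted$m_end, iv$end)
  expect_true(all(lifted$fraction == 1))
})

test_that("a single offset block shifts intervals by the offset", {
  ch <- list(score = 1000, t_chrom = "chr1", t_size = 10000L,
             t_strand = "+", t_start = 1000L, t_end = 3000L,
             q_chrom = "chrB", q_size = 10000L, q_strand = "+",
             q_start = 1500L, q_end = 3500L,
             blocks = data.frame(size = 2000L, dt = 0L, dq = 0L))
  out <- liftover_interval(list(chrom = "chr1", start = 1200, end = 1700),
                           list(ch))
  expect_true(out$mapped)
  expect_equal(c(out$start, out$end), c(1700L, 2200L))
})

test_that("min_match governs partially covered intervals", {
  ch <- list(score = 1000, t_chrom = "chr1", t_size = 10000L,
             t_strand = "+", t_start = 0L, t_end = 1000L,
             q_chrom = "chrB", q_size = 10000L, q_strand = "+",
             q_start = 0L, q_end = 1000L,
             blocks = data.frame(size = 1000L, dt = 0L, dq = 0L))
  half_in <- list(chrom = "chr1", start = 500, end = 1500)
  expect_false(liftover_interval(half_in, list(ch), 0.95)$mapped)
  relaxed <- liftover_interval(half_in, list(ch), 0.4)
  expect_true(relaxed$mapped)
  expect_equal(c(relaxed$start, relaxed$end), c(500L, 1000L))
  expect_equal(relaxed$fraction, 0.5)
})

test_that("liftover agrees with the per-base oracle on generated chains", {
  cfg <- small_sim_config(seed = 71)
  set.seed(cfg$seed)
  gg <- gen_genome_and_genes(cfg)
  sp <- gen_species_pair(cfg, gg$genome, gg$genes)
  set.seed(72)
  for (rep in 1:25) {
    s <- sample.int(750000, 1)
    iv <- list(chrom = "chrA1", start = s, end = s + sample.int(8000, 1))
    got <- liftover_interval(iv, sp$chains_ab, 0.95)
    bases <- oracle_liftover_bases(iv$chrom, iv$start, iv$end, sp$chains_ab)
    ok <- !is.na(bases$mapped)
    frac <- mean(ok)
    if (frac < 0.95 || length(unique(bases$chrom[ok])) > 1) {
      expect_false(got$mapped)
    } else {
      expect_true(got$mapped)
      # the hull is taken over the majority strand of the mapped bases
      by_strand <- tapply(ok, bases$strand, sum)
      major <- names(by_strand)[which.max(by_strand)]
      sel <- ok & bases$strand == major
      expect_equal(got$strand, major)
      expect_equal(got$start, min(bases$mapped[sel]))
      expect_equal(got$end, max(bases$mapped[sel]) + 1L)
      expect_equal(got$fraction, frac, tolerance = 1e-12)
    }
  }
})

test_that("an inverted block maps with flipped strand and coordinates", {
  # 10 kb inversion: source [2000, 12000) maps reversed into [5000, 15000)
  ch <- list(score = 10000, t_chrom = "chr1", t_size = 20000L,
             t_strand = "+", t_start = 2000L, t_end = 12000L,
             q_chrom = "chrB", q_size = 20000L, q_strand = "-",
             q_start = 5000L, q_end = 15000L,
             blocks = data.frame(size = 10000L, dt = 0L, dq = 0L))
  out <- liftover_interval(list(chrom = "chr1", start = 2000, end = 2100),
                           list(ch))
  expect_true(out$mapped)
  expect_equal(out$strand, "-")
  # strand-space [5000,5100) flips to forward [20000-5100, 20000-5000)
  expect_equal(c(out$start, out$end), c(14900L, 15000L))
  # coordinate arithmetic: source base x -> forward base
  # q_size - 1 - (q_start + (x - t_start)); hull matches for the interval
  xs <- 2000:2099
  fwd <- 20000L - 1L - (5000L + (xs - 2000L))
  expect_equal(out$start, min(fwd))
  expect_equal(out$end, max(fwd) + 1L)
})

test_that("liftover agrees with rtracklayer on a plus-strand chain file", {
  tf <- withr::local_tempfile()
  ch <- list(score = 5000, t_chrom = "chr1", t_size = 50000L,
             t_strand = "+", t_start = 1000L, t_end = 21000L,
             q_chrom = "chr1", q_size = 60000L, q_strand = "+",
             q_start = 2000L, q_end = 21900L,
             blocks = data.frame(size = c(10000L, 9900L),
                                 dt = c(100L, 0L), dq = c(0L, 0L)))
  write_chain(list(ch), tf)
  chains <- read_chain(tf)
  iv <- genomic_intervals("chr1", 3000, 3500)
  mine <- liftover_intervals(iv, chains)
  rt <- rtracklayer::liftOver(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(3001, 3500)),
    rtracklayer::import.chain(tf))[[1]]
  expect_equal(mine$m_start + 1L, BiocGenerics::start(rt))
  expect_equal(mine$m_end, BiocGenerics::end(rt))
})

test_that("identical SE sets under identity chains match fully reciprocally", {
  ses <- genomic_intervals("chr1", c(1000, 20000, 40000),
                           c(6000, 26000, 47000),
                           name = c("se1", "se2", "se3"))
  chains <- list(identity_chain(size = 100000L))
  syn <- match_syntenic_ses(ses, ses, chains, chains)
  expect_equal(syn$summary$n_a_matched, 3)
  expect_equal(syn$summary$n_b_matched, 3)
  expect_equal(syn$summary$n_reciprocal_pairs, 3)
  expect_true(all(syn$matches$reciprocal))
  # a private SE stays unmatched
  ses_b <- ses[1:2, ]
  syn2 <- match_syntenic_ses(ses, ses_b, chains, chains)
  expect_equal(syn2$summary$n_a_matched, 2)
})

test_that("planted syntenic pairs are recovered and decoys never match", {
  cfg <- small_sim_config(seed = 81)
  set.seed(cfg$seed)
  gg <- gen_genome_and_genes(cfg)
  sp <- gen_species_pair(cfg, gg$genome, gg$genes)
  syn <- match_syntenic_ses(sp$ses_a, sp$ses_b, sp$chains_ab, sp$chains_ba)
  rec <- unique(syn$matches[syn$matches$reciprocal,
                            c("a_index", "b_index")])
  got_pairs <- data.frame(se_a = sp$ses_a$name[rec$a_index],
                          se_b = sp$ses_b$name[rec$b_index])
  got_pairs <- got_pairs[order(got_pairs$se_a), ]
  expect_equal(got_pairs$se_a, sp$truth$pairs$se_a)
  expect_equal(got_pairs$se_b, sp$truth$pairs$se_b)
  matched_names <- unique(c(sp$ses_a$name[syn$matches$a_index]))
  expect_false(any(sp$truth$decoys_a %in% matched_names))
  matched_b <- unique(sp$ses_b$name[syn$matches$b_index])
  expect_false(any(sp$truth$decoys_b %in% matched_b))
  # reciprocal matches are a subset of each direction
  ab <- syn$matches[syn$matches$direction == "A_to_B", ]
  expect_true(all(paste(rec$a_index, rec$b_index) %in%
                    paste(ab$a_index, ab$b_index)))
})

test_that("orientation table flags same-side SEs of homologous genes", {
  mk_genes <- function(gene_id, chrom, strand, gs, ge) {
    g <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                    gene_start = gs, gene_end = ge)
    g$tss <- ifelse(g$strand == "+", g$gene_start, g$gene_end - 1L)
    g$tes <- ifelse(g$strand == "+", g$gene_end - 1L, g$gene_start)
    g
  }
  # SE 6.2 kb downstream of the gene in A; homolog 5.9 kb downstream in B
  genes_a <- mk_genes("gA1", "chr1", "+", 10000L, 20000L)
  genes_b <- mk_genes("gB1", "chrB", "+", 30000L, 40000L)
  ses_a <- genomic_intervals("chr1", 16100, 16300, name = "sa")
  ses_b <- genomic_intervals("chrB", 35800, 36000, name = "sb")
  matches <- list(matches = data.frame(a_index = 1L, b_index = 1L,
                                       direction = "A_to_B",
                                       reciprocal = TRUE))
  hom <- data.frame(gene_id_a = "gA1", gene_id_b = "gB1")
  tab <- orientation_distance_table(matches, ses_a, ses_b, genes_a,
                                    genes_b, hom)
  expect_true(tab$homologous)
  expect_true(tab$same_orientation)
  expect_equal(tab$distance_a, 6200L)
  expect_equal(tab$distance_b, 5900L)
  # SE upstream in A but downstream in B: opposite orientation
  ses_a2 <- genomic_intervals("chr1", 3900, 4100, name = "sa")
  tab2 <- orientation_distance_table(matches, ses_a2, ses_b, genes_a,
                                     genes_b, hom)
  expect_false(tab2$same_orientation)
  # non-homologous nearest genes are flagged and excluded
  hom2 <- data.frame(gene_id_a = "gA1", gene_id_b = "gOther")
  tab3 <- orientation_distance_table(matches, ses_a, ses_b, genes_a,
                                     genes_b, hom2)
  expect_false(tab3$homologous)
  expect_true(is.na(tab3$same_orientation))
})
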