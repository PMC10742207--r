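write_de <- function(df) {
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  tf
}

test_that("DE tables read with preserved NA padj; duplicates are an error", {
  tf <- write_de(data.frame(gene_id = c("G1", "G2"), log2fc = c(2.3, 0.5),
                            padj = c(0.001, NA)))
  de <- read_de_table(tf, "mCCS")
  expect_equal(de$dataset, c("mCCS", "mCCS"))
  expect_true(is.na(de$padj[2]))
  dup <- write_de(data.frame(gene_id = c("G1", "G1"), log2fc = 1:2,
                             padj = 0.1))
  expect_error(read_de_table(dup, "mCCS"), "duplicate")
  # sign flip for contrasts coded the other way round
  flipped <- read_de_table(tf, "knockdown", flip_sign = TRUE)
  expect_equal(flipped$log2fc, c(-2.3, -0.5))
})

test_that("classification applies each dataset's own cutoff rule", {
  rec <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    log2fc = c(0.8, 0.8, 1.2, -1.4, 2.0),
    padj = c(0.01, 0.01, 0.06, 0.01, NA),
    dataset = c("mCCS", "knockdown", "mCCS", "hCCS", "mCCS"))
  lab <- classify_degs(rec)$label
  expect_equal(lab, c("neither",  # below tumor cutoff of 1
                      "up",       # knockdown cutoff is 0
                      "neither",  # padj 0.06 fails everywhere
                      "down",
                      "neither")) # missing padj is non-significant
  bad <- rec; bad$dataset[1] <- "mystery"
  expect_error(classify_degs(bad), "mystery")
  # total function, invariant to row order
  shuf <- rec[5:1, ]
  expect_equal(classify_degs(shuf)$label, rev(lab))
})

test_that("three-way intersection honours per-dataset rules and homologs", {
  uni <- sprintf("G%02d", 1:30)
  shared <- uni[1:10]
  mk <- function(ds, up_ids, lfc_up) {
    data.frame(gene_id = if (ds == "mCCS") paste0("m_", uni) else uni,
               log2fc = ifelse(uni %in% up_ids, lfc_up, 0.1),
               padj = ifelse(uni %in% up_ids, 0.001, 0.5),
               dataset = ds)
  }
  hom <- data.frame(gene_id = paste0("m_", uni), shared_id = uni)
  tabs <- list(mk("mCCS", c(shared, "G11"), 2),
               mk("hCCS", c(shared, "G11", "G12"), 1.5),
               mk("knockdown", shared, 0.5)) # below 1 but above the kd cutoff
  res <- intersect_degs(tabs, hom)
  expect_equal(sort(res$up$three_way), sort(shared))
  expect_equal(unname(res$up$counts["three_way"]), 10L)
  # G11 significant in two datasets: at-least-two only
  expect_true("G11" %in% res$up$at_least_two)
  expect_false("G11" %in% res$up$three_way)
  expect_equal(unname(res$up$counts["exactly_two"]), 1L)
  # three-way is a subset of every pairwise/at-least-two set
  expect_true(all(res$up$three_way %in% res$up$at_least_two))
  # dataset order does not change results
  res2 <- intersect_degs(tabs[c(3, 1, 2)], hom)
  expect_equal(sort(res2$up$three_way), sort(res$up$three_way))
  # an empty knockdown table empties the three-way sets
  tabs3 <- tabs
  tabs3[[3]] <- tabs3[[3]][0, ]
  tabs3[[3]] <- rbind(tabs3[[3]],
                      data.frame(gene_id = "Gzz", log2fc = 0, padj = NA,
                                 dataset = "knockdown"))
  res3 <- intersect_degs(tabs3, hom)
  expect_equal(length(res3$up$three_way), 0)
})

test_that("multi-homolog genes resolve to the first mapping", {
  hom <- data.frame(gene_id = c("m_G1", "m_G1"), shared_id = c("G1", "G1b"))
  tabs <- list(
    data.frame(gene_id = "m_G1", log2fc = 2, padj = 0.01, dataset = "mCCS"),
    data.frame(gene_id = "G1", log2fc = 2, padj = 0.01, dataset = "hCCS"),
    data.frame(gene_id = "G1", log2fc = 1, padj = 0.01,
               dataset = "knockdown"))
  expect_message(res <- intersect_degs(tabs, hom), "first mapping")
  expect_equal(res$up$three_way, "G1")
})

test_that("promoter-binding fraction recovers a planted 44/100 layout", {
  tss <- seq(10000L, by = 50000L, length.out = 100)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:100), chrom = "chr1",
                      strand = "+", gene_start = tss, gene_end = tss + 5000L,
                      tss = tss, tes = tss + 4999L)
  bound <- sort(sample(100, 44))
  peaks <- genomic_intervals("chr1", tss[bound] - 500L, tss[bound] + 500L)
  res <- promoter_binding_fraction(list(all = genes$gene_id), peaks, genes)
  expect_identical(res$fraction, 0.44)
  expect_equal(res$bound, 44L)
  # all bound and none bound edges
  res2 <- promoter_binding_fraction(
    list(hit = genes$gene_id[bound], none = genes$gene_id[-bound],
         empty = character()),
    peaks, genes)
  expect_equal(res2$fraction[1], 1)
  expect_equal(res2$fraction[2], 0)
  expect_true(is.na(res2$fraction[3]))
  expect_true(all(res2$bound <= res2$total))
})

test_that("binding scores stratify by expression class of the bound gene", {
  set.seed(91)
  genes <- sprintf("g%03d", 1:300)
  cls <- rep(c("up", "unchanged", "down"), each = 100)
  lfc <- ifelse(cls == "up", 2.5, ifelse(cls == "down", -2.5, 0.2))
  de <- data.frame(gene_id = genes, log2fc = lfc)
  score <- ifelse(cls == "up", rnorm(300, 387, 40),
                  ifelse(cls == "down", rnorm(300, 213, 40),
                         rnorm(300, 272, 40)))
  pairs <- data.frame(gene_id = genes, peak_score = score)
  res <- score_by_expression_class(pairs, de)
  sem <- 40 / sqrt(100)
  expect_lt(abs(res$means[["up"]] - 387), 4 * sem)
  expect_lt(abs(res$means[["unchanged"]] - 272), 4 * sem)
  expect_lt(abs(res$means[["down"]] - 213), 4 * sem)
  expect_true(all(res$tests$p_value < 1e-6))
  expect_equal(res$n, c(100L, 100L, 100L))
  # identical distributions: t statistics near zero
  pairs2 <- data.frame(gene_id = genes, peak_score = rep(rnorm(100, 300, 1),
                                                         3))
  res2 <- score_by_expression_class(pairs2, de)
  expect_true(all(abs(res2$tests$t) < 1e-8))
  # a single represented class yields no tests
  res3 <- score_by_expression_class(pairs[1:100, ], de)
  expect_equal(nrow(res3$tests), 0)
})

test_that("SE-looped genes are found regardless of anchor order", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = "+", gene_start = c(10000L, 50000L),
                      gene_end = c(15000L, 55000L),
                      tss = c(10000L, 50000L), tes = c(14999L, 54999L))
  ses <- genomic_intervals("chrE", 100000, 110000)
  loops <- data.frame(
    chrom1 = c("chrE", "chr1", "chrE"),
    start1 = c(100500L, 49800L, 100500L),
    end1 = c(101000L, 50200L, 101000L),
    chrom2 = c("chr1", "chrE", "chrE"),
    start2 = c(9800L, 105000L, 105000L),
    end2 = c(10200L, 105500L, 105500L))
  de <- data.frame(gene_id = c("g1", "g2"), log2fc = c(3, -0.5))
  res <- se_loop_genes(loops, ses, genes, de)
  # loop 1: SE->promoter(g1); loop 2: promoter(g2)->SE (swapped order);
  # loop 3: SE->SE contributes nothing
  expect_equal(res$genes$gene_id, c("g1", "g2"))
  expect_equal(res$n_up, 1L)
  expect_equal(res$n_down, 0L)
})

test_that("planted loop wiring is recovered exactly with its DE tallies", {
  cfg <- small_sim_config(seed = 93)
  set.seed(cfg$seed)
  gg <- gen_genome_and_genes(cfg)
  ses <- genomic_intervals("chrE1", seq(0, 9) * 50000L,
                           seq(0, 9) * 50000L + 3000L)
  de <- gen_de_tables_and_loops(cfg, gg$genes, ses)
  loops <- de$loops
  res <- se_loop_genes(loops, ses, gg$genes, de$tables$knockdown)
  expect_equal(res$genes$gene_id, de$truth$looped_genes)
  expect_equal(res$n_up, cfg$n_loop_up)
  expect_equal(res$n_down, cfg$n_loop_down)
  # with zero decoys the same genes are returned
  planted_only <- loops[grepl("^loop", loops$name), ]
  res2 <- se_loop_genes(planted_only, ses, gg$genes, de$tables$knockdown)
  expect_equal(res2$genes$gene_id, de$truth$looped_genes)
})

test_that("generator plants exact three-way shared sets at paper scale", {
  cfg <- small_sim_config(seed = 95)
  set.seed(cfg$seed)
  gg <- gen_genome_and_genes(cfg)
  ses <- genomic_intervals("chrE1", 0, 5000)
  de <- gen_de_tables_and_loops(cfg, gg$genes, ses)
  tabs <- list(
    transform(de$tables$mCCS, dataset = "mCCS"),
    transform(de$tables$hCCS, dataset = "hCCS"),
    transform(de$tables$knockdown, dataset = "knockdown"))
  res <- intersect_degs(tabs, de$homologs)
  expect_equal(sort(res$up$three_way), sort(de$truth$shared_up))
  expect_equal(sort(res$down$three_way), sort(de$truth$shared_down))
  expect_equal(unname(res$up$counts["exactly_two"]),
               cfg$n_exactly_two_up)
  expect_equal(unname(res$down$counts["exactly_two"]),
               cfg$n_exactly_two_down)
})
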