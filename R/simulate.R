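#' Simulation configuration
#'
#' Defaults mirror the study conditions the pipeline is designed around:
#' binding-site category proportions 34.7/36.5/28.8% (promoter / intragenic /
#' intergenic), motif-class planting rates of roughly 6/34/13% (canonical
#' TGACGTCA, variant TGANNTCA excluding canonical, AP1 TGAGTCA), 20 planted
#' super-enhancer regions among 500 background regions (background signal
#' exponential with mean 1, supers normal 50 +/- 5), 50 planted syntenic SE
#' pairs between the two synthetic species, shared DEG sets of 432 up and
#' 194 down across the three expression datasets, and 20 SE-looped genes of
#' which 5 have log2FC > 2 and 2 have log2FC < -2. Identical seed and
#' configuration give byte-identical outputs.
#'
#' @param seed Integer seed driving every generator.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp) for
#'   species A.
#' @param n_genes Number of non-overlapping genes to place.
#' @param gene_length_range,intergene_gap_range Sampling ranges (bp).
#' @param n_peaks Number of binding sites.
#' @param peak_width_range Peak width range (bp).
#' @param category_proportions Promoter / intragenic / intergenic planting
#'   proportions (must sum to 1).
#' @param motif_rates Planting rates for the canonical, variant and AP1
#'   motif classes (remainder is class `none`).
#' @param repeat_prevalence Probability a peak's central window carries a
#'   planted TGA/TCA repeat tract.
#' @param tract_units_range Units per planted tract.
#' @param promoter_halfwidth Promoter window half-width (bp).
#' @param n_background_regions,n_super_regions Enhancer-region counts for
#'   the coverage generator.
#' @param background_signal_mean,super_signal_mean,super_signal_sd Region
#'   net-signal distributions (exponential background, normal supers).
#' @param region_width_range,region_gap_range Region geometry (bp); gaps
#'   exceed the 12.5 kb stitch distance so regions stay separate.
#' @param block_length_range Alignment block lengths for the species-B
#'   derivation (bp).
#' @param deletion_rate,insertion_rate,inversion_rate Per-block perturbation
#'   rates for the species pair.
#' @param insertion_length_range Length of inserted species-B-only sequence.
#' @param n_syntenic_se_pairs Planted syntenic SE pairs.
#' @param n_decoy_ses Decoy SEs per species (placed in unalignable
#'   sequence).
#' @param se_width_range Planted SE widths (bp).
#' @param n_de_universe Size of the shared gene universe for the DE tables.
#' @param n_shared_up,n_shared_down Genes planted significant in all three
#'   datasets.
#' @param n_exactly_two_up,n_exactly_two_down Genes planted significant in
#'   exactly two datasets.
#' @param n_only_up,n_only_down Genes planted significant in exactly one
#'   dataset (per dataset).
#' @param n_looped_genes,n_loop_up,n_loop_down SE-looped gene planting.
#' @param n_decoy_loops Loops that connect no SE to a promoter.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chrA1 = 3000000L, chrA2 = 3000000L),
                       n_genes = 150,
                       gene_length_range = c(8000, 20000),
                       intergene_gap_range = c(10000, 30000),
                       n_peaks = 1000,
                       peak_width_range = c(200, 400),
                       category_proportions = c(promoter = 0.347,
                                                intragenic = 0.365,
                                                intergenic = 0.288),
                       motif_rates = c(canonical = 0.06, variant = 0.34,
                                       ap1 = 0.13),
                       repeat_prevalence = 0.30,
                       tract_units_range = c(4, 12),
                       promoter_halfwidth = 3000,
                       n_background_regions = 500,
                       n_super_regions = 20,
                       background_signal_mean = 1,
                       super_signal_mean = 50,
                       super_signal_sd = 5,
                       region_width_range = c(1000, 3000),
                       region_gap_range = c(13000, 20000),
                       block_length_range = c(20000, 60000),
                       deletion_rate = 0.08,
                       insertion_rate = 0.08,
                       inversion_rate = 0.10,
                       insertion_length_range = c(3000, 8000),
                       n_syntenic_se_pairs = 50,
                       n_decoy_ses = 10,
                       se_width_range = c(5000, 15000),
                       n_de_universe = 2000,
                       n_shared_up = 432,
                       n_shared_down = 194,
                       n_exactly_two_up = 120,
                       n_exactly_two_down = 80,
                       n_only_up = 100,
                       n_only_down = 80,
                       n_looped_genes = 20,
                       n_loop_up = 5,
                       n_loop_down = 2,
                       n_decoy_loops = 30) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$category_proportions) - 1) > 1e-9) {
    stop("category proportions must sum to 1")
  }
  if (sum(cfg$motif_rates) > 1) stop("motif rates must sum to <= 1")
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

runif_int <- function(n, range) {
  as.integer(sample(seq.int(range[1], range[2]), n, replace = TRUE))
}

#' Generate a random genome with non-overlapping genes
#'
#' Chromosomes are uniform random sequence; genes are placed left to right
#' with random intergenic gaps and random strands. An error is raised when
#' the requested gene count does not fit the genome at the configured
#' spacing.
#'
#' @param config A [sim_config()].
#' @return list with `genome` ([Biostrings::DNAStringSet]) and `genes`
#'   (gene-model data.frame as from [read_gene_models()]).
#' @export
gen_genome_and_genes <- function(config) {
  seqs <- lapply(config$chrom_lengths, rand_dna)
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(config$chrom_lengths)
  rows <- list()
  placed <- 0L
  for (chr in names(config$chrom_lengths)) {
    if (placed >= config$n_genes) break
    len <- config$chrom_lengths[[chr]]
    pos <- 5000L
    while (placed < config$n_genes) {
      gap <- runif_int(1, config$intergene_gap_range)
      glen <- runif_int(1, config$gene_length_range)
      gs <- pos + gap
      ge <- gs + glen
      if (ge + config$promoter_halfwidth + 100L > len) break
      placed <- placed + 1L
      rows[[placed]] <- data.frame(
        gene_id = sprintf("gA%04d", placed), chrom = chr,
        strand = sample(c("+", "-"), 1),
        gene_start = gs, gene_end = ge, stringsAsFactors = FALSE)
      pos <- ge
    }
  }
  if (placed < config$n_genes) {
    stop("cannot place ", config$n_genes, " non-overlapping genes; ",
         "reduce n_genes or gene/gap sizes, or enlarge chromosomes")
  }
  genes <- do.call(rbind, rows)
  genes$tss <- ifelse(genes$strand == "+", genes$gene_start,
                      genes$gene_end - 1L)
  genes$tes <- ifelse(genes$strand == "+", genes$gene_end - 1L,
                      genes$gene_start)
  list(genome = genome, genes = genes)
}

# Draw a 100 bp background window free of the three motif classes and of
# repeat tracts, then plant the requested features and verify the planted
# state is exactly what the classifiers recover.
plant_window <- function(class, tract_units, config, width = 100L) {
  motif_seq <- c(canonical = "TGACGTCA", variant = "TGACATCA",
                 ap1 = "TGAGTCA")
  sc <- scanner_config()
  for (try in 1:200) {
    w <- rand_dna(width)
    if (classify_by_motif(w)$flags$class != "none") next
    if (nrow(detect_repeat_tracts(w, sc)) > 0) next
    if (class != "none") {
      m <- motif_seq[[class]]
      substr(w, 11, 10 + nchar(m)) <- m
    }
    tract_offset <- NA_integer_
    if (!is.na(tract_units)) {
      unit <- sample(c("TGA", "TCA"), 1)
      tr <- strrep(unit, tract_units)
      substr(w, 41, 40 + nchar(tr)) <- tr
      tract_offset <- 40L
    }
    want <- switch(class, canonical = "canonical_TGACGTCA",
                   variant = "variant_TGANNTCA", ap1 = "AP1_TGAGTCA",
                   none = "none")
    if (classify_by_motif(w)$flags$class != want) next
    tracts <- detect_repeat_tracts(w, sc)
    if (is.na(tract_units)) {
      if (nrow(tracts) > 0) next
    } else {
      if (nrow(tracts) != 1 || tracts$occurrences != tract_units) next
    }
    return(list(seq = w, tract_offset = tract_offset))
  }
  stop("failed to construct a planted window after 200 attempts")
}

#' Generate binding sites with planted categories, motifs and repeat tracts
#'
#' Peaks are placed so that their annotation category is determined by
#' construction: promoter peaks inside a TSS window, intragenic peaks inside
#' a gene body clear of every promoter window, intergenic peaks clear of
#' both. Motif instances and TGA/TCA tracts are planted by overwriting the
#' genome bases of each peak's central 100 bp window (windows of distinct
#' peaks never overlap, and every planted window is verified to classify
#' exactly as planted). Two jittered replicate subsets are also produced for
#' consensus analysis.
#'
#' @param config A [sim_config()].
#' @param genome,genes Output of [gen_genome_and_genes()].
#' @return list with `genome` (with planted bases), `peaks`, `replicates`
#'   (list of 2 interval data.frames) and `truth` (per-peak planted
#'   category, gene, motif class, tract units).
#' @export
gen_peaks_with_sequences <- function(config, genome, genes) {
  n <- config$n_peaks
  counts <- round(n * config$category_proportions)
  counts[1] <- n - sum(counts[-1])
  category <- rep(names(config$category_proportions), counts)
  h <- config$promoter_halfwidth

  # candidate intergenic zones: gaps clear of gene bodies and TSS windows
  zones <- list()
  for (chr in unique(genes$chrom)) {
    g <- genes[genes$chrom == chr, ]
    g <- g[order(g$gene_start), ]
    len <- config$chrom_lengths[[chr]]
    bounds <- data.frame(s = c(0L, g$gene_end), e = c(g$gene_start, len))
    zs <- pmax(bounds$s + h + 10L, 0L)
    ze <- bounds$e - h - 10L
    ok <- ze - zs >= max(config$peak_width_range) + 250L
    if (any(ok)) {
      zones[[chr]] <- data.frame(chrom = chr, start = zs[ok], end = ze[ok])
    }
  }
  zones <- do.call(rbind, zones)

  used <- list() # per-chrom window midpoints already taken
  window_free <- function(chr, mid) {
    u <- used[[chr]]
    is.null(u) || all(abs(u - mid) >= 110L)
  }
  peaks <- vector("list", n)
  truth <- vector("list", n)
  n_classes <- stats::rmultinom(1, n, c(config$motif_rates,
                                        none = 1 - sum(config$motif_rates)))
  class_vec <- sample(rep(c(names(config$motif_rates), "none"), n_classes))
  has_tract <- stats::runif(n) < config$repeat_prevalence

  for (i in seq_len(n)) {
    width <- runif_int(1, config$peak_width_range)
    placed_ok <- FALSE
    for (try in 1:300) {
      if (category[i] == "promoter") {
        gi <- sample(nrow(genes), 1)
        tss <- genes$tss[gi]
        lo <- tss - (h - 500L)
        hi <- tss + (h - 500L) - width
        if (hi <= lo) next
        start <- lo + sample.int(hi - lo, 1)
        chr <- genes$chrom[gi]
        gene_id <- genes$gene_id[gi]
      } else if (category[i] == "intragenic") {
        gi <- sample(nrow(genes), 1)
        g <- genes[gi, ]
        if (g$strand == "+") {
          lo <- g$gene_start + h + 60L
          hi <- g$gene_end - width - 10L
        } else {
          lo <- g$gene_start + 10L
          hi <- g$gene_end - h - 60L - width
        }
        if (hi <= lo) next
        start <- lo + sample.int(hi - lo, 1)
        chr <- g$chrom
        gene_id <- g$gene_id
      } else {
        zi <- sample(nrow(zones), 1, prob = zones$end - zones$start)
        z <- zones[zi, ]
        hi <- z$end - width - 60L
        lo <- z$start + 60L
        if (hi <= lo) next
        start <- lo + sample.int(hi - lo, 1)
        chr <- z$chrom
        gene_id <- NA_character_
      }
      mid <- as.integer(floor((start + start + width) / 2))
      if (mid - 50L < 0 || mid + 50L > config$chrom_lengths[[chr]]) next
      if (!window_free(chr, mid)) next
      placed_ok <- TRUE
      break
    }
    if (!placed_ok) stop("could not place peak ", i, "; relax geometry")
    used[[chr]] <- c(used[[chr]], mid)
    units <- if (has_tract[i]) runif_int(1, config$tract_units_range) else
      NA_integer_
    pw <- plant_window(class_vec[i], units, config)
    score <- max(1, stats::rnorm(1, if (category[i] == "promoter") 320 else
      260, 80))
    peaks[[i]] <- data.frame(
      chrom = chr, start = start, end = start + width, strand = ".",
      name = sprintf("pk%04d", i), score = round(score, 2),
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      name = sprintf("pk%04d", i), chrom = chr, start = start,
      end = start + width, mid = mid, category = category[i],
      gene_id = gene_id, motif_class = class_vec[i],
      tract_units = units, window_seq = pw$seq,
      stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, peaks)
  truth <- do.call(rbind, truth)

  # splice every planted window into the genome in one pass per chromosome
  for (chr in unique(truth$chrom)) {
    t <- truth[truth$chrom == chr, ]
    genome[[chr]] <- Biostrings::replaceAt(
      genome[[chr]],
      IRanges::IRanges(t$mid - 50L + 1L, t$mid + 50L),
      t$window_seq)
  }

  make_replicate <- function() {
    idx <- sort(sample(nrow(peaks), round(0.85 * nrow(peaks))))
    rep <- peaks[idx, , drop = FALSE]
    jit_s <- runif_int(nrow(rep), c(-25, 25))
    jit_e <- runif_int(nrow(rep), c(-25, 25))
    rep$start <- pmax(rep$start + jit_s, 0L)
    rep$end <- pmax(rep$end + jit_e, rep$start + 50L)
    rownames(rep) <- NULL
    rep
  }
  list(genome = genome, peaks = peaks,
       replicates = list(make_replicate(), make_replicate()),
       truth = truth)
}

#' Generate coverage tracks with planted super-enhancer regions
#'
#' Lays enhancer regions along a dedicated coverage chromosome, separated by
#' gaps larger than the 12.5 kb stitch distance. Background regions draw a
#' low exponential net signal; planted supers draw a high normal signal. The
#' ChIP track carries depth `input + signal/width` over each region above a
#' flat input of depth 1, so region scoring recovers each planted signal
#' exactly. About a third of the regions are emitted as two constituent
#' peaks separated by less than the stitch distance to exercise stitching.
#' One binding site is planted inside every super region, plus decoy sites
#' in the gaps.
#'
#' @param config A [sim_config()].
#' @param chrom Name of the coverage chromosome.
#' @return list with `regions` (truth: interval data.frame with `signal`,
#'   `is_super`), `peaks` (constituent peaks), `chip`, `input` (bedGraph
#'   data.frames), `binding_sites`, and `chrom_length`.
#' @export
gen_coverage <- function(config, chrom = "chrE1") {
  n <- config$n_background_regions + config$n_super_regions
  widths <- runif_int(n, config$region_width_range)
  gaps <- runif_int(n, config$region_gap_range)
  starts <- cumsum(c(20000L, widths[-n] + gaps[-n]))
  ends <- starts + widths
  is_super <- seq_len(n) %in% sample(n, config$n_super_regions)
  signal <- numeric(n)
  signal[!is_super] <- stats::rexp(sum(!is_super),
                                   rate = 1 / config$background_signal_mean)
  signal[is_super] <- stats::rnorm(sum(is_super), config$super_signal_mean,
                                   config$super_signal_sd)
  regions <- data.frame(chrom = chrom, start = starts, end = ends,
                        strand = ".", name = sprintf("re%04d", seq_len(n)),
                        score = NA_real_, signal = signal,
                        is_super = is_super, stringsAsFactors = FALSE)
  chrom_length <- ends[n] + 20000L

  split_it <- stats::runif(n) < 0.3
  peak_rows <- list()
  for (i in seq_len(n)) {
    if (split_it[i] && widths[i] >= 1000L) {
      # both constituents stay inside the region so stitching restores the
      # exact region span (gap always < the stitch distance)
      g <- runif_int(1, c(100, min(2000L, widths[i] - 500L)))
      w1 <- runif_int(1, c(200, widths[i] - g - 200L))
      peak_rows[[length(peak_rows) + 1]] <- data.frame(
        chrom = chrom, start = c(starts[i], starts[i] + w1 + g),
        end = c(starts[i] + w1, ends[i]), stringsAsFactors = FALSE)
    } else {
      peak_rows[[length(peak_rows) + 1]] <- data.frame(
        chrom = chrom, start = starts[i], end = ends[i],
        stringsAsFactors = FALSE)
    }
  }
  peaks <- do.call(rbind, peak_rows)
  peaks <- genomic_intervals(peaks$chrom, peaks$start, peaks$end)

  chip <- data.frame(chrom = chrom, start = starts, end = ends,
                     depth = 1 + signal / widths, stringsAsFactors = FALSE)
  input <- data.frame(chrom = chrom, start = 0L, end = chrom_length,
                      depth = 1, stringsAsFactors = FALSE)

  site_rows <- list()
  for (i in which(is_super)) {
    s <- starts[i] + runif_int(1, c(0, widths[i] - 300L))
    site_rows[[length(site_rows) + 1]] <- data.frame(
      chrom = chrom, start = s, end = s + 300L, stringsAsFactors = FALSE)
  }
  for (k in 1:30) {
    i <- sample(n - 1L, 1)
    s <- ends[i] + 2000L + runif_int(1, c(0, 5000))
    site_rows[[length(site_rows) + 1]] <- data.frame(
      chrom = chrom, start = s, end = s + 300L, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows)
  sites <- genomic_intervals(sites$chrom, sites$start, sites$end,
                             name = sprintf("bs%03d", seq_len(nrow(sites))))
  list(regions = regions, peaks = peaks, chip = chip, input = input,
       binding_sites = sites, chrom_length = chrom_length)
}

#' Derive a second species with exact chains and planted syntenic SEs
#'
#' Species B is built from species A chromosome by chromosome: the A
#' sequence is cut into blocks, a fixed number of blocks are deleted from B,
#' random sequence is inserted between some blocks, and some blocks are
#' inverted (reverse-complemented). Exact chain files are emitted in both
#' directions, one chain per conserved block (inverted blocks map on the
#' minus strand). Genes fully inside conserved blocks receive a species-B
#' homolog. Syntenic SE pairs are planted inside conserved blocks; decoy SEs
#' are placed in deleted blocks (species A) and inserted sequence
#' (species B), which cannot map.
#'
#' @param config A [sim_config()].
#' @param genome_a,genes_a Species-A genome and gene models.
#' @return list with `genome_b`, `genes_b`, `homologs` (data.frame
#'   `gene_id_a`, `gene_id_b`), `chains_ab`, `chains_ba`, `ses_a`, `ses_b`,
#'   and `truth` (planted pair names and decoy names).
#' @export
gen_species_pair <- function(config, genome_a, genes_a) {
  b_name <- function(chr) paste0(chr, "b")
  all_blocks <- list()
  for (chr in names(genome_a)) {
    L <- Biostrings::width(genome_a[chr])
    cuts <- integer()
    pos <- 0L
    while (pos < L) {
      pos <- min(pos + runif_int(1, config$block_length_range), L)
      cuts <- c(cuts, pos)
    }
    bs <- c(0L, cuts[-length(cuts)])
    be <- cuts
    nb <- length(bs)
    n_del <- max(ceiling(config$n_decoy_ses / length(genome_a)),
                 round(config$deletion_rate * nb))
    n_ins <- max(ceiling(config$n_decoy_ses / length(genome_a)),
                 round(config$insertion_rate * nb))
    status <- rep("kept", nb)
    status[sample(nb, n_del)] <- "deleted"
    kept_idx <- which(status == "kept")
    inv_idx <- sample(kept_idx, round(config$inversion_rate *
                                        length(kept_idx)))
    status[inv_idx] <- "inverted"
    ins_before <- rep(FALSE, nb)
    ins_before[sample(which(status != "deleted"), n_ins)] <- TRUE
    ins_len <- ifelse(ins_before, runif_int(nb,
                                            config$insertion_length_range), 0L)
    all_blocks[[chr]] <- data.frame(
      chrom = chr, a_start = bs, a_end = be, status = status,
      ins_before = ins_before, ins_len = ins_len, stringsAsFactors = FALSE)
  }

  genome_b <- list()
  chains_ab <- list()
  chains_ba <- list()
  insert_zones <- list()
  for (chr in names(genome_a)) {
    blk <- all_blocks[[chr]]
    # first pass: species-B coordinates
    b_pos <- 0L
    blk$b_start <- NA_integer_
    blk$b_end <- NA_integer_
    blk$ins_start <- NA_integer_
    for (i in seq_len(nrow(blk))) {
      if (blk$status[i] == "deleted") next
      if (blk$ins_before[i]) {
        blk$ins_start[i] <- b_pos
        b_pos <- b_pos + blk$ins_len[i]
      }
      blk$b_start[i] <- b_pos
      b_pos <- b_pos + (blk$a_end[i] - blk$a_start[i])
      blk$b_end[i] <- b_pos
    }
    L_a <- Biostrings::width(genome_a[chr])
    L_b <- b_pos
    pieces <- character()
    for (i in seq_len(nrow(blk))) {
      if (blk$status[i] == "deleted") next
      if (blk$ins_before[i]) pieces <- c(pieces, rand_dna(blk$ins_len[i]))
      seq <- Biostrings::subseq(genome_a[[chr]], blk$a_start[i] + 1L,
                                blk$a_end[i])
      if (blk$status[i] == "inverted") {
        seq <- Biostrings::reverseComplement(seq)
      }
      pieces <- c(pieces, as.character(seq))
    }
    genome_b[[b_name(chr)]] <- paste0(pieces, collapse = "")
    for (i in seq_len(nrow(blk))) {
      if (blk$status[i] == "deleted") next
      size <- blk$a_end[i] - blk$a_start[i]
      inv <- blk$status[i] == "inverted"
      blocks <- data.frame(size = size, dt = 0L, dq = 0L)
      chains_ab[[length(chains_ab) + 1]] <- list(
        score = size, t_chrom = chr, t_size = L_a, t_strand = "+",
        t_start = blk$a_start[i], t_end = blk$a_end[i],
        q_chrom = b_name(chr), q_size = L_b,
        q_strand = if (inv) "-" else "+",
        q_start = if (inv) L_b - blk$b_end[i] else blk$b_start[i],
        q_end = if (inv) L_b - blk$b_start[i] else blk$b_end[i],
        blocks = blocks)
      chains_ba[[length(chains_ba) + 1]] <- list(
        score = size, t_chrom = b_name(chr), t_size = L_b, t_strand = "+",
        t_start = blk$b_start[i], t_end = blk$b_end[i],
        q_chrom = chr, q_size = L_a,
        q_strand = if (inv) "-" else "+",
        q_start = if (inv) L_a - blk$a_end[i] else blk$a_start[i],
        q_end = if (inv) L_a - blk$a_start[i] else blk$a_end[i],
        blocks = blocks)
    }
    iz <- blk[blk$ins_before & blk$status != "deleted", , drop = FALSE]
    if (nrow(iz)) {
      insert_zones[[chr]] <- data.frame(
        chrom = b_name(chr), start = iz$ins_start,
        end = iz$ins_start + iz$ins_len, stringsAsFactors = FALSE)
    }
    all_blocks[[chr]] <- blk
  }
  genome_b <- Biostrings::DNAStringSet(unlist(genome_b))

  # map an A interval fully inside a conserved block to B coordinates
  map_interval <- function(blk_row, s, e) {
    off_s <- s - blk_row$a_start
    off_e <- e - blk_row$a_start
    if (blk_row$status == "inverted") {
      c(blk_row$b_end - off_e, blk_row$b_end - off_s)
    } else {
      c(blk_row$b_start + off_s, blk_row$b_start + off_e)
    }
  }
  blocks_all <- do.call(rbind, all_blocks)

  rows_b <- list()
  homs <- list()
  for (k in seq_len(nrow(genes_a))) {
    g <- genes_a[k, ]
    hit <- which(blocks_all$chrom == g$chrom &
                   blocks_all$a_start <= g$gene_start &
                   blocks_all$a_end >= g$gene_end &
                   blocks_all$status != "deleted")
    if (!length(hit)) next
    b <- blocks_all[hit[1], ]
    m <- map_interval(b, g$gene_start, g$gene_end)
    strand <- if (b$status == "inverted") {
      if (g$strand == "+") "-" else "+"
    } else g$strand
    gid_b <- sub("^gA", "gB", g$gene_id)
    rows_b[[length(rows_b) + 1]] <- data.frame(
      gene_id = gid_b, chrom = b_name(g$chrom), strand = strand,
      gene_start = m[1], gene_end = m[2], stringsAsFactors = FALSE)
    homs[[length(homs) + 1]] <- data.frame(
      gene_id_a = g$gene_id, gene_id_b = gid_b, stringsAsFactors = FALSE)
  }
  genes_b <- do.call(rbind, rows_b)
  genes_b$tss <- ifelse(genes_b$strand == "+", genes_b$gene_start,
                        genes_b$gene_end - 1L)
  genes_b$tes <- ifelse(genes_b$strand == "+", genes_b$gene_end - 1L,
                        genes_b$gene_start)
  homologs <- do.call(rbind, homs)

  # planted syntenic SE pairs inside conserved blocks, one per block
  margin <- 200L
  cand <- which(blocks_all$status != "deleted" &
                  blocks_all$a_end - blocks_all$a_start >=
                  config$se_width_range[2] + 2L * margin)
  if (length(cand) < config$n_syntenic_se_pairs) {
    stop("not enough conserved blocks to plant syntenic SE pairs")
  }
  sel <- sample(cand, config$n_syntenic_se_pairs)
  ses_a_rows <- list()
  ses_b_rows <- list()
  for (j in seq_along(sel)) {
    b <- blocks_all[sel[j], ]
    w <- runif_int(1, config$se_width_range)
    s <- b$a_start + margin +
      sample.int(b$a_end - b$a_start - w - 2L * margin, 1)
    m <- map_interval(b, s, s + w)
    ses_a_rows[[j]] <- data.frame(chrom = b$chrom, start = s, end = s + w,
                                  name = sprintf("sea%03d", j),
                                  stringsAsFactors = FALSE)
    ses_b_rows[[j]] <- data.frame(chrom = b_name(b$chrom), start = m[1],
                                  end = m[2], name = sprintf("seb%03d", j),
                                  stringsAsFactors = FALSE)
  }
  # decoys: species-A SEs in deleted blocks, species-B SEs in insertions
  del_blocks <- blocks_all[blocks_all$status == "deleted", , drop = FALSE]
  del_blocks <- del_blocks[del_blocks$a_end - del_blocks$a_start >= 4000L, ,
                           drop = FALSE]
  nda <- min(config$n_decoy_ses, nrow(del_blocks))
  for (j in seq_len(nda)) {
    b <- del_blocks[j, ]
    w <- min(3000L, b$a_end - b$a_start - 500L)
    s <- b$a_start + 200L
    ses_a_rows[[length(ses_a_rows) + 1]] <- data.frame(
      chrom = b$chrom, start = s, end = s + w,
      name = sprintf("dea%03d", j), stringsAsFactors = FALSE)
  }
  iz <- do.call(rbind, insert_zones)
  iz <- iz[iz$end - iz$start >= 2500L, , drop = FALSE]
  ndb <- min(config$n_decoy_ses, nrow(iz))
  for (j in seq_len(ndb)) {
    s <- iz$start[j] + 200L
    ses_b_rows[[length(ses_b_rows) + 1]] <- data.frame(
      chrom = iz$chrom[j], start = s, end = s + 2000L,
      name = sprintf("deb%03d", j), stringsAsFactors = FALSE)
  }
  ses_a <- do.call(rbind, ses_a_rows)
  ses_b <- do.call(rbind, ses_b_rows)
  ses_a <- genomic_intervals(ses_a$chrom, ses_a$start, ses_a$end,
                             name = ses_a$name)
  ses_b <- genomic_intervals(ses_b$chrom, ses_b$start, ses_b$end,
                             name = ses_b$name)
  list(genome_b = genome_b, genes_b = genes_b, homologs = homologs,
       chains_ab = chains_ab, chains_ba = chains_ba,
       ses_a = ses_a, ses_b = ses_b,
       truth = list(
         pairs = data.frame(se_a = sprintf("sea%03d",
                                           seq_len(config$n_syntenic_se_pairs)),
                            se_b = sprintf("seb%03d",
                                           seq_len(config$n_syntenic_se_pairs)),
                            stringsAsFactors = FALSE),
         decoys_a = grep("^dea", ses_a$name, value = TRUE),
         decoys_b = grep("^deb", ses_b$name, value = TRUE)))
}

#' Generate three DE tables, a homolog map and SE-promoter loops
#'
#' Plants disjoint gene pools: genes significant in all three datasets
#' (shared up/down), in exactly two, and in exactly one, each honoring its
#' dataset's cutoff rule (|log2FC| > 1 for the two tumor datasets, > 0 for
#' the knockdown dataset, padj < 0.05 everywhere). The mouse table is
#' written in a mouse namespace translated by the emitted homolog map.
#' Loops wire a planted subset of gene promoters to super-enhancer spans,
#' plus decoy loops touching no SE-promoter pair.
#'
#' @param config A [sim_config()].
#' @param genes Species-A gene models (their ids join the shared universe).
#' @param ses Interval data.frame of SE spans to anchor loops in.
#' @return list with `tables` (named list of three DE data.frames),
#'   `homologs` (`gene_id`, `shared_id`), `loops` (BEDPE-style data.frame)
#'   and `truth`.
#' @export
gen_de_tables_and_loops <- function(config, genes, ses) {
  n_uni <- config$n_de_universe
  universe <- c(genes$gene_id,
                sprintf("xg%04d", seq_len(n_uni - nrow(genes))))
  reserve <- sample(genes$gene_id, min(3 * config$n_looped_genes,
                                       nrow(genes)))
  pool <- sample(setdiff(universe, reserve))
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  shared_up <- take(config$n_shared_up)
  shared_down <- take(config$n_shared_down)
  two_up <- take(config$n_exactly_two_up)
  two_down <- take(config$n_exactly_two_down)
  only_up <- lapply(1:3, function(i) take(config$n_only_up))
  only_down <- lapply(1:3, function(i) take(config$n_only_down))
  ds_pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  two_up_ds <- ds_pairs[(seq_along(two_up) - 1L) %% 3L + 1L]
  two_down_ds <- ds_pairs[(seq_along(two_down) - 1L) %% 3L + 1L]

  looped <- sample(reserve, config$n_looped_genes)
  loop_lfc <- c(stats::runif(config$n_loop_up, 2.3, 4),
                stats::runif(config$n_loop_down, -4, -2.3),
                stats::runif(config$n_looped_genes - config$n_loop_up -
                               config$n_loop_down, -1.5, 1.5))

  sig_lfc <- function(n, dataset, dir) {
    lo <- if (dataset == 3) 0.3 else 1.5
    dir * stats::runif(n, lo, 4)
  }
  make_table <- function(ds) {
    lfc <- stats::rnorm(n_uni, 0, 0.4)
    padj <- stats::runif(n_uni, 0.06, 0.99)
    names(lfc) <- names(padj) <- universe
    set_sig <- function(ids, dir) {
      lfc[ids] <<- sig_lfc(length(ids), ds, dir)
      padj[ids] <<- stats::runif(length(ids), 1e-8, 0.04)
    }
    set_sig(shared_up, 1)
    set_sig(shared_down, -1)
    in2up <- two_up[vapply(two_up_ds, function(p) ds %in% p, logical(1))]
    in2down <- two_down[vapply(two_down_ds, function(p) ds %in% p,
                               logical(1))]
    set_sig(in2up, 1)
    set_sig(in2down, -1)
    set_sig(only_up[[ds]], 1)
    set_sig(only_down[[ds]], -1)
    if (ds == 3) lfc[looped] <- loop_lfc # knockdown fold changes; padj stays ns
    data.frame(gene_id = universe, log2fc = round(unname(lfc), 4),
               padj = signif(unname(padj), 4), stringsAsFactors = FALSE)
  }
  tab_m <- make_table(1)
  tab_h <- make_table(2)
  tab_k <- make_table(3)
  homologs <- data.frame(gene_id = paste0("m_", universe),
                         shared_id = universe, stringsAsFactors = FALSE)
  tab_m$gene_id <- paste0("m_", tab_m$gene_id)

  # loops: SE anchor <-> promoter anchor for every planted looped gene
  loop_rows <- list()
  gidx <- match(looped, genes$gene_id)
  for (j in seq_along(looped)) {
    se <- ses[sample(nrow(ses), 1), ]
    a1s <- se$start + sample.int(max(se$end - se$start - 500L, 1L), 1) - 1L
    tss <- genes$tss[gidx[j]]
    loop_rows[[j]] <- data.frame(
      chrom1 = se$chrom, start1 = a1s, end1 = min(a1s + 500L, se$end),
      chrom2 = genes$chrom[gidx[j]], start2 = max(tss - 400L, 0L),
      end2 = tss + 400L, name = sprintf("loop%03d", j), score = 5,
      stringsAsFactors = FALSE)
  }
  # decoys: SE<->SE, desert<->desert, promoter<->desert (no SE side)
  desert <- function() {
    se <- ses[sample(nrow(ses), 1), ]
    s <- se$end + 3000L + runif_int(1, c(0, 4000))
    c(se$chrom, s, s + 500L)
  }
  nd <- config$n_decoy_loops
  for (j in seq_len(nd)) {
    kind <- j %% 3L
    if (kind == 0L) {
      s1 <- ses[sample(nrow(ses), 1), ]
      s2 <- ses[sample(nrow(ses), 1), ]
      row <- data.frame(chrom1 = s1$chrom, start1 = s1$start,
                        end1 = s1$start + 500L, chrom2 = s2$chrom,
                        start2 = s2$start, end2 = s2$start + 500L,
                        stringsAsFactors = FALSE)
    } else if (kind == 1L) {
      d1 <- desert(); d2 <- desert()
      row <- data.frame(chrom1 = d1[1], start1 = as.integer(d1[2]),
                        end1 = as.integer(d1[3]), chrom2 = d2[1],
                        start2 = as.integer(d2[2]), end2 = as.integer(d2[3]),
                        stringsAsFactors = FALSE)
    } else {
      g <- genes[match(sample(setdiff(reserve, looped), 1), genes$gene_id), ]
      d <- desert()
      row <- data.frame(chrom1 = g$chrom, start1 = max(g$tss - 400L, 0L),
                        end1 = g$tss + 400L, chrom2 = d[1],
                        start2 = as.integer(d[2]), end2 = as.integer(d[3]),
                        stringsAsFactors = FALSE)
    }
    row$name <- sprintf("decoy%03d", j)
    row$score <- 2
    loop_rows[[length(loop_rows) + 1]] <- row
  }
  loops <- do.call(rbind, loop_rows)
  list(
    tables = list(mCCS = tab_m, hCCS = tab_h, knockdown = tab_k),
    homologs = homologs, loops = loops,
    truth = list(shared_up = shared_up, shared_down = shared_down,
                 exactly_two_up = two_up, exactly_two_down = two_down,
                 looped_genes = sort(looped),
                 n_loop_up = config$n_loop_up,
                 n_loop_down = config$n_loop_down))
}

write_gtf <- function(genes, path) {
  lines <- sprintf(
    "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    genes$chrom, genes$gene_start + 1L, genes$gene_end, genes$strand,
    genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

write_bedgraph <- function(track, path) {
  writeLines(paste(track$chrom, track$start, track$end,
                   format(track$depth, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

write_bedpe <- function(loops, path) {
  writeLines(paste(loops$chrom1, loops$start1, loops$end1, loops$chrom2,
                   loops$start2, loops$end2, loops$name, loops$score,
                   sep = "\t"), path)
  invisible(path)
}

#' Run every generator and write a complete synthetic study to disk
#'
#' Writes, under `out_dir`: the species-A genome FASTA and gene GTF, binding
#' sites with two jittered replicate sets, coverage tracks and constituent
#' enhancer peaks with planted supers plus SE binding sites, the species-B
#' genome, gene table, homolog map, both chain files and both SE sets,
#' three DE tables with their homolog map, SE-promoter loops, and
#' `ground_truth.json` recording every planted feature. Identical seed and
#' configuration give byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects and `truth`.
#' @export
simulate_study <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  gg <- gen_genome_and_genes(config)
  pk <- gen_peaks_with_sequences(config, gg$genome, gg$genes)
  cov <- gen_coverage(config)
  sp <- gen_species_pair(config, pk$genome, gg$genes)
  se_spans <- genomic_intervals(cov$regions$chrom[cov$regions$is_super],
                                cov$regions$start[cov$regions$is_super],
                                cov$regions$end[cov$regions$is_super])
  de <- gen_de_tables_and_loops(config, gg$genes, se_spans)

  p <- function(f) file.path(out_dir, f)
  Biostrings::writeXStringSet(pk$genome, p("genome_a.fa"))
  write_gtf(gg$genes, p("genes_a.gtf"))
  write_bed(pk$peaks, p("peaks.bed"))
  write_bed(pk$replicates[[1]], p("peaks_rep2.bed"))
  write_bed(pk$replicates[[2]], p("peaks_rep3.bed"))
  write_bed(cov$peaks, p("se_peaks.bed"))
  write_bed(cov$binding_sites, p("se_binding_sites.bed"))
  write_bedgraph(cov$chip, p("chip.bedgraph"))
  write_bedgraph(cov$input, p("input.bedgraph"))
  Biostrings::writeXStringSet(sp$genome_b, p("genome_b.fa"))
  write_gene_tsv(sp$genes_b, p("genes_b.tsv"))
  utils::write.table(sp$homologs, p("homologs_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_chain(sp$chains_ab, p("a_to_b.chain"))
  write_chain(sp$chains_ba, p("b_to_a.chain"))
  write_bed(sp$ses_a, p("ses_a.bed"))
  write_bed(sp$ses_b, p("ses_b.bed"))
  utils::write.table(de$tables$mCCS, p("de_mccs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(de$tables$hCCS, p("de_hccs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(de$tables$knockdown, p("de_kd.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(de$homologs, p("homologs_deg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bedpe(de$loops, p("loops.bedpe"))

  truth <- list(
    peaks = pk$truth[, c("name", "chrom", "start", "end", "category",
                         "gene_id", "motif_class", "tract_units")],
    category_counts = as.list(table(pk$truth$category)),
    se_regions = cov$regions[, c("name", "chrom", "start", "end", "signal",
                                 "is_super")],
    synteny = sp$truth,
    deg = de$truth)
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(genome = pk$genome, genes = gg$genes, peaks = pk$peaks,
                 coverage = cov, species_pair = sp, de = de, truth = truth))
}
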