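# Independent brute-force oracles. These deliberately use naive loops and
# string operations, sharing no code path with the package implementation.

# Sliding 3 bp window, step 1: chain matches while the gap from the end of
# the previous match to the start of the next is within tolerance; restart
# from the match that broke the chain; emit tracts with >= threshold units.
oracle_repeat_tracts <- function(seq, patterns = c("TGA", "TCA"),
                                 gap_tolerance = 5, threshold = 4) {
  seq <- toupper(seq)
  L <- nchar(seq)
  tracts <- list()
  units <- integer(0)
  emit <- function() {
    if (length(units) >= threshold) {
      tracts[[length(tracts) + 1]] <<- data.frame(
        start = units[1], end = units[length(units)] + 3L,
        occurrences = length(units))
    }
  }
  if (L >= 3) for (i in 0:(L - 3)) {
    w <- substr(seq, i + 1, i + 3)
    if (w %in% patterns) {
      if (length(units) == 0) {
        units <- i
      } else if (i - (units[length(units)] + 3L) <= gap_tolerance) {
        units <- c(units, i)
      } else {
        emit()
        units <- i
      }
    }
  }
  emit()
  if (!length(tracts)) {
    return(data.frame(start = integer(), end = integer(),
                      occurrences = integer()))
  }
  do.call(rbind, tracts)
}

# All-pairs overlap test (>= 1 shared bp, same chromosome, half-open).
oracle_pair_overlaps <- function(a, b) {
  sapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end)
  })
}

oracle_intersect_report_a <- function(a, b) {
  hit <- oracle_pair_overlaps(a, b)
  out <- a[hit, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Position-by-position IUPAC motif scan on both strands.
oracle_scan_motif <- function(seq, motif) {
  codes <- Biostrings::IUPAC_CODE_MAP
  expand <- function(m) strsplit(codes[strsplit(m, "")[[1]]], "")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- function(m) paste(rev(comp[strsplit(m, "")[[1]]]), collapse = "")
  seq <- toupper(seq)
  match_at <- function(m, off) {
    allowed <- expand(m)
    all(vapply(seq_along(allowed), function(k) {
      substr(seq, off + k, off + k) %in% allowed[[k]]
    }, logical(1)))
  }
  L <- nchar(seq)
  w <- nchar(motif)
  hits <- list()
  if (L >= w) for (off in 0:(L - w)) {
    f <- match_at(motif, off)
    r <- match_at(rc(motif), off)
    if (f || r) {
      hits[[length(hits) + 1]] <- data.frame(
        offset = off, strand = if (f) "+" else "-",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(offset = integer(), strand = character()))
  }
  do.call(rbind, hits)
}

# Per-base liftover through chains in descending score order; returns the
# mapped (chrom, strand, position) of every base or NA.
oracle_liftover_bases <- function(chrom, start, end, chains) {
  ord <- order(vapply(chains, `[[`, numeric(1), "score"), decreasing = TRUE)
  res <- data.frame(pos = start:(end - 1), chrom = NA_character_,
                    strand = NA_character_, mapped = NA_integer_)
  for (r in seq_len(nrow(res))) {
    x <- res$pos[r]
    for (ci in ord) {
      ch <- chains[[ci]]
      if (ch$t_chrom != chrom) next
      t_pos <- ch$t_start
      q_pos <- ch$q_start
      found <- FALSE
      for (bi in seq_len(nrow(ch$blocks))) {
        size <- ch$blocks$size[bi]
        if (x >= t_pos && x < t_pos + size) {
          q <- q_pos + (x - t_pos)
          if (ch$q_strand == "-") q <- ch$q_size - 1L - q
          res$chrom[r] <- ch$q_chrom
          res$strand[r] <- ch$q_strand
          res$mapped[r] <- q
          found <- TRUE
          break
        }
        t_pos <- t_pos + size + ch$blocks$dt[bi]
        q_pos <- q_pos + size + ch$blocks$dq[bi]
      }
      if (found) break
    }
  }
  res
}

# Random interval set generator for property tests.
rand_interval_set <- function(n, chroms = c("chr1", "chr2"),
                              max_pos = 10000, max_len = 300) {
  start <- sample.int(max_pos, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start,
                    start + sample.int(max_len, n, replace = TRUE))
}

rand_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small simulation configuration for fast module tests.
small_sim_config <- function(seed = 11) {
  sim_config(
    seed = seed,
    chrom_lengths = c(chrA1 = 1500000L),
    n_genes = 25,
    n_peaks = 120,
    n_background_regions = 80,
    n_super_regions = 5,
    block_length_range = c(15000, 40000),
    n_syntenic_se_pairs = 8,
    n_decoy_ses = 3,
    se_width_range = c(4000, 8000),
    n_de_universe = 600,
    n_shared_up = 40,
    n_shared_down = 20,
    n_exactly_two_up = 15,
    n_exactly_two_down = 9,
    n_only_up = 12,
    n_only_down = 10,
    n_looped_genes = 8,
    n_loop_up = 3,
    n_loop_down = 1,
    n_decoy_loops = 9)
}
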