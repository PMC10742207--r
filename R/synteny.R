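#' Read a UCSC chain file
#'
#' Parses blockwise genome alignments. Each chain header carries the score,
#' source ("target" in chain terminology: the genome lifted FROM) and query
#' (the genome lifted TO) coordinates; each alignment line is
#' `size [dt dq]`. Coordinates on a `-` strand are in reversed-strand space
#' per the format specification. Block bookkeeping is validated against the
#' header spans.
#'
#' @param path Path to a chain file.
#' @return list of chain alignments, each a list with `score`, `t_chrom`,
#'   `t_size`, `t_strand`, `t_start`, `t_end`, `q_chrom`, `q_size`,
#'   `q_strand`, `q_start`, `q_end` and `blocks` (data.frame `size`, `dt`,
#'   `dq`).
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (f[1] != "chain" || length(f) < 12) {
      stop("line ", i, ": expected chain header")
    }
    hdr <- list(score = as.numeric(f[2]),
                t_chrom = f[3], t_size = as.integer(f[4]), t_strand = f[5],
                t_start = as.integer(f[6]), t_end = as.integer(f[7]),
                q_chrom = f[8], q_size = as.integer(f[9]), q_strand = f[10],
                q_start = as.integer(f[11]), q_end = as.integer(f[12]))
    if (!hdr$t_strand %in% c("+", "-") || !hdr$q_strand %in% c("+", "-")) {
      stop("line ", i, ": invalid strand in chain header")
    }
    i <- i + 1L
    sizes <- integer(); dts <- integer(); dqs <- integer()
    done <- FALSE
    while (i <= n && nzchar(trimws(lines[i]))) {
      b <- suppressWarnings(as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (any(is.na(b))) stop("line ", i, ": malformed block line")
      if (length(b) == 3) {
        sizes <- c(sizes, b[1]); dts <- c(dts, b[2]); dqs <- c(dqs, b[3])
      } else if (length(b) == 1) {
        sizes <- c(sizes, b[1]); dts <- c(dts, 0L); dqs <- c(dqs, 0L)
        done <- TRUE
        i <- i + 1L
        break
      } else {
        stop("line ", i, ": malformed block line")
      }
      i <- i + 1L
    }
    if (!done) stop("truncated chain (missing terminal block) near line ", i)
    if (any(sizes <= 0)) stop("chain block with non-positive size")
    if (sum(sizes) + sum(dts) != hdr$t_end - hdr$t_start) {
      stop("chain source span does not match its blocks")
    }
    if (sum(sizes) + sum(dqs) != hdr$q_end - hdr$q_start) {
      stop("chain target span does not match its blocks")
    }
    hdr$blocks <- data.frame(size = sizes, dt = dts, dq = dqs)
    chains[[length(chains) + 1]] <- hdr
  }
  chains
}

#' Write chain alignments to a UCSC chain file
#'
#' Companion writer for [read_chain()]; used by the synthetic species-pair
#' generator to emit exact chains.
#'
#' @param chains list of chain alignments (see [read_chain()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  out <- character()
  for (k in seq_along(chains)) {
    ch <- chains[[k]]
    out <- c(out, paste("chain", format(ch$score, scientific = FALSE),
                        ch$t_chrom, ch$t_size, ch$t_strand,
                        ch$t_start, ch$t_end,
                        ch$q_chrom, ch$q_size, ch$q_strand,
                        ch$q_start, ch$q_end, k))
    b <- ch$blocks
    nb <- nrow(b)
    if (nb > 1) {
      out <- c(out, paste(b$size[-nb], b$dt[-nb], b$dq[-nb]))
    }
    out <- c(out, as.character(b$size[nb]), "")
  }
  writeLines(out, path)
  invisible(path)
}

# Absolute block coordinate table for one chain: source (forward) and query
# (strand-space) starts/ends of every aligned block.
chain_block_table <- function(ch) {
  b <- ch$blocks
  t_s <- ch$t_start + cumsum(c(0L, b$size[-nrow(b)] + b$dt[-nrow(b)]))
  q_s <- ch$q_start + cumsum(c(0L, b$size[-nrow(b)] + b$dq[-nrow(b)]))
  data.frame(t_start = t_s, t_end = t_s + b$size,
             q_start = q_s, q_end = q_s + b$size)
}

#' Lift an interval through chain alignments
#'
#' Every base falling inside an aligned block is mapped through the block
#' offset, strand-aware; chains are applied in descending score order, each
#' base mapped by the best chain covering it. The result is the hull of the
#' mapped bases on the majority target strand. The interval is unmapped when
#' the mapped-base fraction falls below `min_match` or when mapped bases
#' split across target chromosomes. Unmapped is a value, not an error.
#'
#' @param interval One-row interval data.frame (or list with `chrom`,
#'   `start`, `end`).
#' @param chains Chains from [read_chain()] (source coordinates = the
#'   interval's genome).
#' @param min_match Minimum fraction of bases that must map (default 0.95,
#'   the reference liftover tool's default).
#' @return list with `mapped` (logical), and when mapped: `chrom`, `start`,
#'   `end`, `strand`, `fraction`.
#' @export
liftover_interval <- function(interval, chains, min_match = 0.95) {
  s <- as.integer(interval$start[1])
  e <- as.integer(interval$end[1])
  chrom <- as.character(interval$chrom[1])
  width <- e - s
  ord <- order(vapply(chains, `[[`, numeric(1), "score"), decreasing = TRUE)
  # sub-intervals of [s, e) not yet mapped by a higher-scoring chain
  remaining <- data.frame(start = s, end = e)
  segs <- list()
  for (ci in ord) {
    ch <- chains[[ci]]
    if (ch$t_chrom != chrom || nrow(remaining) == 0) next
    bt <- chain_block_table(ch)
    new_remaining <- list()
    for (r in seq_len(nrow(remaining))) {
      rs <- remaining$start[r]; re <- remaining$end[r]
      ov <- which(bt$t_end > rs & bt$t_start < re)
      if (!length(ov)) {
        new_remaining[[length(new_remaining) + 1]] <-
          data.frame(start = rs, end = re)
        next
      }
      cur <- rs
      for (bi in ov) {
        os <- max(rs, bt$t_start[bi]); oe <- min(re, bt$t_end[bi])
        if (cur < os) {
          new_remaining[[length(new_remaining) + 1]] <-
            data.frame(start = cur, end = os)
        }
        o1 <- os - bt$t_start[bi]; o2 <- oe - bt$t_start[bi]
        qs <- bt$q_start[bi] + o1; qe <- bt$q_start[bi] + o2
        if (ch$q_strand == "-") {
          fs <- ch$q_size - qe; fe <- ch$q_size - qs
        } else {
          fs <- qs; fe <- qe
        }
        segs[[length(segs) + 1]] <- data.frame(
          chrom = ch$q_chrom, strand = ch$q_strand,
          start = fs, end = fe, bases = oe - os,
          stringsAsFactors = FALSE)
        cur <- oe
      }
      if (cur < re) {
        new_remaining[[length(new_remaining) + 1]] <-
          data.frame(start = cur, end = re)
      }
    }
    remaining <- if (length(new_remaining)) {
      do.call(rbind, new_remaining)
    } else {
      data.frame(start = integer(), end = integer())
    }
  }
  if (!length(segs)) return(list(mapped = FALSE))
  segs <- do.call(rbind, segs)
  if (length(unique(segs$chrom)) > 1) return(list(mapped = FALSE))
  fraction <- sum(segs$bases) / width
  if (fraction < min_match) return(list(mapped = FALSE))
  by_strand <- tapply(segs$bases, segs$strand, sum)
  strand <- names(by_strand)[which.max(by_strand)]
  keep <- segs[segs$strand == strand, , drop = FALSE]
  list(mapped = TRUE, chrom = segs$chrom[1],
       start = as.integer(min(keep$start)), end = as.integer(max(keep$end)),
       strand = strand, fraction = fraction)
}

#' Lift many intervals through chain alignments
#'
#' Vectorised wrapper around [liftover_interval()].
#'
#' @param intervals Interval data.frame.
#' @inheritParams liftover_interval
#' @return data.frame with one row per input: `mapped`, `m_chrom`, `m_start`,
#'   `m_end`, `m_strand`, `fraction`.
#' @export
liftover_intervals <- function(intervals, chains, min_match = 0.95) {
  validate_intervals(intervals)
  res <- lapply(seq_len(nrow(intervals)), function(i) {
    liftover_interval(intervals[i, , drop = FALSE], chains, min_match)
  })
  data.frame(
    mapped = vapply(res, `[[`, logical(1), "mapped"),
    m_chrom = vapply(res, function(r) {
      if (r$mapped) r$chrom else NA_character_ }, character(1)),
    m_start = vapply(res, function(r) {
      if (r$mapped) r$start else NA_integer_ }, integer(1)),
    m_end = vapply(res, function(r) {
      if (r$mapped) r$end else NA_integer_ }, integer(1)),
    m_strand = vapply(res, function(r) {
      if (r$mapped) r$strand else NA_character_ }, character(1)),
    fraction = vapply(res, function(r) {
      if (r$mapped) r$fraction else NA_real_ }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Match syntenic super-enhancers between two species
#'
#' Lifts every species-A SE to species-B coordinates and records overlaps
#' with B SEs (and vice versa). A pair is reciprocal when both directions
#' connect the same two SEs. Matching is many-to-many, so the number of
#' distinct matched SEs may differ between species.
#'
#' @param ses_a,ses_b Interval data.frames of SE spans per species.
#' @param chain_a_to_b,chain_b_to_a Chains from [read_chain()].
#' @param min_match Liftover minimum mapped fraction.
#' @return list with `matches` (data.frame `a_index`, `b_index`, `direction`,
#'   `reciprocal`) and `summary` (`n_a_matched`, `n_b_matched`,
#'   `n_reciprocal_pairs`).
#' @export
match_syntenic_ses <- function(ses_a, ses_b, chain_a_to_b, chain_b_to_a,
                               min_match = 0.95) {
  validate_intervals(ses_a)
  validate_intervals(ses_b)
  one_direction <- function(from, to, chains) {
    lifted <- liftover_intervals(from, chains, min_match)
    ok <- which(lifted$mapped)
    if (!length(ok) || nrow(to) == 0) {
      return(data.frame(from_index = integer(), to_index = integer()))
    }
    lg <- GenomicRanges::GRanges(
      lifted$m_chrom[ok],
      IRanges::IRanges(lifted$m_start[ok] + 1L, lifted$m_end[ok]))
    hits <- find_overlaps(lg, ivs_to_gr(to))
    data.frame(from_index = ok[S4Vectors::queryHits(hits)],
               to_index = S4Vectors::subjectHits(hits))
  }
  ab <- one_direction(ses_a, ses_b, chain_a_to_b)
  ba <- one_direction(ses_b, ses_a, chain_b_to_a)
  key_ab <- paste(ab$from_index, ab$to_index)
  key_ba <- paste(ba$to_index, ba$from_index) # as (a, b)
  m_ab <- data.frame(a_index = ab$from_index, b_index = ab$to_index,
                     direction = "A_to_B",
                     reciprocal = key_ab %in% key_ba,
                     stringsAsFactors = FALSE)
  m_ba <- data.frame(a_index = ba$to_index, b_index = ba$from_index,
                     direction = "B_to_A",
                     reciprocal = key_ba %in% key_ab,
                     stringsAsFactors = FALSE)
  matches <- rbind(m_ab, m_ba)
  rec <- unique(matches[matches$reciprocal, c("a_index", "b_index")])
  list(
    matches = matches,
    summary = list(
      n_a_matched = length(unique(matches$a_index)),
      n_b_matched = length(unique(matches$b_index)),
      n_reciprocal_pairs = nrow(rec)
    )
  )
}

#' Gene orientation and distance table for syntenic SE pairs
#'
#' For each reciprocal SE pair, finds the nearest gene to the SE midpoint in
#' each species, the signed TSS-to-SE distance (negative = SE upstream of the
#' TSS in gene orientation) and whether the two species place the SE on the
#' same side of their homologous genes.
#'
#' @param matches Output of [match_syntenic_ses()].
#' @param ses_a,ses_b SE interval data.frames used in the matching.
#' @param genes_a,genes_b Gene models per species.
#' @param homologs data.frame with columns `gene_id_a`, `gene_id_b`.
#' @return data.frame with one row per reciprocal pair: SE indices, nearest
#'   gene per species, signed distances, `homologous` and `same_orientation`
#'   (`NA` for non-homologous nearest genes, which are excluded from
#'   orientation tallies).
#' @export
orientation_distance_table <- function(matches, ses_a, ses_b,
                                       genes_a, genes_b, homologs) {
  rec <- unique(matches$matches[matches$matches$reciprocal,
                                c("a_index", "b_index")])
  nearest_one <- function(se, genes) {
    mid <- as.integer(floor((se$start + se$end) / 2))
    gi <- which(genes$chrom == se$chrom)
    if (!length(gi)) return(NULL)
    d <- abs(mid - genes$tss[gi])
    sel <- gi[order(d, genes$gene_id[gi])[1]]
    list(gene_id = genes$gene_id[sel],
         dist = signed_tss_distance(mid, genes$tss[sel], genes$strand[sel]))
  }
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    a <- nearest_one(ses_a[rec$a_index[i], , drop = FALSE], genes_a)
    b <- nearest_one(ses_b[rec$b_index[i], , drop = FALSE], genes_b)
    if (is.null(a) || is.null(b)) return(NULL)
    hom <- any(homologs$gene_id_a == a$gene_id &
                 homologs$gene_id_b == b$gene_id)
    data.frame(
      a_index = rec$a_index[i], b_index = rec$b_index[i],
      gene_a = a$gene_id, gene_b = b$gene_id,
      distance_a = a$dist, distance_b = b$dist,
      homologous = hom,
      same_orientation = if (hom) sign(a$dist) == sign(b$dist) else NA,
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(a_index = integer(), b_index = integer(),
                      gene_a = character(), gene_b = character(),
                      distance_a = integer(), distance_b = integer(),
                      homologous = logical(), same_orientation = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
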