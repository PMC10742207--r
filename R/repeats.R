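#' Configuration for the trinucleotide repeat scanner
#'
#' The scanner slides a 3 bp window with 1 bp step over a sequence, matching
#' the pattern set (TGA and its reverse complement TCA by default). Matches
#' are chained into a tract while each gap between consecutive matches (start
#' of the next minus end of the previous) stays within `gap_tolerance`; a
#' larger gap closes the tract and the scan restarts from the match that
#' broke the chain. A tract is reported when it accumulates at least
#' `threshold` matches.
#'
#' Two gap-tolerance settings have been used for this statistic in published
#' work (5 bp and 2 bp); the default is 5 and the parameter is exposed.
#'
#' @param patterns Character vector of 3-mers to match (default TGA, TCA).
#' @param gap_tolerance Maximum allowed gap in bp between consecutive matches
#'   (default 5).
#' @param threshold Minimum number of matches for a tract to be reported
#'   ("4 or more"; default 4).
#' @return A list of class `scanner_config`.
#' @export
scanner_config <- function(patterns = c("TGA", "TCA"), gap_tolerance = 5,
                           threshold = 4) {
  patterns <- toupper(patterns)
  if (any(nchar(patterns) != 3)) stop("patterns must be 3 bp (window size 3)")
  if (gap_tolerance < 0) stop("gap_tolerance must be >= 0")
  if (threshold < 1) stop("threshold must be >= 1")
  structure(list(patterns = patterns,
                 gap_tolerance = as.integer(gap_tolerance),
                 threshold = as.integer(threshold)),
            class = "scanner_config")
}

#' Detect gap-tolerant trinucleotide repeat tracts
#'
#' Left-to-right scan of `sequence` for runs of TGA/TCA units (see
#' [scanner_config()]). `N` never matches. Matches of the default pattern set
#' can never overlap each other, so gaps are well defined. Returned tracts
#' are maximal and non-overlapping.
#'
#' @param sequence A single DNA string over `{A, C, G, T, N}` (case
#'   insensitive).
#' @param config A [scanner_config()].
#' @return data.frame with one row per tract: `start` (0-based offset),
#'   `end` (exclusive), `occurrences`, and a list column `unit_positions`
#'   with the 0-based offset of every matched unit.
#' @export
#'
#' @examples
#' detect_repeat_tracts("TGATGATGATGA")       # one tract of 4 units
#' detect_repeat_tracts("TGATGATGA")          # below threshold: none
detect_repeat_tracts <- function(sequence, config = scanner_config()) {
  stopifnot(length(sequence) == 1)
  v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(v)
  empty <- data.frame(start = integer(), end = integer(),
                      occurrences = integer())
  empty$unit_positions <- list()
  if (L < 3) return(empty)
  is_match <- rep(FALSE, L - 2L)
  for (p in config$patterns) {
    pv <- strsplit(p, "", fixed = TRUE)[[1]]
    is_match <- is_match |
      (v[1:(L - 2)] == pv[1] & v[2:(L - 1)] == pv[2] & v[3:L] == pv[3])
  }
  off <- which(is_match) - 1L # 0-based unit starts
  if (!length(off)) return(empty)
  # gap between consecutive units = next start - previous end (= start + 3)
  grp <- cumsum(c(TRUE, diff(off) - 3L > config$gap_tolerance))
  starts <- tapply(off, grp, min)
  counts <- tapply(off, grp, length)
  keep <- which(counts >= config$threshold)
  if (!length(keep)) return(empty)
  units <- split(off, grp)[keep]
  out <- data.frame(
    start = as.integer(starts[keep]),
    end = as.integer(vapply(units, max, integer(1)) + 3L),
    occurrences = as.integer(counts[keep])
  )
  out$unit_positions <- unname(lapply(units, as.integer))
  rownames(out) <- NULL
  out
}

#' Extract the central window of a peak's sequence
#'
#' Returns the `width` bp of genome sequence centred on the peak midpoint
#' (left-biased by 1 bp when parity forces a choice), clipped to the peak and
#' the chromosome when necessary. Motif and repeat statistics are computed on
#' the central 100 bp of binding sites by default.
#'
#' @param peaks Interval data.frame (one or more peaks).
#' @param genome A named [Biostrings::DNAStringSet] (names = chromosomes) or
#'   path to a FASTA file.
#' @param width Window width in bp (default 100).
#' @return Character vector of sequences, one per peak.
#' @export
extract_central_window <- function(peaks, genome, width = 100) {
  validate_intervals(peaks)
  if (is.character(genome) && length(genome) == 1) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  missing_chr <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chr)) {
    stop("chromosome not in FASTA: ", missing_chr[1])
  }
  mids <- peak_midpoint(peaks)
  ws <- mids - floor(width / 2)
  we <- ws + as.integer(width)
  clip_s <- pmax(ws, peaks$start, 0L)
  chr_len <- Biostrings::width(genome)[match(peaks$chrom, names(genome))]
  clip_e <- pmin(we, peaks$end, chr_len)
  if (any(clip_s > ws | clip_e < we)) {
    warning("window clipped to peak/chromosome bounds for ",
            sum(clip_s > ws | clip_e < we), " peak(s)")
  }
  vapply(seq_len(nrow(peaks)), function(i) {
    as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                    clip_s[i] + 1L, clip_e[i]))
  }, character(1))
}

#' Scan a sequence for an IUPAC motif on both strands
#'
#' Reports every offset where the motif matches the forward sequence or
#' where its reverse complement does (bZIP motifs are read on either strand).
#' A palindrome hit is reported once per offset.
#'
#' @param sequence A single DNA string.
#' @param iupac_motif Motif over the IUPAC alphabet (`N` matches any base).
#' @return data.frame with columns `offset` (0-based) and `strand`.
#' @export
#'
#' @examples
#' scan_motif("AATGACGTCAAA", "TGACGTCA")
scan_motif <- function(sequence, iupac_motif) {
  iupac_motif <- toupper(iupac_motif)
  ok <- names(Biostrings::IUPAC_CODE_MAP)
  chars <- strsplit(iupac_motif, "", fixed = TRUE)[[1]]
  if (any(!chars %in% ok)) {
    stop("non-IUPAC character in motif: ", chars[!chars %in% ok][1])
  }
  subj <- Biostrings::DNAString(toupper(sequence))
  fixed <- c(pattern = FALSE, subject = TRUE)
  fwd <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(iupac_motif), subj, fixed = fixed)) - 1L
  rcm <- Biostrings::reverseComplement(Biostrings::DNAString(iupac_motif))
  rev <- Biostrings::start(Biostrings::matchPattern(
    rcm, subj, fixed = fixed)) - 1L
  rev <- setdiff(rev, fwd) # palindromes reported once
  out <- data.frame(
    offset = c(fwd, rev),
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify peak sequences by fixed binding motifs
#'
#' Flags each sequence for the canonical ATF/CREB motif (TGACGTCA), the
#' variant motif (TGANNTCA) and the AP1 motif (TGAGTCA), double-stranded.
#' The exclusive partition reports canonical with precedence over variant
#' (a variant call excludes sequences that contain the canonical motif);
#' AP1 is the third class, then `none`.
#'
#' @param peak_sequences Character vector of sequences (e.g. central 100 bp
#'   windows from [extract_central_window()]).
#' @return list with `flags` (data.frame of per-sequence logicals
#'   `has_canonical`, `has_variant` (excluding canonical), `has_ap1`, and the
#'   exclusive `class`) and `counts` (named integer vector over the classes).
#' @export
classify_by_motif <- function(peak_sequences) {
  subj <- Biostrings::DNAStringSet(toupper(peak_sequences))
  fixed <- c(pattern = FALSE, subject = TRUE)
  count2 <- function(motif) {
    m <- Biostrings::DNAString(motif)
    Biostrings::vcountPattern(m, subj, fixed = fixed) +
      Biostrings::vcountPattern(Biostrings::reverseComplement(m), subj,
                                fixed = fixed)
  }
  has_canonical <- count2("TGACGTCA") > 0
  has_variant_raw <- count2("TGANNTCA") > 0
  has_ap1 <- count2("TGAGTCA") > 0
  has_variant <- has_variant_raw & !has_canonical
  class <- ifelse(has_canonical, "canonical_TGACGTCA",
           ifelse(has_variant, "variant_TGANNTCA",
           ifelse(has_ap1, "AP1_TGAGTCA", "none")))
  lv <- c("canonical_TGACGTCA", "variant_TGANNTCA", "AP1_TGAGTCA", "none")
  counts <- table(factor(class, levels = lv))
  list(
    flags = data.frame(has_canonical = has_canonical,
                       has_variant = has_variant,
                       has_ap1 = has_ap1,
                       class = class,
                       stringsAsFactors = FALSE),
    counts = stats::setNames(as.integer(counts), lv)
  )
}

#' Fraction of peaks containing a repeat tract, with a two-set comparison
#'
#' Computes the proportion of sequences containing at least one TGA/TCA
#' repeat tract, and, when a second set is supplied, a two-sided Welch
#' t-test on the per-peak binary indicators.
#'
#' @param peak_sequences Character vector of sequences for the first set.
#' @param other_sequences Optional second set to compare against.
#' @param config A [scanner_config()].
#' @return list with `fraction` (and `fraction_other` when supplied),
#'   per-set indicator vectors, and `t_statistic` / `p_value` when the test
#'   is performed (both sets of size >= 2).
#' @export
repeat_fraction <- function(peak_sequences, other_sequences = NULL,
                            config = scanner_config()) {
  has_tract <- function(seqs) vapply(seqs, function(s) {
    nrow(detect_repeat_tracts(s, config)) > 0
  }, logical(1), USE.NAMES = FALSE)
  ind <- has_tract(peak_sequences)
  out <- list(fraction = mean(ind), indicator = ind)
  if (!is.null(other_sequences)) {
    ind2 <- has_tract(other_sequences)
    out$fraction_other <- mean(ind2)
    out$indicator_other <- ind2
    if (length(ind) < 2 || length(ind2) < 2) {
      warning("a set has fewer than 2 peaks; t-test skipped")
    } else if (stats::var(ind) == 0 && stats::var(ind2) == 0 &&
               mean(ind) == mean(ind2)) {
      # identical constant indicators: no detectable difference
      out$t_statistic <- 0
      out$p_value <- 1
    } else {
      tt <- stats::t.test(ind, ind2)
      out$t_statistic <- unname(tt$statistic)
      out$p_value <- tt$p.value
    }
  }
  out
}
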