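#' Intersect two interval sets
#'
#' Overlap is defined as at least 1 shared bp on the same chromosome,
#' strand-blind, under the half-open convention (abutting intervals do not
#' overlap). Mirrors the two `bedtools intersect` modes used for
#' intersectional consensus analysis.
#'
#' @param a,b Interval data.frames.
#' @param mode `"report_a_overlapping_b"` returns the rows of `a` that
#'   overlap at least one interval of `b`, each reported once;
#'   `"report_overlap_segments"` returns the pairwise overlap segments.
#' @return Interval data.frame sorted by `(chrom, start)`.
#' @export
intersect_intervals <- function(a, b,
                                mode = c("report_a_overlapping_b",
                                         "report_overlap_segments")) {
  mode <- match.arg(mode)
  validate_intervals(a)
  validate_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    out <- a[integer(0), , drop = FALSE]
    return(out)
  }
  hits <- find_overlaps(ivs_to_gr(a), ivs_to_gr(b))
  if (mode == "report_a_overlapping_b") {
    idx <- sort(unique(S4Vectors::queryHits(hits)))
    out <- a[idx, , drop = FALSE]
    out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  seg <- data.frame(
    chrom = a$chrom[qi],
    start = pmax(a$start[qi], b$start[si]),
    end = pmin(a$end[qi], b$end[si]),
    strand = ".", name = NA_character_, score = NA_real_,
    stringsAsFactors = FALSE
  )
  seg <- seg[order(seg$chrom, seg$start, seg$end), , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Consensus binding sites across replicate peak sets
#'
#' Iterated `report_a` intersection: the intervals of the first set that
#' overlap at least one interval in every other set.
#'
#' @param sets List of two or more interval data.frames. The first set is the
#'   anchor whose intervals are reported.
#' @return Interval data.frame (subset of `sets[[1]]`, sorted).
#' @export
consensus_sites <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) {
    stop("consensus requires at least 2 interval sets")
  }
  out <- sets[[1]]
  for (i in seq_along(sets)[-1]) {
    out <- intersect_intervals(out, sets[[i]], "report_a_overlapping_b")
    if (nrow(out) == 0) break
  }
  out
}

#' Three-way overlap tallies of interval sets
#'
#' For each anchor set, counts its intervals by their overlap pattern with
#' the other two sets (membership is >= 1 bp overlap). Because membership is
#' per anchor interval, the three anchored tallies need not agree with each
#' other (many-to-many overlaps), mirroring how peak-set Venn counts are
#' reported per dataset.
#'
#' @param a,b,c Interval data.frames (e.g. three ChIP-seq peak sets).
#' @param labels Character vector of length 3 naming the sets.
#' @return data.frame with columns `anchor`, `in_second`, `in_third`,
#'   `second`, `third`, `count`: for each anchor set, the four overlap
#'   patterns with the other two sets (in `labels` order).
#' @export
three_way_overlap_counts <- function(a, b, c, labels = c("A", "B", "C")) {
  sets <- list(a, b, c)
  for (s in sets) validate_intervals(s)
  grs <- lapply(sets, ivs_to_gr)
  rows <- list()
  for (i in 1:3) {
    others <- setdiff(1:3, i)
    m1 <- if (nrow(sets[[i]])) {
      overlaps_any(grs[[i]], grs[[others[1]]])
    } else logical(0)
    m2 <- if (nrow(sets[[i]])) {
      overlaps_any(grs[[i]], grs[[others[2]]])
    } else logical(0)
    for (p1 in c(FALSE, TRUE)) for (p2 in c(FALSE, TRUE)) {
      rows[[length(rows) + 1]] <- data.frame(
        anchor = labels[i],
        in_second = p1, in_third = p2,
        second = labels[others[1]], third = labels[others[2]],
        count = sum(m1 == p1 & m2 == p2),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
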