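#' Read a bedGraph coverage track
#'
#' @param path Path to a 4-column bedGraph (chrom, start, end, depth).
#' @return data.frame with columns `chrom`, `start`, `end`, `depth`, sorted
#'   by `(chrom, start)`. Overlapping steps are an error; stretches without a
#'   step are read as depth 0 by [score_regions()].
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "depth"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric"))
  if (any(df$end <= df$start)) {
    stop("bedGraph step with end <= start at line ",
         which(df$end <= df$start)[1])
  }
  if (any(df$depth < 0)) stop("negative depth at line ", which(df$depth < 0)[1])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  same <- df$chrom[-1] == df$chrom[-nrow(df)]
  if (nrow(df) > 1 && any(same & df$start[-1] < df$end[-nrow(df)])) {
    stop("overlapping bedGraph steps")
  }
  df
}

#' Stitch peaks into candidate enhancer regions
#'
#' ROSE-style stitching: two peaks on the same chromosome join when the gap
#' between them (start of the later minus end of the earlier) is at most
#' `stitch_distance` ("within 12.5 kb", read inclusively); the region span is
#' the hull of its constituents. Peaks falling fully inside an optional
#' TSS-exclusion zone are removed before stitching.
#'
#' @param peaks Interval data.frame (e.g. H3K27ac peaks).
#' @param stitch_distance Maximum gap in bp (default 12500).
#' @param tss_exclusion Optional interval data.frame (e.g. promoter windows);
#'   peaks fully contained in any exclusion interval are dropped.
#' @return Interval data.frame of stitched regions with `n_constituents` and
#'   a list column `constituents` (row indices into the retained peak set).
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500,
                         tss_exclusion = NULL) {
  validate_intervals(peaks)
  if (!is.null(tss_exclusion) && nrow(peaks) > 0 && nrow(tss_exclusion) > 0) {
    hits <- find_overlaps(ivs_to_gr(peaks),
                                        ivs_to_gr(tss_exclusion),
                                        type = "within")
    drop <- unique(S4Vectors::queryHits(hits))
    if (length(drop)) peaks <- peaks[-drop, , drop = FALSE]
  }
  if (nrow(peaks) == 0) {
    out <- genomic_intervals(character(), integer(), integer())
    out$n_constituents <- integer()
    out$constituents <- list()
    return(out)
  }
  ord <- order(peaks$chrom, peaks$start, peaks$end)
  p <- peaks[ord, , drop = FALSE]
  if (nrow(p) == 1) {
    grp <- 1L
  } else {
    new_region <- c(TRUE, p$chrom[-1] != p$chrom[-nrow(p)] |
                      p$start[-1] - cummax_by_chrom(p) > stitch_distance)
    grp <- cumsum(new_region)
  }
  out <- data.frame(
    chrom = tapply(p$chrom, grp, `[`, 1),
    start = as.integer(tapply(p$start, grp, min)),
    end = as.integer(tapply(p$end, grp, max)),
    strand = ".",
    name = NA_character_,
    score = NA_real_,
    stringsAsFactors = FALSE
  )
  out$n_constituents <- as.integer(tapply(grp, grp, length))
  out$constituents <- unname(split(ord, grp))
  rownames(out) <- NULL
  out
}

# Running maximum of peak ends within each chromosome, lagged by one peak,
# so the gap test compares each peak against the furthest end seen so far.
cummax_by_chrom <- function(p) {
  res <- integer(nrow(p) - 1L)
  cur_chrom <- p$chrom[1]
  cur_max <- p$end[1]
  for (i in 2:nrow(p)) {
    if (p$chrom[i] != cur_chrom) {
      cur_chrom <- p$chrom[i]
      cur_max <- p$end[i]
      res[i - 1L] <- 0L # unused: chromosome change forces a new region
    } else {
      res[i - 1L] <- cur_max
      cur_max <- max(cur_max, p$end[i])
    }
  }
  res
}

#' Score stitched regions by input-normalised coverage
#'
#' The signal of a region is the total ChIP reads minus the total input reads
#' over its span (depth x bp summed over bedGraph steps), floored at zero.
#' Stretches missing from a track count as depth 0.
#'
#' @param regions Interval data.frame of stitched regions.
#' @param chip,input Coverage tracks from [read_bedgraph()].
#' @return `regions` with added columns `chip_signal`, `input_signal`,
#'   `net_signal`.
#' @export
score_regions <- function(regions, chip, input) {
  validate_intervals(regions)
  track_sum <- function(track) {
    if (nrow(regions) == 0 || nrow(track) == 0) return(numeric(nrow(regions)))
    tg <- GenomicRanges::GRanges(track$chrom,
                                 IRanges::IRanges(track$start + 1L, track$end))
    hits <- find_overlaps(ivs_to_gr(regions), tg)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    bp <- pmin(regions$end[qi], track$end[si]) -
      pmax(regions$start[qi], track$start[si])
    sums <- numeric(nrow(regions))
    if (length(qi)) {
      agg <- tapply(bp * track$depth[si], qi, sum)
      sums[as.integer(names(agg))] <- agg
    }
    sums
  }
  regions$chip_signal <- track_sum(chip)
  regions$input_signal <- track_sum(input)
  regions$net_signal <- pmax(regions$chip_signal - regions$input_signal, 0)
  regions
}

#' Call super-enhancers from ranked region signals
#'
#' Regions are sorted ascending by `net_signal`; rank and signal are each
#' scaled to `[0, 1]`. The cutoff is the point of the ranked curve where the
#' tangent has slope 1 — the point lying furthest below the diagonal, i.e.
#' the argmax of (scaled rank - scaled signal), with ties broken toward fewer
#' supers. Regions with signal strictly above the cutoff signal are flagged
#' super. If all signals are equal the curve is degenerate and no region is
#' called super (with a warning).
#'
#' @param regions Scored regions from [score_regions()] (or any interval
#'   data.frame with a `net_signal` column; >= 2 rows).
#' @return `regions` sorted ascending by signal, with columns `rank`
#'   (1..N ascending), `scaled_rank`, `scaled_signal`, `is_super`; the cutoff
#'   signal is attached as attribute `cutoff_signal`.
#' @export
call_superenhancers <- function(regions) {
  if (!"net_signal" %in% names(regions)) stop("regions must carry net_signal")
  n <- nrow(regions)
  if (n < 2) stop("need at least 2 regions to rank")
  ord <- order(regions$net_signal, regions$chrom, regions$start)
  out <- regions[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- seq_len(n)
  sig <- out$net_signal
  if (max(sig) == min(sig)) {
    warning("all region signals equal; no super-enhancers called")
    out$scaled_rank <- (out$rank - 1) / (n - 1)
    out$scaled_signal <- 0
    out$is_super <- FALSE
    attr(out, "cutoff_signal") <- Inf
    return(out)
  }
  out$scaled_rank <- (out$rank - 1) / (n - 1)
  out$scaled_signal <- (sig - min(sig)) / (max(sig) - min(sig))
  below <- out$scaled_rank - out$scaled_signal
  cut_idx <- max(which(below == max(below))) # ties -> fewer supers
  cutoff <- sig[cut_idx]
  out$is_super <- sig > cutoff
  attr(out, "cutoff_signal") <- cutoff
  out
}

#' Fraction of super-enhancers containing a binding site
#'
#' @param superenhancers Interval data.frame of SE spans (non-empty).
#' @param binding_sites Interval data.frame of binding sites.
#' @return list with `fraction` (SEs containing >= 1 site) and `site_counts`
#'   (per-SE counts).
#' @export
se_binding_overlap <- function(superenhancers, binding_sites) {
  validate_intervals(superenhancers)
  if (nrow(superenhancers) == 0) stop("empty super-enhancer set")
  counts <- if (nrow(binding_sites) == 0) {
    integer(nrow(superenhancers))
  } else {
    count_overlaps(ivs_to_gr(superenhancers),
                                 ivs_to_gr(binding_sites))
  }
  list(fraction = mean(counts > 0), site_counts = as.integer(counts))
}

#' Compare binding-site score distributions between site classes
#'
#' Group means plus all-pairs Tukey honestly-significant-difference adjusted
#' p-values (one-way ANOVA followed by `TukeyHSD`), e.g. for
#' promoter-associated vs distal vs SE-associated binding sites.
#'
#' @param scores Numeric vector of per-site scores.
#' @param groups Character/factor vector of group labels, same length.
#' @return list with `means` (named vector), `n` (group sizes) and `tukey`
#'   (data.frame `comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
compare_site_classes <- function(scores, groups) {
  stopifnot(length(scores) == length(groups))
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with fewer than 2 members: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    scores <- scores[keep]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop("need at least 2 groups of size >= 2")
  df <- data.frame(score = scores, group = factor(groups))
  fit <- stats::aov(score ~ group, data = df)
  tk <- stats::TukeyHSD(fit)$group
  list(
    means = tapply(df$score, df$group, mean),
    n = as.integer(table(df$group)),
    tukey = data.frame(comparison = rownames(tk),
                       diff = tk[, "diff"], lwr = tk[, "lwr"],
                       upr = tk[, "upr"], p_adj = tk[, "p adj"],
                       row.names = NULL)
  )
}
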