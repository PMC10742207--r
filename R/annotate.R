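# Promoter windows: the closed window [tss - h, tss + h] expressed half-open.
promoter_windows <- function(genes, promoter_halfwidth = 3000) {
  data.frame(
    chrom = genes$chrom,
    start = pmax(genes$tss - as.integer(promoter_halfwidth), 0L),
    end = genes$tss + as.integer(promoter_halfwidth) + 1L,
    strand = genes$strand,
    name = genes$gene_id,
    score = NA_real_,
    stringsAsFactors = FALSE
  )
}

# Peak midpoint under the left-biased convention.
peak_midpoint <- function(x) as.integer(floor((x$start + x$end) / 2))

# Signed midpoint-to-TSS distance in gene orientation (negative = upstream).
signed_tss_distance <- function(mid, tss, strand) {
  ifelse(strand == "+", mid - tss, tss - mid)
}

#' Annotate peaks relative to gene models
#'
#' Each peak receives exactly one category. A peak is `promoter` if it
#' overlaps the closed window `[tss - h, tss + h]` of any gene (promoter
#' takes precedence, as in ChIPseeker's ranking); otherwise `intragenic` if
#' it overlaps any gene body; otherwise `intergenic`. The nearest gene is the
#' gene minimising the absolute distance from the peak midpoint to the TSS,
#' with ties broken lexicographically by `gene_id`; its distance is signed in
#' gene orientation (negative = upstream of the TSS).
#'
#' @param peaks Interval data.frame of binding sites.
#' @param genes Gene models from [read_gene_models()].
#' @param promoter_halfwidth Promoter window half-width in bp (default 3000,
#'   i.e. +/- 3 kb of the TSS).
#' @return data.frame: the peak columns plus `category`, `nearest_gene`,
#'   `distance_to_tss`.
#' @export
annotate_peaks <- function(peaks, genes, promoter_halfwidth = 3000) {
  validate_intervals(peaks)
  n <- nrow(peaks)
  out <- peaks
  out$category <- rep("intergenic", n)
  out$nearest_gene <- rep(NA_character_, n)
  out$distance_to_tss <- rep(NA_integer_, n)
  if (n == 0 || nrow(genes) == 0) return(out)

  pg <- ivs_to_gr(peaks)
  prom <- ivs_to_gr(promoter_windows(genes, promoter_halfwidth))
  body <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$gene_start + 1L, genes$gene_end))
  in_prom <- overlaps_any(pg, prom)
  in_body <- overlaps_any(pg, body)
  out$category <- ifelse(in_prom, "promoter",
                         ifelse(in_body, "intragenic", "intergenic"))

  mids <- peak_midpoint(peaks)
  known <- peaks$chrom %in% genes$chrom
  if (any(!known)) {
    warning(sum(!known), " peak(s) on chromosomes absent from the gene ",
            "annotation; categorized intergenic with no nearest gene")
    out$category[!known] <- "intergenic"
  }
  for (chr in unique(peaks$chrom[known])) {
    pi <- which(peaks$chrom == chr)
    gi <- which(genes$chrom == chr)
    # |midpoint - tss| over all genes of the chromosome; peak sets and gene
    # sets are small enough for the dense form
    d <- abs(outer(mids[pi], genes$tss[gi], "-"))
    ord <- order(genes$gene_id[gi])
    best <- apply(d[, ord, drop = FALSE], 1, which.min)
    sel <- gi[ord][best]
    out$nearest_gene[pi] <- genes$gene_id[sel]
    out$distance_to_tss[pi] <- signed_tss_distance(
      mids[pi], genes$tss[sel], genes$strand[sel])
  }
  out
}

#' Nearest genes to each peak within a distance cutoff
#'
#' GREAT-style assignment: up to `k` genes per peak, ranked by the absolute
#' distance from the peak midpoint to each TSS; genes beyond `max_distance`
#' are excluded; ties are broken lexicographically by `gene_id`.
#'
#' @param peaks Interval data.frame.
#' @param genes Gene models.
#' @param max_distance Maximum |midpoint - TSS| in bp (default 500 kb).
#' @param k Maximum number of genes per peak (default 2).
#' @return data.frame with columns `peak_index`, `peak_name`, `rank`,
#'   `gene_id`, `distance` (signed, gene orientation).
#' @export
nearest_genes <- function(peaks, genes, max_distance = 500000, k = 2) {
  validate_intervals(peaks)
  mids <- peak_midpoint(peaks)
  rows <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    gi <- which(genes$chrom == peaks$chrom[i])
    if (!length(gi)) next
    d <- abs(mids[i] - genes$tss[gi])
    keep <- d <= max_distance
    gi <- gi[keep]; d <- d[keep]
    if (!length(gi)) next
    ord <- order(d, genes$gene_id[gi])[seq_len(min(k, length(gi)))]
    sel <- gi[ord]
    rows[[i]] <- data.frame(
      peak_index = i,
      peak_name = peaks$name[i],
      rank = seq_along(sel),
      gene_id = genes$gene_id[sel],
      distance = signed_tss_distance(mids[i], genes$tss[sel],
                                     genes$strand[sel]),
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(peak_index = integer(), peak_name = character(),
                      rank = integer(), gene_id = character(),
                      distance = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map peaks to the promoters they overlap
#'
#' One row per (peak, gene) promoter overlap. A peak may hit the promoters of
#' several genes and one promoter may host several peaks; the count of unique
#' genes with at least one promoter peak is reported alongside.
#'
#' @inheritParams annotate_peaks
#' @return list with `pairs` (data.frame `peak_index`, `peak_name`,
#'   `gene_id`, `peak_score`) and `n_unique_genes`.
#' @export
map_peaks_to_promoters <- function(peaks, genes, promoter_halfwidth = 3000) {
  validate_intervals(peaks)
  if (nrow(peaks) == 0 || nrow(genes) == 0) {
    return(list(pairs = data.frame(peak_index = integer(),
                                   peak_name = character(),
                                   gene_id = character(),
                                   peak_score = numeric()),
                n_unique_genes = 0L))
  }
  prom <- promoter_windows(genes, promoter_halfwidth)
  hits <- find_overlaps(ivs_to_gr(peaks), ivs_to_gr(prom))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  pairs <- data.frame(
    peak_index = qi,
    peak_name = peaks$name[qi],
    gene_id = genes$gene_id[si],
    peak_score = peaks$score[qi],
    stringsAsFactors = FALSE
  )
  list(pairs = pairs, n_unique_genes = length(unique(pairs$gene_id)))
}
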