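#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames in BED convention: 0-based, half-open
#' `[start, end)`. This single convention is used everywhere in the package;
#' 1-based formats (GTF) are converted on read.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector, 0-based inclusive start coordinates (>= 0).
#' @param end Integer vector, exclusive end coordinates (> start).
#' @param strand Strand of each interval: one of `"+"`, `"-"`, `"."`.
#'   Recycled. Peak sets are typically unstranded (`"."`).
#' @param name Optional label per interval (recycled; `NA` allowed).
#' @param score Optional non-negative numeric score (enrichment). Recycled.
#'
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, `score`.
#' @export
#'
#' @examples
#' genomic_intervals("chr1", 100, 200)
genomic_intervals <- function(chrom, start, end, strand = ".",
                              name = NA_character_, score = NA_real_) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

#' Validate genomic-interval invariants
#'
#' Checks the interval invariants: `start >= 0`, `end > start`, non-empty
#' chromosome names, strand in `{+, -, .}`, non-negative scores.
#'
#' @param x A data.frame with at least `chrom`, `start`, `end` columns.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(is.na(x$chrom) | !nzchar(x$chrom))
  if (length(bad)) stop("empty chromosome name at row ", bad[1])
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0)
  if (length(bad)) stop("negative or missing coordinate at row ", bad[1])
  bad <- which(x$end <= x$start)
  if (length(bad)) {
    stop("end <= start at row ", bad[1], " (", x$chrom[bad[1]], ":",
         x$start[bad[1]], "-", x$end[bad[1]], ")")
  }
  if ("strand" %in% names(x)) {
    bad <- which(!x$strand %in% c("+", "-", "."))
    if (length(bad)) stop("invalid strand at row ", bad[1])
  }
  if ("score" %in% names(x)) {
    bad <- which(!is.na(x$score) & x$score < 0)
    if (length(bad)) stop("negative score at row ", bad[1])
  }
  invisible(x)
}

# Internal: convert 0-based half-open intervals to GRanges (1-based closed).
# Strand is deliberately dropped: overlap arithmetic is strand-blind.
ivs_to_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

# Internal overlap helpers with harmonised seqlevels, so pairing interval
# sets from different chromosome subsets stays silent.
gr_pair <- function(q, s) {
  lv <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(s))
  GenomeInfoDb::seqlevels(q) <- lv
  GenomeInfoDb::seqlevels(s) <- lv
  list(q = q, s = s)
}

find_overlaps <- function(q, s, ...) {
  p <- gr_pair(q, s)
  GenomicRanges::findOverlaps(p$q, p$s, ...)
}

overlaps_any <- function(q, s) {
  p <- gr_pair(q, s)
  IRanges::overlapsAny(p$q, p$s)
}

count_overlaps <- function(q, s) {
  p <- gr_pair(q, s)
  GenomicRanges::countOverlaps(p$q, p$s)
}

#' Read a BED file
#'
#' Reads BED3/BED6 into the package's interval data.frame. Coordinates are
#' kept 0-based half-open as in the file. Optional columns 4-6 populate
#' `name`, `score` and `strand`; a name of `"."` is read as missing. Input
#' order is preserved.
#'
#' @param path Path to a tab-separated BED file (>= 3 columns).
#' @return Interval data.frame (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("line ", which(nf < 3)[1], ": fewer than 3 tab-separated columns")
  }
  get_col <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[i] else NA_character_
  }, character(1))
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("line ", bad[1], ": malformed coordinate")
  bad <- which(end <= start | start < 0)
  if (length(bad)) stop("line ", bad[1], ": end <= start or negative start")
  name <- get_col(4)
  name[!is.na(name) & name == "."] <- NA_character_
  score <- suppressWarnings(as.numeric(get_col(5)))
  strand <- get_col(6)
  strand[is.na(strand)] <- "."
  bad <- which(!strand %in% c("+", "-", "."))
  if (length(bad)) stop("line ", bad[1], ": invalid strand '", strand[bad[1]], "'")
  genomic_intervals(get_col(1), start, end, strand, name, score)
}

#' Write intervals to a BED file
#'
#' Writes BED3 when `name`, `score` and `strand` are all unset, otherwise
#' BED6 (missing names become `"."`, missing scores `0`). Round-trips through
#' [read_bed()] losslessly for populated columns.
#'
#' @param intervals Interval data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  x <- intervals
  if (nrow(x) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  plain <- all(is.na(x$name)) && all(is.na(x$score)) && all(x$strand == ".")
  if (plain) {
    out <- paste(x$chrom, x$start, x$end, sep = "\t")
  } else {
    nm <- ifelse(is.na(x$name), ".", x$name)
    sc <- ifelse(is.na(x$score), 0, x$score)
    out <- paste(x$chrom, x$start, x$end, nm, sc, x$strand, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read gene models from GTF or a gene TSV
#'
#' Gene records become one row per gene with the transcription start site
#' (TSS) derived from strand: on `+` the TSS is `gene_start`, on `-` it is
#' `gene_end - 1` (0-based). GTF coordinates (1-based closed) are converted
#' to 0-based half-open on read.
#'
#' @param path Path to a GTF file or a tab-separated gene table with columns
#'   `gene_id`, `chrom`, `strand`, `start`, `end` (already 0-based half-open).
#' @param format `"gtf"` or `"tsv"`.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `gene_start`, `gene_end`, `tss`, `tes`.
#' @export
read_gene_models <- function(path, format = c("gtf", "tsv")) {
  format <- match.arg(format)
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "gene"]
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(!strand %in% c("+", "-"))) {
      stop("unknown strand symbol in gene record ",
           which(!strand %in% c("+", "-"))[1])
    }
    df <- data.frame(
      gene_id = as.character(gr$gene_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = strand,
      gene_start = BiocGenerics::start(gr) - 1L,
      gene_end = BiocGenerics::end(gr),
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "start", "end")
    if (!all(need %in% names(df))) {
      stop("gene TSV must have columns: ", paste(need, collapse = ", "))
    }
    if (any(!df$strand %in% c("+", "-"))) {
      stop("unknown strand symbol in gene record ",
           which(!df$strand %in% c("+", "-"))[1])
    }
    df <- data.frame(
      gene_id = as.character(df$gene_id),
      chrom = as.character(df$chrom),
      strand = df$strand,
      gene_start = as.integer(df$start),
      gene_end = as.integer(df$end),
      stringsAsFactors = FALSE
    )
  }
  if (any(df$gene_start >= df$gene_end)) stop("gene with start >= end")
  df$tss <- ifelse(df$strand == "+", df$gene_start, df$gene_end - 1L)
  df$tes <- ifelse(df$strand == "+", df$gene_end - 1L, df$gene_start)
  df
}

#' Write gene models as a gene TSV
#'
#' Companion writer for the TSV format accepted by [read_gene_models()].
#'
#' @param genes Gene-model data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_tsv <- function(genes, path) {
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand, start = genes$gene_start,
                    end = genes$gene_end)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read loop anchors from a BEDPE file
#'
#' @param path Path to a BEDPE file (>= 6 tab-separated columns). Anchor
#'   pairs are unordered.
#' @return data.frame with columns `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2` and, when present, `name` and `score` (loop support).
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6)) {
    stop("line ", which(lengths(fields) < 6)[1], ": fewer than 6 columns")
  }
  col <- function(i, as = identity) as(vapply(fields, function(f) {
    if (length(f) >= i) f[i] else NA_character_
  }, character(1)))
  df <- data.frame(
    chrom1 = col(1), start1 = col(2, as.integer), end1 = col(3, as.integer),
    chrom2 = col(4), start2 = col(5, as.integer), end2 = col(6, as.integer),
    stringsAsFactors = FALSE
  )
  if (any(lengths(fields) >= 7)) df$name <- col(7)
  if (any(lengths(fields) >= 8)) df$score <- suppressWarnings(col(8, as.numeric))
  bad <- which(df$end1 <= df$start1 | df$end2 <= df$start2)
  if (length(bad)) stop("line ", bad[1], ": anchor with end <= start")
  df
}
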