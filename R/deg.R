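#' Default per-dataset DEG classification rules
#'
#' The tumor-versus-muscle datasets (mouse and human CCS) use an absolute
#' log2 fold-change cutoff of 1; the cell-line knockdown contrast uses any
#' fold change (cutoff 0) because its DEGs reflect loss of the fusion
#' protein rather than the tumor/muscle state. Adjusted p < 0.05 everywhere.
#'
#' @return Named list of log2FC cutoffs per dataset label.
#' @export
default_deg_rules <- function() list(mCCS = 1, hCCS = 1, knockdown = 0)

#' Read a differential-expression result table
#'
#' @param path Tab-separated file with columns `gene_id`, `log2fc`, `padj`.
#'   Missing `padj` (`NA`) is preserved and treated as non-significant by
#'   [classify_degs()]. Duplicate gene ids are an error.
#' @param dataset_label Label attached to every record (e.g. `"mCCS"`).
#' @param flip_sign If `TRUE`, negate `log2fc` (for contrasts coded in the
#'   opposite direction, e.g. knockdown vs control instead of control vs
#'   knockdown).
#' @return data.frame with columns `gene_id`, `log2fc`, `padj`, `dataset`.
#' @export
read_de_table <- function(path, dataset_label, flip_sign = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(df))) {
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in DE table: ",
         df$gene_id[duplicated(df$gene_id)][1])
  }
  data.frame(
    gene_id = as.character(df$gene_id),
    log2fc = (if (flip_sign) -1 else 1) * as.numeric(df$log2fc),
    padj = as.numeric(df$padj),
    dataset = dataset_label,
    stringsAsFactors = FALSE
  )
}

#' Classify differential-expression records as up, down or neither
#'
#' A record is `up` when `log2fc` exceeds its dataset's cutoff and
#' `padj < padj_cutoff`; `down` when `log2fc` is below minus the cutoff;
#' otherwise `neither`. Missing `padj` is non-significant. Every record gets
#' exactly one label.
#'
#' @param records data.frame from [read_de_table()].
#' @param rules Named list of per-dataset log2FC cutoffs
#'   (default [default_deg_rules()]). An unknown dataset label is an error.
#' @param padj_cutoff Adjusted-p cutoff (default 0.05).
#' @return `records` with an added `label` column.
#' @export
classify_degs <- function(records, rules = default_deg_rules(),
                          padj_cutoff = 0.05) {
  unknown <- setdiff(unique(records$dataset), names(rules))
  if (length(unknown)) stop("no classification rule for dataset: ", unknown[1])
  cut <- unlist(rules)[records$dataset]
  sig <- !is.na(records$padj) & records$padj < padj_cutoff
  records$label <- ifelse(sig & records$log2fc > cut, "up",
                   ifelse(sig & records$log2fc < -cut, "down", "neither"))
  records
}

#' Intersect DEG sets across three datasets
#'
#' Translates gene ids into a shared namespace via the homolog map (genes
#' with multiple homologs resolve to the first mapping, with a message),
#' classifies each dataset under its own cutoff rule, then reports
#' per-dataset, pairwise, three-way, at-least-two and exactly-two shared
#' up/down sets.
#'
#' @param tables List of three labeled record data.frames
#'   ([read_de_table()]).
#' @param homologs Optional data.frame with columns `gene_id`, `shared_id`;
#'   applied to any record whose `gene_id` appears in it.
#' @param rules,padj_cutoff Passed to [classify_degs()].
#' @return list with `up` / `down`, each containing `per_dataset` (list of
#'   character vectors), `three_way`, `at_least_two`, `exactly_two`, and
#'   `counts` (named integer vector `three_way`, `at_least_two`,
#'   `exactly_two`).
#' @export
intersect_degs <- function(tables, homologs = NULL,
                           rules = default_deg_rules(), padj_cutoff = 0.05) {
  stopifnot(is.list(tables), length(tables) == 3)
  if (!is.null(homologs)) {
    if (anyDuplicated(homologs$gene_id)) {
      message("homolog map has multi-mapping genes; using first mapping")
      homologs <- homologs[!duplicated(homologs$gene_id), , drop = FALSE]
    }
  }
  sets <- lapply(tables, function(tab) {
    tab <- classify_degs(tab, rules, padj_cutoff)
    if (!is.null(homologs)) {
      idx <- match(tab$gene_id, homologs$gene_id)
      tab$gene_id <- ifelse(is.na(idx), tab$gene_id, homologs$shared_id[idx])
    }
    list(up = unique(tab$gene_id[tab$label == "up"]),
         down = unique(tab$gene_id[tab$label == "down"]))
  })
  names(sets) <- vapply(tables, function(t) t$dataset[1], character(1))
  tally <- function(dir) {
    gs <- lapply(sets, `[[`, dir)
    all_genes <- unique(unlist(gs))
    k <- vapply(all_genes, function(g) {
      sum(vapply(gs, function(s) g %in% s, logical(1)))
    }, integer(1))
    list(per_dataset = gs,
         three_way = all_genes[k == 3],
         at_least_two = all_genes[k >= 2],
         exactly_two = all_genes[k == 2],
         counts = c(three_way = sum(k == 3), at_least_two = sum(k >= 2),
                    exactly_two = sum(k == 2)))
  }
  list(up = tally("up"), down = tally("down"))
}

#' Fraction of DEGs with a binding site in their promoter
#'
#' @param deg_sets Named list of character vectors of gene ids (e.g. shared
#'   up / shared down sets).
#' @param peaks Interval data.frame of binding sites.
#' @param genes Gene models.
#' @param promoter_halfwidth Promoter half-width in bp (default 3000).
#' @return data.frame with one row per set: `set`, `bound`, `total`,
#'   `fraction` (`NA` for an empty set).
#' @export
promoter_binding_fraction <- function(deg_sets, peaks, genes,
                                      promoter_halfwidth = 3000) {
  pp <- map_peaks_to_promoters(peaks, genes, promoter_halfwidth)
  bound_genes <- unique(pp$pairs$gene_id)
  rows <- lapply(names(deg_sets), function(nm) {
    set <- unique(deg_sets[[nm]])
    data.frame(set = nm,
               bound = sum(set %in% bound_genes),
               total = length(set),
               fraction = if (length(set)) {
                 sum(set %in% bound_genes) / length(set)
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Binding-site score by expression class of the bound gene
#'
#' Joins promoter peak-gene pairs with an expression table, bins genes by
#' log2 fold change (above `upper`, between, below `-upper` by default the
#' >1 / 1..-1 / <-1 classes), and reports the mean peak score per class with
#' pairwise Welch t-tests.
#'
#' @param promoter_pairs `pairs` data.frame from [map_peaks_to_promoters()]
#'   (columns `gene_id`, `peak_score`).
#' @param de_records DE table with `gene_id`, `log2fc`. Peaks on genes
#'   without a record are excluded.
#' @param upper Fold-change boundary (default 1).
#' @return list with `means` (named), `n`, and `tests` (data.frame
#'   `comparison`, `t`, `p_value`; classes with < 2 members are excluded).
#' @export
score_by_expression_class <- function(promoter_pairs, de_records, upper = 1) {
  idx <- match(promoter_pairs$gene_id, de_records$gene_id)
  keep <- !is.na(idx) & !is.na(promoter_pairs$peak_score)
  lfc <- de_records$log2fc[idx[keep]]
  score <- promoter_pairs$peak_score[keep]
  cls <- ifelse(lfc > upper, "up",
         ifelse(lfc < -upper, "down", "unchanged"))
  cls <- factor(cls, levels = c("up", "unchanged", "down"))
  means <- tapply(score, cls, mean)
  sizes <- tapply(score, cls, length)
  sizes[is.na(sizes)] <- 0
  testable <- names(sizes)[sizes >= 2]
  tests <- list()
  if (length(testable) >= 2) {
    cmb <- utils::combn(testable, 2)
    for (j in seq_len(ncol(cmb))) {
      x <- score[cls == cmb[1, j]]
      y <- score[cls == cmb[2, j]]
      tt <- stats::t.test(x, y)
      tests[[j]] <- data.frame(
        comparison = paste(cmb[1, j], "vs", cmb[2, j]),
        t = unname(tt$statistic), p_value = tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  list(means = means, n = as.integer(sizes),
       tests = if (length(tests)) do.call(rbind, tests) else
         data.frame(comparison = character(), t = numeric(),
                    p_value = numeric()))
}

#' Genes whose promoters loop to a super-enhancer
#'
#' A loop connects an SE to a gene when one anchor overlaps the SE span and
#' the other overlaps the gene's promoter window; anchor order does not
#' matter. When an expression table is supplied, the genes with
#' `log2fc > lfc_cutoff` and `< -lfc_cutoff` are tallied.
#'
#' @param loops data.frame from [read_bedpe()].
#' @param superenhancers Interval data.frame of SE spans.
#' @param genes Gene models.
#' @param de_records Optional DE table (`gene_id`, `log2fc`).
#' @param lfc_cutoff Fold-change magnitude for the tallies (default 2).
#' @param promoter_halfwidth Promoter half-width (default 3000).
#' @return list with `genes` (data.frame `gene_id`, `log2fc`),
#'   `n_genes`, `n_up`, `n_down` (`NA` without `de_records`).
#' @export
se_loop_genes <- function(loops, superenhancers, genes, de_records = NULL,
                          lfc_cutoff = 2, promoter_halfwidth = 3000) {
  prom <- promoter_windows(genes, promoter_halfwidth)
  anchor_gr <- function(chrom, start, end) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  }
  a1 <- anchor_gr(loops$chrom1, loops$start1, loops$end1)
  a2 <- anchor_gr(loops$chrom2, loops$start2, loops$end2)
  se_gr <- ivs_to_gr(superenhancers)
  prom_gr <- ivs_to_gr(prom)
  in_se_1 <- overlaps_any(a1, se_gr)
  in_se_2 <- overlaps_any(a2, se_gr)
  genes_hit <- character()
  collect <- function(anchor, loop_idx) {
    hits <- find_overlaps(anchor[loop_idx], prom_gr)
    prom$name[S4Vectors::subjectHits(hits)]
  }
  genes_hit <- c(collect(a2, which(in_se_1)), collect(a1, which(in_se_2)))
  genes_hit <- sort(unique(genes_hit))
  lfc <- if (!is.null(de_records)) {
    de_records$log2fc[match(genes_hit, de_records$gene_id)]
  } else rep(NA_real_, length(genes_hit))
  list(
    genes = data.frame(gene_id = genes_hit, log2fc = lfc,
                       stringsAsFactors = FALSE),
    n_genes = length(genes_hit),
    n_up = if (is.null(de_records)) NA_integer_ else
      sum(!is.na(lfc) & lfc > lfc_cutoff),
    n_down = if (is.null(de_records)) NA_integer_ else
      sum(!is.na(lfc) & lfc < -lfc_cutoff)
  )
}
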