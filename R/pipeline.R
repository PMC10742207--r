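#' Run the full analysis pipeline on a study directory
#'
#' Consumes the file layout written by [simulate_study()] (or any study with
#' the same file names) and runs every stage: peak annotation and category
#' fractions, replicate consensus, motif classification and repeat-tract
#' scanning of central 100 bp windows, super-enhancer stitching, scoring and
#' calling, SE/binding-site overlap, reciprocal cross-species SE synteny
#' with gene orientation, three-dataset DEG intersection, promoter-binding
#' fractions, binding-score by expression class and SE-looped genes. Result
#' tables are written as TSV under `out_dir`; the run is deterministic (no
#' randomness), so identical inputs give byte-identical outputs.
#'
#' @param study_dir Directory holding the input files.
#' @param out_dir Output directory for result tables (created if needed).
#' @param scanner A [scanner_config()] for the repeat scan.
#' @param promoter_halfwidth Promoter half-width in bp.
#' @param stitch_distance Super-enhancer stitch distance in bp.
#' @return Invisibly, a list with every computed result.
#' @export
run_study_pipeline <- function(study_dir, out_dir,
                               scanner = scanner_config(),
                               promoter_halfwidth = 3000,
                               stitch_distance = 12500) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- function(f) file.path(study_dir, f)
  outp <- function(f) file.path(out_dir, f)
  wt <- function(x, f) utils::write.table(x, outp(f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)

  genes <- read_gene_models(inp("genes_a.gtf"), "gtf")
  peaks <- read_bed(inp("peaks.bed"))

  ann <- annotate_peaks(peaks, genes, promoter_halfwidth)
  wt(ann, "annotation.tsv")
  cat_tab <- table(factor(ann$category,
                          c("promoter", "intragenic", "intergenic")))
  fractions <- data.frame(category = names(cat_tab),
                          count = as.integer(cat_tab),
                          fraction = as.numeric(cat_tab) / nrow(ann))
  wt(fractions, "category_fractions.tsv")

  cons <- consensus_sites(list(peaks, read_bed(inp("peaks_rep2.bed")),
                               read_bed(inp("peaks_rep3.bed"))))
  write_bed(cons, outp("consensus.bed"))

  genome <- Biostrings::readDNAStringSet(inp("genome_a.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  windows <- extract_central_window(peaks, genome, 100)
  cls <- classify_by_motif(windows)
  motif_tab <- data.frame(peak = peaks$name, class = cls$flags$class)
  wt(motif_tab, "motif_classes.tsv")
  tract_rows <- lapply(seq_along(windows), function(i) {
    tr <- detect_repeat_tracts(windows[i], scanner)
    if (!nrow(tr)) return(NULL)
    data.frame(peak = peaks$name[i], start = tr$start, end = tr$end,
               occurrences = tr$occurrences, stringsAsFactors = FALSE)
  })
  tract_rows <- tract_rows[!vapply(tract_rows, is.null, logical(1))]
  tracts <- if (length(tract_rows)) do.call(rbind, tract_rows) else
    data.frame(peak = character(), start = integer(), end = integer(),
               occurrences = integer())
  wt(tracts, "repeat_tracts.tsv")
  rep_frac <- length(unique(tracts$peak)) / nrow(peaks)

  se_peaks <- read_bed(inp("se_peaks.bed"))
  chip <- read_bedgraph(inp("chip.bedgraph"))
  input <- read_bedgraph(inp("input.bedgraph"))
  regions <- score_regions(stitch_peaks(se_peaks, stitch_distance),
                           chip, input)
  ses <- call_superenhancers(regions)
  se_out <- ses[, c("chrom", "start", "end", "n_constituents",
                    "chip_signal", "input_signal", "net_signal", "rank",
                    "is_super")]
  wt(se_out, "superenhancers.tsv")
  se_spans <- ses[ses$is_super, , drop = FALSE]
  seov <- se_binding_overlap(se_spans, read_bed(inp("se_binding_sites.bed")))

  ses_a <- read_bed(inp("ses_a.bed"))
  ses_b <- read_bed(inp("ses_b.bed"))
  chains_ab <- read_chain(inp("a_to_b.chain"))
  chains_ba <- read_chain(inp("b_to_a.chain"))
  syn <- match_syntenic_ses(ses_a, ses_b, chains_ab, chains_ba)
  matches_out <- syn$matches
  matches_out$se_a <- ses_a$name[matches_out$a_index]
  matches_out$se_b <- ses_b$name[matches_out$b_index]
  wt(matches_out, "synteny_matches.tsv")
  genes_b <- read_gene_models(inp("genes_b.tsv"), "tsv")
  homologs_genes <- utils::read.delim(inp("homologs_genes.tsv"),
                                      stringsAsFactors = FALSE)
  orient <- orientation_distance_table(syn, ses_a, ses_b, genes, genes_b,
                                       homologs_genes)
  wt(orient, "orientation.tsv")

  de_tabs <- list(read_de_table(inp("de_mccs.tsv"), "mCCS"),
                  read_de_table(inp("de_hccs.tsv"), "hCCS"),
                  read_de_table(inp("de_kd.tsv"), "knockdown"))
  homologs_deg <- utils::read.delim(inp("homologs_deg.tsv"),
                                    stringsAsFactors = FALSE)
  degs <- intersect_degs(de_tabs, homologs_deg)
  deg_out <- data.frame(
    direction = c("up", "down"),
    three_way = c(degs$up$counts["three_way"], degs$down$counts["three_way"]),
    at_least_two = c(degs$up$counts["at_least_two"],
                     degs$down$counts["at_least_two"]),
    exactly_two = c(degs$up$counts["exactly_two"],
                    degs$down$counts["exactly_two"]))
  wt(deg_out, "deg_intersection.tsv")

  pbf <- promoter_binding_fraction(
    list(shared_up = degs$up$three_way, shared_down = degs$down$three_way),
    peaks, genes, promoter_halfwidth)
  wt(pbf, "promoter_binding.tsv")

  prom_pairs <- map_peaks_to_promoters(peaks, genes, promoter_halfwidth)
  sbc <- score_by_expression_class(prom_pairs$pairs, de_tabs[[2]])
  wt(data.frame(class = names(sbc$means), mean_score = as.numeric(sbc$means),
                n = sbc$n), "expression_class_scores.tsv")

  loops <- read_bedpe(inp("loops.bedpe"))
  slg <- se_loop_genes(loops, se_spans, genes, de_tabs[[3]])
  wt(slg$genes, "se_loop_genes.tsv")

  invisible(list(
    annotation = ann, category_fractions = fractions, consensus = cons,
    motif = cls, tracts = tracts, repeat_fraction = rep_frac,
    superenhancers = ses, se_binding = seov, synteny = syn,
    orientation = orient, degs = degs, promoter_binding = pbf,
    score_by_class = sbc, se_loop = slg,
    n_promoter_pairs = nrow(prom_pairs$pairs),
    n_promoter_genes = prom_pairs$n_unique_genes))
}
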