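# End-to-end orchestration: simulate -> clean -> annotate -> quantify ->
# novel -> differential expression -> targets -> enrichment, with a
# consolidated report bundle of plain TSV/JSON intermediates.

#' Run the full synthetic two-library pipeline
#'
#' Generates a synthetic experiment from `config`, writes the raw inputs
#' (genome FASTA, GFF3 annotation, two FASTQ libraries, ground truth),
#' then runs every analysis stage from the on-disk files so each stage is
#' independently reproducible: read cleaning and tag collapsing, genome
#' mapping, priority-rule annotation, known-miRNA quantification,
#' novel-miRNA prediction, differential expression, and (optionally)
#' consensus target prediction with term enrichment on synthetic UTRs.
#' All stage outputs are plain text under `outdir`; the returned report
#' aggregates the headline numbers, each re-derivable from the stage
#' files.
#'
#' @param config a [sim_config()].
#' @param outdir output directory.
#' @param run_targets also run target prediction/enrichment for the
#'   differentially expressed known miRNAs (default TRUE).
#' @return invisibly, a list of class `srna_report`: `files` (paths),
#'   `clean_log` (per-library rejection counts), `summary`
#'   (library summary), `qc` (rRNA check), `category_counts`,
#'   `known`, `novel`, `de`, `targets`, `enrichment`, `truth`.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         run_targets = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- build_genome(config)
  reads <- simulate_libraries(sim)
  files <- write_simulation(sim, reads, outdir)

  # stage: clean
  clean <- lapply(1:2, function(i) {
    fq <- read_fastq(file.path(outdir, sprintf("lib%d.fastq", i)))
    clean_reads(fq$seq, fq$qual, adapter = config$adapter)
  })
  totals <- vapply(clean, function(x) length(x$inserts), integer(1))
  tags <- collapse_tags(clean[[1]]$inserts, clean[[2]]$inserts)
  files["tags"] <- file.path(outdir, "tags.fasta")
  write_tag_fasta(tags, files[["tags"]])
  summ <- summarize_library(tags)

  # stage: map + annotate
  features <- import_gff3(file.path(outdir, "features.gff3"))
  genome <- as.character(Biostrings::readDNAStringSet(
    file.path(outdir, "genome.fa")))
  hits <- map_tags(tags, genome)
  annotated <- assign_category(tags, hits, features)
  cats <- category_counts(annotated)
  strands <- chrom_strand_table(hits, tags)
  qc <- qc_rrna_fraction(annotated)
  files["annotation"] <- file.path(outdir, "annotation.tsv")
  write.table(annotated, files[["annotation"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  files["categories"] <- file.path(outdir, "category_counts.tsv")
  write.table(cats, files[["categories"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  files["strands"] <- file.path(outdir, "chrom_strand.tsv")
  write.table(strands, files[["strands"]], sep = "\t", quote = FALSE,
              row.names = FALSE)

  # stage: quantify known
  known <- quantify_known(tags, hits, features, totals)
  files["known"] <- file.path(outdir, "known_mirna_counts.tsv")
  write.table(known, files[["known"]], sep = "\t", quote = FALSE,
              row.names = FALSE)

  # stage: novel
  novel <- call_novel(annotated, hits, genome, totals)
  files["novel"] <- file.path(outdir, "novel_candidates.tsv")
  write.table(novel, files[["novel"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  files["novel_bed"] <- file.path(outdir, "novel_mirnas.bed")
  write_novel_bed(novel, files[["novel_bed"]])

  # stage: differential expression
  novel_counts <- NULL
  called <- novel[novel$verdict, , drop = FALSE]
  if (nrow(called) > 0)
    novel_counts <- data.frame(mirna_id = called$novel_id,
                               count_A = called$count_A,
                               count_B = called$count_B)
  de <- de_table(data.frame(mirna_id = known$mirna_id,
                            count_A = known$count_A,
                            count_B = known$count_B),
                 novel_counts, totals)
  files["de"] <- file.path(outdir, "de_results.tsv")
  write.table(as.data.frame(de), files[["de"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  rendered <- render_tables(de)
  for (nm in names(rendered)) {
    files[paste0("table_", nm)] <-
      file.path(outdir, sprintf("table_%s.tsv", nm))
    write.table(rendered[[nm]], files[[paste0("table_", nm)]], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # stage: targets + enrichment on synthetic UTRs
  targets <- NULL; enrichment <- NULL
  if (run_targets) {
    de_known <- de[de$set == "known" & de$call != "NS", , drop = FALSE]
    arm_of <- function(id) {
      base <- sub("-(5p|3p)$", "", id)
      arm <- sub("^.*-", "", id)
      r <- sim$truth[sim$truth$mirna_id == base, ]
      if (arm == "5p") r$seq_5p else r$seq_3p
    }
    if (nrow(de_known) > 0) {
      mirnas <- setNames(vapply(de_known$mirna_id, arm_of, character(1)),
                         de_known$mirna_id)
      planted <- data.frame(
        mirna_id = rep(names(mirnas), each = 3),
        gene_id = sprintf("gene-%04d", seq_len(3 * length(mirnas))))
      utrs <- simulate_utrs(mirnas, n_genes = max(60, nrow(planted) + 20),
                            planted = planted, seed = config$seed + 2)
      preds <- predict_targets_multimethod(mirnas, utrs)
      targets <- consensus_filter(preds)
      term_map <- simulate_term_map(names(utrs), seed = config$seed + 3)
      enrichment <- enrich(unique(targets$gene_id), term_map,
                           universe = names(utrs), alpha = 1)
      files["targets"] <- file.path(outdir, "targets.tsv")
      write.table(targets, files[["targets"]], sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files["enrichment"] <- file.path(outdir, "enrichment.tsv")
      write.table(enrichment, files[["enrichment"]], sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  report <- list(files = files,
                 clean_log = lapply(clean, `[[`, "log"),
                 totals = totals, summary = summ, qc = qc,
                 category_counts = cats, strand_table = strands,
                 known = known, novel = novel, de = de,
                 targets = targets, enrichment = enrichment,
                 truth = sim$truth, truth_arms = sim$truth_arms,
                 config = config)
  class(report) <- "srna_report"
  files["summary_json"] <- file.path(outdir, "summary.json")
  jsonlite::write_json(list(
    clean = report$clean_log, totals = totals,
    sharing = as.list(summ$sharing),
    qc = qc, de_summary = attr(de, "summary")),
    files[["summary_json"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$files <- files
  invisible(report)
}

#' @export
print.srna_report <- function(x, ...) {
  cat("Small RNA pipeline report\n")
  cat(sprintf("  clean reads: %d / %d\n", x$totals[1], x$totals[2]))
  cat(sprintf("  known mature miRNAs detected: %d (A), %d (B)\n",
              sum(x$known$count_A > 0), sum(x$known$count_B > 0)))
  cat(sprintf("  novel miRNA candidates called: %d\n",
              sum(x$novel$verdict)))
  s <- attr(x$de, "summary")
  for (set in names(s))
    cat(sprintf("  %s miRNAs: %d up, %d down\n", set,
                s[[set]]["n_up"], s[[set]]["n_down"]))
  invisible(x)
}

#' Render differential-expression results in the publication table style
#'
#' Formats log2 fold changes to two decimals and adjusted p-values in
#' scientific notation with two decimals (e.g. `9.04  Up  1.56E-23`),
#' one table per miRNA set.
#'
#' @param de an `srna_de` object from [de_table()].
#' @return named list of data.frames (`known`, `novel` as present) with
#'   columns `mirna_id`, `log2_fc`, `direction`, `p_adj`.
#' @export
render_tables <- function(de) {
  sig <- as.data.frame(de)[de$call != "NS", , drop = FALSE]
  out <- lapply(split(sig, sig$set), function(d) {
    data.frame(mirna_id = d$mirna_id,
               log2_fc = sprintf("%.2f", d$log2_fc),
               direction = d$call,
               p_adj = sprintf("%.2E", d$p_adj),
               stringsAsFactors = FALSE)
  })
  out[lengths(out) > 0]
}
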