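# Reported summary tables from the original HepG2 vs HepG2/DOX profiling
# study, shipped as plain TSVs. They serve as fixed inputs for the
# table-arithmetic checks (fold-rule counts, significance-filter counts,
# exon strand ratios) that the pipeline's filter and summary logic must
# reproduce.

ref_path <- function(file) {
  system.file("extdata", file, package = "srnapipe", mustWork = TRUE)
}

#' Reported differential-expression tables of the HepG2/DOX contrast
#'
#' `reference_known_de()` returns the printed per-miRNA rows for the most
#' significantly differentially expressed known miRNAs (log2 fold change,
#' direction, BH-adjusted P); `reference_novel_de()` the same for the
#' significantly differentially expressed novel miRNAs;
#' `reference_summary_counts()` the printed headline counts (significant
#' up/down known miRNA totals and the exon sense/antisense tag counts per
#' cell line).
#'
#' @return data.frames; see each table's columns.
#' @export
reference_known_de <- function() {
  read.delim(ref_path("hepg2_dox_known_de.tsv"), stringsAsFactors = FALSE)
}

#' @rdname reference_known_de
#' @export
reference_novel_de <- function() {
  read.delim(ref_path("hepg2_dox_novel_de.tsv"), stringsAsFactors = FALSE)
}

#' @rdname reference_known_de
#' @export
reference_summary_counts <- function() {
  read.delim(ref_path("hepg2_dox_summary_counts.tsv"),
             stringsAsFactors = FALSE)
}

#' Count miRNAs beyond a fold-change magnitude
#'
#' Applies the ">16-fold" style rule (|log2FC| > `threshold_log2`) to a
#' differential-expression table with `log2_fc` and `direction` columns.
#'
#' @param de data.frame with `log2_fc` and `direction`.
#' @param threshold_log2 magnitude threshold on log2FC, strict
#'   (default 4, i.e. 16-fold).
#' @return named vector: `n_up`, `n_down`.
#' @export
fold_rule_counts <- function(de, threshold_log2 = 4) {
  c(n_up = sum(de$direction == "Up" & de$log2_fc > threshold_log2),
    n_down = sum(de$direction == "Down" & de$log2_fc < -threshold_log2))
}

#' Count rows passing the significance filter
#'
#' Applies the standard call (adjusted P < `alpha` and at least
#' `min_fold`-fold change) to a table with `log2_fc` and `p_adj` columns
#' via [call_de()].
#'
#' @param de data.frame with `log2_fc` and `p_adj`.
#' @param alpha,min_fold see [call_de()].
#' @return named vector: `n_up`, `n_down`.
#' @export
significance_filter_counts <- function(de, alpha = 0.05, min_fold = 2) {
  call <- call_de(de$log2_fc, de$p_adj, alpha, min_fold)
  c(n_up = sum(call == "Up"), n_down = sum(call == "Down"))
}

#' Rounded sense:antisense ratio
#'
#' @param sense,antisense tag counts.
#' @param digits rounding digits (default 0).
#' @return `round(sense / antisense, digits)`.
#' @export
sense_antisense_ratio <- function(sense, antisense, digits = 0) {
  round(sense / antisense, digits)
}
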