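# File format helpers: FASTA/GFF3 via Biostrings/rtracklayer, FASTQ with a
# byte-deterministic writer (Sanger +33 qualities).

#' Read a FASTQ file
#'
#' @param path FASTQ file (optionally gzipped).
#' @return data.frame with columns `seq` and `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param seqs,quals character vectors of equal length.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, quals, path) {
  stopifnot(length(seqs) == length(quals))
  if (length(seqs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  ids <- sprintf("@read_%d", seq_along(seqs))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(ids, seqs, "+", quals)), con)
  invisible(path)
}

#' Export / import feature annotations as GFF3
#'
#' Thin wrappers over [rtracklayer::export] / [rtracklayer::import] that
#' keep the `type`, `source`, `ID` and `Parent` columns in the plain
#' character form the rest of the package uses. Coordinates are 1-based
#' inclusive on disk and in the returned [GenomicRanges::GRanges].
#'
#' @param features GRanges with mcols `type`, `source`, `ID`, `Parent`.
#' @param path GFF3 file path.
#' @return `import_gff3` returns a GRanges; `export_gff3` returns `path`
#'   invisibly.
#' @export
export_gff3 <- function(features, path) {
  gr <- features
  mc <- S4Vectors::mcols(gr)
  parent <- as.character(mc$Parent)
  mc$Parent <- IRanges::CharacterList(
    lapply(parent, function(p) if (is.na(p)) character(0) else p))
  S4Vectors::mcols(gr) <- mc
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname export_gff3
#' @export
import_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  parent <- vapply(as.list(mc$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::ranges(gr),
                                strand = GenomicRanges::strand(gr))
  S4Vectors::mcols(out)$type <- as.character(mc$type)
  S4Vectors::mcols(out)$source <- as.character(mc$source)
  S4Vectors::mcols(out)$ID <- as.character(mc$ID)
  S4Vectors::mcols(out)$Parent <- parent
  out
}

#' Write collapsed tags as FASTA
#'
#' Headers carry the per-library counts: `>tagN_countA_countB`.
#'
#' @param tags a tag table from [collapse_tags()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tag_fasta <- function(tags, path) {
  ids <- sprintf("tag%d_%d_%d", seq_len(nrow(tags)), tags$count_A,
                 tags$count_B)
  x <- Biostrings::DNAStringSet(setNames(tags$sequence, ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a collapsed-tag FASTA back into a tag table
#'
#' @param path FASTA written by [write_tag_fasta()].
#' @return tag table (`sequence`, `count_A`, `count_B`).
#' @export
read_tag_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "_", fixed = TRUE)
  data.frame(sequence = as.character(x),
             count_A = as.integer(vapply(parts, `[`, "", 2)),
             count_B = as.integer(vapply(parts, `[`, "", 3)),
             row.names = NULL, stringsAsFactors = FALSE)
}
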