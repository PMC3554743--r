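# Read cleaning: quality filter, 3' adapter trimming, length filter,
# collapsing to unique tags and per-library summary statistics.

#' Trim the 3' adapter from raw reads
#'
#' Locates, for each read, the leftmost position where a prefix of the
#' adapter matches with at most `floor(max_mismatch_rate * overlap)`
#' mismatches and at least `min_overlap` bases of overlap; the bases 5' of
#' that position are the insert. Reads where the adapter starts at the
#' first base are adapter-dimer contaminants (empty insert); reads with no
#' acceptable match are rejected as `no_adapter`. When several positions
#' score equally the leftmost (longest-overlap) one wins.
#'
#' @param reads character vector of read sequences.
#' @param adapter 3' adapter sequence in DNA form (default: the study's
#'   adapter; the terminal inverted-dT chemical modification of the oligo
#'   is not sequence and is omitted).
#' @param min_overlap minimum adapter overlap (default 6).
#' @param max_mismatch_rate maximum fraction of mismatching bases in the
#'   overlap (default 0.1).
#' @return list with `insert` (character; `NA` where no adapter found) and
#'   `status` (factor: `trimmed`, `dimer`, `no_adapter`).
#' @export
#' @examples
#' trim_adapter(c("ACGTACGTACGTACGTACTCGTATGCCGTCTTCTGCTTGTAAAAACGGGT"))
trim_adapter <- function(reads, adapter = "TCGTATGCCGTCTTCTGCTTGT",
                         min_overlap = 6, max_mismatch_rate = 0.1) {
  if (nchar(adapter) < min_overlap)
    stop("adapter shorter than min_overlap")
  if (length(reads) == 0)
    return(list(insert = character(0),
                status = factor(character(0),
                                levels = c("trimmed", "dimer", "no_adapter"))))
  pos <- adapter_match_pos(reads, adapter, as.integer(min_overlap),
                           max_mismatch_rate)
  status <- ifelse(pos < 0, "no_adapter", ifelse(pos == 0, "dimer",
                                                 "trimmed"))
  insert <- ifelse(pos > 0, substr(reads, 1, pmax(pos, 0)), NA_character_)
  insert[status == "dimer"] <- ""
  list(insert = insert,
       status = factor(status, levels = c("trimmed", "dimer", "no_adapter")))
}

#' Drop reads with low-quality base calls
#'
#' Rejects reads containing any base below `min_q` (Phred, Sanger +33)
#' within the first `n_cycles` sequencing cycles.
#'
#' @param quals character vector of quality strings.
#' @param min_q Phred threshold (default 20).
#' @param n_cycles cycles inspected (default 36).
#' @return logical vector: TRUE for reads that pass.
#' @export
quality_filter <- function(quals, min_q = 20, n_cycles = 36) {
  if (length(quals) == 0) return(logical(0))
  vapply(substr(quals, 1, n_cycles), function(q) {
    min(as.integer(charToRaw(q))) - 33L >= min_q
  }, logical(1), USE.NAMES = FALSE)
}

#' Retain inserts of 18--30 nt
#'
#' @param inserts character vector of trimmed inserts.
#' @param min_len,max_len inclusive length bounds (defaults 18 and 30).
#' @return list with `kept` (the retained inserts), `n_short`, `n_long`.
#' @export
length_filter <- function(inserts, min_len = 18, max_len = 30) {
  n <- nchar(inserts)
  list(kept = inserts[n >= min_len & n <= max_len],
       n_short = sum(n < min_len), n_long = sum(n > max_len))
}

#' Clean one library of raw reads
#'
#' Applies, in order: the quality filter, adapter trimming (rejecting
#' adapter-dimer and adapter-less reads), removal of N-containing inserts,
#' and the 18--30 nt length filter. Every rejection class is counted so
#' that `reads_in = rejected + retained` holds exactly.
#'
#' @param seqs,quals read sequences and qualities (quals may be NULL to
#'   skip the quality filter).
#' @param adapter,min_overlap,max_mismatch_rate see [trim_adapter()].
#' @param min_len,max_len see [length_filter()].
#' @param min_q,n_cycles see [quality_filter()].
#' @return list with `inserts` (clean inserts, one element per retained
#'   read) and `log` (named counts per stage).
#' @export
clean_reads <- function(seqs, quals = NULL,
                        adapter = "TCGTATGCCGTCTTCTGCTTGT",
                        min_overlap = 6, max_mismatch_rate = 0.1,
                        min_len = 18, max_len = 30,
                        min_q = 20, n_cycles = 36) {
  n_in <- length(seqs)
  if (!is.null(quals)) {
    ok <- quality_filter(quals, min_q, n_cycles)
    n_low_q <- sum(!ok)
    seqs <- seqs[ok]
  } else n_low_q <- 0L
  tr <- trim_adapter(seqs, adapter, min_overlap, max_mismatch_rate)
  n_dimer <- sum(tr$status == "dimer")
  n_no_adapter <- sum(tr$status == "no_adapter")
  ins <- tr$insert[tr$status == "trimmed"]
  has_n <- grepl("N", ins, fixed = TRUE)
  n_with_n <- sum(has_n)
  ins <- ins[!has_n]
  lf <- length_filter(ins, min_len, max_len)
  log <- c(reads_in = n_in, low_quality = n_low_q, adapter_dimer = n_dimer,
           no_adapter = n_no_adapter, with_n = n_with_n,
           too_short = lf$n_short, too_long = lf$n_long,
           retained = length(lf$kept))
  list(inserts = lf$kept, log = log)
}

#' Collapse cleaned inserts into unique tags
#'
#' One row per distinct sequence with per-library read counts; the column
#' sums equal the clean read totals of each library. Ordered by total
#' count (descending), ties alphabetically.
#'
#' @param inserts_A,inserts_B character vectors of clean inserts.
#' @return data.frame with `sequence`, `count_A`, `count_B`.
#' @export
#' @examples
#' collapse_tags(c("AAA", "AAA", "CCC"), c("CCC"))
collapse_tags <- function(inserts_A, inserts_B) {
  seqs <- sort(unique(c(inserts_A, inserts_B)))
  ca <- table(factor(inserts_A, levels = seqs))
  cb <- table(factor(inserts_B, levels = seqs))
  out <- data.frame(sequence = seqs, count_A = as.integer(ca),
                    count_B = as.integer(cb), stringsAsFactors = FALSE)
  out <- out[order(-(out$count_A + out$count_B), out$sequence), ]
  rownames(out) <- NULL
  out
}

#' Expand a tag table back into the read multiset
#'
#' Inverse of [collapse_tags()] (up to ordering); used to verify the
#' collapse conserves reads.
#'
#' @param tags a tag table.
#' @return list with `inserts_A`, `inserts_B`.
#' @export
expand_tags <- function(tags) {
  list(inserts_A = rep(tags$sequence, tags$count_A),
       inserts_B = rep(tags$sequence, tags$count_B))
}

#' Per-library summary statistics of a tag table
#'
#' Computes, for each library: the clean-read total, the read-weighted
#' insert length histogram (18--30 nt), the first-base composition by
#' length and the positionwise base composition; plus the common/specific
#' tag fractions between the libraries, both in unique-tag space and
#' read-weighted (total-tag) space. The three sharing fractions sum to 1
#' in either space.
#'
#' @param tags a tag table from [collapse_tags()].
#' @param min_len,max_len length range of the histograms.
#' @return list of class `srna_library_summary` with elements `library_A`,
#'   `library_B` (each: `total_reads`, `length_histogram`,
#'   `first_base_by_length`, `position_base_composition`) and `sharing`
#'   (`unique_common`, `unique_specific_A`, `unique_specific_B`,
#'   `total_common`, `total_specific_A`, `total_specific_B`).
#' @export
summarize_library <- function(tags, min_len = 18, max_len = 30) {
  lens <- min_len:max_len
  bases <- c("A", "C", "G", "T")
  empty <- function() list(
    total_reads = 0L,
    length_histogram = setNames(integer(length(lens)), lens),
    first_base_by_length = matrix(0L, 4, length(lens),
                                  dimnames = list(bases, lens)),
    position_base_composition = matrix(0L, 4, max_len,
                                       dimnames = list(bases, 1:max_len)))
  if (nrow(tags) == 0) {
    warning("empty tag table: all-zero summary")
    out <- list(library_A = empty(), library_B = empty(),
                sharing = setNames(rep(0, 6),
                                   c("unique_common", "unique_specific_A",
                                     "unique_specific_B", "total_common",
                                     "total_specific_A",
                                     "total_specific_B")))
    class(out) <- "srna_library_summary"
    return(out)
  }
  nch <- nchar(tags$sequence)
  first <- substr(tags$sequence, 1, 1)
  one_lib <- function(counts) {
    s <- empty()
    s$total_reads <- sum(counts)
    hist <- tapply(counts, factor(nch, levels = lens), sum)
    hist[is.na(hist)] <- 0
    s$length_histogram <- setNames(as.integer(hist), lens)
    for (b in bases) {
      sel <- first == b
      h <- tapply(counts[sel], factor(nch[sel], levels = lens), sum)
      h[is.na(h)] <- 0
      s$first_base_by_length[b, ] <- as.integer(h)
    }
    for (p in 1:max_len) {
      covers <- nch >= p
      bp <- substr(tags$sequence[covers], p, p)
      cnt <- tapply(counts[covers], factor(bp, levels = bases), sum)
      cnt[is.na(cnt)] <- 0
      s$position_base_composition[, p] <- as.integer(cnt)
    }
    s
  }
  in_a <- tags$count_A > 0; in_b <- tags$count_B > 0
  total <- sum(tags$count_A) + sum(tags$count_B)
  common <- in_a & in_b
  sharing <- c(
    unique_common = mean(common),
    unique_specific_A = mean(in_a & !in_b),
    unique_specific_B = mean(!in_a & in_b),
    total_common = sum((tags$count_A + tags$count_B)[common]) / total,
    total_specific_A = sum(tags$count_A[in_a & !in_b]) / total,
    total_specific_B = sum(tags$count_B[!in_a & in_b]) / total)
  out <- list(library_A = one_lib(tags$count_A),
              library_B = one_lib(tags$count_B), sharing = sharing)
  class(out) <- "srna_library_summary"
  out
}

#' @export
print.srna_library_summary <- function(x, ...) {
  cat("Small RNA library summary\n")
  cat(sprintf("  clean reads: A = %d, B = %d\n",
              x$library_A$total_reads, x$library_B$total_reads))
  pk <- function(l) {
    h <- l$length_histogram
    if (sum(h) == 0) return("-")
    sprintf("%s nt (%.1f%%)", names(which.max(h)),
            100 * max(h) / sum(h))
  }
  cat(sprintf("  modal insert length: A = %s, B = %s\n",
              pk(x$library_A), pk(x$library_B)))
  cat(sprintf("  unique tags common/specific A/specific B: %.3f / %.3f / %.3f\n",
              x$sharing["unique_common"], x$sharing["unique_specific_A"],
              x$sharing["unique_specific_B"]))
  invisible(x)
}
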