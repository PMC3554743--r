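# Novel miRNA prediction from unannotated mapped tags: strand-aware read
# clustering, precursor window extraction, MFE folding, Dicer-cleavage
# read-stack consistency and the candidate gates (hairpin shape,
# MFE < -20 kcal/mol, detectable expression in both libraries).

#' Cluster unannotated tag hits along the genome
#'
#' Merges genomic hits of unannotated tags on the same strand whose gap is
#' at most `merge_distance` nt into candidate loci.
#'
#' @param annotated result of [assign_category()].
#' @param hits result of [map_tags()].
#' @param merge_distance maximum gap for merging (default 10).
#' @return list of clusters; each is a list with `chrom`, `start`, `end`,
#'   `strand` and `hits` (the member hit rows joined with tag counts).
#' @export
cluster_unannotated <- function(annotated, hits, merge_distance = 10) {
  pool <- annotated$sequence[annotated$category == "unannotated"]
  h <- hits[hits$sequence %in% pool, , drop = FALSE]
  if (nrow(h) == 0) return(list())
  idx <- match(h$sequence, annotated$sequence)
  h$count_A <- annotated$count_A[idx]
  h$count_B <- annotated$count_B[idx]
  gr <- hits_to_granges(h)
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_distance + 1,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  lapply(seq_along(red), function(i) {
    list(chrom = as.character(GenomicRanges::seqnames(red))[i],
         start = GenomicRanges::start(red)[i],
         end = GenomicRanges::end(red)[i],
         strand = as.character(GenomicRanges::strand(red))[i],
         hits = h[revmap[[i]], , drop = FALSE])
  })
}

#' Extract candidate precursor windows around a cluster
#'
#' Emits two windows per cluster -- one placing the read stack on the 5'
#' arm of a putative hairpin (stack plus downstream flank) and one placing
#' it on the 3' arm (upstream flank plus stack) -- oriented 5' to 3' on
#' the cluster strand and clipped at chromosome bounds.
#'
#' @param cluster one element of [cluster_unannotated()]'s result.
#' @param genome named character vector of chromosome sequences.
#' @param flank_up,flank_down flank lengths in nt (default 70).
#' @return data.frame with `role` (`stack5p`/`stack3p`), `win_start`,
#'   `win_end` (genomic, 1-based) and `sequence` (strand-oriented DNA).
#' @export
extract_precursor <- function(cluster, genome, flank_up = 70,
                              flank_down = 70) {
  chrlen <- nchar(genome[[cluster$chrom]])
  plus <- cluster$strand == "+"
  w <- if (plus) {
    data.frame(role = c("stack5p", "stack3p"),
               win_start = c(cluster$start, cluster$start - flank_up),
               win_end = c(cluster$end + flank_down, cluster$end))
  } else {
    data.frame(role = c("stack5p", "stack3p"),
               win_start = c(cluster$start - flank_down, cluster$start),
               win_end = c(cluster$end, cluster$end + flank_up))
  }
  w$win_start <- pmax(w$win_start, 1L)
  w$win_end <- pmin(w$win_end, chrlen)
  seqs <- substr(rep(genome[[cluster$chrom]], 2), w$win_start, w$win_end)
  w$sequence <- if (plus) seqs else revcomp(seqs)
  w
}

#' Dicer-cleavage consistency of a read stack
#'
#' Fraction of a cluster's reads sharing the modal 5' end (start on the
#' plus strand, end on the minus strand); homogeneous 5' ends are the
#' signature of genuine Dicer processing.
#'
#' @param cluster_hits the `hits` data.frame of one cluster.
#' @param threshold pass threshold on the fraction (default 0.7).
#' @return list with `fraction`, `pass` and `modal_five_prime`.
#' @export
dicer_consistency <- function(cluster_hits, threshold = 0.7) {
  w <- cluster_hits$count_A + cluster_hits$count_B
  fp <- ifelse(cluster_hits$strand == "+", cluster_hits$start,
               cluster_hits$end)
  tot <- tapply(w, fp, sum)
  modal <- names(tot)[which.max(tot)]
  frac <- max(tot) / sum(w)
  list(fraction = as.numeric(frac), pass = frac >= threshold,
       modal_five_prime = as.integer(modal))
}

# hairpin-shape gate: the mature arm must sit in a stem of >= min_paired
# pairs closing a 3-20 nt loop, with <= max_unpaired unpaired arm bases
# (the 2-nt 3' overhang excluded)
hairpin_shape_check <- function(structure, mature_start, mature_end,
                                min_paired = 16, loop_range = c(3, 20),
                                max_unpaired = 4) {
  pt <- pair_table(structure)
  span <- mature_start:mature_end
  partners <- pt[span]
  outside <- partners != 0 & (partners < mature_start |
                                partners > mature_end)
  n_stem <- sum(outside)
  core <- span[seq_len(max(length(span) - 2, 0))]  # exclude 2-nt 3' overhang
  n_unpaired <- sum(pt[core] == 0)
  loop_len <- NA_integer_
  if (n_stem > 0) {
    up <- span[outside & partners > mature_end]
    down <- span[outside & partners < mature_start]
    if (length(up) >= length(down)) {
      p <- max(up); loop_len <- pt[p] - p - 1L
    } else {
      p <- min(down); loop_len <- p - pt[p] - 1L
    }
  }
  pass <- n_stem >= min_paired && !is.na(loop_len) &&
    loop_len >= loop_range[1] && loop_len <= loop_range[2] &&
    n_unpaired <= max_unpaired
  list(pass = pass, n_stem_pairs = n_stem, n_unpaired = n_unpaired,
       loop_len = loop_len)
}

#' Predict novel miRNAs from the unannotated tag pool
#'
#' For every read cluster with at least `min_reads` supporting reads, the
#' stack's modal 5'-end tag defines the putative mature arm; both
#' precursor windows are folded with [fold_rna()] and the better-scoring
#' window that satisfies the hairpin-shape gate is kept. A candidate is
#' called a novel miRNA when all four criteria hold: hairpin shape,
#' MFE strictly below `min_mfe` (-20 kcal/mol), Dicer 5'-end homogeneity
#' at or above `dicer_threshold`, and detectable expression (at least
#' `min_tpm` TPM in both libraries, or in either when
#' `require_both_samples = FALSE`). Called candidates are named
#' `novel-miR-1 ... N` by descending total read count.
#'
#' @param annotated result of [assign_category()].
#' @param hits result of [map_tags()].
#' @param genome named character vector of chromosomes.
#' @param totals clean-read totals per library.
#' @param merge_distance see [cluster_unannotated()].
#' @param flank_up,flank_down see [extract_precursor()].
#' @param min_reads minimum supporting reads per cluster (default 5).
#' @param min_mfe MFE gate in kcal/mol, strict (default -20).
#' @param min_tpm expression gate in TPM, inclusive (default 1).
#' @param dicer_threshold 5'-end homogeneity gate (default 0.7).
#' @param require_both_samples require `min_tpm` in both libraries
#'   (default TRUE).
#' @param params folding energy table.
#' @return data.frame of class `srna_novel`, one row per candidate:
#'   locus, `novel_id` (NA unless called), `mfe`, `structure`,
#'   `precursor_seq`, window and mature coordinates, `dicer_fraction`,
#'   `tpm_A`, `tpm_B`, the four criteria flags and `verdict` (their AND).
#' @export
call_novel <- function(annotated, hits, genome, totals,
                       merge_distance = 10, flank_up = 70, flank_down = 70,
                       min_reads = 5, min_mfe = -20, min_tpm = 1,
                       dicer_threshold = 0.7, require_both_samples = TRUE,
                       params = energy_params()) {
  clusters <- cluster_unannotated(annotated, hits, merge_distance)
  rows <- list()
  for (cl in clusters) {
    ch <- cl$hits
    utags <- !duplicated(ch$sequence)
    n_reads <- sum(ch$count_A[utags] + ch$count_B[utags])
    if (n_reads < min_reads) next
    dc <- dicer_consistency(ch, dicer_threshold)
    # mature arm: heaviest tag among those sharing the modal 5' end
    fp <- ifelse(ch$strand == "+", ch$start, ch$end)
    cand <- ch[fp == dc$modal_five_prime, , drop = FALSE]
    mat <- cand[which.max(cand$count_A + cand$count_B), , drop = FALSE]
    wins <- extract_precursor(cl, genome, flank_up, flank_down)
    best <- NULL
    for (k in seq_len(nrow(wins))) {
      f <- fold_rna(wins$sequence[k], params)
      if (cl$strand == "+") {
        ms <- mat$start - wins$win_start[k] + 1L
        me <- mat$end - wins$win_start[k] + 1L
      } else {
        ms <- wins$win_end[k] - mat$end + 1L
        me <- wins$win_end[k] - mat$start + 1L
      }
      shape <- hairpin_shape_check(f$structure, ms, me)
      sc <- list(fold = f, shape = shape, win = wins[k, ],
                 mature = c(ms, me))
      better <- is.null(best) ||
        (shape$pass && !best$shape$pass) ||
        (shape$pass == best$shape$pass && f$mfe < best$fold$mfe)
      if (better) best <- sc
    }
    tpm_a <- tpm(sum(ch$count_A[utags]), totals[1])
    tpm_b <- tpm(sum(ch$count_B[utags]), totals[2])
    expr_pass <- if (require_both_samples)
      tpm_a >= min_tpm && tpm_b >= min_tpm
    else tpm_a >= min_tpm || tpm_b >= min_tpm
    mfe_pass <- best$fold$mfe < min_mfe
    rows[[length(rows) + 1]] <- data.frame(
      chrom = cl$chrom, start = cl$start, end = cl$end,
      strand = cl$strand, novel_id = NA_character_,
      mfe = best$fold$mfe, structure = best$fold$structure,
      precursor_seq = best$win$sequence,
      win_start = best$win$win_start, win_end = best$win$win_end,
      mature_start = best$mature[1], mature_end = best$mature[2],
      n_reads = n_reads, dicer_fraction = dc$fraction,
      count_A = sum(ch$count_A[utags]), count_B = sum(ch$count_B[utags]),
      tpm_A = tpm_a, tpm_B = tpm_b,
      hairpin_shape = best$shape$pass, mfe_pass = mfe_pass,
      dicer_pass = dc$pass, expression_pass = expr_pass,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      novel_id = character(0), mfe = numeric(0),
                      structure = character(0), precursor_seq = character(0),
                      win_start = integer(0), win_end = integer(0),
                      mature_start = integer(0), mature_end = integer(0),
                      n_reads = integer(0), dicer_fraction = numeric(0),
                      count_A = integer(0), count_B = integer(0),
                      tpm_A = numeric(0), tpm_B = numeric(0),
                      hairpin_shape = logical(0), mfe_pass = logical(0),
                      dicer_pass = logical(0), expression_pass = logical(0),
                      verdict = logical(0))
    class(out) <- c("srna_novel", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$verdict <- out$hairpin_shape & out$mfe_pass & out$dicer_pass &
    out$expression_pass
  called <- which(out$verdict)
  called <- called[order(-(out$count_A + out$count_B)[called])]
  out$novel_id[called] <- sprintf("novel-miR-%d", seq_along(called))
  rownames(out) <- NULL
  class(out) <- c("srna_novel", "data.frame")
  out
}

#' Write called novel miRNAs as BED
#'
#' BED is 0-based half-open; only candidates passing all gates are
#' written.
#'
#' @param novel result of [call_novel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_novel_bed <- function(novel, path) {
  called <- novel[novel$verdict, , drop = FALSE]
  bed <- data.frame(called$chrom, called$start - 1L, called$end,
                    called$novel_id, 0L, called$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
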