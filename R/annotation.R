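# Genome mapping of tags, priority-rule category assignment, known-miRNA
# quantification and QC.

CATEGORY_LEVELS <- c("rRNA_etc_genbank", "rRNA_etc_rfam", "known_miRNA",
                     "repeat", "exon_sense", "exon_antisense",
                     "intron_sense", "intron_antisense", "unannotated",
                     "unmapped")
NCRNA_TYPES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA")

#' Map tags to the genome by exact full-length matching
#'
#' Reports every exact occurrence of each tag on both strands of the
#' genome (a minus-strand hit means the genome's reverse complement equals
#' the tag there). Tags containing N are unmappable by construction.
#' Matching is seeded per tag width with [Biostrings::PDict] and is exact
#' (0 mismatches), the conventional setting for miRNA tag mapping.
#'
#' @param tags a tag table from [collapse_tags()] or a character vector of
#'   sequences.
#' @param genome named character vector or [Biostrings::DNAStringSet] of
#'   chromosomes.
#' @return data.frame with `sequence`, `chrom`, `start`, `end` (1-based,
#'   inclusive) and `strand`; zero rows for tags with no hits.
#' @export
map_tags <- function(tags, genome) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  seqs <- unique(seqs)
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)))
    names(genome) <- paste0("chr", seq_along(genome))
  ok <- !grepl("[^ACGT]", seqs)
  seqs <- seqs[ok]
  res <- list()
  if (length(seqs)) {
    fwd <- Biostrings::DNAStringSet(setNames(seqs, seqs))
    rev <- Biostrings::reverseComplement(fwd)
    names(rev) <- seqs
    tb <- min(nchar(seqs))
    pd_f <- Biostrings::PDict(fwd, tb.start = 1, tb.end = tb)
    pd_r <- Biostrings::PDict(rev, tb.start = 1, tb.end = tb)
    for (chr in names(genome)) {
      subj <- genome[[chr]]
      for (strand in c("+", "-")) {
        m <- Biostrings::matchPDict(
          if (strand == "+") pd_f else pd_r, subj)
        ir <- unlist(m)
        if (length(ir) == 0) next
        res[[length(res) + 1]] <- data.frame(
          sequence = names(ir), chrom = chr,
          start = IRanges::start(ir), end = IRanges::end(ir),
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0)
    return(data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

hits_to_granges <- function(hits) {
  GenomicRanges::GRanges(hits$chrom,
                         IRanges::IRanges(hits$start, hits$end),
                         strand = hits$strand,
                         sequence = hits$sequence)
}

#' Assign every tag exactly one category under the priority rule
#'
#' Each genomic hit of a tag is intersected with the feature annotation;
#' categories are ranked
#' `rRNA etc (GenBank) > rRNA etc (Rfam) > known miRNA > repeat >
#' exon (sense > antisense) > intron (sense > antisense)`, and the
#' highest-priority category over all hits wins, so a tag gets one
#' annotation even when it maps to several loci. miRNA overlap requires
#' the same strand; exon/intron overlap is split by strand; ncRNA and
#' repeat overlap ignores strand. Mapped tags overlapping nothing are
#' `unannotated` (the novel-miRNA candidate pool); tags without hits are
#' `unmapped`. Ties within a priority level go to the first hit in genome
#' order.
#'
#' @param tags a tag table.
#' @param hits result of [map_tags()] for those tags.
#' @param features feature GRanges (as from [build_genome()] or
#'   [import_gff3()]).
#' @return data.frame: `sequence`, `count_A`, `count_B`, `category`
#'   (factor over all category levels), `feature_id`, `feature_type`,
#'   `n_hits`.
#' @export
assign_category <- function(tags, hits, features) {
  ftype <- S4Vectors::mcols(features)$type
  fsource <- S4Vectors::mcols(features)$source
  fid <- S4Vectors::mcols(features)$ID
  fstrand <- as.character(GenomicRanges::strand(features))

  cat_rank <- setNames(seq_along(CATEGORY_LEVELS), CATEGORY_LEVELS)
  best_rank <- setNames(rep(cat_rank[["unmapped"]], nrow(tags)),
                        tags$sequence)
  best_feat <- setNames(rep(NA_character_, nrow(tags)), tags$sequence)
  best_type <- best_feat
  mapped <- tags$sequence %in% hits$sequence
  best_rank[mapped] <- cat_rank[["unannotated"]]

  if (nrow(hits) > 0 && length(features) > 0) {
    hit_gr <- hits_to_granges(hits)
    ov <- GenomicRanges::findOverlaps(hit_gr, features,
                                      ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    if (length(qh)) {
      hstrand <- hits$strand[qh]
      typ <- ftype[sh]; src <- fsource[sh]
      same <- hstrand == fstrand[sh]
      cat <- rep(NA_character_, length(qh))
      is_nc <- typ %in% NCRNA_TYPES
      cat[is_nc & src == "GenBank"] <- "rRNA_etc_genbank"
      cat[is_nc & src != "GenBank"] <- "rRNA_etc_rfam"
      is_mir <- typ %in% c("miRNA_precursor", "mature_miRNA")
      cat[is_mir & same] <- "known_miRNA"
      cat[typ == "repeat"] <- "repeat"
      cat[typ == "exon" & same] <- "exon_sense"
      cat[typ == "exon" & !same] <- "exon_antisense"
      cat[typ == "intron" & same] <- "intron_sense"
      cat[typ == "intron" & !same] <- "intron_antisense"
      keep <- !is.na(cat)
      if (any(keep)) {
        df <- data.frame(seq = hits$sequence[qh][keep],
                         rank = cat_rank[cat[keep]],
                         feat = fid[sh][keep], typ = typ[keep],
                         ord = qh[keep], stringsAsFactors = FALSE)
        # hits are in genome order already; first winning hit breaks ties
        df <- df[order(df$seq, df$rank, df$ord), ]
        df <- df[!duplicated(df$seq), ]
        sel <- match(df$seq, tags$sequence)
        upd <- df$rank < best_rank[sel]
        best_rank[sel[upd]] <- df$rank[upd]
        best_feat[sel[upd]] <- df$feat[upd]
        best_type[sel[upd]] <- df$typ[upd]
      }
    }
  }
  nh <- table(factor(hits$sequence, levels = tags$sequence))
  data.frame(sequence = tags$sequence, count_A = tags$count_A,
             count_B = tags$count_B,
             category = factor(CATEGORY_LEVELS[best_rank],
                               levels = CATEGORY_LEVELS),
             feature_id = unname(best_feat),
             feature_type = unname(best_type),
             n_hits = as.integer(nh), stringsAsFactors = FALSE)
}

#' Category composition of a library pair
#'
#' The pie-chart analogue: per category, unique-tag counts and read
#' (total-tag) counts per library, with fractions.
#'
#' @param annotated result of [assign_category()].
#' @return data.frame with one row per category.
#' @export
category_counts <- function(annotated) {
  agg <- function(x) as.integer(tapply(x, annotated$category, sum,
                                       default = 0L))
  out <- data.frame(category = CATEGORY_LEVELS,
                    unique_tags = as.integer(table(annotated$category)),
                    reads_A = agg(annotated$count_A),
                    reads_B = agg(annotated$count_B))
  out$unique_fraction <- out$unique_tags / max(sum(out$unique_tags), 1)
  out$reads_A_fraction <- out$reads_A / max(sum(out$reads_A), 1)
  out$reads_B_fraction <- out$reads_B / max(sum(out$reads_B), 1)
  out
}

#' Per-chromosome strand distribution of mapped tags
#'
#' @param hits result of [map_tags()].
#' @param tags tag table (for read weights).
#' @return data.frame: `chrom`, `strand`, `unique_tags`, `reads_A`,
#'   `reads_B` (each distinct tag contributes once per chromosome/strand).
#' @export
chrom_strand_table <- function(hits, tags) {
  if (nrow(hits) == 0)
    return(data.frame(chrom = character(0), strand = character(0),
                      unique_tags = integer(0), reads_A = integer(0),
                      reads_B = integer(0)))
  u <- unique(hits[, c("sequence", "chrom", "strand")])
  idx <- match(u$sequence, tags$sequence)
  out <- stats::aggregate(
    cbind(unique_tags = rep(1L, nrow(u)),
          reads_A = tags$count_A[idx], reads_B = tags$count_B[idx]),
    by = list(chrom = u$chrom, strand = u$strand), FUN = sum)
  out[order(out$chrom, out$strand), ]
}

#' Exon sense:antisense unique-tag ratio
#'
#' Rounded ratio of sense to antisense exon-assigned unique tags, the
#' summary printed alongside the category pies.
#'
#' @param annotated result of [assign_category()].
#' @param library `"A"`, `"B"` or `"unique"` (default: unique-tag space).
#' @param digits rounding digits (default 0).
#' @return a single number (Inf if no antisense tags).
#' @export
exon_strand_ratio <- function(annotated, library = "unique", digits = 0) {
  w <- switch(library,
              unique = rep(1L, nrow(annotated)),
              A = annotated$count_A, B = annotated$count_B)
  s <- sum(w[annotated$category == "exon_sense"])
  a <- sum(w[annotated$category == "exon_antisense"])
  if (a == 0) return(Inf)
  round(s / a, digits)
}

#' Quantify known mature miRNAs
#'
#' A tag's reads count toward an annotated mature miRNA when the tag has a
#' same-strand hit whose 5' end lies within `tol` nt of the mature arm's
#' annotated 5' end (isomiR wobble) and the hit falls inside the parent
#' precursor. A tag matching several matures is assigned to the one with
#' the smallest 5' offset (first in annotation order on ties). Tags inside
#' a precursor but outside both mature windows count toward the precursor
#' only. TPM is `count / total clean reads * 1e6`.
#'
#' @param tags tag table.
#' @param hits result of [map_tags()].
#' @param features feature GRanges containing `mature_miRNA` and
#'   `miRNA_precursor` rows.
#' @param totals clean-read totals per library, length-2 vector.
#' @param tol 5'-end tolerance in nt (default 2).
#' @return data.frame of class `srna_mirna_counts`: `mirna_id`,
#'   `precursor_id`, `count_A`, `count_B`, `tpm_A`, `tpm_B` for every
#'   annotated mature arm (zeros included); attribute `precursor` holds
#'   per-precursor totals including mature-window misses.
#' @export
quantify_known <- function(tags, hits, features, totals, tol = 2) {
  mt <- features[S4Vectors::mcols(features)$type == "mature_miRNA"]
  pc <- features[S4Vectors::mcols(features)$type == "miRNA_precursor"]
  mid <- S4Vectors::mcols(mt)$ID
  mparent <- S4Vectors::mcols(mt)$Parent
  pid <- S4Vectors::mcols(pc)$ID

  out <- data.frame(mirna_id = mid, precursor_id = mparent,
                    count_A = 0L, count_B = 0L, stringsAsFactors = FALSE)
  prec_out <- data.frame(precursor_id = pid, count_A = 0L, count_B = 0L,
                         stringsAsFactors = FALSE)
  if (nrow(hits) > 0 && length(mt) > 0) {
    hit_gr <- hits_to_granges(hits)
    ov <- GenomicRanges::findOverlaps(hit_gr, mt)  # strand-aware
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    if (length(qh)) {
      plus <- hits$strand[qh] == "+"
      off <- ifelse(plus,
                    abs(hits$start[qh] - GenomicRanges::start(mt)[sh]),
                    abs(hits$end[qh] - GenomicRanges::end(mt)[sh]))
      # inside parent precursor
      pidx <- match(mparent[sh], pid)
      inside <- hits$start[qh] >= GenomicRanges::start(pc)[pidx] &
        hits$end[qh] <= GenomicRanges::end(pc)[pidx]
      keep <- off <= tol & inside
      if (any(keep)) {
        df <- data.frame(seq = hits$sequence[qh][keep],
                         mature = sh[keep], off = off[keep])
        df <- df[order(df$seq, df$off, df$mature), ]
        df <- df[!duplicated(df$seq), ]
        ti <- match(df$seq, tags$sequence)
        for (r in seq_len(nrow(df))) {
          m <- df$mature[r]
          out$count_A[m] <- out$count_A[m] + tags$count_A[ti[r]]
          out$count_B[m] <- out$count_B[m] + tags$count_B[ti[r]]
        }
      }
    }
    # precursor totals: any same-strand hit inside a precursor
    if (length(pc) > 0) {
      ovp <- GenomicRanges::findOverlaps(hit_gr, pc, type = "within")
      qp <- S4Vectors::queryHits(ovp); sp <- S4Vectors::subjectHits(ovp)
      if (length(qp)) {
        dfp <- unique(data.frame(seq = hits$sequence[qp], prec = sp))
        dfp <- dfp[!duplicated(dfp$seq), ]
        ti <- match(dfp$seq, tags$sequence)
        for (r in seq_len(nrow(dfp))) {
          p <- dfp$prec[r]
          prec_out$count_A[p] <- prec_out$count_A[p] + tags$count_A[ti[r]]
          prec_out$count_B[p] <- prec_out$count_B[p] + tags$count_B[ti[r]]
        }
      }
    }
  }
  out$tpm_A <- tpm(out$count_A, totals[1])
  out$tpm_B <- tpm(out$count_B, totals[2])
  attr(out, "precursor") <- prec_out
  class(out) <- c("srna_mirna_counts", "data.frame")
  out
}

#' rRNA-fraction quality check
#'
#' Read-weighted fraction of each library annotated to rRNA features; a
#' library passes while the fraction stays below 0.40 (a fraction of
#' exactly 0.40 fails: the mark is "less than 40%").
#'
#' @param annotated result of [assign_category()].
#' @return data.frame with one row per library: `fraction`, `pass`.
#' @export
qc_rrna_fraction <- function(annotated) {
  is_rrna <- !is.na(annotated$feature_type) &
    annotated$feature_type == "rRNA"
  fr <- function(counts) {
    tot <- sum(counts)
    if (tot == 0) 0 else sum(counts[is_rrna]) / tot
  }
  f <- c(A = fr(annotated$count_A), B = fr(annotated$count_B))
  data.frame(library = names(f), fraction = as.numeric(f),
             pass = as.numeric(f) < 0.40, row.names = NULL)
}
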