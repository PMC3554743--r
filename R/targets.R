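# Consensus target prediction with four in-house seed-match methods and
# hypergeometric term enrichment with Bonferroni correction.

seed_site <- function(mirna, first, last) revcomp(substr(mirna, first, last))

# duplex energy of the miRNA hybridised to the site window, modelled as a
# hairpin: miRNA + neutral linker + window folded with the package's
# nearest-neighbour model
duplex_energy <- function(mirna, window, params) {
  linker <- "AACACA"  # weakly pairing spacer
  fold_rna(paste0(window, linker, mirna), params)$mfe
}

#' Predict miRNA targets with four seed-match parameterizations
#'
#' Four internal methods emulate independent prediction tools so the
#' at-least-3-of-4 consensus rule is testable offline:
#' \describe{
#'   \item{M1}{7mer-m8: perfect complement of miRNA positions 2--8 in the
#'     3'UTR.}
#'   \item{M2}{8mer: the 7mer-m8 site followed by an A opposite miRNA
#'     position 1.}
#'   \item{M3}{7mer-A1 (positions 2--7 plus the A) or a 7mer-m8 site with
#'     3'-supplementary pairing: at least 4 contiguous complementary bases
#'     of miRNA positions 13--17 within 16 nt upstream of the site.}
#'   \item{M4}{a 7mer-m8 site whose miRNA:site-window duplex energy under
#'     the package's folding model is below `energy_threshold`.}
#' }
#' Per-gene support is the union over sites.
#'
#' @param mirnas named character vector of mature miRNA sequences (DNA,
#'   each at least 19 nt).
#' @param utrs named character vector of 3'UTR sequences (DNA).
#' @param energy_threshold duplex-energy gate for M4 in kcal/mol
#'   (default -14).
#' @param params folding energy table.
#' @return data.frame with `mirna_id`, `gene_id`, `methods`
#'   (comma-separated), `n_methods`, `site_pos` (first 7mer-m8 or 7mer-A1
#'   site in the UTR), `seed_type`.
#' @export
predict_targets_multimethod <- function(mirnas, utrs,
                                        energy_threshold = -14,
                                        params = energy_params()) {
  if (any(nchar(mirnas) < 19))
    stop("mature miRNA sequences must be at least 19 nt")
  rows <- list()
  for (m in names(mirnas)) {
    mir <- toupper(mirnas[[m]])
    s78 <- seed_site(mir, 2, 8)              # 7mer-m8 site
    s8 <- paste0(s78, "A")                   # 8mer
    s7a1 <- paste0(seed_site(mir, 2, 7), "A")  # 7mer-A1
    sup <- substr(mir, 13, 17)
    sup_rc <- c(revcomp(substr(sup, 1, 4)), revcomp(substr(sup, 2, 5)))
    for (g in names(utrs)) {
      utr <- toupper(utrs[[g]])
      if (nchar(utr) < 7) next
      pos_m8 <- gregexpr(s78, utr, fixed = TRUE)[[1]]
      has_m8 <- pos_m8[1] != -1
      has_8 <- grepl(s8, utr, fixed = TRUE)
      pos_a1 <- gregexpr(s7a1, utr, fixed = TRUE)[[1]]
      has_a1 <- pos_a1[1] != -1
      methods <- character(0)
      if (has_m8) methods <- c(methods, "M1")
      if (has_8) methods <- c(methods, "M2")
      m3 <- has_a1
      if (!m3 && has_m8) {
        for (p in pos_m8) {
          upstream <- substr(utr, max(1, p - 16), p - 1)
          if (any(vapply(sup_rc, grepl, TRUE, x = upstream,
                         fixed = TRUE))) { m3 <- TRUE; break }
        }
      }
      if (m3) methods <- c(methods, "M3")
      if (has_m8) {
        p <- pos_m8[1]
        win <- substr(utr, max(1, p - 10), min(nchar(utr), p + 16))
        if (duplex_energy(mir, win, params) < energy_threshold)
          methods <- c(methods, "M4")
      }
      if (length(methods)) {
        rows[[length(rows) + 1]] <- data.frame(
          mirna_id = m, gene_id = g,
          methods = paste(methods, collapse = ","),
          n_methods = length(methods),
          site_pos = if (has_m8) pos_m8[1] else pos_a1[1],
          seed_type = if (has_8) "8mer" else if (has_m8) "7mer-m8"
          else "7mer-A1",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      methods = character(0), n_methods = integer(0),
                      site_pos = integer(0), seed_type = character(0)))
  do.call(rbind, rows)
}

#' Keep targets supported by enough methods
#'
#' @param predictions result of [predict_targets_multimethod()], or a
#'   merge of four externally produced prediction lists with the same
#'   columns.
#' @param min_support minimum number of supporting methods (default 3).
#' @return the retained rows, plus attribute `per_mirna` (target counts
#'   per miRNA).
#' @export
consensus_filter <- function(predictions, min_support = 3) {
  out <- predictions[predictions$n_methods >= min_support, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_mirna") <- table(out$mirna_id)
  out
}

#' Merge externally produced per-tool target lists
#'
#' Accepts up to four two-column (`mirna_id`, `gene_id`) tables, one per
#' external tool, and produces the support-count table
#' [consensus_filter()] expects, intersecting on the supplied gene
#' identifiers verbatim.
#'
#' @param ... data.frames, one per tool.
#' @return data.frame with `mirna_id`, `gene_id`, `methods`, `n_methods`.
#' @export
merge_tool_predictions <- function(...) {
  tools <- list(...)
  names(tools) <- paste0("M", seq_along(tools))
  rows <- do.call(rbind, lapply(names(tools), function(nm) {
    t <- unique(tools[[nm]][, c("mirna_id", "gene_id")])
    t$method <- nm
    t
  }))
  agg <- stats::aggregate(method ~ mirna_id + gene_id, data = rows,
                          FUN = function(x) paste(sort(x), collapse = ","))
  agg$n_methods <- lengths(strsplit(agg$method, ","))
  names(agg)[names(agg) == "method"] <- "methods"
  agg
}

#' Hypergeometric term enrichment with Bonferroni correction
#'
#' For each term, the upper-tail hypergeometric probability of observing
#' at least the seen number of target genes annotated to the term, given
#' the universe size, the term size and the target-set size; the
#' correction multiplies by the number of terms tested (capped at 1).
#' The percentage column is the term's target count over the number of
#' retained target genes with at least one term annotation.
#'
#' @param target_genes character vector of target gene ids.
#' @param term_map data.frame with columns `gene_id`, `term_id` and
#'   optionally `term_name`.
#' @param universe gene universe (must contain the targets); genes without
#'   term annotations count toward the universe but no term.
#' @param alpha reporting threshold on the corrected p (default 0.05);
#'   use 1 to report every term.
#' @return data.frame with `term_id`, `term_name`, `gene_count`,
#'   `percentage`, `p_raw`, `bonferroni`, sorted by corrected p; rows with
#'   `bonferroni < alpha`.
#' @export
enrich <- function(target_genes, term_map, universe, alpha = 0.05) {
  target_genes <- unique(target_genes)
  universe <- unique(universe)
  if (!all(target_genes %in% universe))
    stop("universe must contain all target genes")
  if (length(target_genes) == 0) {
    warning("empty target set: no enrichment computed")
    return(data.frame(term_id = character(0), term_name = character(0),
                      gene_count = integer(0), percentage = numeric(0),
                      p_raw = numeric(0), bonferroni = numeric(0)))
  }
  tm <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  terms <- unique(tm$term_id)
  N <- length(universe)
  n <- length(target_genes)
  annotated_targets <- length(intersect(target_genes, tm$gene_id))
  res <- lapply(terms, function(t) {
    genes_t <- unique(tm$gene_id[tm$term_id == t])
    K <- length(genes_t)
    k <- length(intersect(genes_t, target_genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t,
               term_name = if ("term_name" %in% names(tm))
                 tm$term_name[match(t, tm$term_id)] else t,
               gene_count = k,
               percentage = k / max(annotated_targets, 1),
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$bonferroni <- pmin(1, out$p_raw * length(terms))
  if (alpha < 1)
    out <- out[out$bonferroni < alpha, , drop = FALSE]
  out <- out[order(out$bonferroni, out$p_raw), ]
  rownames(out) <- NULL
  out
}
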