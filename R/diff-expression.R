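# Two-library differential expression: TPM normalization, exact
# conditional binomial test, Benjamini-Hochberg adjustment and Up/Down
# calls at adjusted P < 0.05 and at least 2-fold change.

#' Transcripts per million
#'
#' @param count read count(s).
#' @param library_total total clean reads of the library.
#' @return `count / library_total * 1e6`.
#' @export
#' @examples
#' tpm(1, 1e6)   # 1 TPM: one transcript per million tags
#' tpm(57, 250000)
tpm <- function(count, library_total) {
  if (any(library_total <= 0)) stop("library_total must be positive")
  count / library_total * 1e6
}

#' Exact two-library test for a count difference
#'
#' The replicate-free exact test for two sequencing libraries: conditional
#' on `n = count_a + count_b`, `count_b` is Binomial(n, q) with
#' `q = total_b / (total_a + total_b)` under the null of equal relative
#' abundance. The two-sided p-value sums the probabilities of all outcomes
#' no more likely than the observed one (minimum-likelihood convention).
#'
#' @param count_a,count_b tag counts in the two libraries (vectorized).
#' @param total_a,total_b clean-read totals.
#' @return two-sided p-value(s) in (0, 1].
#' @export
#' @examples
#' two_library_test(5, 5, 1e6, 1e6)    # symmetric center: p = 1
#' two_library_test(0, 20, 1e6, 1e6)   # = 2 * 0.5^20
two_library_test <- function(count_a, count_b, total_a, total_b) {
  if (any(total_a <= 0) || any(total_b <= 0))
    stop("library totals must be positive")
  if (any(count_a < 0) || any(count_b < 0)) stop("counts must be >= 0")
  n <- count_a + count_b
  if (any(n == 0)) stop("both counts zero: test undefined")
  q <- total_b / (total_a + total_b)
  m <- max(length(n), length(q))
  n <- rep_len(n, m); q <- rep_len(q, m)
  cb <- rep_len(count_b, m)
  vapply(seq_len(m), function(i) {
    dens <- dbinom(0:n[i], n[i], q[i])
    p <- sum(dens[dens <= dens[cb[i] + 1] * (1 + 1e-7)])
    min(p, 1)
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_i = min(1, min_{j >= i} m * p_(j) / j)` over the ascending sort,
#' with the original order restored. Monotone in the raw p-values.
#'
#' @param p raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Call differential expression for one miRNA
#'
#' `Up` requires adjusted P below `alpha` and at least `min_fold`-fold
#' higher normalized expression in library B; `Down` the mirror; `NS`
#' otherwise.
#'
#' @param log2_fc log2 fold change (B over A, zero sides floored upstream).
#' @param p_adj BH-adjusted p-value.
#' @param alpha significance level (default 0.05).
#' @param min_fold fold-change gate (default 2).
#' @return character vector over `Up`, `Down`, `NS`.
#' @export
call_de <- function(log2_fc, p_adj, alpha = 0.05, min_fold = 2) {
  lf <- log2(min_fold)
  ifelse(p_adj < alpha & log2_fc >= lf, "Up",
         ifelse(p_adj < alpha & log2_fc <= -lf, "Down", "NS"))
}

#' Differential expression table for known and novel miRNAs
#'
#' Tests every miRNA detected in at least one library with the exact
#' two-library test, adjusts with Benjamini-Hochberg within each set
#' (known and novel are corrected separately, mirroring their separate
#' reporting), computes the log2 fold change of TPM with a configurable
#' floor applied to zero sides only (so library-specific miRNAs get a
#' large finite fold change), and calls Up/Down/NS. Rows are sorted by
#' |log2FC| descending within direction.
#'
#' @param known data.frame with `mirna_id`, `count_A`, `count_B` (e.g.
#'   from [quantify_known()]).
#' @param novel same schema for novel candidates, or NULL.
#' @param totals clean-read totals per library, length-2.
#' @param alpha,min_fold see [call_de()].
#' @param tpm_floor TPM floor for zero sides (default 0.01).
#' @return object of class `srna_de`: a data.frame with `mirna_id`, `set`
#'   (`known`/`novel`), counts, TPMs, `log2_fc`, `p_raw`, `p_adj`, `call`;
#'   attribute `summary` holds the headline counts (n_up, n_down,
#'   n_over_16fold_up/down per set, and the number of miRNAs shared by
#'   both libraries).
#' @export
de_table <- function(known, novel = NULL, totals, alpha = 0.05,
                     min_fold = 2, tpm_floor = 0.01) {
  one_set <- function(df, set) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    df <- df[df$count_A + df$count_B > 0, , drop = FALSE]
    if (nrow(df) == 0) return(NULL)
    ta <- tpm(df$count_A, totals[1])
    tb <- tpm(df$count_B, totals[2])
    lfc <- log2(pmax(tb, tpm_floor) / pmax(ta, tpm_floor))
    p <- two_library_test(df$count_A, df$count_B, totals[1], totals[2])
    padj <- bh_adjust(p)
    data.frame(mirna_id = df$mirna_id, set = set,
               count_A = df$count_A, count_B = df$count_B,
               tpm_A = ta, tpm_B = tb, log2_fc = lfc,
               p_raw = p, p_adj = padj,
               call = call_de(lfc, padj, alpha, min_fold),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_set(known, "known"), one_set(novel, "novel"))
  if (is.null(out))
    out <- data.frame(mirna_id = character(0), set = character(0),
                      count_A = integer(0), count_B = integer(0),
                      tpm_A = numeric(0), tpm_B = numeric(0),
                      log2_fc = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), call = character(0))
  dir_rank <- match(out$call, c("Up", "Down", "NS"))
  out <- out[order(out$set, dir_rank, -abs(out$log2_fc)), ]
  rownames(out) <- NULL
  summ <- lapply(split(out, out$set), function(d) {
    c(n_tested = nrow(d),
      n_shared = sum(d$count_A > 0 & d$count_B > 0),
      n_up = sum(d$call == "Up"), n_down = sum(d$call == "Down"),
      n_over_16fold_up = sum(d$call == "Up" & d$log2_fc > 4),
      n_over_16fold_down = sum(d$call == "Down" & d$log2_fc < -4))
  })
  attr(out, "summary") <- summ
  attr(out, "alpha") <- alpha
  attr(out, "min_fold") <- min_fold
  class(out) <- c("srna_de", "data.frame")
  out
}

#' @export
print.srna_de <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "Two-library differential expression (adjusted P < %g, >= %g-fold)\n",
    attr(x, "alpha"), attr(x, "min_fold")))
  for (set in names(s))
    cat(sprintf("  %s: %d tested (%d shared), %d up, %d down\n", set,
                s[[set]]["n_tested"], s[[set]]["n_shared"],
                s[[set]]["n_up"], s[[set]]["n_down"]))
  top <- head(as.data.frame(x)[, c("mirna_id", "set", "log2_fc", "p_adj",
                                   "call")], 10)
  top$log2_fc <- sprintf("%.2f", top$log2_fc)
  top$p_adj <- sprintf("%.2E", top$p_adj)
  print(top, row.names = FALSE)
  invisible(x)
}

#' @export
summary.srna_de <- function(object, ...) {
  attr(object, "summary")
}
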