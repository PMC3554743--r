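#' Fold an RNA sequence to its minimum free energy structure
#'
#' Computes the minimum-free-energy pseudoknot-free secondary structure of a
#' single strand under the simplified nearest-neighbour model of
#' [energy_params()]: Watson-Crick and G.U wobble pairs, stacking energies,
#' loop-size penalties and an affine multiloop term. The dynamic program is
#' the classic interval recursion (interior loops capped at 30 unpaired
#' bases); ties are broken toward structures with fewer pairs, and the empty
#' structure (energy 0) is always admissible, so the reported MFE is never
#' positive.
#'
#' @param sequence a single RNA or DNA string (T is read as U); length
#'   1 to 2000 nt, alphabet ACGU/T.
#' @param params energy table, see [energy_params()].
#' @return An object of class `srna_fold`: a list with `sequence` (as RNA),
#'   `structure` (dot-bracket) and `mfe` (kcal/mol).
#' @export
#' @examples
#' fold_rna("GGGGGAAAACCCCC")$mfe
#' fold_rna("AAAAAAAAAAAAAAAAAAAA")$structure  # no pairs possible
fold_rna <- function(sequence, params = energy_params()) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence))
    stop("'sequence' must be a single string")
  rna <- dna_to_rna(sequence)
  n <- nchar(rna)
  if (n < 1 || n > 2000)
    stop("sequence length must be between 1 and 2000 nt")
  bases <- strsplit(rna, "")[[1]]
  code <- match(bases, c("A", "C", "G", "U")) - 1L
  if (anyNA(code))
    stop("sequence contains characters outside ACGU/ACGT")
  res <- fold_nn_cpp(code, params)
  out <- list(sequence = rna, structure = res$structure,
              mfe = min(res$mfe, 0))
  class(out) <- "srna_fold"
  out
}

#' @export
print.srna_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n",
      sprintf("MFE: %.2f kcal/mol\n", x$mfe), sep = "")
  invisible(x)
}

# pair partner table from dot-bracket (0 = unpaired), internal helper
pair_table <- function(structure) {
  db <- strsplit(structure, "")[[1]]
  pt <- integer(length(db))
  stk <- integer(0)
  for (i in seq_along(db)) {
    if (db[i] == "(") stk <- c(stk, i)
    else if (db[i] == ")") {
      j <- stk[length(stk)]; stk <- stk[-length(stk)]
      pt[i] <- j; pt[j] <- i
    }
  }
  pt
}
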