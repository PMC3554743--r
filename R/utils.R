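#' @useDynLib srnapipe, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods is
#' @importFrom stats dbinom phyper rmultinom runif rlnorm setNames
#' @importFrom utils read.delim write.table head
NULL

# reverse complement of plain DNA character vectors
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sample random DNA of given lengths (one RNG draw, then split)
random_dna <- function(lengths, prob = rep(0.25, 4)) {
  total <- sum(lengths)
  if (length(lengths) == 0) return(character(0))
  if (total == 0) return(rep("", length(lengths)))
  s <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE,
                    prob = prob), collapse = "")
  ends <- cumsum(lengths)
  substring(s, ends - lengths + 1, ends)
}

# run code under a temporary RNG state restored afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != floor(x))
    stop(sprintf("'%s' must be a single non-negative integer", name))
}
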