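#' Nearest-neighbour energy parameters for hairpin folding
#'
#' Returns the energy table used by [fold_rna()] and [structure_energy()]:
#' stacking free energies (kcal/mol, 37 C) for the 36 ordered combinations of
#' the six canonical/wobble pairs (CG, GC, GU, UG, AU, UA), loop-size
#' penalties for hairpin, bulge and internal loops (tabulated to 30 nt and
#' extrapolated logarithmically beyond), and an affine multiloop penalty.
#' The values are Turner-like but deliberately simplified: the model has no
#' sequence-dependent loop terms, dangles or coaxial stacking. It is stable
#' enough that a designed 20+ bp stem folds well below the -20 kcal/mol
#' novel-miRNA gate while unstructured sequences stay near zero.
#'
#' The stack table is symmetrised on construction so that a helix has the
#' same energy read from either strand, which the dynamic program and the
#' independent structure evaluator both rely on.
#'
#' @return A list with elements `stack` (6x6 matrix, dimnames the pair
#'   types), `hairpin`, `bulge`, `internal` (length-30 numeric, index =
#'   loop size), `extrap` (coefficient of the `log(L/Lmax)` extrapolation),
#'   and `multi_offset`, `multi_branch`, `multi_unpaired` (kcal/mol).
#' @export
#' @examples
#' p <- energy_params()
#' p$stack["CG", "GC"]
energy_params <- function() {
  pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")
  st <- matrix(c(
    # inner:  CG    GC    GU    UG    AU    UA      outer:
    -3.3, -3.4, -2.1, -1.4, -2.1, -2.1,  # CG
    -2.4, -3.3, -2.5, -1.5, -2.2, -2.4,  # GC
    -1.4, -2.5, -1.3, -0.5, -1.3, -1.0,  # GU
    -2.1, -2.1, -0.5,  0.0, -1.4, -1.0,  # UG
    -2.1, -2.2, -1.4, -0.6, -1.1, -0.9,  # AU
    -2.4, -2.1, -1.0, -0.7, -1.3, -1.3), # UA
    nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  # symmetry: stack (i,j)/(i+1,j-1) == the same helix read from the other
  # strand, i.e. E[p1, p2] == E[flip(p2), flip(p1)] with flip(XY) = YX
  flip <- c(CG = "GC", GC = "CG", GU = "UG", UG = "GU", AU = "UA", UA = "AU")
  sym <- st
  for (a in pairs) for (b in pairs)
    sym[a, b] <- (st[a, b] + st[flip[b], flip[a]]) / 2
  extrap <- 1.079  # 1.75 * RT at 310 K

  hairpin <- c(99, 99, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4,
               6.4 + extrap * log((10:30) / 9))
  bulge <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4,
             4.4 + extrap * log((7:30) / 6))
  internal <- c(99, 4.1, 5.1, 4.9, 5.3, 5.7,
                5.7 + extrap * log((7:30) / 6))
  list(stack = sym, hairpin = hairpin, bulge = bulge, internal = internal,
       extrap = extrap, multi_offset = 3.4, multi_branch = 0.4,
       multi_unpaired = 0.0)
}

#' Read or write the energy table as YAML
#'
#' The folding parameters can be round-tripped through a plain YAML file so
#' alternative tables can be supplied to [fold_rna()].
#'
#' @param path file path.
#' @param params parameter list as returned by [energy_params()].
#' @return `read_energy_params` returns a parameter list;
#'   `write_energy_params` returns `path` invisibly.
#' @export
write_energy_params <- function(params, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to write parameter files")
  out <- params
  out$stack <- as.list(as.data.frame(params$stack))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_energy_params
#' @export
read_energy_params <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read parameter files")
  raw <- yaml::read_yaml(path)
  pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")
  st <- do.call(cbind, lapply(raw$stack, unlist))
  dimnames(st) <- list(pairs, pairs)
  raw$stack <- st
  for (f in c("hairpin", "bulge", "internal"))
    raw[[f]] <- as.numeric(raw[[f]])
  raw
}

loop_penalty <- function(tab, L, extrap) {
  m <- length(tab)
  ifelse(L <= 0, Inf, ifelse(L <= m, tab[pmax(L, 1)],
                             tab[m] + extrap * log(L / m)))
}

pair_type_chr <- function(a, b) {
  key <- paste0(a, b)
  ok <- c("CG", "GC", "GU", "UG", "AU", "UA")
  ifelse(key %in% ok, key, NA_character_)
}

#' Evaluate the free energy of a given secondary structure
#'
#' Computes the energy of a dot-bracket structure for a sequence under the
#' same nearest-neighbour decomposition as [fold_rna()], but by direct loop
#' parsing rather than dynamic programming. Used as an independent check
#' that the folding DP returns the energy of the structure it reports, and
#' as the scorer for the exhaustive-enumeration folding oracle.
#'
#' @param sequence RNA/DNA string (T read as U).
#' @param structure dot-bracket string of the same length.
#' @param params energy table, see [energy_params()].
#' @return energy in kcal/mol (a single number); `Inf` if the structure
#'   contains a non-canonical pair or a hairpin loop shorter than 3 nt.
#' @export
structure_energy <- function(sequence, structure, params = energy_params()) {
  seq <- strsplit(dna_to_rna(sequence), "")[[1]]
  db <- strsplit(structure, "")[[1]]
  n <- length(seq)
  if (length(db) != n) stop("sequence and structure lengths differ")
  # pair table
  pt <- integer(n)
  stk <- integer(0)
  for (i in seq_len(n)) {
    if (db[i] == "(") stk <- c(stk, i)
    else if (db[i] == ")") {
      if (length(stk) == 0) stop("unbalanced structure")
      j <- stk[length(stk)]
      stk <- stk[-length(stk)]
      pt[i] <- j; pt[j] <- i
    } else if (db[i] != ".") stop("invalid structure character")
  }
  if (length(stk) > 0) stop("unbalanced structure")

  e <- 0
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j <= i) next                      # visit each pair once, i < j
    if (is.na(pair_type_chr(seq[i], seq[j]))) return(Inf)
    # children of (i,j)
    children <- list(); unp <- 0L; p <- i + 1L
    while (p < j) {
      if (pt[p] == 0) { unp <- unp + 1L; p <- p + 1L }
      else { children[[length(children) + 1L]] <- c(p, pt[p]); p <- pt[p] + 1L }
    }
    nc <- length(children)
    if (nc == 0) {
      L <- j - i - 1L
      if (L < 3) return(Inf)
      e <- e + loop_penalty(params$hairpin, L, params$extrap)
    } else if (nc == 1) {
      k <- children[[1]][1]; l <- children[[1]][2]
      l1 <- k - i - 1L; l2 <- j - l - 1L
      if (l1 == 0 && l2 == 0) {
        e <- e + params$stack[pair_type_chr(seq[i], seq[j]),
                              pair_type_chr(seq[k], seq[l])]
      } else if (l1 == 0 || l2 == 0) {
        e <- e + loop_penalty(params$bulge, l1 + l2, params$extrap)
      } else {
        e <- e + loop_penalty(params$internal, l1 + l2, params$extrap)
      }
    } else {
      e <- e + params$multi_offset + params$multi_branch * (nc + 1) +
        params$multi_unpaired * unp
    }
  }
  e
}
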