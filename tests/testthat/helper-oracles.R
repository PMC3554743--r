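# Independent oracles used across the suite: exhaustive structure
# enumeration for folding, definitional BH and exact-test computations,
# and a brute-force interval merger.

CAN_PAIR <- c("CG", "GC", "GU", "UG", "AU", "UA")

# every pseudoknot-free structure (min hairpin loop 3) as a flat integer
# vector of pairs c(i1, j1, i2, j2, ...); memoized recursion
enum_structures <- function(bases) {
  n <- length(bases)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < 4) return(list(integer(0)))
    key <- paste0(i, "_", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    res <- rec(i + 1, j)
    for (k in (i + 4):j) {
      if (paste0(bases[i], bases[k]) %in% CAN_PAIR) {
        left <- rec(i + 1, k - 1)
        right <- if (k + 1 <= j) rec(k + 1, j) else list(integer(0))
        for (L in left) for (R in right)
          res[[length(res) + 1]] <- c(i, k, L, R)
      }
    }
    memo[[key]] <- res
    res
  }
  rec(1, n)
}

pairs_to_dotbracket <- function(pairs, n) {
  db <- rep(".", n)
  if (length(pairs)) {
    i <- pairs[seq(1, length(pairs), 2)]
    j <- pairs[seq(2, length(pairs), 2)]
    db[i] <- "("; db[j] <- ")"
  }
  paste(db, collapse = "")
}

# exhaustive-minimum MFE over all structures, scored independently of the
# dynamic program by structure_energy()
mfe_oracle <- function(sequence, params = energy_params()) {
  rna <- chartr("Tt", "Uu", toupper(sequence))
  bases <- strsplit(rna, "")[[1]]
  structs <- enum_structures(bases)
  best <- 0
  for (s in structs) {
    e <- structure_energy(rna, pairs_to_dotbracket(s, length(bases)),
                          params)
    if (e < best) best <- e
  }
  best
}

# definitional BH step-up: adj_i = min(1, min_{j>=i} m p_(j) / j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) min(1, min(m * ps[i:m] / (i:m))),
                numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact conditional test by explicit summation with choose() arithmetic
two_lib_oracle <- function(a, b, ta, tb) {
  n <- a + b
  q <- tb / (ta + tb)
  k <- 0:n
  dens <- choose(n, k) * q^k * (1 - q)^(n - k)
  min(sum(dens[dens <= dens[b + 1] * (1 + 1e-7)]), 1)
}

# brute-force strand-blind interval merge with gap tolerance
merge_oracle <- function(starts, ends, gap) {
  o <- order(starts, ends)
  s <- starts[o]; e <- ends[o]
  out_s <- s[1]; out_e <- e[1]
  res <- NULL
  for (i in seq_along(s)[-1]) {
    if (s[i] - out_e - 1 <= gap) out_e <- max(out_e, e[i])
    else { res <- rbind(res, c(out_s, out_e)); out_s <- s[i]; out_e <- e[i] }
  }
  rbind(res, c(out_s, out_e))
}

# hypergeometric upper tail by explicit summation
hyper_oracle <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# small standard config for integration-style tests
small_config <- function(seed = 11, ...) {
  args <- list(genome_length = 20000, n_known_mirnas = 4,
               n_hidden_hairpins = 2, n_other_ncrna = 6, n_repeats = 2,
               n_genes = 2, library_sizes = c(8000, 8000), seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
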