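#' Configuration for the synthetic small RNA experiment
#'
#' Builds and validates the configuration driving [build_genome()] and
#' [simulate_libraries()]. The generator emulates the statistical structure
#' a two-library small RNA contrast assumes: a miniature genome carrying
#' designed miRNA stem-loops (known, i.e. annotated, and hidden, i.e. left
#' out of the annotation as the novel-miRNA truth set), assorted ncRNA,
#' repeat and gene features, and two adapter-ligated 50-nt read libraries
#' whose per-miRNA expected counts follow
#' `library_size * TPM / 1e6`, scaled by a per-miRNA true log2 fold change
#' in library B, with counts drawn multinomially.
#'
#' @param genome_length genome size in bases.
#' @param n_known_mirnas number of annotated miRNA precursors to plant.
#' @param n_hidden_hairpins hairpins planted identically but omitted from
#'   the annotation (ground truth for novel-miRNA prediction).
#' @param n_other_ncrna number of rRNA/tRNA/sn(o)RNA/scRNA features.
#' @param n_repeats,n_genes numbers of repeat features and exon/intron gene
#'   models.
#' @param library_sizes reads per library, length-2 non-negative vector.
#' @param log2_fc per-known-miRNA true log2 fold change (library B vs A);
#'   a single value recycled, a vector of length `n_known_mirnas`, or NULL
#'   for all-zero.
#' @param hidden_log2_fc same for hidden hairpins.
#' @param insert_length_dist named probability vector over insert lengths
#'   18--30 (must sum to 1); drives random-noise insert lengths. Defaults
#'   peak at 22 nt (64%), mirroring the parental library's size profile.
#' @param first_base_u_prob probability that a planted mature 5p arm (and,
#'   by stem design, the 3p arm) starts with U.
#' @param mature_len,loop_len designed mature arm and hairpin loop lengths.
#' @param mix mixture over read sources: named fractions for `mirna`,
#'   `hidden`, `ncrna`, `genic`, `noise`, `dimer` (adapter-only reads);
#'   must sum to 1.
#' @param ncrna_frag_len_range length range of contaminating ncRNA/genic
#'   fragments (deliberately wider than 18--30 to exercise the length
#'   filter).
#' @param adapter 3' adapter in DNA form.
#' @param read_length raw read length.
#' @param error_rate optional uniform substitution rate (off by default).
#' @param seed RNG seed; the same config is bit-reproducible.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 50000,
                       n_known_mirnas = 12,
                       n_hidden_hairpins = 6,
                       n_other_ncrna = 10,
                       n_repeats = 4,
                       n_genes = 4,
                       library_sizes = c(50000, 50000),
                       log2_fc = NULL,
                       hidden_log2_fc = NULL,
                       insert_length_dist = NULL,
                       first_base_u_prob = 0.8,
                       mature_len = 22,
                       loop_len = 8,
                       mix = c(mirna = 0.52, hidden = 0.15, ncrna = 0.16,
                               genic = 0.05, noise = 0.09, dimer = 0.03),
                       ncrna_frag_len_range = c(16, 34),
                       adapter = "TCGTATGCCGTCTTCTGCTTGT",
                       read_length = 50,
                       error_rate = 0,
                       seed = 1) {
  if (is.null(insert_length_dist)) {
    insert_length_dist <- c(0.02, 0.03, 0.05, 0.08, 0.64, 0.08, 0.04,
                            0.02, 0.01, 0.01, 0.01, 0.005, 0.005)
    names(insert_length_dist) <- 18:30
  }
  if (is.null(names(insert_length_dist)))
    names(insert_length_dist) <- 18:30
  if (!isTRUE(all.equal(sum(insert_length_dist), 1, tolerance = 1e-9)))
    stop("insert_length_dist must sum to 1")
  if (any(insert_length_dist < 0)) stop("insert_length_dist must be >= 0")
  if (length(library_sizes) != 2 || any(library_sizes < 0))
    stop("library_sizes must be two non-negative counts")
  if (!isTRUE(all.equal(sum(mix), 1, tolerance = 1e-9)) || any(mix < 0))
    stop("mix must be non-negative and sum to 1")
  if (first_base_u_prob < 0 || first_base_u_prob > 1)
    stop("first_base_u_prob must be in [0, 1]")
  if (loop_len < 4 || loop_len > 12) stop("loop_len must be 4..12")
  expand_fc <- function(fc, n, what) {
    if (is.null(fc)) return(rep(0, n))
    if (length(fc) == 1) return(rep(fc, n))
    if (length(fc) != n)
      stop(sprintf("%s must have length 1 or %d", what, n))
    as.numeric(fc)
  }
  cfg <- list(genome_length = genome_length,
              n_known_mirnas = n_known_mirnas,
              n_hidden_hairpins = n_hidden_hairpins,
              n_other_ncrna = n_other_ncrna,
              n_repeats = n_repeats, n_genes = n_genes,
              library_sizes = library_sizes,
              log2_fc = expand_fc(log2_fc, n_known_mirnas, "log2_fc"),
              hidden_log2_fc = expand_fc(hidden_log2_fc, n_hidden_hairpins,
                                         "hidden_log2_fc"),
              insert_length_dist = insert_length_dist,
              first_base_u_prob = first_base_u_prob,
              mature_len = mature_len, loop_len = loop_len,
              mix = mix, ncrna_frag_len_range = ncrna_frag_len_range,
              adapter = adapter, read_length = read_length,
              error_rate = error_rate, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

# design a mature 5p arm: first base U with prob u (5' U bias) and last
# base A with prob u so the 3p arm (reverse complement) starts with U too
design_arm <- function(len, u_prob) {
  b <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (runif(1) < u_prob) b[1] <- "T"
  if (runif(1) < u_prob) b[len] <- "A"
  paste(b, collapse = "")
}

place_features <- function(lengths, genome_length, buffer = 20,
                           max_tries = 500) {
  placed_start <- integer(0); placed_end <- integer(0)
  starts <- integer(length(lengths))
  for (i in seq_along(lengths)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(genome_length - lengths[i] - buffer, 1) + buffer
      e <- s + lengths[i] - 1
      if (!any(s <= placed_end + buffer & e >= placed_start - buffer)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop(sprintf(paste0("cannot place %d features of total span %d in a ",
                          "%d nt genome without overlap; increase ",
                          "genome_length or reduce feature counts"),
                   length(lengths), sum(lengths) + buffer * length(lengths),
                   genome_length))
    placed_start <- c(placed_start, s); placed_end <- c(placed_end, e)
    starts[i] <- s
  }
  starts
}

#' Build the synthetic genome, annotation and ground truth
#'
#' Generates a random genome, plants designed miRNA stem-loops (perfect
#' reverse-complement stems of `mature_len` bp with a `loop_len` nt loop,
#' so both mature arms are fully paired in the stem), ncRNA features split
#' between a GenBank-labelled and an Rfam-labelled source, repeats and
#' exon/intron gene models. Hidden hairpins are constructed identically but
#' omitted from the annotation. Per-arm true abundances (TPM) are drawn
#' log-normally within the configured mixture fraction and scaled by the
#' true log2 fold changes in library B.
#'
#' @param config a [sim_config()].
#' @return list of class `srna_sim` with elements `genome`
#'   (named character, one chromosome), `features`
#'   ([GenomicRanges::GRanges] with `type`, `source`, `ID`, `Parent`),
#'   `truth` (data.frame, one row per planted arm: id, precursor
#'   coordinates, arm coordinates, sequence, hidden flag, true TPM per
#'   library and true log2 fold change) and `config`.
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  genome <- random_dna(L)

  ml <- config$mature_len; ll <- config$loop_len
  prec_len <- 2 * ml + ll
  nk <- config$n_known_mirnas; nh <- config$n_hidden_hairpins
  nc <- config$n_other_ncrna; nr <- config$n_repeats; ng <- config$n_genes

  ncrna_len <- if (nc > 0) sample(70:120, nc, replace = TRUE) else integer(0)
  rep_len <- rep(150L, nr)
  gene_len <- rep(150L + 120L + 150L, ng)
  lens <- c(rep(prec_len, nk + nh), ncrna_len, rep_len, gene_len)
  starts <- if (length(lens)) place_features(lens, L) else integer(0)

  gchars <- strsplit(genome, "")[[1]]
  feat <- list()
  truth <- list()
  idx <- 0

  add_feat <- function(start, end, strand, type, source, id, parent = NA) {
    feat[[length(feat) + 1]] <<- data.frame(
      start = start, end = end, strand = strand, type = type,
      source = source, ID = id, Parent = parent, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nk + nh)) {
    idx <- idx + 1
    s <- starts[idx]
    arm5 <- design_arm(ml, config$first_base_u_prob)
    loop <- random_dna(ll)
    arm3 <- revcomp(arm5)
    prec <- paste0(arm5, loop, arm3)
    gchars[s:(s + prec_len - 1)] <- strsplit(prec, "")[[1]]
    hidden <- i > nk
    id <- if (hidden) sprintf("hid-%03d", i - nk) else sprintf("mir-%03d", i)
    if (!hidden) {
      add_feat(s, s + prec_len - 1, "+", "miRNA_precursor", "sim", id)
      add_feat(s, s + ml - 1, "+", "mature_miRNA", "sim",
               paste0(id, "-5p"), id)
      add_feat(s + prec_len - ml, s + prec_len - 1, "+", "mature_miRNA",
               "sim", paste0(id, "-3p"), id)
    }
    truth[[length(truth) + 1]] <- data.frame(
      mirna_id = id, hidden = hidden,
      prec_start = s, prec_end = s + prec_len - 1,
      m5p_start = s, m5p_end = s + ml - 1,
      m3p_start = s + prec_len - ml, m3p_end = s + prec_len - 1,
      seq_5p = arm5, seq_3p = arm3, stringsAsFactors = FALSE)
  }

  nc_types <- c("rRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "scRNA")
  for (i in seq_len(nc)) {
    idx <- idx + 1
    s <- starts[idx]; e <- s + ncrna_len[i] - 1
    type <- nc_types[(i - 1) %% length(nc_types) + 1]
    src <- if (i %% 2 == 1) "GenBank" else "Rfam"
    add_feat(s, e, "+", type, src, sprintf("%s-%03d", tolower(type), i))
  }
  for (i in seq_len(nr)) {
    idx <- idx + 1
    s <- starts[idx]
    add_feat(s, s + rep_len[i] - 1, "+", "repeat", "sim",
             sprintf("rep-%03d", i))
  }
  for (i in seq_len(ng)) {
    idx <- idx + 1
    s <- starts[idx]
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("gene-%03d", i)
    add_feat(s, s + 149, strand, "exon", "sim", paste0(gid, "-ex1"), gid)
    add_feat(s + 150, s + 269, strand, "intron", "sim",
             paste0(gid, "-in1"), gid)
    add_feat(s + 270, s + 419, strand, "exon", "sim", paste0(gid, "-ex2"),
             gid)
  }

  genome <- paste(gchars, collapse = "")
  fdf <- if (length(feat)) do.call(rbind, feat) else
    data.frame(start = integer(0), end = integer(0), strand = character(0),
               type = character(0), source = character(0), ID = character(0),
               Parent = character(0))
  gr <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(start = fdf$start, end = fdf$end),
    strand = fdf$strand)
  S4Vectors::mcols(gr)$type <- fdf$type
  S4Vectors::mcols(gr)$source <- fdf$source
  S4Vectors::mcols(gr)$ID <- fdf$ID
  S4Vectors::mcols(gr)$Parent <- fdf$Parent

  tdf <- if (length(truth)) do.call(rbind, truth) else NULL
  truth_arms <- NULL
  if (!is.null(tdf)) {
    # per-arm true abundance: log-normal within the mixture budget,
    # 80/20 split between 5p and 3p arm
    known <- !tdf$hidden
    assign_tpm <- function(rows, budget, fcs) {
      n <- sum(rows)
      if (n == 0) return(NULL)
      base <- rlnorm(n, 0, 0.7)
      base <- base / sum(base) * budget
      w5 <- base * 0.8; w3 <- base * 0.2
      data.frame(
        mirna_id = rep(tdf$mirna_id[rows], 2),
        arm = rep(c("5p", "3p"), each = n),
        weight_a = c(w5, w3),
        log2_fc = rep(fcs, 2), stringsAsFactors = FALSE)
    }
    truth_arms <- rbind(
      assign_tpm(known, config$mix[["mirna"]], config$log2_fc),
      assign_tpm(!known, config$mix[["hidden"]], config$hidden_log2_fc))
    if (!is.null(truth_arms)) {
      truth_arms$weight_b <- truth_arms$weight_a * 2^truth_arms$log2_fc
      truth_arms$tpm_a <- truth_arms$weight_a * 1e6
      truth_arms$tpm_b <- truth_arms$weight_b * 1e6
      if (sum(truth_arms$weight_b) +
          sum(config$mix[c("ncrna", "genic", "dimer")]) > 1)
        stop("log2 fold changes inflate library B beyond total capacity; ",
             "reduce fold changes or the miRNA mixture fraction")
    }
  }

  out <- list(genome = c(chr1 = genome), features = gr,
              truth = tdf, truth_arms = truth_arms, config = config)
  class(out) <- "srna_sim"
  out
}

# sample a fragment (sequence, strandedness) from a feature interval
sample_fragment <- function(genome, start, end, len_range, sense_prob) {
  flen <- sample(seq(len_range[1], len_range[2]), 1)
  flen <- min(flen, end - start + 1)
  fs <- start + sample.int(end - start + 2 - flen, 1) - 1
  frag <- substr(genome, fs, fs + flen - 1)
  if (runif(1) >= sense_prob) frag <- revcomp(frag)
  frag
}

#' Simulate the two adapter-ligated FASTQ libraries
#'
#' Draws per-class read counts multinomially from the ground-truth weights
#' of `sim` (arms scaled by their true log2 fold change in library B, a
#' `noise` class absorbing the residual mass so expected miRNA counts equal
#' `library_size * TPM / 1e6` exactly), then emits 50-nt reads: insert +
#' 3' adapter + random filler, constant high base qualities. Noise inserts
#' are rejection-sampled to be absent from the genome on either strand so
#' they exercise the unmapped path deterministically; `dimer` reads are
#' adapter-only contaminants.
#'
#' @param sim result of [build_genome()].
#' @param config usually `sim$config`.
#' @return list of class `srna_sim_reads` with `reads` (list of two
#'   data.frames: `seq`, `qual`, `label`), `provenance` (per-class read
#'   counts per library) and `truth_arms` carried over from `sim`.
#' @export
simulate_libraries <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "srna_sim"))
  set.seed(config$seed + 1L)
  genome <- sim$genome[[1]]
  genome_rc <- revcomp(genome)
  arms <- sim$truth_arms
  feats <- sim$features
  type <- S4Vectors::mcols(feats)$type
  nc_idx <- which(type %in% c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA"))
  genic_idx <- which(type %in% c("repeat", "exon", "intron"))

  arm_seq <- character(0)
  if (!is.null(arms)) {
    key <- match(arms$mirna_id, sim$truth$mirna_id)
    arm_seq <- ifelse(arms$arm == "5p", sim$truth$seq_5p[key],
                      sim$truth$seq_3p[key])
  }
  n_arm <- length(arm_seq)
  classes <- c(if (n_arm) paste0(arms$mirna_id, "-", arms$arm),
               "ncrna", "genic", "noise", "dimer")

  weights <- function(lib) {
    wa <- if (n_arm) {
      if (lib == 1) arms$weight_a else arms$weight_b
    } else numeric(0)
    rest <- config$mix[c("ncrna", "genic", "dimer")]
    noise <- 1 - sum(wa) - sum(rest)
    if (noise < -1e-9)
      stop("mixture weights exceed 1 in library ", lib)
    c(wa, rest[["ncrna"]], rest[["genic"]], max(noise, 0), rest[["dimer"]])
  }

  lens <- as.integer(names(config$insert_length_dist))
  max_insert <- config$read_length - 6L   # keep a minimal adapter anchor
  n_rejected_long <- 0L

  draw_insert <- function(class_i, count) {
    if (count == 0) return(character(0))
    if (class_i <= n_arm) return(rep(arm_seq[class_i], count))
    cls <- classes[class_i]
    if (cls == "dimer") return(rep("", count))
    if (cls == "ncrna" || cls == "genic") {
      idx <- if (cls == "ncrna") nc_idx else genic_idx
      if (length(idx) == 0) return(rep("", 0))
      out <- character(count)
      for (r in seq_len(count)) {
        f <- idx[sample.int(length(idx), 1)]
        out[r] <- sample_fragment(
          genome, GenomicRanges::start(feats)[f],
          GenomicRanges::end(feats)[f],
          config$ncrna_frag_len_range, sense_prob = 0.9)
      }
      return(out)
    }
    # noise: random sequences guaranteed absent from both genome strands
    out <- character(count)
    for (r in seq_len(count)) {
      repeat {
        lr <- sample(lens, 1, prob = config$insert_length_dist)
        b <- strsplit(random_dna(lr), "")[[1]]
        if (runif(1) < config$first_base_u_prob) b[1] <- "T"
        cand <- paste(b, collapse = "")
        if (!grepl(cand, genome, fixed = TRUE) &&
            !grepl(cand, genome_rc, fixed = TRUE)) break
      }
      out[r] <- cand
    }
    out
  }

  make_lib <- function(lib) {
    N <- config$library_sizes[lib]
    if (N == 0)
      return(data.frame(seq = character(0), qual = character(0),
                        label = character(0), stringsAsFactors = FALSE))
    counts <- as.integer(rmultinom(1, N, weights(lib)))
    inserts <- character(0); labels <- character(0)
    for (ci in seq_along(classes)) {
      ins <- draw_insert(ci, counts[ci])
      too_long <- nchar(ins) > max_insert
      if (any(too_long)) {
        n_rejected_long <<- n_rejected_long + sum(too_long)
        warning(sum(too_long), " inserts longer than ", max_insert,
                " nt dropped (no adapter anchor)")
        ins <- ins[!too_long]
      }
      inserts <- c(inserts, ins)
      labels <- c(labels, rep(classes[ci], length(ins)))
    }
    fill_len <- pmax(config$read_length - nchar(inserts) -
                       nchar(config$adapter), 0)
    fill <- random_dna(fill_len)
    reads <- substr(paste0(inserts, config$adapter, fill), 1,
                    config$read_length)
    if (config$error_rate > 0) {
      for (r in seq_along(reads)) {
        pos <- which(runif(nchar(reads[r])) < config$error_rate)
        if (length(pos)) {
          ch <- strsplit(reads[r], "")[[1]]
          ch[pos] <- vapply(pos, function(p)
            sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1), character(1))
          reads[r] <- paste(ch, collapse = "")
        }
      }
    }
    ord <- sample.int(length(reads))
    data.frame(seq = reads[ord],
               qual = strrep("I", nchar(reads[ord])),
               label = labels[ord], stringsAsFactors = FALSE)
  }

  libs <- list(make_lib(1), make_lib(2))
  prov <- lapply(libs, function(l) table(factor(l$label, levels = classes)))
  out <- list(reads = libs, provenance = prov, truth_arms = arms,
              n_rejected_long = n_rejected_long, config = config)
  class(out) <- "srna_sim_reads"
  out
}

#' Write a simulated experiment to disk
#'
#' Emits the genome FASTA, the feature GFF3 (1-based inclusive), the two
#' FASTQ libraries (Sanger +33 qualities) and the ground-truth TSV.
#'
#' @param sim result of [build_genome()].
#' @param reads result of [simulate_libraries()] (optional; skipped if NULL).
#' @param outdir output directory, created if needed.
#' @return named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, reads = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             features = file.path(outdir, "features.gff3"),
             truth = file.path(outdir, "truth.tsv"))
  gen <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(gen, paths[["genome"]])
  export_gff3(sim$features, paths[["features"]])
  write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(reads)) {
    for (i in 1:2) {
      p <- file.path(outdir, sprintf("lib%d.fastq", i))
      write_fastq(reads$reads[[i]]$seq, reads$reads[[i]]$qual, p)
      paths[[sprintf("fastq%d", i)]] <- p
    }
  }
  invisible(paths)
}

#' Simulate a two-library count table at the count level
#'
#' A fast path through the same multinomial sampling machinery as
#' [simulate_libraries()], skipping read construction: expected counts per
#' miRNA are `library_size * weight`, with library-B weights scaled by the
#' true log2 fold change and a residual class absorbing the remainder so
#' the configured fold changes are exact in expectation. Used for power /
#' false-discovery simulations of the differential expression stage.
#'
#' @param mean_counts expected counts per miRNA in library A.
#' @param log2_fc true per-miRNA log2 fold changes (B vs A).
#' @param library_size reads per library (the same for both).
#' @param seed RNG seed.
#' @return data.frame with `mirna_id`, `true_log2_fc`, `count_a`,
#'   `count_b`, and attributes `total_a`, `total_b` (= `library_size`).
#' @export
simulate_count_table <- function(mean_counts, log2_fc,
                                 library_size = 1e6, seed = 1) {
  stopifnot(length(mean_counts) == length(log2_fc))
  set.seed(seed)
  wa <- mean_counts / library_size
  wb <- wa * 2^log2_fc
  if (sum(wa) > 1 || sum(wb) > 1)
    stop("expected counts exceed library size")
  ca <- as.integer(rmultinom(1, library_size, c(wa, 1 - sum(wa))))
  cb <- as.integer(rmultinom(1, library_size, c(wb, 1 - sum(wb))))
  n <- length(mean_counts)
  out <- data.frame(
    mirna_id = sprintf("sim-mir-%03d", seq_len(n)),
    true_log2_fc = log2_fc,
    count_a = ca[seq_len(n)], count_b = cb[seq_len(n)])
  attr(out, "total_a") <- library_size
  attr(out, "total_b") <- library_size
  out
}

#' Simulate 3'UTR sequences with planted miRNA target sites
#'
#' Generates random UTRs and embeds canonical 8mer seed sites (reverse
#' complement of miRNA positions 2--8 followed by an A) for chosen
#' miRNA/gene pairs, for testing the consensus target-prediction stage.
#'
#' @param mirnas named character vector of mature miRNA sequences (DNA).
#' @param n_genes number of UTRs.
#' @param utr_len UTR length.
#' @param planted data.frame with columns `mirna_id`, `gene_id` naming the
#'   pairs to receive a site, or NULL.
#' @param seed RNG seed.
#' @return named character vector of UTR sequences (names `gene-0001`...).
#' @export
simulate_utrs <- function(mirnas, n_genes = 50, utr_len = 300,
                          planted = NULL, seed = 1) {
  set.seed(seed)
  genes <- sprintf("gene-%04d", seq_len(n_genes))
  utrs <- setNames(random_dna(rep(utr_len, n_genes)), genes)
  if (!is.null(planted)) {
    for (r in seq_len(nrow(planted))) {
      m <- mirnas[[planted$mirna_id[r]]]
      site <- paste0(revcomp(substr(m, 2, 8)), "A")
      pos <- sample.int(utr_len - nchar(site) - 20, 1) + 10
      g <- planted$gene_id[r]
      substr(utrs[[g]], pos, pos + nchar(site) - 1) <- site
    }
  }
  utrs
}

#' Simulate a gene-to-term annotation map
#'
#' Random term assignments over a gene universe (1--4 terms per gene),
#' for testing the hypergeometric enrichment stage.
#'
#' @param genes gene universe.
#' @param n_terms number of terms.
#' @param seed RNG seed.
#' @return data.frame with columns `gene_id`, `term_id`, `term_name`.
#' @export
simulate_term_map <- function(genes, n_terms = 20, seed = 1) {
  set.seed(seed)
  terms <- sprintf("TERM:%04d", seq_len(n_terms))
  rows <- lapply(genes, function(g) {
    k <- sample(1:4, 1)
    data.frame(gene_id = g, term_id = sample(terms, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$term_name <- sub("TERM:", "process ", out$term_id)
  out
}
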