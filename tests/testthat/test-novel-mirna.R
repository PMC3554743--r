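empty_features <- function() {
  feats <- GenomicRanges::GRanges()
  S4Vectors::mcols(feats)$type <- character(0)
  S4Vectors::mcols(feats)$source <- character(0)
  S4Vectors::mcols(feats)$ID <- character(0)
  S4Vectors::mcols(feats)$Parent <- character(0)
  feats
}

# builds a small genome with one planted hairpin and a hand-set read stack
hairpin_scene <- function(seed = 5, counts5 = c(80L, 60L),
                          counts3 = c(20L, 15L)) {
  set.seed(seed)
  g <- srnapipe:::random_dna(600)
  arm5 <- paste0("T", srnapipe:::random_dna(20), "A")
  hp <- paste0(arm5, srnapipe:::random_dna(8), srnapipe:::revcomp(arm5))
  substr(g, 201, 200 + nchar(hp)) <- hp
  arm3 <- srnapipe:::revcomp(arm5)
  tags <- data.frame(sequence = c(arm5, arm3),
                     count_A = c(counts5[1], counts3[1]),
                     count_B = c(counts5[2], counts3[2]))
  hits <- map_tags(tags, c(chr1 = g))
  ann <- assign_category(tags, hits, empty_features())
  list(genome = c(chr1 = g), tags = tags, hits = hits, ann = ann,
       hairpin = c(201L, 200L + nchar(hp)))
}

test_that("clustering merges nearby same-strand hits and splits strands", {
  ann <- data.frame(sequence = c("t1", "t2", "t3"),
                    count_A = c(5L, 5L, 5L), count_B = c(1L, 1L, 1L),
                    category = factor(rep("unannotated", 3),
                                      levels = srnapipe:::CATEGORY_LEVELS),
                    feature_id = NA, feature_type = NA, n_hits = 1L)
  hits <- data.frame(sequence = c("t1", "t2", "t3"), chrom = "chr1",
                     start = c(100L, 127L, 100L), end = c(121L, 148L, 121L),
                     strand = c("+", "+", "-"))
  cl <- cluster_unannotated(ann, hits, merge_distance = 10)
  # gap t1-t2 is 5 bp: merged; the minus-strand hit is its own cluster
  expect_identical(length(cl), 2L)
  plus <- cl[[which(vapply(cl, `[[`, "", "strand") == "+")]]
  expect_identical(c(plus$start, plus$end), c(100L, 148L))

  # same positions, opposite strands stay apart even at zero gap
  hits2 <- hits[c(1, 3), ]
  cl2 <- cluster_unannotated(ann, hits2, merge_distance = 10)
  expect_identical(length(cl2), 2L)
})

test_that("clustering agrees with a brute-force interval merge", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    starts <- sort(sample.int(2000, n))
    ends <- starts + sample(18:30, n, replace = TRUE) - 1L
    ann <- data.frame(sequence = paste0("t", seq_len(n)),
                      count_A = 1L, count_B = 1L,
                      category = factor(rep("unannotated", n),
                                        levels = srnapipe:::CATEGORY_LEVELS),
                      feature_id = NA, feature_type = NA, n_hits = 1L)
    hits <- data.frame(sequence = ann$sequence, chrom = "chr1",
                       start = starts, end = ends, strand = "+")
    gap <- sample(0:15, 1)
    cl <- cluster_unannotated(ann, hits, merge_distance = gap)
    got <- t(vapply(cl, function(x) c(x$start, x$end), integer(2)))
    expected <- merge_oracle(starts, ends, gap)
    expect_identical(got[order(got[, 1]), , drop = FALSE],
                     matrix(as.integer(expected), ncol = 2))
  }
})

test_that("precursor windows cover the planted stem-loop and clip bounds", {
  sc <- hairpin_scene()
  cl <- cluster_unannotated(sc$ann, sc$hits)
  plus <- cl[[which(vapply(cl, `[[`, "", "strand") == "+")]]
  wins <- extract_precursor(plus, sc$genome, 70, 70)
  hp_seq <- substr(sc$genome[[1]], sc$hairpin[1], sc$hairpin[2])
  expect_true(any(vapply(wins$sequence, grepl, TRUE, pattern = hp_seq,
                         fixed = TRUE)))
  # zero flanks give exactly the cluster span
  w0 <- extract_precursor(plus, sc$genome, 0, 0)
  expect_true(all(w0$win_start == plus$start & w0$win_end == plus$end))
  # a cluster at the chromosome start is clipped at base 1
  near <- list(chrom = "chr1", start = 5L, end = 26L, strand = "+",
               hits = NULL)
  wn <- extract_precursor(near, sc$genome, 70, 70)
  expect_true(all(wn$win_start >= 1))
})

test_that("Dicer 5'-end homogeneity is the weighted modal fraction", {
  h <- data.frame(sequence = c("a", "b"), chrom = "chr1",
                  start = c(100L, 100L), end = c(121L, 123L),
                  strand = "+", count_A = c(10L, 5L), count_B = c(5L, 0L))
  d <- dicer_consistency(h)
  expect_equal(d$fraction, 1)        # same 5' start
  expect_true(d$pass)

  h2 <- h; h2$start <- c(100L, 110L)
  d2 <- dicer_consistency(h2)
  expect_equal(d2$fraction, 15 / 20)
  h3 <- h2; h3$count_A <- c(10L, 10L); h3$count_B <- c(0L, 0L)
  d3 <- dicer_consistency(h3)
  expect_equal(d3$fraction, 0.5)
  expect_false(d3$pass)

  # simulated ragged stack 80/20
  h4 <- h2; h4$count_A <- c(80L, 20L); h4$count_B <- c(0L, 0L)
  expect_equal(dicer_consistency(h4)$fraction, 0.8)
  expect_true(dicer_consistency(h4)$pass)
})

test_that("a planted hairpin is called and all gates behave", {
  sc <- hairpin_scene()
  nv <- call_novel(sc$ann, sc$hits, sc$genome, totals = c(1e5, 1e5))
  expect_gt(nrow(nv), 0)
  expect_true(any(nv$verdict))
  called <- nv[nv$verdict, ][1, ]
  expect_lt(called$mfe, -20)
  expect_gte(called$dicer_fraction, 0.7)
  # verdict is exactly the conjunction of the four criteria flags
  expect_identical(nv$verdict, nv$hairpin_shape & nv$mfe_pass &
                     nv$dicer_pass & nv$expression_pass)
  # mfe_pass is strict at -20
  expect_identical(nv$mfe_pass, nv$mfe < -20)
  # called ids are assigned by descending total count
  ids <- nv$novel_id[!is.na(nv$novel_id)]
  expect_identical(ids[1], "novel-miR-1")
})

test_that("the 1-TPM-in-both-samples gate is inclusive and switchable", {
  # counts chosen so library A sits exactly at 1 TPM
  sc <- hairpin_scene(counts5 = c(80L, 60L), counts3 = c(20L, 15L))
  # cluster counts are A = 100, B = 75, so totals of 1e8 put library A
  # at exactly 1 TPM
  nv <- call_novel(sc$ann, sc$hits, sc$genome, totals = c(1e8, 1e5))
  plus <- nv[nv$strand == "+", ][1, ]
  expect_equal(plus$tpm_A, 1)
  expect_true(plus$expression_pass)   # exactly 1 TPM passes

  # below 1 TPM in one library fails unless both-sample rule is relaxed
  nv2 <- call_novel(sc$ann, sc$hits, sc$genome, totals = c(2e8, 1e5))
  plus2 <- nv2[nv2$strand == "+", ][1, ]
  expect_false(plus2$expression_pass)
  nv3 <- call_novel(sc$ann, sc$hits, sc$genome, totals = c(2e8, 1e5),
                    require_both_samples = FALSE)
  expect_true(nv3[nv3$strand == "+", ][1, ]$expression_pass)
})

test_that("weak AT-only stems fail the energy gate", {
  # a poly-C background contributes no pairing, so the window MFE is the
  # weak A/U stem alone
  g <- strrep("C", 500)
  arm <- paste0(strrep("T", 7), strrep("A", 7), strrep("T", 4))  # 18 nt A/T
  hp <- paste0(arm, "CCCCCCCC", srnapipe:::revcomp(arm))
  substr(g, 151, 150 + nchar(hp)) <- hp
  tags <- data.frame(sequence = c(arm, srnapipe:::revcomp(arm)),
                     count_A = c(50L, 10L), count_B = c(50L, 10L))
  hits <- map_tags(tags, c(chr1 = g))
  ann <- assign_category(tags, hits, empty_features())
  nv <- call_novel(ann, hits, c(chr1 = g), totals = c(1e5, 1e5))
  expect_gt(nrow(nv), 0)
  expect_false(any(nv$mfe_pass))
  expect_false(any(nv$verdict))
})

test_that("hidden hairpins are recovered without touching the annotation", {
  cfg <- small_config(seed = 29)
  sim <- build_genome(cfg)
  reads <- simulate_libraries(sim)
  cls <- lapply(reads$reads, function(r) clean_reads(r$seq, r$qual))
  totals <- vapply(cls, function(x) length(x$inserts), integer(1))
  tags <- collapse_tags(cls[[1]]$inserts, cls[[2]]$inserts)
  hits <- map_tags(tags, sim$genome)
  ann <- assign_category(tags, hits, sim$features)
  nv <- call_novel(ann, hits, sim$genome, totals)
  called <- nv[nv$verdict, ]
  hid <- sim$truth[sim$truth$hidden, ]
  recovered <- vapply(seq_len(nrow(hid)), function(i)
    any(called$start <= hid$prec_end[i] &
          called$end >= hid$prec_start[i]), logical(1))
  expect_true(all(recovered))
  # and no call overlaps any annotated feature
  fs <- GenomicRanges::start(sim$features)
  fe <- GenomicRanges::end(sim$features)
  for (r in seq_len(nrow(called)))
    expect_false(any(called$start[r] <= fe & called$end[r] >= fs))
})
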