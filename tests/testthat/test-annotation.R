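make_feats <- function(start, end, strand, type, source = "sim",
                       id = paste0(type, "-1"), parent = NA) {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$ID <- id
  S4Vectors::mcols(gr)$Parent <- parent
  gr
}

test_that("exact mapping finds plus, minus and palindromic hits", {
  set.seed(8)
  g <- srnapipe:::random_dna(3000)
  tag_plus <- substr(g, 101, 122)
  tag_minus <- srnapipe:::revcomp(substr(g, 501, 522))
  half <- srnapipe:::random_dna(11)
  palin <- paste0(half, srnapipe:::revcomp(half))
  g <- paste0(g, palin)  # planted once at the end
  hits <- map_tags(c(tag_plus, tag_minus, palin), c(chr1 = g))

  hp <- hits[hits$sequence == tag_plus, ]
  expect_true(any(hp$start == 101 & hp$strand == "+"))
  hm <- hits[hits$sequence == tag_minus, ]
  expect_true(any(hm$start == 501 & hm$strand == "-"))
  # palindrome: same locus on both strands
  hpal <- hits[hits$sequence == palin, ]
  expect_identical(nrow(hpal), 2L)
  expect_setequal(hpal$strand, c("+", "-"))
})

test_that("mapping agrees with a brute-force scan of the genome string", {
  set.seed(9)
  g <- srnapipe:::random_dna(2000)
  tags <- c(substr(g, 50, 71), substr(g, 900, 921),
            srnapipe:::revcomp(substr(g, 1500, 1521)),
            srnapipe:::random_dna(rep(22, 5)))
  hits <- map_tags(tags, c(chr1 = g))
  rc <- srnapipe:::revcomp(g)
  n <- nchar(g)
  for (tg in tags) {
    fwd <- gregexpr(tg, g, fixed = TRUE)[[1]]
    fwd <- fwd[fwd > 0]
    rev_rc <- gregexpr(tg, rc, fixed = TRUE)[[1]]
    rev_rc <- rev_rc[rev_rc > 0]
    rev_start <- sort(n - (rev_rc + nchar(tg) - 1) + 1)
    h <- hits[hits$sequence == tg, ]
    expect_identical(sort(h$start[h$strand == "+"]), as.integer(sort(fwd)),
                     label = tg)
    expect_identical(sort(h$start[h$strand == "-"]),
                     as.integer(rev_start), label = tg)
  }
  # a tag containing N never maps
  expect_identical(nrow(map_tags("ACGTNACGTACGTACGTACGTA", c(chr1 = g))),
                   0L)
})

test_that("priority rule picks the highest category over all overlaps", {
  set.seed(10)
  g <- srnapipe:::random_dna(1000)
  tag <- substr(g, 101, 122)
  tags <- data.frame(sequence = tag, count_A = 3L, count_B = 1L)
  hits <- map_tags(tags, c(chr1 = g))

  # rRNA (GenBank) beats a co-located mature miRNA
  feats <- c(make_feats(90, 140, "+", "rRNA", "GenBank", "rrna-1"),
             make_feats(95, 150, "+", "mature_miRNA", "sim", "mir-1-5p",
                        "mir-1"))
  ann <- assign_category(tags, hits, feats)
  expect_identical(as.character(ann$category), "rRNA_etc_genbank")
  expect_identical(ann$feature_id, "rrna-1")

  # Rfam loses to GenBank but beats known miRNA
  feats2 <- c(make_feats(90, 140, "+", "snoRNA", "Rfam", "sno-1"),
              make_feats(95, 150, "+", "mature_miRNA", "sim", "mir-1-5p",
                         "mir-1"))
  expect_identical(
    as.character(assign_category(tags, hits, feats2)$category),
    "rRNA_etc_rfam")

  # exon on the sense strand beats intron overlap on the antisense strand
  feats3 <- c(make_feats(90, 140, "+", "exon", "sim", "ex-1"),
              make_feats(95, 150, "-", "intron", "sim", "in-1"))
  expect_identical(
    as.character(assign_category(tags, hits, feats3)$category),
    "exon_sense")

  # miRNA overlap requires the same strand
  feats4 <- make_feats(90, 140, "-", "mature_miRNA", "sim", "mir-1-5p",
                       "mir-1")
  expect_identical(
    as.character(assign_category(tags, hits, feats4)$category),
    "unannotated")

  # mapped tag with no features at all is unannotated; unmappable tag is
  # unmapped
  tags2 <- data.frame(sequence = c(tag, strrep("ACGT", 6)),
                      count_A = c(1L, 1L), count_B = c(0L, 0L))
  hits2 <- map_tags(tags2, c(chr1 = g))
  ann2 <- assign_category(tags2, hits2, feats[0])
  expect_identical(as.character(ann2$category[1]), "unannotated")
})

test_that("category counts partition the tags in both spaces", {
  cfg <- small_config(seed = 19)
  sim <- build_genome(cfg)
  reads <- simulate_libraries(sim)
  cls <- lapply(reads$reads, function(r) clean_reads(r$seq, r$qual))
  tags <- collapse_tags(cls[[1]]$inserts, cls[[2]]$inserts)
  hits <- map_tags(tags, sim$genome)
  ann <- assign_category(tags, hits, sim$features)
  cc <- category_counts(ann)
  expect_identical(sum(cc$unique_tags), nrow(tags))
  expect_identical(sum(cc$reads_A), sum(tags$count_A))
  expect_identical(sum(cc$reads_B), sum(tags$count_B))
  expect_equal(sum(cc$unique_fraction), 1)

  # no unannotated tag overlaps any feature: brute-force interval scan
  # (in this simulation the unannotated pool is exactly the hidden
  # hairpin arms, whose loci carry no annotation at all)
  un <- ann$sequence[ann$category == "unannotated"]
  expect_gt(length(un), 0)
  fs <- GenomicRanges::start(sim$features)
  fe <- GenomicRanges::end(sim$features)
  hu <- hits[hits$sequence %in% un, ]
  for (r in seq_len(nrow(hu)))
    expect_false(any(hu$start[r] <= fe & hu$end[r] >= fs))

  # exon sense:antisense unique-tag ratio matches a direct count oracle
  n_sense <- sum(ann$category == "exon_sense")
  n_anti <- sum(ann$category == "exon_antisense")
  if (n_anti > 0)
    expect_identical(exon_strand_ratio(ann), round(n_sense / n_anti))
})

test_that("known-miRNA quantification recovers the planted ground truth", {
  cfg <- small_config(seed = 23)
  sim <- build_genome(cfg)
  reads <- simulate_libraries(sim)
  cls <- lapply(reads$reads, function(r) clean_reads(r$seq, r$qual))
  totals <- vapply(cls, function(x) length(x$inserts), integer(1))
  tags <- collapse_tags(cls[[1]]$inserts, cls[[2]]$inserts)
  hits <- map_tags(tags, sim$genome)
  q <- quantify_known(tags, hits, sim$features, totals)
  # no-error simulation: recovered counts equal per-class read provenance
  for (lib in 1:2) {
    prov <- reads$provenance[[lib]]
    cnt <- if (lib == 1) q$count_A else q$count_B
    for (r in seq_len(nrow(q))) {
      expect_identical(cnt[r], as.integer(prov[[q$mirna_id[r]]]),
                       label = paste(q$mirna_id[r], "lib", lib))
    }
  }
  expect_equal(q$tpm_A, q$count_A / totals[1] * 1e6)
})

test_that("isomiR tolerance accepts small 5'-end shifts only", {
  set.seed(30)
  g <- srnapipe:::random_dna(500)
  prec_start <- 101L
  arm <- substr(g, prec_start, prec_start + 21)
  feats <- c(make_feats(prec_start, prec_start + 51, "+",
                        "miRNA_precursor", "sim", "mir-1"),
             make_feats(prec_start, prec_start + 21, "+", "mature_miRNA",
                        "sim", "mir-1-5p", "mir-1"))
  shift2 <- substr(g, prec_start + 2, prec_start + 23)  # within precursor
  shift3 <- substr(g, prec_start + 3, prec_start + 24)
  tags <- data.frame(sequence = c(arm, shift2, shift3),
                     count_A = c(40L, 5L, 7L), count_B = c(0L, 0L, 0L))
  hits <- map_tags(tags, c(chr1 = g))
  q <- quantify_known(tags, hits, feats, totals = c(1e6, 1e6), tol = 2)
  expect_identical(q$count_A[q$mirna_id == "mir-1-5p"], 45L)
})

test_that("the rRNA quality mark fails at 40% and passes below", {
  ann <- data.frame(sequence = c("a", "b"), count_A = c(39L, 61L),
                    count_B = c(40L, 60L),
                    category = factor(c("rRNA_etc_genbank", "unannotated"),
                                      levels = srnapipe:::CATEGORY_LEVELS),
                    feature_id = c("rrna-1", NA),
                    feature_type = c("rRNA", NA), n_hits = c(1L, 1L))
  qc <- qc_rrna_fraction(ann)
  expect_true(qc$pass[qc$library == "A"])    # 39%: pass
  expect_false(qc$pass[qc$library == "B"])   # exactly 40%: fail
  ann0 <- ann
  ann0$count_A <- c(0L, 100L); ann0$count_B <- c(0L, 50L)
  qc0 <- qc_rrna_fraction(ann0)
  expect_true(all(qc0$pass))
  expect_equal(qc0$fraction, c(0, 0))
})

test_that("GFF3 round trip preserves types, sources, ids and coordinates", {
  sim <- build_genome(small_config(seed = 31))
  tmp <- tempfile(fileext = ".gff3")
  export_gff3(sim$features, tmp)
  back <- import_gff3(tmp)
  expect_identical(length(back), length(sim$features))
  expect_identical(S4Vectors::mcols(back)$type,
                   S4Vectors::mcols(sim$features)$type)
  expect_identical(S4Vectors::mcols(back)$source,
                   S4Vectors::mcols(sim$features)$source)
  expect_identical(GenomicRanges::start(back),
                   GenomicRanges::start(sim$features))
  expect_identical(S4Vectors::mcols(back)$ID,
                   S4Vectors::mcols(sim$features)$ID)
})
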