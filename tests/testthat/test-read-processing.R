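ADAPTER <- "TCGTATGCCGTCTTCTGCTTGT"

test_that("the 3' adapter is trimmed off a standard read", {
  insert <- "TGAGGTAGTAGGTTGTATAGTT"   # 22 nt
  read <- substr(paste0(insert, ADAPTER, strrep("A", 20)), 1, 50)
  tr <- trim_adapter(read, ADAPTER)
  expect_identical(as.character(tr$status), "trimmed")
  expect_identical(tr$insert, insert)
})

test_that("adapter-only reads are rejected as adapter-dimer contaminants", {
  read <- substr(paste0(ADAPTER, ADAPTER, strrep("G", 10)), 1, 50)
  tr <- trim_adapter(read, ADAPTER)
  expect_identical(as.character(tr$status), "dimer")
  expect_identical(tr$insert, "")
  # and a read with no adapter at all is rejected
  tr2 <- trim_adapter(strrep("A", 50), ADAPTER)
  expect_identical(as.character(tr2$status), "no_adapter")
})

test_that("every single-mismatch adapter variant is still recovered", {
  insert <- "TGAGGTAGTAGGTTGTATAGTT"
  for (pos in seq_len(nchar(ADAPTER))) {
    for (b in setdiff(c("A", "C", "G", "T"),
                      substr(ADAPTER, pos, pos))) {
      bad <- ADAPTER
      substr(bad, pos, pos) <- b
      read <- substr(paste0(insert, bad, strrep("C", 20)), 1, 50)
      tr <- trim_adapter(read, ADAPTER, max_mismatch_rate = 0.1)
      expect_identical(tr$insert, insert,
                       label = sprintf("mismatch at %d", pos))
    }
  }
})

test_that("length filter keeps exactly the 18-30 nt window", {
  lens <- 15:35
  ins <- vapply(lens, function(L) strrep("A", L), character(1))
  lf <- length_filter(ins)
  expect_identical(sort(nchar(lf$kept)), 18:30)
  expect_identical(lf$n_short, 3L)
  expect_identical(lf$n_long, 5L)
  expect_equal(length(lf$kept) / length(ins), 13 / 21)
})

test_that("collapsing counts per-library occurrences and conserves reads", {
  tt <- collapse_tags(c("AAACCCGGGTTTAAACCCGGGT", "AAACCCGGGTTTAAACCCGGGT",
                        "TTTTTTTTTTTTTTTTTTTTTT"),
                      c("TTTTTTTTTTTTTTTTTTTTTT"))
  expect_identical(nrow(tt), 2L)
  row1 <- tt[tt$sequence == "AAACCCGGGTTTAAACCCGGGT", ]
  expect_identical(c(row1$count_A, row1$count_B), c(2L, 0L))
  row2 <- tt[tt$sequence == "TTTTTTTTTTTTTTTTTTTTTT", ]
  expect_identical(c(row2$count_A, row2$count_B), c(1L, 1L))

  # 1000 reads drawn from 10 sequences: at most 10 tags, totals conserved
  set.seed(1)
  pool <- srnapipe:::random_dna(rep(22, 10))
  a <- sample(pool, 600, replace = TRUE)
  b <- sample(pool, 400, replace = TRUE)
  tt2 <- collapse_tags(a, b)
  expect_lte(nrow(tt2), 10)
  expect_identical(sum(tt2$count_A), 600L)
  expect_identical(sum(tt2$count_B), 400L)
  # round trip reproduces the multisets
  ex <- expand_tags(tt2)
  expect_identical(sort(ex$inserts_A), sort(a))
  expect_identical(sort(ex$inserts_B), sort(b))
})

test_that("cleaning conserves reads across all rejection classes", {
  cfg <- small_config(seed = 13)
  reads <- simulate_libraries(build_genome(cfg))
  for (i in 1:2) {
    cl <- clean_reads(reads$reads[[i]]$seq, reads$reads[[i]]$qual)
    lg <- cl$log
    expect_identical(lg[["reads_in"]],
                     lg[["low_quality"]] + lg[["adapter_dimer"]] +
                       lg[["no_adapter"]] + lg[["with_n"]] +
                       lg[["too_short"]] + lg[["too_long"]] +
                       lg[["retained"]])
    expect_identical(length(cl$inserts), lg[["retained"]])
    expect_true(all(nchar(cl$inserts) >= 18 & nchar(cl$inserts) <= 30))
  }
})

test_that("low-quality reads are dropped by the quality gate", {
  good <- strrep("I", 50)
  bad <- paste0(strrep("I", 10), "#", strrep("I", 39))   # Q2 at cycle 11
  late <- paste0(strrep("I", 40), "#", strrep("I", 9))   # beyond cycle 36
  expect_identical(quality_filter(c(good, bad, late)),
                   c(TRUE, FALSE, TRUE))
})

test_that("library sharing fractions behave and sum to one", {
  one <- data.frame(sequence = strrep("ACGT", 5), count_A = 2L,
                    count_B = 2L)
  s1 <- summarize_library(one)
  expect_equal(unname(s1$sharing["unique_common"]), 1)
  expect_equal(unname(s1$sharing["total_common"]), 1)

  two <- data.frame(sequence = c(strrep("AC", 10), strrep("GT", 10)),
                    count_A = c(1L, 0L), count_B = c(0L, 1L))
  s2 <- summarize_library(two)
  expect_equal(unname(s2$sharing["unique_common"]), 0)
  expect_equal(unname(s2$sharing["unique_specific_A"]), 0.5)
  expect_equal(unname(s2$sharing["unique_specific_B"]), 0.5)

  set.seed(4)
  pool <- srnapipe:::random_dna(rep(20, 30))
  tt <- collapse_tags(sample(pool, 200, TRUE), sample(pool, 150, TRUE))
  s3 <- summarize_library(tt)
  expect_equal(sum(s3$sharing[1:3]), 1)
  expect_equal(sum(s3$sharing[4:6]), 1)
  # histogram sums to total reads
  expect_identical(sum(s3$library_A$length_histogram),
                   s3$library_A$total_reads)
  expect_identical(s3$library_A$total_reads, 200L)
})

test_that("an empty tag table yields an all-zero summary with a warning", {
  tt <- collapse_tags(character(0), character(0))
  expect_warning(s <- summarize_library(tt), "empty")
  expect_identical(s$library_A$total_reads, 0L)
  expect_true(all(s$sharing == 0))
})

test_that("the simulated length profile peaks at 22 nt", {
  cfg <- small_config(seed = 17)
  reads <- simulate_libraries(build_genome(cfg))
  cl <- clean_reads(reads$reads[[1]]$seq, reads$reads[[1]]$qual)
  tt <- collapse_tags(cl$inserts, character(0))
  s <- summarize_library(tt)
  h <- s$library_A$length_histogram
  expect_identical(names(which.max(h)), "22")
})

test_that("tag FASTA round-trips through the countA_countB headers", {
  tt <- collapse_tags(c("ACGTACGTACGTACGTACGTAA", "ACGTACGTACGTACGTACGTAA"),
                      c("TTGGCCAATTGGCCAATTGGCA"))
  tmp <- tempfile(fileext = ".fa")
  write_tag_fasta(tt, tmp)
  back <- read_tag_fasta(tmp)
  expect_identical(back$sequence, tt$sequence)
  expect_identical(back$count_A, tt$count_A)
  expect_identical(back$count_B, tt$count_B)
})
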