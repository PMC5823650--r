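test_that("guide index applies exact, neighborhood and tie rules", {
  lib <- toy_library()
  idx0 <- build_guide_index(lib, max_mismatch = 0L)
  idx1 <- build_guide_index(lib, max_mismatch = 1L)
  expect_equal(lookup_guides(idx0, "AAAAAAAA")$hairpin_id, "h1")
  # one substitution away: unmapped at mm0, rescued at mm1
  expect_equal(lookup_guides(idx0, "AAAAACAA")$status, "unmapped")
  expect_equal(lookup_guides(idx1, "AAAAACAA")$hairpin_id, "h1")
  # within one mismatch of two guides: ambiguous
  expect_equal(lookup_guides(idx1, "AAAAAAAC")$status, "ambiguous")
  # an exact hit wins its stratum even near another guide
  expect_equal(lookup_guides(idx1, "AAAAAAAT")$hairpin_id, "h2")
  expect_equal(lookup_guides(idx1, "GGGGGGGG")$status, "unmapped")
  dup <- lib; dup$guide[2] <- dup$guide[1]
  expect_error(build_guide_index(dup), "duplicate guide")
})

test_that("read preprocessing extracts guides and labels discards", {
  ad <- "ACGT"
  q30 <- strrep("?", 16)  # Phred 30
  pp <- preprocess_reads(paste0(ad, "AAAAAAAA", "TTTT"), q30, ad, 8)
  expect_equal(pp$guide, "AAAAAAAA")
  expect_true(is.na(pp$reason))
  # no adapter anywhere
  pp <- preprocess_reads("TTTTTTTTTTTTTTTT", q30, ad, 8)
  expect_equal(pp$reason, "no_adapter")
  # mean Phred 12 ('-') below the default floor of 20
  pp <- preprocess_reads(paste0(ad, "AAAAAAAA", "TTTT"), strrep("-", 16),
                         ad, 8, min_mean_quality = 20)
  expect_equal(pp$reason, "low_quality")
  # adapter present but read ends before a full guide
  pp <- preprocess_reads(paste0(ad, "AAAA"), strrep("?", 8), ad, 8)
  expect_equal(pp$reason, "no_adapter")
})

test_that("a single hairpin's counts become exactly its reads", {
  lib <- toy_library()
  cnt <- tibble::tibble(hairpin_id = lib$hairpin_id, s1 = c(5L, 0L, 0L))
  d <- withr::local_tempdir()
  emit_fastq(cnt, lib, d, adapter = "ACGT", read_length = 20, seed = 1)
  rec <- read_fastq_records(file.path(d, "s1.fastq"))
  expect_equal(nrow(rec), 5)
  expect_true(all(startsWith(rec$seq, paste0("ACGT", "AAAAAAAA"))))
  expect_true(all(nchar(rec$seq) == 20))
})

test_that("junk injection matches its binomial expectation and the ledger", {
  sim <- tiny_screen(seq_depth_per_sample = 1000, replicates_per_arm = 1L)
  d <- withr::local_tempdir()
  man <- emit_fastq(sim$counts, sim$library, d, junk_fraction = 0.1,
                    read_length = 40, seed = 9)
  expect_equal(man$n_records, man$n_true + man$n_junk)
  # ~ n_true * 0.1/0.9 junk reads; allow 4 sigma around the expectation
  expected <- man$n_true * 0.1 / 0.9
  expect_true(all(abs(man$n_junk - expected) <
                    4 * sqrt(man$n_true * (0.1 / 0.9)) + 4))
  cr <- count_reads(man, sim$library, adapter = default_adapter())
  rep <- cr$report
  expect_equal(rep$total_reads, man$n_records)
  expect_equal(rep$discarded_no_adapter, man$n_junk)
  expect_equal(rep$total_reads,
               rep$discarded_no_adapter + rep$discarded_low_quality +
                 rep$unmapped + rep$ambiguous + rep$mapped)
})

test_that("emit then count is the identity on counts", {
  sim <- tiny_screen(seq_depth_per_sample = 2000)
  d <- withr::local_tempdir()
  for (junk in c(0, 0.1)) {
    man <- emit_fastq(sim$counts, sim$library, file.path(d, paste0("j", junk)),
                      junk_fraction = junk, read_length = 45, seed = 13)
    cr <- count_reads(man, sim$library)
    got <- counts_matrix(cr$counts)
    want <- counts_matrix(sim$counts)[rownames(got), , drop = FALSE]
    expect_identical(got, want)
  }
})

test_that("read order within a FASTQ does not change counts", {
  sim <- tiny_screen(n_genes = 10, seq_depth_per_sample = 500,
                     replicates_per_arm = 1L)
  d <- withr::local_tempdir()
  man <- emit_fastq(sim$counts, sim$library, d, read_length = 40, seed = 2)
  before <- count_reads(man, sim$library)$counts
  path <- man$path[1]
  rec <- read_fastq_records(path)
  withr::with_seed(4, perm <- sample.int(nrow(rec)))
  writeLines(rbind(rec$id[perm], rec$seq[perm], "+", rec$qual[perm]), path)
  after <- count_reads(man, sim$library)$counts
  expect_equal(before, after)
})

test_that("missing FASTQ files are reported by sample", {
  expect_error(count_reads(c(sA = "/nonexistent/sA.fastq"), toy_library()),
               "sA")
})
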