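test_that("barcode quality rule matches the stated thresholds case by case", {
  mk <- function(scores) read_tbl("ACGTACGTACGTACG", qual_string(c(scores, rep(30, 6))))
  # all nine prefix scores exactly 20: both rules pass
  r <- filter_barcode_quality(read_tbl("ACGTACGTACGTACG",
                                       qual_string(rep(20, 15))),
                              keep_all = TRUE)
  expect_true(r$qc_keep)
  # two experimental positions below 20 fail
  q <- rep(30, 15); q[4] <- 19; q[6] <- 19
  r <- filter_barcode_quality(read_tbl("ACGTACGTACGTACG", qual_string(q)),
                              keep_all = TRUE)
  expect_false(r$qc_keep)
  expect_equal(r$qc_reason, "exp_barcode_quality")
  # any random position below 17 fails
  q <- rep(40, 15); q[8] <- 16
  r <- filter_barcode_quality(read_tbl("ACGTACGTACGTACG", qual_string(q)),
                              keep_all = TRUE)
  expect_false(r$qc_keep)
  expect_equal(r$qc_reason, "rand_barcode_quality")
  # exactly one experimental failure is tolerated
  q <- rep(30, 15); q[5] <- 19
  r <- filter_barcode_quality(read_tbl("ACGTACGTACGTACG", qual_string(q)),
                              keep_all = TRUE)
  expect_true(r$qc_keep)
  # a read shorter than the prefix is dropped with its own reason
  r <- filter_barcode_quality(read_tbl("ACGTAC", strrep("I", 6)),
                              keep_all = TRUE)
  expect_false(r$qc_keep)
  expect_equal(r$qc_reason, "short_prefix")
})

test_that("barcode quality decisions agree with the exhaustive 512-pattern oracle", {
  exp_pos <- 4:7; rand_pos <- c(1:3, 8:9)
  seqs <- character(512); quals <- character(512)
  expected <- logical(512)
  for (k in 0:511) {
    fail <- as.logical(bitwAnd(bitwShiftR(k, 0:8), 1L))
    scores <- rep(30L, 9)
    scores[exp_pos][fail[exp_pos]] <- 19L   # fails the exp threshold only
    scores[rand_pos][fail[rand_pos]] <- 16L # fails the rand threshold
    seqs[k + 1] <- "ACGTACGTACGTACG"
    quals[k + 1] <- qual_string(c(scores, rep(30L, 6)))
    expected[k + 1] <- oracle_barcode_qc(scores)
  }
  got <- filter_barcode_quality(read_tbl(seqs, quals), keep_all = TRUE)
  expect_identical(got$qc_keep, expected)
})

test_that("demultiplexing requires an exact experimental-barcode match", {
  sheet <- c(s1 = "ACGT")
  r <- demultiplex(read_tbl("AAAACGTCCTTTT"), sheet, keep_all = TRUE)
  expect_equal(r$sample, "s1")
  # one mismatch leaves the read unassigned
  r <- demultiplex(read_tbl("AAAACGACCTTTT"), sheet, keep_all = TRUE)
  expect_true(is.na(r$sample))
  # N in the barcode is a mismatch
  r <- demultiplex(read_tbl("AAAACGNCCTTTT"), sheet, keep_all = TRUE)
  expect_true(is.na(r$sample))
  # empty sheet: everything unassigned
  r <- demultiplex(read_tbl(c("AAAACGTCCTTTT", "CCCCGTACCTTTT")),
                   tibble::tibble(sample = character(), barcode = character()),
                   keep_all = TRUE)
  expect_true(all(is.na(r$sample)))
  # duplicate barcodes are a configuration error
  expect_error(demultiplex(read_tbl("AAAACGTCCTTTT"),
                           c(a = "ACGT", b = "ACGT")),
               "duplicate")
})

test_that("demultiplexing partitions the input", {
  cfg <- tiny_cfg(seed = 9)
  sim <- simulate_iclip_reads(cfg, generate_reference(cfg))
  flagged <- demultiplex(sim$reads, cfg$barcode_map, keep_all = TRUE)
  assigned <- demultiplex(sim$reads, cfg$barcode_map)
  expect_equal(nrow(assigned) + sum(is.na(flagged$sample)), nrow(sim$reads))
})

test_that("adapter trimming removes the longest tolerated 3' overlap", {
  adapter <- "AGATCGGAAGAGC"
  # full adapter at the read end is removed entirely
  r <- trim_adapter(read_tbl(paste0("TTTTGGGG", adapter)), adapter)
  expect_equal(r$seq, "TTTTGGGG")
  expect_equal(nchar(r$qual), 8)
  # a single trailing nucleotide matching the adapter start is removed
  r <- trim_adapter(read_tbl("TTTTGGGCA"), adapter)
  expect_equal(r$seq, "TTTTGGGC")
  # a 20-nt suffix with 2 mismatches (rate 0.1) goes, with 3 it stays
  adapter20 <- "AGATCGGAAGAGCACACGTC"
  mut2 <- adapter20; substr(mut2, 3, 3) <- "T"; substr(mut2, 10, 10) <- "T"
  mut3 <- mut2; substr(mut3, 15, 15) <- "G"
  base <- "CCCCCCCCCC"
  r2 <- trim_adapter(read_tbl(paste0(base, mut2)), adapter20)
  expect_equal(r2$seq, base)
  r3 <- trim_adapter(read_tbl(paste0(base, mut3)), adapter20)
  # the 20-nt overlap is rejected; a shorter valid suffix may still trim
  expect_equal(nchar(r3$seq), nchar(base) +
                 20 - oracle_trim_length(paste0(base, mut3), adapter20))
  expect_gt(nchar(r3$seq), nchar(base))
})

test_that("adapter trimming agrees with the brute-force suffix oracle", {
  set.seed(42)
  adapter <- "AGATCGGAAGAGC"
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(1:60, function(i) {
    core <- paste(sample(bases, sample(10:30, 1), TRUE), collapse = "")
    tail_len <- sample(0:13, 1)
    tail <- substr(adapter, 1, tail_len)
    # sprinkle mismatches into the adapter part
    if (tail_len > 2 && runif(1) < 0.5) {
      p <- sample(tail_len, 1)
      substr(tail, p, p) <- sample(bases, 1)
    }
    paste0(core, tail)
  }, character(1))
  got <- trim_adapter(read_tbl(seqs), adapter)
  expected_len <- nchar(seqs) -
    vapply(seqs, oracle_trim_length, numeric(1), adapter = adapter)
  expect_equal(nchar(got$seq), unname(expected_len))
})

test_that("barcode relocation moves the prefix into the name", {
  r <- relocate_barcode(read_tbl("AAACGTGCCTTTT", strrep("I", 13),
                                 name = "read1"))
  expect_equal(r$seq, "TTTT")
  expect_equal(r$qual, strrep("I", 4))
  expect_equal(r$exp_barcode, "CGTG")
  expect_equal(r$rand_barcode, "AAACC")
  expect_equal(r$name, "read1__exp=CGTG__rand=AAACC")
  # a 9-nt read leaves an empty insert for the length filter to drop
  r9 <- relocate_barcode(read_tbl("AAACGTGCC", strrep("I", 9)))
  expect_equal(r9$seq, "")
  expect_equal(nrow(length_filter(r9)), 0)
  # too-short reads must have been dropped upstream
  expect_error(relocate_barcode(read_tbl("ACGT", "IIII")), "upstream")
})

test_that("relocated name fields round-trip through FASTQ", {
  r <- relocate_barcode(read_tbl("AAACGTGCCTTTTTTTTTTTTTTT", strrep("F", 24),
                                 name = "rd7"))
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(r, path)
  back <- read_fastq(path)
  expect_equal(back$name, r$name)
  expect_equal(back$seq, r$seq)
  expect_equal(back$qual, r$qual)
})

test_that("the length filter drops inserts under 15 nt and keeps 15-nt ones", {
  r <- read_tbl(c(strrep("A", 14), strrep("A", 15)))
  kept <- length_filter(r)
  expect_equal(kept$seq, strrep("A", 15))
  expect_equal(nrow(length_filter(r[0, ])), 0)
})

test_that("clean simulated reads pass the whole preprocessing unscathed", {
  cfg <- tiny_cfg(seed = 21, corruption_prob = 0)
  sim <- simulate_iclip_reads(cfg, generate_reference(cfg))
  pp <- preprocess_reads(sim$reads, cfg$barcode_map, cfg$adapter_seq)
  expect_equal(nrow(pp), nrow(sim$reads))
  # each read lands in its molecule's true sample
  mol_idx <- as.integer(sub("^m(\\d+)/.*", "\\1", pp$name))
  expect_equal(pp$sample, sim$molecules$sample[mol_idx])
  # and carries its molecule's random barcode
  expect_equal(pp$rand_barcode, sim$molecules$random_barcode[mol_idx])
})

test_that("corrupted base qualities trigger the documented drop reasons", {
  cfg <- tiny_cfg(seed = 22, corruption_prob = 0.2)
  sim <- simulate_iclip_reads(cfg, generate_reference(cfg))
  flagged <- filter_barcode_quality(sim$reads, keep_all = TRUE)
  expect_gt(sum(!flagged$qc_keep), 0)
  expect_true(all(flagged$qc_reason[!flagged$qc_keep] %in%
                    c("exp_barcode_quality", "rand_barcode_quality")))
  # decisions agree with the oracle on every read
  scores <- lapply(strsplit(substr(sim$reads$qual, 1, 9), ""),
                   function(ch) utf8ToInt(paste(ch, collapse = "")) - 33L)
  expect_identical(flagged$qc_keep,
                   vapply(scores, oracle_barcode_qc, logical(1)))
})
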