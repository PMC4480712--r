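# Format round trips and the SAM ingest conventions.

test_that("FASTA round trip preserves sequences and normalizes case", {
  g <- make_reference(2, c(10000, 12000), gc = 0.5, seed = 3)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, fa)
  g2 <- read_fasta(fa)
  expect_identical(g2$chromosomes, g$chromosomes)

  lc <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "acgtacgt"), lc)
  expect_equal(read_fasta(lc)$chromosomes[["a"]], "ACGTACGT")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">rec1", "ACGTNACG"), bad)
  expect_error(read_fasta(bad), "rec1.*offset 4")
})

test_that("SAM ingest converts coordinates, drops secondaries, counts orphans", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:100000",
    # pair q1: fwd 50 bp at pos 101, rev 50 bp at pos 2001
    "q1\t65\tchr1\t101\t60\t50M\tchr1\t2001\t0\t*\t*",
    "q1\t145\tchr1\t2001\t60\t50M\tchr1\t101\t0\t*\t*",
    # secondary alignment for q1 (ignored)
    "q1\t321\tchr1\t5001\t60\t50M\tchr1\t2001\t0\t*\t*",
    # proper pairs q2, q3
    "q2\t65\tchr1\t301\t60\t50M\tchr1\t3001\t0\t*\t*",
    "q2\t145\tchr1\t3001\t60\t50M\tchr1\t301\t0\t*\t*",
    "q3\t65\tchr1\t501\t60\t50M\tchr1\t3501\t0\t*\t*",
    "q3\t145\tchr1\t3501\t60\t50M\tchr1\t501\t0\t*\t*",
    # orphan q4
    "q4\t65\tchr1\t9001\t60\t50M\t*\t0\t0\t*\t*"), sam)
  res <- read_pairs_sam(sam)
  expect_equal(nrow(res$pairs), 3)
  expect_equal(res$n_orphans, 1)
  expect_equal(res$n_secondary, 1)
  q1 <- res$pairs[res$pairs$pair_id == "q1", ]
  expect_equal(q1$startA, 100)  # 1-based 101 -> 0-based 100
  expect_equal(q1$endA, 150)
  expect_equal(q1$strandA, "+")
  expect_equal(q1$strandB, "-")
})

test_that("SAM ingest applies the mapq floor to whole pairs", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@SQ\tSN:chr1\tLN:100000",
    "q1\t65\tchr1\t101\t60\t50M\tchr1\t2001\t0\t*\t*",
    "q1\t145\tchr1\t2001\t5\t50M\tchr1\t101\t0\t*\t*",
    "q2\t65\tchr1\t301\t60\t50M\tchr1\t3001\t0\t*\t*",
    "q2\t145\tchr1\t3001\t60\t50M\tchr1\t301\t0\t*\t*"), sam)
  res <- read_pairs_sam(sam, mapq_floor = 10)
  expect_equal(res$pairs$pair_id, "q2")
  expect_equal(res$n_low_mapq, 1)
})

test_that("simulated library survives a SAM write/read round trip", {
  g <- make_reference(1, 30000, gc = 0.45, seed = 11)
  sim <- simulate_mate_pairs(reference_haplotype(g, "chr1"),
                             library_model(seed = 12), coverage = 5,
                             emit_reads = TRUE)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sim, g, sam)
  res <- read_pairs_sam(sam, sample = "S1")
  expect_equal(res$n_orphans, 0)
  got <- res$pairs[order(res$pairs$pair_id), ]
  want <- sim$pairs[order(sim$pairs$pair_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got[, c("pair_id", "chromA", "startA", "endA", "strandA",
                       "chromB", "startB", "endB", "strandB")],
               want[, c("pair_id", "chromA", "startA", "endA", "strandA",
                        "chromB", "startB", "endB", "strandB")])
})

test_that("BEDPE round trip is lossless for mixed truth records", {
  pols <- list(junction_policy(), junction_policy(microhomology_len = 4),
               junction_policy(duplication_len = c(555, 293)),
               junction_policy(net_loss = 2275),
               junction_policy(untemplated_len = 3))
  recs <- list()
  set.seed(42)
  for (i in 1:100) {
    k <- (i %% 5) + 1
    recs[[i]] <- switch((i %% 3) + 1,
      truth_record("deletion", "chr1", i * 100, i * 100 + 50,
                   policy = pols[[ifelse(k <= 2 || k == 5, k, 1)]],
                   sample = "S", name = paste0("r", i)),
      truth_record("reciprocal_translocation", "chr1", i * 100, i * 100 + 1,
                   "chr2", i * 50, i * 50 + 1,
                   policy = pols[[ifelse(k %in% c(1, 2, 3), k, 1)]],
                   sample = "S", name = paste0("r", i)),
      truth_record("inversion", "chr1", i * 100, i * 100 + 5000,
                   policy = pols[[ifelse(k == 4, 4, 1)]],
                   sample = "S", name = paste0("r", i)))
  }
  path <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(recs, path)
  back <- read_bedpe(path)
  expect_equal(back, recs)
})

test_that("BEDPE encodes an absent end B with the dot sentinel", {
  r <- truth_record("deletion", "chr1", 100, 200, name = "d1")
  path <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(list(r), path)
  f <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(f[4], ".")
  expect_equal(as.integer(f[5:6]), c(-1L, -1L))
  expect_equal(f[9:10], c("+", "-"))
})

test_that("call sets serialize to BEDPE and back", {
  cs <- make_call_set("TRA", "chr17", 1000000, "chr1", 400000,
                      balanced = TRUE)
  path <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(cs, path)
  back <- read_bedpe(path)
  expect_equal(back$sv_type, "TRA")
  expect_true(back$balanced)
  expect_equal(back$support, 5L)
})

test_that("BED and track files round trip with the 0-based convention", {
  bed <- data.frame(chrom = "chr17", start = 7520000L, end = 7680000L,
                    name = "target", stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(bed, p)
  expect_equal(read_bed(p), bed)
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t500\t400", bad)
  expect_error(read_bed(bad), "start >= end")

  tr <- simulate_cn_profile(data.frame(start = 0, end = 20000,
                                       copy_number = 2), 1000, 0.05, seed = 2)
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_track(tr, tp)
  expect_equal(read_track(tp), tr, tolerance = 1e-12)
})
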