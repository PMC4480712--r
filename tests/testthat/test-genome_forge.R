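# Reference generation, SV planting mechanics, and the three simulators.

test_that("make_reference honours lengths, seed determinism and GC target", {
  g <- make_reference(1, 10000, gc = 0.5, seed = 7)
  expect_equal(nchar(g$chromosomes[["chr1"]]), 10000)

  g2 <- make_reference(1, 10000, gc = 0.5, seed = 7)
  expect_identical(g$chromosomes, g2$chromosomes)
  g3 <- make_reference(1, 10000, gc = 0.5, seed = 8)
  expect_false(identical(g$chromosomes, g3$chromosomes))

  # base-count oracle on a 200 kb chromosome at GC 0.40
  g4 <- make_reference(1, 200000, gc = 0.40, seed = 3)
  counts <- table(strsplit(g4$chromosomes[["chr1"]], "")[[1]])
  gc_frac <- sum(counts[c("G", "C")]) / sum(counts)
  expect_gte(gc_frac, 0.38)
  expect_lte(gc_frac, 0.42)

  expect_error(make_reference(1, 5000, 0.5, 1), "10 kb")
  expect_error(make_reference(1, 10000, 1.2, 1), "gc")
})

test_that("planted deletion shortens the haplotype by the deleted span", {
  g <- make_reference(1, 10000, gc = 0.5, seed = 2)
  pl <- plant_sv(g, truth_record("deletion", "chr1", 1000, 2000))
  expect_equal(nchar(pl$haplotypes[[1]]$seq), 9000)
  expect_equal(pl$truth$junctions$posL, 1000)
  expect_equal(pl$truth$junctions$posR, 2000)
})

test_that("translocation duplication places the same segment on both derivatives", {
  g <- make_reference(2, c(100000, 60000), gc = 0.41, seed = 9)
  tr <- truth_record("reciprocal_translocation", "chr1", 50000, 50001,
                     "chr2", 30000, 30001,
                     policy = junction_policy(duplication_len = c(555, 0)))
  pl <- plant_sv(g, tr)
  seg <- substring(pl$genome$chromosomes[["chr1"]], 50000 - 555 + 1, 50000)
  expect_equal(nchar(seg), 555)
  # exact-substring oracle: the duplicated reference segment is in BOTH
  expect_true(grepl(seg, pl$haplotypes[[1]]$seq, fixed = TRUE))
  expect_true(grepl(seg, pl$haplotypes[[2]]$seq, fixed = TRUE))
  # conservation: total derivative length = total source + duplication
  expect_equal(sum(nchar(vapply(pl$haplotypes, `[[`, "", "seq"))),
               100000 + 60000 + 555)
})

test_that("inversion net loss shortens the derivative by exactly that amount", {
  g <- make_reference(1, 100000, gc = 0.41, seed = 4)
  pl <- plant_sv(g, truth_record("inversion", "chr1", 20000, 70000,
                                 policy = junction_policy(net_loss = 2275)))
  expect_equal(nchar(pl$haplotypes[[1]]$seq), 100000 - 2275)
  # the two locus-side breakpoints are net_loss apart
  expect_equal(diff(sort(pl$truth$junctions$posL)), 2275)
})

test_that("invalid policies and loci are rejected", {
  expect_error(junction_policy(microhomology_len = 4, duplication_len = 10),
               "at most one")
  g <- make_reference(1, 20000, gc = 0.5, seed = 1)
  expect_error(plant_sv(g, truth_record("deletion", "chr1", 15000, 25000)),
               "outside")
  expect_error(truth_record("deletion", "chr1", 5000, 5000), "start")
  expect_error(truth_record("deletion", "chr1", 1000, 2000,
                            policy = junction_policy(net_loss = 10)),
               "net_loss")
})

test_that("mate-pair count contract and exact-substring oracle hold", {
  g <- make_reference(1, 50000, gc = 0.45, seed = 5)
  hap <- reference_haplotype(g, "chr1")
  model <- library_model(error_rate = 0, seed = 6)
  # coverage chosen so ceiling(cov * 50000 / 3000) = 500
  sim <- simulate_mate_pairs(hap, model, coverage = 30, emit_reads = TRUE)
  expect_equal(sim$n_pairs, 500)
  expect_equal(nrow(sim$pairs) + sim$n_unmapped, 500)

  # with error rate 0 every tag is an exact substring of its source (read 2
  # as reverse complement)
  ref <- g$chromosomes[["chr1"]]
  expect_true(all(vapply(sim$reads$read1, grepl, logical(1), x = ref,
                         fixed = TRUE)))
  expect_true(all(vapply(revcomp(sim$reads$read2), grepl, logical(1),
                         x = ref, fixed = TRUE)))

  # seeded determinism
  sim2 <- simulate_mate_pairs(hap, model, coverage = 30, emit_reads = TRUE)
  expect_identical(sim$pairs, sim2$pairs)
})

test_that("pairs spanning a planted deletion have insert inflated by its size", {
  g <- make_reference(1, 60000, gc = 0.45, seed = 8)
  del <- c(30000L, 35000L)
  pl <- plant_sv(g, truth_record("deletion", "chr1", del[1], del[2]))
  model <- library_model(seed = 2)
  sim <- simulate_mate_pairs(pl$haplotypes, model, coverage = 20,
                             emit_reads = FALSE)
  spanning <- sim$pairs$endA <= del[1] & sim$pairs$startB >= del[2]
  expect_gt(sum(spanning), 0)
  ins <- sim$pairs$endB[spanning] - sim$pairs$startA[spanning]
  # apparent insert = fragment + deletion size
  expect_true(all(ins >= model$frag_min + diff(del)))
  expect_true(all(ins <= model$frag_max + diff(del)))
  # and the true alignment ends flank the deletion on both sides
  expect_true(all(sim$pairs$endA[spanning] <= del[1]))
  expect_true(all(sim$pairs$startB[spanning] >= del[2]))
})

test_that("copy-number profile simulator matches the log2 model", {
  segs <- data.frame(start = 0, end = 50000, copy_number = 2)
  tr <- simulate_cn_profile(segs, 1000, noise_sd = 0, seed = 1)
  expect_true(all(tr$log2 == 0))

  segs1 <- data.frame(start = 0, end = 50000, copy_number = 1)
  tr1 <- simulate_cn_profile(segs1, 1000, noise_sd = 0, seed = 1)
  expect_true(all(tr1$log2 == -1))

  # CLT check: 10,000 probes at noise 0.1
  segs2 <- data.frame(start = 0, end = 1e7, copy_number = 2)
  tr2 <- simulate_cn_profile(segs2, 1000, noise_sd = 0.1, seed = 9)
  expect_lt(abs(mean(tr2$log2)), 3 * 0.1 / sqrt(10000))

  expect_error(simulate_cn_profile(
    data.frame(start = c(0, 600), end = c(500, 1000), copy_number = 2),
    100, 0, 1), "contiguous")
})

test_that("BAF simulator centers follow the purity mixture", {
  b0 <- simulate_baf(50, "het-normal", purity = 1, noise_sd = 0, seed = 1)
  expect_true(all(b0$baf == 0.5))
  b1 <- simulate_baf(50, "cn-neutral-LOH", purity = 1, noise_sd = 0, seed = 1)
  expect_true(all(b1$baf %in% c(0, 1)))
  b7 <- simulate_baf(500, "cn-neutral-LOH", purity = 0.7, noise_sd = 0,
                     seed = 2)
  expect_equal(sort(unique(b7$baf)), c(0.15, 0.85))
  expect_error(simulate_baf(10, "het-normal", purity = 0), "purity")
})
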