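# Junction micro-homology / untemplated analysis, balanced-pair shared/lost
# signatures, and pairwise event overlap.

test_that("junction analysis equals the exhaustive split-point oracle", {
  cases <- list(junction_policy(),                       # blunt
                junction_policy(microhomology_len = 1),
                junction_policy(microhomology_len = 4),
                junction_policy(microhomology_len = 12),
                junction_policy(untemplated_len = 1),
                junction_policy(untemplated_len = 3),
                junction_policy(untemplated_len = 8))
  for (i in seq_along(cases)) {
    fx <- deletion_junction_fixture(cases[[i]], seed = 100 + i)
    got <- analyze_junction(fx$junction, fx$refA, fx$refB)
    want <- bf_junction_oracle(fx$junction, fx$refA, fx$refB)
    expect_equal(got$microhomology_len, want$microhomology_len,
                 info = paste("case", i))
    expect_equal(got$untemplated_len, want$untemplated_len,
                 info = paste("case", i))
    pol <- cases[[i]]
    expect_equal(got$microhomology_len, pol$microhomology_len)
    expect_equal(got$untemplated_len, pol$untemplated_len)
    expect_false(got$microhomology_len > 0 && got$untemplated_len > 0)
  }
})

test_that("junctions longer fixtures match the oracle up to 2 kb windows", {
  fx <- deletion_junction_fixture(junction_policy(microhomology_len = 7),
                                  seed = 200, flank = 2000)
  expect_lte(nchar(fx$junction), 2000)
  got <- analyze_junction(fx$junction, fx$refA, fx$refB)
  want <- bf_junction_oracle(fx$junction, fx$refA, fx$refB)
  expect_equal(got$microhomology_len, want$microhomology_len)
})

test_that("unanchored or ambiguous junctions fail loudly", {
  fx <- deletion_junction_fixture(junction_policy(), seed = 300)
  random <- svhotspot:::random_dna(400)
  expect_error(analyze_junction(random, fx$refA, fx$refB), "not anchored")
  # a locus containing the anchor twice is ambiguous
  dup_locus <- paste0(fx$refA, fx$refA)
  expect_error(junction_locus_coverage(fx$junction,
                                       list(chrom = "chr1", start = 0,
                                            end = nchar(dup_locus),
                                            seq = dup_locus)),
               "ambiguous")
})

test_that("balanced-pair analysis recovers planted policies exactly", {
  # reciprocal translocation with two-sided duplication
  g <- make_reference(2, c(200000, 100000), gc = 0.41, seed = 61,
                      names = c("chr17", "chr1"))
  a <- 100000; b <- 50000
  pl <- plant_sv(g, truth_record("reciprocal_translocation", "chr17", a, a + 1,
                                 "chr1", b, b + 1,
                                 policy = junction_policy(
                                   duplication_len = c(555, 293))))
  j <- pl$truth$junctions
  w1 <- junction_window(pl$haplotypes[[1]], j$der_pos[1])
  w2 <- junction_window(pl$haplotypes[[2]], j$der_pos[2])
  refA <- list(chrom = "chr17", start = a - 3000, end = a + 3000)
  refB <- list(chrom = "chr1", start = b - 3000, end = b + 3000)
  sig <- analyze_balanced_pair(w1, w2, refA, refB, genome = pl$genome)
  expect_equal(sig$sharedA, 555)
  expect_equal(sig$sharedB, 293)
  expect_equal(sig$mechanism_class, "duplication")

  # symmetry under derivative swap
  sig_sw <- analyze_balanced_pair(w2, w1, refA, refB, genome = pl$genome)
  expect_equal(sig_sw$sharedA, sig$sharedA)
  expect_equal(sig_sw$sharedB, sig$sharedB)
  expect_equal(sig_sw$mechanism_class, sig$mechanism_class)

  # blunt join
  pl0 <- plant_sv(g, truth_record("reciprocal_translocation", "chr17", a, a + 1,
                                  "chr1", b, b + 1))
  j0 <- pl0$truth$junctions
  sig0 <- analyze_balanced_pair(
    junction_window(pl0$haplotypes[[1]], j0$der_pos[1]),
    junction_window(pl0$haplotypes[[2]], j0$der_pos[2]),
    refA, refB, genome = pl0$genome)
  expect_equal(sig0$sharedA, 0)
  expect_equal(sig0$sharedB, 0)
  expect_equal(sig0$mechanism_class, "blunt")
})

test_that("full parameter recovery holds across policies and seeds", {
  for (seed in c(71, 72)) {
    # inversion with net loss
    g <- make_reference(1, 300000, gc = 0.41, seed = seed, names = "chr17")
    s <- 100000; e <- 220000; loss <- 2275
    pl <- plant_sv(g, truth_record("inversion", "chr17", s, e,
                                   policy = junction_policy(net_loss = loss)))
    j <- pl$truth$junctions
    sig <- analyze_balanced_pair(
      junction_window(pl$haplotypes[[1]], j$der_pos[1]),
      junction_window(pl$haplotypes[[1]], j$der_pos[2]),
      list(chrom = "chr17", start = s - 2000, end = s + loss + 2000),
      list(chrom = "chr17", start = e - 3000, end = e + 3000),
      genome = pl$genome)
    expect_equal(sig$sharedA, -loss)
    expect_equal(sig$sharedB, 0)
    expect_equal(sig$mechanism_class, "net_loss")

    # inverted insertion with target-site duplication
    g2 <- make_reference(2, c(200000, 100000), gc = 0.41, seed = seed + 10,
                         names = c("chr17", "chr6"))
    p <- 100000
    pl2 <- plant_sv(g2, truth_record("inverted_insertion", "chr17", p, p,
                                     "chr6", 40000, 52500,
                                     policy = junction_policy(
                                       duplication_len = 59)))
    j2 <- pl2$truth$junctions
    sig2 <- analyze_balanced_pair(
      junction_window(pl2$haplotypes[[1]], j2$der_pos[1]),
      junction_window(pl2$haplotypes[[1]], j2$der_pos[2]),
      list(chrom = "chr17", start = p - 3000, end = p + 3000),
      genome = pl2$genome)
    expect_equal(sig2$sharedA, 59)
    expect_equal(sig2$mechanism_class, "duplication")

    # micro-homology-scale translocation
    g3 <- make_reference(2, c(100000, 60000), gc = 0.41, seed = seed + 20)
    pl3 <- plant_sv(g3, truth_record("reciprocal_translocation", "chr1",
                                     50000, 50001, "chr2", 30000, 30001,
                                     policy = junction_policy(
                                       microhomology_len = 6)))
    j3 <- pl3$truth$junctions
    sig3 <- analyze_balanced_pair(
      junction_window(pl3$haplotypes[[1]], j3$der_pos[1]),
      junction_window(pl3$haplotypes[[2]], j3$der_pos[2]),
      list(chrom = "chr1", start = 47000, end = 53000),
      list(chrom = "chr2", start = 27000, end = 33000),
      genome = pl3$genome)
    expect_equal(sig3$sharedA, 6)
    expect_equal(sig3$mechanism_class, "microhomology")
  }
})

test_that("pairwise event overlap reports spacing and shared locus sequence", {
  # two blunt translocations 46 bases apart in retained-coordinate terms
  g <- make_reference(3, c(200000, 100000, 100000), gc = 0.41, seed = 81,
                      names = c("chr17", "chr1", "chr6"))
  E <- 100000; S <- E - 46
  pm <- plant_multi(g, list(
    truth_record("reciprocal_translocation", "chr17", E, E + 1, "chr1",
                 50000, 50001, name = "ev1"),
    truth_record("reciprocal_translocation", "chr17", S, S + 1, "chr6",
                 60000, 60001, name = "ev2")),
    keeps = list("der1", "der2"))
  ref17 <- list(chrom = "chr17", start = E - 3000, end = E + 3000)
  covA <- junction_locus_coverage(
    junction_window(pm$haplotypes[[1]], pm$truths[[1]]$junctions$der_pos[1]),
    ref17, genome = pm$genome)
  covB <- junction_locus_coverage(
    junction_window(pm$haplotypes[[2]], pm$truths[[2]]$junctions$der_pos[1]),
    ref17, genome = pm$genome)
  ov <- pairwise_event_overlap(covA, covB)
  expect_equal(ov$spacing, 45)
  expect_equal(ov$shared_len, 46)
  expect_false(ov$disjoint)

  # identical breakpoints: spacing 0
  expect_equal(pairwise_event_overlap(covA, covA)$spacing, 0)

  # disjoint retained intervals: shared_len floored at 0 with the flag set
  covX <- covA; covX$interval <- c(lo = 1000, hi = 2000); covX$pos <- 1999
  covY <- covA; covY$interval <- c(lo = 5000, hi = 6000); covY$pos <- 5000
  ov2 <- pairwise_event_overlap(covX, covY)
  expect_equal(ov2$shared_len, 0)
  expect_true(ov2$disjoint)
})
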