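# Library statistics, pair classification, clustering, breakpoint geometry,
# call typing and germline subtraction.

test_that("library statistics reproduce median and raw MAD", {
  p1 <- concordant_pairs(1200, insert = 3000)
  st <- estimate_library_stats(p1)
  expect_equal(st$insert_median, 3000)
  expect_equal(st$insert_mad, 0)

  ins <- rep(c(2900L, 3000L, 3100L), each = 334)
  st2 <- estimate_library_stats(make_pairs(
    "chrA", seq_along(ins) * 10L, seq_along(ins) * 10L + 50L, "+",
    "chrA", seq_along(ins) * 10L + ins - 50L, seq_along(ins) * 10L + ins, "-"))
  expect_equal(st2$insert_median, 3000)
  expect_equal(st2$insert_mad, 100)

  expect_error(estimate_library_stats(concordant_pairs(500)),
               "insufficient pairs")
})

test_that("pair classification follows chromosome, orientation and insert", {
  st <- library_stats(3000, 100, k = 5)
  same_ok <- make_pairs("chrA", 100, 150, "+", "chrA", 3050, 3100, "-")
  expect_equal(classify_pairs(same_ok, st), "concordant")

  inter <- make_pairs("chrA", 100, 150, "+", "chrB", 3050, 3100, "-")
  expect_equal(classify_pairs(inter, st), "inter-chromosomal")

  # pair spanning a 94 kb deletion with a ~3 kb fragment: apparent insert
  # ~97 kb, far over the concordance ceiling
  del <- make_pairs("chrA", 100, 150, "+", "chrA", 97050, 97100, "-")
  expect_equal(classify_pairs(del, st), "del-type")

  inv <- make_pairs("chrA", 100, 150, "+", "chrA", 3050, 3100, "+")
  expect_equal(classify_pairs(inv, st), "inv-type")

  evert <- make_pairs("chrA", 100, 150, "-", "chrA", 3050, 3100, "+")
  expect_equal(classify_pairs(evert, st), "dup-type")
})

test_that("clustering co-locates junction mates and separates distant ones", {
  # 5 pairs from one junction
  one <- make_pairs("chrA", c(100, 400, 700, 1000, 1300),
                    c(150, 450, 750, 1050, 1350), "+",
                    "chrA", 97000 + c(0, 300, 600, 900, 1200),
                    97050 + c(0, 300, 600, 900, 1200), "-")
  cl <- cluster_discordant(one, max_gap = 4000, min_support = 3)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$support, 5)

  # two junctions 1 Mb apart
  two <- rbind(one, within(one, {
    startA <- startA + 1000000L; endA <- endA + 1000000L
    startB <- startB + 1000000L; endB <- endB + 1000000L
    pair_id <- paste0(pair_id, "_b")
  }))
  cl2 <- cluster_discordant(two, max_gap = 4000, min_support = 3)
  expect_length(cl2, 2)
})

test_that("clustering equals brute-force single linkage on random pairs", {
  withr::with_seed(123, {
    for (rep in 1:3) {
      n <- 200
      pairs <- make_pairs(
        chromA = sample(c("chrA", "chrB"), n, TRUE),
        startA = sample(0:80000, n), endA = 0, strandA = sample(c("+", "-"), n, TRUE),
        chromB = sample(c("chrA", "chrC"), n, TRUE),
        startB = sample(0:80000, n), endB = 0, strandB = sample(c("+", "-"), n, TRUE))
      pairs$endA <- pairs$startA + 50L
      pairs$endB <- pairs$startB + 50L
      max_gap <- 3000
      expect_identical(pkg_partition(pairs, max_gap),
                       bf_single_linkage(pairs, max_gap))
    }
  })
})

test_that("breakpoint intervals have the contracted width and shrink with support", {
  st <- library_stats(3000, 200, k = 5)   # insert ceiling 4000
  rl <- 50L
  single <- make_pairs("chrA", 1000, 1050, "+", "chrA", 98000, 98050, "-")
  cl <- cluster_discordant(single, 4000, min_support = 1)[[1]]
  bp <- predict_breakpoints(cl, st, rl)
  expect_equal(bp$A$hi - bp$A$lo, 4000 - 2 * rl)
  expect_equal(bp$B$hi - bp$B$lo, 4000 - 2 * rl)

  many <- make_pairs("chrA", seq(0, 1900, by = 100), seq(50, 1950, by = 100),
                     "+", "chrA", seq(98000, 99900, by = 100),
                     seq(98050, 99950, by = 100), "-")
  clm <- cluster_discordant(many, 4000, min_support = 1)[[1]]
  bpm <- predict_breakpoints(clm, st, rl)
  expect_lte(bpm$A$hi - bpm$A$lo, bp$A$hi - bp$A$lo)
  expect_lte(bpm$B$hi - bpm$B$lo, bp$B$hi - bp$B$lo)
})

test_that("predicted intervals contain the true junction on an error-free sim", {
  g <- make_reference(1, 500000, gc = 0.41, seed = 17)
  del <- c(200000L, 260000L)
  pl <- plant_sv(g, truth_record("deletion", "chr1", del[1], del[2]))
  sim <- simulate_mate_pairs(pl$haplotypes, library_model(seed = 18),
                             coverage = 12, emit_reads = FALSE)
  cp <- call_pipeline(sim$pairs, 50)
  expect_length(cp$clusters, 1)
  bp <- predict_breakpoints(cp$clusters[[1]], cp$stats, 50)
  expect_true(bp$A$lo <= del[1] && del[1] < bp$A$hi)
  expect_true(bp$B$lo <= del[2] && del[2] < bp$B$hi)
  # and the DEL call's span is close to the planted 60 kb
  dcall <- cp$calls$calls[cp$calls$calls$sv_type == "DEL", ]
  expect_equal(nrow(dcall), 1)
  expect_lt(abs(dcall$span - diff(del)), 500)
})

test_that("calls are typed, sorted, deterministic, and respect min_support", {
  tum <- simulate_os_tumor("PZP", seed = 33, coverage = 12)
  cp <- call_pipeline(tum$sim$pairs, tum$model$read_len)
  ins <- cp$calls$calls[cp$calls$calls$sv_type == "INS", ]
  expect_equal(nrow(ins), 1)
  expect_lt(abs(ins$donor_len - 12500), 600)
  expect_true(all(cp$calls$calls$support >= 3))
  expect_false(is.unsorted(order(cp$calls$calls$chromA,
                                 cp$calls$calls$bpA_pos)))
  # determinism end to end
  tum2 <- simulate_os_tumor("PZP", seed = 33, coverage = 12)
  cp2 <- call_pipeline(tum2$sim$pairs, tum2$model$read_len)
  expect_identical(cp$calls$calls, cp2$calls$calls)
})

test_that("a lone del-pattern cluster yields exactly one DEL call", {
  st <- library_stats(3000, 100)
  pairs <- make_pairs("chrA", c(100, 300, 500), c(150, 350, 550), "+",
                      "chrA", 97000 + c(0, 200, 400), 97050 + c(0, 200, 400),
                      "-")
  cl <- cluster_discordant(pairs, 4000, 3)
  calls <- call_svs(cl, st, 50)
  expect_equal(calls$calls$sv_type, "DEL")
  expect_equal(nrow(calls$calls), 1)
})

test_that("germline subtraction keeps exactly the planted somatic events", {
  g <- make_reference(1, 2000000, gc = 0.41, seed = 51)
  germ <- data.frame(start = 60000 + (0:49) * 30000)
  germ$end <- germ$start + rep(c(3000L, 4000L, 5000L, 6000L, 3500L), 10)
  som <- data.frame(start = 75000 + (0:9) * 150000)
  som$end <- som$start + 5000
  normal_hap <- plant_deletions(g, "chr1", germ, name = "normal")
  tumor_hap <- plant_deletions(g, "chr1", rbind(germ, som), name = "tumor")
  mdl <- library_model(seed = 52)
  sim_n <- simulate_mate_pairs(normal_hap, mdl, 12, sample = "N",
                               emit_reads = FALSE, seed = 53)
  sim_t <- simulate_mate_pairs(tumor_hap, mdl, 12, sample = "T",
                               emit_reads = FALSE, seed = 54)
  cp_n <- call_pipeline(sim_n$pairs, 50)
  cp_t <- call_pipeline(sim_t$pairs, 50)
  somatic <- somatic_subtract(cp_t$calls, cp_n$calls, window = 2000)
  dels <- somatic$calls[somatic$calls$sv_type == "DEL", ]
  expect_equal(nrow(dels), 10)
  hits <- vapply(seq_len(nrow(som)), function(i) {
    any(abs(dels$bpA_pos - som$start[i]) <= 2000 &
          abs(dels$bpB_pos - som$end[i]) <= 2000)
  }, logical(1))
  expect_true(all(hits))
  # identical germline calls were removed; tumor-only retained
  expect_lt(nrow(somatic$calls), nrow(cp_t$calls$calls))
})
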