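# Canonical study configurations: the named rearrangement events observed at
# the intron-1 hotspot (a 94 kb deletion removing the gene; a reciprocal
# translocation carrying 555/293 bp junctional duplications; a 12.5 kb
# inverted insertion with a 59 bp target-site overlap; a complex tumor with
# three independent translocations, two of them 45 bp apart sharing 46 bp;
# and a germline 445 kb inversion with a 2,275 bp net loss), rebuilt inside
# synthetic genomes. These are the package's reference simulations: the
# event geometry is fixed; only the random sequence context and library
# sampling vary with the seed.

HOTSPOT_WINDOW <- c(995000L, 1005000L)   # intron-1-like window on chr17

#' The intron-1 hotspot window used by the reference simulations
#' @return list with `chrom`, `start`, `end`.
#' @export
hotspot_window <- function() {
  list(chrom = "chr17", start = HOTSPOT_WINDOW[1], end = HOTSPOT_WINDOW[2])
}

#' Event catalog of the reference tumors
#'
#' Returns the planted-event specifications for each named tumor
#' configuration. Coordinates are fixed positions inside the synthetic
#' genomes built by [simulate_os_tumor()].
#'
#' @param tumor one of `"AJF"`, `"YZH"`, `"PZP"`, `"KRD"`, `"LFS"`.
#' @return list with `specs` (list of [truth_record()]s), `keeps`
#'   (derivatives retained per event), `chrom_lengths` (named lengths for
#'   the reference), and for `"LFS"` a `target` capture region.
#' @export
os_event_catalog <- function(tumor = c("AJF", "YZH", "PZP", "KRD", "LFS")) {
  tumor <- match.arg(tumor)
  both <- c("der1", "der2")
  switch(tumor,
    AJF = list(  # 94 kb deletion removing the whole gene
      specs = list(truth_record("deletion", "chr17", 950000L, 1044000L,
                                sample = "AJF", name = "AJF_del")),
      keeps = list("der1"),
      chrom_lengths = c(chr17 = 2000000L)),
    YZH = list(  # balanced translocation, 555 bp / 293 bp duplications
      specs = list(truth_record("reciprocal_translocation", "chr17",
                                1000000L, 1000001L, "chr1", 400000L, 400001L,
                                policy = junction_policy(
                                  duplication_len = c(555L, 293L)),
                                sample = "YZH", name = "YZH_tra")),
      keeps = list(both),
      chrom_lengths = c(chr17 = 2000000L, chr1 = 1000000L)),
    PZP = list(  # 12.5 kb inverted insertion, 59 bp target-site overlap
      specs = list(truth_record("inverted_insertion", "chr17",
                                1002000L, 1002000L, "chr6", 500000L, 512500L,
                                policy = junction_policy(duplication_len = 59L),
                                sample = "PZP", name = "PZP_ins")),
      keeps = list("der1"),
      chrom_lengths = c(chr17 = 2000000L, chr6 = 1000000L)),
    KRD = list(  # three independent translocations; chr1/chr6 breaks 45 bp
                 # apart sharing 46 bp of the locus; chr5 on another allele
                 # or clone
      specs = list(
        truth_record("reciprocal_translocation", "chr17", 998000L, 998001L,
                     "chr1", 500000L, 500001L, sample = "KRD",
                     name = "KRD_chr1"),
        truth_record("reciprocal_translocation", "chr17", 997954L, 997955L,
                     "chr6", 600000L, 600001L, sample = "KRD",
                     name = "KRD_chr6"),
        truth_record("reciprocal_translocation", "chr17", 999500L, 999501L,
                     "chr5", 300000L, 300001L, sample = "KRD",
                     name = "KRD_chr5")),
      keeps = list("der1", "der2", "der1"),
      chrom_lengths = c(chr17 = 2000000L, chr1 = 1000000L, chr5 = 1000000L,
                        chr6 = 1000000L)),
    LFS = list(  # germline 445 kb inversion, 2,275 bp net loss at the
                 # gene-side junction, discoverable through a 160 kb capture
      specs = list(truth_record("inversion", "chr17", 2000000L, 2445000L,
                                policy = junction_policy(net_loss = 2275L),
                                sample = "LFS", name = "LFS_inv")),
      keeps = list("der1"),
      chrom_lengths = c(chr17 = 5000000L),
      target = target_region("chr17", 1920000L, 2080000L, "capture")))
}

#' Build and sequence a reference tumor configuration
#'
#' Generates the synthetic reference, plants the tumor's events
#' ([plant_multi()]), and simulates a mate-pair library over the derivative
#' haplotypes at the requested physical coverage.
#'
#' @param tumor tumor name (see [os_event_catalog()]).
#' @param seed master seed; the genome, planting and library draws are
#'   derived from it deterministically.
#' @param coverage physical coverage (default 15).
#' @param error_rate per-base substitution rate (default 0.001).
#' @param read_len tag length (default 50).
#' @param gc reference GC fraction (default 0.41, genome-like).
#' @param emit_reads keep tag sequences (default FALSE for speed).
#' @return list with `genome`, `haplotypes`, `truths`, `sim` (pairs etc.),
#'   `model`, `catalog`.
#' @export
simulate_os_tumor <- function(tumor, seed = 1L, coverage = 15,
                              error_rate = 0.001, read_len = 50L, gc = 0.41,
                              emit_reads = FALSE) {
  cat_ <- os_event_catalog(tumor)
  ref <- make_reference(length(cat_$chrom_lengths), cat_$chrom_lengths,
                        gc = gc, seed = seed,
                        names = names(cat_$chrom_lengths))
  planted <- plant_multi(ref, cat_$specs, keeps = cat_$keeps,
                         seed = seed + 1L)
  model <- library_model(read_len = read_len, error_rate = error_rate,
                         seed = seed + 2L)
  sim <- simulate_mate_pairs(planted$haplotypes, model, coverage,
                             sample = tumor, emit_reads = emit_reads)
  list(genome = planted$genome, haplotypes = planted$haplotypes,
       truths = planted$truths, sim = sim, model = model, catalog = cat_)
}

#' Run the standard discordant-pair calling pipeline
#'
#' Library statistics, concordance classification, single-linkage clustering
#' of the discordant pairs (`max_gap = insert_median + k * MAD`) and call
#' typing.
#'
#' @param pairs canonicalized pair table.
#' @param read_len tag length.
#' @param min_support minimum dPET cluster size (default 3).
#' @param pairing_window reciprocal-cluster pairing window (default 5000).
#' @return list with `stats`, `clusters`, `calls`.
#' @export
call_pipeline <- function(pairs, read_len, min_support = 3L,
                          pairing_window = 5000L) {
  stats <- estimate_library_stats(pairs)
  disc <- pairs[classify_pairs(pairs, stats) != "concordant", , drop = FALSE]
  max_gap <- stats$insert_median + stats$k * stats$insert_mad
  clusters <- cluster_discordant(disc, max_gap, min_support)
  calls <- call_svs(clusters, stats, read_len,
                    pairing_window = pairing_window)
  list(stats = stats, clusters = clusters, calls = calls)
}

#' Synthetic copy-number cohort with the observed transition-class mix
#'
#' Builds 23 probe tracks, each planting exactly one copy-number boundary
#' inside the gene window: 17 transitions into loss, 3 into gain and 3
#' abrupt loss-to-gain transitions (the class composition observed across
#' the array cohort).
#'
#' @param seed master seed.
#' @param noise_sd probe noise in log2 units (default 0.1).
#' @param probe_spacing bases between probes (default 1000).
#' @return list with `tracks` (list of 23 probe tracks), `classes` (planted
#'   class per track) and `window` (`c(start, end)`).
#' @export
simulate_transition_cohort <- function(seed = 1L, noise_sd = 0.1,
                                       probe_spacing = 1000L) {
  classes <- c(rep("into-loss", 17), rep("into-gain", 3),
               rep("loss-to-gain", 3))
  window <- c(290000L, 310000L)
  total <- 600000L
  tracks <- lapply(seq_along(classes), function(i) {
    b <- withr::with_seed(seed + 100L + i, {
      as.integer(round(stats::runif(1, window[1] + 2000, window[2] - 2000)))
    })
    cls <- classes[i]
    cn <- switch(cls, "into-loss" = c(2, 1), "into-gain" = c(2, 3),
                 "loss-to-gain" = c(1, 3))
    segs <- data.frame(start = c(0L, b), end = c(b, total),
                       copy_number = cn)
    simulate_cn_profile(segs, probe_spacing, noise_sd, seed = seed + i)
  })
  list(tracks = tracks, classes = classes, window = window)
}

#' Screening cohort counts
#'
#' The cohort counts the frequency analyses are computed from: 23 of 215
#' evaluable tumors positive by break-apart FISH; 23 of 73 tumors with an
#' intron-1 copy-number transition on high-density arrays; 54 of 73 with any
#' copy-number alteration affecting the gene on the same arrays.
#'
#' @return data frame with `platform`, `positives`, `total`.
#' @export
os_cohort_counts <- function() {
  data.frame(platform = c("FISH_TMA", "CytoScan_intron1", "CytoScan_any"),
             positives = c(23L, 23L, 54L),
             total = c(215L, 73L, 73L),
             stringsAsFactors = FALSE)
}
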