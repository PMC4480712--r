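# Targeted-capture breakpoint discovery: one-end-anchored pair filtering
# against a capture target and cluster-size ranking of the mate loci, the
# strategy used to find a germline rearrangement point inside a gene-sized
# target region.

#' Define a capture target region
#' @param chrom chromosome.
#' @param start,end 0-based half-open bounds.
#' @param name region name.
#' @return object of class `target_region`.
#' @export
target_region <- function(chrom, start, end, name = "target") {
  if (start >= end) stopf("target start must be < end")
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), name = name),
            class = "target_region")
}

#' Filter read pairs anchored on one end in a target region
#'
#' A pair is retained iff exactly one end overlaps the target by at least one
#' base (half-open coordinates: an end abutting the target boundary does not
#' overlap). Both-in and both-out pairs are dropped; the partition counts are
#' returned so that retained + both_in + both_out equals the input.
#'
#' @param pairs canonicalized pair table.
#' @param target a [target_region()] (or a one-row BED data frame).
#' @return list with `pairs` (the anchored subset), `n_retained`,
#'   `n_both_in`, `n_both_out`.
#' @export
filter_target_pairs <- function(pairs, target) {
  if (is.data.frame(target)) {
    target <- target_region(target$chrom[1], target$start[1], target$end[1])
  }
  inA <- pairs$chromA == target$chrom & pairs$startA < target$end &
    pairs$endA > target$start
  inB <- pairs$chromB == target$chrom & pairs$startB < target$end &
    pairs$endB > target$start
  anchored <- xor(inA, inB)
  list(pairs = pairs[anchored, , drop = FALSE],
       n_retained = sum(anchored),
       n_both_in = sum(inA & inB),
       n_both_out = sum(!inA & !inB))
}

#' Cluster anchored pairs and rank candidates by cluster size
#'
#' Delegates clustering to [cluster_discordant()] after optionally removing
#' concordant pairs (pairs straddling the target boundary are concordant and
#' would otherwise pile up at the target edges). Clusters are ordered by
#' support descending, ties broken by the mate locus coordinate -- the order
#' in which candidates would be prioritized for validation.
#'
#' @param anchored output of [filter_target_pairs()] (or its `pairs`).
#' @param max_gap clustering gap in bases.
#' @param min_support minimum cluster size.
#' @param stats optional `library_stats`; when given, concordant pairs are
#'   dropped before clustering.
#' @return list of `dpet_cluster` ordered by (support desc, chromB, startB).
#' @export
rank_candidates <- function(anchored, max_gap, min_support = 3L,
                            stats = NULL) {
  pairs <- if (is.data.frame(anchored)) anchored else anchored$pairs
  if (!is.null(stats)) {
    pairs <- pairs[classify_pairs(pairs, stats) != "concordant", ,
                   drop = FALSE]
  }
  clusters <- cluster_discordant(pairs, max_gap, min_support)
  if (length(clusters) == 0L) return(clusters)
  ord <- order(-vapply(clusters, function(c) c$support, numeric(1)),
               vapply(clusters, function(c) c$sideB$chrom, character(1)),
               vapply(clusters, function(c) c$sideB$start, numeric(1)))
  clusters[ord]
}
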