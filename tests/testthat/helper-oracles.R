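# Independent oracles and small fixture builders used across the suite.

# build a canonical pair table from parallel vectors
make_pairs <- function(chromA, startA, endA, strandA, chromB, startB, endB,
                       strandB, sample = "T", mapq = 60L) {
  n <- length(startA)
  df <- data.frame(
    pair_id = sprintf("p%04d", seq_len(n)),
    chromA = rep_len(chromA, n), startA = as.integer(startA),
    endA = as.integer(endA), strandA = rep_len(strandA, n),
    chromB = rep_len(chromB, n), startB = as.integer(startB),
    endB = as.integer(endB), strandB = rep_len(strandB, n),
    sample = sample, mapq = mapq, stringsAsFactors = FALSE)
  svhotspot:::canonicalize_pairs(df)
}

# concordant-looking pairs around a given insert size
concordant_pairs <- function(n, insert = 3000L, chrom = "chrA",
                             read_len = 50L, start0 = 0L, jitter = 0L) {
  st <- start0 + seq_len(n) * 10L
  ins <- insert + if (jitter > 0) sample(-jitter:jitter, n, TRUE) else 0L
  make_pairs(chrom, st, st + read_len, "+",
             chrom, st + ins - read_len, st + ins, "-")
}

# O(n^2) single-linkage clustering by transitive closure; returns the
# partition as a sorted list of sorted pair_id vectors
bf_single_linkage <- function(pairs, max_gap) {
  n <- nrow(pairs)
  linked <- matrix(FALSE, n, n)
  gap <- function(s1, e1, s2, e2) max(0, max(s1, s2) - min(e1, e2))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      same <- pairs$chromA[i] == pairs$chromA[j] &&
        pairs$chromB[i] == pairs$chromB[j] &&
        pairs$strandA[i] == pairs$strandA[j] &&
        pairs$strandB[i] == pairs$strandB[j]
      if (!same) next
      ga <- gap(pairs$startA[i], pairs$endA[i], pairs$startA[j], pairs$endA[j])
      gb <- gap(pairs$startB[i], pairs$endB[i], pairs$startB[j], pairs$endB[j])
      linked[i, j] <- ga <= max_gap && gb <= max_gap
    }
  }
  reach <- linked
  repeat {
    nxt <- (reach %*% reach) > 0 | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[which(reach[i, ])] <- cid
    }
  }
  parts <- unname(split(pairs$pair_id, comp))
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, character(1), 1))]
}

# partition actually produced by the package clusterer (min_support 1),
# normalized the same way
pkg_partition <- function(pairs, max_gap) {
  cl <- cluster_discordant(pairs, max_gap, min_support = 1L)
  parts <- lapply(cl, function(c) sort(c$member_ids))
  parts[order(vapply(parts, `[`, character(1), 1))]
}

# exhaustive split-point oracle for a junction sequence: the longest prefix
# found in flank A and the longest suffix found in flank B
bf_junction_oracle <- function(junction, refA, refB) {
  n <- nchar(junction)
  p <- 0L
  for (k in seq_len(n)) {
    if (grepl(substring(junction, 1, k), refA, fixed = TRUE)) p <- k else break
  }
  s <- 0L
  for (k in seq_len(n)) {
    if (grepl(substring(junction, n - k + 1, n), refB, fixed = TRUE)) s <- k
    else break
  }
  ov <- p + s - n
  list(microhomology_len = max(0L, ov), untemplated_len = max(0L, -ov))
}

# independent recursive exhaustive single-change-point segmentation oracle
bf_segment_bounds <- function(x, penalty, min_probes) {
  rss <- function(v) sum((v - mean(v))^2)
  rec <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2 * min_probes) return(integer(0))
    best_k <- NA_integer_; best <- Inf
    for (k in (lo + min_probes - 1):(hi - min_probes)) {
      tot <- rss(x[lo:k]) + rss(x[(k + 1):hi])
      if (tot < best) { best <- tot; best_k <- k }
    }
    if (rss(x[lo:hi]) - best <= penalty) return(integer(0))
    sort(c(rec(lo, best_k), best_k, rec(best_k + 1, hi)))
  }
  rec(1L, length(x))
}

# plant a deletion junction with a given policy and return the pieces the
# junction analyzer needs
deletion_junction_fixture <- function(policy, seed, len = 50000L,
                                      s = 20000L, e = 25000L, flank = 800L) {
  g <- make_reference(1, len, gc = 0.45, seed = seed)
  pl <- plant_sv(g, truth_record("deletion", "chr1", s, e, policy = policy),
                 seed = seed + 1L)
  seqC <- pl$genome$chromosomes[["chr1"]]
  list(junction = junction_window(pl$haplotypes[[1]], s, flank %/% 2),
       refA = svhotspot:::subseq0(seqC, s - flank, s + flank),
       refB = svhotspot:::subseq0(seqC, e - flank, e + flank),
       planted = pl)
}

# a hand-built sv_call_set with a single typed call
make_call_set <- function(sv_type, chromA, posA, chromB = NA, posB = NA,
                          sample = "T", balanced = FALSE) {
  calls <- data.frame(
    call_id = paste0(sample, "_c1"), sv_type = sv_type, chromA = chromA,
    bpA_lo = as.integer(posA - 100), bpA_hi = as.integer(posA + 100),
    bpA_pos = as.integer(posA),
    chromB = as.character(chromB),
    bpB_lo = as.integer(if (is.na(posB)) NA else posB - 100),
    bpB_hi = as.integer(if (is.na(posB)) NA else posB + 100),
    bpB_pos = as.integer(posB),
    support = 5L, balanced = balanced, sample = sample, clusters = "1",
    donor_len = NA_real_, span = NA_real_, stringsAsFactors = FALSE)
  junctions <- data.frame(
    call_id = calls$call_id, cluster = 1L,
    side = c("A", "B"), chrom = c(chromA, as.character(chromB)),
    pos = c(as.integer(posA), as.integer(posB)), stringsAsFactors = FALSE)
  junctions <- junctions[!is.na(junctions$chrom), , drop = FALSE]
  structure(list(calls = calls, junctions = junctions),
            class = "sv_call_set")
}
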