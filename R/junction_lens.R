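# Junction-sequence characterization: micro-homology vs untemplated
# insertion at single junctions, and the shared/lost-base signature across
# the two derivatives of a balanced event (junctional duplication from
# overhang fill-in, or net loss). Matching is exact -- Sanger-grade junction
# sequence is assumed -- and ambiguous anchoring is an explicit failure, not
# a guess (repeat-rich loci motivate failing loudly).

# longest common substring between query and subject via diagonal scan;
# returns 0-based [q_start, q_end) / [s_start, s_end)
lcs_run <- function(query, subject) {
  qr <- charToRaw(query); sr <- charToRaw(subject)
  nq <- length(qr); ns <- length(sr)
  best <- list(len = 0L, q_start = 0L, s_start = 0L)
  for (d in seq(-(nq - 1L), ns - 1L)) {
    i1 <- max(1L, 1L - d); i2 <- min(nq, ns - d)
    if (i2 - i1 + 1L <= best$len) next
    eq <- qr[i1:i2] == sr[(i1 + d):(i2 + d)]
    r <- rle(eq)
    if (!any(r$values)) next
    lens <- r$lengths[r$values]
    if (max(lens) > best$len) {
      ends <- cumsum(r$lengths)
      w <- which(r$values & r$lengths == max(lens))[1]
      q_end <- i1 + ends[w] - 1L
      best <- list(len = max(lens),
                   q_start = q_end - max(lens),  # 0-based
                   s_start = q_end - max(lens) + d)
    }
  }
  best
}

#' Locate the unique maximal exact match of a derivative in a reference locus
#'
#' Searches both orientations; errors if the maximal match occurs more than
#' once in the locus (ambiguous anchoring) or is shorter than `min_anchor`.
#'
#' @param query derivative (junction window) sequence.
#' @param subject reference locus sequence.
#' @param min_anchor minimum acceptable match length (default 20).
#' @return list with `len`, `q_start`, `q_end`, `s_start`, `s_end` (forward
#'   subject coordinates, 0-based half-open), `orientation` (`"+"`/`"-"`).
#' @export
match_longest <- function(query, subject, min_anchor = 20L) {
  fwd <- lcs_run(query, subject)
  rc_sub <- revcomp(subject)
  rev <- lcs_run(query, rc_sub)
  ns <- nchar(subject)
  if (fwd$len >= rev$len) {
    m <- list(len = fwd$len, q_start = fwd$q_start,
              q_end = fwd$q_start + fwd$len, s_start = fwd$s_start,
              s_end = fwd$s_start + fwd$len, orientation = "+")
  } else {
    m <- list(len = rev$len, q_start = rev$q_start,
              q_end = rev$q_start + rev$len,
              s_start = ns - (rev$s_start + rev$len),
              s_end = ns - rev$s_start, orientation = "-")
  }
  if (m$len < min_anchor) {
    stopf("no anchor of >= %d bases in the locus (best %d)", min_anchor, m$len)
  }
  seg <- subseq0(subject, m$s_start, m$s_end)
  occ <- Biostrings::countPattern(seg, subject) +
    Biostrings::countPattern(revcomp(seg), subject)
  if (occ > 1L) stopf("ambiguous anchoring: maximal match occurs %d times", occ)
  m
}

#' Characterize a single junction sequence
#'
#' Finds the maximal prefix of `junction_seq` occurring in the locus-A flank
#' and the maximal suffix occurring in the locus-B flank (exact matching).
#' If the matched spans overlap inside the junction sequence the overlap is
#' micro-homology; if they leave a gap, the gap is untemplated insertion.
#'
#' @param junction_seq sequence reading across the A-to-B transition.
#' @param refA_flank,refB_flank reference flank sequences (each at least as
#'   long as their matched span; given in junction orientation).
#' @param min_anchor minimum anchor length per side (default 20).
#' @return list with `microhomology_len`, `untemplated_len` and
#'   `ambiguity` -- the `[lo, hi)` interval of junction coordinates within
#'   which the true split point is unresolvable (micro-homology) or that is
#'   untemplated sequence.
#' @export
analyze_junction <- function(junction_seq, refA_flank, refB_flank,
                             min_anchor = 20L) {
  n <- nchar(junction_seq)
  longest_hit <- function(get_sub, flank) {
    lo <- 0L; hi <- n
    while (lo < hi) {   # largest k with the k-prefix/suffix present in flank
      mid <- as.integer(ceiling((lo + hi) / 2))
      if (Biostrings::countPattern(get_sub(mid), flank) > 0) lo <- mid
      else hi <- mid - 1L
    }
    lo
  }
  p <- longest_hit(function(k) substring(junction_seq, 1L, k), refA_flank)
  s <- longest_hit(function(k) substring(junction_seq, n - k + 1L, n),
                   refB_flank)
  if (p < min_anchor) stopf("junction not anchored in the locus-A flank")
  if (s < min_anchor) stopf("junction not anchored in the locus-B flank")
  if (Biostrings::countPattern(substring(junction_seq, 1L, p), refA_flank) > 1) {
    stopf("ambiguous anchoring in the locus-A flank")
  }
  if (Biostrings::countPattern(substring(junction_seq, n - s + 1L, n),
                               refB_flank) > 1) {
    stopf("ambiguous anchoring in the locus-B flank")
  }
  overlap <- p + s - n
  list(microhomology_len = max(0L, overlap),
       untemplated_len = max(0L, -overlap),
       ambiguity = c(lo = min(p, n - s), hi = max(p, n - s)))
}

#' Reference-locus coverage of one derivative junction window
#'
#' Anchors the window in the locus (unique maximal exact match, either
#' orientation) and reports the covered reference interval, which side of
#' the junction the locus material sits on within the window, and `pos`: the
#' reference coordinate of the junction-adjacent retained base.
#'
#' @param der_seq derivative junction window (see [junction_window()]).
#' @param ref_locus list with `chrom`, `start`, `end`, `seq` -- the locus
#'   coordinates and sequence (`seq` may be omitted if `genome` is given).
#' @param genome optional [genome()] to extract the locus sequence from.
#' @param min_anchor minimum anchor length.
#' @return list with `interval` (`c(lo, hi)`, genome coordinates), `side`
#'   (`"left"`: locus material forms the start of the window and the
#'   junction edge is at its high end in window orientation; `"right"`:
#'   the reverse), `pos`, and `orientation`.
#' @export
junction_locus_coverage <- function(der_seq, ref_locus, genome = NULL,
                                    min_anchor = 20L) {
  if (is.null(ref_locus$seq)) {
    ref_locus$seq <- subseq0(chrom_seq(genome, ref_locus$chrom),
                             ref_locus$start, ref_locus$end)
  }
  m <- match_longest(der_seq, ref_locus$seq, min_anchor = min_anchor)
  nq <- nchar(der_seq)
  side <- if (m$q_start == 0L) "left"
          else if (m$q_end == nq) "right"
          else "internal"
  lo <- ref_locus$start + m$s_start
  hi <- ref_locus$start + m$s_end
  pos <- if (side == "left") {
    if (m$orientation == "+") hi - 1L else lo
  } else {
    if (m$orientation == "+") lo else hi - 1L
  }
  list(interval = c(lo = lo, hi = hi), side = side, pos = pos,
       orientation = m$orientation)
}

classify_mechanism <- function(shared, mh_scale = 10L) {
  shared <- shared[!is.na(shared)]
  hi <- max(shared); lo <- min(shared)
  if (hi > mh_scale && lo < -mh_scale) "mixed"
  else if (hi > mh_scale) "duplication"
  else if (lo < -mh_scale) "net_loss"
  else if (all(shared == 0)) "blunt"
  else "microhomology"
}

#' Shared/lost base signature of a balanced derivative pair
#'
#' For each reference locus, anchors both derivative junction windows and
#' intersects the covered intervals. A positive shared length means the same
#' reference segment is present on both derivatives (junctional duplication,
#' the overhang fill-in signature); a negative value is the gap between the
#' two covered intervals (net loss); zero is a blunt join. Values within
#' `mh_scale` bases are micro-homology scale.
#'
#' @param der1_seq,der2_seq junction windows of the two derivatives (for an
#'   inversion: its two junctions).
#' @param refA,refB reference loci as in [junction_locus_coverage()]
#'   (`refB = NULL` analyzes locus A only, e.g. the acceptor site of an
#'   insertion).
#' @param genome optional [genome()] supplying locus sequences.
#' @param mh_scale threshold separating micro-homology scale from
#'   duplication/net-loss calls (default 10 bases).
#' @param min_anchor minimum anchor length.
#' @return list with signed `sharedA`, `sharedB`, `mechanism_class`
#'   (`blunt`, `microhomology`, `duplication`, `net_loss`, `mixed`) and the
#'   per-derivative coverage intervals `coverA`, `coverB`. Symmetric in
#'   der1/der2.
#' @export
analyze_balanced_pair <- function(der1_seq, der2_seq, refA, refB = NULL,
                                  genome = NULL, mh_scale = 10L,
                                  min_anchor = 20L) {
  covA1 <- junction_locus_coverage(der1_seq, refA, genome, min_anchor)
  covA2 <- junction_locus_coverage(der2_seq, refA, genome, min_anchor)
  sharedA <- interval_overlap(covA1$interval[1], covA1$interval[2],
                              covA2$interval[1], covA2$interval[2])
  sharedB <- NA_integer_
  covB1 <- covB2 <- NULL
  if (!is.null(refB)) {
    covB1 <- junction_locus_coverage(der1_seq, refB, genome, min_anchor)
    covB2 <- junction_locus_coverage(der2_seq, refB, genome, min_anchor)
    sharedB <- interval_overlap(covB1$interval[1], covB1$interval[2],
                                covB2$interval[1], covB2$interval[2])
  }
  list(sharedA = as.integer(sharedA), sharedB = as.integer(sharedB),
       mechanism_class = classify_mechanism(c(sharedA, sharedB), mh_scale),
       coverA = list(der1 = covA1, der2 = covA2),
       coverB = list(der1 = covB1, der2 = covB2))
}

#' Breakpoint spacing and shared locus sequence between two events
#'
#' For two rearrangement events breaking in one locus (each summarized by the
#' locus coverage of the derivative retaining that locus, from
#' [junction_locus_coverage()]): the spacing is the distance between the two
#' junction-adjacent retained bases, and the shared length is the size of
#' the intersection of the retained intervals -- the stretch of locus
#' sequence carried by both derivatives. Two junctions retaining `[.., E)`
#' and `[S, ..)` with `E - S = 46` are 45 bases apart with 46 bases shared.
#'
#' @param covA,covB `junction_locus_coverage()` results for the two events.
#' @return list with `spacing`, `shared_len` (floored at 0) and `disjoint`
#'   (TRUE when the retained intervals share no base).
#' @export
pairwise_event_overlap <- function(covA, covB) {
  spacing <- abs(covA$pos - covB$pos)
  raw <- interval_overlap(covA$interval[1], covA$interval[2],
                          covB$interval[1], covB$interval[2])
  list(spacing = as.integer(spacing),
       shared_len = as.integer(max(0L, raw)),
       disjoint = raw <= 0L)
}
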