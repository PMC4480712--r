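# Cross-sample recurrence, in-silico break-apart FISH emulation, cohort
# frequency pooling and the delta-delta-Cq fold-change utility.

#' Count call breakpoints recurring in a genomic window
#'
#' Counts every call junction end whose point estimate falls inside the
#' half-open window; a call with both ends in the window contributes two
#' breakpoints. Samples are counted once regardless of how many of their
#' breakpoints hit.
#'
#' @param call_sets list of `sv_call_set` objects (one per sample), or one
#'   `sv_call_set`.
#' @param window list or vector with `chrom`, `start`, `end`.
#' @return list with `n_breakpoints`, `n_samples` and `per_sample` (data
#'   frame of per-sample breakpoint counts).
#' @export
recurrence <- function(call_sets, window) {
  if (inherits(call_sets, "sv_call_set")) call_sets <- list(call_sets)
  wchrom <- window$chrom %||% window[[1]]
  wstart <- as.numeric(window$start %||% window[[2]])
  wend <- as.numeric(window$end %||% window[[3]])
  rows <- lapply(call_sets, function(cs) {
    j <- cs$junctions
    if (nrow(j) == 0L) return(NULL)
    hit <- j$chrom == wchrom & j$pos >= wstart & j$pos < wend
    smp <- cs$calls$sample[match(j$call_id, cs$calls$call_id)]
    data.frame(sample = smp, hit = hit, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    return(list(n_breakpoints = 0L, n_samples = 0L,
                per_sample = data.frame(sample = character(),
                                        n_breakpoints = integer())))
  }
  agg <- stats::aggregate(hit ~ sample, data = rows, FUN = sum)
  names(agg)[2] <- "n_breakpoints"
  list(n_breakpoints = as.integer(sum(rows$hit)),
       n_samples = sum(agg$n_breakpoints > 0),
       per_sample = agg)
}

#' Break-apart FISH probe configuration
#'
#' Two probes flanking a gene; the assay is positive when at least
#' `positive_fraction_threshold` of cells show separated signals. The
#' default probe footprints mimic BAC-sized probes (169 kb and 159 kb).
#'
#' @param probeA,probeB `c(start, end)` probe intervals (same chromosome,
#'   non-overlapping, probeA left of probeB).
#' @param chrom chromosome name.
#' @param positive_fraction_threshold cell fraction cutoff (default 0.10).
#' @return object of class `breakapart_config`.
#' @export
breakapart_config <- function(probeA, probeB, chrom = "chr17",
                              positive_fraction_threshold = 0.10) {
  if (probeA[2] > probeB[1]) stopf("probes must not overlap (A left of B)")
  if (positive_fraction_threshold <= 0 || positive_fraction_threshold >= 1) {
    stopf("threshold must be inside (0, 1)")
  }
  structure(list(chrom = chrom, probeA = probeA, probeB = probeB,
                 positive_fraction_threshold = positive_fraction_threshold),
            class = "breakapart_config")
}

#' Emulate the break-apart FISH assay on SV calls
#'
#' A call separates the probes when it puts them on different derivatives or
#' relocates one relative to the other: a translocation or inversion with a
#' junction strictly between the probes (for inversions, exactly one
#' junction -- an inversion entirely inside the gap leaves the fusion signal
#' intact), or a deletion removing an entire probe. Insertions and
#' deletions confined to the gap preserve the two-probe adjacency and score
#' negative, mirroring the limited resolution of the assay for small
#' events. The result is positive iff some call separates the probes and
#' the fraction of cells carrying it reaches the threshold.
#'
#' @param calls an `sv_call_set`.
#' @param config a [breakapart_config()].
#' @param cell_fraction fraction of cells carrying the events.
#' @return `"positive"` or `"negative"`.
#' @export
breakapart_in_silico <- function(calls, config, cell_fraction) {
  if (cell_fraction < config$positive_fraction_threshold) return("negative")
  gap <- c(config$probeA[2], config$probeB[1])
  df <- calls$calls
  if (nrow(df) == 0L) return("negative")
  in_gap <- function(chrom, pos) {
    !is.na(pos) & chrom == config$chrom & pos >= gap[1] & pos < gap[2]
  }
  sep <- vapply(seq_len(nrow(df)), function(i) {
    type <- df$sv_type[i]
    endA <- in_gap(df$chromA[i], df$bpA_pos[i])
    endB <- in_gap(df$chromB[i], df$bpB_pos[i])
    if (type %in% c("TRA", "UNCLASSIFIED")) {
      # partner on another chromosome: any junction between the probes splits
      (endA && df$chromB[i] != config$chrom) ||
        (endB && df$chromA[i] != config$chrom)
    } else if (type == "INV") {
      xor(endA, endB)
    } else if (type == "DEL") {
      # must remove a whole probe
      lo <- df$bpA_pos[i]; hi <- df$bpB_pos[i]
      df$chromA[i] == config$chrom && !is.na(hi) &&
        ((lo <= config$probeA[1] && hi >= config$probeA[2]) ||
         (lo <= config$probeB[1] && hi >= config$probeB[2]))
    } else {
      FALSE  # INS: adjacency of the probes is preserved
    }
  }, logical(1))
  if (any(sep)) "positive" else "negative"
}

#' Per-platform and pooled cohort frequencies
#'
#' Percentages are rounded to integers, matching how screening frequencies
#' are conventionally reported; raw fractions are returned alongside.
#'
#' @param counts data frame with columns `platform`, `positives`, `total`.
#' @return list with `per_platform` (platform, positives, total, percent,
#'   fraction) and `pooled` (percent, fraction, positives, total). The
#'   pooled value is invariant to row order.
#' @export
cohort_frequency <- function(counts) {
  if (any(counts$total <= 0)) stopf("zero total in cohort counts")
  if (any(counts$positives < 0 | counts$positives > counts$total)) {
    stopf("positives must be within [0, total]")
  }
  per <- data.frame(platform = counts$platform,
                    positives = counts$positives, total = counts$total,
                    percent = round(100 * counts$positives / counts$total),
                    fraction = counts$positives / counts$total,
                    stringsAsFactors = FALSE)
  pooled_pos <- sum(counts$positives); pooled_tot <- sum(counts$total)
  list(per_platform = per,
       pooled = list(percent = round(100 * pooled_pos / pooled_tot),
                     fraction = pooled_pos / pooled_tot,
                     positives = pooled_pos, total = pooled_tot))
}

#' Relative expression fold change from quantification cycles
#'
#' Normalizes the target gene Cq against a reference gene (delta Cq) in both
#' the sample and the control, and returns `2^-ddCq` where
#' `ddCq = dCq_sample - dCq_control`.
#'
#' @param cq_target,cq_reference quantification cycles for the sample.
#' @param cq_target_ctrl,cq_reference_ctrl cycles for the control.
#' @return fold change (1 when all four cycles are equal).
#' @export
foldchange_ddcq <- function(cq_target, cq_reference, cq_target_ctrl,
                            cq_reference_ctrl) {
  if (any(c(cq_target, cq_reference, cq_target_ctrl, cq_reference_ctrl) <= 0)) {
    stopf("Cq values must be positive")
  }
  ddcq <- (cq_target - cq_reference) - (cq_target_ctrl - cq_reference_ctrl)
  2^(-ddcq)
}
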