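# Copy-number probe-track segmentation, transition classification inside a
# gene window, and copy-neutral LOH detection from B-allele fractions.
# Segmentation is penalized least-squares binary segmentation with an
# exhaustive per-split scan -- the contract is boundary recovery, not
# reproduction of any proprietary array pipeline.

# best single split of x[lo..hi] (1-based, inclusive) minimizing total RSS;
# cumulative sums make each scan O(n)
best_split <- function(cs, cs2, lo, hi, min_probes) {
  n <- hi - lo + 1L
  if (n < 2L * min_probes) return(NULL)
  ks <- (lo + min_probes - 1L):(hi - min_probes)  # last index of left part
  sum_all <- cs[hi + 1L] - cs[lo]
  sq_all <- cs2[hi + 1L] - cs2[lo]
  rss_all <- sq_all - sum_all^2 / n
  sum_l <- cs[ks + 1L] - cs[lo]
  sq_l <- cs2[ks + 1L] - cs2[lo]
  n_l <- ks - lo + 1L
  rss_l <- sq_l - sum_l^2 / n_l
  rss_r <- (sq_all - sq_l) - (sum_all - sum_l)^2 / (n - n_l)
  tot <- rss_l + rss_r
  k <- ks[which.min(tot)]
  list(split = k, gain = rss_all - min(tot))
}

#' Segment a copy-number probe track
#'
#' Recursive binary segmentation: at each step the split minimizing the
#' residual sum of squares is accepted if the RSS reduction exceeds
#' `penalty`; segments shorter than `min_probes` are never produced. Segment
#' states are assigned by thresholds on the segment mean.
#'
#' @param track data frame with `pos` and `log2` columns (probe-sorted).
#' @param penalty model-complexity weight per accepted breakpoint; default
#'   10 times a robust noise-variance estimate from first differences.
#' @param min_probes minimum probes per segment (default 10).
#' @param loss_threshold,gain_threshold log2 state thresholds
#'   (defaults -0.2 / 0.2).
#' @return data frame of segments tiling the track: `start`, `end`
#'   (0-based half-open probe indices), `start_pos`, `end_pos` (track
#'   coordinates; `end_pos` is one probe-spacing past the last probe),
#'   `mean_log2`, `state`, `n_probes`.
#' @export
segment_profile <- function(track, penalty = NULL, min_probes = 10L,
                            loss_threshold = -0.2, gain_threshold = 0.2) {
  x <- track$log2
  n <- length(x)
  if (n < 2L * min_probes) stopf("track too short: %d probes (need >= %d)",
                                 n, 2L * min_probes)
  if (is.null(penalty)) {
    sigma <- stats::mad(diff(x)) / sqrt(2)
    penalty <- 10 * max(sigma^2, 1e-12)
  }
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  bounds <- integer(0)
  recurse <- function(lo, hi) {
    sp <- best_split(cs, cs2, lo, hi, min_probes)
    if (is.null(sp) || sp$gain <= penalty) return(invisible())
    bounds <<- c(bounds, sp$split)
    recurse(lo, sp$split)
    recurse(sp$split + 1L, hi)
  }
  recurse(1L, n)
  bounds <- sort(bounds)
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  mean_log2 <- (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
  state <- ifelse(mean_log2 < loss_threshold, "loss",
                  ifelse(mean_log2 > gain_threshold, "gain", "neutral"))
  spacing <- if (n > 1) track$pos[2] - track$pos[1] else 1L
  data.frame(start = starts - 1L, end = ends,
             start_pos = track$pos[starts],
             end_pos = c(track$pos[starts[-1]],
                         track$pos[n] + spacing),
             mean_log2 = mean_log2, state = state,
             n_probes = ends - starts + 1L, stringsAsFactors = FALSE)
}

#' Classify copy-number state transitions inside a gene window
#'
#' Every boundary between adjacent segments yields one call: a change
#' between neutral and loss (either direction) is `into-loss`, between
#' neutral and gain `into-gain`, and a direct change between loss and gain
#' (no neutral between) `loss-to-gain`. Boundaries between segments of the
#' same state are reported with class `none`. `window_hit` flags boundaries
#' inside the half-open window.
#'
#' @param segments output of [segment_profile()].
#' @param window `c(start, end)` in track coordinates (half-open).
#' @return data frame with `position`, `class`, `window_hit`.
#' @export
classify_window_transitions <- function(segments, window) {
  k <- nrow(segments)
  if (k < 2L) {
    return(data.frame(position = integer(), class = character(),
                      window_hit = logical(), stringsAsFactors = FALSE))
  }
  pos <- segments$start_pos[-1]
  left <- segments$state[-k]
  right <- segments$state[-1]
  pair <- paste(pmin(left, right), pmax(left, right))
  cls <- ifelse(pair == "loss neutral", "into-loss",
                ifelse(pair == "gain neutral", "into-gain",
                       ifelse(pair == "gain loss", "loss-to-gain", "none")))
  data.frame(position = pos, class = cls,
             window_hit = pos >= window[1] & pos < window[2],
             stringsAsFactors = FALSE)
}

#' Detect loss of heterozygosity from a BAF track
#'
#' LOH is called when the mean absolute deviation of B-allele fractions from
#' 0.5 exceeds `threshold`; it is copy-neutral when the overlapping
#' copy-number state is neutral. At tumor purity p the deviation of an LOH
#' region is p/2 (0.5 at purity 1), so the default threshold 0.3 calls LOH
#' down to 60% purity.
#'
#' @param baf data frame with `pos` and `baf`.
#' @param region `c(start, end)` half-open region to assess.
#' @param cn_state copy-number state of the overlapping segment
#'   (`"loss"`, `"neutral"`, `"gain"`).
#' @param threshold mean |BAF - 0.5| cutoff (default 0.3).
#' @param min_snps minimum informative SNPs (default 20).
#' @return list with `region`, `loh`, `copy_neutral`, `mean_baf_deviation`,
#'   `n_snps`.
#' @export
detect_loh <- function(baf, region, cn_state, threshold = 0.3,
                       min_snps = 20L) {
  sel <- baf$pos >= region[1] & baf$pos < region[2]
  if (sum(sel) < min_snps) {
    stopf("too few informative SNPs in region: %d (need >= %d)",
          sum(sel), min_snps)
  }
  dev <- mean(abs(baf$baf[sel] - 0.5))
  loh <- dev > threshold
  list(region = region, loh = loh,
       copy_neutral = loh && cn_state == "neutral",
       mean_baf_deviation = dev, n_snps = sum(sel))
}
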