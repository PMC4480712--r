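# Discordant mate-pair (dPET) structural-variant calling: insert-size model,
# pair classification, single-linkage clustering of discordant pairs,
# breakpoint prediction from cluster geometry, call typing and germline
# subtraction.

#' Estimate insert-size statistics of a mate-pair library
#'
#' Apparent insert is the outer span of a pair (end B end minus end A start).
#' The estimate uses intra-chromosomal pairs in the expected inward
#' orientation; the spread is the raw median absolute deviation (unscaled),
#' so three inserts {2900, 3000, 3100} give MAD 100.
#'
#' @param pairs pair table (canonicalized; see [simulate_mate_pairs()] or
#'   [read_pairs_sam()]).
#' @param k MAD multiplier defining the concordant insert window (default 5).
#' @param min_pairs minimum usable pairs (default 1000).
#' @return object of class `library_stats` with `insert_median`,
#'   `insert_mad`, `k`, `n_used`.
#' @export
estimate_library_stats <- function(pairs, k = 5, min_pairs = 1000L) {
  ok <- pairs$chromA == pairs$chromB & pairs$strandA == "+" &
    pairs$strandB == "-"
  ins <- pairs$endB[ok] - pairs$startA[ok]
  if (length(ins) < min_pairs) {
    stopf("insufficient pairs: %d intra-chromosomal inward pairs (need >= %d)",
          length(ins), min_pairs)
  }
  med <- stats::median(ins)
  mad_raw <- stats::median(abs(ins - med))
  structure(list(insert_median = med, insert_mad = mad_raw, k = k,
                 n_used = length(ins)), class = "library_stats")
}

#' Manually construct library statistics
#' @param insert_median,insert_mad insert-size median and raw MAD in bases.
#' @param k MAD multiplier for the concordance window.
#' @return a `library_stats` object.
#' @export
library_stats <- function(insert_median, insert_mad, k = 5) {
  if (insert_median <= 0 || insert_mad < 0) stopf("invalid library stats")
  structure(list(insert_median = insert_median, insert_mad = insert_mad,
                 k = k, n_used = NA_integer_), class = "library_stats")
}

insert_bounds <- function(stats) {
  if (stats$insert_mad == 0) {
    stats$insert_median * c(0.99, 1.01)
  } else {
    stats$insert_median + c(-1, 1) * stats$k * stats$insert_mad
  }
}

#' Classify read pairs as concordant or by discordance type
#'
#' A pair is concordant iff both ends map to one chromosome, in the expected
#' inward orientation (`+` on the lower-coordinate end, `-` on the higher),
#' with apparent insert inside `median +/- k * MAD` (or within 1% of the
#' median when MAD is 0). Otherwise: different chromosomes are
#' `inter-chromosomal`; equal strands are `inv-type`; everted orientation or
#' an undersized insert is `dup-type`; an oversized insert is `del-type`.
#'
#' @param pairs canonicalized pair table.
#' @param stats a `library_stats`.
#' @return character vector of classifications, one per pair.
#' @export
classify_pairs <- function(pairs, stats) {
  bounds <- insert_bounds(stats)
  ins <- pairs$endB - pairs$startA
  cls <- rep("concordant", nrow(pairs))
  inter <- pairs$chromA != pairs$chromB
  inv <- !inter & pairs$strandA == pairs$strandB
  evert <- !inter & pairs$strandA == "-" & pairs$strandB == "+"
  fr <- !inter & pairs$strandA == "+" & pairs$strandB == "-"
  cls[inter] <- "inter-chromosomal"
  cls[inv] <- "inv-type"
  cls[evert] <- "dup-type"
  cls[fr & ins > bounds[2]] <- "del-type"
  cls[fr & ins < bounds[1]] <- "dup-type"
  cls
}

# --------------------------------------------------------------- clustering

#' Cluster discordant pairs with similar mapping patterns
#'
#' Two pairs belong to the same cluster iff they share the chromosome pair
#' and strand pattern and both end regions are within `max_gap` of each other
#' (gap between mapping intervals; single linkage, transitive closure). The
#' cluster size (number of supporting pairs) is the dPET cluster size.
#'
#' @param pairs canonicalized pair table of discordant pairs.
#' @param max_gap maximum gap in bases between member mapping regions
#'   (sensible default: one fragment length, `insert_median + k * MAD`).
#' @param min_support minimum cluster size kept (default 3).
#' @return list of `dpet_cluster` objects sorted by (chromA, startA); each
#'   has `sideA`/`sideB` (chrom, start, end, strand), `support`,
#'   `member_ids`, `members` (per-pair coordinates) and `sample`.
#' @export
cluster_discordant <- function(pairs, max_gap, min_support = 3L) {
  if (nrow(pairs) == 0L) return(list())
  key <- paste(pairs$chromA, pairs$chromB, pairs$strandA, pairs$strandB,
               sep = "|")
  out <- list()
  for (kk in unique(key)) {
    sub <- pairs[key == kk, , drop = FALSE]
    sub <- sub[order(sub$startA, sub$startB), , drop = FALSE]
    n <- nrow(sub)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    # sorted by startA: once startA[i] - startA[j] exceeds max_gap plus the
    # widest mapping region, no earlier pair can link to i on side A
    maxw <- max(sub$endA - sub$startA)
    for (i in seq_len(n)) {
      j <- i - 1L
      while (j >= 1L) {
        if (sub$startA[i] - sub$startA[j] > max_gap + maxw) break
        gapA <- interval_gap(sub$startA[i], sub$endA[i],
                             sub$startA[j], sub$endA[j])
        gapB <- interval_gap(sub$startB[i], sub$endB[i],
                             sub$startB[j], sub$endB[j])
        if (gapA <= max_gap && gapB <= max_gap) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
        j <- j - 1L
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      idx <- which(roots == r)
      if (length(idx) < min_support) next
      mem <- sub[idx, , drop = FALSE]
      cl <- structure(list(
        sideA = list(chrom = mem$chromA[1], start = min(mem$startA),
                     end = max(mem$endA), strand = mem$strandA[1]),
        sideB = list(chrom = mem$chromB[1], start = min(mem$startB),
                     end = max(mem$endB), strand = mem$strandB[1]),
        support = length(idx), member_ids = mem$pair_id,
        members = mem, sample = mem$sample[1]), class = "dpet_cluster")
      out[[length(out) + 1L]] <- cl
    }
  }
  ord <- order(vapply(out, function(c) c$sideA$chrom, character(1)),
               vapply(out, function(c) c$sideA$start, numeric(1)),
               vapply(out, function(c) c$sideB$chrom, character(1)),
               vapply(out, function(c) c$sideB$start, numeric(1)))
  out[ord]
}

#' Summarize clusters as a data frame
#' @param clusters list of `dpet_cluster`.
#' @return one row per cluster.
#' @export
clusters_summary <- function(clusters) {
  if (length(clusters) == 0L) {
    return(data.frame(chromA = character(), startA = integer(),
                      endA = integer(), strandA = character(),
                      chromB = character(), startB = integer(),
                      endB = integer(), strandB = character(),
                      support = integer(), sample = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(clusters, function(c) {
    data.frame(chromA = c$sideA$chrom, startA = c$sideA$start,
               endA = c$sideA$end, strandA = c$sideA$strand,
               chromB = c$sideB$chrom, startB = c$sideB$start,
               endB = c$sideB$end, strandB = c$sideB$strand,
               support = c$support, sample = c$sample,
               stringsAsFactors = FALSE)
  }))
}

# ------------------------------------------------------ breakpoint geometry

# point estimate and interval for one cluster side. Strand "+" means the
# junction lies to the right of the mapping region (tags point toward it),
# "-" to the left. The interval is the region the junction must occupy given
# that no member fragment exceeds insert_max; the point estimate is the
# junction-proximal edge of the union of member mappings plus a uniform-max
# (range/(n-1)) correction toward the junction.
side_breakpoint <- function(members, side, stats, read_len) {
  st <- members[[paste0("start", side)]]
  en <- members[[paste0("end", side)]]
  strand <- members[[paste0("strand", side)]][1]
  imax <- max(insert_bounds(stats)[2], stats$insert_median)
  n <- length(st)
  if (strand == "+") {
    tip <- max(en)
    corr <- if (n > 1) (tip - min(en)) / (n - 1) else 0
    lo <- tip
    hi <- max(lo + 1, min(st) + round(imax) - read_len)
    point <- tip + corr
  } else {
    tip <- min(st)
    corr <- if (n > 1) (max(st) - tip) / (n - 1) else 0
    hi <- tip
    lo <- min(hi - 1, max(en) - round(imax) + read_len)
    point <- tip - corr
  }
  list(chrom = members[[paste0("chrom", side)]][1], strand = strand,
       lo = as.integer(lo), hi = as.integer(hi), tip = as.integer(tip),
       point = round(point))
}

#' Predict breakpoint intervals for a dPET cluster
#'
#' Per side, the interval starts at the junction-proximal edge of the union
#' of member mapping regions and extends junction-ward as far as the largest
#' concordant fragment allows; with error-free reads the true junction falls
#' inside it. A single-pair cluster gives the widest interval
#' (about `frag_max - 2 * read_len`); more members shrink it monotonically.
#'
#' @param cluster a `dpet_cluster`.
#' @param stats a `library_stats`.
#' @param read_len tag length in bases.
#' @return list with elements `A` and `B`, each `(chrom, strand, lo, hi,
#'   tip, point)`; `[lo, hi)` is the interval, `point` the point estimate.
#' @export
predict_breakpoints <- function(cluster, stats, read_len) {
  list(A = side_breakpoint(cluster$members, "A", stats, read_len),
       B = side_breakpoint(cluster$members, "B", stats, read_len))
}

# --------------------------------------------------------------- SV calling

cluster_class <- function(cl, stats) {
  if (cl$sideA$chrom != cl$sideB$chrom) return("inter")
  sp <- paste0(cl$sideA$strand, cl$sideB$strand)
  if (sp %in% c("++", "--")) return("inv")
  if (sp == "-+") return("dup")
  ins <- cl$sideB$end - cl$sideA$start
  if (ins > insert_bounds(stats)[2]) "del" else "dup"
}

new_call <- function(id, sv_type, bpA, bpB, support, balanced, sample,
                     clusters, donor_len = NA_real_, span = NA_real_) {
  data.frame(call_id = id, sv_type = sv_type,
             chromA = bpA$chrom, bpA_lo = bpA$lo, bpA_hi = bpA$hi,
             bpA_pos = bpA$point,
             chromB = if (is.null(bpB)) NA_character_ else bpB$chrom,
             bpB_lo = if (is.null(bpB)) NA_integer_ else bpB$lo,
             bpB_hi = if (is.null(bpB)) NA_integer_ else bpB$hi,
             bpB_pos = if (is.null(bpB)) NA_integer_ else bpB$point,
             support = support, balanced = balanced, sample = sample,
             clusters = paste(clusters, collapse = ","),
             donor_len = donor_len, span = span, stringsAsFactors = FALSE)
}

#' Type SV calls from dPET clusters
#'
#' * a `del`-pattern cluster becomes a DEL (span = distance between the two
#'   breakpoint point estimates);
#' * a `++` and a `--` inversion cluster flanking the same segment (both
#'   breakpoint pairs within `pairing_window`) merge into one balanced INV,
#'   whose span is the outer distance between breakpoints;
#' * two reciprocal inter-chromosomal clusters (A- and B-side breakpoints
#'   both within `pairing_window`) merge into one balanced TRA;
#' * two inter-chromosomal clusters joining both ends of a short donor
#'   segment (B-side breakpoints separated by more than `pairing_window` but
#'   at most `donor_ceiling`) into one acceptor locus become an INS with the
#'   donor length reported;
#' * everything else is emitted as an UNCLASSIFIED single-sided call, never
#'   silently dropped.
#'
#' @param clusters list of `dpet_cluster` from one sample.
#' @param stats a `library_stats`.
#' @param read_len tag length.
#' @param pairing_window bases within which reciprocal breakpoints must agree
#'   (default 5000).
#' @param donor_ceiling maximum insertion donor length (default 100 kb).
#' @return an `sv_call_set`: list with `calls` (one row per call) and
#'   `junctions` (one row per contributing cluster end: call_id, cluster,
#'   side, chrom, pos).
#' @export
call_svs <- function(clusters, stats, read_len, pairing_window = 5000L,
                     donor_ceiling = 100000L) {
  n <- length(clusters)
  calls <- list(); junctions <- list()
  if (n == 0L) return(empty_call_set())
  sample <- clusters[[1]]$sample
  bps <- lapply(clusters, predict_breakpoints, stats = stats,
                read_len = read_len)
  cls <- vapply(clusters, cluster_class, character(1), stats = stats)
  used <- rep(FALSE, n)
  cid <- 0L
  next_id <- function() {
    cid <<- cid + 1L
    sprintf("%s_call%03d", sample, cid)
  }
  add_junctions <- function(id, ks) {
    for (k in ks) {
      junctions[[length(junctions) + 1L]] <<- data.frame(
        call_id = id, cluster = k,
        side = c("A", "B"),
        chrom = c(bps[[k]]$A$chrom, bps[[k]]$B$chrom),
        pos = c(bps[[k]]$A$point, bps[[k]]$B$point),
        stringsAsFactors = FALSE)
    }
  }
  near <- function(x, y) abs(x - y) <= pairing_window

  # balanced inversions: ++ matched with --
  for (i in which(cls == "inv" & !used)) {
    if (used[i]) next
    spi <- clusters[[i]]$sideA$strand
    for (j in which(cls == "inv" & !used)) {
      if (j == i || clusters[[j]]$sideA$strand == spi) next
      if (clusters[[i]]$sideA$chrom != clusters[[j]]$sideA$chrom) next
      if (near(bps[[i]]$A$point, bps[[j]]$A$point) &&
          near(bps[[i]]$B$point, bps[[j]]$B$point)) {
        id <- next_id()
        aa <- list(chrom = bps[[i]]$A$chrom,
                   lo = min(bps[[i]]$A$lo, bps[[j]]$A$lo),
                   hi = max(bps[[i]]$A$hi, bps[[j]]$A$hi),
                   point = min(bps[[i]]$A$point, bps[[j]]$A$point))
        bb <- list(chrom = bps[[i]]$B$chrom,
                   lo = min(bps[[i]]$B$lo, bps[[j]]$B$lo),
                   hi = max(bps[[i]]$B$hi, bps[[j]]$B$hi),
                   point = max(bps[[i]]$B$point, bps[[j]]$B$point))
        calls[[length(calls) + 1L]] <- new_call(
          id, "INV", aa, bb,
          support = max(clusters[[i]]$support, clusters[[j]]$support),
          balanced = TRUE, sample = sample, clusters = c(i, j),
          span = bb$point - aa$point)
        add_junctions(id, c(i, j))
        used[c(i, j)] <- TRUE
        break
      }
    }
  }

  # inter-chromosomal: reciprocal TRA, then INS
  for (i in which(cls == "inter" & !used)) {
    if (used[i]) next
    for (j in which(cls == "inter" & !used)) {
      if (j == i) next
      ci <- clusters[[i]]; cj <- clusters[[j]]
      if (ci$sideA$chrom != cj$sideA$chrom ||
          ci$sideB$chrom != cj$sideB$chrom) next
      same_pattern <- ci$sideA$strand == cj$sideA$strand
      if (same_pattern) next
      if (near(bps[[i]]$A$point, bps[[j]]$A$point) &&
          near(bps[[i]]$B$point, bps[[j]]$B$point)) {
        id <- next_id()
        calls[[length(calls) + 1L]] <- new_call(
          id, "TRA",
          list(chrom = bps[[i]]$A$chrom,
               lo = min(bps[[i]]$A$lo, bps[[j]]$A$lo),
               hi = max(bps[[i]]$A$hi, bps[[j]]$A$hi),
               point = round(mean(c(bps[[i]]$A$point, bps[[j]]$A$point)))),
          list(chrom = bps[[i]]$B$chrom,
               lo = min(bps[[i]]$B$lo, bps[[j]]$B$lo),
               hi = max(bps[[i]]$B$hi, bps[[j]]$B$hi),
               point = round(mean(c(bps[[i]]$B$point, bps[[j]]$B$point)))),
          support = max(ci$support, cj$support), balanced = TRUE,
          sample = sample, clusters = c(i, j))
        add_junctions(id, c(i, j))
        used[c(i, j)] <- TRUE
        break
      }
      donor <- abs(bps[[i]]$B$point - bps[[j]]$B$point)
      if (near(bps[[i]]$A$point, bps[[j]]$A$point) &&
          donor > pairing_window && donor <= donor_ceiling) {
        id <- next_id()
        calls[[length(calls) + 1L]] <- new_call(
          id, "INS",
          list(chrom = bps[[i]]$A$chrom,
               lo = min(bps[[i]]$A$lo, bps[[j]]$A$lo),
               hi = max(bps[[i]]$A$hi, bps[[j]]$A$hi),
               point = round(mean(c(bps[[i]]$A$point, bps[[j]]$A$point)))),
          list(chrom = bps[[i]]$B$chrom,
               lo = min(bps[[i]]$B$lo, bps[[j]]$B$lo),
               hi = max(bps[[i]]$B$hi, bps[[j]]$B$hi),
               point = round(mean(c(bps[[i]]$B$point, bps[[j]]$B$point)))),
          support = max(ci$support, cj$support), balanced = FALSE,
          sample = sample, clusters = c(i, j), donor_len = donor)
        add_junctions(id, c(i, j))
        used[c(i, j)] <- TRUE
        break
      }
    }
  }

  # deletions and leftovers
  for (i in which(!used)) {
    id <- next_id()
    if (cls[i] == "del") {
      calls[[length(calls) + 1L]] <- new_call(
        id, "DEL", bps[[i]]$A, bps[[i]]$B, clusters[[i]]$support,
        balanced = FALSE, sample = sample, clusters = i,
        span = bps[[i]]$B$point - bps[[i]]$A$point)
    } else {
      calls[[length(calls) + 1L]] <- new_call(
        id, "UNCLASSIFIED", bps[[i]]$A, bps[[i]]$B, clusters[[i]]$support,
        balanced = FALSE, sample = sample, clusters = i)
    }
    add_junctions(id, i)
    used[i] <- TRUE
  }

  calls <- do.call(rbind, calls)
  calls <- calls[order(calls$chromA, calls$bpA_pos), , drop = FALSE]
  rownames(calls) <- NULL
  junctions <- do.call(rbind, junctions)
  rownames(junctions) <- NULL
  structure(list(calls = calls, junctions = junctions),
            class = "sv_call_set")
}

empty_call_set <- function() {
  structure(list(
    calls = data.frame(call_id = character(), sv_type = character(),
                       chromA = character(), bpA_lo = integer(),
                       bpA_hi = integer(), bpA_pos = integer(),
                       chromB = character(), bpB_lo = integer(),
                       bpB_hi = integer(), bpB_pos = integer(),
                       support = integer(), balanced = logical(),
                       sample = character(), clusters = character(),
                       donor_len = numeric(), span = numeric(),
                       stringsAsFactors = FALSE),
    junctions = data.frame(call_id = character(), cluster = integer(),
                           side = character(), chrom = character(),
                           pos = integer(), stringsAsFactors = FALSE)),
    class = "sv_call_set")
}

#' @export
print.sv_call_set <- function(x, ...) {
  tb <- table(x$calls$sv_type)
  cat(sprintf("<sv_call_set> %d call(s): %s\n", nrow(x$calls),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Subtract germline calls from tumor calls
#'
#' A tumor call is removed iff a normal call of the same type (and same
#' chromosome pair) has both breakpoint point estimates within `window`
#' bases of the tumor call's.
#'
#' @param tumor_calls,normal_calls `sv_call_set`s on the same reference.
#' @param window matching distance in bases (default 2000).
#' @return an `sv_call_set` holding the somatic subset of `tumor_calls`.
#' @export
somatic_subtract <- function(tumor_calls, normal_calls, window = 2000L) {
  tc <- tumor_calls$calls; nc <- normal_calls$calls
  if (nrow(tc) == 0L || nrow(nc) == 0L) return(tumor_calls)
  keep <- vapply(seq_len(nrow(tc)), function(i) {
    m <- nc$sv_type == tc$sv_type[i] & nc$chromA == tc$chromA[i] &
      (is.na(tc$chromB[i]) | (!is.na(nc$chromB) & nc$chromB == tc$chromB[i])) &
      abs(nc$bpA_pos - tc$bpA_pos[i]) <= window &
      (is.na(tc$bpB_pos[i]) | abs(nc$bpB_pos - tc$bpB_pos[i]) <= window)
    !any(m, na.rm = TRUE)
  }, logical(1))
  structure(list(calls = tc[keep, , drop = FALSE],
                 junctions = tumor_calls$junctions[
                   tumor_calls$junctions$call_id %in% tc$call_id[keep], ,
                   drop = FALSE]),
            class = "sv_call_set")
}
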