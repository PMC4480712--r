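# Readers and writers for the standard formats the pipeline touches.
# FASTA goes through Biostrings; SAM ingest goes through Rsamtools/htslib.
# The BEDPE dialect (10 standard columns + key=value extensions carrying
# junction policy and support) and the minimal name-paired SAM writer are
# implemented here because no installed package emits them from plain tables.
# All coordinates inside the package are 0-based half-open; SAM's 1-based
# positions are converted at this boundary.

# -------------------------------------------------------------------- FASTA

#' Read a FASTA file into a genome
#'
#' Sequences are uppercased on ingest; any non-A/C/G/T character is an error
#' naming the record and offset.
#'
#' @param path FASTA file path.
#' @param name genome name (defaults to the file name).
#' @return a [genome()].
#' @export
read_fasta <- function(path, name = basename(path)) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stopf("no records in '%s'", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) stopf("duplicate sequence name '%s'", nm[duplicated(nm)][1])
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  genome(seqs, name = name)
}

#' Write a genome (or haplotype list) to FASTA
#'
#' @param x a [genome()] or a list of `haplotype` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "genome")) {
    x$chromosomes
  } else {
    stats::setNames(vapply(x, function(h) h$seq, character(1)),
                    vapply(x, function(h) h$name, character(1)))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# ---------------------------------------------------------------------- SAM

cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]", "", ops))
    sum(n[substring(ops, nchar(ops)) %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read name-paired alignments from a SAM file
#'
#' Parses a SAM file (mandatory fields suffice) via Rsamtools, drops
#' unmapped, secondary and supplementary records, joins mates by query name,
#' converts 1-based positions to the internal 0-based half-open convention
#' and takes strand from the reverse flag. Query names with anything other
#' than two primary mapped records are counted as orphans and skipped. Pairs
#' whose lower mapping quality falls below `mapq_floor` are dropped and
#' counted -- the floor stands in for upstream alignment filtering and is
#' deliberately explicit.
#'
#' @param path SAM file path.
#' @param sample sample identifier to stamp on the pairs.
#' @param mapq_floor minimum per-end mapping quality (default 10).
#' @param orientation `"inward"` leaves strands as mapped; `"same-strand"`
#'   flips end B's strand to normalize a SOLiD-style same-strand mate-pair
#'   library to the internal inward (FR) convention.
#' @return list with `pairs` (canonicalized pair table), `n_orphans`,
#'   `n_low_mapq`, `n_secondary`.
#' @export
read_pairs_sam <- function(path, sample = "S1", mapq_floor = 10L,
                           orientation = c("inward", "same-strand")) {
  orientation <- match.arg(orientation)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "qwidth"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- rec$flag
  secondary <- bitwAnd(flag, 256L) > 0 | bitwAnd(flag, 2048L) > 0
  unmapped <- bitwAnd(flag, 4L) > 0 | is.na(rec$pos)
  keep <- !secondary & !unmapped
  qname <- rec$qname[keep]
  width <- rec$qwidth[keep]
  no_w <- is.na(width)
  if (any(no_w)) width[no_w] <- cigar_ref_width(rec$cigar[keep][no_w])
  df <- data.frame(
    qname = qname,
    chrom = as.character(rec$rname[keep]),
    start = rec$pos[keep] - 1L,
    end = rec$pos[keep] - 1L + width,
    strand = ifelse(bitwAnd(flag[keep], 16L) > 0, "-", "+"),
    mapq = rec$mapq[keep], stringsAsFactors = FALSE)
  cnt <- table(df$qname)
  paired <- names(cnt)[cnt == 2L]
  n_orphans <- sum(cnt != 2L)
  df <- df[df$qname %in% paired, , drop = FALSE]
  df <- df[order(df$qname, df$start), , drop = FALSE]
  i1 <- seq(1L, nrow(df), by = 2L)
  i2 <- i1 + 1L
  pairs <- data.frame(
    pair_id = df$qname[i1],
    chromA = df$chrom[i1], startA = df$start[i1], endA = df$end[i1],
    strandA = df$strand[i1],
    chromB = df$chrom[i2], startB = df$start[i2], endB = df$end[i2],
    strandB = df$strand[i2],
    sample = sample, mapq = pmin(df$mapq[i1], df$mapq[i2]),
    stringsAsFactors = FALSE)
  if (orientation == "same-strand") {
    pairs$strandB <- ifelse(pairs$strandB == "+", "-", "+")
  }
  low <- !is.na(pairs$mapq) & pairs$mapq < mapq_floor
  pairs <- canonicalize_pairs(pairs[!low, , drop = FALSE])
  rownames(pairs) <- NULL
  list(pairs = pairs, n_orphans = as.integer(n_orphans),
       n_low_mapq = sum(low), n_secondary = sum(secondary))
}

#' Write simulated pairs as a minimal name-paired SAM file
#'
#' Emits mandatory fields only (plus read sequences when supplied).
#' Internal 0-based starts become SAM 1-based positions.
#'
#' @param sim result of [simulate_mate_pairs()] (or any list with `pairs`
#'   and optionally `reads`).
#' @param genome the reference [genome()] (for `@SQ` header lines).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim, genome, path) {
  pairs <- sim$pairs
  reads <- sim$reads
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(genome$chromosomes),
                       nchar(genome$chromosomes))), con)
  flag_of <- function(strand, mate_strand, first) {
    1L + 64L * first + 128L * (1 - first) +
      16L * (strand == "-") + 32L * (mate_strand == "-")
  }
  rec <- function(end, other, first, seqs) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t0\t%s\t*",
            pairs$pair_id,
            flag_of(pairs[[paste0("strand", end)]],
                    pairs[[paste0("strand", other)]], first),
            pairs[[paste0("chrom", end)]],
            pairs[[paste0("start", end)]] + 1L,
            pairs$mapq,
            pairs[[paste0("end", end)]] - pairs[[paste0("start", end)]],
            pairs[[paste0("chrom", other)]],
            pairs[[paste0("start", other)]] + 1L,
            seqs)
  }
  s1 <- if (!is.null(reads)) reads$read1 else "*"
  s2 <- if (!is.null(reads)) reads$read2 else "*"
  writeLines(rec("A", "B", 1L, s1), con)
  writeLines(rec("B", "A", 0L, s2), con)
  invisible(path)
}

# --------------------------------------------------------------------- BEDPE

policy_to_tags <- function(pol) {
  sprintf("mh=%d;dup=%d,%d;untemplated=%d;net_loss=%d",
          pol$microhomology_len, pol$duplication_len[1],
          pol$duplication_len[2], pol$untemplated_len, pol$net_loss)
}

tags_to_policy <- function(tags) {
  kv <- strsplit(strsplit(tags, ";")[[1]], "=")
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  dup <- as.integer(strsplit(vals[["dup"]], ",")[[1]])
  junction_policy(microhomology_len = as.integer(vals[["mh"]]),
                  duplication_len = dup,
                  untemplated_len = as.integer(vals[["untemplated"]]),
                  net_loss = as.integer(vals[["net_loss"]]))
}

#' Write truth records or SV calls as BEDPE
#'
#' Ten standard BEDPE columns (chrom1 start1 end1 chrom2 start2 end2 name
#' score strand1 strand2) followed by key=value extension columns carrying
#' the event type, junction policy and sample (truth records) or support and
#' balanced flag (calls). An absent end B is encoded as chrom ".", coordinates
#' -1, per BEDPE convention.
#'
#' @param x list of [truth_record()]s or an `sv_call_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(x, path) {
  lines <- if (inherits(x, "sv_call_set")) {
    calls <- x$calls
    sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t%s\t%s\tsv_type=%s;balanced=%d;sample=%s",
            calls$chromA, calls$bpA_lo, calls$bpA_hi,
            ifelse(is.na(calls$chromB), ".", calls$chromB),
            ifelse(is.na(calls$bpB_lo), -1L, calls$bpB_lo),
            ifelse(is.na(calls$bpB_hi), -1L, calls$bpB_hi),
            calls$call_id, calls$support, "+", "-",
            calls$sv_type, as.integer(calls$balanced), calls$sample)
  } else {
    vapply(x, function(r) {
      stopifnot(inherits(r, "truth_record"))
      noB <- is.na(r$chromB)
      sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t%s\t%s\tsv_type=%s;%s;haplotype=%d;sample=%s",
              r$chromA, r$startA, r$endA,
              if (noB) "." else r$chromB,
              if (noB) -1L else r$startB,
              if (noB) -1L else r$endB,
              r$name, 0L, "+", "-",
              r$sv_type, policy_to_tags(r$policy), r$haplotype, r$sample)
    }, character(1))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BEDPE file written by [write_bedpe()]
#'
#' @param path BEDPE path.
#' @return for truth-record files, a list of [truth_record()]s (lossless
#'   round trip); for call files, a data frame of the call fields.
#' @export
read_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 10L)
  if (length(bad)) stopf("malformed BEDPE at line %d", bad[1])
  parse_tags <- function(s) {
    kv <- strsplit(strsplit(s, ";")[[1]], "=")
    stats::setNames(vapply(kv, `[`, character(1), 2),
                    vapply(kv, `[`, character(1), 1))
  }
  first_tags <- parse_tags(fields[[1]][11])
  if ("balanced" %in% names(first_tags)) {
    rows <- lapply(fields, function(f) {
      tg <- parse_tags(f[11])
      data.frame(chromA = f[1], bpA_lo = as.integer(f[2]),
                 bpA_hi = as.integer(f[3]),
                 chromB = if (f[4] == ".") NA_character_ else f[4],
                 bpB_lo = as.integer(f[5]), bpB_hi = as.integer(f[6]),
                 call_id = f[7], support = as.integer(f[8]),
                 sv_type = tg[["sv_type"]],
                 balanced = tg[["balanced"]] == "1",
                 sample = tg[["sample"]], stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  lapply(fields, function(f) {
    tg <- parse_tags(f[11])
    pol_tags <- paste(sprintf("%s=%s", names(tg), tg)[
      names(tg) %in% c("mh", "dup", "untemplated", "net_loss")],
      collapse = ";")
    noB <- f[4] == "."
    truth_record(sv_type = tg[["sv_type"]],
                 chromA = f[1], startA = as.integer(f[2]),
                 endA = as.integer(f[3]),
                 chromB = if (noB) NA_character_ else f[4],
                 startB = if (noB) NA_integer_ else as.integer(f[5]),
                 endB = if (noB) NA_integer_ else as.integer(f[6]),
                 policy = tags_to_policy(pol_tags),
                 haplotype = as.integer(tg[["haplotype"]]),
                 sample = tg[["sample"]], name = f[7])
  })
}

# ------------------------------------------------------------ BED and tracks

#' Read a BED file of target regions or windows
#'
#' BED is already 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged.
#'
#' @param path BED path (3 or more columns, tab-separated).
#' @return data frame with `chrom`, `start`, `end` and, when present, `name`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (any(df$start >= df$end)) stopf("BED interval with start >= end")
  df
}

#' Write a BED file
#' @param df data frame with `chrom`, `start`, `end` (+ optional `name`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(df))
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write two-column probe or BAF tracks
#'
#' Plain TSV with a header line: `pos` and either `log2` or `baf`.
#'
#' @param df data frame (`pos` + value column).
#' @param path file path.
#' @return the track data frame, or `path` invisibly for the writer.
#' @export
write_track <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
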