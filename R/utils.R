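# Internal helpers shared across modules. Coordinates are 0-based half-open
# everywhere inside the package; conversion to/from 1-based happens only at
# format boundaries (SAM, report output).

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of A/C/G/T sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substring in 0-based half-open coordinates
subseq0 <- function(seq, start, end) {
  substring(seq, start + 1L, end)
}

# signed overlap of two half-open intervals; negative values measure the gap
interval_overlap <- function(s1, e1, s2, e2) {
  min(e1, e2) - max(s1, s2)
}

# gap between two half-open intervals (0 when they touch or overlap)
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# a base different from every base in `avoid`
other_base <- function(avoid) {
  sample(setdiff(DNA_BASES, toupper(avoid)), 1L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x)

# canonical end ordering for a pair table: end A is the lexicographically
# smaller (chrom, start); keeps clustering and classification orientation-free
canonicalize_pairs <- function(pairs) {
  swap <- (pairs$chromB < pairs$chromA) |
    (pairs$chromB == pairs$chromA & pairs$startB < pairs$startA)
  if (any(swap)) {
    for (f in c("chrom", "start", "end", "strand")) {
      a <- paste0(f, "A"); b <- paste0(f, "B")
      tmp <- pairs[[a]][swap]
      pairs[[a]][swap] <- pairs[[b]][swap]
      pairs[[b]][swap] <- tmp
    }
  }
  pairs
}

empty_pairs <- function() {
  data.frame(
    pair_id = character(), chromA = character(), startA = integer(),
    endA = integer(), strandA = character(), chromB = character(),
    startB = integer(), endB = integer(), strandB = character(),
    sample = character(), mapq = integer(), stringsAsFactors = FALSE
  )
}
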