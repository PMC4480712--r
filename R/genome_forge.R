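# Synthetic genomes, planted structural variants with explicit junction
# mechanics, and mate-pair library / array-track simulators. Everything is
# seeded and returns truth records so the downstream caller, junction analyzer
# and segmentation stages can be tested against known answers.

# ---------------------------------------------------------------- constructors

#' Construct a genome object
#'
#' A genome is a named list of chromosome sequences (A/C/G/T, uppercase) plus
#' bookkeeping. Sequences are stored as plain character strings; coordinates
#' are 0-based half-open throughout the package.
#'
#' @param chromosomes named character vector of chromosome sequences.
#' @param name identifier for the genome.
#' @param seed integer seed recorded for provenance (not consumed here).
#' @return an object of class `genome`.
#' @export
genome <- function(chromosomes, name = "synthetic", seed = NA_integer_) {
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes))) {
    stopf("chromosomes must have unique names")
  }
  chromosomes <- toupper(chromosomes)
  bad <- grepl("[^ACGT]", chromosomes)
  if (any(bad)) {
    i <- which(bad)[1L]
    stopf("chromosome '%s' contains a non-ACGT character at offset %d",
          names(chromosomes)[i], regexpr("[^ACGT]", chromosomes[i]) - 1L)
  }
  if (any(nchar(chromosomes) == 0L)) stopf("empty chromosome sequence")
  structure(list(name = name, chromosomes = chromosomes, seed = seed),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome '%s'> %d chromosome(s), %s bp total\n", x$name,
              length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ",")))
  invisible(x)
}

chrom_seq <- function(genome, chrom) {
  s <- genome$chromosomes[[chrom]]
  if (is.null(s)) stopf("unknown chromosome '%s'", chrom)
  s
}

chrom_len <- function(genome, chrom) nchar(chrom_seq(genome, chrom))

#' Junction mechanics policy
#'
#' Describes what happens at the breakpoint junction(s) of a planted event:
#' micro-homology of a few bases, an untemplated insertion, a junctional
#' duplication in which the same reference segment ends up on both derivatives
#' of a balanced event (the overhang fill-in signature), or a net loss of
#' bases spanning the junction of a balanced event pair.
#'
#' At most one of `microhomology_len`, `duplication_len`, `untemplated_len`
#' may be non-zero. `duplication_len` may be a length-2 vector giving the
#' locus-A-side and locus-B-side duplications of a reciprocal translocation.
#' `net_loss` is only valid for balanced events (inversions).
#'
#' @param microhomology_len bases of micro-homology (>= 0).
#' @param duplication_len bases duplicated onto both derivatives (>= 0;
#'   scalar, or `c(A, B)` for the two sides of a reciprocal translocation).
#' @param untemplated_len bases of random untemplated sequence at the
#'   junction (>= 0).
#' @param net_loss bases lost across the junction of a balanced event (>= 0).
#' @return an object of class `junction_policy`.
#' @export
junction_policy <- function(microhomology_len = 0L, duplication_len = 0L,
                            untemplated_len = 0L, net_loss = 0L) {
  if (length(duplication_len) == 1L) duplication_len <- c(duplication_len, 0L)
  if (length(duplication_len) != 2L) stopf("duplication_len must have length 1 or 2")
  vals <- c(microhomology_len, duplication_len, untemplated_len, net_loss)
  if (any(vals < 0)) stopf("junction policy lengths must be >= 0")
  n_active <- (microhomology_len > 0) + (any(duplication_len > 0)) +
    (untemplated_len > 0)
  if (n_active > 1L) {
    stopf("at most one of microhomology/duplication/untemplated may be non-zero")
  }
  structure(list(microhomology_len = as.integer(microhomology_len),
                 duplication_len = as.integer(duplication_len),
                 untemplated_len = as.integer(untemplated_len),
                 net_loss = as.integer(net_loss)),
            class = "junction_policy")
}

#' Truth record for a planted structural variant
#'
#' @param sv_type one of `"deletion"`, `"inversion"`,
#'   `"reciprocal_translocation"`, `"inverted_insertion"`.
#' @param chromA,startA,endA locus A (0-based half-open). For an inverted
#'   insertion this is the acceptor site and `startA == endA` is allowed.
#' @param chromB,startB,endB locus B, or `NA` for intra-chromosomal events
#'   that need no second locus.
#' @param policy a [junction_policy()].
#' @param haplotype haplotype index the event is planted on.
#' @param sample sample identifier.
#' @param name event name (auto-generated if missing).
#' @return object of class `truth_record`.
#' @export
truth_record <- function(sv_type, chromA, startA, endA,
                         chromB = NA_character_, startB = NA_integer_,
                         endB = NA_integer_, policy = junction_policy(),
                         haplotype = 1L, sample = "S1", name = NULL) {
  sv_type <- match.arg(sv_type, c("deletion", "inversion",
                                  "reciprocal_translocation",
                                  "inverted_insertion"))
  if (sv_type == "inverted_insertion") {
    if (startA > endA) stopf("acceptor coordinates inverted")
  } else if (startA >= endA) stopf("locusA start must be < end")
  if (!is.na(chromB) && !is.na(startB) && startB >= endB &&
      sv_type != "inverted_insertion") {
    stopf("locusB start must be < end")
  }
  if (sv_type %in% c("deletion", "inversion") && !is.na(chromB) &&
      chromB != chromA) {
    stopf("%s must be intra-chromosomal", sv_type)
  }
  if (sv_type == "reciprocal_translocation" &&
      (is.na(chromB) || chromB == chromA)) {
    stopf("reciprocal translocation must be inter-chromosomal")
  }
  if (!inherits(policy, "junction_policy")) stopf("policy must be a junction_policy")
  if (policy$net_loss > 0 && sv_type != "inversion") {
    stopf("net_loss is only supported for balanced inversion junctions")
  }
  structure(list(sv_type = sv_type, chromA = chromA,
                 startA = as.integer(startA), endA = as.integer(endA),
                 chromB = chromB, startB = as.integer(startB),
                 endB = as.integer(endB), policy = policy,
                 haplotype = as.integer(haplotype), sample = sample,
                 name = name %||% sprintf("%s_%s_%d", sample,
                                          substr(sv_type, 1, 3), startA)),
            class = "truth_record")
}

#' Mate-pair library model
#'
#' Long-fragment (default 1-4 kb) mate-pair library in the style of DNA
#' paired-end tag sequencing: short tags from both ends of each fragment.
#'
#' @param frag_min,frag_max fragment size bounds in bases.
#' @param frag_mean,frag_sd truncated-normal fragment-size law.
#' @param read_len tag length in bases (35 or 50 in the emulated chemistry).
#' @param error_rate per-base substitution probability, in `[0, 0.1)`.
#' @param concordant_orientation `"inward"` (FR, the normalized internal
#'   convention) or `"same-strand"` (SOLiD mate-pair chemistry; normalized at
#'   SAM ingest).
#' @param seed default RNG seed for simulations using this model.
#' @return object of class `library_model`.
#' @export
library_model <- function(frag_min = 1000L, frag_max = 4000L,
                          frag_mean = 3000L, frag_sd = 300L, read_len = 50L,
                          error_rate = 0, concordant_orientation = "inward",
                          seed = 1L) {
  concordant_orientation <- match.arg(concordant_orientation,
                                      c("inward", "same-strand"))
  if (!(frag_min <= frag_mean && frag_mean <= frag_max)) {
    stopf("need frag_min <= frag_mean <= frag_max")
  }
  if (error_rate < 0 || error_rate >= 0.1) stopf("error_rate must be in [0, 0.1)")
  if (read_len >= frag_min) stopf("read_len must be < frag_min")
  structure(list(frag_min = as.integer(frag_min),
                 frag_max = as.integer(frag_max),
                 frag_mean = as.integer(frag_mean),
                 frag_sd = as.numeric(frag_sd),
                 read_len = as.integer(read_len),
                 error_rate = error_rate,
                 concordant_orientation = concordant_orientation,
                 seed = as.integer(seed)),
            class = "library_model")
}

# a haplotype is a derivative (or unrearranged) sequence plus the block map
# back to reference coordinates; blocks with chrom NA are untemplated sequence
haplotype <- function(name, seq, blocks) {
  stopifnot(sum(blocks$der_end - blocks$der_start) == nchar(seq))
  structure(list(name = name, seq = seq, blocks = blocks), class = "haplotype")
}

identity_blocks <- function(chrom, len) {
  data.frame(der_start = 0L, der_end = as.integer(len), chrom = chrom,
             ref_start = 0L, ref_end = as.integer(len), strand = "+",
             stringsAsFactors = FALSE)
}

#' Haplotype carrying an unrearranged chromosome
#'
#' @param genome a [genome()].
#' @param chrom chromosome name.
#' @param name haplotype name.
#' @return a `haplotype` object mapping identically to the reference.
#' @export
reference_haplotype <- function(genome, chrom, name = paste0(chrom, "_ref")) {
  haplotype(name, chrom_seq(genome, chrom),
            identity_blocks(chrom, chrom_len(genome, chrom)))
}

# ------------------------------------------------------------- make_reference

#' Generate a random reference genome
#'
#' @param n_chromosomes number of chromosomes.
#' @param lengths integer vector of chromosome lengths (each >= 10 kb).
#' @param gc target GC fraction in (0, 1); the realized GC of a >= 100 kb
#'   chromosome is within about 2 percentage points of this.
#' @param seed integer seed; identical inputs reproduce identical sequences.
#' @param names optional chromosome names (default `chr1`, `chr2`, ...).
#' @return a [genome()].
#' @export
make_reference <- function(n_chromosomes, lengths, gc = 0.5, seed = 1L,
                           names = NULL) {
  if (length(lengths) == 1L) lengths <- rep(lengths, n_chromosomes)
  if (length(lengths) != n_chromosomes) stopf("lengths must match n_chromosomes")
  if (any(lengths < 10000)) stopf("chromosome lengths must be >= 10 kb")
  if (gc <= 0 || gc >= 1) stopf("gc must be inside (0, 1)")
  names <- names %||% paste0("chr", seq_len(n_chromosomes))
  chroms <- withr::with_seed(seed, {
    vapply(lengths, random_dna, character(1), gc = gc)
  })
  names(chroms) <- names
  genome(chroms, name = sprintf("ref_gc%.2f_seed%d", gc, seed), seed = seed)
}

# -------------------------------------------------- junction guard machinery

# One guard: the base at `fix` (complemented if fix_comp) must differ from the
# base at `against` (complemented if against_comp); on violation the reference
# base at `fix` is rewritten. `fix` positions are always continuation bases
# that sit next to, never at, a junction, so rewriting them cannot change the
# planted mechanics -- only suppress accidental homology extension.
guard <- function(fix_chrom, fix_pos, against_chrom, against_pos,
                  fix_comp = FALSE, against_comp = FALSE) {
  list(fix_chrom = fix_chrom, fix_pos = as.integer(fix_pos),
       against_chrom = against_chrom, against_pos = as.integer(against_pos),
       fix_comp = fix_comp, against_comp = against_comp)
}

base_at <- function(genome, chrom, pos, comp = FALSE) {
  b <- substring(genome$chromosomes[[chrom]], pos + 1L, pos + 1L)
  if (comp) chartr("ACGT", "TGCA", b) else b
}

set_base <- function(genome, chrom, pos, base) {
  substring(genome$chromosomes[[chrom]], pos + 1L, pos + 1L) <- base
  genome
}

apply_guards <- function(genome, guards) {
  for (iter in seq_len(25L)) {
    ok <- TRUE
    for (g in guards) {
      if (g$fix_pos < 0 || g$against_pos < 0) next
      a <- base_at(genome, g$fix_chrom, g$fix_pos, g$fix_comp)
      b <- base_at(genome, g$against_chrom, g$against_pos, g$against_comp)
      if (a == b) {
        ok <- FALSE
        # avoid the partner base of every guard fixing this same position
        avoid <- vapply(guards, function(h) {
          if (h$fix_pos >= 0 && h$against_pos >= 0 &&
              h$fix_chrom == g$fix_chrom && h$fix_pos == g$fix_pos) {
            v <- base_at(genome, h$against_chrom, h$against_pos, h$against_comp)
            if (h$fix_comp) chartr("ACGT", "TGCA", v) else v
          } else NA_character_
        }, character(1))
        new_plain <- other_base(stats::na.omit(avoid))
        genome <- set_base(genome, g$fix_chrom, g$fix_pos, new_plain)
      }
    }
    if (ok) return(genome)
  }
  stopf("could not satisfy junction guards")  # nocov
}

# ------------------------------------------------------------------- plant_sv

#' Plant a structural variant into a genome
#'
#' Builds the derivative haplotype(s) realizing `spec` with the exact junction
#' mechanics of its policy. To make the planted policy exactly recoverable by
#' the junction analyzer, the reference bases immediately *beyond* each
#' junction may be minimally rewritten (guards against accidental homology
#' extension; micro-homology planting copies the homologous bases into the
#' partner flank). The possibly-adjusted genome is returned and is the
#' reference all downstream steps should use.
#'
#' Mechanics per type (0-based half-open, `J` a junction):
#' * deletion `[s,e)`: derivative drops `e - s` bases; supports blunt,
#'   micro-homology, untemplated policies.
#' * inversion `[s,e)`: segment reverse-complemented in place; `net_loss g`
#'   removes bases `[s, s+g)`, so the two locus-side breakpoints are `g`
#'   apart and the derivative is `g` bases shorter.
#' * reciprocal translocation at `(A:a | B:b)`: two derivatives
#'   `A-left + B-right` and `B-left + A-right`; `duplication_len = c(dA, dB)`
#'   places `A[a-dA, a)` and `B[b-dB, b)` on *both* derivatives
#'   (overhang fill-in signature).
#' * inverted insertion: donor `B[b1,b2)` reverse-complemented into acceptor
#'   position `p`; `duplication_len t` leaves the acceptor bases `A[p-t, p)`
#'   on both sides of the insertion (target-site duplication).
#'
#' @param genome a [genome()].
#' @param spec a [truth_record()].
#' @param keep for reciprocal translocations, which derivatives to return
#'   (`c("der1","der2")`; a single name plants a one-sided event as seen in
#'   complex, possibly non-clonal tumors).
#' @param seed seed for untemplated-sequence generation and guard repair.
#' @return list with `haplotypes` (list of `haplotype`), `truth` (the realized
#'   [truth_record()] with a `junctions` data frame of reference breakpoint
#'   coordinates and derivative junction positions), and `genome` (the
#'   possibly guard-adjusted reference).
#' @export
plant_sv <- function(genome, spec, keep = c("der1", "der2"), seed = 1L) {
  stopifnot(inherits(genome, "genome"), inherits(spec, "truth_record"))
  withr::with_seed(seed, {
    switch(spec$sv_type,
           deletion = plant_deletion(genome, spec),
           inversion = plant_inversion(genome, spec),
           reciprocal_translocation = plant_translocation(genome, spec, keep),
           inverted_insertion = plant_inverted_insertion(genome, spec))
  })
}

check_locus <- function(genome, chrom, start, end) {
  L <- chrom_len(genome, chrom)
  if (start < 0 || end > L) stopf("locus [%d,%d) outside chromosome '%s' (len %d)",
                                  start, end, chrom, L)
}

plant_deletion <- function(genome, spec) {
  C <- spec$chromA; s <- spec$startA; e <- spec$endA
  check_locus(genome, C, s, e)
  pol <- spec$policy
  if (any(pol$duplication_len > 0)) stopf("duplication policy invalid for deletion")
  m <- pol$microhomology_len; u <- pol$untemplated_len
  if (m >= e - s) stopf("microhomology longer than the deletion")
  if (m > 0) {
    # copy the homologous stretch into the right flank (deleted interior)
    hom <- subseq0(chrom_seq(genome, C), s - m, s)
    seqC <- chrom_seq(genome, C)
    substring(seqC, e - m + 1L, e) <- hom
    genome$chromosomes[[C]] <- seqC
  }
  guards <- list(guard(C, e - m - 1L, C, s - m - 1L))
  ins <- ""
  if (u > 0) {
    ins <- random_dna(u)
    # ends of the insert must not extend either flank match
    substring(ins, 1L, 1L) <- other_base(base_at(genome, C, s))
    substring(ins, u, u) <- other_base(c(base_at(genome, C, e - 1L),
                                         if (u == 1L) base_at(genome, C, s)))
  } else {
    guards <- c(guards, list(guard(C, e, C, s)))
  }
  genome <- apply_guards(genome, guards)
  seqC <- chrom_seq(genome, C); L <- nchar(seqC)
  der_seq <- paste0(subseq0(seqC, 0, s), ins, subseq0(seqC, e, L))
  blocks <- data.frame(
    der_start = c(0L, if (u > 0) s, s + u),
    der_end = c(s, if (u > 0) s + u, s + u + (L - e)),
    chrom = c(C, if (u > 0) NA_character_, C),
    ref_start = c(0L, if (u > 0) NA_integer_, e),
    ref_end = c(s, if (u > 0) NA_integer_, L),
    strand = c("+", if (u > 0) NA_character_, "+"),
    stringsAsFactors = FALSE)
  hap <- haplotype(paste0(spec$name, "_der1"), der_seq, blocks)
  spec$junctions <- data.frame(
    junction = "J1", der = hap$name, der_pos = s,
    chromL = C, posL = s, strandL = "+", chromR = C, posR = e, strandR = "+",
    stringsAsFactors = FALSE)
  list(haplotypes = list(hap), truth = spec, genome = genome)
}

plant_inversion <- function(genome, spec) {
  C <- spec$chromA; s <- spec$startA; e <- spec$endA
  check_locus(genome, C, s, e)
  pol <- spec$policy
  if (pol$microhomology_len > 0 || pol$untemplated_len > 0 ||
      any(pol$duplication_len > 0)) {
    stopf("inversion supports blunt or net_loss policies only")
  }
  g <- pol$net_loss
  if (g >= e - s) stopf("net_loss larger than the inverted segment")
  # guards: J1 joins C[s-1] | comp(C[e-1]); J2 joins comp(C[s+g]) | C[e]
  guards <- list(
    guard(C, s, C, e - 1L, against_comp = TRUE),      # comp(C[e-1]) != C[s]
    guard(C, e, C, s - 1L, fix_comp = TRUE),          # C[s-1] != comp(C[e])
    guard(C, s + g - 1L, C, e, fix_comp = TRUE),      # C[e] != comp(C[s+g-1])
    guard(C, e - 1L, C, s + g, against_comp = TRUE))  # comp(C[s+g]) != C[e-1]
  genome <- apply_guards(genome, guards)
  seqC <- chrom_seq(genome, C); L <- nchar(seqC)
  mid <- revcomp(subseq0(seqC, s + g, e))
  der_seq <- paste0(subseq0(seqC, 0, s), mid, subseq0(seqC, e, L))
  blocks <- data.frame(
    der_start = c(0L, s, s + (e - s - g)),
    der_end = c(s, s + (e - s - g), s + (e - s - g) + (L - e)),
    chrom = C, ref_start = c(0L, s + g, e), ref_end = c(s, e, L),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  hap <- haplotype(paste0(spec$name, "_der1"), der_seq, blocks)
  spec$junctions <- data.frame(
    junction = c("J1", "J2"), der = hap$name,
    der_pos = c(s, s + (e - s - g)),
    chromL = C, posL = c(s, s + g), strandL = c("+", "-"),
    chromR = C, posR = c(e, e), strandR = c("-", "+"),
    stringsAsFactors = FALSE)
  list(haplotypes = list(hap), truth = spec, genome = genome)
}

plant_translocation <- function(genome, spec, keep) {
  keep <- match.arg(keep, c("der1", "der2"), several.ok = TRUE)
  A <- spec$chromA; a <- spec$startA
  B <- spec$chromB; b <- spec$startB
  check_locus(genome, A, a, a + 1L); check_locus(genome, B, b, b + 1L)
  pol <- spec$policy
  dA <- pol$duplication_len[1L]; dB <- pol$duplication_len[2L]
  m <- pol$microhomology_len
  if (pol$untemplated_len > 0) stopf("untemplated policy not supported for translocations")
  if (m > 0 && (dA > 0 || dB > 0)) stopf("policy combining duplication with micro-homology")
  if (m > 0) {
    # homology shared by both junctions: copy A's m bases before the break
    # into B's flank before its break; the derivatives stay blunt joins and
    # the ambiguity comes entirely from the edited reference
    hom <- subseq0(chrom_seq(genome, A), a - m, a)
    seqB <- chrom_seq(genome, B)
    substring(seqB, b - m + 1L, b) <- hom
    genome$chromosomes[[B]] <- seqB
  }
  # guards (cover both junctions symmetrically):
  guards <- list(
    guard(B, b - dB, A, a),                 # der1 rightFirst vs A continuation
    guard(B, b - dB - 1L, A, a - 1L),       # der1 leftLast continuation
    guard(A, a - dA, B, b),                 # der2 rightFirst vs B continuation
    guard(A, a - dA - 1L, B, b - 1L))       # der2 leftLast continuation
  if (m > 0) {
    guards <- list(guard(B, b, A, a), guard(B, b - m - 1L, A, a - m - 1L))
  }
  genome <- apply_guards(genome, guards)
  seqA <- chrom_seq(genome, A); seqB <- chrom_seq(genome, B)
  LA <- nchar(seqA); LB <- nchar(seqB)
  haps <- list(); junc <- list()
  if ("der1" %in% keep) {
    der1 <- paste0(subseq0(seqA, 0, a), subseq0(seqB, b - dB, LB))
    blocks1 <- data.frame(der_start = c(0L, a),
                          der_end = c(a, a + (LB - (b - dB))),
                          chrom = c(A, B), ref_start = c(0L, b - dB),
                          ref_end = c(a, LB), strand = "+",
                          stringsAsFactors = FALSE)
    haps$der1 <- haplotype(paste0(spec$name, "_der1"), der1, blocks1)
    junc$J1 <- data.frame(junction = "J1", der = haps$der1$name, der_pos = a,
                          chromL = A, posL = a, strandL = "+",
                          chromR = B, posR = b - dB, strandR = "+",
                          stringsAsFactors = FALSE)
  }
  if ("der2" %in% keep) {
    der2 <- paste0(subseq0(seqB, 0, b), subseq0(seqA, a - dA, LA))
    blocks2 <- data.frame(der_start = c(0L, b),
                          der_end = c(b, b + (LA - (a - dA))),
                          chrom = c(B, A), ref_start = c(0L, a - dA),
                          ref_end = c(b, LA), strand = "+",
                          stringsAsFactors = FALSE)
    haps$der2 <- haplotype(paste0(spec$name, "_der2"), der2, blocks2)
    junc$J2 <- data.frame(junction = "J2", der = haps$der2$name, der_pos = b,
                          chromL = B, posL = b, strandL = "+",
                          chromR = A, posR = a - dA, strandR = "+",
                          stringsAsFactors = FALSE)
  }
  spec$junctions <- do.call(rbind, unname(junc))
  list(haplotypes = unname(haps), truth = spec, genome = genome)
}

plant_inverted_insertion <- function(genome, spec) {
  A <- spec$chromA; p <- spec$startA
  B <- spec$chromB; b1 <- spec$startB; b2 <- spec$endB
  check_locus(genome, A, p, p); check_locus(genome, B, b1, b2)
  pol <- spec$policy
  t <- pol$duplication_len[1L]
  if (pol$microhomology_len > 0 || pol$untemplated_len > 0) {
    stopf("inverted insertion supports blunt or target-site-duplication policies")
  }
  if (t > p) stopf("target-site duplication exceeds acceptor position")
  guards <- list(
    guard(A, p, B, b2 - 1L, against_comp = TRUE),        # J1 right-extension
    guard(B, b2, A, p - 1L, fix_comp = TRUE),            # J1 left-extension
    guard(B, b1 - 1L, A, p - t, fix_comp = TRUE),        # J2 right-extension
    guard(A, p - t - 1L, B, b1, against_comp = TRUE))    # J2 left-extension
  genome <- apply_guards(genome, guards)
  seqA <- chrom_seq(genome, A); seqB <- chrom_seq(genome, B)
  LA <- nchar(seqA); d <- b2 - b1
  der <- paste0(subseq0(seqA, 0, p), revcomp(subseq0(seqB, b1, b2)),
                subseq0(seqA, p - t, LA))
  blocks <- data.frame(
    der_start = c(0L, p, p + d), der_end = c(p, p + d, p + d + (LA - (p - t))),
    chrom = c(A, B, A), ref_start = c(0L, b1, p - t),
    ref_end = c(p, b2, LA), strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
  hap <- haplotype(paste0(spec$name, "_der1"), der, blocks)
  spec$junctions <- data.frame(
    junction = c("J1", "J2"), der = hap$name, der_pos = c(p, p + d),
    chromL = c(A, B), posL = c(p, b1), strandL = c("+", "-"),
    chromR = c(B, A), posR = c(b2, p - t), strandR = c("-", "+"),
    stringsAsFactors = FALSE)
  list(haplotypes = list(hap), truth = spec, genome = genome)
}

#' Plant several deletions on one haplotype
#'
#' Convenience for germline/somatic bookkeeping simulations: builds one
#' derivative haplotype of `chrom` carrying every (blunt) deletion in `dels`.
#'
#' @param genome a [genome()].
#' @param chrom chromosome name.
#' @param dels data frame with 0-based half-open `start`, `end` columns;
#'   must be non-overlapping.
#' @param name haplotype name.
#' @return a `haplotype`.
#' @export
plant_deletions <- function(genome, chrom, dels, name = paste0(chrom, "_dels")) {
  dels <- dels[order(dels$start), , drop = FALSE]
  if (any(dels$start >= dels$end)) stopf("deletion with start >= end")
  if (nrow(dels) > 1 && any(dels$start[-1] < dels$end[-nrow(dels)])) {
    stopf("overlapping deletions")
  }
  seqC <- chrom_seq(genome, chrom); L <- nchar(seqC)
  keep_start <- c(0L, dels$end)
  keep_end <- c(dels$start, L)
  pieces <- subseq0(seqC, keep_start, keep_end)
  widths <- keep_end - keep_start
  der_end <- cumsum(widths)
  blocks <- data.frame(der_start = c(0L, der_end[-length(der_end)]),
                       der_end = der_end, chrom = chrom,
                       ref_start = keep_start, ref_end = keep_end,
                       strand = "+", stringsAsFactors = FALSE)
  blocks <- blocks[blocks$der_end > blocks$der_start, , drop = FALSE]
  haplotype(name, paste(pieces, collapse = ""), blocks)
}

# ------------------------------------------------------- mate-pair simulation

# map derivative read intervals to reference coordinates through a block map;
# a read crossing a block boundary (i.e. a junction) does not map full-length
# against the reference and is reported unmapped, as a short tag would be
map_reads <- function(blocks, start, end) {
  i <- findInterval(start, blocks$der_start)
  crossing <- end > blocks$der_end[i]
  end <- pmin(end, blocks$der_end[i])
  chrom <- blocks$chrom[i]
  chrom[crossing] <- NA_character_
  plus <- !is.na(blocks$strand[i]) & blocks$strand[i] == "+"
  off1 <- start - blocks$der_start[i]
  off2 <- end - blocks$der_start[i]
  ref_start <- ifelse(plus, blocks$ref_start[i] + off1,
                      blocks$ref_end[i] - off2)
  ref_end <- ifelse(plus, blocks$ref_start[i] + off2,
                    blocks$ref_end[i] - off1)
  flip <- !plus
  data.frame(chrom = chrom, start = as.integer(ref_start),
             end = as.integer(ref_end), flip = flip,
             der_start = start, der_end = end, stringsAsFactors = FALSE)
}

apply_read_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_err > 0)) {
    s <- strsplit(seqs[i], "")[[1]]
    pos <- sample(length(s), n_err[i])
    s[pos] <- vapply(s[pos], other_base, character(1))
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate a mate-pair library from haplotypes
#'
#' Draws fragments (truncated-normal size law within
#' `[frag_min, frag_max]`), sequences a tag from each end (inward
#' orientation), and reports the *true* alignment of every tag in reference
#' coordinates through each haplotype's block map, so pairs spanning a planted
#' junction map to the two reference loci. The emitted pair count is
#' `ceiling(coverage * total_length / frag_mean)` (physical coverage).
#'
#' @param haplotypes list of `haplotype` objects (each longer than `frag_max`).
#' @param model a [library_model()].
#' @param coverage physical-coverage multiple.
#' @param sample sample identifier stamped on every pair.
#' @param weights relative haplotype abundances (default equal); pairs are
#'   allocated with probability proportional to `weight * length`.
#' @param emit_reads also return the tag sequences (needed for FASTQ output
#'   and the exact-substring checks; skip for speed in large scans).
#' @param seed RNG seed (default `model$seed`).
#' @return list with `pairs` (canonicalized read-pair alignment table: end A
#'   is the lexicographically smaller (chrom, start)), `reads` (per-pair tag
#'   sequences or `NULL`), `n_pairs`, and `n_unmapped` (pairs dropped because
#'   a tag fell in untemplated sequence).
#' @export
simulate_mate_pairs <- function(haplotypes, model, coverage, sample = "S1",
                                weights = NULL, emit_reads = TRUE,
                                seed = NULL) {
  stopifnot(inherits(model, "library_model"))
  if (inherits(haplotypes, "haplotype")) haplotypes <- list(haplotypes)
  lens <- vapply(haplotypes, function(h) nchar(h$seq), numeric(1))
  if (any(lens <= model$frag_max)) {
    stopf("every haplotype must be longer than frag_max (%d)", model$frag_max)
  }
  weights <- weights %||% rep(1, length(haplotypes))
  total_len <- sum(lens)
  n_pairs <- as.integer(ceiling(coverage * total_len / model$frag_mean))
  rl <- model$read_len
  withr::with_seed(seed %||% model$seed, {
    hap_idx <- sample.int(length(haplotypes), n_pairs, replace = TRUE,
                          prob = weights * lens)
    frag <- round(stats::rnorm(n_pairs, model$frag_mean, model$frag_sd))
    for (it in 1:50) {
      bad <- frag < model$frag_min | frag > model$frag_max
      if (!any(bad)) break
      frag[bad] <- round(stats::rnorm(sum(bad), model$frag_mean, model$frag_sd))
    }
    frag <- pmin(pmax(frag, model$frag_min), model$frag_max)
    f <- floor(stats::runif(n_pairs) * (lens[hap_idx] - frag + 1))

    res <- vector("list", length(haplotypes))
    reads1 <- reads2 <- character(n_pairs)
    aln1 <- aln2 <- NULL
    ord <- order(hap_idx)
    for (h in unique(hap_idx)) {
      sel <- which(hap_idx == h)
      hp <- haplotypes[[h]]
      a1 <- map_reads(hp$blocks, f[sel], f[sel] + rl)
      a2 <- map_reads(hp$blocks, f[sel] + frag[sel] - rl, f[sel] + frag[sel])
      a1$idx <- sel; a2$idx <- sel
      aln1 <- rbind(aln1, a1); aln2 <- rbind(aln2, a2)
      if (emit_reads) {
        reads1[sel] <- subseq0(hp$seq, a1$der_start, a1$der_end)
        reads2[sel] <- revcomp(subseq0(hp$seq, a2$der_start, a2$der_end))
      }
    }
    aln1 <- aln1[order(aln1$idx), , drop = FALSE]
    aln2 <- aln2[order(aln2$idx), , drop = FALSE]
    # read 1 is forward on the derivative, read 2 reverse; block strand flips
    strand1 <- ifelse(aln1$flip, "-", "+")
    strand2 <- ifelse(aln2$flip, "+", "-")
    mapped <- !is.na(aln1$chrom) & !is.na(aln2$chrom)
    pairs <- data.frame(
      pair_id = sprintf("%s_p%07d", sample, seq_len(n_pairs)),
      chromA = aln1$chrom, startA = aln1$start, endA = aln1$end,
      strandA = strand1,
      chromB = aln2$chrom, startB = aln2$start, endB = aln2$end,
      strandB = strand2,
      sample = sample, mapq = 60L, stringsAsFactors = FALSE)
    reads <- NULL
    if (emit_reads) {
      reads <- data.frame(pair_id = pairs$pair_id,
                          read1 = apply_read_errors(reads1, model$error_rate),
                          read2 = apply_read_errors(reads2, model$error_rate),
                          stringsAsFactors = FALSE)
      reads <- reads[mapped, , drop = FALSE]
    }
    pairs <- canonicalize_pairs(pairs[mapped, , drop = FALSE])
    rownames(pairs) <- NULL
    list(pairs = pairs, reads = reads, n_pairs = n_pairs,
         n_unmapped = sum(!mapped))
  })
}

# --------------------------------------------------------------- array tracks

#' Simulate a copy-number probe track
#'
#' Probe log2 ratios are `log2(cn / 2)` plus Gaussian noise; a diploid segment
#' sits at 0, a one-copy loss at -1, a one-copy gain at `log2(3/2)`.
#'
#' @param segments data frame with columns `start`, `end` (contiguous,
#'   non-overlapping, 0-based half-open) and `copy_number` (>= 0).
#' @param probe_spacing bases between probes.
#' @param noise_sd Gaussian noise standard deviation in log2 units.
#' @param seed RNG seed.
#' @return data frame with `pos` and `log2` columns.
#' @export
simulate_cn_profile <- function(segments, probe_spacing, noise_sd = 0,
                                seed = 1L) {
  if (any(segments$copy_number < 0)) stopf("copy_number must be >= 0")
  if (nrow(segments) > 1 &&
      any(segments$start[-1] != segments$end[-nrow(segments)])) {
    stopf("segments must be contiguous (no gaps, no overlap)")
  }
  pos <- seq(segments$start[1], segments$end[nrow(segments)] - 1L,
             by = probe_spacing)
  idx <- findInterval(pos, segments$start)
  base <- log2(segments$copy_number[idx] / 2)
  withr::with_seed(seed, {
    data.frame(pos = as.integer(pos),
               log2 = base + stats::rnorm(length(pos), 0, noise_sd))
  })
}

#' Simulate a B-allele-fraction track
#'
#' Heterozygous SNPs sit at BAF 0.5; under loss of heterozygosity at tumor
#' purity `p` the two homozygous states mix linearly with the normal
#' contamination, centering at `0.5 - p/2` and `0.5 + p/2` (0 and 1 at
#' purity 1).
#'
#' @param n_snps number of informative SNPs.
#' @param state `"het-normal"`, `"cn-neutral-LOH"` or `"deletion-LOH"`.
#' @param purity tumor fraction in (0, 1].
#' @param noise_sd Gaussian noise (fraction units); values clamped to [0, 1].
#' @param seed RNG seed.
#' @param spacing bases between SNPs (positions `0, spacing, ...`).
#' @return data frame with `pos` and `baf` columns.
#' @export
simulate_baf <- function(n_snps, state = c("het-normal", "cn-neutral-LOH",
                                           "deletion-LOH"),
                         purity = 1, noise_sd = 0, seed = 1L,
                         spacing = 1000L) {
  state <- match.arg(state)
  if (purity <= 0 || purity > 1) stopf("purity must be in (0, 1]")
  withr::with_seed(seed, {
    centers <- if (state == "het-normal") {
      rep(0.5, n_snps)
    } else {
      sample(c(0.5 - purity / 2, 0.5 + purity / 2), n_snps, replace = TRUE)
    }
    baf <- pmin(pmax(centers + stats::rnorm(n_snps, 0, noise_sd), 0), 1)
    data.frame(pos = as.integer(seq(0, by = spacing, length.out = n_snps)),
               baf = baf)
  })
}

#' Extract the sequence window around a planted junction
#'
#' @param hap a `haplotype` from [plant_sv()].
#' @param der_pos junction position on the derivative (from the realized
#'   truth record's `junctions` table).
#' @param flank bases kept on each side of the junction.
#' @return character sequence of up to `2 * flank` bases.
#' @export
junction_window <- function(hap, der_pos, flank = 1500L) {
  L <- nchar(hap$seq)
  subseq0(hap$seq, max(0L, der_pos - flank), min(L, der_pos + flank))
}

#' Plant several events that share a genome
#'
#' Plants each spec in turn, feeding the guard-adjusted genome forward, and
#' repeats until the genome reaches a fixed point so that every derivative is
#' built from the final reference (needed when events break near each other,
#' as in complex multi-translocation tumors).
#'
#' @param genome a [genome()].
#' @param specs list of [truth_record()]s.
#' @param keeps list of `keep` arguments, one per spec (default both
#'   derivatives).
#' @param seed seed passed to each [plant_sv()] call.
#' @return list with `haplotypes` (flat list across events), `truths`
#'   (realized records) and `genome` (final reference).
#' @export
plant_multi <- function(genome, specs, keeps = NULL, seed = 1L) {
  keeps <- keeps %||% rep(list(c("der1", "der2")), length(specs))
  for (round in 1:5) {
    before <- genome$chromosomes
    haps <- list(); truths <- list()
    for (i in seq_along(specs)) {
      res <- plant_sv(genome, specs[[i]], keep = keeps[[i]], seed = seed)
      genome <- res$genome
      haps <- c(haps, res$haplotypes)
      truths[[i]] <- res$truth
    }
    if (identical(before, genome$chromosomes)) break
  }
  list(haplotypes = haps, truths = truths, genome = genome)
}
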