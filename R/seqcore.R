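# Sequence primitives: IUPAC algebra, FASTA I/O, intervals, ORF scanning.
# Sequences are plain character scalars/vectors (ids as names), stored
# uppercase with U converted to T; coordinates are 1-based fully closed.

IUPAC_DNA <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

# 4-bit encoding (A=1, C=2, G=4, T=8); a degenerate symbol is the union of
# its expansion. Used by the primer scanner: match <=> bitwAnd() > 0.
.iupac_bits <- local({
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  vapply(IUPAC_DNA, function(s) {
    sum(bit[strsplit(s, "")[[1]]])
  }, integer(1))
})

#' Canonicalize a nucleotide string
#'
#' Uppercases, converts U to T and validates against the IUPAC DNA alphabet.
#'
#' @param x character vector of nucleotide strings.
#' @param allow_gap also accept `-` (kept as is), for aligned input.
#' @return character vector, uppercase, RNA U replaced by T.
#' @export
dna_canonical <- function(x, allow_gap = FALSE) {
  nm <- names(x)
  x <- chartr("u", "U", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  names(x) <- nm
  alphabet <- paste0("ACGTRYSWKMBDHVN", if (allow_gap) "-" else "")
  bad <- grepl(sprintf("[^%s]", alphabet), x)
  if (any(bad)) {
    sym <- regmatches(x[bad][1], regexpr(sprintf("[^%s]", alphabet), x[bad][1]))
    stop("invalid nucleotide symbol '", sym, "' in sequence", call. = FALSE)
  }
  x
}

.seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement with full IUPAC support
#'
#' Complements every IUPAC symbol (R<->Y, K<->M, B<->V, D<->H; S, W and N are
#' self-complementary) and reverses the string. An involution on the full
#' degenerate alphabet.
#'
#' @param x character vector of DNA strings (IUPAC, case-insensitive).
#' @return character vector of reverse complements, names preserved.
#' @examples
#' reverse_complement("CASTGCTGCCAATTTAGCYA")
#' @export
reverse_complement <- function(x) {
  x <- dna_canonical(x)
  out <- vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    paste(rev(IUPAC_COMPLEMENT[.seq_chars(s)]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  names(out) <- names(x)
  out
}

#' Does a (possibly degenerate) pattern base match a genome base?
#'
#' Set membership under the IUPAC expansion table: `iupac_match("W", "A")` is
#' TRUE because W = \{A, T\}. The genome side is expected to be A/C/G/T/N; an
#' N in the genome matches nothing by default (conservative for primer
#' scanning over assembly gaps), unless `genome_n_matches = TRUE`.
#'
#' @param pattern_base,genome_base single characters (vectorized).
#' @param genome_n_matches policy for genome-side N.
#' @return logical vector.
#' @export
iupac_match <- function(pattern_base, genome_base, genome_n_matches = FALSE) {
  p <- toupper(pattern_base); g <- toupper(genome_base)
  if (any(!p %in% names(IUPAC_DNA))) {
    stop("invalid IUPAC pattern symbol", call. = FALSE)
  }
  if (any(!g %in% c("A", "C", "G", "T", "N"))) {
    stop("genome base must be A/C/G/T/N", call. = FALSE)
  }
  res <- bitwAnd(.iupac_bits[p], .iupac_bits[g]) > 0L
  if (!genome_n_matches) res[g == "N"] <- FALSE
  unname(res)
}

#' Read a (possibly line-wrapped) FASTA file
#'
#' @param path FASTA file.
#' @param moltype "dna" (canonicalized, validated) or "protein" (uppercased
#'   only).
#' @param allow_gap accept `-` in DNA records (aligned FASTA).
#' @return named character vector, one element per record.
#' @export
read_fasta <- function(path, moltype = c("dna", "protein"), allow_gap = FALSE) {
  moltype <- match.arg(moltype)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  seqs <- as.character(set)
  names(seqs) <- ids
  if (moltype == "dna") dna_canonical(seqs, allow_gap = allow_gap)
  else toupper(seqs)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector (names become headers).
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named", call. = FALSE)
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' GC content over unambiguous bases
#'
#' (#G + #C) / (#A + #C + #G + #T); degenerate symbols and gaps are excluded
#' from both numerator and denominator.
#'
#' @param x DNA string.
#' @return fraction in \[0, 1\].
#' @export
gc_content <- function(x) {
  ch <- .seq_chars(dna_canonical(x, allow_gap = TRUE))
  n_gc <- sum(ch %in% c("G", "C"))
  n_tot <- sum(ch %in% c("A", "C", "G", "T"))
  if (n_tot == 0L) stop("no unambiguous bases: GC content undefined", call. = FALSE)
  n_gc / n_tot
}

.GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")

#' Find open reading frames on both strands
#'
#' Scans all six frames for ATG..stop ORFs (stop codon included in the
#' interval) of at least `min_aa` coded amino acids. Within one frame, nested
#' ATGs inside an already-reported ORF are not re-reported (leftmost ATG per
#' stop wins).
#'
#' @param x DNA string.
#' @param min_aa minimum protein length in amino acids (ATG and stop excluded
#'   from the count is not applied: an ORF of `3*(min_aa+1)` nt codes
#'   `min_aa` residues plus the stop).
#' @param seq_id id used in the returned intervals.
#' @return data.frame with columns `seq_id`, `start`, `end`, `strand` (+/-),
#'   `aa_len`; coordinates always on the forward strand, 1-based closed.
#' @export
find_orfs <- function(x, min_aa, seq_id = "seq") {
  x <- dna_canonical(x)
  n <- nchar(x)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") x else reverse_complement(x)
    ch <- .seq_chars(s)
    for (frame in 0:2) {
      starts <- seq.int(1L + frame, n - 2L, by = 3L)
      if (frame + 3L > n) next
      codons <- paste0(ch[starts], ch[starts + 1L], ch[starts + 2L])
      is_atg <- codons == "ATG"
      is_stop <- codons %in% .GENETIC_CODE_STOPS
      open_at <- NA_integer_
      for (i in seq_along(codons)) {
        if (is.na(open_at) && is_atg[i]) open_at <- i
        if (!is.na(open_at) && is_stop[i]) {
          aa_len <- i - open_at
          if (aa_len >= min_aa) {
            b <- starts[open_at]; e <- starts[i] + 2L
            if (strand == "-") { tmp <- b; b <- n - e + 1L; e <- n - tmp + 1L }
            res[[length(res) + 1L]] <- data.frame(
              seq_id = seq_id, start = b, end = e, strand = strand,
              aa_len = aa_len, stringsAsFactors = FALSE)
          }
          open_at <- NA_integer_
        }
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      aa_len = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$end), , drop = FALSE]
}

# ---- interval helpers (1-based, fully closed) -------------------------------

interval_length <- function(start, end) end - start + 1L

.as_granges <- function(iv) {
  GenomicRanges::GRanges(
    seqnames = iv$seq_id,
    ranges = IRanges::IRanges(start = iv$start, end = iv$end),
    strand = if ("strand" %in% names(iv)) iv$strand else "*")
}

#' Write intervals as BED6
#'
#' Internal coordinates are 1-based closed; BED output is converted to
#' 0-based half-open at this boundary.
#'
#' @param iv data.frame with `seq_id`, `start`, `end` and optionally
#'   `strand`, `name`, `score`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path) {
  gr <- .as_granges(iv)
  if ("name" %in% names(iv)) names(gr) <- iv$name
  if ("score" %in% names(iv)) gr$score <- iv$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write intervals as GFF3
#'
#' @param iv data.frame with `seq_id`, `start`, `end` and optionally
#'   `strand`, `type`, `ID`, `Parent`.
#' @param path output file.
#' @param source value of the GFF source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(iv, path, source = "hATpipe") {
  gr <- .as_granges(iv)
  gr$source <- source
  gr$type <- if ("type" %in% names(iv)) iv$type else "region"
  if ("ID" %in% names(iv)) gr$ID <- iv$ID
  if ("Parent" %in% names(iv)) gr$Parent <- iv$Parent
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
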