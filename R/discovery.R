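# Element discovery: in-silico PCR with degenerate primers, TIR/TSD
# structural validation, copy classification, exon-model splice/translate.

#' Build an in-silico PCR query from a primer pair
#'
#' Concatenates the forward primer with the reverse complement of the reverse
#' primer, i.e. the two element termini a convergent primer pair is designed
#' against, joined head to tail.
#'
#' @param forward,reverse IUPAC DNA primer strings.
#' @return single DNA string.
#' @examples
#' build_ispcr_query("CAGTGCTGCCAACAWTTYGT", "CASTGCTGCCAATTTAGCYA")
#' @export
build_ispcr_query <- function(forward, reverse) {
  paste0(dna_canonical(forward), reverse_complement(reverse))
}

.genome_bits <- function(genome, genome_n_matches = FALSE) {
  ch <- .seq_chars(genome)
  bad <- !ch %in% c("A", "C", "G", "T", "N")
  if (any(bad)) {
    stop("genome must contain only A/C/G/T/N (got '", ch[bad][1], "')",
         call. = FALSE)
  }
  b <- unname(.iupac_bits[ch])
  if (!genome_n_matches) b[ch == "N"] <- 0L
  b
}

.scan_one_strand <- function(gbits, pattern, max_mismatch) {
  m <- nchar(pattern)
  n <- length(gbits)
  if (m == 0L || m > n) return(integer(0))
  pbits <- unname(.iupac_bits[.seq_chars(pattern)])
  w <- n - m + 1L
  mism <- integer(w)
  for (j in seq_len(m)) {
    mism <- mism + as.integer(bitwAnd(gbits[j:(j + w - 1L)], pbits[j]) == 0L)
  }
  starts <- which(mism <= max_mismatch)
  attr(starts, "mismatches") <- mism[starts]
  starts
}

#' Scan a genome for degenerate-primer matches
#'
#' Slides the primer over both strands and reports every position matching
#' under IUPAC set-membership with at most `max_mismatch` mismatching
#' positions. A genome base inside a degenerate primer position's expansion
#' set counts as a full match; genome N matches nothing unless
#' `genome_n_matches = TRUE`.
#'
#' @param genome DNA string over A/C/G/T/N (or named vector of one).
#' @param primer IUPAC primer string.
#' @param max_mismatch maximum mismatches per site.
#' @param primer_name label for the output.
#' @param seq_id genome record id (defaults to the genome's name).
#' @param genome_n_matches policy for genome-side N.
#' @return data.frame of hits sorted by coordinate: `seq_id`, `start`, `end`
#'   (forward-strand 1-based closed, length == primer length), `primer`,
#'   `mismatches`, `orientation` ("forward" = primer as given matches the
#'   plus strand, "reverse" = its reverse complement does).
#' @export
scan_primer <- function(genome, primer, max_mismatch = 3L,
                        primer_name = "primer", seq_id = NULL,
                        genome_n_matches = FALSE) {
  if (is.null(seq_id)) seq_id <- if (!is.null(names(genome))) names(genome)[1] else "seq"
  genome <- dna_canonical(unname(genome[1]))
  primer <- dna_canonical(primer)
  m <- nchar(primer)
  gbits <- .genome_bits(genome, genome_n_matches)
  rows <- list()
  for (ori in c("forward", "reverse")) {
    pat <- if (ori == "forward") primer else reverse_complement(primer)
    st <- .scan_one_strand(gbits, pat, max_mismatch)
    if (length(st)) {
      rows[[ori]] <- data.frame(
        seq_id = seq_id, start = as.integer(st), end = as.integer(st + m - 1L),
        primer = primer_name, mismatches = attr(st, "mismatches"),
        orientation = ori, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    seq_id = character(), start = integer(), end = integer(),
    primer = character(), mismatches = integer(), orientation = character(),
    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair convergent primer hits into predicted amplicons
#'
#' Takes forward-orientation hits of the forward primer and
#' reverse-orientation hits of the reverse primer on the same record and
#' returns every convergent pairing whose span (outermost primer bounds,
#' inclusive) lies within `[min_len, max_len]`. When one forward hit has
#' several admissible partners, the innermost (shortest-span) pairing is
#' kept, which resolves nested candidate elements deterministically.
#'
#' @param f_hits,r_hits hit data.frames from [scan_primer()].
#' @param genome optional DNA string; when supplied each amplicon carries its
#'   sequence.
#' @param min_len,max_len admissible amplicon span in bp.
#' @param innermost keep only the shortest valid span per forward hit.
#' @return data.frame: `seq_id`, `start`, `end`, `length`, `f_start`,
#'   `f_mismatches`, `r_start`, `r_mismatches`, `sequence` (NA without
#'   `genome`).
#' @export
pair_amplicons <- function(f_hits, r_hits, genome = NULL,
                           min_len = 400L, max_len = 1200L,
                           innermost = TRUE) {
  f <- f_hits[f_hits$orientation == "forward", , drop = FALSE]
  r <- r_hits[r_hits$orientation == "reverse", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(f))) {
    ri <- r[r$seq_id == f$seq_id[i] & r$start >= f$start[i], , drop = FALSE]
    if (nrow(ri) == 0L) next
    span <- ri$end - f$start[i] + 1L
    ok <- span >= min_len & span <= max_len
    if (!any(ok)) next
    ri <- ri[ok, , drop = FALSE]; span <- span[ok]
    sel <- if (innermost) which.min(span) else seq_along(span)
    for (k in sel) {
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = f$seq_id[i], start = f$start[i], end = ri$end[k],
        length = span[k], f_start = f$start[i],
        f_mismatches = f$mismatches[i], r_start = ri$start[k],
        r_mismatches = ri$mismatches[k],
        sequence = if (is.null(genome)) NA_character_ else
          substr(unname(genome[1]), f$start[i], ri$end[k]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    seq_id = character(), start = integer(), end = integer(),
    length = integer(), f_start = integer(), f_mismatches = integer(),
    r_start = integer(), r_mismatches = integer(), sequence = character(),
    stringsAsFactors = FALSE)
  out <- out[order(out$seq_id, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.hamming <- function(a, b) sum(.seq_chars(a) != .seq_chars(b))

#' Detect terminal inverted repeats on an element copy
#'
#' Compares every prefix window of length `tir_len` starting within
#' `search_window` bp of the 5' terminus against every suffix window ending
#' within `search_window` bp of the 3' terminus, and returns the pair with
#' the fewest mismatches between the prefix and the reverse complement of
#' the suffix (ties broken outermost: smallest combined offset, then
#' smallest 5' offset). `NULL` when no pair reaches `max_mismatch`.
#'
#' @param copy DNA string of the candidate element.
#' @param tir_len TIR length in bp (hAT elements: 12).
#' @param max_mismatch tolerated mismatches between the two TIRs.
#' @param search_window how far from each terminus the TIR may start/end.
#' @return `NULL`, or a list with `left` and `right` (start/end pairs on the
#'   copy), `length` and `mismatches`.
#' @export
detect_tir <- function(copy, tir_len = 12L, max_mismatch = 2L,
                       search_window = 5L) {
  if (tir_len <= 0L) stop("tir_len must be positive", call. = FALSE)
  copy <- dna_canonical(unname(copy[1]))
  L <- nchar(copy)
  if (L < 2L * tir_len) {
    stop("copy shorter than two TIRs (", L, " bp)", call. = FALSE)
  }
  best <- NULL
  for (i in 0:search_window) {
    lw_start <- 1L + i
    if (lw_start + tir_len - 1L > L) break
    lw <- substr(copy, lw_start, lw_start + tir_len - 1L)
    for (j in 0:search_window) {
      rw_end <- L - j
      rw_start <- rw_end - tir_len + 1L
      if (rw_start <= lw_start + tir_len - 1L) next
      rw <- substr(copy, rw_start, rw_end)
      mm <- .hamming(lw, reverse_complement(rw))
      if (mm > max_mismatch) next
      cand <- list(left = c(start = lw_start, end = lw_start + tir_len - 1L),
                   right = c(start = rw_start, end = rw_end),
                   length = tir_len, mismatches = mm, offsets = c(i, j))
      if (is.null(best) ||
          mm < best$mismatches ||
          (mm == best$mismatches &&
           (sum(cand$offsets) < sum(best$offsets) ||
            (sum(cand$offsets) == sum(best$offsets) && i < best$offsets[1])))) {
        best <- cand
      }
    }
  }
  if (!is.null(best)) best$offsets <- NULL
  best
}

#' Detect a target site duplication around an inserted element
#'
#' Compares the `k` bp immediately 5' of the element with the `k` bp
#' immediately 3' of it. Transposition by staggered-cut repair duplicates the
#' target, so the two flanks of a genuine insertion are (near-)identical.
#'
#' @param genome DNA string the element sits in.
#' @param element_start,element_end element interval (1-based closed).
#' @param k TSD length (hAT elements: 8).
#' @param max_mismatch tolerated flank mismatches.
#' @return `NULL`, or a list with `left`, `right` (the flank k-mers) and
#'   `mismatches`.
#' @export
detect_tsd <- function(genome, element_start, element_end, k = 8L,
                       max_mismatch = 1L) {
  genome <- dna_canonical(unname(genome[1]))
  if (element_start - k < 1L || element_end + k > nchar(genome)) {
    stop("insufficient flank for a ", k, "-bp TSD", call. = FALSE)
  }
  left <- substr(genome, element_start - k, element_start - 1L)
  right <- substr(genome, element_end + 1L, element_end + k)
  mm <- .hamming(left, right)
  if (mm > max_mismatch) return(NULL)
  list(left = left, right = right, mismatches = mm)
}

#' Classify an element copy as complete, MITE or fragment
#'
#' A copy with TIRs and coding capacity (an ORF of at least `orf_min_aa`
#' amino acids on either strand) is a complete element; a short copy with
#' TIRs but no such ORF is a MITE (miniature inverted-repeat transposable
#' element, the internal-deletion derivative mobilized in trans); anything
#' else is a fragment.
#'
#' @param copy DNA string of the copy.
#' @param tir result of [detect_tir()] (`NULL` if absent).
#' @param tsd result of [detect_tsd()] (`NULL` if absent), carried through.
#' @param mite_max_len maximum MITE length in bp.
#' @param orf_min_aa ORF threshold defining coding capacity.
#' @param notes free-text annotation carried through.
#' @return list with `klass` ("complete"/"mite"/"fragment"), `length`,
#'   `tir`, `tsd`, `has_orf`, `notes`.
#' @export
classify_copy <- function(copy, tir, tsd = NULL, mite_max_len = 1000L,
                          orf_min_aa = 100L, notes = "") {
  copy <- dna_canonical(unname(copy[1]))
  len <- nchar(copy)
  has_orf <- nrow(find_orfs(copy, min_aa = orf_min_aa)) > 0L
  klass <- if (!is.null(tir) && has_orf) "complete"
    else if (!is.null(tir) && len <= mite_max_len && !has_orf) "mite"
    else "fragment"
  list(klass = klass, length = len, tir = tir, tsd = tsd,
       has_orf = has_orf, notes = notes)
}

#' Splice an exon model and translate the coding sequence
#'
#' Concatenates the exon substrings of an element in order and translates
#' them with the standard genetic code. The protein excludes the terminal
#' stop; `premature_stop` flags any stop codon before the final one (e.g. a
#' nonsense mutation inactivating a transposase).
#'
#' @param element DNA string.
#' @param exons data.frame with `start` and `end` columns (1-based closed,
#'   strictly increasing, non-overlapping) on the element.
#' @return list: `exons`, `cds`, `protein`, `premature_stop`,
#'   `cds_length`, `protein_length`.
#' @export
splice_and_translate <- function(element, exons) {
  element <- dna_canonical(unname(element[1]))
  exons <- as.data.frame(exons)
  if (nrow(exons) == 0L) stop("no exons supplied", call. = FALSE)
  if (any(exons$start > exons$end)) {
    stop("exon with start > end", call. = FALSE)
  }
  if (any(exons$start < 1L) || any(exons$end > nchar(element))) {
    stop("exon outside element bounds", call. = FALSE)
  }
  if (nrow(exons) > 1L &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exons must be strictly increasing and non-overlapping",
         call. = FALSE)
  }
  cds <- paste(substring(element, exons$start, exons$end), collapse = "")
  if (nchar(cds) %% 3L != 0L) {
    stop("spliced CDS length ", nchar(cds), " not divisible by 3",
         call. = FALSE)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  n_aa <- nchar(aa)
  body <- substr(aa, 1L, n_aa - 1L)
  premature <- grepl("*", body, fixed = TRUE)
  protein <- if (substr(aa, n_aa, n_aa) == "*") body else aa
  list(exons = exons, cds = cds, protein = protein,
       premature_stop = premature,
       cds_length = nchar(cds), protein_length = nchar(protein))
}

#' Run the full discovery pipeline on one genome record
#'
#' scan both primers -> pair convergent hits -> per amplicon detect TIRs and
#' TSDs -> classify. The amplicon interval is taken as the element interval
#' (for TIR-anchored primer pairs the two coincide).
#'
#' @param genome DNA string (name used as record id).
#' @param forward,reverse IUPAC primer strings.
#' @param max_mismatch per-primer mismatch tolerance.
#' @param min_len,max_len amplicon span bounds (defaults suit MITE screens;
#'   use c(2000, 5000) for full-element screens).
#' @param tir_len,tir_max_mismatch,tir_window see [detect_tir()].
#' @param tsd_len,tsd_max_mismatch see [detect_tsd()].
#' @param mite_max_len,orf_min_aa see [classify_copy()].
#' @return data.frame, one row per recovered copy: interval, class, TIR/TSD
#'   presence and mismatch counts, TSD strings, sequence.
#' @export
annotate_genome <- function(genome, forward, reverse, max_mismatch = 3L,
                            min_len = 400L, max_len = 1200L,
                            tir_len = 12L, tir_max_mismatch = 2L,
                            tir_window = 5L, tsd_len = 8L,
                            tsd_max_mismatch = 1L, mite_max_len = 1000L,
                            orf_min_aa = 100L) {
  seq_id <- if (!is.null(names(genome))) names(genome)[1] else "seq"
  g <- dna_canonical(unname(genome[1]))
  f_hits <- scan_primer(g, forward, max_mismatch, "F", seq_id)
  r_hits <- scan_primer(g, reverse, max_mismatch, "R", seq_id)
  amps <- pair_amplicons(f_hits, r_hits, g, min_len, max_len)
  rows <- lapply(seq_len(nrow(amps)), function(i) {
    s <- amps$sequence[i]
    tir <- detect_tir(s, tir_len, tir_max_mismatch, tir_window)
    tsd <- tryCatch(
      detect_tsd(g, amps$start[i], amps$end[i], tsd_len, tsd_max_mismatch),
      error = function(e) NULL)
    cls <- classify_copy(s, tir, tsd, mite_max_len, orf_min_aa)
    data.frame(
      seq_id = seq_id, start = amps$start[i], end = amps$end[i],
      length = amps$length[i], klass = cls$klass,
      tir_present = !is.null(tir),
      tir_mismatches = if (is.null(tir)) NA_integer_ else tir$mismatches,
      tir_left_start = if (is.null(tir)) NA_integer_ else
        unname(tir$left["start"]),
      tir_right_end = if (is.null(tir)) NA_integer_ else
        unname(tir$right["end"]),
      tir_length = if (is.null(tir)) NA_integer_ else tir$length,
      tsd_present = !is.null(tsd),
      tsd_mismatches = if (is.null(tsd)) NA_integer_ else tsd$mismatches,
      tsd_left = if (is.null(tsd)) NA_character_ else tsd$left,
      tsd_right = if (is.null(tsd)) NA_character_ else tsd$right,
      has_orf = cls$has_orf, sequence = s, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    seq_id = character(), start = integer(), end = integer(),
    length = integer(), klass = character(), tir_present = logical(),
    tir_mismatches = integer(), tir_left_start = integer(),
    tir_right_end = integer(), tir_length = integer(),
    tsd_present = logical(),
    tsd_mismatches = integer(), tsd_left = character(),
    tsd_right = character(), has_orf = logical(), sequence = character(),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Export annotated copies as GFF3 (copies with TIR child features)
#'
#' @param copies output of [annotate_genome()].
#' @param path output GFF3 file.
#' @return `path`, invisibly.
#' @export
copies_to_gff3 <- function(copies, path) {
  if (nrow(copies) == 0L) {
    iv <- data.frame(seq_id = character(), start = integer(),
                     end = integer(), type = character(), ID = character())
    return(write_gff3(iv, path))
  }
  ids <- sprintf("copy%03d", seq_len(nrow(copies)))
  parent <- data.frame(seq_id = copies$seq_id, start = copies$start,
                       end = copies$end, type = "mobile_genetic_element",
                       ID = ids, Parent = NA_character_,
                       stringsAsFactors = FALSE)
  kids <- copies[copies$tir_present, , drop = FALSE]
  kid_ids <- ids[copies$tir_present]
  children <- if (nrow(kids)) rbind(
    data.frame(seq_id = kids$seq_id, start = kids$start + kids$tir_left_start - 1L,
               end = kids$start + kids$tir_left_start + kids$tir_length - 2L,
               type = "terminal_inverted_repeat",
               ID = paste0(kid_ids, ".tirL"), Parent = kid_ids,
               stringsAsFactors = FALSE),
    data.frame(seq_id = kids$seq_id,
               start = kids$start + kids$tir_right_end - kids$tir_length,
               end = kids$start + kids$tir_right_end - 1L,
               type = "terminal_inverted_repeat",
               ID = paste0(kid_ids, ".tirR"), Parent = kid_ids,
               stringsAsFactors = FALSE)) else NULL
  write_gff3(rbind(parent, children), path)
}
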