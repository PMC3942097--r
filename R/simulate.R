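# Synthetic data: host genomes with planted elements and MITEs
# (transposition-realistic target site duplications), internal-deletion MITE
# derivation, substitution-model sequence evolution, VT/HT divergence
# scenarios, and the bundled primer/coordinate fixtures of the canonical
# element.

#' Canonical element fixtures
#'
#' The four degenerate screening primers, the five-exon transposase gene
#' model of the canonical 2,775-bp element (spliced CDS 1,932 nt, 643-aa
#' protein), and its structural constants: 12-bp terminal inverted repeats
#' and 8-bp target site duplications.
#'
#' @return list: `primers` (named IUPAC strings), `exons` (data.frame of
#'   1-based closed intervals), `tss`, `polya_site`, `element_len`,
#'   `tir_len`, `tsd_len`.
#' @export
but2_fixtures <- function() {
  list(
    primers = c(
      BuT2_F  = "CAGTGCTGCCAACAWTTYGT",
      BuT2_R  = "CASTGCTGCCAATTTAGCYA",
      BuT2C_F = "AGACYTCGGGRACAGTTTTGC",
      BuT2C_R = "AGCATTAATGCYAARCTTTC"),
    exons = data.frame(start = c(366L, 925L, 1486L, 2044L, 2495L),
                       end = c(864L, 1331L, 1985L, 2436L, 2627L)),
    tss = 325L,
    polya_site = 2636L,
    element_len = 2775L,
    tir_len = 12L,
    tsd_len = 8L)
}

#' Simulation configuration
#'
#' @param seed RNG seed.
#' @param genome_len host genome length in bp.
#' @param gc GC content of host background and element filler.
#' @param n_complete,n_mite number of full-length elements / MITE
#'   derivatives to plant.
#' @param element_len full element length (default the canonical 2,775 bp).
#' @param tir_len,tsd_len structural constants (12 / 8 bp for hAT).
#' @param terminal_mut_rate,body_mut_rate per-site post-insertion
#'   substitution rates inside the TIRs / in the element interior.
#' @param mite_keep5,mite_keep3 bases kept from each element end when
#'   deriving the MITE (defaults give a 700-bp derivative, the scale of
#'   empirically observed MITEs).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_len = 20000L, gc = 0.4,
                       n_complete = 1L, n_mite = 2L, element_len = 2775L,
                       tir_len = 12L, tsd_len = 8L,
                       terminal_mut_rate = 0, body_mut_rate = 0,
                       mite_keep5 = 350L, mite_keep3 = 350L,
                       orf_min_aa = 100L) {
  stopifnot(genome_len >= 0, gc > 0, gc < 1, n_complete >= 0, n_mite >= 0,
            element_len > 2 * tir_len, tir_len > 0, tsd_len > 0,
            terminal_mut_rate >= 0, terminal_mut_rate <= 1,
            body_mut_rate >= 0, body_mut_rate <= 1,
            mite_keep5 >= tir_len, mite_keep3 >= tir_len,
            mite_keep5 + mite_keep3 < element_len, orf_min_aa > 0)
  structure(as.list(environment()), class = "sim_config")
}

.random_bases <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Random host genome
#'
#' i.i.d. bases at the configured GC content; reproducible from the seed.
#'
#' @param genome_len length in bp (0 gives the empty sequence).
#' @param gc GC content in (0, 1).
#' @param seed optional RNG seed.
#' @return single DNA string.
#' @export
random_genome <- function(genome_len, gc = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(.random_bases(genome_len, gc), collapse = "")
}

# Stop-free sense codons for CDS filler.
.SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

#' Build a full-length synthetic element
#'
#' Constructs an element with exact 12-bp inverted termini compatible with
#' the bundled primer pair (the degenerate primer positions are resolved so
#' that the first 12 bases are the exact reverse complement of the last 12),
#' and a transposase-like gene. At the canonical length of 2,775 bp the gene
#' follows the canonical five-exon model (CDS 1,932 nt, 643-aa protein, stop
#' codon forced immediately after the first-exon junction closes the
#' unspliced frame); at other lengths a single long ORF is placed in the
#' element interior.
#'
#' @param cfg a [sim_config()] (fields `element_len`, `gc` used).
#' @param seed optional RNG seed.
#' @return DNA string of length `cfg$element_len`, with attributes `exons`
#'   (the gene model) and `protein_length`.
#' @export
make_element <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- cfg$element_len
  fx <- but2_fixtures()
  # degenerate positions resolved (W->A, Y->T; S->G, Y->T) so the termini
  # are exactly inverted
  f_site <- "CAGTGCTGCCAACAATTTGT"
  r_site_rc <- reverse_complement("CAGTGCTGCCAATTTAGCTA")
  ch <- .random_bases(L, cfg$gc)
  .put <- function(ch, at, s) { ch[at:(at + nchar(s) - 1L)] <- .seq_chars(s); ch }
  ch <- .put(ch, 1L, f_site)
  ch <- .put(ch, L - nchar(r_site_rc) + 1L, r_site_rc)
  if (L == fx$element_len) {
    exons <- fx$exons
    n_codon <- sum(exons$end - exons$start + 1L) / 3L   # 644
    cds <- paste0("ATG",
                  paste(sample(.SENSE_CODONS, n_codon - 2L, replace = TRUE),
                        collapse = ""), "TAA")
    pos <- 1L
    for (i in seq_len(nrow(exons))) {
      w <- exons$end[i] - exons$start[i] + 1L
      ch <- .put(ch, exons$start[i], substr(cds, pos, pos + w - 1L))
      pos <- pos + w
    }
    # close the unspliced first-exon reading frame so the ORF scanner sees a
    # bounded ORF (167 aa) even before splicing
    ch <- .put(ch, 867L, "TAA")
    ch <- .put(ch, fx$polya_site, "AATAAA")
  } else {
    n_codon <- min(644L, max(120L, (L %/% 5L) %/% 3L))
    cds <- paste0("ATG",
                  paste(sample(.SENSE_CODONS, n_codon - 2L, replace = TRUE),
                        collapse = ""), "TAA")
    at <- max(nchar(f_site) + 1L, (L - nchar(cds)) %/% 2L)
    ch <- .put(ch, at, cds)
    exons <- data.frame(start = at, end = at + nchar(cds) - 1L)
  }
  el <- paste(ch, collapse = "")
  attr(el, "exons") <- exons
  attr(el, "protein_length") <- if (L == fx$element_len)
    sum(fx$exons$end - fx$exons$start + 1L) / 3L - 1L else n_codon - 1L
  el
}

#' Derive a MITE by internal deletion
#'
#' Concatenates the first `keep5` and last `keep3` bases of an element: the
#' internal (transposase-coding) portion is deleted while both TIRs and the
#' primer annealing sites are retained, which is how non-autonomous MITEs
#' arise from autonomous elements.
#'
#' @param element DNA string.
#' @param keep5,keep3 bases retained from the 5' / 3' end (each must cover
#'   at least one TIR).
#' @param tir_len TIR length used for validation.
#' @return DNA string of length `keep5 + keep3`.
#' @export
derive_mite <- function(element, keep5 = 350L, keep3 = 350L, tir_len = 12L) {
  element <- dna_canonical(unname(element[1]))
  L <- nchar(element)
  if (keep5 < tir_len || keep3 < tir_len || keep5 + keep3 >= L) {
    stop("invalid breakpoints: need tir_len <= keep5, keep3 and ",
         "keep5 + keep3 < element length", call. = FALSE)
  }
  paste0(substr(element, 1L, keep5), substr(element, L - keep3 + 1L, L))
}

# replace each hit base by one of the other three, uniformly
.substitute <- function(ch, hit) {
  if (length(hit) == 0L) return(ch)
  bases <- c("A", "C", "G", "T")
  cur <- match(ch[hit], bases)
  ch[hit] <- bases[(cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
  ch
}

.mutate_positions <- function(ch, idx, rate) {
  if (rate <= 0 || length(idx) == 0L) return(list(ch = ch, n = 0L))
  hit <- idx[stats::runif(length(idx)) < rate]
  list(ch = .substitute(ch, hit), n = length(hit))
}

#' Plant element copies into a host genome with target site duplication
#'
#' Each insertion mimics transposition by staggered-cut repair: an
#' independent random target site is chosen, its `tsd_len`-mer is duplicated
#' and the copy inserted between the two duplicates, so both flanks of one
#' copy are identical while the TSDs of distinct copies differ (with
#' probability 1 - 4^-tsd_len). Post-insertion substitutions are applied at
#' `terminal_mut_rate` within the TIRs and `body_mut_rate` elsewhere in the
#' copy, so structural decay is controllable independently of insertion.
#'
#' @param genome host DNA string.
#' @param copies named character vector/list of element sequences to insert.
#' @param cfg a [sim_config()] (`tsd_len`, `tir_len`, mutation rates).
#' @param seed optional RNG seed.
#' @return list: `genome` (post-insertion sequence) and `truth`, a
#'   data.frame with per-copy final coordinates, TSD string, TIR coordinates
#'   and applied mutation counts. Truth intervals are mutually
#'   non-overlapping.
#' @export
plant_copies <- function(genome, copies, cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- dna_canonical(unname(genome[1]))
  n <- nchar(genome)
  k <- cfg$tsd_len
  ids <- names(copies)
  copies <- as.character(copies)
  if (is.null(ids)) ids <- sprintf("copy%02d", seq_along(copies))
  nc <- length(copies)
  min_sep <- k + 10L
  if (nc > 0L && n < nc * min_sep + k) {
    stop("genome too small to plant ", nc, " copies", call. = FALSE)
  }
  # rejection-sample distinct target sites separated by >= min_sep
  sites <- integer(0)
  tries <- 0L
  while (length(sites) < nc) {
    cand <- sample.int(n - k, 1L)
    if (all(abs(cand - sites) >= min_sep)) sites <- c(sites, cand)
    tries <- tries + 1L
    if (tries > 1000L * max(nc, 1L)) {
      stop("could not place ", nc, " non-overlapping insertions", call. = FALSE)
    }
  }
  ord <- order(sites)
  sites <- sites[ord]; copies <- copies[ord]; ids <- ids[ord]
  lens <- nchar(copies)
  offset <- c(0L, cumsum(lens + k))[seq_len(max(nc, 1L))]
  rows <- list()
  pieces <- character(0)
  prev <- 1L
  for (i in seq_len(nc)) {
    s <- sites[i]
    tsd <- substr(genome, s, s + k - 1L)
    body <- .seq_chars(copies[i])
    tir_idx <- c(seq_len(cfg$tir_len),
                 (lens[i] - cfg$tir_len + 1L):lens[i])
    mt <- .mutate_positions(body, tir_idx, cfg$terminal_mut_rate)
    mb <- .mutate_positions(mt$ch, setdiff(seq_len(lens[i]), tir_idx),
                            cfg$body_mut_rate)
    mutated <- paste(mb$ch, collapse = "")
    pieces <- c(pieces, substr(genome, prev, s + k - 1L), mutated, tsd)
    prev <- s + k
    start_i <- s + k + offset[i]
    rows[[i]] <- data.frame(
      copy_id = ids[i], start = start_i, end = start_i + lens[i] - 1L,
      length = lens[i], tsd = tsd,
      tir_left_start = start_i, tir_right_end = start_i + lens[i] - 1L,
      terminal_muts = mt$n, body_muts = mb$n, stringsAsFactors = FALSE)
  }
  pieces <- c(pieces, substr(genome, prev, n))
  truth <- if (nc) do.call(rbind, rows) else data.frame(
    copy_id = character(), start = integer(), end = integer(),
    length = integer(), tsd = character(), tir_left_start = integer(),
    tir_right_end = integer(), terminal_muts = integer(),
    body_muts = integer(), stringsAsFactors = FALSE)
  list(genome = paste(pieces, collapse = ""), truth = truth)
}

#' Simulate a host genome with planted elements and MITEs
#'
#' Convenience wrapper: builds one full-length element, derives a MITE from
#' it, plants `n_complete` copies of the former and `n_mite` of the latter,
#' and returns the mutated genome with ground truth (including the true
#' structural class of each copy).
#'
#' @param cfg a [sim_config()].
#' @return list: `genome`, `truth` (with `klass` column), `element`,
#'   `mite`.
#' @export
simulate_host_genome <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  host <- random_genome(cfg$genome_len, cfg$gc)
  # the deletion junction can occasionally create a chance ORF long enough
  # to count as coding capacity; regenerate until the derivative is a true
  # non-coding MITE
  for (attempt in 1:50) {
    element <- make_element(cfg)
    mite <- derive_mite(element, cfg$mite_keep5, cfg$mite_keep3, cfg$tir_len)
    if (nrow(find_orfs(mite, min_aa = cfg$orf_min_aa)) == 0L) break
  }
  copies <- c(rep(list(element), cfg$n_complete), rep(list(mite), cfg$n_mite))
  names(copies) <- c(sprintf("complete%02d", seq_len(cfg$n_complete)),
                     sprintf("mite%02d", seq_len(cfg$n_mite)))
  klass <- rep(c("complete", "mite"), c(cfg$n_complete, cfg$n_mite))
  names(klass) <- names(copies)
  planted <- plant_copies(host, unlist(copies), cfg)
  planted$truth$klass <- unname(klass[planted$truth$copy_id])
  c(planted, list(element = element, mite = mite))
}

#' Evolve two descendants from an ancestor to a target p-distance
#'
#' Each lineage undergoes independent Jukes-Cantor substitution (no indels)
#' with branch length chosen so the expected p-distance between the two
#' descendants equals `target_d`: the total branch length is
#' `b = -3/4 * log(1 - 4/3 * d)` and each site ends different from its
#' ancestor with probability `3/4 * (1 - exp(-4*(b/2)/3))` per lineage.
#'
#' @param ancestor DNA string.
#' @param target_d expected p-distance, in \[0, 0.75).
#' @param seed optional RNG seed.
#' @return character vector of the two descendant sequences.
#' @export
evolve_pair <- function(ancestor, target_d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (target_d < 0 || target_d >= 0.75) {
    stop("target_d must lie in [0, 0.75)", call. = FALSE)
  }
  ancestor <- dna_canonical(unname(ancestor[1]))
  if (target_d == 0) return(c(ancestor, ancestor))
  b_lineage <- -3 / 4 * log(1 - 4 / 3 * target_d) / 2
  p_change <- 3 / 4 * (1 - exp(-4 * b_lineage / 3))
  ch <- .seq_chars(ancestor)
  evolve_one <- function() {
    hit <- which(stats::runif(length(ch)) < p_change)
    paste(.substitute(ch, hit), collapse = "")
  }
  c(evolve_one(), evolve_one())
}

#' Generate one VT or HT divergence scenario
#'
#' Produces a [marker_pair()] whose nuclear-gene alignment is evolved to
#' `d_gene` and whose transposon alignment to `d_te`. VT (vertical
#' transmission) scenarios force `d_te == d_gene` — the null of the
#' chi-squared HT test; HT scenarios require `d_te < d_gene`, modelling a
#' transposon that crossed the species boundary after the hosts split.
#' Alignments are gap-free, so they feed the distance functions directly.
#'
#' @param mode "VT" or "HT".
#' @param d_gene true nuclear-gene p-distance.
#' @param d_te true transposon p-distance (defaults to `d_gene` under VT).
#' @param L_te,L_gene alignment lengths in bp.
#' @param gc GC content of the simulated ancestors.
#' @param seed optional RNG seed.
#' @param gene_name marker label.
#' @return a [marker_pair()] with attribute `mode`.
#' @export
make_scenario <- function(mode = c("VT", "HT"), d_gene = 0.2, d_te = NULL,
                          L_te = 1000L, L_gene = 5000L, gc = 0.5,
                          seed = NULL, gene_name = "gene") {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(d_te)) d_te <- if (mode == "VT") d_gene else d_gene / 10
  if (mode == "VT" && d_te != d_gene) {
    stop("VT scenario requires d_te == d_gene", call. = FALSE)
  }
  if (mode == "HT" && d_te >= d_gene) {
    stop("HT scenario requires d_te < d_gene", call. = FALSE)
  }
  te <- evolve_pair(random_genome(L_te, gc), d_te)
  gene <- evolve_pair(random_genome(L_gene, gc), d_gene)
  mp <- marker_pair("speciesA", "speciesB", te[1], te[2], gene[1], gene[2],
                    gene_name)
  attr(mp, "mode") <- mode
  mp
}
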