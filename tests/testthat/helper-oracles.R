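# Independent brute-force oracles and small generators used across tests.
# These deliberately avoid the package's optimized code paths.

BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

chars <- function(x) strsplit(x, "")[[1]]

# symbol-by-symbol complement + reverse, via the expansion sets: the
# complement of a degenerate symbol is the symbol whose set is the
# base-complement of its set
oracle_revcomp <- function(x) {
  comp_base <- c(A = "T", C = "G", G = "C", T = "A")
  set_key <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  out <- vapply(rev(chars(x)), function(sym) {
    comp_set <- sort(unname(comp_base[IUPAC_SETS[[sym]]]))
    names(which(set_key == paste(comp_set, collapse = "")))
  }, "")
  paste(out, collapse = "")
}

# position-by-position primer scan, one strand
oracle_scan_strand <- function(genome, pattern, max_mismatch) {
  g <- chars(genome); p <- chars(pattern)
  m <- length(p); n <- length(g)
  if (m == 0 || m > n) return(integer(0))
  hits <- integer(0)
  for (s in 1:(n - m + 1)) {
    mm <- 0
    for (j in 1:m) {
      gb <- g[s + j - 1]
      ok <- gb != "N" && gb %in% IUPAC_SETS[[p[j]]]
      if (!ok) mm <- mm + 1
    }
    if (mm <= max_mismatch) hits <- c(hits, s)
  }
  hits
}

# column-by-column p-distance with pairwise deletion
oracle_p_distance <- function(a, b) {
  ca <- chars(a); cb <- chars(b)
  ok <- ca %in% BASES & cb %in% BASES
  sum(ca[ok] != cb[ok]) / sum(ok)
}

# six-frame ORF scan by regex on each frame's codon string
oracle_orfs <- function(x, min_aa) {
  n <- nchar(x)
  found <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") x else oracle_revcomp(x)
    for (frame in 0:2) {
      i <- 1 + frame
      codons <- character(0)
      while (i + 2 <= n) { codons <- c(codons, substr(s, i, i + 2)); i <- i + 3 }
      open <- NA
      for (ci in seq_along(codons)) {
        if (is.na(open) && codons[ci] == "ATG") open <- ci
        if (!is.na(open) && codons[ci] %in% c("TAA", "TAG", "TGA")) {
          if (ci - open >= min_aa) {
            b <- 1 + frame + (open - 1) * 3; e <- 1 + frame + ci * 3 - 1
            if (strand == "-") { t <- b; b <- n - e + 1; e <- n - t + 1 }
            found[[length(found) + 1]] <- c(b, e)
          }
          open <- NA
        }
      }
    }
  }
  found
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

random_iupac <- function(n) {
  paste(sample(names(IUPAC_SETS), n, replace = TRUE), collapse = "")
}

# random unrooted tree with positive branch lengths and its additive
# distance matrix (path lengths), for NJ consistency tests
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  d <- ape::cophenetic.phylo(tr)
  list(tree = tr, d = d[tr$tip.label, tr$tip.label])
}
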