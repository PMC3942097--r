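# Pairwise evolutionary distances on pre-aligned sequences and
# neighbor-joining tree construction.
#
# Gap handling is pairwise deletion: for each pair, only columns where both
# sequences carry an unambiguous A/C/G/T are compared; gaps and degenerate
# symbols (R, Y, N, ...) are treated as missing at that site.

.PURINES <- c("A", "G")

#' Per-pair alignment statistics under pairwise deletion
#'
#' @param a,b gapped DNA strings of equal length.
#' @return list: `compared_sites`, `diffs`, `transitions` (A<->G, C<->T),
#'   `transversions`, `gc` (GC fraction over the compared sites of both
#'   sequences pooled).
#' @export
alignment_stats <- function(a, b) {
  a <- dna_canonical(unname(a[1]), allow_gap = TRUE)
  b <- dna_canonical(unname(b[1]), allow_gap = TRUE)
  if (nchar(a) != nchar(b)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  ca <- .seq_chars(a); cb <- .seq_chars(b)
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  ca <- ca[ok]; cb <- cb[ok]
  diff <- ca != cb
  both_purine <- ca %in% .PURINES & cb %in% .PURINES
  both_pyrimidine <- !ca %in% .PURINES & !cb %in% .PURINES
  ts <- sum(diff & (both_purine | both_pyrimidine))
  list(compared_sites = length(ca), diffs = sum(diff), transitions = ts,
       transversions = sum(diff) - ts,
       gc = if (length(ca)) mean(c(ca, cb) %in% c("G", "C")) else NaN)
}

#' Proportion of differing sites (p-distance)
#'
#' diffs / compared_sites over pairwise-deleted columns.
#'
#' @param a,b gapped DNA strings of equal length.
#' @return distance in \[0, 1\].
#' @export
p_distance <- function(a, b) {
  st <- alignment_stats(a, b)
  if (st$compared_sites == 0L) {
    stop("no comparable sites: p-distance undefined", call. = FALSE)
  }
  st$diffs / st$compared_sites
}

#' Tamura 3-parameter distance from substitution proportions
#'
#' Closed form `d = -h*log(1 - P/h - Q) - (1-h)/2 * log(1 - 2Q)` with
#' `h = 2*theta*(1-theta)`, where `P` and `Q` are the transition and
#' transversion proportions and `theta` the GC content. Corrects the
#' p-distance for multiple hits, transition/transversion bias and GC bias.
#'
#' @param P transition proportion.
#' @param Q transversion proportion.
#' @param theta GC content in (0, 1).
#' @return corrected distance (>= 0).
#' @export
tamura_3p <- function(P, Q, theta) {
  h <- 2 * theta * (1 - theta)
  arg1 <- 1 - P / h - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    stop(sprintf(
      "Tamura 3-parameter distance saturated (P = %.4g, Q = %.4g)", P, Q),
      call. = FALSE)
  }
  -h * log(arg1) - (1 - h) / 2 * log(arg2)
}

#' Tamura 3-parameter distance between two aligned sequences
#'
#' @param a,b gapped DNA strings of equal length.
#' @return corrected distance.
#' @seealso [tamura_3p()] for the closed form.
#' @export
tamura_3p_distance <- function(a, b) {
  st <- alignment_stats(a, b)
  if (st$compared_sites == 0L) {
    stop("no comparable sites: distance undefined", call. = FALSE)
  }
  if (st$diffs == 0L) return(0)
  tamura_3p(st$transitions / st$compared_sites,
            st$transversions / st$compared_sites, st$gc)
}

#' Pairwise distance matrix over an aligned sequence set
#'
#' @param seqs named character vector of gapped DNA strings, equal length.
#' @param metric "p" (p-distance) or "t92" (Tamura 3-parameter).
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
distance_matrix <- function(seqs, metric = c("p", "t92")) {
  metric <- match.arg(metric)
  n <- length(seqs)
  labels <- names(seqs)
  if (is.null(labels)) labels <- paste0("seq", seq_len(n))
  if (length(unique(nchar(seqs))) > 1L) {
    stop("all aligned sequences must have equal length", call. = FALSE)
  }
  fn <- if (metric == "p") p_distance else tamura_3p_distance
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- tryCatch(
        fn(seqs[[i]], seqs[[j]]),
        error = function(e) stop("pair (", labels[i], ", ", labels[j], "): ",
                                 conditionMessage(e), call. = FALSE))
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Agglomerative tree construction with the rate-corrected selection
#' criterion `Q[i,j] = (n-2) d[i,j] - r[i] - r[j]`; exact on additive
#' distances. Ties are broken deterministically by the lowest (i, j) index
#' pair in the current node order (input label order first). Negative branch
#' lengths are clamped to zero and counted in the `negative_branches`
#' attribute of the result.
#'
#' @param d symmetric numeric distance matrix with labels as dimnames
#'   (n >= 3).
#' @return unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix not symmetric",
                                      call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  frag <- labels                 # newick fragment per active node
  clamped <- 0L
  .bl <- function(x) {           # branch length, clamped at zero
    if (x < 0) clamped <<- clamped + 1L
    max(x, 0)
  }
  fmt <- function(x) sprintf("%.15g", x)
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest (i, j) among minima, row-major over i < j
    best <- NULL
    qmin <- min(q)
    for (i in seq_len(m - 1L)) {
      j <- which(q[i, (i + 1L):m] <= qmin + 1e-12)
      if (length(j)) { best <- c(i, i + j[1]); break }
    }
    i <- best[1]; j <- best[2]
    bi <- .bl(d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    bj <- .bl(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    new_frag <- paste0("(", frag[i], ":", fmt(bi), ",",
                       frag[j], ":", fmt(bj), ")")
    keep <- setdiff(seq_len(m), c(i, j))
    du <- (d[i, keep] + d[j, keep] - d[i, j]) / 2
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du), c(du, 0))
    frag <- c(frag[keep], new_frag)
    dimnames(d2) <- list(NULL, NULL)
    d <- d2
  }
  ba <- .bl((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  bb <- .bl((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  bc <- .bl((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- paste0("(", frag[1], ":", fmt(ba), ",", frag[2], ":", fmt(bb),
                ",", frag[3], ":", fmt(bc), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_branches") <- clamped
  tree
}

#' Serialize a tree to Newick
#'
#' @param tree an `ape::phylo` object.
#' @return single Newick string with branch lengths.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Parse a Newick string
#'
#' @param text Newick string.
#' @return `ape::phylo` tree; malformed input raises an error.
#' @export
read_newick <- function(text) {
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tree)) stop("malformed Newick string", call. = FALSE)
  tree
}
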