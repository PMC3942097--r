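# Horizontal-transfer vs vertical-transmission classification.
#
# Rationale: a vertically transmitted transposon accumulates divergence
# between species for at least as long as the host's nuclear genes, so TE
# divergence significantly below nuclear-gene divergence suggests the
# element crossed the species boundary more recently (horizontal transfer).

#' Bundle the two alignments of one species pair
#'
#' @param species_a,species_b species labels.
#' @param te_a,te_b aligned transposon sequences (equal gapped length).
#' @param gene_a,gene_b aligned nuclear-gene sequences.
#' @param gene_name nuclear marker name (e.g. "Adh", "Amd").
#' @return a `marker_pair` list consumed by [ht_chi2_test()].
#' @export
marker_pair <- function(species_a, species_b, te_a, te_b, gene_a, gene_b,
                        gene_name = "gene") {
  structure(list(species_a = species_a, species_b = species_b,
                 te_a = te_a, te_b = te_b, gene_a = gene_a, gene_b = gene_b,
                 gene_name = gene_name),
            class = "marker_pair")
}

#' Chi-squared test of transposon vs nuclear-gene divergence
#'
#' One-sample goodness-of-fit on the transposon alignment's (different,
#' identical) site counts, with expected proportions taken from the
#' nuclear-gene p-distance: with `L` compared TE sites and observed counts
#' `O = (diffs, L - diffs)`, the expectation is
#' `E = (d_gene * L, (1 - d_gene) * L)` and `chi2 = sum((O - E)^2 / E)` on
#' 1 degree of freedom.
#'
#' Decision rule: vertical transmission (VT) whenever the TE divergence is
#' greater than or equal to the gene divergence, regardless of significance;
#' horizontal transfer (HT) only when the TE divergence is below the gene
#' divergence AND the chi-squared p-value is below `alpha`. When an expected
#' cell count falls below `min_expected` the chi-squared approximation is
#' not trusted and the verdict is "inconclusive".
#'
#' @param mp a [marker_pair()].
#' @param alpha significance level (default 0.01).
#' @param min_expected expected-count floor per cell (default 5).
#' @return one-row data.frame: `species_a`, `species_b`, `gene_name`,
#'   `d_te`, `d_gene`, `chi2`, `p_value`, `call` (HT/VT/inconclusive).
#' @export
ht_chi2_test <- function(mp, alpha = 0.01, min_expected = 5) {
  st_te <- alignment_stats(mp$te_a, mp$te_b)
  d_te <- p_distance(mp$te_a, mp$te_b)
  d_gene <- p_distance(mp$gene_a, mp$gene_b)
  if (d_gene <= 0 || d_gene >= 1) {
    stop("degenerate expectation: gene p-distance is ", d_gene, call. = FALSE)
  }
  L <- st_te$compared_sites
  O <- c(st_te$diffs, L - st_te$diffs)
  E <- c(d_gene * L, (1 - d_gene) * L)
  chi2 <- sum((O - E)^2 / E)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  if (min(E) < min_expected) {
    warning("expected count below ", min_expected,
            "; chi-squared approximation unreliable", call. = FALSE)
    call <- "inconclusive"
  } else if (d_te < d_gene && p < alpha) {
    call <- "HT"
  } else {
    call <- "VT"
  }
  data.frame(species_a = mp$species_a, species_b = mp$species_b,
             gene_name = mp$gene_name, d_te = d_te, d_gene = d_gene,
             chi2 = chi2, p_value = p, call = call,
             stringsAsFactors = FALSE)
}

#' Screen many species pairs for horizontal transfer
#'
#' @param pairs list of [marker_pair()] objects.
#' @param alpha significance level per test.
#' @param correction "none" or "bonferroni" (tests each pair at
#'   `alpha / length(pairs)`).
#' @return data.frame of verdicts (one row per pair, sorted by species
#'   pair); a pair whose test errors yields `call = NA` and the message in
#'   `note` instead of aborting the screen.
#' @export
ht_screen <- function(pairs, alpha = 0.01,
                      correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  if (length(pairs) == 0L) stop("no marker pairs supplied", call. = FALSE)
  alpha_eff <- if (correction == "bonferroni") alpha / length(pairs) else alpha
  rows <- lapply(pairs, function(mp) {
    tryCatch({
      v <- ht_chi2_test(mp, alpha = alpha_eff)
      v$note <- ""
      v
    }, error = function(e) {
      data.frame(species_a = mp$species_a, species_b = mp$species_b,
                 gene_name = mp$gene_name, d_te = NA_real_,
                 d_gene = NA_real_, chi2 = NA_real_, p_value = NA_real_,
                 call = NA_character_, note = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species_a, out$species_b, out$gene_name), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
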