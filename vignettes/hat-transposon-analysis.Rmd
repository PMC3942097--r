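---
title: "Annotating hAT transposons and testing horizontal transfer"
author: "hATpipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating hAT transposons and testing horizontal transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hATpipe)
```

## The biological problem

Class II (DNA) transposons of the hAT superfamily move by a cut-and-paste
mechanism. Three structural consequences make them recognizable in an
assembly, and this package is built around all three:

* **Terminal inverted repeats (TIRs).** The transposase binds short
  reverse-complementary motifs at the element ends — 12 bp for the family
  modelled here.
* **Target site duplications (TSDs).** Insertion repairs a staggered cut,
  duplicating an 8-bp host motif on both flanks. The two flanks of *one*
  copy are identical; flanks of *different* copies match only by chance
  (probability $4^{-8} \approx 1.5\times10^{-5}$). This asymmetry is the
  cleanest evidence that copies arose by transposition rather than segmental
  duplication.
* **MITE derivatives.** Internal deletion of an autonomous copy yields a
  short element that keeps the TIRs (and hence mobility in trans) but loses
  the transposase. A MITE family therefore looks like: short length, no
  coding capacity, conserved termini, high copy number.

Beyond annotation, the package asks *how the element spread*: a transposon
inherited vertically accumulates between-species divergence for at least as
long as the host's nuclear genes, so a transposon significantly **less**
diverged than a nuclear gene between the same two species points to
horizontal transfer (HT).

## Discovery: in-silico PCR

Wet-lab screens for this family use degenerate primers; the in-silico
analogue keeps that interface. A primer is an IUPAC string; a genome
position matches a primer position when the genome base is a member of the
primer symbol's expansion set (`W = {A,T}`, `Y = {C,T}`, ...). Two policies
are fixed and exposed as flags:

* a genome base inside a degenerate set counts as a *full* match, not a
  partial one;
* genome `N` (assembly gap) matches nothing by default — conservative, so
  gaps cannot fabricate primer sites.

`scan_primer()` scans both strands with a per-primer mismatch budget
(default 3 — a deliberate stand-in, since homology-search screens do not
state one; it is a parameter, not a constant). `pair_amplicons()` keeps
convergent forward/reverse hits whose span falls in a length window, and
resolves nested candidates to the **innermost** (shortest) span per forward
hit. Manual curation in published screens kept hits that "visibly" contained
both primer regions; an automated pipeline must pick a deterministic rule,
and innermost pairing is the one that cannot swallow two tandem copies into
one call.

Default windows: `[400, 1200]` bp for MITE screens (bracketing the
empirically observed 532–927 bp family with margin) and `[2000, 5000]` bp
for full-element screens (canonical length 2,775 bp).

## Structural validation

`detect_tir()` compares every prefix window against every suffix window
within 5 bp of the respective terminus (length 12, ≤ 2 mismatches by
default, matching the most decayed TIR pair accepted in the source survey)
and returns the fewest-mismatch, outermost pair. `detect_tsd()` is
deliberately strict: it compares exactly the `k` bases immediately flanking
the element (default `k = 8`, ≤ 1 mismatch) — no window search, because the
TSD position is fully determined by the element boundaries.

`classify_copy()` applies the MITE criteria: *complete* = TIRs + an open
reading frame of ≥ 100 aa on either strand; *mite* = TIRs, ≤ 1000 bp, and
no such ORF; everything else *fragment*. The two thresholds bracket the
observed MITE family (532–927 bp, non-coding) while excluding any copy
retaining a substantial transposase fragment; both are arguments, not
constants.

`splice_and_translate()` validates exon models. The canonical element's
five exons (366–864, 925–1331, 1486–1985, 2044–2436, 2495–2627 in 1-based
closed coordinates) sum to 1,932 nt = 644 codons, i.e. a 643-aa protein
after the terminal stop — the desk check the test-suite pins exactly. A stop
codon upstream of the final one sets `premature_stop`, modelling
nonsense-inactivated copies.

## Distances and trees

Distances operate on pre-aligned sequences (alignment itself is outside the
package's scope). Gap and ambiguity handling is **pairwise deletion**: each
pair uses every column where both sequences have an unambiguous base. This
keeps per-pair site counts maximal, which matters because the HT test
consumes the raw site counts, not just the proportion.

The Tamura 3-parameter distance corrects the p-distance for multiple hits,
transition/transversion bias and GC bias:

$$d = -h \ln(1 - P/h - Q) - \tfrac{1}{2}(1-h)\ln(1 - 2Q), \quad
h = 2\theta(1-\theta)$$

with transitions defined as A↔G and C↔T, and $\theta$ estimated as the GC
fraction of the compared sites of both sequences pooled. Saturated pairs
(non-positive log arguments) raise an error carrying P and Q rather than
returning `NaN`. A gamma-rates variant is a documented extension point, not
implemented: in the motivating analyses the gamma correction belonged to the
likelihood machinery, not the NJ distances.

`nj_tree()` is a from-scratch Saitou–Nei implementation with the
rate-corrected criterion $Q_{ij} = (n-2)d_{ij} - r_i - r_j$. Two numerical
policies are fixed: ties in the criterion break to the lowest (i, j) index
pair in the current node order, so output is reproducible; negative branch
lengths are clamped to zero and counted in an attribute. NJ is exact on
additive matrices — the test-suite exploits this, checking 200 random 4–8
taxon trees for exact topology (Robinson–Foulds 0 against an independent NJ
implementation) and path lengths within 1e-9. Newick serialization goes
through `ape`, the field-standard container.

## The chi-squared HT/VT classifier

The published decision rule is verbal: assume vertical transmission when
transposon divergence ≥ nuclear-gene divergence; suspect HT when it is
smaller and a chi-squared test finds the difference significant. The test's
exact construction was not specified, so the package fixes the simplest one
consistent with "observed vs expected divergence" and documents it:

With $L$ compared transposon sites, observed counts
$O = (\text{diffs}, L - \text{diffs})$ and expectation
$E = (\hat d_g L, (1-\hat d_g)L)$ from the gene p-distance $\hat d_g$,

$$\chi^2 = \sum_i (O_i - E_i)^2 / E_i, \qquad \text{df} = 1.$$

The test is two-sided; directionality comes from the decision rule (HT
requires $d_{te} < d_g$ *and* $p < \alpha$), so under the null roughly
$\alpha/2$ of pairs are miscalled HT — conservative by construction. Default
$\alpha = 0.01$, matching the significance tiers flagged in the motivating
study. Guard rails: expected cell counts below 5 make the verdict
*inconclusive* (the chi-squared approximation is not trusted), and a gene
p-distance of exactly 0 or 1 is a degenerate expectation and errors.
Multiple-testing correction is off by default, with Bonferroni available in
`ht_screen()`.

Treating $\hat d_g$ as *the* expectation ignores its own sampling noise.
That is inherent to the goodness-of-fit construction, which is why the
default null scenario gives the gene the longer alignment (below).

## What the simulator emulates — and what it does not

`simulate_host_genome()` generates i.i.d. background sequence at a set GC
(default 0.4, a typical insect euchromatin value), builds an element whose
termini are exact 12-bp inverted repeats compatible with the bundled primer
pair, a five-exon transposase gene at the canonical coordinates, and a
polyadenylation signal; `derive_mite()` deletes the interior (default
350 + 350 bp, giving a 700-bp derivative — the scale of the observed
family, mean ≈ 739 bp). Because a random deletion junction can by chance
create a ≥ 100-aa ORF, the generator verifies the derivative is non-coding
and redraws otherwise. Each insertion duplicates an independently chosen
8-mer target, and post-insertion substitutions are applied at separate
terminal (TIR) and body rates, so structural decay is controllable
independently of age.

Divergence scenarios evolve two descendants from a random ancestor under
Jukes–Cantor substitution with branch lengths solved from the target
p-distance ($b = -\tfrac34\ln(1-\tfrac43 d)$, split equally); no indels, so
the "alignment" is exact by construction. VT scenarios force equal true
transposon and gene divergence; HT scenarios require the transposon below
the gene.

Defaults for the null calibration were chosen once, on biological grounds:
true divergence 0.20 (mid-range for the interspecific comparisons that
motivate the test), transposon alignment 1,000 bp (MITE-scale), gene
alignment 5,000 bp — long enough that the gene-side estimate behaves like
the known expectation the goodness-of-fit test assumes.

Features of real data the simulator does **not** model, and which passing
tests therefore say nothing about: indels and alignment error, nested TE
insertions (supported structurally as a disruptor flag but off by default),
rate heterogeneity across sites, selection on the transposase, and
assembly artefacts (collapsed repeats, gaps). Real screens also face
diverged primer sites; the mismatch budget is the only knob for that.

## Problem sizes and runtime choices

The validation suite runs at the following scales, chosen to give tight
Monte-Carlo bounds while staying desk-sized: 100 simulated 20-kb genomes ×
3 copies for recovery (precision = recall = 1 required at zero mutation);
2,000 null scenarios for the type-I error (required within
$\alpha \pm 3\sqrt{\alpha(1-\alpha)/2000}$); 300 HT scenarios at
$d_{te} = 0.02$ vs $d_g = 0.20$ for power (> 99% required); 200 additive
matrices for NJ; 100 random instances against brute-force oracles for the
primer scanner and p-distance. `scripts/acceptance.R` re-runs the same
computations from scratch and writes the numbers as JSON.

## Known limitations

* Whole-assembly homology search (BLAST-style) is intentionally out of
  scope; discovery is primer-anchored, so copies with decayed primer sites
  beyond the mismatch budget are invisible.
* Distances assume the input is a trustworthy alignment; there is no
  alignment or alignment-quality machinery.
* The HT test is a screening statistic, not a dating method: it flags
  divergence deficits but cannot localize the transfer on a tree, and its
  null calibration treats the nuclear gene divergence as exact.
* Maximum-likelihood and Bayesian phylogenetics, bootstrap support, and
  protein-domain annotation belong to external tools.
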