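---
title: "Screening quartet orthogroup alignments for lineage-specific selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening quartet orthogroup alignments for lineage-specific selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(orthosnp)
```

## The problem

Closely related species that differ in a derived phenotype — here, the
elongated electric organ discharge of one mormyrid fish species relative to
its short-discharge sister species — should carry some of the responsible
genetic variation as fixed, expressed coding substitutions specific to the
derived lineage. Given single-copy orthogroups (SCOs) with exactly one coding
sequence per species for a quartet of taxa `((focal, sister), out1, out2)`,
the package runs two complementary screens:

* **Quartet candidate screen.** A gene is a candidate when (i) its dN/dS
  ratio $\omega$, estimated by maximum likelihood under the Goldman–Yang
  (GY94) M0 codon model on the fixed quartet topology, exceeds 1, and
  (ii) it carries at least one non-synonymous substitution found *only* in
  the focal taxon while sister and both outgroups agree. The three-way
  unanimity of the non-focal taxa polarizes the allele as derived on the
  focal branch.
* **Comparative annotation screen.** Species-specific non-synonymous SNP
  sets are built for focal and sister species separately, filtered by a
  pairwise Nei–Gojobori (NG86) $\omega > 1$ estimate on the focal/sister
  pair, and their GO/KEGG annotation profiles compared: per-term two-species
  counts against an exact binomial 50:50 acceptance region, Fisher tests on
  KEGG level A totals, chi-squared tests on level B distributions,
  BH-adjusted Fisher enrichment against the transcriptome, and two-proportion
  comparisons with Wald confidence limits.

## Models and estimators

### NG86 pairwise dN/dS

For each codon, the synonymous site count is the fraction of the nine
possible single-base changes that preserve the amino acid (changes into stop
codons count as non-synonymous); site counts are averaged over the two
sequences. Codons differing at more than one position are resolved by
averaging the synonymous/non-synonymous step classification over all
orderings of the single-base steps, excluding orderings that pass through a
stop codon (if every ordering is blocked, all orderings are used and steps
touching a stop count as non-synonymous — a rare fallback). Proportions are
corrected with the Jukes–Cantor map $d = -\tfrac{3}{4}\log(1-\tfrac{4}{3}p)$,
and $\omega = d_N/d_S$. When $d_S = 0$ the ratio is reported as *undefined*
(flagged), never as infinity, and such genes are excluded from $\omega > 1$
screens. A published pairwise tool with model averaging across several
estimators stands behind the original analysis at this step; this package
standardizes on plain NG86 counting so that every number it produces is
reproducible from the definition above.

### GY94/M0 maximum likelihood

The M0 model assigns rate $\pi_j \kappa^{\mathrm{ts}} \omega^{\mathrm{ns}}$
to single-base codon changes (zero for multi-base changes), with one
$\omega$ and one $\kappa$ shared by all sites and branches. The likelihood
on the unrooted quartet is computed by Felsenstein pruning over compressed
codon site patterns, with transition matrices from the symmetrized
eigendecomposition of the reversible generator (one decomposition per
likelihood evaluation, shared across the five branches; the kernel is
compiled). Optimization is Nelder–Mead on log-transformed parameters —
$(\log\kappa, \log\omega$, five log branch lengths) — from three starts at
$\omega_0 \in \{0.2, 1, 3\}$, explored coarsely and then polished to a
relative log-likelihood change below $10^{-8}$. The log scale keeps rates
positive and avoids boundary traps as $\omega \to 0$. Alignments with no
variable codon carry no information about $\omega$; the fit returns
`converged = FALSE` with `omega = NA` rather than failing. Codon
frequencies default to equal ($1/61$): the screen's target quantity is
$\omega$, equal frequencies make every expectation enumerable in closed
form, and the simulator uses the same convention, so estimator and
generator are exactly matched. $\omega > 1$ screens use the point estimate
with no likelihood-ratio test, mirroring the screening (not hypothesis-
testing) role of the filter.

### SNP polarization

Variant columns are called on gap-free, `N`-free columns with at least two
bases among the four taxa. Classification is site-wise: `focal_specific_strict`
requires the focal base to differ while sister and both outgroups are
unanimous (symmetrically for the sister taxon); biallelic focal/sister
disagreements without three-way unanimity are `focal_vs_sister_only`,
which separates the looser pairwise screen from the strict one —
`specificity_mode = "pairwise"` reproduces that looser reading for audit.
Columns with three or four distinct alleles are never species-specific:
the strict criterion is defined by three-way identity, and relabeling the
two outgroups never changes any classification. The VCF emitter uses the
majority allele across the four taxa as REF (ties broken toward the
outgroup-shared allele, then alphabetically); coordinates are 1-based
alignment columns throughout, and codon indices follow
$\lceil (\mathrm{pos} - \mathrm{offset})/3 \rceil$. The frame offset
defaults to 0 (ORF-trimmed alignments begin in frame) and is exposed
per orthogroup rather than guessed.

### Annotation statistics

The per-term comparison treats each term's total $n$ as fixed and asks
whether the focal share is compatible with Binomial$(n, 1/2)$: the exact
acceptance region keeps every count whose two-sided exact p-value exceeds
$\alpha$, mapped to proportions, and is symmetric about $0.5$ by the
symmetry of the null. Because the null is discrete the region is
conservative — its true rejection rate is at or below $\alpha$, which the
calibration suite verifies by simulation. A Wald variant
($0.5 \pm z_{1-\alpha/2}\sqrt{0.25/n}$) is provided because published
tables of such intervals rarely state their method; both are offered and
the choice is recorded in output. The per-term scan is deliberately *not*
FDR-adjusted (it flags raw outliers to a plotted band), while the
candidate-vs-transcriptome enrichment *is* BH-adjusted at FDR 0.05; both
conventions are stated in the output headers. Fisher tests use the
point-probability two-sided convention; level A margins take each species'
total as its number of annotated candidate sequences, a convention the
package documents rather than asserts, since printed contingency tables in
comparable analyses rarely pin down their margins; chi-squared tests are
Pearson without continuity correction, with small-expected-count flags.

## The synthetic-data generator

No sequencing data ship with the package; `simulate_study()` generates
complete studies with known ground truth:

* Alignments evolve from a stationary root along the quartet under the same
  GY94 matrices the estimator fits — gap-free, in frame, with substitutions
  into stops given rate zero. Defaults describe closely related species:
  terminal branches of 0.02 (focal, sister), 0.04 and 0.06 (outgroups) and
  0.02 (internal) expected substitutions per codon, $\kappa = 2$,
  background $\omega = 0.2$ (typical purifying selection), candidate
  $\omega = 3$ with the focal terminal branch further doubled.
* Candidate genes carry 1–3 *planted* focal substitutions: non-synonymous
  single-base changes applied to the focal sequence at codons that are
  conserved across all four simulated sequences, so each planted site is
  strictly focal-specific with no homoplasy and site-level truth is exact.
* Contaminants violate exactly one filter each: identity contaminants have
  a quarter of the focal sequence rescrambled (pairwise identity well below
  90\%) at full length, and short contaminants are 30–66 codons
  ($< 200$ bp) with clean identity.
* GO tables attach terms independently per gene at background rates of
  2–10\% per term; terms planted as enriched attach to candidate genes with
  probability 0.9 against 0.05 background. KEGG tables draw from a fixed
  six-category level A hierarchy. Per-term two-species count asymmetries
  for the ratio scan are planted with `simulate_term_counts()`, which works
  at the count level where that test operates.
* Determinism: one master seed, per-gene seeds derived by the counter
  scheme $(\mathrm{seed} + 7919\,i) \bmod (2^{31}-1)$, so individual genes
  are reproducible in isolation and whole studies are byte-identical
  across runs.

What the generator does **not** emulate: assembly and alignment error,
indels (alignments are gap-free; gap handling is tested with hand-made
fixtures), expression levels, codon-frequency bias, among-site rate
variation, and shared polymorphism within species. Passing tests on this
generator therefore demonstrate correctness of the pipeline's logic and
calibration of its statistics under the stated model — not robustness to
real-data artifacts.

## Filtering rules

Alignments are trimmed to whole codons (columns before the frame offset and
trailing partial codons removed), then kept only if all six pairwise
identities are at least 0.90 — identity computed over columns where neither
sequence has a gap or `N`, boundary inclusive, since the discard rule is
*below* 90\% — the trimmed length is at least 200 bp, and all four taxa are
present. Every input orthogroup receives exactly one outcome in the filter
report, and filtering is order-independent.

## Problem sizes and verification

The test suite and the acceptance script size their simulations as a
desk-scale study: 50 replicates of 500-codon genes per selection regime for
M0 recovery (medians within ±25\% of truth at $\omega \in \{0.2, 1, 2\}$;
$\omega = 3$ genes cross the $\omega > 1$ screen with sensitivity
$\ge 0.9$), one 200-gene study with 20 planted candidates and 8 planted
contaminants for end-to-end recovery, 10,000 binomial draws per $n$ for
acceptance-region calibration, exhaustive Fisher agreement for all tables
with total $\le 30$, and 60 unplanted annotation studies for the structural
null of the enrichment scan. These sizes were chosen to make sampling error
small relative to the tolerances being checked while keeping a full run in
the minutes range on a single core.

## Known limitations

* Single shared $\omega$ (M0) only: no site-class or branch-site models,
  and no significance test on $\omega > 1$ — genes near the boundary enter
  or leave the screen by estimation noise, exactly as in any point-estimate
  filter.
* NG86 without transition-bias-corrected counting; for highly biased or
  saturated data the Jukes–Cantor correction is refused (saturation error)
  rather than extrapolated.
* GO terms are treated as flat labels (no ancestor propagation), and KEGG
  categories as disjoint labels per annotation row.
* The strict specificity rule is applied site-wise; gene-level summaries
  count qualifying sites per gene but no gene-wide deviance rule is
  imposed.
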