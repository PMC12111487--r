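---
title: "Codon usage bias analysis with cubkit: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias analysis with cubkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubkit)
```

## What the package computes

cubkit analyses synonymous codon usage bias in sets of protein-coding
sequences, aimed at organelle (especially chloroplast) genomes. The unit of
analysis is the filtered CDS: at least 300 nt, divisible by three, ATG
start, terminal TAA/TAG/TGA, no internal stop, no ambiguity code. Filtered
genes feed five layers:

1. **Composition** — base fractions at third codon positions and positional
   GC content.
2. **Bias indices** — RSCU, Wright's effective number of codons (ENC), the
   codon adaptation index (CAI) and codon bias index (CBI).
3. **Optimal codons** — the ENC-decile ΔRSCU rule.
4. **Mutation-versus-selection diagnostics** — the ENC–GC3s plot against
   Wright's expectation curve, the ENC-ratio distribution, the PR2 plot,
   and the neutrality (GC12–GC3) regression.
5. **Ordination** — correspondence analysis of per-gene RSCU profiles with
   Axis-1 correlation follow-up.

All statistics operate on the 59-codon analysis set: the 61 sense codons of
the standard/plastid code minus ATG (Met) and TGG (Trp), grouped into 18
synonymous families (9 two-fold, the three-fold Ile, 5 four-fold, and
Leu/Ser/Arg treated as whole six-fold families).

## Two composition dialects, on purpose

Third-position statistics come in two conventions that disagree numerically,
and both are exposed because each feeds different downstream displays:

- **Synonymous-only** (`third_position_composition()`, default): A3/T3/C3/G3
  and GC3s are computed over the 59 analysis codons only. This is the
  convention of classical codon-usage software and is what the ENC plot's
  x-axis (GC3s) requires.
- **All-codon positional GC** (`positional_gc()`): GC, GC1, GC2, GC3 count
  every codon of the CDS, including Met, Trp and the terminal stop — the
  EMBOSS-cusp convention, and what the neutrality plot uses. GC12 is defined
  as (GC1 + GC2)/2 exactly.

Genome-level summaries pool the codon counts of the filtered CDSs rather
than re-reading whole-genome sequence; pooled statistics equal the
count-weighted mean of the per-gene values, which the tests assert.

## ENC: estimator and edge cases

Per family with n ≥ 2 counted codons, the bias-corrected homozygosity is
F = (n·Σp² − 1)/(n − 1). Class means are taken over usable families of each
degeneracy class and ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, capped at 61.
Numerical conventions:

- Families with n < 2 or F ≤ 0 are unusable and drop out of their class
  mean (F ≤ 0 is treated as unusable rather than clamped).
- A class with no usable family is imputed: F3 as (F2 + F4)/2 when both
  neighbours exist, any other class as the mean of the available class
  means; the count of imputed classes is reported.
- ENC is undefined (an error at the single-gene level, `NA` in per-gene
  tables) only when no class has a usable family.

The one-codon-per-family construction gives ENC = 20 exactly and equal
counts of all 59 codons exceed 61 before the cap — both asserted in the
test suite.

## The expectation curve and an honest tolerance

The mutation-only expectation used in the ENC plot is
ENC_exp = 2 + s + 29/(s² + (1 − s)²) with s = GC3s. This classical formula
is an *approximation*: under the generative model in which every third
base is drawn independently with GC probability s, the exact expected ENC
(computable in closed form from the family structure) deviates from the
curve by up to about +0.95 at low s and −0.85 at high s, and is 61 rather
than 60.5 at s = 0.5. Finite gene length adds a further upward convexity
bias because 1/F̄ is convex. The curve-tracking tests therefore simulate
long genes (3.6–7.2 kb, 60 genes per point, a size at which the
finite-length bias is small) and require the mean ENC of mutation-only
genomes to sit within 1.5 ENC units of the curve — a band fixed in advance
from the analytic gap, not fitted to test outcomes. Genomes generated with
strong planted preference fall below the curve gene-by-gene.

## Optimal codons and the expression proxy

Genes are ranked by ENC and the extreme deciles (size ceiling(0.10·n),
ties broken by gene id) form the putative expression groups. The package
maps **low ENC → high expression**: strong bias is the expression proxy,
and it is the mapping under which ΔRSCU = RSCU_high − RSCU_low is positive
for preferred codons. The gate "RSCU > 1" is evaluated in the
high-expression group's pooled RSCU by default; both the mapping and the
gate scope are config switches (`high_group`, `rscu_scope`), since the
procedure is described in the literature without fixing either. Pooled
group RSCU (not the mean of per-gene RSCU) is used for ΔRSCU.

## CAI and CBI references

CAI is the geometric mean of relative adaptiveness w over a gene's
analysis-codon occurrences. The reference is derived from the genome's own
low-ENC decile via `reference_w_from_high_set()` (pooled RSCU rescaled by
the family maximum), so the analysis is self-contained and needs no
foreign-organism reference table; codons unobserved in the reference get a
floor of w = 0.01 so the geometric mean stays defined. Because reference
choice changes CAI values materially, CAI and CBI are treated as relative,
within-genome quantities, not cross-study reproduction targets. CBI uses
the genome's identified optimal-codon set by default and is scaled so that
exclusive use of optimal codons gives 1, random usage 0, and complete
avoidance −1.

A caution on a tempting "self-reference" property: a gene scored against
w derived from its own usage is *not* maximal among all references — any
reference that assigns w = 1 to every codon the gene uses scores higher
(the unconstrained maximiser is w ≡ 1, giving CAI = 1). The test suite
asserts the true property instead: with a fixed reference, CAI ≤ 1 with
equality exactly for genes confined to w = 1 codons.

## PR2: two variants

The PR2 plot places each gene at x = G3/(G3 + C3), y = A3/(A3 + T3).
Computed over the full 59-codon set (the default, matching how composition
statistics are usually quoted), even perfectly unbiased usage does **not**
sit at (0.5, 0.5): the three purine-ending two-fold families (Gln, Lys,
Glu) contribute G3 but can never contribute C3, displacing the unbiased
expectation to x ≈ 0.41 under uniform usage. The classical formulation
restricts to the five strictly four-fold degenerate families, where every
third base is available and unbiased usage centres exactly;
`selection_diagnostics(pr2_variant = "fourfold")` provides it and carries
the centre-concentration test. Genes with a zero denominator are flagged
and excluded from the plot rather than raising an error.

## Neutrality regression

The regression is ordinary least squares of GC3 on GC12 (x = GC12,
y = GC3), following the axis description in the applied literature; the
conventional reversed orientation is available via
`neutrality_orientation = "gc3_x"` and the fitted orientation is recorded
in the output, because the two slopes differ. The slope is read as the
mutational share: mutation% = 100·slope, selection% = 100 − mutation%,
which sum to 100 by construction.

## What the synthetic generator emulates — and what it does not

`generate_genome()` builds CDSs as ATG + sampled sense codons + a uniform
stop, so generated data pass the filters by construction. Within each
family, codon probabilities are a softmax combining third-position GC
pressure (G/C bases weighted s/2, A/T bases (1 − s)/2) with a planted
preferred-codon bonus of `bias_strength` log-units, active in the
high-bias gene class. Defaults describe a chloroplast-like study
condition: 40 genes of 300–1500 nt, GC3 pressure 0.08, GC12 around 0.33,
20% high-bias genes at strength 2, planted preferred codons all A/T-ending,
and a planted neutrality slope of 0.37.

Two generator modes differ in how `gc3_target` is read:

- **Slope off** (`neutrality_slope = NA`): `gc3_target` is the raw
  mutational pressure s. Realized GC3s then deviates slightly from s only
  through the Ile family (no G-ending codon; its third-position GC is
  s/(2 − s)) — a documented residual, about 0.002 at the default settings.
- **Slope on**: per-gene GC12 targets are drawn and achieved by tilting
  amino-acid frequencies (solving the tilt exactly with `uniroot`), GC3
  targets follow the planted linear relation, and the generator *inverts*
  the expected realized all-codon GC3 (accounting for ATG/TGG, start and
  stop codons, and the Ile renormalisation) to find the pressure s that
  lands each gene on its target. Without this inversion the realized slope
  is compressed by roughly 5% with a positive offset, and parameter
  recovery would test the distortion rather than the regression.

Slope-recovery validation uses 40-gene genomes of 1.5–3 kb with GC12
spread 0.12 and recovers planted slopes {0, 0.37, 1} within two standard
errors of the mean over 20 seeds. The residual attenuation from sampling
error in realized GC12 is below 1% at these sizes.

The generator does **not** emulate: realistic gene order or length
distributions, inverted repeats and gene duplication, intergenic sequence,
amino-acid composition differences between real chloroplast proteins,
within-genome expression-correlated amino acid usage, or evolution along a
phylogeny. Passing tests on synthetic data therefore validate the
*statistics and their inversions*, not any biological claim about a
particular genome.

## Correspondence analysis conventions

CA is computed by singular value decomposition of the standardised
residual matrix of the per-gene RSCU table (rows = genes, columns = the 59
codons; raw counts are accepted too). All-zero columns are dropped with a
record; rows for genes with unobserved families keep their zeros. Axis
signs are intrinsically arbitrary: the package first fixes them
deterministically (largest-magnitude column loading positive), and
`axis1_correlations()` reflects Axis 1 when needed so its correlation with
GC3s is non-negative, making reported correlation signs reproducible.
Total inertia equals the matrix chi-square statistic divided by the grand
total, axes are ordered by decreasing inertia, and row scores satisfy the
CA transition formulas — all asserted against an independent brute-force
eigendecomposition in the tests. Spearman rank correlation is the default
for the Axis-1 follow-up (per-gene indices are rarely normal), with
Pearson available; raw p-values are reported alongside Benjamini–Hochberg
adjusted ones.

## Degenerate inputs and tie-breaks, in one place

- Filter rejections are tallied under the *first* failing reason in the
  fixed order partial, not_multiple_of_3, short, no_atg_start,
  no_stop_end, internal_stop, ambiguous_base.
- RSCU of an unobserved family is all-zero and flagged, not NaN.
- ENC decile ties are broken lexically by gene id.
- Genes with undefined ENC are excluded from ENC-based summaries and
  counted.
- PR2 zero denominators flag the gene; CA sign indeterminacy is fixed as
  above; a rank-0 CA input yields zero informative axes rather than an
  error.

## Problem sizes used in validation

The shipped tests run genomes of 12–60 genes with lengths from 300 nt up
to 7.2 kb (30 kb for the single-gene GC3s consistency check), 20 seeds per
planted slope, and 1000 random count vectors for the RSCU conservation
property — sizes chosen so each check is decisive for the property it
targets while the whole suite stays fast.

## Known limitations

- GenBank parsing is deliberately minimal (LOCUS/FEATURES/ORIGIN, CDS
  locations with `join`/`complement` and partial markers); records relying
  on external references (`CONTIG`, accession-qualified spans) are out of
  scope.
- CAI/CBI depend on the reference/optimal-set choices described above and
  should not be compared across packages without aligning those choices.
- The ENC expectation curve is an approximation; systematic deviations of
  up to ~1 ENC unit from generative models are expected even without
  selection (quantified above).
- The per-genome analysis treats genes as independent; no phylogenetic or
  operon structure is modelled.
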