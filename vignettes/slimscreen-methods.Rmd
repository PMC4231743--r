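---
title: "slimscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slimscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimscreen)
```

## The problem

Short linear motifs (SLiMs) are 3–11 residue elements, typically in
disordered protein regions, that mediate transient protein–protein
interactions. Given a multi-isoform proteome and a gene label set — here,
genes whose transcripts oscillate with a ~24 h circadian period — the
screen asks: are genes encoding a given motif over-represented among the
labelled genes, and reciprocally, are labelled genes over-represented
among motif carriers? slimscreen implements the full pipeline: pattern
compilation, proteome scanning, per-gene collapse, the bidirectional
percent-enrichment statistics with an optional significance layer,
ortholog conservation reports for the CtBP-binding PXDLS motif family,
and a synthetic proteome generator with planted enrichment used to
validate every stage end to end.

## The pattern dialect and its matcher

Patterns use PROSITE/fuzzpro-style notation: a literal residue letter is a
singleton class, `[ABC]` a fixed class, `[^P]` a negated class (the
typographic wedge `∧` is accepted and normalised to `^`), `X` a wildcard
over the 20 standard residues, and `X(1,2)` a wildcard repeated one or two
times. Repeats attach only to wildcards — the dialect never writes a
repeated class, and `parse_pattern()` rejects one. The built-in registry
(`motif_registry()`) carries 17 patterns: 12 interaction motifs screened
proteome-wide (WRPW, TRAF6, RGD, PXDLS, PTAP, PPXY, PDZ-binding, PAM2,
NPF, LXXLL, LXCXE, calmodulin-binding) and the 5 PXDLS family variants
from broad (`PX[NDS]L[VTSAC]X(1,2)[KR]`) to stringent
(`PXDLSX(1,2)[KR]`).

Matching semantics, fixed once and tested:

* **All distinct spans.** A variable-width pattern may match two spans
  from the same start; both `(start, end)` pairs are reported. Per-gene
  counting collapses them downstream, so this choice cannot change any
  enrichment value.
* **Boundary rule.** An edge wildcard must consume an actual residue;
  `XNPFX` does not match `NPFA`. This mirrors fuzzpro's behaviour.
* **Nonstandard letters.** B, J, O, U, Z and the ambiguity letter X in a
  *sequence* match nothing, wildcards included. This keeps ambiguity codes
  from inflating counts; it is the one place where behaviour is our
  documented choice rather than something the dialect pins down.
* **Coordinates.** 1-based inclusive residue numbering, so a motif whose
  leading proline is the 72nd residue anchors at 72 — the convention
  behind mutant names like P72A.
* **No anchoring beyond the printed pattern.** The PDZ-binding pattern
  `X[ST]X[LV]` is matched anywhere, not C-terminally anchored, because the
  pattern as printed carries no anchor.

Internally each repeat allocation becomes one fixed-length regular
expression over explicit residue classes, applied through a zero-width
lookahead so overlapping starts are all found (stringi/ICU). The test
suite checks the scanner against an independent brute-force matcher —
direct recursion over the element list, trying every substring and repeat
allocation — on a thousand random pattern/sequence instances, plus
shift-equivariance and fixed-length properties.

## Universes, counting, and the enrichment statistics

Genes are the counting unit: a gene is motif-positive if any of its
isoforms has at least one hit (`genes_with_motif()`), and gene symbols are
case-normalised so capitalisation differences between resources do not
split genes. FASTA records whose header yields no symbol are kept but
excluded from the universe, and their count is reported.

With universe size $N$, motif-positive genes $n$, set genes $M$ and
motif-positive set genes $k$:

$$\text{forward} = \frac{k/M - n/N}{n/N} \times 100,\qquad
  \text{reciprocal} = \frac{k/n - M/N}{M/N} \times 100.$$

Both compare $k$ with its independence expectation $nM/N$; algebraically
both equal $(kN - nM)/(nM) \times 100$, so on identical counts they
coincide and always share a sign (verified by enumeration over every
valid tuple with $N \le 30$). They diverge in practice only when the two
directions are computed over different universes — e.g. a proteome
universe for one and an expression-dataset universe for the other. Because
published analyses of this kind are ambiguous about the intersection rule,
`run_screen()` exposes it: the default universe is the mapped proteome
genes, and an explicit `universe` list restricts it.

Degenerate inputs are typed, not coerced: $n = 0$ or $M = 0$ makes the
statistic undefined and raises a classed error (or flags the row, under
the default screen policy) — reporting 0 would falsely claim the count
sits exactly at expectation. $k = 0$ with $n > 0$ is well defined and
yields exactly $-100$.

The significance layer is an extension beyond the percent statistics: a
one-sided hypergeometric upper-tail p-value (`stats::phyper`) and a
permutation p-value that resamples size-$M$ sets uniformly from the
universe, reported as $(1 + \#\{k^* \ge k\})/(1 + n_\text{perm})$ with a
mandatory seed. No multiple-testing correction is applied by default; a
Benjamini–Hochberg column is optional. Tests pin the hypergeometric
p-value to exact enumeration of all draws for $N \le 12$, the permutation
p-value to the hypergeometric within Monte-Carlo error, and the null
permutation p-value distribution to approximate uniformity
(Kolmogorov–Smirnov at $\alpha = 0.001$ across simulated screens).

## The synthetic generator

`synthetic_proteome()` emulates the shape of the screen's inputs:
`n_genes` genes with 1–2 isoforms, i.i.d. background residues (uniform by
default, with a Swiss-Prot-like composition preset — uniform keeps
chance-match rates analytically simple), a circadian label on a fixed
fraction of genes, and one concrete motif instance spliced into one
isoform of each planted gene. Defaults are fixed once as the study
conditions: circadian fraction 0.127 (matching a 2777-of-21,865 label
set), planting probabilities 0.25 (circadian) versus 0.20 (other), the
stringent `PXDLSX(1,2)[KR]` variant planted, and sequence lengths drawn
uniformly from 80–300 residues — deliberately on the short side of real
proteins to keep the validation suite's 50-replicate recovery runs at
20,000 genes fast, while leaving chance-match rates realistic
(per-gene chance rate under the uniform background is of order $10^{-3}$
for this pattern).

Planting only one isoform per gene deliberately exercises the per-gene
dedup logic. The generator is deterministic given its mandatory seed, and
`splice_motif_instance()` verifies by construction that the planted span
matches (negated classes are instantiated from their complement sets).

Two expectations matter when reading recovery results. The *planted*
forward enrichment, ignoring both chance matches and labelling, is
$(p_c - p_n)/p_n \times 100 = +25\%$ at the default calibration. But the
forward statistic compares circadian genes against the *whole* universe,
which includes the circadian genes themselves, so its exact expectation is
$(p_c - p_\text{mix})/p_\text{mix}$ with
$p_\text{mix} = f\,p_c + (1-f)\,p_n \approx 0.206$, i.e. $\approx
+21.2\%$ at $f = 0.127$ — chance background matches then shrink this very
slightly (they add equally to both rates, inflating the denominator). The
test suite checks both: the 50-seed mean lies within the replicate-SD 99%
band of the planted $+25\%$, and within the much tighter CI of the mean
around the exact mixture expectation.

What the generator does **not** emulate: real residue composition
autocorrelation, disorder context, isoform-specific exon structure,
homology between genes, or any circadian expression dynamics (the label
is just a label). Passing recovery tests therefore demonstrate that the
pipeline measures what was planted — not that any particular biological
dataset will show a given enrichment.

## Conservation reports and the variant cascade

`conservation_report()` reduces a cross-species conservation schematic to
per-species presence/position records: one sequence per species (the first
FASTA record per file), scanned independently — no alignment, no
phylogenetic scoring — so a species' record never depends on which other
species are supplied. "Conserved" is operationally "motif present in all
supplied species"; positional drift is reported, not scored.

For the PXDLS family the scan uses a broad-to-stringent cascade
(`pxdls_cascade()`): the broad variant first, then consensus, stringent,
and the two relaxed/core variants without the basic tail. Which variant a
given protein actually satisfies is not something the family definition
fixes, so the cascade order — broadest first — is the package's choice;
`motif_anchor_position()` instead takes the smallest hit start across all
variants (ties broken in cascade order), because the anchor convention
refers to the first motif proline regardless of variant.

Where real ortholog records are wanted but unavailable,
`synthetic_ortholog()` builds labelled stand-ins: random background
sequences with one family instance planted so the first family anchor
falls at a prescribed residue (backgrounds with an accidental earlier hit
are regenerated). `synthetic_ortholog_panel()` ships the three stand-ins
used in the tests, carrying the documented mutant anchors 72
(REV-ERB-alpha–like, 615 aa), 440 (NRIP1-like, 1158 aa) and 1133
(CBP-like, 2441 aa). Only the lengths and anchor coordinates are real;
the sequences are synthetic, and results on them validate the machinery,
not the biology of those proteins.

## Problem sizes and numerical choices

The validation suite runs entirely on data generated in code: the
matcher–oracle comparison uses 1000 random instances with sequences up to
200 residues; sign coherence is enumerated for all ~86,000 valid count
tuples with $N \le 30$; null-uniformity uses 500 simulated screens of a
20,000-gene universe with 199 permutations each; parameter recovery uses
50 seeds at 20,000 genes. All ratios are computed in double precision;
the sign-coherence check treats magnitudes below $10^{-9}$ as zero to
keep floating-point noise at exact independence from flipping a sign.

## Known limitations

* The dialect is exactly what the screen needs — no arbitrary repeats on
  classes, no alternation, no nucleotide scanning.
* Absolute prevalence counts and enrichment percentages from any specific
  proteome release are database-version-dependent; the package reproduces
  the method, and its tests assert distributional and constructed-truth
  properties, not historical database snapshots.
* Enrichment thresholds (e.g. "more than 10% is interesting") are left to
  the user; the screen reports raw signed percentages and, optionally,
  p-values.
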