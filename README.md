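# slimscreen

Short linear motif (SLiM) screening over multi-isoform proteomes, with
bidirectional gene-set enrichment, ortholog motif conservation reports,
and a synthetic-proteome validation harness.

SLiMs are 3–11 residue elements — WRPW, RGD, LXXLL, the CtBP-binding
PXDLS family, and their kin — that mediate transient protein–protein
interactions. Given a protein FASTA whose headers carry gene symbols and a
gene label set (for instance, genes with ~24 h circadian transcript
oscillation), slimscreen compiles PROSITE/fuzzpro-style patterns such as
`PX[NDS]LSX(1,2)[KR]`, finds every match on every isoform, collapses hits
to non-redundant motif-positive genes, and reports the percent enrichment
in both directions. With universe size *N*, motif-positive genes *n*, set
genes *M*, and motif-positive set genes *k*:

    forward    = (k/M − n/N) / (n/N) × 100   — motif carriers within the set
    reciprocal = (k/n − M/N) / (M/N) × 100   — set members among motif carriers

A hypergeometric / permutation significance layer is available as a
clearly-labelled extension, and `conservation_report()` /
`motif_anchor_position()` reduce cross-species conservation questions to
per-species presence and 1-based anchor coordinates (the convention behind
mutant names like P72A).

## Worked example

Everything below is generated in code — a 5,000-gene synthetic proteome
with the stringent PXDLS variant planted at 25% of circadian and 20% of
other genes:

```r
library(slimscreen)

syn <- synthetic_proteome(n_genes = 5000, seed = 11)
scr <- run_screen(syn$proteome, syn$circadian,
                  patterns = motif_registry(group = "pxdls_variant"))
tidy(scr)
#> # A tibble: 5 × 8
#>   pattern             N     n     M     k forward_pct reciprocal_pct p_hypergeom
#>   <chr>           <int> <int> <int> <int>       <dbl>          <dbl>       <dbl>
#> 1 PXDLS_broad      5000  1099   635   172        23.2           23.2    0.000658
#> 2 PXDLS_relaxed    5000  1105   635   172        22.6           22.6    0.000868
#> 3 PXDLS_core       5000  1095   635   170        22.2           22.2    0.00107
#> 4 PXDLS_consensus  5000  1091   635   170        22.7           22.7    0.000894
#> 5 PXDLS_stringent  5000  1091   635   170        22.7           22.7    0.000894
```

Of the 5,000-gene universe, 1,091 genes carry the stringent variant
(planted plus a handful of chance background matches); 170 of the 635
circadian genes do, a +22.7% excess over the genome-wide rate. The
recovered value sits near the exact expectation for this design, ≈ +21%
— the planted +25% contrast is diluted because circadian genes are part
of the genome-wide denominator (see the methods vignette). Both
directions coincide here because they are computed over the same
universe.

Anchors on the synthetic ortholog panel (stand-in sequences carrying the
family motif at the documented mutant coordinates):

```r
panel <- synthetic_ortholog_panel(seed = 42)
motif_anchor_position(panel$sequence[2])
#> # A tibble: 1 × 3
#>   anchor pattern     peptide
#>    <int> <chr>       <chr>
#> 1    440 PXDLS_broad PRDLCQHR
```

`autoplot(scr)` draws the enrichment bar chart; `glance(scr)` gives a
one-row summary. A thin command-line wrapper with `scan`, `enrich`,
`conserve`, `simulate` and `list-patterns` subcommands is installed at
`system.file("scripts", "slimscreen", package = "slimscreen")`.

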