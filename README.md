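# dupdiverge

Sequence, structural and expression divergence of duplicate gene pairs.

After a gene duplicates, the two copies drift apart along three axes: their
coding sequences accumulate synonymous and nonsynonymous substitutions (dS,
dN), their exon–intron structures change (exon gains, losses, boundary
shifts), and their tissue-expression profiles decouple. dupdiverge is an R
package for scientists who want to run this whole analysis from flat files —
protein and CDS FASTA, gene models (GFF3 or TSV), an all-vs-all protein
alignment table, and a genes × tissues FPKM matrix — and get tidy tables,
tests and figures out.

## What it computes

* **Duplicate pair identification** — reciprocal best hits from a BLAST-style
  tabular file, filtered by coverage of the longer protein (≥ 80%) and a
  length-dependent identity threshold (0.30 above 150 aa, the
  `0.01·n + 4.8·L^(−0.32(1+e^(−L/1000)))` homology curve below); pseudogene
  removal; classification as intra-/interchromosomal and
  species-specific/shared; per-chromosome duplicate-content summaries.
* **dN/dS** — Needleman–Wunsch protein alignment (BLOSUM62, affine gaps)
  guiding a codon alignment of the CDSs; Nei–Gojobori counting with
  stop-exclusion and equal pathway weighting; Jukes–Cantor correction
  `d = −(3/4)·ln(1 − (4/3)p)` with saturation flagged at `p ≥ 3/4`.
* **Structural divergence** — Class 1 (different exon counts) vs Class 2
  (equal counts, ≥ 1 homologous exon length differs, matched positionally in
  transcription order), and the binned trend of the divergent proportion
  against dS.
* **Expression divergence** — per-tissue on/off calls (off < 1 FPKM,
  on > 2 FPKM, the gap ambiguous), Pearson r of `log2(FPKM + 1)` across
  tissues, the similarity scale `T = ln((1+r)/(1−r))`, binned regressions of
  T on dS or dN, and flagging of species-specific pairs with very low r.
* **Statistics** — Wilcoxon/KS comparisons of identity distributions and of
  structurally divergent vs conserved pairs, chi-square and exact binomial
  chromosome-distribution tests, and the common-slope ANCOVA
  `T ~ dS + SD` that asks whether structural divergence predicts expression
  divergence *after controlling for* synonymous divergence.
* **A synthetic-data generator** — codon evolution with an ω acceptance
  factor, Poisson structure events, correlation-decaying tissue profiles with
  silencing — so the full pipeline runs and is tested without any downloads.

## A worked example

Simulate a 100-pair study, write it to disk in the exact dialects the readers
consume, and run the pipeline end to end:

```r
library(dupdiverge)

cfg <- simulation_config(seed = 42, n_pairs = 100)
paths <- make_fixture(cfg, "fixture42")

pipeline <- pipeline_config(
  proteins = paths$proteins, cds = paths$cds,
  gene_models = paths$gene_models, hits = paths$hits,
  expression = paths$expression,
  out_dir = "results42", structure_bin_size = 20
)
res <- run_pipeline(pipeline)

dplyr::select(res$pairs, gene_a, gene_b, identity, coverage, locality, lineage)
#> # A tibble: 67 × 6
#>   gene_a gene_b identity coverage locality lineage
#>   <chr>  <chr>     <dbl>    <dbl> <chr>    <chr>
#> 1 g0002a g0002b    0.404        1 inter    shared
#> 2 g0003a g0003b    0.635        1 inter    species_specific
#> 3 g0004a g0004b    0.815        1 inter    species_specific
#> 4 g0005a g0005b    0.615        1 intra    shared
#> # i 63 more rows
```

67 of the 100 simulated pairs survive identification — the most diverged
families fall below the 30% identity threshold, as they would in a real
database search. Sequence divergence per pair:

```r
dplyr::select(res$divergences, pair_id, dS, dN, saturated)
#> # A tibble: 67 × 4
#>   pair_id          dS    dN saturated
#>   <chr>         <dbl> <dbl> <lgl>
#> 1 g0002a|g0002b 1.19  0.484 FALSE
#> 2 g0003a|g0003b 0.189 0.218 FALSE
#> 3 g0004a|g0004b 0.330 0.101 FALSE
#> 4 g0005a|g0005b 0.644 0.233 FALSE
```

dS is substitutions per synonymous site (a clock-like proxy for time since
duplication); dN per nonsynonymous site. Expression divergence and the
structure–expression link:

```r
res$expression_summary$overall
#> # A tibble: 2 × 4
#>   stratum          n_pairs frac_ge1 frac_ge2
#> 1 all                   67    0.791    0.478
#> 2 species_specific      19    0.474    0.158

res$ancova
#> ANCOVA: transformed_r ~ dS + SD (n = 50 SD, 17 NSD)
#>   structure effect = -1.2508 (SE 0.3766, p = 0.00148)
#>   dS effect = -1.0844 (p = 0.00912), R^2 = 0.347
```

79% of pairs have switched a tissue on/off in at least one tissue (48% in at
least two), recently duplicated species-specific pairs less so; expression
similarity falls with dS, and structurally divergent pairs are less
correlated in expression even at matched dS — the negative SD coefficient.
`autoplot()` methods draw the binned trend, the binned regression, the group
comparison and the two-line ANCOVA view; every table is also on disk under
`results42/` as TSV/JSON with a reproducibility manifest.

A thin command-line wrapper (`inst/cli/dupdiverge.R`) exposes the same two
entry points: `simulate --config sim.yaml --out-dir dir` and
`run --config pipeline.yaml`.

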