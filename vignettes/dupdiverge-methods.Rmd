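---
title: "Methods: sequence, structural and expression divergence of duplicate genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence, structural and expression divergence of duplicate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dupdiverge analyses what happens to the two copies of a duplicated gene after
the duplication event, along three axes: coding-sequence divergence (dS, dN),
exon–intron structural divergence, and tissue-expression divergence. This
vignette is the package's own account of the models behind each stage, the
tunable parameters and their defaults, the synthetic-data generator the test
suite runs against, and the numerical and design choices a maintainer should
know about.

## Identifying duplicate pairs

Candidate pairs come from an all-vs-all protein alignment table (the 12-column
BLAST tabular dialect). For every ordered query–subject pair only the
top-scoring HSP is considered; the best partner per query is chosen by bit
score, with identity and then the lexicographically smallest subject id as
deterministic tie-breaks, and a pair is retained only when the choice is
mutual (reciprocal best hits). RBH by itself over-calls at short alignment
lengths, so two filters follow:

* **coverage**: the aligned region must span at least 80% of the *longer*
  protein (`min_coverage`, default 0.8);
* **identity**: at least 0.30 when the alignment is longer than 150 aa, and
  the length-dependent homology curve
  `0.01 n + 4.8 L^(-0.32 (1 + exp(-L/1000)))` with `n = 6` below that —
  short alignments must clear a much higher bar. Both constants are
  config-overridable because reasonable variants of this curve circulate.

Pairs touching any biotype containing `pseudogene` are removed. A pair is
*intrachromosomal* when both genes share a chromosome, and *species-specific*
when **both** genes lack a recorded homolog outside the focal species — the
conservative reading of "observed only in this genome"; requiring one gene
only would let one annotated ortholog leak through.

Per-chromosome summaries count **genes**, not pairs: a gene is counted once
per locality class in which it participates, so a gene duplicated both intra-
and interchromosomally appears in both columns, matching how published
summary tables of this kind are laid out. Duplicate content is
`100 (intra + inter) / genes`; chromosomes are flagged when their content
exceeds twice the genome average.

## dN/dS by counting

Each pair's proteins are aligned globally (Needleman–Wunsch, BLOSUM62, affine
gaps: opening a gap costs 10 and every gapped position 0.5, so a gap of
length L costs `10 + 0.5 L`; ties prefer match over a gap in the second
sequence over a gap in the first, making the traceback deterministic). The
protein alignment guides a codon-level alignment of the CDSs: each aligned
residue column becomes its source codon, each gap residue a codon gap.
Terminal stop codons are trimmed before the length check; internal stops are
errors.

Divergence is estimated by Nei–Gojobori (1986) counting with stop-codon
exclusion:

* a codon position's synonymous-site fraction is the share of its three
  single-nucleotide changes that are synonymous, with changes creating stop
  codons removed from the denominator; sites are averaged over the two
  sequences, so `S_sites + N_sites = 3 × (ungapped codon columns)` exactly;
* differences between two codons are averaged over all minimal mutational
  pathways, equally weighted, pathways through stop codons excluded (if every
  pathway is blocked — essentially impossible between sense codons — all are
  used);
* proportions are corrected with Jukes–Cantor, `d = -(3/4) ln(1 - (4/3) p)`;
  `p ≥ 3/4` saturates and the corresponding `d` is reported missing.

Counting was chosen over likelihood estimation deliberately: every downstream
analysis uses dS and dN *ordinally* (ranking, binning, regression), a regime
where counting and ML agree closely at moderate divergence, and counting is
exactly testable against a brute-force enumeration oracle. The
`divergence_table()` interface isolates per-pair failures in an `error`
column, so an external ML estimator could be slotted in behind the same
surface.

## Structural divergence

Coding-exon layouts are compared: different exon counts are **Class 1**;
equal counts with at least one differing exon length are **Class 2**; exon
lengths are `end − start + 1` and exons are matched *positionally in
transcription order* (reversed genomic order on the minus strand). Positional
matching is the only definition consistent with a count-and-length based
classification; it does not attempt intron-position mapping onto the protein
alignment. CDS segments, not UTR-containing exons, are compared, because the
proteins define the pairs.

The structure-vs-dS relationship is summarized by ranking pairs by dS,
grouping into consecutive bins of 200 (a trailing partial bin is dropped),
and correlating per-bin mean dS with the per-bin proportion of structurally
divergent pairs (Pearson, two-sided). Saturated-dS pairs are excluded. When
the proportions are constant across bins the correlation is reported as
undefined rather than invented.

## Expression divergence

Expression enters as a genes × tissues FPKM matrix (seven tissues in the
motivating design: adipose, muscle, hypothalamus, duodenum, liver, lung,
kidney). Two measures are computed per pair:

* **on/off divergence**: a gene is *off* in a tissue below 1 FPKM and *on*
  above 2 FPKM; the 1–2 gap is *ambiguous* and never counts as divergence
  (the conservative reading of a two-threshold call). A tissue is divergent
  when one gene is on and the other off.
* **profile similarity**: Pearson r across tissues of `log2(FPKM + 1)`
  (raw-scale r is a config flag), undefined if either gene has zero variance.
  r is mapped to the variance-stabilizing scale `T = ln((1+r)/(1−r))`,
  with r clamped to `±(1 − 10⁻⁶)` so identical profiles stay finite.

Correlation analyses use only *eligible* pairs — both genes on in at least
one tissue (`min_tissues_expressed`, default 1; the ≥3-tissues robustness
variant is the same code path). The similarity-vs-divergence relationship is
again binned: pairs ranked by dS (or dN), bins of 5, OLS of mean T on the
mean covariate across bins; with bin size 1 this reduces exactly to the
unbinned regression. For dN the regression runs separately below and above
`dn_split` (default 0.3) — the weaker-correlation regime at high dN is a
different biological question (protein-level constraint) than the
time-decay at low dN.

## The statistical layer

* **SD vs NSD**: structurally divergent (Class 1 or 2) vs non-divergent
  pairs, compared on T by two-sided Wilcoxon rank-sum (exact for small
  groups), optionally within species-specific pairs.
* **ANCOVA**: `T ~ dS + SD` (common slope). The SD coefficient is the
  structure effect controlling for synonymous divergence; an interaction term
  sits behind a flag. A one-class design is rank-deficient and errors rather
  than silently refitting.
* **Identity distributions**: species-specific vs shared and intra vs inter,
  by two-sided Wilcoxon and Kolmogorov–Smirnov, with 5%-bin histograms. The
  groups are disjoint by construction; testing a subset against its superset
  would violate the independence both tests assume.
* **Chromosome distribution**: chi-square goodness of fit of duplicate-gene
  counts against expectation proportional to gene counts (cells with expected
  count < 1 are merged, smallest first), plus per-chromosome exact binomial
  tests of the intra count against the genome-wide intra fraction.

The tests themselves are the standard nonparametric choices; no
multiple-testing correction is applied by default (a Benjamini–Hochberg flag
exists), since each contrast answers a separate question.

## The synthetic-data generator

`simulate_study()` produces everything the pipeline consumes — FASTA, gene
models, an alignment-hit table, lineage flags, an FPKM matrix — plus a truth
table, so every stage is testable without downloads. Its components:

* **Codon evolution** (`simulate_cds_pair`): an ancestral CDS of uniform
  sense codons is duplicated; each copy receives `Poisson(3 L t / 2)`
  proposed single-nucleotide changes (uniform over sites and target
  nucleotides), accepted with probability 1 if synonymous, ω if
  nonsynonymous, 0 if creating a stop. `t` is therefore the expected number
  of proposed changes per nucleotide site separating the copies, and realized
  synonymous divergence tracks `t` closely. This is a minimal
  Goldman–Yang-flavoured scheme — no transition/transversion asymmetry, no
  codon-frequency bias — sufficient to create the dS/dN gradients the
  analyses need. Every proposal is logged, so tests replay the log
  independently.
* **Structure evolution** (`simulate_structure_pair`): `Poisson(rate · t)`
  events, each applied to one copy — exon gain, exon loss, or a
  frame-preserving boundary shift (multiples of 3 nt). Exon lengths are
  multiples of 3 so gains and losses preserve frame.
* **Expression** (`simulate_expression_pair`): per tissue, latent log2
  signals are bivariate normal with correlation `ρ = e^{−λt}`; independent
  measurement noise (SD 0.25 log2 units) is the floor that keeps sample
  correlations below 1; values are exponentiated to FPKM. Silencing events
  (one copy forced below 1 FPKM in a tissue) occur with logistic-in-t
  probability `0.3 · plogis((t − 0.5)/0.25)` — a shape chosen so that
  per-tissue on/off divergence is rare for young pairs and reaches realistic
  magnitudes for old ones. Structurally divergent pairs additionally receive an
  additive shift (default −0.5) of the latent correlation on the
  `ln((1+r)/(1−r))` scale — the class effect the ANCOVA is expected to
  recover.
* **Defaults as study conditions**: `t ~ U(0.05, 1.5)` (dS spanning the
  unsaturated range), `ω ~ U(0.05, 0.8)`, structure-event rate 3 per unit t
  (most pairs structurally divergent, as observed in mammalian surveys),
  λ = 1, 7 tissues, 31% intrachromosomal pairs, species-specific label for
  `t < 0.35` (recent duplicates), CDS length 200 codons, 2–12 coding exons.
* **The hit table** is computed with the package's own aligner behind a
  shared-5-mer seeding prescreen (at least 2 shared 5-mers), emulating how a
  seeded database search only reports pairs with local similarity; unrelated
  random proteins essentially never pass, and deeply diverged pairs can fail
  the seed — which usefully exercises the detection limit.

What the generator does **not** emulate: indels within exons (protein
alignments in tests are therefore unambiguous), linkage between CDS length
and exon-layout totals (sequence and structure evolution are decoupled),
tandem-array genomic context, read-level RNA-seq noise, and correlated
evolution across tissues. Passing tests therefore demonstrate correctness of
the estimators and the statistical machinery under a clean generative model,
not robustness to alignment ambiguity or quantification artefacts in real
data.

## Numerical choices and known limitations

* RNG: all simulation draws come from R's default Mersenne–Twister stream;
  `simulate_study()` wraps everything in a single seeded block, so a bundle
  is byte-reproducible from its config.
* Problem sizes: the routine test suite runs 50-pair bundles; the deeper
  mechanism checks use a 2000-pair bundle, 200-pair parameter-recovery grids,
  and 200-replicate null calibrations — sizes at which binomial/regression
  standard errors are small enough for 3-SE assertions to be meaningful.
* Null calibration feeds true divergence times in as the dS covariate:
  the calibration targets the statistical layer, and estimation noise is
  orthogonal to its null.
* **ANCOVA curvature caveat**: `E[T | dS]` is convex under correlation decay
  (`T = 2 atanh(ρ)` diverges as ρ → 1), and structural class correlates with
  t by construction. A common-slope linear adjustment for dS therefore
  leaves class-correlated curvature in the residuals, biasing the class
  coefficient away from zero — by a few tenths on the T scale at the default
  settings, several standard errors at n = 2000 — even though the class
  contrast *at matched divergence time* equals the injected effect exactly.
  Within-band contrasts confirm the injection; the pooled
  coefficient overstates it. Estimating dS (rather than using the true time)
  adds a further layer through the correction's convexity at high divergence.
  The same caveat applies verbatim to real-data ANCOVAs of expression
  similarity on dS; the package reports the per-class regression lines
  alongside the pooled fit so the linearity assumption can be inspected
  (`autoplot()` on the ANCOVA object).
* Multi-isoform genes collapse to the longest-CDS transcript (the common
  convention for paralog analyses); how real annotation pipelines chose
  isoforms is generally unknowable downstream.
* The gene-model TSV dialect exists so fixtures need no GFF3 writer; GFF3
  input goes through `rtracklayer` and the same validation.

## Reproducing the analysis end to end

```{r, eval = FALSE}
library(dupdiverge)

cfg <- simulation_config(seed = 1, n_pairs = 200)
paths <- make_fixture(cfg, "fixture")

pipeline <- pipeline_config(
  proteins = paths$proteins, cds = paths$cds,
  gene_models = paths$gene_models, hits = paths$hits,
  expression = paths$expression,
  out_dir = "results", structure_bin_size = 20
)
res <- run_pipeline(pipeline)
res$ancova
autoplot(res$structure_trend)
```

Every table the pipeline writes (pairs, chromosome summary, divergence,
structure, expression, flagged high-divergence pairs, stats report, manifest)
is plain TSV/JSON, and a rerun with the same config and seed reproduces the
tables byte for byte.
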