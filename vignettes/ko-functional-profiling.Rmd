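---
title: "KO functional profiling: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KO functional profiling: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koprofiler)
library(dplyr)
```

## The problem

Shotgun metagenomic and metatranscriptomic reads are routinely translated
and aligned against a protein reference in which every protein carries a
KEGG Orthology (KO) annotation. Downstream of that alignment, a functional
profile asks three nested questions: how abundant is each KO in each
sample; which KOs differ between sample groups; and which higher-order
units — co-transcribed operons and metabolic pathways — are enriched in
those differences. koprofiler implements that downstream chain, starting
from standard 12-column tabular alignment output (the `outfmt 6` dialect
shared by BLAST, DIAMOND and USEARCH-compatible aligners), so it is
agnostic to the aligner actually used.

## From hits to KO assignments

Hits are filtered on `evalue < 1e-3` and `percent identity > 80` — both
strict inequalities, so a hit sitting exactly on a boundary is excluded.
Each read is then resolved to a single best hit: the tier of hits tied on
maximum bitscore and then minimum e-value. Proteins assigned to the same KO
differ in length across taxa, so the read's effective protein length
`PL(r)` is defined as the *minimum* protein length within the tier; the
reported KO and protein are those of the minimum-length tier member, with a
final lexicographic tie-break on protein id. The chain
(bitscore desc, e-value asc, length asc, id asc) is fully value-based, so
assignments do not depend on file order or platform. Paired-end mates are
treated as independent reads. Reads whose only hits are to proteins absent
from the reference are dropped (and counted); they do not contribute to the
mapped-read total.

## Quantification

Two abundance measures are computed per sample. The raw count of KO $g$ is
simply $|R(g)|$, the number of reads assigned to $g$. The length-normalized
measure is a protein-length RPKM:

$$\mathrm{RPKM}(g) \;=\; \sum_{r \in R(g)} \frac{1}{PL(r)\cdot 3}
  \times \frac{1}{T} \times 10^{9}$$

where $PL(r)\cdot 3$ converts the best-hit protein length from amino acids
to nucleotides (no stop-codon correction is added), and $T$ is the total
number of mapped reads in the sample. Because each read contributes its own
$1/(PL(r)\cdot 3)$ term, two reads hitting the same KO through proteins of
different lengths contribute differently — this is deliberate: KO families
mix proteins of very different lengths, and a single "gene length" per KO
is not well defined.

$T$ is taken as the number of reads with a passing best-hit assignment.
Every reference protein carries a KO here, so mapped and assigned coincide;
$T$ is recorded in every output for audit. Raw counts are conserved by
construction: per sample, the counts sum to $T$ exactly. KOs with zero
reads are materialized as explicit zero rows only when samples are merged
into the KO × sample table, keeping per-sample outputs sparse.

## Differential abundance

Two test families are implemented, both consuming RPKM values:

* **Kruskal–Wallis rank-sum** (default): tie-corrected H statistic against
  a $\chi^2_{k-1}$ reference. An all-tied profile has zero rank variance
  and is defined to return $p = 1$.
* **Quasi-Poisson GLM**: log link, group factor, fitted by IRLS (iteration
  cap 50, relative deviance tolerance $10^{-8}$), dispersion estimated as
  Pearson $X^2/(n-k)$ *at the converged fit* — `summary.glm()`'s dispersion
  reuses the working weights of the penultimate IRLS iterate, which is off
  by enough to matter when validating against a closed form. For two groups
  the reported p is the two-sided Wald t-test on the group coefficient with
  $n-k$ df; for $k>2$ a quasi-likelihood F-test of the group factor. A
  group whose values are all zero makes the log-link fit degenerate; the
  test returns $p = 1$ with a warning rather than an unstable estimate.

A third method name, `metagenomeseq`, is reserved for the external
zero-inflated Gaussian package and errors with a clear message; it is an
extension point, not a re-implementation.

Fold changes are $\log_2\frac{\bar{x}_{case}+c}{\bar{x}_{ref}+c}$ with
pseudocount $c = 10^{-3}$ RPKM by default — small relative to any
detectable abundance, present only to keep zero means finite. The reference
group is the first label in the design (overridable); with more than two
groups the "case" mean pools all non-reference samples. P-values are
BH-adjusted, and a KO is called differentially abundant (DA) when the
selected p-value (raw by default, FDR-adjusted on request) is `< 0.05` and
`|log2FC| > 1`, both strict. KOs with zero abundance in every design sample
are excluded before testing (the count is logged) so enrichment universes
stay clean.

## Operon and pathway enrichment

An operon (ODB3-style: a set of member KOs) is a DA candidate exactly when
*all* of its members are DA — the all-members rule, which is monotone in
the DA set. Candidates are then annotated with a Fisher's exact p-value
against the chosen universe; both the rule output and the annotated table
are exposed, since the two gates answer different questions. Pathways skip
the all-members gate: every pathway with at least one DA KO is tested.

The Fisher test crosses feature membership with DA status over the
universe; the two-sided p-value sums the probabilities of all fixed-margin
tables no more likely than the observed one (relative tolerance $10^{-7}$,
the `stats::fisher.test()` convention — validated in the test suite against
brute-force hypergeometric enumeration). Two-sidedness is the default
because both over- and under-representation are of interest; one-sided
alternatives are available. Per feature the output reports the DA member
count, coverage (DA members / members within the universe), the average
log2 fold change over DA members only (the report accompanies the DA
analysis, so non-DA members are not averaged in), and a BH q-value within
the tested set of that kind. Single-member features are reported but
flagged: enrichment evidence from one gene is weak.

The universe is a genuine free choice: the default is every KO in the
reference (`reference`), and `detected` restricts to KOs observed in at
least one design sample. Both are exposed because the background strongly
affects enrichment p-values and neither choice is canonical.

## Visual exports

`kegg_colors()` emits the two-column paste format of the KEGG
map_pathway2 web form: one line per DA KO, `red` for over-abundant
(log2FC > 0), `blue` for under-abundant (log2FC < 0); exact zeros are
omitted. `heatmap_matrix()` exports the RPKM matrix (optionally restricted
to DA KOs) with `log10(x+1)` or row z-score transforms; the z-score uses
the population standard deviation and maps zero-variance rows to all
zeros. `autoplot()` methods provide a volcano plot for comparisons and a
dot plot for enrichment results.

## The synthetic study

Every stage is testable without downloads through a seed-reproducible
generator. Its defaults define the package's standard study:

| parameter | default | rationale |
|---|---|---|
| KOs | 500 | large enough for stable rate estimates, small enough to run in seconds |
| proteins per KO | 1–3, 100–1000 aa | exercises the minimum-length tie rule |
| pathways / operons | 20 (5–40 KOs) / 30 (2–6 KOs) | operons nest inside pathways where possible |
| design | 10 control vs 10 case | a typical small case–control study |
| depth | 20,000 mapped reads/sample | ~40 reads per KO on average |
| counts | negative binomial, size 5 | moderate overdispersion, stressing both tests beyond Poisson |
| spikes | 10% of KOs at |log2FC| = 3 | strong, clearly recoverable effects |
| hits | identity 85–99%, e-value 1e-30–1e-5, decoys at 20% | all true hits pass the filters; decoys sit at strictly lower bitscore |

Per-KO expected reads are depth × the group's true relative abundance
(log-normal baseline). Spiked units shift **two-sidedly**: alternating
units move up or down by $2^{\pm 3}$ in the case group. This matters
because abundances are compositional — with one-sided spiking at these
settings the case totals grow by ×1.7 and every unspiked KO would shift by
$-\log_2 1.7 \approx -0.77$ in relative space, a real artifact that is not
a false positive of the tests but of the design; balancing the directions
keeps the unspiked majority approximately null, which is what the
false-positive-rate checks assume. Half the spike budget preferentially
covers whole operons (a spiked operon moves as one unit in one direction),
emulating co-regulation and exercising the all-members rule.

Each sample draws from its own RNG stream derived from `(seed, sample_id)`,
so adding a sample never perturbs existing ones, and a fixed seed
reproduces byte-identical files.

What the generator does *not* emulate: sequence-level errors (it starts at
alignment output, by contract), strain-level length variation within a KO
beyond the uniform protein-length draw, correlated KOs outside spiked
operons, library-size imbalance between groups, and sparse zero-inflation.
Passing the recovery checks therefore shows the chain is implemented
correctly under a clean abundance model — not that the statistical power
observed here transfers to real, sparser, more correlated data.

## Numerical and degenerate-input choices

* Threshold comparisons are strict everywhere (`<`, `>`); boundary hits and
  boundary p-values are excluded.
* RPKM is kept at full double precision in memory; file output rounds to 3
  decimals (configurable).
* Best-hit tie-breaks are value-based; no stage depends on input order.
* All-tied test inputs return $p = 1$; all-zero groups under quasi-Poisson
  return $p = 1$ with a warning; all-zero KOs are dropped pre-test.
* BH adjustment preserves input order and enforces monotonicity.
* Pipeline outputs are pure functions of inputs + configuration; reruns are
  byte-identical apart from the manifest timestamp. A failed stage leaves a
  `.partial` marker and a stage-named error.

## Problem sizes used in validation

The test suite validates the statistics against independent oracles:
RPKM against a naive per-read loop (200 random read sets, relative
$10^{-12}$), Fisher against full hypergeometric enumeration (500 random
tables up to $N = 40$, absolute $10^{-10}$), quasi-Poisson against the
closed-form two-group Wald solution (100 random fixtures, $10^{-6}$),
Kruskal–Wallis null calibration on 2000 replicate KOs (two groups of 8,
negative-binomial), and full-pipeline truth recovery on the standard
500-KO study plus a spike-free null study. These sizes are the package's
validation conditions and are re-run by `scripts/acceptance.R`.

## Known limitations

* No paired or longitudinal designs: samples are exchangeable within
  groups, even though twin-style studies are a natural application.
* No covariate adjustment in either test.
* The operon p-value is reported only for operons passing the all-members
  rule; a user wanting Fisher p-values for *all* operons can call
  `fisher_enrichment()` directly over the operon table's member sets.
* `metagenomeSeq` is an extension point, not included.
* Reference construction filters a user-supplied `taxon_domain` column;
  taxonomy resolution from raw database records is out of scope.
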