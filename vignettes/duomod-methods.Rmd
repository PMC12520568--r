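---
title: "Methods: subtraction-free dual profiling of 5mC and 5hmC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtraction-free dual profiling of 5mC and 5hmC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duomod)
```

## The problem and the model

Bisulfite-based sequencing reads both 5-methylcytosine (5mC) and
5-hydroxymethylcytosine (5hmC) as C, so a common practice is to estimate
5mC by subtracting a 5hmC-assay level from a BS-seq level measured in a
different library. Both levels are binomial proportions; their difference
has the summed variance of the two and no floor at zero, so sites with
high 5hmC and modest depth routinely yield negative "5mC" estimates.
Paired conversion chemistries sidestep this: one assay reads only 5mC as
C (CD-seq: CMD1 glycerylates 5mC to deaminase-resistant 5gmC, then a
deaminase converts everything else; CT-seq: CMD1 followed by TET
oxidation and bisulfite), the other reads only 5hmC as C (ACE-seq: βGT
glucosylation protects 5hmC from the deaminase; TAB-seq: βGT protection,
TET oxidation of 5mC, bisulfite). Each level is then a direct, bounded
per-site estimate.

`duomod` models each protocol as an ordered list of enzymatic steps.
A step is a map from substrate state to product state with an efficiency
in [0, 1]; states not listed pass through unchanged; each molecule takes
each step independently (no within-molecule correlation between adjacent
cytosines, matching the per-site binomial model downstream). The tracked
states are C, 5mC, 5hmC, 5gmC, 5fC, 5caC and 5ghmC plus a terminal
deaminated/converted state that reads T; 5fC and 5caC are collapsed into
one oxidised pool because no protocol here reads them out separately.
`prob_read_C()` propagates a point mass through the steps in closed form;
a site with 5mC level $m$ and 5hmC level $h$ has expected raw C-fraction

$$\mathbb{E}[\text{raw}] = m\,P_C(\text{5mC}) + h\,P_C(\text{5hmC}) +
(1-m-h)\,P_C(\text{C}).$$

### Default efficiencies

The assays' published quality metrics are achieved end-to-end rates, not
per-enzyme constants, so the defaults are calibrated to reproduce those
aggregates and every entry is overridable:

| parameter | default | consequence |
|---|---|---|
| CMD1 on 5mC | 0.93 | CD/CT-seq retain ~93% of 5mC as C (≥ 92%) |
| deaminase on 5hmC | 0.97 | CD/ACE-seq convert ~97% of 5hmC to T |
| deaminase on C, 5mC | 0.995 | near-complete conversion of unprotected states |
| TET on 5mC | 0.98 | TAB-seq misreads ~2% of 5mC as C |
| TET on 5hmC | 0.95 | CT-seq converts ~95% of 5hmC |
| βGT on 5hmC | 0.98 | ACE/TAB-seq protect ~98% of 5hmC |
| bisulfite on C | 0.995 | standard conversion completeness |
| sequencing error | 0.001 | symmetric C↔T flip applied after chemistry |

Two modelling choices deserve note. First, the ~7% loss of 5mC in CD-seq
could reflect incomplete CMD1 glycerylation or residual deamination of
5gmC; the two are not separable from aggregate rates, so the defaults
attribute the loss entirely to CMD1 and treat 5gmC (and 5ghmC) as fully
resistant. Both knobs exist in the config. Second, sequencer noise is a
single symmetric flip applied after the chemistry, since published rates
do not separate chemistry from sequencing error.

## The synthetic study

`generate_scenario()` builds a desk-scale stand-in for a two-condition
brain methylome study: a 1 Mb genome with 200 non-overlapping genes,
CpG-enriched promoters (TSS ± 1 kb), bimodal CpG methylation
(promoter CpGs ~ Beta(1, 10), others ~ Beta(6, 1.5)), 5hmC concentrated
in gene bodies (~ Beta(2, 18), mean ≈ 0.1, consistent with neuronal
tissue where 5hmC is a sizeable fraction of 5mC), near-zero CHG/CHH
modification, and $m + h \le 1$ enforced by capping $m$ at $1-h$. The
AD-like condition multiplies gene-body 5hmC by 0.6 (a genome-wide loss)
and plants eight 2-kb hyper-methylated regions (effect +0.3) and eight
2-kb focal 5hmC losses (effect −0.2). Planted regions redraw the base
state first — hyper-m regions start from a hypomethylated state
(~ Beta(2, 8) capped to leave headroom), focal-loss regions from a
strongly hydroxymethylated state (~ Beta(10, 15) floored above the
effect) — so the configured effect is realised exactly rather than being
clipped by the $m + h \le 1$ constraint. Per-site 5hmC level
distributions for real hippocampus are not published at base resolution;
these are design choices, not literature values.

Spike-ins follow the experimental design: the printed 480-bp construct
(amplified with 5hm-dCTP, every cytosine 5hmC) and a lambda-like
fully methylated control, each at 0.5% library mass. The lambda control
is emulated as a random 5-kb contig with $m = 1$ in all contexts — M.SssI
methylates CpG only, but only the pooled readout of a uniformly modified
contig matters for calibration. Spike-in coverage follows mass over
length: depth × f·L/((1−2f)·l) for mass fraction f, genome length L,
contig length l. Pileups, not reads, are the simulation product: per site
coverage ~ Poisson(depth), C-count ~ Binomial(coverage, expected raw
level); read-level artefacts (fragment length, duplicates, alignment) are
out of scope, so passing tests say nothing about aligner-induced biases
in real data. Strands are simulated and reported independently.

Expression is simulated per gene as negative-binomial counts whose
log-mean couples to per-sample-jittered gene-level modification:
coefficients −3 on promoter and gene-body 5mC and +3 on promoter and
gene-body 5hmC (fraction scale), NB size 50, per-sample jitter SD 0.05,
plus a planted ±1 log2 fold-change for 20 genes independent of
modification. Six expression samples per condition are simulated: a
per-gene across-sample correlation is not estimable at the modification
assays' two replicates, and six is a realistic RNA-seq design; this is a
documented deviation from the n = 2 modification design.

## Calling and calibration

For each assay the false-positive source is the spike-in whose uniform
state should read T (the hydroxymethylated construct for CD/CT, the
methylated control for ACE/TAB). `calibrate()` pools counts over all
positions of that contig — a per-position rate would be noisier and the
binomial model only needs the pooled p̂ — and reports the complement as
the conversion rate, plus the retention of the should-read-C spike-in.
`call_sites()` computes the one-sided upper-tail binomial p-value (a
modification can only inflate the C-count above p̂), applies BH jointly
over all tested sites of one assay/sample, and calls q ≤ 0.05. Sites
with coverage < 5 are excluded before adjustment — not called negative —
matching the coverage criterion's role as an eligibility filter. A
degenerate p̂ = 0 (perfect spike-in conversion at finite depth) is
floored at 1/(spike-in coverage + 1) to keep the test proper. No
correction of 5mC levels for residual 5hmC leakage is applied: the
calibrated p̂ already absorbs it at the calling stage.

## Differential analysis

Site tests pool replicates within each group (coverage ≥ 5 required in
both pooled groups) and compare proportions with a two-proportion z-test
with continuity correction. This is a deliberate surrogate for
dispersion-shrinkage count models: with two replicates the shrinkage
machinery is hard to validate, the pooled test is transparent, and the
interface isolates it so a different site test can be swapped in.
Significance is conjunctive: p < 0.05 *and* |Δ| ≥ 0.1.

Region segmentation is greedy rather than recursive binary segmentation:
significant sites of one sign are chained while consecutive members are
< 300 bp apart, and a chain is emitted when it has ≥ 10 members, |mean
Δ| ≥ 0.1 and a Mann–Whitney U p < 0.001 comparing member-site levels
between groups. Two refinements matter numerically. "At least 10
differentially modified CpGs" is read as ten *significant* member CpGs
(not ten tested CpGs): with 60× pooled coverage a null site passes the
candidate gate a few percent of the time, and chains of merely-tested
CpGs would make null genomes sprout spurious regions. And boundaries are
trimmed density-aware: an outermost member whose distance to its
neighbour exceeds 5× the chain's median spacing (floored at 20 bp,
capped at the 300-bp gap rule) is shed, so one stray null-significant
site in a dense CpG island cannot drag a boundary hundreds of bp
outward. Region MWU p-values are not multiplicity-adjusted (the stated
criterion is a raw threshold), and every emitted region is re-validated
against all four criteria from its member sites. Regions map to genes
through promoter (TSS ± 1 kb) or gene-body overlap; a site or region in
both is counted as promoter, keeping the categories disjoint.

## Expression association

The DE surrogate is a per-gene Welch t-test on log2(CPM + 1) with the
fold-change taken on the same scale; DEG requires p < 0.05 and |log2 FC|
> 0.58 conjunctively. Correlations are across-sample Pearson per gene,
computed separately per covariate (promoter/gene-body × 5mC/5hmC), with
genes below 5 informative CpGs or zero variance reported NA and excluded
from the sign summary. Across-gene correlation is a different estimand
and is not what the per-gene sign summaries report.

## Numerical choices and degenerate inputs

All coordinates are 0-based half-open internally and in TSV/bedGraph
output. Determinism: every stochastic function takes an explicit seed and
the pipeline derives per-stage seeds from the scenario seed, so reruns
are byte-identical. Zero-coverage rows propagate NaN raw levels and are
excluded with a logged count; contexts within 2 bp of a contig end are
NA; genomes without CpGs, uncovered spike-ins, p̂ = 1 calibrations and
unsorted region input are errors, not warnings. Problem sizes in the test
suite (60 kb–1 Mb genomes, 30× depth, two replicates) were chosen so the
full suite and the demo pipeline run comfortably on a laptop while
keeping every estimate's Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

The binomial caller ignores biological overdispersion across molecules
(no beta-binomial layer) and SNPs (a C>T variant looks like complete
conversion). The site test pools replicates, so replicate-level
variability informs only the region MWU, not site p-values. The greedy
segmentation approximates, but does not reproduce, recursive binary
segmentation; agreement is at the level of the stated output criteria.
Synthetic pileups cannot expose alignment, duplication or
strand-bleed-through artefacts, and the generator's level distributions
are plausible rather than fitted to tissue data — recovery results here
demonstrate correctness of the machinery, not field performance on real
libraries.
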