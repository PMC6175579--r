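---
title: "Pooled transposon fitness and interaction classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled transposon fitness and interaction classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barseqfit)
library(dplyr)
```

## The experiment barseqfit models

Random-barcode transposon sequencing (RB-TnSeq) profiles the fitness of tens
of thousands of insertion mutants in a single pooled culture. Each mutant
carries a unique DNA barcode, so the abundance of every mutant can be read
out by amplifying and sequencing only the barcode region (BarSeq) and
counting reads per barcode. Comparing abundances between a harvest sample
and the inoculum (T0) yields a per-strain fitness; averaging strains within
a gene yields gene fitness. Genes whose disruption slows growth in a
condition have negative fitness there and are interpreted as *required* for
optimal growth in that condition.

barseqfit implements this analysis for experiments that compare a focal
organism's genetic requirements across community contexts — growth alone,
pairwise co-culture with each partner species, and growth with the full
community — and classifies how requirements change between contexts
(conserved, induced, alleviated), including the decomposition of
community-level interactions into pairwise-derived and higher-order parts.
A synthetic-data generator reproduces the statistical structure of such an
experiment so that every stage of the pipeline can be tested end to end
against a known ground truth.

## Fitness model

For retained strain $s$ of gene $g$, with harvest count $n_h$, T0 count
$n_0$, and sample totals $N_h$, $N_0$ (totals are over retained barcodes):

$$f_s = \log_2\frac{n_h + \psi}{n_0 + \psi} - \log_2\frac{N_h}{N_0},$$

with pseudocount $\psi = 1$ guarding zero counts. The depth term makes
$f_s$ a change in *relative* abundance, so multiplying a sample's depth by a
constant leaves fitness unchanged (up to a vanishing pseudocount
perturbation). Raw gene fitness is the weighted mean over the gene's
retained strains,

$$f_g = \frac{\sum_s w_s f_s}{\sum_s w_s}, \qquad
  w_s = \left(\frac{1}{1 + n_0} + \frac{1}{1 + n_h}\right)^{-1},$$

where $w_s$ is the inverse of the Poisson-approximate variance of the
strain log-ratio (up to the constant $1/\ln^2 2$): well-measured strains
dominate the average.

Three count-based filters precede everything: only insertions within the
central 10–90% of a gene's coding sequence are used (terminal insertions
often fail to disrupt function; the boundaries are inclusive and measured
from the translational start, strand-aware); barcodes with fewer than 3 T0
reads are ignored; genes whose retained barcodes sum to fewer than 30 T0
reads are not scored.

### Two-stage normalisation

Raw gene fitness is normalised per replicate, then replicates are averaged:

1. **Chromosome position.** Genes near the replication fork have elevated
   copy number in dividing cells, inflating their apparent abundance. We
   subtract the running median of raw fitness over a window of $W = 251$
   genes centred on each gene in chromosome order (wrapping around circular
   scaffolds; truncating at the ends of linear ones; scaffolds with fewer
   than $W$ scored genes use the scaffold-wide median). The running median
   removes any additive effect that is locally constant in position while
   leaving isolated gene-level effects intact.
2. **Mode.** Most gene disruptions have no fitness consequence, so the bulk
   of the distribution should sit at exactly 0. We subtract the mode,
   estimated as the argmax of a Gaussian kernel density (Silverman's
   rule-of-thumb bandwidth) on a 512-point uniform grid spanning the data
   range. The mode is preferred to the mean or median because it is
   insensitive to the size of the deleterious tail.

Normalising each replicate before averaging (rather than averaging raw
values first) keeps replicate-specific depth and position artefacts from
leaking across replicates; this order is a package choice where either
would be defensible.

### Moderated t-scores

Each gene × condition × timepoint gets $t = \bar f_g / \sqrt{V_\mathrm{mod}}$,
where $\bar f_g$ is the replicate mean of normalised fitness. The variance
combines, per replicate $r$:

* the strain-to-strain spread
  $V_{\mathrm{strain},g,r} = \sum_s w_s^2 (f_s - f_{g,r})^2 / (\sum_s w_s)^2$
  (zero for single-strain genes), floored by the Poisson counting variance
  $V_{\mathrm{floor},g,r} = \frac{1}{\ln^2 2}\left(\frac{1}{1 + N_{0,g}} +
  \frac{1}{1 + N_{h,g,r}}\right)$ built from the gene's summed counts, so a
  gene can never look more precise than its read support allows:
  $V_{g,r} = \max(V_{\mathrm{strain}}, V_{\mathrm{floor}})$.
* the shared-T0 component
  $C_g = \frac{1}{\ln^2 2}\,\sum_s w_s^2/(1 + n_{0,s}) \,/\, (\sum_s w_s)^2$:
  because every replicate is measured against the *same* T0 sample, the T0
  counting noise is common to all replicates and does not average away.
  Ignoring it would understate $\mathrm{Var}(\bar f_g)$ by roughly a factor
  of two at three replicates, inflating null t-scores by $\sim$1.4 and the
  false-positive rate by an order of magnitude. Hence

$$V_g = \frac{1}{R^2}\sum_r V_{g,r} + \frac{R - 1}{R}\, \bar C_g .$$

Moderation shrinks each gene's variance halfway toward the across-gene
median, $V_\mathrm{mod} = (V_g + \tilde V)/2$, stabilising genes whose
spread is accidentally small. The package validates this construction by
calibration rather than by reference to any particular formula: under null
simulations the across-gene standard deviation of $t$ lies in $[0.7, 1.3]$
and the fraction of fitness values flagged significant-negative
($|t| \ge 3$ with $f < 0$) stays below 0.2%.

### Significance rule

A gene is *significant-negative* in a condition-timepoint when
$|t| \ge 3$ (inclusive) and its fitness is strictly negative. Per-condition
gene sets pool timepoints by union — a gene is counted as required in a
condition if it is significant-negative at at least one timepoint — with the
contributing timepoints recorded as provenance.

## Interaction classification

Writing $A$ for the growth-alone set, $S_1..S_k$ for the pairwise sets and
$C$ for the community set:

* **conserved** (vs pairwise): $A \cap S_1 \cap \dots \cap S_k$ — required
  alone and with every partner. The default requires *all* pairwise
  conditions; `rule = "any"` switches to the union reading, because the two
  conventions genuinely differ for genes with mixed partner patterns and
  either is defensible. **alleviated** is the complement within $A$, and
  **induced** is $(S_1 \cup \dots \cup S_k) \setminus A$. Against the
  community ($k = 1$) the two rules coincide.
* **partner breakdown**: an alleviated gene is attributed to "all partners"
  when absent from every pairwise set, "specific to partner $i$" when
  absent only from $S_i$, and "other" for mixed patterns (induced is
  symmetric).
* **cross-classification**: the pairwise and community versions of each
  family are intersected into conserved-interaction, pairwise-specific and
  community-specific pieces.
* **core set**: genes significant in every condition.
* **higher-order summary**: interactions conserved from pairwise to
  community (`conserved_induced + conserved_alleviated`) versus those seen
  in only one of the two levels; both reported as counts and as integer
  percentages of their total (rounded half to even).

All of these are pure set operations, so the package asserts their
partition identities ($|A| = |\mathrm{conserved}| + |\mathrm{alleviated}|$,
families equal the union of their cross-classification pieces) against
brute-force enumeration on random instances.

## Differential-expression classification

The DE module consumes result tables from any external tool (gene,
contrast, timepoint, log2 fold change, BH-adjusted p). The thresholds are
adjusted $p < 0.01$ and $|\log_2 \mathrm{FC}| \ge 1$; the fold-change
threshold is inclusive (an observed value of exactly 1 passes), with a
`strict_gt` flag for the exclusive convention. Timepoints pool by union per
direction; pairwise-union versus community sets cross-classify exactly as
above. The amplified-response subset re-applies the same thresholds to a
community-versus-pairwise contrast restricted to the conserved upregulated
genes; the thresholds for that contrast are not independently motivated, so
reusing $\alpha = 0.01$, $\lambda = 1$ is a documented package default.
Category enrichment is a plain hypergeometric upper tail with BH correction
across categories (enriched at adjusted $p < 0.05$); p-values are checked
against an exact combinatorial summation to $10^{-10}$.

## Competition assays

Knockout-versus-wild-type competitions are scored from CFU plate counts:
mutant fraction $p = \mathrm{CFU}_\mathrm{mutant} / \mathrm{CFU}_\mathrm{total}$
from paired selective/non-selective plates, per-replicate fitness
$f = \log_2(p_1 / p_0)$, and confidence $z = \bar f / (s / \sqrt R)$ with
the sample standard deviation. A mutant is called significantly less fit
than wild type at one-sided 95% confidence, $z \le -1.645$. The normal
critical value is anticonservative at small $R$ (with $R = 3$ the statistic
is Student-t with 2 degrees of freedom, for which
$P(T \le -1.645) \approx 12\%$); a `test = "t"` option substitutes the
$t_{R-1}$ critical value and holds the nominal level, which the test suite
verifies empirically. Degenerate inputs are explicit: one replicate gives
an undefined $z$ and no call; zero spread with nonzero mean gives
$z = \pm\infty$ and the call follows the sign; a zero endpoint fraction is
a below-detection $-\infty$ fitness.

## The synthetic-data generator

The generator reproduces the features of a BarSeq experiment that the
estimator actually confronts:

* **Library structure**: a scaled-down pool of 3,300 genes with a median of
  ~16 central insertions per gene (~55,000 mutants) mirrors the per-gene
  statistics of a genome-scale library at desk scale; an option places an
  exact number of central insertions per gene for calibration studies.
* **Uneven representation**: T0 strain abundances are log-normal
  (sdlog 0.5), so T0 read filters and count-based weights are exercised.
* **Sequencing**: each sample is one multinomial draw of $N$ reads
  (default $2 \times 10^6$, within the 1.5–7.5 million per sample typical
  of BarSeq runs) over strain weights, so column sums are exact and
  sampling noise is realistic.
* **Copy-number artefact**: harvest samples multiply strain weights by
  $2^{b \cos(2\pi\,\mathrm{pos}/L)}$ (default $b = 0.3$), a smooth
  chromosome-position bias that the position normalisation must remove.
* **Planted truth**: per-gene cumulative log2 effects $\varphi$ accumulate
  linearly over timepoints ($\varphi = d \times$ per-day effect).
  Parameterising truth directly on the estimator's scale makes parameter
  recovery a crisp test. Categories name requirement patterns over
  (alone, pairwise, community): conserved (1,1,1), alone_required (1,0,0),
  pairwise_induced (0,1,1), pairwise_alleviated (1,0,1),
  community_specific_induced (0,0,1), community_specific_alleviated
  (1,1,0) — the unique assignment under which the six names denote six
  distinct membership patterns. Default category fractions (2% conserved,
  2% alone-required, 1.5% pairwise-induced, 1% pairwise-alleviated, 0.5%
  each community-specific) put a few percent of genes in each class,
  matching the scale of genome-wide interaction screens.
* **Reads**: FASTQ emission writes exactly the reads implied by a count
  matrix (random pad, fixed flanks, barcode, fixed quality), and barcode
  extraction inverts it bit-exactly — the round-trip is asserted as an
  identity.

What it deliberately does **not** model: sequencing errors (so the
exact-match extractor is exactly right for it), PCR
duplicates, spatial structure on the plate, strain-to-strain interactions
within the library, or partner genomes (partner presence is a condition
label only). Passing tests therefore demonstrate correctness of the
estimator and classifier under the stated statistical model, not robustness
to these additional real-data artefacts.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `pseudocount` | 1 | reads | guards zeros in the log-ratio; biases large depletions slightly toward zero |
| `min_t0_reads` | 3 | reads | barcode retention floor at T0 |
| `min_t0_gene_reads` | 30 | reads | gene scoring floor at T0 |
| `window` | 251 | genes | running-median width (odd); must exceed the width of copy-number features |
| `t_threshold` | 3 | – | significance threshold on \|t\| (inclusive) |
| `mode_grid` | 512 | points | KDE grid for the mode estimate |
| `depth` | 2e6 | reads | simulated reads per sample |
| `position_bias` | 0.3 | log2 | amplitude of the simulated copy-number bias |
| `t0_sdlog` | 0.5 | ln | spread of simulated T0 abundances |

## Numerical and testing choices

* Coordinates are 1-based inclusive throughout (GFF3 convention).
* All thresholds stated as "at least"/"lower than" in the analysis are
  implemented inclusively on the magnitude (\|t\| ≥ 3, \|log2FC\| ≥ 1,
  central fraction in [0.1, 0.9]) and exclusively on p-values (padj < α).
* All simulation randomness flows from one integer seed per generator call;
  callers' RNG state is saved and restored.
* Parameter-recovery checks plant a −2 per-day effect and require the
  day-1 estimate within ±0.3 for ≥ 90% of planted genes. Recovery is
  assessed without the copy-number bias (as in the null-calibration runs)
  so that it measures estimator accuracy rather than residual smoothing
  error; a small attenuation (mean estimate ≈ −1.83 for a true −2) is
  expected from the pseudocount and from the correlation between
  count-based weights and measured fitness at low coverage, and the ±0.3
  band accommodates it.
* Category-recovery checks use a −3 per-day effect, where planted genes
  sit far outside the null and recovery through the full pipeline is exact
  across seeds.
* Test problem sizes are the package's desk-scale defaults: 3,300 genes ×
  16 central insertions at 2 × 10⁶ reads per sample for calibration runs
  (five seeds), 500 genes for mid-scale pipeline tests, and a few hundred
  barcodes for FASTQ round-trips. A full simulate–fit–classify cycle at
  the default scale runs in seconds.

## Known limitations

* The moderated t-statistic is a calibrated construction, not a claim about
  any particular upstream implementation; other pipelines' t-scores will
  differ in detail while ranking genes very similarly.
* With a single shared T0, fitness errors are correlated across conditions
  and timepoints; the classification treats condition sets as independent
  evidence, as the underlying experimental design does.
* Gene fitness assumes insertion mutants of a gene share its fitness
  effect; polar effects and domain-specific insertions violate this and are
  not modelled.
* The exact-match barcode extractor discards reads with any flank or
  barcode mismatch; on real data with sequencing errors this loses a few
  percent of reads, roughly uniformly across strains, so fitness estimates
  remain unbiased but read support is slightly understated.
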