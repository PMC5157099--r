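---
title: "The tumorcn model: purity, ploidy, allele-specific copy number and SNV classification"
author: "tumorcn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tumorcn model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorcn)
```

# The problem

Hybrid-capture sequencing of tumors mixes tumor-derived and normal DNA. The
fraction of tumor DNA (purity, $p$) and the tumor's average copy number
(ploidy, $D$) jointly determine both the coverage log-ratios against a
normal reference and the allelic fractions of every variant. Without a
matched normal sample, telling a private germline variant from a somatic
mutation requires knowing $p$ and the local copy number: a heterozygous
germline SNP in a balanced diploid region is expected at allelic fraction
$0.5$ regardless of purity, while a clonal heterozygous somatic mutation sits
at $p/2$ in that region. `tumorcn` estimates $p$, $D$, per-segment total and
minor copy number (hence LOH), and per-variant somatic status and clonality
from per-target coverage plus a VCF, with or without a matched normal.

# The copy-number model

Log-ratios $r_i$ of a segment $i$ with integer tumor copy number $C_i$ are
modeled as Gaussian:

$$ r_i \sim N\!\left(\log_2 \frac{p\,C_i + 2(1-p)}
{p\,D + 2(1-p)},\; \sigma_{ri}\right),
\qquad D = \frac{\sum_j l_j C_j}{\sum_j l_j}, $$

where $l_j$ is the genomic segment length and $\sigma_{ri}$ the per-target
standard deviation of log-ratios within the segment. Each segment
contributes its number of targets times the log-density, so the likelihood
is weighted by targets (robust to uneven tiling) while ploidy is weighted by
base pairs. Multiplying the per-target log-density by the target count gives
the same curvature as a standard-error model, so the two conventions (noise
as per-target SD with target weighting, versus noise as a standard error)
coincide; we store the per-target SD, floored at $10^{-4}$.

Copy numbers 0 through 7 are modeled explicitly. A sub-clonal state with a
constant density — equal to an integer state missing the observation by
exactly $2\sigma_{ri}$ — absorbs segments that no integer state explains
(including amplifications beyond copy number 7): a segment goes sub-clonal
only when every integer state fits worse than a 2-SD mismatch.

## Grid search and heated Gibbs refinement

A 2D grid search (purity 0.15–0.95 in steps of 0.01; ploidy 1–6 in steps of
0.1) scores each point by the sum over segments of the best-fitting state,
treating ploidy as continuous. Local optima (points not below any of their
8 neighbors) are candidate solutions; ridges of numerically tied optima —
for example the purity continuum of a flat genome — collapse to one
representative at the highest purity. A non-aberrant genome is aliased
across integer ploidies, so one candidate per integer ploidy survives; the
SNV stage disambiguates them.

Each candidate is refined by heated Gibbs sampling: per sweep, (a) each
segment's copy state is sampled from its posterior at temperature $T$
(annealed as $T_k = \max(1, 4 \times 0.9^k)$), (b) purity is sampled over
its grid given the assignment, and (c) a global log-ratio recalibration
shift is sampled within $\pm 0.25 \times \overline{\sigma_r}$ (log-ratio
miscalibration otherwise biases ploidy). Ploidy is recomputed from the
assignment every sweep; sub-clonal segments contribute the continuous copy
number implied by their log-ratio, clipped to $[0, 16]$. After the
maximum-likelihood assignment is stable for 3 sweeps (or 100 sweeps), a
deterministic coordinate ascent polishes the solution. If the converged
ploidy is more than 0.75 from the candidate, one retry widens the shift
range to $\pm 1 \times \overline{\sigma_r}$; a still-divergent solution is
flagged discarded and excluded from ranking. Ties between equally likely
copy states resolve to the lower copy number. All randomness flows from one
integer seed.

# Coverage normalization and segmentation

Coverage is first divided by a loess trend on GC fraction (span 0.3, fitted
on nonzero targets, sample mean preserved). With a pool of normals,
PCA of coverage (each sample rescaled so its maximum equals 100×, per-target
centered) selects the reference normal nearest the tumor on the first three
components; rescaling every sample to the cap makes the selection exactly
invariant to global scale. Target weights are proportional to the inverse
per-target SD of coverage ratios across the pool (clipped at 3, mean 1), and
targets below 20% of their chromosome's median coverage are excluded.
Sex is called from relative chrX/chrY coverage; males exclude both sex
chromosomes from the fit (the model assumes a diploid normal), everyone
excludes chrY.

Log-ratios are segmented by a weighted circular binary segmentation: the arc
maximizing the weighted two-sample statistic is tested by permutation
(10,000 maximum, with early stopping in both directions: a split is rejected
as soon as the exceedance count forces $p > \alpha$ and accepted once a
clean run bounds $p$ below the pruning threshold). The pipeline default
$\alpha$ is 0.005 while breakpoints are only *guaranteed* kept at
$p \le 0.001$; the band in between is pruned with germline evidence:
a borderline breakpoint is removed when the mirrored allelic fractions
($\min(f, 1-f)$) of heterozygous dbSNP SNPs (tumor fraction 0.1–0.9, within
a target or its 50 bp flank) in the two flanking segments do not differ
(two-sided Welch t-test, $p > 0.2$), or when either flank has fewer than 3
SNPs. Copy-neutral LOH that coverage cannot see is recovered by recursively
splitting segments at the SNP boundary minimizing the pooled mirrored-SD,
accepted at $\alpha_{LOH} = 0.005$ after a Bonferroni correction over the
scanned candidate splits (the split point is chosen to minimize the SD, so
the nominal p-value is optimistic); at least 10 SNPs per side are required.
Finally, Ward clustering on (mean log-ratio, mean mirrored fraction) — with
missing mirrored means imputed at 0.5 — cut at $0.5 \times
\overline{\sigma_r}$ harmonizes the means of segments with the same
underlying state.

# The SNV model

For a variant with multiplicity $M$ (copies carrying it) in a segment of
copy number $C$, germline indicator $g$:

$$ E[f] = \frac{p M + g (1-p)}{p C + 2 (1-p)}, $$

and the likelihood of an observation $(f, n)$ is the Beta density with
shapes $nf + 1$ and $n(1-f) + 1$ evaluated at $E[f]$, with $n$ capped at 300
so unmodeled mapping biases cannot dominate at extreme depths. States
enumerate $C \in 0..7$ (weighted by the segment's copy-number posterior),
minor copy number $K \le \lfloor C/2 \rfloor$ (flat prior $1/(C+1)$),
multiplicity, and $g$. Allowed multiplicities ($M = K$, $M = C-K$, or
$M \le 1$ for somatic states, counting the sub-clonal $M = 1/3$ which
replaces the impossible somatic $M = 0$) share prior mass $P_K = 0.999$;
remaining integer states share the rest; when every support state is allowed
they carry all mass equally, keeping the prior normalized for every
$(C, K, g)$.

Somatic-status priors: with a matched normal, 0.999 (somatic) / 0.0001
(germline); without one, 0.95 if seen more than twice in COSMIC, 0.0005 if
in dbSNP, 0.01 if in both, 0.5 otherwise. Two contamination states (admitted
for dbSNP variants, prior 0.01, contamination rate 0.01) catch allelic
fractions just below 1 or just above 0 produced by DNA from another
individual. In high-purity mode a germline-homozygous state (binomial
likelihood of the reference reads at error rate $10^{-3}/3$) replaces the
up-front removal of homozygous calls, since in a pure sample those may be
heterozygous SNPs in LOH regions. The posterior is normalized per variant;
ties resolve toward germline. For somatic calls the cellular fraction is
$h = (f/M)(pC + 2(1-p))/p$; values above 1 are flagged rather than silently
clipped (the reported `CELLFRACTION` is capped at 1, the raw value is kept).

The SNV log-likelihood of a solution is the sum over variants of the most
likely state's log-likelihood; solutions are ranked by copy-number plus SNV
log-likelihood. Because a missing tumor chromosome barely unbalances
germline fractions at low purity, haploid solutions below purity 0.35 have
their SNV log-likelihood capped at the best near-diploid solution's
(ploidy 1.5–2.5) before ranking, giving both explanations the same
effective prior; exact ties resolve toward the ploidy nearest 2. An
optional post-optimization (off by default, recommended for variant
classification) re-maximizes the total likelihood over the purity grid and
refreshes assignments and posteriors once.

## Filtering

Homozygous germline variants are removed up front (matched-normal fraction
above 0.9, or tumor fraction above 0.95 when unmatched) unless high-purity
mode is on. Variants whose matched-normal fraction is incompatible with 0.5
under the Beta model (two-sided tail below 0.05) are removed as mapping
artifacts; the pool-of-normals variant of the rule requires the bias in at
least half of at least 5 informative normals.

# Curation

The goodness of fit maps the mean absolute deviation $d$ between observed
and expected allelic fractions to $100 \times \max(0, 1 - d/0.2)$ percent —
anchored so $d = 0.2$ is the worst plausible fit. Bootstrap re-ranking
resamples variants with replacement (500 replicates, at least 20 variants),
re-ranks solutions per replicate, removes solutions that never reach the top
2, and flags the sample when the winner's bootstrap value falls below 0.95.
Sample flags (all thresholds configurable, chosen as this package's
defaults since the flag categories come without numbers): noisy segmentation
(mean $\sigma_r > 0.25$), rare ploidy (< 1.5 or > 4.5), excessive LOH
(> 90% of genome length), excessive homozygous loss (> 5%), non-aberrant
(< 1% off diploid-balanced), poly-genomic (> 20% sub-clonal), contamination
(≥ 2% of dbSNP variants in contamination states), low goodness of fit
(< 75%).

# The simulator

The generator emulates a benchmarking design for targeted sequencing:

* **Genomes.** Segment lengths are log-normal over target counts (minimum
  5 targets, 40 segments over 20 chromosomes); integer copy numbers are
  drawn around the target ploidy and accepted when the length-weighted mean
  lands within ±0.15; minor copy numbers are uniform in
  $0..\lfloor C/2 \rfloor$. Exome-like: 2,000 targets at 100×; panel-like:
  3,000 small targets at 400× (a 560-gene-panel scale). These sizes are the
  package's benchmark scale, a reduced rendering of genome-wide designs.
* **Coverage.** Per-target capture efficiencies (log-normal, CV 0.2) are
  shared between tumor and reference — a process-matched normal — while
  each sample gets its own random linear GC-bias slope (SD 0.2), which the
  GC normalization must remove. The tumor expectation is scaled by
  $(pC + 2(1-p))/2$, and both samples receive counting noise whose CV
  shrinks with depth (Poisson-equivalent at the default noise setting; zero
  noise gives exact ratios).
* **Variants.** One heterozygous SNP per 10 targets, phased to a random
  parental chromosome (multiplicity $K$ or $C-K$); 100 somatic variants
  per exome-like sample (60 for the panel), clonal at $M = 1$ except for a
  10% sub-clonal share carried by a third of tumor cells. Depths are
  Poisson, alt counts binomial around $E[f]$, and variants sampled with
  zero alt reads are not emitted (no caller would report them). dbSNP
  membership has a 1% false-negative rate for SNPs and a 0.1% overlap rate
  for somatic variants; 2% of somatic variants get COSMIC hotspot counts —
  enough to exercise every cell of the prior table.

What the simulator does *not* emulate: segmental-duplication mapping
artifacts, position-specific reference bias, FFPE damage, subclonal copy
number (other than the high-amplification state), or correlated noise along
the genome. Passing recovery benchmarks therefore demonstrates correctness
of the inference given the model's assumptions, not robustness to every
artifact of real libraries — the filtering and weighting stages that target
those artifacts are tested on constructed fixtures instead.

# Numerical choices and limitations

* Welch's t-test is used wherever flanking allelic fractions are compared
  (the variance of mirrored fractions differs between balanced and
  unbalanced segments); degenerate (constant) inputs count as "not
  significantly different".
* Segments too short to estimate their own noise (< 3 targets) inherit a
  robust profile-wide value (scaled median absolute difference).
* The grid-search score uses the maximum over copy states per segment
  (a log-sum-exp alternative is a configuration switch).
* Permutation p-values use the add-one estimator $(b+1)/(B+1)$.
* The sweep order of the Gibbs sampler (assignments, then purity, then
  shift) is a fixed design choice; sampling uses the Gumbel-max trick on
  heated log-posteriors, so identical seeds give identical solutions.
* Benchmark scale: cohorts of 20 samples with 2,000–3,000 targets run in
  minutes; the method has no whole-genome ambitions, and runtimes grow with
  the number of local optima times variants.
* Copy numbers above 7 are only represented through the sub-clonal state;
  multiplicities of germline variants at homozygous-deleted loci are modeled
  as reads from normal DNA only.
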