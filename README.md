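# tumorcn

Tumor purity, ploidy, allele-specific copy number, LOH and somatic/germline
SNV classification from targeted (hybrid-capture) short-read sequencing —
with or without a matched normal sample.

Sequenced tumors are mixtures of tumor and normal DNA. The tumor fraction
*p* (purity) and the tumor's length-weighted mean copy number *D* (ploidy)
jointly shape two observables:

* coverage log-ratios against a normal reference,
  `r_i ~ N(log2((p·C_i + 2(1−p)) / (p·D + 2(1−p))), σ_ri)`
  for a segment with integer tumor copy number `C_i`;
* allelic fractions of variants,
  `E[f] = (p·M + g(1−p)) / (p·C + 2(1−p))`,
  where `M` is the number of tumor chromosome copies carrying the variant
  and `g` indicates germline (1) vs. somatic (0), with the sampling
  variance of `f` at depth `n` modeled by a Beta density with shapes
  `n·f + 1` and `n(1−f) + 1`.

`tumorcn` fits both jointly: GC- and pool-of-normals-normalized coverage is
segmented by weighted circular binary segmentation (refined by germline
allelic fractions), a 2D grid search finds candidate purity/ploidy optima,
each candidate is refined by a heated Gibbs sampler that assigns integer
copy numbers 0–7 (plus a sub-clonal state) to all segments, and every
variant is classified over all `(C, K, M, g)` states — including
contamination and homozygous states — yielding somatic posteriors,
multiplicities and cellular fractions `h = (f/M)(pC + 2(1−p))/p`.
Candidates are ranked by the combined copy-number and SNV log-likelihood,
bootstrap re-ranked, and flagged for manual curation when the fit looks
atypical. See `vignette("tumorcn-methods")` for the full model.

## Worked example

Simulate an exome-like tumor (2,000 targets, 100×) with known truth and run
the full tumor-only pipeline:

```r
library(tumorcn)
sim <- simulateSample("exome", purity = 0.6, target.ploidy = 3.0, seed = 7)
res <- runPipeline(sim$tumor, sim$intervals,
                   normal.coverage = sim$reference,
                   variants = sim$variants, seed = 11)
print(res)
#> tumorcn result for sample
#>   purity 0.58, ploidy 2.954 (rank 1 of 4 solutions)
#>   goodness of fit: 82.9%
#>   flags: SEX_UNKNOWN
```

The simulated truth was purity 0.60 and ploidy 2.962; the maximum-likelihood
solution recovers 0.58 / 2.954. (`SEX_UNKNOWN` is expected: the simulated
genome has no sex chromosomes.) Per-segment calls carry total copy number
`C`, minor copy number `K` and the LOH flag:

```r
head(res$segments[, c("chrom","start","end","num.targets","seg.mean","C","K","loh")])
#>   chrom  start    end num.targets     seg.mean C K   loh
#> 1  chr1      0 177200          60 -0.005941868 3 0  TRUE
#> 2  chr1 180000 333200          52 -0.873211485 1 0  TRUE
#> 3  chr2      0 309200         104  0.300240574 4 2 FALSE
```

and per-variant calls carry the somatic posterior, state and clonality:

```r
head(subset(res$variant.fit$calls, ml.somatic,
            select = c(chrom,pos,f,n,posterior.somatic,ml.C,ml.M,cellfraction)), 3)
#>   chrom    pos         f   n posterior.somatic ml.C ml.M cellfraction
#> 1  chr1  27199 0.1935484  93         0.5806896    3    1    0.8609566
#> 4  chr1 177064 0.2477876 113         0.9361979    3    1    1.0000000
#> 5  chr1 186002 0.4545455 110         0.9965889    1    1    1.0000000
```

A variant at fraction 0.45 in a copy-1 LOH segment can only be somatic (a
germline variant there would sit near 0.69 or 0), hence its posterior of
0.997. `writeOutputs(res, "out/sample")` writes the SEG file (with `C`,
`K`, `LOH` columns), the variant table and run summaries;
`inst/scripts/tumorcn.R` exposes the same pipeline as a command line with
`normaldb`, `run`, `simulate` and `classify` subcommands.

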