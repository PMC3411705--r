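# quantdiff

Differential enrichment calling for histone-modification ChIP-seq,
built around a two-stage normalization that removes stochastic
background noise and local genomic bias before any two libraries are
compared.

## Who this is for

Epigenomics analysts comparing one histone mark (H3K27me3, H3K4me3,
...) between two cell types or conditions, given mapped tags or binned
counts for the two ChIP libraries and their input-DNA controls.  The
output is a per-bin labeling — differentially enriched toward library 1
or 2 (DHE), constitutively highly enriched in both (CHE), or neither —
plus the merged regions, the four classic comparator normalizations,
and the evaluation procedures (gene-density bias profiles, promoter
sensitivity/error, ROC, replicate false-positive rate, promoter gene
types, 16-class bivalent states).

## The method

Counts are modeled as amplified, biased, noisy observations of the true
modification level.  Stage one treats each library separately:

* **Amplified-binomial null.** Background fragments scatter over the
  *B* bins binomially and are PCR-amplified by a constant factor *a*.
  Its parameters come from two amplification-invariant observables:
  empty bins, `B(1 - 1/B)^n0 = Z0`, and the total, `a = N/n0`.  Bins
  are called significant at the smallest count threshold whose
  empirical FDR — expected null bins at or above the threshold over
  observed bins there — drops below 0.05.
* **Iterative control normalization.** The input-DNA control is
  quantile-mapped onto the data, bins with data/control fold ≥ 2 are
  flagged as enriched outliers, and the map is refitted without them
  (two rounds by default); enrichment relative to the refitted control
  removes open-chromatin and mappability bias.

Bins passing both tests are *enriched-significant*; the union over the
two libraries proceeds to stage two, where each library's stage-2
counts are placed on the other's scale through monotone-spline inverse
CDFs (`f(F1^-1(p)) = F2^-1(p)`).  A bin is DHE toward a library when
its value sits above that library's stage-2 median and its mapped fold
change reaches *t* (default 3); CHE when both medians are cleared and
neither fold reaches *t*.  Adjacent same-label bins merge into regions.

## Worked example

Simulate a paired study with planted 4-fold differences and mismatched
technical conditions (library 1 amplified 4x, library 2 not), then run
the full two-stage call:

```r
library(quantdiff)
sim <- sim_study_pair(seed = 1, scenario = "recovery")
fit <- quantdiff(sim$lib1, sim$ctrl1, sim$lib2, sim$ctrl2)
fit
#> <quantdiff_fit>
#>   stage 1: 1287 / 1275 enriched-significant bins (lib1 / lib2)
#>   stage 2: 1300 bins; DHE_LIB1 543, DHE_LIB2 531, CHE 83
#>   regions: 1122
head(fit$regions, 3)
#>    chrom  start    end    label
#> 1:  chr1  13000  14000 DHE_LIB2
#> 2:  chr1 103000 104000 DHE_LIB2
#> 3:  chr1 569000 570000      CHE
mean(fit$labels$labels[sim$truth$labels == "DIFF_1"] == "DHE_LIB1")
#> [1] 0.905
```

Stage one found ~1290 enriched-significant bins per library (the 1200
planted differential bins plus the 100 shared ones, with a handful of
noise bins); stage two labeled 543 and 531 bins differential toward
each side and recovered 90% of the planted library-1 differences at
fold threshold 3.  `write_regions(fit$regions, "regions.bed")` exports
the calls; `run_pipeline()` drives the same computation from a YAML
configuration and file inputs (BED6 tags or bedGraph counts), and
`inst/cli/quantdiff.R` wraps it for the shell.

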