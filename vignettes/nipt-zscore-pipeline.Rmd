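---
title: "Methods: z-score NIPT for fetal trisomy 18 and 21"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: z-score NIPT for fetal trisomy 18 and 21}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niptr)
```

## The screening problem and the model

Maternal plasma carries cell-free DNA (cfDNA) from both mother and
placenta. In a pregnancy with fetal trisomy 21, the fetal component
contributes three copies of chromosome 21 instead of two, so a sequencing
run of plasma cfDNA slightly over-represents chr21 reads. With fetal
fraction $f$ (the proportion of plasma cfDNA of fetal origin), the
trisomic chromosome's expected share of reads is multiplied by

$$1 - f + f \cdot \tfrac{3}{2} \;=\; 1 + \tfrac{f}{2}$$

before renormalisation over the genome. At $f \approx 0.10$ this is a
~5% excess — invisible per read, detectable in aggregate at millions of
reads per sample.

The detection statistic is a per-chromosome z-score. Each sample $s$ is
summarised by a representation statistic $x_{sc}$ per chromosome $c$
(see *Representation modes* below); a reference panel of $n$ euploid
pregnancies provides $\mu_c$ and the sample standard deviation $\sigma_c$
(denominator $n-1$), and

$$z_{sc} = \frac{x_{sc} - \mu_c}{\sigma_c}.$$

A sample is called trisomic for the target chromosome when $z$ strictly
exceeds a cutoff. Cutoffs are chosen by the interactive dot-diagram
procedure: every observed $z$ value is scanned as a candidate cutoff for
the rule "positive iff $z > \text{cutoff}$" and the Youden index
(sensitivity + specificity − 1) is maximised; ties go to the largest
qualifying cutoff, so with perfectly separated groups the cutoff equals
the maximum of the negative group.

## Pipeline stages and their parameters

| Stage | Parameter | Default | Why |
|---|---|---|---|
| 3' trimming | quality threshold | Phred 15 | trailing bases with quality ≤ 15 are removed; no windowed (Mott) trimming — the simplest reading of a "trim by quality > 15" rule |
| length filter | minimum length | 50 bp | reads shorter than 50 bp after trimming are discarded; exactly 50 bp is retained (the removal predicate is "< 50 bp") |
| GC filter | window | [0.35, 0.45], inclusive | per read, on the retained (trimmed) bases; ambiguous bases count as non-GC |
| unique mapping | predicate | primary, not supplementary, MAPQ > 0 | "uniquely mapped" is operationalised, not standardised; the predicate is swappable (`unique_rule`) |
| duplicate removal | key | (chromosome, 0-based 5' start, strand) | single-end positional duplicates, the same key Picard reduces to for single-end data; first record after a stable sort is kept, making the operation deterministic and idempotent |
| binning | bin size | 300 kb | fixed-width, half-open bins; each read increments exactly one bin by its 5'-most mapped coordinate |
| z-score | panel SD | sample SD (n − 1) | matches standard practice; at n = 139 the difference from the population SD is < 0.4% |
| CIs | method | exact (Clopper–Pearson) | see *Exact versus Wilson* below; `wilson` available |

Coordinates are 0-based half-open internally; SAM input (1-based) is
converted once at the reader (`read_alignments_sam()`). The shipped hg19
layout covers chr1–22, chrX, chrY only; unplaced and alternate contigs
are excluded, and any layout (including toy genomes) can be supplied as a
two-column TSV.

## Representation modes

The z-score formula can consume raw per-chromosome read counts
(`mode = "count"`) or the chromosome's fraction of the sample's total
autosomal count (`mode = "fraction"`, the default). Raw counts confound
sequencing depth: two samples of identical karyotype but different yield
get different counts on every chromosome, inflating the panel SD and
blunting the statistic. The fraction mode removes depth and, by using an
autosome-only denominator, also removes the fetal-sex shift that chrX/chrY
reads would otherwise inject into the total. The count mode is retained to
reproduce the formula literally; the choice is surfaced in every profile
and panel artifact and mode mismatches are errors.

## The euploid reference panel

The panel is built from all samples labelled euploid, and every sample —
including each panel member — is scored against it. This matches the
design in which 139 euploids serve as the reference for all 155 z-scores.
In-panel scoring makes the panel members' z-scores standardised exactly
(mean 0, sample SD 1 — an algebraic identity the tests assert to 1e-9)
but slightly shrinks outliers, since a sample's own value contributes to
its panel mean and SD. A `leave_one_out` option rescores panel members
against the panel rebuilt without them; it is off by default.

## Exact versus Wilson intervals

Both binomial interval methods are implemented. For an all-success
observation ($k = n$) the exact lower bound is $(\alpha/2)^{1/n}$ and
Wilson's is $n/(n + z_{\alpha}^2)$ with $z_{\alpha} = 1.959964$. The
published feasibility tables this pipeline emulates are numerically
consistent with the exact method (5/5 successes gives a 47.8% lower
bound; Wilson would give 56.6%), so the report defaults to exact while
`ci_wilson()` covers the stated alternative. The two bounds cross: the
exact bound is the more conservative (smaller) one only up to $n = 45$;
beyond that Wilson is lower — which is why the all-success sample-size
planner needs fewer samples under the exact method (183 versus 189 for a
98% lower bound at 95% confidence). Report percentages are rounded half
away from zero to one decimal, the convention of the printed tables.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults encode the cohort the analysis is designed for:
139 euploid / 5 trisomy-18 / 11 trisomy-21 pregnancies, 6.5 million raw
reads per sample of which 59% map uniquely, read lengths ~150 bp (SD 15),
and a per-sample fetal fraction drawn from a normal with mean 0.10
truncated to (0, 1). The fetal-fraction SD default of 0.02 keeps
essentially all positives above $f = 0.04$; this emulates a cohort in
which positives separate completely from euploids (minimum positive z
above 4), which is the regime the dot-diagram cutoff rule presumes.
Population surveys of fetal fraction show a wider spread; widening
`fetal_fraction_sd` produces low-$f$ positives that no cutoff can rescue,
which is exactly the known failure mode of z-score NIPT without a
fetal-fraction QC gate. The duplicate rate (0.05) and the per-read GC
target (0.40, SD 0.02) are typical of shallow single-end cfDNA libraries.

Counts are drawn as a single multinomial over the bin grid with
length-proportional (optionally GC-weighted) bin probabilities, the
trisomic chromosome scaled by $(1 + f/2)$. This captures the first-order
statistical structure — multinomial sampling noise and the dosage shift —
but deliberately not: mappability and GC *coverage* bias along the genome
(real pipelines see structured, not exchangeable, bin noise), maternal or
placental mosaicism, maternal copy-number variants, or sequencing error
at the base level realistic enough for variant calling. Passing tests on
this generator therefore demonstrate the statistical machinery, not
robustness to real-data artefacts.

The read-level generator (`simulate_reads()`) exists to exercise the QC
stage end to end: 3' low-quality tails (`quality = list(body_q, tail_q,
tail_len)`), per-read GC targets, exact positional duplicates and a
non-unique share, with a truth table that makes every filter's retained
set computable by brute force in tests.

## Numerical and degenerate-input choices

- Candidate cutoffs are the **observed z values themselves**, not
  midpoints between them: this is what makes a selected cutoff coincide
  exactly with the euploid maximum under perfect separation. Youden ties
  break to the largest cutoff; equality at the cutoff is a negative call
  (strict `>`).
- A panel with fewer than two euploid samples, or zero SD on any scored
  chromosome, is an error, not a silent NaN.
- Zero denominators in PPV/NPV yield `NA` ("not available"), not errors.
- Trimming may empty a read; the GC filter runs after the length filter
  so it never sees empty reads (an empty read there is an error).
- Truncated-normal draws use the inverse-CDF transform, so a config
  consumes a fixed number of uniforms and identical config + seed gives
  bit-identical cohorts; `fetal_fraction_sd = 0` degenerates to the mean.
- Fraction-mode profiles error on a zero autosomal total.

## Problem sizes used in the tests

The statistical property tests run on a three-chromosome toy genome
(60/30/10 Mb, the 10 Mb chromosome playing the trisomy analog, 1 Mb
bins): calibration uses 500 panel + 500 held-out euploids at 50,000
retained reads; the power property uses 100 seeded replicates of a
44-sample cohort at 200,000 retained reads and mean fetal fraction 0.10.
The acceptance script runs the full study design — 155 samples at 6.5 M
reads on the hg19 300 kb grid — which is still only seconds of work,
since the per-sample cost is one multinomial draw over ~10,300 bins.

## Known limitations

- No fetal-fraction estimation: samples whose true $f$ is too low for
  the depth are undetectable and the pipeline does not flag them.
- No GC LOESS correction or bin-level segmentation; GC handling is the
  read-level filter only, and calls are chromosome-level only.
- Thresholds selected by the dot diagram are optimised on the same data
  they are evaluated on; training-set predictive values of 100% carry the
  usual in-sample optimism, and the report documents the selection mode.
- The combined-detection summary pools both trisomies over the same
  cohort; it is not an independent test of either.
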