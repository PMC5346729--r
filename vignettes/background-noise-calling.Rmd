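---
title: "Calling low allele-fraction variants against local background noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling low allele-fraction variants against local background noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauvc)
library(GenomicRanges)
```

## The problem

Tumor samples are genetically heterogeneous: a clinically relevant mutation
may be carried by a small subclone, or be diluted by healthy tissue, so its
variant allele fraction (VAF) in a targeted sequencing experiment can sit at
a few percent — the same order as the combined error level of PCR, the
sequencer and alignment. Matched-normal callers sidestep this by contrasting
tumor against normal tissue, but a matched sample is often unavailable in
diagnostic practice. `tauvc` addresses the tumor-only setting the way an
experienced reviewer inspects an alignment: it first measures how noisy the
sequencing is *around* each candidate, then asks whether the candidate stands
out from that local noise.

## The model

For one target region (typically an exon), the pileup is reduced to the
per-position count of alternative-allele reads, $x_1, \dots, x_m$. Around a
candidate at position $p$, a window of `windowBp` bases (default 200, i.e.
$\pm 100$) is taken, the candidate's own position is excluded, and all zero
counts are removed. The remaining counts are a sample of the local error
process, possibly contaminated by true variants elsewhere in the window.
Those contaminants are removed by the **modified Thompson Tau test**,
applied iteratively: at each step compute the sample mean $\bar x$ and
standard deviation $S$, find the single most-suspect point (maximal
$\delta_i = |x_i - \bar x|$), and reject it iff

$$\delta_i > \tau S, \qquad
  \tau = \frac{t_{\alpha/2}\,(n-1)}{\sqrt{n}\,\sqrt{n - 2 + t_{\alpha/2}^2}},$$

where $t_{\alpha/2}$ is the upper $\alpha/2$ quantile of Student's $t$ with
$n-2$ degrees of freedom and $\alpha$ defaults to 0.001. The procedure
repeats on the reduced sample until the most-suspect point is retained. The
**local background noise** is the largest surviving count; the **noise
rate** divides it by the mean depth over the window.

A candidate with $c$ supporting reads is promoted past the **statistical
step** iff $c$ is *strictly* greater than the noise count. It is then
subject to four quality filters, each recorded independently:

1. its VAF must exceed `noiseMultiplier` (default 2) times the noise rate
   (`low_ratio_vs_noise`);
2. the mean Phred score of its supporting bases must be strictly greater
   than 20 (`low_mean_qual`);
3. the standard deviation of those Phred scores must be strictly below 7
   (`high_qual_sd`);
4. the fraction of its reads on the forward strand must lie in
   $[0.30, 0.70]$, bounds inclusive (`strand_imbalance`).

Candidates failing a filter are still written to the VCF with their failed
tags (use `passOnly = TRUE` or `--pass-only` to suppress them); candidates
failing the statistical step are considered part of the noise and produce
no record at all.

Inverting the two calling criteria gives the **limit of detection** at a
position with depth $d$, noise count $k$ and noise rate $r$:

$$\mathrm{LOD}(p) = \max\!\left(2r,\ \frac{k+1}{d}\right),$$

the smallest VAF that a clean variant there could have been reported with.
`lodReport()` summarises it per region (mean and worst case) or per
position; `positionReport()` answers the converse question — what exactly
was seen at one locus.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.001 | two-tailed risk of the Tau test; larger values trim more aggressively |
| `windowBp` | 200 bp | total span of the noise window; it should be wide enough to hold a few dozen covered positions but local enough to track error heterogeneity |
| `noiseMultiplier` | 2 | safety factor of the rate filter |
| `minMeanPhred` | 20 | strict lower bound on mean supporting quality |
| `maxPhredSd` | 7 | strict upper bound on supporting-quality SD |
| `strandBalanceLow/High` | 0.30 / 0.70 | inclusive bounds on the forward-read fraction |
| `vafMinSnv` / `vafMinIndel` | off | optional reporting cutoffs (e.g. 1% / 2%) applied to emitted records only, never inside the algorithm |

All are set via `callerConfig()` or the corresponding CLI flags, and every
run echoes its effective values into `##parameter=` VCF header lines.

## Numerical and design choices

Several details are deliberate choices where more than one convention is
defensible:

* **Standard deviation.** $S$ is the sample ($n-1$ denominator) standard
  deviation, the standard convention of the Thompson Tau test.
* **Degenerate samples.** The test needs $n \ge 3$ (df $= n-2$); with fewer
  nonzero counts the trimming is skipped and the raw maximum is used (0 for
  an empty sample). When $S = 0$ the test stops (no point can exceed
  $\tau \cdot 0$ by the strict inequality).
* **Ties.** Points tied at the maximal deviation are tested as one group
  and removed together, making the result invariant under input
  permutations.
* **Candidate exclusion.** The candidate position's own alternative count
  is removed from its noise sample before trimming: the noise sample is
  meant to characterise the surroundings, and a strong true variant would
  otherwise inflate its own noise estimate. `includeCenter = TRUE` restores
  the pooled behaviour.
* **Noise sample pooling.** Counts are pooled over all alternative alleles
  per position (substitutions and indels together), matching the idea of a
  single per-position "variant reads" list.
* **Noise rate denominator.** The mean declared depth over the window; the
  rate-space filter then compares like with like.
* **Single-read qualities.** The SD of one quality value is defined as 0,
  so filter 3 passes; a single-read candidate still fails the strand
  balance filter (fraction 0 or 1), which is the worded behaviour and is
  noted for users.
* **Indel qualities.** The pileup text carries no per-indel quality, so the
  anchor base's quality stands in for each indel-supporting read; it is the
  only quality observable for the event in this input format.
* **Filter emission.** Filter-failing candidates are emitted with FILTER
  tags rather than dropped — diagnostically useful and reversible with
  `--pass-only`.
* **Concurrency.** Regions are processed serially; output ordering and
  content are therefore identical for any `--threads` value.

## What the simulator emulates — and what it does not

`simulationConfig()` / `simulateProfiles()` generate pileups that emulate a
targeted capture experiment: per-position depth (fixed, or Poisson around
the mean), a uniform per-base substitution error rate (default 0.1%,
typical of Illumina data after alignment) spread uniformly over the three
non-reference bases and both strands, and injected variants drawn
binomially at their target VAF. Correct bases draw Phred scores from
$N(35, 3)$ and error bases from $N(25, 6)$, both clipped to $[2, 41]$ —
chosen so the default quality filters are exercised but not trivially
decisive. Injected variant reads are split across strands
*deterministically* at the configured forward fraction, so the
strand-balance filter responds to the configured bias rather than to
binomial sampling noise; error reads get Bernoulli(½) strands.

The simulator intentionally omits several properties of real data: FFPE
deamination artifacts (systematic C>T/G>A damage that no caller can fully
correct from sequence alone), mapping-error hotspots that produce recurrent
false positives in real panels, overdispersed strand ratios, correlated
errors within reads, and polymerase-slippage indel errors. Passing tests on
simulated data therefore demonstrate the statistical machinery —
noise estimation, trimming, filtering, LOD inversion — not robustness to
alignment pathology.

## Validation problem sizes

The package validates itself at desk scale, chosen to keep the full suite
in a few minutes while leaving Monte-Carlo margins interpretable: the Tau
critical value is checked against an independent quantile inversion for
$n \in [3, 200]$ and $\alpha \in \{0.1, 0.01, 0.001\}$ to $10^{-9}$;
trimming against a literal reimplementation on 1,000 random samples of
size 3–50; calling on fixed-seed simulations at 1000× with 0.1% error
(injected VAF ≥ 5% always called; ≤ 5 false PASS calls per 10,000
pure-noise positions); and the coverage–sensitivity profile on
100 replicates per cell over representative depths 100×, 225×, 450×, 800×
and 1200× with injected VAFs of 1, 2 and 5%. Under those conditions
sensitivity is monotone in depth, 5% variants are reliably detected from
the 150–300× bin upward, and 2% variants above 1000×.

## Worked example

```{r example}
region <- GRanges("chr7", IRanges::IRanges(55242401, 55242600))
sim <- simulateProfiles(simulationConfig(
  regions = region, depth = 1200, errorRate = 0.001,
  variants = data.frame(chrom = "chr7", pos = 55242500, alt = "T",
                        vaf = 0.02),
  seed = 11))
calls <- callVariants(sim$profiles)
subset(calls, filter == "PASS")
lodReport(sim$profiles)
```

## Limitations

Beyond the simulator's idealisations listed above: the caller assumes a
single sample (no tumor/normal contrast, no joint genotyping); the noise
model pools both strands (a strand-specific error process is only caught
by the balance filter); indels are judged on anchor-base qualities; and the
LOD formula inverts only the statistical step and the rate filter — a
variant above the LOD can still fail the quality or strand filters if its
reads are genuinely poor.
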