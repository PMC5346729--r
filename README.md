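# tauvc — tumor-only low allele-fraction variant calling

`tauvc` calls single-nucleotide variants and indels from **non-matched
(tumor-only) targeted sequencing** data, down to allele fractions of a few
percent, by statistically estimating the *local* sequencing background
noise instead of applying a global threshold. It is aimed at diagnostic
and research settings where no matched normal sample exists and where the
relevant mutation may be carried by a small tumor subclone.

## Method

For a window of `w` bp (default 200) centered on each candidate, the
per-position alternative-read counts are collected, zeros removed, and the
sample is trimmed by the **iterative modified Thompson Tau test**: with
sample mean x̄, standard deviation S and size n, the most-deviant point
(maximal δᵢ = |xᵢ − x̄|) is rejected iff

    δᵢ > τ·S,   τ = t(α/2, n−2) · (n−1) / ( √n · √(n−2+t²) )

with α = 0.001 by default, repeating until no outlier remains. The largest
surviving count is the local **background noise**; a candidate is called
only if its supporting-read count strictly exceeds it (statistical step)
and then passes four quality filters: VAF > 2× the noise rate, mean Phred
> 20, Phred SD < 7, and a forward-strand fraction within [30%, 70%].
Filter-failing candidates are written to the VCF with FILTER tags;
`--pass-only` suppresses them.

Two auxiliary modes answer routine diagnostic questions: `lod` reports the
**minimum detectable allele ratio** per BED region or single position
(`max(2·noiseRate, (noiseCount+1)/depth)`), and `query` prints the raw
metrics of one locus (depth, alleles, strand counts, qualities, local
noise).

A built-in simulator (`simulate`, `bench-sensitivity`) generates pileups
with known truth — configurable depth, error rate and injected variants —
for validation and coverage planning; `downsampleProfile()` performs
in-silico read thinning.

## Input

`tauvc` reads samtools mpileup text (one sample, six columns, Phred+33)
over your target regions:

```sh
samtools mpileup -f ref.fa -l targets.bed sample.bam > sample.pileup
```

Note samtools applies its own base-quality floor (`-Q`, default 13) before
emitting the pileup; `tauvc` does not apply a second one.

## Worked example

```sh
tauvc=$(Rscript -e 'cat(system.file("scripts","tauvc",package="tauvc"))')

# simulate a 200-bp exon at 1200x with a 2% VAF mutation (sim.yaml:
# regions chr7:55242401-55242600, depth 1200, error_rate 0.001,
# one variant chr7:55242500 C>T vaf 0.02, seed 11)
Rscript $tauvc simulate --config sim.yaml --out egfr
printf 'chr7\t55242400\t55242600\tEGFR_ex19\n' > targets.bed

Rscript $tauvc call --pileup egfr.pileup --bed targets.bed \
        --out egfr.vcf --sample patient1
# call: 1 region(s), 2 call(s) after statistical step, 1 PASS -> egfr.vcf
```

The VCF body shows one sequencing artifact caught by the filters and the
injected mutation passing:

```text
chr7  55242480  .  C  T  .  low_ratio_vs_noise;strand_imbalance  DP=1200;AO=5;AF=0.00416667;SAF=0;SAR=5;MQS=26.2;SQS=4.76445;NC=3;NR=0.0025
chr7  55242500  .  C  T  .  PASS                                 DP=1200;AO=21;AF=0.0175;SAF=10;SAR=11;MQS=35.381;SQS=3.21677;NC=3;NR=0.0025
```

Read: at chr7:55242500 the C>T variant is supported by 21 of 1200 reads
(VAF 1.75%), balanced across strands (10/11), with high, uniform base
qualities (mean 35.4, SD 3.2), against a local background noise of 3 reads
(rate 0.25%) — a confident low-fraction call. The 5-read candidate at
55242480 sits below twice the noise rate and is all-reverse, so it is
tagged, not passed.

```sh
Rscript $tauvc lod --pileup egfr.pileup --bed targets.bed --out egfr.lod.tsv
# target     mean_depth  mean_noise_rate  lod_mean    lod_max
# EGFR_ex19  1200        0.00252          0.00504     0.00667

Rscript $tauvc query --pileup egfr.pileup --position chr7:55242500
# depth=1200  ref=C  alt=T  alt_count=21  alt_fwd=10  alt_rev=11
# mean_qual=34.9167  noise_count=3  noise_rate=0.0025
```

So on this sample any variant above ~0.5–0.7% VAF was detectable in this
exon. The same operations are available in R: `parsePileup()`,
`parseBed()`, `callVariants()`, `writeVcfCalls()`, `lodReport()`,
`positionReport()`, `simulateProfiles()`, `sensitivityHarness()`. See the
vignette (`vignettes/background-noise-calling.Rmd`) for the model,
parameter meanings and design choices.

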