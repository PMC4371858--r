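---
title: "Methods: somatic mtDNA signatures, selection and drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic mtDNA signatures, selection and drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the models it implements, the
choices behind their parameters, and what the synthetic-data tests do and
do not establish.

## Coordinate and strand conventions

The reference sequence is stored on the light (L) strand, 1-based and
circular: position arithmetic wraps modulo the genome length, and features
may span the origin (`end < start`). Heavy (H) strand alleles and contexts
are reverse complements of the stored sequence. Protein translation uses
the vertebrate mitochondrial genetic code (NCBI table 2; TGA = Trp,
ATA = Met, AGA/AGG = stop), read on the coding strand of each gene — the
strand whose sequence equals the mRNA sense. Overlapping genes are
annotated once per containing gene; downstream counts use the most severe
consequence (`worstConsequence()`).

## QC and contamination

Sample swaps are flagged when the tumor's genotype mismatch rate at
normal-homozygous common-SNP sites, $(N_{het}+N_{wt})/(N_{hom}+N_{het}+N_{wt})$,
exceeds 0.1. A perfectly matched pair gives 0. For a panel of
minor-allele-frequency ≈ 0.5 sites, an unrelated individual is expected to
be heterozygous at about half the sites and homozygous reference at a
quarter, so the expected mismatch rate for a true swap is about 0.75 —
comfortably above the threshold either way.

Minor cross-contamination is estimated from wild-type reads at those same
homozygous sites. A contaminant contributes wild-type alleles at roughly
half of its reads (it is heterozygous or homozygous-reference at most such
sites), giving

$$\hat C = \frac{2\,(\sum RC_{wt} - N_e)}{\sum RD_{hom} - N_e},
\qquad N_e = e \cdot \sum RD_{hom},$$

with $e$ the assumed sequencing error rate (default 0.001) and the error
reads pooled across sites rather than per site. The 95% CI is
Clopper–Pearson on $\sum RC_{wt}$ propagated through the same formula, and
the somatic VAF floor is 5× its upper bound (fallback 0.10 when the
estimate is unavailable). The estimator is scale-invariant in depth; depth
only narrows the CI.

## The somatic filter chain

Candidate non-reference alleles at each tumor site pass when **all** of
the following hold: at least 4 Q20 variant reads, or 3 with VAF ≥ 20%
(tagged `low_read_rescue`); VAF ≥ 3% (VAF = variant reads / (variant +
reference Q20 reads)); at most 90% of variant reads on one sequencing
strand, unless the perfect-match (reference-read) strand bias differs from
the mismatch bias by less than 0.1 (tagged `strand_bias_rescue`, for
regions where only one read orientation aligns); the position+allele is
not one of the 13 recurrent homopolymer/reference-error artifacts; VAF
exceeds the per-sample contamination floor; and the allele is essentially
absent in the matched normal (VAF < 1% — the normal-side threshold is not
fixed by any published rule, so it is exposed as `normal_max_vaf`). Indels
pass through the same read-count and VAF thresholds. Every failing rule is
recorded, so pipeline reports reconcile exactly: candidates = passed +
attributed failures.

Phasing of nearby pairs counts spanning-read haplotypes. A haplotype
"observed" requires ≥ 2 supporting reads (`min_phasing_reads`,
configurable — a single chimeric or error read should not change a call):
co-clonal = only wt1-wt2 and subs1-subs2; different copies = both
single-mutant haplotypes without the double mutant; sub-clonal = the
double mutant plus exactly one single-mutant haplotype, the variant whose
single-mutant haplotype is missing being the later one.

## Strand-resolved signatures

Each substitution is assigned to the strand carrying the mutated
pyrimidine: 12 classes (6 pyrimidine changes × 2 strands) or 192 (× 16
flanking combinations). Counts are normalized by context opportunities —
the number of region positions whose pyrimidine-strand (tri)nucleotide
matches the class — giving per-class rates on the circular genome. The
strand-bias summary reports, per change, the H-strand share of mutations,
the L:H opportunity ratio, and their product identity
$\text{fold} = \frac{h}{1-h}\cdot\frac{opp_L}{opp_H}$.

Replicative vs transcriptional causation is separated by labelling the
same gene-region mutations two ways — by physical strand, and by
coding/template strand of the containing gene — and scoring each labelling
against a background signature with a chi-square statistic whose expected
counts are proportional to background rate × local opportunity (a small
floor keeps the statistic finite when a labelling places mutations where
the background has no mass). Building the background from genes coded on
one strand and scoring the opposite-strand gene subset discriminates the
two models, because the labellings coincide on the background set and
diverge on the test set.

The Ori-b–O_H segment (defaults 16197 and 191 for rCRS-like coordinates;
boundary positions inside) wraps the origin; under bidirectional
replication initiation the leading/lagging roles reverse there, so its
signature appears strand-swapped relative to the rest of the genome.
`dloopSegmentSignature()` computes both parts; counts are additive with
the whole-genome table.

## Poisson dN/dS

Substitution classes for selection are directional changes on the L strand
(12, or 192 with L-strand flanks) — directional because the mutational
process is strand-asymmetric, and keyed independently of the signature
module's pyrimidine representation. Opportunity counts $L_{syn,k}$,
$L_{mis,k}$, $L_{non,k}$, $L_{stoploss,k}$ enumerate every possible change
at every protein-coding position. The likelihood is a product of Poisson
terms with $\lambda_{syn,k} = r_k L_{syn,k}$ and
$\lambda_{mis,k} = r_k w_{mis} L_{mis,k}$ (and
$\lambda_{non,k} = r_k w_{non} L_{non,k}$ when the nonsense coefficient is
fitted; stop-loss sites fold into the missense class by default — they are
rare and behave like severe missense).

Maximization is a hill climb: coordinate ascent alternating the closed-form
conditional updates
$r_k = N_{\cdot,k} / (L_{syn,k} + w_{mis} L_{mis,k} + w_{non} L_{non,k})$
and $w = \sum_k N_{mis,k} / \sum_k r_k L_{mis,k}$, from 5 random restarts,
stopping when the log-likelihood improves by less than $10^{-8}$. Each
update cannot decrease the likelihood, and the tests verify agreement with
a dense grid search over the profile likelihood to three decimals.
Neutrality is tested by an LRT with one chi-square df per selection
parameter; 95% CIs are profile likelihood (bisection on the
half-chi-square drop), with the search bracketed in $[10^{-4}, 10^{4}]$.
The model is unidentifiable without synonymous observations, which is an
error rather than a silent estimate.

The tRNA anticodon test weights each tRNA site by its summed signature
rate, apportions the observed tRNA mutation total by the anticodon share
of that weight, and uses a two-sided exact Poisson tail (doubled smaller
tail). Recurrence is keyed by position by default (allele-keying is
available) and compared to Monte-Carlo placements under a uniform or
signature-weighted null, with an occupancy closed form as the test oracle;
the group-resampling comparison reuses the iterated draw-and-count design
with a one-way ANOVA. That design reuses fixed groups across iterations,
which makes it sensitive to small real differences between the groups —
the null calibration in the tests is set accordingly. VAF comparisons use
two-sided Wilcoxon rank-sum tests.

## Sequence evolution to stationarity

`evolveSequence()` interprets the 12- or 192-class rate table as per-site,
per-generation substitution probabilities. Each generation, every site
mutates independently with probability equal to the summed rate of its
three possible changes given its current trinucleotide context; the target
base is chosen in proportion to the class rates. Sites hit within one
generation are applied sequentially with context re-evaluation. This
synchronous per-site scheme was chosen over drawing a Poisson number of
single events per generation because it vectorizes in R and has the same
stationary behaviour — which is the quantity the simulation exists to
produce; since rates only enter as per-generation probabilities, their
overall scale sets the time resolution, not the stationary state.
Stationarity is declared when the total-variation distance between 3-mer
compositions sampled `window = 100` generations apart falls below
$10^{-3}$ (configurable); a generation cap bounds the run regardless.

Under the `synonymous_only` constraint, a proposal inside any protein
feature is rejected unless every containing gene's codon keeps its amino
acid (stop may exchange for stop), holding the proteome byte-identical —
the mutation–selection equilibrium configuration. For a context-free
12-class table the per-site process is a 4-state Markov chain whose
stationary distribution is the eigenvalue-1 left eigenvector of the
transition matrix; `stationaryComposition()` computes it analytically and
the tests require the simulated composition to match within 1% (run at
10 kb with a 4000-generation cap and rates scaled so a site mutates with
probability of order $10^{-2}$ per generation — comfortably past mixing).

Codon skew counts third-position bases per strand gene group,
$T{>}C\,\text{skew} = (N_C - N_T)/(N_C + N_T)$ and
$G{>}A\,\text{skew} = (N_A - N_G)/(N_A + N_G)$, plus NNA:NNG and NNT:NNC
ratios within synonymous codon families. L- and H-strand genes are
reported separately because they sit under opposite mutational pressure.

## Wright–Fisher drift

A cell carries a fixed number $M$ of mtDNA copies; each cell generation
resamples every segregating site's mutant count as Binomial$(M, X/M)$,
with absorbing states at 0 and $M$ (homoplasmy). New mutations enter as
Poisson$(\mu L M)$ events on single genome copies; sites evolve
independently (the marginal single-site model) and multiple hits at one
site are not modelled within a run. Neutral theory gives fixation
probability $\rho = X/M$, conditional fixation time $\approx 2M$
generations, and the delayed-accumulation closed form
$E[N] = \mu L (T - 2M)$ for the expected homoplasmic count —
`expectedHomoplasmic()` returns 0 with a warning for $T < 2M$, where the
approximation has not begun. The Monte-Carlo checks in the tests and
acceptance script verify all three against simulation (the discrete-time
conditional fixation time at small $M$ sits somewhat below $2M$, within
the 15% band used). Note that with $\mu = 10^{-7}$/bp/division and
$L = 16569$, the supply $\mu L \approx 1.66\times10^{-3}$ per division
implies roughly one homoplasmic mutation per thousand cell generations
once $T \gg 2M$.

## The synthetic-data generator

The generator defines the package's test conditions:

* **Genomes** — random circular sequences with ORF-valid protein genes
  (ATG start, no internal stop under the mitochondrial code), tRNAs with
  anticodon triplets, an rRNA, and a control region placed across the
  origin (exercising circular arithmetic); default 3 kb with a 12:1-like
  L:H protein-gene split at miniature scale.
* **Cohorts** — substitutions placed with probability ∝ class rate ×
  context opportunity under a 192-class preset qualitatively shaped like
  the somatic mtDNA process (H-strand C>T dominant, ~10× at NpCpG;
  L-strand T>C next, ~6× at NpTpC; small floor elsewhere — illustrative
  presets, not calibrated estimates). Strand roles swap inside the
  configured origin segment when the inversion flag is set. Heteroplasmy
  comes from fixed, uniform, or Wright–Fisher-drift VAF models (the drift
  model conditions on allele survival).
* **Pileups** — Poisson depth, binomial variant reads at the
  contamination-adjusted VAF, uniform sequencing errors, even strand
  splitting; matched normals carry only germline sites. Homozygous-SNP
  panels and genotype panels carry the contamination/swap signal.
* **Phasing reads** — multinomial haplotype counts for co-clonal,
  sub-clonal and different-copy configurations.

Passing tests on these data shows the estimators invert the generative
models they assume. Real sequencing data differ in ways the generator
deliberately omits: alignment artifacts beyond the fixed blacklist,
context-dependent and strand-correlated error, depth heterogeneity along
the genome, NuMT contamination (handled in practice by the 3% VAF floor),
linked heteroplasmies, and indel realignment noise. Results on real data
therefore depend on upstream alignment quality in ways these tests cannot
certify.

## Problem sizes and determinism

Test and acceptance runs use deliberately small configurations — 1.2–3 kb
genomes, cohorts of tens to hundreds of samples (≥ 5000 variants where
recovery is asserted), $10^4$–$10^5$ drift replicates, 10 kb × ≤ 4000
generations of sequence evolution, ~100 selection fits for CI coverage —
sizes at which every Monte-Carlo tolerance asserted is comfortably
resolved. All generators and simulators consume explicit seeds and restore
the caller's RNG state; a pipeline run is byte-reproducible given its
seed.

## Known limitations

* The filter chain consumes allele-count pileups; it does not realign
  reads or recalibrate qualities, and the blacklist is a fixed site list
  rather than a homopolymer model.
* The dN/dS model shares one $w$ across genes by default; per-gene fits
  simply restrict the opportunity and observed tables (`genes =`).
* The transcriptional/replicative comparison assumes a trustworthy
  background signature; with few mutations the chi-square discrimination
  is weak.
* The drift model is neutral and single-cell; clonal expansion is assumed
  to preserve allele frequencies, and selection on heteroplasmy level is
  outside the model.
* The evolution simulator holds sequence length fixed (substitutions
  only); indel-driven composition change is out of scope.
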