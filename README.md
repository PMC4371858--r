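# mitosig

Somatic mitochondrial DNA mutations in cancer behave very differently from
nuclear ones: sequencing a tumor/normal pair covers the 16.6 kb circular
mitochondrial genome thousands of times over, so heteroplasmic variants can
be called down to a few percent allele fraction, and the mutations that
emerge are dominated by a single, strongly strand-asymmetric endogenous
process — C>T on the heavy (H) strand and T>C on the light (L) strand,
coupled to the asymmetric mechanism of mtDNA replication. `mitosig` is an R
package for the full analysis chain around that observation, aimed at
anyone working with tumor/normal mtDNA allele-count data:

* **QC and contamination** — sample-swap detection from a homozygous-SNP
  genotype panel; minor cross-contamination estimated from wild-type reads
  at homozygous sites, `C = 2(ΣRC_wt − Ne)/(ΣRD_hom − Ne)` with a
  Clopper–Pearson CI, feeding a per-sample VAF floor (5× the upper bound);
  known-polymorphism and back-mutation sample filters.
* **Somatic variant filtering** — the heteroplasmy-aware filter chain on
  tumor/normal pileups: ≥4 Q20 variant reads (3 with VAF ≥ 20% via a
  low-read rescue), VAF ≥ 3%, a one-sided strand filter with a
  perfect-match-bias rescue, a 13-site homopolymer blacklist, the
  contamination floor, and matched-normal exclusion; plus read-backed
  phasing of nearby variant pairs (co-clonal / sub-clonal / different
  strand).
* **Mutational signatures** — strand-resolved 12- or 192-class
  (trinucleotide-context) signatures normalized by context opportunities
  on the circular genome; strand-bias summaries
  (`rate fold = hShare/(1−hShare) × composition ratio`); replicative vs
  transcriptional strand-model comparison by chi-square against a
  background signature; and the Ori-b–O_H segment analysis, where
  bidirectional replication inverts the leading/lagging strand roles.
* **Selection inference** — context-dependent Poisson dN/dS: per-class
  rates `λ_syn,k = r_k L_syn,k`, `λ_mis,k = r_k w_mis L_mis,k`
  (optionally `w_non`), maximum likelihood by hill climbing, LRT against
  neutrality and profile-likelihood CIs; tRNA anticodon depletion test;
  recurrence analysis against uniform or signature-weighted Monte-Carlo
  nulls; VAF comparisons across consequence classes.
* **Evolutionary simulation** — sequence evolution under a signature to
  stationary composition, unconstrained or proteome-preserving
  (synonymous-only), with an analytic 4-state Markov stationary
  distribution as a cross-check; codon-usage skew statistics
  (`T>C skew = (N_C−N_T)/(N_C+N_T)`, `G>A skew = (N_A−N_G)/(N_A+N_G)`).
* **Heteroplasmy drift** — a Wright–Fisher model of the M genome copies in
  a cell: binomial resampling, absorption at loss/homoplasmy, fixation
  probability ρ = X/M, conditional fixation time ≈ 2M, and the closed form
  `E[N] = μL(T − 2M)` for homoplasmic mutation accumulation.

A synthetic-data module generates circular annotated genomes (valid ORFs
under the vertebrate mitochondrial code), signature-driven cohorts with
drift-derived heteroplasmy, binomial pileups with sequencing error, phasing
read evidence, genotype panels, and injectable swaps/contamination — so the
whole pipeline runs end-to-end with no external data.

## Worked example

```r
library(mitosig)

sim   <- simulateReference(length = 3000, seed = 7)
truth <- simulateCohort(sim$ref, sim$annotation, nSamples = 60,
                        mutationRate = 10, seed = 8)
piles <- simulatePileups(truth, depth = 1000, errorRate = 0.001, seed = 9)
calls <- callSomatic(piles$tumor, piles$normal, vafFloor = 0.01)
cat("called", nrow(calls), "of", nrow(truth$variants), "true variants\n")
#> called 621 of 622 true variants

sig12 <- computeSignature(calls, sim$ref, nclass = 12L)
strandBiasSummary(sig12)$by_class[c(3, 5), ]
#>   sub n_H n_L    h_share comp_ratio   rate_fold
#> 3 C>T 371   4 0.98933333   1.038043 96.27853261
#> 5 T>C  11 139 0.07333333   1.021563  0.08084314

opp <- opportunityCounts(sim$ref, sim$annotation, nclass = 12L)
obs <- observedCounts(calls, sim$ref, sim$annotation, nclass = 12L)
fitDnds(obs, opp)
#> SelectionFit (12-rate model)
#>   w_mis = 1.163 (95% CI 0.926-1.47)
#>   logLik = -39.1967, LRT stat = 1.674, p = 0.1957

ft <- fixationTimeCheck(M = 10, reps = 20000, seed = 1)
cat(sprintf("conditional fixation time: %.1f generations (2M = %d)\n",
            ft$mean_time, ft$reference))
#> conditional fixation time: 17.1 generations (2M = 20)
```

Reading the output: the filter chain recovers essentially every simulated
variant at depth 1000 with no false calls; the 12-class signature shows the
expected extreme asymmetry — virtually all C>T mutations carry the
pyrimidine on the H strand while T>C sits on the L strand, and after
opportunity normalization the per-strand rate folds are far from 1; the
dN/dS fit on this neutral cohort is compatible with w = 1 (CI spans 1, LRT
p = 0.2); and drift of a new single-copy mutant among M = 10 genome copies
fixes, when it fixes, in roughly 2M generations.

For an end-to-end run with per-stage outputs and a JSON summary:

```r
cfg <- defaultPipelineConfig()
cfg$outdir <- "out"
res <- runPipeline(cfg)
```

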