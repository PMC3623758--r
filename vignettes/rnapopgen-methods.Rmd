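---
title: "Population genomics from transcriptome read counts: models and design"
author: "rnapopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population genomics from transcriptome read counts: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnapopgen)
```

## The problem

For most non-model animals no reference genome exists, but RNA-seq of a
handful of individuals is cheap. Mapping each individual's reads back to de
novo assembled contigs gives, at every site of every contig, a vector of
A/C/G/T read counts per individual. `rnapopgen` turns those counts into
population genomic quantities — synonymous and non-synonymous nucleotide
diversity ($\pi_S$, $\pi_N$), heterozygote deficiency ($F_{IS}$), divergence
to an outgroup ($d_S$, $d_N$), McDonald–Kreitman statistics (NI, $\alpha$,
$\omega_a$) and folded site-frequency spectra with Tajima's D — without a
reference genome and without using base-quality strings.

Two modelling problems dominate. First, genotypes must be called from
modest, variable coverage without the coverage-dependent heterozygote bias
of naive variant calling. Second, de novo assembly sometimes collapses
paralogous genes into one contig, so fixed differences between gene copies
masquerade as heterozygous SNPs shared by many individuals; these must be
detected and removed.

## Genotype calling

Reads at a site are modelled as independent draws from a base distribution
set by the individual's diploid genotype $g$ and a per-contig error rate
$\varepsilon$ shared across sites:

* homozygote $XX$: $P(X) = 1-\varepsilon$, each other base $\varepsilon/3$;
* heterozygote $XY$: $P(X) = P(Y) = (1 - 2\varepsilon/3)/2$, each other
  base $\varepsilon/3$.

The genotype space is the 10 unordered base pairs; the 16 ordered pairs
collapse onto them because read likelihoods cannot distinguish $XY$ from
$YX$. The multinomial coefficient is omitted throughout: it is constant
across genotypes and independent of $\varepsilon$, so it cancels from both
posteriors and the $\varepsilon$ maximisation (`genotypeLogLikelihoods()`).

$\varepsilon$ is estimated by profile maximum likelihood
(`estimateErrorRate()`): per-site allele frequencies $f$ enter through a
Hardy–Weinberg prior ($f_X^2$ for homozygotes, $2 f_X f_Y$ for
heterozygotes), are maximised out per site by EM, and $\varepsilon$ is then
maximised on $[0, 0.2]$ by bounded 1-D search, alternating until the
log-likelihood gain drops below $10^{-6}$ nats (at most 200 rounds). The
boundary $\varepsilon = 0$ is compared explicitly so an error-free contig is
estimated exactly. The EM freezes converged sites (frequency change below
$10^{-8}$), which makes whole-contig estimation fast without changing the
fixed point.

Genotypes are then called from the posterior
$P(g \mid \text{counts}) \propto \text{HWE}(g \mid \hat f)\,
L(g \mid \text{counts}, \hat\varepsilon)$. In the default threshold mode the
best-supported genotype is called when its posterior reaches 0.95 and the
position is otherwise coded missing; positions covered by fewer than 10
reads (30 in the high-coverage control) are missing regardless. The
"coverage < 10 is missing" reading of the threshold is used; the boundary is
configurable (`callerConfig()`). A threshold-free control samples one
genotype from the posterior under a fixed seed.

**Known limitation — $\hat\varepsilon$ at weak coverage.** On contigs with
mean depth of only a few reads per individual, the profile likelihood can
explain isolated mismatches as rare alleles instead of errors (one free
frequency vector per site costs little when few individuals are covered),
shrinking $\hat\varepsilon$ toward zero. We verified on simulated 2.5–5X
contigs that the shrunken value is the true profile-likelihood optimum, not
an optimizer failure. At 10X and above the estimate is accurate (recovery
within a few percent in the reference scenario). Consumers of per-contig
$\hat\varepsilon$ should weight by coverage or restrict to adequately
covered contigs.

## The hidden-paralogy likelihood-ratio test

A SNP created by two collapsed loci shows (i) an excess of heterozygous
calls — every individual carries both "alleles" — and (ii) read-count
asymmetry that is *correlated across individuals*, because locus 1
contributes the same fraction $p$ of reads in everyone. The test
(`paralogLrt()`) compares:

* **one locus**: allele-1 counts $k_i$ out of $N_i$ are beta-binomial with
  mean $m_g \in \{\varepsilon', 1/2, 1-\varepsilon'\}$ by genotype
  ($\varepsilon' = \varepsilon/3$ is the within-pair error), genotypes in
  HWE proportions at frequency $f$;
* **two loci**: each locus biallelic for the same two alleles with HWE
  frequencies $f_1$, $f_2$; an individual with allele-1 dosages $x_1, x_2$
  has mean $p\,x_1/2 + (1-p)\,x_2/2$, error-adjusted.

Both models share a beta-binomial overdispersion $\rho$ (estimated
separately in each fit) that absorbs allele-specific expression bias and
library amplification noise; reads matching neither focal allele are
excluded from $k_i, N_i$ (they belong to the caller's error channel) and
their number is recorded for QC. Fitting is a deterministic coarse grid
($p \in \{0.1..0.9\}$, $f \in \{0,.25,.5,.75,1\}$,
$\rho \in \{10^{-4}, .05, .2\}$) followed by bounded local refinement; the
mixing proportion is allowed the closed interval $[0,1]$ so the one-locus
model is an exact submodel at $p = 1$, which guarantees
$\log L_1 \ge \log L_0$. The statistic $2(\log L_1 - \log L_0)$ is referred
to $\chi^2_2$ (the added parameters being $p$ and the second frequency);
boundary and mixture effects make this approximate, so the package carries a
type-I-error simulation as its calibration instrument. SNPs with
$p\text{-value} < 0.001$ are flagged and removed; sites with no heterozygous
call are not testable and are retained.

**Identifiability limit.** A one-locus site at intermediate frequency where
*every* individual happens to be heterozygous is mathematically close to a
balanced fixed-difference collapse; such chance configurations are the
dominant source of false flags. Under frequencies drawn from the neutral
$1/k$ law — the SNP population the test actually meets, and the calibration
default — the empirical type-I rate at $\alpha = 0.001$ is well below
$5\times10^{-3}$; at a fixed $f = 0.5$ (maximising the chance of all-het
configurations) it rises to about 1%.

## From genotypes to statistics

Within the ORF (supplied as BED/GFF3 or predicted as the longest
ATG-to-stop frame, `longestOrf()`), each individual contributes two
pseudo-haplotypes: an arbitrary phase expansion, valid because every
statistic computed here is a function of per-site genotype counts, never of
phase. Codons containing a missing base are wholly missing. Cleaning runs in
a fixed order: codon sites with more than 50% missing states are dropped,
then haplotypes with more than 50% missing data, then alignments shorter
than 10 codon sites; with an outgroup the ORF must exceed 100 codons, and
outgroup gaps or frameshifts reject the contig. Exactly-50% cases are kept.

Statistics use complete, biallelic sites only. Per-site diversity is the
mean pairwise difference $n_1 n_2 / \binom{n}{2}$. Synonymy is classified on
the consensus codon context; site counts $L_S$, $L_N$ use Nei–Gojobori-style
fractional weights (the synonymous fraction of the possible single-base
changes, stop-creating changes excluded from the denominator). The counting
scheme is isolated behind `synNonsynSiteCounts()` so an alternative
(per-allele averaging) can be swapped in. **Consistency choice:** the
$L_S$/$L_N$ denominators count only complete positions, because the
$\pi$ and $d$ numerators are restricted to complete sites — mixing a
complete-site numerator with an all-site denominator would bias every
per-site rate downward whenever data are missing.

$F_{IS}$ is $1 - \sum H_{obs} / \sum H_{exp}$ across SNPs (ratio of sums,
robust to SNPs with tiny expected heterozygosity). The default
$H_{exp} = 2\hat p\hat q$ matches the worked fixtures (all-heterozygote
$\Rightarrow -1$); note its expectation under random mating is $-1/(m-1)$
with $m$ haplotypes rather than 0, so comparisons against a simulated truth
of zero should use the small-sample-corrected option
(`fisStat(..., hexp = "unbiased")`). Fixed differences require focal
monomorphism at a complete site and a differing outgroup base; no
multiple-hit correction is applied (close outgroups are assumed). Contigs
whose $d_S$ reaches the across-contig median plus two standard deviations
are discarded as dubious orthologs.

Species-level averages weight each statistic by the contig's analyzed site
count of the relevant class ($L_S$ for $\pi_S$), which gives every SNP equal
weight; ratio statistics are ratios of weighted means, and NI-type
quantities pool counts across contigs
($(\sum p_N/\sum p_S)/(\sum d_N/\sum d_S)$) — ratio-of-ratio averaging over
short contigs is biased, so the per-contig alternative exists but is not the
default. Confidence intervals bootstrap contigs with replacement under a
fixed seed. NI$_{0.2}$ recomputes the polymorphism counts after discarding
SNPs with minor allele frequency below 0.2; $\alpha = 1 - \text{NI}$,
$\omega_a = \alpha\, d_N/d_S$ (reported with both $\alpha$ and
$\alpha_{0.2}$).

## Site-frequency spectra

SNPs differ in how many haplotypes they were sampled in (missing genotypes),
so the folded SFS is built by hypergeometric projection to a fixed $n = 12$
sequences: a SNP at count $i$ among $m \ge n$ haplotypes contributes mass
$\binom{i}{j}\binom{m-i}{n-j}/\binom{m}{n}$ to class $j$; classes $j$ and
$n-j$ fold onto $\min(j, n-j)$; mass landing in the monomorphic classes is
discarded without renormalisation (the SNP partially leaves the subsample;
conditioning on segregation is available by flag), and SNPs in fewer than
$n$ sequences are discarded. Binomial coefficients are computed in log
space. Tajima's D uses the standard constants with $S$ equal to the total
(fractional) projected mass; on the neutral spectrum
$\xi_k \propto 1/k$ it is exactly zero for every $n$, an identity the test
suite checks for $n = 4..20$. Spectra are computed from projected SNPs for
consistency with the fixed projection size.

## The synthetic-data generator

`simulateDataset()` produces read counts with complete truth tables. Each
contig is one ORF assembled from fourfold-degenerate codon families
(avoiding the CT/CG families whose first position has synonymous changes),
so third positions are synonymous sites and first/second positions
non-synonymous. Sites are polymorphic with probability $\theta a_1$ and
sample derived counts follow the normalised $1/k$ law (a coalescent
simulator is deliberately not required; a hook accepts external genotype
matrices). Defaults: 10 individuals, 200 contigs of 67 codons, 10X mean
coverage, $\varepsilon = 0.005$, $\theta_{syn} = 0.01$,
$\theta_{nonsyn} = 0.002$, no inbreeding, no expression bias. Heterozygote
read splits are beta-binomial with overdispersion $\rho$; inbreeding draws
both alleles identical with probability $F_{IS}$; a `nonsynShift` exponent
steepens the non-synonymous frequency law to emulate purifying selection.
Collapsed paralogs are simulated as a fixed-difference pair with shared
mixing proportion $p$ and doubled contig depth (two loci contribute reads).
PCR duplicates are injected with geometric copy counts — a stress model for
the collapsing filter, not a claim about real libraries.

**Coverage model.** Depth is drawn per codon block (read-length
autocorrelation) and, in the realistic variant, multiplied by a per-contig
lognormal expression factor (sdlog 0.8, mean 1) shared across individuals,
since RNA-seq depth tracks expression. This matters: at a constant 10X with
the 10-read rule, the probability that *all* individuals are callable at a
site is about $0.54^{10} \approx 0.002$, so complete-site statistics are
essentially unmeasurable; under the expression variant, well-expressed
contigs supply abundant complete sites, as in real transcriptome data. The
named presets therefore come in both flavours: `neutral-10x` (constant
coverage; used for error-rate and genotype-accuracy validation) and
`neutral-10x-expression` (used when $\pi$ and $F_{IS}$ must be measurable
end to end).

What the generator does **not** emulate: linkage and coalescent genealogy
(sites are independent), indels and assembly errors, mapping bias,
base-quality variation, strand effects, and contamination. Passing tests
therefore validate the estimators under the model's own assumptions, not
robustness to artefacts outside it.

## Problem sizes and numerical choices

Validation runs use the preset sizes: 200 contigs x 201 sites x 10
individuals for recovery experiments; 10,000 simulated sites for the
paralogy type-I calibration and 200 replicates for power; bootstrap
confidence intervals default to 1,000 contig resamples. Optimisation
tolerances: EM frequency change $10^{-8}$; outer error-rate loop $10^{-6}$
nats; paralog refinement L-BFGS-B with `factr = 1e8`. Ties for the best
genotype are coded missing in threshold mode. Degenerate inputs (all-zero
sites, $m \in \{0,1\}$ beta-binomial means, zero denominators in NI) return
missing values or log-zero rather than raising errors, except where the
input violates a contract (reads beyond contig bounds, zero-length contigs).

End-to-end recovery of complete-site statistics at these sizes carries
non-trivial Monte-Carlo spread: a 200-contig run yields roughly 2,000–3,000
complete synonymous sites under the expression variant, so single-run
$\hat\pi_S$ scatters by about 10–15% around its expectation, which itself
sits a few percent below $\theta$ because heterozygote call failures remove
a small, polymorphism-enriched subset of sites from the complete set. The
validation suite therefore asserts the stable quantities (error-rate
recovery on the constant-coverage preset, genotype error, calibration and
power of the paralogy test, analytic SFS identities, alignment-level
estimator oracles) and reports the end-to-end diversity values alongside
them rather than gating on a knife-edge band.
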