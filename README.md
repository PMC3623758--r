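# rnapopgen

Reference-free population genomics from RNA-seq read counts.

For species without a reference genome, population genomic parameters can be
estimated by sequencing the transcriptomes of a population sample, assembling
contigs de novo, and mapping each individual's reads back to them. This
package implements that pipeline from the per-site base counts onward:

* **Genotype calling** by maximum likelihood: a per-contig sequencing/mapping
  error rate ε is estimated from the read counts themselves (no base
  qualities), assuming a multinomial read model and Hardy–Weinberg
  equilibrium; diploid genotypes are called when their posterior probability
  exceeds 0.95, with positions under 10 reads coded missing. Because a
  heterozygote is called by posterior weight rather than by variant
  detection, heterozygosity estimates carry no coverage-dependent bias.
* **Hidden-paralogy filtering**: when assembly collapses two paralogous genes
  into one contig, between-copy differences masquerade as heterozygous SNPs.
  A likelihood-ratio test compares a one-locus biallelic model with a
  two-locus model in which locus 1 contributes a constant proportion *p* of
  every individual's reads, both with Dirichlet-multinomial (beta-binomial)
  read-count overdispersion; SNPs with p < 0.001 are discarded.
* **Statistics**: per-contig and species-level πS, πN, FIS, dN/dS, the
  neutrality index NI = (pN/pS)/(dN/dS), α = 1 − NI (also α₀.₂ after
  removing SNPs with minor allele frequency < 0.2), ωa = α·dN/dS,
  length-weighted averaging with contig bootstrap confidence intervals, and
  folded site-frequency spectra via hypergeometric projection to n = 12
  sequences with Tajima's D.
* **A synthetic-data generator** with complete truth tables (genotypes,
  error rates, synonymy, collapsed paralogs) validates every stage end to
  end.

## Worked example

Simulate the reference scenario (10 diploid individuals, 200 contigs, 10X,
ε = 0.005, synonymous θ = 0.01, with contig-level expression variation so
that complete sites exist) and run the full pipeline:

```r
library(rnapopgen)

cfg <- scenarioPresets(seed = 1)[["neutral-10x-expression"]]
sim <- simulateDataset(cfg)
res <- runPipeline(sim$counts, sequences = sim$sequences, orfs = sim$orfs,
                   config = pipelineConfig(nBootstrap = 200))
#> [rnapopgen] contigs in                   200
#> [rnapopgen] contigs >= coverage filter   176
#> [rnapopgen] SNPs called                  315
#> [rnapopgen] SNPs after paralog filter    315
#> [rnapopgen] contigs with cleaned alignment 90
#> [rnapopgen] contigs analyzed             90

res$summary$summary[, c("meanPiS", "meanPiN", "piNPiS", "meanFIS")]
#>       meanPiS     meanPiN    piNPiS     meanFIS
#> 1 0.008910481 0.002044333 0.2294302 -0.03932584
```

Reading: the length-weighted synonymous diversity recovers the simulated
θ = 0.01 (to within the Monte-Carlo spread of a 200-contig run), πN/πS
reflects the lower non-synonymous mutation input of the scenario
(θN/θS = 0.2), and FIS is near zero, as expected for a random-mating
simulation. Per-contig error-rate estimates, genotype calls with
posteriors, the annotated SNP table with paralogy-test results, cleaned
codon alignments, and per-class folded spectra with Tajima's D are all in
`res`; `outDir =` additionally writes a VCF (FORMAT `GT:DP`, FILTER
`paralog`, INFO `EPS`/`AF`), per-contig and species TSV tables, SFS tables
and a JSON run summary.

A thin command-line front end over these functions is installed at
`inst/scripts/rnapopgen` with subcommands `simulate`, `run`, `call`,
`paralog-test` and `sfs` (flags `--min-coverage`, `--high-coverage`,
`--posterior-threshold`, `--mode`, `--paralog-alpha`,
`--no-paralog-filter`, `--maf-cutoff`, `--projection-n`, `--bootstrap`,
`--seed`).

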