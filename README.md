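# genload

Genetic-erosion analysis from low-coverage whole-genome data: genotype
likelihoods, diversity, kinship and inbreeding, differentiation scans, and
the potential/realized genetic-load statistics — with a forward
Wright–Fisher simulator that generates fully annotated synthetic datasets
for calibration.

## Who this is for

Conservation and population genomicists working with opportunistically
collected, low-coverage (~1–4x) resequencing data from small or fragmented
wildlife populations, who need to quantify how much variation a population
has lost, how inbred its individuals are, and how its burden of deleterious
variation is distributed between "carried" and "exposed".

## What it computes

Starting from per-site read counts (simulated, or parsed from standard
VCF/GFF3/FASTA inputs), `genload` implements:

* **Genotype likelihoods** under the classical read-error model
  (match `1-e`, mismatch `e/3`), ML allele frequencies by EM, a
  likelihood-ratio polymorphism test (chi-square 1 df), MAF / coverage /
  heterozygote-excess filters, and posterior genotype calls
  (`gl_from_pileup`, `estimate_af_em`, `call_snps`, `hwe_test`,
  `call_genotypes`).
* **Diversity**: folded SFS with bootstraps, Watterson's
  `theta_W = S/(a_n L)`, per-individual heterozygosity, mutation rate from
  interspecific divergence `mu = (mismatches/valid length)/(2t)`, and
  `Ne = theta_W/(4 mu)` with CI (`folded_sfs`, `watterson_theta`,
  `mutation_rate_from_divergence`, `ne_from_theta`).
* **Relatedness**: KING-robust kinship from joint-genotype counts
  `(N11 - 2 Nopp)/(Nhet1 + Nhet2)` with R0/R1 ratios and degree bins,
  ML individual inbreeding `F in [-1, 1]`, and covariance PCA
  (`pair_ibs_stats`, `individual_F`, `covariance_pca`).
* **Scans**: Hudson Fst as windowed ratio-of-sums with bootstrap CIs,
  `Z(Fst)` outliers beyond 5 SD, absolute divergence Dxy, and Fu & Li's
  D and F neutrality statistics from polarised variants
  (`fst_window`, `z_fst_outliers`, `dxy_window`, `fu_li_stats`).
* **Genetic load**: strand- and frame-aware variant impact classification
  (HIGH / MODERATE / LOW / MODIFIER), and per impact class `i`,
  individual `j`, population `k`:

  - potential load `Load_P[i,j,k]` — class-`i` genic sites carried by `j`
    over all genic variants in `k`'s gene pool;
  - realized load `Load_R[i,j,k]` — homozygous-alternate class-`i` alleles
    over twice the class-`i` sites genotyped in `j`;

  with Welch tests between populations (`classify_variants`,
  `load_potential`, `load_realized`, `load_table`).
* **Alignment statistics** for mitogenome-style comparisons: haplotype
  counts and diversity, nucleotide diversity, Kimura 2-parameter distances,
  and subsampled permutation comparisons (`haplotype_stats`,
  `nucleotide_diversity`, `k2p_distance`, `subsample_compare`).
* **Simulation**: a compiled forward Wright–Fisher engine with
  class-specific selection (fitness 1, `1-hs`, `1-s`), per-population
  selfing, population splits, coalescent-seeded equilibrium, an engineered
  reference genome whose codons reproduce each variant's simulated impact
  class, and writers/readers for VCF + GFF3 + FASTA + pileup truth bundles
  (`sim_config`, `simulate_populations`, `simulate_pileups`,
  `write_truth_bundle`).

## Worked example

Simulate the default scenario — a large outbred population (2N = 2000) and
a small partially selfing population (2N = 100, selfing 0.3) that split 200
generations ago, 850 kb of gene-dense sequence — then push the reads
through the full pipeline:

```r
library(genload)

cfg    <- sim_config(seed = 42)
truth  <- simulate_populations(cfg)
pile   <- simulate_pileups(truth, cfg)
gl     <- gl_matrix(pile, e = cfg$error_rate)
snps   <- call_snps(gl, min_ind = 12, maf_min = 0.01)
geno   <- call_genotypes(gl, snps)
models <- gene_models_from_layout(truth$layout)
snps   <- classify_variants(snps, models, truth$reference)
loads  <- load_table(geno, snps$impact_class, truth$pop,
                     genic = snps$context != "intergenic")
```

This prints (abridged):

```
sim_truth: 1429 segregating sites x 14 individuals (2 pops)
called 1416 SNPs; genotype concordance vs truth: 0.9981

    HIGH      LOW MODERATE MODIFIER
       5       82      105     1224

# Welch tests on realized load (pop1 = large, pop2 = small):
     class  mean_a mean_b     t    df        p
  MODIFIER 0.12590  0.756 -76.3  7.95 1.12e-12
  MODERATE 0.00482  0.390 -17.5  6.13 1.82e-06
       LOW 0.09722  0.763 -47.5 11.83 7.21e-15

pop1: S = 1300, theta_W = 0.000481, Ne_hat = 802 (true N = 1000)
pop2: S = 162,  theta_W = 5.99e-05, Ne_hat = 100 (true N = 50)
```

Reading this: the pipeline recovers 1416 of 1429 true variants with 99.8%
genotype concordance; the small population has lost ~7/8 of its nucleotide
diversity (`theta_W` 6.0e-5 vs 4.8e-4), its Watterson effective size tracks
the true census (100 vs 50 diploids, i.e. the right order against
`Ne = theta/4mu`), and its individuals expose far more of every deleterious
class as homozygotes (realized load 0.39 vs 0.005 for MODERATE) — the
erosion signature the load statistics are built to detect.
`run_all(pipeline_config())` chains every stage (diversity, kinship,
inbreeding, PCA, Fst/Dxy scans, Fu & Li, load, alignment statistics) into
one deterministic report; `write_report()` serialises it.

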