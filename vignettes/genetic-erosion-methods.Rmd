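---
title: "Methods: genotype-likelihood population genetics and the load statistics"
author: "genload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-likelihood population genetics and the load statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`genload` quantifies genetic erosion — the loss of within-population
variation through drift, isolation and inbreeding — from low-coverage
whole-genome resequencing, and contrasts two complementary summaries of
deleterious variation: the *potential load* carried in a gene pool and the
*realized load* exposed as homozygotes in individual genomes.  This vignette
explains each model in the package, the tunable parameters and their
defaults, what the bundled simulator does and does not emulate, and the
numerical and design choices a maintainer would want recorded.

## 1. Genotype likelihoods and site filters

At coverages of a few reads per site, hard genotype calls discard too much
information; all downstream estimators therefore start from genotype
likelihoods.  For a biallelic site with `r` reference and `a` alternate
reads and a per-base error rate `e`, a read matches its template allele with
probability `1 - e` and reports any specific other base with probability
`e/3`.  The likelihood of a diploid genotype is the product over reads of
the mean over the genotype's two alleles:

* hom-ref: `(1-e)^r (e/3)^a`
* het: `((1-e+e/3)/2)^(r+a)`
* hom-alt: `(e/3)^r (1-e)^a`

`gl_from_pileup()` returns these in natural log; a site with no reads has a
flat triplet and is treated as missing.

The per-site alternate-allele frequency is the maximum-likelihood value
under Hardy–Weinberg genotype proportions, found by EM
(`estimate_af_em()`; tolerance `1e-8`, at most 200 iterations, started from
0.25 — the likelihood is unimodal in `f`, so the start only affects the
iteration count).  A site is called polymorphic when the likelihood-ratio
test of `f̂` against `f = 0` is significant against a chi-square(1) null
(`p < 1e-6` by default).  The null is used without the boundary halving
correction; this matches common practice for this test and only makes the
cutoff slightly conservative.

`call_snps()` then applies, in order: the minor-allele-frequency floor
(default 0.05), the minimum number of individuals with data, the summed-depth
ceiling (a guard against collapsed repeats), and a Hardy–Weinberg
heterozygote-excess filter (`p < 0.01` removed).  The heterozygote-excess
test is a one-sided likelihood-ratio test of a per-site inbreeding-style
parameter `F` in the genotype prior `P(0) = (1-f)^2 + f(1-f)F`,
`P(1) = 2f(1-f)(1-F)`, `P(2) = f^2 + f(1-f)F`; an exact genotype-count test
is not available because genotypes are uncertain at low coverage.  Only
heterozygote *excess* is penalised — the signature of paralogous sequence
collapsed onto one locus — while homozygote excess (real inbreeding) passes.

Two filter profiles mirror the two ways a low-coverage cohort is typically
analysed (`filter_profile()`): `"population"` (min 60 individuals, max
summed depth 500) retains maximum per-individual information;
`"genomic"` (min 15 individuals, max depth 100) retains maximum genomic
information from a small balanced subset.  At simulation scale the pipeline
uses thresholds scaled to the cohort (80% of individuals, no depth ceiling),
and the load scenario calls SNPs with a MAF floor below `1/(2n)`: with only
28 chromosomes a 5% floor would censor singletons, which is precisely the
frequency class where strongly deleterious variants live.  At genome scale
(millions of SNPs) the 0.05 filter leaves every impact class with large
counts and is the default.

Genotypes, where needed (kinship, realized load), are maximum-a-posteriori
calls under a Hardy–Weinberg prior built from `f̂`, with individuals below
5x depth at a site set missing (`call_genotypes()`).

## 2. Diversity, mutation rate and effective population size

`folded_sfs()` tabulates minor-allele counts and attaches 100 site-bootstrap
replicates; the bootstrap mean is the downstream point estimate.
Watterson's estimator is `theta_W = S / (a_n L)` with
`a_n = sum_{i<n} 1/i`; per-individual heterozygosity is the heterozygous
fraction of genotyped sites (optionally per bp of surveyed sequence).
Genic-region estimates reuse the same code path through a site mask, so
whole-genome and genic values are always computed identically.

The mutation rate comes from an interspecific alignment:
`mu = (mismatches / valid length) / (2 t)`, excluding alignment columns with
a gap or N in either sequence from numerator and denominator.  With a
divergence time in years this gives a per-site per-year rate, and
`Ne = theta_W / (4 mu)` is then computed literally, without a
generation-time correction — the arithmetic the headline effective-size
figures use — with a `gen_per_year` argument exposed for users who want the
per-generation version.  A standard error on `theta_W` propagates to a 95%
CI on `Ne`.

## 3. Kinship, inbreeding and structure

`pair_ibs_stats()` counts the joint-genotype categories `N(g1, g2)` for a
pair and forms the allele-frequency-free KING-robust kinship

```
kinship = (N(1,1) - 2[N(0,2) + N(2,0)]) / (Nhet_1 + Nhet_2)
```

plus the IBS ratios `R0 = [N(0,2)+N(2,0)] / N(1,1)` and
`R1 = N(1,1) / (all discordant + double-het categories)`.  Self-comparison
gives exactly 1/2.  Degrees use the standard powers-of-two bins
(`2^-1.5`, `2^-2.5`, `2^-3.5`, `2^-4.5`); the relationship categories are
named in the field but the cutoffs are a package choice.  Pairs compared at
fewer than 100,000 sites (configurable) are flagged and excluded from
summaries, the conventional guard for sparse low-coverage overlap.
Kinship is computed from called genotypes so that exact pedigree oracles
can verify it; at 20x simulated coverage genotype error is negligible.

Individual inbreeding `F in [-1, 1]` is estimated against population allele
frequencies by maximising the same inbreeding-parameterised likelihood used
by the HWE filter, with per-site priors clipped at zero and renormalised
where `F < 0` would make one negative.  The maximisation is a 1-D Brent
search (`optimize`, tolerance `1e-9`) with explicit boundary snapping; an EM
formulation exists for `F >= 0` (a mixture over an IBD indicator) but has no
valid latent-variable interpretation for negative `F`, so the direct search
is used for the whole interval — the target (the MLE) is identical.
Estimating against population rather than individual-specific frequencies is
a simplification appropriate for single-population estimates; against pooled
frequencies of a structured cohort, `F̂` absorbs the Wahlund effect and
should be read as homozygosity relative to the pooled gene pool.

`covariance_pca()` standardises genotypes as `(g - 2f)/sqrt(2f(1-f))`,
averages the individual-by-individual covariance over sites (missing values
contribute zero after centring) and eigendecomposes.

## 4. Differentiation scans and neutrality statistics

Window differentiation uses Hudson's estimator with sample-size correction,

```
N = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)
D = p1(1-p2) + p2(1-p1)
```

combined as a ratio of sums over the sites in each 100-kb window (50-kb
step).  Ratio-of-sums, not mean-of-ratios, is the estimator with acceptable
bias in sparse windows, and it is analytically checkable against a per-site
recomputation.  The global estimate is the ratio of sums over all sites with
a 95% CI from 100 site bootstraps.  Negative window values are retained:
clipping at zero would distort the null standard deviation that the outlier
scan standardises against.  `z_fst_outliers()` excludes windows below a
10-site floor (low-data windows produce spuriously extreme values), then
flags `|Z| > 5`.  `dxy_window()` computes absolute divergence
`p1(1-p2) + p2(1-p1)` summed over variant sites and divided by window length
in bp; sites fixed in one population still contribute, which is why the
scan's allele frequencies are estimated per population at the pooled site
list.

Neutrality statistics require ancestrally polarised derived-allele counts.
`fu_li_stats()` implements the singleton-contrast statistics

```
D = (eta - a_n eta_s) / sqrt(u_D eta + v_D eta^2)
F = (pi - eta_s) / sqrt(u_F eta + v_F eta^2)
```

with the standard variance coefficients for a sample with an outgroup
(including the later-corrected `u_F`, `v_F`).  The coefficients are
validated in the test suite by the property that the statistics have
mean ~ 0 and unit-scale variance over neutral equilibrium replicates.
An excess of rare variants (expansion, or recovery after erosion) drives
them negative; a deficit (bottleneck) positive.  A single non-recombining
locus gives these statistics a noticeably skewed null (mean ~ -0.15), so
the package's neutral calibration aggregates ~20 unlinked loci per window,
the appropriate analogue of a recombining 100-kb window.

## 5. Variant impact and the load statistics

`classify_variant()` translates each coding SNP in frame and strand and
maps the effect: premature stop, lost stop or start, and splice-site
disruptions (the first/last two intronic bases) are HIGH; missense is
MODERATE; synonymous and stop-retained changes are LOW; intron, UTR, flank
(5 kb, the conventional annotation default) and intergenic variants are
MODIFIER.  The reference allele is assumed non-deleterious and the
alternate deleterious — the stated working assumption of this class of
analysis — even where ancestral-state information disagrees; a
polarisation-aware mode can be layered on by re-orienting the input table.
Genes whose CDS length is not a codon multiple are skipped with a warning.
The classifier is verified exhaustively against a brute-force
mutate-retranslate-diff oracle on a toy gene set covering both strands,
introns, UTRs and flanks.

For impact class `i`, individual `j` and population `k`:

* **Potential load** `Load_P[i,j,k]` is the number of class-`i` genic sites
  at which `j` carries at least one alternate allele, divided by the total
  number of genic variants in `k`'s gene pool.  The population-level form
  replaces the numerator with `k`'s class-`i` count, so classes partition
  to 1.  Both forms are computed: the per-individual form carries the
  dispersion needed for between-population tests, the population form is
  the gene-pool summary.
* **Realized load** `Load_R[i,j,k]`, default mode `"hom"`, is
  `2 x (class-i sites hom-alt in j) / (2 x class-i sites genotyped in j)`;
  mode `"alleles"` counts heterozygous alleles in the numerator too.  The
  `"hom"` numerator follows the displayed definition of realized load as
  zygosity-dependent exposure; outputs always label the mode.

A population's variant set is the sites where it *carries* at least one
alternate allele — not the sites polymorphic within it.  The distinction
matters in small isolated populations: variants fixed by drift are no longer
polymorphic there but are fully exposed homozygous load, and excluding them
would systematically understate erosion.  Welch's two-sample t-test
(`welch_t()`, via `stats::t.test`) compares classes between populations,
per test without multiple-testing correction to mirror conventional
reporting; a BH option exists on `load_table()`.

## 6. Alignment-based (mitogenome-style) statistics

`alignment_set()` masks columns containing gaps or N in any sequence
(complete deletion, the convention of the classical packages; end-trimming
for circularisation artifacts is available via `trim_ends`).  Haplotypes
are unique sequences over valid columns; haplotype diversity is
`Hd = n(1 - sum p_h^2)/(n-1)`; parsimony-informative columns have at least
two alleles each seen at least twice; `nucleotide_diversity()` is mean
pairwise difference per valid site; `k2p_distance()` is
`-1/2 log(1-2P-Q) - 1/4 log(1-2Q)` with transition/transversion proportions
`P`, `Q`, returning `NA` with a warning at saturation.  Unequal sample
sizes are handled by `subsample_compare()`: draw `n_sub = 7` sequences per
population, 100 times, recompute the statistic, and report the empirical
two-sided p-value (twice the fraction of draws whose difference reverses
sign against the mean difference), with a labelled Welch test on the
permutation values as a secondary output — the permutation design stays
within what the subsampling literally supports.

## 7. The simulator: what it emulates and what it does not

`simulate_populations()` is a forward Wright–Fisher engine (compiled, with
all randomness tied to R's RNG so identical seeds give identical output).
Fitness is multiplicative across sites — 1, `1-hs`, `1-s` for genotypes
0/1/2 — with `s`, `h` per impact class; each population has a selfing
probability; daughter populations split from the ancestor and evolve
independently; sites are transmitted independently (free recombination).
New mutations arise at `2N mu L` per generation on an infinite-sites
approximation over the finite mutable sequence.  Because the engine's sites
are unlinked, the coalescent initialisation draws one neutral genealogy per
5-kb block (a single whole-sequence genealogy is not stationary for this
process and inflates between-replicate variance severalfold).  After the
neutral seed, a selection-equilibration burn-in of `0.5 N` generations runs
before any split: the slowest selected class here has `1/(hs) = 100`
generations, so `0.5 N = 500` generations at the default ancestral size is
several equilibration timescales; a from-scratch `10 N`-generation burn-in
is available via `init = "monomorphic"` when full mutation–drift
equilibration from an invariant sequence is wanted.

The gene architecture places non-overlapping genes on the plus strand, each
with a 5' UTR, two CDS exons around one intron, and a 3' UTR; splice
dinucleotides, start and stop codons are held invariant so that every
non-CDS variant is MODIFIER.  Coding mutations draw their class from the
configured DFE, renormalised per codon position (mid-codon changes cannot
be synonymous under the standard code).  After the simulation the reference
sequence is built so that re-translating each engineered codon reproduces
the simulated class — the bundle (VCF/GFF3/FASTA) is therefore internally
consistent and the sequence-based classifier recovers the simulated truth
exactly, which the tests exploit as an end-to-end check.

Default parameters (one diploid census per population):

| parameter | default | rationale |
|---|---|---|
| `pop_sizes` | 1000, 50 (2N = 2000, 100) | large outbred vs small eroded population |
| `selfing_rates` | 0, 0.3 | partial inbreeding in the small population |
| `split_gens` | 200 | ~4N generations of drift for the small population |
| `seq_length`, `n_genes`, `gene_length` | 850 kb, 90 genes, 3 kb CDS | gene-dense target so each impact class segregates at countable numbers in a 7-per-population sample |
| `mu_sim` | 1.5e-7 /site/gen | theta ~ 6e-4/site, the diversity scale of an eroded galliform genome |
| `class_probs` | 0.05 / 0.70 / 0.25 (H/M/L) | nonsense ~5% and missense ~70% of coding SNVs |
| `sel_coeffs` | 0.3 / 0.02 / 0.002 / 0 | strong, intermediate, nearly neutral, neutral |
| `dominance_h` | 0 / 0.25 / 0.5 / 0.5 | strongly deleterious mutations are mostly recessive; with `h > 0` they would segregate at `mu/(hs)` and be invisible at this genome size, while recessives segregate at `sqrt(mu/s)` and are exactly the class exposed by inbreeding |
| `mean_depth`, `error_rate` | 20x, 0.01 | calibration regime: genotype error is negligible, so estimator properties are tested rather than coverage; set ~2x to emulate opportunistic field data |
| `n_sample` | 7 per population | the balanced genomic-subset design |

The simulator does **not** emulate: read mapping and its artifacts
(paralog collapse is tested with synthetic forced-heterozygote pileups
instead), base-quality miscalibration, indels or triallelic sites, linkage
(sites are unlinked, so linked-selection effects like background selection
are absent), migration after the split, sex chromosomes, or organelle
inheritance (the "mitogenome" alignment is a haploid projection of nuclear
haplotypes).  Passing tests therefore demonstrate estimator correctness and
the direction of demographic/selection effects at desk scale, not
robustness to alignment artifacts or to linked selection.

Problem sizes in the test-suite calibrations are deliberately desk-scale:
e.g. the Watterson recovery uses 100 replicates of 100 unlinked 10-kb loci
(a 1-Mb genome is not one genealogy), kinship oracles use 50,000 unlinked
sites, the selfing ladder uses single populations of 2N = 300–500, and the
two-population load contrast uses 20 replicates of the default scenario.

## 8. Known limitations and open choices

* The polymorphism LRT's chi-square(1) null is anti-conservative at the
  extreme tail in principle; at 20x simulated coverage the realised type-I
  count at `p < 1e-6` over 1e6 monomorphic sites is within the expected
  handful, but at ~2x with clustered errors the test can be driven by
  triple-error pileups — a property of the error model, not the test.
* Triallelic sites are removed upstream and never modelled; the
  three-minor-allele re-weighting refinement of frequency estimation is not
  reconstructed.
* `Load_R`'s denominator uses sites genotyped in the individual; an
  all-population-sites denominator would shrink every individual value by a
  near-constant factor at high call rates.
* The effective-size arithmetic mixes a per-year mutation rate with
  `theta = 4 Ne mu` without generation-time conversion, reproducing the
  conventional presentation; `gen_per_year` exposes the correction.
* The kinship degree thresholds, the 5-kb flank, the 10-site window floor
  and the simulation-scale filter defaults are package choices where the
  field's conventions, not a single authoritative value, define the range.
* This is an R package: the module surfaces are exported functions plus the
  `run_all()` orchestrator, and the reproducible entry point is
  `scripts/acceptance.R`; no shell CLI is shipped.
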