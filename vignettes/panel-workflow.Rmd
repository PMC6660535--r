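---
title: "Methods: amplicon SNP panel QC and genomic prediction in rice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon SNP panel QC and genomic prediction in rice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the tunable parameters, the
synthetic-data generators and the numerical choices behind `ricepanel`. It
is the package's methods reference: nothing stated here goes beyond what
the test suite and `scripts/acceptance.R` actually compute.

## The setting

A low-density amplicon panel genotypes a fixed set of ~1000 biallelic SNPs,
chosen to be highly informative in the *indica* rice breeding pool:
candidates from reference collections are filtered for call rate > 95% and
MAF ≥ 0.4 (strict vs inclusive boundaries deliberately asymmetric, matching
the design rule as stated), then gaps in physical coverage are filled from a
secondary resource. Physical distance converts to genetic distance with a
single genome-wide constant, 1 cM ≈ 244 kb, on a 373,245,519 bp genome —
995 uniformly spaced markers are then ~1.53 cM apart. The package does not
model per-region recombination because no analysis here needs more than the
constant.

Gap filling (`fill_gaps()`) is a documented stand-in for an unspecified
procedure: greedily take the largest remaining gap (chromosome ends count
as half-open gaps from position 1 and to the chromosome end, so telomeric
holes are rankable), add the pool candidate nearest the gap midpoint, break
ties toward the lower coordinate for determinism. The maximum gap is
non-increasing at every successful step, which the tests verify.

## Genotype representation

Diploid calls are unordered allele pairs stored alphabetically ("AG", never
"GA"); "NN", "N" and "--" all decode to missing; IUPAC one-letter
heterozygote codes are supported as a second HapMap dialect since the
interchange files in circulation use both. Calls whose alleles fall outside
a marker's declared pair are retained but reported (`allele_violations()`)
— silently dropping them would hide assay faults. Dosages count the
marker's alternate allele (0/1/2). Strand is not modelled at I/O; the one
place strand matters — comparing two genotyping platforms — reconciles
reverse-complement allele pairs explicitly and excludes strand-ambiguous
(A/T, C/G) markers whose declared pairs disagree, because for those the
complement is indistinguishable from a genuine allele swap.

## QC statistics

Per marker: call rate = called/total samples; heterozygosity = heterozygous
calls among called; MAF over called allele counts. The filter boundaries
are inclusive exactly as printed (MAF ≤ 0.01, het ≥ 10%, CR ≤ 75% fail).

Repeatability uses the per-locus error rate $e_l = m_l / n_l$: among all
replicate-locus genotypes of accessions with ≥ 4 independent replicates,
$m_l$ counts calls differing from the accession's reference genotype in at
least one allele (a heterozygote against a homozygote is a mismatch — one
shared allele does not rescue it), $n_l$ counts non-missing comparisons.
$R = 100 - \bar e_l$ in percent. The reference genotype is the
within-accession strict-majority consensus; ties and all-missing loci give
a missing reference, which removes those comparisons from $n_l$ rather
than counting them as errors — missingness is accounted separately by the
call rate. `drop_hets = TRUE` sets replicate heterozygous calls missing
before comparison, mirroring the workflow of removing and re-imputing
heterozygous calls in inbred material; whether the original analysis
recomputed $e_l$ on imputed heterozygotes or simply dropped them is
ambiguous, so both modes are exposed and the drop mode is the default
reading.

LD-kNN imputation follows the LinkImpute scheme with the published settings
(30 high-LD sites, 30 neighbours): LD is the squared Pearson correlation of
dosages on pairwise-complete observations; the sample-to-sample distance is
the mean absolute dosage difference over the target marker's top-LD sites;
neighbours vote with weight $1/(d + 10^{-6})$; the weighted mean dosage is
rounded to 0/1/2 with exact half-way ties resolved to the nearest
neighbour's genotype. Non-missing calls are never altered.

## Trait markers

The packaged definition table encodes 21 SNPs across 11 loci, each used as
a single diagnostic SNP or as an ordered haplotype. Haplotype calling
enumerates every completion of heterozygous/missing components over the
marker's declared alleles and assigns a label only when all completions
agree, so a missing component whose completions all map to one class is
still called (forced completion). The amylose (Waxy) locus maps haplotypes
to high/intermediate/low classes; the high class is recorded under both
reported spellings (GAC and GAT), which conflict in the source material —
the definition file carries a note rather than silently choosing one.

Utility = share of assessed cultivars *not* carrying the favorable allele
(unknown calls excluded: utility measures pool composition). FPR = share of
known recipients without the unfavorable allele; FNR = share of known
donors without the favorable allele — here unknown calls *count* as
failures, because these two rates measure marker performance and a marker
that cannot classify a known donor has failed. In single-SNP mode a
heterozygote counts as carrying the favorable allele (dominant reporting,
the breeding-relevant convention for inbred-line panels).

## F1 validation

The predicted F1 of a cross is heterozygous where its homozygous parents
differ, homozygous where they agree, and undefined where either parent is
heterozygous or missing. Similarity is the exact-match percentage over
loci where both prediction and observation are called; per-cross similarity
macro-averages over the cross's F1 plants. The polymorphic-marker count of
a pair equals the heterozygous-locus count of its predicted F1 — an
identity the tests assert.

## Population structure

PCA runs on alternate-allele dosages, mean-imputed per marker, centered and
by default unscaled (the standard default of the underlying routine; the
preprocessing record in the result makes the choice auditable). Components
carry a deterministic sign convention (largest-magnitude loading positive).
Ward clustering squares dissimilarities before the Lance–Williams update
(`ward.D2`), verified in tests against a brute-force minimal
variance-increase oracle on 6-item instances. Cluster number is chosen by
average silhouette width of k-means solutions (10 restarts, fixed seed) on
the leading PCs capturing ≥ 80% variance (capped at 10), with argmax ties
resolved to the smaller k for parsimony. Undetermined accessions are
assigned by nearest centroid in the first two PCs; exact ties stay
unassigned.

## Genomic selection

Plot phenotypes follow $Y_{ijk} = \mu + g_i + t_j + r(t)_{jk} + e_{ijk}$,
fitted by REML (genotypes fixed for BLUEs, all terms random for BLUPs).
Grain yield converts plot harvests as
$GY = \frac{100-MC}{86}\cdot\frac{\text{weight (g)}}{\text{area (m}^2)}\cdot 0.01$
t/ha. Broad-sense heritability of accession means is
$H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{gy}/t + \sigma^2_e/(tr))$ with
$t$ the mean trials per accession and $r$ the mean plots per accession per
trial. The stated plot model has no genotype-by-trial term, yet the
heritability formula includes $\sigma^2_{gy}$; the package defaults
$\sigma^2_{gy}=0$ and offers `gxt = TRUE` to fit the interaction — the
discrepancy is surfaced, not hidden.

Kernels: $G = WW^\top / 2\sum_j p_j(1-p_j)$ on column-centered dosages
(VanRaden), and the pedigree $A$ by the tabular method (verified against a
recursive-kinship oracle). Ridge/GBLUP maximizes the restricted likelihood
of the variance ratio after one eigendecomposition (golden-section/Brent on
log-λ to 1e-8, verified against a dense grid-search oracle on small
instances); held-out samples are predicted through the kernel cross-block.

The Bayesian families are single-site Gibbs samplers over marker effects:
per-marker scaled-inverse-$\chi^2$ variances (scaled-t shrinkage); a
point-mass + Gaussian-slab mixture with common slab variance and a
Beta-updated inclusion probability; a point-mass + per-marker scaled-t
slab mixture; and the Bayesian lasso via per-marker exponential mixing
with inverse-Gaussian updates and a Gamma hyperprior on $\lambda^2$.
Hyperpriors use 5 prior degrees of freedom with scales set from the
phenotypic variance at a prior marker $R^2$ of 0.5 (the common software
default when none is specified); mixtures divide the slab scale by the
inclusion probability. The residual-variance trace is returned every
iteration for convergence inspection, mirroring the usual
`plot(scan("varE.dat"))` habit. The default chain is 12,000 iterations,
2,000 burn-in, thinning 5; cross-validation at package-test and
reproduction scale uses 1,200/300/5 — with ~950 markers and ~350 lines the
posterior means that enter GEBVs stabilize well within that, which the
seed-stability and shrinkage tests exercise.

RKHS G + A fits two random effects, $a \sim N(0, A\sigma^2_a)$ and
$g \sim N(0, G\sigma^2_{gu})$, by Gibbs sampling in each kernel's
eigenbasis (eigenvalues below $10^{-8}$ of the maximum dropped); the GEBV
is the summed posterior-mean effect. When one kernel is uninformative its
variance retains prior mass (the likelihood cannot fully identify the
split against the residual), so predictions — not variance components —
are the meaningful output; the tests compare GEBVs against single-kernel
fits. Pedigree BLUP is ridge on $A$.

Cross-validation is family-stratified: within each family, members are
shuffled and dealt round-robin to the k folds, with the dealing start
rotated from family to family so fold sizes balance. This prevents the
inflation that occurs when close relatives are split between training and
validation at random. Predictive ability pools all validation folds within
a repeat, correlates pooled GEBVs with the observed BLUEs, and averages
over repeats (10 by default). BLUEs are computed once on all plots before
cross-validation — matching the stated workflow of extracting adjusted
means first — which leaks a small amount of trial information across folds;
a fold-safe alternative (re-fit BLUEs per training set) is a
straightforward variation but is not the default because it changes the
estimand being reproduced.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions used throughout the tests and
the acceptance script; they were fixed from the stated assay properties,
once, and are not tuned per test:

* **Panel**: 995 SNPs allocated to the 12 chromosomes proportionally to
  physical length, evenly spaced with ±30% jitter. Ancestral alternate-
  allele frequencies come from a symmetric Beta(3.25, 3.25) — the shape
  fitted once so the folded (minor-allele) spectrum has median ≈ 0.36 and
  interquartile range ≈ 0.28–0.44, the stated spectrum of the panel on
  diverse indica lines.
* **Subpopulations**: Balding–Nichols drift around the ancestral
  frequency, divergence 0 for indica (the spectrum *is* the indica
  spectrum), 0.75 for japonica and 0.45 for aus. The japonica value was
  calibrated once to the stated japonica-within-japonica polymorphism
  regime (~97 of ~895 markers), reproducing the designed-in property that
  indica-ascertained markers are largely fixed within japonica.
* **Assay errors**: 1.5% residual heterozygosity in inbreds; 1% per-locus
  replicate error with 70% of errors rendered heterozygous (the dominant
  miscall mode in inbred material); and a *bimodal* missingness model —
  2% missing calls at well-behaved markers while 10% of markers amplify
  poorly and lose 32% of their calls. The mixture reproduces two facts of
  a fixed-content amplicon assay simultaneously: a panel-wide *mean* call
  rate of 95%, and roughly a tenth of the panel falling under the 75%
  call-rate filter. A uniform 5% per-call rate would match the mean but
  produce no filterable markers and overstate missingness in the QC-passing
  set.
* **Breeding program**: 30 bi-parental families, 353 RIL lines (family
  sizes multinomial with minimum 1, mean ~12), 3 trials with p-rep
  replication 1.2, and a 300-QTL additive architecture whose residual
  variance is set from the target $H^2$ of accession means (0.85 for the
  flowering-time regime, 0.8/0.5 for the height/yield regimes). RILs
  inherit parental *chromosome segments*: crossover breakpoints are
  Poisson with rate twice the chromosome's cM length / 100 (the RIL map
  expansion under repeated selfing) on the genetic map implied by the
  244 kb/cM constant. Linked inheritance is essential here — with fully
  independent segregation the within-family component of genomic
  prediction collapses and cross-validated abilities lose all resemblance
  to a real program.

Elsewhere markers are simulated in linkage equilibrium, except where LD is
itself the object of study: the correlated-blocks option gives consecutive
markers a shared latent haplotype (copy probability 0.95, within-block
$r^2 \approx 0.8$) for exercising LD-kNN imputation.

What the emulation does **not** carry: real germplasm has pervasive LD,
sub-family structure within subpopulations, and closely related accession
clusters. Consequences the user should expect and that we report rather
than hide: (i) LD-kNN imputation on linkage-equilibrium data degenerates
toward mode imputation — the dedicated blocks option exists for honest
imputation tests; (ii) the leading-PC variance share of a
linkage-equilibrium mixture is bounded by the between-group allele
frequency divergence. With the diverse-panel composition used here
(~211 indica-side, ~63 japonica-side, ~9 aus of 283) the bound is roughly
$4 w_1 w_2 \sum_j (\Delta p_j)^2$ against a within-group variance of
$4\sum_j \overline{p_j q_j}$, i.e. a PC1 share of ~15–30% for any drift
divergence — far below the ~57% observed on the real panel, whose
within-group variance is concentrated on few axes by relatedness and LD.
The acceptance checks therefore treat the *separation* structure (PC1
dominant and splitting indica from japonica cleanly) as reproducible and
the 57% share as a property of the real germplasm that this generator
cannot and should not be bent to match.

The same honesty applies to the seven-model cross-validation benchmark.
The marker-based models are well centered: ridge/GBLUP predictive ability
on simulated flowering-time programs averages ~0.69 across program draws
(with a dataset-level spread of ±0.06 driven mostly by the realized
between-family share of breeding-value variance, theoretical value 0.5 for
random bi-parental crosses of unrelated founders). Pedigree BLUP, however,
can only reach ~0.5 here: with founder parents and no ancestral pedigree,
it predicts nothing but family means. A real elite program's pedigree is
deep and interconnected and its between-family variance share is larger,
which is how pedigree BLUP attains genomic-model-like ability on real
data. The seven-model average in this emulation therefore sits ~0.05–0.07
below the real benchmark; the package reports the computed values rather
than inventing founder relatedness to close the gap. Because each
simulated program is itself a random draw, the reproduction script and the
acceptance test average over three independent draws — the appropriate
surrogate for a fixed real training set.

## Numerical choices

* Golden-section/Brent tolerance 1e-8 on log-λ for REML; eigenvalues
  clipped at 0 (kernels) or dropped below 1e-8 of the maximum (RKHS).
* Gibbs guards: effect variances floored at 1e-10, inclusion probabilities
  clipped to [1e-4, 1 − 1e-4], non-finite draws abort with the iteration
  index.
* Consensus ties, classification ties and imputation half-way ties all
  have deterministic documented resolutions (missing, unassigned, nearest
  neighbour respectively).
* All generators and samplers are pure functions of (parameters, seed).

## Problem sizes used in tests and reproduction

The suite runs panels of 12–1000 markers and populations of 10–431
samples; the cross-validation checks use the full 353-line / ~950-marker
scale with 3 repeats in the test suite and 10 repeats in
`scripts/acceptance.R`, both at chain length 1,200 (burn-in 300). These
sizes were chosen as the smallest that keep Monte-Carlo error comfortably
inside the stated tolerances.

## Known limitations

* No multi-allelic sites, indels, phasing, or VCF/PLINK conversion.
* No recombination maps; RIL/F2 simulation segregates markers
  independently.
* No multi-environment or multi-trait prediction models; no GWAS.
* Pedigree-free parentage inference is out of scope; crosses must be
  declared.
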