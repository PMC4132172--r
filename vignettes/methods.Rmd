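---
title: "Methods: multilocus population genetics of a highly selfing annual"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilocus population genetics of a highly selfing annual}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`ivypopgen` reimplements, as a tested pipeline, the multilocus analysis used
to characterize North American *Ipomoea hederacea* — a self-compatible vine
with a single-locus leaf-shape polymorphism (lobed `LL`, heterozygote `Ll`,
entire `ll`) that clines with latitude. The unit of data is a per-locus
alignment of phased haplotypes, two per diploid maternal line
(`hap_alignment`); phasing is an input contract, not a computation. All
coordinates are 0-based and half-open.

Statistics are restricted to **silent sites** (noncoding plus synonymous
positions). Columns holding gaps or ambiguity codes are excluded from every
statistic: the source data for this kind of study are hand-edited Sanger
chromatographs and no indel model is described, so exclusion is a
conservative choice, not an inference about the original treatment.
Multiallelic columns are likewise excluded everywhere (from the SNP matrix
*and* from segregating-site counts) for internal consistency.

Per-site denominators use an effective silent length: noncoding columns
count 1 and every coding position counts its Nei–Gojobori fractional
degeneracy (the fraction of the three possible point mutations that preserve
the amino acid, averaged over observed haplotype codons). Monomorphic coding
positions therefore still contribute to the denominator, which a per-site
estimate needs. Coding positions whose codon is truncated by the fragment
edge cannot be evaluated and are excluded. A polymorphic coding column is
classified synonymous only when every observed change preserves the amino
acid in every observed codon context.

# Coalescent engine

Time is scaled in units of 2N generations and `theta = 4Nmu`, so the
classical identities used by the tests hold exactly: `E[TMRCA(2)] = 1` and
`E[S] = theta * a1(n)`. The structured coalescent supports an island model
(per-lineage emigration `migration_rate/2`, destinations weighted by an
optional adjacency matrix, which also yields stepping-stone chains),
exponential growth (hazard rescaled by `exp(alpha * t)` backwards in time,
sampled by inversion), deme extinction–recolonization (all lineages of a
deme jump to a random source deme), and a pooling time at which all demes
merge — the device used to give two isolated ancestral clusters a finite
common ancestor. Deme sizes are relative to the per-deme 2N, so an island
system of `d` demes of size 1 coalesces like one pool of `d` times the deme
size under strong migration; the tests account for that scaling.

Selfing is modeled at the diploidization step: an individual is autozygous
with the equilibrium probability `F = s/(2 - s)`, in which case one
haplotype is duplicated. This reproduces the FIS and homozygosity structure
the downstream analyses consume without putting selfing inside the
genealogy; the within-genealogy effective-size reduction `1/(1+F)` is
available as an opt-in time rescaling (`ne_scale_inbreeding`) and is off by
default.

Null distributions for the neutrality tests condition on the observed number
of segregating sites (fixed-S placement proportional to branch length), the
convention of the desktop tools this pipeline emulates; an unconditioned
theta-based mode exists as well. Empirical p-values use the add-one
correction `(r + 1)/(reps + 1)` and count ties in both tails.

A note on a numerical fact the tests encode: conditioned on S, the neutral
mean of Tajima's D is not 0 but slightly negative (about −0.08 for n = 20,
S = 17, confirmed against an independent coalescent simulator). Published
"simulated D" columns for comparable settings are likewise all small and
negative. Tests therefore freeze the independently verified value rather
than zero. Similarly, a *single* short locus has modest power (roughly
0.15–0.25 at the 5% level) against growth of `alpha = 10`; the powerful
version of the inference is the multilocus randomization test, which
re-draws every locus's D from its own fixed-S null and compares the observed
mean across loci — literal shuffling of locus labels cannot change a mean,
so the coalescent re-draw is the only sensible reading of that procedure.

# Diversity and neutrality statistics

Watterson's `theta_W = S/(a1 * L_silent)` and pairwise `theta_pi` (mean
silent differences over all haplotype pairs, per silent site) are computed
per population, per locus, and pooled. Pooled ("population-wide") estimates
concatenate all haplotypes before computing, then length-weight across loci;
they are *not* means of per-population values — pooling is why a total
Watterson estimate can exceed every per-population value when most variants
are local, a pattern the original table also shows. Fu's Fs uses the Ewens
sampling formula with `theta` estimated by the mean pairwise difference
count, with Stirling numbers built by a log-space recurrence (exactness is
tested by rational enumeration at n = 4, and the probabilities sum to 1 up
to n = 60). Haplotype counting for Fs treats the concatenated multi-locus
haplotypes as units; with 384 haplotypes and very low diversity the
statistic is strongly negative under expansion, as expected. R2 uses the
folded singleton definition (minor-allele count 1), the practical choice
without an outgroup.

# F-statistics and differentiation

One estimator family backs every differentiation number: Weir & Cockerham
(1984) variance components `a` (among populations), `b` (among individuals
within populations), `c` (within individuals), summed over SNPs. The
three-level AMOVA partition is the truncated-percentage view of the same
components (negative components floored at 0, Excoffier's convention), so
`FIT = FST + (1 - FST) FIS` holds by construction. FST significance permutes
individuals among populations; FIS significance permutes allele pairing
within individuals within populations (one slot permutation per population
per replicate, preserving cross-SNP structure the same way individual
permutation does). The per-SNP FST distribution, the pairwise population
FST, and the leaf-shape locus FST (computed on an L-allele dosage recoding)
all reuse the same components, making the leaf-vs-background contrast an
apples-to-apples comparison.

Isolation by distance uses Nei's (1972) standard distance, pairwise FST and
its linearization `FST/(1 - FST)`, each against great-circle (haversine,
R = 6371 km) distances, with one-tailed Mantel tests (9,999 permutations by
default) delegated to `vegan::mantel`. LD between SNPs is the squared
Pearson correlation of dosage vectors — the composite measure that needs no
phase assumption and converges to gametic r² under strong inbreeding — with
significance from the `n r² ~ chi²(1)` approximation; pruning removes every
SNP in significant LD with any other. The equilibrium selfing rate is
`SR = 2 FIS/(1 + FIS) × 100`.

# Admixture clustering with inbreeding

The clustering model is a deliberate simplification of the InStruct family:
per-individual admixture `q_i` (Dirichlet, fixed mass `alpha`), per-cluster
allele frequencies (Beta, mass `lambda = 1`), and a per-individual
inbreeding coefficient `f_i`. At a SNP, with probability `f_i` the two
copies are one draw from a single cluster of origin; otherwise two copies
with independent origins. Because autozygosity indicators and origins are
sampled explicitly, every update is conjugate — including `f_i`, which gets
a Beta draw rather than a Metropolis step (an exact conditional, so nothing
is lost). Heterozygous genotypes force the allozygous branch, which is what
lets the model separate inbreeding from subdivision.

Label switching is handled by greedily aligning each post-burn-in draw's
allele-frequency matrix to a reference draw before averaging. Model choice
uses DIC with the plug-in posterior-mean deviance, as in the tools this
mirrors. Two honest caveats, both visible in this package's own runs: (i)
plug-in DIC rewards extra clusters even on unstructured data by ~15–25
units, the same overfitting tendency that produced a large "optimal" K in
the original study while only two clusters were interpretable — so
`choose_k` reports the smallest K within 2 DIC units of the minimum
alongside the argmin; (ii) with `alpha = 1` assignments of genuinely pure
individuals are deliberately soft (a pure individual's minor-allele copies
look like immigrants under the admixture likelihood), while a small fixed
mass (`alpha ~ 0.02`, the regime alpha-inference reaches on unadmixed
selfers) reproduces the crisp ≥95% assignments reported for such data. The
package default stays at `alpha = 1`; the analysis driver uses the small
mass and says so.

Default chain settings (20,000 iterations, 2,000 burn-in) are desk-scale;
multi-chain runs report a split-chain PSRF on the deviance and flag > 1.2.
PCoA (classical MDS of an allele-sharing distance) is the model-free
cross-check.

# Leaf-shape genotypes from progeny arrays

Maternal genotypes are inferred by maximum likelihood from the segregation
of leaf shapes among 10 selfed progeny: `LL → (1,0,0)`, `Ll → (¼,½,¼)`,
`ll → (0,0,1)` on (lobed, het, entire). Ties break toward `Ll`, the only
genotype compatible with mixed classes. Under pure selfing the only
misclassification route is an `Ll` mother whose 10 selfed progeny all land
in a single homozygote class (combined probability `2·(¼)^10 ≈ 2e-6` per
family; an all-heterozygote family still identifies the mother correctly),
so recovery exceeds 99% by a wide margin, which the tests verify on 10,000
simulated arrays. An outcrossing-aware likelihood (mixture
with a configured pollen-pool L frequency) is provided but off by default,
since no pollen-pool model accompanies the original rule-based assignment.

# Synthetic data: what it emulates and what it does not

`scenario_config()` defaults encode the study design: 24 populations × 8
maternal lines (192 diploids), 7 loci of 500–800 bp, `theta` of order 0.001
per site, selfing 0.92, latitudes spanning ~31–41° with longitudes
correlated to latitude, a north/south boundary at 36°, and a leaf-shape
locus whose L frequency follows a logistic cline (0.1 south to 0.9 north,
width 0.5°) with genotypes drawn at inbreeding `F = s/(2-s)`. Demographic
options: panmixia, island, stepping-stone, exponential expansion,
metapopulation, and the patchy two-cluster scenario (populations assigned to
two ancestral pools independent of geography, no between-pool migration,
merged at a pooling time).

`calibrated_preset()` fixes `theta_per_site = 0.0007`, within-cluster
`4Nm = 4`, and a cluster split 0.5 × 2N ago. These three numbers were
chosen once from a small grid (3 seeds per setting, recorded in the
repository's calibration script) so that median pipeline outputs land near
the four calibration anchors — silent `theta_pi ≈ 0.001`, global
`FST ≈ 0.15`, `FIS ≈ 0.85`, and a strongly outlying clinal leaf locus —
while yielding ~100 biallelic SNPs, close to the 93 of the emulated study.
Mutations are realized as transitions from a random ancestral sequence at
distinct positions (infinite sites preserved); each locus carries a central
CDS covering half its length, so site classification is exercised on every
dataset.

What passing on synthetic data does **not** show: the generator has no
sequencing error, no indels, no recombination within loci, no missing data,
and its demography is exchangeable where real range expansion is not — so
agreement on synthetic data demonstrates correctness of the estimators and
the internal consistency of the pipeline, not that the original study's
numbers would be recovered from resequenced material.

# Numerical choices and problem sizes

Monte-Carlo assertions in the test-suite use fixed seeds and tolerance bands
derived from binomial standard errors at the stated replicate counts
(e.g. rejection rates checked to ±1.5 percentage points at 1,000–2,000
trials; closed-form means to 2–3% at 10,000 genealogies). The analysis
drivers use 1,000–2,000 coalescent replicates per null, 999–9,999
permutations, and 2,000 MCMC iterations per K — sizes chosen so the full
workflow re-runs in minutes on one core while leaving every qualitative
conclusion unchanged at larger settings. Ties in empirical p-values count
in both tails; undefined statistics (D with S = 0, Fs with `pi = 0`) are
reported as NA and excluded from averages rather than zero-filled; Fs
returns ±Inf sentinels when `S'` saturates numerically; Nei's D returns
+Inf when two populations share no alleles.

# Known limitations

The clustering model is not InStruct: inbreeding is per-individual rather
than a per-population selfing-rate hierarchy, `alpha` is fixed, and chains
are aligned greedily rather than CLUMPP-style. The fixed-S null follows the
desktop-tool convention rather than conditioning on the full data. AMOVA is
the Weir–Cockerham component view, which differs in small-sample detail
from sums-of-squares implementations in other packages. The metapopulation
option moves whole-deme lineage sets without an explicit propagule
bottleneck. None of these affect the identities and calibrations the tests
pin down, but all are places where a faithful reimplementation of a
specific desktop tool would differ in decimals.
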