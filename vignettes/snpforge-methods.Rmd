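---
title: "snpforge: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{snpforge: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpforge)
```

# Scope

`snpforge` reimplements, as a reusable pipeline, the computational path
used to build fixed-content genotyping arrays for non-model species from
sequencing-based SNP discovery, and to validate them by population-genetic
analysis: simultaneous SNP-exclusion filters on discovery VCFs, 71-base
probe extraction with k-mer frequency screening, Axiom-style genotyping QC
classification, and the estimator suite (heterozygosities, Weir–Cockerham
*f* and θ, hierarchical AMOVA, pairwise Fst, PCoA, SNP-subset resampling,
site frequency spectra, Evanno ΔK). Because the real sequencing and array
data behind such a study are not required, a synthetic-data module
generates every input with planted ground truth; all tests run against
that truth.

# The synthetic world

## Two-level hierarchical island model

Genotypes are simulated under a nested Balding–Nichols model. Per locus an
ancestral frequency $p_0$ is drawn uniformly from `ancestral_maf_range`
(default 0.05–0.5, emulating array SNPs ascertained to be common). Each
region draws

$$p_r \sim \mathrm{Beta}\!\left(p_0\tfrac{1-\theta_R}{\theta_R},\;
(1-p_0)\tfrac{1-\theta_R}{\theta_R}\right),$$

and each population inside a region draws analogously from $p_r$ with
$\theta_P$. Genotypes within a population follow
$P(\text{het}) = 2pq(1-F)$ with per-population inbreeding $F$. Under this
construction the expected among-region and among-population-within-region
fixation indices equal $\theta_R$ and $\theta_P$, which is exactly what
makes the generator usable for estimator-recovery testing.

Defaults are the stated world of a range-wide conifer survey: 2 regions
(7 + 8 populations), 12 diploid trees per population, 2,022 biallelic
loci, $\theta_R = 0.28$, $\theta_P = 0.05$, and small per-population $F$
of either sign (one population at 0.14, one at 0.084, the rest near
zero). These values are fixed once; tests never tune them.

Degenerate corners are defined rather than left to chance: $\theta = 0$
copies the parent frequency exactly; negative $F$ can make a homozygote
class probability negative at extreme frequencies, in which case the
class probabilities are clamped at zero, renormalised and a warning
raised (so the realised inbreeding at such loci is slightly shallower
than configured — the Weir–Cockerham estimator weights those loci weakly
and recovery stays within ±0.02).

## Discovery data and planted filter truth

The discovery simulator emits reference contigs, a two-sample VCF
(`single_haploid`, a conifer megagametophyte that can never truly be
heterozygous, and `pool_diploid`), a mask BED, contig exclusion lists and
a truth ledger. Planted artifacts: indels, clustered SNPs
(`cluster_fraction`), an AT-repeat low-complexity stretch per contig
(`lcr_fraction`), artifactual heterozygous haploid calls
(`haploid_het_fraction`) and sub-threshold genotype confidences
(`lowconf_fraction`). Non-cluster SNPs are planted more than 30 bp apart
so that `cluster_fraction = 0` provably implies zero expected cluster
tags.

The ledger's expected tags are computed inside the generator by brute
force on the *realised* sequences and positions (pairwise distance scans,
interval membership, run-length scans) — never by calling the
ascertainment code — so exact tag recovery is a genuine two-route check.

What the generator does **not** emulate: read-level error, linkage
disequilibrium, coalescent genealogy, allele dropout, and any spatial
cline mechanism. A green recovery test therefore establishes that the
estimators invert the stated generative model, not that the model is a
demographically realistic portrait of any species.

# Ascertainment filters

Filters are simultaneous and additive: a variant can carry several tags,
and PASS means an empty tag set. Constants (all in
`ascertainment_config()`): calls with RAD `GT_CONF` < 3 or RNA `GQ` < 30
are NULLed (strictly-lower rule; sites with no remaining call are
removed); indels are `TypeIndel` and SNPs within 60 bp (inclusive) of any
base of an indel's reference span are `SnpGap`; a SNP with at least one
other SNP within 30 bp (inclusive) is `snpCluster`, symmetrically. The
wording "more than one SNP within a 30 bp window" is ambiguous between
≥ 1 and ≥ 2 neighbours; we read it as counting the target itself
(≥ 1 neighbour) and expose `cluster_min_neighbors`.

Low-complexity masking is a DUST-style scorer because the published
method names no parameters: windows of 64 bases are scored
$10 \sum_t c_t(c_t-1)/2 \,/\, (k-1)$ over their overlapping triplets and
masked at score ≥ 20; homopolymer runs of ≥ 6 bases are reported
separately and SNPs within 5 bp of a run are tagged `Homopolymer` (the
run/margin rule is a configurable stand-in — published pipelines count
homopolymer exclusions without defining one). Users can supply their own
BED instead. Hard-filter tagging uses GATK's published SNP defaults
(QD < 2, FS > 60, MQ < 40, MQRankSum < −12.5, ReadPosRankSum < −8,
SOR > 3; strict inequalities, absent annotations never fail) and applies
to RNA-source variants only. A/T and C/G SNPs are `NonSingleProbeType`
because they need two probes on the array. Coordinates are 1-based closed
internally (VCF convention); BEDs are emitted 0-based half-open.

# Probe design

For each catalog SNP the 35-bp flanks are extracted in both orientations
with the site encoded `[ref/alt]` at position 36. All 56 16-mers of the
71-base window — for *both* center alleles, the worst case governing the
verdict — are looked up in a canonical (strand-collapsed) k-mer index of
the whole reference; a probe whose worst k-mer has strictly more than 100
reference matches is `not_recommended`. Canonicalisation reflects
strand-agnostic hybridisation; whether the original pipeline collapsed
strands is unstated, so this is recorded as a design choice. Array
content sampling draws uniformly under caps: one SNP per contig, up to
two for contigs at or above the 90th length percentile (the threshold is
configurable; none is published).

# Array QC

Samples pass with DQC > 0.82 and call rate > 0.97 (strict). SNPs are
classified with precedence CRBT (CR < 0.97) → MHR (minor allele in fewer
than 2 samples) → NMH (polymorphic but no minor homozygote) → PHR.
Singleton-minor-allele SNPs are MHR under the reading "passes everything
except polymorphism"; intensity-dependent classes (OTV/OTH) require
signal data this pipeline never sees and are never emitted. The
conventional criteria are inclusive: success at CR ≥ 0.90, converted with
additionally MAF ≥ 0.005. Duplicate concordance is computed over
co-called SNPs only; duplicates are copied *before* missingness is
applied so the concordance path genuinely exercises missing-data
handling.

# Population-genetic estimators

Expected heterozygosity uses Nei's unbiased small-sample correction
$(2n/(2n-1))(1 - \sum_a p_a^2)$. The within-population inbreeding
estimator is Weir–Cockerham's *f*, multilocus as a ratio of sums of the
per-locus variance components (never a mean of per-locus ratios), with
percentile bootstrap CIs over loci (default 1,000 replicates);
significance means the CI excludes zero. Regional summaries are
unweighted means of per-population values. The overall row uses
unweighted means for Ho/He but pools the *b*, *c* components across
populations for *f* — the ratio-of-sums convention of the classic
estimator, which keeps the overall *f* consistent with its bootstrap.

Hierarchical AMOVA works at the allele level: per locus, sums of squares
among regions, among populations within regions and within populations
are converted to variance components with the unbalanced nested-ANOVA
coefficients, components are summed over loci, and
$F_{stR} = V_a/(V_a+V_b+V_c)$, $F_{stP/R} = V_b/(V_b+V_c)$,
$F_{stT} = (V_a+V_b)/(V_a+V_b+V_c)$, which satisfy
$(1-F_{stR})(1-F_{stP/R}) = 1-F_{stT}$ identically. Negative components
are retained (moment estimators) and flagged. Permutation tests permute
whole populations among regions ($F_{stR}$), individuals among
populations within regions ($F_{stP/R}$), and individuals among all
populations ($F_{stT}$); defaults 999 permutations, 1,000 bootstrap
replicates, every seed logged.

Individual distances use the codominant squared scheme
($d^2(AA,AB)=1$, $d^2(AA,BB)=4$, $d^2(AB,AB)=0$), summed over co-called
loci and divided by their number; uniform scaling cancels in the
AMOVA/PCoA ratios while per-pair scaling keeps pairs with different
missingness comparable. PCoA is Gower double-centering of the
squared-distance matrix with eigendecomposition; axis percentages are
taken over positive eigenvalues only.

Evanno's statistic is
$\Delta K = |L(K+1) - 2L(K) + L(K-1)| / \mathrm{sd}(L(K))$, defined for
interior $K$ only; zero run-to-run sd makes ΔK undefined at that K (it
is excluded from the arg-max with a warning). Note a boundary subtlety:
with a run over $K = 2\ldots15$, ΔK at $K = 2$ is undefined, so a study
whose true K is 2 can only be confirmed by ΔK if $K = 1$ is included —
the likelihood-table simulator therefore defaults to `k_range = 1:15`.

Microsatellite-style multiallelic data are supported by generalising the
allele-count formulas per allele. The simulator for such markers adds a
per-allele-copy mutation rate (`mu`): under a pure Dirichlet island model
with equal θ, the Weir–Cockerham estimator is unbiased for any allele
count, and it is recurrent-mutation homoplasy — not allele number per se
— that dampens differentiation at hypervariable markers. The qualitative
contrast (higher He, lower θ̂ for 10-allele loci with mutation) is
reproduced in the test suite with `mu = 0.08`.

# Numerical and degenerate-input choices

* All-NoCall SNPs get `NA` metrics rather than errors; populations with a
  single genotyped individual are excluded from diversity summaries with
  a warning; duplicate pairs without co-called SNPs are skipped with a
  warning.
* MAF ties at 0.5 treat the B allele as minor (affects only the carrier
  count of perfectly balanced SNPs).
* Percentages in performance tables are rounded to one decimal; a zero
  denominator yields `NA`, not an error.
* All randomised operations take explicit seeds; the pipeline driver
  derives stage seeds from one global seed and writes them to the run
  log, so a run is fully reproducible from its resolved-config copy.

# Known limitations

No variant calling, realignment, intensity/CEL processing, OTV
resolution, Bayesian STRUCTURE clustering or CLUMPAK consensus — those
stages are consumed as inputs (VCFs, DQC values, likelihood tables). The
DUST parameters and the homopolymer rule are stand-ins for unpublished
choices and are exposed in the configuration. The synthetic world has no
linkage disequilibrium, so estimator variances on simulated data are
smaller than real-data variances at equal locus counts.
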