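---
title: "Methods: sex-linked marker discovery from DArTseq matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-linked marker discovery from DArTseq matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexlinkr)
```

## The problem

Many amphibians carry homomorphic sex chromosomes: X and Y (or Z and W)
that are cytogenetically indistinguishable, so the heterogametic sex cannot
be read off a karyotype. Reduced-representation genotyping
(DArTseq and its SilicoDArT presence–absence companion) offers an indirect
route: a locus residing on the differentiated portion of a sex chromosome
shows a characteristic pattern across phenotypically sexed individuals —
heterozygous (or present) in the heterogametic sex, homozygous (or absent)
in the homogametic one. `sexlinkr` implements that inference, the
association statistics that validate it, and the population-structure
analyses that must precede it (because marker–sex concordance can only be
interpreted within a genetically homogeneous cohort).

## Data model

SNP calls use the one-row DArT coding: `0` homozygous reference, `1`
homozygous alternate, `2` heterozygous, `-` missing. Presence–absence (PA)
loci are `1` present / `0` absent / `-` missing. In memory both live in a
tibble with one row per locus, locus metadata columns, and one integer
column per sample; `calls_matrix()` exposes the loci × samples matrix.
`SnpPosition` is treated as a 0-based offset into the trimmed sequence
(the DArT convention). Metadata columns absent from an input file are kept
as all-`NA` columns and flagged, so downstream code need not special-case
them.

## The sex-linkage scan

For each locus surviving an 80% call-rate filter (inclusive: a locus
called in exactly 80% of samples is kept), fractions are computed over the
*called* individuals of each phenotypic sex; unknown-sex individuals are
excluded. A SNP is called **XY-linked** when

$$\mathrm{het}_M \ge c \quad\text{and}\quad \mathrm{hom}_F \ge c,$$

and **ZW-linked** with the sexes swapped, with concordance threshold
$c = 0.8$ by default. "Homozygous" here counts both homozygote classes.
PA loci use presence in place of heterozygosity and absence in place of
homozygosity. Since $c > 0.5$, a locus can never satisfy both systems at
once. A locus is graded **PERFECT** when both qualifying fractions equal 1
and **MODERATE** otherwise; the 0.8 threshold means a moderate marker is
discordant in fewer than 20% of individuals of either sex. Thresholds are
compared inclusively (`>=`), matching the "at least 80%" phrasing of the
criteria.

Denominators are called individuals rather than cohort sizes. The 80%
call-rate pre-filter bounds how far the two can diverge, and computing
concordance on genotyped animals is the only option that does not conflate
missingness with discordance.

**False-positive test.** With few individuals, chance splits can satisfy
the concordance criterion. Candidate SNPs are therefore additionally
required to be at least 80% homozygous *for a single consistent allele
class* in the homogametic sex (females under XY, males under ZW). We read
"either reference or alternate" as one majority class per locus, not as
the sum of both homozygote classes — under the summed reading the test
would be implied by the main criterion and would never reject anything,
so the single-class reading is the only one under which it adds power.
This interpretation is a package decision and is stated in the function
documentation. The test applies to SNPs only: for PA loci
presence/absence concordance *is* the criterion, there being no genotypic
homozygosity to check.

**Strict mode.** Below 13 individuals per sex (the conventional
small-sample bound for sex-linkage scans of this kind), chance
concordance becomes non-negligible even with the false-positive test, so
the scan auto-enables strict mode, which demands 100% concordance. The
threshold and the auto-enabling are both overridable
(`sex_link_criteria(auto_strict = FALSE)` or `strict = TRUE`). Strict
results are always a subset of default-mode results, and raising the
concordance threshold can only remove calls — both properties are
asserted in the test suite.

## Association statistics

**Hamming distances.** Pairwise distances are the fraction of differing
codes among loci co-called in both samples (pairwise-complete
normalization, values in $[0,1]$). Codes are compared as categorical
states — a heterozygote differs from either homozygote — with no
allele-sharing weighting. Pairs with zero co-called loci are flagged
undefined rather than zero. Over a perfectly sex-linked marker panel the
between-sex mean is exactly 1 and the within-sex means exactly 0, which
is the signature the scan's output should reproduce and the package's
acceptance script recomputes.

**Cochran–Armitage trend test.** The classic 1-df trend statistic
$\chi^2 = N r^2$, with $r$ the Pearson correlation between
alternate-allele dosage (scores 0/1/2, customizable) and the sex
indicator over called, known-sex samples. The permutation p-value
shuffles sex labels; because the permutation distribution of the
statistic is heavily discrete, the mid-p estimate is reported (ties
counted half, the observed statistic included among its own ties), which
keeps the p-value uniform under the null — the tie-inclusive estimator is
conservative and fails a uniformity check by construction. A combined
test across a marker panel (trend test on the first principal-component
score of the dosage matrix) is offered as a clearly labelled extension;
published applications of the test to whole panels do not document a
joint statistic, and the per-locus median/minimum plus the combined score
are reported instead of imitating one.

## Population structure

Structure analyses run on a stringent autosomal subset: sex-linked loci
are removed, then only loci with exactly 100% call rate and 100%
reproducibility (`RepAvg`) are kept.

- **PCA**: dosage encoding, per-locus mean imputation of missing calls,
  column centering, eigendecomposition of the sample covariance
  (`stats::prcomp`).
- **F\_ST**: the Weir–Cockerham (1984) estimator, multi-locus
  ratio-of-sums over the per-locus $a$, $b$, $c$ components. The
  estimator choice is documented so users comparing against other tools
  (e.g. Nei-based estimators) know what they are looking at.
- **Nei (1972) standard distance**:
  $D = -\ln\left(J_{xy} / \sqrt{J_x J_y}\right)$ with the $J$'s
  arithmetic means over loci of the allele-frequency identity sums.
  Individual-level mean distances within clusters use
  1 − (proportion of shared alleles) over co-called loci; the convention
  is stated because published individual-distance values depend on it and
  alternatives (e.g. Euclidean on dosage) give different numbers.
- **AMOVA**: allele-level, three strata (between clusters, between
  individuals within clusters, within individuals). Each diploid
  individual contributes two allele vectors; sums of squares use allele
  mismatch, equivalent to the F-statistics formulation. Degrees of
  freedom are $k-1$, $N-k$, $N$ and $2N-1$ for the total. Variance
  components follow the method-of-moments equations with the unequal-size
  coefficient $n_0 = (M - \sum_c m_c^2/M)/(k-1)$ on allele counts
  $m_c = 2N_c$. Negative component estimates are truncated at zero for
  the percentage decomposition and reported raw alongside. Permutation
  p-values: individuals across clusters for the between-cluster
  component; alleles across individuals within clusters for the
  between-individual component; alleles across all individuals for the
  within-individual component (left-tailed on the within-individual
  variance, which shrinks relative to the null when structure is
  present).

## The simulator

`simulate_dataset()` produces DArTseq-like SNP and PA matrices with known
truth so every downstream stage is testable without access to restricted
genotype data.

- **Autosomal SNPs**: ancestral alternate-allele frequency
  $p \sim U(0.05, 0.95)$; cluster frequencies from the Balding–Nichols
  Beta$\left(p\frac{1-F}{F}, (1-p)\frac{1-F}{F}\right)$ distribution with
  $F$ the target divergence; Hardy–Weinberg genotypes within cluster.
  Autosomal PA loci get presence frequencies by the same construction.
- **Sex-linked loci**: under XY, each male is heterozygous (present) and
  each female homozygous for a per-locus fixed class (absent) with
  probability $1 - d$, where $d$ is the per-individual discordance; ZW
  mirrors. The fixed homozygote class matches the single-allele
  expectation the false-positive test assumes.
- Missing calls are i.i.d.; metadata (CallRate, frequencies, PIC,
  RepAvg = 1) are recomputed from the realized matrix; a single global
  RNG stream seeded from `config$seed` makes output bit-for-bit
  reproducible.

Defaults encode the cohort the package was built around: 44 individuals
(19 males, 25 females) in two clusters of 36 (14M/22F) and 8 (5M/3F),
between-cluster $F_{ST}$ 0.24, 11 sex-linked SNP and 24 sex-linked PA
loci under male heterogamety, discordance 0.1 (inside the <20% moderate
band), 5% missingness. The autosomal locus count defaults to 5000 — large
enough that chance-concordance rates and divergence recovery are measured
meaningfully, small enough that a full pipeline run takes seconds. The
simulator adds autosomal PA loci (default 1000) so false-discovery
behaviour of the PA scan is measurable; no published count constrains
this, it is simply a realistic background.

What the simulator does **not** emulate: linkage disequilibrium between
loci, coalescent ancestry, read-depth-driven genotyping error (missingness
is uniform rather than coverage-correlated), sex-chromosome dosage effects
on call quality, and technical replicate structure (RepAvg is fixed at 1).
Passing recovery tests on simulated data therefore demonstrates the
correctness of the filtering arithmetic and the estimators under the
stated model, not robustness to every artefact of real reduced-
representation data.

## Numerical choices

- Threshold comparisons use `>=` with a $10^{-12}$ tolerance so that
  fractions like $28/35 = 0.8$ are not lost to floating-point error.
- PIC is computed in expected-heterozygosity form ($1 - \sum p_i^2$;
  DArT-style per-allele PICs from the one-ratios). DArT does not publish
  its PIC formula; the value is informational and never used for
  filtering.
- An all-missing locus has call rate 0 and undefined (`NA`) frequencies.
- Loci with any missing call are dropped from AMOVA (the strict autosomal
  filter already guarantees completeness in the pipeline path).
- `FROM_PCA` clustering is 2-means on the first two PC scores with 10
  restarts; supplied labels always take precedence when present.
- Permutation p-values use the add-one estimator for AMOVA (statistics
  effectively continuous there) and mid-p for the trend test (statistic
  heavily discrete).

## Problem sizes in the test suite

The suite exercises the pipeline at the cohort sizes above; simulation-
heavy properties (divergence recovery at $F_{ST}$ 0.24 over 5000 loci,
marker recovery over 10 seeds, false-positive rates at 3 vs 13+ per sex,
null uniformity of the permutation p at 500 permutations) run at sizes
chosen to keep each check's Monte Carlo error well below the asserted
tolerance. These are the package's own settings, stated here so that
anyone re-running the suite knows what was measured.

## Known limitations

- The scan detects loci in the *differentiated* region of a sex
  chromosome; a young or freely recombining sex chromosome yields few or
  no qualifying loci, and an absence of markers is not evidence of
  environmental sex determination.
- With very small cohorts even strict mode admits chance-perfect
  autosomal loci (the expected count grows linearly in the number of loci
  tested); marker counts from cohorts below ~13 per sex should be treated
  as candidate sets for validation, not final inventories.
- Phenotypic sexing errors are indistinguishable from genuine discordance;
  a consistently mis-sexed individual depresses the concordance of every
  true sex-linked locus.
- The individual-level distance and PIC conventions are choices among
  several in circulation; cross-study comparisons should verify the
  convention before comparing numbers.
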