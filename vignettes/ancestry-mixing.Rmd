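---
title: "Estimating ancestry mixing proportions from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ancestry mixing proportions from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancmix)
```

## The problem

A genome-wide association study (GWAS) over a multi-ethnic cohort is, for
many downstream purposes, characterised by its *ancestry mixing
proportions*: the fractions $w_k$ of study subjects attributable to each of
$K$ reference populations, with $w_k \ge 0$ and $\sum_k w_k = 1$. Accurate
$w$ estimates feed summary-statistics imputation, ancestry-adjusted allele
frequencies, and stratification diagnostics. Individual-level genotypes are
rarely shareable, so the estimators in this package consume only summary
statistics: per-SNP study reference-allele frequencies (AFs) when these are
released, or — because AFs are increasingly withheld for privacy reasons —
only per-SNP association Z-scores.

Three estimators are provided, against a reference panel that carries
per-population allele frequencies $p_{ik}$ (SNP $i$, population $k$) and,
for the Z-score route, subject-level genotype dosages:

* **afmix** (covariance matching). Modelling the study AF vector as
  $S = \sum_k w_k P_k$ gives $\mathrm{Cov}(S, P) = \mathrm{Cov}(P)\, W$, so
  $\widehat W = \mathrm{Cov}(P)^{-1} \mathrm{Cov}(S, P)$ with sample
  covariances taken across SNPs. To blunt linkage disequilibrium (LD), SNPs
  are divided into quasi-independent strided sets (every `n_sets`-th SNP)
  and the closed form is evaluated per set.
* **summix** (constrained least squares). Minimises
  $\sum_i (S_i - \sum_k w_k p_{ik})^2$ over the probability simplex in a
  single quadratic program over all matched SNPs.
* **zmix** (Z-scores only). Under the null, Z-scores inherit the
  correlation structure of the standardized genotypes
  $G'_{ijk} = (G_{ijk} - 2 p_{ik}) / \sqrt{2 p_{ik} (1 - p_{ik})}$, and for
  a mixed cohort
  $E(Z_i Z_l) = \sum_k w_k \,\mathrm{Cor}(G'_{i\ast k}, G'_{l\ast k})$,
  where the per-population correlations are approximated from the reference
  panel. zmix forms all SNP pairs within each quasi-independent set
  (subsampled beyond `max_pairs_per_set`) and minimises
  $\sum_{i \ne l} \big(Z_i Z_l - \sum_k w_k \mathrm{Cor}_k(i, l)\big)^2$ on
  the simplex.
* **zmix_legacy** reconstructs the older consecutive-pair, unconstrained
  baseline that zmix supersedes (clip negatives, renormalize, average); it
  is included for comparison only. Its exact historical pairing rule was
  never published; consecutive pairs within each set are this package's
  explicit interpretation.

## How the constraints are applied, and why

The simplex constraints are solved by quadratic programming
(`pracma::quadprog`, with an exact active-set fallback; every solution is
certified by a Karush-Kuhn-Tucker residual below $10^{-6}$).

Where the constraint is applied matters. The classic construction solves
every quasi-independent set under the simplex constraints and averages the
per-set solutions. That is unbiased only when each set is
information-rich (thousands of SNPs or pairs per set, as when millions of
GWAS SNPs are split into 1000 sets). At the desk scales this package
targets (tens of thousands of SNPs), per-set solutions are noisy, and
averaging *projected* estimates is biased toward the centre of the simplex:
on a cohort drawn 100% from one super-population group, per-set averaging
over small sets visibly shrinks the dominant-group weight toward uniform,
while the information-preserving alternatives below recover it. The package
therefore defaults to:

* **afmix**: average the *unconstrained* per-set closed-form solutions
  (each unbiased), then project the average onto the simplex once
  (`constrain = "average"`). The literal per-set clipping
  (`constrain = "per_set"`) and a per-set QP (`constrain = "strict_qp"`)
  remain available.
* **zmix**: accumulate the per-set normal equations and solve the summed
  objective once on the simplex (`combine = "pooled"`). This is exactly the
  printed objective $\min_w \sum_{i \ne l} (Z_i Z_l - \sum_k w_k
  \mathrm{Cor}_k)^2$ extended over all sets; `combine = "per_set"` gives
  the classic averaging. In both cases the per-set constrained solutions
  are retained in `per_set_weights` and their spread is reported as
  `sd_weights`, so the across-set variability remains visible.

In the information-rich regime the defaults and the per-set averaging
agree; at desk scale the defaults are the statistically sound choice.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_sets` | 1000 | quasi-independent strided SNP sets; reduced with a warning to `n_snps/10` when SNPs are scarce, since tiny sets give degenerate covariances |
| `max_pairs_per_set` | 5000 | cap on Z-score pairs per set; all pairs is $O(m^2)$ and explodes for dense input; beyond the cap pairs are subsampled uniformly under `seed` |
| `maf_min` | 0.01 | minor-allele-frequency filter (pooled panel AF, and study AF in AF mode); stabilises the $\sqrt{2p(1-p)}$ standardization denominators; 0 disables |
| `drop_ambiguous` | TRUE | drop strand-ambiguous (A/T, C/G) SNPs during harmonization — a strand flip is undetectable for them |
| `match_by` | "both" | match records to the panel by rsid and position; "rsid" or "position" alone tolerate coordinate or annotation drift |

Within-population monomorphic SNPs contribute correlation 0 for that
population (they carry no information there but remain informative for
others); SNPs monomorphic in *every* population are excluded before
partitioning. These sites occur naturally — zero-inflated reference allele
counts are a known hazard for Z-score-based estimation — and the generator
below deliberately retains them.

## The synthetic panel generator

`generate_panel()` builds a structured reference panel by a hierarchical
Balding-Nichols construction: per SNP an ancestral frequency
$q \sim U(0.05, 0.95)$; each super-population group $g$ draws
$q_g \sim \mathrm{Beta}(q (1-F_g)/F_g,\; (1-q)(1-F_g)/F_g)$; each
population $k$ in group $g$ draws $p_k$ from $q_g$ with its own drift
$F_k$; dosages are $\mathrm{Binomial}(2, p_k)$ per subject. With group
drift 0 this collapses to the flat single-level model. The Balding-Nichols
drift parameter equals the expected pairwise Hudson FST between two
populations sharing the parent frequency, which the tests verify against an
independent Hudson estimator.

The default layout (`sim_panel_template()`) has 13 populations in five
super groups — AFR (2), AMR (2), ASN (4), EUR (4), SAS (1) — sized so that
all four benchmark mixtures (a pure European-group cohort, a pure
East-Asian-group cohort, an equal-thirds three-group cohort, and a
50/25/15/10 African/admixed-American mixture) can be simulated. Group
drifts are AFR 0.05, AMR 0.04, ASN 0.09, EUR 0.05, SAS 0.07: the
African-analog group is deliberately the least drifted, mirroring real
continental panels where African populations are ancestral-proximal and
carry the highest heterozygosity (an earlier inverted assignment makes the
African-analog AFs more extreme than reality and visibly distorts the
Z-score estimator on admixed cohorts). Pairwise between-group FST lands at
roughly 0.08–0.15 and within-group FST at 0.006–0.02. Per-population
subject counts default to 200 and SNP counts to 20000 — large enough for
the estimators' asymptotics to be visible, small enough to run on a
laptop.

`simulate_cohort()` resamples subject columns with replacement from the
source populations ($n_k = p_k N$, fractional counts resolved by the
largest-remainder method so the counts sum to $N$ exactly);
`simulate_zscores()` draws one standard-normal dummy phenotype shared
across SNPs and computes each SNP's regression t-statistic. Sharing one
phenotype vector preserves the cross-SNP Z correlation structure the
Z-score estimator consumes; redrawing per SNP would destroy it.

**What the generator does not emulate.** SNPs are generated independently —
there is no LD, no haplotype structure, and no admixture *within*
individuals (cohorts are mixtures of unadmixed subjects). The
quasi-independent-set machinery is still exercised (the estimators cannot
know the SNPs are independent), but passing tests on this generator say
nothing about LD-induced bias in real data, about INDELs/multi-allelic
sites, or about case-control phenotypes with real effects. The AMR-analog
populations are drifted groups, not two-way admixed genomes as real
admixed-American populations are.

## Numerical choices and degenerate inputs

* Sample covariances use denominator $m - 1$; within-set covariance
  matrices receive a ridge of $10^{-8} \cdot \mathrm{tr}/K$ before
  inversion, and sets that remain singular (near-duplicate populations) are
  skipped and counted.
* Sets smaller than $K + 1$ SNPs (afmix) or 2 SNPs (zmix) are skipped and
  counted; if every set is skipped the estimator errors rather than
  returning a vacuous answer.
* Monomorphic rows error inside `normalize_genotypes()` (division by
  zero); upstream code must exclude or zero them, as described above.
* All randomness flows through explicit `seed` arguments; the caller's RNG
  state is saved and restored, so repeated calls with equal seeds are
  bit-identical and no hidden global state leaks.
* Weight vectors are reported to full precision; weights within
  $10^{-10}$ of the boundary are clipped into $[0, 1]$ and renormalized.

## Scale of the shipped checks

The package's acceptance checks replay the four benchmark mixtures on the
default 20000-SNP, 200-subject-per-population panel with 2000-subject
cohorts; the Z-score estimator uses 200 sets, the 5000-pair cap and 10
replicate cohorts. These sizes were chosen as the point where the
estimators' behaviour is clearly resolved while a full replay stays in the
minutes range. At this scale the AF-based estimators recover the
population-level truth to well under one percentage point, and the Z-score
estimator resolves super-population composition to a few points — with the
admixed 75/25 African/admixed-American mixture its African-group weight
sits several points below the AF-based estimators', the expected behaviour
of the linear within-population-correlation approximation under strong
admixture LD (cohort-wide standardization attenuates the within-population
signal; the simplex constraint then redistributes the deficit).

## Limitations

* The Z-score estimator needs genome-wide input; the AF estimators work on
  a chromosome or region, but products of Z-scores carry far less
  information per SNP.
* Harmonization assumes both files are on the same genome build; no
  liftover is attempted.
* Z-scores from heavily ancestry-adjusted association models may deviate
  from the null correlation model; the estimator assumes the adjustment
  rescales effects without reshaping their correlation.
* Only biallelic SNVs are supported.

## A worked run

```{r example, eval = FALSE}
panel <- generate_panel(n_snps = 20000, n_per_pop = 200, seed = 42)
props <- read_scenario("cohort4")$proportions  # 50/25/15/10 admixed mixture
cohort <- simulate_cohort(panel, props, 2000, seed = 1)

# allele-frequency route
study_af <- study_vector(cohort_afs(cohort), "af")
summary(summix(study_af, panel))

# Z-score-only route
zs <- simulate_zscores(cohort, seed = 2)
study_z <- study_vector(zs$z, "z")
fit <- zmix(study_z, panel, n_sets = 200, seed = 3)
round(100 * aggregate_superpop(fit), 1)
```
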