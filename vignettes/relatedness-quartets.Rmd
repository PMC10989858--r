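---
title: "Relatedness from triplets and quartets of marker genes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relatedness from triplets and quartets of marker genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relquartet)
```

## The model

Two diploid individuals A and B carry four genes at a locus. Every
distinguishable identity-by-descent (ibd) partition of those four genes is
one of the nine Jacquard condensed modes $\Delta_1,\dots,\Delta_9$, from
all four ibd ($\Delta_1$) down to no ibd at all ($\Delta_9$). A Jacquard
vector is the complete generative description of pairwise relatedness at
one locus: draw a mode from $\Delta$, expand it uniformly at random into a
detailed configuration compatible with the mode (which of B's genes joins
A's pair under $\Delta_3$, which disjoint cross-pairing under $\Delta_7$,
which single cross pair under $\Delta_8$), then assign every ibd class an
allele drawn independently from the locus frequencies $p$. The function
`quartet_mode_probability()` evaluates this definition by direct
enumeration and is the oracle against which everything else in the package
is validated.

Eight relatedness coefficients summarize $\Delta$:

* $F_A, F_B$ — inbreeding coefficients (within-individual pair ibd),
* $R$ — the kinship-scale pairwise coefficient: one gene sampled from
  each individual, probability of ibd,
* $G_A, G_B$ — three-gene coefficients: one individual's pair plus a
  random gene of the other, all ibd,
* $F_{AB}$ — both within-individual pairs simultaneously ibd,
* $R_{AB}$ — a random disjoint cross-pairing ibd as two pairs,
* $H$ — all four genes ibd.

The map implemented in `jacquard_to_coefficients()` carries the
"sampling" weights ($\Delta_3/2$, $\Delta_7/2$, $\Delta_8/4$, ...) that
arise because a randomly sampled gene of the partially shared individual
hits the ibd class with probability 1/2 (or a single pairing out of four).
It is an affine bijection; `coefficients_to_jacquard()` inverts it.
Because the map is linear and the mode probabilities are exact
polynomials in $p$, every genotype-pair class probability is affine in
the eight coefficients. The closed forms in `quartet_class_probability()`
were derived symbolically from the mode mixture and are tested against
the enumeration at machine precision for all nine pure modes; this
single property pins down all nine class formulas simultaneously.
Several secondary transcriptions of these class formulas circulate with
typographic corruption (wrong factors of two, a sign on the $F_{AB}$ term
of the double-heterozygote class, $p_j$ where $p_i$ is required); the
generative enumeration is treated as authoritative throughout, and the
suite enforces it.

Cumulants enter at order four: through order three, cumulants of allele
indicators equal central moments, but
$\kappa_4 = \mu_{4c} - 3\kappa_2^2$ (univariate) and
$\kappa_{1234} = \mu_{1234c} - \sigma_{12}\sigma_{34}
- \sigma_{13}\sigma_{24} - \sigma_{14}\sigma_{23}$. $H$ is the
order-four cumulant normalized by $p(1-p)(1-6p(1-p))$; $F_{AB}$ and
$R_{AB}$ are covariance-bearing: under a population mixture
$F_{AB} = F_A F_B + \mathrm{Cov}(F_A, F_B)$, so estimated values may
legitimately exceed the product bounds that pure probabilities satisfy.
For this reason admissibility (the ordering chain
$H \le G_\bullet \le F_\bullet$, $H \le F_{AB} \le \min(F_A,F_B)$,
$H \le R_{AB} \le R$, checked by `coefficient_consistency_report()`) is
enforced softly: a warning, with a hard error only when a class
probability itself would go negative.

## Estimators

All inverters are algebraic inversions of the forward model above, never
transcribed closed forms:

* `estimate_R()`: $\hat R_{ii} = (f_{ii} - p_i^2)/(p_i q_i)$ per allele,
  combined with weights summing to one. The default
  $w_i = (1-p_i)/(n-1)$ equals the constrained minimum-variance weights
  at the null prior, which `allele_weights()` recomputes numerically as
  the minimizer of $w^\top V w$ with $V$ obtained by exact enumeration.
* `estimate_G()`: per-allele inversion of the triple-homozygote class
  given prior $F$ and $R$; the denominator $p q (1-2p)$ vanishes at
  $p = 1/2$, and such components are flagged non-estimable, never
  zero-filled.
* `estimate_H_Fab()` / `estimate_H_F_R()`: joint closed-form solves of
  the 2x2 system (classes $f_{AAAA}$, $f_{AaAa}$; unknowns $H, F_{AB}$)
  and the 3x3 system (adding the alternate-homozygote class
  $f_{AAaa}$, either orientation; unknowns $H, F_{AB}, R_{AB}$). Both
  need a third allele in the population ($p + q < 1$); the 2x2
  determinant carries $(1-2p)$ and the 3x3 determinant $(1-3p)$, so
  $p = 1/2$ and $p = 1/3$ respectively are noninformative and flagged.
  The systems are built at run time from the model's derivative rows and
  solved with `solve()`; the test suite verifies exact inversion of the
  forward system and verifies the determinant vanishes only at the
  stated frequencies on a 0.01 grid.
* `estimate_all_eight()`: the residual solve of the eight chosen classes
  (`iiii, ijij, iijj, iiij, ijjj, iijk, ijkk, ijik` on an allele triple)
  against `design_matrix()`. The matrix is nonsingular for generic
  frequencies but degenerates when two chosen alleles share a frequency
  (the i/j-symmetric classes become linearly dependent); this is flagged
  via the reciprocal condition number rather than a frequency rule, and
  the estimate is withheld when flagged.
* `weir_identity_disequilibrium()`: the classic double-homozygote
  contrast with coefficients $a = 6(6pq-2p-2q+1)$, $b = 1-6pq$,
  $c = 6pq(1-p-q)(1-3p)$; the sign of $c$ is reported because it
  changes at $p = 1/3$.

Estimates are never truncated to $[0,1]$: unbiasedness requires an
unbounded estimator, and out-of-range values are flagged instead.

## Maximum likelihood

`fit_ml()` maximizes the multinomial likelihood across loci by EM over
the latent identity mode of each genotype-pair observation: the E-step
computes posterior mode memberships $\gamma_{k}\propto\Delta_k
m_k(\text{obs})$, the M-step averages them. Operating on the $\Delta$
simplex makes the latent structure exact (a true nine-component
mixture), guarantees admissible estimates and a monotone log-likelihood,
and the fit is mapped to coefficients afterwards; the alternative of
iterating directly on the eight coefficients has no closed E-step and
can leave the admissible set. Convergence defaults to
$|\Delta\ell| < 10^{-8}$ or 5000 iterations with three starts (uniform,
null-heavy, moment-derived), reflecting the genuinely slow convergence
of mixture EM on this model; boundary estimates
($\hat\Delta_k \approx 0$) are flagged. Loci are treated as independent
(no linkage), matching the single-locus probability structure. In the
simulation study shipped in the test suite (200 replicates of 30 loci
by 500 pairs at an interior Jacquard vector), the replicate means of
$\hat R$ and $\hat H$ fall within three Monte-Carlo standard errors of
the truth; panels of about 20 loci suffice for stable three-gene fits
while the four-gene coefficients want 30--50, consistent with the
slower information accrual of higher-order classes.

## The simulator and what it emulates

`simulate_dataset()` draws genotype pairs exactly from the generative
definition, so simulator and probability model validate each other (the
suite checks empirical class frequencies against `class_spectrum()`
within four binomial standard errors for every pure mode).
`simulate_mixture()` assigns each *pair* one mixture component shared
across all its loci; that shared assignment is precisely what creates
across-locus covariance of homozygosity — identity disequilibrium — in
the absence of physical linkage. The canonical two-population model
(`mixture_two_pop()`) uses frequencies $p \pm a$ mixed equally; its
exact moment consequences come from `mixture_moments()`, which computes
everything by brute-force expectation over components. For the focal
homozygosity $p_m^2$ the across-component variance works out to
$4a^2p^2$ at equal mixing, and the expected identity excess between two
loci equals the across-component variance of total homozygosity
$\sum_a p_{a,m}^2$; the package asserts only the brute-force values, not
secondary closed-form claims whose exact referent (heterozygosity versus
homozygosity, and over which pairing) is ambiguous.

What the generator does *not* emulate: linkage between loci,
allele-frequency estimation error (frequencies are treated as known),
genotyping error, and pedigree-induced heterogeneity beyond what a
finite mixture of Jacquard vectors expresses. Passing tests therefore
demonstrate internal consistency of model, estimators and simulator
under known frequencies — not robustness to the additional noise of real
marker panels.

## Exact estimator variances

`exact_estimator_variance()` enumerates the full observation unit
(genotype; cross-individual gene pair; genotype plus one gene; genotype
pair), weights configurations by their exact model probabilities at the
stated truth, and applies the per-allele component estimators. Means
equal the truth exactly (unbiasedness is a test assertion), and
variances carry no Monte-Carlo error. Five weighting variants are
exposed: `minvar` (exact constrained minimum variance, the default, and
the package's reading of the stated weighting principle), `equal`,
`oneminus`, `invvar` and `focal`. Under `minvar` the null variance of
both the weighted inbreeding and pairwise estimators is exactly
$1/(n-1)$ for $n$ alleles.

`variance_table()` renders the classic three-array layout (F, G_A, G_B,
phi_XY, H with "x" for non-estimable cells). Reproducing the
historically printed numbers in that table turned out to be only
partially possible: the focal-allele variant reproduces the printed
$G_A = 73.5$ and (via a companion class) $G_B = 74.3$ of the array
(0.6, 0.3, 0.1) exactly, and the "x" cells of (0.5, 0.3, 0.2) fall out
of the $p = 1/2$ singularity, but the printed F and phi_XY columns match
no variant in a wide scan (single-class, all weightings, joint-solve
component variances), and the printed H values sit 2--30% from the
nearest candidate. The printed table appears to mix estimator variants
and allele choices cell by cell; the package therefore reports its own
exactly-defined variances under documented weightings and makes no
attempt to tune toward the printed numbers. This is the one acceptance
check shipped red, with the comparison left in the suite so the
discrepancy stays visible.

## Numerical choices and degenerate inputs

* Frequency validation rejects nonpositive entries, monomorphic loci and
  sums off unity by more than $10^{-6}$; validated vectors are
  renormalized exactly.
* Singularity tolerances: $|1-2p| \le 10^{-9}$ (order 3),
  $|pq(1-6pq)| \le 10^{-9}$ (order 4), reciprocal condition number
  $10^{-10}$ for the 8x8 solve. Flags, not numbers, are returned at
  singular points.
* Likelihood evaluation floors class probabilities at $10^{-300}$ with a
  warning; structurally impossible observed classes are reported
  distinctly.
* Problem sizes in the shipped tests — 200 EM replicates of 30 loci by
  500 pairs, mixture panels of $10^5$ pairs, simulator validation at
  $3\times10^4$ pairs per mode — were chosen so exact enumeration
  oracles and 3--4 standard-error bands are decisive while the whole
  suite stays inside a couple of minutes.

## Known limitations

Frequencies are conditioning inputs, as in the underlying theory;
estimating them from the same sample introduces bias the package logs
but does not correct. The 2x2/3x3 joint solvers hold the remaining
coefficients at zero, as their derivation assumes. No standard errors
are computed from observed information — use the simulator for
Monte-Carlo uncertainty. VCF ingestion discards phase deliberately
(genotypes are unordered throughout) and is limited to the GT field.
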