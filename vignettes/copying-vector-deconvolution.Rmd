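---
title: "Decomposing copying vectors into ancestry proportions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing copying vectors into ancestry proportions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copymix)
library(dplyr)
```

## The problem

Chromosome painting describes an admixed individual's genome as a mosaic
of segments copied from a panel of donor haplotypes grouped into $D$ donor
clusters. Summing segment lengths per donor cluster gives the *copying
vector* $l^r = (l^r_1, \dots, l^r_D)$, in cM, with total
$C = \sum_d l^r_d$ (twice the genome length when both haploid genomes are
painted). Candidate source populations are represented by *surrogate
clusters*: homogeneous reference clusters whose members were painted
against the same donors. A surrogate's profile $f^s$ is the unweighted
mean of its members' normalized copying vectors — averaging after
normalizing makes the profile robust to per-individual differences in
total copied length, which is the natural reading of a frequency-vector
profile.

The quantity of interest is the simplex vector $\beta^r$ expressing the
recipient's normalized copying vector $f^r = l^r / C$ as a mixture
$\sum_s \beta_s f^s$ of surrogate profiles: $\beta_s$ is the proportion of
ancestry attributed to surrogate $s$.

## The Bayesian mixture model

The model treats the copying vector as multinomial:

$$\Pr(l^r \mid \beta) = \mathrm{Multinomial}\!\left(C;\;
  \textstyle\sum_s \beta_s f^s_1, \dots, \sum_s \beta_s f^s_D\right),$$

with prior $\beta \sim \mathrm{Dirichlet}(\lambda_1, \dots, \lambda_S)$
and $\lambda_s \sim \mathrm{Uniform}(0, 10)$ independently. Small
$\lambda$ favour sparse $\beta$, letting the data decide how many
surrogates a recipient actually needs.

### Continuous lengths as pseudo-counts

Copied lengths are continuous cM, not counts. We evaluate the log-gamma
generalization of the multinomial log-pmf on pseudo-counts
$\tilde\ell = f^r \cdot N$:

$$\log L = \log\Gamma(N + 1) - \sum_d \log\Gamma(\tilde\ell_d + 1)
 + \sum_d \tilde\ell_d \log p_d,$$

where $N$ is the `effective_total`. By default $N$ is the recipient's own
rounded $C$, which keeps the stated model; exposing $N$ as a knob makes
the posterior's concentration explicit and testable — larger $N$ sharpens
the likelihood exactly as more painted genome would. For integer
$\tilde\ell$ this reduces to the exact multinomial pmf (checked against
the factorial formula in the tests). Mixture probabilities are floored at
$10^{-300}$ inside the log so a donor copied by the recipient but absent
from every surrogate produces a huge finite penalty instead of $-\infty$;
on realistic panels this keeps chains alive without affecting any
non-degenerate configuration.

### The sampler

Each run starts from $\beta \sim \mathrm{Dirichlet}(0.5, \dots, 0.5)$ and
$\lambda_s = 0.5$, and alternates:

1. **Simplex proposal.** Draw one $Y \sim \mathrm{Uniform}(0, 0.1)$; add
   $Y/5$ to each of five surrogates sampled with replacement, subtract
   $Y/5$ from another five sampled with replacement, clamp every touched
   entry into $[10^{-7}, 1 - 10^{-7}]$, renormalize, and accept by
   Metropolis-Hastings on likelihood × prior. The single shared $Y$ (as
   opposed to redrawing per sub-move) is the literal reading of the
   published update; the clamp-then-renormalize proposal is treated as
   symmetric, with no Hastings correction, again following the published
   acceptance ratio. Any bias this induces is bounded empirically: the
   grid-quadrature oracle test demands posterior means within 0.02.
2. **Concentration sweep.** For each $s$, propose
   $\lambda_s' \sim \mathcal{N}(\lambda_s, 0.2)$, auto-reject outside
   $[0, 10]$, otherwise accept on the Dirichlet density ratio. $\lambda$
   is a per-surrogate vector (the prior is
   $\mathrm{Dirichlet}(\lambda_1, \dots, \lambda_S)$ and the update loops
   over $s$), initialized by broadcasting 0.5. `fix_lambda` disables the
   sweep entirely, which is also how the grid-oracle tests isolate the
   $\beta$ kernel.

Default run lengths are 200,000 iterations thinned every 1,000, combined
over 50 independent runs: from each run we take the thinned state with the
highest log posterior and average these states with weights
$\mathrm{softmax}(\max \log \text{posterior per run})$. Softmax of the
shifted log posteriors is the only numerically meaningful reading of
"weighted by posterior probability" — unnormalized densities across runs
differ by hundreds of log units. A single run with an exceeding posterior
therefore dominates, which the tests verify in the 100-log-unit limit.

Reporting is raw by default; `min_report` optionally zeroes components
below a cutoff and renormalizes (downstream analyses often keep only
surrogates contributing more than 1%, or 5% for display).

### Seeding and determinism

Every user-facing stochastic entry point takes a `seed`; chains derive
per-run seeds as `seed + run index` (offset per recipient), so identical
seeds give bit-identical estimates — an explicit acceptance property.

## The NNLS baseline

`nnls_mixture()` solves $\min_{w \ge 0} \|F^\top w - f^r\|^2$ by
Lawson-Hanson active sets and rescales $w$ to sum to 1, reporting the
pre-rescale residual. Imposing the simplex by post-hoc rescaling, rather
than as a solver constraint, matches the mixture-regression usage this
baseline reproduces. Noiseless identifiable mixtures are recovered to
$10^{-6}$; the Bayesian estimates agree with NNLS within 0.03 per
component on such inputs. Which donor dimensions enter the regression is
decided by the columns of the supplied tables — profiles may span all
donors or any subset, since the functions operate on whatever donor
columns the chunklengths and profile tables share.

## What the simulator emulates — and what it does not

`simulate_profiles()` draws Dirichlet profile rows mixed toward distinct
one-hot basis vectors; `separation` interpolates from exchangeable rows
(0) to near-orthogonal profiles (1), so pairwise total-variation distance
is tunable. `simulate_recipients()` draws copying vectors
multinomially from $\sum_s \beta_s f^s$ — the generative model *is* the
inference likelihood, so recovery experiments test the estimator, not
model robustness. A finite `overdispersion` adds Dirichlet-multinomial
noise for misspecification stress tests. `drift_profile()` concentrates a
profile on a private self-copy column, emulating a heavily drifted
reference cluster; recipients lacking that signature should assign it
negligible weight (< 0.02 in the tests).

Real copying vectors have correlated noise across donors (linked
segments), unequal per-individual totals, and surrogate profiles
estimated from finite, sometimes heterogeneous clusters. Passing recovery
tests here demonstrates correctness of the inference machinery under the
stated model, not immunity to painting artefacts, panel misspecification
or collinear surrogates — duplicated surrogates are the worked example:
only the *sum* of their weights is identifiable, and the tests assert
exactly that.

Recipients who are themselves members of a surrogate cluster never copy
from themselves during painting; their zero self-copying column must be
handled when building the panel. The package documents this rather than
re-weighting for it.

## Admixture-date post-processing

Dated admixture inferences arrive per individual in three categories: one
date with two sources, one date with more than two sources, and two dated
pulses. `simplify_events()` passes the first through and expands each of
the other two into two two-source single-date events carrying best-guess
source labels. `filter_events()` applies the standard exclusions — dates
of exactly 1 generation (artefact-prone and conventionally read as "no
admixture"), events with source-ancestry fraction ≤ 5% (the boundary is
dropped: the rule is "≤ 5%"), and dates ≥ 30 generations (pre-colonial) —
and is idempotent. The optional one-event-per-individual restriction
drops two-pulse records and keeps the stronger event of multiway records,
quantifying "stronger" by the source-ancestry fraction (the fit score is
not part of the event schema; the choice is flagged in the
documentation). `generations_to_year()` applies
$y = 1990 - 28\,(g + 1)$: mean cohort birth year 1990, 28-year generation
time, so $g = 0 \mapsto 1962$.

`compare_admixture_dates()` is a one-sided Wilcoxon rank-sum test that
group A's dates are skewed toward more recent — numerically smaller —
generations. It delegates to `wilcox.test` with an explicit policy: exact
enumeration when $n_A + n_B \le 12$ without ties, otherwise the normal
approximation with midranks, tie correction and continuity correction.
The tests check the exact mode against full rank-assignment enumeration
and the two modes against each other.

## Ancestry-conditioned allele-frequency tests

To compare allele frequencies between two Native ancestry components
using admixed individuals, panels are selected on global ancestry
(> 10% from the target component, < 1% combined from other Native
components, < 1% East Asian), and per SNP only alleles carried on
haplotypes with Native local ancestry are pooled
(`aggregate_ancestry_frequencies()`); SNPs with no qualifying haplotype
are flagged rather than dropped.

`welch_freq_test()` computes the unequal-variance t statistic from
frequency summaries, $t = (f_A - f_B) / \sqrt{f_A(1-f_A)/n_A +
f_B(1-f_B)/n_B}$, with Welch-Satterthwaite degrees of freedom. This uses
the Bernoulli maximum-likelihood variance $f(1-f)/n$; `t.test` on the raw
0/1 vectors uses the $n/(n-1)$-corrected sample variance, so the two
agree to $O(1/n)$ rather than exactly — at the panel sizes involved
(hundreds of haplotypes) the difference is far below any decision
threshold, and the summary-statistic form is what the stated formula
prescribes. Degenerate inputs are handled explicitly: both variances zero
with equal frequencies gives $t = 0, p = 1$; with unequal frequencies the
record is flagged and $p \to 0$. Calibration is an acceptance property:
under a simulated shared-frequency null with 200 haplotypes per group the
empirical type-I error at $\alpha = 0.05$ must lie in $0.05 \pm 0.01$.
`fdr_adjust()` is Benjamini-Hochberg — the default reading of "the FDR
procedure" at a stated level.

The joint test asks whether index SNPs are collectively more
differentiated than matched random SNPs. Pools are matched on power:
haplotype counts within 20 in both groups and folded minor-allele
frequency within 0.01 of the index SNP, in group A (set I) or group B
(set II), always excluding the index SNPs themselves. Each of 10,000
resampled sets draws one pool SNP per index SNP; the statistic is the
mean of $-\log p$; the empirical p-value is $(k+1)/(n+1)$, the standard
Monte-Carlo correction that avoids zero p-values. One genuine ambiguity
is the tail: the literal procedure counts random sets with statistic *at
most* the observed yet interprets the result as excess differentiation.
The default here is the internally consistent `tail = "ge"` (random sets
at least as differentiated); `tail = "le"` reproduces the literal
counting. Both are exposed rather than silently resolved.
`direction_consistency()` is the sign check
$\mathrm{sign}(f_A - f_B)\cdot\mathrm{sign}(\beta_{\mathrm{GWAS}}) =
\mathrm{sign}(\beta_{\mathrm{contrast}})$, with equal frequencies flagged
indeterminate.

## Numerical choices and problem sizes

- Clamp $10^{-7}$ on perturbed simplex entries and probability floor
  $10^{-300}$, as above; $\beta$ acceptance is computed entirely in log
  space.
- The Dirichlet density ratio in the $\lambda$ sweep updates one
  coordinate at a time in $O(1)$ using the incremental
  $\log\Gamma(\sum\lambda)$ term.
- Degenerate inputs error loudly: zero-total copying vectors, empty
  surrogate clusters, unmapped surrogates in group collapsing, empty
  matched pools (naming the SNP), empty date samples.
- The test and acceptance problems use deliberately small instances —
  e.g. $S = 2, D = 4$, effective total 200 against a 2,001-point grid
  posterior; $S = 5$, effective total 20,000, 20 replicates with
  20,000-iteration, 4-run chains for recovery — chosen so the whole suite
  re-runs routinely on one CPU while leaving the acceptance tolerances
  (0.02 posterior-mean and recovery error) comfortably non-trivial. The
  200,000 × 50-run default configuration is what one would use on a real
  cohort, where per-recipient runtime is dominated by $S$ and the chain
  length.

## Known limitations

- The sampler inherits the published proposal's lack of a Hastings
  correction for the clamp-renormalize move; the grid-oracle agreement
  bounds the induced bias at the tested scales but the kernel is not
  exactly reversible in pathological corners of the simplex.
- Surrogate profiles are plain member means; no outlier trimming or
  shrinkage is applied.
- The empirical differentiation test resamples pool SNPs independently
  per index SNP; linkage between pool SNPs is not modelled.
- The one-event-per-individual filter quantifies event strength by
  ancestry fraction only.
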