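---
title: "Methods: multi-gene Mendelian risk prediction from pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-gene Mendelian risk prediction from pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelrisk)
```

## The model

mendelrisk answers two questions for a counselee (the *proband*) with a
family history of cancer:

1. **What is the probability that they carry a germline pathogenic variant**
   in each of K susceptibility genes, or in any combination of them?
2. **Given that, what is their probability of developing each cancer** over
   the coming years?

The genotype of individual $i$ is $\mathbf G_i = (G_{1i},\dots,G_{Ki})$,
a vector of binary carrier indicators over the modelled genes. The observed
history $\mathbf H$ collects, for every family member, the censoring age
$C_i$ (current age or age at death), and for each cancer $r$ the affection
indicator $\delta_{ri}$ with the diagnosis age $T_{ri}$ when affected. The
posterior over the proband's genotype is, by Bayes' rule and the standard
assumption that phenotypes are independent across family members given
genotypes and sex,

$$
P(\mathbf G_1 \mid \mathbf H, \mathbf U) \;\propto\;
P(\mathbf G_1) \sum_{\mathbf G_2,\dots,\mathbf G_I}
\prod_{i=1}^{I} P(\mathbf H_i \mid \mathbf G_i, U_i)\,
P(\mathbf G_2, \dots, \mathbf G_I \mid \mathbf G_1),
$$

where $U_i$ is sex, founders carry Hardy–Weinberg priors derived from
ancestry-specific allele frequencies, and the joint distribution of the
relatives' genotypes given the proband's follows Mendelian transmission.
The per-cancer phenotype likelihood is the usual censored two-case form,
built from **net** age-specific penetrances $P(T_{ri} = t \mid \mathbf G_i,
U_i)$:

$$
P(\mathbf H_{ri}\mid \mathbf G_i,U_i)=
\begin{cases}
1-\sum_{s=1}^{C_i} P(T_{ri}=s\mid \mathbf G_i,U_i) & \delta_{ri}=0\\[2pt]
P(T_{ri}=T^{\mathrm{obs}}_{ri}\mid \mathbf G_i,U_i) & \delta_{ri}=1.
\end{cases}
$$

Net penetrances are the right object here because family histories record
cancers, not competing deaths.

### Peeling and paring

The sum over relatives' genotypes is exponential both in family size and in
K. Two standard devices make it tractable:

* **Peeling** (Elston–Stewart): the pedigree likelihood factorises over
  nuclear families, so the sum can be evaluated by recursive elimination.
  We implement it as sum–product variable elimination on a factor graph
  with one genotype variable per *unit* — an individual, or a set of
  identical twins, who share one genotype variable by construction. Founder
  units carry prior × likelihood factors; each non-founder unit carries a
  (child, mother, father) transmission factor scaled by its likelihood. On
  loop-free pedigrees the marriage graph is a tree and every intermediate
  factor involves at most three variables. Any valid elimination order
  gives the same marginal (a tested invariant); the default order is
  greedy smallest-factor-first with deterministic tie-breaks. Products are
  rescaled by their maximum after each elimination so that long
  likelihood chains cannot underflow; the constants cancel when the
  marginal is normalized.
* **Paring**: the genotype space is truncated to vectors carrying at most
  `max_mut` simultaneous mutations (default 2), giving
  $\sum_{j \le \texttt{max\_mut}} \binom{K}{j}$ states — 11 states for 4
  genes, 301 for 24. Both founder priors and each per-family transmission
  distribution are renormalized over the retained states, so every
  conditional remains a proper distribution and posteriors sum to one
  exactly. With `max_mut = K` the computation is exact. We chose
  renormalization (rather than dropping the truncated mass) because the
  normalization invariant is what downstream aggregation and risk mixing
  rely on; the exact-mode path is unaffected and anchors all testing.

Carriers are modelled as heterozygous for "any pathogenic variant" at
unlinked autosomal loci: a carrier parent transmits the variant with
probability exactly 1/2. At panel allele frequencies the homozygous-carrier
correction to the transmission probability is $O(f)$ and is deliberately
ignored; this is the same simplification the classical single-syndrome
models make, and it keeps the simulator and the engine exactly conjugate.

An exact **brute-force posterior** (`brute_force_posterior()`) enumerates
every genotype configuration directly. It is exponential in family size and
exists purely as an independent oracle: the test suite and the acceptance
script verify `peel()` against it to $10^{-10}$ on hundreds of random
families.

### Penetrance for multi-carrier genotypes

Parameter databases store penetrance per single variant (plus a
`noncarrier` baseline); no published source defines the joint penetrance of
carrying two variants. For a genotype carrying several variants we use, per
cancer, the carried variant with the **largest cumulative net penetrance**
for that cancer and sex (dominant-gene rule, ties broken by gene order).
This keeps every per-genotype curve a proper sub-distribution and reduces
to the stored curves on single carriers, which is where essentially all
posterior mass lies at realistic frequencies.

### Future risk

For a proband free of cancer $r$ at censoring age $C_1$, the risk of
developing it by age $C_1 + t_0$ mixes genotype-specific cumulative
penetrances over the posterior:

$$
\mathrm{risk}(a) = \sum_{\mathbf G_1}
P(\mathbf G_1 \mid \mathbf H, \mathbf U)\,
\frac{F_{\mathbf G_1}(a) - F_{\mathbf G_1}(C_1)}{1 - F_{\mathbf G_1}(C_1)},
$$

with $F_{\mathbf G}$ the cumulative **crude** penetrance by default (the
probability of developing the cancer without first dying of another cause)
or the net penetrance when `net = TRUE`. We condition on being
cancer-$r$-free at $C_1$ *within each genotype* and then mix: this makes
the reported number a proper conditional probability, keeps the mixture
linear in the posterior (a point-mass posterior reproduces the genotype's
own conditional curve exactly, a tested invariant), and applies identically
to crude and net output. An unconditional variant would differ by the
factor $1 - F_{\mathbf G}(C_1)$; we document this prominently because the
choice is invisible in the formula above the fold. Risks are reported on
the grid $C_1 + k\cdot\texttt{age\_by}$ capped at 94, the end of the
penetrance age axis.

## Tunable parameters

| Option | Default | Meaning |
|---|---|---|
| `max_mut` | unset → 2 | paring parameter; clamped to K, exact at K |
| `iterations` | 20 | imputation draws when ages are missing |
| `parallel` | TRUE | parallel imputation passes; bit-identical to sequential |
| `net` | FALSE | net instead of crude penetrances for future risk |
| `age_by` | 5 | years between future-risk grid points |
| `seed` | unset | drives all imputation draws |
| `germline_sensitivity/specificity` | 1 / 1 | test-error model for germline results |
| `riskmod_factors` | all 1 | per-surgery hazard factor from the intervention age on |

Germline results enter the likelihood as a sensitivity/specificity factor
per tested gene; at the perfect-test default a positive result zeroes all
non-carrier genotypes for that gene and a negative zeroes the carriers.
Tumor-marker results (ER, PR, HER2, CK14, CK5.6, MSI) are handled by a
pluggable per-marker factor `P(marker | G)` that defaults to uninformative;
the hook isolates a modelling question (how marker likelihoods should enter
the family likelihood) that published descriptions leave open. Prophylactic
surgeries (mastectomy, oophorectomy, hysterectomy) scale the target
cancer's per-age penetrance from the intervention age onward by a
configurable factor; the shipped defaults are neutral (factor 1), so
supplying evidence-based reduction factors is a deliberate user decision.

## Pedigree checking

`check_pedigree()` applies, in order: structural checks (unique positive
IDs, parent references of the correct sex, at least one proband, acyclic
parentage), value-range checks (ages in 1..94, with ages beyond 94 clamped
because penetrances are undefined past the axis; diagnosis ages never after
the censoring age), sex–cancer compatibility (a diagnosis is incompatible
exactly when the database's penetrance slice for that sex is identically
zero — the rule is derived from the data, not hard-coded), germline-column
resolution to default variant labels, heredity harmonization, twin
consistency, loop detection, disconnected-member removal, and pseudo-parent
insertion. Every automatic change is reported with the IDs involved; the
check is idempotent.

Design choices where the behaviour was genuinely open:

* **Heredity harmonization.** A child's race/ancestry must match a parental
  value (or the neutral category) whenever any parent's value is known;
  conflicts reset the child to the neutral category (`All_Races` /
  `nonAJ`) with a message, processed top-down so resets cascade to
  descendants. Race and ancestry are harmonized by the same rule.
* **Loops.** A loop is a cycle in the marriage-node graph (individuals plus
  mating units). Looped pedigrees are a hard error — no loop-breaking
  approximation is attempted, because peeling on a loopy graph is simply a
  different algorithm.
* **Disconnected members.** "Will not influence the counselee" is
  operationalized as connectivity through parent–child edges: a member
  linked only by a childless mating contributes no genotype information,
  and removing such members provably leaves the posterior unchanged (the
  suite verifies this against the brute-force oracle).
* **Pseudo-parents.** A non-founder with one recorded parent gains a
  synthetic founder of the opposite sex with no phenotype, unknown age and
  the known parent's ancestry, so its founder prior matches that
  population. All children sharing the same single recorded parent share
  one pseudo-parent (they are treated as full siblings).
* **Twins.** Identical twins must share parents, sex, race and ancestry;
  violations are errors rather than auto-fixes, because the engine enforces
  a shared genotype downstream and a silent repair could flip its meaning.

## Missing ages

Missing censoring and diagnosis ages are handled by multiple imputation
(`iterations` draws; estimate = mean, lower/upper = min/max across draws —
deliberately not Rubin's rules, since the bounds are meant as an
uncertainty *range*, not a variance estimate). The sampling rules, which no
published description pins down, are:

* **Censoring ages** are drawn around the mean of same-generation known
  ages with Normal(0, 10) noise, clamped to [1, 94] and to at least 15
  years above every known child and below every known parent; a generation
  with no known ages borrows from other generations shifted by 25 years per
  level, and a pedigree with no known ages at all falls back to 75 minus 25
  per generation, with a warning. The constants (10, 15, 25) are package
  conventions chosen to respect generational ordering; they are defined in
  one place and documented here.
* **Diagnosis ages** for affected members are drawn from the net penetrance
  averaged over the noncarrier and single-carrier genotype classes under
  the founder priors (the genotype is unknown at imputation time;
  multi-carrier mass is negligible at panel frequencies), truncated at the
  censoring age.

A member who is unaffected everywhere and whose censoring age was *not
observed* contributes a likelihood of 1 — imputing an age for them and then
claiming survival-to-that-age information would manufacture evidence. Their
imputed ages serve only as bounds and references for other draws. This is
also exactly what makes a pseudo-parent a pure prior carrier.

All draws derive from per-iteration substreams of the master seed, so
results are reproducible and parallel execution is bit-identical to
sequential execution. The proband's censoring age must be observed for
future risk (otherwise the reporting grid itself would be random); such
probands get a warning and no risk table.

## The synthetic-data generator

`make_toy_database()` builds fully synthetic parameter sets: smooth
unimodal (discretized Gaussian) net penetrance curves with carrier lifetime
risk drawn in [0.25, 0.55] against a noncarrier baseline in [0.02, 0.08];
crude curves equal to net times a fixed Gompertz-like other-cause survival
curve; male curves a scaled-down copy of the female ones (identically zero
for ovarian, endometrial and cervical cancers); allele frequencies in
[1e-4, 1e-2], with Ashkenazi frequencies doubled and Italian at 0.8× —
magnitudes typical of panel genes, not curated estimates. The bundled
`toy_database()` is one such draw (three genes, two cancers, single race
axis level) and is clearly synthetic: examples run on it, counseling should
not.

`simulate_family()` draws founder genotypes from the Hardy–Weinberg carrier
priors, transmits alleles under the same heterozygous-carrier model the
engine uses, censors at generation-dependent current ages
(Normal(75/50/25, 8) from the top down), and samples diagnosis ages from
the genotype-specific net penetrances. Because the simulator and the
inference share the generative model, `calibration_experiment()` is a
genuine parameter-recovery check: predicted carrier probabilities binned
over 2000 simulated families match the observed carrier fractions within
99% binomial intervals. What this does **not** show about real data:
real pedigrees are ascertained through affected probands, real penetrances
are misspecified, and real families are not regular trees — the simulator
models none of these, by design.

## Numerical choices and limitations

* Likelihood products accumulate in log space; elimination rescales factors
  by their maximum. Posteriors are reproducible across elimination orders
  to $10^{-10}$.
* The dense (child, mother, father) transmission factor is cubic in the
  number of genotype states; the engine guards it at 150 states (about 10
  genes at paring 2). Scaling to full 24-gene panels at interactive speed
  is a compiled-code exercise the design deliberately leaves out; the
  genotype-space and prior/transmission layers already handle 301 states.
* Problem sizes used by the test suite and acceptance script — families of
  up to 7 members against the exact enumeration oracle (200 random cases),
  2000 simulated families for calibration — were chosen so the whole suite
  runs in about a minute on one core while still exercising every
  (K ≤ 3, max_mut) combination.
* An affected member with an unknown diagnosis age but an observed
  censoring age contributes $P(T \le C)$ when no imputation is in play (a
  direct `peel()` call); under `run_model()` the age is imputed instead.
* Looped pedigrees, X-linked inheritance, de novo mutations,
  recessive two-hit modelling, second primaries and contralateral risks are
  out of scope; a diagnosis is incompatible with a sex only when the
  database says so.
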