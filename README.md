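# pidsect

Partial information decomposition of intersectional identity effects.

## The problem

Intersectionality theory holds that the disadvantage (or privilege)
attached to holding several social identities at once — being Black
*and* a woman, say — is not reducible to the sum of the effects of each
identity alone. The standard quantitative test, a multiplicative
interaction term in a linear regression, detects *some* interaction but
cannot say what kind: a significant coefficient is equally compatible
with **redundant** dependence (both identities carry the same
information about the outcome, e.g. through a common cause) and with
**synergistic** dependence (information that only exists in the joint
state of both identities — the statistical signature of
intersectionality proper).

`pidsect` implements the information-theoretic alternative for
categorical survey data (race, sex, coarse-grained income, 5-level
self-rated health): it decomposes the mutual information that identity
variables disclose about an outcome into redundant, unique and
synergistic atoms, and provides the surrounding pipeline — inclusion
filters, income coarse-graining, balanced resampling, robustness
sweeps, a local outcome-unit decomposition, and the regression
comparison. It is aimed at quantitative social scientists and
methodologists working with census-scale microdata (e.g. the CPS ASEC
person files) or any comparable person-level table.

## The method

For two sources `X1`, `X2` and a target `Y`, the joint mutual
information splits as

```
I(X1,X2; Y) = Red(X1,X2;Y) + Unq(X1;Y/X2) + Unq(X2;Y/X1) + Syn(X1,X2;Y)
I(Xi; Y)    = Red(X1,X2;Y) + Unq(Xi;Y/Xj)
```

Two redundancy measures close this underdetermined system:

* **Imin** (Williams–Beer): `Red = Σ_y P(y) · min_i I(Xi; Y=y)`, the
  expected minimum specific information. It extends to three sources
  via the 18-node antichain lattice with Möbius inversion
  (`pid_imin()`, `build_lattice()`, `classify_atoms()`).
* **Optimized unique information** (two sources): `Unq(X1;Y/X2) =
  min_Q I_Q(X1; Y | X2)` over all joint distributions `Q` preserving
  the `(X1,Y)` and `(X2,Y)` marginals; the remaining atoms follow by
  algebra (`pid_broja()`). The convex program is solved by a
  log-barrier interior-point method with analytic gradients.

Decompositions are computed on **effective information**: the joint
identity marginal is forced to uniform by balanced resampling (equal
per-cell draws, 1000 replicates by default, equal-weight mixture), so
the result measures the dependence that would remain if identities
were assigned uniformly at random
(`balanced_resample_mixture()`). A parallel **local decomposition in
outcome units** compares `E[Y]`, `E[Y | A ∨ B]` and `E[Y | A ∧ B]`:
the disjunctive drop is the shared (redundant) cost of holding at
least one identity, and the conjunctive drop beyond it is the
synergistic, intersection-specific cost
(`intersection_decomposition()`).

Everything is testable offline: a seeded generator produces
census-like populations with independently planted unique, redundant
(latent common cause) and synergistic (conjunctive and parity)
structure (`generate_population()`), plus the exact logic-gate
fixtures (`gate_distribution()`).

## Worked example

```r
library(pidsect)

# canonical check: the XOR gate is pure synergy
pid_imin(gate_distribution("xor"), list("x1", "x2"), "y")
#>    atom bits fraction
#>  {1}{2}    0        0
#>     {1}    0        0
#>     {2}    0        0
#>    {12}    1        1

# one synthetic census-like year, filtered and balanced
pop <- generate_population(generator_config(n = 20000, seed = 7), year = 2020)
cfg <- cohort_config(n_resamples = 100, seed = 3)

decade_analysis(pop, triads = list(
  race_sex_income = list(sources = list("race", "sex"), target = "income")),
  config = cfg)
#>            triad   atom mean_fraction sd_fraction
#>  race_sex_income    {1}        0.0187           0
#>  race_sex_income {1}{2}        0.3854           0
#>  race_sex_income   {12}        0.5202           0
#>  race_sex_income    {2}        0.0757           0

intersection_decomposition(pop, "income",
  identity_pred("race", "Black"), identity_pred("sex", "Female"),
  config = cfg)
#>   E[Y]         = 43330.49
#>   E[Y | A or B]  = 39036.42
#>   E[Y | A and B] = 36194.38
#>   redundant shift  (disj - base): -4294.07
#>   synergistic shift (conj - disj): -2842.04
```

Reading the output: about 52% of the effective information race and
sex jointly carry about income is synergistic (only visible when both
identities are considered together) and about 39% is redundant
(available from either), with little uniquely attributable to one
identity. In dollars, holding *at least one* of the two marginalized
identities is associated with a $4,294 lower expected income, and
holding *both* carries a further $2,842 penalty that no single-identity
analysis can attribute.

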