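---
title: "Context-specific network reconstruction by iterative LP: model, parameters and design notes"
author: "ternflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-specific network reconstruction by iterative LP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternflux)
```

## The problem and the model

Genome-scale metabolic reconstructions describe everything an organism *can*
do; a given cell under given conditions uses only a subnetwork of it. Given
per-gene present/absent expression calls for one sample, the package
extracts a subnetwork that (i) satisfies steady-state mass balance, (ii) can
grow — carry at least a minimum biomass flux under the supplied growth
medium — and (iii) is maximally consistent with the evidence: it favours
reactions whose GPR rules evaluate as highly expressed (H), tolerates
medium-evidence reactions (M), and avoids lowly expressed ones (L).

Every reversible reaction is split into two nonnegative steps, so the
decision space is a flux vector $v \ge 0$ with $S v = 0$,
$v_i \le v_i^{\max}$ and $v_{\text{biomass}} \ge v^{*}$. The caps
$v_i^{\max}$ come from a flux variability analysis run under these same
constraints; steps whose maximum is numerically zero are *blocked* and
removed from all subsequent optimisation. The extraction itself minimises

$$ W^L \sum_{i\in L} \frac{v_i}{\delta\, v_i^{\max}}
 + W^M \sum_{i\in M} \frac{v_i}{\delta\, v_i^{\max}}
 - W^H \sum_{i\in H} z_i, $$

with one continuous activation variable $z_i \in [0,1]$ per non-blocked H
step, coupled by $\delta\, v_i^{\max} z_i \le v_i$. Two modelling points are
worth spelling out:

* **Scale invariance.** Both the flux costs and the activation thresholds
  are expressed relative to $\delta\, v_i^{\max}$. Rewriting a reaction in
  different flux units (multiplying its stoichiometric column by $k$ and
  dividing its bounds by $k$) leaves the extracted network unchanged,
  because $v_i^{\max}$ absorbs the factor. This is the invariant the tests
  assert; multiplying column *and* bounds by the same factor is not a
  reparametrisation (it changes the reaction's mass-flow capacity
  quadratically) and genuinely changes the problem whenever bounds bind.
* **Relaxed activation.** $z$ is continuous, so the whole extraction is an
  LP rather than a MILP. The price is an artefact: a reversible H reaction
  can run its forward and backward steps simultaneously at equal rates — a
  net-zero "spurious cycle" that satisfies mass balance on its own and earns
  two activation rewards for free. L and M pairs never do this, because flux
  minimisation already suppresses them.

## The iterative cycle elimination

The solver loop is: solve the relaxed LP; collect all reversible H pairs
with both steps active above `actTol` (ordered by descending
$\min(v_f, v_b)$, ties by reaction id); for each pair keep the direction
whose activation variable has the more favourable (more negative) reduced
cost, fix the other step and its activation variable to zero, and re-solve.
Reduced costs are the right signal here: at the optimum both activation
variables sit at their upper bound, and the reduced cost measures exactly
how much the objective would deteriorate per unit of de-activation — the
direction the objective values more survives. Ties keep the forward step.
Each round fixes at least one direction, so the loop terminates in at most
one round per reversible H reaction; `maxIterations` (default 50) is a
safety net, and `fixAll = FALSE` switches to fixing a single pair per round
for diagnostic runs.

Fixing a direction is heuristic, so after convergence every direction that
was fixed off and whose surviving partner ended up inactive gets one
*verification LP* with only that direction open. If it then earns activation
($z > 0$) at an objective no worse than the accepted optimum plus a relative
`objTol` (default $10^{-6}$), it is re-admitted and the problem re-solved
once. This rendering of the procedure is deliberately conservative: it can
only improve the objective, and its quality is validated behaviourally
against an exact branch-and-bound MILP (binary $z$, explicit per-pair
complementarity) rather than against any pseudocode — on one hundred random
fixtures of 12–20 reactions the final integral-semantics objective lies
within 5% of the MILP optimum in well over 95% of instances (the acceptance
script recomputes this rate).

The final network consists of the parent reactions whose net flux exceeds
`actTol` in the last LP solution, plus the biomass reaction. Coverage is
reported as the included fraction of H and of L reactions, together with a
feasibility ceiling for H: H reactions blocked under the medium (dead ends,
cycles that cannot carry net flux) are unreachable for any extraction
method, so 100% H coverage is not generally attainable.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `delta` | 0.1 | fraction of $v^{\max}$ a reaction must carry to count as fully active; dimensionless, in $(0, 1]$. Chosen well above `actTol` and well below 1 so that activation is meaningful but not confiscatory. |
| `alpha` | $10^3$ | weight magnitude separating the H/M/L priorities. |
| `schema` | 3 | (wH, wM, wL) = $(\alpha, 1, \alpha^2)$, $(\alpha, 1, \alpha)$ or $(\alpha^2, 1, \alpha)$ for schemas 1–3. Schema 1 trusts absence calls (avoid L at all cost); schema 3 trusts presence calls (include H at all cost) and is the default because absence calling is the harder problem on microarray evidence. |
| `vbiomassStar` | NA | minimum biomass flux (flux units of the model). NA means 1% of the wild-type maximum, which adapts across fixtures and media; fix it explicitly to compare networks across configurations. |
| `actTol` | $10^{-6}$ | flux level treated as "active" in cycle detection and extraction — a modelling threshold, deliberately far above solver noise. |
| `feasTol` | $10^{-9}$ | LP feasibility/pivot tolerance — solver noise, not a modelling decision. |
| `zThreshold` | 5 | z-score above which a gene is called present when only probe- or gene-level z-scores are supplied; stringent single-sample calling. Precomputed ±1 calls are the preferred input and bypass it. |
| `essentialTol` | $10^{-6}$ | knockout biomass optimum below which a gene is essential — the "numerically zero growth" reading. Passing `vbiomassStar` instead gives the stricter "below required growth" reading; both are exposed because the choice is a biological judgement, not a numerical one. |

## Gene essentiality and the skip rule

A knockout disables the reactions whose GPR evaluates false with that gene
removed and all others present; their step bounds are zeroed and biomass is
re-maximised. Before the per-gene loop the package computes one reference
distribution: the flux vector attaining the wild-type biomass maximum (to a
relative $10^{-9}$) with minimum total flux through gene-associated
reactions. Any knockout touching only reactions idle in that distribution
cannot change the optimum — the wild-type solution remains feasible and
optimal — so the gene is skipped without an LP. The rule is sound for *any*
optimal reference distribution (skipping demands zero flux on every affected
reaction), so no canonicalisation of degenerate optima is attempted;
`skip = FALSE` forces the exhaustive path, and the test suite asserts label
equality between both paths on every fixture.

## Randomisation and comparison statistics

Permutation backgrounds shuffle the ±1 calls among the metabolic genes only,
preserving the multiset, with one deterministic stream per sample derived
from a master seed; reaction labels are then re-derived through the GPRs,
and the permuted networks are reconstructed under the same schema as the
matched sample. Per-gene essentiality frequencies in the sample group versus
the permuted group separate reference-network artefacts (essential
everywhere) from expression-driven targets (frequent in samples, rare in
backgrounds).

For comparison against external per-gene essentiality scores (supplied
lower = more essential; the loader never re-signs), the one-sided two-sample
Kolmogorov–Smirnov statistic $D^{+} = \sup_x [F_{\text{ess}}(x) -
F_{\text{other}}(x)]$ tests whether predicted-essential genes have
stochastically smaller scores. The p-value is the one-sided asymptotic
Smirnov formula $\exp(-2 m n D^2/(m+n))$ capped at 1, with an exact mode
that enumerates all $\binom{m+n}{m}$ group assignments of the pooled values
(default whenever $m + n \le 16$); ties are handled identically in both the
statistic and the enumeration. A score of exactly zero counts as
non-negative in the negative-score fraction, since the criterion is strict
negativity.

## The LP machinery

No LP library is part of the package's dependency footprint; the solver is
an in-package dense bounded-variable two-phase revised simplex. This is a
deliberate design: the algorithm consumes simplex-exact reduced costs, and
the solver guarantees them deterministically — Dantzig pricing with
lowest-index tie-breaks, Bland's rule as an anti-cycling fallback, explicit
refactorisation at every iteration, single-threaded, no randomisation. On
the package's problem sizes (tens of rows and columns) this is fast enough
by a wide margin and numerically transparent. The branch-and-bound MILP
built on top of it exists only as the exact oracle for testing; the
production path is purely LP-based. In tests, an unrelated simplex
implementation (`pracma::linprog`) provides the independent cross-check for
both FBA/FVA values and raw LP optima.

## What the synthetic generators emulate — and what they do not

All test inputs are generated in code. `makeSpuriousCycleDemo()` is a
hand-designed 10-reaction + biomass network that exhibits every qualitative
behaviour the method is built around: a biomass route mixing M and H
reactions, two isolated reversible H reactions that can only carry net-zero
cycles, an H dead end that is blocked under the medium, and two L reactions
that a good extraction leaves out. `makeRandomFixture()` plants a feasible
uptake-to-biomass backbone into otherwise random single-substrate
conversions, with optional spurious pair, isozyme pair and blocked branch;
internal caps sit at 2.5× the uptake bound so that activation thresholds
remain reachable from the medium. The two designed cohorts expose,
respectively, the schema trade-off (branches whose H reward requires L
support of calibrated price) and the structural-versus-context essentiality
contrast (a capacity-limited context route shadowed by a higher-capacity
isozyme alternative).

These generators emulate the *decision structure* of genome-scale models,
not their scale or biochemistry: no compartments, no cofactor coupling, no
mass/charge balancing, unit stoichiometries almost everywhere, and tens
rather than thousands of reactions. Passing tests therefore demonstrate the
correctness of the algorithms — cycle elimination, oracle-level optimality,
skip-rule soundness, statistical exactness — under the planted conditions;
they do not certify recovery quality on real transcriptome-and-Recon inputs,
where probe annotation quality, biomass composition and medium definition
dominate the outcome. Problem sizes in the shipped tests and the acceptance
script (fixtures of 12–20 reactions, cohorts of 20 profiles, 10 permutations
per profile, 100 fixtures for the oracle-gap rate) were chosen as the
smallest sizes at which each property is exercised with clear margins.

## Numerical choices and degenerate inputs

* Equality of reduced costs within $10^{-9}$ counts as a tie (forward step
  wins); all orderings are by reaction id, so runs are bit-reproducible.
* Blocked steps are removed from the objective and bound-fixed to zero
  rather than carried with zero cost, which keeps the basis small and the
  reduced costs of live variables meaningful.
* An empty H class makes H coverage `NA` (undefined), never 0; the same for
  L.
* A model whose wild type cannot reach `essentialTol` biomass, a medium that
  starves `vbiomassStar`, or forcing flux through a blocked step all fail
  loudly with a description of the constraint at fault.
* Probe sets mapping to several genes contribute to each mapped gene's
  median; genes with no probe are absent from the aggregate, not
  zero-filled, and later evaluate as "unmeasured" (ternary 0) rather than
  absent.

## Known limitations

* No thermodynamic/loopless constraints: irreversible loops that do not
  involve a single reversible pair can still carry flux and earn activation
  rewards, in the relaxed LP and in the MILP oracle alike. Moderate bound
  caps mitigate this in the fixtures; genome-scale use would inherit the
  standard caveats of loop-prone FBA.
* The verification pass re-admits directions one at a time; a set of
  mutually dependent discarded directions that only pay off jointly would
  stay excluded. The oracle-gap rate bounds how often anything of this kind
  matters on the tested distribution.
* The dense simplex targets the package's fixture scale; a Recon-sized
  model would need a sparse factorised LP backend behind the same
  interfaces.
* Synthetic lethality (pairwise knockouts) is out of scope; only single-gene
  essentiality is implemented.

## A worked run

```{r}
fx <- makeSpuriousCycleDemo()
res <- reconstructNetwork(fx$model, fx$profile,
                          config = reconstructionConfig(schema = 3))
res
includedReactions(res)
```

```{r}
sub <- extractSubmodel(res, splitReversible(fx$model))
geneEssentiality(sub)
```
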