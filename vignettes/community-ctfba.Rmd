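---
title: "Cooperative trade-off FBA for syntrophic methanogenic communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative trade-off FBA for syntrophic methanogenic communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctfba)
```

## The problem

Anaerobic communities that upgrade CO2 (or acetate) into methane are usually
dominated by one hydrogenotrophic archaeon supported by a handful of
low-abundance bacteria. The interesting biology is in the support: syntrophic
acetate-oxidising bacteria (SAOB) can convert acetate into H2/CO2 or formate
that the methanogen consumes, and the oxidative route need not be the
canonical Wood-Ljungdahl (WL) pathway — many such bacteria lack the
carbonyl-branch CODH/ACS complex and instead appear to run the reductive
glycine (RG) pathway in reverse, joining the WL methyl branch to the glycine
cleavage system. `ctfba` provides the modelling half of that investigation
as a reusable pipeline: abundance-weighted multi-species genome-scale
models, cooperative trade-off flux balance analysis, transcriptomics-scaled
reaction bounds calibrated against measured growth, cross-feeding network
extraction, and pathway completeness / ATP-yield accounting — together with
a synthetic-community generator that stands in for sequencing data and
provides ground truth for every test.

## The community model

Each member $i$ is a stoichiometric model with fluxes $v$ in
mmol gDW$_i^{-1}$ h$^{-1}$ and a biomass (growth) reaction $\mu_i$. Members
are namespaced and coupled through a shared extracellular lumen: a member
exchange reaction moves a metabolite between the member and the lumen, and
its contribution to the lumen mass balance is weighted by the member's
relative abundance $a_i$ (fluxes stay per gDW of member; lumen balances are
per gDW of community). Environmental exchange reactions connect the lumen to
the medium; uptake is negative, release positive, everywhere in the package.
The community objective is $\mu_c = \sum_i a_i \mu_i$.

Members below an inclusion threshold (default $\theta = 0.01$, i.e. 1%
relative abundance, configurable and logged) are dropped and the remaining
abundances renormalised. The threshold is a modelling choice, not an
inference from data: below it a member's weighted fluxes are dominated by
the numerical noise of the dominant organism's solution.

## The three optimisation stages

1. **Community growth maximum.** An LP: maximise $\sum_i a_i\mu_i$ subject
   to $S v = 0$ and bounds, giving $\mu^\*$.
2. **Cooperative trade-off.** Among all states retaining a fraction $f$ of
   the optimum ($\sum_i a_i \mu_i \ge f\mu^\*$), pick the member growth
   vector of minimal Euclidean norm, $\min \sum_i \mu_i^2$. Geometrically
   this is the point of the achievable growth polytope closest to the
   inoculation point (zero growth) — the "shortest path" from inoculation
   toward the maximal-growth regime, a static surrogate for the growth
   trajectory. An abundance-weighted variant
   ($\min \sum_i a_i \mu_i^2$) is available behind a flag.
3. **Parsimonious environmental exchange.** With every $\mu_i$ pinned to its
   stage-2 value (within a relative tolerance $\delta$, default $10^{-6}$;
   $\delta = 0$ pins exactly), minimise the total absolute flux through the
   *environmental* exchange reactions. The uptake components of this
   solution are the **minimal medium** — minimal in total uptake flux, not
   in component count. Member-lumen exchanges are deliberately excluded
   from the objective (parsimony of environmental resources, not of
   internal trade); among the optima we additionally minimise total
   member-lumen exchange as a lexicographic tie-break, which removes
   degenerate futile shuttling loops (e.g. a bacterium re-synthesising the
   formate the methanogen just oxidised) without changing the reported
   minimum.

`flux_range()` computes the flux interval of any reaction consistent with
the stage-2 growth regime, the community analogue of flux variability
analysis.

### Why the solvers are in the package

No linear- or quadratic-programming package is available in the target
environment, and the trade-off stage is the methodological heart of the
pipeline, so both solvers are first-class code here. Stage 1 and 3 use a
dense bounded-variable two-phase revised simplex (periodic refactorisation,
Dantzig pricing with a Bland's-rule fallback). The stage-2 QP is solved in
the projection onto member-growth coordinates by fully corrective
Frank-Wolfe: each linear oracle is one simplex solve, and the master step
computes the exact minimum-norm point over the hull of collected vertices
with Wolfe's algorithm. On polytopes this terminates finitely, which is why
the worked two-member examples reproduce their hand-derived solutions to
$10^{-9}$ rather than to a first-order-method tolerance. Both solvers are
validated in the test suite against an exhaustive vertex-enumeration oracle
on small instances.

### Numerical choices

* Solver feasibility/pivot tolerance $10^{-9}$; steady-state residuals of
  returned solutions are checked to $10^{-6}$.
* Reported fluxes below $\tau = 10^{-6}$ are rounded to zero — only in
  reports and derived tables, never inside the solver.
* The growth-fixing tolerance $\delta$ exists because the reference
  analysis does not state whether growth was fixed exactly before flux
  minimisation; exact fixing ($\delta = 0$) is used wherever a test asserts
  a rational hand-derived value.
* Degenerate inputs: an all-closed medium yields $\mu^\* = 0$ and an empty
  minimal medium rather than an error; an infeasible community reports the
  reactions with forced non-zero flux.

One stated monotonicity — minimal total uptake non-decreasing in the
trade-off $f$ — holds in homogeneous communities (single substrate, shared
economics, where exchange scales with growth) and is asserted there. It is
*not* a theorem in general: lowering $f$ lets the min-norm step reallocate
growth across members with different byproduct economics, and the stage-3
objective (which counts release as well as uptake) can then increase. The
test suite documents this with a concrete counterexample class.

## Transcriptomics integration

Per member, RNA fragment counts are depth-normalised with median-of-ratios
size factors, log-transformed ($\log_2(c/s_j + 1)$), back-transformed to the
linear scale and propagated through each reaction's gene-protein-reaction
rule (complex = min over subunits, isozymes = sum — a declared convention;
the annotation source does not distinguish the two cases reliably). Each
scored reaction's bounds are scaled by

$$ w_r = \beta\,\min\!\left(1, \left(E_r / E_{\mathrm{ref}}\right)^{\alpha}\right), $$

with $E_{\mathrm{ref}}$ the member-wise 75th-percentile reaction score
(robust to the dominant-methanogen skew) and $\beta = 1$: under-expressed
reactions are penalised with steepness $\alpha$, and nothing is ever boosted
above its base bounds. The exact functional form of the original
integration tool is not published in the source we reimplement from, so the
form above is this package's declared choice, isolated in one function
(`expression_bounds()`) for substitution.

### Calibration

`calibrate()` grid-searches $f \in \{0.1, \dots, 1.0\}$ and $\alpha$ over 10
log-spaced points in $[0.1, 10]$, scoring each grid point by Pearson
correlation between predicted ($\sum_i a_i\mu_i$) and measured community
growth across datasets. One structural fact matters: because $\mu = 0$ is
always feasible, the stage-2 constraint binds and predictions at fixed
$\alpha$ are *exactly proportional* across $f$ — Pearson's $r$ cannot
separate $f$ values. A tie-break on $r$ alone would therefore always return
the extreme of the grid. Ties in $r$ (within $10^{-9}$) are consequently
broken by the root-mean-square error between predicted and measured growth
(which does see the scale, hence $f$), then by smaller $\alpha$ (the weaker,
more parsimonious constraint), then larger $f$. With that rule the seeded
benchmark recovers its generating point $(f^\*, \alpha^\*) = (0.5, 1.0)$
within one grid step.

## Pathway scoring and the RG ATP ledger

`pathway_completeness()` scores WL and RG definitions whose steps are sets
of alternative gene symbols (the pta-ackA module and AMP-forming acetyl-CoA
synthetase both count as acetate activation; por, pdh and pfl all count for
acetyl-CoA/pyruvate interconversion). `rg_atp_yield()` answers the
substrate-level energetics question on a built-in lumped network: acetate
activation costs 1 ATP; every C1 released as formate through the
formate-THF ligase running in reverse recovers 1 ATP. The canonical branch
(through pyruvate and serine) feeds *two* C1 units per acetate into the THF
arm and nets +1 ATP; the glycine-reductase branch loses one carbon as CO2
at the glycine cleavage step and breaks even at 0. Electron carriers are
free sinks (an H2-evolution surrogate), so the figures deliberately exclude
any chemiosmotic yield (RNF/Pnt-style complexes), and the in-vivo direction
of the glycine reductase step — which requires reducing a thioredoxin —
remains an open question that the permissive free-sink treatment sidesteps
rather than answers. Cofactor coefficients are textbook stoichiometry, as
the source material names enzymes, not coefficients.

## What the synthetic generator emulates — and what it does not

`make_toy_member()` builds three elementally consistent lumped models
(checked by `validate_model()` against chemical formulas): a methanogen with
ATP-coupled methanogenesis, reversible formate dehydrogenase and a fixed
aspartate overflow in its biomass reaction; an acetate-oxidising RG
bacterium whose whole pathway is one reversible reaction
(acetate + H2O + ADP + Pi <-> 2 formate + 2 H2 + ATP) plus an irreversible
formate synthesis from CO2 + H2; and an aspartate fermenter working through
fumarate and succinate. Coefficients are rational so the worked LP examples
have exact solutions. Internal enzyme capacities are set near the operating
fluxes the feeding scenarios demand — the biological reading is enzymes
running close to saturation — so that transcript-scaled bounds can actually
become limiting; with generous capacities, expression integration would be
inert and $\alpha$ unidentifiable.

`make_scenario()` fixes the three feeding regimes at equal total carbon
moles (default 10 mmol C/gDW/h) split 90/10, 50/50 or 0/100 between acetate
and CO2, H2 always at 4x the CO2 cap, plus unrestricted ammonia and water;
`formate_only` feeds the same carbon entirely as formate.
`make_benchmark()` wires abundances 0.85/0.09/0.06 (inside the observed
dominant-archaeon range of 72-89% without reproducing any particular
sample), negative-binomial counts (dispersion 0.05, size factors uniform in
[0.6, 1.6]) whose condition fold-changes under-express the acetate
oxidation machinery when no acetate is fed, and growth measurements equal
to the model's own prediction at $(f^\*, \alpha^\*) = (0.5, 1.0)$ with 5%
log-normal noise.

What a green test therefore establishes: the optimisation, integration,
calibration and network machinery recover known ground truth in a world
whose biology is, by construction, exactly the model family the pipeline
assumes. It does not establish anything about real sequencing data: the
generator has no read-level error, no mis-binning, no unmodelled taxa, no
thermodynamic constraints, and member "genomes" of a dozen reactions
instead of thousands. The headline statistics of the motivating study
(e.g. growth-correlation $r$, absolute exchange fluxes of real taxa) depend
on deposited sequencing data and reconstructed genome-scale models and are
out of desk-scale reach; the acceptance targets are correspondingly the
two analytic ATP yields plus property-based criteria.

## Known limitations

* No thermodynamic/loopless constraints and no dynamic FBA; the trade-off
  is a static surrogate for dynamics.
* SBML support is the Level 3 core + fbc subset the pipeline itself writes;
  exotic SBML features are out of scope.
* Pairwise attribution of multi-producer/multi-consumer transfers in
  `crossfeeding_network()` is a presentation choice (proportional
  allocation); only net per-member fluxes are solver facts.
* The dense simplex targets community models up to a few hundred reactions;
  metagenome-scale models (thousands of reactions) would need a sparse
  backend behind the same interfaces.
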