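---
title: "Inverse modeling and network analysis of food-web carbon flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse modeling and network analysis of food-web carbon flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limnet)
```

## The problem

A plankton food web exchanges carbon through many more flows than can be
measured. At steady state, mass balance ties the flows together: for every
compartment, carbon in equals carbon out. Together with the handful of
flows that *were* measured and with ecological bounds (a grazer cannot
respire more than it ingests, a parasite cannot produce more spores than
the carbon it drains from its host), the unknown flow vector `x` is
constrained to a convex polytope

\[
E x = f,\qquad G x \ge h,\qquad x \ge 0 ,
\]

where the rows of `E` are the per-compartment mass balances plus the
measured-flow equalities, and `G`, `h` collect the inequality bounds. This
is the linear inverse modeling (LIM) formulation. Rather than selecting a
single "best" vector, the whole polytope is sampled uniformly, each sample
is scored with Ecological Network Analysis (ENA) indices, and two model
variants are compared through the resulting index distributions.

The package ships the Lake Pavin spring-bloom models as worked fixtures:
`pavin_model("mwc")` includes the chytrid fungi that parasitize bloom
diatoms (host-attached sporangia `spg` and free-swimming zoospores `zsp`,
53 flows over 11 compartments), `pavin_model("mwoc")` is the same web
without them (44 flows, 9 compartments). The published mean flows are
available via `pavin_flows()` and are used by the deterministic index
checks.

## Model files and assembly

Models are declared in a plain-text format with `COMPARTMENTS`, `FLOWS`,
`EQUALITIES` and `CONSTRAINTS` sections. Mass-balance equalities are never
written by hand: `parse_model()` generates one per compartment from the
flow topology. This is deliberate — a printed equation list can drift out
of sync with a printed flow table, while the topology-derived balances are
correct by construction, and the packaged mean-flow vectors balance to
printed-rounding error (at most 0.31 mg C m⁻² d⁻¹, under 0.7% of any
compartment's throughput) under exactly this topology.

The packaged inequality set deserves a caveat. The constraints documented
in prose for the original study are encoded verbatim: chytrid respiration
at most 20% of carbon uptake, zoospore ingestion by microzooplankton at
least twice that by mesozooplankton, a minimum sporangia-to-zoospore
transfer (15 mg C m⁻² d⁻¹, below the published mean), gross primary
production shares per size class bounded by observed biomass fractions,
and a minimum flagellate bacterivory of 50 mg C m⁻² d⁻¹. The remaining
rows are generic planktonic physiology in the Vézina–Platt tradition:
respiration 20–80% of ingestion for heterotrophs and 5–55% of gross
production for phytoplankton, excretion bounded by respiration, egestion
6–50% of ingestion, and nonnegativity for every flow. The original
study's full constraint listing is not publicly recoverable, so the only
testable contract — enforced in the test suite — is that the published
mean flow vectors of both models are feasible at zero tolerance under the
packaged sets. Consequences for sampling are discussed below.

## The mirror sampler

`mirror_mcmc()` samples the polytope uniformly. The chain lives in the
null space of `E` (an orthonormal basis from the singular value
decomposition), so equalities hold exactly at every state; inequalities
become half-spaces `A q \ge b` in the reduced coordinates. Each proposal
is an isotropic Gaussian displacement with standard deviation `jump`
(flow units; 10 by default, the value used for the original analysis).
The displacement is traced as a segment: at the first crossed half-space
boundary the remaining segment is specularly reflected, repeatedly until
the step length is exhausted. Reflections are isometries, so the proposal
stays symmetric and the uniform distribution is invariant; every retained
state is feasible by construction. A cap of 1000 reflections per step
aborts with a geometry diagnostic rather than looping on degenerate
(tangential or duplicated) faces.

Two configuration points the original description leaves open:

* **Burn-in and thinning.** The reference run retained 100,000 iterations
  with no stated burn-in. Defaults here are `burn_in = 1000`, `thin = 1`,
  both configurable, so either reading of "100,000 iterations" can be
  reproduced.
* **Starting point.** `feasible_point()` returns a deep-interior point:
  after an Agmon–Motzkin relaxation pass, the minimum normalized
  constraint slack is maximized through a smooth log-sum-exp surrogate
  (BFGS, sharpness schedule β ∈ {1, 4, 16, 64, 256} scaled by the
  constraint magnitudes). The result is deterministic, satisfies the
  equalities to machine precision, and is strictly interior whenever the
  polytope has volume. An infeasible system raises an error naming the
  conflicting rows.

Uniformity is verified, not assumed: `rejection_oracle()` draws exactly
uniform points (uniform proposals in the bounding box of the reduced
polytope — obtained by exact vertex enumeration, which is why the oracle
is restricted to dimension ≤ 3 — accepted when feasible), and the test
suite requires Kolmogorov–Smirnov agreement between mirror and oracle
marginals on batches of randomly generated low-dimensional problems, at
instance-level α = 0.01 with a Bonferroni correction across a problem's
marginals (a raw per-marginal α would mislabel ~6% of perfectly uniform
instances with six marginals). Chains for these checks are thinned
(`thin = 10`) so the two-sample test sees approximately independent
draws.

## ENA indices

All information-theoretic indices are computed on the *extended flow
matrix*: compartments plus an import row, an export column and a
dissipation column (`extend_matrix()`). With `T..` the total system
throughput (TST, the sum of every entry):

* average mutual information
  \(\mathrm{AMI} = \sum_{ij} \frac{T_{ij}}{T_{..}} \log_2
  \frac{T_{ij} T_{..}}{T_{i.} T_{.j}}\) (bits; base 2 throughout),
* ascendency \(A = \mathrm{TST}\cdot\mathrm{AMI}\) and development
  capacity \(DC = -\sum_{ij} T_{ij} \log_2 (T_{ij}/T_{..})\),
* the overhead \(DC - A\) partitioned by flow class into import, export
  and dissipation overheads and internal redundancy, so
  \(A + O_i + O_e + O_d + R = DC\) holds to machine precision (a tested
  invariant),
* internal variants (`Ai`, `DCi`, `Ri`) computed on the
  compartment-to-compartment submatrix with its own marginals,
* the Finn cycling index from the Leontief inverse of the
  output-normalized transfer matrix, and
* the average path length \((\mathrm{TST} - Z)/Z\) with `Z` the total
  import. The variant \(\mathrm{TST}/Z\) is exposed through
  `average_path_length(..., variant = "gross")` because published APL
  values are not always attributable to one convention; on the Pavin
  fixtures the net variant reproduces the published "3" for the chytrid
  model, while neither variant exactly matches the published 2.6 for the
  chytrid-free model (the net variant gives 2.69), so APL is reported but
  not used as a hard acceptance quantity.

On the published mean-flow vectors this stack reproduces TST = 1464.5 and
1332.3 mg C m⁻² d⁻¹ and AMI = 1.905 and 1.715 bits. The published
ascendencies (2812, 2305) equal the published TST times the published
*sample-mean* AMI (1.92, 1.73); an index evaluated at the mean flows is
not the mean of the index over samples, and that Jensen-type gap
(≈ 0.015 bits, ≈ 20 flow units of A) is visible here because the exact
sampling polytope of the original study is not reproducible. The test
suite therefore holds AMI to ±0.02 bits, where the evaluation passes, and
documents that the ascendency band of ±10 implied by the printed values
is tighter than what the printed AMI tolerance itself propagates
(±0.02 × TST ≈ ±30).

## Trophic aggregation

`lindeman_spine()` maps the web onto integer trophic levels. Nonliving
pools (detritus, dissolved organic carbon) and primary producers sit
wholly at level 1; each consumer is apportioned across levels by powers of
the diet-fraction matrix, truncated at level 8 or when the residual
apportionment falls below 1e-9. Three conventions matter and are chosen
to be internally consistent (they also reproduce the published trophic
table exactly, which is how they were validated):

* **Level-1 input** is the import plus detrital *returns*: flows into
  nonliving pools weighted by the donor's above-level-1 fraction.
  Producer exudation and detritus dissolution circulate within level 1
  and are not counted as new input.
* **Transfer efficiency** of level k is the input to level k+1 divided by
  the input to level k; the global efficiency is the logarithmic
  (geometric) mean over the first four levels.
* **Detritivory** is the carbon flowing from nonliving pools into living
  compartments (including dissolved-organic-carbon uptake by bacteria);
  **herbivory** is the carbon from primary producers into living
  consumers, with parasitism of a producer counted as herbivory. The two
  are reported as percentages of their sum, which is exactly 100 by
  construction.

Under these conventions the fixtures yield transfer efficiencies of
66.4/48.0/41.9/30.5% (with chytrids) and 53.9/42.3/30.8/22.9% (without),
global efficiencies of 44.9% and 35.6%, and detritivory of 55.8% and
67.3%. The grazing-chain efficiencies (the same aggregation restricted to
carbon of producer origin, detrital diet excluded) follow a stated
convention but legacy network-analysis programs do not document theirs;
they are asserted only as orderings (the chytrid model transfers better
at every level).

## The synthetic generator

`random_lim()` builds the test bed the analysis assumes: imports enter
producers only, every living node respires, one or two nonliving pools
receive egestion and (unless `acyclic = TRUE`) feed detritivores. Carbon
is routed along random import-to-sink walks, so the generating vector
`x_star` is mass-balanced *exactly* and strictly positive; box bounds at
`x_star (1 ± u)` with `u ~ U(0.2, 0.8)` make `x_star` strictly interior,
and a measured total-import equality pins the scale. Because the boxes
are symmetric about `x_star` and the equality manifold passes through it,
the polytope is centrally symmetric about `x_star` — so the sampler's
mean must recover it, a parameter-recovery property the tests exercise.
What the generator does *not* emulate: measurement noise (its balances
are exact where field data balance only to rounding), empirically shaped
constraint sets (its bounds are symmetric boxes), and realistic lake
parameter magnitudes. Passing tests demonstrate algorithmic correctness,
not field realism.

## Statistical comparison

`compare_models()` reproduces the published protocol: per index, the
0.5%/99.5% quantile interval per model, their overlap, and a two-tailed
t-test on the raw Markov chain draws. Draws from an MCMC chain are
autocorrelated, so these p-values are anti-conservative; an
effective-sample-size-corrected variant (Geyer-style initial-sequence
autocorrelation truncation) is available via `ess_correct = TRUE` and is
off by default for fidelity to the original protocol. Box-plot numbers
(median, quartiles, Tukey 1.5-IQR whiskers) are emitted as data so
plotting is optional.

## Problem sizes used in the checks

The deterministic index checks on the Pavin fixtures are instantaneous.
The sampler checks use 2,000–6,000 retained iterations per chain for
feasibility, mean-recovery and between-model ordering properties, and
20 low-dimensional problems × 5,000 draws per side for the uniformity
comparison; these sizes give Monte Carlo errors far inside the asserted
tolerances while keeping the default suite fast. Full-scale runs
(`jump = 10`, 100,000 iterations, as in the original analysis) are
supported unchanged through `sampler_config()` and the `limnet sample`
command-line entry point; on the Pavin models such a run takes on the
order of a minute per model. Sampled index means on the packaged
(reconstructed) polytopes land within ~11% of the published means with
the published ordering preserved, which is the agreement one can expect
without the original study's full constraint listing.

## Known limitations

* The inequality sets are reconstructions; sampled index distributions
  are therefore compared with the published ones only qualitatively.
* Indices are carbon-flow based only; stock (biomass) indices, mixed
  trophic impact and environ analysis are out of scope, as are
  time-dynamic (non-steady-state) models and nutrient co-cycling.
* The t-test protocol inherits the autocorrelation caveat above.
* The grazing-chain efficiency convention is package-defined (documented
  here) and should not be compared numerically against legacy programs.
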