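---
title: "Methods: the two-compartment lignin model and its parameterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-compartment lignin model and its parameterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the model, its assumptions, the tunable parameters, the numerical choices,
and what the synthetic-data harness does and does not establish.

## The model and its assumptions

The monolignol pathway of *Brachypodium distachyon* is represented over two
well-mixed "compartments": the bulk cytosol (pools $X_i$) and the outer ER
surface (pools $Y_i$). These are activity centers, not membrane-bounded
organelles; they exchange every metabolite through a first-order diffusion
link $D_j = d_j\,(X_i - Y_i)$. The three cytochrome P450s (C4H, C3′H, F5H)
are ER-anchored and act only on $Y$ pools; PAL and PTAL act on the
cytosolic amino-acid supplies; the other soluble enzymes are instantiated
in both compartments, except for the sinapyl tail downstream of the two
F5H products, which runs in the cytosol (see *Degenerate pools* below for
why the pathway's stoichiometry requires exactly this placement).
Phenylalanine and tyrosine are boundary variables fixed by the feeding
regime — the model has 17 interior metabolites with 34 pools, hence 68
ODEs after the labeled/unlabeled doubling, plus ten sink accumulators.

Rates are generalized mass action (GMA) power laws on pooled
(labeled + unlabeled) substrates; enzymes are blind to labels, and each
flux is split into labeled/unlabeled portions in proportion to its
substrate pool's label richness. Diffusion terms enter ER equations with
the volume ratio $R = r/(1-r)$; cytosolic equations carry the unscaled
term. The conserved quantity is therefore the volume-weighted mass
$r\sum X + (1-r)\sum Y$ (+ sinks), and the normalization pins
$r X_i + (1-r) Y_i = 100$ for every metabolite at the wild-type steady
state.

The default network includes the direct C3H hydroxylation of *p*-coumaric
acid and the free caffeic/ferulic acid branch (4CL re-activation into the
CoA esters, wall-bound ferulate effluxes from the ferulic-acid pools).
Three structural facts force this inclusion: (i) the paired-metabolite
count of 17; (ii) without a second lineage into the CoA-ester nodes,
every pool downstream of the ER-only C3′H step would carry a single label
lineage and the label-degenerate set would be much larger than the four
pools the two-compartment stoichiometry actually produces; (iii) the
wall-bound ferulate effluxes come from free ferulic acid. The branch can
be removed (`c3h = FALSE`), which shrinks the network to 15 paired
metabolites and reroutes wall-FA to feruloyl-CoA; the 34/68 counts and
the four-pool degeneracy statement then no longer apply.

There is no product inhibition in the default model (the type system
supports modifiers, and inhibitor kinetic orders would be sampled from
$[-4, 0]$): the *Brachypodium* data are explainable without it, and we
follow that parsimony.

## Parameters that matter

| parameter | meaning | default | units |
|---|---|---|---|
| `r` | cytosol volume fraction | 0.9 | dimensionless |
| `g_j` | kinetic orders (substrates) | sampled U[0,1] | dimensionless |
| efflux orders | E₁–E₄ wall-phenolic effluxes | sampled U[0,4] | dimensionless |
| `a_j` | rate constants | back-calculated | normalized flux units |
| `d_j` | diffusion constants | solved / sampled | 1/time |
| lignin band | admissibility half-width | ±25 % | fraction of mean |
| wall band | wall-phenolic half-width | ±50 % | fraction of mean |
| `inc_floor` | absolute floor on incorporation bands | 0.02 | fraction |
| `d_max` | cap on accepted `d_j` | 50 | 1/time |
| validation `n` | knockdown activity profiles | 20 000 | draws |
| influx scaling | knockdown carbon-influx factor | log-U[0.5, 1] | relative |

The wall-phenolic band is "slightly more relaxed" in the source analysis
without a stated number; ±50 % is this package's choice, configurable.
The absolute floor on incorporation bands exists because a ±25 % band
around a near-zero fraction would be empty at assay precision; 0.02 is an
absolute-error allowance, applied symmetrically to every candidate, fixed
before any fitting.

## Label propagation: two conventions, one construction

The steady-state label field can be written against two bookkeeping
conventions. The **net-donor** convention treats each net diffusion flux
as a directed flow carrying the donor pool's label; it needs no
compartmental concentrations and is what `propagate_label_fractions()`
solves (a 34×34 linear system per feed). The **gross-exchange** convention
recognizes that diffusion moves $d X$ one way and $d Y$ back, each
carrying its own donor's label; `steady_state_label_field()` solves this
given concentrations and diffusion constants, and it is the field the
68-equation ODE system actually relaxes to.

The static sampler bridges the two: alongside each net flux sample it
draws a gross backflow $b$ per link (the receiver-to-donor gross ratio is
uniform on [0.2, 0.8]; links with zero net transfer get an absolute
backflow draw). The stationary label field under these gross flows is
linear and always well-posed, and the implied compartment split is exactly
$X/Y = \text{gross}_{\to}/\text{gross}_{\leftarrow}$ — equivalently, the
solution of the three link equations ($d(X-Y)=D$, Eq. for the labeled
portion, and the normalization). By construction the resulting parameter
set makes the sampled label field exactly stationary for the dynamic
model, for both labeling feeds at once (the two feeds' fields are
complementary because the two sources are the only label entry points).
The package's tests verify this stationarity to machine precision.

Because the network is a directed acyclic graph, the labeling scenarios'
endpoint readouts are computed algebraically (quasi-steady incorporation);
trajectory-based readouts from the integrator converge to the same values
and are used for cross-checks and for the CLI's trajectory export. The
experiment horizon question ("when is incorporation quasi-steady?") is
resolved by using the stationary field as the endpoint; the integrator's
`quiescent_tol` stop implements the same idea for trajectories.

## Degenerate pools

Under any single-source labeling, exactly four metabolites have equal
label levels in both compartments: cinnamic acid (produced only in the
cytosol, consumed only in the ER), caffeoyl shikimate, 5-OH-coniferaldehyde
and 5-OH-coniferyl alcohol (each produced only behind an ER-only P450 and
drained to the cytosol). For these the link equations are linearly
dependent and the split is unidentifiable from label data; the receiving
pool (structurally forced to be $Y_2$, $X_9$, $X_{16}$, $X_{17}$) is
sampled uniformly in (0, 100) and the partner follows from the
normalization. Links with zero net diffusion (the dead ER pools of the
cytosol-only sinapyl tail) are pinned at $X = Y = 100$ with the rate
constant taken from the gross-backflow draw; a link that is degenerate
*and* has zero net flux would draw its rate constant from a log-uniform
prior on $[10^{-3}, 10]$.

## Numerical choices

- **Integrator**: adaptive Cash–Karp RK4(5) with mixed-tolerance error
  control (defaults rtol 1e−8, atol 1e−10 on the 0–100 scale), written
  in-package because no ODE solver exists in the dependency closure.
  Severe negative undershoots force step rejection; small ones are clipped.
- **Steady states**: the default network is feedforward, so perturbed
  steady states are computed exactly by a sequential pair-by-pair solve in
  topological order, with the pair unknowns parameterized as
  $(\log Y, \Delta = X - Y)$ to avoid catastrophic cancellation in the
  diffusion term when both pools are large and nearly equal. A damped
  Newton iteration in log-concentration space (with integration fallback)
  covers non-DAG variants. Since the network has no feedback loops and all
  outflows are increasing in their substrate, the steady state reached is
  the stable one; the generator additionally verifies Jacobian eigenvalues.
- **Rejection guards**: candidates whose diffusion constants exceed
  `d_max = 50` are rejected ($d_j = D_j/(X_j - Y_j)$ diverges as the split
  degenerates, making the ODE system arbitrarily stiff); scenario steady
  states with any pool above `conc_cap = 1e6` (10,000-fold above wild
  type) are reported as failures — such parameter sets are biologically
  meaningless and numerically unusable, and the admissibility machinery
  scores them as infeasible rather than silently accepting them.
- **Degeneracy tolerance**: 1e−9 relative, since degeneracy here is
  structural, not a near-miss of continuous values.

## Sampling design

Steady-state flux distributions are sampled on a positive basis of
source-to-sink **routes** (17 of them) rather than on a raw null-space
basis: any nonnegative route combination satisfies mass balance exactly
and stays in the flux cone, so rejection is spent on the observational
constraints only. Route weights are drawn uniformly in boxes around the
baseline flows (half-width 50 %). This is the package's realization of
"uniform priors on free fluxes within bounds"; the acceptance rate is
recorded on the returned ensemble.

The explore-and-exploit search is ε-greedy (ε = 0.2): exploration draws a
fresh static member, kinetic orders and degenerate splits; exploitation
perturbs the best candidate (truncated-Gaussian moves on orders,
log-normal moves on the degenerate receiving pools) in a neighborhood that
halves after each improvement and resets after a 500-evaluation stall.
Scenarios are evaluated in the staged order control → labeled-Phe →
labeled-Tyr → dilutions, accumulating score until the first violated
stage; admissible candidates pass all scenarios jointly. The search is a
pure function of (seed, budget, configuration).

## The synthetic generator: its stated world and its limits

The generator emulates the observable surface of the feeding experiments:
per-scenario monomer totals, label-incorporation fractions in the five
sinks, and S/G. Its baseline route flows describe a G-rich grass stem —
roughly H 8 %, G 58 %, S 35 % of monomer flux (S/G ≈ 0.6), Phe:Tyr entry
≈ 55:45, substantial wall-bound *p*CA and moderate wall-FA — with the
channeling signature built in: the dominant Phe route reaches G through
the ER shikimate gate and returns to the cytosol at caffeoyl shikimate,
while the dominant Tyr route crosses into the ER ferulate channel and
exits through F5H toward S. Dilution feeds add an unlabeled influx of 22
normalized flux units (≈ 20 % of total carbon entry). Noise defaults are
lognormal sd 0.1 on totals and truncated-Gaussian sd 0.03 on fractions
over 3 replicates. All of these are harness choices fixed once, not
estimates.

A green test therefore establishes: internal consistency of the pipeline
(mass balance, label conservation, exact reconstruction), the ability of
the two-compartment structure to produce and recover the qualitative
channeling pattern, and correct plumbing of the admissibility machinery.
It does **not** establish agreement with any real measurement: the study's
measured values live in supplementary material and a companion dataset
that are not packaged, so numeric biological agreement is out of scope by
design; user-supplied target files take that place.

## Known limitations

- Compartments are well-mixed; no spatial structure of the ER surface, no
  delays, no cell-wall polymerization chemistry (sinks are absorbing).
- The paired-pool representation forces every metabolite to have an ER
  pool even where it is dynamically inert (the sinapyl tail).
- The route catalog fixes which flux sign patterns are reachable by the
  static sampler; it spans the biologically motivated cone, not the full
  null space with arbitrary signs.
- Label fields are deterministic given fluxes; isotopic fractionation and
  partial labeling of ring carbons are not modeled.
- The SBML export is structurally valid and round-trips the stoichiometry,
  but no external SBML validator is available in the offline environment,
  so conformance is checked by the package's own rules.
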