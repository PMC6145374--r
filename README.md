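# brachylignin

A two-compartment dynamic model of monolignol (lignin) biosynthesis in the
grass *Brachypodium distachyon*, with explicit ¹³C₉ label tracking.

## The scientific problem

Lignin hardness is the main obstacle to forage digestibility and to
enzymatic release of fermentable sugars from plant biomass. Engineering
lignin amount or composition requires understanding a pathway that is
grid-like, reuses the same enzymes (4CL, CCR, CAD, COMT, ...) on several
substrates, and in *Brachypodium* can enter from **two** amino acids:
phenylalanine (via PAL) and tyrosine (via the grass-specific PTAL).
Feeding experiments show a counterintuitive pattern: labeled Phe ends up
preferentially in **G**-lignin, labeled Tyr preferentially in **S**-lignin,
even though both routes merge at *p*-coumaric acid. A single well-mixed
compartment cannot reproduce this. The model resolves it by splitting the
pathway over two activity centers — the bulk cytosol (pools `X_i`) and the
outer ER surface (pools `Y_i`), where the cytochrome P450s C4H, C3′H and
F5H are anchored — coupled by per-metabolite diffusion links.

## The model

Concentrations are normalized so that the volume-weighted wild-type steady
state of every metabolite is 100:

    r·X_i + (1−r)·Y_i = 100,   r = 0.9 (cytosol volume fraction)

Each enzymatic flux follows a generalized mass action (GMA) power law on
the pooled (labeled + unlabeled) substrate — enzymes are blind to labels:

    V_j = a_j · (X_{i,L} + X_{i,UL})^{g_{i,j}} · Π enzyme^{h_{i,j}}

and is split into labeled/unlabeled portions in proportion to the label
richness of its substrate pool. Diffusion between paired pools is
`D_j = d_j (X_i − Y_i)`, entering ER equations with the volume-ratio
multiplier `R = r/(1−r)`. With 17 paired metabolites this yields
**68 ordinary differential equations** (34 pools × labeled/unlabeled),
plus absorbing sinks for H/G/S lignin and wall-bound *p*-coumaric and
ferulic acid (effluxes E₁–E₄).

Parameterization mirrors the study: steady-state flux distributions are
sampled under mass balance and observational constraints; compartmental
concentrations and diffusion constants are solved algebraically from label
incorporation levels (with the four label-degenerate pools — cinnamic
acid, caffeoyl shikimate, 5-OH-coniferaldehyde, 5-OH-coniferyl alcohol —
sampled on the receiving side of their diffusion links); kinetic orders
are drawn from [0,1] (effluxes [0,4]); rate constants are back-calculated
so the flux sample is an exact steady state; and an explore-and-exploit
search keeps parameter sets whose simulated readouts fall within ±25%
bands (lignin observables; wall phenolics relaxed) across seven scenarios:
control, labeled-Phe, labeled-Tyr, and unlabeled CA/*p*CA dilutions of
each labeling feed. A transcript-bounded sampling step validates the model
against a *BdPTAL* knockdown line.

## Worked example

```r
library(brachylignin)

topo <- build_brachypodium_topology()
topo
#> Two-compartment lignin pathway topology (Brachypodium)
#>   metabolites: 19 (17 paired -> 34 pools; 2 sources)
#>   enzymatic reactions: 33 (17 cytosol, 16 ER)
#>   sinks: 7, diffusion links: 17, state equations: 68

# synthetic ground truth standing in for the feeding-experiment data
gt <- generate_ground_truth(topo, seed = 1)
round(gt$observations$phe_label$incorporation[c("G", "S")], 3)
#>     G     S
#> 0.687 0.455      # labeled Phe: G-preference
round(gt$observations$tyr_label$incorporation[c("G", "S")], 3)
#>     G     S
#> 0.313 0.545      # labeled Tyr: S-preference

# fit an admissible ensemble against the (noise-free) synthetic targets
crit <- generate_observations(gt, noise_model(0, 0, 1), seed = 2)$criteria
static_ens <- sample_steady_state_fluxes(topo, crit, n = 3, seed = 5)
ens <- explore_exploit_search(topo, static_ens, crit, budget = 40, seed = 9)
length(ens)
#> [1] 29          # admissible parameter sets (all seven scenarios in-band)

# in silico PTAL knockdown under labeled-Tyr feeding
kd <- simulate_knockdown(topo, gt$params, enzyme_profile(topo, PTAL = 0.1),
                         list(tyr = feed_spec(tyr_label = 1)))
round(kd$tyr$relative_totals[c("H", "G", "S", "total")], 2)
#>    H    G    S total
#> 0.76 0.69 0.66  0.69   # about 30% less lignin at the new steady state
```

The numbers above are what the code prints at these seeds: the ground
truth realizes the channeling signature (G incorporation 0.687 > S 0.455
under Phe; S 0.545 > G 0.313 under Tyr), the search recovers a nonempty
admissible ensemble (29 sets from 40 candidate evaluations), and knocking
PTAL down to 10% removes about 30% of total lignin at the new steady
state.

A command-line surface wraps the same pipeline
(`bl_cli()`: subcommands `synth`, `simulate`, `fit`, `validate`,
`export`), reading a JSON configuration and writing CSV/JSON(-lines)
outputs plus the resolved configuration. `export_sbml()` writes the model
as SBML Level 3 with GMA kinetic laws.

## Layout

- `R/topology.R` — the published reaction network as data
- `R/static.R`, `R/labelfield.R`, `R/construct.R` — static model: flux
  ensembles, label propagation, algebraic compartment splits
- `R/gma.R` — the 68-equation GMA system, integrator, steady-state solvers
- `R/search.R` — admissibility bands and the explore-and-exploit search
- `R/experiments.R` — scenarios, readouts, knockdown validation
- `R/synthetic.R` — ground-truth generator and noise model
- `R/io.R` — JSON config/CLI, ensemble files, SBML export
- `vignettes/two-compartment-lignin-model.Rmd` — methods notes
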