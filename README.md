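# retinox

Simulation of blood flow and oxygen transport in heterogeneous retinal
arteriolar networks, for researchers studying how microvascular branching
structure shapes tissue oxygenation — e.g. why two retinas with identical
vessel calibers, perfusion pressures and arterial saturation can develop
very different pockets of low tissue PO2.

The package implements a hybrid microvascular model:

* **Arterioles** are an explicit rooted tree of cylindrical segments
  (branching orders 1–5 with diameters 117, 73, 44, 32, 22 µm). Flow obeys
  Poiseuille's law per segment, `Q = ΔP·πD⁴/(128µL)`; nodal pressures come
  from conservation of flow solved by successive over-relaxation between
  fixed boundary pressures (40 → 24 mmHg), alternating with a hematocrit /
  empirical apparent-viscosity update until convergence.
* **Flow regulation** (optional) evolves each arteriole's diameter `D` and
  smooth-muscle activation `A` by wall-mechanics ODEs: the Laplace tension
  `(P − IOP)·D/2` balances passive plus active wall tension
  `C_pass·e^{C'_pass(D/D₀−1)} + A·C_act·e^{−((D/D₀−C'_act)/C''_act)²}`,
  with `A` relaxing toward a sigmoid of the myogenic − shear − metabolic
  tone stimulus.
* **Oxygen transport** couples a Green's-function tissue PO2 field around
  the arterioles (vessels as line sources, tissue as Michaelis–Menten
  sinks, convective blood PO2 marched down the tree with the Hill
  saturation curve, P50 = 26 mmHg, n = 2.7) to closed-form Krogh-cylinder
  transport in the capillary compartments attached to every terminal
  arteriole (`n_C = max(1, round(Q_TA/Q_C))` capillaries each,
  `Q_C ≈ 0.211 nl/min` from a 6 µm, 15 dyn/cm², 9.05 cP capillary). The
  Krogh sleeve width is set by the capillary density through a bracketed
  root solve.
* **Metrics**: oxygen extraction fraction
  `OEF = Σ Qᵢ(SaO₂ − SvO₂ᵢ) / (Q_total·SaO₂)`, hypoxia threshold curves,
  pathway-averaged radial profiles, demand/density/regulation sweeps, and
  paired comparisons between networks.

A seeded synthetic network generator produces heterogeneous branches with
realistic order statistics; `branch1_config()` / `branch2_config()` are two
frozen study configurations with identical diameters, pressures and inlet
saturation but different branching structure, for heterogeneity
experiments. A finite-difference solver (`finite_difference_oracle()`)
validates the Green's-function method independently.

## Worked example

```r
library(retinox)

net <- generate_arteriolar_tree(generator_config(seed = 1, n_terminals = 12))
net
#> <vascular_network> 36 nodes, 35 segments, 12 terminal arterioles
#>   boundary pressures: 40 -> 24 mmHg
#>   segments by order: 1:3, 2:4, 3:7, 4:9, 5:12

rep <- run_pipeline(generator_config(seed = 1, n_terminals = 12),
                    params = oxygen_params(m0 = 3))
rep
#> <metrics_report>
#>   OEF: 0.566   (M0 = 3, CD = 500/mm^2, regulation off)
#>   arteriolar tissue PO2: mean 22.0 mmHg; 66.1% below 25 mmHg
#>   downstream capillary-end tissue PO2: mean 19.0 mmHg
#>   capillaries: 24077 total, median 1793 per compartment; d = 20.4 um

rep$field
#> <oxygen_field> 27679 tissue points, 281 vessel source elements
#>   tissue PO2: median 17.8 mmHg, range [3.1, 64.2]
#>   O2 balance: efflux 1.37e-07, consumption 1.37e-07 cm^3 O2/s (residual 0%)
```

Reading the output: at an oxygen demand of 3 cm³O₂/100 cm³/min this
12-terminal branch extracts 57 % of the delivered oxygen; two thirds of the
arteriolar tissue sits below the 25 mmHg hypoxia threshold; each terminal
arteriole feeds a compartment of ~1800 capillaries whose Krogh tissue
sleeves are 20.4 µm wide at a capillary density of 500/mm²; and the solved
oxygen field conserves mass (vessel efflux = tissue consumption) to
rounding error. `run_pipeline(..., regulation = "on")` lets the arterioles
dilate in response to the hypoxic metabolic signal, raising inflow and
lowering the extraction fraction; `sweep_conditions()` tabulates OEF over
demand or capillary density; `compare_networks()` contrasts two branches
run under identical conditions.

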