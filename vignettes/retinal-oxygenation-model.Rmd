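---
title: "Modeling blood flow and oxygen transport in heterogeneous retinal arteriolar networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling blood flow and oxygen transport in heterogeneous retinal arteriolar networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinox)
```

# The model

`retinox` simulates steady blood flow and oxygen transport in a retinal
arteriolar branch and its downstream microcirculation. The model is a hybrid:
the arterioles are represented explicitly as a heterogeneous rooted tree of
cylindrical segments, while the capillaries, small venules and large venules
downstream of each terminal arteriole are lumped compartments of identical
parallel vessels. This hybrid structure preserves the flow heterogeneity that
the arteriolar branching pattern imposes on the capillary beds without
needing a capillary-scale reconstruction.

The pipeline has five coupled stages:

1. **Network generation** — a seeded stochastic tree with 4–5 branching
   orders and prescribed per-order diameters (117, 73, 44, 32, 22 µm from
   the feeding artery to the terminal arterioles).
2. **Hemodynamics** — nodal pressures from conservation of flow with
   Poiseuille's law per segment, $Q = \Delta P\,\pi D^4/(128 \mu L)$,
   solved by successive over-relaxation between fixed boundary pressures
   (40 mmHg at the inlet, 24 mmHg at every terminal outlet, a 16 mmHg
   arteriolar pressure drop), alternating with a hematocrit and
   apparent-viscosity update until a fixed point.
3. **Flow regulation** (optional) — each arteriole's diameter and smooth
   muscle activation evolve by wall-mechanics ODEs balancing the Laplace
   tension $(P-\mathrm{IOP})D/2$ against passive plus active wall tension,
   with a sigmoidal activation driven by myogenic, shear and conducted
   metabolic stimuli.
4. **Oxygen transport** — a Green's-function solution of the tissue PO2
   field around the arterioles (vessels as line sources, tissue as
   Michaelis–Menten sinks) coupled to convective transport in the blood,
   and a closed-form Krogh cylinder model in the capillary compartments.
5. **Metrics** — the oxygen extraction fraction
   $\mathrm{OEF} = \sum_i Q_i (S_{a} - S_{v,i}) / (Q_{tot} S_a)$, tissue
   hypoxia threshold curves, pathway-averaged radial profiles, and paired
   network comparisons.

# The synthetic network generator

The two study geometries are produced by `branch1_config()` and
`branch2_config()`. A vessel of a given order is built as a chain of
segments that sheds side branches of deeper order along its course and
ends in a bifurcation; side branches occasionally step down two orders at
once, so different pathways traverse 4 or 5 distinct orders. Terminal
allocation among sibling subtrees is drawn from a Dirichlet-type split
whose concentration is set by the `asymmetry` parameter; larger asymmetry
produces more uneven subtree sizes and hence a more right-skewed
distribution of terminal flows. The embedding is quasi-planar (small
out-of-plane jitter) with rejection of branch directions that bring a new
segment closer than ~90 µm to unrelated vessels, and whole-tree retries
when residual contacts remain.

**What is calibrated, and what is not.** The per-order diameters, boundary
pressures, inlet saturation, and the single-capillary flow recipe
(diameter 6 µm, wall shear 15 dyn/cm², viscosity 9.05 cP, giving
$Q_C \approx 0.211$ nl/min) are study conditions taken as given. Per-order
segment *lengths* are not reported for the study geometries, so they are
calibration choices of this package: lognormal draws with mean
`c(550, 480, 420, 400, 650)` µm scaled by 1.7 (branch 1) and 1.4
(branch 2), truncated to [0.2×, 5×] the mean. These scales were chosen
once so that the full-scale branches (220 and 130 terminal arterioles)
carry capillary totals in the tens of thousands with right-skewed
per-compartment counts (medians of order 10², tails above 10³), and were
not revisited afterwards. The capillary count of a compartment is the
anatomical consequence of the reference flow solution,
`n_C = max(1, round(Q_TA / Q_C))`; it is attached once at the reference
state and held fixed when demand, density or regulation change.

What the generator does *not* emulate: image-derived vessel positions,
venous network geometry (compartments only), fractal-dimension statistics,
and capillary-scale anastomoses. Passing tests on these synthetic networks
therefore validate the *solvers and couplings*, not the correspondence of
any particular generated geometry to a patient's retina.

# Hemodynamics

Nodal pressures solve a symmetric diffusion-type linear system; a rooted
tree is bipartite by depth parity, so red–black successive over-relaxation
makes every half-sweep an exact Gauss–Seidel update (relaxation factor 1.5,
convergence when the largest per-sweep pressure update falls below
10⁻¹² mmHg). A dense direct solve is kept in the test suite as an
independent oracle; agreement is at the 10⁻⁸ relative level and nodal flow
and red-cell-flux conservation hold to 10⁻¹⁰ relative.

Discharge hematocrit propagates from the inlet (0.4) assuming conservation
of red-cell and plasma flow at each node. The default split rule is
proportional — daughters inherit the parent discharge hematocrit, which is
the exact content of the conservation statement; an empirical red-cell
phase-separation rule for two-daughter bifurcations is available behind the
same interface (`hematocrit_rule = "phase_separation"`). Apparent viscosity
uses the classic empirical in-vitro law $\eta(D, H_D)$ relative to plasma
(plasma viscosity 1.2 cP by default), or a constant-viscosity mode.

The venule compartment dimensions (small venules: radius 9 µm, length
500 µm, one per ten capillaries; large venules: radius 31 µm, length
2000 µm, one per hundred) are model defaults, not literature-reported
values; they only affect the compartment pressure profile and the volume
term of the capillary-density relation, not the oxygen results, since
venular oxygen exchange is neglected.

# Flow regulation

Per arteriole, total wall tension is
$T_{tot}(D, A) = C_{pass} e^{C'_{pass}(D/D_0 - 1)} +
A\,C_{act} e^{-((D/D_0 - C'_{act})/C''_{act})^2}$ with the standard
diameter-dependent coefficient set ($C_{pass} = 1.67 D_0$,
$C'_{pass} = -0.027 D_0 + 12.52$, $C_{act} = 1.30 D_0^{1.48}$, …, $D_0$
in µm), and the dynamics are
$\dot D = (D_c/(\tau_d T_c))\,(T - T_{tot})$,
$\dot A = (A_{tot} - A)/\tau_a$ with $\tau_d = 1$ s, $\tau_a = 20$ s, where
$T$ is the Laplace tension at the local midpoint pressure and
$A_{tot} = 1/(1 + e^{-S_{tone}})$,
$S_{tone} = C_{myo} T_{tot} - C_{shear}\tau_{wall} - C_{meta} S_{meta} + C''_{tone}$.

Three quantities deserve comment because the model leaves them open:

* **$D_0$ (passive reference diameter).** Defined as the passive diameter
  at 40 mmHg. With $C_{pass} = 1.67 D_0$ and IOP = 15 mmHg the passive
  equilibrium condition at 40 mmHg is an identity to 0.2 %
  ($25 \times 1333.22 \times 10^{-4}/2 = 1.6665 \approx 1.67$): any $D_0$
  satisfies it, so it cannot be obtained by root-solving. The package sets
  $D_0 = 1.3\,D_c$ per vessel, which lands $D_0$ in 29–152 µm for control
  diameters 22–117 µm — the physiologically reported range. The same
  near-identity is itself the reason IOP defaults to 15 mmHg: it is the
  external pressure for which the standard coefficient set is
  self-consistent.
* **$C''_{tone}$.** Chosen per vessel so that the control state (reference
  diameters, control flows and shear, baseline oxygen field at the control
  demand of 2 cm³O₂/100 cm³/min) is an exact equilibrium. Regulated and
  unregulated runs therefore coincide at the control demand by
  construction, and differences appear only away from it.
* **$S_{meta}$ (conducted metabolic signal).** The underlying formulation
  is not specified by the wall-mechanics model; the package reconstructs it
  as the flow-weighted integral of hemoglobin desaturation $(1 - S)$ over
  the downstream pathway — including the capillary compartment of each
  terminal — attenuated exponentially upstream (decay length 1 cm), scaled
  by a concentration `meta_c_ref`. The scale (0.1 µM) is chosen so a full
  swing of capillary-bed desaturation moves $S_{tone}$ by order one, the
  width of the activation sigmoid; larger scales make the activation
  effectively all-or-none and the coupled dynamics limit-cycle. This
  reconstruction is *not* a literature formulation and is exposed behind
  `metabolic_signal()` so alternatives can be swapped in.

**Integrator.** Near the control state the diameter equation is stiff: its
effective relaxation rate $(D_c/(\tau_d T_c))\,\partial T_{tot}/\partial D$
reaches ~20 s⁻¹ for large arterioles, far above $1/\tau_d$. The package
therefore advances the diameter with a per-vessel exponential (locally
linearized) update — unconditionally stable, with exactly the ODE's fixed
points — and the activation with its exact exponential relaxation toward
the current target. Steady state is declared when
$\max |\dot D|\tau_d/D_c$ and $\max|\dot A|\tau_a$ fall below tolerance
(10⁻⁵ in the pipeline, tighter in tests). The oxygen field (and hence
$S_{meta}$) is refreshed every `oxygen_every` steps (default 20, i.e.
every 10 s of model time at the 0.5 s pipeline step) and once more at the
converged state for self-consistency.

# Oxygen transport

## Arterioles: Green's-function field

Vessel segments are split into line-source elements no longer than twice
their diameter (and no shorter than a radius); tissue is a regular grid of
Michaelis–Menten point sinks ($M_0 P/(P_0 + P)$, $P_0 = 10$ mmHg) with
spacing 25 µm by default, clipped to a sleeve within 100 µm of the vessels
— the arteriolar tissue region. The field is represented as

$$P(x) = P_\infty + \sum_j G(x, x_j)\,q_j - \sum_k G(x, x_k)\,m_k,$$

with the free-space kernel in the line-source surface convention
($G = 2\,\mathrm{asinh}(l/2\rho)/(4\pi K l)$, the point kernel at long
range and the element's surface self-potential at $\rho = a$;
$K = D\alpha = 6\times10^{-10}$ cm³O₂/cm/s/mmHg). The uniform level
$P_\infty$ is an explicit unknown determined by the global source–sink
balance $\sum q = \sum m$ — the interior-Neumann ansatz for a tissue
region that exchanges no net oxygen with its surroundings. Source
strengths are one unknown per *segment* (uniform per unit length):
per-element strengths collocated only at element midpoints form a
near-singular first-kind system for parallel vessels a few radii apart,
which concentrates flux into single elements and bulges the field between
collocation points. Strengths are constrained non-negative (oxygen leaves
the blood; venular re-uptake is not modeled) by a small active-set
iteration. Finally, the iterate is capped at the arterial blood PO2 — the
maximum principle of the continuous problem — which bounds the residual
collocation error where closely spaced vessels meet.

Sink–sink interactions on the regular grid are evaluated exactly by FFT
convolution (cell self-interaction as an equal-volume sphere); the sink
field at the vessel elements is read from the same discrete grid field by
trilinear interpolation, so tissue and wall see one consistent operator.
Blood PO2 is marched down the tree by conservation of the convective flux
$f(P_b) = Q (H_D C_0 S(P_b) + \alpha_b P_b)$, with the oxygen content per
unit volume conserved at diverging nodes and inverted by a vectorized
Newton iteration. The whole nonlinear system is iterated to a fixed point
with Irons–Tuck adaptive mixing; a fixed under-relaxation factor fails at
high demand because the Michaelis–Menten sink feedback carries a loop gain
above one, while the adaptive scheme converges in 5–15 iterations across
the demand range 1–4 cm³O₂/100 cm³/min.

**Boundary treatment.** The free-space kernel treats the tissue as
effectively unbounded; this is the production default for sleeve domains
around a network, where the real retina continues beyond the domain and a
hard boundary would be artificial. For validation against the
finite-difference oracle on a *closed* box, `boundary = "mirror"` adds the
first shell of mirror images of all sources and sinks across the box faces
(sink images via an even-reflected FFT with a minimum-image kernel),
approximating the zero-flux box. The residual first-shell truncation error
concentrates at the box corners, which is why oracle comparisons are made
on interior points (at least a quarter of the box extent away from the
faces).

## The finite-difference oracle

`finite_difference_oracle()` solves the same steady diffusion–consumption
equation by a 7-point finite-volume scheme with zero-flux box faces and the
vessel wall built in through cut faces: a grid face crossed by the cylinder
surface at arm fraction $\theta$ carries conductance $1/\theta$ to the wall
PO2. This face treatment is what makes the oracle usable at 41³: a plain
"Dirichlet cells inside the vessel" representation carries an
effective-radius bias of order the grid spacing, which at 41³ amounts to
15–20 % of the vessel–tissue PO2 difference — larger than anything the
Green's method itself gets wrong. The scheme is symmetric, so one sparse
Cholesky factorization serves all Picard iterations of the consumption
nonlinearity.

## Capillary compartments: Krogh cylinders

Every capillary in a compartment is identical, so one representative
capillary determines the compartment. The radial profile in the tissue
sleeve of width $d$ is the closed form
$P(r) = P_{wall} + (M_0/4K)(r^2 - r_c^2) - (M_0 r_t^2/2K)\ln(r/r_c)$
with zero flux at $r_t = r_c + d$; consumption in the sleeve is the
constant demand $M_0$. If the form would go negative, consumption is
limited to the oxygenated annulus (the radius where both the PO2 and its
gradient vanish) — a guard against unphysical negative PO2, flagged as a
hypoxic annulus. Along the capillary, $df/ds = -q_v$ with
$q_v = M_0 \pi (r_t^2 - r_c^2)$ while oxygenated, so the outlet content is
exact (`f_in - f_out = q_v L_C`); the sub-stepped integration engages only
in the hypoxic regime. Venule stages have $d = 0$ and change nothing,
exactly.

The sleeve width is global: it solves the capillary-density relation
(total capillary length over total vessel-plus-tissue volume, with
$VOL_A = 0.00115$ cm³ for the arteriolar region) by bracketed
root-finding to 10⁻⁴ µm. At the reference density of 500/mm² the
full-scale branch geometry yields a width near the reference value of
22 µm; lower densities give wider sleeves and more extraction.

# Numerical choices and degenerate inputs

* Unit system: CGS internally (cm, s, dyn, poise); µm, mmHg, nl/min, cP at
  all interfaces; conversion constants centralized in `retinox_units`.
* SOR: relaxation 1.5, tolerance 10⁻¹² mmHg per sweep, warm starts inside
  the regulation loop.
* Green's iteration: tolerance 0.01 mmHg on the tissue field change,
  adaptive mixing clamped to [0.05, 1]; warm starts across regulation
  refreshes.
* Blood-content inversion: vectorized Newton with step floor `p/4`,
  uniroot fallback; depleted blood (content ≤ 0) reports PO2 = 0 with a
  depletion flag.
* Ties and degeneracy: terminal allocation remainders go to the largest
  fractional weights; a generated tree that cannot satisfy the clearance
  or domain-extent constraints after bounded retries errors (extent) or
  warns (clearance) rather than silently degrading.
* Problem sizes: the package's own experiments run the oxygen stages on
  reduced-scale branches (10–24 terminals, 30–40 µm tissue spacing,
  ~2–5×10⁴ tissue points, ≤ ~500 source elements) and the structural
  quantities (capillary totals, sleeve width) at full scale (220/130
  terminals), where only the flow solve is needed. These are the sizes at
  which the method is exercised and validated here; the solvers themselves
  do not depend on them.

# Known limitations

* The Green's field neglects intravascular (wall) transport resistance:
  wall PO2 equals mixed blood PO2.
* The free-space kernel understates the drawdown near the outer rim of the
  tissue sleeve (quantified against the finite-difference oracle; the
  mirror mode exists for closed-box validation only).
* Segment-uniform source strengths smooth axial flux variation within a
  segment; with the maximum-principle cap this bounds, rather than
  eliminates, collocation error at close vessel contacts.
* The conducted metabolic signal is a documented reconstruction, not a
  literature formulation; regulated results should be read as qualitative.
* Capillary compartments are independent Krogh cylinders: no diffusive
  interaction between neighboring capillary beds, no venular re-uptake.
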