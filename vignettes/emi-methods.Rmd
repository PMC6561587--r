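---
title: "Methods: the EMI strand simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the EMI strand simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`emir` simulates electrical conduction in a short strand of cardiomyocytes
with the EMI (Extracellular–Membrane–Intracellular) framework: the
extracellular space, the intracellular space of every cell, the cell
membranes and the intercalated discs are all explicit geometric parts of the
computational domain.  The potentials obey

* Laplace equations in the volumes: $\nabla\cdot\sigma_e\nabla u_e = 0$ in
  the extracellular domain and $\nabla\cdot\sigma_i\nabla u_i^k = 0$ inside
  cell $k$;
* interface conditions on each membrane $\Gamma_k$: continuity of the
  normal current ($n_e\cdot\sigma_e\nabla u_e = -n_i\cdot\sigma_i\nabla
  u_i^k \equiv I_m^k$), the potential jump $v^k = u_i^k - u_e$, and the
  membrane equation $C_m\,\partial v/\partial t = I_m - I_{ion}(v, s)$;
* analogous conditions on each disc $\Gamma_{k,k+1}$ with jump
  $w = u_i^k - u_i^{k+1}$, disc capacitance $C_{1,2}$ and the passive
  gap-junction current $I_{gap} = w / R_g$;
* grounded ($u_e = 0$) outer boundaries in the x- and y-directions and
  zero-flux boundaries in the z-direction.

Membrane kinetics $s_t = F(v, s)$ live on membrane nodes only; disc nodes
carry no ionic current.  The unit system is mV, ms, cm, mS/cm,
µF/cm² and µA/cm², which is dimensionally closed (note mV/kΩcm² = µA/cm²);
user-facing constructors accept µm/nm and convert on entry.

Default parameters: $\sigma_i = 4$, $\sigma_e = 20$ mS/cm, $C_m = 1$,
$C_{1,2} = 0.5$ µF/cm², $R_g = 0.0045$ kΩcm².  The default cell is a
composition of five cuboids: the body $\Omega_O$ (100×18×18 µm), end
connectors $\Omega_W,\Omega_E$ (2×14×14 µm) through which neighbouring
cells join at a shared disc plane, and side slabs $\Omega_S,\Omega_N$
(14×2×14 µm).  Extracellular padding is 10 µm (x, y) and 4 µm (z).

## Discretization

The domain is a node-centred rectilinear lattice; every interface lies
exactly on a lattice plane.  Nodes are classified as extracellular,
intracellular, membrane, disc, or outer boundary; a node is *membrane* when
it belongs to exactly one cell and has an axis neighbour outside every
cell, and *disc* when it is shared by two cells — the intercalated disc is
the full overlap face of the abutting connectors, rim included, so the
gap-junction contact area equals the geometric disc area.  At the rim
triple line (disc meets cleft) the extracellular stencil reflects.
Membrane nodes carry **two** unknowns (the extracellular and intracellular
traces) so the jump $v$ across the zero-thickness interface is well
defined; disc nodes carry the two intracellular traces.

Volume nodes use the standard 7-point second-difference stencil, written
for unequal neighbour spacings so graded lattices are handled exactly; the
outer z-faces use a mirrored ghost (zero flux), the x/y faces take
precedence where they meet (Dirichlet).  The interface equations are in
conservative control-volume form: at every membrane node the total
conduction inflow from adjacent same-cell unknowns (one-sided differences
weighted by the transverse column areas, tangential in-layer couplings
included) balances the capacitive membrane current $A_i C_m\,dv/dt$, and
the extracellular-side inflow balances its negative.  Disc nodes carry the
analogous two-sided balance with the interface current
$C_{1,2}\,dw/dt + w/R_g$ weighted by the disc-area quadrature, whose
transverse bands are clipped to the connector overlap so the total
disc-current area equals the geometric disc area exactly.  Because every
conduction coupling appears antisymmetrically in the two rows of its
endpoints, the per-cell discrete charge balance — the sum of $I_m A$ over
the membrane plus $I_{1,2} A$ over the discs — is an algebraic identity of
the solved system (verified to 1e-8 at every step in the tests).  An
earlier non-conservative variant (pointwise flux-continuity rows) leaked
up to 70 % of the junction current through concave-rim couplings on
composed geometries, which is why the conservative form is the
discretization of record.

Each time step splits into (1) `m = dt/dt*` forward-Euler substeps of the
membrane ODEs with the spatial coupling frozen ($dv/dt = -I_{ion}/C_m$,
stimulus applied as an inward current), with `dt* = min(0.001 ms, dt)`, and
(2) one implicit solve of the full linear potential system with
$I_{ion} = 0$, closing $v$ and $w$ with backward Euler.  Backward Euler was
chosen for the implicit half because it is unconditionally stable and keeps
the operator linear and constant: the sparse matrix depends only on mesh,
parameters and dt, so it is assembled and LU-factorised once per run
(`Matrix`).  Rows are equilibrated before factorisation because Laplacian
rows (≈ σ/h², h in cm) and capacitive rows (≈ C/dt) differ by nine orders
of magnitude.  The splitting is first order in dt; the convergence fixture
measures the observed order on a three-cell strand.

### Membrane quadrature

Surface integrals use per-node area weights: the product of the two
transverse spacings for nodes interior to a face, the mean of the two
products on face-intersection edges, and one third of the three products at
corners.  Along *concave* junction lines (where a connector or slab meets
the cell body) the adjacent half-spacing band has no owning node, so the
quadrature total $A_c$ under-estimates the analytic area of the composed
solid by ≈ 3 % at the default spacings (and converges with refinement); the
same quadrature is used on both sides of every conductance computation, so
channel-conservation identities hold to machine precision regardless.

### Graded meshes for nanometre clefts

For junctional clefts of width $d$ in the nanometre range the x-spacing is
$d/4$ inside the junction region only, growing geometrically (factor ≤ 2
per step) into the bulk spacing inside the adjacent cell bodies and
padding.  A globally uniform $d/4$ lattice would be intractable at
$d = 5$ nm, and the cleft potential is governed by the junction-local
resolution; the grading is configurable through `grid_spec(cleft_dx =)`.
The x-extent of the side slabs snaps to the nearest lattice plane when the
centred position is not representable (it is off-lattice at 2 µm spacing).

## Sodium-channel placement

`assign_gna()` realises a distribution $(p, \text{region})$: the fraction
$p$ of channels moves from the whole membrane to the junctional region
$\Gamma_j$, with densities $(1-p)\bar g$ on the remainder and $(1-p)\bar g
+ p (A_c/A_j)\bar g$ on $\Gamma_j$.  Because $A_c$ and $A_j$ are quadrature
sums over the same node weights, the whole-cell conductance equals the
uniform total for every $p$ (asserted at 1e-12 relative).  Region
`horizontal_ends` is the connector side faces (used with the default 4 µm
cell distance, placing channels as close to the discs as the geometry
allows); `vertical_ends` is the x-normal end faces (used for nanometre
clefts, keeping the channel-bearing area independent of $d$).  Nodes shared
between $\Gamma_j$ and the remainder belong to $\Gamma_j$.  For cell-length
sweeps, `rescale_for_cell_length()` substitutes the default-cell area
$A_c^*$ so the channel *count* per cell stays constant: uniformly scaled
density in the U case, $A_c^*$ in the junctional formula in the NU case.

## Membrane models

The physiological reference is a port of the Grandi–Pasqualini–Bers human
ventricular action-potential model (epicardial parameter set): 38 state
variables per membrane node covering I_Na (with junctional/subsarcolemmal
compartments), I_to fast/slow, I_Kr, I_Ks, I_K1, I_Kp, Cl currents, the
L-type Ca current, NCX, pumps, SR release/uptake and the full buffer set.
Initial conditions are the model's quiescent state after 20 s of
equilibration from the published values — long enough that the fast
buffers and gates are self-consistent at rest (drift < 1 %/s per variable,
asserted in the tests) while the slow Na⁺ state remains near its published
value.  The port is validated behaviourally: resting stability, the I_Na
clamp transient (activation then inactivation within 2 ms), AP overshoot
and an epicardial APD90 range, rather than bit-reproduction of any
particular reference trace.  The local conductance `gna` scales only the
fast I_Na component, linearly at fixed state.

For solver work a reduced three-gate surrogate (`reduced_test_model()`) is
bundled: the same fast-I_Na gating kinetics, an inward-rectifier-like
background K⁺ current that pins the resting potential (computed as the
root of the steady-state current at model construction), and a slow
delayed-rectifier gate.  It fires regenerative upstrokes
(dv/dt_max > 50 mV/ms) and repolarises within tens of ms, which keeps
fixture runs fast; it is not meant to reproduce a ventricular AP shape.

## Measurements

All metrics are pure functions of recorded traces.  Activation time is the
first upward crossing of 0 mV, linearly interpolated between samples.
Conduction velocity divides the cell-center x-distance by the
activation-time difference at membrane probes placed at the axial cell
center (mid-y, top-z — $v$ lives on the membrane, so "cell center" means
the membrane node nearest the center plane; the tie-break is fixed and
documented in `probe_cell_centers()`).  Gap delay is the activation
difference between the last membrane node before a disc and the first
after it; a downstream node that never activates reports an infinite delay
and an explicit block flag (never a sentinel number).  Whole-cell sodium
current integrates $I_{Na} A_i$ over a cell's membrane nodes, with a
trapezoidal time integral for influx comparisons.  The cleft sweep fits
min $u_e \approx a/d$ by least squares through the origin against $1/d$.

## Desk-scale protocols

The scripted experiments reproduce the standard protocols at reduced size
so a full run fits on one CPU in minutes; each table carries its scale as
an attribute.  The defaults are 7-cell strands (the full protocols use
10–20), bulk spacings dx = dy = 2 µm with junction-local x-refinement,
dz = 2 µm, dt = 0.01 ms with 0.001 ms membrane substeps, CV measured
between the centers of cells 3 and 6.  At this scale the uniform-channel
calibration gives CV ≈ 45.5 cm/s against the 50 cm/s full-resolution
calibration.  Cleft protocols keep the full cross-section resolution
(dy = dz = 1 µm) where the quantitative cleft values matter, since the
knife-edge between ephaptic depolarization and downstream firing at
σ_e = 20 mS/cm is sensitive to the cleft cross-section resolution.

One known desk-scale limitation deserves emphasis.  End-localized
distributions concentrate the sodium conductance to densities of several
hundred mS/cm², where the junctional membrane time constant C_m/g_Na
drops to a microsecond or so — far below any affordable dt.  Because the
splitting integrates the membrane ODEs with the spatial coupling frozen,
those nodes saturate toward the sodium reversal potential within each ODE
half-step and deliver at most ≈ C_m (E_Na − v) of charge per step instead
of g_Na (E_Na − v) dt.  The localization-ordering experiments (CV against
the end-localized fraction, uniform-versus-localized gap delays, the
localized cell-length optimum) are therefore not resolution-stable at
desk scale — the fully localized branch can even fail to propagate —
and reproducing those orderings requires full-fidelity runs (1 µm
lattice, dt ≤ 0.001 ms, 15-cell strands) outside a desk budget.  The
corresponding acceptance assertions are kept at their stated tolerances
and simply report as failures at desk scale rather than being relaxed.

The stimulus default is 80 A/F for 1 ms to all membrane nodes of the first
two cells (the protocol statement does not single out a sub-face; whole
cells are assumed).  Threshold-trigger protocols instead set
`v_init = -55` mV on every membrane node.

## What the fixtures do and do not show

The test fixtures are miniature strands (≤ 30×20×15 nodes) with the reduced
membrane model.  They exercise every structural property of the scheme —
classification partition, quadrature identities, conservation, charge
balance, dense-vs-sparse equivalence, determinism, mirror symmetry,
convergence order — and the qualitative conduction phenomenology.  They do
not calibrate physiology: absolute velocities, delays and AP shapes on
fixtures are meaningless, and passing fixture tests says nothing about real
tissue beyond the model equations being solved correctly.  Physiological
numbers come only from the epicardial-model protocols at the documented
desk scale, with their stated resolutions.

## Known limitations

* No diffusion of ions in the volumes and no cleft ion accumulation: ionic
  concentrations exist only as membrane-node state.
* Gap junctions are passive ohmic resistors; gated junction models are out
  of scope.
* Single straight strands of axis-aligned cuboid compositions only; no
  brick-offset architectures or curved geometries.
* First-order splitting and first-order one-sided interface fluxes; the
  convergence suite, not an analytic estimate, is the accuracy guard.
* The sparse direct factorisation is computed once per operator; very
  large meshes (beyond ~2×10⁵ unknowns) need more memory than a desk run
  should assume.
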