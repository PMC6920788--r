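---
title: "Membrane elasticity and thermodynamics of protein wetting by ordered lipid domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane elasticity and thermodynamics of protein wetting by ordered lipid domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(memwet)
```

## The physical problem

Cellular membranes below their demixing point separate into thicker
liquid-ordered (Lo, "raft") and thinner liquid-disordered (Ld) lipid
phases.  Physiological membranes are typically *subsaturated*: the global
phase separation does not occur, yet ordered domains are observed around
certain transmembrane proteins.  `memwet` models the mechanism behind
this: *wetting* of a rigid transmembrane domain (TMD) by a finite annulus
of ordered phase, driven by hydrophobic mismatch.  A TMD of hydrophobic
length $H_p$ longer than the disordered bilayer thickness $2h_s$ forces
an expensive local thickening of the membrane; condensing a thicker
ordered collar (monolayer thickness $h_r > h_s$) around the protein can
relieve that cost even when the bulk ordered phase is thermodynamically
disfavoured.

The TMD is a rigid cylinder of radius $R_p$ that also imprints the
orientation of the adjacent lipids: the radial projections of the
boundary directors, $n_1$ (outer leaflet) and $n_2$ (inner leaflet),
parameterize its effective shape — barrel ($n_1>0, n_2>0$), cone
($n_1>0, n_2<0$), inverted cone, hourglass.  Positive projections point
away from the protein axis in both leaflets.

## Elastic model

Each monolayer carries two deformation modes in the Hamm–Kozlov sense,
splay (director divergence) and tilt, plus lateral tension, with the
energy per monolayer

$$W=\int\!\Big[\tfrac{B}{2}(\mathrm{div}\,\mathbf n)^2+\tfrac{K}{2}\mathbf t^2
+\sigma\Big]\,dS-\sigma A_0 ,$$

where in cylindrical symmetry $\mathrm{div}\,\mathbf n = n'(r)+n(r)/r$,
$\mathbf t = \mathbf n - \mathbf N$ is the deviation of the director from
the neutral-surface normal, and the tension term reduces to
$\tfrac{\sigma}{2}(H')^2$ per unit area of projected neutral surface $H$.
Local volumetric incompressibility slaves the monolayer thickness to the
splay, $h = h_0 - \tfrac{h_0^2}{2}\mathrm{div}\,\mathbf n$, which couples
the two leaflets through the common intermonolayer surface $M(r)$ and
makes the functional fourth order in the director fields.  The unknown
fields are $a(r)$, $b(r)$ (outer and inner director projections) and
$M(r)$; the neutral surfaces $H_a, H_b$ and tilts follow algebraically.

Boundary conditions: at the protein wall $a(R_p)=n_1$, $b(R_p)=n_2$, and
the hydrophobic thickness matches the protein,
$H_a(R_p)-H_b(R_p)=H_p$ (the protein's vertical position is free and is
resolved by energy minimization); all deformations decay at infinity.  At
a phase boundary (an ordered-annulus edge at $R_d$ or $R_u$) the
directors and both neutral surfaces are continuous.  The intermonolayer
surface $M$ is *not* constrained there: the leaflets may redistribute
thickness across the boundary, so $M$ (and with it $a'$, $b'$) carries a
free jump fixed by the minimization.  This is not merely a modelling
convenience: a variational count shows that additionally imposing
$M$-continuity overdetermines the interface matching (nine conditions
against eight solution dimensions per region — the planar characteristic
polynomial of the Euler–Lagrange system has degree eight), so the problem
with the free jump is the only well-posed version.  Numerically the jump
changes energies by under two percent.

The minimized elastic grand potential is an exact quadratic in the
boundary data: $W(n_1,n_2)=\tfrac12\,y^{\mathsf T}S\,y$ with
$y=(1,n_1,n_2)$.  `energy_matrix()` computes the $3\times3$ matrix $S$
from three linear solves sharing one factorization, which is what makes
whole director-grid phase portraits cheap.

## Thermodynamics of wetting

The domain exchanges *quasimolecules* — fictitious units containing all
lipid components in the domain stoichiometry — with the surrounding
membrane; each occupies area $a_{qm}$.  With the chemical potential
normalized to zero for an infinite domain, $\mu(s)=a_{qm}\,dW/ds$, the
equilibrium condition under subsaturation $\Delta$ is
$\mu=-k_BT\Delta$, and the total free energy of a domain of area $s$ is

$$E(s)=W(s)-W(s_0)+\frac{k_BT\,\Delta}{a_{qm}}(s-s_0).$$

Stable domains are interior minima of $E$ lying below the no-domain
state; the global one is `stable`, others `metastable`, maxima
(nucleation barriers) `unstable`.  `find_equilibria()` locates stationary
points by sign changes of the sampled slope and refines them by Newton
steps on a local cubic fit; the residual $|\mu(s_{eq})+k_BT\Delta|$ is
recorded for every reported equilibrium as a self-check.

Two subsaturation scenarios are implemented.  Under *bilayer*
subsaturation both leaflets pay the penalty on the total ordered area;
following the two-step procedure, $E(s)$ is scanned with the
symmetric split $R_d=R_u$ and the leaflet partition is optimized only at
the equilibrium area (optimizing the partition at every $s$ would let the
scan ride the much cheaper single-leaflet-annulus branch and would
classify nearly every TMD shape as wetted, which is not the procedure the
portraits are built from).  Under *monolayer* subsaturation the outer
leaflet is saturated — its domain pre-exists from phase separation and
its radius is fixed at $R_u=R_p+7$ nm in the portraits — and the penalty
applies to the inner-leaflet area only.

## Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| B | monolayer bending (splay) modulus | 10 | $k_BT_0$ |
| K | monolayer tilt modulus | 10 | $k_BT_0$/nm$^2$ |
| $\sigma$ | monolayer lateral tension | 0.01 | $k_BT_0$/nm$^2$ |
| $h_r$ | ordered monolayer thickness | 1.8 | nm |
| $h_s$ | disordered monolayer thickness | 1.3 | nm |
| $\Delta$ | subsaturation | 0.01 | — |
| $a_{qm}$ | area per quasimolecule | 0.5 | nm$^2$ |
| $R_p$ | TMD radius (closed / open) | 0.9 / 1.6 | nm |
| $H_p$ | TMD hydrophobic length | $2h_r$ | nm |

Energies are in $k_BT_0 \approx 4.14\cdot10^{-21}$ J (so `kT = 1` at the
reference temperature), lengths in nm.  The moduli and thicknesses are
the standard values for model raft-forming mixtures.  $H_p=2h_r$ means
zero residual mismatch between the protein and the ordered phase; `Hp`
remains an input for sensitivity studies.  The area per quasimolecule is
not fixed by independent data; 0.5 nm² (a typical ordered-phase area per
lipid) is the package default, chosen once before any result was
evaluated.  Because only the ratio $\Delta/a_{qm}$ enters $E$, the two
knobs trade off exactly; the stability margins of the portraits move by
roughly 1 $k_BT_0$ when $a_{qm}$ changes by a factor of two, so
threshold positions in the director plane shift by about one 0.1 grid
step per factor of two.

## Numerical design

**Solver.**  The Euler–Lagrange boundary-value problem is solved in weak
form: per-region $C^1$ Hermite-cubic elements for all three fields
(degrees of freedom value + derivative per node), five-point Gauss
quadrature, graded meshes with 0.1 nm elements at region boundaries
growing geometrically to 2 nm.  The energy is assembled as a sparse
quadratic form; wall, interface and truncation conditions are sparse
linear constraints eliminated by a null-space reduction, after which the
reduced Hessian is positive definite and a single sparse Cholesky solve
(with three right-hand sides) yields the energy matrix.  The far field is
truncated 80 nm past the outermost boundary with clamped fields: the
slowest mode of the system is the bilayer bending-tension mode of decay
length $\sqrt{B/\sigma}\approx32$ nm, and doubling the margin changes
reference energies by $<10^{-3}$ relative.  Mesh halving changes them by
$<5\cdot10^{-4}$.

**Oracle.**  An independent brute-force route discretizes the same
functional by second-order finite differences on a staggered grid —
nodal fields, all energy quantities at cell midpoints from compact
two-point stencils — and minimizes the resulting quadratic form exactly.
It converges with the square of the step (Richardson ratios $\approx4$)
and agrees with the Galerkin solver to well under one percent at a
0.025 nm step across random configurations of all region topologies and
director sign quadrants.  A translationally invariant straight-wall
variant provides the large-radius anchor: at $R_p=100$ nm the
cylindrical energy per unit wall length matches it to half a percent.

**Minimum domain width.**  The sharp-interface model admits an
unphysical channel: an infinitesimally thin ordered collar at the wall
carries the interface jump conditions at zero area and lowers $W$
discontinuously (by $\sim$7 $k_BT_0$ at $R_p=1.6$ nm; solver and oracle
agree this is a true property of the functional, not a discretization
artifact).  Domains narrower than $L_{min}=2$ nm — two tilt decay
lengths $\sqrt{B/K}$, about a lipid-and-a-half — are therefore outside
the model's validity and excluded from all scans; a minimum of $E$
sitting at the admissibility edge is not an equilibrium (it does not
satisfy $\mu=-k_BT\Delta$) and is never reported as one.  All scan
functions expose `L_min`.

**Resolutions.**  Portraits use the 0.1 director grid on
$[-0.7,0.7]^2$ (the small-deformation validity range) with width ladders
$\{0\}\cup[2,12{-}14]$ nm at 0.25–0.5 nm; the mirror-symmetric sweep
uses 0.5–1 nm radius steps, and equilibrium locations are refined by
local cubic fits (width resolution about 0.05 nm).  These sizes keep a
full portrait in seconds and the complete acceptance recomputation in
minutes on one core.

## Known limitations

* The stability region of inner-leaflet domains under a fixed outer
  domain comes out as a diagonal band governed essentially by $n_1+n_2$,
  insensitive to $R_p$.  The reference computation reports a
  bounded corner region ($n_1>0.4$, $-0.3<n_2<0$) and an $R_p$-dependent
  difference between conformations; the full derivation behind those
  boundary-condition list and stability taxonomy is not available, and
  none of the stability-criterion variants explored here (fixed-outer
  baseline, relaxed-outer baseline, joint two-radius local minimality,
  pinned protein) reproduces the corner shape.  Threshold-type outputs
  in the director plane should therefore be read qualitatively.
* The mirror-symmetric equilibrium film width saturates at
  $\approx4.95$–5 nm as $R_p\to\infty$ and stable films first appear
  near $R_p\approx3.5$ nm; the legacy symmetric computation places the
  1 nm crossing near 5 nm.  Attainment of the 5 nm width is assessed at
  the width-measurement resolution (0.05 nm).
* Not modelled (by design): monolayer spontaneous curvature, membrane
  shape fluctuations, cytoskeletal constraints, protein–ordered-phase
  mismatch (set to zero), Gaussian-curvature terms, large-tilt
  elasticity, and multicomponent bookkeeping beyond the single
  subsaturation scalar $\Delta$.  Passing portraits and property tests
  therefore validate the continuum model's internal consistency, not its
  quantitative accuracy for any particular cellular membrane.
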