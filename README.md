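# memwet

Continuum modelling of liquid-ordered ("raft") lipid domain formation
around transmembrane proteins by **wetting**, for membrane biophysicists
studying protein–lipid nanoclusters and lipid-mediated receptor
activation (the reference case is the EGFR transmembrane-domain dimer and
its closed → open conformational switch).

A subsaturated membrane has no global ordered/disordered phase
separation, yet a rigid transmembrane domain (TMD) whose hydrophobic
length `Hp` exceeds the disordered bilayer thickness `2*h_s` can condense
a finite ordered annulus around itself. `memwet` solves the underlying
continuum problem end to end:

* **Elasticity** — the Hamm–Kozlov tilt + splay energy per monolayer,

  `W = ∫ [ B/2 (div n)² + K/2 t² + σ ] dS − σA₀`,

  with local volumetric incompressibility `h = h₀ − (h₀²/2) div n`
  coupling the leaflets through the common intermonolayer surface. The
  Euler–Lagrange boundary-value problem around the cylindrical inclusion
  is solved in weak form (C¹ Hermite elements, sparse null-space
  Cholesky), for any leaflet-resolved domain configuration
  `(Rd, Ru, n1, n2)`. An independent finite-difference minimization
  oracle cross-checks every energy to <1 %.
* **Thermodynamics** — chemical potential per quasimolecule
  `μ(s) = a_qm dW/ds`, total free energy
  `E(s) = ΔW + kT·Δ·(s−s₀)/a_qm`, equilibrium condition `μ = −kT·Δ`,
  and stability classification of domain sizes.
* **Scans** — phase portraits over the TMD shape plane `(n1, n2)` under
  bilayer or monolayer subsaturation, stable-width measurement, and the
  mirror-symmetric film sweep over the protein radius.

Units: lengths in nm, energies in kBT0 (≈ 4.14·10⁻²¹ J).

## Worked example

```r
library(memwet)
params <- make_params()                       # reference raft-lipid moduli
geom   <- egfr_geometry("open", n1 = 0.5, n2 = -0.2)

prof <- solve_profile(params, geom, domain_configuration(5.6, 8.6, geom))
elastic_energy(prof)
#> Elastic grand potential W = 17.5806 kBT0
#>   bending inner      4.2034 kBT0
#>   tension inner      0.0616 kBT0
#>   tilt    inner      1.9363 kBT0
#>   bending outer      9.4062 kBT0
#>   tension outer      0.0309 kBT0
#>   tilt    outer      1.9423 kBT0

pt <- monolayer_wetting_portrait(params, Rp = 1.6, L_u_fixed = 7, grid_step = 0.2)
pt
#> Wetting phase portrait (monolayer subsaturation), Rp = 1.6 nm, grid step 0.2
#> inner-domain         none
#>           43           21
mean(pt$L_d[pt$class == "inner-domain"])
#> [1] 4.12
```

The first block solves the deformation field around an open-conformation
EGFR TMD (radius 1.6 nm, barrel-to-cone shape `n1 = +0.5`, `n2 = −0.2`)
dressed with a staggered ordered domain (inner radius 5.6 nm, outer
8.6 nm): the elastic grand potential is ≈17.6 kBT0, dominated by splay.
The portrait then scans TMD shapes with the outer leaflet saturated
(pre-existing 7 nm outer domain): 43 of 64 shapes support a stable
ordered domain in the inner leaflet, with mean width ≈4 nm — the
membrane-spanning domain believed to transmit the activation signal.

A command-line interface wraps the same functions
(`inst/cli/memwet.R`; subcommands `profile`, `energy-curve`,
`portrait-bilayer`, `portrait-monolayer`, `symmetric-scan`,
`egfr-report`, `validate`), reading a YAML configuration
(`inst/extdata/default_config.yaml`) with `--set key.path=value`
overrides, and writing CSV/JSON products plus a run manifest that
reproduces outputs byte-for-byte.

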