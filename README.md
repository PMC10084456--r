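# ctocd

Origin-independent magnetically induced current densities and isotropic NMR
shieldings via the CTOCD-GRRO and CTOCD-GPRO schemes, with single-pass
Becke/Biot–Savart integration and two-point parameter calibration.

## The problem

Nuclear magnetic shieldings computed from the induced first-order current
density **J**^B(r) suffer from the gauge-origin problem: in a finite basis
the common-origin (CO) current depends on the arbitrary vector-potential
origin **r**₀.  The *continuous transformation of the origin of the current
density* (CTOCD) family removes this by distributing the origin with a shift
function **d**(r).  The GRRO and GPRO variants use

> **d**(r) = r − f(ρ) ∇ln ρ,  with f = α (GRRO) or f = β ρ^(−2/3) (GPRO),

which makes the diamagnetic component **J**_d = −(f/2c) **B** × ∇ρ exactly
divergenceless for any f(ρ).  The GPRO exponent −2/3 is fixed by dimensional
analysis ([f ∇ln ρ] = length, β dimensionless); with the Thomas–Fermi
(Harris–Cina) value β = −(3π²)^{1/3}/(18π²) = −0.0174 the GPRO diamagnetic
term coincides with the local-density current approximation.  At α = β = 0
both schemes reduce to the ipsocentric CTOCD-DZ1 form, whose diamagnetic
part vanishes identically.

The central, machine-checkable property is **linearity**: the GRRO/GPRO
current — and hence any shielding obtained from it through the Biot–Savart
law

> σ^N_{γβ} = −(1/c) ∫ ε_{γδν} (∂J_δ/∂B_β)(r) (R_N − r)_ν / |R_N − r|³ d³r,
> σ^N_Av = tr σ^N / 3 (ppm)

— is an exactly linear function of its own defining parameter.  Two probe
evaluations therefore calibrate, per nucleus, the α or β that reproduces a
reference (basis-set-limit) shielding *analytically*, and small-basis
calculations equipped with calibrated per-element or per-chemical-environment
parameters (ᾱ_CE, β̄_CE) recover near-reference accuracy at a fraction of
the cost.  This package implements the whole chain for closed-shell
molecules:

- molecular geometry handling (XYZ), covalent-radius bond perception, and
  connectivity-based chemical-environment typing (heavy atoms by first
  shell, hydrogens by first and second shell);
- a compact restricted Hartree–Fock + coupled-perturbed response backend
  (McMurchie–Davidson integrals over s/p Gaussians; STO-3G built in, plus
  an even-tempered basis generator) supplying the density and the six
  angular-/linear-momentum response kernels;
- CO, DZ1, GRRO and GPRO current-density tensors with an explicit
  unit-parameter kernel K such that total(p) = total(0) + p·K exactly;
- Becke multicenter quadrature (fuzzy cells, Bragg–Slater size adjustment)
  and Biot–Savart integration of **all** nuclei in one pass, with the scheme
  parameter switched per atomic cell;
- two-point analytical calibration, parameter tables with dispersion
  statistics, error propagation |slope|·std, and AD/MAD/F-test comparison
  statistics;
- Gaussian cube export of current fields and a `ctocd` command-line tool
  (subcommands `compute`, `calibrate`, `envtype`, `report`, `fixtures`).

It is aimed at method developers and computational spectroscopists who want
a transparent, fully scriptable reference implementation of the
parameter-linear CTOCD machinery on desk-scale systems.

## Worked example

```r
library(ctocd)

mol   <- make_fixture("H2O")                 # r(OH) = 0.9572 A, 104.52 deg
state <- build_response_state(mol)           # RHF/STO-3G + response
grid  <- molecular_grid(mol)                 # Becke-partitioned quadrature

## all shieldings in one pass, GPRO at the Thomas-Fermi beta
res <- integrate_shielding_all_nuclei(
  state, scheme_parameter("GPRO", beta = beta_harris_cina()), grid)
print(res)
#> CTOCD shielding result (GPRO scheme, 3 nuclei)
#>  nucleus element scheme  parameter sigma_av_ppm
#>        1       O   GPRO -0.0174141    -152.1227
#>        2       H   GPRO -0.0174141      17.4526
#>        3       H   GPRO -0.0174141      17.4526

## calibrate per-nucleus GRRO alphas against reference shieldings
cal <- calibrate_molecule(state, c("1" = 330, "2" = 30, "3" = 30),
                          scheme = "GRRO", grid = grid)
print(cal)
#> CTOCD GRRO calibration (3 nuclei, probes 0, -0.01)
#>  nucleus element     key scheme       slope intercept  parameter reference residual
#>        1       O  O[H,H]   GRRO -43519.0672 -217.8642 -0.0125891       330        0
#>        2       H H[O][H]   GRRO    -54.9714   10.6201 -0.3525456        30        0
#>        3       H H[O][H]   GRRO    -54.9714   10.6201 -0.3525456        30        0

aggregate_parameters(cal, grouping = "environment")
#> CTOCD GRRO parameter table (grouping: environment)
#>      key       mean          sd n
#>  H[O][H] -0.3525456 5.49532e-16 2
#>   O[H,H] -0.0125891 0.00000e+00 1
```

Reading the numbers: at this small basis the uncalibrated (DZ1, α = 0)
shieldings are far from reference values — that is exactly the basis-set
incompleteness the parameters absorb.  The slopes dσ/dα are ~ −4×10⁴
ppm·a₀⁻¹ for oxygen but only ~ −55 ppm·a₀⁻¹ for the protons (heavy nuclei
are orders of magnitude stiffer in the parameter), the fitted α of the two
symmetry-equivalent hydrogens coincide to machine precision, and the zero
residuals are the linearity of σ(α) at work: the two-point fit is exact,
not least-squares.  Re-integrating with each fitted parameter reproduces
the references; using environment-averaged parameters (here trivial) is
the transferable variant.

From a shell:

```sh
ctocd fixtures write H2O h2o.xyz
ctocd compute --xyz h2o.xyz --scheme GPRO --beta -0.0174 --out shieldings.csv
ctocd calibrate --xyz h2o.xyz --references refs.json --scheme GRRO \
      --grouping environment --out parameters.json
```

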