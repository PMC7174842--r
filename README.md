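# dotstripe

Joints form at stereotyped positions, numbers and orientations along every
digit of the tetrapod limb, yet the patterning logic behind them is not
explained by the molecular joint markers alone. `dotstripe` simulates a
two-Turing-system account of that logic: a **dot-forming** circuit positions
evenly spaced condensations (future phalanx centres) along the digit, and a
**stripe-forming** circuit — gated by the dot system — lays down a thin
stripe (the future joint, or interzone) in each gap between dots. On a
narrow, growing digit this yields iterative transverse joints; on a wide
domain it yields polygonal joint lattices that follow the Voronoi
tessellation of the dot positions.

The package is for quantitative/developmental biologists and modellers who
want to reproduce, probe or extend this mechanism: it bundles the solver,
the digit geometry and growth machinery, a generic one-field-per-system
Swift–Hohenberg formulation of the same logic, and the analysis toolkit
used to score the resulting patterns.

## The model

Dot subsystem (activator `A`, substrate `S`) — an activator–substrate
Turing pair:

    dA/dt = D_A lap(A) + h_A + k_A A^2 S - mu_A A
    dS/dt = D_S lap(S) + h_S - k_S A^2 S

Stripe subsystem (activator `B`, inhibitor `I`) — a saturating
activator–inhibitor pair:

    dB/dt = D_B lap(B) + k_B_eff(S) B^2 / (I (1 + kappa_eff(A) B^2)) - mu_B B
    dI/dt = D_I lap(I) + k_I B^2 - mu_I I

The coupling makes stripes form away from dots: `S` activates `B`
(`k_B_eff = k_B (S/S*)^s_act`) and `A` raises the self-activation
saturation of `B` (`kappa_eff = kappa_B (1 + s_thr A/A*)`). Outside the
digit mask Ω only degradation acts. The generic variant replaces each pair
with a Swift–Hohenberg equation — a quadratic term selects dots, an
additive bias and the instability parameter (both decreasing in the dot
field) select and orient stripes.

Everything is solved by operator splitting on a regular grid: an implicit
(backward-Euler) diffusion step, exact in the discrete cosine basis (hence
reflective boundaries), followed by a forward-Euler reaction step, with
geometry updates for tip growth, uniform stretching, a committed (frozen)
proximal zone and the digital-crescent boundary strip.

## A worked example

```r
library(dotstripe)

run <- simulate_pattern(preset("fig1F_wildtype"))
summary(run)
#> Pattern metrics of final snapshot:
#>   class       : stripes
#>   joint count : 7
#>   wavelength  : 12.80
#>   orientation : 90.0 deg from digit axis
#>   dot maxima  : 6
#>   voronoi     : undefined
plot(run)               # joint marker B with the digit outline
plot(run, field = "A")  # the dot field
```

Six dots sit on the digit midline and seven stripe bands cross the digit at
90 degrees to its axis — one joint in every gap between neighbouring dots
plus one at each end: the wild-type phalanx/joint arrangement. (The Voronoi
score is undefined here because midline dots are collinear; run
`preset("fig4_lattice")` for the wide-domain tessellation.)

Other regimes are one preset away (`preset_names()` lists all 17): tip
growth with sequential joint addition (`fig2B_growth`), a committed zone
(`fig2C_committed`), uniform growth with proximal-to-distal phalanx-length
gradients (`fig2D_uniform_growth`), misoriented joints at reduced dot
diffusivities (`fig3B_jaws`), wide-domain joint lattices (`fig4_lattice`),
the stripe-only and dot-hole alternative models (`fig5A_*`, `fig5B_*`), and
the Swift–Hohenberg variants (`fig6B_*`, `figS4_*`).

A thin command-line front end lives at `inst/cli/dotstripe.R`:

```sh
Rscript inst/cli/dotstripe.R simulate --preset fig1F_wildtype --out out/run1
Rscript inst/cli/dotstripe.R preset-list
Rscript inst/cli/dotstripe.R dispersion --preset fig1F_wildtype
```

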