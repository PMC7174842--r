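---
title: "The dot-stripe mechanism: models, solver and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dot-stripe mechanism: models, solver and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the two coupled Turing systems behind digit joint patterning, the generic
Swift–Hohenberg formulation of the same logic, the numerical scheme, and —
most importantly for a reader who wants to trust or extend the package —
the places where the design was genuinely open and what we chose there.

## 1. The four-species model

The digit is a binary mask $\Omega$ on a regular grid of square bins. Inside
$\Omega$, two reaction–diffusion pairs run in parallel.

**Dot subsystem** (activator $A$, substrate $S$; activator–substrate
class): $A$ catalyses its own production by consuming $S$ through the
classical $A^2S$ term, is linearly degraded, and both species have
constant basal production:

$$\partial_t A = D_A \nabla^2 A + h_A + k_A A^2 S - \mu_A A, \qquad
  \partial_t S = D_S \nabla^2 S + h_S - k_S A^2 S.$$

With $D_S \gg D_A$ this forms *dots* of $A$ on a depleted-$S$ background —
the phalanx condensation centres. The homogeneous steady state is closed
form: $A^* = (h_A + k_A h_S/k_S)/\mu_A$, $S^* = h_S/(k_S A^{*2})$.

**Stripe subsystem** (activator $B$, inhibitor $I$; saturated
activator–inhibitor class): $B$ self-activates through $B^2/I$, saturating
at high $B$, and drives its own fast-diffusing inhibitor:

$$\partial_t B = D_B \nabla^2 B +
   \frac{k_B^{\mathrm{eff}}(S)\, B^2}{I\,(1 + \kappa^{\mathrm{eff}}(A) B^2)}
   - \mu_B B, \qquad
  \partial_t I = D_I \nabla^2 I + k_I B^2 - \mu_I I.$$

**Coupling.** Stripes must form *between* dots. Two monotone gates do
this: $S$ activates $B$ and $A$ raises $B$'s saturation threshold,

$$k_B^{\mathrm{eff}}(S) = k_B\,(S/S^*)^{s_{\mathrm{act}}}, \qquad
  \kappa^{\mathrm{eff}}(A) = \kappa_B\,(1 + s_{\mathrm{thr}} A/A^*).$$

The threshold gate carries the suppression: at a dot centre
($A \approx 3A^*$) the saturation is so high that the stripe instability is
extinguished (its fastest growth rate is negative), while between dots
($A \approx 0.6A^*$) it is strongly positive. The activation gate is kept
*weak* ($s_{\mathrm{act}} = 0.1$) and in power-law rather than linear form.
This was a genuinely open design point, and the saturated
activator–inhibitor algebra decides it: lowering $k_B$ shrinks the steady
state $B^*$, which *de*-saturates the self-activation and paradoxically
*destabilises* the subsystem. A strong linear $S$-gate therefore undermines
the suppression at dot centres that it is meant to support. The power form
keeps the stated behaviours — zero at $S=0$, $k_B$ at $S^*$, strictly
increasing — at a gate strength that does not fight the threshold gate.

**Outside the digit** only $A$ is degraded (rate $k_{\mathrm{deg}}$) in the
minimal model; we additionally decay $B$ and $I$ outside by their interior
rates (`outside_decay_BI = TRUE` by default). Without this, inhibitor
leaking through the digit boundary de-represses the stripe system along the
rim, and the joint pattern locks into rim-hugging longitudinal bands rather
than width-spanning transverse joints. The flag is configurable for readers
who want the strictly minimal boundary condition.

**Variants.** `stripe_only` runs $(B, I)$ alone with constant $k_B,
\kappa_B$ and reads $I$ as the joint marker; `dot_hole` runs $(A, S)$ alone
and reads $S$ as the joint marker. A configuration key names the joint
marker so all analysis code is variant-agnostic.

## 2. Default parameters and what pins them

No canonical parameter table ships with the model class, so the defaults
were placed by an explicit, reproducible procedure (all steps are exported
functions):

1. **Dot kinetics** with a closed-form steady state:
   $k_A = k_S = \mu_A = 1$, $h_S = 1$, $h_A = 0.15$. The basal production
   $h_A$ matters more than it looks: new tissue enters the growing digit
   essentially free of $A$, and must *ignite* the dot instability from the
   low-$A$ state. The quiescent state disappears (and patterning can
   invade) once local $S$ exceeds $\mu_A^2/(4 k_A h_A)$; at $h_A = 0.15$
   this is about $2.2\,S^*$, which tip accumulation reaches readily. At
   $h_A = 0.05$ the barrier is $5.5\,S^*$ and a growing digit simply never
   patterns behind its tip.
2. **Dot diffusivities** from the dispersion relation
   (`dot_linear_stability()`): $D_A = 1.15$, $D_S = 23$ give a Turing-
   unstable band with predicted wavelength $\lambda_{\mathrm{dot}} \approx
   13$ bins at growth rate $\sigma_{\max} \approx 0.13$.
3. **Stripe wavelength against the digit width.** A width-$W$ digit
   supports clean transverse joints only if the stripe wavelength
   *exceeds* $W$, so that exactly one across-width mode fits; with
   $\lambda_{\mathrm{stripe}} \lesssim W$ the stripe field settles into an
   across-width antiphase state (bands along both rims, a pinched midline).
   The defaults use $W = 8$ and $\lambda_{\mathrm{stripe}} \approx 12$
   ($D_B = 1.65$, $D_I = 74.25$), matching the dot spacing so each
   inter-dot gap hosts one stripe. On *wide* domains the opposite holds —
   the joint network must resolve cells of size $\lambda_{\mathrm{dot}}$ —
   so the lattice presets reduce $(D_B, D_I)$ at fixed ratio
   ($\lambda_{\mathrm{stripe}} \approx 5$), exactly the per-regime
   wavelength adjustment the underlying experimental presets are built
   around.
4. **Gate strengths** $s_{\mathrm{thr}} = 5$, $s_{\mathrm{act}} = 0.1$ and
   saturation $\kappa_B = 0.03$, chosen so the stripe dispersion relation
   is stable at the measured dot-centre field values
   ($A \approx 3A^*, S \approx 0.12S^*$) and clearly unstable at the
   measured inter-dot values ($A \approx 0.6A^*, S \approx 0.95S^*$), with
   a monotone growth-rate profile along the dot-centre-to-far clamp path.
5. **Stripe clock** twice the dot clock ($k_B = \mu_B = k_I = 2$,
   $\mu_I = 3$): joints then crystallise promptly once dots open the gate,
   which is what keeps joint addition in register with tip growth.

The robustness of the headline phenotype (six midline dots, one transverse
joint per gap) was checked over eight independent noise seeds before the
defaults were frozen; they are pinned in `default_config()` and every
preset references them.

## 3. Geometry, growth, commitment, crescent

The digit is a rectangle of length $L(t)$ and width $W$ capped by two
half-ellipses of along-axis extent $\varepsilon$. The caps are *appended*
(total extent $L + 2\varepsilon$); the distal cap advances with growth
while the proximal end never moves. A bin is inside iff its centre is
inside the continuous shape. Length grows piecewise linearly from $L_0$
(after a settling time $T_i$) to $L$ at time $T$, rounded to bin
resolution, with geometry refreshed every `growth_every` solver steps.
Newly covered bins keep whatever state they held outside — they ignite, as
discussed above, rather than being seeded.

*Uniform growth* interleaves tip extension with uniform stretching: at each
growth event a fraction `stretch_ratio` of the length increment is realised
by linearly resampling all fields along the axis about the proximal anchor.
Linear interpolation is the entire choice here; band counts are preserved
and field integrals scale by the stretch factor to interpolation accuracy.

*Committed zone*: bins farther than $L_P$ (along-axis, strict inequality)
from the distal-most digit column are frozen — they stop updating but keep
diffusing into their neighbours. Freezing engages only after the settling
time $T_i$: committing earlier would fix pre-pattern noise, which is an
artefact of discrete initial conditions, not part of the mechanism.

*Digital crescent*: the layer of inside bins within a configured thickness
of the distal cap boundary, carrying extra production of $A$ ($h_A^{DC}$)
and a linear sink of $B$ ($-h_B^{DC} B$). The crescent is rebuilt at each
geometry update rather than advected.

## 4. The generic Swift–Hohenberg formulation

The same logic with one field per system:

$$\partial_t u = \alpha_{\mathrm{dot}} u - (1 + \ell_{\mathrm{dot}}^2
  \nabla^2)^2 u + \gamma u^2 - u^3,$$
$$\tau\, \partial_t v = \alpha_{\mathrm{eff}}(u)\, v -
  (1 + \ell_{\mathrm{stripe}}^2 \nabla^2)^2 v - v^3 + h_{\mathrm{eff}}(u),$$

with $\alpha_{\mathrm{eff}} = \alpha_0 - s_\alpha\,\mathrm{rect}(u)$,
$h_{\mathrm{eff}} = h_0 - s_h\,\mathrm{rect}(u)$ and $\mathrm{rect}(u) =
\max(u, 0)/\max(|u|)$ (floored normalisation). Defaults
$\alpha_{\mathrm{dot}} = 0.2$, $\gamma = 1.5$ sit close to onset — at
$\alpha \gtrsim 0.35$ the quadratic term no longer wins and the dot
equation produces labyrinths. The *h*-only coupling (with
$\alpha_{\mathrm{stripe}} = 0$) yields a hole-like response; the
$\alpha$-only coupling lets stripes self-organise between dots but with
unconstrained orientation; both together give transverse joints on the
narrow digit and polygonal lattices on wide domains. Two geometry-driven
caveats, observed in this implementation and reflected in how the tests
are framed: on the narrow digit, confinement alone orients stripes
transversely, so the orientation *contrast* between coupling modes is
evaluated on the wide domain; and wide domains use
$\ell_{\mathrm{stripe}} = 1.2 < \ell_{\mathrm{dot}} = 2$ so the stripe
field can resolve closed cells (the narrow preset keeps them equal).

## 5. Numerics

* **Operator splitting**, diffusion first, then reactions (forward Euler).
* **Diffusion is exact per step** for the discrete operator: fields are
  expanded in the orthonormal DCT-II basis (bin-centred cosines), which
  diagonalises the 5-point Neumann Laplacian with eigenvalues
  $\lambda_m = (2/h^2)(1 - \cos(\pi m/n))$; each mode is divided by
  $1 + \Delta t\, D\, \lambda$. Reflective (zero-flux) boundaries are exact
  at bin faces; the field total is conserved to round-off. The
  Swift–Hohenberg operator is handled the same way with symbol
  $(1 - \ell^2 \lambda)^2$.
* **Time step**: $\Delta t = 0.1$ for the growth presets and $0.05$ for
  the reference wild-type preset, at which halving $\Delta t$ moves the
  final fields by under 2% in relative $L_2$ norm.
* **Negative concentrations** are clipped to zero after each sub-step in
  the four-species model (spectral steps can overshoot on sharp gradients
  by a tiny negative amount); the SH fields are sign-indefinite and never
  clipped.
* **Noise** enters once, at initialisation: uniform, relative amplitude
  `noise_amp` (2%) about the homogeneous steady state (absolute for SH,
  about zero). Identical seeds give bit-identical trajectories.
* **Degenerate inputs**: the $B^2/I$ division is floored at
  $I_{\mathrm{floor}} = 10^{-6}$; an overflow guard aborts a run if any
  field exceeds $10^6\times$ its steady-state scale and reports a
  time-step suggestion.

## 6. Pattern analysis

* **Dot maxima**: 8-neighbourhood local maxima with a prominence test over
  a window scaled to a third of the measured dot wavelength (plateaus
  resolved to centroids). The default prominence is 20% of the field range
  inside $\Omega$.
* **Wavelength**: peak of the radially averaged power spectrum of the
  mean-subtracted, $\Omega$-windowed field; the window-dominated lowest
  rings are excluded and a flat spectrum (peak below $3\times$ the median
  ring power) is an error, not a number.
* **Orientation**: gradient structure tensor averaged over the digit
  interior (boundary bins excluded), reported in degrees from the digit
  axis folded into $[0, 90]$; a near-isotropic tensor (coherence $< 0.15$)
  is an error.
* **Joint counting**: threshold at mean $+ 1$ SD inside $\Omega$; count
  components spanning the midline with at least $W/6$ of reach into each
  half; centroid positions are returned for spacing analyses.
* **Classification** (documented constants throughout): a supra-quantile
  phase (thresholds at the 0.5 and 0.35 quantiles, closed with a
  $3\times3$ kernel to bridge sub-resolution gaps) that fully encloses
  $\ge 4$ deep interior cells is a network — "lattice" for positive skew,
  "holes" for negative; otherwise phases split at the mean give "dots"
  (disconnected positive phase, connected background, positive skew), the
  mirror "holes", or "stripes" for balanced multi-component phases. The
  depth requirement (cell minimum $0.7$ SD below the threshold) stops the
  shallow oscillatory skirts around isolated peaks from reading as cells.
* **Voronoi agreement**: inside bins are labelled by their nearest dot
  point; bins flanking label changes are the rasterised Voronoi edges;
  stripe ridges are the top decile of the joint marker. The score is the
  *larger* of the two median distances (ridge-to-edge and edge-to-ridge)
  over the pattern wavelength. The symmetric form matters: scoring only
  ridge-to-edge lets any sufficiently dense point set place an edge near
  every ridge bin and claim spurious agreement — precisely the degeneracy
  the stripe-only model's inferred cell centres produce.
* **Band curvature**: per supra-threshold band, the centerline through
  principal-frame slices is fit by a line; the RMS residual over band
  length measures bow. Straight transverse bands score near zero; the
  dot-hole model's arcs around phalanx centres score several-fold higher.
  This shape contrast is evaluated on the wide lattice geometry: a
  narrow channel leaves no room for crescents, and both models produce
  straight bands there.
* **Clamp experiments** reuse the solver with frozen $(A, S)$ fields over
  the *entire* domain (no digit mask — rim effects would otherwise
  dominate the response): uniform clamps report the final spatial SD of
  $B$; gradient clamps report stripe orientation relative to the imposed
  gradient.

## 7. What the synthetic conditions do and do not show

Everything here is pattern formation from seeded noise on idealised
geometries: rectangles with elliptical caps, piecewise-linear growth laws,
parameters constant in space and time. Passing tests show the *mechanism*
behaves as claimed — joints between dots, sequential addition, Voronoi
lattices, the coupling-mode contrasts — under controlled conditions. They
do not show that real digits use these molecules, these rate laws, or
boundary conditions this clean; anterior–posterior parameter gradients,
mechanics, cell movement and three-dimensionality are all outside the
model class. The analysis thresholds (ridge decile, joint SD offset,
classifier constants) are repository constants with sensitivity covered in
the test suite, not biological measurements.

## 8. Problem sizes

The shipped study conditions run on one CPU in minutes: the narrow digit
on a $128 \times 40$ grid (3,000–13,200 steps), wide domains at
$96 \times 96$, dispersion checks at $192 \times 192$, clamp domains at
$64 \times 64$. These sizes give at least four pattern periods in every
measured direction, which is what the spectral wavelength estimator needs;
larger grids change the measured quantities only through slower statistics.
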