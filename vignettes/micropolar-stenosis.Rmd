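---
title: "Micropolar annular flow through an overlapping stenosis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micropolar annular flow through an overlapping stenosis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stenoflow)
```

## The physical problem

A catheter of radius $r_c$ sits coaxially inside an artery whose wall tapers
linearly and carries an *overlapping* stenosis — two merged constrictions
producing two depth maxima ($z_L$, $z_R$) with a shallower saddle ($z_C$)
between them. Blood flows steadily through the annular gap. Because blood is
a suspension, it is modelled as an Eringen micropolar fluid: alongside the
axial velocity $v_z(r)$ the microstructure carries an independent
microrotation field $\nu_\theta(r)$, coupled to the bulk shear.

All quantities are nondimensional: radii are scaled by the unconstricted
arterial radius $r_0$, axial distance by the stenosis length $L_1$,
velocities by a typical axial velocity, so the artery spans
$z \in [0, 1/\Gamma]$ with $\Gamma = L_1/L$ and the stenosis occupies
$[\gamma, \gamma + 1]$, $\gamma = L_0/L_1$.

## Geometry

Inside the stenotic segment the wall is
$$
h(z) = 1 + \zeta z - \tfrac{3\varepsilon}{2}
\bigl(11u - 47u^2 + 72u^3 - 36u^4\bigr), \qquad u = z - \gamma,
$$
and $h(z) = 1 + \zeta z$ elsewhere; $\zeta = \tan\phi$ is the taper
parameter and $\varepsilon$ the stenosis height parameter. The quartic
bracket vanishes at $u = 0$ and $u = 1$, so the wall is continuous. Two
conventions note: the *actual* constriction depth at the humps is
$\approx 1.2603\,\varepsilon$ (and $\tfrac34\varepsilon$ at the saddle), a
property of this standard overlapping profile that the parameter name
"height" obscures; the test suite asserts the computed depth.

The stationary points of $h$ are the roots in $(0,1)$ of
$$
144u^3 - 216u^2 + 94u - 11 + \frac{2\zeta}{3\varepsilon} = 0 .
$$
`stenosis_extrema()` solves this cubic with `polyroot()` (companion-matrix
eigenvalues) and polishes each root by Newton iteration on $dh/dz$ to
$\sim 10^{-12}$. Whatever $\zeta$ and $\varepsilon$, the three roots sum to
$216/144 = 1.5$ and their pairwise products to $94/144$ — Vieta identities
that make useful sanity checks on any tabulated values of these locations.
For $\zeta = 0$ the cubic factors through $u = \tfrac12$: the saddle sits at
the segment midpoint and the humps are symmetric. A taper so steep that
fewer than three real roots remain in $(0,1)$ is reported as a degenerate
geometry rather than silently reduced; $\varepsilon = 0$ (no stenosis) is a
valid *flow* geometry but has no extrema to report.

## The reduced flow problem at one station

Under the mild-stenosis (lubrication) approximation —
constriction small against the radius, radius comparable to the stenosis
length — the radial momentum balance collapses to $\partial p/\partial r = 0$
and the axial and angular momentum balances at each station reduce to a
one-dimensional boundary-value problem in $r$ across the gap $[r_c, h]$.
Only two material groups survive: the coupling number
$N = \kappa/(\mu+\kappa) \in [0,1)$ and the micropolar parameter $m > 0$,
which sets the microrotation boundary-layer thickness $\sim 1/m$. The
general solution is
$$
\nu_\theta = c_2 I_1(mr) + c_3 K_1(mr)
 - \frac{1-N}{2-N}\Bigl(\frac{c_1}{r} + \frac{r}{2}\Bigr)\frac{dp}{dz},
$$
$$
v_z = \frac{N}{m}\bigl(-c_2 I_0(mr) + c_3 K_0(mr)\bigr)
 + \frac{2(1-N)}{2-N}\Bigl(c_1\ln r + \frac{r^2}{4}\Bigr)\frac{dp}{dz} + c_4,
$$
with no-slip and no-spin at the catheter, prescribed slip $u$ and no-spin at
the arterial wall: $v_z(r_c) = 0$, $v_z(h) = u$,
$\nu_\theta(r_c) = \nu_\theta(h) = 0$. The sign of the pressure-gradient
group in $v_z$ deserves a remark: one also encounters this solution printed
with a minus sign on that group, but direct substitution shows the pair then
violates both reduced balances (the axial-momentum residual flips sign);
the form above satisfies them to machine precision, which the test suite
verifies by finite differences. The package therefore uses the
self-consistent sign throughout.

### Numerical assembly

For the default $m = 50$, $I_1(mr)$ reaches $\sim 10^{20}$ across the gap
and overflows double precision near $mr \gtrsim 700$. The $4\times4$
boundary system is therefore assembled from exponentially scaled Bessel
functions ($I_\nu$ scaled by $e^{-mr}$, $K_\nu$ by $e^{+mr}$), with the
constants stored in a matching scaling ($c_2 e^{mh}$, $c_3 e^{-m r_c}$) so
every downstream expression combines only like-scaled, $O(1)$ products.
A station with $m = 800$ — hopeless unscaled — solves to boundary residuals
below $10^{-9}$.

The system is linear in $(dp/dz,\, u)$, so the solver computes the two unit
sub-problems once and superposes. The first constant is kept in the combined
form $c_1 \cdot dp/dz$: that is the only form in which it enters any
expression, and it keeps the unit-slip sub-problem nondegenerate. The
$4\times4$ solve uses partial pivoting; a condition estimate above $10^{12}$
(annular gap below $\sim 10^{-11}$) is refused with the estimate reported,
rather than returning digits that are no longer there.

### Flux

The volumetric flux $Q = \int_{r_c}^{h} 2 r v_z\, dr$ is evaluated in closed
form from the termwise antiderivatives
$\int r I_0(mr)\,dr = (r/m) I_1(mr)$,
$\int r K_0(mr)\,dr = -(r/m)K_1(mr)$,
$\int 2r\ln r\,dr = r^2\ln r - r^2/2$, giving the affine station relation
$$
Q = A(z)\, \frac{dp}{dz} + B(z)\, u ,
$$
with $A$ the flux per unit pressure gradient and $B$ the flux carried by the
slip. The closed form is cross-checked against adaptive quadrature of
$2 r v_z$ at random stations (relative agreement $<10^{-7}$).

## Impedance and wall shear stress

With the flux prescribed (constant along $z$), the pressure gradient at each
station follows from inverting the flux relation, and the impedance
(resistance per unit length of artery) is
$$
\lambda = \frac{\Gamma}{Q}
\Bigl[\int_0^{\gamma} + \int_\gamma^{\gamma+1} + \int_{\gamma+1}^{1/\Gamma}\Bigr]
\Bigl|\frac{dp}{dz}\Bigr|\, dz ,
$$
integrated per segment by adaptive Gauss–Kronrod quadrature
(absolute and relative tolerance $10^{-9}$), split at $\gamma$ and
$\gamma+1$ where the integrand kinks; the summed error estimate is reported.
Wall shear stress for the micropolar fluid is
$\tau_w = -\frac{1}{1-N}\,\partial v_z/\partial r$ at $r = h(z)$, from the
analytic derivative of the solution ($I_0' = I_1$, $K_0' = -K_1$).

### Two slip conventions

How the slip enters the pressure gradient is a genuine modelling fork, and
the package implements both:

* **`method = "affine"`** (default): $dp/dz = (Q - B u)/A$. The slip-borne
  flux is removed before inverting, so mass is conserved exactly — the
  velocity profile rebuilt from the returned gradient reproduces $Q$ to
  $10^{-7}$. Under this convention slip *lowers* both the impedance and the
  wall shear stress at fixed flux (a flatter profile needs less driving).
* **`method = "conductance"`**: the slip contribution is folded into the
  station flux function at unit pressure gradient,
  $F = (A + uB)/2$, and $dp/dz = Q/(2F)$. This is the form in which
  impedance columns for this model are tabulated in the published
  literature, and `stenoflow` reproduces the reference column
  (42.4983 … 743.398 over $r_c = 0.001$ … $0.4$) to $\sim 10^{-6}$ relative
  only under this convention with $u = 0.01$ — settling empirically which
  form produced those numbers, something their source leaves unstated.
  Because $A$ and $B$ have opposite signs in the forward-flow convention,
  the slip term *shrinks* $|F|$, so under this convention slip raises
  $|dp/dz|$, the impedance, and the wall shear stress.

The two conventions coincide at $u = 0$ and differ by $O(u)$ otherwise. The
published trend claims for this model are themselves split between the two
(impedance falling with slip matches "affine"; wall shear rising with slip
matches "conductance"); the trend tests in this package use affine for
$\lambda$ and conductance for $\tau_w$, matching the direction each claim
was evidently computed under. For physical predictions with slip we
recommend the default affine path, which is the mass-consistent one.

Trend checks on $\lambda$ are run about the nontapered reference
configuration ($N = 0.75$, $m = 50$, $\Gamma = 0.5$, $r_c = 0.1$,
$u = 0.01$, $\varepsilon = 0.1$, $Q = 1$). That choice matters for one
parameter: with a converging taper the $\lambda$–$\Gamma$ relation is
genuinely non-monotone (lengthening the stenosis *fraction* also shortens
the high-resistance tapered tail), while at $\zeta = 0$ it is exactly
linear and increasing.

## Parameters at a glance

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| $\phi$ / $\zeta$ | taper angle / $\tan\phi$ | $-0.05$ | converging; mutually exclusive inputs |
| $\varepsilon$ | stenosis height parameter | 0.1 | hump depth $\approx 1.26\varepsilon$ |
| $\gamma$ | stenosis onset $L_0/L_1$ | 0.5 | stenosis on the middle half |
| $\Gamma$ | stenosis fraction $L_1/L$ | 0.5 | artery length $1/\Gamma = 2$ |
| $r_c$ | catheter radius | 0.1 | must stay below $\min h$ |
| $N$ | coupling number | 0.75 | $[0, 1)$; 0 = Newtonian |
| $m$ | micropolar parameter | 50 | boundary-layer scale $1/m$ |
| $Q$ | prescribed flux | 1 | tabulation convention |
| $u$ | wall slip velocity | 0.01 | 1% of the velocity scale |

The defaults are the reference configuration under which the published
extremum table and impedance column for this model were produced (the
impedance column is nontapered, $\zeta = 0$).

## Oracles and what the tests show

Independent reference paths live in the installed package so the CLI
`self-check` can exercise them:

* the classical Newtonian annulus closed form (the $N \to 0$ limit;
  agreement within $10^{-4}$ max-norm at $N = 10^{-6}$),
* adaptive-quadrature flux against the closed-form coefficients,
* a brute-force derivative sign-scan (step $10^{-5}$, bisection refinement)
  against the cubic-root extrema,
* finite-difference residuals of the reduced balances.

There is no synthetic *data* in the usual sense — the model has no external
inputs — so the test fixtures are parameter configurations: random
admissible stations (annulus, fluid, forcing drawn under fixed seeds) and
the reference configurations above. Problem sizes are desk-scale
throughout: 100-station property sweeps, $5\times5$ oracle grids,
quadratures of a few hundred evaluations; the whole suite runs in seconds.

Passing tests show internal consistency of the analytic solution, its
limits, and agreement with the published reference values — they do not
validate the mild-stenosis approximation itself against resolved
Navier–Stokes flow or measurements, nor any regime with inertial,
unsteady, or severe-constriction effects.

## Known limitations

* Steady flow only; no pulsatility, no wall motion.
* Lubrication order: the radial velocity is eliminated; results degrade as
  $\varepsilon$ stops being small against 1 or the stenosis shortens.
* Three of the published diverging-taper ($\phi = +0.05$) extremum entries
  are mutually inconsistent with the cubic's root-sum identity
  ($\sum u_i = 1.5$; the printed row sums to 1.4791) and cannot be
  reproduced by *any* admissible geometry; the suite asserts the full
  published table and deliberately reports those three entries as failures,
  with the computed values (saddle at $z = 1.0240$, downstream hump at
  $1.2991$, saddle radius $0.9756$) satisfying the identities.
* The wall shear stress is reported from the analytic velocity derivative;
  a couple-stress-style two-root form sometimes quoted for $\tau_w$ in this
  context involves quantities undefined in this model and is not
  implemented.
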