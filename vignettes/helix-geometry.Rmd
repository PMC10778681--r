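---
title: "Discrete Frenet-frame geometry and the critical-state free energy of DNA duplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete Frenet-frame geometry and the critical-state free energy of DNA duplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixframe)
```

## The model

A DNA duplex is treated as a ribbon surface: two sugar-phosphate strands
winding around a central helical axis. `helixframe` quantifies the shape and
the elastic cost of that ribbon with a chain of purely geometric steps:

1. **Backbone reduction.** Each deoxynucleotide is reduced to one point, the
   arithmetic mean of its C3', C4', O3' and C1' atoms. The deoxyribose links
   base and phosphate backbone, so this average localizes the residue on the
   strand without committing to any base atom.
2. **Helical axis.** Paired residues of the two antiparallel strands are
   connected positionally (position $i$ of strand A with position $n_b+1-i$ of
   strand B); the axis point $r_i$ is the midpoint of the paired backbone
   points. Coordinates are converted from ångström to nanometres here, once.
3. **Discrete Frenet frame.** At each interior axis site,
   $t_i = \widehat{r_{i+1}-r_i}$,
   $b_i = \widehat{t_{i-1}\times t_i}$ (where the cross product is nonzero)
   and $n_i = b_i \times t_i$ form a right-handed orthonormal triple — a frame
   for the curve *as a curve on the ribbon surface*.
4. **Euler angles.** zyz Euler angles $R_z(\alpha)R_y(\beta)R_z(\gamma)$
   describe frame orientations; their period-corrected site-to-site
   differences feed the geometry.
5. **Geometry.** Normal curvature $k_n = \Delta\beta/\Delta s$, geodesic
   curvature $k_g = -(\Delta\alpha/\Delta s)\sin\beta_i$, geodesic torsion
   $\tau_g = (\Delta\alpha/\Delta s)\cos\beta_i$, overall curvature
   $k = \sqrt{k_g^2+k_n^2}$ and overall torsion
   $\tau = \tau_g + \Delta\chi/\Delta s - \Delta\rho$.
6. **Free energy.** The discretized critical-state density per site,
   $$F_i = \tfrac{B_i}{2}\left(k_{n,i}^2+k_{g,i}^2\right)
        + \tfrac{C_i}{2}\left(\tau_{g,i} + \tfrac{\Delta\chi}{\Delta s}
          - \Delta\rho\right)^2
        + \tfrac{d_1}{2}\left(\tfrac{\Delta\rho}{\Delta s}\right)^2
        + \tau_c\,\Delta\rho,$$
   with the gauge identification $\Delta\rho \equiv \Delta\chi$: the gauge
   potential is the rotation angle between consecutive base pairs. Its sign
   is the chirality call — positive for a right-handed (B-type) helix,
   negative for a left-handed (Z-type) one — and the linear $\tau_c\Delta\rho$
   term (with $\tau_c < 0$) is what makes right-handed twist energetically
   favourable.

## Conventions that needed a decision

### Two zyz readings of one frame set

For a screw-symmetric helix every site is equivalent, so any per-site angle
series inherits the screw: the full per-step twist lands in exactly *one* of
the three zyz slots, which one depending on how the rotation relating frames
is written down. No single reading can simultaneously express "the tangent
direction changes azimuth by the twist each step" (what the curvature
formulas need) and "the ribbon rotates about its axis by the twist each step"
(what the gauge potential is). `helixframe` therefore uses the same zyz
extraction on two different rotation matrices:

* **Orientation angles** $\alpha_i, \beta_i$ are taken from the frame matrix
  itself, the rotation carrying the laboratory basis onto
  $(n_i, b_i, t_i)$. Then $\alpha$ is the azimuth and $\beta$ the polar angle
  of the tangent — the discrete counterpart of the continuous
  curve-on-surface chart, where
  $n = (\cos\beta\cos\alpha, \cos\beta\sin\alpha, -\sin\beta)$. These angles
  make the discrete estimators converge to the classical circular-helix
  closed forms $k = R_h/(R_h^2+c^2)$, $\tau_g = c/(R_h^2+c^2)$ (exactly, for
  uniform sampling), and they reproduce the characteristic pattern that
  $\beta$ barely changes along a duplex while $\alpha$ advances steadily —
  hence $|k_g| \gg |k_n|$.
* **The gauge angle** $\chi_i$ is taken from the cumulative transfer
  rotation $R_{i,\mathrm{base}} = C_i C_\mathrm{base}^T$ (columns
  $C = [n\,|\,b\,|\,t]$), the lab-frame rotation carrying the first valid
  frame onto frame $i$. For an ideal duplex this telescopes to exactly
  $R_z(k\,\omega)$, the accumulated helical rotation. $\chi$ is stored as
  the z-twist $(\alpha+\gamma) \bmod 2\pi$ of that rotation, which is
  continuous across the gimbal singularity and coincides with the third
  Euler angle on the lock branch (see below). Its wrapped difference is
  $\Delta\rho$.

The transfer convention $C_{i+1} = R_{i+1,i}C_i$ is fixed by its own
behaviour: frames advanced by a constant $R_z(0.6)$ per step must yield
cumulative rotations $R_z(0.6k)$, which holds for $R_{i+1,i} = C_{i+1}C_i^T$
and for no transposed variant.

### Gimbal lock

An ideal, axis-aligned duplex puts every cumulative transfer rotation exactly
on the zyz singularity ($\sin\beta = 0$), where only $\alpha+\gamma$ is
defined. The package convention assigns the whole z angle to $\gamma$ with
$\alpha = 0$ (threshold $\sqrt{r_{13}^2+r_{23}^2} < 10^{-8}$), so the gauge
angle is well defined on the ideal geometry that real duplexes approximate;
storing $\chi = \alpha+\gamma$ makes the value insensitive to which side of
the threshold a near-ideal structure falls on.

### Chain-direction canonicalization

The discrete binormal $b = t_{i-1}\times t_i$ is a pseudo-vector: under a
mirror reflection the frame set transforms improperly and the cumulative
z-rotation angle alone would *not* change sign — a mirrored right-handed
duplex would read as right-handed. The physical twist is a rotation about the
axis *oriented along the chain*. `orient_axis()` therefore applies one proper
rotation ($180^\circ$ about x) whenever the end-to-end vector of the axis
trace points toward $-z$, so the reference strand always advances along $+z$.
A mirrored duplex then becomes an upright left-handed helix and its mean
gauge potential is the exact negation of the original's. Input structures
are expected to have their helix axis roughly along $\pm z$ (as the
axis-aligned generator output does); strongly tilted inputs should be
rotated upright first, since lab-frame zyz angles are not rotation-invariant.

### Evaluable sites and blind spots

Frames need both neighbours, so they exist on sites $2..N-1$. The first frame
anchors the cumulative rotation — its angles are a pinned reference, not a
measurement — so measured angles live on $3..N-1$ and differences (hence
curvature, torsion and free energy) on $3..N-2$. A clean $N$-site duplex thus
has $N-4$ evaluable sites: two blind sites at each end.

## Parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `b` | 50 | nm | bending persistence length, sets $B_i = (b/\Delta s)\times10^{-1}\times4.1\times10^{-21}$ J |
| `c_twist` | 100 | nm | twisting persistence length, sets $C_i$ analogously |
| `kT_R` | $4.1\times10^{-21}$ | J | thermal energy scale at room temperature |
| `D1` | $4.1\times10^{-21}$ | J | effective-potential stiffness, $d_1 = D_1/\omega_0^2$ |
| `omega0` | 0.6 | rad/bp | unstressed helical rotation per base pair |
| `tau_c` | $-7.9\times10^{-21}$ | J | critical torque, linear gauge coupling |
| frame tolerance | $10^{-8}$ | — | $|t_{i-1}\times t_i|$ below which a site is invalid |
| chirality threshold | 0.05 | rad | mean $\Delta\rho$ band called "ambiguous" |

The persistence lengths are literature-typical B-DNA values and are mandatory
config: absolute free-energy magnitudes depend on them directly, so summaries
echo every physical parameter used. The overall torsion $\tau$ and the $d_1$
term mix rad/nm with rad once discretized with $\Delta\rho = \Delta\chi$;
they are applied exactly as the discretized model prescribes, and $\tau$ is
reported in "model units" rather than 1/nm.

## The synthetic generator

`ideal_duplex()` places strand A backbone points on a cylinder (radius
0.94 nm) at angle $i\,\omega$ and height $i \times \mathrm{rise}$, and strand B
points at the same heights offset by the strand phase gap, emitted in
reversed order (antiparallel) with complementary bases. Four pseudo-atoms
named C3', C4', O3', C1' sit at fixed tetrahedral offsets scaled by
`atom_jitter`; the offsets sum to zero, so the backbone mean is exact at any
jitter and backbone-point tests are independent of it.

Defaults: B form $\omega = +2\pi/10.5$ rad/bp, rise 0.34 nm, phase gap
$154^\circ$; Z form $\omega = -2\pi/12$ rad/bp, rise 0.37 nm, phase gap
$160^\circ$ with an alternating CG sequence. The phase gap encodes the
groove asymmetry: at $180^\circ$ the midpoint axis would degenerate to a
straight line (all frames invalid), so the Z default stays safely away from
it while remaining closer to symmetric than the B form; both are
overridable. With the B defaults the midpoint axis is itself a helix of
radius $0.94\cos(77^\circ) \approx 0.21$ nm and pitch-per-radian
$0.34/0.598 \approx 0.57$ nm.

What the generator does *not* emulate: sequence-dependent roll/slide/
propeller variation, bent or supercoiled axes, thermal disorder, missing
atoms, or the zigzag dinucleotide repeat of real Z-DNA. Passing tests on
generator output therefore validate the geometric machinery and the sign
conventions, not the biology of any particular crystal structure; absolute
free-energy values for real structures additionally depend on persistence
lengths that must be supplied.

## Numerical choices

* Degenerate sites (collinear tangents) are flagged invalid, excluded from
  statistics, counted in the run log; runs of invalid frames split the
  rotation series into independently anchored segments.
* Consecutive axis points closer than 0.01 nm raise a degenerate-geometry
  error rather than producing huge curvatures.
* All stored angles live in $[0, 2\pi)$; all differences are wrapped to the
  minimal signed rotation in $(-\pi, \pi]$, which reduces to the "+2$\pi$ at
  the period edge" rule for right-handed steps and handles left-handed steps
  symmetrically.
* The arc step pairs the angle difference $(i+1,i)$ with the step $(i,i-1)$
  by default (`step_pairing = "trailing"`); a `"forward"` mode exists for
  sensitivity checks. The two agree exactly on uniform helices.
* Alternate locations in PDB input resolve to the highest occupancy; both
  primed (`C3'`) and asterisk (`C3*`) atom-name dialects are accepted.
* Output numbers are serialized with 10 significant digits and no
  timestamps, so identical runs produce byte-identical files.

## A worked example

```{r example}
spec <- helix_spec("B", n_bp = 50, atom_jitter = 0)
analysis <- run_pipeline(ideal_duplex(spec))
analysis$summary

# the mean gauge potential recovers the generator twist
c(mean_d_rho = analysis$summary$mean_d_rho, twist = spec$twist)

# mirroring the duplex negates it exactly
mirrored <- run_pipeline(mirror_structure(ideal_duplex(spec)))
mirrored$summary$mean_d_rho
```

The test suite exercises the same pipeline at 8–50 bp and the convergence
checks sample continuous helices at angular steps down to 0.01 rad (a few
thousand sites); everything runs in seconds on one core.

## Known limitations

* The gauge angle is defined relative to the $\pm z$-oriented chain
  direction; arbitrary rigid rotations of the input change $\alpha, \beta$
  and, for strongly tilted axes, blur the gauge potential. Align the helix
  axis with z for quantitative per-step twist.
* Pairing is positional. Bulges, internal loops or frame-shifted duplexes
  need curated chains; non-complementary pairs are only flagged.
* Only the per-rung midpoint axis is implemented — no smoothed or globally
  fitted helical axis.
* RNA and mmCIF input are out of scope; modified nucleotides are accepted
  whenever the four backbone atoms are present.
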