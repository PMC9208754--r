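---
title: "Quantifying biofilm wrinkling under flow: models, pipelines and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biofilm wrinkling under flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrinklekit)
```

# The system

Bacterial biofilms grown on the wall of a microfluidic channel develop, over
tens of hours, a striking pattern of dark wrinkles that merge into a
connected network. The wrinkles are not folds of a passive sheet: they are
hollow, matrix-walled channels formed when the growing biofilm, compressed
in the plane by its own confined growth, buckles away from the substrate
over small delaminated patches and the delamination then propagates as an
interface crack. Whether buckling-delamination starts and spreads is set by
three ingredients: the elastic properties of the biofilm layer, the
growth-induced compressive stress, and the adhesion (interface toughness)
between the biofilm and the substrate — the last of which can be tuned
through the surface free energy of the PDMS wall. Once channels exist, they
fill with motile bacteria, which can be detected and quantified from
high-speed imaging.

`wrinklekit` implements the complete quantitative toolchain for this
system: the closed-form mechanics, the image pipeline that turns
phase-contrast timelapses into wrinkle counts and lengths, differential
dynamic microscopy (DDM) for swimming speeds inside the channels, spatially
resolved correlation ("activity") maps, and Owens–Wendt surface-energy
estimation. Because raw microscopy is bulky and external, each analysis
stage ships with a seeded synthetic generator that produces data with the
statistical structure the stage assumes, together with machine-readable
ground truth; the test suite validates every stage against those truths.

# Buckling-delamination mechanics

The biofilm is modelled as a thin, isotropic elastic film (Young's modulus
$E_f$, Poisson ratio $\nu_f$, thickness $h$) bonded to a rigid substrate
and loaded by a uniform equi-biaxial compressive stress $\sigma$. Over a
circular delaminated blister of radius $R$ the film buckles once $\sigma$
exceeds

$$\sigma_c = 1.2235\,\frac{E_f}{1-\nu_f^2}\left(\frac{h}{R}\right)^2 .$$

The quadratic dependence on $h/R$ is the scientific crux: reducing the
flaw size $R$ tenfold raises the threshold a hundredfold, which is why
strongly adhering biofilms — where only single-cell-scale flaws exist —
never buckle, and why substrate surface energy controls the morphology.

Once buckled, propagation of the delamination front is governed by the
energy release rate $G$ against the interface toughness $\Gamma$. The
stored elastic energy per unit area of the unbuckled film is
$G_0 = (1-\nu_f)h\sigma^2/E_f$, and the normalized driving force is

$$\frac{G}{G_0} = c^2\left[1-\left(\frac{\sigma_c}{\sigma}\right)^2\right],
\qquad c^2 = \left[1 + 0.9021\,(1-\nu_f)\right]^{-1},$$

monotone in $\sigma$ and approaching $c^2 G_0$ at large overstress. Below
$\sigma_c$ the film is unbuckled and the energy release rate is exactly
zero; `normalized_energy_release()` reports that as a state
(`buckled = FALSE`) rather than an error so that sweeps over a growing
stress history stay convenient. The crack verdict uses the strict
inequality $G > \Gamma$: at the tie the crack is arrested. No numerical
value of $\Gamma$ is available for this system, so
`delamination_verdict()` keeps it a free parameter; the mode-mix angle is
carried as metadata only, because the deformation mode is essentially
constant here.

Biofilm rheology is usually reported as a shear-modulus magnitude
(~1 kPa). Following the usage established for this estimate, that
magnitude is inserted directly as `youngs_modulus` without a
$2(1+\nu)$ conversion; the worked numbers (`critical_stress()` of the
reference film: ≈3.45 kPa at $h$ = 15 µm, $R$ = 10 µm) reproduce the
published arithmetic, and the documentation states this convention
explicitly rather than silently converting.

Channel hydrodynamics use the infinite-parallel-plate laminar profile:
mean velocity $U = Q/(wh)$ and wall shear stress $\tau_w = 6\mu U/h$. At
the 5:1 width-to-height aspect ratio of the device the parallel-plate
approximation is accurate to a few percent, which is tighter than the
rounding of the quoted operating point (0.3 ml/h → 1.7 mm/s → 0.1 Pa);
the exact rectangular-duct series solution is deliberately out of scope.

# Wrinkle-network quantification

The pipeline mirrors the standard workflow: Otsu thresholding, small-object
removal, morphological opening, skeletonization, connected-component
labeling. Design choices the method description leaves open are fixed as
follows:

* **One threshold for the whole movie**, computed from the *last* frame
  (configurable), where the histogram is most clearly bimodal. Applying a
  per-frame threshold would make early, low-contrast frames noisy and
  would break comparability across time.
* **Otsu** is implemented over the image's own gray levels with the
  between-class variance maximized by cumulative sums; the returned
  threshold is the midpoint between the straddling levels, so `<` vs `<=`
  conventions cannot change the class assignment. The test suite checks
  it against an exhaustive double-loop oracle on every frame it touches.
* **Cleaning**: 8-connected objects smaller than 5 px are removed, then a
  binary opening with a 3×3 square structuring element is applied (the
  element size is our declared choice; the method names only the
  operation).
* **Skeletonization** uses Guo–Hall two-subiteration thinning. The choice
  matters: simpler thinning rules leave staircase redundancy on oblique
  ribbons, inflating pixel counts by up to ~25%, whereas Guo–Hall
  skeletons count pixels like an ideal 8-connected digital line. No
  installed R package provides topology-preserving thinning, so it is
  implemented here (vectorized over whole-image shifts).
* **Components are 8-connected**; labeling is done via graph components
  over the pixel adjacency graph (igraph), because the available
  morphology library labels 4-connected only.
* **N and L.** `N` is the number of skeleton components. `L` is, by
  default, the *total skeleton length* of the largest component (pixel
  count × pixel size, reported in mm) — which is what component labeling
  followed by extraction of the longest connected structure yields for a
  branched network. A geodesic (end-to-end) variant is available behind
  `length_method = "geodesic"`; it uses a double-sweep shortest-path
  search with $\sqrt 2$ diagonal weights, exact on tree-like skeletons.
  Pixel count measures the *Chebyshev* (chessboard) length of a digital
  curve, a convention shared by the synthetic ground truth.

Stage segmentation of the $N(t)/L(t)$ series places the stage-1/2
boundary at the argmax of a 5-frame moving average of $N$ and the
stage-2/3 boundary at the first run of `plateau_frames` (default 5)
consecutive frames in which $L$ stays within 5% of its final value. A
series whose $L$ never plateaus is flagged (`plateau_found = FALSE`) with
an empty stage 3. The smoothing window is a declared default, not an
inferred one.

Effective biofilm thickness from a confocal z-stack is the height of the
topmost voxel above a signal threshold, per (x, y) position, averaged over
the field of view. Voids under a buckled roof therefore *count* toward the
effective thickness — precisely why channel-forming biofilms read thicker
than flat ones.

# Differential dynamic microscopy

`image_structure_function()` computes, for each frame lag $\tau$, the
azimuthally averaged power of the Fourier-transformed image difference,
normalized so that spectral power sums to the real-space sum of squared
differences (a Parseval identity asserted in the tests). Lags default to
24 log-spaced values up to a quarter of the movie; up to 300 start times
per lag are averaged; radial bins are linear up to the axial Nyquist
wavenumber with the DC pixel excluded.

The model fitted to $D(q,\tau) = A(q)[1-f(q,\tau)] + B(q)$ is the
Schulz-swimmer intermediate scattering function

$$f(q,\tau) = e^{-q^2 D \tau}\Big[(1-\alpha) + \alpha\,
\frac{Z+1}{Zq\bar v\tau}\,
\frac{\sin(Z\arctan\Lambda)}{(1+\Lambda^2)^{Z/2}}\Big],
\qquad \Lambda = \frac{q\bar v\tau}{Z+1},$$

with mean swim speed $\bar v$, Schulz shape $Z$ (speed spread
$\bar v/\sqrt{Z+1}$), diffusivity $D$ shared by swimmers and diffusers,
and motile fraction $\alpha$.

Two estimation details carry most of the accuracy:

* **Plateau anchoring.** On a short movie the slow (diffusive) branch of
  $D(q,\tau)$ never levels off, leaving $A(q)$ — and with it $\alpha$ and
  $D$ — unidentified. But the large-lag plateau $A(q)+B(q)$ equals twice
  the mean single-frame power spectrum, which is computed directly from
  the movie and substituted into the fit. Only $B$, $\bar v$, $Z$, $D$,
  $\alpha$ remain free, with bounds $\bar v \in [1,100]$ µm/s,
  $Z \in [0.5,10]$, $D \in [0,5]$ µm²/s, $\alpha \in [0,1]$.
* **Pooled shape estimation.** From a single q bin, $Z$ trades off almost
  freely against $\alpha$ and $D$. `ddm_global_fit()` therefore fits one
  set of $(\bar v, Z, D, \alpha)$ jointly across the window (per-q noise
  floors stay free), exploiting the fact that ballistic rates scale with
  $q$ while diffusive rates scale with $q^2$. Its window reaches higher q
  (default 0.5–3.2 µm⁻¹) than the speed window, because the high-q bins
  pin the noise floor and the diffusive branch. The per-q fits of
  `fit_swimmer_isf()` (default window 0.5–2.2 µm⁻¹; low q is
  drift-dominated, high q noise-dominated) then hold $Z$ at the pooled
  value by default; `shape = "free"` restores fully independent fits.

`swim_speed()` reports the mean and standard deviation of $\bar v(q)$
over converged bins — the quantity plotted against flow rate in the
original experiments — and refuses to aggregate fewer than three bins.

# Activity maps

The degree of correlation of a region of interest between frames $\tau$
apart is $c_I = \langle I_1 I_2\rangle_r / (\langle I_1\rangle_r\langle
I_2\rangle_r) - 1$: the squared coefficient of variation of the ROI
texture when nothing moves, and ~0 when the intensity has decorrelated.
`activity_map()` tiles the frame with square ROIs (2.5 µm rounded to the
nearest even pixel count), averages $c_I$ over 200 frame pairs at
$\tau = 1$ s, and normalizes by the same average at a one-frame lag,
clamped to $[0,1]$. The one-frame reference carries the full static
texture contrast, so the ratio cancels texture and leaves the fraction of
correlation surviving to $\tau$: static biofilm → ≈1, channels full of
swimming bacteria → ≈0. The normalization formula is not specified by the
method's published description; this $\tau_0$-ratio convention is our
declared choice. ROIs whose reference correlation is not positive (no
texture, no particles) are reported as `NA` rather than guessed.

# Owens–Wendt surface energy

With probe liquids of known total, dispersive and polar surface tensions,
the Owens–Wendt relation linearizes to a regression of
$\gamma_L(1+\cos\theta)/(2\sqrt{\gamma_L^d})$ on
$\sqrt{\gamma_L^p/\gamma_L^d}$; the squared intercept and slope are the
dispersive and polar components of the solid. The shipped liquid table
(water 72.8 = 21.8 + 51.0, nitromethane 36.8 = 22.0 + 14.8, hexadecane
26.35 fully dispersive, all mN/m) uses standard literature splits and is
data (`inst/extdata/probe_liquids.csv`), replaceable wholesale. A
negative fitted square root is clamped to zero with a warning. The
forward model `predict_contact_angle()` closes the loop for round-trip
testing; measured angles for the original PDMS surfaces were never
published, so recovery of known synthetic solids is the accuracy surface.

# Synthetic data: what it emulates, and what it does not

All generators are seed-deterministic, use only forward models (ribbon
geometry, particle kinematics, the Owens–Wendt relation), and never call
analysis code, so they are legitimate oracles.

**Wrinkle timelapses.** Wrinkles are the edges of a latent random planar
network: nodes sampled with a minimum separation, edges accepted only if
junction angles are ≥35° and non-incident edges stay separated or cross
steeply. Each wrinkle nucleates (during the first 45% of the movie) as a
blister-sized spot with diameter drawn from 10–30 µm, elongates along its
edge at a constant tip speed (36 µm/frame) while widening toward a final
20–30 µm, and merges with neighbours at the network's vertices; once a
vertex has been reached by two arms their ribbons overshoot it by half a
width, so merged junctions are transversal crossings. This construction
makes the ground truth exactly computable: connectivity by union-find
over ribbon contact, and the largest cluster's centreline length as the
sum of member Chebyshev arclengths (deduplicated at junctions) — the same
length convention the skeleton measures. Defaults are 256×256 px at
3 µm/px, 64 frames at 5 min, contrast-to-noise 10. The renders emulate
binarizable phase contrast with i.i.d. Gaussian noise; they do **not**
emulate uneven illumination, focus drift, biofilm texture inside
wrinkles, or wrinkle coarsening/disappearance, so a passing pipeline is
evidence of correct geometry extraction, not of robustness to every
real-microscopy artifact. Stage-segmentation accuracy is validated
separately on metric-level series (`simulate_wrinkle_metrics()`) built
with the observed stage durations (6.5 h nucleation, 3.5 h merging at
5-minute frames), where boundary frames are exactly known.

**Swimmer movies.** Point particles rendered as Gaussian spots (σ 0.5 µm,
amplitude 0.25 on a 0.4 background) with Poisson shot noise (300
full-scale counts) and Gaussian read noise; a motile fraction moves
ballistically with Schulz-distributed speeds and directions uniform on
the 3-D sphere projected onto the image plane (the isotropic average
behind the sinc-type ISF kernel), all particles share the thermal
diffusivity, boundaries are periodic. Defaults mirror high-speed
acquisition at desk scale: 256×256 px at 0.33 µm/px, 2000 frames at
2000 fps, 300 particles, $\bar v$ = 25 µm/s, $Z$ = 2, $D$ = 0.4 µm²/s,
$\alpha$ = 0.7. With an `active_rect`, the population is confined to that
rectangle and the outside is filled with density-matched tracers advected
uniformly — a closed channel in an external nutrient flow (0–11.1 mm/s in
the flow-independence checks). Not emulated: run-and-tumble
reorientation, hydrodynamic interactions, depth-of-field effects, walls.

**Activity movies.** Swimmers confined to a rectangle on a static
spot-texture background (20 fps, 0.5 µm/px by default; particle and
texture densities chosen so that every 2.5 µm ROI carries signal), with
an optional `switch_frame` after which the swimmers freeze — emulating
the observed transition of active channel regions back to high
correlation as the biofilm matures.

**Contact angles.** Forward Owens–Wendt angles for a known solid plus
Gaussian angle noise, with wetting saturation flagged per liquid.

# Numerical conventions and degenerate inputs

Internally SI units throughout the mechanics; micrometres and seconds in
the imaging layers; `L` in mm by convention. Intensities live in
$[0,1]$ on the 8- or 16-bit grid (`quantize_stack()`), making TIFF round
trips lossless. Thresholding a constant frame, a stack shorter than the
requested lag, an unrepresentable correlation lag, all-dispersive liquid
sets, zero-area channels, and sub-3-px ribbons all fail with specific
errors; zero stress yields an infinite buckling radius; an all-dark
z-stack warns and returns zero thickness. All randomness flows through
explicit seeds, and generators restore the caller's RNG state.

Problem sizes used by the test suite were chosen to keep a full run on a
single CPU within tens of minutes: full-scale DDM recovery uses five
2000-frame movies; the wrinkle fidelity checks use five 64-frame
timelapses; unit tests run on 64×64–128×128 stand-ins with
correspondingly looser tolerances.

# Known limitations

* The mechanics module is a closed-form criterion set, not a
  spatio-temporal simulation of blister growth or wrinkle coarsening.
* Total-skeleton-length `L` and geodesic `L` differ on branched networks;
  both are provided because the published description does not
  disambiguate, with total length as the default.
* The DDM model class excludes run-and-tumble and anisotropic motion; the
  diffusivity of the mixed population is the least identified parameter
  on short movies, and its per-q estimates scatter accordingly — the
  pooled fit is the supported estimator.
* The activity-map normalization convention (one-frame-lag ratio) is a
  package choice; other normalizations would change absolute values but
  not the active/static contrast.
* Interface toughness Γ is a free parameter; no published value exists
  for this system, so only verdicts conditional on Γ are possible.
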