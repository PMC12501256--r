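---
title: "Single-pixel thermal imaging with cyclic S-matrix encoding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-pixel thermal imaging with cyclic S-matrix encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptherm)
```

## The measurement model

Single-pixel imaging trades a camera's pixel array for a sequence of known
binary masks in front of a single (non-imaging) detector. One measurement,
the *bucket signal*, is the inner product of the scene with one mask:

$$y_u = \sum_{v=0}^{n-1} S_{u,v}\, x_v,$$

where $x$ is the scene flattened row-major over a $p \times q$ grid and
$S$ is an $n \times n$ binary measurement matrix, $n = pq$. For long-wave
infrared thermometry this is attractive because cooled single-element
HgCdTe detectors are far more sensitive than microbolometer arrays and
because transmissive metal masks with coarse (250 µm) pixels modulate
8–10.6 µm light without the diffraction losses of pixelated spatial light
modulators.

`sptherm` implements the computational side of such a system for the
operating point of an 11 × 13 frame: mask construction, scan design,
acquisition simulation, non-iterative reconstruction, and radiometric
calibration to temperature.

### The cyclic S-matrix

The measurement matrix is an *S-matrix*: a $\{0,1\}$ matrix of order
$n \equiv 3 \pmod 4$ that maximizes the determinant, giving the best
multiplexing advantage achievable with non-negative (mask) weights. Its
inverse is closed-form,

$$S^{-1} = \frac{2}{n+1}\left(2S^{\mathsf T} - J\right),$$

with $J$ the all-ones matrix, so reconstruction is a single
matrix–vector product — no iterative compressed-sensing solver.

`twin_prime_smatrix(p, q)` builds a *cyclic* S-matrix of order $n = pq$
for twin primes $q = p + 2$ from two quadratic-residue indicator
functions, $f$ modulo $p$ and $g$ modulo $q$: entry $j$ of the first row
is 0 iff $[f(j) - g(j)]\,g(j) = 0$, and row $i$ is the $i$-step left
circular shift of the first row, $S_{i,j} = S_{0,\,i+j \bmod n}$.
Cyclicity is what makes the design physical: every mask is a crop of one
master pattern at a shifted position, so a single fabricated stripe and a
translation stage replace $m$ separate masks.

A note on the residue function $g$: the construction only yields an
S-matrix when $g$ is taken modulo $q$. `validate_smatrix()` machine-checks
the invariants this implies — row/column weight exactly $(n+1)/2$, the
Gram identity $SS^{\mathsf T} = \frac{n+1}{4}(I + J)$, and cyclicity — and
the test suite verifies them for orders 15, 35 and 143, together with the
inverse identity in exact integer arithmetic
($S(2S^{\mathsf T} - J) = \frac{n+1}{2} I$ entrywise).

### Diagonal compressed scanning

Bucket signals indexed row-major on the $p \times q$ grid vary smoothly:
shifting a cyclic mask by one pixel barely changes its overlap with the
scene. The scan exploits this by measuring along the 2D diagonal,
$y(0,0), y(1,1), \dots$, i.e. linear indices $u_k = (q+1)k \bmod n$. For
the 11 × 13 system, $m = 91$ of the 143 rows are measured; the diagonal
set spreads over the signal grid far more uniformly than $91$ consecutive
rows, which `max_neighbor_distance()` quantifies (maximum
unsampled-to-sampled Chebyshev torus distance 1 versus 2 for the linear
scan; the ordering also holds under Euclidean and Manhattan metrics).

One caveat the implementation surfaced: the diagonal indices are distinct
only while $m \le n/\gcd(q+1, n)$, and $\gcd(q+1, pq) = \gcd(3, p)$. For
every twin-prime pair except (3, 5) the diagonal is a full permutation;
for (3, 5) it cycles after 5 steps. `diagonal_scan_rows()` refuses
requests beyond the cycle, and full scans fall back to natural row order
there. The deployed (11, 13) geometry is unaffected.

### Laplace interpolation and reconstruction

Unmeasured bucket signals are filled by discrete harmonic extension:
every unmeasured index $u$ satisfies

$$y_u = \tfrac14\left(y_{u+1} + y_{u-1} + y_{u+q} + y_{u-q}\right),$$

with all indices reduced modulo $n$ (the linear index is periodic, so the
signal grid is a torus; wrap-around at the row ends mirrors the
cyclic-shift similarity of adjacent measurement rows). Because unknowns
neighbor unknowns, the equations couple; `laplace_interpolate()`
assembles the coupled system as a sparse matrix and solves it directly —
the system is strictly diagonally dominant after eliminating measured
values and is never singular for $m \ge 1$. A Gauss–Seidel sweep solver
is kept internally purely as an independent cross-check in the tests
(tolerance $10^{-12}$). Interpolated values obey the discrete maximum
principle (they lie within the range of the measured data), which the
property tests assert on random measurement subsets.

Reconstruction then applies the closed-form inverse without forming it:
$\tilde x = \frac{2}{n+1}(2S^{\mathsf T}\tilde y - \mathbf 1\,\Sigma\tilde y)$,
an $O(n^2)$ product. With $m = n$ and no noise this recovers the scene to
machine precision; the test suite locks exact recovery over 100 random
order-143 scenes.

## Radiometric calibration

Reconstructed intensity relates to source temperature through the
Stefan–Boltzmann law with per-pixel system response:

$$\tilde x = C\,\varepsilon\sigma T_{\mathrm s}^4 + \Delta,$$

with emissivity $\varepsilon = 0.98$ (blackbody source and human skin),
$\sigma = 5.67\times10^{-8}\,\mathrm{W\,m^{-2}\,K^{-4}}$, and per-pixel
gain $C$ and offset $\Delta$ found by ordinary least squares over a
blackbody sweep (default: 31.7 °C to 39.8 °C in 0.9 °C steps, five
replicate frames per level — 715 per-pixel samples per temperature at
order 143). The temperature map inverts this law. The bare fourth-root
form $T_{\mathrm m} = (\tilde x / C\varepsilon\sigma)^{1/4}$ is only the
inverse when $\Delta = 0$, so `temperature_map()` subtracts the fitted
offset before taking the root; pixels whose radicand is not strictly
positive are masked invalid. All internal temperatures are kelvin
(absolute temperature is required by the $T^4$ law); Celsius appears only
at interfaces, and `region_mean_temperature()` applies the recommended
37.1 °C inner-canthus screening threshold.

The field's "temperature resolution" has no standard formula;
`temperature_resolution()` therefore reports two clearly labelled
definitions of this package: the smallest sweep step at which adjacent
levels' interquartile boxes separate, and the pooled per-pixel RMS
recovery error.

## The synthetic-scene generator

`make_phantom()` produces the study scenes: uniform blackbody fields,
engraved dot-matrix letters (X and Z among them, 180°-rotation symmetric
as engraved test plates are), sub-pixel slits at 0°/90°/±45°, two-level
plates, and inner-canthi-like Gaussian hot-spot pairs (default 36.5 °C
spots on a 34 °C skin-level background, one spot per window region).
Slit rasterization uses exact area overlap for axis-aligned slits and
16× supersampling for diagonal ones, and partial coverage mixes
*radiance*, not temperature. The acquisition chain models the
chopper/lock-in electronics as a scalar gain plus i.i.d. Gaussian noise
per bucket; at a bucket noise of $\sigma = 10$ detector units (against
uniform-scene buckets near $3.7\times10^4$) the recovered per-pixel
temperature spread is ≈ 0.25 °C, the scale of the deployed system's
reported resolution, and that value is used in the noisy studies.

What the generator does **not** emulate: optical point-spread and
diffraction at mask edges, detector nonlinearity and drift, 1/f noise,
synchronization jitter, and anatomical realism. Passing tests therefore
certify the coding, interpolation, inversion and calibration
mathematics — not end-to-end hardware performance.

## Spatial resolution, and a known limitation

The resolution procedure images a 0.5-pixel slit, averages intensity
along lines parallel to the slit, normalizes the across-slit profile to
$[0,1]$ and counts pixels above 0.5. Through the noiseless full-scan
chain the count is 1 at all four orientations — resolution is set by the
encoding pixel itself, anisotropy of the 1 mm sampling notwithstanding.

Under the compressed $m = 91$ scan, this idealized point-sampling
simulation reproduces one-pixel resolution at 0°, 90° and −45°, but a
+45° slit degrades to 2–3 pixels: its support in linear index is an
arithmetic progression of step $q + 1$ — exactly the diagonal scan's
step — so its bucket signal aliases maximally with the measured set and
harmonic interpolation under-resolves it. A physical system's optical
blur low-passes the bucket signal and suppresses this worst case, but
PSF modelling is outside this package's scope; the behaviour is locked
in the test suite as documentation.

## Numerical and design choices

* 0-based, row-major indexing everywhere; every shifted index is reduced
  modulo $n$. The ±45° mounting of stripes and windows in the lab frame
  is carried as display metadata only — computation happens in unrotated
  logical coordinates, where the vertical stage translation is the
  (1, 1) diagonal shift.
* Matrices are dense integer grids ($n \le$ a few thousand); invariant
  checks use integer arithmetic, runtime math uses doubles; the
  interpolation system is solved by a sparse direct factorization.
* Window split widths are $(q+1)/2$ and $(q-1)/2$ (7 and 6 columns at
  $q = 13$); per-part horizontal/vertical flips are configurable (default
  none) and `reassemble_pattern()` inverts them exactly.
* Run-way L-markers (default 3 × 3) and the top/bottom alignment pixels
  are fabrication-export metadata, excluded from the measurement matrix.
* Physical defaults: 250 µm mask pixels, 4:1 magnification (hence 1 mm
  object-plane sampling), 7.5 mm stripe separation (30 mm between the
  imaged regions).
* Problem sizes in the shipped tests: orders 15 and 35 for exhaustive
  oracles, order 143 for system-level checks; 100-scene recovery runs and
  10-level × 5-replicate sweeps complete in seconds.

## A worked chain

```{r}
S <- twin_prime_smatrix(11, 13)
scheme <- coding_scheme(11, 13, m = 91)
model <- calibration_model(11, 13)

scene <- make_phantom(phantom_spec("canthi", temperature_C = 36.5), scheme,
                      model)
record <- simulate_scan(scene, S, scheme, noise_sigma = 10, seed = 1)
image <- reconstruct(laplace_interpolate(record, scheme), S)
tmap <- temperature_map(image, model)

left <- matrix(FALSE, 11, 13); left[, 1:7] <- TRUE
region_mean_temperature(tmap, left & scene$coverage > 0.5)
```

## Limitations

Beyond the +45° aliasing discussed above: the calibration model is the
total-radiance $T^4$ law (no band-limited Planck integration, no
atmospheric or reflected-temperature correction); noise is i.i.d.
Gaussian on buckets (no shot/1-f structure); and the package neither
drives hardware nor co-registers a visible camera. These match the
boundaries of the computational problem the package solves.
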