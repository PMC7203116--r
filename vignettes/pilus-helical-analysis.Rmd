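---
title: "Helical analysis of type IV pilus filaments with pilihelix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical analysis of type IV pilus filaments with pilihelix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pilihelix)
```

## The problem

Type IV pili (T4P) are flexible extracellular filaments assembled as helical
homopolymers of pilin subunits. A single bacterium can assemble structurally
distinct pilus forms — a wider, stiffer filament and a narrower, more
flexible one — built from different pilins with different helical
parameters. Characterising such filaments computationally involves a chain
of small, well-defined analyses:

1. **Helical lattice arithmetic.** A 1-start helix is specified by the rise
   (axial translation per subunit, Å) and twist (azimuthal rotation per
   subunit, degrees). Equivalent parameterisations are the pitch
   (`rise * 360 / twist`) and subunits per turn (`360 / twist`), which is
   what a power spectrum measures directly: the meridional reflection sits
   at spatial frequency 1/rise and the order-1 layer line at 1/pitch.
2. **Rational repeats and the selection rule.** Most filaments have a
   non-integer number of subunits per turn; the structure repeats exactly
   after `u` subunits in `t` turns for coprime `(u, t)`. Layer line `l` of
   such a repeat carries Bessel orders `n` satisfying `l = t*n + u*m` for
   integer `m`.
3. **Model generation.** A refined subunit is expanded to an `n`-mer
   filament model by applying the screw operation repeatedly.
4. **Interaction analysis.** Contact partner maps, salt bridges, and
   nearest-acidic-residue-to-N-terminus distances on the filament model.
5. **Curvature analysis.** Traced centrelines of imaged filaments are
   profiled for local curvature and populations classified by the fraction
   of filaments exceeding a curvature threshold (2 µm⁻¹).

pilihelix implements this chain with synthetic generators standing in for
micrographs and maps, so every stage can be exercised and verified at the
desk.

## Symmetry determination

The wide *Thermus* pilus serves as the running example: a meridional
reflection near 9 Å and an order-1 layer line near 36 Å imply roughly four
subunits per turn; candidate scoring refines this to 3.89 subunits in a
36.3 Å pitch:

```{r lattice}
symmetry_from_lattice(lattice_estimate(36.3, 3.89))
best_rational_repeat(3.89, max_turns = 20)
```

The repeat (35 subunits, 9 turns) makes layer line 9 the order-1 line
(`allowed_bessel_orders(9, r, 1)` returns 1) and layer line 35 the
meridional.

`recover_symmetry()` reproduces the determination end to end on simulated
data: average power spectra of the input projections, detect layer lines
(per-row maxima with relative prominence at least 0.1, equator excluded),
and score lattice candidates by correlating `log(1 + amplitude)` of the
observed spectrum with that simulated from each candidate filament over an
annulus that excludes the equator and radial frequencies below 1/diameter.

One design point deserves comment. Assigning detected lines to roles
(which is the meridional, which is order 1) before indexing is unreliable:
an order-1 line can peak within one radial sample of the meridian and be
mistaken for a meridional, the meridional of a weakly-scattering subunit
can be faint, and other low-index lines (`l = t - 1`, order ±3) can outshine
the pitch line. `recover_symmetry()` therefore makes no early assignment.
Every detected line spawns two candidate families — one treating its
spacing as the pitch, one treating it as the rise (with pitch =
subunits-per-turn × spacing) — and a coarse-to-fine scoring pass over all
families arbitrates. Wrong lattices cannot reproduce the full
two-dimensional amplitude pattern, so the correct lattice wins the ranking
even when individual lines would be misassigned by eye; the scoring step
performs the indexing.

Amplitude spectra cannot determine the hand of the screw. Twist is stored
as a positive angle with a separate handedness flag defaulting to +1
(right-handed); this is a documented convention, not a measurement, and
candidate scoring is invariant under it (the enantiomer projects to the
mirror image, which has the same amplitude spectrum).

### Problem sizes and defaults

Simulated projections use Gaussian-rendered atoms (σ = 1.5 Å, pixel 1 Å),
boxes of 768 × 128 pixels holding ~55-subunit filaments, and a raised-cosine
(10 % taper) window before the transform, because boxed segments are not
periodic. These sizes resolve a 9.33 Å meridional to about one part in
eighty (one Fourier sample is 1/768 Å⁻¹) while keeping a full recovery —
roughly a thousand scored candidates across all hypothesis families — well
under a minute on one CPU. The default
subunits-per-turn grid is 3.5–4.5 in steps of 0.01, bracketing the published
candidate sets at both pitches. Additive white Gaussian noise at a
signal-to-noise ratio of 5 emulates the contrast of averaged segment data;
no CTF or detector statistics are modelled, so recovery results demonstrate
the indexing-and-scoring logic, not robustness to microscope physics.

## Filament models and interaction analysis

`build_filament()` applies the screw operation: subunit *i* is the template
rotated by `i × twist` about z and translated `i × rise` along z. Distances
are preserved to floating-point accuracy in every copy, and the radial
coordinate is invariant, so the filament diameter equals that of the
template subunit.

The interaction criteria follow standard structural-biology conventions,
since distance cutoffs defining a "physical interaction partner" are rarely
published: two subunits are partners when at least one heavy-atom pair lies
within 4.5 Å; a salt bridge is an acidic group (Asp OD1/OD2, Glu OE1/OE2, or
the C-terminal carboxylate) within 4.0 Å of a basic group (Lys NZ, Arg
NE/NH1/NH2, or the N-terminal amine). Histidine is treated as neutral. The
terminal groups are treated as charged because pilin filaments bury the
N-terminal amine in the hydrophobic core, where an acidic partner (a
conserved Glu5 in T4P pilins) neutralises it, and C-terminal carboxylates
can complete intramolecular bridges. Partner counts can shift at other
cutoffs, so every output records the settings used. Pair counting prunes by
axial slab overlap before computing exact distances; the test suite checks
it against a plain all-pairs oracle.

The deposited pilus models are not bundled with the package. To exercise
the analysis at realistic parameter values, `make_synthetic_pilin()`
constructs labelled-synthetic stand-ins: contact scaffolds engineered so the
wide-form filament (rise 9.33 Å, twist 92.5°) has exactly six interaction
partners per direction (offsets +1…+4, +6, +7, with +5 absent) and the
narrow form (11.26 Å, 84.3°) seven, plus charged probes reproducing the
published salt-bridge topology. These stand-ins share only interaction
topology and symmetry with the real filaments — their geometry is
engineered, and conclusions about the real structures require the deposited
coordinates.

```{r pilin}
wide <- make_synthetic_pilin("wide")$filament
interaction_partners(wide)
find_salt_bridges(wide)
```

## Curvature analysis

`curvature_profile()` resamples a trace at uniform arc length (interval =
median point spacing), fits each coordinate with a cubic smoothing spline,
and evaluates κ = |x′y″ − y′x″| / (x′² + y′²)^{3/2}. The first and last two
samples are excluded from the per-trace summary, where spline derivatives
are least reliable. The smoothing parameter defaults to generalised
cross-validation, which is exact on noise-free traces; for noisy traces a
fixed `spar` near 0.5 keeps the mean curvature of a κ = 2 µm⁻¹ circle with
5 nm point noise within a few percent. The per-filament statistic defaults
to the mean interior curvature — robust for constant-curvature synthetic
truth — with max and median available, because the statistic behind
published exceedance fractions is typically unstated.

```{r curvature}
th <- seq(0, 1.5 * pi, length.out = 120)
curvature_profile(filament_trace(cbind(0.5 * cos(th), 0.5 * sin(th))))$summary
```

`make_trace_population()` draws constant-curvature arcs with an exact
number of traces above the 2 µm⁻¹ threshold, so `classify_population()`
recovers the generator fraction exactly at zero noise. This emulates the
*reported proportions* of high-curvature narrow (~40 %) and wide (~13 %)
pili; it does not re-measure them, which would require the original
micrographs. Real traces carry tracing noise, non-constant curvature and
finite length effects that the generator deliberately omits, so passing
these tests validates the curvature mathematics, not any biological claim.

## Numerical choices and degenerate inputs

* Rational repeat search enumerates all coprime `(u, t)` with `t` up to
  `max_turns` (20 by default), breaking ties toward smaller `t`, the
  convention of reading the repeat off the lowest-index order-1 line.
* `allowed_bessel_orders()` restricts |m| to 3 by default; higher-order
  contributions fall outside the resolved radial range at typical spectral
  resolution.
* Projection rendering deposits atoms with bilinear weights and applies the
  Gaussian blur once in Fourier space, keeping integrated intensity exactly
  proportional to atom count.
* Spectra are normalised so the summed squared amplitudes equal the
  windowed-image energy (Parseval), making amplitude thresholds
  comparable across images.
* Traces with consecutive duplicate points are cleaned with a warning;
  fewer than three distinct points is an error; arcs shorter than eight
  resampled points fall back to circumscribed-circle (Menger) curvature.
* Generators are pure functions of their parameter records (seed included),
  never touching process-global RNG state, and each returns a
  machine-readable ground-truth record that serialises to JSON.

## Limitations

* No CTF simulation or correction, no out-of-plane tilt, no 3D
  reconstruction: the diffraction module validates symmetry logic on
  idealised projections.
* Handedness is a convention; nothing in the package can determine it.
* The interaction analysis reports only distance-based criteria — no
  buried surface area, no continuum electrostatics.
* The synthetic pilin stand-ins carry engineered geometry; only their
  interaction topology mirrors the real filaments.
* MRC support covers single-section mode 0/1/2 images — sufficient for
  boxed segments, not for volumes.
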