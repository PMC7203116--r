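# pilihelix

Desk-scale tools for the computational chain of helical analysis of
bacterial type IV pili (T4P) — flexible surface filaments assembled as
helical homopolymers of pilin subunits. The package is aimed at structural
microbiologists and methods developers who want the arithmetic and
simulation scaffolding of a helical-reconstruction study as small, tested,
reproducible functions.

## What it computes

A 1-start helix is specified by the **rise** `h` (axial translation per
subunit, Å) and **twist** `φ` (rotation per subunit, degrees), equivalently
by the pitch `P = 360 h / φ` and subunits per turn `N = 360 / φ`. The
package covers:

* **Lattice arithmetic** — conversions between (P, N) and (h, φ); subunits
  per turn from the meridional (1/h) and order-1 layer-line (1/P)
  spacings; best rational repeat (u subunits, t turns) with coprime u/t ≈ N;
  the helical selection rule `l = t·n + u·m` for allowed Bessel orders;
  asymmetric-unit bookkeeping for segment extraction.
* **Filament models** — symmetry expansion of a subunit into an n-mer
  coordinate model (PDB in/out, one chain per subunit), diameter.
* **Diffraction simulation** — projection images of models (Gaussian
  atoms), windowed power spectra, layer-line detection, and recovery of the
  helical symmetry by scoring candidate lattices against an observed
  spectrum.
* **Interaction analysis** — inter-subunit contact partner maps, salt
  bridges (Asp/Glu/C-terminus vs Lys/Arg/N-terminus), and the nearest
  acidic group to each subunit's buried N-terminal amine.
* **Curvature** — per-trace curvature profiles
  (κ = |x′y″ − y′x″| / (x′² + y′²)^{3/2} on smoothed, arc-length-resampled
  centrelines) and population classification at a 2 µm⁻¹ threshold.
* **Synthetic data** — seeded generators for subunits, engineered-contact
  filaments, projection images with known symmetry, and trace populations
  with a stated curvature mixture, each with a machine-readable
  ground-truth record.

## Worked example

Convert a measured lattice to symmetry parameters and its exact repeat:

```r
library(pilihelix)
symmetry_from_lattice(lattice_estimate(36.3, 3.89))
#> Helical symmetry: rise 9.33 A, twist 92.5 deg (right-handed convention)
#>   pitch 36.31 A, 3.892 subunits per turn
best_rational_repeat(3.89, max_turns = 20)
#> Helical repeat: 35 subunits in 9 turns (3.8889 per turn)
```

So the filament repeats exactly after 9 turns (35 subunits), and layer line
9 is the order-1 line (`allowed_bessel_orders(9, r, 1)` returns `1`).

Recover the symmetry of a simulated noisy filament image end to end:

```r
gen <- make_filament_image(helical_symmetry(9.33, 92.5), n_subunits = 55,
                           snr = 5, seed = 1, box = c(768L, 128L))
res <- recover_symmetry(list(gen$image), gen$subunit,
                        units_range = c(3.5, 4.5), step = 0.01)
head(res, 3)
#>      pitch units_per_turn     rise    twist     score
#> 1 36.43317           3.89 9.365854 92.54499 0.9051330
#> 2 36.52683           3.89 9.389930 92.54499 0.8769582
#> 3 36.52683           3.90 9.365854 92.30769 0.8678668
```

The top candidate sits within 0.002 subunits/turn of the generator truth
(360 / 92.5 = 3.892); the recovered rise and twist round to 9.37 Å and
92.5° against a generator truth of 9.33 Å / 92.5° (the rise is limited by
the Fourier sampling of a 768-pixel box). Contact analysis on a synthetic pilin stand-in:

```r
wide <- make_synthetic_pilin("wide")$filament
interaction_partners(wide)
#> Interaction map for subunit 7 (cutoff 4.50 A, >= 1 pairs)
#>   6 partners per direction; offsets: -7, -6, -4, -3, -2, -1, 1, 2, 3, 4, 6, 7
```

Six partners per direction, with the ±5 neighbour not in contact — the
interaction topology of the wide pilus form.

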