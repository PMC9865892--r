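---
title: "lamellipid: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lamellipid: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Multilamellar vesicles (MLV) of anionic phosphatidylserine lipids differ
from large unilamellar vesicles (LUV) chiefly through the thin, confined
water layer between adjacent bilayers. In simulation this is emulated with
one periodic bilayer and two water-slab thicknesses: a thick slab whose
midsection behaves as bulk water (the unilamellar, UL, regime) and a thin
slab in which every water molecule feels both surfaces (the multilamellar,
ML, regime). The experimental side of the same question is thermotropic:
melting curves from temperature-dependent turbidity spectra and DSC
thermograms, and the mechanical response expressed through area
fluctuations.

`lamellipid` implements both halves as testable estimators, plus seeded
synthetic generators that realise a *stated world* — a pseudo-bilayer and
melting data with known ground truth — so that every estimator has a
parameter-recovery test that needs no external data.

## The trajectory model

Configurations are an atom table (name, element, residue, mass in amu) plus
frames of coordinates (nm) in orthorhombic boxes (Lx, Ly, Lz). Internal
units are nm / ps / amu / kJ mol^-1 everywhere; converters exist only at
the I/O boundary (e.g. diffusion coefficients in cm^2 s^-1). The membrane
normal is fixed to z. Triclinic boxes are rejected explicitly.

Coordinates produced by the generator are stored *unwrapped*: the Einstein
mean-square-displacement estimators are meaningless on wrapped paths and
refuse input containing jumps larger than half a box edge. Analyses that
histogram positions (density profiles, RDFs, hydrogen bonds) wrap
internally, so one trajectory serves both families. `wrap_trajectory()` /
`unwrap_trajectory()` convert explicitly, the latter with per-atom image
counters; unwrapping is well defined only when true per-frame moves stay
below L/2.

## The synthetic bilayer

`build_bilayer()` places 122 DPPS + 6 DPPG pseudo-lipids (64 per leaflet)
on a jittered square lattice whose cross-section realises the target area
per lipid exactly, with phosphorus pseudo-atoms at +/- half the target P-P
thickness. Each lipid is coarse but chemically labelled: phosphate
(P, OP1/OP2), serine ammonium (N, HN1-3) and carboxylate (CC, OC1/OC2),
glycerol (CG, OG1/OG2), two ester carbonyls (CE/OE), and two acyl chains
whose carbons carry two explicit pseudo-hydrogens. That is exactly enough
structure for every analysis in the package — which depend only on
geometry and labels — without pretending to force-field realism.

Key generator choices:

* **Chain order.** C-H vectors are drawn on the cone with
  cos^2(beta) = (1 - 2s)/3, which realises a requested -S_CD = s exactly
  in expectation (s in [0, 0.5]; gel plateau default 0.28, fluid 0.12).
* **Water.** Rigid 3-site geometry (O-H 0.09572 nm, H-O-H 104.5 deg) at
  bulk density in the slab outside the P planes; a build whose requested
  count exceeds ~40 molecules nm^-3 errors. The achieved density is
  recorded on the trajectory.
* **Orientation model.** `orientation_shell(angle, kappa, cutoff, range)`
  draws the cosine of the angle between the (nearest headgroup atom ->
  oxygen) vector and the water dipole from a reflected Gaussian centred on
  cos(angle) (default 130 deg, i.e. -0.64); the oriented fraction is 1
  inside the first shell (0.3 nm) and decays linearly to zero at `range`.
  In a thin ML slab every water sits within `range` of some surface, so
  mean ordering persists across the whole gap; in a UL slab it decays to
  zero — the generator-level analogue of the published UL/ML contrast.
* **Dynamics.** `evolve()` is Brownian, not Newtonian: waters (and ions)
  random-walk with per-dimension step variance 2 D dt, lipids rigidly
  random-walk in-plane at D_xy, and orientations/chain hydrogens are
  re-sampled each frame so orientational statistics stay stationary while
  positions diffuse. Per-frame box-area jitter (`area_jitter_frac`,
  preset defaults taken from the published APL standard deviations, e.g.
  0.7% in the gel phase) emulates barostat area fluctuation for the
  compressibility estimator; coordinates are left untouched by it.
* **Determinism.** Every generator takes a seed; identical seeds give
  bit-identical output. Pipeline child seeds are derived from the master
  seed.

The presets UL35 / UL65 / ML35 / ML65 encode the published system
geometries (APL 0.458/0.578/0.462/0.563 nm^2, P-P thickness
4.514/4.057/4.516/4.194 nm, box heights 11.2/9.4/7.5/6.5 nm, 6400 vs 2781
waters) and dynamical coefficients (water D 3.12/4.16/1.83/2.30 x 1e-5
cm^2 s^-1; lipid D_xy 0.91/4.24/0.25/3.94 x 1e-7 cm^2 s^-1).

What the generator does **not** emulate: excluded volume (waters may drift
into the bilayer region over long runs), electrostatics, conformational
sampling, or any emergent phase behaviour. A green recovery test therefore
establishes that an estimator is unbiased and correctly normalised on data
with known truth — not that the package reproduces molecular physics.

## Structural estimators

* **APL** is Lx Ly divided by lipids per leaflet, per frame; mean and SD
  over the window.
* **Density profiles** are mass-weighted z-histograms centred on the
  bilayer midplane (mean P z), in kg m^-3; bin width 0.05 nm for bulk
  profiles, 0.01 nm for P-plane peaks. The integral times the box
  cross-section returns the selection mass (tested to 1%).
* **Thickness** is the distance between the two P-density peak maxima,
  each refined by 3-point parabolic interpolation (the published values
  carry 4 significant figures — finer than any sensible bin width); its
  error is |symmetrised - unsymmetrised|.
* **Order parameters** use S_CD = <3 cos^2 beta - 1>/2 against z, averaged
  over lipids, hydrogens and frames, reported as -S_CD.
* **Diffusion** uses multi-origin MSD with an ordinary-least-squares slope
  over lags spanning 10-50% of the trajectory (the standard compromise
  between short-time contamination and poor long-lag statistics; the
  window is a logged parameter). D = slope/4 (in-plane) or slope/6 (3-D).
  The origin stride is 1 unless the workload exceeds ~2e7 terms. Lateral
  D is reported in both nm^2 ns^-1 and cm^2 s^-1 because published unit
  annotations for D_xy are ambiguous ("In nm"); this package does not
  guess the intended unit and emits both.

## Interfacial water

The headgroup reference for orientation analyses is the nearest heavy atom
of {P, CC, OG1, OG2} — the nearest-atom rule makes "the vector from the
lipid headgroup" unambiguous where the original description is silent.
RDFs are shell-volume and bulk-density normalised; the first-shell cutoff
defaults to 0.3 nm (the first RDF minimum) and is a config value, not
re-derived per run. cos(theta) profiles are binned by distance to the
nearest reference atom (dr = 0.05 nm default); the cumulative curve is the
running sum of per-water cos(theta) over distance-ordered waters, whose
last value equals the total sum. The dipole tilt profile bins the cosine
of the dipole/z angle by midplane-centred z.

## Hydrogen bonds and contacts

A bond is a triple (donor, H, acceptor) with donor-acceptor distance
< 0.3 nm and H-donor-acceptor angle (vertex at the donor) < 30 degrees —
strictly that vertex convention, not donor-H...acceptor. Acceptors are all
O/N; donors are O/N with bound hydrogens inferred from the generator's
naming (configurable two-column table for real topologies). Classes:
lipid-lipid (intramolecular excluded by default, flag to include),
water-water, water-lipid, and the moiety classes water-PO2/C=O/COO/
glycerol defined by a named-atom map. Per-molecule normalisation is the
exact quotient, conventionally printed to two decimals. Cation contacts
count ion-oxygen pairs within 0.32 nm (a typical Na+ first-shell minimum;
the choice is logged and overridable).

## Melting curves and mechanics

* **Smoothing** is Savitzky-Golay by explicit local least squares, with
  windows shrinking at the ends; polynomial inputs up to the fit order are
  reproduced exactly, and even window lengths (the published "10 points")
  are supported by splitting the window as evenly as possible.
* **Decomposition** of a wavelength x temperature matrix is plain
  truncated SVD, D = S C' + E: the one-component case of interest is
  rotation-unambiguous up to sign and scale, so no ALS/non-negativity
  machinery is warranted. Signs are fixed so C follows the mean absorbance;
  explained variance is the retained fraction of squared singular values,
  and orthogonality guarantees ||D||^2 = ||S C'||^2 + ||E||^2 (tested to
  1e-8 relative).
* **Boltzmann fits** minimise least squares of
  y0 + sum a_i / (1 + exp((T_i - T)/w_i)) by multi-start L-BFGS-B (centre
  candidates from derivative extrema and range quantiles, widths from 2-10%
  of the span), with Gauss-Newton standard errors at the optimum. chi^2 is
  reported as the raw sum of squared residuals (matching the mixed
  magnitudes of published values); a reduced form is also given, labelled.
  Double fits whose centres are closer than 2 max(w)/5 are flagged
  "unresolved" rather than reported as two transitions.
* **Synthetic melting data.** Transition centres default to the published
  51.5 / 53.3 degrees C; widths are not published, so 0.5 / 0.35 degrees C
  were fixed once such that two events ~1.8 degrees apart appear as two
  resolved inflection points — the qualitative feature the experiment
  reports. The DSC generator uses two-sided Gaussians parameterised by
  centre, integrated area and left/right widths (height =
  area / (sqrt(pi/2) (sd_l + sd_r)) so areas are exact).
* **DSC features.** T_max by parabolic interpolation; T_onset as the
  intersection of the extrapolated pre-transition baseline (linear fit on
  the quiet leading 15%) with the tangent at the leading-edge inflection;
  minor events are out-of-peak local maxima above a prominence threshold
  (default 2% of the main height, catching the published ~3% satellite
  near 60 degrees C).
* **Fluctuation mechanics.** c_p = var(H)/(R T^2) (J mol^-1 K^-1 for H in
  kJ mol^-1), kappa_A = var(A)/(<A> R T), K_A = d^2/(16 kappa_A); unbiased
  variances throughout. These are estimators over supplied sample series;
  the pipeline feeds them the box-area series when area jitter is enabled.

## Pipeline and reproducibility

`run_pipeline()` takes one JSON-serialisable config (systems, frame
counts, every cutoff and window), derives per-system child seeds from the
master seed, and emits per-analysis CSV tables with metadata headers plus
a JSON report; identical config + seed reproduces the report exactly.
`compare_systems()` reports per-metric ratios and differences with
first-order (delta-method) SD propagation, validated against Monte-Carlo
resampling in the tests. The config is JSON rather than YAML because no
YAML parser is available in the supported dependency set; the structure is
the same.

Documented pipeline tolerances at the default scale (100 frames, dt 5 ps):
APL 1%, thickness 0.02 nm, -S_CD 0.02, water D 5%, lipid D_xy 25% (the
gel-phase coefficients are small and the default run is short; the
dedicated recovery tests use 10^3 steps and correspondingly tighter 5%/10%
bounds), angular-distribution maximum within 0.12 of cos(130 deg).

## Known limitations

* Brownian pseudo-dynamics cannot exhibit emergent transitions; melting
  behaviour enters only through the spectral/DSC generators.
* The hydrogen-bond counts of the random-placement water slab are far
  below real water's (~1.5 per molecule): placement is uniform, not
  correlated; only the counting machinery, not the chemistry, is testable.
* Pair search is brute force O(N M) in compiled code — ample for ~3e4
  atoms, not for much larger systems.
* Single and double Boltzmann models only; more transitions were not
  needed for the target profiles.
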