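---
title: "Force-profile analysis and coarse-grained simulation of cotranslational membrane integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-profile analysis and coarse-grained simulation of cotranslational membrane integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fpatools)
```

## The assay and its quantities

Translational arrest peptides (APs) such as the 17-residue E. coli SecM
peptide stall the ribosome when their last codon reaches the A site, and
the stall is relieved in proportion to the pulling force acting on the
nascent chain at that moment. In force-profile analysis (FPA) a series of
constructs places a force-generating element — typically a transmembrane
helix (TMH) entering the SecYEG translocon — at increasing distance from
the AP. For each construct the fraction full-length product,
`f_FL = I_FL / (I_FL + I_A)`, measures the force at chain length `N`
(residues from the protein start through the last AP residue). The
`f_FL`-versus-`N` curve is the force profile (FP).

Three AP variants of increasing stalling strength are built in
(`arrest_peptides()`): `SecM-Ec`, `SecM-Ec-Ms`, and `SecM-Ec-Sup1`.
Stronger APs saturate later, resolving force maxima that a weak AP clips.

Distances along the nascent chain are counted in residues from the
peptidyl-transferase center (PTC): residue `i` of a construct of length `N`
is `N - i` residues from the PTC (`ptc_distance()`), about `3 * (N - i)`
Angstrom of extended chain. TMHs typically begin generating force when
their N-terminal end is ~45 residues from the PTC and stop when their
C-terminal end reaches the same distance; `window_at_ptc_offset()` builds
the anchored sequence alignments used to read such regularities off a set
of called peaks.

## From gel lanes to f_FL

`quantify_lane()` processes a 1-D densitometry trace: the background is a
rolling-minimum envelope (window one fifth of the trace, smoothed by a
same-width rolling mean — deterministic, no fitting), bands are local
maxima at least 5% of the tallest band, and each band integrates between
its flanking local minima by the trapezoidal rule. Bands are labelled FL
and A in migration order (or matched to an `expected_bands` template when
extra species are present). Any later band whose center lies within 1.5
A-band-widths below the A band is labelled `stacked` — ribosomes queued
behind the stalled one — and excluded from `f_FL`; the exclusion is the
assay's convention, and adding a stacked band of any area leaves `f_FL`
unchanged. Slowly migrating extra species can optionally be pooled into
`I_FL` (`include_other_in_fl`), the default being exclusion. Intensities
are never corrected for methionine content; `f_FL` is the raw intensity
ratio.

Replicate statistics use the sample standard deviation over `sqrt(n)`
(`aggregate_replicates()`). For two replicates this SEM equals half the
range — plotting mean ± SEM is plotting the two measurements — which fixes
the `n - 1` convention. A single replicate reports a missing SEM rather
than 0.

## Peak calling

`call_peaks()` segments a profile at interior local minima and prunes
boundaries by topographic prominence: a dividing minimum is kept only if
both neighbouring segment maxima rise at least `min_prominence` (default
0.1 in `f_FL` units) above it. This is what makes the caller robust on
single-residue-resolution profiles, where replicate noise creates local
minima everywhere. Per surviving segment the baseline is the segment
minimum (default; a global-minimum option exists), the amplitude is the
maximum minus baseline, `N_max` is the position of the maximum (ties to
the smallest `N`), and `N_start` / `N_end` are the half-maximal crossings,
linearly interpolated between sampled points. A crossing that never occurs
inside the segment — a peak riding a high shoulder, or clipped at the
profile edge — is reported missing rather than extrapolated. Peak metrics
are baseline-relative, so adding a constant to the profile changes
nothing. Overlapping-peak deconvolution is deliberately not attempted;
where peaks merge (high-`f_FL` plateaus) a stronger AP, not a cleverer
algorithm, is the appropriate instrument.

Segment-minimum baselines make `N_start` well defined for subpeaks riding
on elevated shoulders; raw (unsmoothed) profiles are used throughout, with
linear interpolation the only continuity assumption.

`hydropathy_profile()` computes sliding-window means (default window 19)
over either the biological translocon-insertion free-energy scale
(default; negative = membrane-favourable) or the Kyte-Doolittle index. The
scale is a configuration choice recorded in the output attributes.

`compare_mutant()` applies Welch's unequal-variance two-sided t-test to
replicate `f_FL` values at a single `N`. `align_profiles()` scans integer
shifts for the maximum Pearson correlation over the overlapping support,
breaking ties toward the smallest |shift|; it is the data-driven way to
register a simulated profile against an experimental one.

## The coarse-grained simulator

`compute_cgmd_profile()` runs an overdamped Langevin model of the growing
nascent chain: beads of three residues (0.8 nm bonds; stiffness set for
~10% length fluctuation), timestep 300 ns, diffusion coefficient
253 nm²/s, 310 K. Bead hydrophobicity is the summed biological-scale
transfer free energy of its residues; bead charge is the summed formal
charge (K/R +1, D/E −1).

The geometry (`cg_geometry()`) is a parameterized idealization, not a
cryo-EM model: a 3 nm membrane slab centered on z = 0; an aqueous
translocon pore (radius 0.5 nm) through it on the axis, with a lateral
gate opening toward +x over a 60° half-width sector; a truncated exit
tunnel (radius 0.6 nm, length 2 nm) above the membrane with the PTC anchor
at its top, separated from the membrane by a 0.8 nm gap through which the
chain can escape into the cytoplasm. Only the gate state changes during a
run.

The potential has six terms: harmonic bonds; soft walls (tunnel, ribosome
body, membrane slab wherever lipid is inaccessible); a z-tapered transfer
energy inside the bilayer (cosine interface of width 0.3 nm, radial switch
at the pore edge); a linear transmembrane potential contributing
`q * Phi(z)` (cytoplasm negative at the default −100 mV: exporting +1
costs 0.1 eV = 2.306 kcal/mol); a headgroup-crossing barrier (4 kcal/mol
Gaussian bands at both faces, outside the pore) so the lipid interior is
reached through the lateral gate from inside the channel rather than from
the aqueous surfaces; and short-range bead-bead repulsion restricted to
the confined channel region, which enforces single-file ordering — without
it the chain can pass itself inside the pore and upstream charged segments
cannot delay downstream integration. The last two terms are standard
ingredients of this model class that the four "core" terms alone cannot
emulate; both are config-exposed (`k_head`, `k_excl`/`d_excl`).

The lateral gate is two-state. Flips are Metropolis moves attempted every
100 steps (30 µs — faster than every conformational relaxation, slower
than per-step noise) on the state-dependent energy: a basal bias
`gate_dG0` (default 2 kcal/mol favouring closed), the wall energies of all
beads under the proposed state, and a coupling term summing the
hydrophobicity of hydrophobic beads (`min(h, 0)`) inside the gate region
(channel interior below the tunnel exit). Detailed balance holds for fixed
bead positions, and the empty-gate open fraction matches
`1 / (1 + exp(dG0 / kBT))` to within Monte-Carlo error.

Interaction strengths for this model family are calibration choices (they
are not derivable from the assay itself). `transfer_scale = 2` multiplies
bead transfer energies so that a 21-residue poly-Leu-like TMH robustly
partitions; it was fixed against that qualitative behaviour and not
revisited. Quantitative reproduction of any particular published simulated
profile is explicitly out of scope; the simulator is calibrated to
invariants (diffusion law, Boltzmann statistics, charge energetics,
qualitative integration behaviour).

### Force measurement and the entropic baseline

Translation adds one bead every `3 / translation_rate` seconds at the
anchor; at the target length translation halts, the system relaxes briefly
(`equilibration`, default 30 ms), and the tension on the anchored
C-terminal bead (z-component of the harmonic anchor restoring force,
positive toward the membrane) is sampled every 3 ms. Any tethered bead
chain exerts a sequence-independent entropic tension on its anchor (~18 pN
at the defaults, from the 3-D bond-length fluctuation bias plus tunnel
confinement), so reported forces subtract a reference constant measured
once per geometry/interaction set on a non-interacting 20-bead chain with
more replicates and a longer sampling window than any profile point
(cached; `baseline = "none"` gives the raw tension). A non-interacting or
fully polar chain then reads ~0 pN.

### Reporting shift

Because the model tunnel is truncated, simulated lengths are reported as
`reported_N = length_aa + shift`. The default shift
(`estimate_tunnel_shift()`) is the real PTC-to-lateral-gate span in
residues (~40–50 from real-time FRET and model-helix FPA studies; 40 is
used) minus the residues the model geometry holds between anchor and slab
center at the bead contour length (0.267 nm/residue) — +24 for the default
geometry. `align_profiles()` offers the data-driven alternative against an
experimental profile.

### Problem sizes

Two parameter scales run the same engine. `scale = "full"` is the full
protocol: 100 replicates per length, 6 s of sampling at 3 ms intervals
(2000 samples), translation at 5 aa/s from 12 residues, lengths every 4
residues. The desk-scale defaults used by the test suite and the
acceptance script are 6–10 replicates, 0.24–0.6 s sampling, lengths every
8 residues, and accelerated growth at 500 aa/s — overdamped relaxation
(milliseconds) remains far faster than bead-addition intervals even at
that rate. The one exception is the membrane-potential comparisons: charge
retention by the field during translocation is kinetic, and at 500 aa/s
the growing chain shoves a charged flank through the pore before the field
can act, so those runs grow at 50 aa/s, the closest-to-paper rate
affordable at desk scale. Replicate streams are derived deterministically
from one master seed; the same seed reproduces a profile bit for bit.

## Relative contact order

`relative_contact_order()` implements
`RCO = 100 * mean(j - i) / L` over residue pairs with any heavy-atom pair
within 6 Angstrom and sequence separation ≥ 1 (both config-exposed, since
the canonical server's exact settings are not published; comparisons to
printed values should allow ±1 percentage point). Contacts are counted
once per residue pair; multi-model files use the first model. The
implementation is validated against a brute-force all-pairs oracle and is
invariant under rigid-body motion. A fast-folding cytoplasmic domain
(RCO ~15%, ms folding) equilibrates between folded and unfolded states
within one ~100 ms elongation cycle, which is how RCO enters the
interpretation of early FP peaks.

## Synthetic data: what it does and does not show

The generators define the conditions under which the pipeline is tested.
`synth_profile()` draws replicate `f_FL` values around a truth curve of
Gaussian peaks on a baseline, clipped to [0, 1], with truncated-normal
additive noise (SD 0.05, matching typical experimental SEM bars at n = 3;
a mean-preserving beta model is available). Truth peak metrics
(half-max crossings `center ± fwhm/2`) are returned analytically, making
parameter recovery testable: the planted `N_start` is recovered within ±2
residues in well over 90% of seeded runs at amplitudes ≥ 0.3. Real peaks
are asymmetric where Gaussians are not, but recovery is judged against the
same truth shape, so the shape choice does not bias the test.
`synth_lane()` builds Gaussian bands over a polynomial background;
`synth_topology()` alternates polar loops (with positive-inside charge
placement) and hydrophobic TMHs; `synth_structure()` produces ideal
CA-only helices, hairpins and a packed toy domain — synthetic geometry,
not a deposited structure.

What passing these tests shows: the statistics, geometry, peak calling and
simulator physics are correct under controlled conditions with known
truth. What they do not show: behaviour on real gels (overlapping bands,
nonlinear detection), on real profiles with asymmetric or merged peaks,
or quantitative agreement with any published simulated profile, whose
interaction parameters are not public.

## Numerical choices and degenerate inputs

Flat profiles yield empty peak tables, not errors; a zero-intensity lane
is flagged missing rather than reported as `f_FL = 0`; `I_FL + I_A = 0` is
NA with a warning; half-max crossings that leave the segment are missing,
not extrapolated; alignment requires ≥ 3 overlapping points and breaks
score ties toward the smallest |shift|; peak-caller ties in the maximum go
to the smallest `N`. The amino-acid alphabet is restricted to the 20
canonical letters everywhere. Bond and anchor stiffnesses, wall constants,
tapers and the gate schedule are all arguments with documented defaults.

## Known limitations

The simulator has no residue-level structure: helicity, loop orientation
and topology are emergent only through path ordering and energetics, so
topology-dependent effects (e.g. delayed integration of an N_out helix
behind a retained positively charged loop) appear as force differences
only in constructs where the path constraint is geometrically enforced.
The gate is a single two-state degree of freedom; partial openings and
sliding intermediates are out of scope. Peak deconvolution of overlapping
force maxima is intentionally absent. RCO parameters replicate the
standard definition, not any particular server's unpublished settings.
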