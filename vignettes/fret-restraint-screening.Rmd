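---
title: "FRET-restraint screening of docking poses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FRET-restraint screening of docking poses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretscreen)
```

## The measurement model

FRET between a single donor–acceptor pair at distance $r$ transfers energy
with efficiency

$$E(r) = \frac{1}{1 + (r/R)^6},$$

where the Förster radius $R$ is the distance of half-maximal transfer —
50 Å for the Atto-495/Atto-565 pair this package is parameterised for
(`fret_params()`). The inverse transform $(1/E - 1)^{1/6}$ gives a relative
distance in units of $R$, and multiplying by $R$ an *apparent* distance.

The experiment this package operationalises is not a single-pair
measurement. The donor protein (the Agp2 homodimer) is labeled
sub-stoichiometrically through its seven surface cysteines, so a measured
sample carries roughly one donor per dimer at an *unknown* one of 14
candidate sites; the acceptor protein (the Agp1 homodimer) carries one
engineered acceptor cysteine per chain, i.e. two acceptors per dimer. The
expected efficiency at one acceptor position is therefore modelled in two
steps (`predict_position_efficiency()`):

1. per acceptor-bearing monomer $m$, an occupancy-weighted mean over donor
   sites, $E_m = \sum_j w_j E_{mj}$ with $\sum_j w_j = 1$
   (`aggregate_monomer_efficiency()`);
2. combination over the two monomers,
   $E_{total} = 1 - (1 - E_1)(1 - E_2)$ (`combine_total()`) — the
   probability that the excitation is transferred to at least one acceptor.

The occupancy weights default to uniform ($w_j = 1/14$), the assumption the
experimental incorporation data support (similar yields across positions, no
site strongly preferred). Because any weighted *sum* larger than a mean
could exceed 1, the aggregation is a mean by construction; a literal
summation over sites is not a probability and is not offered.

Step 1-then-2 is the convention the original analysis used. The physically
alternative order — combine the two monomer efficiencies per donor site
first, then average over sites — is available as
`predict_position_efficiency(..., combine = "pairwise")`; the two coincide
exactly for point-mass weights and differ little at the efficiencies
relevant here.

The fluorophore position is approximated by the labeled residue's Cβ atom
with no linker correction (`site_coordinate()`; glycine falls back to Cα
with a warning). The real dye sits a few Å further out; this systematic
error is common to all poses being compared and therefore largely cancels
in ranking.

## Spectroscopic efficiency estimators

Measured efficiencies come from absorbance and emission spectra of
donor-only, acceptor-only and mixed samples. The mixture spectra are
unmixed against the single-component references by linear least squares
(`decompose_mixture()`); since negative component amounts are unphysical,
coefficients are constrained to be nonnegative by default (the unmixing
software used in the original study is closed and its settings unknown, so
unconstrained fitting is available via `nonnegative = FALSE`). Two
estimators then apply (`efret_from_spectra()`):

* **donor quenching**: $E = 1 - \dfrac{I_{DA} A_D}{I_D A_{DA}}$,
* **stimulated emission**: $E = \dfrac{I_{AD} A_A - I_A A_{AD}}{I_A A_{DA}}$,

with $I$ integrated emission intensities (donor band 500–560 nm, acceptor
band 575–650 nm by default; bands configurable) and $A$ absorbances of the
named component with/without the partner present. The published description
of the second formula is ambiguous about the wavelength at which $A_A$ is
taken ("at the emission wavelength"). Algebraically the estimator is exact
— both estimators recover a known ground-truth efficiency from noiseless
synthetic spectra — only when *all* absorbance symbols are evaluated at the
excitation wavelength (470 nm), because each term then scales emission
intensities by the excitation each component actually received. That is the
package default; `efret_from_spectra(abs_wavelength = ...)` exposes the
choice rather than silently reinterpreting the source.

The acceptor/donor emission peak ratio $F_{590}/F_{523}$
(`emission_ratio()`) is a concentration-robust relative FRET indicator; the
defaults follow the tabulated header (590/523 nm) rather than the 595 nm
mentioned in passing in the running text, and both wavelengths are
arguments.

## Pose scoring and the three selection criteria

For each candidate pose, predicted and measured efficiency sets are
compared by the sum of squared differences (`score_model()`), by default in
efficiency space. A relative-distance-space variant
(`space = "distance"`) is provided. The published per-model
"Sum of DE²" column could not be reproduced by either convention (for one
model the printed value is 0.65 where the efficiency-space SSD is 0.0881);
the packaged table carries that column verbatim for reference, and no test
asserts equality with it.

Absolute SSD depends on labeling efficiency, which is uncertain, so pose
*selection* uses within-model contrasts (`apply_selection_criteria()`):

* **C1**: $E(554) > E(122)$ — the measured efficiencies are lowest at
  position 122 and highest at 554, and that difference is statistically
  significant.
* **C2**: $E(554) > 2\,E(362)$ — position 362 measured significantly lower
  than 554. A plain strict inequality here is demonstrably too lenient: on
  the packaged model table it admits three additional borderline poses with
  $E(554)/E(362)$ barely above 1, incompatible with the measured 2.8-fold
  contrast. The factor 2 reflects that accepted poses show a mid-position
  value around half the maximum; `c2_ratio = 1` selects the strict reading,
  and `c1_margin` adds an absolute margin to C1 if wanted.
* **C3**: the interface must involve the acceptor protein's histidine
  kinase but not its photosensory module (PCM), and the donor protein's PCM
  but not its kinase region — the flag pattern No/Yes/Yes/No. This encodes
  the truncation experiments: an acceptor-PCM construct shows no transfer,
  while a donor-PCM construct transfers undiminished. The flags are derived
  from a residue-contact analysis rather than visual inspection
  (`classify_domain_involvement()`), with domain boundaries as
  configuration (`domain_ranges()`: acceptor PCM 1–517 / kinase 518–745;
  donor PCM 1–501 / kinase+response-regulator from 502). Poses lacking
  flags are audited as "C3 (flags unavailable)", never silently selected.

One known consequence of the ratio form of C2: a manually built
antiparallel reference arrangement that passes a strict-inequality reading
is rejected by the default. The audit trail (`eliminated_by`) makes the
applied rule explicit for every pose. Near-duplicate pose collapsing is
deliberately left out of the automatic path; all survivors are reported.

## Occupancy robustness

The uniform-occupancy assumption is probed by resampling
(`robustness_resample()`): occupancy vectors are drawn per site log-uniform
on $[1, F]$ and normalised, which bounds the max/min weight ratio by $F$
*by construction* (no rejection step ever triggers), with $F = 40$ by
default. For every position pair the fraction of draws preserving the
uniform-weight ordering is reported. When a pose's donor–acceptor distances
to one position dominate those to another pointwise, any weighted mean
preserves the ordering, so the corresponding fraction is exactly 1 — the
property that makes the C1 contrast a robust selection feature.

## Interface contact analysis

`find_contacts()` reports one row per cross-protein residue pair whose
minimum interatomic distance is at or below the cutoff (3 Å default),
computed over all atoms present in the model. Several published contact
distances are below 2 Å, shorter than heavy-atom contact geometry allows,
suggesting the original analysis included hydrogens or a different atom
selection; exact per-pair distance reproduction is therefore not attempted,
and an `include_hydrogens` switch exists for models that carry hydrogens.
`group_contacts()` merges interface residues, per chain, into sequence
regions whenever at most `gap_threshold` residues (default 15) lie between
consecutive members; single-member regions are reported as solo residues,
the positions most likely to reflect specific rather than incidental
surface complementarity. `conservation_column()` maps a reference position
through alignment gaps to check such positions across homologs.

## The synthetic-data generator

Every pipeline stage is testable offline through generators that emulate
the *statistical* structure of the real inputs, not their biophysics:

* `make_toy_dimer()` builds two parallel rod-like chains of CA/CB
  pseudo-residues at 3.8 Å rise, optionally decorated with dummy
  side-chain atoms for contact analysis. Because the rod has no tertiary
  fold, the real residue numbers (spanning ~600 positions) would put label
  sites thousands of Å apart; screening tests therefore use compact ranges
  (residues 1–30, with position patterns mimicking the real label layout)
  so that donor–acceptor distances fall in the 30–130 Å regime the real
  models show.
* `make_pose_ensemble()` surrounds a true pose with clash-rejected random
  rigid decoys (uniform Euler angles, centroid shell 30–80 Å).
* `simulate_measurements()` adds replicate-level Gaussian noise, clamped to
  $[0,1]$ as measured efficiencies are; at the noise scale of the real data
  (SE 0.02–0.06) the clamping bias is negligible except at efficiencies
  within one SD of the boundaries.
* `make_synthetic_spectra()` builds all six spectra from Gaussian bands
  (donor absorbance 500 nm plus a 475 nm satellite, donor emission 530 nm,
  acceptor absorbance 565 nm plus a blue shoulder that carries its 470 nm
  excitation, acceptor emission 595 nm). Amplitudes are set so the
  acceptor's directly excited emission is comparable to the donor band, as
  in the real spectra. Mixture emission implements energy conservation:
  the donor band scaled by $(1-E)$, the acceptor band driven by
  $A_{acceptor}(470) + E\,A_{donor}(470)$.

The generator computes its noiseless ground-truth efficiencies *with the
package's own predictor*, so generator and predictor cannot drift apart;
the test suite asserts their equality to $10^{-9}$ across seeded complexes.
What passing these tests does **not** show: behaviour under orientation
factor ($\kappa^2$) variation, dye linker flexibility and accessible-volume
effects, spectral overlap changes, photobleaching, or real protein
flexibility — none of which the generator models.

## Numerical and design choices

* Efficiencies are clamped to $[0,1]$ only within $10^{-12}$ (floating
  error); larger violations raise, since they indicate a logic error.
* Spectrum resampling and point evaluation are linear interpolation
  restricted to the measured range; extrapolation is an error.
* Two-component nonnegative least squares is solved exactly by case
  analysis of the active constraints.
* PDB altloc records resolve to the highest-occupancy conformer, ties
  broken by altloc letter; insertion codes are rejected outright.
* Chain-to-protein assignment is always explicit configuration, never
  inferred from sequence; construct-versus-database numbering differences
  are handled by per-protein integer offsets (`numbering_offset`).
* All stochastic functions take an explicit integer seed and are
  bit-reproducible given it.

Problem sizes used by the test and acceptance suites — chosen as the
smallest sizes at which the statistical assertions are stable: 100 seeded
complexes for generator/predictor agreement; 50 replicates of 1 true + 19
decoy poses at measurement noise SE 0.03 for pose recovery (the true pose
must rank first in at least 80%); 1000 occupancy draws at 40-fold range for
ordering robustness; 500 seeded trials at 1% peak noise for the spectral
estimators (mean absolute error at most 0.02, "peak" being the noiseless
mixture-emission maximum); 50 random complexes for the contact-detection
oracle comparison.

## Known limitations

* The printed per-model SSD column's scale is unexplained; only within-run
  SSDs computed by this package are comparable to each other.
* The exact stringency behind the published intermediate elimination counts
  is not recoverable from the published values; the package's criteria are
  explicit, configurable approximations that reproduce the published final
  shortlist.
* Sub-2 Å published contact distances cannot be reproduced from heavy-atom
  models; contact *identities*, not distances, are the stable output.
* Apparent distances from multi-label measurements are effective values;
  they are not physical site–site distances and are only used for ranking
  and sanity checks.
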