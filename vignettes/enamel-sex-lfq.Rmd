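---
title: "Sexing tooth enamel by targeted amelogenin peptidomics: methods"
author: "enamelLFQ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sexing tooth enamel by targeted amelogenin peptidomics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enamelLFQ)
```

## The problem and the model

Tooth enamel is dominated by amelogenin, a protein encoded on both sex
chromosomes. The X-linked isoform (AmelX) is expressed in both sexes; the
Y-linked isoform (AmelY) only in males, and it differs from AmelX by single
amino acid variants (SAAVs). Native enamel peptides (produced in vivo by the
enamel proteases MMP20 and KLK4, so no laboratory digestion is involved)
that span these SAAVs are therefore sex-diagnostic: AmelY-unique peptides
occur only in male enamel, while AmelX-unique peptides occur in everyone and
double as a control that enamel protein was recovered at all.

`enamelLFQ` implements the computational half of this assay as a targeted,
label-free MS1 quantification pipeline over a four-peptide bovine panel,
quantified as doubly protonated ions:

| id | peptide       | protein | [M+2H]²⁺ (m/z) |
|----|---------------|---------|-----------------|
| Y1 | `LRYPYP`      | AmelY   | 404.7212        |
| Y2 | `LRYPYPSY`    | AmelY   | 529.7689        |
| X1 | `SM(ox)IRHPYP`| AmelX   | 508.7527        |
| X2 | `IRHPYPSY`    | AmelX   | 516.7667        |

The reference m/z values are recomputed from sequence, modification deltas
and pinned physical constants (proton 1.00727646688 Da, water 18.0105647 Da,
isotopologue spacing 1.0033548 Da) every time a panel is constructed; a
disagreement beyond 0.002 m/z is a hard error. The X1 methionine oxidation
is fixed at peptide position 2, where the oxidized residue sits in the
curated form of that marker.

Each marker is quantified by:

1. **XIC extraction** — per MS1 scan, summed intensity within ±10 ppm of
   each of the first four isotopologue m/z values of the marker ion.
2. **Peak detection and integration** — apex at the global maximum of the
   monoisotopic trace (optionally restricted to an expected RT ± 30 s),
   bounds extended until the trace falls below 1% of the apex, trapezoidal
   integration per isotopologue.
3. **Envelope validation** — cosine similarity between the integrated
   per-isotopologue areas and the theoretical envelope computed by
   per-element convolution of isotope distributions (aggregated at
   nominal-mass resolution, which is appropriate because isotopic fine
   structure is unresolvable at the 120,000 resolution typical of these
   acquisitions).
4. **MS2 validation** — distinct theoretical b/y ions (charges 1–2) matched
   within 20 ppm in MS2 spectra whose precursor lies within the isolation
   half-width of the marker m/z. Runs without MS2 spectra are quantified in
   MS1-only mode with this check marked "not evaluated".

A marker is *detected* when its area exceeds the detection floor, its
envelope score reaches the threshold, and MS2 validation passes or was not
evaluated.

## The decision rule

Sex is called per sample from the detection pattern:

* **indeterminate** — no AmelX marker detected. The recovery control
  failed, so the absence of AmelY carries no information; the pipeline
  never reports "female" on an empty run.
* **male** — at least one AmelY marker detected; *high* confidence when
  both are.
* **female** — AmelX positive, AmelY negative; *high* confidence when both
  AmelX markers are detected.

Female is deliberately a negative-evidence call gated on the AmelX control,
and no X:Y intensity-ratio criterion is used: the biological signal is
presence/absence, and male AmelY signal in practice sits orders of magnitude
above the female background. Raising AmelY signal can move a call only
toward male, never away from it (a property the test suite checks
exhaustively over all detection patterns).

## Thresholds and their provenance

All thresholds live in `quantParams()` and are echoed into every cohort
report. Two come from the acquisition/search settings standard for this
assay; the rest are this package's own documented choices:

| parameter | default | unit | provenance |
|---|---|---|---|
| `tolPpmMs1` | 10 | ppm | standard MS1 tolerance for this instrument class |
| `tolPpmMs2` | 20 | ppm | standard MS2 tolerance |
| `nPeaks` | 4 | isotopologues | >99% of envelope intensity for ~1 kDa peptides |
| `minEnvelopeScore` | 0.90 | cosine | rejects single-trace artifacts: a monoisotopic-only signal for an ~800 Da peptide scores ≈ 0.897 |
| `floorFactor` | 10 | × baseline | relative floor; no absolute LOD is assumed |
| `minIons` | 4 | b/y ions | automates what is usually a manual fragment check |
| `rtWindow` | 30 | s | apex search half-window when an expected RT is given |

## Bulk deamidation as a diagenesis check

Spontaneous Asn/Gln deamidation (+0.984016 Da per site) accumulates with
age and is the standard authenticity proxy for ancient proteins. The
package computes an intensity-weighted site-level occupancy over quantified
peptide forms:

$$\mathrm{occ}(X) \;=\; \frac{\sum_i A_i\, d_i(X)}{\sum_i A_i\, s_i(X)},
\qquad X \in \{\mathrm{N}, \mathrm{Q}\}$$

where \(A_i\) is the XIC area of form \(i\), \(s_i\) its number of class-X
sites and \(d_i\) its number of deamidated class-X sites. Site-level
weighting keeps the statistic unbiased when forms carry unequal site
counts. When no eligible intensity exists the result is missing, never 0.

Two identifiability caveats are handled explicitly:

* **Positional isomers are isobaric.** Deamidation moves mass identically
  wherever it lands, so the MS1-observable species of a peptide with
  *k* sites are the deamidation counts 0..k, not the \(2^k\) site
  combinations. `occupancyFromRun()` extracts one XIC envelope per count.
* **N vs Q attribution needs single-class peptides.** A count on a
  mixed-N/Q peptide cannot be assigned to a residue class from MS1 alone;
  such peptides are quantified but flagged ambiguous and excluded from the
  per-class statistic. The shipped default background peptides are
  single-class by design (`INHSYENSHSA`: Asn only; `QQHPPQHTLQ`: Gln only).
  They are also chosen short enough that adjacent deamidation species at
  charge 2 are separated by ≥ 15 ppm, comfortably more than the 10 ppm
  extraction window — for longer (heavier) peptides the 0.0193 Da gap
  between a species' A+1 peak and the next species' monoisotopic peak
  shrinks, in ppm terms, below the tolerance and the ladders bleed into
  each other.

The modern-vs-archaeological comparison is a descriptive ratio of group
mean occupancies per class. No hypothesis test is attached, because the
scientific claim is a fold direction, not a significance statement. The
residue classes are implemented as N and Q (chemically, deamidation affects
Asn and Gln); deamidation of arginine, which some search configurations
also track, is excluded from the bulk statistic.

## What the simulator emulates — and what it does not

`simulateRun()` generates DDA runs with known ground truth, standing in for
instrument data so that every stage is testable. Its defaults are the study
conditions the package is tested under:

* 600 s runs at 1 s MS1 cycle time (a desk-scale stand-in for a 50-min
  gradient), MS1 range 350–1650 m/z;
* Gaussian elution, 6 s FWHM (sd ≈ 2.548 s); marker apexes 5 × 10⁷ ion
  counts, spread across 15–85% of the run;
* mass error: Gaussian, 2 ppm sd; intensity noise: log-normal with 5% CV;
  a 50-count baseline at each marker m/z; 20 uniform-m/z decoy peaks per
  scan with exponential intensities;
* deamidation occupancies by era — modern \(p_N = 0.20, p_Q = 0.10\);
  archaeological \(p_N = 0.60, p_Q = 0.50\). These encode a 3× and 5×
  fold direction with a controllable gap; they are simulation settings,
  not measurements;
* DDA: top-10 precursors per cycle above a 10⁴-count trigger, 20 s dynamic
  exclusion, ties broken by intensity then m/z; selected peptides emit
  their singly charged b/y ions plus decoys;
* deamidated background forms are split deterministically across site
  combinations by the product of per-site probabilities (forms under 0.1%
  pruned, weights renormalized) — so occupancy recovery tests the
  estimator, not Bernoulli sampling noise;
* everything is reproducible: a run is a pure function of its
  `SampleSpec`, and cohorts derive per-sample sub-seeds from the master
  seed so one sample can be regenerated without disturbing the others.

Deliberately not modeled: peak tailing and RT drift, charge-state
heterogeneity of the markers, enzyme (MMP20/KLK4) cleavage preferences,
co-isolation chimeras, and detector saturation. Passing tests on this
generator therefore demonstrate the correctness of the quantification and
decision logic under idealized chromatography, not robustness to every
real-data pathology; on real runs the expected-RT restriction and the MS2
gate carry more of the burden.

## Numerical choices and degenerate inputs

* Envelope convolution uses exponentiation-by-squaring of single-atom
  distributions with tails below 10⁻¹⁵ truncated; the returned `nPeaks`
  abundances are renormalized to sum to 1 (set `normalize = FALSE` for the
  absolute probabilities).
* I and L are distinct letters with identical mass; no interconversion.
* Di-oxidation is a distinct registry entry (+31.989829 Da), not Oxidation
  applied twice, so "at most one modification per position per name" can
  hold structurally.
* All-zero chromatograms integrate to area 0 with no apex, and report
  "area below floor" downstream; ties at equal apex intensity resolve to
  the earliest RT.
* The uniqueness check is exact substring matching (optionally with
  mismatches) against user-supplied protein sequences — panel-scope
  specificity, not a proteome-wide homology claim. The shipped FASTA is a
  constructed amelogenin-like pair (file and records labelled synthetic)
  that preserves the marker substrings and SAAV coordinates (AmelX
  Ser44/Ile46/His48, AmelY Leu46/Tyr48) for testing this check offline.

## Problem sizes used by the test suite

The acceptance checks run, per invocation: the four-marker m/z table; 100
random ≤20-atom compositions against an exhaustive enumeration oracle; 10
low-noise runs for area recovery (±5%); occupancy grids
\(p \in \{0.1, 0.3, 0.6, 0.9\}\) (±0.02); 4+4-sample era cohorts for the
fold ratio (±15%); ten 8-sample and ten 12-sample cohorts for
classification (100% agreement required); and 20 female runs for the
empirical AmelY false-positive rate (must be 0). These sizes were chosen as
the smallest that exercise every decision path with non-trivial statistics.

## Known limitations

* The shipped panel is bovine; other taxa need their own panel file (the
  format supports this, but no other panel is shipped or validated).
* Quantification is per-run: no retention-time alignment or
  match-between-runs across samples.
* The female call is inference from absence; contamination of a female
  sample with male material would produce a male call, as in any
  amelogenin-based assay.
* Deamidation occupancy is bulk, not site-resolved, and is a diagenesis
  screen, not a dating method.
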