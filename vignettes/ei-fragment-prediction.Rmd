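---
title: "Methods: combinatorial EI fragment prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial EI fragment prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eifrag)
```

## The problem and the model

Under electron ionization, unfunctionalized amino acids and short
peptides fragment extensively; many small fragments converge to similar
m/z values, so a single peak rarely identifies anything. The model
implemented here takes the opposite tack: enumerate *every* fragment a
candidate sequence can plausibly produce under a catalogue of confirmed
mechanisms, and judge a spectrum by how much of it the resulting m/z
fingerprint explains.

All bookkeeping is done on elemental compositions `[C, H, N, O, S, z]`.
A peptide is the sum of its residues' free-molecule formulas minus one
water per peptide bond. Detection is positive-mode and singly charged:
the molecular ion is the radical cation M⁺·, whose m/z equals the
neutral monoisotopic mass (we flag the charge as +1 and neglect the
electron mass, a 0.00055 Da effect three orders of magnitude below the
matching tolerance). Masses use CODATA-style monoisotopic atomic masses;
the originating measurements are unit-resolution, so any modern mass
table gives indistinguishable results at the ±0.25 m/z tolerance.

Fragmentation events are of two kinds. **Relative** events subtract a
neutral or radical payload from their parent (an M−x change) and are
combinable; **charged** (non-relative) events detect the expelled
side-chain piece itself as a cation with a sequence-independent m/z, and
are terminal. Backbone cleavage (Types A, B, C) and C-terminal carboxyl
degradation are intrinsic to all peptides and are built into the engine;
side-chain events live in the mechanism catalogue, which also ships as an
editable text file. Reserved words in event labels carry semantics:
`type` is reserved for backbone-cleavage path records and may not appear
in labels; `side` marks a side-chain event; a residue-scoped relative
event *without* `side` (the alkene formation of Lys/Pro/Ile) is
C-terminal-associated and fires only paired with a C-terminal loss.

## Enumeration conventions

The enumeration protocol is: assemble the intact peptide; apply all Type
A, then B, then C cuts to it; apply the three C-terminal degradations
(with alkene pairing); then subject every pooled fragment, and
recursively every child, to side-chain events with **at most one side
event per residue position**; finally drop negative-atom-count species
and collapse duplicates. Several conventions in that pipeline were
genuinely open design choices; we fixed them as follows, using the
well-characterized QFA tripeptide — whose full enumeration is known to
comprise 55 fragments including the intact peptide — as the calibration
point:

* **Charge retention at cuts.** Which piece keeps the charge is not
  predictable without rate information, so *both* complementary pieces
  are emitted as candidate cations. False candidates are tolerated: the
  goal is an exhaustive fingerprint, and scoring counts matched observed
  peaks, not matched predictions.
* **Hydrogen bookkeeping.** Cleavage is homolytic with no hydrogen
  rearrangement: each piece keeps exactly the atoms on its side of the
  severed bond. This reproduces every tabulated nominal delta (M−45
  Type A on a free amino acid, the 72.04 acylium of Ala-Ala, …);
  rearrangement variants (±H) remain expressible as definition-file
  entries.
* **Backbone depth.** Backbone cleavage applies to the original peptide
  only; side-chain events recurse over all fragments. Recursive
  backbone cutting would generate internal multi-cut fragments the
  model's reference behavior does not include.
* **Residue-less pieces.** A cleavage piece containing no residue — the
  bare carboxyl radical complementary to a Type A cut at the last
  residue, or the bare NH2 from a Type C cut at position 1 — is not
  emitted: a fragment is modeled as a chain of positioned residues, and
  such pieces carry no amino-acid information.
* **C-terminal eligibility.** The three carboxyl degradations apply to
  the intact peptide, alongside backbone cleavage. Side-chain carboxyls
  of Asp/Glu carry their own independent events, so the observed
  combinatorial acid losses (e.g. water plus whole carboxyl in Glu) are
  still generated through the side-event recursion.
* **Deduplication.** Duplicates are collapsed at the elemental-formula
  level; the first-generated mechanism path is kept as the
  representative and `n_routes` counts the collapsed routes. A
  path-multiset key was considered and rejected: it roughly doubles the
  QFA output by keeping formula-identical species that differ only in
  bookkeeping, and the m/z list — the quantity scoring consumes — is
  unchanged either way.

Each convention was fixed once against the QFA reference count and then
left alone; the single-amino-acid enumerations are independently verified
in the test suite against a closed-form brute-force enumerator that
shares no code with the engine.

## Catalogue notes

The generic lost-side-chain event applies to 16 residues; Ala, Gly, Pro
and Tyr are deliberately absent from that list, following the confirmed
observations the catalogue encodes. Supplementary evidence exists that
Tyr shows the mechanism too; users who want it can add one line to a
definition file. Thr's β-elimination is modeled with the same water loss
as Ser's, ignoring its extra methyl. Glycine has no side-chain events at
all — its lack of side-chain structure is a genuine model blind spot, not
an omission. Lys cyclization and Asn/Gln ammonia loss share the −NH3
payload but keep distinct labels so path records stay interpretable.

One rounding quirk is documented rather than absorbed: the His alkene
ion C5H5N2⁺ computes to m/z 93.045, which some reference tabulations
print as 93.1; that printed value conflicts with standard rounding, so
the package reports the computed value. Similarly, the reference M⁺
value for WFA (422.19) reflects truncation of the computed 422.1954;
this package rounds half-up everywhere and treats that row as the single
known truncation case.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tolerance` | 0.25 | m/z | typical maximum calibration error of a unit-resolution EI instrument across its scan range; the match boundary is **inclusive** |
| `threshold_fraction` | 0.05 / 0.25 | fraction of base peak | permissive vs prominent-peak fitness scoring |
| `scan_range` | 60–350 | m/z | typical DEP acquisition window; applied to synthetic observations, never to predictions |
| `mz_jitter_sd` | 0.05 | m/z | fixture m/z noise; kept at or below tolerance/3 so planted peaks stay matchable |
| `fraction_observed` | 0.8 | — | fraction of the fingerprint planted in a fixture; crude spectra rarely show every predicted fragment |
| `n_background` | 15 | peaks | unexplained peaks, emulating the background every crude spectrum shows |

Contaminant masking uses the same ±0.25 tolerance as prediction matching
and precedes threshold filtering; the base-peak intensity is taken over
the full spectrum, so thresholds keep their instrumental meaning even
when the base peak itself is a protecting-group contaminant. Each
observed peak matches at most one prediction (the nearest; ties to the
smaller absolute error, then the smaller predicted m/z), while several
peaks may match the same prediction — the score counts matched *peaks*.

## The synthetic-spectrum generator

`simulate_spectrum()` emulates the structure of a crude-sample DEP-EI
spectrum: a sampled fraction of the sequence's own predictions with
Gaussian m/z jitter, optionally the characteristic peaks of one
protecting-group standard (Fmoc-Cl, Trt-Cl, Pbf-Cl or Boc/OtBu), and
uniform background peaks in the scan window. Intensities are log-uniform
(planted peaks 1e5–1e8 counts, the scale of typical DEP base peaks;
background a decade lower). All randomness is derived from an explicit
seed and the global RNG state is restored on exit.

What it does **not** emulate: realistic relative intensities (the model
predicts which m/z can occur, not how abundant they are), isotope
envelopes, peak shape and centroiding artifacts, and mechanism classes
absent from the catalogue. Passing the scoring tests on fixtures
therefore demonstrates the pipeline's internal consistency — planted
fragments are recovered, decoy sequences score lower — not predictive
completeness on real spectra, where unmodeled mechanisms depress the
match percentage, most visibly for Gly and Arg.

## Numerical and degenerate-input choices

m/z values are carried at full double precision and printed at four
decimals; comparisons to tabulated reference values use those tables'
precision (two decimals for molecular ions, one for charged side-chain
ions). Atom counts may go transiently negative while events stack and
are filtered only at emission. An empty peak list scores as
not-applicable (`NA`) rather than 0 or 100; an empty spectrum file parses
to an empty peak list with a warning. Output ordering is deterministic
(ascending m/z, then path text), and identical inputs always produce
byte-identical outputs.

## Problem sizes

The test suite and acceptance script run on the scales the model is
designed for: single amino acids (4–14 fragments), tripeptides
(QFA: 55), and one tetrapeptide (SEQA: 210 fragments). The
fixture-based scoring checks use 20 seeded synthetic spectra of ~60–80
peaks each; everything completes in seconds on one CPU.

## Known limitations

No intensity or probability prediction; no internal multi-cut fragments;
no rearrangement chemistry beyond the catalogue; no multiply charged
arithmetic (the charge field is structural, and m/z computation refuses
|z| > 1); no protected or nonconventional residues in the shipped tables
(both are expressible through the residue and mechanism definition
files); average (isotope-weighted) masses and isotope patterns are out of
scope.
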