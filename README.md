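# eifrag — combinatorial EI fragment prediction for peptides

Electron ionization (EI) is a hard ionization method: a ~70 eV electron
beam shatters the analyte, so the spectrum of an unfunctionalized amino
acid or short peptide is a forest of fragment peaks rather than a clean
molecular ion. That makes EI spectra hard to interpret by eye, but EI
instruments are far more widely available than soft-ionization platforms,
and with a direct exposure probe (DEP) unfunctionalized peptides can be
volatilized straight into the beam. `eifrag` is for chemists who want to
use such an instrument to answer a practical question: *is my desired
peptide present in this crude synthesis aliquot?*

## The model

Every species is a six-component integer vector `[C, H, N, O, S, z]`. A
peptide assembled from free amino-acid formulas (one water condensed per
bond) is fragmented by systematically applying a catalogue of mechanisms:

* **Type A / B / C backbone cleavage** — cuts at the Cα–carbonyl bond,
  the peptide bond, and the N–Cα bond respectively; Type C only at the
  aromatic residues Phe, Trp, Tyr. Both complementary pieces are kept as
  candidate cations. Cleavage is homolytic: each piece keeps exactly the
  atoms on its side of the severed bond, so a single free amino acid's
  Type A cut is the familiar M−45 carboxyl-radical loss.
* **C-terminal degradations** — loss of CO2H (M−45), OH• (M−17) or H2O
  (M−18) from the original C-terminal carboxyl; for Lys/Pro/Ile each may
  pair with alkene formation (−H), giving the observed M−46.
* **Relative side-chain events** — residue-specific neutral/radical
  losses (ammonia from Asn/Gln, β-elimination from Ser/Thr/Cys, side-chain
  carboxyl losses from Asp/Glu, guanidino losses from Arg, the generic
  lost-side-chain event, …). These are *combinable*: a fragment's m/z is
  relative to its parent, with at most one side event per residue.
* **Charged (non-relative) side-chain ions** — the expelled side chain
  detected as the cation (e.g. C7H7⁺ at 91.1 from Phe). Their m/z never
  depends on the sequence context and they seed no further fragmentation.

Backbone cleavage applies to the original peptide; side-chain events
recurse over all fragments. After removing negative-atom-count species and
formula-level duplicates, the sorted m/z list is the peptide's predicted
**fingerprint**. Observed peaks are matched within an instrumental
tolerance (±0.25 m/z by default, boundary inclusive), known
protecting-group contaminant peaks are masked, and the fitness score is
the percentage of peaks at or above an intensity threshold (relative to
the base peak) that match a prediction.

The mechanism catalogue ships as a plain-text file
(`inst/extdata/mechanisms.txt`, dialect
`residues | label | kind | C,H,N,O,S,z`), so new mechanisms or
nonstandard residues can be added without touching code.

## Worked example

```r
library(eifrag)

ps <- enumerate_fragments("QFA")
ps
#> <prediction_set QFA: 55 fragments, m/z 29.03-364.17 (built-in)>
head(as.data.frame(ps), 5)
#>        mz composition                                               path n_routes
#> 1 29.0265     C1H3N1+                      typeA@Q1 > side chain loss@Q1        1
#> 2 57.0215   C2H3N1O1+                   typeB@Q1-F2 > side chain loss@Q1        1
#> 3 72.0324   C2H4N2O1+                      typeC@F2 > side chain loss@Q1        1
#> 4 84.0449   C4H6N1O1+                    typeA@Q1 > side ammonia loss@Q1        1
#> 5 85.0402   C3H5N2O1+ typeA@F2 > side chain loss@Q1 > side chain loss@F2        2
```

The tripeptide QFA yields 55 unique fragments including the intact
molecular ion at m/z 364.17; each row records the mechanism path that
generated it (`n_routes` counts distinct paths collapsing to the same
formula). Scoring a synthetic crude-sample spectrum (80 % of the
fingerprint observed, plus Fmoc protecting-group peaks and random
background) against the right and a wrong sequence:

```r
pk <- simulate_spectrum("QFA", seed = 3, fraction_observed = 0.8,
                        contaminant_set = "fmoc")
fm <- contaminant_list("fmoc")
score_spectrum(pk, ps, threshold_fraction = 0.05, contaminants = fm)
#>   threshold_fraction n_considered n_matched percent_matched mean_abs_error sd_abs_error
#> 1               0.05           19        17        89.47368     0.04931266   0.02663163
score_spectrum(pk, ps, threshold_fraction = 0.25, contaminants = fm)
#>   threshold_fraction n_considered n_matched percent_matched mean_abs_error sd_abs_error
#> 1               0.25           10        10             100      0.0494254   0.03072595
score_spectrum(pk, enumerate_fragments("CIA"), 0.05, contaminants = fm)
#>   threshold_fraction n_considered n_matched percent_matched mean_abs_error sd_abs_error
#> 1               0.05           19         7        36.84211     0.04735636   ...
```

At the permissive 5 % threshold the true sequence explains 89 % of the
considered peaks and 100 % of the prominent (≥25 %) ones, while the
composition-disjoint decoy CIA explains far fewer — the contrast that
makes the fingerprint usable for presence/absence decisions.

A thin command-line wrapper covering `predict`, `match`, `score` and
`simulate` is installed at `system.file("cli", "eifrag.R", package =
"eifrag")`.

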