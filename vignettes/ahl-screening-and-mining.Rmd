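---
title: "Methods: AHL screening by characteristic daughter ions and LuxI/LuxR genome mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AHL screening by characteristic daughter ions and LuxI/LuxR genome mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The two tracks

`ahltools` implements two complementary computational procedures around
N-acyl-homoserine lactone (AHL) quorum-sensing signals:

1. **MS/MS screening** of LC-MS/MS product-ion data for AHLs by their
   characteristic daughter ion, with structural annotation against a
   theoretical mass library; and
2. **genome-mining post-processing** of profile-HMM and BLAST searches for
   the AHL synthase (LuxI) and receptor (LuxR) protein families, down to
   per-species copy-number distributions.

Both tracks are deterministic functions of their inputs and parameters, and
both are exercised end to end by a synthetic-data module that plants known
ground truth.

# The screening model

An AHL consists of a homoserine-lactone ring amide-linked to a fatty acyl
chain of `n` carbons, optionally 3-oxo substituted and with `u` C=C double
bonds. Under collision-induced dissociation in positive mode, the protonated
molecule releases the protonated ring fragment at m/z 102 regardless of the
chain, which makes a precursor-ion scan for daughter m/z 102 a family-wide
screen. Secondary ring-derived daughters at m/z 56, 74 and 84 serve as
confirmation; their chemical identity is not modelled here — they are treated
as fixed target masses, which is how they are used diagnostically in
practice.

The chain determines the elemental formula: C(n+4)H(2n+5)NO3 for the plain
chain, +O −2H for 3-oxo, −2H per double bond. With integer atomic masses
(C=12, H=1, N=14, O=16) plus one proton this gives the nominal
\[M+H\]$^+$ a unit-resolution triple quadrupole reports, i.e.
$14n + 116 + 14\,[\text{oxo}] - 2u$; with most-abundant-isotope masses it
gives the monoisotopic mass for high-resolution work.

The pipeline chains six stages, each an exported function:

| stage | function | default parameters |
|---|---|---|
| characteristic-ion screen | `precursor_ion_screen()` | m/z 102, tol ±0.5, ≥1% of base peak |
| confirmation | `confirm_daughters()` | ≥1 of {56, 74, 84}, same rule |
| EIC extraction | `extract_eic()` | precursor tol ±0.5 m/z |
| peak detection | `detect_peaks()` | height ≥1000 a.u., SNR ≥3 × MAD, 0.2 min apex spacing |
| control comparison | `control_compare()` | ≥3× control max in ±0.5 min, floor 1 a.u. |
| annotation | `annotate_mz()` | nominal mode, tol ±0.5 m/z |

Tolerances of ±0.5 m/z for both fragments and precursors reflect
unit-resolution quadrupoles; for high-resolution instruments switch
`annotate_mz()` to monoisotopic mode with a tolerance around 0.01 m/z.
Masses in the feature table are reported as nominal integers, the precision
at which this instrument class prints them.

Candidate features are finally grouped by `cluster_features()`: k-means on
z-standardised (m/z, retention time) with k = 4 by default, 10 restarts and
a fixed seed. Standardising both axes keeps the (hundreds-wide) mass axis
from dominating the (minutes-wide) time axis. The cluster count is a
descriptive choice for the dot-plot view of a feature table, not a model
claim; change `k` freely.

## Numerical choices

* **"Significant peak"** has no instrument-independent definition; here it is
  a local EIC maximum above both an absolute height (1000 a.u.) and 3× the
  median-absolute-deviation of the trace. A zero MAD (noiseless traces)
  disables the SNR gate rather than dividing by zero.
* **Apex spacing.** An EIC keeps one point per scan of the run, including
  zeros for scans devoted to other precursors. Those interleaved zeros would
  turn every shoulder sample into a local maximum, so an apex must also
  dominate its ±0.2 min neighbourhood; of two apices closer than that, the
  higher survives.
* **Control rule.** Medium components elute in both runs, so a sample peak
  must exceed `fold_threshold` (default 3) times the control EIC maximum
  near its apex; the control maximum is floored at 1 a.u. so a silent
  control gives a large, finite fold-change.
* **Annotation ties.** Nominal masses collide (e.g. a 3-oxo-C(n) species is
  isobaric with C(n+1):1). All co-matches within tolerance are returned;
  the ranking prefers smaller absolute mass error, then even chain lengths —
  acyl chains are assembled from C2 units, so even chains dominate in
  nature — then fewer double bonds, then name. This reproduces the field's
  usual structure calls for masses such as 256 (C10-HSL over Oxo-C9-HSL)
  and 324 (Oxo-C14:1-HSL over C15:1-HSL).
* **Library bounds.** The default library spans n = 4–18 with 3-oxo variants
  and up to two double bonds: wide enough for all common standards and the
  longer predicted species, while excluding 3-hydroxy variants by default
  (enable `allow_hydroxy` to add them, +O at unchanged hydrogen count).
  Aryl-HSLs (e.g. p-coumaroyl-HSL) are outside the straight-chain model and
  are deliberately not enumerated; an empty annotation is the intended
  answer for such masses.

# The genome-mining model

The mining track post-processes per-genome `hmmsearch --tblout` tables in
which concatenated synthase-family and receptor-family profile HMMs were
searched against predicted proteomes. The chain is:

1. `filter_significant()` — keep hits with full-sequence E-value strictly
   below 1e-5. The strict inequality is deliberate: borderline hits such as
   one at 9.7e-5 fall out naturally rather than by special-casing. The
   full-sequence column (not best-domain) is the filtered quantity; the
   reader exposes both positions should the other convention be needed.
2. `assign_best_model()` — when several models recognise one protein, keep
   the lowest E-value; ties break by higher bit score, then lexicographic
   model id, making the outcome order-independent.
3. `count_copies()` — per assembly, copy number per family is the count of
   distinct surviving proteins. The assembly universe comes from an explicit
   manifest, so zero-hit genomes are reported as (0, 0) rather than
   silently dropped.
4. `dedup_species()` — where one species has several assemblies, the one
   maximising LuxI-count × LuxR-count is kept (ties: higher receptor count,
   then smallest assembly id). Strain suffixes can be collapsed to the
   binomial with a configurable regex; the default grouping uses the
   manifest's names as-is, since name-mapping conventions vary by source.
5. `summarize_copy_numbers()` — median (midpoint for even n), mean, min,
   max, and counts of species with ≥1 and exactly 1 copy, per family.

`filter_blast()` applies the same strict-threshold idea (default 0.01) to
BLAST tabular output, counting unique species and identity/coverage ranges
of the significant hits.

# What the synthetic data emulates — and what it does not

`make_ms_run()` emulates a product-ion acquisition over a 40-minute
gradient at a 0.05 min scan interval: each planted AHL elutes as a Gaussian
(default sigma 0.1 min) whose spectra carry the 102 daughter, a random
non-empty subset of {56, 74, 84} with lognormal intensity scatter, and
Poisson-count chemical-noise fragments; decoys come in exactly the two kinds
the screen must reject (no 102; 102 without confirmation); medium ions elute
identically in sample and control. Runs are written as both mzML (minimal
PSI 1.1.0, uncompressed 64-bit arrays) and MGF from one internal truth, so
the two readers cross-validate each other.

`make_cohort()` emulates the hit tables of a genus-wide search: synthase
copies as `synthase_min + Poisson(4.3)` and receptor copies as a rounded
Normal(123, 25) floored at 5. These shapes are fixture choices loosely
matched to the scale of real actinomycete genomes (receptor regulators
outnumber synthases by an order of magnitude); they are not a biological
model. Significant E-values are log-uniform in 1e-30–1e-6, decoys sit above
the threshold, a fraction of targets is hit by two models, and a fraction of
species gets a second assembly with independently drawn counts.

What the generator does **not** emulate: chromatographic drift and
tailing, isotope patterns, detector saturation, real fragmentation
chemistry beyond the fixed daughter set, correlated noise, realistic
protein sequences or HMM scores. Passing tests therefore demonstrate that
the pipeline's logic is correct under its stated rules — full recovery of
planted signals with zero decoy leakage, exact truth-table recovery for the
mining chain — not that the default thresholds are optimal for any
particular instrument or genome set. Reproducing published genus-scale
numbers (thousands of genomes against live databases) is explicitly out of
scope; the package's claim is the correctness of the post-processing given
such inputs.

# Problem sizes and determinism

The test suite works at desk scale: screening checks run 20 seeded
noiseless sample/control pairs with three planted AHLs each and full decoy
complements; mining checks use one 200-species cohort with ≥10% duplicated
assemblies plus 100 small randomised cohorts against brute-force oracles.
These sizes keep the whole suite under a minute per track while leaving no
combinatorial case of the dedup and best-model rules unexercised.

Every entry point is a pure function of (inputs, parameters, seed): file
writers format numbers explicitly, k-means is seeded with fixed restarts,
and reruns produce byte-identical CSVs — asserted in the tests, and worth
preserving in any extension.

# Known limitations

* Nominal-mass annotation cannot separate isobars; the ranked co-match list
  is the honest output, and high-resolution (monoisotopic) mode is the
  remedy when the data support it.
* Peak areas use trapezoidal integration between valley bounds with no
  baseline model; quantification and calibration are out of scope.
* The MGF reader supports the common key=value dialect (PEPMASS,
  RTINSECONDS, SCANS), not every vendor extension.
* `read_tblout()` trusts the 18-column layout; HMMER versions that change
  column order would need a new position map.
* No chromatographic alignment across runs: the control comparison assumes
  sample and control share a retention-time frame, as they do when acquired
  back-to-back on one method.
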