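---
title: "Locating small-molecule binding sites from dose-resolved LiP-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating small-molecule binding sites from dose-resolved LiP-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipsite)
```

## The problem and the method

Limited-proteolysis mass spectrometry (LiP-MS) probes protein conformation
in a native lysate: a broad-specificity protease (proteinase K) briefly
digests the proteome, and the yield of each half-tryptic or tryptic peptide
reflects how accessible its region was. When a small molecule binds a
protein, it locally shields or exposes backbone, so the intensities of a
handful of peptides near the binding site change with compound
concentration — and they do so sigmoidally, with a midpoint near the
binding affinity. `lipsite` turns that observation into a structural
prediction in four stages:

1. **Differential filtering.** Each peptide is tested at the high doses
   (by default 2, 20 and 100 µM, the concentrations above a typical
   compound IC50) against vehicle with a Welch t-test on per-sample
   median-centred log2 intensities. Benjamini–Hochberg q-values are
   computed per comparison, and candidates must satisfy q < 0.01 and
   |log2FC| > 0.46.
2. **Dose–response fitting.** Every candidate is fitted with a
   four-parameter log-logistic (4PL) model on the log2 intensity scale,

   $$f(d) = \text{bottom} + \frac{\text{top} - \text{bottom}}
   {1 + (\text{EC}_{50}/d)^{s}},$$

   with the analytic limit $f(0) = \text{bottom}$ so the vehicle point
   participates without a pseudo-dose. Goodness of fit is summarised as
   $R^2 = 1 - SS_{res}/SS_{tot}$ over replicate-level points.
3. **Ranking and selection.** Peptides are ranked by $R^2$ (ties broken by
   lower EC50, then sequence) and the top three are retained; peptides with
   $R^2 > 0.9$ and low EC50 have repeatedly been found to lie closest to
   binding sites.
4. **Triangulation.** The top peptides are located on a PDB structure by
   exact substring match against the chain sequence, their atoms are pooled
   (atoms shared by overlapping peptides counted once), and the
   mass-weighted centre of mass (CoM) of the pooled atoms is reported as
   the predicted site, together with all residues within a neighbour
   radius of it.

The same package also ranks candidate targets from an upstream
reverse-competition pulldown: proteins enriched on immobilised compound,
with free compound at 8, 80 and 800 µM competing genuine targets away.
After per-channel median normalisation, proteins are ordered by their
log2 fold-change at the highest free-compound dose, aggregated across
replicates by the minimum, and called significant above a log2FC of 2 in
every replicate.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| comparison doses | 2, 20, 100 µM | molar | doses above a typical IC50, where responsive peptides are near their plateau |
| q threshold | 0.01 | — | conventional strict FDR for candidate lists |
| \|log2FC\| threshold | 0.46 | log2 units | ≈1.4-fold, separates genuine LiP changes from run-to-run drift |
| R² threshold | 0.9 | — | "very high correlation" band used for flagging |
| k (top peptides) | 3 | count | three peptides triangulate a site; more dilutes locality |
| slope bounds | [0.05, 20] | — | positive slope; direction carried by top − bottom |
| log10(EC50) bounds | dose range ± 2 decades | log10 M | allows fits slightly beyond the ladder without runaway |
| neighbour radius | 8 | Å | typical first-shell contact distance for a pocket |
| weighting | mass | — | "centre of mass" proper; geometric mean by flag |

The dose ladder itself (`default_dose_series()`) is 7–10-fold dilutions
from 2 mM down to 2 nM plus intermediates at 1 mM and 100 µM and a vehicle,
ten points in all; the intermediates stabilise the upper part of the curve
during fitting.

## Numerical choices

The 4PL fit is parameterised in log10(EC50) with the Levenberg–Marquardt
solver (`minpack.lm::nlsLM`), bounds as above, and five multi-starts with
log-spaced EC50 guesses across the dose range; bottom/top start from the
vehicle and highest-dose means and the best residual sum of squares wins.
Convergence tolerances are 1e-15 on relative sum-of-squares and parameter
change with at most 500 iterations per start; on noise-free data this
recovers all four parameters to better than 1e-6 relative error anywhere
in the ladder (this is asserted by the test suite). Fits are flagged
*degenerate* — and excluded from ranking, never thrown as errors — when
fewer than five distinct doses have data, when the response is constant
(SS~tot~ = 0), or when no start converges.

Median-centring is applied per sample (dose × replicate) across all
peptides of the table before any statistics; it removes loading
differences and makes $R^2$ invariant to global intensity shifts. Welch
p-values for zero-variance groups are defined as 1 for equal means and 0
otherwise, so noiseless fixtures behave deterministically. In peptide
mapping, occurrences are searched with overlap allowed, so a repeated
motif is reported as ambiguous rather than silently mapped to its first
occurrence; isoleucine/leucine are distinct by default (structures
distinguish them even though mass spectrometry does not) with an
equivalence flag available.

## What the simulator emulates — and what it does not

`simulate_lip_experiment()` reproduces the statistical structure of the
experiment: the 10-point ladder, 3 replicates, log-normal multiplicative
intensity noise (log2-additive Gaussian, parameterised by CV), a minority
of peptides on a 4PL mean curve with a planted EC50 and a random response
direction, and a toy single-chain structure in which each responsive
peptide is an ideal helical segment whose centroid sits 5 Å from a
designated pocket centre while filler segments sit 60 Å and further away.
The default noise CV of 5% is a choice of plausible replicate
reproducibility for DIA peptide quantities, not a measured value. The
geometry choice makes the pocket centre a construction-level ground truth:
the CoM of any subset of responsive peptides lies within a few Å of it.

Deliberately not simulated: fragment-level interference, retention-time
drift, missing values, batch effects, shared peptides between proteins,
and any realism in side-chain packing (segments carry backbone + Cβ only).
Passing tests therefore demonstrate that the pipeline recovers planted
dose–response structure and geometry under clean, well-behaved noise; they
do not certify performance on real search-engine output, where missingness
and interference add failure modes upstream of this package.

`simulate_competition_experiment()` plants one target whose competition
grows monotonically over the 8/80/800 µM channels to a configurable
log2FC, over a background centred at 0 with 0.3 SD; vehicle-channel ratios
are identically 0 by construction, matching how iTRAQ ratios against the
vehicle channel are formed.

## Open design decisions, as resolved here

* **Test statistic.** The upstream search tool's internal peptide-level
  test is proprietary; the transparent equivalent used here is a Welch
  t-test on log2 quantities at the modified-sequence level. Where
  fragment-level rows are supplied they should be summed to peptide
  quantities first.
* **FDR scope.** Whether q-values are per-comparison or global is exposed
  as `fdr_scope`; the default is per-comparison.
* **Pass rule.** Whether a candidate must pass one or all of the three
  high-dose comparisons is exposed as `rule`; default `"any"`.
* **Atom pooling.** Whether atoms shared by overlapping top peptides count
  once or per peptide is exposed as `dedupe`; default counts them once
  (the union reading of "all atoms assigned").
* **Chain choice.** Multi-chain structures map onto the first chain
  containing all top peptides unless `chain` is given explicitly.
* **Competition statistic.** The headline ranking uses the highest
  free-compound dose only (not a trend statistic across the three doses),
  with the minimum across replicates as the aggregated score.

## Problem sizes used in validation

The test suite and the acceptance script validate on simulations sized to
the method's operating point: 500 peptides with 10 responsive for
parameter recovery, 1000 pure-noise peptides for fit specificity, 200
peptides for exact candidate filtering, 20 independent 120-peptide
experiments for end-to-end site recovery, and 500-protein competition
tables. These sizes keep a full validation run around two minutes on a
single core while leaving each estimate comfortably stable.

## Known limitations

* Exact substring matching cannot place peptides spanning residues missing
  from the crystal model; such peptides are reported unmapped rather than
  partially placed.
* The CoM of three peptides is a point estimate with no spread; distant
  peptides with high $R^2$ (e.g. allosteric responders) will pull it away
  from the true pocket. Inspecting the per-peptide ranges in the site TSV
  alongside the CoM is recommended.
* EC50s outside the dose ladder are extrapolations; the fitter bounds them
  to two decades beyond the ladder and they should be read as censored.
* The package consumes peptide-level quantification reports; search,
  identification FDR and protein inference are upstream concerns.
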