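---
title: "Methods: histone PTM quantification from DIA runs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histone PTM quantification from DIA runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoneDIA)
```

This vignette is the package's own account of the models and numerical
choices behind its pipeline: mass bookkeeping for derivatized histone
peptides, isolation-window design, peak detection and integration,
positional-isomer deconvolution, the synthetic-data model that everything
is validated against, and the limitations of that validation.

## Chemistry model

Peptide masses are monoisotopic, built from IUPAC atomic masses (C 12,
H 1.0078250319, N 14.0030740052, O 15.9949146221, S 31.97207069,
P 30.97376151) with the proton at 1.007276 Da. Modifications are defined
by elemental composition, so every delta is exact by construction:
acetyl C2H2O = 42.0106 Da, methyl CH2 = 14.0157 Da, trimethyl
C3H6 = 42.0470 Da, propionyl C3H4O = 56.0262 Da, phospho HPO3 = 79.9663
Da. The acetyl/trimethyl pair differs by 0.0364 Da — about 24 ppm on a
doubly charged histone peptide — which is why the MS1 tolerance defaults
to 10 ppm.

Derivatization follows standard propionylation chemistry: the peptide
N-terminus and every lysine that is unmodified **or monomethylated**
receives one propionyl group; acetylated, dimethylated and trimethylated
lysines are blocked. Monomethyl-lysine therefore carries me1 + prop
(+70.0419 Da). The registry also defines `Kacme` (methyl-acetyl), which
is exactly isobaric with propionyl — a deliberate stress case for the
grouping logic.

Isotope envelopes are computed by exact truncated convolution of the
per-element isotope distributions. Since the elemental composition of
every target is always known here, no averagine approximation is needed;
the suite verifies the convolution against a brute-force multinomial
enumeration to within 1% relative intensity. Three isotope peaks are used
for MS1 quantification, spaced 1.00336/z apart.

## Target database

Digestion emulates trypsin on a fully propionylated substrate: cleavage
after arginine only (lysine is blocked), never before proline, zero
missed cleavages. Histone community numbering (1-based after
initiator-Met removal) is used throughout; the FASTA reader trims a
leading Met by default. PTM forms are enumerated per peptide — one PTM
per site, up to a configurable number of simultaneous PTMs — then
derivatized, in a deterministic order (by position, then modification
name) so databases are reproducible.

Forms of one backbone are grouped per charge by precursor m/z proximity
on the sorted m/z axis (chaining gaps below the tolerance), which makes
grouping independent of input order. Positional isomers co-group at any
tolerance because their m/z is identical; the acetyl/trimethyl pair
separates at the default 10 ppm and merges only at method-match-scale
tolerances (several tens of ppm), which is exactly the regime in which
fragment ions covering all candidate sites become informative.

## Isolation-window design

`fixed_scheme()` reproduces center-stepped constant-width schemes (the
35-window, m/z 24, 1-Da-overlap layout spanning centers 307–1089).
`variable_scheme()` places interior boundaries at equal-count quantiles
of the target m/z distribution — the midpoint between the two targets on
either side of each cut — so per-window target counts differ by at most
one, then enforces a minimum width (default 5 m/z) and applies the
overlap (default 1 Da) symmetrically. This emulates vendor
variable-window calculators, whose exact algorithm is unpublished; the
equal-density objective is the documented design choice.

Cycle time is MS1 accumulation + the sum of window accumulations +
per-scan overhead × (n windows + 1). The overhead is an explicit
parameter (default 5.6 ms) because published cycle times imply a
per-scan cost that accumulation times alone do not account for: 42
windows at 10 ms MS2 and 100 ms MS1 give 0.52 s of accumulation but a
0.761 s cycle.

## Peak detection and quantification

XICs sum centroided intensities within a ppm tolerance (MS1 10 ppm, MS2
20 ppm) per spectrum; MS2 traces are confined to one isolation window.
Detection applies a 3-point moving average, takes local maxima of the
smoothed trace within the RT assignment window (±0.5 min by default),
and picks the highest (ties broken toward the expected RT). Integration
boundaries extend outward to the first sample below 1% of the apex on
the raw trace, or to a smoothed local valley — the raw-trace threshold
keeps the boundary at the true 1% crossing instead of the
smoothing-widened one. The area is the trapezoidal integral of the raw
trace (intensity × minutes); points-across-the-peak counts samples at or
above the 1% threshold, so a peak of width `w` sampled at cycle time `c`
reports `w/c ± 1` points. The noise floor is
`max(absolute floor, 3 × median of the trace)`; the absolute floor
defaults to 0 and should be raised for data with a real baseline.

A form's MS1 area sums the first three isotopologue XICs over shared
boundaries detected on their summed trace. Expected RTs come from a
landmark calibration: every distinct target m/z is located by its
maximal MS1 peak, the most intense dozen anchors are kept, and a linear
map from library RT to observed RT is fitted (falling back to identity
if fewer than three anchors or a non-positive slope). A linear map is
the default because within-method RT drift is dominated by offset and
scale; nonlinear warping is out of scope.

## Positional-isomer splitting

For a group with candidate sites $s_1 < \dots < s_k$ and one variable
modification per member, each inter-site span $j$ yields an estimate of
the cumulative signal fraction $F_j$ of members modified at a site
$\le s_j$:

$$F_j = \frac{\sum_i h_i^{mod}}{\sum_i \left(h_i^{mod} + h_i^{unmod}\right)}$$

over the discriminating b ions $i$ of span $j$, where $h$ is the
smoothed MS2 XIC height at the MS1 apex RT. Heights, not areas, are used
deliberately: at the apex the co-eluting members all contribute at their
full proportion, and height ratios of co-measured variants cancel the
common elution profile. y ions estimate $1 - F_j$ the same way and the
two estimates are averaged where both exist. Member fractions are first
differences of $F$ (with $F_0 = 0$, $F_k = 1$), after monotone clipping
to $[0,1]$ and renormalization; a span with no observed ions is filled
by linear interpolation between its neighbors, and a group with no
fragment evidence at all falls back to uniform fractions flagged
low-confidence.

The formulation is exact when variant ions of one cleavage position
share a response factor — the fragmentation efficiency of the backbone
bond — which holds in the simulator by construction and is the standard
assumption behind fragment-ratio-based isomer quantification. For groups
whose members differ in more than one placement (e.g. mixed-PTM
candidate sets), a nonnegative-least-squares route solves the full
ion-membership system: each discriminating ion contributes rows
`indicator(member ∈ variant) · x = normalized variant height`, plus the
simplex constraint; `pracma::lsqnonneg` solves it when available.

MS1 area is split at the apex (fractions applied once), not per cycle;
per-cycle splitting would allow within-peak fraction drift but is
unnecessary under the co-elution assumption and noisier in practice.

## The synthetic-data model

`synthetic_truth()` + `simulate_run()` emulate the acquisition: cycles at
fixed cadence (default scheme: 42 variable windows, 100 ms MS1, 10 ms
MS2, 5.6 ms/scan overhead → 0.761 s) across the gradient. Each MS1
spectrum carries every form's first-three-isotope envelope scaled by a
Gaussian elution profile normalized so the trapezoidal XIC area equals
the injected area; each MS2 window spectrum carries the b/y fragments of
in-window forms, mixed across isomer-group members according to the
truth fractions. Fragment base intensities are drawn once per backbone
and ion index from a seeded uniform(0.2, 1) — shared by the members of
an isomer group, encoding the backbone-bond response-factor assumption
above, and making discriminating ions non-degenerate. Noise is per-peak
multiplicative log-normal (default sigma 1%) plus an optional additive
uniform floor; between-replicate RT jitter is proportional to each
apex RT (default sigma 1%), applied per group so co-eluting isomers stay
co-eluting.

`default_histone_truth()` encodes the study conditions: derivatized
tryptic peptides of mature human H3.1 and H4 carrying mono-ac/me1/me2/me3
lysine forms, one charge state each (the lowest of 2–4 with precursor in
m/z 300–900), 110 forms in 78 groups, a 10-min gradient, and the
42-window variable scheme designed from the target m/z themselves. The
H4 4–17 mono-acetyl quartet is fixed at fractions (0.4, 0.3, 0.2, 0.1)
for K5/K8/K12/K16; other group fractions and all abundances
(log-uniform over 10^4.5–10^6.5) are seed-driven. Peak sigma is 2.5 s
(≈15 s base width, ~20 points per peak at the 0.761 s cycle). Group
apexes are evenly spaced over the central 84% of the gradient with
backbones interleaved: modification families of one backbone share their
unmodified-variant fragment m/z, so adjacent elution would leak between
their splits; interleaving keeps same-backbone groups minutes apart and
makes noiseless end-to-end recovery exact to machine precision.

What the simulator does **not** model — and what passing tests therefore
do not demonstrate about real data: chimeric background proteome and
co-isolated interferences from non-histone peptides, tailing/fronting
peak shapes, charge-state envelopes beyond the configured charge,
detector saturation and dynamic-range compression, and real
ionization-efficiency differences between fragment variants. The
recovery results bound algorithmic error, not instrument error.

## Problem sizes and numerical choices

The test suite and acceptance script run the default truth
(110 forms × ~790 cycles × 43 spectra/cycle) for single-run end-to-end
checks — including one full mzML write/read and one ms1/ms2 round-trip —
and 20 independent seeds at 1% noise for the stochastic recovery checks,
quantifying the isomer quartet plus a fixed sample of singleton groups
per seed; replicate CV checks use three jittered replicates with full
database quantification. Tolerances asserted: noiseless isomer fractions
to 1e-6 (observed: machine precision), areas within 5% at 1% noise
(observed ≲1%), RT CV < 5% for ≥95% of forms (observed 100%), text
round-trips exact at printed precision (m/z 5 dp, RT 4 dp), Gaussian
integration within 2% of the analytic area (boundary truncation at the
1% threshold costs ~0.25%).

Degenerate inputs are defined rather than accidental: empty target
databases warn and return empty tables; all-zero traces and absent forms
yield zero-area records flagged undetected; all-zero regions get NA
ratios and a flag; a group with equal variant heights splits uniformly;
ties in peak picking resolve toward the expected RT; single-target
window design falls back to even spacing.

## Known limitations

* The spans formulation assumes one variable placement per member;
  multi-site differences route to NNLS, which is less statistically
  efficient when ion evidence is sparse.
* RT calibration is linear and per-run; no cross-run alignment or
  match-between-runs.
* Only centroided data are supported; profile spectra are rejected at
  read time.
* The bundled modification list covers the PTMs exercised here
  (ac, me1–3, prop, ph, Kacme) and is user-extensible through the
  registry config; it is not a complete histone PTM space.
* No FDR machinery: the search is targeted and library-free, so
  identification confidence rests on mass accuracy, RT agreement and
  the points-across-peak threshold.
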