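---
title: "Models and methods behind scmsquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scmsquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmsquant)
```

`scmsquant` analyses plate-based single-cell mass spectrometry (scMS) data
from plant protoplasts: per-cell LC-HRMS feature tables become absolute
in-cell metabolite concentrations and cell-population structure. This
vignette explains the models, the parameters that matter, and the design
choices made where the design was genuinely open.

## The measurement model

A picked protoplast is lysed in a 12 µL well (6 µL of 0.1% formic acid for
osmotic lysis plus 6 µL of methanol carrying the ajmaline internal
standard). A 2 µL aliquot is pooled for QC; because removing an aliquot
does not change the extract *concentration* — an intensive quantity — the
full 12 µL extract volume still represents the cell's content, and the QC
aliquot plays no role in quantification. Standards and samples share the
injection volume, so it cancels throughout.

Units are fixed package-wide: calibration levels and extract concentrations
in µM (= pmol/µL), well amounts in mol, cell volumes in pL, in-cell
concentrations in mM, with

amount (mol) = concentration (mM) × volume (pL) × 10⁻¹⁵.

The cell is treated as a sphere, `V = (π/6) d³`, from the single imaged
diameter. Protoplasts are close to spherical once the wall is removed; no
second axis is available from the picking images, so no ellipsoidal
correction is attempted.

## External calibration, linear range, LOQ

Each compound's series (default seven levels, log-spaced 10⁻⁵–10 µM, three
replicates per level) is fit by weighted least squares. Two choices
deserve explanation:

* **Weighting 1/x².** In-cell amounts genuinely span five to six orders of
  magnitude (sub-fmol vinblastine in small cells up to ~10² pmol of
  secologanin in large ones), so the calibration must too. Over such a
  span, 1/x weighting still lets the top levels dominate the squared-error
  sum, which destabilises the intercept relative to the lowest levels;
  1/x² equalises *relative* error across levels and keeps every level
  inside the accuracy filter. On series spanning ≤ 2–3 decades the two are
  practically interchangeable and `weighting = "1/x"` is available.
* **Back-calculation filter.** After each fit, every level's mean area is
  back-calculated through the line; the worst level deviating more than
  20% from nominal is dropped and the line refit, until all retained
  levels pass. Dropping one level at a time matters: a saturated top point
  distorts the global fit enough to push otherwise-linear levels past 20%,
  and batch removal would cascade into a spurious failure. The linear
  range is the span of retained levels; the LOQ is the lowest retained
  level, expressed as an amount in the 12 µL well (0.12 fmol at the
  default bottom level). Fewer than three surviving levels is an error,
  never a silent fallback.

Below-LOQ entries are censored: they carry a status flag
(`below_loq`/`absent`), no number, and count as zero in population
summaries. Concentrations above the linear range are reported but flagged
`above_range`. Areas at or below the intercept are `below_loq`, never
negative amounts.

Internal-standard normalization (each sample scaled by median IS area /
its IS area) is applied before quantification by default. Whether the IS
should correct areas or serve only as a QC monitor is a genuinely open
choice in targeted workflows; it is exposed as `normalize_is` and defaults
to on, which makes quantified concentrations invariant to per-sample
response drift (a property the test suite checks). Samples with a missing
or zero IS area are excluded with a warning rather than silently kept.

## Formula and adduct annotation

Ion m/z arithmetic uses most-abundant-isotope masses and subtracts the
electron mass per charge — at four decimals this is not optional
(`[M+H]+` of C21H24N2O2 is 337.1911, not 337.1917). Enumeration searches
CHNOPS compositions within bounds (default C ≤ 60, H ≤ 100, N ≤ 6, O ≤ 20,
P ≤ 2, S ≤ 2) chosen to cover iridoid, MIA, flavonoid and anthocyanin
space while remaining tractable; the hydrogen count is solved from the
residual mass rather than looped, so the search is effectively
four-dimensional. Candidates must satisfy |ppm| ≤ tolerance (signed error
reported, filter on the absolute value) and RDBE = C − H/2 + N/2 + 1
within 0–40, and are ordered by |ppm|, then lower RDBE, then lexicographic
formula — a deterministic ordering with no hidden score. The test suite
cross-checks the enumerator against an exhaustive grid oracle.

Library matching assigns a feature to a compound only when both the ppm
and RT windows pass; the three C21H24N2O2 isomers (catharanthine,
tabersonine, vindolinine) are indistinguishable by mass and are resolved
by retention time alone. Permanently charged anthocyanins (peonidin
3-O-rutinoside) are carried as `[M]+` of the flavylium cation; serpentine
is handled as `[M+H]+` of C21H20N2O3, which reproduces its reported ion at
m/z 349.15 — its cationic-native form is noted but not separately modelled.
The bundled library's retention times are reconstructions on the 7-minute
gradient (the instrument tables are not reproduced here) and are flagged
as such in its documentation.

## The synthetic population generator

The generator exists so that every downstream stage can be verified
against known truth; its defaults encode the reported population structure
of *C. roseus* tissues, and they are study conditions, not tuning knobs:

* leaf: 2.5% idioblasts (midpoint of the reported 2–3%) carrying the
  alkaloid load including anhydrovinblastine at 0.3–10 mM; an IPAP
  population (10%) defined by loganic acid; two secologanin-rich epidermal
  populations totalling 30% of cells at 50–600 mM, one co-accumulating
  mauritianin (cells carrying both have the lower secologanin range);
  vinblastine restricted to idioblasts at an overall per-cell probability
  of ~1/202.
* root: an alkaloid-specialised population, iridoid + strictosidine cells,
  strictosidine-only cells, and no flavonoids anywhere.
* petals (SA / LBE / ABH): anthocyanin- and flavonoid-rich majorities, a
  small alkaloid-specialised population (largest in LBE, where summed
  alkaloids reach 300–400 mM), and a secologanin population that in LBE
  always co-occurs with flavonoids.

Concentrations given presence are log-uniform between the type's bounds —
the reports state ranges spanning orders of magnitude, not distributions,
and log-uniform is the minimal-assumption draw on such a range. Diameters
are uniform on each type's range within the overall 16–45 µm span.
Presence and concentration draws are independent across compounds;
within-cell correlations beyond the type structure are not modelled, and
no between-compound covariance is claimed. Cross-contamination during
picking defaults to zero (picking is reported clean) but is exposed as a
rate parameter adding a 2% carry-over from a random donor cell.

One modelling convention matters for extreme values: reported maxima are
*observed* (noisy) values, so the generator's true ranges sit slightly
inside the observed envelopes — vinblastine 10–80 µM against an observed
ceiling of 100 µM, SA-petal secologanin 5–50 mM against an observed 5–60
mM. Under the default measurement noise the simulated *observed* maxima
then reproduce the reported ceilings instead of systematically
overshooting them.

The instrument model is multiplicative mean-1 log-normal noise on areas
(default CV 10%, a typical short-gradient LC-MS figure), a per-sample IS
area with 5% CV, fixed per-compound response factors (5×10¹⁴–2×10¹⁵
area/mol), and small m/z (0.3 ppm SD) and RT (1.5 s SD) errors on feature
coordinates — comfortably inside the 2 ppm / 10 s matching windows.
Amounts below the LOQ still produce signal; censoring is a downstream
decision, as in the real workflow. Chromatographic peak shapes, matrix
effects, recovery and isotope patterns are not simulated, so passing tests
demonstrate the correctness of the analysis chain, not robustness to those
real-data effects.

## Partitioning

Clustering operates on `log10(area / volume + pseudocount)` with
pseudocount 1 on the volume-normalized scale: volume normalization stops
large cells from scoring as concentrated ones, the log compresses the
orders-of-magnitude dynamic range, and the pseudocount keeps empty entries
finite at 0.

Hierarchical clustering defaults to Euclidean distance with Ward (ward.D2)
linkage — compact-cluster behaviour suited to "a small population of
extreme cells against a diffuse background" — and orders leaves
deterministically by placing the larger subtree first at every node.
k-means defaults to k = 4 with 50 seeded restarts and per-compound
standardization (without it, the highest-intensity compound class decides
the partition alone); identical input and seed give identical labels.
Neither the distance/linkage pair nor pre-scaling is dictated by the
source workflow; both are documented assumptions here.

Marker annotation applies ordered rules: serpentine ≥ 1 mM → idioblast
first, then loganic acid ≥ 1 mM → IPAP, fallback `other`. Serpentine
precedes loganic acid so that an (unobserved in practice) cell carrying
both is called an idioblast, the rarer and more specific type. The 1 mM
thresholds sit orders of magnitude above the LOQ-equivalent concentration
of either marker in any 16–45 µm cell, and well below the generator's
marker ranges, so annotation on clean data is exact — a property the test
suite asserts.

## Numerical and degenerate-input policy

* Determinism everywhere: one seed per entry point, sub-seeds derived from
  it; identical invocations produce byte-identical files and JSON.
* Boundary conventions: an area exactly at the LOQ's fitted area is
  `quantified` with amount = LOQ (tolerance 10⁻¹² relative); ties in
  candidate ordering break by RDBE then formula string; ties in isobar
  matching break by |ΔRT| then |ppm|.
* Degenerate inputs fail loudly and early: constant calibration areas,
  unknown preset labels, proportions not summing to 1 (tolerance 10⁻⁹),
  nonpositive diameters or volumes, duplicate feature/cell/compound ids,
  negative areas (the offending row is named).
* Quantified concentrations exceeding a solubility ceiling
  (`max_base_solubility`, S₀(1 + 10^(pKa−pH)) for a monoprotic base) are
  flagged, never clipped — supersaturated readings are scientifically
  meaningful (deep-eutectic solubilization has been proposed for exactly
  these compounds).

## Problem sizes

Verification runs use the tissue-preset population sizes (202 leaf, 187
root, 232 petal cells) with 20 seeded replicates for population-recovery
statistics, a 10,000-cell draw for the binomial type-proportion check, and
100 random masses against the exhaustive enumeration oracle on reduced
bounds (C ≤ 25, H ≤ 40, N ≤ 4, O ≤ 12). These sizes give binomial
standard errors of a fraction of a percentage point on the recovered
proportions while keeping the whole suite fast.

## Known limitations

Diameters are taken as given metadata (no image segmentation); feature
detection is upstream (no mzML parsing or peak picking); no MS² or
isotope-pattern evidence enters annotation, so isobars are separable only
by RT; quantification assumes external calibration transfers (no matrix
effect or recovery correction, no isotope dilution); and the generator's
independence assumptions mean co-occurrence statistics beyond the encoded
type structure should not be read into simulated data.
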