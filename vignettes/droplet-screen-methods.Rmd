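---
title: "Models and methods behind dropswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dropswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropswitch)
library(dplyr)
```

`dropswitch` simulates and analyzes high-throughput screens of cell-free
riboswitches performed by fluorescence-activated droplet sorting (FADS).
Riboswitch variant templates are clonally amplified on magnetic beads,
beads are encapsulated with a cell-free protein-synthesis mix in
water-in-oil droplets, each droplet reports transcription (a ROX molecular
beacon) and riboswitch output (split-GFP reconstitution), and a sorter
dispenses droplets falling in a fluorescence gate. Alternating ON and OFF
sorting cycles enrich ligand-responsive variants, which are identified by
sequencing every cycle's pool and ranking variants by the *enrichment
trend*: the least-squares slope of percentage read abundance over cycles.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the simulator does and does not
capture. All quantitative statements here are computed by the package's
test suite or acceptance script; none are copied from elsewhere.

## Bead encapsulation

Bead loading is Poisson: with mean `lam` beads per droplet the occupied
fraction is $1 - e^{-\lambda}$ (`occupancy_fraction()`), inverted by
`lambda_for_occupancy()`. The screening protocol keeps occupancy at
10–30%, because the monoclonal fraction of occupied droplets,
$P(k = 1 \mid k \ge 1) = \lambda e^{-\lambda}/(1 - e^{-\lambda})$, is
~0.95 at 10% occupancy and ~0.83 at 30%. The price is that at least 70% of
droplets are empty, which is why the ROX transcription beacon matters: it
lets the sorter ignore empties.

Magnetic beads aggregate. `loading_model(lam, clump_p)` represents
aggregation as a Poisson number of clumps (mean `lam * (1 - clump_p)`),
each of geometric size with continuation probability `clump_p`, so the
mean beads per droplet stays exactly `lam` while the count distribution
becomes overdispersed. `clump_p` defaults to 0; the mock-sorting presets
use 0.3. No published measurement of aggregation exists, so `clump_p` is a
free simulation parameter — the point of the clump model is qualitative:
multi-bead droplets share one sorting fate, which dilutes enrichment
measured on templates relative to enrichment measured on droplets.

## Phenotypes: what the generator plants in the library

`assign_phenotypes()` attaches a Hill dose-response to every variant,

$$E(c) = \mathrm{off} + (\mathrm{on} - \mathrm{off})
         \frac{c^h}{EC_{50}^h + c^h},$$

with three classes. The defaults describe an inhibitory-stem-loop (ISL)
library screened against a ligand such as histamine:

* **dead** (majority): the stem loop stays intact; expression sits at a
  *leaky repressed baseline*, lognormal with median 0.5 expression units
  (sdlog 0.3), at all concentrations. A non-functional variant in this
  library class is repressed, not silent — an early draft of the generator
  gave dead variants a level far below the switches' OFF state, and the
  low-GFP OFF-sorting gate then selected dead variants, a dynamic the real
  screen cannot show. Making the dead baseline and the switch OFF state
  share one distribution is what makes alternating ON/OFF sorting select
  *switching*, not any fixed level.
* **constitutive** (default 20% of non-switches): the randomized region
  breaks repression regardless of ligand; one lognormal level with median
  5 units. These survive ON rounds and are purged by OFF rounds.
* **switches** (`planted_fraction`, default 1%): OFF level drawn from the
  repressed-baseline distribution, ON/OFF ratio uniform on 5–20× (the
  strongest validated histamine switch reached 19.7×), $EC_{50}$
  lognormal around 1.6 mM (the validated switch's value), Hill
  coefficient 1. The Hill parameterization itself is the simulator's
  choice; the screen only reports empirical ratios and $EC_{50}$s.

Expression units are scaled so that the split-GFP detection ceiling
(`gfp_cap = 26`, echoing the ~26 µM limiting GFP1–10 concentration) sits
above typical ON levels but close enough to compress the strongest ones.

## Optics and the saturation cap

`droplet_signals()` maps content to signals. ROX is a transcription
indicator: occupied droplets emit `rox_baseline + rox_scale` (times
multiplicative lognormal noise, CV `noise_cv = 0.2`), empties only noisy
baseline — so empties cluster at the bottom-left of the GFP × ROX plane.
GFP is the summed expression of all beads in the droplet, **capped** at
`gfp_cap`, scaled, and subjected to the same noise. Because
$\min(on, cap)/\min(off, cap) \le on/off$ whenever $on \ge off$, the cap
can only compress a measured ON/OFF ratio, never inflate it — the
simulator reproduces the compression seen when switches assayed with the
split-GFP reporter are re-assayed with a full-length reporter. One shared
cap is assumed for droplet and bulk assays; whether the two saturate
identically in reality is unknown.

## Gate construction and sorting

`build_gate()` follows the bench procedure. The empty droplets are found
as the dominant low-ROX cluster (located around the median of log ROX —
valid while occupancy < 50% — with a 6-MAD band; a deliberate choice of a
simple, testable rule over mixture fitting). The ROX threshold is that
cluster's 99.9th percentile. The GFP bound is then the quantile of GFP
among ROX-positive droplets such that the gate holds at most
`cap_fraction` of *all* droplets (protocol cap 10%, typical 0.1–3%;
default 3%). Ties at the bound are resolved in favor of respecting the
cap, so with a discrete noiseless population the gate may hold fewer
droplets than the cap but never more.

`sort_droplets()` adds sorter errors: in-gate droplets are missed with
probability `miss` (default 0.02) and out-of-gate droplets — almost all
empty — are dispensed anyway with probability `false_sort` (default
0.0025). The published mock experiments report only composite efficiency
and purity, not separate error rates, so these defaults are calibrated,
not measured: `false_sort` was derived analytically from the purity
target (~85%, the middle of the observed 79.9–89.3% range) given a ~1.5%
desired in-gate fraction, via
$\mathrm{false\_sort} \approx g(1-p)/(p(1-g))$.

`regenerate_pool()` turns each sorted bead into one template lineage,
optionally with lognormal PCR amplification bias (`pcr_bias_cv`, default
0 — the screen gives no handle to estimate it), and renormalizes to
relative abundances (always summing to 1 within 1e-9).

## The mock experiment

`simulate_mock()` reproduces the two-template validation: a strong-RBS
"ON" template and a weak-RBS "OFF" template mixed 5:95, sorted once for
the minor species, under clumped loading. Its default gate caps hug the
desired cluster the way an operator adjusting the gate to the population
would, and the cluster sizes are known a priori from the mixture:
droplets with ≥1 ON bead are ~1.1% of the population (ON cap 1%), while
all-OFF droplets are ~0.65% (OFF cap 0.6%) because aggregated multi-bead
droplets rarely stay pure. Under these defaults the ON mock yields
efficiency ~98%, purity ~78–82%, droplet-level enrichment ~46–48× and
template-level enrichment ~8–9×, against published values of 99.5–99.9%,
79.9–82.5%, 48× and ~7×. The droplet/template gap is driven entirely by
`clump_p`: multi-bead droplets carry hitchhiking templates through the
sorter. Both enrichment folds are ratios of desired fractions *after/
before*, with the droplet-level fractions taken over **all** droplets,
empties included — the convention under which the published
1.7% → 81.6% = 48× arithmetic works. (Under this convention a perfect
sorter without clumping gives purity 100% and template enrichment exactly
1/minor_fraction, not droplet = template equality, which would require
counting occupied droplets only.)

## Sequencing simulation and read processing

`simulate_reads()` writes one read per template draw: cycle barcode
(6–8 nt) + upstream constant + variable region + downstream constant,
truncated to 150 nt (single-end), with i.i.d. substitution errors at
`per_base_error` and constant base qualities at the corresponding Phred
score. The pipeline is deliberately strict and deterministic, since the
original study's filtering script is unpublished:

* `demultiplex()`: exact barcode prefix match, no error correction;
  non-matching reads are tallied as unassigned.
* `filter_reads()`: discard on (1) any base quality below `min_q`
  (default Phred 20), (2) any mismatch in the constant flanks — the
  variable region is located by fixed offsets, not alignment, so indels
  also land here ("errors in unintended positions"), or (3) a variable
  region whose length is not an allowed degenerate length. One reason is
  recorded per read; conservation (assigned = passed + discarded) holds
  at every stage.
* `count_variants()`: the variant id is the extracted variable region;
  the count table is dense (every design variant a row) for designs up to
  1e5 variants, sparse beyond.
* `abundance_matrix()`: percentage of each cycle's total reads; columns
  sum to 100.

## Enrichment trend and ranking

`enrichment_trend()` is the screen's ranking statistic: the OLS slope of
percentage abundance against cycle index 0, 1, …, C−1, with cycle 0 the
unsorted input library (the study sequenced it along with every sorted
round). Undetected cycles contribute abundance 0 — no pseudocounts; this
is a slope on the percentage scale, not a log fold change. The slope is
computed by the closed normal-equations form and is cross-checked in the
tests against `stats::lm` to 1e-10. `rank_variants()` sorts by descending
slope with deterministic tie-breaks (final-cycle abundance, then variant
id); OFF-screens use the same order because enrichment of the desired
behavior is always "up". Whether the original analysis included cycle 0
or used fractional rather than percentage abundance is unstated; both
choices rescale all slopes jointly, so ranks are unaffected, and the
defaults above are declared rather than reconstructed.

## Dose-response fitting and normalization

Bulk characterization arithmetic follows the published normalization
chain: GFP/ROX per well, then division by the no-riboswitch control's
GFP/ROX without ligand (`normalize_expression()`); ON/OFF ratios are
corrected for nonspecific ligand effects on the control by the ratio of
fold changes at each concentration (`corrected_fold_change()` — e.g. a
raw 26.8× over a control that itself rises 1.36× is a corrected 19.7×).
The ratio-of-ratios at each concentration is the only reading consistent
with correcting "at each concentration"; the package reports both raw and
corrected ratios since the published figures vary in which they show.

`fit_dose_response()` fits the four-parameter Hill model by
Levenberg–Marquardt with positivity bounds, in `activation` or
`repression` mode (same parameterization, different starting values, with
a warning if the fitted direction contradicts the requested mode).
Constant responses raise a degenerate-fit error rather than returning a
meaningless $EC_{50}$. Two objective scales are offered: `"linear"` (the
default; plain least squares on the response) and `"log"` (least squares
on log response), the efficient choice when measurement error is
multiplicative, as fluorescence ratios typically are. This matters for
parameter recovery: at 5% multiplicative noise with 8 concentrations × 3
replicates, a *single* dataset yields median $EC_{50}$ errors of ~6–9%
(linear scale) or ~5% (log scale) — at the information limit of that
design — while the mean estimate across 20 replicate datasets is within
~1% of truth. The test suite therefore checks exact recovery (1e-6) at
zero noise and unbiasedness (mean estimate within 5%) under noise, rather
than demanding 5% from every single noisy dataset.

## Problem sizes and determinism

Every stochastic operation takes an explicit `seed` (applied via
`withr::with_seed`, leaving the caller's RNG untouched); a screen's
per-round seeds derive from the campaign seed by a fixed offset, so runs
are bit-reproducible. Default droplet counts are 1e5 per round — a
desk-scale version of the ~2.2 × 10⁶ droplets per 10-minute sorter run —
which for a 5376-variant library gives only ~7 beads per variant and
correspondingly strong round-to-round drift. The end-to-end analyses in
the tests and README run at 5 × 10⁵ droplets per round, which restores
per-variant bead coverage to the 10–40× band the original study cites as
sufficient; at that scale the slope ranking recovers 19–20 of the top 20
as planted switches, mirroring the study's 20/20 validation rate.

Selection in this simulator, as on the bench, is harsh on *final
abundance*: the last OFF round re-ranks every repressed-level variant
(switch OFF states and dead baselines are statistically identical by
construction), so surviving dead variants can out-draw true switches in
the final pool. It is the slope across cycles, not the final abundance,
that separates switches — which is precisely why the screen ranks by
enrichment trend.

## What the generator does not capture

* Sequence–function relationships: switch status is assigned at random,
  so enriched variants share no sequence motif (a real screen's hits can,
  e.g. the GYGU consensus; `consensus_sequence()` is provided for such
  analyses but the simulator will not reproduce motif convergence).
* Droplet physics: volume variation, coalescence, chip geometry; droplet
  diameter is metadata only. No FCS cytometry files are read or written.
* Sequencing artifacts beyond i.i.d. substitutions: no indels, no
  quality decay along the read, no paired-end structure (reads are
  simulated pre-merged), no PCR chimeras.
* Secondary-structure prediction and free energies, aptamer selection,
  and all wet-lab protocol chemistry are out of scope.

Passing tests on this generator therefore demonstrate that the *analysis*
(pipeline, ranking, metrics) behaves correctly under the stated stochastic
model of the screen, not that the model predicts any particular real
library's outcome.
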