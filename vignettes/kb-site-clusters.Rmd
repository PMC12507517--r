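---
title: "Weak kB-site clusters, cumulative affinity and ChIP occupancy"
author: "kbscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak kB-site clusters, cumulative affinity and ChIP occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbscan)
```

## The model

NF-kB dimers (RelA:RelA, p50:RelA) bind ~10-bp kB sites with the degenerate
consensus GGGRNNYYCC (R = A/G, Y = C/T, N = any). Measured affinities across
thousands of 10-mers form a continuum, summarised per 10-mer by a
dimensionless affinity Z-score. Two observations motivate this package:

1. A single high-affinity ("strong") site rarely predicts in-cell occupancy.
   In ChIP experiments the occupancy signal at a peak tracks better with the
   *summed* affinity of all kB sites — including many low-affinity ("weak")
   ones — clustered within roughly 150-200 bp around the strongest motif.
2. A weak site on its own is expected to be nearly empty at equilibrium:
   with free nuclear dimer concentration $C$ and dissociation constant
   $K_D$, fractional occupancy under the free-ligand approximation is
   $$f = \frac{C}{C + K_D},$$
   which for $C = 200$ nM and $K_D = 3\ \mu M$ gives $f = 0.0625$ — about
   6% bound. Clusters of such sites, through avidity and cofactor
   recruitment, can nonetheless matter; quantifying their joint signal is
   the point of the cumulative Z-score.

The pipeline is: **designate** sites from a 10-mer Z-score table,
**classify** them strong/weak at a Z boundary, **sum** Z in dynamic windows
around each peak's strongest motif, and **correlate** the cumulative score
with ChIP occupancy as a function of window length. A companion module
scores DNA-pulldown proteomics for proteins enriched on kB-containing
probes versus control DNA.

## Site designation

A 10-bp window (either strand) is designated a kB site when

* its 10-mer is present in the affinity table with $Z > 0$, and
* it deviates from GGGRNNYYCC at no more than `max_mismatches` positions
  (default 3, matching the spread of sites with measurable affinity).

Designation decisions that the data do not fully pin down, and how we
resolved them:

* **Positive-Z requirement.** Table entries with $Z \le 0$ are retained in
  the table but never designated. This guarantees the cumulative Z-score is
  non-decreasing in window length, which the correlation analysis relies
  on; a site with no measurable positive affinity contributes no occupancy
  signal.
* **Boundary class.** A site with Z exactly at the strong threshold
  (default 6.0, calibrated elsewhere to roughly $K_D \approx 300$ nM) is
  classified *strong*: the strong set is closed, so reference sites quoted
  at the boundary do not silently flip class.
* **Strand collapse.** When both strands of one window qualify, only the
  larger-Z strand is reported (tie to the plus strand). Near-palindromic
  sites would otherwise be counted twice at one physical position.
  Overlapping sites at *different* starts are all kept — the analysis
  counts sites, it does not tile the sequence.
* **Fixed width.** Scanning is fixed 10-bp. Real promoters contain a few
  shorter deviant elements (9-bp sites are documented); mapping those onto
  a 10-mer table would require an alignment convention the table itself
  does not define, so variable-width designation is out of scope.

Coordinates are 0-based half-open throughout, including BED export. A
site's *center* is `start + 4.5`, the true midpoint of the 10-bp interval;
all window membership is decided on centers.

## Cumulative Z and the correlation curve

For a peak region (nominally the ±500 bp around a ChIP peak), the *anchor*
is the designated site with maximal Z; ties break by proximity to the
region center (or the peak summit when the input provides one), then by
the smaller start. The cumulative Z at window length $L$ is the sum of
$Z$ over sites whose center falls within $\pm L/2$ of the anchor center.

* The window is symmetric around the anchor: "a window of length $L$
  surrounding the strongest motif" has only one reading that is continuous
  in $L$ from 10 to 500 bp.
* The anchor is always included, and excluding weak sites zeroes their
  contribution without re-anchoring — the comparison "with versus without
  weak sites" must hold the anchor fixed to be interpretable.
* Pearson correlation is computed between raw ChIP scores and cumulative
  Z at each window length (a `log1p` option exists but is off by default;
  occupancy scores arrive on whatever scale the peak caller produced and
  are accepted as provided). Zero-variance windows yield explicit `NA`
  values, flagged via an attribute, never dropped.
* The weak-site abundance comparison between occupancy-ranked halves uses
  a two-sided pooled-variance Student's t-test (Welch available by flag).
  Ties in the ranking break lexically by region id so the split is
  deterministic; with odd $n$ the extra peak goes to the bottom half. When
  both halves are constant with equal means the statistic degenerates to
  $t = 0,\ p = 1$; constant halves with unequal means return $t = \pm\infty$,
  $p = 0$.

## Occupancy projection

`fraction_bound()` implements the free-ligand closed form only. The
approximation (site concentration ≪ TF concentration) is appropriate for
genomic sites in a nucleus with hundreds of nanomolar TF; a
ligand-depletion quadratic or multi-site cooperative models would suggest
precision the underlying back-of-envelope projection does not have. No
continuous Z-to-$K_D$ mapping is provided: the only calibrated point is
the strong/weak boundary, and inventing an interpolation would be
unsupported.

## Pulldown enrichment

The fixed pipeline order is: exclude proteins with total peptide count
below 5 (strictly "fewer than", so a total of exactly 5 survives);
normalize each pulldown by its peptide sum (columns then sum to 1 over
retained proteins); compute per-protein Z-scores across *all* experiments
(row-wise, sample s.d. with $n-1$; a per-experiment option exists but the
natural reading of "a Z-score for each protein" is row-wise); score each
protein as mean experimental Z minus mean control Z; pass when the score
strictly exceeds 0.5. Enrichment is a difference, not a ratio — Z-scores
are already on a common standardized scale, and a ratio of signed values
is ill-behaved near zero.

Replicates, when averaged for display, are averaged on *counts* before
normalization (averaging Z-scores instead would weight experiments with
different peptide depths equally and is not what "total peptides ...
normalized by total number of peptides" describes). The heatmap row
clustering is plain Euclidean k-means on Z-score rows, seeded, with up to
100 restarts; the cluster count is a user parameter (default 4) because no
principled value is dictated by the scoring model.

## What the synthetic generator emulates

`gen_zscore_table()` draws 10-mers within 3 mismatches of the consensus
with log-normal Z-scores (median ~4, s.d. of logs 0.65): most entries
weak, a minority above the strong boundary, mimicking the right-skewed
shape of measured affinity spectra. Two benchmark entries are always
present: GGGAAATTCC at Z = 14 (strong A-centric reference) and GGGAAGTTCC
at Z = 5.8 (weak G-centric reference).

`gen_peak_cohort()` plants, per 1001-bp region: one strong site at the
center (random strand) and 2-8 weak sites (uniform count) with centers
uniform within ±75 bp of the anchor — a 150-bp cluster span, the width
such clusters and their open-chromatin context typically occupy. Defaults
chosen once and why:

* `span_bp = 150`: lower edge of the observed 150-200 bp cluster span.
* `n_weak_range = c(2, 8)`: strongly induced chemokine promoters carry
  roughly 8-13 weak sites across the full ±500 bp region; the cluster core
  holds a subset, and 8 non-overlapping 10-bp sites already approach the
  packing limit of a 150-bp span under random sequential placement.
* `background_gc = 0.45`: typical of murine promoter neighbourhoods.
* `alpha = 1`, `noise_sd = 5` Z-units: occupancy linear in planted
  cumulative Z with noise around 10-20% of a typical cluster total.

The chip score is `alpha * (planted cumulative Z at span_bp) + N(0, sd)`,
floored at zero — the simplest model supporting correlation-recovery
tests. Background sequences are i.i.d.; windows that *accidentally*
qualify for designation are tolerated and recorded as incidental sites
rather than rejected, because rejection sampling would bias the
background's dinucleotide content. All randomness flows from one seed
through named substreams (sequence, placement, noise, counts), so
regenerating one component never perturbs another.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: genomic background structure (repeats, CpG
islands, nucleosome positioning), read-level ChIP noise and peak-calling
artefacts, correlated site spacing from shared evolutionary origin, and
any nonlinearity between cluster affinity and occupancy. Recovery of a
planted linear signal demonstrates the estimator chain is correct, not
that real promoters behave linearly.

`gen_pulldown()` draws baseline counts Poisson with log-normal
protein-specific rates (median 10 peptides) and multiplies planted
proteins' rates by `effect_size` in experimental columns only. Note one
consequence of compositional normalization: strong planted enrichment
depresses every other protein's normalized share in experimental columns,
which sharpens the separation between planted and background proteins.

## Numerical choices and degenerate inputs

* Windows containing N emit nothing (both strands); sequences shorter than
  10 bp or an empty table yield an empty site list, not an error.
* Pearson r is `stats::cor`; the correlation-curve implementation is
  cross-checked in the tests against a from-sums textbook computation at
  1e-12 relative tolerance.
* The pooled t-test is `stats::t.test(var.equal = TRUE)` except in the
  zero-variance degeneracies noted above, which `t.test` refuses.
* Weak-site placement resamples collisions up to 1000 times and then
  fails with guidance rather than silently packing fewer sites.
* Manifest files contain parameters, seed and MD5 checksums but no
  timestamps, so identical runs are byte-identical.

## Problem sizes used in validation

The test suite exercises: brute-force scanner equivalence on 200 random
sequence/table instances (sequences to 2 kb); cumulative-Z monotonicity on
1000 generated peaks; correlation-span recovery on 20 cohorts of 100 peaks
(noise s.d. set to half the mean planted cumulative Z); ranked-halves
power and empirical size on 20 + 20 cohorts of 60 peaks; exact recovery of
5 planted proteins among 50 at 20-fold effect; and byte-identical
end-to-end reruns. These sizes give stable means across seeds while
keeping the full suite under a couple of minutes on one core.

## Known limitations

* The Z-score table is the sole affinity authority; no PWM or energy-model
  scoring, and no de-novo motif discovery.
* ChIP scores are taken as given; no tag-window quantification or
  normalization across experiments is attempted.
* Gene-to-peak assignment is assumed done upstream (regions arrive with
  identifiers); TSS-proximity assignment across a genome annotation is out
  of scope.
* The occupancy module describes a single site at equilibrium; it does not
  model cooperative occupancy of a cluster, which is precisely the open
  mechanistic question the cumulative-score analysis is designed to probe,
  not answer.
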