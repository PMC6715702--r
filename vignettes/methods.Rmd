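---
title: "Methods: correlation-network analysis of brain morphometry cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation-network analysis of brain morphometry cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`morphnet` treats each MRI scan as a point in a P-dimensional morphometry
space and asks which scans look alike *as whole profiles*. The analysis has
four statistical components, each with explicit assumptions:

**1. Normalization.** Raw measurements confound anatomy with body size,
head conformation and patient positioning. Each registered parameter
carries one normalization class: division by total brain volume (mm³; for
intracranial compartments), by body weight (kg; allometric control for
whole-head measures), by head angle (degrees; positioning control), or
none. The assumption is proportionality — e.g. that compartment size scales
linearly with total brain volume across the cohort. Division (rather than
residualization) is what the field's morphometric literature uses and keeps
every value interpretable as a ratio. Ventricle height is deliberately
*not* kept numeric: most patients measure exactly 0 mm, so the distribution
is a point mass plus a tail; it is binned into septal-integrity categories
(0 intact; (0,3) minor; [3,6) moderate; [6,10) severe; ≥ 10 mm absent) and
used as an annotation instead. The boundary values 3, 6, 10 mm are assigned
to the more severe bin: the category edges are otherwise open on both
sides, and a consistent half-open convention is the only deterministic
choice; which side the original analysis used is unknowable from the
published bins.

**2. Median-centering.** Parameter magnitudes span seven orders
(10⁻⁵-scale ratios to thousands of mm³/kg). Without rescaling, profile
correlations would be driven entirely by the largest parameter.
"Median-centering" is ambiguous between dividing by and subtracting the
per-parameter cohort median; we default to **division** (every parameter's
median becomes 1) because the purpose is to equalize the *magnitude of
variation* between parameters, which subtraction cannot do — a subtracted
matrix still has mm³-scale variance next to ratio-scale variance.
Subtraction is available (`mode = "difference"`) for sensitivity analysis.
One caution the test suite makes explicit: subtracting a per-parameter
median is **not** an affine shift of a scan's profile (each coordinate
moves by a different amount), so scan-by-scan Pearson correlations are *not*
invariant to difference-centering, even though parameter-by-parameter
correlations are. The two centering modes genuinely produce different
networks; the default is part of the method definition, not a cosmetic
choice.

**3. The correlation network.** Pearson r between scan profiles, edges kept
where r strictly exceeds the threshold (default 0.7). Scans with no
surviving edge are excluded from the graph but tracked. The threshold is a
user decision; `threshold_scan()` tabulates node/edge counts over a grid
and `suggest_threshold()` encodes the heuristic "largest threshold that
still retains ≥ 95 % of the maximal node count" — maximum nodes, minimum
edges. The node and edge counts are provably non-increasing in the
threshold (property-tested). Scans whose *centered* profile is constant
have undefined correlations and are excluded with a warning rather than
imputed.

**4. Markov clustering.** Canonical MCL on the weighted adjacency matrix:
self-loops are added (default: each node's maximum incident edge weight,
which stabilizes attractors on weighted graphs; unit loops available),
columns are normalized to a stochastic matrix, then the loop *expand*
(matrix power, default 2) → *inflate* (entry-wise power 2.2, column
renormalization) → *prune* runs until successive matrices differ by less
than 10⁻⁸ in max-norm or 200 iterations pass (non-convergence yields a
flagged, still-valid partition). Pruning zeroes entries below 10⁻⁶ *after*
inflation only, always keeping each column's maximum so no column empties.
Clusters are read from the converged matrix with a documented
interpretation: attractors are nodes with diagonal mass above ε = 10⁻⁴;
attractors directly linked above ε share a system; a node joins the system
of any attractor holding ≥ ε of its column. A node supported by several
systems (an MCL overlap) is assigned to the larger system, ties broken by
the lexicographically smallest member id — deterministic and
order-independent. Clusters smaller than 3 members join the unclustered
set, as do graph-excluded scans. A naive dense implementation
(`naive_mcl_oracle`, loops, no pruning, independent code) exists solely so
tests can prove the optimized path changes nothing: on 100+ random and
planted graphs the two partitions are identical.

The inflation default 2.2 and minimum cluster size 3 are the granularity
settings the pipeline is designed around. The original network tool's
self-loop, pruning and overlap conventions are undocumented, so exact
cluster-count reproduction of any particular published network is treated
as a soft target: the statistics are reported (`study_network_statistics`)
but not asserted.

**5. Enrichment and risk.** For a cluster of n scans in an annotated
population of N, a descriptor held by K scans overall and k in the cluster
is scored with the one-sided hypergeometric upper tail P(X ≥ k) — Fisher's
exact test for over-representation. Under-representation is deliberately
untested. P-values are adjusted per category family, Benjamini–Hochberg by
default (Bonferroni by option) — the original analysis's adjustment is
unstated, so both conventions are exposed rather than guessed. Rows with
k < 3 stay in the table flagged `reported = FALSE`, mirroring the minimum
cluster size. `co_enrich()` forms label intersections (e.g. breed × age)
and reuses the same machinery. Odds ratios use the cross-product with a
Haldane–Anscombe 0.5 correction only when a cell is zero; the two-sided
Fisher p sums hypergeometric probabilities of all margin-fixed tables no
more probable than the observed one (the classical definition, matching
`fisher.test` and a full-enumeration oracle to 10⁻¹²). CIs default to
Woolf's log-OR normal interval; the conditional-exact interval is
delegated to `stats::fisher.test`. Neither is claimed to reproduce any
particular published interval, since published intervals rarely state
their method or raw counts.

## The synthetic cohort: what it does and does not emulate

`generate_cohort()` draws, per scan: a breed (20-breed panel with lognormal
weights, breed-typical CFR, and a dominant morphometric archetype), sex and
neuter status (female 50 %, of whom 66 % neutered → neutered-female
fraction ≈ 0.33), an age (lognormal, tilted old for the aged-brain
archetype and young for the immature one), an archetype from the breed's
mixture (dominant weight 0.8; 0.9 for the planted boxer/aged-brain link;
neutered females have 40 % of their mixture mass moved to aged-brain), a
normalized profile (archetype mean + Gaussian noise), and a tumour outcome
from a logistic model on sex × neuter status.

Key construction choices:

* **Within-archetype correlation is the stated dial.** The noise sd is
  derived from the target correlation (default 0.95) via
  sd² = Var(m)/E[m²] · (1−r)/r for archetype multiplier vector m, so "the
  within-archetype r ≈ 0.95 world" is what the defaults generate.
* **Archetype separation is designed, not tuned.** The six multiplier
  vectors (aged-brain, brachycephalic-ventriculomegaly,
  cerebellar-compression, immature-large-brain, dolichocephalic-narrow,
  mesocephalic-compact) were constructed so pairwise correlations stay ≤
  0.58 — below the 0.7 edge threshold — because two archetypes whose mean
  profiles correlate above the threshold would merge by construction, and
  the generator is supposed to emit *resolvable* structure.
* **Raw measurements are emitted by inverting the normalization**, so
  preprocessing is genuinely exercised; the round trip recovers the drawn
  profiles to ~10⁻¹³ relative error (tested).
* **Allometry.** Total brain volume is tilted by (weight/20 kg)^(b−1) with
  b = 0.9, making the brain-volume and body-weight denominators genuinely
  distinct. Real interbreed allometry is steeper (b ≈ 0.5–0.6), but a
  steep tilt would inject weight-driven variance into one coordinate of
  the *normalized* profile and contradict the stated within-archetype
  correlation; 0.9 keeps the tilt subordinate to the archetype signal. This
  is a limitation of realism, chosen once and documented.
* **The programmed odds ratio is marginal by design.** Tumour odds depend
  only on sex and neuter status (entire female baseline 4.6 %, neutered
  females × 13.5, males × 7.5), *not* on archetype, so the
  neutered-vs-entire female 2×2 table estimates exactly the programmed OR
  and CI coverage is interpretable. The aged-brain ↔ neutered-female link
  is purely morphometric; any cluster-tumour enrichment arises indirectly
  through demographics, as in real data.

What a green test therefore establishes: the pipeline recovers planted
block structure of the stated strength, its exact tests are exact, its null
behaviour is calibrated, and its CI procedure covers a known truth. What it
does not establish: that any real cohort has archetypes this clean, that
breed effects are this modular, or that the published cluster counts of any
study would be reproduced — real data have measurement error, observer
effects, repeat scans and continuous (non-archetypal) variation the
generator does not model.

## Numerical and scale choices

* Convergence: max-norm, 10⁻⁸; interpretation ε 10⁻⁴; prune 10⁻⁶ with
  column-max retention. The oracle shares these documented conventions but
  no code.
* Degenerate inputs: zero/negative normalizers abort with the offending
  scan names; scans missing any retained parameter are dropped with a
  warning (pairwise-complete correlation is intentionally not used, to keep
  the correlation matrix well-defined and runs reproducible); a zero median
  aborts ratio-centering by parameter name; empty groups are skipped in
  enrichment with a warning; 2×2 tables with an empty margin are rejected.
* Null calibration runs 200 single-archetype cohorts of **160** scans
  (not the full 286): under the null the network is near-empty and the
  quantity of interest — false-positive rates — does not depend on cohort
  scale, while 200 full-pipeline runs must fit a CI runtime budget. The
  scale was fixed before the calibration was first run.
* CI-coverage runs use 441 scans, the scale at which cohort-level risk
  tables of this kind are typically assembled (a referral caseload
  including follow-up scans).

## Known limitations

* Craniofacial rule (iii) — cohort-level cut-offs without a CFR — is not
  algorithmic; such scans stay `unassigned` unless the category is supplied
  in metadata.
* Repeat scans of one patient remain separate nodes (patient ids are
  carried for users who wish to deduplicate).
* MCL cluster structure at inflation values far from 2.2, alternative
  similarity measures (Spearman, cosine), imputation, and visualization are
  out of scope.
* The 24-parameter panel is user-extensible via the registry; the default
  registry covers the 17 parameters named in the measurement protocol and
  treats additional ventricle-prefixed parameters as brain-volume
  normalized.
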