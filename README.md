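# morphnet

Correlation-network analysis of patient-level brain morphometry profiles.

Veterinary (and comparative) neuroimaging cohorts are heterogeneous: skull
conformation, body size, age, sex and neuter status all shape brain
morphometry, and no single group comparison captures how these factors
interact. `morphnet` implements a data-driven alternative: treat every MRI
scan as a node, connect scans whose *whole morphometry profiles* correlate
strongly, cluster the resulting graph, and then ask which clinical
descriptors are statistically over-represented in each cluster.

The pipeline:

1. **Normalization** — compartment measurements (brain length, cerebellar
   volume/diameter, interthalamic adhesion height, corpus callosum
   thickness, ventricular volume) are divided by total brain volume;
   whole-head measurements (cranial length, brain width, total brain
   volume, sulcus depth) by body weight (allometric control); positioning-
   sensitive measurements (cerebellar compression length/index, obex
   position) by head angle. Corpus callosum angle is untouched; head angle
   is dropped; ventricle height is categorized into septal integrity
   (intact / minor / moderate / severe / absent) instead of entering the
   matrix. Each parameter is then median-centered (default: divided by its
   cohort median) so parameters of very different magnitude contribute
   comparably.
2. **Network** — Pearson correlation *r* between every pair of scan
   profiles; edges kept where *r* > 0.7 (strict), with a threshold-scan
   diagnostic for choosing the cut-off.
3. **Clustering** — Markov clustering (MCL) of the weighted graph,
   inflation 2.2, minimum cluster size 3, implemented from scratch with a
   naive dense oracle for verification.
4. **Enrichment** — for each cluster and each categorical descriptor
   (breed, breed group, craniofacial category, age category, sex/neuter
   status, septal integrity, diagnostic class, clade), the one-sided
   hypergeometric tail `P(X >= k)` with Benjamini–Hochberg adjustment per
   category; rows with fewer than 3 observed members are flagged
   unreported.
5. **Risk** — odds ratios from 2×2 exposure × outcome tables
   (Haldane–Anscombe corrected when needed), two-sided Fisher exact
   p-values, Woolf or conditional-exact confidence intervals, and relative
   risk.

Clinical categorizations follow the field's conventions: craniofacial ratio
CFR = muzzle length / cranial length, with brachycephalic ≤ 0.52 <
mesocephalic < 0.67 ≤ dolichocephalic; age bins Immature (< 2 y), Young
adult [2, 4), Middle-aged [4, 8), Mature [8, 10), Geriatric (≥ 10 y).

Because clinical cohorts cannot be bundled, the package ships a
**synthetic-cohort generator**: 6 morphometric archetypes (including an
"aged-brain" motif — small normalized brain width/volume with
ventriculomegaly), 20 breeds with lognormal weights and breed-typical CFRs,
a neutered-female tilt toward the aged-brain archetype, and a programmed
neuter-status × tumour odds ratio (default 13.5). The generator inverts the
normalization rules to emit *raw* measurements, so the whole pipeline is
exercised end-to-end, and ships recovery metrics (adjusted Rand index,
enrichment detection, CI coverage).

## Worked example

```r
library(morphnet)

sim <- generate_cohort(synthetic_config(n_scans = 250), seed = 42)
res <- analyze_cohort(sim$cohort)          # r > 0.7, MCL inflation 2.2
res$network
#> <corr_network> r > 0.7: 250 nodes, 6373 edges, 0 excluded scans
res$partition
#> <cluster_partition> 6 clusters (250 scans), 0 unclustered

truth <- setNames(sim$truth$archetype, sim$truth$scan_id)
ids <- c(unlist(res$partition$clusters), res$partition$unclustered)
adjusted_rand_index(res$partition, truth[ids])
#> [1] 1

enr <- res$enrichment
subset(enr, descriptor == "boxer" & reported,
       c(group, observed, expected, p_value, adjusted_p))
#>        group observed expected      p_value   adjusted_p
#> 2 cluster_01       16     5.78 1.417865e-07 3.402875e-06
```

All 250 scans form a 6373-edge network, MCL recovers the six planted
archetypes exactly (ARI = 1), and the planted boxer / aged-brain
association surfaces as a strong cluster-one breed enrichment (16 boxers
observed where 5.8 were expected, BH-adjusted p = 3.4 × 10⁻⁶).

Risk statistics work directly on 2×2 counts:

```r
odds_ratio(contingency_2x2(10, 10, 10, 10))
#> $or 1, $ci_low 0.29…, $ci_high 3.45…, $p_value 1
```

## Command line

```sh
inst/cli/morphnet simulate --out sim --seed 3 --n 250
inst/cli/morphnet run --cohort sim/cohort.tsv --out results
inst/cli/morphnet risk --table 8,30,2,41 --ci woolf
```

`run` writes the centered matrix, edge list + GraphML, threshold-scan
diagnostic, partition, enrichment and risk tables, a JSON run manifest
with per-stage counts, and a plain-text summary.

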