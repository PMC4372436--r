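---
title: "Methods: phylodiversity assessment of bioregional communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylodiversity assessment of bioregional communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bioregdiv)
```

This vignette is the package's own account of the models and procedures it
implements, the conventions it fixes where the field's software disagrees,
and the limits of what its synthetic-data tests demonstrate.

## The setting

The unit of analysis is a *bio-subregion*: a mapped biogeographic unit with
a presence/absence list of (here, rainforest plant) taxa. The evolutionary
information comes from a rooted, dated, ultrametric phylogeny (chronogram)
covering the regional species pool, with branch lengths in time units. All
diversity quantities are functions of the chronogram's branch lengths and
the incidence matrix; abundances enter only through the family-composition
rollup (counts of taxa per family per site).

## Alpha diversity

**Faith's PD** of a taxon set is the total branch length of the minimal
spanning subtree. The package uses the *rooted* convention: the path from
the set's MRCA back to the tree root is included, so PD of a single taxon
equals the tree height and PD of the full pool equals the total branch
length. This matches the dominant convention of the community-phylogenetics
software lineage (e.g. `picante::pd` with `include.root = TRUE`, validated
in the test suite). `faith_pd(..., include_root = FALSE)` gives the unrooted
alternative.

**MPD** is the mean patristic distance over all unordered pairs in a
community; **MNTD** the mean distance from each member to its nearest
co-occurring relative. Both are undefined below two taxa and returned as
missing with a warning rather than an error, so depauperate sites survive a
tabulation.

### The sample-pool null and the sign of NRI/NTI

Standardized effect sizes compare an observed MPD or MNTD to null
communities drawn uniformly at random, without replacement and at equal
richness, from the pool of all taxa occurring in at least one site. With 999
randomizations,

    z = (observed − null mean) / null sd
    p = 2 · min(r, n+1−r) / (n+1),

where r is the mid-rank of the observed value among observed plus nulls
(two-tailed). The package reports **NRI = z(MPD)** and **NTI = z(MNTD)**
with positive values meaning *evenness* (members more distant than chance)
and negative meaning *clustering*. This is the orientation in which the
refugium signature is positive; most textbook definitions multiply by −1,
so comparisons with other software must flip signs. The choice is
deliberate and surfaces in every docstring that touches the indices.

Degenerate case: a site equal to the whole pool has null sd 0; z is
reported missing with a `degenerate` flag instead of propagating NaN.

Reproducibility: each site's null stream is seeded by a stable string hash
of its id folded into the master seed, so adding or reordering sites never
changes another site's z. This is why two runs of the pipeline with the same
seed are byte-identical.

The null machinery is calibrated, not assumed: at 1000 uniform-random sites
× 999 randomizations the acceptance suite requires mean z within ±0.1 of 0,
4–6 % of |z| ≥ 1.96, and rank p-values uniform on their achievable grid
(Kolmogorov–Smirnov at α = 0.01). These sizes run in well under a minute and
give standard errors small enough to make the bands meaningful.

## Beta diversity

- **Dpw** averages patristic distance over *all* cross pairs, including
  shared taxa at distance 0 (the `comdist` convention, cross-checked against
  picante). The site-vs-itself value of this formula is the site's MPD; the
  stored matrix keeps a zero diagonal and reports within-site MPD as an
  attribute.
- **Dnn** symmetrizes the two directed mean nearest-neighbour distances by
  averaging. An alternative convention pools all nearest-neighbour
  distances before averaging; the two agree at equal richness (the picante
  cross-check uses equal-richness sites for exactly this reason). Averaging
  was chosen because it weights both communities equally regardless of size.
- **Unweighted UniFrac** classifies each edge by whether it lies on the
  rooted spanning set of either community: U = (length unique to A + unique
  to B) / (length of the union). The identity
  U = (PD(A) + PD(B) − 2·PD_shared) / PD(A∪B) is asserted in tests. The
  "Bray–Curtis-type PD dissimilarity" reported by some pipelines is
  interpreted here as this unweighted UniFrac on presence/absence spanning
  sets; no printed value can arbitrate between that and PhyloSor-style
  variants without the underlying data, so the convention is documented
  rather than inferred.
- **Bray–Curtis** in binary mode is the Sørensen complement
  1 − 2|A∩B|/(|A|+|B|); in count mode Σ|x−y|/Σ(x+y) (used for family
  composition). Regional Ecosystem composition reuses binary mode on a
  site × RE incidence table.

## Ordination

NMDS minimizes Kruskal stress-1 between configuration distances and a
monotone regression of the input dissimilarities (primary tie treatment).
The optimization is `vegan::metaMDS`'s global NMDS over `n_starts = 20`
random starts (`max_iter = 500` per start); the best configuration is then
centred, rotated to principal axes, and reflected so the first non-zero
coordinate on each axis is positive — a deterministic orientation, since an
NMDS configuration is otherwise only defined up to rotation and reflection.
Defaults were chosen for robustness at the ≤ 20-site problems this package
targets. A k-dimensional fit needs at least k + 2 sites; all-equal
dissimilarity inputs are flagged as degenerate (any configuration of equal
distances fits them).

## Matrix and attribute correlation

The RELATE-style Mantel statistic is the Spearman correlation of
corresponding upper-triangle entries. The null permutes the ids of the
second matrix only (rows and columns jointly) and the test is one-tailed
for positive association, p = (#{null ρ ≥ observed} + 1)/(n_perm + 1).
`exact = TRUE` enumerates all n! relabelings instead (p = #{ρ ≥ obs}/n!,
identity included), which the tests compare against an independent
enumeration at n = 5.

Spearman correlations use average ranks; p-values are exact by permutation
enumeration for n ≤ 9 and use the t approximation above that. Bonferroni
adjustment is `min(1, m·p)` with m the number of tests in the same family.
The attribute suite runs every diversity × attribute pair twice — on all
sites and with a configured exclusion list removed — because a handful of
depauperate outlying sites can dominate rank patterns; missing attribute
values (a real feature of such tables) are dropped pairwise.

The PD–richness scaling is an ordinary least squares fit of log₁₀(PD) on
log₁₀(SR). Base 10 is fixed: the slope is base-invariant but the intercept
is not, and only base 10 is consistent with the published intercept on the
packaged tables.

## Tree dating ("MPL-lite")

`mpl_ultrametricize` converts a phylogram into a calibrated ultrametric
tree. Node ages are estimated bottom-up as the mean over children of (child
age + child branch length); calibrated nodes (MRCA of a labelled pair, plus
a mandatory root age) are pinned exactly, intermediate nodes are rescaled
linearly between their nearest calibrated ancestor and the oldest calibrated
node below them (or the leaves at age 0), and any remaining age reversal is
clamped to the parent's age. Full path-length dating programs additionally
smooth rate deviations using reference-node statistics; that machinery is
deliberately not reproduced — the routine exists to obtain a usable
chronogram, and conflicting calibrations (a descendant older than its
ancestor) are an error, not something to smooth over.

## The synthetic study system

The generator exists so every stage is testable without any sequence data.
It emulates three things:

1. **The chronogram**: a birth–death tree conditioned on the number of
   extant taxa (`ape::rphylo`), ultrametric by construction. Defaults in the
   analysis scripts (150 taxa, birth 1, death 0.3, 18 sites with richness
   spanning depauperate to rich) mirror the scale of a regional flora
   assessment — a pool of a few hundred taxa and ~18 subregions — reduced
   ~5× so the full battery runs in seconds.
2. **Community assembly** at a fixed richness per site:
   - *random* — uniform draws from the pool;
   - *clustered* — a uniformly chosen anchor leaf plus draws weighted by
     exp(−strength · d(leaf, anchor)/tree height), the standard exponential
     attraction kernel in patristic distance;
   - *overdispersed* — iterative max–min selection (each step adds the leaf
     farthest from the chosen set), applied with probability
     1 − exp(−strength) per step and uniform otherwise.

   The strength parameterization is chosen so that strength = 0 reduces
   *every* scenario exactly to random (a scale-type kernel parameter would
   instead blow up at 0), and the default strength 5 makes the kernel and
   the max–min rule nearly deterministic: at that default, clustered sites
   recover negative z(MPD) and overdispersed positive with ≥ 95 % sign
   consistency over 200 sites in the acceptance battery.
3. **Attribute tables**: a Gaussian rank copula couples the
   remnant-rainforest percentage of subregion area to PD at a target
   Spearman ρ (using the bivariate-normal identity r = 2 sin(πρ/6)); the
   remaining fields are filled by consistent arithmetic (remnant ≤
   preclearing ≤ total area, percentages recomputed from hectares), so
   generated tables always pass the consistency checker. Hectare fields are
   kept real-valued: rounding them would perturb rank ties and break the
   exact ρ = 1 case.

What passing these tests shows — and does not. The generator produces
equal-richness, independently assembled sites on a clean chronogram. Real
subregional data have spatially autocorrelated composition, richness varying
over two orders of magnitude, imperfect sampling, and a chronogram with its
own reconstruction and dating error. The tests therefore validate the
*machinery* (metrics, nulls, estimators, determinism), not the ecological
interpretation of any particular dataset.

## Packaged reference tables

The published subregional summary tables (18 subregions plus a pooled Total
row) ship as plain CSVs and anchor the reproduction tests: the PD~SR
regression (slope 0.7069, intercept 2.5016, R² 0.9985), the derived extent
percentages, the 86 % sampling coverage of the 870-species flora, and the
47 % remnant-weighted protection coverage are all recomputed from these
tables at test time. Two printed cells deserve note: row 11_22's
remnant-percent-of-subregion (3.32) is inconsistent with its own hectare
fields (1.08) — the consistency checker flags it, and a unit test asserts
that it is the *only* such cell — and the Total row's "% Rem RF" (336.5)
appears to be a misprint of 36.5; region-level quantities are therefore
always recomputed from the row data rather than read from the Total row.

## Conservation report

The report operationalizes two narrative priorities — keep what is diverse,
and keep what is distinctive — as explicit, configurable rules: a site is
flagged when its PD rank is in the top third *and* less than 17 % of its
remnant rainforest is in protected areas (17 % echoing the international
area-based conservation target; the threshold is a parameter).
Distinctiveness is each site's mean UniFrac distance to all others. The
regional summary is the remnant-area-weighted mean of per-site protection
percentages. These rules are this package's operationalization, not a claim
about any published priority rule.

## Known limitations

- The sample-pool null is the only implemented randomization; swap-based
  nulls that preserve richness *and* taxon frequencies are out of scope.
- MPD/MNTD and their effect sizes are presence/absence only.
- MPL-lite is not a substitute for model-based dating when rates vary
  strongly among lineages.
- NMDS at very small n (≤ 6 sites) routinely reaches near-zero stress;
  stress values there carry little information and should not be compared
  across datasets.
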