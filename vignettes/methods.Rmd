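---
title: "Methods: distance- and character-based barcode species delimitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance- and character-based barcode species delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## Scope and data model

The package analyzes a pre-aligned set of DNA barcode (COI) sequences joined
to specimen records (species label, ingroup/outgroup role). It performs no
alignment itself and no sequence retrieval: inputs are a FASTA alignment and
a TSV table, or the output of the built-in simulator.

Characters are divided into two classes. `A`, `C`, `G`, `T` are *determined*;
everything else — gaps (`-`), `N`, `?`, and all IUPAC ambiguity codes
(`R,Y,S,W,K,M,B,D,H,V`) — is *missing* for every computation. Treating
ambiguity codes as missing rather than partial matches is deliberately
conservative: a `Y` could match either `C` or `T`, so letting it support a
distance of 0 or veto a diagnostic would manufacture certainty the chromatogram
did not provide. In practice the missing data in barcode studies are
unsequenced leading/trailing runs, which is exactly what the simulator
emulates. Input is case-folded and `U` is accepted as `T` so RNA-styled
public-database records parse.

Site indices are 1-based alignment columns in every user-facing report.

## p-distances and the summary table

For two rows, the p-distance is computed under pairwise deletion: the
*overlap* is the number of sites determined in both, and the distance is the
fraction of those that differ. A pair with zero overlap has an undefined
distance, carried as `NA` in the matrix and excluded from summaries with a
reported count — propagating `NA` into a species mean would let a single
fragmentary sequence erase an otherwise well-sampled summary row.

Per species, the intraspecific set is all unordered within-species pairs and
the interspecific set all pairs against other in-scope species; each set is
summarized as Min / Max / Mean ± SD. Two choices here were genuinely open:

* **SD is the sample standard deviation** (n−1) of the set of pairwise
  distances, not a bootstrap standard error of the mean. Both appear in
  published tables under "± SD"; the sample SD is what the column name says
  and needs no resampling convention.
* **A single-pair set reports SD = 0**, not `NA`, with the pair count
  (`n_intra_pairs`, `n_inter_pairs`) carried alongside so the degeneracy is
  visible. Intra fields are `NA` exactly when a species has a single
  specimen, which keeps the table shape uniform.

Distances are stored as proportions; reports can render ×100 with the
`percent` flag, since the field mixes both conventions.

## Neighbor joining, bootstrap, monophyly

The tree is classical Saitou–Nei neighbor joining on the p-distance matrix:
join the pair minimizing Q(i,j) = (r−2)·d(i,j) − R(i) − R(j), with the
standard two-point branch-length formulas. Numerical choices:

* **Ties in Q are broken by the smallest (row, column) pair in the current
  working order.** This makes results deterministic, which the bootstrap
  and all tests rely on. A consequence worth knowing: when two sequences are
  identical (common at low intraspecific divergence) their join order is a
  genuine tie, so tip input order can change the arrangement *within* such a
  zero-distance cluster — never across it.
* **Negative branch lengths are retained by default.** They are legitimate
  NJ arithmetic on non-additive input and most distance software reports
  them. `clamp_negative = TRUE` maps each negative edge to zero and
  transfers the deficit to the adjacent edge from the same join, preserving
  path lengths through the new node — the common cosmetic alternative.
* On an additive matrix the output path-length matrix reproduces the input
  (verified to 1e-9 in tests against exhaustive topology enumeration for 4-5
  taxa and random generating trees up to 10).
* A matrix with an undefined entry, or fewer than 3 tips, is rejected up
  front with a specific error.

Bootstrap supports resample alignment *columns* with replacement, recompute
the p-distance matrix and NJ tree, and report for each internal edge of the
full-data tree the percentage of replicates containing the same bipartition
(canonicalized against a fixed reference tip, so comparison is rooting- and
order-independent). A resample can leave a fragmentary pair with zero
overlap; such replicates are redrawn, counted, and capped at ten times the
replicate count — beyond that the data are too fragmentary for column
resampling to be meaningful, and the run stops with an error rather than
silently reporting supports from a biased subset. The replicate count
defaults to 1000, the customary choice; the seed is an explicit argument and
the whole computation is reproducible from (input, replicates, seed).

A species is monophyletic iff the bipartition (its tips | the rest) occurs in
the tree; its support is that edge's bootstrap percentage. Single-specimen
species are trivially monophyletic with support `NA`. The monophyly of the
ingroup as a whole against the outgroups is reported as an extra row
(`<ingroup>`), since that is the split a reader checks first when outgroups
are present.

## Site statistics and pure diagnostics

A site is *variable* with ≥2 determined states, and *parsimony-informative*
with ≥2 states each carried by ≥2 sequences; missing symbols never count as
states.

A site is a **pure diagnostic** for a focal species when (a) all determined
focal bases at the site equal one state, with at least `min_observed` of them
(default 1), and (b) no other species in the comparison universe carries that
state there. Species wholly missing at the site impose no constraint — they
cannot contradict what was never observed — and are shown as `-` in the
matrix view. Two defaults were open calls:

* `min_observed = 1` lets single-specimen species own diagnostics, matching
  how such species are treated in practice; fixation observed once is weak
  evidence, which is why the threshold is exposed rather than hard-coded.
* The comparison universe defaults to **ingroup species only**. Outgroups
  anchor the tree but are not candidates for delimitation; a flag widens the
  universe to all species for users who want outgroup-proof diagnostics.

The detector is vectorized over per-species × per-site state counts and is
tested for exact agreement with a naive per-site, per-species reference
implementation on random alignments with random missing masks.

## The synthetic generator

`simulate_barcodes()` produces datasets with full ground truth: (1) a uniform
random root sequence; (2) per species, Binomial(L, `inter_sub`) substitutions
from the root (uniform over the three alternative bases) giving the species
haplotype; (3) `planted_diagnostics` disjoint sites per species where the
owner carries a non-root state and all other species keep the root state;
(4) per specimen, Binomial(L, `intra_sub`) substitutions from its haplotype,
never touching any planted site; (5) with probability `missing_end_prob`, a
uniform-length terminal run (≤ `missing_end_max` sites) replaced by `-`;
(6) outgroups drawn as in step 2 at `outgroup_sub`.

Defaults are fixed at the regime of a real barcode study of a close species
group: 10 species with 1–9 specimens (44 sequences), L = 664 sites,
`intra_sub` = 0.005 (realized intraspecific distances mostly < 1%, maxima
around 2–3%), `inter_sub` = 0.05 (interspecific distances ≈ 8–13%), 3 planted
diagnostics per species, `missing_end_prob` = 0.2 with runs up to 60 sites,
and 2 outgroups at `outgroup_sub` = 0.15.

Shielding *all* planted sites from within-species mutation (step 4) is what
makes recovery tests exact: a comparator specimen mutating into the focal
state at a planted site would break purity by chance, conflating detector
correctness with simulation noise. Outgroups get no such shielding; they are
outside the default purity universe.

Expected distances have a closed form. A mutation round at rate *r* has
transition matrix (1 − 4r/3)·I + (r/3)·J, so independent rounds compose by
multiplying their (1 − 4r/3) factors, and two sequences separated by rounds
r₁…r_m differ at a site with probability ¾·(1 − Π(1 − 4rᵢ/3)). For two
conspecific specimens (rates p, p) this is 2p(1−p) + ⅔p², i.e. 0.00997 at
p = 0.005 — the collision term ⅔p² is the probability both specimens were hit
and drew the same target base. `expected_distance()` implements these forms
and is verified by Monte-Carlo (100 simulated pairs, agreement within 3
standard errors).

What the generator does **not** emulate: a shared genealogy (species
haplotypes radiate independently from one root, a star phylogeny — so the
*ingroup* need not be monophyletic against outgroups, and deep hierarchical
structure within the ingroup is absent), rate heterogeneity across sites,
transition/transversion bias, indels (missing data are terminal runs only),
and intraspecific haplotype structure. Tests passing on synthetic data
therefore demonstrate the correctness of the computations and the detector's
behaviour under the stated regime — not robustness to model violations in
real COI data.

## Problem sizes and runtime choices

The test suite runs the oracle comparisons at 100 random alignments per
engine (n ≤ 10, L ≤ 80), exhaustive topology enumeration at 4–5 taxa,
planted-diagnostic recovery over 20 generator seeds at the full default
scale (46 × 664), and the bootstrap-regime check at 100 replicates; the whole
suite completes in well under a minute on one core. The acceptance script
uses 1000 bootstrap replicates at the default scale. These sizes were chosen
so the distributional claims (barcode-gap frequency ≥ 95% of seeds, species
clade supports ≥ 95) are stable across seeds while the scripts remain quick
to re-run.

## Known limitations

* p-distance only; no model-corrected distances (JC69, K2P), though the
  distance layer is the single place they would slot in.
* NJ only; no likelihood or Bayesian tree inference, and no tree figures
  beyond Newick plus a basic `plot()` method.
* The purity rule is the strict "pure" criterion; "private" characters
  (fixed in the focal species but shared with some other species) are not
  reported, and no minimal diagnostic-combination search is attempted.
* Monophyly is read from the NJ topology; near-zero internal edges are
  taken at face value rather than collapsed.
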