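# barcodegap

Distance- and character-based species delimitation from aligned DNA barcode
(COI) sequences.

## The problem

DNA barcoding delimits closely related animal species from a short
mitochondrial COI fragment (~660 bp) using two complementary lines of
evidence:

1. **The barcode gap.** The *p*-distance between two aligned sequences is the
   proportion of sites at which they differ, computed under *pairwise
   deletion* — only sites determined in both sequences count:

   *p* = (# differing sites among shared determined sites) / (# shared determined sites)

   Within a species, *p* is typically below 1–3%; between species in the same
   group it is typically 3–13%. When the largest intraspecific distance is
   smaller than the smallest interspecific distance, the "gap" supports the
   species boundaries. The package summarizes, per species, the intra- and
   interspecific distance sets as Min / Max / Mean ± SD (sample SD over the
   set of pairwise distances; NA for single-specimen species).

2. **Tree support and monophyly.** A neighbor-joining tree (Saitou–Nei
   Q-criterion agglomeration on the p-distance matrix) is built and each
   internal edge is given a column-bootstrap support: the percentage of trees
   from site-resampled replicates containing the same bipartition. A species
   is monophyletic when the bipartition (its sequences | all others) occurs
   in the tree.

3. **Pure diagnostic characters.** A site is a *pure diagnostic* for a
   species when every determined base that species carries there is one fixed
   state and no other species in the comparison set carries that state at
   that site. This is the character-based (CAOS-style "pure" characters)
   delimitation criterion; it works even for species represented by a single
   specimen.

The package also ships a seeded synthetic barcode generator that plants known
diagnostic sites and known divergence levels, so every stage of the pipeline
is testable with full ground truth and no sequence downloads.

## Worked example

```r
library(barcodegap)

# a COI-like dataset: 10 species x 1-9 specimens, 664 sites, 2 outgroups,
# 3 planted diagnostic sites per species
sim <- simulate_barcodes(barcode_sim_config(seed = 11))
fit <- delimit_species(sim$aln, replicates = 50, seed = 11)
fit
```

```
Barcode species delimitation
  alignment: 46 sequences x 664 sites (449 variable, 259 parsimony-informative)
  species:   10 in scope (ingroup_only)
  barcode gap: max intra 0.0219 < min inter 0.0769 (gap present)
  monophyly: 10/10 species monophyletic (50 bootstrap replicates)
  diagnostics: 274 pure diagnostic site(s)
```

Every species is recovered as a clade, the largest within-species distance
(2.2%) sits well below the smallest between-species distance (7.7%), and the
detector finds all 30 planted diagnostics (plus fixed differences that arose
from the random divergence itself). `summary(fit)` prints the per-species
Min/Max/Mean ± SD table, the monophyly report with bootstrap percentages, and
the per-species diagnostic counts; `plot(fit)` draws the tree with supports.

File-based workflows use the same machinery:

```r
run_analysis("alignment.fasta", "metadata.tsv", "out/",
             replicates = 1000, seed = 42)
```

which writes `distances.tsv`, `summary.tsv`, `tree.nwk`, `monophyly.tsv`,
`diagnostics.tsv`, `matrix.tsv`, `sitestats.json` and a provenance
`run_log.json`. A command-line wrapper with `run` and `simulate` subcommands
is installed at `inst/cli/barcodegap.R`.

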