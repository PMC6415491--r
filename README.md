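# teclusterkit

Tools for analysing **recurrent transposable element (TE) insertions in gene
promoter regions** across large panels of strains — the situation found for
the *roo* family in the promoter of the *Drosophila melanogaster* stress
response gene *CG18446*, where repeated, independent insertions accumulate at
one locus while the rest of the genome shows no comparable cluster.

The package is aimed at population genomicists working with per-strain TE
insertion calls (from PCR screens or short-read callers that report a
coordinate range per insertion) who want to ask: *is this locus a genuine
insertional cluster, how do its alleles behave across populations, and are
the insertions independent events?*

## What it computes

**Canonical sites and cluster scanning.** Callers report a coordinate range,
so each call is reduced to its midpoint, `floor((start + end - 1) / 2)` of
the 0-based half-open interval. Midpoints within 5 bp are chain-merged into
one canonical site (transitive merging of sorted midpoints), and sites are
counted in non-overlapping 1-kb windows anchored at coordinate 0; windows
with ≥ 7 sites are called as candidate clusters. Promoter regions are the
strand-aware 1 kb upstream of the TSS unioned with the 5'UTR, and a promoter
is a recurrence candidate when insertions are found there in ≥ 3 strains.

**Population summaries.** Allele frequencies use diploid counting,
*f* = (2·hom + het) / (2·strains), with failed genotypings excluded from
denominators; plus occupancy (populations per insertion), private
insertions, expected double-insertion genotype frequency (the product
*f*<sub>a</sub>·*f*<sub>b</sub> for insertions on different haplotypes, with
a Hardy–Weinberg 2ab alternative), Pearson latitude correlations and
Fisher-exact climate associations.

**TSD detection.** The target site duplication of an insertion is recovered
from an occupied/empty allele pair via longest common prefix *p* and suffix
*s*: the TSD length is *t* = *p* + *s* − |empty|, and the reassembly
prefix + TSD + element + TSD + suffix reproduces the occupied allele
exactly. Consensus matrices report per-column base frequencies and
information content IC = 2 + Σ *f* log₂ *f* bits; identical element copies
are grouped as transposition-burst candidates.

**Detection power.** For a screen of *n* strains drawn from *N* screened
strains, the expected number of distinct insertions detected is
Σ<sub>i</sub> [1 − C(N−c<sub>i</sub>, n)/C(N, n)] for carrier counts
c<sub>i</sub>, checked against a seeded Monte-Carlo subsampler.

**Synthetic data.** `simulate_dataset()` generates a complete ground-truthed
screen (GFF3 genes, BED calls, genotype TSV, population TSV, occupied/empty
FASTA pairs, truth JSON) with a planted promoter cluster, so every stage is
testable without downloads.

## Worked example

```r
library(teclusterkit)

# the packaged 15-population PCR screen summary
catalog <- table1_to_catalog(load_table1_fixture())
distinct_insertions(catalog)
#> [1] 20
occupancy(catalog)[c("roo-90", "roo-68")]
#> roo-90 roo-68
#>     13      9
private_insertions(catalog)
#> [1] "roo-393" "roo-56" "roo+192" "roo+278" "roo+37" "roo+7" "roo+7_rev"

# would screening 10 strains reveal a cluster like this one?
pe <- mean_distinct_subsample(synthetic_dgrp_carrier_map(),
                              n = 10, trials = 1000, seed = 17)
c(mc_mean = pe$mean_distinct, exact = round(pe$exact_expectation, 3))
#> mc_mean   exact
#>   3.635   3.687

# TSD detection from an occupied/empty allele pair
rec <- detect_tsd("AAACGTGGGGCGTTT", "AAACGTTT")
rec[c("tsd_sequence", "tsd_length", "inserted_sequence")]
#> $tsd_sequence  "CGT"   $tsd_length  3   $inserted_sequence  "GGGG"
```

The 20 distinct insertions, 13/15 and 9/15 population occupancies and 7
private insertions summarise the multi-population catalogue; the subsample
expectation of ≈ 3.7 (rounding to 4) distinct insertions per 10-strain
screen is what justifies small validation screens for cluster candidates.

A thin command-line wrapper is available at `inst/scripts/teclusterkit`
(`convert`, `scan`, `power`, `simulate` subcommands).

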