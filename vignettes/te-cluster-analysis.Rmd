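---
title: "Detecting and characterising recurrent TE insertion clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterising recurrent TE insertion clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teclusterkit)
```

## The problem

Transposable element (TE) callers applied to panels of resequenced strains
produce per-strain insertion calls; PCR screens of natural populations
produce per-strain presence/absence genotypes. Occasionally many distinct
insertions of one TE family pile up in a single gene promoter — the pattern
seen for *roo* solo-LTRs upstream of a stress-response gene in
*D. melanogaster*. Deciding whether such a pile-up is a genuine insertional
cluster requires several coordinated analyses: normalising imprecise call
coordinates to canonical sites, scanning for windows and promoters with
unusually many sites, summarising allele frequencies across populations,
showing by target-site-duplication (TSD) evidence that the insertions are
independent events, and checking that a small validation screen has enough
power to notice a cluster at all. `teclusterkit` implements that pipeline.

## Coordinates and canonical sites

All internal coordinates are 0-based half-open; BED input is native, GFF3
and 1-based-inclusive caller ranges are converted at the boundary
(`start - 1`, end unchanged). A single convention avoids off-by-one drift
between modules.

Range-reporting callers do not give the exact insertion point, so the
canonical site of a call is the **midpoint** of its range. For a half-open
interval \[start, end) we take the floor of the median of the inclusive
span, `floor((start + end - 1) / 2)` — a symmetric, dialect-independent
choice (the convention is silent on rounding; tests pin this semantics).

Calls within **5 bp** of each other are the same insertion. We implement
this as *transitive chain merging* of sorted midpoints (consecutive gap
≤ tolerance joins the run), not as fixed 5-bp bins: bins would split true
duplicate observations straddling a bin edge. A run 10, 15, 20 therefore
merges into one site even though its extremes are 10 bp apart; the
union-find oracle in the test suite fixes this as the intended semantics.
The site position is the floor-median of member midpoints, which always
lies within the range of member midpoints, and collapse is idempotent and
monotone in the tolerance.

## Window scan and promoter recurrence

Genome-wide scanning counts merged sites in non-overlapping 1-kb tiles
anchored at coordinate 0 on each arm (the source analysis is silent on
anchoring; fixed tiles are the simplest reproducible choice, and
`sliding_max_count()` is provided as a sensitivity check). Windows with at
least 7 sites are called as cluster candidates, ordered by (chrom, start)
so ties are deterministic.

A **promoter region** is the strand-aware 1-kb window upstream of the TSS —
\[tss − 1000, tss) on `+`, \[tss + 1, tss + 1001) on `-` — unioned with the
gene's 5'UTR intervals and clipped at contig bounds. The alternative
reading "less than 1 kb from a gene" (which could include downstream
proximity) is not implemented; the explicit upstream ∪ 5'UTR definition is
used throughout. Promoter recurrence counts, per promoter, the strains
with at least one call inside it and the distinct sites after collapse;
promoters with ≥ 3 supporting strains are reported and those with ≥ 2
distinct sites flagged as multi-insertion (cluster) candidates. Merging
happens across strains before counting — the alternative (count first,
merge later) would double-count a site observed in many strains.

## Population summaries

Allele frequencies use standard diploid counting,
$f = (2\,\mathrm{hom} + \mathrm{het}) / (2\,n_\mathrm{strains})$, with
failed genotypings excluded from every denominator (they stay in the files
for provenance). The global frequency is therefore the strain-count-weighted
combination of population frequencies.

The expected fraction of flies carrying two focal insertions on different
haplotypes defaults to the **product** of the two allele frequencies, the
rule used in the source screen; a Hardy–Weinberg trans-heterozygote mode
(2ab, exactly twice the product) is exposed for comparison rather than
silently substituted, since the factor-of-two question is a genuine
ambiguity in the screen's stated rule.

Latitude association uses the Pearson correlation with the two-sided
t-test (n − 2 df). The climate test in the source work is unnamed; we use a
two-sided **Fisher exact test** on the 2×2 table (focal climate class vs
pooled others) × (carrier vs non-carrier), appropriate for the small strain
counts involved. The printed climate p-values are consequently not treated
as reference values. No multiple-testing correction is applied by default
(none was applied in the source analysis); `climate_association_scan()`
offers Benjamini–Hochberg.

## TSD detection

For an occupied/empty allele pair, let $p$ be the longest common prefix
length and $s$ the longest common suffix length (capped so $p + s$ does not
exceed the occupied length). The TSD length is $t = p + s - |\mathrm{empty}|$;
$t \le 0$ means the insertion created no duplication. The record stores the
duplicated sequence, the insertion point and the inserted element, and the
reassembly prefix + TSD + inserted + TSD + suffix reproduces the occupied
allele exactly — a property tested on every synthetic pair. One can show
$t$ is the *maximum* over all valid (cut point, TSD length) decompositions,
which is what the exhaustive oracle in the tests enumerates. When element
ends coincidentally match flanking sequence, $t$ over-extends; records with
$t$ beyond `max_tsd` (default 20) are flagged `ambiguous` rather than
truncated, preserving both boundary candidates for manual review.

Consensus matrices drop sequences that differ from the modal length
(mirroring the removal of shorter detected duplications before logo
building; ties resolve to the longer length), then report per-column base
frequencies and information content $IC_j = 2 + \sum_b f_{bj}\log_2 f_{bj}$
bits with **no small-sample correction** — the matrix carries $n$ so users
can correct downstream. Motif scanning delegates IUPAC-degenerate matching
to `Biostrings::matchPattern`. Identical-copy grouping is exact string
identity after uppercasing; alignment and tree inference are out of scope
and delegated to external tools, with `pairwise_substitutions()` counting
differing non-gap columns of pre-aligned pairs.

## Detection power of a small screen

Whether 10 strains suffice to notice a cluster is answered two ways. The
Monte-Carlo route draws `trials` subsamples of $n$ strains without
replacement (sampling *with* replacement would not match choosing strains
for a PCR screen) and counts distinct insertions carried; heterozygous
strains count as carriers because a presence/absence screen calls presence,
not dosage. The closed form
$E = \sum_i \left[1 - \binom{N - c_i}{n}\big/\binom{N}{n}\right]$
is attached to every estimate, and the two agree within Monte-Carlo error
by construction of the estimator (property-tested at 10,000 trials, and
against full subset enumeration for all $N \le 8$, $n \le 4$).

The per-strain genotype calls behind the original DGRP subsampling are not
redistributable, so the package ships
`synthetic_dgrp_carrier_map()` — explicitly synthetic — at the scale the
published summary prints for the DGRP population: 49 screened strains, 36
homozygous carriers each with exactly one of the 8 listed insertions.
Carrier counts follow a geometric rank-abundance series (ratio 1/2, every
insertion in at least one strain → counts 17, 9, 4, 2, 1, 1, 1, 1), the
canonical shape of TE insertion frequency spectra in which a couple of
insertions are common and the rest rare. Its closed-form expectation for
10-strain subsamples is 3.69, rounding to the published average of four.

## The synthetic-data generator

`simulate_dataset()` emulates the study design: 15 populations with the
strain counts of the packaged screen table (257 strains total,
representative latitudes and climate classes for the named collection
sites), a scaled-down genome of three 150-kb contigs with 30 genes (2-kb
bodies, 200-bp 5'UTRs, placed deterministically, random strand), one
planted promoter cluster of five distinct sites ≥ 12 bp apart with allele
frequencies 16.5 %, 6.3 %, 2 %, 2 %, 1 % (the two common frequencies match
the screen's two most common insertions), genotypes drawn per strain under
Hardy–Weinberg within population, and a Poisson background of scattered
calls at 5 × 10⁻⁴ insertions/kb/strain — the genome-wide density of de novo
roo calls in large panels (≈ 12,700 calls over 177 strains and ~137 Mb).
Carrier strains emit a coordinate-range call whose midpoint jitters by at
most ±2 bp, so 5-bp collapse reunites observations of one site while
≥ 12-bp site spacing keeps distinct sites separate. Allele pairs are built
as flank + TSD + 428-bp element + TSD + flank and re-drawn until TSD
detection recovers the planted duplication exactly, which guarantees
repeat-free flank boundaries for the oracle tests. Everything is a
deterministic function of the seed; emitted files are byte-identical across
runs.

What the generator does *not* emulate: sequence divergence between element
copies, read-level noise or caller false positives/negatives, linkage
between insertions, and population structure beyond independent
Hardy–Weinberg draws. Passing tests on synthetic data therefore show the
pipeline's algorithms are correct under the stated model, not that a real
caller's error profile is handled.

## Numerical and degenerate-input choices

Problem sizes in the tests are kept small deliberately (call sets of tens
to hundreds, one 12,745-call scan, 500-strain frequency checks, 10,000-trial
Monte-Carlo runs) — large enough to exercise the asymptotics the properties
rely on while keeping the suite quick to run. Empty call sets, empty
catalogues and all-absent genotype tables return empty/zero results rather
than erroring; zero-variance correlations, all-failed genotype scopes,
all-zero contingency tables and oversize subsamples error with messages
naming the problem. Cluster and recurrence rankings break ties by
(chrom, start) lexicographic order for determinism. Monte-Carlo functions
require an explicit seed and restore the caller's RNG state on exit.

## Known limitations

- The 5-bp chain merge can, in pathological dense data, chain distant calls
  through intermediates; the genome-wide density of real call sets makes
  this rare, and the tolerance is exposed.
- Fixed 1-kb tiles can split a cluster across a window boundary; use
  `sliding_max_count()` to check sensitivity.
- TSD detection assumes a single insertion differentiates the pair; tandem
  or nested events produce `ambiguous` flags, not resolved boundaries.
- The climate test conditions on observed carrier totals; with very few
  strains per class its power is limited, which is intrinsic to the design,
  not the implementation.
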