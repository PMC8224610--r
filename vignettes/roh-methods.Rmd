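---
title: "Detecting runs of homozygosity: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting runs of homozygosity: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

## The problem

When two copies of a chromosomal segment descend from a single recent
ancestor, the individual is autozygous there and a SNP array sees an
uninterrupted run of homozygous genotypes. The summed length of such
runs, relative to the autosomal genome, estimates the realized
inbreeding coefficient (`F_ROH`) without any pedigree; the length
distribution dates the inbreeding (long runs: recent ancestors, since
recombination has had few meioses to break them; short runs: distant
ancestors); and genome positions where many individuals' runs pile up
("ROH islands") flag haplotypes driven toward fixation by selection or
shared demography. rohscan implements this whole chain for diploid
autosomal SNP-array data such as a caprine 50K panel.

## Quality control

Markers are filtered in a fixed order: non-autosomal or unplaced markers
first, then minor allele frequency (MAF), then call rate, then sample
missingness. Boundary semantics are deliberate and tested: MAF ≤ 0.02
and call rate ≤ 0.98 **remove** at the boundary, while sample
missingness > 5% keeps an individual at exactly 5%. Marker statistics
are computed once, on the cohort before sample removal, and are not
recomputed afterwards; the order of filters changes how removals are
attributed in the report but not which markers survive. MAF filtering
matters for ROH work because rare-allele markers are nearly always
homozygous and would inflate run calls.

## The detection model

A segment must satisfy, with the package defaults in parentheses:

| constraint | default | unit |
|---|---|---|
| minimum length | 2 | Mb |
| minimum SNPs spanned | 20 | SNPs |
| heterozygous calls allowed | 1 | calls |
| missing calls allowed | 1 | calls |
| minimum density | 1 per 100 | SNP/kb |
| maximum inter-SNP gap | 500 | kb |

These are the conventional medium-density settings: ~20 SNPs over 2 Mb
matches the information content of a 50K chip on a 2.45-Gb genome, the
single-heterozygote allowance absorbs one genotyping error per segment,
and the gap/density rules prevent a run from being declared across
regions the array does not actually interrogate. Coordinates are 1-based
inclusive throughout; segment length is `end − start + 1` bp; the
density check passes at exact equality; segments start and end on a
homozygous call so an allowed heterozygote can never inflate the
length.

### Run mode (default)

The published parameter sets in this field specify *constraints*, not an
algorithm. Run mode therefore solves the constraint problem exactly: it
reports all **maximal** valid intervals (not contained in any other
valid interval) and reduces overlapping candidates to a disjoint set,
longest first, ties to the leftmost. The implementation exploits that
the heterozygote budget, missing budget and gap ceiling are hereditary
(every sub-interval of a feasible window is feasible): a two-pointer
sweep yields the staircase of maximal feasible windows, within which the
maximal valid interval is found in constant time unless the density
bound bites, in which case an explicit per-start enumeration runs inside
that window only. The test suite holds this algorithm equal to an
independent brute-force enumeration over all O(n²) intervals on hundreds
of random instances with randomized constraint sets.

### Window mode

Window mode emulates the classic sliding-window scanner: 50-SNP windows
are flagged homozygous when they contain at most one heterozygous and
one missing call; each SNP's hit fraction is the share of flagged
windows among those overlapping it; stretches of SNPs with fraction
≥ 0.05 are split at oversized gaps, trimmed to homozygous end SNPs, and
filtered on length, SNP count and density. Window size and hit-fraction
threshold are that scanner's defaults, not values fixed by the
constraint set, and both are configurable.

Two documented consequences of the window formulation: the
heterozygote/missing allowances act **per window**, not per final
segment (a final stretch almost always absorbs one flanking heterozygote
on each side, so a run-level cap of one would discard nearly every real
segment); and runs spanning fewer SNPs than the window cannot be
detected at all, because every window covering them also covers
heterozygote-rich flanks. On clean data the two modes agree closely for
runs well above the window size — a simulation cross-check in the tests
bounds the boundary disagreement at a few SNPs — but run mode is the
default precisely because its output is defined by the constraints
alone.

## Summary statistics

`F_ROH = L_ROH / L_aut` with `L_aut` defaulting to 2,450 Mb of autosome
(configurable, or computable from the map span). Individuals without any
ROH stay in every denominator: the mean segment count per population is
`TN_ROH / n` including them, which is what reproduces the published
style of summary tables. The average segment length `AL_ROH` is reported
two ways, pooled over all of a population's segments (default,
reconstructible from totals) and as the mean of per-carrier averages,
because the field's usual wording ("per individual and per population")
is ambiguous between them. Length classes are left-open/right-closed —
(2, 4], (4, 8], (8, 16], (16, ∞) Mb — so a segment of exactly 4 Mb falls
in the lower class; per-class mean coverages are averaged over **all**
individuals (zeros included) and therefore add up exactly to the mean
total coverage.

## Islands

The incidence track counts, per SNP, the fraction of the pooled cohort
(all populations, the "meta-population") with a run covering that
position. The island threshold is the 99.9th percentile of this
distribution, computed with the linear-interpolation percentile
definition (`quantile` type 7; the convention had to be fixed since
percentile definitions differ); a fixed override is available because
analysts often round the realized threshold (e.g. to 0.16) for
reporting. Islands are maximal runs of at least two consecutive
at-or-above-threshold SNPs; no published minimum exists, so two SNPs is
the weakest defensible default and is configurable. Island length is
reported as `(end − start)/1e6` rounded to two decimals, matching the
arithmetic of printed island tables. Gene annotation takes any interval
overlapping the island by at least one base pair, in 1-based inclusive
coordinates (an interval starting at `end + 1` does not overlap); BED
input is converted from its 0-based half-open convention at the reader.

## Population structure

IBS similarity between two individuals is the mean shared-allele
fraction over markers typed in both (pairwise-complete handling of
missing data, chosen because listwise deletion would discard markers
for all pairs over a single bad call). The distance `1 − IBS` enters
classical (Torgerson) MDS: double-centred squared distances,
eigendecomposition, coordinates ordered by eigenvalue. Each axis is
oriented so its largest-magnitude coordinate is positive, making output
deterministic under reordering; negative eigenvalues (non-Euclidean
input) are truncated with a warning. Euclidean configurations are
recovered to 1e-9, which the tests assert.

## The simulator's stated world

`sim_config()` defaults describe the cohort the package is built
around: five populations of 48/32/59/16/22 individuals, 29 autosomes
summing to 2,450 Mb with exponentially decaying lengths (~148 Mb down
to ~42 Mb — plausible for a caprine karyotype; the true assembly lengths
are not part of the stated world), ~48,000 markers on a jittered grid,
ancestral allele frequencies uniform on [0.05, 0.5], and per-population
autozygosity targets of 0.009/0.097/0.108/0.125/0.012 — the regime
spanned by the five breeds that motivated the design.

Autozygosity is planted geometrically: non-overlapping intervals are
drawn until their summed length reaches the target fraction of the
genome, each length from a mixture of exponentials with mean
`100/(2g)` Mb parameterized by the generations `g` to the common
ancestor (default equal-weight mixture of `g = 3`, mean ~16.7 Mb, and
`g = 25`, mean 2 Mb, truncated to [0.5, 150] Mb) — direct control over
exactly the quantity `F_ROH` estimates, rather than a pedigree
simulation whose realized autozygosity would be random. The last drawn
segment may overshoot the target; the realized fraction is recorded in
the truth table and is the right comparator on small toy genomes.
Inside a planted interval genotypes are homozygous with the allele
drawn by its frequency; outside they are Hardy–Weinberg draws from
per-population frequencies differentiated by a Balding–Nichols model
(default Fst 0.05, a typical between-breed value, so that structure
analyses have signal). Genotyping error flips in-segment markers to
heterozygous (default 0.001, "sparse"), and missing calls are sprinkled
genome-wide (default 0.001).

What the generator does **not** emulate — and what a green test
therefore does not establish — includes linkage disequilibrium in the
background (markers are independent given the allele frequencies, so
the false-positive regime of real, LD-rich data is understated),
mutation inside autozygous tracts, and any realistic site-frequency
spectrum. It is a test harness for the caller and estimators, not a
population-genetic simulator; for LD-faithful data one would reach for
a coalescent simulator instead.

## Numerical conventions and degenerate inputs

Genotypes are coded 0/1/2 by alternate-allele count with `NA` for
missing; allele letters are dropped at import since only zygosity
matters downstream, and the alternate allele of a marker is its
ASCII-larger observed allele (for markers whose only calls are
alternate homozygotes this flips the immaterial labels; calls are
proven label-flip invariant in the tests). A marker with no non-missing
calls is removed by the call-rate rule without ever dividing by zero.
An all-heterozygous or all-missing individual yields an empty call set
but remains in the cohort denominators. Empty ROH sets propagate: the
incidence track is all zeros, summaries report zero counts, writers
emit header-only files.

## Known limitations

Binary BED/BIM/FAM input is not supported (text PED/MAP only); the X
chromosome is always excluded; genotype likelihoods are not modelled,
so low-confidence calls count like any other; and window mode inherits
the documented blind spot for runs shorter than its window. The
segment-level recovery statistics (sensitivity/precision at 90%
overlap) in `recovery_experiment()` treat the single best-overlapping
call as the match, so a planted segment recovered as two abutting calls
counts as missed — a conservative convention.
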