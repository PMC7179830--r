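---
title: "genocube: storage model, query semantics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{genocube: storage model, query semantics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The data model

`genocube` treats a cohort's variant calls as a sparse matrix with sample
rows and genomic-position columns. The column axis is the concatenation of
the contigs of a genome map: a (contig, 1-based position) pair flattens to a
0-based global column, and every conversion between the two conventions
happens in exactly two functions, `flatten_position()` and
`unflatten_position()`. Keeping a single conversion point is what prevents
off-by-one drift between the half-open column intervals used internally and
the 1-based inclusive coordinates of VCF and of user-facing regions.
Columns are stored as doubles, which represent integers exactly up to
2^53, so genomes longer than the 32-bit integer range are safe.

A **cell** is one sample's call at one site: genotype as a pair of allele
indices plus a phasing flag, the ref and alternate allele list of its source
record, optional depth and quality fields (DP, GQ, AD, PL), and the record's
rs-identifier when present. Multi-allelic records stay one cell per
(record, sample) with the full alternate list, matching the site-merged
query output; splitting per allele would force allele remapping at query
time, which is out of scope. A record carrying an INFO `END` (a deletion)
becomes an interval cell whose `col_end` exceeds its `col_start`.

## Partitioned, tiled storage

The column space `[0, L)` is split at import time into `n` static,
evenly sized partitions (default 1000): widths are `ceiling(L / n)` with a
short final partition. When `n` approaches `L` the ceiling rule exhausts the
columns early; trailing partitions are then empty but still contiguous, so
the tiling invariant (no gap, no overlap) holds for every valid `n`.
Equal-width partitioning ignores data density — variant density varies along
the genome, so partitions are unevenly loaded; density-balanced
partitioning would improve worker balance and is noted as future work.

Within a partition, cells are sorted by `(col_start, row)` and grouped into
**tiles** of at most `cells_per_tile` cells (default 1000), the unit of
compression and of index-based skipping. Tiles are serialized data frames,
compressed independently (deflate by default, "none" available), and
concatenated into segment files that roll over when the pre-compression byte
count passes `segment_size` (default 1 MiB). The byte layout is
package-defined; the knobs it honours are the observable surface. A
`size_per_column_partition` key is accepted in loader configuration for
compatibility and ignored — it has no observable semantics here. The tile
index records per-tile column bounds, so a read decompresses only
intersecting tiles; a debug flag disables skipping and the tests assert the
results are identical either way.

Sample rows are assigned in import order and recorded in a registry;
indices are stable and never reused, so appending a new batch of samples
(the accrual use case — up to a thousand new samples a week at the system
this design models) is a merge-rewrite that leaves existing row ids intact.

### Interval cells at partition boundaries

A cell belongs to the partition containing its `col_start`. A deletion may
reach past its partition's right edge; each partition records its maximum
**END overhang** (how far any of its cells reaches past `col_end`). At
planning time, a task whose first queried column could be covered by a
preceding partition's overhang sets a `probe_preceding` flag; at execution
the preceding partition is scanned for cells spanning into the task's range,
and probed cells whose start column is itself covered by another task of the
same query are dropped — so a boundary-spanning deletion is returned exactly
once, whether the query starts before, at, or after the boundary. Overhang
metadata bounds the look-back to one partition; an interval cell reaching
past the *next* partition's end is rejected at import. This keeps the probe
cheap and the invariant local. (The alternative — materializing anchor
copies of spanning cells in later partitions — would duplicate data and
complicate conservation counts.)

## Query execution

`plan_query()` merges overlapping input regions (keeping tasks pairwise
column-disjoint), intersects them with the partition table, and emits one
task per (interval × partition). `execute_query()` runs tasks on a worker
pool (`parallel::mclapply`), retries a failed task once, then fails the
query with the underlying error. Gathered cells merge by column into
site records: cells sharing (column, ref, alt list) form one site with all
per-sample calls; a differing alt list at the same column is a separate site
— allele harmonization is deliberately not attempted. Because gathering is
by task order and merging sorts by `(column, ref, alt)`, output is
byte-identical for any worker count and completion order; the tests assert
this metamorphically. "Number of variants" counts merged site records, not
per-sample cells.

## Clinical joins and reports

The mapping registry is a flat table (`patient_id`, `sample_name`,
`consent`); a relational engine adds nothing at this scale, and the loader
isolates the schema so one could be substituted. `resolve_rows()` never
drops a patient silently: every input id lands in the included set or in an
excluded table with a reason (`not in mapping`, `no consent`, `no sample`).
A patient with several sequenced samples contributes every row to reports —
each call counted once per sample — a documented choice where conventions
differ.

Patient sets use a deliberately minimal XML dialect (patients with `id`;
observations with `patient_id`, `concept_code`, `concept_label`, `value`;
schema in `inst/extdata/patient_set.xsd`) plus an equivalent TSV path, so
the clinical side is testable without a deployed cohort service. Subgroups
formed by `group_patients()` are *not* forced disjoint: a patient on two
medications appears under both codes, because the distribution report is a
per-subgroup conditional tally, not a partition of patients; patients with
no matching concept form `"(none)"`, and the union of subgroups is always
the full set.

Genotypes classify totally: any missing allele → `nocall`; `0/0` →
`homref`; equal non-reference alleles → `homvar`; otherwise `het` (`1/2`
included). For both reports, an included row with no cell at a queried site
is `nocall` (two nocall alleles in allele counts). On a fixed-panel assay
absence means "assayed, not called", so this is the default; the allele
count report exposes `absent_as_nocall = FALSE` for sparse (exome-like)
stores where absence merely means "not covered", and emits both raw and
called-only totals since conventions for displayed totals differ.

## The synthetic generator

`gen_cohort()` emulates the two data types the store is designed around, at
desk scale:

* **microarray mode** — one merged VCF over a fixed shared panel
  (`n_loci`, default 2000 — a scaled-down stand-in for the ~600k-locus
  arrays used in production settings), `FORMAT=GT` only, every site
  rs-identified;
* **wes mode** — per-sample VCFs, each sample carrying a
  Bernoulli(`site_rate`) subset of the candidate panel, full
  `GT:DP:GQ:AD:PL`, and a configured fraction of multi-base deletions
  carrying INFO `END`. Per-sample site presence is drawn against a shared
  candidate panel (rather than fully independent positions) so that
  cross-sample site overlap is nontrivial, which the site-merging code
  needs exercising on.

Per-site allele frequencies are drawn from Beta(0.5, 0.5) — a U-shaped
folded site-frequency spectrum, many rare and some common variants, which is
what an unselected panel looks like; genotypes are Hardy-Weinberg draws at
the site frequency, then masked to `./.` at the missingness rate (default
2%). The default toy genome (two contigs, 150 kb total) keeps the flatten /
partition arithmetic honest across a contig boundary while staying fast.
Consent (90%) and concept prevalence (30% per concept over 5 medication
codes) give realistic subgroup structure. One seed determines every output
byte; the generator saves and restores the session RNG state.

Deliberately absent from the generator: linkage disequilibrium and
haplotype structure, per-read error models, relatedness, population
stratification. Passing tests therefore demonstrate storage/query/report
correctness and scaling shape on realistic *marginal* distributions — they
say nothing about behavior under correlated genotypes, which none of the
implemented operations depend on. A `boundary_deletion` override injects
one deletion across a chosen partition boundary; by default deletions are
nudged to avoid crossing the 1000-way grid so the overhang path is exercised
only intentionally.

## Scaling benchmark

`run_scaling()` regenerates, imports and queries cohorts at increasing
sample counts and fits ordinary least squares on the log-log points. The
asserted metrics are deterministic proxies — total store bytes and cells
touched per query — because the linearity claim is about the scaling
*shape*; wall-clock import and query times are measured (queries repeated
five times and averaged) but reported only, never asserted: absolute times
on arbitrary hardware are not a meaningful acceptance surface. The test and
acceptance conditions use 50/100/200/400-sample cohorts on the 2000-locus
panel with 7 partitions — sizes chosen so the cell payload dominates the
store's fixed metadata (manifest, tile indexes, site dictionary), below
which a log-log slope on bytes is not informative. The benchmark regions
and sizes are this package's choice; the source system's region sizes were
not fully specified.

## Numerical and degenerate-input choices

* Ploidy is fixed at 2; any non-diploid GT is an import error (the four
  genotype classes presume diploidy). A bare `.` genotype is read as `./.`.
* Breakend alternate alleles are skipped with a counted warning (the
  genotype algebra is undefined for them); symbolic alts like `<NON_REF>`
  are kept verbatim.
* A duplicate call for one (sample, column) keeps the last occurrence and
  warns — imports are file-ordered, so "last" is well defined.
* Empty inputs are values, not errors: empty patient sets, empty row sets
  and regions without variants yield empty/zero reports.
* Report serialization sorts keys and fixes column order, so outputs are
  diffable; determinism is asserted end to end in the tests.
* rs-identifier collisions (same id, different position) fail fast at
  dictionary build, listing both sites.

## Known limitations

Local filesystem backend only (the paths go through one seam, but no
object-store backend is implemented); no concurrent writers, deletion or
compaction; no gVCF reference blocks, joint genotyping or annotation; gene
regions resolve through a user-supplied BED rather than an ontology service;
no statistical testing on report tables. The test-suite problem sizes
(dozens to hundreds of samples, thousands of loci) are the package's
intended desk scale — the design mirrors a system built for six orders of
magnitude more data, but this implementation's constant factors are R's.
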