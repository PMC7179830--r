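# genocube

A desk-scale columnar store and query engine for clinical-genomic cohort
exploration, written in R.

Genomic variant calls form a sparse two-dimensional matrix: samples on one
axis, genomic positions on the other, with cells holding each sample's call
(genotype, depth, quality) at a site. `genocube` persists this matrix as a
set of **vertically partitioned arrays**: the flattened genome column space
`[0, L)` is split into `n` evenly sized half-open ranges (1000 by default),
each stored as compressed tiles of at most 1000 cells with a per-tile column
index for skipping. Region queries are decomposed into one **query task per
intersected partition**, executed on a worker pool, and merged into
site-level records (one record per distinct column/ref/alt-list with all
per-sample calls) — a scatter-gather contract whose output is provably
independent of partition count, worker count and task order.

On top of the store sit the clinical joins a cohort-exploration frontend
needs:

* a **mapping registry** linking de-identified patient ids to sample rows
  with consent flags (`patient_id`, `sample_name`, `consent`);
* **patient sets** with clinical concept observations, read from a minimal
  XML dialect or a flat TSV;
* three **reports**: total allele counts per region, genotype distributions
  (homref / het / homvar / nocall) per position and clinical subgroup, and
  genomic-only cohorts from filters of the form
  `rs### (is | is not) (homref | homvar | het | nocall)`.

Diploid genotypes classify as: any missing allele → `nocall`; `0/0` →
`homref`; two equal non-reference alleles → `homvar`; anything else → `het`
(so `1/2` is heterozygous). A consented patient with no cell at a queried
site counts as `nocall` — on a fixed-panel assay, absence is informative.

A deterministic synthetic-cohort generator (microarray-like fixed panels
with `FORMAT=GT`, and exome-like sparse per-sample VCFs with
`GT:DP:GQ:AD:PL` and END-bearing deletions; genotypes drawn from
Hardy-Weinberg proportions at Beta-distributed allele frequencies) and a
scaling-benchmark harness complete the package.

## Worked example

```r
library(genocube)

td <- tempfile(); dir.create(td)
spec <- synth_spec(seed = 42, n_samples = 10, n_loci = 100,
                   genome = c(chr1 = 10000, chr2 = 5000))
man <- gen_cohort(spec, file.path(td, "cohort"))

res <- import_vcfs(man$files$vcf, man$genome, file.path(td, "store"),
                   loader_config(n_partitions = 7))
res$report
#> <import_report> 1 file(s), 10 sample(s), 100 record(s) -> 981 cell(s) in 3.13s
#>   skipped: missing_genotype=19
```

One hundred panel records over ten samples give 1000 potential cells; 19
genotypes were drawn missing (`./.`) and discarded, leaving 981. Query a
region and join the clinical side:

```r
h <- res$store
count_variants(h, data.frame(contig = "chr1", start = 1, end = 10000))
#> [1] 59

reg <- load_mapping(man$files$mapping)       # patient <-> sample + consent
ps  <- parse_patient_set(man$files$patient_set)
rep <- genotype_distribution_report(h, c("rs000001", "rs000002"),
                                    ps, "MED:", reg)
head(tibble::as_tibble(rep), 3)
#> # A tibble: 3 × 9
#>   position contig   pos subgroup homref   het homvar nocall n_samples
#>   <chr>    <chr>  <dbl> <chr>     <int> <int>  <int>  <int>     <int>
#> 1 rs000001 chr1      16 MED:01        0     0      4      0         4
#> 2 rs000001 chr1      16 MED:02        1     0      0      0         1
#> 3 rs000001 chr1      16 MED:03        0     0      2      0         2
```

Each row is one (position, clinical subgroup) pair; the four class counts
always sum to the subgroup's sample count. `tidy()` and `glance()` give long
tables and one-row summaries; `autoplot()` draws the stacked distributions.

```r
genomic_cohort(h, list("rs000001 is het"), reg)   # patients, not samples
#> [1] "P0004" "P0005"
allele_count_report(h, data.frame(contig = "chr1", start = 1, end = 10000))
```

The same operations are available from the shell via the thin launcher in
`exec/genocube`:

```sh
genocube simulate --spec spec.json -o data/
genocube import --genome data/genome.json -o store/ data/cohort.vcf
genocube report genotype-dist --store store/ --mapping data/mapping.tsv \
  --patient-set data/patient_set.xml --config query.json -o report.json
```

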