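Package: genocube
Title: Column-Partitioned Sparse Variant Store with Clinical-Genomic Reporting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale columnar store for genomic variant calls. VCF files are
    imported into a tiled, compressed, column-partitioned sparse sample-by-position
    matrix; region queries are decomposed into per-partition tasks executed on a
    worker pool and merged into site records. A mapping registry joins de-identified
    patient ids (with consent flags) to store rows, clinical patient sets are read
    from a minimal XML dialect or TSV, and three aggregate reports are computed over
    the joined data: allele counts by region, genotype distributions by clinical
    subgroup, and genotype-filter cohorts. Includes a deterministic synthetic cohort
    generator (microarray-like and exome-like) and a scaling benchmark harness that
    fits log-log slopes for storage size and query cost against sample count.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    xml2
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
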