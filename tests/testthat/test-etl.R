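test_that("two single-sample VCFs with three shared sites yield six cells", {
  td <- withr::local_tempdir()
  contigs <- c(chr1 = 1000, chr2 = 500)
  gm <- genome_map(contigs)
  recs <- rbind(
    make_record("chr1", 10, "A", "T", "0/1", id = "rs1"),
    make_record("chr1", 700, "G", "C", "1/1", id = "rs2"),
    make_record("chr2", 20, "T", "A", "0/0", id = "rs3")
  )
  v1 <- write_test_vcf(file.path(td, "a.vcf"), contigs, recs, "S_A")
  v2 <- write_test_vcf(file.path(td, "b.vcf"), contigs, recs, "S_B")
  res <- import_vcfs(c(v1, v2), gm, file.path(td, "store"),
                     loader_config(n_partitions = 3))
  expect_equal(res$report$n_cells, 6)
  expect_equal(sum(res$report$per_partition$n_cells), 6)
  expect_equal(res$store$samples$sample_name, c("S_A", "S_B"))
  expect_equal(res$store$samples$row, c(0L, 1L))
})

test_that("missing genotypes are discarded or kept per config", {
  td <- withr::local_tempdir()
  contigs <- c(chr1 = 1000)
  gm <- genome_map(contigs)
  recs <- rbind(
    make_record("chr1", 10, "A", "T", "0/1"),
    make_record("chr1", 20, "G", "C", "./."),
    make_record("chr1", 30, "T", "A", "1/1")
  )
  v <- write_test_vcf(file.path(td, "s.vcf"), contigs, recs, "S1")
  res <- import_vcfs(v, gm, file.path(td, "st1"),
                     loader_config(n_partitions = 2))
  expect_equal(res$report$n_cells, 2)
  expect_equal(res$report$skipped$n[res$report$skipped$reason == "missing_genotype"], 1L)

  res2 <- import_vcfs(v, gm, file.path(td, "st2"),
                      loader_config(n_partitions = 2,
                                    discard_missing_genotypes = FALSE))
  expect_equal(res2$report$n_cells, 3)
  cells <- read_partition(res2$store, 0, 0, 500)
  nocall <- cells[cells$col_start == 19, ]
  expect_true(is.na(nocall$a1) && is.na(nocall$a2))
})

test_that("a default import writes 1000 partitions", {
  td <- withr::local_tempdir()
  contigs <- c(chr1 = 2000, chr2 = 1000)
  gm <- genome_map(contigs)
  v <- write_test_vcf(file.path(td, "s.vcf"), contigs,
                      t(make_record("chr1", 10, "A", "T", "0/1")), "S1")
  res <- import_vcfs(v, gm, file.path(td, "store"))
  expect_equal(res$store$manifest$n_partitions, 1000)
  expect_equal(nrow(res$store$parts), 1000)
})

test_that("duplicate sample names across files are rejected", {
  td <- withr::local_tempdir()
  contigs <- c(chr1 = 100)
  gm <- genome_map(contigs)
  rec <- t(make_record("chr1", 10, "A", "T", "0/1"))
  v1 <- write_test_vcf(file.path(td, "a.vcf"), contigs, rec, "S1")
  v2 <- write_test_vcf(file.path(td, "b.vcf"), contigs, rec, "S1")
  expect_error(import_vcfs(c(v1, v2), gm, file.path(td, "store"),
                           loader_config(n_partitions = 1)),
               "duplicate sample names: S1")
})

test_that("cell count equals called (record, sample) pairs from a direct scan", {
  fx <- make_test_store(seed = 13, n_samples = 8, n_loci = 120,
                        missingness = 0.1)
  oracle <- oracle_scan(fx$manifest$files$vcf, fx$spec$genome)
  expect_equal(fx$report$n_cells, nrow(oracle))
  expect_equal(sum(fx$report$per_partition$n_cells), nrow(oracle))
})

test_that("imports are reproducible and independent of reader parallelism", {
  td <- withr::local_tempdir()
  spec <- synth_spec(seed = 17, n_samples = 6, n_loci = 80, mode = "wes",
                     genome = c(chr1 = 8000, chr2 = 4000))
  man <- gen_cohort(spec, file.path(td, "cohort"))
  cfgs <- list(loader_config(n_partitions = 4, parallel_readers = 1),
               loader_config(n_partitions = 4, parallel_readers = 4))
  outs <- purrr::imap(cfgs, function(cfg, i) {
    out <- file.path(td, paste0("store", i))
    import_vcfs(man$files$vcf, man$genome, out, cfg)
    out
  })
  for (f in c("partitions.json", "samples.tsv", "sites.tsv")) {
    expect_identical(readLines(file.path(outs[[1]], f)),
                     readLines(file.path(outs[[2]], f)))
  }
  region <- data.frame(contig = "chr1", start = 1, end = 8000)
  s1 <- query_regions(open_store(outs[[1]]), region)
  s2 <- query_regions(open_store(outs[[2]]), region)
  expect_equal(s1, s2)
})

test_that("END records become interval cells; multi-partition spans fail", {
  td <- withr::local_tempdir()
  contigs <- c(chr1 = 1000)
  gm <- genome_map(contigs)
  recs <- t(make_record("chr1", 96, "AAAAAAAAAA", "A", "0/1", info = "END=105"))
  v <- write_test_vcf(file.path(td, "del.vcf"), contigs, recs, "S1")
  res <- import_vcfs(v, gm, file.path(td, "store"),
                     loader_config(n_partitions = 10))
  cells <- read_partition(res$store, 0, 0, 100)
  expect_equal(cells$col_start, 95)
  expect_equal(cells$col_end, 104)
  expect_equal(res$store$parts$max_end_overhang[1], 5)

  # END reaching past the *next* partition is refused
  recs2 <- t(make_record("chr1", 96, paste(rep("A", 110), collapse = ""), "A",
                         "0/1", info = "END=205"))
  v2 <- write_test_vcf(file.path(td, "del2.vcf"), contigs, recs2, "S1")
  expect_error(import_vcfs(v2, gm, file.path(td, "store2"),
                           loader_config(n_partitions = 10)),
               "more than one partition boundary")

  # with intervals disabled the same record is a point cell
  res3 <- import_vcfs(v2, gm, file.path(td, "store3"),
                      loader_config(n_partitions = 10,
                                    treat_deletions_as_intervals = FALSE))
  expect_equal(read_partition(res3$store, 0, 0, 100)$col_end, 95)
})

test_that("breakend alternates are skipped with a count; symbolic alts kept", {
  td <- withr::local_tempdir()
  contigs <- c(chr1 = 1000)
  gm <- genome_map(contigs)
  recs <- rbind(
    make_record("chr1", 10, "A", "T", "0/1"),
    make_record("chr1", 20, "G", "G]chr1:500]", "0/1"),
    make_record("chr1", 30, "T", "<NON_REF>", "0/1")
  )
  v <- write_test_vcf(file.path(td, "b.vcf"), contigs, recs, "S1")
  res <- import_vcfs(v, gm, file.path(td, "store"),
                     loader_config(n_partitions = 1))
  expect_equal(res$report$n_cells, 2)
  expect_equal(res$report$skipped$n[res$report$skipped$reason == "breakend_alt"], 1L)
  cells <- read_partition(res$store, 0, 0, 1000)
  expect_true("<NON_REF>" %in% cells$alt)
})

test_that("non-diploid genotypes are an import error", {
  td <- withr::local_tempdir()
  contigs <- c(chr1 = 100)
  gm <- genome_map(contigs)
  v <- write_test_vcf(file.path(td, "h.vcf"), contigs,
                      t(make_record("chr1", 10, "A", "T", "1")), "S1")
  expect_error(import_vcfs(v, gm, file.path(td, "store"),
                           loader_config(n_partitions = 1)),
               "ploidy")
})

test_that("duplicate (sample, column) calls keep the last writer with a warning", {
  td <- withr::local_tempdir()
  contigs <- c(chr1 = 100)
  gm <- genome_map(contigs)
  recs <- rbind(
    make_record("chr1", 10, "A", "T", "0/1"),
    make_record("chr1", 10, "A", "T", "1/1")
  )
  v <- write_test_vcf(file.path(td, "d.vcf"), contigs, recs, "S1")
  expect_warning(
    res <- import_vcfs(v, gm, file.path(td, "store"),
                       loader_config(n_partitions = 1)),
    "last writer wins")
  cells <- read_partition(res$store, 0, 0, 100)
  expect_equal(nrow(cells), 1)
  expect_equal(c(cells$a1, cells$a2), c(1L, 1L))
})

test_that("append imports merge new samples into an existing store", {
  td <- withr::local_tempdir()
  contigs <- c(chr1 = 1000)
  gm <- genome_map(contigs)
  recs <- rbind(make_record("chr1", 10, "A", "T", "0/1", id = "rs1"),
                make_record("chr1", 600, "G", "C", "1/1", id = "rs2"))
  v1 <- write_test_vcf(file.path(td, "a.vcf"), contigs, recs, "S_A")
  v2 <- write_test_vcf(file.path(td, "b.vcf"), contigs, recs, "S_B")
  out <- file.path(td, "store")
  import_vcfs(v1, gm, out, loader_config(n_partitions = 2))
  expect_error(import_vcfs(v2, gm, out, loader_config(n_partitions = 2)),
               "already exists")
  res <- import_vcfs(v2, gm, out, loader_config(n_partitions = 2), append = TRUE)
  expect_equal(res$store$samples$sample_name, c("S_A", "S_B"))
  expect_equal(sum(res$store$parts$n_cells), 4)
  sites <- query_regions(res$store, data.frame(contig = "chr1", start = 1, end = 1000))
  expect_equal(sites$n_calls, c(2L, 2L))
})

test_that("the site dictionary resolves rs-identifiers and flags collisions", {
  td <- withr::local_tempdir()
  contigs <- c(chr17 = 50000000)
  gm <- genome_map(contigs)
  recs <- rbind(
    make_record("chr17", 41244936, "G", "A", "0/1", id = "rs16942"),
    make_record("chr17", 41244000, "T", "C", "0/1"),
    make_record("chr17", 41245237, "A", "G", "1/1", id = "rs1799966")
  )
  v <- write_test_vcf(file.path(td, "brca.vcf"), contigs, recs, "S1")
  dict <- build_site_dictionary(v, gm)
  hit <- lookup_site(dict, "rs16942")
  expect_equal(hit$contig, "chr17")
  expect_equal(hit$pos, 41244936)
  expect_equal(nrow(dict), 2)  # the "." record is absent
  expect_error(lookup_site(dict, "rs0"), "unknown identifier")

  recs2 <- rbind(
    make_record("chr17", 100, "G", "A", "0/1", id = "rsX"),
    make_record("chr17", 200, "T", "C", "0/1", id = "rsX")
  )
  v2 <- write_test_vcf(file.path(td, "clash.vcf"), contigs, recs2, "S1")
  expect_error(build_site_dictionary(v2), "collision.*rsX@chr17:100.*rsX@chr17:200")
})
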