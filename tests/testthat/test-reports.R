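import_hand_vcf <- function(td, recs, samples, contigs = c(chr1 = 1000),
                            n_partitions = 2) {
  gm <- genome_map(contigs)
  v <- write_test_vcf(file.path(td, "r.vcf"), contigs, recs, samples)
  import_vcfs(v, gm, file.path(td, "store"),
              loader_config(n_partitions = n_partitions))$store
}

test_that("allele counts tally ref/alt/nocall per site", {
  td <- withr::local_tempdir()
  h <- import_hand_vcf(td, t(make_record("chr1", 10, "A", "T",
                                         c("0/0", "0/1", "1/1", "./."))),
                       c("S1", "S2", "S3", "S4"))
  rep <- allele_count_report(h, data.frame(contig = "chr1", start = 1, end = 1000))
  expect_equal(nrow(rep$sites), 1)
  expect_equal(rep$sites$ref_count, 3L)
  expect_equal(rep$sites$alt_counts[[1]], 3L)
  # ./. discarded at import: 4 included rows, 3 with cells -> 2 nocall alleles
  expect_equal(rep$sites$nocall_count, 2L)
  expect_equal(rep$sites$raw_total, 2L * 4L)
  expect_equal(rep$regions$called_total, 6L)

  long <- tidy(rep)
  expect_equal(long$count[long$allele == "ref"], 3L)
})

test_that("multi-allelic sites tally each alternate separately", {
  td <- withr::local_tempdir()
  h <- import_hand_vcf(td, t(make_record("chr1", 10, "A", "T,G",
                                         c("0/1", "1/2", "2/2"))),
                       c("S1", "S2", "S3"))
  rep <- allele_count_report(h, data.frame(contig = "chr1", start = 1, end = 1000))
  expect_equal(rep$sites$ref_count, 1L)
  expect_equal(rep$sites$alt_counts[[1]], c(2L, 3L))
  expect_equal(rep$sites$nocall_count, 0L)
})

test_that("a region with no variants reports zeros, not an error", {
  td <- withr::local_tempdir()
  h <- import_hand_vcf(td, t(make_record("chr1", 10, "A", "T", "0/1")), "S1")
  rep <- allele_count_report(h, data.frame(contig = "chr1", start = 500, end = 900))
  expect_equal(nrow(rep$sites), 0)
  expect_equal(rep$regions$n_sites, 0L)
  expect_equal(rep$regions$raw_total, 0L)
  # empty row set is not an error either
  rep0 <- allele_count_report(h, data.frame(contig = "chr1", start = 1, end = 1000),
                              rows = integer())
  expect_equal(rep0$regions$called_total, 0L)
})

test_that("allele-count conservation holds on a randomized store", {
  fx <- make_test_store(seed = 43, n_samples = 9, n_loci = 120,
                        missingness = 0.15)
  rep <- allele_count_report(
    fx$store, data.frame(contig = c("chr1", "chr2"), start = c(1, 1),
                         end = c(10000, 5000)))
  n_rows <- nrow(fx$store$samples)
  expect_true(all(rep$sites$raw_total == 2L * n_rows))
  # cross-check against a direct scan of the generated VCF
  oracle <- oracle_scan(fx$manifest$files$vcf, fx$spec$genome)
  alleles <- unlist(strsplit(oracle$gt, "[/|]"))
  expect_equal(sum(rep$sites$ref_count), sum(alleles == "0"))
  expect_equal(sum(purrr::map_int(rep$sites$alt_counts, sum)),
               sum(alleles == "1"))
})

test_that("genotype distributions tally classes per subgroup", {
  td <- withr::local_tempdir()
  h <- import_hand_vcf(td, t(make_record("chr1", 10, "A", "T",
                                         c("0/0", "0/1", "1/1"), id = "rs1")),
                       c("S1", "S2", "S3"))
  reg <- load_mapping(data.frame(patient_id = c("pA", "pB", "pC"),
                                 sample_name = c("S1", "S2", "S3"),
                                 consent = TRUE))
  ps <- genocube:::new_patient_set(
    c("pA", "pB", "pC"),
    tibble::tibble(patient_id = c("pA", "pB", "pC", "pA"),
                   concept_code = c("MED:A", "MED:A", "MED:B", "MED:B"),
                   concept_label = "m", value = ""))
  rep <- genotype_distribution_report(h, "rs1", ps, "MED:", reg)
  a <- rep[rep$subgroup == "MED:A", ]
  b <- rep[rep$subgroup == "MED:B", ]
  expect_equal(c(a$homref, a$het, a$homvar, a$nocall), c(1, 1, 0, 0))
  # pA is in both subgroups and counted in both
  expect_equal(c(b$homref, b$het, b$homvar, b$nocall), c(1, 0, 1, 0))
  expect_equal(rep$homref + rep$het + rep$homvar + rep$nocall, rep$n_samples)
})

test_that("positions with no calls report everyone as nocall", {
  td <- withr::local_tempdir()
  h <- import_hand_vcf(td, t(make_record("chr1", 10, "A", "T",
                                         c("0/1", "0/1"), id = "rs1")),
                       c("S1", "S2"))
  reg <- load_mapping(data.frame(patient_id = c("pA", "pB"),
                                 sample_name = c("S1", "S2"), consent = TRUE))
  ps <- genocube:::new_patient_set(c("pA", "pB"),
                                   tibble::tibble(patient_id = character(),
                                                  concept_code = character(),
                                                  concept_label = character(),
                                                  value = character()))
  rep <- genotype_distribution_report(
    h, data.frame(contig = "chr1", pos = 500), ps, "MED:", reg)
  expect_equal(rep$subgroup, "(none)")
  expect_equal(rep$nocall, rep$n_samples)
})

test_that("distribution conservation holds on a randomized cohort", {
  fx <- make_test_store(seed = 47, n_samples = 14, n_loci = 100,
                        missingness = 0.2)
  reg <- load_mapping(fx$manifest$files$mapping)
  ps <- parse_patient_set(fx$manifest$files$patient_set)
  rep <- genotype_distribution_report(fx$store, fx$manifest$sites$id[1:5],
                                      ps, "MED:", reg)
  expect_true(all(rep$homref + rep$het + rep$homvar + rep$nocall == rep$n_samples))
  groups <- group_patients(ps, "MED:")
  inc <- resolve_rows(reg, fx$store, ps$patients)$included
  for (g in names(groups)) {
    expect_equal(unique(rep$n_samples[rep$subgroup == g]),
                 sum(inc$patient_id %in% groups[[g]]))
  }
})

test_that("genomic cohorts apply conjunctive genotype filters", {
  td <- withr::local_tempdir()
  recs <- rbind(
    make_record("chr1", 10, "A", "T", c("1/1", "0/1"), id = "rs1"),
    make_record("chr1", 20, "G", "C", c("0/0", "0/1"), id = "rs2")
  )
  h <- import_hand_vcf(td, recs, c("S1", "S2"))
  reg <- load_mapping(data.frame(patient_id = c("pA", "pB"),
                                 sample_name = c("S1", "S2"), consent = TRUE))
  expect_equal(genomic_cohort(h, list("rs1 is homvar"), reg), "pA")
  expect_equal(genomic_cohort(h, list("rs1 is het", "rs2 is het"), reg), "pB")
  # contradictory conjunction is empty
  expect_equal(genomic_cohort(h, list("rs1 is het", "rs1 is homref"), reg),
               character())
  # empty base patient set yields an empty cohort
  empty_ps <- genocube:::new_patient_set(character(),
                                         tibble::tibble(patient_id = character(),
                                                        concept_code = character(),
                                                        concept_label = character(),
                                                        value = character()))
  expect_equal(genomic_cohort(h, list("rs1 is homvar"), reg, base = empty_ps),
               character())
  expect_error(genomic_cohort(h, list(), reg), "at least one")
})

test_that("reports are invariant to partition count and worker count", {
  td <- withr::local_tempdir()
  spec <- synth_spec(seed = 53, n_samples = 8, n_loci = 120,
                     genome = c(chr1 = 10000, chr2 = 5000))
  man <- gen_cohort(spec, file.path(td, "cohort"))
  reg <- load_mapping(man$files$mapping)
  ps <- parse_patient_set(man$files$patient_set)
  regions <- data.frame(contig = "chr1", start = 1, end = 10000)

  reports <- purrr::map(c(1, 7, 100), function(np) {
    out <- file.path(td, paste0("store", np))
    h <- import_vcfs(man$files$vcf, man$genome, out,
                     loader_config(n_partitions = np))$store
    list(
      ac = allele_count_report(h, regions),
      gd = genotype_distribution_report(h, man$sites$id[1:3], ps, "MED:", reg),
      q1 = format_sites_tsv(query_regions(h, regions, workers = 1)),
      q8 = format_sites_tsv(query_regions(h, regions, workers = 8))
    )
  })
  for (i in 2:3) {
    expect_equal(reports[[i]]$ac, reports[[1]]$ac)
    expect_equal(reports[[i]]$gd, reports[[1]]$gd)
    expect_identical(reports[[i]]$q1, reports[[1]]$q1)
  }
  expect_identical(reports[[1]]$q8, reports[[1]]$q1)
})
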