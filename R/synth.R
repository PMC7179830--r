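#' Specification for a synthetic clinical-genomic cohort
#'
#' Describes a deterministic cohort: a toy genome, a panel of variant loci,
#' per-site allele frequencies drawn from a Beta distribution, diploid
#' genotypes drawn from Hardy-Weinberg proportions at each site's frequency,
#' and the clinical side (concept observations, consent flags, patient ids).
#' One seed fully determines every output byte.
#'
#' Two modes emulate the two data types the store was designed for:
#' `"microarray"` writes one merged VCF with a fixed shared locus panel and
#' `FORMAT=GT` only (rs-style IDs at every site); `"wes"` writes per-sample
#' VCFs where each sample carries a Bernoulli(`site_rate`) subset of the
#' candidate panel with `GT:DP:GQ:AD:PL` and a configured fraction of
#' multi-base deletion records carrying an INFO `END`.
#'
#' By default a deletion is nudged so it never crosses a boundary of the
#' `avoid_boundaries`-way partition grid; `boundary_deletion` injects one
#' deliberately boundary-spanning deletion (into the first sample) to
#' exercise the query engine's look-back path.
#'
#' @param seed Integer seed (the only entropy source).
#' @param n_samples Number of samples.
#' @param genome Named vector of contig lengths in bp.
#' @param mode `"microarray"` or `"wes"`.
#' @param n_loci Panel size (shared loci in microarray mode; candidate loci in
#'   wes mode).
#' @param site_rate Per-sample Bernoulli presence rate of each candidate
#'   locus (wes mode).
#' @param af_beta Beta(a, b) parameters for per-site allele frequencies.
#' @param deletion_fraction Fraction of panel loci that are deletions (wes).
#' @param max_deletion_length Maximum deletion length in bp (wes).
#' @param missingness Probability a drawn genotype is masked to `./.`.
#' @param n_concepts Number of clinical concepts (medication codes `MED:k`).
#' @param concept_prevalence Per-patient probability of each concept.
#' @param consent_rate Probability a patient consents to genomic sharing.
#' @param avoid_boundaries Partition count whose grid deletions must not
#'   cross (`NULL` disables the nudge).
#' @param boundary_deletion Optional list `(contig, pos, end)` forcing one
#'   boundary-spanning deletion record for the first sample.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(seed = 1L,
                       n_samples = 50L,
                       genome = c(chr1 = 100000, chr2 = 50000),
                       mode = c("microarray", "wes"),
                       n_loci = 2000L,
                       site_rate = 0.3,
                       af_beta = c(0.5, 0.5),
                       deletion_fraction = 0.05,
                       max_deletion_length = 20L,
                       missingness = 0.02,
                       n_concepts = 5L,
                       concept_prevalence = 0.3,
                       consent_rate = 0.9,
                       avoid_boundaries = 1000L,
                       boundary_deletion = NULL) {
  mode <- match.arg(mode)
  rates <- c(site_rate = site_rate, deletion_fraction = deletion_fraction,
             missingness = missingness, concept_prevalence = concept_prevalence,
             consent_rate = consent_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "),
         call. = FALSE)
  }
  stopifnot(n_samples >= 1, n_loci >= 1, length(af_beta) == 2, all(af_beta > 0),
            max_deletion_length >= 2)
  if (n_loci > sum(genome)) stop("more loci than genome columns", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_samples = as.integer(n_samples),
         genome = genome, mode = mode, n_loci = as.integer(n_loci),
         site_rate = site_rate, af_beta = af_beta,
         deletion_fraction = deletion_fraction,
         max_deletion_length = as.integer(max_deletion_length),
         missingness = missingness, n_concepts = as.integer(n_concepts),
         concept_prevalence = concept_prevalence, consent_rate = consent_rate,
         avoid_boundaries = avoid_boundaries,
         boundary_deletion = boundary_deletion),
    class = "synth_spec"
  )
}

with_spec_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

BASES <- c("A", "C", "G", "T")

draw_panel <- function(spec, gm) {
  cols <- sort(sample.int(gm$total_columns, spec$n_loci)) - 1
  up <- unflatten_position(gm, cols)
  ref <- sample(BASES, spec$n_loci, replace = TRUE)
  alt <- purrr::map_chr(ref, ~ sample(setdiff(BASES, .x), 1))
  af <- stats::rbeta(spec$n_loci, spec$af_beta[1], spec$af_beta[2])
  sites <- tibble::tibble(
    contig = up$contig, pos = up$pos, column = cols,
    id = sprintf("rs%06d", seq_len(spec$n_loci)),
    ref = ref, alt = alt, af = af, is_deletion = FALSE, end = up$pos
  )
  if (spec$mode == "wes" && spec$deletion_fraction > 0) {
    n_del <- round(spec$deletion_fraction * spec$n_loci)
    if (n_del > 0) {
      del_idx <- sort(sample.int(spec$n_loci, n_del))
      len <- sample(2:spec$max_deletion_length, n_del, replace = TRUE)
      for (j in seq_along(del_idx)) {
        i <- del_idx[j]
        clen <- spec$genome[[sites$contig[i]]]
        L <- min(len[j], clen - sites$pos[i] + 1)
        if (!is.null(spec$avoid_boundaries)) {
          width <- ceiling(gm$total_columns / spec$avoid_boundaries)
          room <- width - (sites$column[i] %% width)  # columns left in grid cell
          L <- min(L, room)
        }
        if (L < 2) next
        sites$is_deletion[i] <- TRUE
        sites$end[i] <- sites$pos[i] + L - 1
        seq_extra <- sample(BASES, L - 1, replace = TRUE)
        sites$ref[i] <- paste0(sites$ref[i], paste(seq_extra, collapse = ""))
        sites$alt[i] <- substr(sites$ref[i], 1, 1)
      }
    }
  }
  sites
}

draw_genotypes <- function(n_samples, af, missingness) {
  # one column per sample; Hardy-Weinberg at each site's frequency
  n_sites <- length(af)
  a1 <- matrix(stats::rbinom(n_sites * n_samples, 1, af), nrow = n_sites)
  a2 <- matrix(stats::rbinom(n_sites * n_samples, 1, af), nrow = n_sites)
  miss <- matrix(stats::runif(n_sites * n_samples) < missingness, nrow = n_sites)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  list(a1 = a1, a2 = a2)
}

vcf_header <- function(gm, mode, sample_names) {
  fmt <- if (mode == "microarray") {
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  } else {
    c("##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of interval\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
      "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred genotype likelihoods\">")
  }
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", gm$contigs$name,
            as.integer(gm$contigs$length)),
    fmt,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
}

gt_field <- function(a1, a2) {
  ifelse(is.na(a1), "./.", paste0(a1, "/", a2))
}

#' Generate a synthetic cohort on disk
#'
#' Writes the VCF(s), `genome.json`, `mapping.tsv`, `clinical.tsv` and
#' `patient_set.xml` (all consented patients with their observations) into
#' `out`, mutually consistent: every VCF sample appears in the mapping, every
#' patient-set patient appears in the clinical table. Rerunning with the same
#' spec reproduces every file byte-for-byte.
#'
#' @param spec A [synth_spec()].
#' @param out Output directory (created).
#' @return A manifest list: `files` (named paths), `sites` (panel truth table
#'   incl. drawn allele frequencies), `samples` (sample/patient/consent),
#'   `clinical` (observations tibble).
#' @export
gen_cohort <- function(spec, out) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  gm <- genome_map(spec$genome)
  with_spec_seed(spec$seed, {
    sites <- draw_panel(spec, gm)
    sample_names <- sprintf("S%04d", seq_len(spec$n_samples))
    patient_ids <- sprintf("P%04d", seq_len(spec$n_samples))
    gt <- draw_genotypes(spec$n_samples, sites$af, spec$missingness)

    files <- list(genome = file.path(out, "genome.json"))
    write_genome_map(gm, files$genome)

    info_col <- ifelse(sites$is_deletion, sprintf("END=%d", as.integer(sites$end)), ".")
    if (spec$mode == "microarray") {
      body <- character(nrow(sites))
      gt_mat <- matrix(gt_field(gt$a1, gt$a2), nrow = nrow(sites))
      for (i in seq_len(nrow(sites))) {
        body[i] <- paste(c(sites$contig[i], as.integer(sites$pos[i]), sites$id[i],
                           sites$ref[i], sites$alt[i], ".", "PASS", ".",
                           "GT", gt_mat[i, ]), collapse = "\t")
      }
      files$vcf <- file.path(out, "cohort.vcf")
      writeLines(c(vcf_header(gm, spec$mode, sample_names), body), files$vcf)
    } else {
      present <- matrix(stats::runif(nrow(sites) * spec$n_samples) < spec$site_rate,
                        nrow = nrow(sites))
      files$vcf <- character(spec$n_samples)
      for (s in seq_len(spec$n_samples)) {
        sel <- which(present[, s])
        dp <- stats::rpois(length(sel), 30) + 1L
        lines <- character(length(sel))
        for (k in seq_along(sel)) {
          i <- sel[k]
          a1 <- gt$a1[i, s]; a2 <- gt$a2[i, s]
          gq <- 99L
          if (is.na(a1)) {
            fmt_vals <- sprintf("./.:%d:.:.:.", dp[k])
          } else {
            n_alt_reads <- round(dp[k] * (a1 + a2) / 2)
            ad <- sprintf("%d,%d", dp[k] - n_alt_reads, n_alt_reads)
            pl <- switch(as.character(a1 + a2),
                         "0" = "0,60,600", "1" = "60,0,60", "2" = "600,60,0")
            fmt_vals <- sprintf("%d/%d:%d:%d:%s:%s", a1, a2, dp[k], gq, ad, pl)
          }
          lines[k] <- paste(c(sites$contig[i], as.integer(sites$pos[i]),
                              sites$id[i], sites$ref[i], sites$alt[i], ".",
                              "PASS", info_col[i], "GT:DP:GQ:AD:PL", fmt_vals),
                            collapse = "\t")
        }
        if (s == 1 && !is.null(spec$boundary_deletion)) {
          bd <- spec$boundary_deletion
          L <- bd$end - bd$pos + 1
          ref_seq <- paste(rep("A", L), collapse = "")
          bline <- paste(c(bd$contig, as.integer(bd$pos), "rsBOUNDARY", ref_seq,
                           "A", ".", "PASS", sprintf("END=%d", as.integer(bd$end)),
                           "GT:DP:GQ:AD:PL", "0/1:30:99:15,15:60,0,60"),
                         collapse = "\t")
          lines <- c(lines, bline)
          ord <- order(match(c(sites$contig[sel], bd$contig), gm$contigs$name),
                       c(sites$pos[sel], bd$pos))
          lines <- lines[ord]
        }
        path <- file.path(out, sprintf("sample_%s.vcf", sample_names[s]))
        writeLines(c(vcf_header(gm, spec$mode, sample_names[s]), lines), path)
        files$vcf[s] <- path
      }
    }

    consent <- stats::runif(spec$n_samples) < spec$consent_rate
    samples <- tibble::tibble(sample_name = sample_names,
                              patient_id = patient_ids, consent = consent)
    files$mapping <- file.path(out, "mapping.tsv")
    utils::write.table(
      tibble::tibble(patient_id = patient_ids, sample_name = sample_names,
                     consent = ifelse(consent, "true", "false")),
      files$mapping, sep = "\t", quote = FALSE, row.names = FALSE)

    concepts <- sprintf("MED:%02d", seq_len(spec$n_concepts))
    has <- matrix(stats::runif(spec$n_samples * spec$n_concepts) <
                    spec$concept_prevalence, nrow = spec$n_samples)
    obs <- purrr::map(seq_len(spec$n_samples), function(p) {
      k <- which(has[p, ])
      if (length(k) == 0) return(NULL)
      tibble::tibble(patient_id = patient_ids[p], concept_code = concepts[k],
                     concept_label = sprintf("medication %02d", k), value = "")
    }) %>% dplyr::bind_rows()
    if (nrow(obs) == 0) {
      obs <- tibble::tibble(patient_id = character(), concept_code = character(),
                            concept_label = character(), value = character())
    }
    clin <- dplyr::bind_rows(
      tibble::tibble(patient_id = patient_ids, concept_code = "",
                     concept_label = "", value = ""),
      obs
    )
    files$clinical <- file.path(out, "clinical.tsv")
    utils::write.table(clin, files$clinical, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    ps <- new_patient_set(patient_ids[consent],
                          obs[obs$patient_id %in% patient_ids[consent], ])
    files$patient_set <- file.path(out, "patient_set.xml")
    write_patient_set(ps, files$patient_set)

    list(files = files, sites = sites, samples = samples, clinical = obs,
         genome = gm)
  })
}

#' Generate a patient-set file from a generated cohort
#'
#' Stands in for the clinical cohort service response: selects the consented
#' patients of a generated cohort, optionally restricted to those carrying a
#' concept code matching `concept_filter` (prefix match) and subsampled to
#' `cohort_fraction`, and writes them as a patient-set XML.
#'
#' @param cohort_dir Directory produced by [gen_cohort()].
#' @param path Output XML path.
#' @param concept_filter Optional concept-code prefix patients must carry.
#' @param cohort_fraction Fraction of matching patients to keep.
#' @param seed Seed for the subsampling draw.
#' @return The selected `patient_set`, invisibly; the file is written.
#' @export
gen_patient_set <- function(cohort_dir, path,
                            concept_filter = NULL, cohort_fraction = 1,
                            seed = 1L) {
  reg <- load_mapping(file.path(cohort_dir, "mapping.tsv"))
  ps_all <- read_clinical_tsv(file.path(cohort_dir, "clinical.tsv"))
  keep <- reg$patient_id[reg$consent]
  if (!is.null(concept_filter)) {
    obs <- ps_all$observations
    hit <- unique(obs$patient_id[startsWith(obs$concept_code, concept_filter)])
    keep <- intersect(keep, hit)
  }
  if (cohort_fraction < 1) {
    keep <- with_spec_seed(seed, {
      sort(sample(keep, round(length(keep) * cohort_fraction)))
    })
  }
  ps <- new_patient_set(
    keep, ps_all$observations[ps_all$observations$patient_id %in% keep, ])
  write_patient_set(ps, path)
  invisible(ps)
}
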