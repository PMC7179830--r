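#' Allele-count report over regions
#'
#' For each site in each region, tallies the allele indices of the selected
#' rows' genotypes: index 0 counts toward the reference allele, index k >= 1
#' toward the k-th alternate, and a missing allele toward `nocall`. When
#' `absent_as_nocall` is set (the default), a selected row with no cell at a
#' site contributes two nocall alleles — on a fixed-panel (microarray) store,
#' absence is informative. Region totals sum the site tallies; both raw
#' totals (including nocall) and called-only totals are reported.
#'
#' With `absent_as_nocall`, every biallelic site satisfies
#' `ref + alt + nocall == 2 * length(rows)`.
#'
#' @param handle A `variant_store`.
#' @param regions Data frame of `contig`, `start`, `end` (1-based inclusive)
#'   and optionally `label`.
#' @param rows Integer vector of sample rows to include (e.g. from
#'   [resolve_rows()]); defaults to all rows in the store.
#' @param absent_as_nocall Count absent cells as two nocall alleles.
#' @param workers Worker-pool size for the underlying queries.
#' @return An `allele_count_report`: list with `sites` (per-site tallies,
#'   alternate-allele counts as a list column), `regions` (per-region totals)
#'   and the inclusion settings.
#' @export
allele_count_report <- function(handle, regions, rows = NULL,
                                absent_as_nocall = TRUE, workers = 1) {
  if (!is.data.frame(regions)) regions <- dplyr::bind_rows(regions)
  regions <- tibble::as_tibble(regions)
  if (!"label" %in% names(regions)) {
    regions$label <- sprintf("%s:%s-%s", regions$contig, regions$start, regions$end)
  }
  if (is.null(rows)) rows <- handle$samples$row
  rows <- sort(unique(rows))
  n_rows <- length(rows)

  site_rows <- purrr::map(seq_len(nrow(regions)), function(i) {
    sites <- query_regions(handle, regions[i, c("contig", "start", "end")],
                           rows = rows, workers = workers)
    if (nrow(sites) == 0) return(NULL)
    sites$region <- regions$label[i]
    sites$ref_count <- purrr::map_int(sites$calls, ~ sum(c(.x$a1, .x$a2) == 0, na.rm = TRUE))
    sites$alt_counts <- purrr::map2(sites$calls, sites$alt, function(calls, alt) {
      n_alts <- if (alt == "") 0L else length(strsplit(alt, ",", fixed = TRUE)[[1]])
      al <- c(calls$a1, calls$a2)
      tabulate(al[!is.na(al) & al > 0], nbins = n_alts)
    })
    sites$nocall_count <- purrr::map_int(sites$calls, ~ sum(is.na(c(.x$a1, .x$a2)))) +
      if (absent_as_nocall) 2L * (n_rows - sites$n_calls) else 0L
    sites$called_total <- sites$ref_count + purrr::map_int(sites$alt_counts, sum)
    sites$raw_total <- sites$called_total + sites$nocall_count
    sites[, c("region", "contig", "pos", "column", "site_id", "ref", "alt",
              "ref_count", "alt_counts", "nocall_count", "called_total",
              "raw_total")]
  })
  sites <- dplyr::bind_rows(site_rows)
  region_totals <- if (nrow(sites) == 0) {
    tibble::tibble(region = regions$label, n_sites = 0L, ref_count = 0L,
                   alt_count = 0L, nocall_count = 0L, called_total = 0L,
                   raw_total = 0L)
  } else {
    sites %>%
      dplyr::group_by(region = factor(.data$region, levels = regions$label)) %>%
      dplyr::summarise(
        n_sites = dplyr::n(),
        ref_count = sum(.data$ref_count),
        alt_count = sum(purrr::map_int(.data$alt_counts, sum)),
        nocall_count = sum(.data$nocall_count),
        called_total = sum(.data$called_total),
        raw_total = sum(.data$raw_total),
        .groups = "drop"
      ) %>%
      tidyr::complete(region = factor(regions$label, levels = regions$label),
                      fill = list(n_sites = 0L, ref_count = 0L, alt_count = 0L,
                                  nocall_count = 0L, called_total = 0L,
                                  raw_total = 0L)) %>%
      dplyr::mutate(region = as.character(.data$region))
  }
  structure(
    list(sites = sites, regions = tibble::as_tibble(region_totals),
         n_rows_included = n_rows, absent_as_nocall = absent_as_nocall),
    class = "allele_count_report"
  )
}

#' @export
print.allele_count_report <- function(x, ...) {
  cat("<allele_count_report> ", nrow(x$sites), " site(s) across ",
      nrow(x$regions), " region(s), ", x$n_rows_included,
      " row(s) included\n", sep = "")
  print(x$regions, ...)
  invisible(x)
}

#' Genotype-distribution report by clinical subgroup
#'
#' For each queried position and each clinical subgroup, classifies every
#' member patient's genotype into homref/het/homvar/nocall and tallies the
#' classes. A patient with no cell at the position is counted as nocall; a
#' patient with several sequenced samples contributes each sample; a patient
#' in two subgroups is counted in both. Per (position, subgroup) the class
#' counts always sum to the subgroup's sample count.
#'
#' @param handle A `variant_store`.
#' @param positions Character vector of rs-identifiers (resolved through the
#'   store's site dictionary) and/or a data frame of `contig`, `pos`.
#' @param ps A [parse_patient_set()] patient set.
#' @param group_concept Concept-code prefix passed to [group_patients()].
#' @param reg A [load_mapping()] registry.
#' @param require_consent Exclude non-consented patients.
#' @param workers Worker-pool size.
#' @return A `genotype_distribution_report`: tibble of `position`, `contig`,
#'   `pos`, `subgroup`, `homref`, `het`, `homvar`, `nocall`, `n_samples`,
#'   with the excluded-patient table as attribute `excluded`.
#' @export
genotype_distribution_report <- function(handle, positions, ps, group_concept,
                                         reg, require_consent = TRUE,
                                         workers = 1) {
  pos_tab <- resolve_positions(handle, positions)
  groups <- group_patients(ps, group_concept)
  res <- resolve_rows(reg, handle, ps$patients, require_consent = require_consent)
  inc <- res$included

  out <- purrr::map(seq_len(nrow(pos_tab)), function(i) {
    sites <- query_regions(handle,
                           tibble::tibble(contig = pos_tab$contig[i],
                                          start = pos_tab$pos[i],
                                          end = pos_tab$pos[i]),
                           workers = workers)
    row_class <- character()
    if (nrow(sites) > 0) {
      calls <- dplyr::bind_rows(sites$calls)
      row_class <- stats::setNames(classify_genotype(calls$a1, calls$a2),
                                   calls$row)
    }
    purrr::imap(groups, function(members, label) {
      rows <- inc$row[inc$patient_id %in% members]
      cls <- rep("nocall", length(rows))
      hit <- as.character(rows) %in% names(row_class)
      cls[hit] <- row_class[as.character(rows[hit])]
      tibble::tibble(
        position = pos_tab$label[i], contig = pos_tab$contig[i],
        pos = pos_tab$pos[i], subgroup = label,
        homref = sum(cls == "homref"), het = sum(cls == "het"),
        homvar = sum(cls == "homvar"), nocall = sum(cls == "nocall"),
        n_samples = length(rows)
      )
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  out <- dplyr::arrange(out, .data$position, .data$subgroup)
  class(out) <- c("genotype_distribution_report", class(out))
  attr(out, "excluded") <- res$excluded
  out
}

resolve_positions <- function(handle, positions) {
  if (is.data.frame(positions)) {
    tab <- tibble::as_tibble(positions)
    stopifnot(all(c("contig", "pos") %in% names(tab)))
    tab$label <- sprintf("%s:%s", tab$contig, tab$pos)
    return(tab[, c("label", "contig", "pos")])
  }
  if (is.null(handle$sites)) {
    stop("store has no site dictionary; cannot resolve rs-identifiers",
         call. = FALSE)
  }
  purrr::map(positions, function(p) {
    hit <- lookup_site(handle$sites, p)
    tibble::tibble(label = p, contig = hit$contig[1], pos = hit$pos[1])
  }) %>% dplyr::bind_rows()
}

#' Genomic-only cohort from genotype filters
#'
#' Applies each genotype filter over the rows of the mapped (and, by default,
#' consented) patients, intersects the satisfying row sets — the filters are
#' a conjunction — and maps the surviving rows back to patient ids. When a
#' base patient set is given, the result is restricted to it.
#'
#' @param handle A `variant_store`.
#' @param filters List of filter strings or `genotype_filter` objects
#'   (grammar: `rs### (is | is not) (homref | homvar | het | nocall)`).
#' @param reg A [load_mapping()] registry.
#' @param base Optional `patient_set` restricting the candidate patients.
#' @param require_consent Exclude non-consented patients.
#' @return Sorted character vector of patient ids.
#' @export
genomic_cohort <- function(handle, filters, reg, base = NULL,
                           require_consent = TRUE) {
  if (length(filters) == 0) stop("need at least one genotype filter", call. = FALSE)
  patients <- if (is.null(base)) unique(reg$patient_id) else base$patients
  res <- resolve_rows(reg, handle, patients, require_consent = require_consent)
  rows <- res$included$row
  if (length(rows) == 0) return(character())
  for (f in filters) {
    rows <- apply_genotype_filter(handle, f, rows = rows)
    if (length(rows) == 0) return(character())
  }
  sort(unique(res$included$patient_id[res$included$row %in% rows]))
}

#' Write a report to JSON with deterministic layout
#'
#' @param report An `allele_count_report` or `genotype_distribution_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- if (inherits(report, "allele_count_report")) {
    list(type = "allele_counts",
         n_rows_included = report$n_rows_included,
         absent_as_nocall = report$absent_as_nocall,
         regions = report$regions,
         sites = report$sites)
  } else if (inherits(report, "genotype_distribution_report")) {
    list(type = "genotype_distribution",
         table = as.data.frame(report),
         excluded = attr(report, "excluded"))
  } else {
    stop("unsupported report type", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
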