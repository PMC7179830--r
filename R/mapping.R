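#' Load a patient-sample mapping registry
#'
#' The mapping registry links de-identified patient ids to genomic sample
#' names together with a consent flag; it is the join point between clinical
#' patient sets and store rows. A sample may belong to at most one patient; a
#' patient may own several samples. Consent values `true/false`, `1/0`,
#' `yes/no` are accepted case-insensitively.
#'
#' @param path TSV (columns `patient_id`, `sample_name`, `consent`) or JSON
#'   (array of objects with those keys). A data frame is accepted directly.
#' @return A tibble of class `mapping_registry`.
#' @export
load_mapping <- function(path) {
  tab <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    tibble::as_tibble(utils::read.delim(path, colClasses = "character"))
  }
  need <- c("patient_id", "sample_name", "consent")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("mapping table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[, need]
  tab$patient_id <- as.character(tab$patient_id)
  tab$sample_name <- as.character(tab$sample_name)
  tab$consent <- parse_consent(tab$consent)
  tab <- dplyr::distinct(tab)
  clash <- tab %>%
    dplyr::distinct(.data$patient_id, .data$sample_name) %>%
    dplyr::count(.data$sample_name) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(clash) > 0) {
    stop("sample mapped to more than one patient: ",
         paste(clash$sample_name, collapse = ", "), call. = FALSE)
  }
  class(tab) <- c("mapping_registry", class(tab))
  tab
}

parse_consent <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "1", "yes")] <- TRUE
  out[v %in% c("false", "0", "no")] <- FALSE
  if (anyNA(out)) {
    stop("unrecognized consent value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Resolve patients to store rows
#'
#' Joins a set of patient ids through the mapping registry to the store's
#' sample registry. A patient is included only if present in the mapping,
#' consented (when `require_consent`), and owning at least one sample loaded
#' in the store; every input patient lands either in `included` or in
#' `excluded` with a reason, never silently dropped. Patients with several
#' sequenced samples contribute all their rows.
#'
#' @param reg A [load_mapping()] registry.
#' @param sreg Sample registry: tibble of `sample_name`, `row` (a
#'   `variant_store` handle's `$samples`, or the handle itself).
#' @param patients Character vector of patient ids.
#' @param require_consent Exclude non-consented patients (default `TRUE`).
#' @return A list: `included`, tibble of `patient_id`, `sample_name`, `row`;
#'   `excluded`, tibble of `patient_id`, `reason` (one of `"not in mapping"`,
#'   `"no consent"`, `"no sample"`).
#' @export
resolve_rows <- function(reg, sreg, patients, require_consent = TRUE) {
  if (inherits(sreg, "variant_store")) sreg <- sreg$samples
  patients <- unique(as.character(patients))
  excl <- list()
  known <- patients %in% reg$patient_id
  if (any(!known)) {
    excl$unknown <- tibble::tibble(patient_id = patients[!known],
                                   reason = "not in mapping")
  }
  cand <- reg[reg$patient_id %in% patients[known], , drop = FALSE]
  if (require_consent) {
    by_pat <- cand %>%
      dplyr::group_by(.data$patient_id) %>%
      dplyr::summarise(any_consent = any(.data$consent), .groups = "drop")
    no_consent <- by_pat$patient_id[!by_pat$any_consent]
    if (length(no_consent) > 0) {
      excl$consent <- tibble::tibble(patient_id = no_consent,
                                     reason = "no consent")
    }
    cand <- cand[cand$consent & !(cand$patient_id %in% no_consent), , drop = FALSE]
  }
  joined <- dplyr::inner_join(cand, sreg, by = "sample_name")
  with_rows <- unique(joined$patient_id)
  no_sample <- setdiff(unique(cand$patient_id), with_rows)
  if (length(no_sample) > 0) {
    excl$sample <- tibble::tibble(patient_id = no_sample, reason = "no sample")
  }
  list(
    included = tibble::as_tibble(joined[, c("patient_id", "sample_name", "row")]) %>%
      dplyr::arrange(.data$patient_id, .data$row),
    excluded = dplyr::bind_rows(excl) %||%
      tibble::tibble(patient_id = character(), reason = character())
  )
}
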