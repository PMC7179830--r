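#' Parse a patient-set XML file
#'
#' Reads the package's minimal patient-set dialect, a flat stand-in for the
#' XML a clinical cohort service (an i2b2 CRC cell) returns:
#'
#' ```xml
#' <patient_set>
#'   <patient id="P0001"/>
#'   <observation patient_id="P0001" concept_code="MED:01"
#'                concept_label="medication 01" value=""/>
#' </patient_set>
#' ```
#'
#' Duplicate patient elements are deduplicated; an observation referencing a
#' patient not declared in the set is an error.
#'
#' @param path XML file in the dialect above.
#' @return A `patient_set`: list with `patients` (character vector) and
#'   `observations` (tibble of `patient_id`, `concept_code`, `concept_label`,
#'   `value`).
#' @export
parse_patient_set <- function(path) {
  doc <- xml2::read_xml(path)
  pts <- xml2::xml_find_all(doc, ".//patient")
  ids <- unique(xml2::xml_attr(pts, "id"))
  if (anyNA(ids)) stop("patient element without id attribute", call. = FALSE)
  obs_nodes <- xml2::xml_find_all(doc, ".//observation")
  obs <- tibble::tibble(
    patient_id = xml2::xml_attr(obs_nodes, "patient_id"),
    concept_code = xml2::xml_attr(obs_nodes, "concept_code"),
    concept_label = xml2::xml_attr(obs_nodes, "concept_label"),
    value = xml2::xml_attr(obs_nodes, "value")
  )
  unknown <- setdiff(obs$patient_id, ids)
  if (length(unknown) > 0) {
    stop("observation references unknown patient(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  new_patient_set(ids, obs)
}

new_patient_set <- function(patients, observations) {
  structure(list(patients = patients,
                 observations = tibble::as_tibble(observations)),
            class = "patient_set")
}

#' @export
print.patient_set <- function(x, ...) {
  cat("<patient_set> ", length(x$patients), " patient(s), ",
      nrow(x$observations), " observation(s)\n", sep = "")
  invisible(x)
}

#' Read a patient set from a flat clinical TSV
#'
#' Equivalent non-XML path: columns `patient_id`, `concept_code`,
#' `concept_label`, `value`. A row with empty `concept_code` declares a
#' patient without observations.
#'
#' @param path TSV file.
#' @param patients Optional explicit patient universe; defaults to the
#'   distinct `patient_id` values in the file.
#' @return A `patient_set`.
#' @export
read_clinical_tsv <- function(path, patients = NULL) {
  tab <- tibble::as_tibble(utils::read.delim(path, colClasses = "character"))
  need <- c("patient_id", "concept_code", "concept_label", "value")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("clinical table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  obs <- tab[nzchar(tab$concept_code), need]
  pts <- unique(c(patients, tab$patient_id))
  unknown <- setdiff(obs$patient_id, pts)
  if (length(unknown) > 0) {
    stop("observation references unknown patient(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  new_patient_set(pts, obs)
}

#' Serialize a patient set back to the XML dialect
#'
#' Lossless for the dialect's fields; parsing the output reproduces the set.
#'
#' @param ps A `patient_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_patient_set <- function(ps, path) {
  doc <- xml2::xml_new_root("patient_set")
  for (p in ps$patients) {
    xml2::xml_add_child(doc, "patient", id = p)
  }
  if (nrow(ps$observations) > 0) {
    for (i in seq_len(nrow(ps$observations))) {
      o <- ps$observations[i, ]
      xml2::xml_add_child(doc, "observation",
                          patient_id = o$patient_id,
                          concept_code = o$concept_code,
                          concept_label = o$concept_label,
                          value = if (is.na(o$value)) "" else o$value)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Group patients by clinical concept
#'
#' Forms one subgroup per distinct concept code whose code starts with
#' `concept_prefix` (e.g. an ICD-10 chapter prefix like `"C50"`, or a
#' medication namespace). A patient joins every subgroup whose concept they
#' have, so subgroups may overlap; patients with no matching observation form
#' the `"(none)"` subgroup. The union of all subgroups is always the full
#' patient set.
#'
#' @param ps A `patient_set`.
#' @param concept_prefix Concept-code prefix selecting the grouping axis.
#' @return Named list of character vectors of patient ids.
#' @export
group_patients <- function(ps, concept_prefix) {
  obs <- ps$observations
  hit <- obs[startsWith(obs$concept_code, concept_prefix), , drop = FALSE]
  groups <- lapply(split(hit$patient_id, hit$concept_code), unique)
  grouped <- unique(hit$patient_id)
  rest <- setdiff(ps$patients, grouped)
  if (length(rest) > 0 || length(groups) == 0) {
    groups[["(none)"]] <- rest
  }
  groups[order(names(groups))]
}
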