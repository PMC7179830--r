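#' Classify diploid genotypes
#'
#' Total classification of a diploid genotype into the four classes used by
#' the genotype-filter grammar: any missing allele is `nocall`; two reference
#' alleles are `homref`; two identical non-reference alleles are `homvar`;
#' two different alleles are `het` (so `1/2` is heterozygous).
#'
#' @param a1,a2 Allele indices (0 = ref, k = k-th alternate, `NA` = missing),
#'   or `a1` may be a character vector of VCF genotype strings like `"0/1"`,
#'   `"0|1"`, `"./."` with `a2` omitted.
#' @return A character vector over `c("homref", "het", "homvar", "nocall")`.
#' @examples
#' classify_genotype("0/0") # homref
#' classify_genotype(1, 2)  # het
#' @export
classify_genotype <- function(a1, a2 = NULL) {
  if (is.character(a1)) {
    if (!is.null(a2)) stop("give either genotype strings or two index vectors",
                           call. = FALSE)
    gt <- parse_gt_strings(a1, "<input>")
    a1 <- gt$a1
    a2 <- gt$a2
  }
  a1 <- as.integer(a1)
  a2 <- as.integer(a2)
  out <- rep("het", length(a1))
  out[is.na(a1) | is.na(a2)] <- "nocall"
  both <- !is.na(a1) & !is.na(a2)
  out[both & a1 == 0 & a2 == 0] <- "homref"
  out[both & a1 == a2 & a1 > 0] <- "homvar"
  out
}

GENOTYPE_CLASSES <- c("homref", "het", "homvar", "nocall")

#' Parse a genotype filter expression
#'
#' Grammar: `rs### (is | is not) (homref | homvar | het | nocall)`.
#'
#' @param text Filter expression, e.g. `"rs16942 is not het"`.
#' @return A list with `rsid`, `negate`, `class` (a `genotype_filter`).
#' @export
parse_genotype_filter <- function(text) {
  m <- regmatches(text, regexec(
    "^\\s*(\\S+)\\s+is(\\s+not)?\\s+(homref|homvar|het|nocall)\\s*$", text))[[1]]
  if (length(m) == 0) {
    stop("cannot parse genotype filter: '", text,
         "' (expected: rs### (is | is not) (homref | homvar | het | nocall))",
         call. = FALSE)
  }
  structure(list(rsid = m[2], negate = nzchar(m[3]), class = m[4]),
            class = "genotype_filter")
}

#' Apply a genotype filter at an rs-identified site
#'
#' Evaluates the class predicate for every row of `rows` at the site the
#' identifier resolves to. A row with no cell at the site is treated as
#' `nocall`, so `(is, C)` and `(is not, C)` always partition the row set.
#'
#' @param sites A `variant_sites` tibble covering the site's column (e.g. from
#'   [query_regions()] over the site), or a `variant_store` handle, in which
#'   case the site is queried directly.
#' @param filter A `genotype_filter` (see [parse_genotype_filter()]) or a
#'   filter expression string.
#' @param site_dict Site dictionary with a `column` column; defaults to the
#'   store's when `sites` is a handle.
#' @param rows Integer vector: the universe of sample rows under
#'   consideration (required so absent rows can be classified as `nocall`).
#' @return The integer subset of `rows` satisfying the filter.
#' @export
apply_genotype_filter <- function(sites, filter, site_dict = NULL, rows) {
  if (is.character(filter)) filter <- parse_genotype_filter(filter)
  if (inherits(sites, "variant_store")) {
    site_dict <- site_dict %||% sites$sites
    hit <- lookup_site(site_dict, filter$rsid)
    sites <- query_regions(sites, tibble::tibble(
      contig = hit$contig, start = hit$pos, end = hit$pos))
  } else {
    if (is.null(site_dict)) stop("site_dict is required", call. = FALSE)
    hit <- lookup_site(site_dict, filter$rsid)
  }
  at_site <- sites[sites$column == hit$column, , drop = FALSE]
  cls <- stats::setNames(rep("nocall", length(rows)), rows)
  for (i in seq_len(nrow(at_site))) {
    calls <- at_site$calls[[i]]
    calls <- calls[calls$row %in% rows, , drop = FALSE]
    cls[as.character(calls$row)] <- classify_genotype(calls$a1, calls$a2)
  }
  match_mask <- cls == filter$class
  if (filter$negate) match_mask <- !match_mask
  rows[match_mask]
}
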