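#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an allele-count report into long per-allele rows
#'
#' @param x An `allele_count_report`.
#' @param ... Unused.
#' @return A tibble with one row per (site, allele) where allele is `"ref"`,
#'   `"alt1"`, ..., or `"nocall"`.
#' @method tidy allele_count_report
#' @export
tidy.allele_count_report <- function(x, ...) {
  if (nrow(x$sites) == 0) {
    return(tibble::tibble(region = character(), contig = character(),
                          pos = numeric(), site_id = character(),
                          allele = character(), count = integer()))
  }
  purrr::pmap(x$sites, function(region, contig, pos, column, site_id, ref, alt,
                                ref_count, alt_counts, nocall_count, ...) {
    tibble::tibble(
      region = region, contig = contig, pos = pos, site_id = site_id,
      allele = c("ref", if (length(alt_counts)) paste0("alt", seq_along(alt_counts)),
                 "nocall"),
      count = c(ref_count, alt_counts, nocall_count)
    )
  }) %>% dplyr::bind_rows()
}

#' @method glance allele_count_report
#' @export
glance.allele_count_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_regions = nrow(x$regions), n_sites = nrow(x$sites),
                   n_rows_included = x$n_rows_included,
                   absent_as_nocall = x$absent_as_nocall)
  )
}

#' Tidy a genotype-distribution report into long class counts
#'
#' @param x A `genotype_distribution_report`.
#' @param ... Unused.
#' @return A tibble with one row per (position, subgroup, class).
#' @method tidy genotype_distribution_report
#' @export
tidy.genotype_distribution_report <- function(x, ...) {
  tibble::as_tibble(x) %>%
    tidyr::pivot_longer(dplyr::all_of(GENOTYPE_CLASSES),
                        names_to = "class", values_to = "count")
}

#' @method glance genotype_distribution_report
#' @export
glance.genotype_distribution_report <- function(x, ...) {
  tibble::tibble(
    n_positions = length(unique(x$position)),
    n_subgroups = length(unique(x$subgroup)),
    n_excluded = nrow(attr(x, "excluded"))
  )
}

#' @method tidy import_report
#' @export
tidy.import_report <- function(x, ...) {
  x$per_partition
}

#' @method glance import_report
#' @export
glance.import_report <- function(x, ...) {
  tibble::tibble(n_files = x$n_files, n_samples = x$n_samples,
                 n_records = x$n_records, n_cells = x$n_cells,
                 n_skipped = sum(x$skipped$n),
                 wall_time_sec = x$wall_time_sec)
}

#' @method tidy scaling_result
#' @export
tidy.scaling_result <- function(x, ...) {
  dplyr::mutate(x$points, metric = x$metric, .before = 1)
}

#' @method glance scaling_result
#' @export
glance.scaling_result <- function(x, ...) {
  tibble::tibble(metric = x$metric, slope = x$slope, r_squared = x$r_squared,
                 n_points = nrow(x$points))
}

#' Plot a scaling result on log-log axes
#'
#' @param object A `scaling_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scaling_result
#' @export
autoplot.scaling_result <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$n_samples, y = .data$value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "samples", y = object$metric,
      title = sprintf("%s vs cohort size (log-log slope %.3f, R² %.3f)",
                      object$metric, object$slope, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a genotype-distribution report as stacked bars per subgroup
#'
#' @param object A `genotype_distribution_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot genotype_distribution_report
#' @export
autoplot.genotype_distribution_report <- function(object, ...) {
  tidy(object) %>%
    dplyr::mutate(class = factor(.data$class, levels = GENOTYPE_CLASSES)) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$subgroup, y = .data$count,
                                 fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~position) +
    ggplot2::labs(x = "clinical subgroup", y = "samples", fill = "genotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
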