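#' Scaling benchmark over increasing cohort sizes
#'
#' Regenerates, imports and queries a synthetic cohort at each sample size
#' and measures one metric per size, then fits ordinary least squares on the
#' log-log points. For a store that scales linearly the slope is ~1. Two
#' metrics are deterministic and suitable for assertions — `storage_bytes`
#' (total store size on disk) and `cells_touched` (cells deserialized while
#' answering the query regions) — while `import_time` and `query_time` are
#' wall-clock measurements, reported for inspection but hardware-dependent.
#' Time metrics repeat each query five times and average.
#'
#' @param metric One of `"storage_bytes"`, `"cells_touched"`,
#'   `"import_time"`, `"query_time"`.
#' @param sizes Increasing vector of at least three sample counts.
#' @param spec A [synth_spec()]; `n_samples` is overridden per size (the seed
#'   is offset by the size so cohorts are independent draws).
#' @param regions Query regions (data frame of `contig`, `start`, `end`);
#'   required for the query metrics.
#' @param n_partitions Partitions used at import.
#' @param workdir Scratch directory for the generated cohorts and stores.
#' @param query_reps Repetitions averaged for time metrics.
#' @return A `scaling_result`: list with `metric`, `points` (tibble of
#'   `n_samples`, `value`), `slope`, `r_squared` from the log-log fit.
#' @export
run_scaling <- function(metric = c("storage_bytes", "cells_touched",
                                   "import_time", "query_time"),
                        sizes, spec, regions = NULL,
                        n_partitions = 25, workdir = tempfile("bench"),
                        query_reps = 5) {
  metric <- match.arg(metric)
  if (length(sizes) < 3) stop("need >=3 sizes", call. = FALSE)
  if (is.unsorted(sizes, strictly = TRUE)) {
    stop("sizes must be strictly increasing", call. = FALSE)
  }
  if (metric %in% c("cells_touched", "query_time") && is.null(regions)) {
    stop("query metrics need regions", call. = FALSE)
  }
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  values <- purrr::map_dbl(sizes, function(n) {
    sp <- spec
    sp$n_samples <- as.integer(n)
    sp$seed <- spec$seed + as.integer(n)
    dir_n <- file.path(workdir, sprintf("n%04d", n))
    man <- gen_cohort(sp, dir_n)
    store_dir <- file.path(dir_n, "store")
    t0 <- Sys.time()
    res <- import_vcfs(man$files$vcf, man$genome, store_dir,
                       loader_config(n_partitions = n_partitions,
                                     parallel_readers = 2))
    import_secs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    switch(metric,
      storage_bytes = store_size_bytes(res$store),
      import_time = import_secs,
      cells_touched = {
        reset_store_counters(res$store)
        invisible(query_regions(res$store, regions))
        store_counters(res$store)$cells_touched
      },
      query_time = {
        mean(purrr::map_dbl(seq_len(query_reps), function(i) {
          t1 <- Sys.time()
          invisible(query_regions(res$store, regions))
          as.numeric(difftime(Sys.time(), t1, units = "secs"))
        }))
      }
    )
  })
  if (any(values <= 0)) {
    stop("degenerate (zero) measurement for metric ", metric, call. = FALSE)
  }
  fit <- stats::lm(log(values) ~ log(sizes))
  structure(
    list(metric = metric,
         points = tibble::tibble(n_samples = sizes, value = values),
         slope = unname(stats::coef(fit)[2]),
         r_squared = summary(fit)$r.squared),
    class = "scaling_result"
  )
}

#' @export
print.scaling_result <- function(x, ...) {
  cat("<scaling_result> ", x$metric, ": log-log slope ",
      sprintf("%.3f", x$slope), " (R^2 ", sprintf("%.4f", x$r_squared), ")\n",
      sep = "")
  print(x$points, ...)
  invisible(x)
}
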