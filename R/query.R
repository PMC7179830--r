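#' Normalize query regions
#'
#' Accepts a data frame with `contig`, `start`, `end` (1-based, inclusive) or
#' a list of such lists, validates each region against the genome map and
#' flattens it to a half-open column interval.
#'
#' @keywords internal
flatten_regions <- function(regions, gm) {
  if (!is.data.frame(regions)) regions <- dplyr::bind_rows(regions)
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("contig", "start", "end") %in% names(regions)))
  if (any(regions$start > regions$end)) {
    i <- which(regions$start > regions$end)[1]
    stop("invalid region ", regions$contig[i], ":", regions$start[i], "-",
         regions$end[i], " (start > end)", call. = FALSE)
  }
  tibble::tibble(
    contig = regions$contig, start = regions$start, end = regions$end,
    lo = flatten_position(gm, regions$contig, regions$start),
    hi = flatten_position(gm, regions$contig, regions$end) + 1
  )
}

merge_intervals <- function(lo, hi) {
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  out_lo <- lo[1]; out_hi <- hi[1]
  res <- list()
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= out_hi) {
      out_hi <- max(out_hi, hi[i])
    } else {
      res[[length(res) + 1]] <- c(out_lo, out_hi)
      out_lo <- lo[i]; out_hi <- hi[i]
    }
  }
  res[[length(res) + 1]] <- c(out_lo, out_hi)
  tibble::tibble(lo = purrr::map_dbl(res, 1), hi = purrr::map_dbl(res, 2))
}

#' Decompose a region query into per-partition tasks
#'
#' One task is emitted per (merged region interval x intersected partition);
#' tasks for one query are pairwise column-disjoint (overlapping input regions
#' are unioned first). A task sets `probe_preceding` when an interval cell
#' recorded in the preceding partition could reach its first queried column,
#' judged from the preceding partition's stored maximum END overhang.
#'
#' @param handle A `variant_store` handle, or a [make_partitions()] table (in
#'   which case overhang metadata is unavailable and every task with a
#'   preceding partition probes it).
#' @param regions Data frame of `contig`, `start`, `end` (1-based inclusive).
#' @param gm Genome map; defaults to the handle's.
#' @param rows Optional row restriction carried on each task.
#' @return A tibble of query tasks: `part_id`, `lo`, `hi`, `probe_preceding`.
#' @export
plan_query <- function(handle, regions, gm = NULL, rows = NULL) {
  if (inherits(handle, "variant_store")) {
    parts <- handle$parts
    gm <- gm %||% handle$genome
    overhang <- parts$max_end_overhang
  } else {
    parts <- handle
    if (is.null(gm)) stop("gm is required when planning against a partition table",
                          call. = FALSE)
    overhang <- rep(Inf, nrow(parts))
  }
  fr <- flatten_regions(regions, gm)
  iv <- merge_intervals(fr$lo, fr$hi)
  tasks <- purrr::pmap(iv, function(lo, hi) {
    first <- findInterval(lo, parts$col_begin)
    last <- findInterval(hi - 1, parts$col_begin)
    purrr::map(first:last, function(k) {
      tlo <- max(lo, parts$col_begin[k])
      thi <- min(hi, parts$col_end[k])
      probe <- k > 1 && overhang[k - 1] >= tlo - parts$col_end[k - 1] + 1
      list(part_id = parts$id[k], lo = tlo, hi = thi, probe_preceding = probe)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(tasks))
  if (!is.null(rows)) out$rows <- list(rows)
  out
}

run_task <- function(handle, task, rows) {
  main <- read_partition(handle, task$part_id, task$lo, task$hi, rows = rows)
  if (isTRUE(task$probe_preceding)) {
    prev <- handle$parts[match(task$part_id, handle$parts$id) - 1, ]
    spill <- read_partition(handle, prev$id, prev$col_begin, prev$col_end,
                            rows = rows)
    spill <- spill[spill$col_end >= task$lo & spill$col_start < task$lo, ,
                   drop = FALSE]
    if (nrow(spill) > 0) {
      spill$.probed <- TRUE
      main$.probed <- logical(nrow(main))
      main <- dplyr::bind_rows(spill, main)
    }
  }
  main
}

#' Execute query tasks on a worker pool and merge cells into sites
#'
#' Tasks are dispatched to `workers` processes; a failed task is retried once
#' before the query fails with the underlying error. Gathered cells are merged
#' by column into site records: cells at one column sharing (ref, alts) form
#' one site; a differing alt list at the same column yields a separate site.
#' Output is identical for any worker count and any task completion order.
#'
#' Cells recovered through a preceding-partition probe are dropped when their
#' start column is itself covered by another task of the same query, so a
#' boundary-spanning deletion is returned exactly once.
#'
#' @param handle A `variant_store`.
#' @param tasks Task tibble from [plan_query()].
#' @param workers Worker-pool size (>= 1).
#' @param rows Optional integer vector of sample rows to restrict to.
#' @return A `variant_sites` tibble, column-ordered: `column`, `contig`,
#'   `pos`, `site_id`, `ref`, `alt`, `n_calls`, and `calls`, a list column of
#'   per-sample call tibbles (`row`, `a1`, `a2`, `phased`, `dp`, `gq`, `ad`,
#'   `pl`).
#' @export
execute_query <- function(handle, tasks, workers = 1, rows = NULL) {
  if (nrow(tasks) == 0) return(empty_sites())
  if (is.null(rows) && "rows" %in% names(tasks)) rows <- tasks$rows[[1]]
  task_list <- purrr::transpose(tasks[, c("part_id", "lo", "hi", "probe_preceding")])
  worker <- function(task) {
    tryCatch(run_task(handle, task, rows), error = function(e) {
      # retry once, then surface the error
      tryCatch(run_task(handle, task, rows), error = function(e2) {
        stop("query task on partition ", task$part_id, " failed twice: ",
             conditionMessage(e2), call. = FALSE)
      })
    })
  }
  chunks <- if (workers > 1) {
    res <- parallel::mclapply(task_list, worker, mc.cores = workers)
    errs <- purrr::keep(res, inherits, "try-error")
    if (length(errs) > 0) stop(attr(errs[[1]], "condition"))
    res
  } else {
    lapply(task_list, worker)
  }
  cells <- dplyr::bind_rows(chunks)
  if (nrow(cells) == 0) return(empty_sites())
  if (".probed" %in% names(cells)) {
    probed <- which(cells$.probed %in% TRUE)
    if (length(probed) > 0) {
      covered <- purrr::map_lgl(cells$col_start[probed], function(c0) {
        any(tasks$lo <= c0 & c0 < tasks$hi)
      })
      drop <- probed[covered]
      if (length(drop) > 0) cells <- cells[-drop, , drop = FALSE]
    }
    cells$.probed <- NULL
  }
  cells <- dplyr::distinct(cells, .data$row, .data$col_start, .keep_all = TRUE)
  merge_sites(cells, handle$genome)
}

empty_sites <- function() {
  out <- tibble::tibble(
    column = numeric(), contig = character(), pos = numeric(),
    site_id = character(), ref = character(), alt = character(),
    n_calls = integer(), calls = list()
  )
  class(out) <- c("variant_sites", class(out))
  out
}

merge_sites <- function(cells, gm) {
  cells <- dplyr::arrange(cells, .data$col_start, .data$row)
  key <- paste(cells$col_start, cells$ref, cells$alt, sep = "\r")
  groups <- split(seq_len(nrow(cells)), factor(key, levels = unique(key)))
  rows <- purrr::map(groups, function(idx) {
    g <- cells[idx, , drop = FALSE]
    sid <- g$site_id[!is.na(g$site_id)]
    tibble::tibble(
      column = g$col_start[1],
      site_id = if (length(sid) > 0) sid[1] else NA_character_,
      ref = g$ref[1], alt = g$alt[1],
      n_calls = nrow(g),
      calls = list(g[, c("row", "a1", "a2", "phased", "dp", "gq", "ad", "pl")])
    )
  })
  out <- dplyr::bind_rows(rows)
  up <- unflatten_position(gm, out$column)
  out <- dplyr::bind_cols(out[, "column"], up,
                          out[, c("site_id", "ref", "alt", "n_calls", "calls")])
  out <- dplyr::arrange(out, .data$column, .data$ref, .data$alt)
  class(out) <- c("variant_sites", class(out))
  out
}

#' Query regions of a store
#'
#' Convenience wrapper: plan, execute, return merged sites.
#'
#' @inheritParams plan_query
#' @inheritParams execute_query
#' @return A `variant_sites` tibble (see [execute_query()]).
#' @export
query_regions <- function(handle, regions, rows = NULL, workers = 1) {
  tasks <- plan_query(handle, regions)
  execute_query(handle, tasks, workers = workers, rows = rows)
}

#' Count variant sites in regions
#'
#' "Variants" counts site-merged records (one per distinct column/ref/alts
#' combination with at least one call among the selected rows), not
#' per-sample cells.
#'
#' @inheritParams query_regions
#' @return Integer count.
#' @export
count_variants <- function(handle, regions, rows = NULL, workers = 1) {
  nrow(query_regions(handle, regions, rows = rows, workers = workers))
}

#' Serialize query results to tab-separated lines
#'
#' Deterministic (sorted, fixed column order) so outputs are diffable.
#'
#' @param sites A `variant_sites` tibble.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
format_sites_tsv <- function(sites, path = NULL) {
  lines <- purrr::pmap_chr(sites, function(column, contig, pos, site_id, ref,
                                           alt, n_calls, calls) {
    gt <- paste(sprintf("%d:%s", calls$row, gt_string(calls$a1, calls$a2, calls$phased)),
                collapse = ";")
    paste(contig, pos, ifelse(is.na(site_id), ".", site_id), ref,
          ifelse(alt == "", ".", alt), n_calls, gt, sep = "\t")
  })
  header <- paste("contig", "pos", "id", "ref", "alt", "n_calls", "genotypes",
                  sep = "\t")
  out <- c(header, lines)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

gt_string <- function(a1, a2, phased) {
  sep <- ifelse(phased, "|", "/")
  paste0(ifelse(is.na(a1), ".", a1), sep, ifelse(is.na(a2), ".", a2))
}
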