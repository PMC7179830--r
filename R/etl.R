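#' Loader configuration
#'
#' Mirrors the import knobs of the column-partitioned store: the number of
#' partitions the genome is split into (1000 by default), cells per tile
#' (1000), the pre-compression segment size in bytes (1048576), the codec,
#' which FORMAT/INFO fields to materialize, whether `./.` genotypes are
#' discarded, whether END-bearing records become interval cells, and the
#' worker-pool size for parallel VCF reading (20). `size_per_column_partition`
#' is accepted for config-file compatibility and ignored; it has no observable
#' effect on the store.
#'
#' @param n_partitions Number of column partitions.
#' @param cells_per_tile Cells per compression tile.
#' @param segment_size Target pre-compression bytes per segment file.
#' @param codec `"deflate"` or `"none"`.
#' @param fields Fields to load; `GT` is always included.
#' @param discard_missing_genotypes Drop `./.` calls instead of storing them.
#' @param treat_deletions_as_intervals Use INFO `END` to extend `col_end`.
#' @param parallel_readers VCF files parsed concurrently.
#' @param size_per_column_partition Accepted and ignored.
#' @return A list of class `loader_config`.
#' @export
loader_config <- function(n_partitions = 1000,
                          cells_per_tile = 1000,
                          segment_size = 1048576,
                          codec = c("deflate", "none"),
                          fields = c("GT", "END", "DP", "GQ", "AD", "PL"),
                          discard_missing_genotypes = TRUE,
                          treat_deletions_as_intervals = TRUE,
                          parallel_readers = 20,
                          size_per_column_partition = NULL) {
  codec <- match.arg(codec)
  fields <- union("GT", match.arg(fields, several.ok = TRUE,
                                  choices = c("GT", "END", "DP", "GQ", "AD", "PL")))
  stopifnot(n_partitions >= 1, cells_per_tile >= 1, segment_size >= 1,
            parallel_readers >= 1)
  structure(
    list(n_partitions = as.integer(n_partitions),
         cells_per_tile = as.integer(cells_per_tile),
         segment_size = as.numeric(segment_size),
         codec = codec, fields = fields,
         discard_missing_genotypes = isTRUE(discard_missing_genotypes),
         treat_deletions_as_intervals = isTRUE(treat_deletions_as_intervals),
         parallel_readers = as.integer(parallel_readers)),
    class = "loader_config"
  )
}

#' Read a loader configuration from JSON
#'
#' @param path JSON file whose keys mirror the [loader_config()] arguments.
#' @return A `loader_config`.
#' @export
read_loader_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(loader_config))
  do.call(loader_config, obj[intersect(names(obj), known)])
}

vcf_sample_names <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0) stop("no #CHROM header line in ", path, call. = FALSE)
    if (startsWith(line, "#CHROM")) {
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      return(if (length(f) > 9) f[-(1:9)] else character())
    }
  }
}

parse_gt_strings <- function(gt, path) {
  gt[is.na(gt)] <- "./."
  gt[gt == "."] <- "./."
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[/|]")
  n <- lengths(parts)
  if (any(n != 2)) {
    bad <- gt[n != 2][1]
    stop("non-diploid genotype '", bad, "' in ", path,
         " (ploidy is fixed at 2)", call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
  a1 <- suppressWarnings(as.integer(m[, 1]))
  a2 <- suppressWarnings(as.integer(m[, 2]))
  ok <- is.na(a1) == (m[, 1] == ".") & is.na(a2) == (m[, 2] == ".")
  if (!all(ok)) {
    stop("malformed genotype '", gt[!ok][1], "' in ", path, call. = FALSE)
  }
  list(a1 = a1, a2 = a2, phased = phased)
}

extract_info_end <- function(info) {
  info[is.na(info)] <- "."
  pos <- regexpr("(^|;)END=[0-9]+", info)
  out <- rep(NA_real_, length(info))
  hit <- pos > 0
  out[hit] <- as.numeric(sub(".*END=", "", regmatches(info, pos)))
  out
}

# Parse one VCF into a cell tibble. sample_rows: named integer vector mapping
# this file's sample names to store rows.
parse_vcf_cells <- function(path, gm, cfg, sample_rows) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  n_rec <- nrow(fix)
  skipped <- c(missing_genotype = 0, breakend_alt = 0)
  if (n_rec == 0) {
    return(list(cells = new_cell_table(), n_records = 0L,
                skipped = skipped, n_dup_warnings = 0L))
  }
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  id <- fix[, "ID"]
  id[!is.na(id) & id == "."] <- NA
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- ""
  info <- fix[, "INFO"]

  breakend <- grepl("[][]", alt)
  skipped["breakend_alt"] <- sum(breakend)

  col_start <- flatten_position(gm, chrom, pos)
  col_end <- col_start
  if (cfg$treat_deletions_as_intervals && "END" %in% cfg$fields) {
    end_pos <- extract_info_end(info)
    has_end <- !is.na(end_pos)
    if (any(has_end)) {
      col_end[has_end] <- flatten_position(gm, chrom[has_end], end_pos[has_end])
      if (any(col_end < col_start)) {
        stop("END before POS at ", chrom[which(col_end < col_start)[1]],
             ":", pos[which(col_end < col_start)[1]], " in ", path, call. = FALSE)
      }
    }
  }

  gt_mat <- vcfR::extract.gt(v, element = "GT")
  want <- function(f) f %in% cfg$fields
  dp_mat <- if (want("DP")) suppressWarnings(vcfR::extract.gt(v, element = "DP")) else NULL
  gq_mat <- if (want("GQ")) suppressWarnings(vcfR::extract.gt(v, element = "GQ")) else NULL
  ad_mat <- if (want("AD")) suppressWarnings(vcfR::extract.gt(v, element = "AD")) else NULL
  pl_mat <- if (want("PL")) suppressWarnings(vcfR::extract.gt(v, element = "PL")) else NULL

  keep_rec <- !breakend
  per_sample <- vector("list", length(sample_rows))
  for (s in seq_along(sample_rows)) {
    name <- names(sample_rows)[s]
    gt <- parse_gt_strings(gt_mat[keep_rec, name], path)
    nocall <- is.na(gt$a1) & is.na(gt$a2)
    if (cfg$discard_missing_genotypes) {
      skipped["missing_genotype"] <- skipped["missing_genotype"] + sum(nocall)
      sel <- !nocall
    } else {
      sel <- rep(TRUE, sum(keep_rec))
    }
    if (!any(sel)) next
    grab_int <- function(mat) {
      if (is.null(mat)) rep(NA_integer_, sum(sel))
      else suppressWarnings(as.integer(mat[keep_rec, name][sel]))
    }
    grab_chr <- function(mat) {
      if (is.null(mat)) rep(NA_character_, sum(sel))
      else as.character(mat[keep_rec, name][sel])
    }
    per_sample[[s]] <- tibble::tibble(
      row = rep(unname(sample_rows[s]), sum(sel)),
      col_start = col_start[keep_rec][sel],
      col_end = col_end[keep_rec][sel],
      ref = ref[keep_rec][sel],
      alt = alt[keep_rec][sel],
      a1 = gt$a1[sel], a2 = gt$a2[sel], phased = gt$phased[sel],
      dp = grab_int(dp_mat), gq = grab_int(gq_mat),
      ad = grab_chr(ad_mat), pl = grab_chr(pl_mat),
      site_id = id[keep_rec][sel]
    )
  }
  cells <- dplyr::bind_rows(per_sample)
  if (nrow(cells) == 0) cells <- new_cell_table()
  list(cells = cells, n_records = n_rec, skipped = skipped)
}

#' Import VCF files into a column-partitioned store
#'
#' Every called genotype in the inputs becomes one cell routed to the
#' partition owning its start column. Files are parsed by a worker pool of
#' `cfg$parallel_readers` processes (one worker per file); partitions are then
#' written from the merged cell set, so results are identical for any worker
#' count. Sample rows are assigned in import order and recorded in the sample
#' registry; a site dictionary of rs-identified sites is persisted alongside.
#'
#' Records with a breakend alternate allele are skipped (counted); `./.`
#' genotypes produce no cell when `discard_missing_genotypes` is set; a
#' duplicate call for the same (sample, column) keeps the last occurrence with
#' a warning. An interval cell reaching past the end of the partition
#' *following* its own is rejected: the query engine's one-partition
#' look-back bounds how far a deletion may span.
#'
#' @param vcf_paths Character vector of VCF paths (plain or gzipped).
#' @param gm A [genome_map()]; all record contigs must be declared in it.
#' @param out Output store directory (created; must not already hold a store
#'   unless `append = TRUE`).
#' @param cfg A [loader_config()].
#' @param append Merge new samples into an existing store (merge-rewrite).
#' @return A list with `store` (an open `variant_store` handle) and `report`
#'   (an `import_report`: per-partition cell counts, skip counts by reason,
#'   wall time).
#' @export
import_vcfs <- function(vcf_paths, gm, out, cfg = loader_config(), append = FALSE) {
  t0 <- Sys.time()
  stopifnot(length(vcf_paths) >= 1)
  missing <- vcf_paths[!file.exists(vcf_paths)]
  if (length(missing) > 0) {
    stop("VCF not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }

  existing_cells <- NULL
  samples0 <- tibble::tibble(sample_name = character(), row = integer())
  if (file.exists(file.path(out, "manifest.json"))) {
    if (!append) {
      stop("store already exists at ", out, " (use append = TRUE)", call. = FALSE)
    }
    old <- open_store(out)
    cfg <- loader_config(
      n_partitions = old$manifest$n_partitions,
      cells_per_tile = old$manifest$cells_per_tile,
      segment_size = old$manifest$segment_size,
      codec = old$manifest$codec, fields = old$manifest$fields,
      discard_missing_genotypes = cfg$discard_missing_genotypes,
      treat_deletions_as_intervals = cfg$treat_deletions_as_intervals,
      parallel_readers = cfg$parallel_readers
    )
    samples0 <- old$samples
    existing_cells <- purrr::map(old$parts$id, function(p) {
      pm <- old$parts[old$parts$id == p, ]
      if (pm$n_cells == 0) new_cell_table()
      else read_partition(old, p, pm$col_begin, pm$col_end)
    })
    existing_cells <- dplyr::bind_rows(existing_cells)
  }

  sample_sets <- purrr::map(vcf_paths, vcf_sample_names)
  all_names <- unlist(sample_sets)
  dup <- c(all_names[duplicated(all_names)],
           intersect(all_names, samples0$sample_name))
  if (length(dup) > 0) {
    stop("duplicate sample names: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  next_row <- if (nrow(samples0) == 0) 0L else max(samples0$row) + 1L
  samples <- dplyr::bind_rows(
    samples0,
    tibble::tibble(sample_name = all_names,
                   row = next_row + seq_along(all_names) - 1L)
  )
  row_of <- stats::setNames(samples$row, samples$sample_name)

  workers <- min(cfg$parallel_readers, length(vcf_paths))
  parse_one <- function(i) {
    sr <- row_of[sample_sets[[i]]]
    parse_vcf_cells(vcf_paths[i], gm, cfg, sr)
  }
  parsed <- if (workers > 1) {
    res <- parallel::mclapply(seq_along(vcf_paths), parse_one, mc.cores = workers)
    errs <- purrr::keep(res, inherits, "try-error")
    if (length(errs) > 0) stop(attr(errs[[1]], "condition"))
    res
  } else {
    lapply(seq_along(vcf_paths), parse_one)
  }

  cells <- dplyr::bind_rows(c(list(existing_cells %||% new_cell_table()),
                              purrr::map(parsed, "cells")))
  n_records <- sum(purrr::map_int(parsed, ~ as.integer(.x$n_records)))
  skipped <- Reduce(`+`, purrr::map(parsed, "skipped"))

  # last-writer-wins on duplicate (sample, column) calls
  dup_mask <- duplicated(cells[, c("row", "col_start")], fromLast = TRUE)
  if (any(dup_mask)) {
    warning(sum(dup_mask), " duplicate (sample, column) call(s) overwritten ",
            "(last writer wins)", call. = FALSE)
    cells <- cells[!dup_mask, , drop = FALSE]
  }

  parts <- make_partitions(gm, cfg$n_partitions)
  if (nrow(cells) > 0) {
    pid <- assign_partition(parts, cells$col_start)
    # an interval cell may reach into the next partition but not beyond it
    nxt_end <- parts$col_end[match(pid, parts$id) + 1]
    nxt_end[is.na(nxt_end)] <- gm$total_columns
    too_far <- cells$col_end >= nxt_end
    if (any(too_far)) {
      i <- which(too_far)[1]
      stop("interval cell at column ", cells$col_start[i],
           " spans more than one partition boundary (col_end ",
           cells$col_end[i], ")", call. = FALSE)
    }
    if (any(cells$col_end >= gm$total_columns)) {
      stop("interval cell extends past the end of the genome", call. = FALSE)
    }
  } else {
    pid <- integer()
  }

  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "partitions"), recursive = TRUE)
  by_part <- split(seq_len(nrow(cells)), factor(pid, levels = parts$id))
  pmeta <- vector("list", nrow(parts))
  for (k in seq_len(nrow(parts))) {
    sel <- by_part[[k]]
    pmeta[[k]] <- write_partition(out, parts[k, ],
                                  cells[sel, , drop = FALSE], cfg)
  }
  pmeta_df <- dplyr::bind_rows(purrr::map(pmeta, tibble::as_tibble))

  write_genome_map(gm, file.path(out, "genome.json"))
  utils::write.table(samples, file.path(out, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(pmeta_df, file.path(out, "partitions.json"),
                       auto_unbox = TRUE, digits = NA)

  site_rows <- cells[!is.na(cells$site_id),
                     c("site_id", "col_start", "ref", "alt"), drop = FALSE]
  sites <- dplyr::distinct(site_rows, .data$site_id, .data$col_start,
                           .keep_all = TRUE)
  conflict <- sites$site_id[duplicated(sites$site_id)]
  if (length(conflict) > 0) {
    stop("rs-identifier at multiple positions: ",
         paste(unique(conflict), collapse = ", "), call. = FALSE)
  }
  up <- unflatten_position(gm, if (nrow(sites)) sites$col_start else numeric())
  sites_out <- tibble::tibble(site_id = sites$site_id, contig = up$contig,
                              pos = up$pos, column = sites$col_start,
                              ref = sites$ref, alt = sites$alt)
  sites_out <- dplyr::arrange(sites_out, .data$column)
  utils::write.table(sites_out, file.path(out, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  write_store_manifest(out, cfg, nrow(samples))

  report <- structure(
    list(
      n_files = length(vcf_paths),
      n_samples = length(all_names),
      n_records = n_records,
      n_cells = nrow(cells),
      per_partition = tibble::tibble(id = parts$id,
                                     n_cells = pmeta_df$n_cells),
      skipped = tibble::tibble(reason = names(skipped),
                               n = as.integer(unname(skipped))),
      wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "import_report"
  )
  list(store = open_store(out), report = report)
}

#' @export
print.import_report <- function(x, ...) {
  cat("<import_report> ", x$n_files, " file(s), ", x$n_samples, " sample(s), ",
      x$n_records, " record(s) -> ", x$n_cells, " cell(s) in ",
      sprintf("%.2fs", x$wall_time_sec), "\n", sep = "")
  sk <- x$skipped[x$skipped$n > 0, ]
  if (nrow(sk) > 0) {
    cat("  skipped:", paste(sprintf("%s=%d", sk$reason, sk$n), collapse = " "), "\n")
  }
  invisible(x)
}

#' Build a site dictionary from VCF files
#'
#' Indexes every record with a non-`.` ID column by its rs-identifier. The
#' same identifier at two different positions is an error (both listed).
#'
#' @param vcf_paths VCF files.
#' @param gm Optional [genome_map()]; when given, flattened columns are added.
#' @return A tibble with `site_id`, `contig`, `pos`, `ref`, `alt` (and
#'   `column` when `gm` is supplied).
#' @export
build_site_dictionary <- function(vcf_paths, gm = NULL) {
  rows <- purrr::map(vcf_paths, function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- v@fix
    if (nrow(fix) == 0) return(NULL)
    id <- fix[, "ID"]
    keep <- !is.na(id) & id != "."
    if (!any(keep)) return(NULL)
    tibble::tibble(site_id = id[keep], contig = fix[keep, "CHROM"],
                   pos = as.numeric(fix[keep, "POS"]),
                   ref = fix[keep, "REF"],
                   alt = ifelse(is.na(fix[keep, "ALT"]), "", fix[keep, "ALT"]))
  })
  dict <- dplyr::distinct(dplyr::bind_rows(rows))
  multi <- dict %>%
    dplyr::count(.data$site_id) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    clash <- dict[dict$site_id %in% multi$site_id, ]
    stop("rs-identifier collision: ",
         paste(sprintf("%s@%s:%s", clash$site_id, clash$contig, clash$pos),
               collapse = ", "), call. = FALSE)
  }
  if (!is.null(gm)) dict$column <- flatten_position(gm, dict$contig, dict$pos)
  dict
}

#' Look up an rs-identifier in a site dictionary
#'
#' @param dict A site dictionary tibble (from [build_site_dictionary()] or a
#'   store handle's `sites`).
#' @param rsid Identifier to resolve.
#' @return The matching one-row tibble.
#' @export
lookup_site <- function(dict, rsid) {
  hit <- dict[dict$site_id == rsid, , drop = FALSE]
  if (nrow(hit) == 0) stop("unknown identifier: ", rsid, call. = FALSE)
  hit
}
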