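#' Empty variant-cell table
#'
#' Cells are the entries of the sparse sample-by-position matrix: one sample's
#' call at one site. Throughout the package a set of cells is a tibble with
#' this schema:
#'
#' * `row` — sample row index (0-based, assigned at import, never reused)
#' * `col_start`, `col_end` — 0-based global columns, both inclusive;
#'   `col_end > col_start` only for interval (END-bearing deletion) records
#' * `ref`, `alt` — reference allele and comma-joined alternate allele list
#' * `a1`, `a2`, `phased` — diploid genotype as allele indices (`NA` = no-call
#'   allele; 0 = ref, k = k-th alternate) and the phasing flag
#' * `dp`, `gq` — read depth and genotype quality (`NA` when absent)
#' * `ad`, `pl` — comma-joined per-allele depths / phred genotype likelihoods
#' * `site_id` — the VCF ID column (rs-identifier) or `NA`
#'
#' @return A zero-row tibble with the cell schema.
#' @export
new_cell_table <- function() {
  tibble::tibble(
    row = integer(), col_start = numeric(), col_end = numeric(),
    ref = character(), alt = character(),
    a1 = integer(), a2 = integer(), phased = logical(),
    dp = integer(), gq = integer(), ad = character(), pl = character(),
    site_id = character()
  )
}

CELL_COLUMNS <- c("row", "col_start", "col_end", "ref", "alt", "a1", "a2",
                  "phased", "dp", "gq", "ad", "pl", "site_id")

#' @keywords internal
validate_cells <- function(cells) {
  missing <- setdiff(CELL_COLUMNS, names(cells))
  if (length(missing) > 0) {
    stop("cell table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(cells$col_end < cells$col_start)) {
    stop("cell with col_end < col_start", call. = FALSE)
  }
  n_alts <- ifelse(cells$alt == "", 0L, lengths(strsplit(cells$alt, ",", fixed = TRUE)))
  for (g in c("a1", "a2")) {
    bad <- !is.na(cells[[g]]) & (cells[[g]] < 0 | cells[[g]] > n_alts)
    if (any(bad)) {
      i <- which(bad)[1]
      stop("allele index ", cells[[g]][i], " out of range at column ",
           cells$col_start[i], " (", n_alts[i], " alts)", call. = FALSE)
    }
  }
  has_ad <- !is.na(cells$ad)
  if (any(has_ad)) {
    ad_len <- lengths(strsplit(cells$ad[has_ad], ",", fixed = TRUE))
    if (any(ad_len != 1L + n_alts[has_ad])) {
      stop("AD length must equal 1 + number of alts", call. = FALSE)
    }
  }
  invisible(cells)
}

part_dir <- function(store_path, part_id) {
  file.path(store_path, "partitions", sprintf("p%05d", part_id))
}

compress_blob <- function(raw, codec) {
  switch(codec,
    none = raw,
    deflate = memCompress(raw, type = "gzip"),
    stop("unknown codec: ", codec, call. = FALSE)
  )
}

decompress_blob <- function(raw, codec) {
  switch(codec,
    none = raw,
    deflate = memDecompress(raw, type = "gzip"),
    stop("unknown codec: ", codec, call. = FALSE)
  )
}

#' Write one partition of cells to disk
#'
#' Cells are sorted by `(col_start, row)`, grouped into tiles of at most
#' `cells_per_tile` cells, and each tile is serialized and compressed
#' independently so that a query can decompress only the tiles whose column
#' range it intersects. Tiles are concatenated into segment files that roll
#' over when the pre-compression byte count passes `segment_size`. A tile
#' index (per-tile column bounds, cell count, byte extent) and partition
#' metadata (including the maximum END overhang past the partition's right
#' edge) are written alongside.
#'
#' @param store_path Store directory.
#' @param part One row of a [make_partitions()] table (or a list with `id`,
#'   `col_begin`, `col_end`).
#' @param cells Cell tibble; every `col_start` must lie inside the partition.
#' @param cfg A [loader_config()].
#' @return Invisibly, the partition metadata list.
#' @export
write_partition <- function(store_path, part, cells, cfg = loader_config()) {
  validate_cells(cells)
  out_of_range <- cells$col_start < part$col_begin | cells$col_start >= part$col_end
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    stop("cell (row ", cells$row[i], ", col ", cells$col_start[i],
         ") outside partition [", part$col_begin, ", ", part$col_end, ")",
         call. = FALSE)
  }
  cells <- dplyr::arrange(cells, .data$col_start, .data$row)
  dir <- part_dir(store_path, part$id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  n <- nrow(cells)
  n_tiles <- if (n == 0) 0L else ceiling(n / cfg$cells_per_tile)
  index <- vector("list", n_tiles)
  seg_id <- 0L
  seg_bytes_raw <- 0   # pre-compression bytes in current segment
  con <- NULL
  open_segment <- function() {
    if (!is.null(con)) close(con)
    con <<- file(file.path(dir, sprintf("seg%04d.bin", seg_id)), "wb")
    seg_bytes_raw <<- 0
  }
  if (n_tiles > 0) open_segment()
  offset <- 0
  for (t in seq_len(n_tiles)) {
    lo <- (t - 1L) * cfg$cells_per_tile + 1L
    hi <- min(t * cfg$cells_per_tile, n)
    tile <- as.data.frame(cells[lo:hi, , drop = FALSE])
    raw <- serialize(tile, NULL, xdr = TRUE)
    if (seg_bytes_raw > 0 && seg_bytes_raw + length(raw) > cfg$segment_size) {
      seg_id <- seg_id + 1L
      open_segment()
      offset <- 0
    }
    blob <- compress_blob(raw, cfg$codec)
    writeBin(blob, con)
    index[[t]] <- list(
      tile = t - 1L, segment = seg_id, offset = offset, length = length(blob),
      min_col = cells$col_start[lo], max_col = cells$col_start[hi],
      n_cells = hi - lo + 1L
    )
    offset <- offset + length(blob)
    seg_bytes_raw <- seg_bytes_raw + length(raw)
  }
  if (!is.null(con)) close(con)

  overhang <- if (n == 0) 0 else max(max(cells$col_end) - part$col_end + 1, 0)
  meta <- list(
    id = part$id, col_begin = part$col_begin, col_end = part$col_end,
    n_cells = n, n_tiles = n_tiles, n_segments = if (n_tiles > 0) seg_id + 1L else 0L,
    max_end_overhang = overhang, codec = cfg$codec
  )
  jsonlite::write_json(index, file.path(dir, "tile_index.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(meta)
}

#' Open an existing variant store
#'
#' Validates the manifest and the checksums of the genome map, sample registry
#' and partition metadata recorded in it, then returns a read-only handle.
#'
#' @param path Store directory containing `manifest.json`.
#' @return A `variant_store` handle: manifest, genome map, partition table with
#'   per-partition metadata, sample registry, site dictionary (when present)
#'   and an I/O counter environment (see [store_counters()]).
#' @export
open_store <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest at ", path, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  for (f in c("genome.json", "samples.tsv", "partitions.json")) {
    expect <- manifest$digests[[f]]
    got <- unname(tools::md5sum(file.path(path, f)))
    if (is.na(got)) stop("store file missing: ", f, call. = FALSE)
    if (!identical(expect, got)) {
      stop("metadata digest mismatch for ", f, call. = FALSE)
    }
  }
  gm <- read_genome_map(file.path(path, "genome.json"))
  samples <- utils::read.delim(file.path(path, "samples.tsv"),
                               colClasses = c("character", "integer"))
  pmeta <- jsonlite::read_json(file.path(path, "partitions.json"),
                               simplifyVector = TRUE)
  parts <- tibble::as_tibble(pmeta)
  sites_path <- file.path(path, "sites.tsv")
  sites <- if (file.exists(sites_path)) {
    tibble::as_tibble(utils::read.delim(sites_path, colClasses = c(
      site_id = "character", contig = "character", pos = "numeric",
      column = "numeric", ref = "character", alt = "character"
    )))
  } else NULL
  counters <- new.env(parent = emptyenv())
  reset_env_counters(counters)
  structure(
    list(path = path, manifest = manifest, genome = gm, parts = parts,
         samples = tibble::as_tibble(samples), sites = sites,
         counters = counters),
    class = "variant_store"
  )
}

reset_env_counters <- function(env) {
  env$tiles_decompressed <- 0
  env$cells_touched <- 0
  env$cells_returned <- 0
  invisible(env)
}

#' Inspect or reset a store handle's I/O counters
#'
#' The handle counts tiles decompressed and cells touched (deserialized) and
#' returned across all reads since the last reset. `cells_touched` is the
#' deterministic cost proxy used by the scaling benchmark.
#'
#' @param handle A `variant_store`.
#' @return `store_counters()` returns a one-row tibble; `reset_store_counters()`
#'   returns the handle invisibly.
#' @export
store_counters <- function(handle) {
  tibble::tibble(
    tiles_decompressed = handle$counters$tiles_decompressed,
    cells_touched = handle$counters$cells_touched,
    cells_returned = handle$counters$cells_returned
  )
}

#' @rdname store_counters
#' @export
reset_store_counters <- function(handle) {
  reset_env_counters(handle$counters)
  invisible(handle)
}

#' @export
print.variant_store <- function(x, ...) {
  cat("<variant_store> ", x$path, "\n",
      "  samples: ", nrow(x$samples),
      "  partitions: ", nrow(x$parts),
      "  cells: ", sum(x$parts$n_cells),
      "  fields: ", paste(x$manifest$fields, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Read cells from one partition
#'
#' Returns exactly the cells with `col_start` in `[col_lo, col_hi)`, in
#' `(col_start, row)` order. Only tiles whose recorded column bounds intersect
#' the query are decompressed (observable via [store_counters()]); the debug
#' flag `skip_tiles = FALSE` decompresses everything and must give identical
#' results.
#'
#' @param handle A `variant_store`.
#' @param part_id Partition id.
#' @param col_lo,col_hi Half-open column range.
#' @param rows Optional integer vector restricting sample rows.
#' @param skip_tiles Use the tile index to skip non-intersecting tiles.
#' @return A cell tibble.
#' @export
read_partition <- function(handle, part_id, col_lo, col_hi, rows = NULL,
                           skip_tiles = TRUE) {
  pm <- handle$parts[handle$parts$id == part_id, ]
  if (nrow(pm) != 1) stop("invalid partition id: ", part_id, call. = FALSE)
  if (col_lo >= col_hi) stop("empty column range", call. = FALSE)
  dir <- part_dir(handle$path, part_id)
  index <- jsonlite::read_json(file.path(dir, "tile_index.json"),
                               simplifyVector = TRUE)
  if (length(index) == 0 || NROW(index) == 0) return(new_cell_table())
  index <- tibble::as_tibble(index)
  hit <- if (skip_tiles) index$max_col >= col_lo & index$min_col < col_hi
         else rep(TRUE, nrow(index))
  hits <- index[hit, , drop = FALSE]
  if (nrow(hits) == 0) return(new_cell_table())
  chunks <- vector("list", nrow(hits))
  for (s in unique(hits$segment)) {
    seg_path <- file.path(dir, sprintf("seg%04d.bin", s))
    seg_raw <- readBin(seg_path, what = "raw", n = file.size(seg_path))
    for (i in which(hits$segment == s)) {
      blob <- seg_raw[(hits$offset[i] + 1):(hits$offset[i] + hits$length[i])]
      tile <- unserialize(decompress_blob(blob, pm$codec))
      chunks[[i]] <- tile
    }
  }
  handle$counters$tiles_decompressed <- handle$counters$tiles_decompressed + nrow(hits)
  cells <- tibble::as_tibble(do.call(rbind, chunks))
  handle$counters$cells_touched <- handle$counters$cells_touched + nrow(cells)
  cells <- cells[cells$col_start >= col_lo & cells$col_start < col_hi, , drop = FALSE]
  if (!is.null(rows)) cells <- cells[cells$row %in% rows, , drop = FALSE]
  handle$counters$cells_returned <- handle$counters$cells_returned + nrow(cells)
  cells
}

#' Total on-disk size of a store
#'
#' @param handle A `variant_store` (or a store path).
#' @return Total bytes of all files under the store directory.
#' @export
store_size_bytes <- function(handle) {
  path <- if (inherits(handle, "variant_store")) handle$path else handle
  files <- list.files(path, recursive = TRUE, full.names = TRUE)
  sum(file.size(files))
}

#' @keywords internal
write_store_manifest <- function(path, cfg, n_samples) {
  digests <- vapply(c("genome.json", "samples.tsv", "partitions.json"),
                    function(f) unname(tools::md5sum(file.path(path, f))),
                    character(1))
  manifest <- list(
    format_version = 1L,
    n_partitions = cfg$n_partitions,
    cells_per_tile = cfg$cells_per_tile,
    segment_size = cfg$segment_size,
    codec = cfg$codec,
    fields = cfg$fields,
    n_samples = n_samples,
    digests = as.list(digests),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
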