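#' Build a genome map
#'
#' A genome map fixes an ordered set of contigs and flattens (contig, 1-based
#' position) pairs onto a single 0-based global column axis, the horizontal
#' axis of the sparse sample-by-position matrix. All downstream partitioning
#' and querying works in flattened columns; conversion to and from VCF-style
#' coordinates happens only in [flatten_position()] and [unflatten_position()].
#'
#' Columns are stored as doubles so genomes larger than `.Machine$integer.max`
#' base pairs are representable exactly (doubles hold integers up to 2^53).
#'
#' @param contigs A data frame with columns `name` and `length`, or a named
#'   numeric vector of contig lengths.
#' @return An object of class `genome_map`: a list with `contigs` (tibble of
#'   `name`, `length`, `offset`) and `total_columns`.
#' @examples
#' gm <- genome_map(c(chr1 = 1000, chr2 = 500))
#' gm$total_columns
#' @export
genome_map <- function(contigs) {
  if (is.numeric(contigs)) {
    if (is.null(names(contigs)) || any(names(contigs) == "")) {
      stop("contig lengths must be named", call. = FALSE)
    }
    contigs <- tibble::tibble(name = names(contigs), length = unname(contigs))
  }
  contigs <- tibble::as_tibble(contigs)
  if (!all(c("name", "length") %in% names(contigs))) {
    stop("contigs needs columns 'name' and 'length'", call. = FALSE)
  }
  contigs$name <- as.character(contigs$name)
  contigs$length <- as.numeric(contigs$length)
  if (nrow(contigs) == 0) stop("genome map needs at least one contig", call. = FALSE)
  if (anyDuplicated(contigs$name)) {
    stop("duplicate contig names: ",
         paste(unique(contigs$name[duplicated(contigs$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(contigs$length < 1 | contigs$length != floor(contigs$length))) {
    stop("contig lengths must be positive integers", call. = FALSE)
  }
  contigs$offset <- cumsum(c(0, contigs$length[-nrow(contigs)]))
  structure(
    list(contigs = contigs[, c("name", "length", "offset")],
         total_columns = sum(contigs$length)),
    class = "genome_map"
  )
}

#' @export
print.genome_map <- function(x, ...) {
  cat("<genome_map> ", nrow(x$contigs), " contigs, ",
      format(x$total_columns, big.mark = ","), " columns\n", sep = "")
  print(x$contigs, ...)
  invisible(x)
}

#' Flatten a genomic position to a global column
#'
#' @param gm A [genome_map()].
#' @param contig Contig name(s).
#' @param pos 1-based position(s) within the contig.
#' @return 0-based global column(s), as numeric.
#' @examples
#' gm <- genome_map(c(chr1 = 1000, chr2 = 500))
#' flatten_position(gm, "chr2", 1) # 1000
#' @export
flatten_position <- function(gm, contig, pos) {
  stopifnot(inherits(gm, "genome_map"))
  idx <- match(contig, gm$contigs$name)
  if (anyNA(idx)) {
    stop("unknown contig: ", paste(unique(contig[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  pos <- as.numeric(pos)
  len <- gm$contigs$length[idx]
  bad <- pos < 1 | pos > len
  if (any(bad)) {
    i <- which(bad)[1]
    stop("position ", pos[i], " out of range for contig ", contig[i],
         " (length ", len[i], ")", call. = FALSE)
  }
  gm$contigs$offset[idx] + pos - 1
}

#' Unflatten a global column back to (contig, position)
#'
#' Inverse of [flatten_position()] for every valid input.
#'
#' @param gm A [genome_map()].
#' @param col 0-based global column(s).
#' @return A tibble with columns `contig` and `pos` (1-based).
#' @export
unflatten_position <- function(gm, col) {
  stopifnot(inherits(gm, "genome_map"))
  col <- as.numeric(col)
  if (any(col < 0 | col >= gm$total_columns)) {
    stop("column out of range [0, ", gm$total_columns, ")", call. = FALSE)
  }
  idx <- findInterval(col, gm$contigs$offset)
  tibble::tibble(
    contig = gm$contigs$name[idx],
    pos = col - gm$contigs$offset[idx] + 1
  )
}

#' Split the column space into evenly sized partitions
#'
#' Static partitioning of the flattened genome into `n` contiguous half-open
#' column ranges, the unit of storage and of query-task assignment. Widths are
#' `ceiling(total_columns / n)` with a possibly shorter final partition, so the
#' ranges tile `[0, total_columns)` exactly. The default of 1000 partitions
#' matches the import layout the store was designed around.
#'
#' @param gm A [genome_map()].
#' @param n Number of partitions (default 1000).
#' @return A tibble of class `partition_spec` with columns `id` (0-based),
#'   `col_begin` (inclusive), `col_end` (exclusive).
#' @examples
#' gm <- genome_map(c(chr1 = 1000, chr2 = 500))
#' make_partitions(gm, 3)
#' @export
make_partitions <- function(gm, n = 1000) {
  stopifnot(inherits(gm, "genome_map"))
  n <- as.integer(n)
  if (length(n) != 1 || is.na(n) || n < 1) stop("n must be a positive integer", call. = FALSE)
  if (n > gm$total_columns) {
    stop("cannot make ", n, " partitions over ", gm$total_columns, " columns",
         call. = FALSE)
  }
  width <- ceiling(gm$total_columns / n)
  begin <- pmin((seq_len(n) - 1) * width, gm$total_columns)
  out <- tibble::tibble(
    id = seq_len(n) - 1L,
    col_begin = begin,
    col_end = pmin(begin + width, gm$total_columns)
  )
  class(out) <- c("partition_spec", class(out))
  out
}

#' Assign a column to its owning partition
#'
#' @param parts A partition table from [make_partitions()].
#' @param col 0-based column(s).
#' @return Partition id(s) such that `col_begin <= col < col_end`.
#' @export
assign_partition <- function(parts, col) {
  col <- as.numeric(col)
  total <- parts$col_end[nrow(parts)]
  if (any(col < 0 | col >= total)) {
    stop("column out of range [0, ", total, ")", call. = FALSE)
  }
  parts$id[findInterval(col, parts$col_begin)]
}

#' Write / read a genome map as JSON
#'
#' The serialized form is `{"contigs": [{"name": ..., "length": ...}, ...]}`.
#'
#' @param gm A [genome_map()].
#' @param path File path.
#' @return `write_genome_map()` returns `path` invisibly; `read_genome_map()`
#'   returns a `genome_map`.
#' @export
write_genome_map <- function(gm, path) {
  stopifnot(inherits(gm, "genome_map"))
  jsonlite::write_json(
    list(contigs = gm$contigs[, c("name", "length")]),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_genome_map
#' @export
read_genome_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  genome_map(tibble::as_tibble(obj$contigs))
}

#' Derive a genome map from VCF header contig lines
#'
#' Contig order is the header order of the file; subsequent files imported into
#' the same store must declare a consistent subset.
#'
#' @param vcf_path Path to a VCF (plain or gzipped) with `##contig` lines.
#' @return A `genome_map`.
#' @export
genome_map_from_vcf <- function(vcf_path) {
  con <- if (grepl("\\.gz$", vcf_path)) gzfile(vcf_path, "rt") else file(vcf_path, "rt")
  on.exit(close(con))
  names <- character()
  lengths <- numeric()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0 || !startsWith(line, "##")) break
    if (startsWith(line, "##contig=")) {
      id <- sub(".*[<,]ID=([^,>]+).*", "\\1", line)
      len <- suppressWarnings(as.numeric(sub(".*[<,]length=([0-9]+).*", "\\1", line)))
      if (is.na(len)) stop("contig line without length: ", line, call. = FALSE)
      names <- c(names, id)
      lengths <- c(lengths, len)
    }
  }
  if (length(names) == 0) stop("no ##contig lines in ", vcf_path, call. = FALSE)
  genome_map(stats::setNames(lengths, names))
}
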