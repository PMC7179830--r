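# Shared fixtures: hand-built VCFs and an independent brute-force oracle that
# parses VCF text directly (no vcfR, no store code) so scatter-gather results
# can be checked against a second, unrelated path.

tiny_gm <- function() genome_map(c(chr1 = 1000, chr2 = 500))

# records: data.frame(contig, pos, id, ref, alt, info, format, <sample gt strings...>)
write_test_vcf <- function(path, contigs, records, sample_names,
                           format = "GT") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  body <- apply(records, 1, function(r) paste(r, collapse = "\t"))
  writeLines(c(header, body), path)
  path
}

make_record <- function(contig, pos, ref, alt, gts, id = ".", info = ".",
                        format = "GT") {
  c(contig, pos, id, ref, alt, ".", "PASS", info, format, gts)
}

# Direct scan of VCF text. Returns one row per called genotype with the raw
# GT string, flattened start column and, if END present, the end column.
oracle_scan <- function(vcf_paths, contig_lengths, discard_missing = TRUE) {
  offsets <- cumsum(c(0, contig_lengths[-length(contig_lengths)]))
  names(offsets) <- names(contig_lengths)
  next_row <- 0
  out <- list()
  for (path in vcf_paths) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "##")]
    hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    samples <- if (length(hdr) > 9) hdr[-(1:9)] else character()
    rows <- as.integer(next_row + seq_along(samples) - 1)
    next_row <- next_row + length(samples)
    for (line in lines[-1]) {
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      col <- offsets[[f[1]]] + as.numeric(f[2]) - 1
      endm <- regmatches(f[8], regexpr("END=[0-9]+", f[8]))
      col_end <- if (length(endm) == 1) {
        offsets[[f[1]]] + as.numeric(sub("END=", "", endm)) - 1
      } else col
      fmt_keys <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      gt_at <- match("GT", fmt_keys)
      for (s in seq_along(samples)) {
        gt <- strsplit(f[9 + s], ":", fixed = TRUE)[[1]][gt_at]
        if (discard_missing && gt %in% c("./.", ".|.", ".")) next
        out[[length(out) + 1]] <- data.frame(
          row = rows[s], col_start = col, col_end = col_end,
          ref = f[4], alt = f[5], id = f[3], gt = gt,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(row = numeric(), col_start = numeric(),
                      col_end = numeric(), ref = character(),
                      alt = character(), id = character(), gt = character())
  }
  res[order(res$col_start, res$row), , drop = FALSE]
}

# Flatten query results into comparable per-call rows.
sites_to_calls <- function(sites) {
  if (nrow(sites) == 0) {
    return(data.frame(row = integer(), col_start = numeric(),
                      ref = character(), alt = character(), gt = character()))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    calls <- sites$calls[[i]]
    sep <- ifelse(calls$phased, "|", "/")
    data.frame(
      row = calls$row, col_start = sites$column[i],
      ref = sites$ref[i], alt = sites$alt[i],
      gt = paste0(ifelse(is.na(calls$a1), ".", calls$a1), sep,
                  ifelse(is.na(calls$a2), ".", calls$a2)),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$col_start, out$row), , drop = FALSE]
  rownames(out) <- NULL
  out
}

filter_oracle <- function(oracle, gm, regions) {
  lo <- flatten_position(gm, regions$contig, regions$start)
  hi <- flatten_position(gm, regions$contig, regions$end) + 1
  keep <- vapply(oracle$col_start, function(c0) any(c0 >= lo & c0 < hi), logical(1))
  out <- oracle[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Small imported store backed by a synthetic microarray cohort.
make_test_store <- function(seed = 11, n_samples = 12, n_loci = 150,
                            n_partitions = 7,
                            genome = c(chr1 = 10000, chr2 = 5000), ...) {
  td <- withr::local_tempdir(.local_envir = parent.frame())
  spec <- synth_spec(seed = seed, n_samples = n_samples, n_loci = n_loci,
                     genome = genome, ...)
  man <- gen_cohort(spec, file.path(td, "cohort"))
  res <- import_vcfs(man$files$vcf, man$genome, file.path(td, "store"),
                     loader_config(n_partitions = n_partitions,
                                   parallel_readers = 2))
  list(dir = td, spec = spec, manifest = man, store = res$store,
       report = res$report)
}
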