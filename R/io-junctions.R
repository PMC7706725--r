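## Junction count tables: the central container of the pipeline.
##
## A `jct_table` holds a junctions-by-samples matrix of non-negative integer
## read counts plus junction identity and sample metadata. Only uniquely
## mapped reads are counted when reading STAR output (column 7); the
## multi-mapping column is ignored.

#' Construct a junction count table
#'
#' @param junctions tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open intron interval), `strand` (`"+"`/`"-"`), and optionally
#'   `annotated` (logical) and `strand_undefined` (logical flag set for
#'   junctions whose input strand was undefined).
#' @param samples tibble with columns `sample_id`, `tissue`, `fraction`
#'   (`"IP"` or `"input"`), `replicate` (positive integer).
#' @param counts integer matrix, junctions x samples, non-negative.
#' @return object of class `jct_table`.
#' @export
jct_table <- function(junctions, samples, counts) {
  junctions <- as_tibble(junctions)
  samples <- as_tibble(samples)
  if (!"annotated" %in% names(junctions)) junctions$annotated <- TRUE
  if (!"strand_undefined" %in% names(junctions)) junctions$strand_undefined <- FALSE
  junctions$junction_id <- junction_key(
    junctions$chrom, junctions$start, junctions$end, junctions$strand
  )
  junctions <- select(
    junctions, "junction_id", "chrom", "start", "end", "strand",
    "annotated", "strand_undefined"
  )
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  stopifnot(
    nrow(counts) == nrow(junctions),
    ncol(counts) == nrow(samples),
    all(counts >= 0L, na.rm = FALSE),
    all(junctions$end > junctions$start),
    all(junctions$start >= 0L)
  )
  if (anyDuplicated(junctions$junction_id)) {
    abort("duplicate junctions in table")
  }
  if (anyDuplicated(samples[c("tissue", "fraction", "replicate")])) {
    abort("sample metadata (tissue, fraction, replicate) must be unique")
  }
  dimnames(counts) <- list(junctions$junction_id, samples$sample_id)
  structure(
    list(junctions = junctions, samples = samples, counts = counts),
    class = "jct_table"
  )
}

#' @export
print.jct_table <- function(x, ...) {
  cat(
    "<jct_table> ", nrow(x$junctions), " junctions x ",
    nrow(x$samples), " samples\n",
    sep = ""
  )
  cat("tissues:", paste(unique(x$samples$tissue), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn jct_table long tibble of counts with junction and sample metadata.
#' @param x a `jct_table`.
#' @param ... unused.
#' @export
tidy.jct_table <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "junction_id") |>
    tidyr::pivot_longer(-"junction_id", names_to = "sample_id", values_to = "count")
  long |>
    left_join(x$junctions, by = "junction_id") |>
    left_join(x$samples, by = "sample_id")
}

#' @describeIn jct_table one-row summary of the table.
#' @export
glance.jct_table <- function(x, ...) {
  tibble(
    n_junctions = nrow(x$junctions),
    n_samples = nrow(x$samples),
    n_tissues = length(unique(x$samples$tissue)),
    total_reads = sum(x$counts)
  )
}

star_sj_columns <- c(
  "chrom", "first_base", "last_base", "strand_code", "motif",
  "annotated", "unique_reads", "multi_reads", "overhang"
)

parse_star_sj_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), annotated = logical(),
      strand_undefined = logical(), count = integer()
    ))
  }
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0) {
    abort(sprintf("malformed STAR SJ line %d in '%s'", bad[1], path))
  }
  m <- do.call(rbind, fields)
  colnames(m) <- star_sj_columns
  num <- suppressWarnings(apply(m[, -1, drop = FALSE], 2, as.numeric))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1, dimnames = list(NULL, star_sj_columns[-1]))
  if (anyNA(num)) {
    abort(sprintf(
      "malformed STAR SJ line %d in '%s' (non-numeric field)",
      which(rowSums(is.na(num)) > 0)[1], path
    ))
  }
  strand_code <- unname(num[, "strand_code"])
  undefined <- strand_code == 0
  if (any(undefined)) {
    warn(sprintf(
      "%d junction(s) with undefined strand kept as '+' in '%s'",
      sum(undefined), path
    ))
  }
  tibble(
    chrom = m[, "chrom"],
    # STAR reports the 1-based first and last intronic base; convert to
    # 0-based half-open: start = first - 1, end = last
    start = as.integer(num[, "first_base"]) - 1L,
    end = as.integer(num[, "last_base"]),
    strand = ifelse(strand_code == 2, "-", "+"),
    annotated = unname(num[, "annotated"] > 0),
    strand_undefined = undefined,
    count = as.integer(unname(num[, "unique_reads"]))
  )
}

#' Read junction read counts
#'
#' Reads one sample per file in the STAR `SJ.out.tab` dialect, or a full
#' multi-sample table in the package's generic TSV dialect, and normalizes
#' intron coordinates to 0-based half-open. For STAR files only the
#' uniquely-mapped read column is used as the count. Junctions are merged
#' across files by identity `(chrom, start, end, strand)`.
#'
#' @param paths file path(s); several STAR files merge into one table.
#' @param dialect `"star_sj"` or `"generic_tsv"`.
#' @param samples optional sample metadata tibble (`sample_id`, `tissue`,
#'   `fraction`, `replicate`), one row per STAR file in order. Defaults to
#'   one IP sample per file named after the file.
#' @return a [jct_table].
#' @export
read_junction_counts <- function(paths, dialect = c("star_sj", "generic_tsv"),
                                 samples = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(all(file.exists(paths)))
  if (dialect == "generic_tsv") {
    stopifnot(length(paths) == 1)
    return(read_junction_generic(paths))
  }
  per_file <- map(paths, parse_star_sj_file)
  if (is.null(samples)) {
    ids <- make.unique(sub("\\.[^.]*$", "", basename(paths)))
    samples <- tibble(
      sample_id = ids, tissue = ids, fraction = "IP",
      replicate = seq_along(paths)
    )
  }
  stopifnot(nrow(samples) == length(paths))
  junctions <- bind_rows(per_file) |>
    group_by(.data$chrom, .data$start, .data$end, .data$strand) |>
    summarise(
      annotated = any(.data$annotated),
      strand_undefined = any(.data$strand_undefined),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$start, .data$end, .data$strand)
  key <- junction_key(junctions$chrom, junctions$start, junctions$end, junctions$strand)
  counts <- matrix(0L, nrow = nrow(junctions), ncol = length(paths))
  for (i in seq_along(per_file)) {
    f <- per_file[[i]]
    if (nrow(f) == 0) next
    idx <- match(junction_key(f$chrom, f$start, f$end, f$strand), key)
    counts[idx, i] <- f$count
  }
  jct_table(junctions, samples, counts)
}

read_junction_generic <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#sample\t", lines, value = TRUE)
  samples <- NULL
  if (length(meta_lines) > 0) {
    parts <- strsplit(meta_lines, "\t", fixed = TRUE)
    samples <- tibble(
      sample_id = map_chr(parts, 2),
      tissue = map_chr(parts, 3),
      fraction = map_chr(parts, 4),
      replicate = as.integer(map_chr(parts, 5))
    )
  }
  tab <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE
  )
  fixed <- c("chrom", "start", "end", "strand", "annotated", "strand_undefined")
  stopifnot(all(fixed %in% names(tab)))
  sample_ids <- setdiff(names(tab), fixed)
  if (is.null(samples)) {
    samples <- tibble(
      sample_id = sample_ids, tissue = sample_ids,
      fraction = "IP", replicate = seq_along(sample_ids)
    )
  }
  stopifnot(identical(sort(samples$sample_id), sort(sample_ids)))
  jct_table(
    tab[fixed],
    samples,
    as.matrix(tab[samples$sample_id])
  )
}

#' Write a junction count table as generic TSV
#'
#' Output rows are sorted by (chrom, start, end, strand) and sample metadata
#' is embedded in `#sample` header lines, so write/read round-trips exactly.
#'
#' @param x a [jct_table].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_junction_counts <- function(x, path) {
  ord <- order(x$junctions$chrom, x$junctions$start, x$junctions$end, x$junctions$strand)
  tab <- bind_cols(
    x$junctions[ord, c("chrom", "start", "end", "strand", "annotated", "strand_undefined")],
    as_tibble(x$counts[ord, , drop = FALSE])
  )
  meta <- sprintf(
    "#sample\t%s\t%s\t%s\t%d",
    x$samples$sample_id, x$samples$tissue, x$samples$fraction, x$samples$replicate
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  if (nrow(tab) > 0) {
    body <- do.call(paste, c(lapply(tab, format_tsv_field), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

format_tsv_field <- function(v) {
  if (is.logical(v)) return(ifelse(v, "TRUE", "FALSE"))
  as.character(v)
}

#' Convert internal junctions back to STAR SJ.out.tab fields
#'
#' The inverse of the `star_sj` coordinate conversion (involution check):
#' internal `[start, end)` maps back to 1-based first/last intronic base.
#'
#' @param junctions junction tibble as in [jct_table()].
#' @return tibble with `chrom`, `first_base`, `last_base`, `strand_code`.
#' @export
junctions_to_star <- function(junctions) {
  tibble(
    chrom = junctions$chrom,
    first_base = junctions$start + 1L,
    last_base = junctions$end,
    strand_code = ifelse(
      junctions$strand_undefined %||% FALSE, 0L,
      ifelse(junctions$strand == "-", 2L, 1L)
    )
  )
}
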