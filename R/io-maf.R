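## Multi-species alignments (MAF blocks) with reference coordinate maps.

#' Construct a species alignment
#'
#' A gapped multiple alignment anchored on one reference species, with a map
#' from ungapped reference positions to alignment columns.
#'
#' @param rows named character vector of equal-length gapped sequences over
#'   `A,C,G,T,N,-` (names are species identifiers).
#' @param reference name of the reference species (must be in `rows`).
#' @param region optional list describing the reference span: `chrom`,
#'   `start` (0-based), `end`, `strand`. Sequences are stored 5'->3' in the
#'   reference's transcription orientation.
#' @return object of class `species_alignment` with `rows`, `reference`,
#'   `ref_map` (1-based alignment column of each ungapped reference base) and
#'   `region`.
#' @export
species_alignment <- function(rows, reference, region = NULL) {
  stopifnot(is.character(rows), !is.null(names(rows)), reference %in% names(rows))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    abort("alignment rows have unequal gapped lengths")
  }
  ref_chars <- strsplit(rows[[reference]], "", fixed = TRUE)[[1]]
  ref_map <- which(ref_chars != "-")
  structure(
    list(rows = rows, reference = reference, ref_map = ref_map, region = region),
    class = "species_alignment"
  )
}

#' @export
print.species_alignment <- function(x, ...) {
  cat(
    "<species_alignment> ", length(x$rows), " species, ",
    nchar(x$rows[[1]]), " columns, reference ", x$reference, "\n",
    sep = ""
  )
  invisible(x)
}

#' Ungapped reference sequence of an alignment
#' @param x a [species_alignment].
#' @return character scalar.
#' @export
reference_sequence <- function(x) {
  gsub("-", "", x$rows[[x$reference]], fixed = TRUE)
}

#' @describeIn species_alignment per-species tidy summary (identity, gap
#'   fraction relative to the reference row).
#' @param x a `species_alignment`.
#' @param ... unused.
#' @export
tidy.species_alignment <- function(x, ...) {
  ref <- strsplit(x$rows[[x$reference]], "", fixed = TRUE)[[1]]
  purrr::map_dfr(names(x$rows), function(sp) {
    s <- strsplit(x$rows[[sp]], "", fixed = TRUE)[[1]]
    at_ref <- x$ref_map
    tibble(
      species = sp,
      n_columns = length(s),
      identity = mean(s[at_ref] == ref[at_ref]),
      gap_fraction = mean(s[at_ref] == "-")
    )
  })
}

#' Read MAF alignments
#'
#' One [species_alignment] per `a` block; blocks lacking the reference
#' species are dropped with a warning. Species identifiers are the `src`
#' field up to the first `.` (the remainder is kept as the chromosome).
#'
#' @param path MAF file.
#' @param reference_species reference species identifier.
#' @return list of [species_alignment] objects in input order, with an
#'   attribute `n_dropped` counting blocks without the reference.
#' @export
read_alignment_maf <- function(path, reference_species) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  block_starts <- grep("^a", lines)
  out <- list()
  dropped <- 0L
  for (bi in seq_along(block_starts)) {
    from <- block_starts[bi]
    to <- if (bi < length(block_starts)) block_starts[bi + 1] - 1L else length(lines)
    s_lines <- grep("^s ", lines[from:to], value = TRUE)
    if (length(s_lines) == 0) next
    parts <- strsplit(trimws(s_lines), "[ \t]+")
    bad <- which(lengths(parts) != 7L)
    if (length(bad) > 0) abort(sprintf("malformed MAF 's' line in block %d", bi))
    src <- map_chr(parts, 2)
    species <- sub("\\..*$", "", src)
    chrom <- sub("^[^.]*\\.?", "", src)
    text <- toupper(map_chr(parts, 7))
    if (length(unique(nchar(text))) != 1) {
      abort(sprintf("rows of unequal gapped length in MAF block %d", bi))
    }
    if (!reference_species %in% species) {
      dropped <- dropped + 1L
      next
    }
    rows <- setNames(text, species)
    ri <- match(reference_species, species)
    region <- list(
      chrom = chrom[ri],
      start = as.integer(map_chr(parts, 3)[ri]),
      end = as.integer(map_chr(parts, 3)[ri]) + as.integer(map_chr(parts, 4)[ri]),
      strand = map_chr(parts, 5)[ri]
    )
    out[[length(out) + 1L]] <- species_alignment(rows, reference_species, region)
  }
  if (dropped > 0) {
    warn(sprintf("%d MAF block(s) lacking reference '%s' dropped", dropped, reference_species))
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Write alignments as MAF
#'
#' @param alignments list of [species_alignment] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment_maf <- function(alignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (aln in alignments) {
    writeLines("", con)
    writeLines("a score=0.0", con)
    for (sp in names(aln$rows)) {
      gapped <- aln$rows[[sp]]
      size <- nchar(gsub("-", "", gapped, fixed = TRUE))
      if (sp == aln$reference && !is.null(aln$region)) {
        src <- paste0(sp, ".", aln$region$chrom)
        start <- aln$region$start
        strand <- aln$region$strand
        src_size <- aln$region$src_size %||% (aln$region$end %||% (start + size))
      } else {
        src <- paste0(sp, ".region")
        start <- 0L
        strand <- "+"
        src_size <- size
      }
      writeLines(
        sprintf("s %s %d %d %s %d %s", src, start, size, strand, src_size, gapped),
        con
      )
    }
  }
  invisible(path)
}
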