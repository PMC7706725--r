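## Gene model I/O.
##
## Gene models are kept as a flat exon/CDS tibble (one row per feature per
## transcript) in 0-based half-open coordinates — the natural shape for the
## splice-graph and exon-feature stages.

#' Read gene models from GTF/GFF3
#'
#' Parses exon (and, when present, CDS) records grouped by transcript and
#' gene, converting 1-based inclusive coordinates to 0-based half-open.
#'
#' @param path GTF or GFF3 file.
#' @return tibble with columns `gene_id`, `transcript_id`, `type`
#'   (`"exon"`/`"CDS"`), `chrom`, `start`, `end`, `strand`, `phase`.
#'   Rows are sorted by gene, transcript, genomic position.
#' @export
read_gene_models <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  tx <- df$transcript_id %||% df$Parent
  if (is.null(tx)) abort("annotation has no transcript_id/Parent attribute")
  if (is(tx, "List") || is.list(tx)) {
    tx <- map_chr(as.list(tx), function(p) {
      if (length(p) == 0) NA_character_ else sub("^transcript:", "", p[[1]])
    })
  }
  if (anyNA(tx)) abort("exon record lacking a transcript parent")
  gene <- df$gene_id %||% sub("\\.t[0-9]+$", "", tx)
  phase <- df$phase %||% rep(NA_integer_, nrow(df))
  models <- tibble(
    gene_id = as.character(gene),
    transcript_id = as.character(tx),
    type = as.character(df$type),
    chrom = as.character(df$seqnames),
    start = as.integer(df$start) - 1L,  # GTF 1-based inclusive -> 0-based half-open
    end = as.integer(df$end),
    strand = as.character(df$strand),
    phase = suppressWarnings(as.integer(phase))
  ) |>
    arrange(.data$gene_id, .data$transcript_id, .data$type, .data$start, .data$end)
  check_exon_overlaps(models)
  models
}

check_exon_overlaps <- function(models) {
  exons <- filter(models, .data$type == "exon")
  bad <- exons |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(
      overlap = n() > 1 && any(.data$start[-1] < head(.data$end, -1)),
      .groups = "drop"
    ) |>
    filter(.data$overlap)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "overlapping exons within transcript(s): %s",
      paste(head(bad$transcript_id, 5), collapse = ", ")
    ))
  }
  invisible(models)
}

#' List exons of a transcript in transcript (5'->3') order
#'
#' Exons are stored in genome order; iteration is reversed on the minus
#' strand.
#'
#' @param models gene model tibble from [read_gene_models()].
#' @param transcript transcript identifier.
#' @return exon tibble ordered 5' to 3'.
#' @export
transcript_exons <- function(models, transcript) {
  ex <- filter(models, .data$transcript_id == transcript, .data$type == "exon")
  ex[transcript_order(ex$start, ex$strand[1]), , drop = FALSE]
}

#' Write gene models as GTF
#'
#' @param models gene model tibble (0-based half-open; converted back to
#'   1-based inclusive on output).
#' @param path output file.
#' @param source source field (column 2).
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path, source = "spliceflow") {
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s";',
    models$gene_id, models$transcript_id
  )
  lines <- sprintf(
    "%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
    models$chrom, source, models$type,
    models$start + 1L, models$end,
    models$strand,
    ifelse(is.na(models$phase), ".", as.character(models$phase)),
    attrs
  )
  writeLines(lines, path)
  invisible(path)
}

#' Derive the introns (junctions) of each transcript
#'
#' @param models gene model tibble.
#' @return tibble of annotated junctions with `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand` (intron intervals, 0-based half-open).
#' @export
annotated_junctions <- function(models) {
  filter(models, .data$type == "exon") |>
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(
      j_start = list(head(.data$end, -1)),
      j_end = list(.data$start[-1]),
      .groups = "drop"
    ) |>
    tidyr::unnest(c("j_start", "j_end")) |>
    rename(start = "j_start", end = "j_end") |>
    filter(!is.na(.data$start)) |>
    distinct(
      .data$gene_id, .data$chrom, .data$start, .data$end, .data$strand
    ) |>
    arrange(.data$chrom, .data$start, .data$end)
}
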