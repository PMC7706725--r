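## Exon feature characterization: frame preservation, lengths, microexons,
## and overlap with protein domains / intrinsically disordered regions.

#' Build exon feature records from triplets
#'
#' @param triplets triplet tibble ([extract_triplets()]).
#' @param microexon_max microexon length boundary in nt (default 27,
#'   inclusive; see `microexon_strict`).
#' @param microexon_strict if `TRUE` use a strict `<` boundary.
#' @return tibble with `exon_id`, `gene_id`, `class_label`, `length`,
#'   `intron_up_length`, `intron_dn_length`, `frame_preserving`,
#'   `is_microexon`.
#' @export
exon_feature_records <- function(triplets, microexon_max = 27,
                                 microexon_strict = FALSE) {
  len <- triplets$exon_in_end - triplets$exon_in_start
  tibble(
    exon_id = triplets$triplet_id,
    gene_id = triplets$gene_id,
    class_label = triplets$class_label,
    length = as.integer(len),
    intron_up_length = as.integer(triplets$intron_up_end - triplets$intron_up_start),
    intron_dn_length = as.integer(triplets$intron_dn_end - triplets$intron_dn_start),
    frame_preserving = len %% 3 == 0,
    is_microexon = if (microexon_strict) len < microexon_max else len <= microexon_max
  )
}

#' Frame-preservation and length statistics per exon class
#'
#' Frame-preservation percentages per class with pairwise 2x2 chi-squared
#' tests (no continuity correction), and exon / flanking-intron length
#' medians with pairwise Wilcoxon rank-sum tests; upstream and downstream
#' intron lengths are reported separately.
#'
#' @param records tibble from [exon_feature_records()].
#' @return list with `frame` (per class), `frame_tests`, `lengths` (per
#'   class medians) and `length_tests` tibbles; classes with fewer than two
#'   records are excluded from the tests and listed in `excluded_classes`.
#' @export
frame_and_length_stats <- function(records) {
  counts <- records |> count(.data$class_label)
  excluded <- counts$class_label[counts$n < 2]
  usable <- setdiff(counts$class_label, excluded)
  if (length(usable) < 2) abort("need at least two classes with >= 2 records")

  frame <- records |>
    group_by(.data$class_label) |>
    summarise(
      n = n(),
      frame_preserving_pct = 100 * mean(.data$frame_preserving),
      .groups = "drop"
    )
  lengths <- records |>
    group_by(.data$class_label) |>
    summarise(
      n = n(),
      median_exon_length = median(.data$length),
      median_intron_up_length = median(.data$intron_up_length),
      median_intron_dn_length = median(.data$intron_dn_length),
      .groups = "drop"
    )

  combs <- utils::combn(sort(usable), 2)
  frame_tests <- purrr::map_dfr(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    ra <- records$frame_preserving[records$class_label == a]
    rb <- records$frame_preserving[records$class_label == b]
    tab <- matrix(c(sum(ra), sum(!ra), sum(rb), sum(!rb)), nrow = 2, byrow = TRUE)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble(
      class_a = a, class_b = b, statistic = unname(ct$statistic),
      p_value = unname(ct$p.value)
    )
  })
  length_tests <- purrr::map_dfr(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    test_for <- function(col) {
      suppressWarnings(wilcox.test(
        records[[col]][records$class_label == a],
        records[[col]][records$class_label == b]
      )$p.value)
    }
    tibble(
      class_a = a, class_b = b,
      p_exon_length = test_for("length"),
      p_intron_up_length = test_for("intron_up_length"),
      p_intron_dn_length = test_for("intron_dn_length")
    )
  })
  list(
    frame = frame, frame_tests = frame_tests,
    lengths = lengths, length_tests = length_tests,
    excluded_classes = excluded
  )
}

#' Detect microexons
#'
#' Returns the records with length at or below `microexon_max` (inclusive
#' by default; the strict `<` variant is available). When a junction table
#' is supplied, each microexon carries provenance marking whether its gene's
#' junction support is exclusive to IP samples (detected only in
#' tissue-enriched data).
#'
#' @param records tibble from [exon_feature_records()].
#' @param microexon_max boundary in nt (default 27).
#' @param strict if `TRUE`, use `<` instead of `<=`.
#' @param ip_only optional logical vector aligned with `records` marking
#'   exons quantifiable only in IP samples (provenance passthrough).
#' @return the microexon subset with a `detected_ip_only` column.
#' @export
detect_microexons <- function(records, microexon_max = 27, strict = FALSE,
                              ip_only = NULL) {
  keep <- if (strict) records$length < microexon_max else records$length <= microexon_max
  out <- records[keep, , drop = FALSE]
  out$detected_ip_only <- if (is.null(ip_only)) NA else ip_only[keep]
  out
}

#' Map an exon to amino-acid coordinates of its protein
#'
#' Converts the exon's coding overlap into 1-based inclusive amino-acid
#' positions: `aa_start = floor(cds_offset / 3) + 1`,
#' `aa_end = ceiling((cds_offset + coding_len) / 3)` where `cds_offset` is
#' the number of coding bases 5' of the exon's first coding base. Exons
#' fully in UTR return "non-coding".
#'
#' @param exon_start,exon_end exon interval (0-based half-open).
#' @param cds tibble of the transcript's CDS intervals (`start`, `end`,
#'   `strand`, optional `phase`), any row order.
#' @return one-row tibble: `coding`, `aa_start`, `aa_end`, `coding_len`.
#' @export
map_exon_to_protein <- function(exon_start, exon_end, cds) {
  cds <- as_tibble(cds)
  strand <- cds$strand[1]
  ord <- transcript_order(cds$start, strand)
  cds <- cds[ord, , drop = FALSE]
  cds_len <- sum(cds$end - cds$start)
  if (cds_len %% 3 != 0) {
    warn("CDS length not a multiple of 3")
  }
  offset <- 0L
  first_off <- NA_integer_
  coding_len <- 0L
  for (i in seq_len(nrow(cds))) {
    s <- cds$start[i]; e <- cds$end[i]
    ov_s <- max(s, exon_start); ov_e <- min(e, exon_end)
    if (ov_s < ov_e) {
      within <- if (strand == "-") e - ov_e else ov_s - s
      if (is.na(first_off)) first_off <- offset + within
      coding_len <- coding_len + (ov_e - ov_s)
    }
    offset <- offset + (e - s)
  }
  if (coding_len == 0) {
    return(tibble(coding = FALSE, aa_start = NA_integer_, aa_end = NA_integer_, coding_len = 0L))
  }
  tibble(
    coding = TRUE,
    aa_start = first_off %/% 3L + 1L,
    aa_end = as.integer(ceiling((first_off + coding_len) / 3)),
    coding_len = as.integer(coding_len)
  )
}

#' Domain / IDR overlap rates per exon class
#'
#' Overlap requires at least one shared amino-acid position between the
#' exon's protein interval and an annotated interval. Records whose protein
#' has no annotation are excluded from the denominator by default.
#'
#' @param records tibble with `class_label`, `protein_id`, `aa_start`,
#'   `aa_end` (1-based inclusive).
#' @param track protein feature tibble: `protein_id`, `start`, `end`
#'   (1-based inclusive aa coordinates), `label` (`"domain"` / `"idr"`).
#' @param include_unannotated count proteins absent from `track` as
#'   non-overlapping instead of excluding them.
#' @return list with `rates` (per class: percentage overlapping domain /
#'   idr), `tests` (pairwise chi-squared per label) and `n_unannotated`.
#' @export
feature_overlap_rates <- function(records, track, include_unannotated = FALSE) {
  track <- as_tibble(track)
  stopifnot(all(track$end >= track$start), all(track$label %in% c("domain", "idr")))
  annotated <- unique(track$protein_id)
  has_ann <- records$protein_id %in% annotated
  n_unann <- sum(!has_ann)
  use <- if (include_unannotated) records else records[has_ann, , drop = FALSE]

  overlaps_with <- function(pid, s, e, lab) {
    iv <- track[track$protein_id == pid & track$label == lab, , drop = FALSE]
    any(iv$start <= e & iv$end >= s)
  }
  use$overlaps_domain <- purrr::pmap_lgl(
    list(use$protein_id, use$aa_start, use$aa_end),
    function(p, s, e) overlaps_with(p, s, e, "domain")
  )
  use$overlaps_idr <- purrr::pmap_lgl(
    list(use$protein_id, use$aa_start, use$aa_end),
    function(p, s, e) overlaps_with(p, s, e, "idr")
  )

  rates <- use |>
    group_by(.data$class_label) |>
    summarise(
      n = n(),
      domain_pct = 100 * mean(.data$overlaps_domain),
      idr_pct = 100 * mean(.data$overlaps_idr),
      .groups = "drop"
    )

  classes <- sort(unique(use$class_label))
  tests <- NULL
  if (length(classes) >= 2) {
    combs <- utils::combn(classes, 2)
    tests <- purrr::map_dfr(seq_len(ncol(combs)), function(i) {
      a <- combs[1, i]; b <- combs[2, i]
      purrr::map_dfr(c("overlaps_domain", "overlaps_idr"), function(col) {
        xa <- use[[col]][use$class_label == a]
        xb <- use[[col]][use$class_label == b]
        tab <- matrix(c(sum(xa), sum(!xa), sum(xb), sum(!xb)), 2, byrow = TRUE)
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        tibble(
          label = sub("overlaps_", "", col), class_a = a, class_b = b,
          statistic = unname(ct$statistic), p_value = unname(ct$p.value)
        )
      })
    })
  }
  list(rates = rates, tests = tests, n_unannotated = n_unann, records = use)
}
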