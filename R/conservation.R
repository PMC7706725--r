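## Exon-triplet conservation across species.
##
## The unit of analysis is the exon triplet: an internal exon with its two
## flanking introns and exons. Triplets are classed constitutive,
## alternative non-tissue-regulated, or tissue-regulated; conservation in a
## species requires presence of all three exons and alignment of the four
## internal splice sites.

triplet_classes <- c("constitutive", "alt_non_tissue", "alt_tissue_regulated")

## resolve a cassette event to its (A, E, B) nodes and the two intron spans
resolve_cassette <- function(event_edges, anchor_side, graph, tpos) {
  je <- event_edges[event_edges$type == "junction", , drop = FALSE]
  distal_col <- if (anchor_side == "source") "acceptor_node" else "donor_node"
  d <- je[[distal_col]]
  o <- order(tpos[d])
  if (anchor_side == "source") {
    A <- je$donor_node[1]
    E <- d[o[1]]; B <- d[o[2]]
    up_edge <- je[je[[distal_col]] == E, ][1, ]
    dn_edge <- graph$edges[
      graph$edges$type == "junction" &
        graph$edges$donor_node == E & graph$edges$acceptor_node == B, ][1, ]
  } else {
    B <- je$acceptor_node[1]
    E <- d[o[2]]; A <- d[o[1]]
    dn_edge <- je[je[[distal_col]] == E, ][1, ]
    up_edge <- graph$edges[
      graph$edges$type == "junction" &
        graph$edges$donor_node == A & graph$edges$acceptor_node == E, ][1, ]
  }
  list(A = A, E = E, B = B, up = up_edge, dn = dn_edge)
}

triplet_row <- function(graph, A, E, B, up_edge, dn_edge, class_label, event_id) {
  nd <- graph$nodes
  iv <- function(n) nd[match(n, nd$node_id), c("start", "end")]
  a <- iv(A); e <- iv(E); b <- iv(B)
  tibble(
    gene_id = graph$gene_id, chrom = graph$chrom, strand = graph$strand,
    class_label = class_label, event_id = event_id,
    exon_up_start = a$start, exon_up_end = a$end,
    intron_up_start = up_edge$start, intron_up_end = up_edge$end,
    exon_in_start = e$start, exon_in_end = e$end,
    intron_dn_start = dn_edge$start, intron_dn_end = dn_edge$end,
    exon_dn_start = b$start, exon_dn_end = b$end
  )
}

#' Extract exon triplets for the conservation analysis
#'
#' Cassette events supply the alternative internal exons
#' (`alt_tissue_regulated` when the event carries a differential call,
#' `alt_non_tissue` otherwise); constitutive triplets are internal exonic
#' segments whose single flanking junctions are the only junctions at their
#' splice sites. Exons at transcript ends yield no triplet.
#'
#' @param events classified events tibble.
#' @param graphs named list of splice graphs (one per gene).
#' @param diff_calls optional differential call tibble ([call_differential()]
#'   output, possibly several tissue pairs bound together); events with
#'   `differential == TRUE` in any pair become tissue-regulated.
#' @return tibble of triplets with genomic intervals for the three exons and
#'   two introns ("up" means 5' in transcript orientation), `class_label`
#'   and `event_id` (`NA` for constitutive triplets), plus attribute
#'   `n_skipped_terminal`.
#' @export
extract_triplets <- function(events, graphs, diff_calls = NULL) {
  regulated_ids <- character(0)
  if (!is.null(diff_calls) && nrow(diff_calls) > 0) {
    regulated_ids <- unique(diff_calls$event_id[diff_calls$differential])
  }
  out <- list()
  n_skipped <- 0L

  cass <- filter(events, .data$event_class == "cassette")
  for (i in seq_len(nrow(cass))) {
    graph <- graphs[[cass$gene_id[i]]]
    tpos <- node_tpos(graph)
    edges <- graph$edges[match(cass$edge_ids[[i]], graph$edges$edge_id), , drop = FALSE]
    r <- resolve_cassette(edges, cass$anchor_side[i], graph, tpos)
    nd <- graph$nodes[match(r$E, graph$nodes$node_id), ]
    if (nd$first_exon || nd$last_exon) {
      n_skipped <- n_skipped + 1L
      next
    }
    label <- if (cass$event_id[i] %in% regulated_ids) "alt_tissue_regulated" else "alt_non_tissue"
    out[[length(out) + 1L]] <- triplet_row(
      graph, r$A, r$E, r$B, r$up, r$dn, label, cass$event_id[i]
    )
  }

  ## the same physical cassette exon appears as a source and a target event;
  ## keep one triplet per internal exon, preferring the regulated label
  alt <- bind_rows(out)
  if (nrow(alt) > 0) {
    alt <- alt |>
      mutate(.pri = match(.data$class_label, rev(triplet_classes))) |>
      arrange(.data$gene_id, .data$exon_in_start, .data$.pri) |>
      distinct(.data$gene_id, .data$exon_in_start, .data$exon_in_end, .keep_all = TRUE) |>
      select(-".pri")
  }

  ## constitutive triplets: internal segment with exactly one junction on
  ## each side, each being the sole junction at both of its splice sites
  cons <- list()
  event_edge_ids <- unique(unlist(events$edge_ids))
  for (graph in graphs) {
    je <- graph$edges[graph$edges$type == "junction", , drop = FALSE]
    for (k in seq_len(nrow(graph$nodes))) {
      node <- graph$nodes$node_id[k]
      if (graph$nodes$first_exon[k] || graph$nodes$last_exon[k]) next
      inc <- graph$edges[graph$edges$acceptor_node == node, , drop = FALSE]
      outg <- graph$edges[graph$edges$donor_node == node, , drop = FALSE]
      if (nrow(inc) != 1 || nrow(outg) != 1) next
      if (inc$type != "junction" || outg$type != "junction") next
      if (sum(je$donor_node == inc$donor_node) != 1) next
      if (sum(je$acceptor_node == outg$acceptor_node) != 1) next
      if (inc$edge_id %in% event_edge_ids || outg$edge_id %in% event_edge_ids) next
      cons[[length(cons) + 1L]] <- triplet_row(
        graph, inc$donor_node, node, outg$acceptor_node, inc, outg,
        "constitutive", NA_character_
      )
    }
  }
  res <- bind_rows(alt, bind_rows(cons))
  if (nrow(res) > 0) {
    res <- res |>
      arrange(.data$gene_id, .data$exon_in_start) |>
      mutate(triplet_id = paste0("tr", sprintf("%04d", row_number()))) |>
      select("triplet_id", dplyr::everything())
  }
  attr(res, "n_skipped_terminal") <- n_skipped
  res
}

#' Star alignment of species sequences onto a reference
#'
#' Each species is aligned globally to the reference with affine gap
#' penalties (match +1, mismatch -1, gap open -2, gap extend -0.5 by
#' default) and the pairwise alignments are merged star-wise on the
#' reference coordinate system.
#'
#' @param sequences named character vector of unaligned sequences (must
#'   include the reference).
#' @param reference name of the reference species.
#' @param match,mismatch,gap_open,gap_extend alignment scores (penalties
#'   given as positive numbers).
#' @param region optional region descriptor stored on the result.
#' @return a [species_alignment].
#' @export
align_center_star <- function(sequences, reference, match = 1, mismatch = -1,
                              gap_open = 2, gap_extend = 0.5, region = NULL) {
  stopifnot(length(sequences) >= 2, reference %in% names(sequences))
  if (any(nchar(sequences) == 0)) abort("empty sequence")
  ref <- sequences[[reference]]
  n <- nchar(ref)
  others <- setdiff(names(sequences), reference)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE
  )

  per_species <- map(others, function(sp) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = sequences[[sp]], subject = ref, type = "global",
      substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend
    )
    s_row <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    r_row <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ## per reference base: the species character aligned to it; plus
    ## insertions keyed by "after k reference bases" (k in 0..n)
    at_ref <- character(n)
    ins <- vector("list", n + 1L)
    k <- 0L
    for (col in seq_along(r_row)) {
      if (r_row[col] == "-") {
        ins[[k + 1L]] <- c(ins[[k + 1L]], s_row[col])
      } else {
        k <- k + 1L
        at_ref[k] <- s_row[col]
      }
    }
    list(at_ref = at_ref, ins = map(ins, ~ .x %||% character(0)), score = Biostrings::score(aln))
  })
  names(per_species) <- others

  ref_chars <- strsplit(ref, "")[[1]]
  rows <- star_merge_rows(ref_chars, per_species, reference)
  aln <- species_alignment(rows, reference, region = region)
  attr(aln, "pairwise_scores") <- map_dbl(per_species, "score")
  aln
}

## map a genomic interval [gs, ge) to transcript-oriented offsets within a
## region [start, end) on `strand`; returns offsets of each base, 5'->3'
region_offsets <- function(gs, ge, region) {
  if (identical(region$strand, "-")) {
    (region$end - 1 - (ge - 1)):(region$end - 1 - gs)
  } else {
    (gs - region$start):(ge - 1 - region$start)
  }
}

#' Assess conservation of one exon triplet in one species
#'
#' An exon is present when at least `exon_presence_min` of its reference
#' columns carry non-gap species characters; a splice site is aligned when
#' the species has non-gap characters at the two intron-terminal reference
#' columns (the GT/AG dinucleotide positions), optionally searching within
#' `splice_site_window` columns. The triplet is conserved iff all three
#' exons are present and all four internal splice sites are aligned.
#'
#' @param triplet one-row triplet tibble ([extract_triplets()]).
#' @param alignment a [species_alignment] whose region covers the triplet.
#' @param species species to assess.
#' @param exon_presence_min minimum non-gap fraction per exon (default 0.5).
#' @param splice_site_window extra columns searched around each site
#'   (default 0 = exact columns).
#' @param require_canonical additionally require the species dinucleotides
#'   to be GT/AG.
#' @return one-row tibble: `triplet_id`, `species`, `conserved`, exon
#'   presence fractions and per-site alignment status.
#' @export
assess_conservation <- function(triplet, alignment, species,
                                exon_presence_min = 0.5,
                                splice_site_window = 0,
                                require_canonical = FALSE) {
  region <- alignment$region
  stopifnot(!is.null(region), species %in% names(alignment$rows))
  spans <- list(
    exon_up = c(triplet$exon_up_start, triplet$exon_up_end),
    intron_up = c(triplet$intron_up_start, triplet$intron_up_end),
    exon_in = c(triplet$exon_in_start, triplet$exon_in_end),
    intron_dn = c(triplet$intron_dn_start, triplet$intron_dn_end),
    exon_dn = c(triplet$exon_dn_start, triplet$exon_dn_end)
  )
  lo <- min(map_dbl(spans, 1)); hi <- max(map_dbl(spans, 2))
  if (lo < region$start || hi > region$end) {
    abort("triplet outside alignment span")
  }
  sp_chars <- strsplit(alignment$rows[[species]], "")[[1]]
  n_ref <- length(alignment$ref_map)

  presence <- map_dbl(spans[c("exon_up", "exon_in", "exon_dn")], function(sp) {
    offs <- region_offsets(sp[1], sp[2], region)
    cols <- alignment$ref_map[offs + 1L]
    mean(sp_chars[cols] != "-")
  })

  site_cols <- function(offs) alignment$ref_map[offs + 1L]
  site_aligned <- function(offs_pair, expect) {
    ok <- map_lgl(seq_along(offs_pair), function(i) {
      o <- offs_pair[i]
      cand <- (o - splice_site_window):(o + splice_site_window)
      cand <- cand[cand >= 0 & cand < n_ref]
      chars <- sp_chars[site_cols(cand)]
      any(chars != "-")
    })
    al <- all(ok)
    if (al && require_canonical) {
      chars <- sp_chars[site_cols(offs_pair)]
      al <- identical(paste(chars, collapse = ""), expect)
    }
    al
  }
  intron_sites <- function(span) {
    offs <- region_offsets(span[1], span[2], region)
    list(donor = offs[1:2], acceptor = offs[c(length(offs) - 1L, length(offs))])
  }
  iu <- intron_sites(spans$intron_up)
  id <- intron_sites(spans$intron_dn)
  sites <- c(
    site_up_donor = site_aligned(iu$donor, "GT"),
    site_up_acceptor = site_aligned(iu$acceptor, "AG"),
    site_dn_donor = site_aligned(id$donor, "GT"),
    site_dn_acceptor = site_aligned(id$acceptor, "AG")
  )

  tibble(
    triplet_id = triplet$triplet_id %||% NA_character_,
    class_label = triplet$class_label %||% NA_character_,
    species = species,
    conserved = all(presence >= exon_presence_min) && all(sites),
    presence_up = presence[["exon_up"]],
    presence_in = presence[["exon_in"]],
    presence_dn = presence[["exon_dn"]],
    site_up_donor = sites[["site_up_donor"]],
    site_up_acceptor = sites[["site_up_acceptor"]],
    site_dn_donor = sites[["site_dn_donor"]],
    site_dn_acceptor = sites[["site_dn_acceptor"]]
  )
}

#' Compare conservation rates of two triplet sets
#'
#' Two-sided Fisher's exact test on the 2x2 (conserved / not) x (set a /
#' set b) table.
#'
#' @param calls_a,calls_b conservation call tibbles with a logical
#'   `conserved` column (one class/species combination each).
#' @return one-row tibble: `rate_a`, `rate_b`, `n_a`, `n_b`, `odds_ratio`,
#'   `p_value`.
#' @export
conservation_rate_compare <- function(calls_a, calls_b) {
  if (nrow(calls_a) == 0 || nrow(calls_b) == 0) abort("empty conservation call set")
  ka <- sum(calls_a$conserved); kb <- sum(calls_b$conserved)
  na <- nrow(calls_a); nb <- nrow(calls_b)
  ft <- fisher.test(matrix(c(ka, na - ka, kb, nb - kb), nrow = 2))
  tibble(
    rate_a = ka / na, rate_b = kb / nb, n_a = na, n_b = nb,
    odds_ratio = unname(ft$estimate), p_value = ft$p.value
  )
}

window_regions <- c(
  "upstream_intron_5p", "upstream_intron_3p",
  "downstream_intron_5p", "downstream_intron_3p"
)

## genomic positions of intron flank positions 1..k, strand-aware:
## position 1 is the first intronic base counted from the splice site
## moving into the intron
intron_flank_positions <- function(s, e, strand, end5, k) {
  len <- e - s
  if (end5) {
    if (strand == "-") (e - 1) - (seq_len(k) - 1) else s + (seq_len(k) - 1)
  } else {
    if (strand == "-") s + (seq_len(k) - 1) else (e - 1) - (seq_len(k) - 1)
  }
}

#' Windowed conservation-score profiles over intron flanks
#'
#' For each triplet class and intron flank region, computes the mean
#' per-base conservation score at positions 1..`flank_len` from the splice
#' site into the intron (strand-aware), applies a centered rolling mean of
#' width `smooth` (truncated at the edges), and compares classes per region
#' with (a) a Wilcoxon signed-rank test paired over the position means and
#' (b) a rank-sum test over per-event mean scores.
#'
#' @param track a [conservation_track].
#' @param triplets class-labelled triplet tibble.
#' @param flank_len positions per flank (default 23, chosen to halve even
#'   the shortest ~40-nt introns).
#' @param smooth rolling window width (default 3; 1 disables smoothing).
#' @return object of class `window_profiles`: list with `profiles` (class,
#'   region, position, mean_score, smoothed, n), `tests` and
#'   `n_short_introns`.
#' @export
window_profile <- function(track, triplets, flank_len = 23, smooth = 3) {
  stopifnot(nrow(triplets) > 0)
  short <- 0L
  per_event <- list()
  for (i in seq_len(nrow(triplets))) {
    tr <- triplets[i, ]
    for (intron in c("upstream", "downstream")) {
      s <- if (intron == "upstream") tr$intron_up_start else tr$intron_dn_start
      e <- if (intron == "upstream") tr$intron_up_end else tr$intron_dn_end
      len <- e - s
      n5 <- min(flank_len, ceiling(len / 2))
      n3 <- min(flank_len, floor(len / 2))
      if (len < 2 * flank_len) short <- short + 1L
      for (endlab in c("5p", "3p")) {
        k <- if (endlab == "5p") n5 else n3
        if (k < 1) next
        pos <- intron_flank_positions(s, e, tr$strand, endlab == "5p", k)
        sc <- track_scores(track, tr$chrom, pos)
        per_event[[length(per_event) + 1L]] <- tibble(
          triplet_id = tr$triplet_id, class_label = tr$class_label,
          region = paste0(
            if (intron == "upstream") "upstream_intron_" else "downstream_intron_",
            endlab
          ),
          position = seq_len(k), score = sc
        )
      }
    }
  }
  long <- bind_rows(per_event)

  miss <- long |>
    group_by(.data$class_label) |>
    summarise(frac_missing = mean(is.na(.data$score)), .groups = "drop") |>
    filter(.data$frac_missing > 0.5)
  if (nrow(miss) > 0) {
    abort(sprintf(
      "conservation track missing >50%% of positions for class '%s'",
      miss$class_label[1]
    ))
  }

  profiles <- long |>
    group_by(.data$class_label, .data$region, .data$position) |>
    summarise(
      mean_score = mean(.data$score, na.rm = TRUE),
      n = sum(!is.na(.data$score)),
      .groups = "drop"
    ) |>
    arrange(.data$class_label, .data$region, .data$position) |>
    group_by(.data$class_label, .data$region) |>
    mutate(smoothed = rolling_mean(.data$mean_score, smooth)) |>
    ungroup()

  event_means <- long |>
    group_by(.data$triplet_id, .data$class_label, .data$region) |>
    summarise(mean_score = mean(.data$score, na.rm = TRUE), .groups = "drop")

  classes <- sort(unique(triplets$class_label))
  tests <- list()
  for (region in unique(profiles$region)) {
    if (length(classes) < 2) next
    combs <- utils::combn(classes, 2)
    for (ci in seq_len(ncol(combs))) {
      a <- combs[1, ci]; b <- combs[2, ci]
      pa <- profiles |> filter(.data$class_label == a, .data$region == !!region)
      pb <- profiles |> filter(.data$class_label == b, .data$region == !!region)
      shared <- intersect(pa$position, pb$position)
      xa <- pa$mean_score[match(shared, pa$position)]
      xb <- pb$mean_score[match(shared, pb$position)]
      p_signed <- if (length(shared) >= 3 && any(xa != xb)) {
        suppressWarnings(wilcox.test(xa, xb, paired = TRUE)$p.value)
      } else NA_real_
      ea <- event_means |> filter(.data$class_label == a, .data$region == !!region)
      eb <- event_means |> filter(.data$class_label == b, .data$region == !!region)
      p_ranksum <- if (nrow(ea) >= 2 && nrow(eb) >= 2) {
        suppressWarnings(wilcox.test(ea$mean_score, eb$mean_score)$p.value)
      } else NA_real_
      tests[[length(tests) + 1L]] <- tibble(
        region = region, class_a = a, class_b = b,
        p_signed_rank = p_signed, p_rank_sum = p_ranksum,
        mean_a = mean(xa), mean_b = mean(xb)
      )
    }
  }
  structure(
    list(
      profiles = profiles,
      tests = bind_rows(tests),
      n_short_introns = short
    ),
    class = "window_profiles"
  )
}

#' @export
print.window_profiles <- function(x, ...) {
  cat(
    "<window_profiles> ", length(unique(x$profiles$class_label)), " classes x ",
    length(unique(x$profiles$region)), " regions; ",
    x$n_short_introns, " short intron flank(s)\n",
    sep = ""
  )
  invisible(x)
}
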