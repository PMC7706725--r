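## End-to-end orchestration: write simulated inputs, run every analysis
## stage deterministically, and emit per-stage TSVs plus a summary and a
## run manifest with file digests.

#' Write a full simulated input set to disk
#'
#' Runs all four generators and writes `genome.fa`, `models.gtf`,
#' `counts.tsv`, `retention.tsv`, `alignments.maf`, `phylop.bedgraph`,
#' `protein_features.tsv` and `truth.json` under `out_dir`.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the generated objects and file paths.
#' @export
run_simulation <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_annotation(config)
  cnt <- simulate_counts(config, ann)
  phy <- simulate_phylogeny(config, ann)
  trk <- simulate_tracks_and_features(config, ann)

  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    models = file.path(out_dir, "models.gtf"),
    counts = file.path(out_dir, "counts.tsv"),
    retention = file.path(out_dir, "retention.tsv"),
    maf = file.path(out_dir, "alignments.maf"),
    track = file.path(out_dir, "phylop.bedgraph"),
    protein_features = file.path(out_dir, "protein_features.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(ann$genome), paths$genome
  )
  write_gtf(ann$models, paths$models)
  write_junction_counts(cnt$table, paths$counts)
  if (!is.null(cnt$retention_counts)) {
    write_tsv_deterministic(cnt$retention_counts, paths$retention)
  }
  write_alignment_maf(phy$alignments, paths$maf)
  write_bedgraph(trk$track, paths$track)
  write_tsv_deterministic(trk$protein_features, paths$protein_features)

  truth <- c(
    ann$truth[c("genes", "junctions", "triplets")],
    list(
      junction_usage = ann$truth$junction_usage,
      events = mutate(
        ann$truth$events,
        junction_keys = map_chr(.data$junction_keys, paste, collapse = ";"),
        psi = map_chr(.data$psi, ~ paste(names(.x), round(.x, 6), sep = "=", collapse = ";"))
      ),
      conservation = phy$truth,
      protein_records = trk$protein_records,
      protein_overlap = trk$truth_overlap
    )
  )
  jsonlite::write_json(truth, paths$truth, digits = NA)

  invisible(list(
    annotation = ann, counts = cnt, phylogeny = phy, tracks = trk,
    paths = paths, config = config
  ))
}

pipeline_params_default <- function() {
  list(
    min_group_reads = 10, minor_psi_min = 0.05,
    enriched_min_reads = 5, enriched_strict = FALSE,
    min_event_reads = 10,
    differential_min = 0.20, switch_min = 0.80,
    exon_presence_min = 0.5, splice_site_window = 0,
    flank_len = 23, smooth = 3,
    kmer_range = 5:7, kmer_correction = "bh",
    kmer_flank = 200,
    reference_species = "elegans",
    microexon_max = 27
  )
}

stage_digest <- function(paths) {
  unname(tools::md5sum(unlist(paths)))
}

#' Run the analysis pipeline end-to-end
#'
#' Executes PSI -> tissue-enriched detection -> splice-graph events ->
#' event quantification -> differential calls -> exon triplets ->
#' conservation (rates and window profiles) -> exon features -> k-mer
#' enrichment on a directory of input files (as written by
#' [run_simulation()] or assembled by hand), writing one TSV per stage, a
#' `summary.tsv` and a `manifest.json` with input/output digests. Re-running
#' with an unchanged manifest performs no recomputation.
#'
#' @param input_dir directory containing `counts.tsv`, `models.gtf`,
#'   `genome.fa`, and optionally `retention.tsv`, `alignments.maf`,
#'   `phylop.bedgraph`, `protein_features.tsv`.
#' @param out_dir report directory.
#' @param params list of stage parameters; defaults from the package are
#'   used for entries not supplied.
#' @param force re-run even if the manifest is up to date.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(input_dir, out_dir, params = list(), force = FALSE) {
  p <- utils::modifyList(pipeline_params_default(), params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  in_paths <- list(
    counts = file.path(input_dir, "counts.tsv"),
    models = file.path(input_dir, "models.gtf"),
    genome = file.path(input_dir, "genome.fa")
  )
  optional <- list(
    retention = file.path(input_dir, "retention.tsv"),
    maf = file.path(input_dir, "alignments.maf"),
    track = file.path(input_dir, "phylop.bedgraph"),
    protein_features = file.path(input_dir, "protein_features.tsv")
  )
  stopifnot(all(file.exists(unlist(in_paths))))
  optional <- optional[file.exists(unlist(optional))]
  in_all <- c(in_paths, optional)

  manifest_path <- file.path(out_dir, "manifest.json")
  in_digests <- stage_digest(in_all)
  if (!force && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    outs <- file.path(out_dir, names(old$outputs))
    if (identical(unname(unlist(old$inputs)), in_digests) &&
        all(file.exists(outs)) &&
        identical(unname(tools::md5sum(outs)), unname(unlist(old$outputs)))) {
      return(invisible(old))
    }
  }

  table <- read_junction_counts(in_paths$counts, dialect = "generic_tsv")
  models <- read_gene_models(in_paths$models)
  genome <- Biostrings::readDNAStringSet(in_paths$genome)
  names(genome) <- sub(" .*$", "", names(genome))
  retention_counts <- if (!is.null(optional$retention)) {
    readr::read_tsv(optional$retention, show_col_types = FALSE, progress = FALSE)
  }

  out_files <- character(0)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    write_tsv_deterministic(x, path)
    out_files <<- c(out_files, name)
    path
  }

  ## 1. junction PSI (pooled per tissue) + alternative groups
  psi <- compute_psi(table, min_group_reads = p$min_group_reads, pool_by = "tissue")
  emit(psi, "psi.tsv")
  alt_groups <- call_alternative_junctions(psi, minor_psi_min = p$minor_psi_min)
  emit(alt_groups, "alternative_groups.tsv")

  ## 2. tissue-enriched junctions per IP tissue
  ip_tissues <- sort(unique(table$samples$tissue[table$samples$fraction == "IP"]))
  enriched <- purrr::map_dfr(
    ip_tissues, detect_tissue_enriched,
    table = table, min_ip_reads = p$enriched_min_reads, strict = p$enriched_strict
  )
  emit(enriched, "enriched.tsv")

  ## 3. splice graphs and classified events
  obs_junctions <- table$junctions
  ret_introns <- if (!is.null(retention_counts)) {
    distinct(retention_counts, .data$chrom, .data$start, .data$end, .data$strand)
  }
  found <- find_splicing_events(models, junctions = obs_junctions, retention = ret_introns)
  events_flat <- found$events |>
    mutate(edge_ids = map_chr(.data$edge_ids, paste, collapse = ";"))
  emit(events_flat, "events.tsv")

  ## 4. event PSI per tissue
  event_psi <- quantify_events(
    found$events, table,
    retention_counts = retention_counts, min_event_reads = p$min_event_reads
  )
  emit(event_psi, "event_psi.tsv")

  ## 5. differential calls for every tissue pair
  tissue_pairs <- if (length(ip_tissues) >= 2) utils::combn(ip_tissues, 2) else NULL
  diff_calls <- NULL
  if (!is.null(tissue_pairs)) {
    diff_calls <- purrr::map_dfr(seq_len(ncol(tissue_pairs)), function(i) {
      call_differential(
        event_psi, tissue_pairs[1, i], tissue_pairs[2, i],
        differential_min = p$differential_min, switch_min = p$switch_min
      )
    })
    emit(diff_calls, "differential.tsv")
  }

  ## 6. exon triplets
  triplets <- extract_triplets(found$events, found$graphs, diff_calls)
  emit(triplets, "triplets.tsv")

  ## 7. conservation: per-species calls + windowed profiles
  cons_calls <- NULL
  cons_rates <- NULL
  if (!is.null(optional$maf) && nrow(triplets) > 0) {
    alignments <- read_alignment_maf(optional$maf, p$reference_species)
    cons_calls <- conservation_calls(
      triplets, alignments,
      exon_presence_min = p$exon_presence_min,
      splice_site_window = p$splice_site_window
    )
    emit(cons_calls, "conservation.tsv")
    cons_rates <- cons_calls |>
      group_by(.data$class_label, .data$species) |>
      summarise(
        n = n(), conserved_pct = 100 * mean(.data$conserved), .groups = "drop"
      )
    emit(cons_rates, "conservation_rates.tsv")
  }
  profiles <- NULL
  if (!is.null(optional$track) && nrow(triplets) > 0) {
    track <- read_conservation_track(optional$track)
    profiles <- window_profile(
      track, triplets, flank_len = p$flank_len, smooth = p$smooth
    )
    emit(profiles$profiles, "window_profiles.tsv")
    emit(profiles$tests, "window_profile_tests.tsv")
  }

  ## 8. exon features
  records <- exon_feature_records(triplets, microexon_max = p$microexon_max)
  emit(records, "exon_features.tsv")
  feature_stats <- frame_and_length_stats(records)
  emit(feature_stats$frame, "frame_rates.tsv")
  emit(feature_stats$lengths, "length_stats.tsv")
  micro <- detect_microexons(records, microexon_max = p$microexon_max)
  emit(micro, "microexons.tsv")
  overlap <- NULL
  if (!is.null(optional$protein_features)) {
    pf <- readr::read_tsv(optional$protein_features, show_col_types = FALSE, progress = FALSE)
    prot_records <- protein_records_from_models(triplets, models)
    if (nrow(prot_records) > 0) {
      overlap <- feature_overlap_rates(prot_records, pf)
      emit(overlap$rates, "feature_overlap.tsv")
    }
  }

  ## 9. k-mer enrichment: tissue-regulated vs non-regulated alternative
  kmers <- NULL
  target <- filter(triplets, .data$class_label == "alt_tissue_regulated")
  background <- filter(triplets, .data$class_label == "alt_non_tissue")
  if (nrow(target) > 0 && nrow(background) > 0) {
    genome_chr <- setNames(as.character(genome), names(genome))
    kmers <- enrich_kmers(
      extract_event_regions(target, genome_chr, flank_len = p$kmer_flank, label = "regulated"),
      extract_event_regions(background, genome_chr, flank_len = p$kmer_flank, label = "background"),
      k_range = p$kmer_range, correction = p$kmer_correction
    )
    emit(head(kmers, 500), "kmers.tsv")
  }

  ## summary
  summary_tab <- pipeline_summary(
    table, enriched, found$events, diff_calls, cons_rates,
    feature_stats, micro, overlap
  )
  emit(summary_tab, "summary.tsv")

  manifest <- list(
    params = p[order(names(p))],
    inputs = as.list(setNames(in_digests, basename(unlist(in_all)))),
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, out_files))), out_files
    ))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Assess conservation of all triplets against a list of alignments
#'
#' Each triplet is matched to the alignment block covering its span on its
#' chromosome; triplets with no covering block (no clear homologous
#' alignment) are excluded, mirroring the exclusion of genes without
#' homologous coverage from rate denominators.
#'
#' @param triplets triplet tibble.
#' @param alignments list of [species_alignment] objects.
#' @param ... passed to [assess_conservation()].
#' @return tibble of conservation calls for every matched triplet x species.
#' @export
conservation_calls <- function(triplets, alignments, ...) {
  regions <- purrr::map_dfr(seq_along(alignments), function(i) {
    r <- alignments[[i]]$region
    tibble(idx = i, chrom = r$chrom, start = r$start, end = r$end)
  })
  purrr::map_dfr(seq_len(nrow(triplets)), function(i) {
    tr <- triplets[i, ]
    lo <- min(tr$exon_up_start, tr$exon_dn_start)
    hi <- max(tr$exon_up_end, tr$exon_dn_end)
    hit <- regions |>
      filter(.data$chrom == tr$chrom, .data$start <= lo, .data$end >= hi)
    if (nrow(hit) == 0) return(tibble())
    aln <- alignments[[hit$idx[1]]]
    species <- setdiff(names(aln$rows), aln$reference)
    purrr::map_dfr(species, function(sp) {
      assess_conservation(tr, aln, sp, ...)
    })
  })
}

## per-triplet protein coordinates from the first transcript carrying the
## internal exon in its CDS
protein_records_from_models <- function(triplets, models) {
  purrr::map_dfr(seq_len(nrow(triplets)), function(i) {
    tr <- triplets[i, ]
    cds_tx <- models |>
      filter(
        .data$gene_id == tr$gene_id, .data$type == "CDS",
        .data$start < tr$exon_in_end, .data$end > tr$exon_in_start
      ) |>
      pull("transcript_id")
    if (length(cds_tx) == 0) return(tibble())
    cds <- filter(
      models, .data$transcript_id == cds_tx[1], .data$type == "CDS"
    )
    aa <- map_exon_to_protein(tr$exon_in_start, tr$exon_in_end, cds)
    if (!aa$coding) return(tibble())
    tibble(
      exon_id = tr$triplet_id, protein_id = tr$gene_id,
      class_label = tr$class_label,
      aa_start = aa$aa_start, aa_end = aa$aa_end
    )
  })
}

pipeline_summary <- function(table, enriched, events, diff_calls, cons_rates,
                             feature_stats, micro, overlap) {
  rows <- list(
    tibble(metric = "n_junctions", value = nrow(table$junctions)),
    tibble(metric = "n_samples", value = nrow(table$samples)),
    tibble(metric = "n_tissue_enriched", value = nrow(enriched)),
    tibble(metric = "n_events", value = nrow(events))
  )
  cls <- events |> count(.data$event_class)
  rows <- c(rows, list(tibble(
    metric = paste0("n_events_", cls$event_class), value = cls$n
  )))
  if (!is.null(diff_calls)) {
    rows <- c(rows, list(
      tibble(metric = "n_differential", value = sum(diff_calls$differential)),
      tibble(metric = "n_switch_like", value = sum(diff_calls$switch_like)),
      tibble(
        metric = "n_differential_events",
        value = length(unique(diff_calls$event_id[diff_calls$differential]))
      )
    ))
  }
  if (!is.null(cons_rates)) {
    rows <- c(rows, list(tibble(
      metric = paste0("conserved_pct_", cons_rates$class_label, "_", cons_rates$species),
      value = cons_rates$conserved_pct
    )))
  }
  rows <- c(rows, list(tibble(
    metric = paste0("frame_preserving_pct_", feature_stats$frame$class_label),
    value = feature_stats$frame$frame_preserving_pct
  )))
  rows <- c(rows, list(tibble(metric = "n_microexons", value = nrow(micro))))
  if (!is.null(overlap)) {
    rows <- c(rows, list(
      tibble(
        metric = paste0("idr_overlap_pct_", overlap$rates$class_label),
        value = overlap$rates$idr_pct
      ),
      tibble(
        metric = paste0("domain_overlap_pct_", overlap$rates$class_label),
        value = overlap$rates$domain_pct
      )
    ))
  }
  bind_rows(rows)
}
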