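## Phylogeny, conservation-track and protein-feature simulators.

## evolve one region for one species against the reference characters;
## returns at_ref / ins representation plus whether the internal exon was
## lost. Substitutions are per-base Bernoulli; indels are Poisson-many
## geometric-length (p = 0.5) single events; exon loss deletes the internal
## exon span atomically.
evolve_species_region <- function(ref_chars, sub_rate, indel_rate,
                                  exon_loss, exon_cols = NULL,
                                  protected_cols = integer(0),
                                  protected_rate_factor = 1) {
  n <- length(ref_chars)
  at_ref <- ref_chars
  ins <- rep(list(character(0)), n + 1L)
  bases <- c("A", "C", "G", "T")

  rate <- rep(sub_rate, n)
  if (length(protected_cols) > 0) {
    rate[protected_cols] <- sub_rate * protected_rate_factor
  }
  hit <- runif(n) < rate
  if (any(hit)) {
    at_ref[hit] <- map_chr(which(hit), function(i) {
      sample(setdiff(bases, ref_chars[i]), 1)
    })
  }

  n_indel <- rpois(1, indel_rate * n)
  for (k in seq_len(n_indel)) {
    len <- stats::rgeom(1, 0.5) + 1L
    if (runif(1) < 0.5) {
      s <- sample.int(n, 1)
      at_ref[s:min(n, s + len - 1L)] <- "-"
    } else {
      after <- sample.int(n + 1L, 1) - 1L
      ins[[after + 1L]] <- c(ins[[after + 1L]], sample(bases, len, replace = TRUE))
    }
  }

  lost <- FALSE
  if (!is.null(exon_cols) && isTRUE(exon_loss)) {
    at_ref[exon_cols] <- "-"
    lost <- TRUE
  }
  list(at_ref = at_ref, ins = ins, exon_lost = lost)
}

#' Simulate cross-species alignments for exon triplets
#'
#' For each ground-truth triplet, evolves the reference region once per
#' species with branch-specific substitution and indel rates. With the
#' per-species exon-loss probability (scaled by the class multiplier) the
#' internal exon is deleted, making the triplet truly non-conserved. The
#' splice-site dinucleotides of tissue-regulated triplets evolve at a
#' reduced substitution rate. Deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @param annotation result of [simulate_annotation()].
#' @param reference name of the reference species row (default "elegans").
#' @return list with `alignments` (named by truth triplet id), each a
#'   [species_alignment] whose region covers the triplet, and `truth`
#'   (tibble: `triplet_id`, `species`, `exon_lost`, `conserved_true`).
#' @export
simulate_phylogeny <- function(config, annotation, reference = "elegans") {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(derive_seed(config$seed, "phylogeny"))

  triplets <- annotation$truth$triplets
  phylo <- config$phylogeny
  alignments <- list()
  truth_rows <- list()

  for (i in seq_len(nrow(triplets))) {
    tr <- triplets[i, ]
    region <- list(
      chrom = tr$chrom, start = tr$exon_up_start, end = tr$exon_dn_end,
      strand = tr$strand
    )
    if (tr$strand == "-") {
      region$start <- tr$exon_dn_start
      region$end <- tr$exon_up_end
    }
    gseq <- annotation$genome[[tr$chrom]]
    ref_seq <- substr(gseq, region$start + 1L, region$end)
    if (tr$strand == "-") ref_seq <- reverse_complement(ref_seq)
    ref_chars <- strsplit(ref_seq, "")[[1]]

    ## transcript-oriented offsets of the internal exon and the four
    ## intron-terminal dinucleotides
    exon_cols <- region_offsets(tr$exon_in_start, tr$exon_in_end, region) + 1L
    iu <- region_offsets(tr$intron_up_start, tr$intron_up_end, region) + 1L
    idn <- region_offsets(tr$intron_dn_start, tr$intron_dn_end, region) + 1L
    site_cols <- c(head(iu, 2), tail(iu, 2), head(idn, 2), tail(idn, 2))
    protect <- tr$class_label == "alt_tissue_regulated"

    loss_mult <- unname(config$exon_loss_multiplier[tr$class_label] %theni% 1)
    per_species <- list()
    for (k in seq_len(nrow(phylo))) {
      sp <- phylo$species[k]
      loss <- runif(1) < min(1, phylo$exon_loss_prob[k] * loss_mult)
      ev <- evolve_species_region(
        ref_chars,
        sub_rate = phylo$substitution_rate[k],
        indel_rate = phylo$indel_rate[k],
        exon_loss = loss,
        exon_cols = exon_cols,
        protected_cols = if (protect) site_cols else integer(0),
        protected_rate_factor = config$splice_site_rate_factor
      )
      per_species[[sp]] <- ev
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        triplet_id = tr$triplet_id, species = sp,
        class_label = tr$class_label,
        exon_lost = ev$exon_lost, conserved_true = !ev$exon_lost
      )
    }
    rows <- star_merge_rows(ref_chars, per_species, reference)
    alignments[[tr$triplet_id]] <- species_alignment(rows, reference, region = region)
  }

  list(alignments = alignments, truth = bind_rows(truth_rows))
}

#' Simulate conservation track and protein feature annotations
#'
#' The conservation track covers every base of every ground-truth triplet
#' with Normal(0, 1) baseline scores; an additive elevation of
#' `conservation_effect` is applied within `conservation_flank` nt of the
#' splice sites of tissue-regulated triplets (both ends of both introns).
#' Protein feature intervals (IDR and domain) are placed so that each
#' triplet class overlaps them at its configured rate. Deterministic given
#' the config seed.
#'
#' @param config a [simulation_config()].
#' @param annotation result of [simulate_annotation()].
#' @return list with `track` (a [conservation_track]), `protein_features`
#'   (tibble `protein_id`, `start`, `end`, `label`), `protein_records`
#'   (per-triplet amino-acid intervals: `exon_id`, `protein_id`,
#'   `class_label`, `aa_start`, `aa_end`) and `truth_overlap` (implanted
#'   IDR/domain overlap flags).
#' @export
simulate_tracks_and_features <- function(config, annotation) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(derive_seed(config$seed, "tracks"))

  triplets <- annotation$truth$triplets
  flank <- config$conservation_flank

  ## conservation track: one baseline draw per covered base (triplet spans
  ## merged per chromosome), then the additive elevation near the splice
  ## sites of regulated exons
  spans <- triplets |>
    mutate(
      lo = pmin(.data$exon_up_start, .data$exon_dn_start),
      hi = pmax(.data$exon_up_end, .data$exon_dn_end)
    ) |>
    group_by(.data$chrom) |>
    summarise(lo = min(.data$lo), hi = max(.data$hi), .groups = "drop")
  score_rows <- map(seq_len(nrow(spans)), function(i) {
    pos <- seq.int(spans$lo[i], spans$hi[i] - 1L)
    tibble(chrom = spans$chrom[i], pos = pos, score = rnorm(length(pos)))
  })
  scores <- bind_rows(score_rows)
  if (config$conservation_effect != 0) {
    reg <- filter(triplets, .data$class_label == "alt_tissue_regulated")
    for (i in seq_len(nrow(reg))) {
      tr <- reg[i, ]
      win <- unlist(map(
        list(
          c(tr$intron_up_start, tr$intron_up_end),
          c(tr$intron_dn_start, tr$intron_dn_end)
        ),
        function(iv) {
          k <- min(flank, iv[2] - iv[1])
          unique(c(seq.int(iv[1], iv[1] + k - 1L), seq.int(iv[2] - k, iv[2] - 1L)))
        }
      ))
      hit <- scores$chrom == tr$chrom & scores$pos %in% win
      scores$score[hit] <- scores$score[hit] + config$conservation_effect
    }
  }
  track <- conservation_track(scores)

  ## protein features: protein = inclusion transcript (t1) of each gene,
  ## amino-acid interval of the internal exon via the CDS map
  models <- annotation$models
  rec_rows <- list()
  for (i in seq_len(nrow(triplets))) {
    tr <- triplets[i, ]
    txid <- paste0(tr$gene_id, ".t1")
    cds <- filter(
      models, .data$transcript_id == txid, .data$type == "CDS"
    )
    if (nrow(cds) == 0) next
    aa <- map_exon_to_protein(tr$exon_in_start, tr$exon_in_end, cds)
    if (!aa$coding) next
    plen <- sum(cds$end - cds$start) %/% 3L
    rec_rows[[length(rec_rows) + 1L]] <- tibble(
      exon_id = tr$triplet_id, protein_id = tr$gene_id,
      class_label = tr$class_label,
      aa_start = aa$aa_start, aa_end = aa$aa_end, protein_length = plen
    )
  }
  records <- bind_rows(rec_rows)

  ## interval placement: overlapping intervals hug the exon's aa span;
  ## non-overlapping ones go into the protein's N-terminal region upstream
  ## of every triplet exon of that protein (first exons are >= 100 nt, so
  ## there is always room)
  feat_rows <- list()
  if (nrow(records) > 0) {
    first_exon_aa <- records |>
      group_by(.data$protein_id) |>
      summarise(free_end = min(.data$aa_start) - 2L, .groups = "drop")
    records <- left_join(records, first_exon_aa, by = "protein_id")
    for (i in seq_len(nrow(records))) {
      r <- records[i, ]
      for (lab in c("idr", "domain")) {
        rate <- if (lab == "idr") {
          config$idr_overlap_rates[r$class_label]
        } else {
          config$domain_overlap_rates[r$class_label]
        }
        overlap <- runif(1) < unname(rate)
        if (overlap) {
          ## keep the interval strictly inside the exon's aa span so it
          ## cannot touch codon-adjacent neighbouring exons
          if (r$aa_end - r$aa_start >= 2L) {
            s <- r$aa_start + 1L; e <- r$aa_end - 1L
          } else {
            s <- r$aa_start; e <- r$aa_end
          }
        } else if (r$free_end >= 3L) {
          s <- 1L; e <- sample(2:r$free_end, 1L)
        } else {
          next  # no room for a non-overlapping interval
        }
        feat_rows[[length(feat_rows) + 1L]] <- tibble(
          protein_id = r$protein_id, start = as.integer(s), end = as.integer(e),
          label = lab, exon_id = r$exon_id, implanted_overlap = overlap
        )
      }
    }
    records$free_end <- NULL
  }
  features <- bind_rows(feat_rows)
  if (nrow(features) == 0) {
    features <- tibble(
      protein_id = character(), start = integer(), end = integer(),
      label = character(), exon_id = character(), implanted_overlap = logical()
    )
  }
  list(
    track = track,
    protein_features = select(features, "protein_id", "start", "end", "label"),
    protein_records = records,
    truth_overlap = select(
      features, "exon_id", "protein_id", "label", "implanted_overlap"
    )
  )
}
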