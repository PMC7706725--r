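## Ground-truthed synthetic data generator.
##
## Emulates the statistical structure of a tissue-enriched IP/input
## (TRAP-seq style) splicing study: genes carrying implanted splicing events
## of every class with known per-tissue PSI, junction read counts with
## replicate noise, and whole-animal "input" samples formed as a Poisson
## re-sample of the tissue mixture — so junctions exclusive to a
## low-fraction subtype are usually absent from input, while broadly
## expressed junctions never are.

#' Simulation configuration
#'
#' Defaults describe the study conditions exercised throughout the test
#' suite: three broad tissues plus two rare neuronal subtypes (mixture
#' fractions summing to 1), event genes at junction-group depth 200,
#' high-depth housekeeping genes expressed everywhere, and subtype-exclusive
#' genes at depth 100.
#'
#' @param seed integer master seed; every generator derives its stream from
#'   it.
#' @param tissues named mixture fractions (must sum to 1).
#' @param broad_tissues tissues in which event/constitutive genes are
#'   expressed.
#' @param events_per_class named counts of implanted event genes per class.
#' @param n_constitutive,n_housekeeping,n_subtype_exclusive numbers of
#'   linear genes: broad-tissue constitutive, all-tissue housekeeping, and
#'   per-subtype exclusive genes.
#' @param depth expected junction-group total per tissue for event and
#'   constitutive genes.
#' @param housekeeping_depth,subtype_depth group depths for housekeeping and
#'   subtype-exclusive genes.
#' @param n_replicates,n_input_replicates IP replicates per tissue and input
#'   replicates.
#' @param replicate_dispersion beta overdispersion of junction usage between
#'   replicates (0 = pure Poisson).
#' @param input_depth_factor per-transcript input sequencing depth relative
#'   to IP (whole-animal libraries spread reads over the full transcriptome
#'   of every tissue, so per-transcript coverage is far below the
#'   enriched IP coverage; this factor sets the dilution regime).
#' @param regulated_fraction fraction of event genes per class implanted as
#'   tissue-regulated.
#' @param switch_fraction among regulated events, fraction with switch-like
#'   (approximately 0.9 vs 0.1) PSI patterns; the rest are moderate
#'   (approximately 0.65 vs 0.35).
#' @param microexon_lengths lengths (nt) implanted as internal cassette
#'   exons of the first regulated cassette genes.
#' @param phylogeny tibble of species with per-branch `substitution_rate`,
#'   `indel_rate` and `exon_loss_prob` (reference species is `"elegans"`).
#' @param exon_loss_multiplier named per-class multipliers on
#'   `exon_loss_prob`.
#' @param splice_site_rate_factor substitution-rate multiplier at the
#'   splice-site dinucleotides of tissue-regulated triplets (< 1 models the
#'   elevated constraint there).
#' @param conservation_effect additive score elevation (delta) within
#'   `conservation_flank` nt of regulated exons' splice sites in the
#'   simulated conservation track.
#' @param conservation_flank width of the elevated windows (nt).
#' @param idr_overlap_rates,domain_overlap_rates named per-class
#'   probabilities that an internal exon overlaps an IDR / domain interval.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(
    seed = 1,
    tissues = c(neurons = 0.30, muscle = 0.30, intestine = 0.36,
                dopaminergic = 0.02, serotonergic = 0.02),
    broad_tissues = c("neurons", "muscle", "intestine"),
    events_per_class = c(cassette = 30, alt3ss = 8, alt5ss = 8,
                         mutually_exclusive = 8, intron_retention = 8,
                         alt_start_terminal = 8, complex = 8),
    n_constitutive = 22,
    n_housekeeping = 30,
    n_subtype_exclusive = 35,
    depth = 200,
    housekeeping_depth = 600,
    subtype_depth = 100,
    n_replicates = 2,
    n_input_replicates = 2,
    replicate_dispersion = 0.001,
    input_depth_factor = 0.012,
    regulated_fraction = 0.5,
    switch_fraction = 2 / 3,
    microexon_lengths = c(6, 15, 21, 27),
    phylogeny = tibble(
      species = c("briggsae", "remanei", "brenneri", "japonica", "angaria"),
      substitution_rate = c(0.05, 0.08, 0.12, 0.20, 0.35),
      indel_rate = c(0.002, 0.003, 0.004, 0.006, 0.010),
      exon_loss_prob = c(0.05, 0.10, 0.15, 0.28, 0.55)
    ),
    exon_loss_multiplier = c(constitutive = 0.5, alt_non_tissue = 1.3,
                             alt_tissue_regulated = 0.9),
    splice_site_rate_factor = 0.1,
    conservation_effect = 2,
    conservation_flank = 23,
    idr_overlap_rates = c(constitutive = 0.4, alt_non_tissue = 0.6,
                          alt_tissue_regulated = 0.8),
    domain_overlap_rates = c(constitutive = 0.6, alt_non_tissue = 0.45,
                             alt_tissue_regulated = 0.35)) {
  cfg <- as.list(environment())
  stopifnot(
    abs(sum(tissues) - 1) <= 1e-9,
    all(tissues > 0), all(tissues < 1),
    all(broad_tissues %in% names(tissues)),
    all(events_per_class >= 0),
    depth > 0, housekeeping_depth > 0, subtype_depth > 0,
    replicate_dispersion >= 0, input_depth_factor > 0,
    regulated_fraction >= 0, regulated_fraction <= 1,
    all(microexon_lengths >= 1),
    all(phylogeny$substitution_rate >= 0),
    all(phylogeny$indel_rate >= 0),
    all(phylogeny$exon_loss_prob >= 0 & phylogeny$exon_loss_prob <= 1)
  )
  cfg$subtype_tissues <- setdiff(names(tissues), broad_tissues)
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  n_genes <- sum(x$events_per_class) + x$n_constitutive + x$n_housekeeping +
    length(x$subtype_tissues) * x$n_subtype_exclusive
  cat(
    "<simulation_config> seed ", x$seed, ": ", n_genes, " genes, ",
    length(x$tissues), " tissues, depth ", x$depth, "\n",
    sep = ""
  )
  invisible(x)
}

## ---- gene structure builders (local plus-strand coordinates) -------------

rlen_between <- function(lo, hi) sample(lo:hi, 1L)

alt_exon_length <- function(frame_prob) {
  len <- rlen_between(45, 120)
  if (runif(1) < frame_prob) {
    len - (len %% 3L)
  } else if (len %% 3L == 0L) {
    len + 1L
  } else {
    len
  }
}

intron_len <- function(kind) {
  switch(kind,
    constitutive = rlen_between(48, 150),
    alt = rlen_between(90, 250),
    regulated = rlen_between(120, 300)
  )
}

## build one gene's exon/junction layout in local + orientation starting at
## `pad`; returns exons (per transcript), junction roles, retention introns,
## and truth triplet coordinates
build_gene_structure <- function(category, regulated, frame_prob,
                                 microexon_len = NA, pad = 60L) {
  ikind <- if (isTRUE(regulated)) "regulated" else "alt"
  exon <- function(len) c(0L, len)  # placeholder
  out <- list(retention = NULL, triplets = list(), alt_exon = NULL)

  if (category == "cassette") {
    e1 <- rlen_between(100, 180); i1 <- intron_len(ikind)
    e2 <- if (!is.na(microexon_len)) as.integer(microexon_len) else alt_exon_length(frame_prob)
    i2 <- intron_len(ikind); e3 <- rlen_between(100, 180)
    s1 <- pad
    E1 <- c(s1, s1 + e1); I1 <- c(E1[2], E1[2] + i1)
    E2 <- c(I1[2], I1[2] + e2); I2 <- c(E2[2], E2[2] + i2)
    E3 <- c(I2[2], I2[2] + e3)
    out$exons <- list(t1 = list(E1, E2, E3), t2 = list(E1, E3))
    out$roles <- tibble(
      start = c(E1[2], E2[2], E1[2]), end = c(E2[1], E3[1], E3[1]),
      role = c("inc", "inc", "alt")
    )
    out$triplets <- list(list(
      exon_up = E1, intron_up = I1, exon_in = E2, intron_dn = I2, exon_dn = E3,
      kind = "alt"
    ))
    out$alt_exon <- E2
  } else if (category %in% c("alt3ss", "alt5ss")) {
    ## the variable exon is internal (flanked on both sides) so the event is
    ## a pure splice-site choice, not confounded with alternative ends
    dd <- sample(c(9L, 12L, 15L, 18L, 21L, 24L), 1L)
    e1 <- rlen_between(100, 180); e2 <- rlen_between(120, 200); e3 <- rlen_between(100, 180)
    i1 <- intron_len(ikind); i2 <- rlen_between(48, 150)
    s1 <- pad
    E1 <- c(s1, s1 + e1)
    if (category == "alt3ss") {
      a1 <- E1[2] + i1
      E2long <- c(a1, a1 + e2); E2short <- c(a1 + dd, a1 + e2)
      E3 <- c(E2long[2] + i2, E2long[2] + i2 + e3)
      out$exons <- list(t1 = list(E1, E2long, E3), t2 = list(E1, E2short, E3))
      out$roles <- tibble(
        start = c(E1[2], E1[2], E2long[2]),
        end = c(a1, a1 + dd, E3[1]),
        role = c("inc", "alt", "const")
      )
    } else {
      s2 <- E1[2] + i2
      d1 <- s2 + e2; d2 <- d1 + dd
      a <- d2 + i1
      E3 <- c(a, a + e3)
      out$exons <- list(
        t1 = list(E1, c(s2, d2), E3), t2 = list(E1, c(s2, d1), E3)
      )
      out$roles <- tibble(
        start = c(d2, d1, E1[2]),
        end = c(a, a, s2),
        role = c("inc", "alt", "const")
      )
    }
  } else if (category == "mutually_exclusive") {
    e1 <- rlen_between(100, 180)
    ga <- intron_len(ikind); ea <- alt_exon_length(frame_prob)
    gab <- intron_len(ikind); eb <- alt_exon_length(frame_prob)
    gb <- intron_len(ikind); e4 <- rlen_between(100, 180)
    s1 <- pad
    E1 <- c(s1, s1 + e1)
    Ea <- c(E1[2] + ga, E1[2] + ga + ea)
    Eb <- c(Ea[2] + gab, Ea[2] + gab + eb)
    E4 <- c(Eb[2] + gb, Eb[2] + gb + e4)
    out$exons <- list(t1 = list(E1, Ea, E4), t2 = list(E1, Eb, E4))
    out$roles <- tibble(
      start = c(E1[2], Ea[2], E1[2], Eb[2]),
      end = c(Ea[1], E4[1], Eb[1], E4[1]),
      role = c("inc", "inc", "alt", "alt")
    )
  } else if (category == "intron_retention") {
    e1 <- rlen_between(100, 180); i1 <- intron_len(ikind); e2 <- rlen_between(100, 180)
    s1 <- pad
    E1 <- c(s1, s1 + e1); I1 <- c(E1[2], E1[2] + i1); E2 <- c(I1[2], I1[2] + e2)
    out$exons <- list(t1 = list(E1, E2), t2 = list(c(E1[1], E2[2])))
    out$roles <- tibble(start = E1[2], end = E2[1], role = "inc")
    out$retention <- tibble(start = I1[1], end = I1[2])
  } else if (category == "alt_start_terminal") {
    l1 <- rlen_between(80, 150); gap <- rlen_between(60, 150)
    l2 <- rlen_between(80, 150); i1 <- intron_len(ikind)
    e2 <- rlen_between(100, 180); i2 <- rlen_between(48, 150); e3 <- rlen_between(100, 180)
    s1 <- pad
    S1 <- c(s1, s1 + l1)
    S2 <- c(S1[2] + gap, S1[2] + gap + l2)
    E2 <- c(S2[2] + i1, S2[2] + i1 + e2)
    E3 <- c(E2[2] + i2, E2[2] + i2 + e3)
    out$exons <- list(t1 = list(S1, E2, E3), t2 = list(S2, E2, E3))
    out$roles <- tibble(
      start = c(S1[2], S2[2], E2[2]),
      end = c(E2[1], E2[1], E3[1]),
      role = c("inc", "alt", "const")
    )
  } else if (category == "complex") {
    e1 <- rlen_between(100, 180)
    s1 <- pad
    E1 <- c(s1, s1 + e1)
    g1 <- intron_len(ikind); e2 <- rlen_between(80, 140)
    E2 <- c(E1[2] + g1, E1[2] + g1 + e2)
    g2 <- rlen_between(60, 150); e3 <- rlen_between(80, 140)
    E3 <- c(E2[2] + g2, E2[2] + g2 + e3)
    g3 <- rlen_between(60, 150); e4 <- rlen_between(80, 140)
    E4 <- c(E3[2] + g3, E3[2] + g3 + e4)
    out$exons <- list(t1 = list(E1, E2), t2 = list(E1, E3), t3 = list(E1, E4))
    out$roles <- tibble(
      start = rep(E1[2], 3L), end = c(E2[1], E3[1], E4[1]),
      role = c("c1", "c2", "c3")
    )
  } else {  # linear gene: constitutive / housekeeping / subtype-exclusive
    s1 <- pad
    exs <- list(); pos <- s1
    for (k in 1:4) {
      len <- rlen_between(100, 180)
      exs[[k]] <- c(pos, pos + len)
      pos <- pos + len + if (k < 4) intron_len("constitutive") else 0L
    }
    out$exons <- list(t1 = exs)
    out$roles <- tibble(
      start = map_dbl(exs[1:3], 2), end = map_dbl(exs[2:4], 1),
      role = "const"
    )
    out$triplets <- list(
      list(exon_up = exs[[1]], intron_up = c(exs[[1]][2], exs[[2]][1]),
           exon_in = exs[[2]], intron_dn = c(exs[[2]][2], exs[[3]][1]),
           exon_dn = exs[[3]], kind = "constitutive"),
      list(exon_up = exs[[2]], intron_up = c(exs[[2]][2], exs[[3]][1]),
           exon_in = exs[[3]], intron_dn = c(exs[[3]][2], exs[[4]][1]),
           exon_dn = exs[[4]], kind = "constitutive")
    )
  }
  out$roles$start <- as.integer(out$roles$start)
  out$roles$end <- as.integer(out$roles$end)
  out
}

flip_iv <- function(iv, L) c(L - iv[2], L - iv[1])

## ---- annotation simulator ------------------------------------------------

#' Simulate annotation: genome, gene models and ground truth
#'
#' Builds one gene per chromosome with 2-4 exon transcripts, introns of at
#' least 48 nt with GT..AG termini, implanted splicing events of every
#' requested class (including microexon-length cassette exons), and linear
#' constitutive / housekeeping / subtype-exclusive genes. Deterministic
#' given the config seed.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (named character vector of chromosome
#'   sequences), `models` (gene model tibble with exon and CDS rows) and
#'   `truth` (list of tibbles: `genes`, `events`, `junction_usage`,
#'   `junctions`, `retention`, `triplets`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(derive_seed(config$seed, "annotation"))

  classes <- names(config$events_per_class)
  plan <- bind_rows(
    purrr::map_dfr(classes, function(cl) {
      n <- config$events_per_class[[cl]]
      if (n == 0) return(tibble())
      n_reg <- round(n * config$regulated_fraction)
      tibble(category = cl, regulated = seq_len(n) <= n_reg)
    }),
    tibble(category = "constitutive", regulated = rep(FALSE, config$n_constitutive)),
    tibble(category = "housekeeping", regulated = rep(FALSE, config$n_housekeeping)),
    purrr::map_dfr(config$subtype_tissues, function(st) {
      tibble(
        category = paste0("subtype_", st),
        regulated = rep(FALSE, config$n_subtype_exclusive)
      )
    })
  )
  plan$gene_id <- sprintf("gene%03d", seq_len(nrow(plan)))
  plan$chrom <- plan$gene_id
  plan$strand <- ifelse(seq_len(nrow(plan)) %% 2 == 0, "-", "+")

  ## microexons go to the first regulated cassette genes
  me_idx <- which(plan$category == "cassette" & plan$regulated)
  plan$microexon_len <- NA_integer_
  n_me <- min(length(config$microexon_lengths), length(me_idx))
  if (n_me > 0) plan$microexon_len[me_idx[seq_len(n_me)]] <- as.integer(config$microexon_lengths[seq_len(n_me)])

  genome <- character(0)
  model_rows <- list()
  usage_rows <- list()
  junction_rows <- list()
  retention_rows <- list()
  triplet_rows <- list()
  event_rows <- list()
  gene_rows <- list()
  pad <- 60L

  for (i in seq_len(nrow(plan))) {
    g <- plan[i, ]
    is_event <- g$category %in% classes
    frame_prob <- if (g$regulated) 0.8 else 0.6
    st <- build_gene_structure(
      g$category, g$regulated, frame_prob, g$microexon_len, pad = pad
    )

    gene_end <- max(map_dbl(st$exons, ~ max(map_dbl(.x, 2))))
    L <- as.integer(gene_end + pad)
    seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                        prob = c(0.32, 0.18, 0.18, 0.32))
    ## force GT..AG termini on every intron (junctions and retained introns)
    introns <- bind_rows(st$roles[c("start", "end")], st$retention)
    for (k in seq_len(nrow(introns))) {
      s <- introns$start[k]; e <- introns$end[k]
      seq_chars[(s + 1):(s + 2)] <- c("G", "T")
      seq_chars[(e - 1):e] <- c("A", "G")
    }

    flip <- g$strand == "-"
    tf_iv <- function(iv) if (flip) flip_iv(iv, L) else iv
    seq_str <- paste(seq_chars, collapse = "")
    if (flip) seq_str <- reverse_complement(seq_str)
    genome[[g$chrom]] <- seq_str

    ## exon + CDS rows (CDS = transcript trimmed to a multiple of 3 at the
    ## transcript 3' end; phases follow GTF conventions)
    for (tx in names(st$exons)) {
      exs <- st$exons[[tx]]
      txid <- paste0(g$gene_id, ".", tx)
      lens <- map_dbl(exs, ~ .x[2] - .x[1])
      total <- sum(lens)
      trim <- total %% 3
      cds <- exs
      cds[[length(cds)]] <- c(cds[[length(cds)]][1], cds[[length(cds)]][2] - trim)
      cum <- cumsum(c(0, head(map_dbl(cds, ~ .x[2] - .x[1]), -1)))
      phases <- (3 - (cum %% 3)) %% 3
      for (k in seq_along(exs)) {
        iv <- tf_iv(exs[[k]])
        model_rows[[length(model_rows) + 1L]] <- tibble(
          gene_id = g$gene_id, transcript_id = txid, type = "exon",
          chrom = g$chrom, start = as.integer(iv[1]), end = as.integer(iv[2]),
          strand = g$strand, phase = NA_integer_
        )
        civ <- tf_iv(cds[[k]])
        if (civ[2] > civ[1]) {
          model_rows[[length(model_rows) + 1L]] <- tibble(
            gene_id = g$gene_id, transcript_id = txid, type = "CDS",
            chrom = g$chrom, start = as.integer(civ[1]), end = as.integer(civ[2]),
            strand = g$strand, phase = as.integer(phases[k])
          )
        }
      }
    }

    ## tissues, depth and per-tissue PSI
    if (g$category == "housekeeping") {
      tiss <- names(config$tissues); dep <- config$housekeeping_depth
    } else if (startsWith(g$category, "subtype_")) {
      tiss <- sub("subtype_", "", g$category); dep <- config$subtype_depth
    } else {
      tiss <- config$broad_tissues; dep <- config$depth
    }
    gene_rows[[length(gene_rows) + 1L]] <- tibble(
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      category = g$category, regulated = g$regulated, depth = dep,
      tissues = paste(tiss, collapse = ",")
    )

    ## usage of each role junction per expressed tissue
    if (is_event) {
      if (g$category == "complex") {
        base <- c(c1 = 0.5, c2 = 0.3, c3 = 0.2)
        usage <- map(seq_along(tiss), function(ti) {
          if (g$regulated) {
            setNames(base[((seq_len(3) + ti - 2) %% 3) + 1], names(base))
          } else {
            base
          }
        })
        names(usage) <- tiss
        psi_vec <- map_dbl(usage, "c1")
      } else {
        if (g$regulated) {
          switchy <- runif(1) < config$switch_fraction
          hi <- if (switchy) runif(1, 0.85, 0.95) else runif(1, 0.60, 0.70)
          lo <- if (switchy) runif(1, 0.05, 0.15) else runif(1, 0.30, 0.40)
          low_tissue <- sample(tiss, 1)
          psi_vec <- setNames(ifelse(tiss == low_tissue, lo, hi), tiss)
        } else {
          minor <- runif(1, 0.05, 0.20)
          psi_vec <- setNames(rep(1 - minor, length(tiss)), tiss)
        }
        usage <- map(psi_vec, function(p) c(inc = p, alt = 1 - p, const = 1, ret = 1 - p))
      }
    } else {
      psi_vec <- setNames(rep(1, length(tiss)), tiss)
      usage <- map(psi_vec, function(p) c(const = 1))
    }

    ## junction truth rows (genomic coordinates)
    roles <- st$roles
    for (k in seq_len(nrow(roles))) {
      iv <- tf_iv(c(roles$start[k], roles$end[k]))
      key <- junction_key(g$chrom, iv[1], iv[2], g$strand)
      junction_rows[[length(junction_rows) + 1L]] <- tibble(
        gene_id = g$gene_id, chrom = g$chrom, start = as.integer(iv[1]),
        end = as.integer(iv[2]), strand = g$strand, junction_id = key,
        role = roles$role[k],
        tissue_exclusive = if (startsWith(g$category, "subtype_")) tiss[1] else NA_character_
      )
      for (tt in tiss) {
        u <- if (is_event && g$category == "complex") {
          unname(usage[[tt]][roles$role[k]])
        } else {
          unname(usage[[tt]][roles$role[k]])
        }
        usage_rows[[length(usage_rows) + 1L]] <- tibble(
          gene_id = g$gene_id, junction_id = key, kind = "junction",
          tissue = tt, usage = u, depth = dep
        )
      }
    }
    if (!is.null(st$retention)) {
      iv <- tf_iv(c(st$retention$start[1], st$retention$end[1]))
      key <- paste0("retention:", junction_key(g$chrom, iv[1], iv[2], g$strand))
      retention_rows[[length(retention_rows) + 1L]] <- tibble(
        gene_id = g$gene_id, chrom = g$chrom, start = as.integer(iv[1]),
        end = as.integer(iv[2]), strand = g$strand, edge_id = key
      )
      for (tt in tiss) {
        usage_rows[[length(usage_rows) + 1L]] <- tibble(
          gene_id = g$gene_id, junction_id = key, kind = "retention",
          tissue = tt, usage = unname(usage[[tt]]["ret"]), depth = dep
        )
      }
    }

    ## event truth
    if (is_event) {
      jk <- map_chr(seq_len(nrow(roles)), function(k) {
        iv <- tf_iv(c(roles$start[k], roles$end[k]))
        junction_key(g$chrom, iv[1], iv[2], g$strand)
      })
      event_rows[[length(event_rows) + 1L]] <- tibble(
        gene_id = g$gene_id, true_class = g$category, regulated = g$regulated,
        junction_keys = list(c(
          jk[roles$role != "const"],
          if (!is.null(st$retention)) {
            iv <- tf_iv(c(st$retention$start[1], st$retention$end[1]))
            paste0("retention:", junction_key(g$chrom, iv[1], iv[2], g$strand))
          }
        )),
        psi = list(psi_vec),
        is_microexon = !is.na(g$microexon_len)
      )
    }

    ## truth triplets
    for (tr in st$triplets) {
      kind <- if (tr$kind == "constitutive") {
        "constitutive"
      } else if (g$regulated) "alt_tissue_regulated" else "alt_non_tissue"
      ivs <- map(tr[c("exon_up", "intron_up", "exon_in", "intron_dn", "exon_dn")], tf_iv)
      if (flip) {
        ## flipping reverses the genomic order but not the transcript roles
        names(ivs) <- c("exon_up", "intron_up", "exon_in", "intron_dn", "exon_dn")
      }
      triplet_rows[[length(triplet_rows) + 1L]] <- tibble(
        gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
        class_label = kind,
        exon_up_start = ivs$exon_up[1], exon_up_end = ivs$exon_up[2],
        intron_up_start = ivs$intron_up[1], intron_up_end = ivs$intron_up[2],
        exon_in_start = ivs$exon_in[1], exon_in_end = ivs$exon_in[2],
        intron_dn_start = ivs$intron_dn[1], intron_dn_end = ivs$intron_dn[2],
        exon_dn_start = ivs$exon_dn[1], exon_dn_end = ivs$exon_dn[2],
        is_microexon = !is.na(g$microexon_len) & tr$kind == "alt"
      )
    }
  }

  truth_triplets <- bind_rows(triplet_rows)
  truth_triplets$triplet_id <- sprintf("truth_tr%04d", seq_len(nrow(truth_triplets)))

  list(
    genome = genome,
    models = bind_rows(model_rows),
    truth = list(
      genes = bind_rows(gene_rows),
      events = bind_rows(event_rows),
      junction_usage = bind_rows(usage_rows),
      junctions = bind_rows(junction_rows),
      retention = bind_rows(retention_rows),
      triplets = truth_triplets
    )
  )
}

## ---- count simulator -----------------------------------------------------

## one overdispersed count: Poisson around depth * usage with a
## beta-perturbed usage (between-replicate dispersion rho)
rcount_overdispersed <- function(n, depth, usage, rho) {
  if (usage <= 0) return(rep(0L, n))
  p <- if (rho > 0 && usage < 1) {
    a <- usage * (1 / rho - 1); b <- (1 - usage) * (1 / rho - 1)
    rbeta(n, a, b)
  } else {
    rep(usage, n)
  }
  rpois(n, depth * p)
}

#' Simulate IP and input junction counts
#'
#' IP counts per tissue and replicate follow an overdispersed Poisson around
#' `usage x depth` per junction. Input samples model whole-animal dilution:
#' the expected input count is `input_depth_factor` times the
#' mixture-weighted sum of expected tissue counts, re-sampled as Poisson per
#' input replicate — junctions exclusive to a low-fraction subtype are
#' therefore usually absent (count 0) from input.
#'
#' @param config a [simulation_config()].
#' @param annotation result of [simulate_annotation()].
#' @return list with `table` (a [jct_table] of IP and input samples),
#'   `retention_counts` (per-tissue intronic support tibble) and
#'   `input_expected` (per-junction input Poisson mean, for reference).
#' @export
simulate_counts <- function(config, annotation) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(derive_seed(config$seed, "counts"))

  usage <- annotation$truth$junction_usage
  jts <- filter(usage, .data$kind == "junction")
  rts <- filter(usage, .data$kind == "retention")
  junctions <- annotation$truth$junctions |>
    distinct(.data$junction_id, .keep_all = TRUE)

  tissues <- names(config$tissues)
  samples <- bind_rows(
    purrr::map_dfr(tissues, function(tt) {
      tibble(
        sample_id = paste0(tt, "_IP_", seq_len(config$n_replicates)),
        tissue = tt, fraction = "IP", replicate = seq_len(config$n_replicates)
      )
    }),
    tibble(
      sample_id = paste0("whole_animal_input_", seq_len(config$n_input_replicates)),
      tissue = "whole_animal", fraction = "input",
      replicate = seq_len(config$n_input_replicates)
    )
  )

  counts <- matrix(
    0L, nrow = nrow(junctions), ncol = nrow(samples),
    dimnames = list(junctions$junction_id, samples$sample_id)
  )

  ## IP counts
  for (tt in tissues) {
    ju <- filter(jts, .data$tissue == tt)
    if (nrow(ju) == 0) next
    idx <- match(ju$junction_id, junctions$junction_id)
    cols <- which(samples$tissue == tt & samples$fraction == "IP")
    for (ci in cols) {
      counts[idx, ci] <- map_int(seq_len(nrow(ju)), function(k) {
        as.integer(rcount_overdispersed(
          1, ju$depth[k], ju$usage[k], config$replicate_dispersion
        ))
      })
    }
  }

  ## input counts: Poisson re-sample of the diluted tissue mixture
  mix <- jts |>
    mutate(lambda = config$tissues[.data$tissue] * .data$depth * .data$usage) |>
    group_by(.data$junction_id) |>
    summarise(lambda = sum(.data$lambda), .groups = "drop") |>
    mutate(lambda = config$input_depth_factor * .data$lambda)
  idx <- match(mix$junction_id, junctions$junction_id)
  input_cols <- which(samples$fraction == "input")
  for (ci in input_cols) {
    counts[idx, ci] <- rpois(nrow(mix), mix$lambda)
  }

  ## per-tissue retention support (pooled over IP replicates)
  retention_counts <- NULL
  if (nrow(rts) > 0) {
    ret_meta <- annotation$truth$retention
    retention_counts <- purrr::map_dfr(seq_len(nrow(rts)), function(k) {
      r <- rts[k, ]
      meta <- ret_meta[match(r$junction_id, ret_meta$edge_id), ]
      tot <- sum(rcount_overdispersed(
        config$n_replicates, r$depth, r$usage, config$replicate_dispersion
      ))
      tibble(
        chrom = meta$chrom, start = meta$start, end = meta$end,
        strand = meta$strand, tissue = r$tissue, count = as.integer(tot)
      )
    })
  }

  list(
    table = jct_table(
      select(junctions, "chrom", "start", "end", "strand"),
      samples, counts
    ),
    retention_counts = retention_counts,
    input_expected = mix
  )
}
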