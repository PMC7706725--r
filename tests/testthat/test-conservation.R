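## a compact hand-built triplet on the plus strand:
## exon [0,10) intron [10,30) exon [30,40) intron [40,60) exon [60,70)
toy_triplet <- function(strand = "+") {
  tibble::tibble(
    triplet_id = "tr1", gene_id = "g1", chrom = "chrI", strand = strand,
    class_label = "alt_non_tissue", event_id = NA_character_,
    exon_up_start = 0L, exon_up_end = 10L,
    intron_up_start = 10L, intron_up_end = 30L,
    exon_in_start = 30L, exon_in_end = 40L,
    intron_dn_start = 40L, intron_dn_end = 60L,
    exon_dn_start = 60L, exon_dn_end = 70L
  )
}

toy_ref_seq <- function() {
  set.seed(404)
  s <- sample(c("A", "C", "G", "T"), 70, replace = TRUE)
  for (iv in list(c(10, 30), c(40, 60))) {
    s[(iv[1] + 1):(iv[1] + 2)] <- c("G", "T")
    s[(iv[2] - 1):iv[2]] <- c("A", "G")
  }
  paste(s, collapse = "")
}

test_that("triplets come from cassette events and isolated internal exons", {
  models <- cassette_models()
  skip_j <- tibble::tibble(chrom = "chrI", start = 200L, end = 500L, strand = "+")
  g <- build_splice_graph(models, "g1", junctions = skip_j)
  ev <- classify_events(enumerate_events(g), g)
  tri <- extract_triplets(ev, list(g1 = g))
  expect_equal(nrow(tri), 1)
  expect_equal(tri$class_label, "alt_non_tissue")
  expect_equal(tri$exon_in_start, 300L)
  expect_equal(tri$exon_in_end, 400L)
  expect_equal(tri$intron_up_start, 200L)
  expect_equal(tri$intron_dn_end, 500L)

  # with a differential call the label becomes tissue-regulated
  dc <- tibble::tibble(event_id = ev$event_id[1], differential = TRUE)
  tri_reg <- extract_triplets(ev, list(g1 = g), dc)
  expect_equal(tri_reg$class_label, "alt_tissue_regulated")

  # a purely linear gene contributes constitutive triplets for internal exons
  lin <- tibble::tibble(
    gene_id = "g2", transcript_id = "g2.t1", type = "exon", chrom = "chrII",
    start = c(0L, 200L, 400L, 600L), end = c(100L, 300L, 500L, 700L),
    strand = "+", phase = NA_integer_
  )
  g2 <- build_splice_graph(lin, "g2")
  tri2 <- extract_triplets(ev[0, ], list(g2 = g2))
  expect_equal(nrow(tri2), 2)
  expect_true(all(tri2$class_label == "constitutive"))
  # first exon of a gene yields no triplet
  expect_false(0L %in% tri2$exon_in_start)
})

test_that("center-star alignment of identical sequences is gap-free with identity 1", {
  seqs <- c(elegans = "ACGTACGTAA", s1 = "ACGTACGTAA", s2 = "ACGTACGTAA")
  aln <- align_center_star(seqs, "elegans")
  expect_false(any(grepl("-", aln$rows, fixed = TRUE)))
  td <- tidy(aln)
  expect_true(all(td$identity == 1))
  expect_equal(aln$ref_map, 1:10)
})

test_that("a single deletion produces one gap run in the species row", {
  aln <- align_center_star(
    c(elegans = "ACGTACGT", sp = "ACGACGT"), "elegans"
  )
  expect_equal(nchar(aln$rows[["sp"]]), 8)
  expect_equal(sum(strsplit(aln$rows[["sp"]], "")[[1]] == "-"), 1)
  expect_error(align_center_star(c(elegans = "ACGT", sp = ""), "elegans"), "empty")
})

test_that("pairwise alignment scores match an independent affine-gap DP", {
  cases <- list(
    c("ACGTACGT", "ACGACGT"),
    c("AAAA", "TTTT"),
    c("ACGTGTTTACA", "ACGTACA"),
    c("GATTACA", "GCATGCATT")
  )
  for (cs in cases) {
    aln <- align_center_star(c(elegans = cs[1], sp = cs[2]), "elegans")
    got <- attr(aln, "pairwise_scores")[["sp"]]
    want <- oracle_align_score(cs[2], cs[1])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("conservation calls require exon presence and aligned splice sites", {
  tr <- toy_triplet()
  ref <- toy_ref_seq()
  region <- list(chrom = "chrI", start = 0L, end = 70L, strand = "+")

  perfect <- species_alignment(
    c(elegans = ref, sp = ref), "elegans", region = region
  )
  call <- assess_conservation(tr, perfect, "sp")
  expect_true(call$conserved)
  expect_equal(call$presence_in, 1)

  # internal exon fully gapped -> presence 0 < 0.5 -> not conserved
  gap_exon <- ref
  sp_row <- strsplit(ref, "")[[1]]
  sp_row[31:40] <- "-"
  lost <- species_alignment(
    c(elegans = ref, sp = paste(sp_row, collapse = "")), "elegans", region = region
  )
  call2 <- assess_conservation(tr, lost, "sp")
  expect_false(call2$conserved)
  expect_equal(call2$presence_in, 0)

  # exons intact but one intron-terminal base gapped -> not conserved
  sp_row <- strsplit(ref, "")[[1]]
  sp_row[11] <- "-"  # first base of the upstream intron (donor G)
  site_gap <- species_alignment(
    c(elegans = ref, sp = paste(sp_row, collapse = "")), "elegans", region = region
  )
  call3 <- assess_conservation(tr, site_gap, "sp")
  expect_false(call3$conserved)
  expect_false(call3$site_up_donor)
  expect_true(call3$site_up_acceptor)

  # columns outside the triplet span do not matter
  sp_row <- strsplit(ref, "")[[1]]
  sp_row[1:5] <- "-"  # inside the upstream exon: presence 0.5 still passes
  edge <- species_alignment(
    c(elegans = ref, sp = paste(sp_row, collapse = "")), "elegans", region = region
  )
  expect_true(assess_conservation(tr, edge, "sp")$conserved)

  # triplet outside the alignment span errors
  short_region <- list(chrom = "chrI", start = 0L, end = 50L, strand = "+")
  short_aln <- species_alignment(
    c(elegans = substr(ref, 1, 50), sp = substr(ref, 1, 50)),
    "elegans", region = short_region
  )
  expect_error(assess_conservation(tr, short_aln, "sp"), "outside")
})

test_that("Fisher comparisons match exact hypergeometric enumeration", {
  calls <- function(k, n) {
    tibble::tibble(conserved = rep(c(TRUE, FALSE), c(k, n - k)))
  }
  # identical rates and sizes -> p = 1
  expect_equal(conservation_rate_compare(calls(5, 10), calls(5, 10))$p_value, 1)
  # the perfectly separated 10/10 table
  res <- conservation_rate_compare(calls(10, 10), calls(0, 10))
  expect_equal(res$p_value, oracle_fisher_p(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)),
               tolerance = 1e-12)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  # the published-scale 81/113 vs 163/277 style table
  res2 <- conservation_rate_compare(calls(81, 113), calls(163, 277))
  expect_equal(
    res2$p_value,
    oracle_fisher_p(matrix(c(81, 32, 163, 114), 2, byrow = TRUE)),
    tolerance = 1e-9
  )
  expect_error(conservation_rate_compare(calls(0, 0)[0, ], calls(1, 2)), "empty")
})

test_that("Fisher p equals brute-force enumeration on all small tables", {
  for (n1 in c(3, 7, 12)) {
    for (n2 in c(5, 9, 15)) {
      for (k1 in seq(0, n1, by = 3)) {
        for (k2 in seq(0, n2, by = 4)) {
          tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
          expect_equal(
            stats::fisher.test(tab)$p.value,
            oracle_fisher_p(tab),
            tolerance = 1e-12
          )
        }
      }
    }
  }
})

test_that("window profiles average strand-aware intron flanks with rolling smoothing", {
  tr <- toy_triplet()
  # scores 1..23 written at the first 23 bases of the upstream intron would
  # exceed the intron (length 20), so use the documented short-intron split:
  # here give every intron base a known value
  up_pos <- 10:29; dn_pos <- 40:59
  track <- conservation_track(tibble::tibble(
    chrom = "chrI",
    pos = c(up_pos, dn_pos, 0:9, 30:39, 60:69),
    score = c(seq_along(up_pos), seq_along(dn_pos), rep(0, 30))
  ))
  wp <- window_profile(track, tr, flank_len = 5, smooth = 3)
  up5 <- wp$profiles[wp$profiles$region == "upstream_intron_5p", ]
  expect_equal(up5$mean_score, 1:5)
  # smoothed position 2 = mean(1,2,3) = 2; edges truncate
  expect_equal(up5$smoothed, c(1.5, 2, 3, 4, 4.5))
  # 3' flank reads backwards from the splice site into the intron
  up3 <- wp$profiles[wp$profiles$region == "upstream_intron_3p", ]
  expect_equal(up3$mean_score, c(20, 19, 18, 17, 16))
  # smooth = 1 leaves the raw means untouched
  wp1 <- window_profile(track, tr, flank_len = 5, smooth = 1)
  expect_equal(
    wp1$profiles$smoothed, wp1$profiles$mean_score
  )

  # on the minus strand position 1 is still the first intronic base from the
  # splice site: for the (genomically mirrored) triplet the 5' flank of the
  # upstream intron now reads right-to-left
  trm <- toy_triplet("-")
  wpm <- window_profile(track, trm, flank_len = 5, smooth = 1)
  upm <- wpm$profiles[wpm$profiles$region == "upstream_intron_5p", ]
  # upstream intron on '-' is genomic [40,60): 5' end at genomic 59 downwards
  expect_equal(upm$mean_score, c(20, 19, 18, 17, 16))
})

test_that("window profile test battery reacts to an implanted flank effect", {
  set.seed(52)
  n <- 40
  mk_tr <- function(i, label) {
    base <- (i - 1) * 1000L
    tibble::tibble(
      triplet_id = paste0("tr", i), gene_id = paste0("g", i), chrom = "c1",
      strand = "+", class_label = label, event_id = NA_character_,
      exon_up_start = base, exon_up_end = base + 100L,
      intron_up_start = base + 100L, intron_up_end = base + 200L,
      exon_in_start = base + 200L, exon_in_end = base + 300L,
      intron_dn_start = base + 300L, intron_dn_end = base + 400L,
      exon_dn_start = base + 400L, exon_dn_end = base + 500L
    )
  }
  tri <- dplyr::bind_rows(
    purrr::map_dfr(1:n, mk_tr, label = "constitutive"),
    purrr::map_dfr((n + 1):(2 * n), mk_tr, label = "alt_tissue_regulated")
  )
  pos_all <- unlist(purrr::map(seq_len(2 * n), function(i) {
    base <- (i - 1) * 1000L
    c(seq(base + 100L, base + 199L), seq(base + 300L, base + 399L))
  }))
  score <- rnorm(length(pos_all))
  # delta = 2 at every intron position of regulated triplets
  reg_mask <- rep(rep(c(FALSE, TRUE), each = n), each = 200)
  score[reg_mask] <- score[reg_mask] + 2
  track <- conservation_track(tibble::tibble(chrom = "c1", pos = pos_all, score = score))
  wp <- window_profile(track, tri)
  expect_true(all(wp$tests$p_signed_rank < 0.05))
  expect_true(all(wp$tests$p_rank_sum < 0.05))

  # missing track for most of a class errors with the class named
  half_track <- conservation_track(tibble::tibble(
    chrom = "c1", pos = pos_all[seq_len(200 * n)], score = 0
  ))
  expect_error(window_profile(half_track, tri), "alt_tissue_regulated")
})

test_that("conservation is monotone in divergence on simulated phylogenies", {
  cfg <- simulation_config(
    seed = 3,
    events_per_class = c(cassette = 10, alt3ss = 0, alt5ss = 0,
                         mutually_exclusive = 0, intron_retention = 0,
                         alt_start_terminal = 0, complex = 0),
    n_constitutive = 20, n_housekeeping = 5, n_subtype_exclusive = 2,
    phylogeny = tibble::tibble(
      species = c("near", "far"),
      substitution_rate = c(0.05, 0.25),
      indel_rate = c(0.002, 0.008),
      exon_loss_prob = c(0.05, 0.35)
    )
  )
  ann <- simulate_annotation(cfg)
  phy <- simulate_phylogeny(cfg, ann)
  calls <- conservation_calls(ann$truth$triplets, phy$alignments)
  rates <- calls |>
    dplyr::group_by(species) |>
    dplyr::summarise(rate = mean(conserved))
  expect_gte(rates$rate[rates$species == "near"], rates$rate[rates$species == "far"])
})
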