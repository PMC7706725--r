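obs_skip <- tibble::tibble(chrom = "chrI", start = 200L, end = 500L, strand = "+")

test_that("splice graph of the cassette substrate has 3 nodes and 3 edges", {
  g <- build_splice_graph(cassette_models(), "g1", junctions = obs_skip)
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 3)
  expect_equal(nrow(g$orphans), 0)
  expect_equal(g$nodes$first_exon, c(TRUE, FALSE, FALSE))
  expect_equal(g$nodes$last_exon, c(FALSE, FALSE, TRUE))
})

test_that("a junction landing mid-exon splits the node at that site", {
  j <- tibble::tibble(chrom = "chrI", start = 200L, end = 350L, strand = "+")
  g <- build_splice_graph(cassette_models(), "g1", junctions = j)
  # exon2 [300, 400) is split at 350 into two segments
  expect_true(all(c(350L) %in% g$nodes$start))
  expect_equal(nrow(g$nodes), 4)
})

test_that("without observed junctions only annotated edges remain; orphans are recorded", {
  g <- build_splice_graph(cassette_models(), "g1")
  # three annotated introns: two from the inclusion transcript plus the
  # skipping transcript's junction
  expect_equal(nrow(g$edges), 3)
  expect_true(all(g$edges$annotated))
  orphan <- tibble::tibble(chrom = "chrI", start = 250L, end = 260L, strand = "+")
  g2 <- build_splice_graph(cassette_models(), "g1", junctions = orphan)
  expect_equal(nrow(g2$orphans), 1)
})

test_that("event enumeration matches exhaustive per-node-side enumeration", {
  oracle_events <- function(graph) {
    out <- character(0)
    for (node in graph$nodes$node_id) {
      for (col in c("donor_node", "acceptor_node")) {
        ids <- sort(graph$edges$edge_id[graph$edges[[col]] == node])
        if (length(ids) >= 2) out <- c(out, paste(ids, collapse = "|"))
      }
    }
    sort(unique(out))
  }
  set.seed(5)
  g <- build_splice_graph(cassette_models(), "g1", junctions = obs_skip)
  ev <- enumerate_events(g)
  expect_equal(
    sort(unique(purrr::map_chr(ev$edge_ids, paste, collapse = "|"))),
    oracle_events(g)
  )
  # purely linear gene -> zero events
  lin <- cassette_models()[1:3, ]
  expect_equal(nrow(enumerate_events(build_splice_graph(lin, "g1"))), 0)
})

test_that("three junctions from one node form a single 3-junction complex event", {
  models <- tibble::tibble(
    gene_id = "g1", transcript_id = rep(c("g1.t1", "g1.t2", "g1.t3"), each = 2),
    type = "exon", chrom = "chrI",
    start = c(0L, 200L, 0L, 400L, 0L, 600L),
    end = c(100L, 300L, 100L, 500L, 100L, 700L),
    strand = "+", phase = NA_integer_
  )
  g <- build_splice_graph(models, "g1")
  ev <- classify_events(enumerate_events(g), g)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_junctions, 3)
  expect_equal(ev$event_class, "complex")
})

test_that("the five canonical classes are recovered from clean substrates", {
  # cassette (plus and minus strand)
  for (strand in c("+", "-")) {
    models <- cassette_models(strand)
    g <- build_splice_graph(models, "g1", junctions = tibble::tibble(
      chrom = "chrI", start = 200L, end = 500L, strand = strand
    ))
    ev <- classify_events(enumerate_events(g), g)
    expect_equal(sort(unique(ev$event_class)), "cassette")
  }

  # alt3ss: shared donor, two acceptors 12 nt apart inside one exon extension
  m3 <- tibble::tibble(
    gene_id = "g1",
    transcript_id = c("g1.t1", "g1.t1", "g1.t1", "g1.t2", "g1.t2", "g1.t2"),
    type = "exon", chrom = "chrI",
    start = c(0L, 200L, 500L, 0L, 212L, 500L),
    end = c(100L, 400L, 600L, 100L, 400L, 600L),
    strand = "+", phase = NA_integer_
  )
  g3 <- build_splice_graph(m3, "g1")
  ev3 <- classify_events(enumerate_events(g3), g3)
  expect_equal(unique(ev3$event_class), "alt3ss")

  # alt5ss: two donors, shared acceptor
  m5 <- tibble::tibble(
    gene_id = "g1",
    transcript_id = c("g1.t1", "g1.t1", "g1.t1", "g1.t2", "g1.t2", "g1.t2"),
    type = "exon", chrom = "chrI",
    start = c(0L, 200L, 500L, 0L, 200L, 500L),
    end = c(100L, 412L, 600L, 100L, 400L, 600L),
    strand = "+", phase = NA_integer_
  )
  g5 <- build_splice_graph(m5, "g1")
  ev5 <- classify_events(enumerate_events(g5), g5)
  expect_equal(unique(ev5$event_class), "alt5ss")

  # mutually exclusive
  mx <- tibble::tibble(
    gene_id = "g1",
    transcript_id = rep(c("g1.t1", "g1.t2"), each = 3),
    type = "exon", chrom = "chrI",
    start = c(0L, 200L, 800L, 0L, 500L, 800L),
    end = c(100L, 300L, 900L, 100L, 600L, 900L),
    strand = "+", phase = NA_integer_
  )
  gx <- build_splice_graph(mx, "g1")
  evx <- classify_events(enumerate_events(gx), gx)
  expect_equal(unique(evx$event_class), "mutually_exclusive")

  # alternative start exons
  ma <- tibble::tibble(
    gene_id = "g1",
    transcript_id = rep(c("g1.t1", "g1.t2"), each = 2),
    type = "exon", chrom = "chrI",
    start = c(0L, 600L, 300L, 600L),
    end = c(100L, 700L, 400L, 700L),
    strand = "+", phase = NA_integer_
  )
  ga <- build_splice_graph(ma, "g1")
  eva <- classify_events(enumerate_events(ga), ga)
  expect_equal(unique(eva$event_class), "alt_start_terminal")

  # intron retention: retention edge competing with the same intron
  mi <- tibble::tibble(
    gene_id = "g1",
    transcript_id = c("g1.t1", "g1.t1", "g1.t2"),
    type = "exon", chrom = "chrI",
    start = c(0L, 300L, 0L),
    end = c(100L, 400L, 400L),
    strand = "+", phase = NA_integer_
  )
  gi <- build_splice_graph(
    mi, "g1",
    retention = tibble::tibble(chrom = "chrI", start = 100L, end = 300L, strand = "+")
  )
  evi <- classify_events(enumerate_events(gi), gi)
  expect_equal(unique(evi$event_class), "intron_retention")
})

test_that("a second skipping junction turns a cassette region complex", {
  models <- tibble::tibble(
    gene_id = "g1",
    transcript_id = rep("g1.t1", 4), type = "exon", chrom = "chrI",
    start = c(0L, 200L, 500L, 800L), end = c(100L, 300L, 600L, 900L),
    strand = "+", phase = NA_integer_
  )
  j <- tibble::tibble(
    chrom = "chrI", start = c(100L, 100L), end = c(500L, 800L), strand = "+"
  )
  g <- build_splice_graph(models, "g1", junctions = j)
  ev <- classify_events(enumerate_events(g), g)
  src <- ev[ev$n_junctions == 3, ]
  expect_equal(src$event_class, "complex")
})

test_that("event tables are byte-deterministic across rebuilds", {
  build <- function() {
    g <- build_splice_graph(cassette_models(), "g1", junctions = obs_skip)
    classify_events(enumerate_events(g), g)
  }
  a <- build(); b <- build()
  expect_identical(a, b)
})

test_that("event PSI shares sum to 1 and respect the quantifiability floor", {
  g <- build_splice_graph(cassette_models(), "g1", junctions = obs_skip)
  ev <- classify_events(enumerate_events(g), g)
  tab <- make_table(
    c("chrI:200-300:+", "chrI:400-500:+", "chrI:200-500:+"),
    matrix(c(90L, 90L, 10L, 3L, 2L, 1L), ncol = 2),
    tissues = c("neurons", "muscle"), fractions = c("IP", "IP")
  )
  ep <- quantify_events(ev, tab, min_event_reads = 10)
  neu <- ep[ep$tissue == "neurons", ]
  sums <- tapply(neu$psi, neu$event_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(sort(unique(round(neu$psi, 2))), c(0.1, 0.9))
  # muscle total 6 < 10 -> unquantifiable
  mus <- ep[ep$tissue == "muscle", ]
  expect_true(all(is.na(mus$psi)) && all(!mus$quantifiable))
})

test_that("retention counts enter event PSI as competing support", {
  mi <- tibble::tibble(
    gene_id = "g1", transcript_id = c("g1.t1", "g1.t1", "g1.t2"),
    type = "exon", chrom = "chrI",
    start = c(0L, 300L, 0L), end = c(100L, 400L, 400L),
    strand = "+", phase = NA_integer_
  )
  gi <- build_splice_graph(
    mi, "g1",
    retention = tibble::tibble(chrom = "chrI", start = 100L, end = 300L, strand = "+")
  )
  ev <- classify_events(enumerate_events(gi), gi)
  tab <- make_table("chrI:100-300:+", matrix(50L), tissues = "neurons")
  ret <- tibble::tibble(
    chrom = "chrI", start = 100L, end = 300L, strand = "+",
    tissue = "neurons", count = 50L
  )
  ep <- quantify_events(ev, tab, retention_counts = ret)
  expect_equal(ep$psi[ep$type == "retention"], 0.5)
  expect_equal(ep$psi[ep$type == "junction"], 0.5)
})

test_that("delta-PSI flags follow the differential and switch thresholds and antisymmetry", {
  g <- build_splice_graph(cassette_models(), "g1", junctions = obs_skip)
  ev <- classify_events(enumerate_events(g), g)
  mk <- function(psi_a, psi_b, depth = 10000L) {
    make_table(
      c("chrI:200-300:+", "chrI:400-500:+", "chrI:200-500:+"),
      matrix(as.integer(c(
        round(depth * psi_a), round(depth * psi_a), round(depth * (1 - psi_a)),
        round(depth * psi_b), round(depth * psi_b), round(depth * (1 - psi_b))
      )), ncol = 2),
      tissues = c("neurons", "muscle"), fractions = c("IP", "IP")
    )
  }
  ep <- quantify_events(ev, mk(0.90, 0.05))
  dc <- call_differential(ep, "neurons", "muscle")
  expect_true(all(abs(abs(dc$dpsi) - 0.85) < 1e-6))
  expect_true(all(dc$differential) && all(dc$switch_like))
  # antisymmetry
  rev <- call_differential(ep, "muscle", "neurons")
  expect_equal(rev$dpsi, -dc$dpsi)

  ep2 <- quantify_events(ev, mk(0.55, 0.40))
  d20 <- call_differential(ep2, "neurons", "muscle", differential_min = 0.20)
  d15 <- call_differential(ep2, "neurons", "muscle", differential_min = 0.15)
  expect_false(any(d20$differential))
  expect_true(all(d15$differential))
  expect_false(any(d15$switch_like))

  ep3 <- quantify_events(ev, mk(0.5, 0.5))
  d0 <- call_differential(ep3, "neurons", "muscle")
  expect_true(all(d0$dpsi == 0) && !any(d0$differential))

  # unquantifiable events are skipped and counted
  ep4 <- quantify_events(ev, mk(0.9, 0.5, depth = 4L), min_event_reads = 10)
  d4 <- call_differential(ep4, "neurons", "muscle")
  expect_equal(nrow(d4), 0)
  expect_gte(attr(d4, "n_skipped"), 1)
})

test_that("class proportion chi-squared equals the direct formula", {
  a <- c(complex = 50, other = 50)
  b <- c(complex = 10, other = 90)
  res <- class_proportion_test(a, b, "complex")
  # hand evaluation of sum((O-E)^2/E) for [[50,50],[10,90]]
  expect_equal(res$statistic, 400 * (2 / 30 + 2 / 70), tolerance = 1e-10)
  expect_equal(res$df, 1L)
  expect_equal(
    res$p_value,
    stats::pchisq(400 * (2 / 30 + 2 / 70), df = 1, lower.tail = FALSE),
    tolerance = 1e-12
  )
  # identical proportions at large n -> statistic ~ 0, p ~ 1
  same <- class_proportion_test(
    c(complex = 500, other = 500), c(complex = 500, other = 500), "complex"
  )
  expect_lt(same$statistic, 1e-10)
  expect_equal(same$p_value, 1, tolerance = 1e-6)
  # class absent from both groups -> statistic 0
  none <- class_proportion_test(c(other = 10), c(other = 20), "complex")
  expect_equal(none$statistic, 0)
})

test_that("expression fold-change, DE flags and decoupled splicing behave as specified", {
  expr <- tibble::tibble(
    gene_id = rep(c("gA", "gB", "gC"), each = 3),
    tissue = rep(c("n", "m", "i"), 3),
    count = c(100L, 100L, 100L, 500L, 100L, 100L, 0L, 0L, 0L)
  )
  dpsi <- tibble::tibble(
    gene_id = c("gA", "gB"), tissue_a = "n", tissue_b = "m",
    dpsi = c(0.1, -0.2)
  )
  res <- expression_vs_splicing(expr, dpsi, min_expression = 50, de_fold = 5)
  # flat gene -> fold change over median 0 everywhere
  fa <- res$fold_changes[res$fold_changes$gene_id == "gA", ]
  expect_true(all(fa$fc_over_median == 0))
  # 5x gene flagged DE
  expect_true(res$de_genes$differential_expression[res$de_genes$gene_id == "gB"])
  expect_false(res$de_genes$differential_expression[res$de_genes$gene_id == "gA"])
  # all-zero gene dropped
  expect_equal(res$n_dropped, 1)

  # independence: |rho| stays small over simulated unrelated vectors
  set.seed(31)
  genes <- sprintf("g%03d", 1:300)
  expr2 <- tibble::tibble(
    gene_id = rep(genes, each = 2),
    tissue = rep(c("n", "m"), 300),
    count = rpois(600, 200)
  )
  dpsi2 <- tibble::tibble(
    gene_id = genes, tissue_a = "n", tissue_b = "m",
    dpsi = runif(300, -0.8, 0.8)
  )
  res2 <- expression_vs_splicing(expr2, dpsi2)
  expect_lt(abs(res2$correlations$rho), 0.15)
  expect_gt(res2$correlations$p_value, 0.01)
})
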