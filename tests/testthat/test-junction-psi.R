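test_that("PSI follows the group-share formula and the coverage gate", {
  # donor group {j:80, k:20} sharing start=100; min 10 -> 0.8 / 0.2
  tab <- make_table(
    c("chrI:100-200:+", "chrI:100-300:+"),
    matrix(c(80L, 20L), nrow = 2)
  )
  psi <- compute_psi(tab, min_group_reads = 10)
  expect_equal(psi$psi_donor, c(0.8, 0.2))
  # acceptor groups are singletons -> psi_acceptor 1, summary min(d, a)
  expect_equal(psi$psi_acceptor, c(1, 1))
  expect_equal(psi$psi, c(0.8, 0.2))

  # junction alone in both groups with count 7, min 5 -> psi 1
  solo <- make_table("chrI:10-50:+", matrix(7L))
  expect_equal(compute_psi(solo, min_group_reads = 5)$psi, 1)

  # group total 4 below min 10 -> undefined on that side
  low <- make_table("chrI:10-50:+", matrix(4L))
  p <- compute_psi(low, min_group_reads = 10)
  expect_true(is.na(p$psi_donor) && is.na(p$psi))
})

test_that("tissue pooling sums replicate counts before division", {
  tab <- make_table(
    c("chrI:100-200:+", "chrI:100-300:+"),
    matrix(c(3L, 1L, 5L, 1L), nrow = 2),
    tissues = c("neurons", "neurons"), fractions = c("IP", "IP"),
    replicates = 1:2
  )
  psi <- compute_psi(tab, min_group_reads = 10, pool_by = "tissue")
  # pooled counts 8 and 2: group total 10 passes only after pooling
  expect_equal(psi$psi_donor[psi$junction_id == "chrI:100-200:+"], 0.8)
  expect_error(
    compute_psi(
      jct_table(tab$junctions,
                dplyr::mutate(tab$samples, tissue = NA_character_),
                tab$counts),
      pool_by = "tissue"
    ),
    "tissue"
  )
})

test_that("compute_psi matches the brute-force pair-scan oracle on random tables", {
  set.seed(421)
  for (rep in 1:40) {
    n <- sample(3:20, 1)
    starts <- sample(seq(0, 500, by = 50), n, replace = TRUE)
    ends <- starts + sample(seq(100, 400, by = 37), n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    keys <- unique(paste0("chr", sample(1:2, n, TRUE), ":", starts, "-", ends, ":", strands))
    counts <- matrix(rpois(length(keys) * 2, 30), ncol = 2)
    tab <- make_table(keys, counts)
    mgr <- sample(c(1, 5, 20), 1)
    got <- compute_psi(tab, min_group_reads = mgr) |>
      dplyr::arrange(unit, junction_id)
    want <- oracle_psi(tab, mgr) |>
      dplyr::arrange(unit, junction_id)
    expect_equal(got$psi, want$psi, tolerance = 1e-12)
    expect_equal(got$psi_donor, want$psi_donor, tolerance = 1e-12)
    expect_equal(got$group_total_donor, as.integer(want$group_total_donor))
  }
})

test_that("defined group PSI values sum to 1 and respond monotonically to reads", {
  set.seed(77)
  keys <- c("chrI:100-200:+", "chrI:100-300:+", "chrI:100-400:+", "chrI:600-700:-")
  tab <- make_table(keys, matrix(rpois(8, 40), ncol = 2))
  psi <- compute_psi(tab, min_group_reads = 5)
  sums <- psi |>
    dplyr::filter(!is.na(psi_donor)) |>
    dplyr::group_by(donor_group, unit) |>
    dplyr::summarise(s = sum(psi_donor), n = dplyr::n(), .groups = "drop")
  # where defined (the gate is per group, so all members define together),
  # shares sum to exactly 1
  expect_true(all(abs(sums$s - 1) < 1e-9))

  # monotonicity: adding reads to j never decreases psi(j), never increases psi(k)
  tab2 <- make_table(keys, matrix(c(50L, 30L, 20L, 10L), ncol = 1))
  tab3 <- make_table(keys, matrix(c(70L, 30L, 20L, 10L), ncol = 1))
  p2 <- compute_psi(tab2, 5); p3 <- compute_psi(tab3, 5)
  expect_gte(p3$psi_donor[1], p2$psi_donor[1])
  expect_lte(p3$psi_donor[2], p2$psi_donor[2])
  expect_lte(p3$psi_donor[3], p2$psi_donor[3])
})

test_that("tissue-enriched detection requires zero input and honours both threshold modes", {
  keys <- c("chrI:100-200:+", "chrI:300-400:+", "chrI:500-600:+")
  tab <- make_table(
    keys,
    matrix(c(
      25L, 25L, 5L,   # IP rep1
      0L, 0L, 0L,     # IP rep2
      0L, 1L, 0L      # input
    ), nrow = 3),
    tissues = c("neurons", "neurons", "whole_animal"),
    fractions = c("IP", "IP", "input"),
    replicates = c(1L, 2L, 1L)
  )
  # ip 25, input 0, strict > 20 -> called
  strict <- detect_tissue_enriched(tab, "neurons", min_ip_reads = 20, strict = TRUE)
  expect_equal(strict$junction_id, "chrI:100-200:+")
  # ip 25 but input 1 -> never called
  expect_false("chrI:300-400:+" %in% strict$junction_id)
  # ip 5, input 0, inclusive >= 5 -> called
  at5 <- detect_tissue_enriched(tab, "neurons", min_ip_reads = 5)
  expect_true(all(c("chrI:100-200:+", "chrI:500-600:+") %in% at5$junction_id))
  # exactly at the strict boundary: 20 reads is not "more than 20"
  tab20 <- make_table(
    keys[1], matrix(c(20L, 0L), nrow = 1),
    tissues = c("neurons", "whole_animal"), fractions = c("IP", "input")
  )
  expect_equal(nrow(detect_tissue_enriched(tab20, "neurons", 20, strict = TRUE)), 0)
  expect_equal(nrow(detect_tissue_enriched(tab20, "neurons", 20, strict = FALSE)), 1)
  # no input samples -> error
  noin <- make_table(keys[1], matrix(5L), tissues = "neurons", fractions = "IP")
  expect_error(detect_tissue_enriched(noin, "neurons"), "input")
})

test_that("detection is empty when every IP junction has input support", {
  keys <- c("chrI:100-200:+", "chrI:300-400:+")
  tab <- make_table(
    keys, matrix(c(50L, 80L, 1L, 2L), nrow = 2),
    tissues = c("muscle", "whole_animal"), fractions = c("IP", "input")
  )
  expect_equal(nrow(detect_tissue_enriched(tab, "muscle", 5)), 0)
})

test_that("alternative groups need a minor variant at or above the PSI floor", {
  build_psi <- function(minor) {
    tab <- make_table(
      c("chrI:100-200:+", "chrI:100-300:+"),
      matrix(c(round(1000 * (1 - minor)), round(1000 * minor)), nrow = 2),
      tissues = c("neurons"), fractions = c("IP")
    )
    compute_psi(tab, min_group_reads = 10, pool_by = "tissue")
  }
  expect_gte(nrow(call_alternative_junctions(build_psi(0.07))), 1)   # 0.93/0.07
  alt3 <- call_alternative_junctions(build_psi(0.03))                # 0.97/0.03
  expect_equal(nrow(alt3), 0)
  # a group with a single defined member is never alternative
  solo <- compute_psi(make_table("chrI:10-60:+", matrix(100L), tissues = "n"),
                      pool_by = "tissue")
  expect_equal(nrow(call_alternative_junctions(solo)), 0)
  # empty input -> empty output
  expect_equal(nrow(call_alternative_junctions(solo[0, ])), 0)
})

test_that("binomial down-sampling is unbiased, deterministic and exact at the edges", {
  tab <- make_table("chrI:10-60:+", matrix(10000L))
  expect_identical(subsample_counts(tab, 1, seed = 1), tab)
  half <- subsample_counts(tab, 0.5, seed = 11)
  # +-4 sigma band for Binomial(10000, 0.5): 5000 +- 200
  expect_gte(half$counts[1, 1], 4800L)
  expect_lte(half$counts[1, 1], 5200L)
  expect_identical(
    subsample_counts(tab, 0.5, seed = 11)$counts,
    half$counts
  )
  zero <- make_table("chrI:10-60:+", matrix(0L))
  expect_equal(subsample_counts(zero, 0.3, seed = 2)$counts[1, 1], 0L)
})

test_that("PSI correlation drops incomplete pairs and matches the closed form", {
  a <- c(0.1, 0.5, 0.9); b <- c(0.9, 0.5, 0.1)
  expect_equal(correlate_psi(a, a)$estimate, 1)
  expect_equal(correlate_psi(a, b)$estimate, -1)
  # hand-computed Pearson for (0.2,0.4,0.6,0.8) vs (0.3,0.3,0.7,0.7):
  # r = 0.16 / sqrt(0.2 * 0.16) = 0.8944272
  r <- correlate_psi(c(0.2, 0.4, 0.6, 0.8), c(0.3, 0.3, 0.7, 0.7))
  expect_equal(r$estimate, 0.16 / sqrt(0.2 * 0.16), tolerance = 1e-12)
  # NA pairs are dropped and counted
  r2 <- correlate_psi(c(NA, 0.2, 0.4, 0.6, 0.8), c(0.5, 0.3, 0.3, 0.7, 0.7))
  expect_equal(r2$n, 4)
  expect_error(correlate_psi(c(0.1, NA, NA), c(0.2, 0.3, 0.4)), "3 complete")
  flat <- correlate_psi(c(0.5, 0.5, 0.5), c(0.1, 0.2, 0.3))
  expect_true(flat$undefined && is.na(flat$estimate))
})

test_that("PSI recovers implanted usage at deep coverage", {
  set.seed(99)
  psis <- runif(40, 0.05, 0.95)
  keys1 <- sprintf("chrI:%d-%d:+", seq(0, by = 1000, length.out = 40),
                   seq(300, by = 1000, length.out = 40))
  keys2 <- sprintf("chrI:%d-%d:+", seq(0, by = 1000, length.out = 40),
                   seq(500, by = 1000, length.out = 40))
  n1 <- rbinom(40, 400, psis)
  tab <- make_table(c(keys1, keys2), matrix(c(n1, 400L - n1), ncol = 1))
  psi <- compute_psi(tab, min_group_reads = 10)
  est <- psi$psi_donor[match(keys1, psi$junction_id)]
  expect_gte(mean(abs(est - psis) <= 0.05), 0.95)
})
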