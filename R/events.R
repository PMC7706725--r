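## Event-level PSI quantification, differential (delta-PSI) calls, class
## proportion tests and the expression-vs-splicing decoupling analysis.

#' Quantify per-tissue event PSI
#'
#' Event PSI of a junction is its pooled tissue count divided by the total
#' count over all of the event's edges in that tissue (retention edges
#' contribute retention counts); PSI is undefined in a tissue when the event
#' total is below `min_event_reads`, and the event is "quantifiable" there
#' only when defined.
#'
#' @param events classified events tibble ([classify_events()] output, any
#'   number of genes).
#' @param table a [jct_table]; IP replicate counts are pooled per tissue.
#' @param retention_counts optional tibble of per-tissue intronic support for
#'   retention edges: `chrom`, `start`, `end`, `strand`, `tissue`, `count`.
#' @param min_event_reads minimum per-tissue event total (default 10).
#' @return long tibble: `event_id`, `gene_id`, `event_class`, `edge_id`,
#'   `type`, `tissue`, `count`, `total`, `psi`, `quantifiable`.
#' @export
quantify_events <- function(events, table, retention_counts = NULL,
                            min_event_reads = 10) {
  stopifnot(inherits(table, "jct_table"))
  m <- pool_count_matrix(table, "tissue")
  tissues <- colnames(m)[!grepl(":", colnames(m))]  # IP units only
  m <- m[, tissues, drop = FALSE]

  ret_lookup <- NULL
  if (!is.null(retention_counts) && nrow(retention_counts) > 0) {
    rc <- as_tibble(retention_counts)
    ret_lookup <- setNames(
      rc$count,
      paste0(
        "retention:",
        junction_key(rc$chrom, rc$start, rc$end, rc$strand), "@", rc$tissue
      )
    )
  }

  rows <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    ids <- events$edge_ids[[i]]
    counts <- vapply(tissues, function(tt) {
      vapply(ids, function(id) {
        if (startsWith(id, "retention:")) {
          unname(ret_lookup[paste0(id, "@", tt)]) %theni% 0
        } else {
          j <- match(id, rownames(m))
          if (is.na(j)) 0 else m[j, tt]
        }
      }, numeric(1))
    }, numeric(length(ids)))
    counts <- matrix(counts, nrow = length(ids), dimnames = list(ids, tissues))
    tot <- unname(colSums(counts))
    tibble(
      event_id = events$event_id[i],
      edge_id = rep(ids, times = length(tissues)),
      tissue = rep(tissues, each = length(ids)),
      count = unname(as.vector(counts)),
      total = rep(tot, each = length(ids))
    )
  })
  rows |>
    mutate(
      psi = if_else(.data$total >= min_event_reads, .data$count / .data$total, NA_real_),
      quantifiable = .data$total >= min_event_reads,
      type = if_else(startsWith(.data$edge_id, "retention:"), "retention", "junction")
    ) |>
    left_join(
      select(events, "event_id", "gene_id", "event_class"),
      by = "event_id"
    ) |>
    select(
      "event_id", "gene_id", "event_class", "edge_id", "type",
      "tissue", "count", "total", "psi", "quantifiable"
    )
}

#' Differential splicing calls between two tissues
#'
#' Delta-PSI is computed on each event's reference junction — the edge with
#' the maximal summed count across the two tissues (ties broken by edge id).
#' An event is flagged `differential` when `|dPSI| >= differential_min` and
#' `switch_like` when `|dPSI| >= switch_min`. Events unquantifiable in either
#' tissue are skipped (counted in the `n_skipped` attribute).
#'
#' @param event_psi tibble from [quantify_events()].
#' @param tissue_a,tissue_b tissue labels present in `event_psi`.
#' @param differential_min differential threshold on |dPSI| (default 0.20;
#'   0.15 is the threshold used for gene-set style summaries).
#' @param switch_min switch-like threshold on |dPSI| (default 0.80).
#' @return tibble: `event_id`, `gene_id`, `event_class`, `tissue_a`,
#'   `tissue_b`, `ref_edge`, `psi_a`, `psi_b`, `dpsi`, `differential`,
#'   `switch_like`; attribute `n_skipped`.
#' @export
call_differential <- function(event_psi, tissue_a, tissue_b,
                              differential_min = 0.20, switch_min = 0.80) {
  sub <- filter(event_psi, .data$tissue %in% c(tissue_a, tissue_b))
  wide <- sub |>
    select("event_id", "gene_id", "event_class", "edge_id", "tissue", "count", "psi") |>
    tidyr::pivot_wider(
      names_from = "tissue", values_from = c("count", "psi"),
      names_glue = "{.value}.{tissue}"
    )
  ca <- paste0("count.", tissue_a); cb <- paste0("count.", tissue_b)
  pa <- paste0("psi.", tissue_a); pb <- paste0("psi.", tissue_b)
  stopifnot(all(c(ca, cb, pa, pb) %in% names(wide)))
  per_event <- wide |>
    group_by(.data$event_id, .data$gene_id, .data$event_class) |>
    arrange(desc(.data[[ca]] + .data[[cb]]), .data$edge_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  quant <- !is.na(per_event[[pa]]) & !is.na(per_event[[pb]])
  skipped <- sum(!quant)
  out <- per_event[quant, , drop = FALSE] |>
    transmute(
      event_id = .data$event_id,
      gene_id = .data$gene_id,
      event_class = .data$event_class,
      tissue_a = tissue_a,
      tissue_b = tissue_b,
      ref_edge = .data$edge_id,
      psi_a = .data[[pa]],
      psi_b = .data[[pb]],
      dpsi = .data[[pa]] - .data[[pb]],
      # small tolerance so thresholds behave as stated when |dPSI| sits
      # exactly on the boundary up to floating-point representation
      differential = abs(.data$dpsi) >= differential_min - 1e-9,
      switch_like = abs(.data$dpsi) >= switch_min - 1e-9
    ) |>
    arrange(.data$event_id)
  attr(out, "n_skipped") <- skipped
  out
}

#' Chi-squared test for one event class's proportion between two groups
#'
#' Builds the 2x2 table (class vs rest) x (group a vs b) and applies
#' Pearson's chi-squared test without continuity correction, so the
#' statistic equals `sum((O - E)^2 / E)`.
#'
#' @param dist_a,dist_b named counts of events per class.
#' @param class the class whose proportion is compared.
#' @return one-row tibble: `class`, `statistic`, `df`, `p_value`,
#'   `prop_a`, `prop_b`, `low_expected` (TRUE when an expected cell < 1).
#' @export
class_proportion_test <- function(dist_a, dist_b, class) {
  stopifnot(sum(dist_a) > 0, sum(dist_b) > 0)
  ka <- unname(dist_a[class] %theni% 0)
  kb <- unname(dist_b[class] %theni% 0)
  na <- sum(dist_a); nb <- sum(dist_b)
  if (ka + kb == 0) {
    return(tibble(
      class = class, statistic = 0, df = 1L, p_value = 1,
      prop_a = 0, prop_b = 0, low_expected = TRUE
    ))
  }
  tab <- matrix(c(ka, na - ka, kb, nb - kb), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  low <- any(expected < 1)
  if (low) warn("chi-squared expected cell count below 1")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(
    class = class,
    statistic = unname(ct$statistic),
    df = as.integer(ct$parameter),
    p_value = unname(ct$p.value),
    prop_a = ka / na,
    prop_b = kb / nb,
    low_expected = low
  )
}

#' Relate expression differences to splicing differences
#'
#' Per gene and tissue, computes the log2 fold change over the median count
#' across tissues (pseudocount 1); flags genes differentially expressed when
#' the maximal pairwise fold change among sufficiently expressed tissues
#' reaches `de_fold`; and reports the Spearman correlation between the
#' between-tissue expression difference and delta-PSI over shared genes for
#' each tissue pair.
#'
#' @param expression long tibble `gene_id`, `tissue`, `count`.
#' @param dpsi tibble `gene_id`, `tissue_a`, `tissue_b`, `dpsi` (gene-level
#'   delta-PSI per tissue pair).
#' @param min_expression minimum count for a tissue to enter the fold-change
#'   comparison (default 50).
#' @param de_fold fold change calling a gene differentially expressed
#'   (default 5).
#' @return list with `fold_changes`, `de_genes`, `correlations` tibbles and
#'   `n_dropped` (all-zero genes removed).
#' @export
expression_vs_splicing <- function(expression, dpsi, min_expression = 50,
                                   de_fold = 5) {
  expression <- as_tibble(expression)
  zero_genes <- expression |>
    group_by(.data$gene_id) |>
    summarise(allzero = all(.data$count == 0), .groups = "drop") |>
    filter(.data$allzero) |>
    pull("gene_id")
  expression <- filter(expression, !.data$gene_id %in% zero_genes)

  fold_changes <- expression |>
    group_by(.data$gene_id) |>
    mutate(
      fc_over_median = log2((.data$count + 1) / (median(.data$count) + 1))
    ) |>
    ungroup()

  de_genes <- expression |>
    filter(.data$count >= min_expression) |>
    group_by(.data$gene_id) |>
    summarise(
      max_fold = if (n() >= 2) max(.data$count) / min(.data$count) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(differential_expression = !is.na(.data$max_fold) & .data$max_fold >= de_fold)

  pairs <- distinct(dpsi, .data$tissue_a, .data$tissue_b)
  correlations <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    ta <- pairs$tissue_a[i]; tb <- pairs$tissue_b[i]
    ed <- expression |>
      filter(.data$tissue %in% c(ta, tb)) |>
      tidyr::pivot_wider(names_from = "tissue", values_from = "count") |>
      mutate(expr_diff = log2((.data[[ta]] + 1) / (.data[[tb]] + 1)))
    dd <- filter(dpsi, .data$tissue_a == ta, .data$tissue_b == tb)
    joined <- inner_join(ed, dd, by = "gene_id") |>
      filter(!is.na(.data$expr_diff), !is.na(.data$dpsi))
    if (nrow(joined) < 3) {
      return(tibble(
        tissue_a = ta, tissue_b = tb, rho = NA_real_,
        p_value = NA_real_, n = nrow(joined)
      ))
    }
    ct <- suppressWarnings(
      cor.test(joined$expr_diff, joined$dpsi, method = "spearman", exact = FALSE)
    )
    tibble(
      tissue_a = ta, tissue_b = tb,
      rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(joined)
    )
  })

  list(
    fold_changes = fold_changes,
    de_genes = de_genes,
    correlations = correlations,
    n_dropped = length(zero_genes)
  )
}
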