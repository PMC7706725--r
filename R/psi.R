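## Junction-level percent spliced in (PSI).
##
## A junction's PSI is its read count divided by the summed counts of all
## junctions sharing its splice donor (or acceptor) site, so within one
## donor/acceptor group and sample the PSI values of the members sum to 1.
## Both sides are computed; the summary PSI is the minimum of the two defined
## sides (conservative), or the single defined side when only one group
## passes the coverage floor.

#' Assign junctions to donor/acceptor splice-site groups
#'
#' @param junctions junction tibble (as in [jct_table()]).
#' @return tibble with one row per junction and side: `junction_id`, `side`
#'   (`"donor"`/`"acceptor"`), `site` (genomic position of the intron-terminal
#'   base), `group_id`.
#' @export
splice_site_groups <- function(junctions) {
  da <- donor_acceptor(junctions$chrom, junctions$start, junctions$end, junctions$strand)
  bind_rows(
    tibble(
      junction_id = junctions$junction_id, side = "donor",
      site = da$donor, chrom = junctions$chrom, strand = junctions$strand
    ),
    tibble(
      junction_id = junctions$junction_id, side = "acceptor",
      site = da$acceptor, chrom = junctions$chrom, strand = junctions$strand
    )
  ) |>
    mutate(group_id = paste(.data$chrom, .data$strand, .data$side, .data$site, sep = ":")) |>
    select("junction_id", "side", "site", "group_id")
}

## pool the count matrix into units: per sample, or per (tissue, fraction)
## with replicate counts summed
pool_count_matrix <- function(x, pool_by = c("sample", "tissue")) {
  pool_by <- match.arg(pool_by)
  if (pool_by == "sample") {
    units <- x$samples$sample_id
    m <- x$counts
    colnames(m) <- units
    return(m)
  }
  if (is.null(x$samples$tissue) || all(is.na(x$samples$tissue))) {
    abort("pool_by = 'tissue' requires tissue metadata")
  }
  unit <- ifelse(
    x$samples$fraction == "IP",
    x$samples$tissue,
    paste(x$samples$tissue, x$samples$fraction, sep = ":")
  )
  groups <- split(seq_len(nrow(x$samples)), unit)
  m <- vapply(
    groups,
    function(idx) rowSums(x$counts[, idx, drop = FALSE]),
    numeric(nrow(x$counts))
  )
  if (nrow(x$counts) == 1) m <- matrix(m, nrow = 1, dimnames = list(rownames(x$counts), names(groups)))
  m[, order(colnames(m)), drop = FALSE]
}

#' Compute junction PSI over splice-site groups
#'
#' For each junction and pooling unit, `psi_donor` is the junction's count
#' divided by the summed counts of its donor group (undefined when that
#' denominator is below `min_group_reads`); `psi_acceptor` analogously. The
#' summary `psi` is the minimum of the defined sides. Pooling by tissue sums
#' replicate counts before division (IP replicates pool per tissue; input
#' replicates pool per `tissue:input` unit).
#'
#' @param table a [jct_table].
#' @param min_group_reads minimum pooled group total for a side's PSI to be
#'   defined (default 10).
#' @param pool_by `"sample"` or `"tissue"`.
#' @return tibble with one row per junction and unit: `junction_id`, `unit`,
#'   `psi_donor`, `psi_acceptor`, `psi`, `group_total_donor`,
#'   `group_total_acceptor`, plus the two group identifiers.
#' @export
compute_psi <- function(table, min_group_reads = 10, pool_by = c("sample", "tissue")) {
  stopifnot(inherits(table, "jct_table"), min_group_reads >= 1)
  pool_by <- match.arg(pool_by)
  if (nrow(table$junctions) == 0) abort("empty junction table")
  m <- pool_count_matrix(table, pool_by)
  groups <- splice_site_groups(table$junctions)
  donor_gid <- groups$group_id[groups$side == "donor"][match(table$junctions$junction_id, groups$junction_id[groups$side == "donor"])]
  acc_gid <- groups$group_id[groups$side == "acceptor"][match(table$junctions$junction_id, groups$junction_id[groups$side == "acceptor"])]

  group_sum <- function(gid) {
    # per-unit group totals broadcast back to members
    agg <- rowsum(m, gid)
    agg[match(gid, rownames(agg)), , drop = FALSE]
  }
  donor_tot <- group_sum(donor_gid)
  acc_tot <- group_sum(acc_gid)

  psi_d <- ifelse(donor_tot >= min_group_reads, m / donor_tot, NA_real_)
  psi_a <- ifelse(acc_tot >= min_group_reads, m / acc_tot, NA_real_)
  psi <- ifelse(
    is.na(psi_d), psi_a,
    ifelse(is.na(psi_a), psi_d, pmin(psi_d, psi_a))
  )

  units <- colnames(m)
  tibble(
    junction_id = rep(table$junctions$junction_id, times = length(units)),
    unit = rep(units, each = nrow(m)),
    psi_donor = as.vector(psi_d),
    psi_acceptor = as.vector(psi_a),
    psi = as.vector(psi),
    group_total_donor = as.integer(donor_tot),
    group_total_acceptor = as.integer(acc_tot),
    donor_group = rep(donor_gid, times = length(units)),
    acceptor_group = rep(acc_gid, times = length(units))
  )
}

#' Detect tissue-enriched junctions absent from input samples
#'
#' Returns junctions whose summed IP count for `tissue` reaches
#' `min_ip_reads` while their summed count across all input samples is
#' exactly 0 ("absent from whole-animal data"). The threshold is inclusive
#' (at least `min_ip_reads` reads) unless `strict = TRUE` (more than
#' `min_ip_reads` reads).
#'
#' @param table a [jct_table] containing IP samples for `tissue` and at
#'   least one input sample.
#' @param tissue tissue whose IP samples are screened.
#' @param min_ip_reads read-support threshold (5 and 20 are the thresholds
#'   of interest).
#' @param strict if `TRUE`, require strictly more than `min_ip_reads`.
#' @param per_replicate if `TRUE`, require the threshold in every IP
#'   replicate instead of on the replicate sum.
#' @return tibble sorted by descending `ip_support` with columns
#'   `junction_id`, `tissue`, `ip_support`, `input_support`, `threshold`,
#'   `strict`.
#' @export
detect_tissue_enriched <- function(table, tissue, min_ip_reads = 5,
                                   strict = FALSE, per_replicate = FALSE) {
  stopifnot(inherits(table, "jct_table"))
  ip_idx <- which(table$samples$tissue == tissue & table$samples$fraction == "IP")
  input_idx <- which(table$samples$fraction == "input")
  if (length(ip_idx) == 0) abort(sprintf("no IP samples for tissue '%s'", tissue))
  if (length(input_idx) == 0) abort("no input samples in table")
  ip_counts <- table$counts[, ip_idx, drop = FALSE]
  ip_sum <- rowSums(ip_counts)
  input_sum <- rowSums(table$counts[, input_idx, drop = FALSE])
  pass <- if (per_replicate) {
    if (strict) apply(ip_counts > min_ip_reads, 1, all) else apply(ip_counts >= min_ip_reads, 1, all)
  } else {
    if (strict) ip_sum > min_ip_reads else ip_sum >= min_ip_reads
  }
  keep <- pass & input_sum == 0
  tibble(
    junction_id = table$junctions$junction_id[keep],
    tissue = tissue,
    ip_support = as.integer(ip_sum[keep]),
    input_support = as.integer(input_sum[keep]),
    threshold = min_ip_reads,
    strict = strict
  ) |>
    arrange(desc(.data$ip_support), .data$junction_id)
}

#' Call alternatively spliced splice-site groups
#'
#' A donor/acceptor group is alternative in a pooling unit when at least two
#' members have defined PSI there and the largest non-maximal (minor) member
#' PSI reaches `minor_psi_min`; it is alternative overall when alternative in
#' at least one unit.
#'
#' @param psi PSI tibble from [compute_psi()] (computed with
#'   `pool_by = "tissue"` for the tissue-level definition).
#' @param minor_psi_min minimum minor-variant PSI (default 0.05).
#' @return tibble of alternative groups: `group_id`, `side`, `n_units_alt`,
#'   `max_minor_psi`.
#' @export
call_alternative_junctions <- function(psi, minor_psi_min = 0.05) {
  if (nrow(psi) == 0) {
    return(tibble(
      group_id = character(), side = character(),
      n_units_alt = integer(), max_minor_psi = numeric()
    ))
  }
  long <- bind_rows(
    psi |>
      select(group_id = "donor_group", unit = "unit", psi_side = "psi_donor") |>
      mutate(side = "donor"),
    psi |>
      select(group_id = "acceptor_group", unit = "unit", psi_side = "psi_acceptor") |>
      mutate(side = "acceptor")
  ) |>
    filter(!is.na(.data$psi_side))
  per_unit <- long |>
    group_by(.data$group_id, .data$side, .data$unit) |>
    summarise(
      n_defined = n(),
      minor_psi = if (n() >= 2) max(.data$psi_side[-which.max(.data$psi_side)]) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(alt = .data$n_defined >= 2 & !is.na(.data$minor_psi) &
             .data$minor_psi >= minor_psi_min)
  per_unit |>
    group_by(.data$group_id, .data$side) |>
    summarise(
      n_units_alt = sum(.data$alt),
      max_minor_psi = suppressWarnings(max(.data$minor_psi, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    filter(.data$n_units_alt >= 1) |>
    arrange(.data$group_id)
}

#' Down-sample junction counts binomially
#'
#' Each count `c` is replaced by a Binomial(`c`, `fraction`) draw; with
#' `fraction = 1` the table is returned unchanged. Deterministic given
#' `seed`. Used for saturation analysis of junction discovery.
#'
#' @param table a [jct_table].
#' @param fraction retention probability in (0, 1].
#' @param seed integer seed.
#' @return a new [jct_table] with down-sampled counts.
#' @export
subsample_counts <- function(table, fraction, seed) {
  stopifnot(inherits(table, "jct_table"), fraction > 0, fraction <= 1)
  if (fraction == 1) return(table)
  counts <- table$counts
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  new_counts <- matrix(
    rbinom(length(counts), size = as.vector(counts), prob = fraction),
    nrow = nrow(counts), dimnames = dimnames(counts)
  )
  jct_table(table$junctions, table$samples, new_counts)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    rm(list = ".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Correlate two PSI vectors
#'
#' Pairs where either value is undefined are dropped; at least three
#' complete pairs are required. Zero variance in either vector yields an
#' `NA` estimate flagged as undefined rather than an error.
#'
#' @param a,b numeric PSI vectors, index-aligned on junctions/events.
#' @param method `"pearson"` or `"spearman"`.
#' @return one-row tibble: `estimate`, `n`, `method`, `undefined`.
#' @export
correlate_psi <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < 3) abort("fewer than 3 complete PSI pairs")
  zero_var <- stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0
  est <- if (zero_var) NA_real_ else cor(a[ok], b[ok], method = method)
  tibble(estimate = est, n = n, method = method, undefined = zero_var)
}
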