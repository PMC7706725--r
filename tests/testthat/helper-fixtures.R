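## Shared fixtures and independent oracles for the test suite.

## tiny junction table builder: junctions as "chrom:start-end:strand" keys,
## counts as a junctions x samples matrix
make_table <- function(keys, counts, tissues = NULL, fractions = NULL,
                       replicates = NULL) {
  parts <- regmatches(keys, regexec("^(.+):(\\d+)-(\\d+):([+-])$", keys))
  junctions <- tibble::tibble(
    chrom = vapply(parts, `[`, "", 2),
    start = as.integer(vapply(parts, `[`, "", 3)),
    end = as.integer(vapply(parts, `[`, "", 4)),
    strand = vapply(parts, `[`, "", 5)
  )
  counts <- matrix(as.integer(counts), nrow = length(keys))
  ns <- ncol(counts)
  samples <- tibble::tibble(
    sample_id = paste0("s", seq_len(ns)),
    tissue = tissues %||% paste0("t", seq_len(ns)),
    fraction = fractions %||% rep("IP", ns),
    replicate = replicates %||% rep(1L, ns)
  )
  jct_table(junctions, samples, counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## brute-force PSI oracle: re-derives donor/acceptor groups by scanning all
## junction pairs, then divides counts; independent of compute_psi internals
oracle_psi <- function(table, min_group_reads, pool_by = "sample") {
  j <- table$junctions
  m <- if (pool_by == "sample") {
    table$counts
  } else {
    unit <- ifelse(table$samples$fraction == "IP", table$samples$tissue,
                   paste(table$samples$tissue, table$samples$fraction, sep = ":"))
    sapply(sort(unique(unit)), function(u) {
      rowSums(table$counts[, unit == u, drop = FALSE])
    })
  }
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(j))
  donor <- ifelse(j$strand == "+", j$start, j$end - 1L)
  acc <- ifelse(j$strand == "+", j$end - 1L, j$start)
  out <- list()
  for (u in seq_len(ncol(m))) {
    for (i in seq_len(nrow(j))) {
      dmask <- j$chrom == j$chrom[i] & j$strand == j$strand[i] & donor == donor[i]
      amask <- j$chrom == j$chrom[i] & j$strand == j$strand[i] & acc == acc[i]
      dtot <- sum(m[dmask, u]); atot <- sum(m[amask, u])
      pd <- if (dtot >= min_group_reads) m[i, u] / dtot else NA_real_
      pa <- if (atot >= min_group_reads) m[i, u] / atot else NA_real_
      psi <- if (is.na(pd)) pa else if (is.na(pa)) pd else min(pd, pa)
      out[[length(out) + 1L]] <- tibble::tibble(
        junction_id = j$junction_id[i], unit = colnames(m)[u] %||% as.character(u),
        psi_donor = pd, psi_acceptor = pa, psi = psi,
        group_total_donor = dtot, group_total_acceptor = atot
      )
    }
  }
  dplyr::bind_rows(out)
}

## independent affine-gap global alignment DP (Gotoh), returning the optimal
## score; mirrors the documented scoring scheme of align_center_star
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = 2, gap_extend = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - gap_extend * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - gap_extend * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend, X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend, Y[i, j - 1] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## exact two-sided Fisher p by enumeration over all tables with fixed margins
oracle_fisher_p <- function(tab) {
  k <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1))
  }, numeric(1))
  p_obs <- probs[k - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## exact hypergeometric upper tail by enumeration
oracle_hyper_tail <- function(k, white, black, draws) {
  xs <- k:min(white, draws)
  sum(vapply(xs, function(x) {
    exp(lchoose(white, x) + lchoose(black, draws - x) - lchoose(white + black, draws))
  }, numeric(1)))
}

## small deterministic gene model: 3-exon plus-strand gene with a skipping
## junction observed (canonical cassette substrate)
cassette_models <- function(strand = "+") {
  tibble::tibble(
    gene_id = "g1",
    transcript_id = rep(c("g1.t1", "g1.t1", "g1.t1", "g1.t2", "g1.t2"), 1),
    type = "exon",
    chrom = "chrI",
    start = c(100L, 300L, 500L, 100L, 500L),
    end = c(200L, 400L, 600L, 200L, 600L),
    strand = strand,
    phase = NA_integer_
  )
}

## write text lines to a temp file, return path
tmpfile_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
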