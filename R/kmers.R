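## K-mer motif enrichment between target and background sequence sets.
##
## A transparent presence/absence (ZOOPS-like) scheme: for each k-mer the
## number of sequences containing at least one exact occurrence is compared
## between the two sets with an exact hypergeometric tail test, corrected
## per k over all observed k-mers of that length. No de novo motif
## optimization, degenerate positions or PWMs are built.

#' Extract event-region sequences for motif analysis
#'
#' Per cassette event: the internal exon sequence plus up to `flank_len`
#' intronic bases on each side, reverse-complemented for minus-strand events
#' so all sequences read 5'->3' in transcript orientation. Flanks are
#' truncated at short introns.
#'
#' @param triplets triplet tibble ([extract_triplets()]); rows supply the
#'   internal exon and flanking introns.
#' @param genome named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param flank_len intronic flank length (default 200).
#' @param label set label attached to the result.
#' @return tibble of class-labelled region sequences: `event_id`
#'   (triplet id), `exon_seq`, `upstream_seq`, `downstream_seq`; attribute
#'   `label` and `flank_len`.
#' @export
extract_event_regions <- function(triplets, genome, flank_len = 200,
                                  label = "regions") {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  slice_seq <- function(chrom, s, e, strand) {
    chromseq <- genome[[chrom]]
    if (is.null(chromseq) || s < 0 || e > nchar(chromseq)) {
      abort(sprintf("region %s:%d-%d outside genome bounds", chrom, s, e))
    }
    x <- substr(chromseq, s + 1L, e)
    if (strand == "-") reverse_complement(x) else x
  }
  out <- purrr::map_dfr(seq_len(nrow(triplets)), function(i) {
    tr <- triplets[i, ]
    up_len <- min(flank_len, tr$intron_up_end - tr$intron_up_start)
    dn_len <- min(flank_len, tr$intron_dn_end - tr$intron_dn_start)
    ## intronic bases adjacent to the internal exon, strand-aware
    if (tr$strand == "-") {
      up <- slice_seq(tr$chrom, tr$intron_up_start, tr$intron_up_start + up_len, "-")
      dn <- slice_seq(tr$chrom, tr$intron_dn_end - dn_len, tr$intron_dn_end, "-")
    } else {
      up <- slice_seq(tr$chrom, tr$intron_up_end - up_len, tr$intron_up_end, "+")
      dn <- slice_seq(tr$chrom, tr$intron_dn_start, tr$intron_dn_start + dn_len, "+")
    }
    tibble(
      event_id = tr$triplet_id,
      class_label = tr$class_label,
      exon_seq = slice_seq(tr$chrom, tr$exon_in_start, tr$exon_in_end, tr$strand),
      upstream_seq = up,
      downstream_seq = dn
    )
  })
  attr(out, "label") <- label
  attr(out, "flank_len") <- flank_len
  out
}

## unique k-mers present in one sequence (exact matches, A/C/G/T only)
sequence_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kk <- unique(substring(seq, 1:(n - k + 1L), k:n))
  kk[!grepl("[^ACGT]", kk)]
}

## per-sequence presence sets for one k over a set of region tibble rows
region_kmer_presence <- function(regions, k) {
  map(seq_len(nrow(regions)), function(i) {
    unique(c(
      sequence_kmers(regions$exon_seq[i], k),
      sequence_kmers(regions$upstream_seq[i], k),
      sequence_kmers(regions$downstream_seq[i], k)
    ))
  })
}

#' K-mer enrichment between target and background sets
#'
#' For each k-mer observed in either set, presence means a sequence contains
#' at least one exact occurrence in any of its regions. The p-value is the
#' hypergeometric upper-tail probability of drawing at least
#' `n_target_with` containing sequences when `n_target` sequences are drawn
#' from the pooled population; correction is applied per k over all
#' observed k-mers of that length.
#'
#' @param target,background region tibbles from [extract_event_regions()]
#'   (or any tibble with `exon_seq`, `upstream_seq`, `downstream_seq`).
#' @param k_range k-mer lengths (default 5:7).
#' @param correction `"bh"` or `"bonferroni"`.
#' @return tibble ranked by corrected p (then raw p, then k-mer):
#'   `kmer`, `k`, `n_target_with`, `n_target`, `n_background_with`,
#'   `n_background`, `target_pct`, `background_pct`, `p_value`,
#'   `corrected_p`.
#' @export
enrich_kmers <- function(target, background, k_range = 5:7,
                         correction = c("bh", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(nrow(target) > 0, nrow(background) > 0)
  out <- purrr::map_dfr(k_range, function(k) {
    pres_t <- region_kmer_presence(target, k)
    pres_b <- region_kmer_presence(background, k)
    all_kmers <- sort(unique(c(unlist(pres_t), unlist(pres_b))))
    if (length(all_kmers) == 0) return(tibble())
    nt <- length(pres_t); nb <- length(pres_b)
    cnt_t <- table(factor(unlist(map(pres_t, unique)), levels = all_kmers))
    cnt_b <- table(factor(unlist(map(pres_b, unique)), levels = all_kmers))
    kt <- as.integer(cnt_t); kb <- as.integer(cnt_b)
    ## upper tail: P(X >= kt), X ~ Hypergeometric(white = kt+kb, draws = nt)
    p <- phyper(kt - 1L, kt + kb, nt + nb - kt - kb, nt, lower.tail = FALSE)
    tibble(
      kmer = all_kmers, k = k,
      n_target_with = kt, n_target = nt,
      n_background_with = kb, n_background = nb,
      target_pct = 100 * kt / nt,
      background_pct = 100 * kb / nb,
      p_value = p,
      corrected_p = p.adjust(p, method = if (correction == "bh") "BH" else "bonferroni")
    )
  })
  arrange(out, .data$corrected_p, .data$p_value, .data$kmer)
}
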