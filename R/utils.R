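## Shared internal helpers.
##
## All genomic coordinates in this package are 0-based half-open [start, end)
## on an explicit strand; conversions to/from 1-based formats (GTF, STAR
## SJ.out.tab, wiggle) happen only at the I/O boundary.

#' Build the canonical junction identity key
#'
#' Junction identity is `(chrom, start, end, strand)`; the annotated flag is
#' advisory and never part of identity.
#'
#' @param chrom,start,end,strand vectors describing intron intervals
#'   (0-based half-open).
#' @return character vector of keys `"chrom:start-end:strand"`.
#' @export
junction_key <- function(chrom, start, end, strand) {
  paste0(chrom, ":", start, "-", end, ":", strand)
}

#' Donor and acceptor genomic positions of an intron
#'
#' The donor is the first intronic base in transcript orientation (the G of
#' the GT dinucleotide), the acceptor the last (the G of AG). On `+` the donor
#' is `start` and the acceptor `end - 1`; on `-` they are reversed.
#'
#' @inheritParams junction_key
#' @return list with integer vectors `donor` and `acceptor`.
#' @export
donor_acceptor <- function(chrom, start, end, strand) {
  plus <- strand != "-"
  list(
    donor    = ifelse(plus, start, end - 1L),
    acceptor = ifelse(plus, end - 1L, start)
  )
}

## centered rolling mean of width `k`, truncated at the edges so the window
## never extends past the profile (width 1 returns x unchanged)
rolling_mean <- function(x, k) {
  stopifnot(k >= 1)
  if (k == 1) return(x)
  n <- length(x)
  half <- (k - 1) %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

## strand-aware transcript-order rank of genomic starts
transcript_order <- function(start, strand) {
  if (identical(strand, "-")) order(-start) else order(start)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## deterministic integer seed derived from a base seed and a stage label
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage)) %% 10000L
  (as.integer(seed) %% 2000000L) * 1000L + offs
}

## write a tibble as a deterministic TSV (fixed column order, no quoting)
write_tsv_deterministic <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

`%theni%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

## merge per-species pairwise alignments onto a common reference frame.
## per_species: named list of list(at_ref = chr vector of length n (the
## species character aligned to each reference base, '-' for deletion),
## ins = list of n+1 character vectors (species bases inserted after k
## reference bases, k = 0..n)). Returns named gapped rows incl. the
## reference.
star_merge_rows <- function(ref_chars, per_species, reference) {
  n <- length(ref_chars)
  ins_len <- vapply(seq_len(n + 1L), function(k) {
    max(c(0L, vapply(per_species, function(x) length(x$ins[[k]]), integer(1))))
  }, integer(1))
  build_row <- function(at_ref, ins) {
    parts <- character(0)
    for (k in 0:n) {
      if (ins_len[k + 1L] > 0) {
        block <- ins[[k + 1L]]
        parts <- c(parts, block, rep("-", ins_len[k + 1L] - length(block)))
      }
      if (k < n) parts <- c(parts, at_ref[k + 1L])
    }
    paste(parts, collapse = "")
  }
  empty_ins <- rep(list(character(0)), n + 1L)
  rows <- c(
    setNames(list(build_row(ref_chars, empty_ins)), reference),
    lapply(per_species, function(x) build_row(x$at_ref, x$ins))
  )
  vapply(rows, identity, character(1))
}
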