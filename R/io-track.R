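## Per-base conservation score tracks (phyloP-style), stored sparsely so
## "missing" is distinguishable from score 0.

#' Construct a conservation track from per-base scores
#'
#' @param scores tibble with columns `chrom`, `pos` (0-based base position)
#'   and `score`. Duplicate positions resolve to the last record (a warning
#'   is emitted), matching the file-reading behaviour.
#' @return object of class `conservation_track`.
#' @export
conservation_track <- function(scores) {
  scores <- as_tibble(scores)
  stopifnot(all(c("chrom", "pos", "score") %in% names(scores)))
  if (anyDuplicated(scores[c("chrom", "pos")])) {
    warn("overlapping track records: last record wins")
    scores <- scores[!duplicated(scores[c("chrom", "pos")], fromLast = TRUE), ]
  }
  by_chrom <- split(scores[c("pos", "score")], scores$chrom)
  by_chrom <- map(by_chrom, function(d) {
    o <- order(d$pos)
    list(pos = as.integer(d$pos[o]), score = as.numeric(d$score[o]))
  })
  structure(list(by_chrom = by_chrom), class = "conservation_track")
}

#' @export
print.conservation_track <- function(x, ...) {
  n <- sum(map_int(x$by_chrom, ~ length(.x$pos)))
  cat(
    "<conservation_track> ", n, " scored bases on ",
    length(x$by_chrom), " chromosome(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Look up per-base scores
#'
#' @param track a [conservation_track].
#' @param chrom chromosome name (scalar).
#' @param positions 0-based base positions.
#' @return numeric vector of scores, `NA` where the track has no record
#'   (missing is distinguishable from score 0).
#' @export
track_scores <- function(track, chrom, positions) {
  ch <- track$by_chrom[[chrom]]
  if (is.null(ch)) return(rep(NA_real_, length(positions)))
  ch$score[match(as.integer(positions), ch$pos)]
}

#' Read a conservation track (bedGraph or fixed-step wiggle)
#'
#' bedGraph records are `chrom start end score` with 0-based half-open
#' intervals; wiggle `fixedStep` declarations use 1-based starts, converted
#' on input. Every covered base maps to its score; for overlapping records
#' the last one wins (with a warning).
#'
#' @param path bedGraph or wiggle file.
#' @return a [conservation_track].
#' @export
read_conservation_track <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  is_wig <- any(grepl("^fixedStep", lines))
  if (is_wig) {
    scores <- parse_fixedstep_wiggle(lines)
  } else {
    parts <- strsplit(lines, "[ \t]+")
    if (any(lengths(parts) != 4L)) abort("malformed bedGraph line")
    val <- suppressWarnings(as.numeric(map_chr(parts, 4)))
    if (anyNA(val)) abort("non-numeric score in bedGraph")
    start <- as.integer(map_chr(parts, 2))
    end <- as.integer(map_chr(parts, 3))
    widths <- end - start
    scores <- tibble(
      chrom = rep(map_chr(parts, 1), widths),
      pos = unlist(map2(start, end, ~ seq.int(.x, .y - 1L))),
      score = rep(val, widths)
    )
  }
  conservation_track(scores)
}

parse_fixedstep_wiggle <- function(lines) {
  decl_idx <- grep("^fixedStep", lines)
  stopifnot(length(decl_idx) > 0)
  out <- list()
  bounds <- c(decl_idx, length(lines) + 1L)
  for (i in seq_along(decl_idx)) {
    decl <- lines[decl_idx[i]]
    get_field <- function(name, default = NULL) {
      m <- regmatches(decl, regexpr(paste0(name, "=[^ \t]+"), decl))
      if (length(m) == 0) return(default)
      sub(paste0(name, "="), "", m)
    }
    chrom <- get_field("chrom")
    start1 <- as.integer(get_field("start"))
    step <- as.integer(get_field("step", "1"))
    span <- as.integer(get_field("span", "1"))
    vals_chr <- lines[seq.int(decl_idx[i] + 1L, bounds[i + 1L] - 1L)]
    vals_chr <- vals_chr[!grepl("^fixedStep", vals_chr)]
    vals <- suppressWarnings(as.numeric(vals_chr))
    if (anyNA(vals)) abort("non-numeric score in wiggle")
    # wiggle is 1-based; convert to 0-based
    starts0 <- (start1 - 1L) + step * (seq_along(vals) - 1L)
    out[[i]] <- tibble(
      chrom = chrom,
      pos = unlist(map(starts0, ~ seq.int(.x, .x + span - 1L))),
      score = rep(vals, each = span)
    )
  }
  bind_rows(out)
}

#' Write a conservation track as bedGraph
#'
#' Adjacent equal-score bases are not merged; one record per base keeps the
#' output trivially round-trippable.
#'
#' @param track a [conservation_track].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$by_chrom)) {
    ch <- track$by_chrom[[chrom]]
    writeLines(
      sprintf("%s\t%d\t%d\t%s", chrom, ch$pos, ch$pos + 1L, format(ch$score, digits = 10, trim = TRUE, scientific = FALSE)),
      con
    )
  }
  invisible(path)
}
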