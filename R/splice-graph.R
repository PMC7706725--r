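## Per-gene splice graphs and local splicing variation (LSV) enumeration.
##
## Nodes are exonic segments (union of transcript exons split at every
## splice-site boundary); edges are junctions (observed or annotated) and
## intron-retention edges. An event is the set of >= 2 edges leaving one
## node's 3' side (source LSV) or entering one node's 5' side (target LSV).

#' Build the splice graph of a gene
#'
#' @param models gene model tibble ([read_gene_models()] output).
#' @param gene gene identifier.
#' @param junctions optional tibble of observed junctions (`chrom`, `start`,
#'   `end`, `strand`); annotated transcript junctions are always added.
#' @param retention optional tibble of introns with intronic read support
#'   (`chrom`, `start`, `end`, `strand`); each becomes a retention edge.
#' @return object of class `splice_graph` with `nodes`, `edges` and
#'   `orphans` tibbles. Junction edge ids are junction keys; retention edge
#'   ids carry a `retention:` prefix.
#' @export
build_splice_graph <- function(models, gene, junctions = NULL, retention = NULL) {
  gm <- filter(models, .data$gene_id == gene)
  if (nrow(gm) == 0) abort(sprintf("gene '%s' not in models", gene))
  exons <- filter(gm, .data$type == "exon")
  chrom <- exons$chrom[1]
  strand <- exons$strand[1]

  ann <- annotated_junctions(gm)
  obs <- junctions
  if (!is.null(obs) && nrow(obs) > 0) {
    span <- c(min(exons$start), max(exons$end))
    obs <- filter(
      as_tibble(obs),
      .data$chrom == !!chrom,
      .data$start >= span[1], .data$end <= span[2]
    )
  }
  all_j <- bind_rows(
    tibble(start = ann$start, end = ann$end, annotated = TRUE),
    if (!is.null(obs) && nrow(obs) > 0) {
      tibble(start = obs$start, end = obs$end, annotated = FALSE)
    }
  ) |>
    group_by(.data$start, .data$end) |>
    summarise(annotated = any(.data$annotated), .groups = "drop") |>
    arrange(.data$start, .data$end)

  ret <- if (!is.null(retention) && nrow(retention) > 0) {
    filter(as_tibble(retention), .data$chrom == !!chrom) |>
      distinct(.data$start, .data$end)
  }

  ## exonic coverage: union of exons, merging touching intervals
  ex <- exons |> distinct(.data$start, .data$end) |> arrange(.data$start, .data$end)
  seg_start <- integer(0); seg_end <- integer(0)
  for (i in seq_len(nrow(ex))) {
    if (length(seg_end) > 0 && ex$start[i] <= seg_end[length(seg_end)]) {
      seg_end[length(seg_end)] <- max(seg_end[length(seg_end)], ex$end[i])
    } else {
      seg_start <- c(seg_start, ex$start[i]); seg_end <- c(seg_end, ex$end[i])
    }
  }

  ## split covered segments at every splice-site boundary
  cut_sites <- sort(unique(c(ex$start, ex$end, all_j$start, all_j$end)))
  nodes <- purrr::map_dfr(seq_along(seg_start), function(i) {
    cuts <- cut_sites[cuts_inside(cut_sites, seg_start[i], seg_end[i])]
    bounds <- sort(unique(c(seg_start[i], cuts, seg_end[i])))
    tibble(start = head(bounds, -1), end = bounds[-1])
  }) |>
    arrange(.data$start) |>
    mutate(node_id = paste0("n", sprintf("%03d", row_number())))

  ## transcript-end flags (strand-aware 5' and 3' transcript exons)
  nodes$first_exon <- FALSE
  nodes$last_exon <- FALSE
  for (txid in unique(exons$transcript_id)) {
    tex <- exons[exons$transcript_id == txid, , drop = FALSE]
    five <- if (strand == "-") tex[which.max(tex$start), ] else tex[which.min(tex$start), ]
    three <- if (strand == "-") tex[which.min(tex$start), ] else tex[which.max(tex$start), ]
    nodes$first_exon <- nodes$first_exon |
      (nodes$start < five$end & nodes$end > five$start)
    nodes$last_exon <- nodes$last_exon |
      (nodes$start < three$end & nodes$end > three$start)
  }

  make_edges <- function(ivs, type, annotated) {
    if (is.null(ivs) || nrow(ivs) == 0) {
      return(list(edges = empty_edges(), orphans = empty_edges()))
    }
    left <- match(ivs$start, nodes$end)
    right <- match(ivs$end, nodes$start)
    ok <- !is.na(left) & !is.na(right)
    key <- junction_key(chrom, ivs$start, ivs$end, strand)
    prefix <- if (type == "retention") "retention:" else ""
    edges <- tibble(
      edge_id = paste0(prefix, key),
      type = type,
      chrom = chrom, start = ivs$start, end = ivs$end, strand = strand,
      left_node = nodes$node_id[left],
      right_node = nodes$node_id[right],
      annotated = annotated
    )
    edges$donor_node <- if (strand == "-") edges$right_node else edges$left_node
    edges$acceptor_node <- if (strand == "-") edges$left_node else edges$right_node
    list(edges = edges[ok, , drop = FALSE], orphans = edges[!ok, , drop = FALSE])
  }
  je <- make_edges(all_j, "junction", all_j$annotated)
  re <- make_edges(ret, "retention", FALSE)

  structure(
    list(
      gene_id = gene, chrom = chrom, strand = strand,
      nodes = select(
        nodes, "node_id", "start", "end", "first_exon", "last_exon"
      ),
      edges = bind_rows(je$edges, re$edges),
      orphans = bind_rows(je$orphans, re$orphans)
    ),
    class = "splice_graph"
  )
}

cuts_inside <- function(cuts, s, e) cuts > s & cuts < e

empty_edges <- function() {
  tibble(
    edge_id = character(), type = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    left_node = character(), right_node = character(),
    annotated = logical(), donor_node = character(), acceptor_node = character()
  )
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(
    "<splice_graph> ", x$gene_id, " (", x$strand, "): ",
    nrow(x$nodes), " nodes, ", nrow(x$edges), " edges (",
    sum(x$edges$type == "retention"), " retention), ",
    nrow(x$orphans), " orphan junction(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Enumerate local splicing variations of a splice graph
#'
#' For every node, the edges leaving its 3' side (source LSV) and entering
#' its 5' side (target LSV) with at least two members form an event; events
#' covering identical edge sets are emitted once (source kept).
#'
#' @param graph a [build_splice_graph()] result.
#' @return tibble with one row per event: `event_id`, `gene_id`,
#'   `anchor_node`, `anchor_side` (`"source"`/`"target"`), `edge_ids`
#'   (list-column), `n_edges`, `n_junctions`.
#' @export
enumerate_events <- function(graph) {
  ev <- list()
  for (side in c("source", "target")) {
    anchor_col <- if (side == "source") "donor_node" else "acceptor_node"
    grp <- split(seq_len(nrow(graph$edges)), graph$edges[[anchor_col]])
    for (anchor in sort(names(grp))) {
      idx <- grp[[anchor]]
      if (length(idx) < 2) next
      ids <- sort(graph$edges$edge_id[idx])
      ev[[length(ev) + 1L]] <- tibble(
        gene_id = graph$gene_id,
        anchor_node = anchor,
        anchor_side = side,
        edge_ids = list(ids),
        n_edges = length(ids),
        n_junctions = sum(graph$edges$type[idx] == "junction")
      )
    }
  }
  if (length(ev) == 0) {
    return(tibble(
      event_id = character(), gene_id = character(), anchor_node = character(),
      anchor_side = character(), edge_ids = list(), n_edges = integer(),
      n_junctions = integer()
    ))
  }
  out <- bind_rows(ev)
  key <- map_chr(out$edge_ids, paste, collapse = "|")
  out <- out[!duplicated(key), , drop = FALSE]
  out |>
    mutate(event_id = paste0(
      .data$gene_id, ":", substr(.data$anchor_side, 1, 1), ":", .data$anchor_node
    )) |>
    select(
      "event_id", "gene_id", "anchor_node", "anchor_side",
      "edge_ids", "n_edges", "n_junctions"
    )
}

## transcript-order position of nodes (smaller = more 5')
node_tpos <- function(graph) {
  p <- rank(graph$nodes$start)
  if (graph$strand == "-") p <- -p
  setNames(p, graph$nodes$node_id)
}

has_junction_edge <- function(graph, donor, acceptor) {
  any(
    graph$edges$type == "junction" &
      graph$edges$donor_node == donor &
      graph$edges$acceptor_node == acceptor
  )
}

classify_one_event <- function(edges, anchor_side, graph, tpos, internal) {
  je <- edges[edges$type == "junction", , drop = FALSE]
  re <- edges[edges$type == "retention", , drop = FALSE]
  n <- nrow(edges)
  matched <- character(0)

  distal_col <- if (anchor_side == "source") "acceptor_node" else "donor_node"

  if (n == 2 && nrow(je) == 2) {
    d <- je[[distal_col]]
    if (d[1] != d[2]) {
      ## order the distal pair: "near" is the one closer to the anchor in
      ## transcript orientation
      o <- order(tpos[d])
      if (anchor_side == "source") {
        near <- d[o[1]]; far <- d[o[2]]
        connecting <- has_junction_edge(graph, near, far)
      } else {
        near <- d[o[2]]; far <- d[o[1]]
        connecting <- has_junction_edge(graph, far, near)
      }
      ## (i) cassette: skip vs include with the inclusion path present
      if (internal[near] && connecting) matched <- c(matched, "cassette")
      ## (ii) alternative 5'/3' splice site: distal segments are contiguous
      ## extensions of one exon
      nd <- graph$nodes[match(d, graph$nodes$node_id), ]
      if (nd$end[1] == nd$start[2] || nd$end[2] == nd$start[1]) {
        matched <- c(matched, if (anchor_side == "source") "alt3ss" else "alt5ss")
      }
      ## (iii) mutually exclusive: both distal internal, joined to a common
      ## far node, with no junction between them
      if (internal[d[1]] && internal[d[2]] && !connecting) {
        common <- if (anchor_side == "source") {
          cands1 <- graph$edges$acceptor_node[graph$edges$type == "junction" & graph$edges$donor_node == d[1]]
          cands2 <- graph$edges$acceptor_node[graph$edges$type == "junction" & graph$edges$donor_node == d[2]]
          intersect(cands1, cands2)
        } else {
          cands1 <- graph$edges$donor_node[graph$edges$type == "junction" & graph$edges$acceptor_node == d[1]]
          cands2 <- graph$edges$donor_node[graph$edges$type == "junction" & graph$edges$acceptor_node == d[2]]
          intersect(cands1, cands2)
        }
        if (length(common) > 0) matched <- c(matched, "mutually_exclusive")
      }
      ## (iv) alternative start/terminal exons
      flag <- if (anchor_side == "source") "last_exon" else "first_exon"
      fl <- graph$nodes[[flag]][match(d, graph$nodes$node_id)]
      if (all(fl)) matched <- c(matched, "alt_start_terminal")
    }
  }
  ## (v) intron retention: a retention edge competing with a junction over
  ## the same intron
  if (n == 2 && nrow(je) == 1 && nrow(re) == 1 &&
      je$start == re$start && je$end == re$end) {
    matched <- c(matched, "intron_retention")
  }

  if (length(matched) == 1) matched else "complex"
}

#' Classify enumerated events into splicing classes
#'
#' Pattern templates are tested in fixed order: cassette, alternative 3'/5'
#' splice site, mutually exclusive, alternative start/terminal exon, intron
#' retention. An event matching exactly one template receives that class;
#' events matching several templates (more than one mode of splicing), or
#' matching none, are labelled `complex`.
#'
#' @param events events tibble from [enumerate_events()].
#' @param graph the corresponding [build_splice_graph()] result.
#' @return `events` with an `event_class` column.
#' @export
classify_events <- function(events, graph) {
  if (nrow(events) == 0) {
    events$event_class <- character(0)
    return(events)
  }
  tpos <- node_tpos(graph)
  internal <- setNames(
    !graph$nodes$first_exon & !graph$nodes$last_exon,
    graph$nodes$node_id
  )
  events$event_class <- map_chr(seq_len(nrow(events)), function(i) {
    edges <- graph$edges[match(events$edge_ids[[i]], graph$edges$edge_id), , drop = FALSE]
    if (nrow(edges) < 2) abort("event with fewer than 2 edges")
    classify_one_event(edges, events$anchor_side[i], graph, tpos, internal)
  })
  events
}

#' Build, enumerate and classify events for many genes
#'
#' Convenience wrapper running [build_splice_graph()], [enumerate_events()]
#' and [classify_events()] over every gene in `models`.
#'
#' @inheritParams build_splice_graph
#' @return list with `events` (classified event tibble over all genes),
#'   `graphs` (named list of splice graphs) and `n_orphans`.
#' @export
find_splicing_events <- function(models, junctions = NULL, retention = NULL) {
  genes <- sort(unique(models$gene_id))
  graphs <- list()
  evs <- list()
  n_orphans <- 0L
  for (g in genes) {
    gr <- build_splice_graph(models, g, junctions = junctions, retention = retention)
    n_orphans <- n_orphans + nrow(gr$orphans)
    graphs[[g]] <- gr
    evs[[g]] <- classify_events(enumerate_events(gr), gr)
  }
  list(events = bind_rows(evs), graphs = graphs, n_orphans = n_orphans)
}
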