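## ggplot2 visualizations for the main result types.

#' Plot windowed conservation profiles
#'
#' Smoothed mean score per intron position, one line per triplet class,
#' faceted by flank region.
#'
#' @param object a `window_profiles` object from [window_profile()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.window_profiles <- function(object, ...) {
  ggplot2::ggplot(
    object$profiles,
    ggplot2::aes(
      x = .data$position, y = .data$smoothed, colour = .data$class_label
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~region, nrow = 1) +
    ggplot2::labs(
      x = "intron position from splice site (nt)",
      y = "mean conservation score (rolling mean)",
      colour = "class"
    ) +
    ggplot2::theme_minimal()
}

#' Plot event class proportions
#'
#' Stacked proportions of splicing event classes, optionally per group
#' (e.g. per tissue or per call set).
#'
#' @param events tibble with an `event_class` column.
#' @param group optional column name used for the x axis.
#' @return a ggplot object.
#' @export
plot_class_proportions <- function(events, group = NULL) {
  if (is.null(group)) {
    events$.group <- "all"
  } else {
    events$.group <- events[[group]]
  }
  ggplot2::ggplot(
    events, ggplot2::aes(x = .data$.group, fill = .data$event_class)
  ) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::labs(x = NULL, y = "proportion of events", fill = "class") +
    ggplot2::theme_minimal()
}

#' Heatmap of event PSI across tissues
#'
#' One tile per event reference junction and tissue, coloured by PSI;
#' undefined PSI is left blank (no reads / below the coverage floor).
#'
#' @param event_psi tibble from [quantify_events()].
#' @return a ggplot object.
#' @export
plot_psi_heatmap <- function(event_psi) {
  ref <- event_psi |>
    group_by(.data$event_id, .data$edge_id) |>
    summarise(total = sum(.data$count), .groups = "drop_last") |>
    arrange(desc(.data$total), .data$edge_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  dat <- inner_join(
    event_psi, select(ref, "event_id", "edge_id"),
    by = c("event_id", "edge_id")
  )
  ggplot2::ggplot(
    dat, ggplot2::aes(x = .data$tissue, y = .data$event_id, fill = .data$psi)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "PSI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot k-mer enrichment results
#'
#' Target versus background presence percentages for the top k-mers,
#' coloured by corrected p-value.
#'
#' @param kmers tibble from [enrich_kmers()].
#' @param top number of top-ranked k-mers shown.
#' @return a ggplot object.
#' @export
plot_kmer_enrichment <- function(kmers, top = 20) {
  dat <- head(kmers, top)
  dat$kmer <- factor(dat$kmer, levels = rev(dat$kmer))
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = .data$background_pct, y = .data$target_pct,
      colour = -log10(.data$corrected_p)
    )
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "% of background sequences", y = "% of target sequences",
      colour = "-log10 corrected p"
    ) +
    ggplot2::theme_minimal()
}
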