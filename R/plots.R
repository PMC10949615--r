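# ggplot2 views of the result objects.

#' Plot a species profile
#'
#' Abundance vs genome coverage on log10 scales, selected species
#' highlighted; threshold lines are drawn when the profile has been through
#' [select_confident_species()].
#'
#' @param object A `condiga_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.condiga_profile <- function(object, ...) {
  th <- attr(object, "thresholds")
  p <- ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$abundance_pct, y = .data$coverage_pct,
                 colour = .data$selected)
  ) +
    ggplot2::geom_point(size = 2, alpha = 0.8, na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "relative sequence abundance (%)",
      y = "genome coverage (%)",
      colour = "selected"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(th)) {
    p <- p +
      ggplot2::geom_vline(xintercept = th[["abundance_min_pct"]],
                          linetype = "dashed") +
      ggplot2::geom_hline(yintercept = th[["coverage_min_pct"]],
                          linetype = "dashed")
  }
  p
}

#' Plot per-species gene counts of an annotation
#'
#' @param object A `condiga_annotation`.
#' @param top Show at most this many species (default 25).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.condiga_annotation <- function(object, top = 25, ...) {
  df <- utils::head(tidy(object), top)
  df$species <- factor(df$species_taxid, levels = rev(df$species_taxid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_genes, y = .data$species)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "genes assigned", y = "species taxid",
                  title = sprintf("%s annotation", object$method[1])) +
    ggplot2::theme_minimal()
}

#' Plot per-taxon MG/MP log2 ratios across ranks
#'
#' One panel per rank; bars show log2(MG/MP), so positive bars mean the
#' taxon is relatively more abundant in the metagenome than the
#' metaproteome. Taxa quantified on only one side are omitted.
#'
#' @param object A `condiga_ratio` from [rank_rollup_ratio()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.condiga_ratio <- function(object, ...) {
  df <- as_tibble(object) %>%
    dplyr::filter(!is.na(.data$log2_ratio)) %>%
    dplyr::mutate(
      rank = factor(.data$rank, levels = condiga_ranks),
      label = dplyr::coalesce(.data$taxon_name, as.character(.data$taxon_id))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_ratio, y = .data$label,
                                   fill = .data$log2_ratio > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::facet_wrap(ggplot2::vars(.data$rank), scales = "free_y") +
    ggplot2::labs(x = "log2(MG / MP)", y = NULL) +
    ggplot2::theme_minimal()
}
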