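#' Plot a conservation profile
#'
#' Per-column conservation as a line, with gap-flagged columns marked
#' along the axis.
#'
#' @param object A `conservation_profile` from
#'   [msa_conservation_profile()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.conservation_profile <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df[!df$gap_flag, ],
                       ggplot2::aes(x = .data$column,
                                    y = .data$conservation)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Alignment column", y = "Conservation",
                  title = attr(object, "family_id"))
  if (any(df$gap_flag)) {
    p <- p + ggplot2::geom_rug(data = df[df$gap_flag, ],
                               ggplot2::aes(x = .data$column),
                               inherit.aes = FALSE, colour = "firebrick")
  }
  p
}

#' Plot specificity labels along the alignment
#'
#' @param object A `position_labels` tibble from [compare_families()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.position_labels <- function(object, ...) {
  df <- as_tibble(object)
  fams <- attr(object, "families") %||% c("A", "B")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column_a, y = 1,
                                   fill = .data$label)) +
    ggplot2::geom_tile(height = 1) +
    ggplot2::scale_fill_brewer(palette = "Set2", drop = FALSE) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank()) +
    ggplot2::labs(x = "Alignment column", y = NULL, fill = "Label",
                  title = paste(fams[1], "vs", fams[2]))
}

#' Plot a contact network as an adjacency heat map
#'
#' Edge values (contact score, delta RRCS, occurrence count or
#' delta-delta RRCS) are shown on the upper-triangular residue-pair grid.
#'
#' @param object A [contact_network()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.contact_network <- function(object, ...) {
  df <- as_tibble(unclass_network(object))
  value_col <- intersect(c("score", "delta", "delta_delta", "count"),
                         names(df))[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$target,
                                   fill = .data[[value_col]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, fill = value_col,
                  title = paste0("Contact network (", network_kind(object),
                                 ")"))
}

#' Plot the activation-metric distribution of classified frames
#'
#' Histogram of GPCRdb activation distances with the active (7.15 A) and
#' inactive (2 A) classification cutoffs marked.
#'
#' @param object A `state_calls` tibble from [classify_states()].
#' @param binwidth Histogram bin width in Angstrom.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.state_calls <- function(object, binwidth = 0.5, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gpcrdb_distance,
                                   fill = .data$call)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(2, 7.15), linetype = "dashed") +
    ggplot2::labs(x = "GPCRdb activation distance (Å)", y = "Frames",
                  fill = "State")
}
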