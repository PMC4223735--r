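# ggplot2 views of the main result types.

#' Gene-map view of a circular gene order
#' @param object A `mito_order`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mito_order
#' @export
autoplot.mito_order <- function(object, ...) {
  p <- parse_gene_label(object$label)
  df <- tibble(
    label = object$label,
    pos = seq_len(nrow(object)),
    ymin = ifelse(object$strand == "+", 0, -1),
    ymax = ifelse(object$strand == "+", 1, 0),
    kind = p$kind,
    pseudo = p$pseudo
  )
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$pos - 0.45, xmax = .data$pos + 0.45,
      ymin = .data$ymin, ymax = .data$ymax, fill = .data$kind,
      alpha = ifelse(.data$pseudo, 0.45, 1)
    ), colour = "grey25", linewidth = 0.2) +
    ggplot2::geom_text(ggplot2::aes(
      x = .data$pos, y = ifelse(.data$ymin == 0, 1.15, -1.15),
      label = .data$label
    ), angle = 90, hjust = ifelse(df$ymin == 0, 0, 1), size = 2.6) +
    ggplot2::scale_alpha_identity() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Circular gene order (linearised)",
                  subtitle = "heavy strand above, light strand below") +
    ggplot2::ylim(-2.6, 2.6) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Linear arm-annotated view of a clover-leaf parse
#' @param object A `mito_cloverleaf`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mito_cloverleaf
#' @export
autoplot.mito_cloverleaf <- function(object, ...) {
  df <- tidy(object) |>
    filter(!is.na(.data$start)) |>
    tidyr::uncount(weights = .data$end - .data$start + 1L, .id = "off") |>
    mutate(pos = .data$start + .data$off - 1L,
           base = strsplit(object$seq, "")[[1]][.data$pos])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = 1,
                                   fill = .data$element)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$base), size = 2.8) +
    ggplot2::labs(x = "position (5' to 3')", y = NULL,
                  title = paste0("Clover-leaf parse, anticodon ",
                                 object$anticodon)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank(),
                   legend.position = "bottom")
}

#' Plot observed vs expected codon usage for the deviation tests
#'
#' @param table Output of [usage_table()].
#' @param panel Panel means used for the expectations.
#' @return A ggplot object.
#' @export
plot_usage_deviation <- function(table, panel = gecko_codon_panel()$panel) {
  long <- table |>
    select("species", "caa", "cag", "gaa", "gag") |>
    tidyr::pivot_longer(-"species", names_to = "codon",
                        values_to = "count") |>
    mutate(codon = toupper(.data$codon))
  exp_tb <- table |>
    mutate(
      CAA = (.data$caa + .data$cag) * panel$caa / (panel$caa + panel$cag),
      CAG = (.data$caa + .data$cag) * panel$cag / (panel$caa + panel$cag),
      GAA = (.data$gaa + .data$gag) * panel$gaa / (panel$gaa + panel$gag),
      GAG = (.data$gaa + .data$gag) * panel$gag / (panel$gaa + panel$gag)
    ) |>
    select("species", "CAA", "CAG", "GAA", "GAG") |>
    tidyr::pivot_longer(-"species", names_to = "codon",
                        values_to = "expected")
  df <- left_join(long, exp_tb, by = c("species", "codon"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected), shape = 95,
                        size = 8, colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$species)) +
    ggplot2::labs(y = "codon count",
                  title = "Observed counts vs panel expectation",
                  subtitle = "bars observed; dashes expected under the panel proportion") +
    ggplot2::theme_minimal()
}
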