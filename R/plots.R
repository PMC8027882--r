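#' Plot active guild richness by land use
#'
#' Boxplots of per-sample active richness for one guild, faceted by
#' substrate, mirroring the standard way SIP activity comparisons across
#' land uses are displayed.
#'
#' @param summary A `sip_active_summary` from [active_summary()].
#' @param meta Sample metadata.
#' @param guild Guild to display.
#' @return A ggplot object.
#' @export
plot_active_richness <- function(summary, meta, guild = "methanogen") {
  d <- summary |>
    dplyr::filter(.data$guild == !!guild) |>
    dplyr::left_join(meta[, c("sample_id", "land_use", "substrate")], by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$land_use, y = .data$richness,
                                  fill = .data$land_use)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$substrate)) +
    ggplot2::labs(x = "Land use", y = paste("Active", guild, "richness")) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_bw()
}

#' Stacked methanotroph type composition per sample
#'
#' @param fractions Output of [methanotroph_type_fractions()].
#' @return A ggplot object.
#' @export
plot_methanotroph_types <- function(fractions) {
  d <- dplyr::filter(fractions, .data$defined)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                                  fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Fraction of methanotroph signal",
                  fill = "Type") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1, size = 6))
}

#' @export
autoplot.sip_permdisp <- function(object, ...) {
  n <- nrow(object$coords)
  d <- tibble::tibble(sample_id = object$distances$sample_id,
                      group = object$distances$group,
                      PCo1 = object$coords[, 1],
                      PCo2 = if (ncol(object$coords) >= 2) object$coords[, 2] else 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PCo1, y = .data$PCo2,
                                  colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::stat_ellipse(level = 0.68, linetype = 2, na.rm = TRUE) +
    ggplot2::labs(colour = "Group") +
    ggplot2::theme_bw()
}

#' @export
autoplot.sip_permanova <- function(object, ...) {
  d <- dplyr::filter(object$table, !.data$term %in% "Total")
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$R2, y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(R^2), y = NULL) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
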