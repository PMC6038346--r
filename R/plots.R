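#' Plot a normalised depth profile with copy-number thresholds
#'
#' Shows the per-target log2 ratio of a sample against its pooled
#' background, with the deletion/duplication decision boundaries and the
#' expected levels for one and three copies.
#'
#' @param ratios A [normalize_depth()] result.
#' @param targets Target metadata (`target_id`, `gene`) for gene colouring;
#'   optional.
#' @param params A [cnv_params()] object supplying the threshold lines.
#' @return A ggplot object.
#' @export
plot_log2_profile <- function(ratios, targets = NULL, params = cnv_params()) {
  tbl <- as_tibble(ratios) %>%
    mutate(index = dplyr::row_number())
  if (!is.null(targets)) {
    tbl <- left_join(tbl, as_tibble(targets), by = "target_id")
  } else {
    tbl$gene <- "targets"
  }
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$index, y = .data$log2_ratio,
                                    colour = .data$gene)) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = c(params$het_del_log2_max,
                                       params$dup_log2_min),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(-1, log2(3 / 2)), linetype = "dotted",
                        colour = "grey50") +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "target index", y = "log2 depth ratio") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pv_depth_ratio <- function(object, ...) {
  plot_log2_profile(object, ...)
}

#' Plot per-gene callability at the depth thresholds
#'
#' @param callability A [compute_callability()] result.
#' @return A ggplot object.
#' @export
plot_callability <- function(callability) {
  ggplot2::ggplot(as_tibble(callability),
                  ggplot2::aes(x = .data$gene, y = .data$callability,
                               fill = factor(.data$threshold))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample)) +
    ggplot2::labs(x = NULL, y = "fraction of target bases",
                  fill = "min depth") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
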