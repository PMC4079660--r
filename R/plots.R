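# ggplot2 displays for the main result types.

#' @export
autoplot.erv_catalog <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "structural category", y = "loci",
                  title = "ERV locus catalog by structural category") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.erv_density <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object),
    c("n_full_length", "n_solo_ltr", "n_truncated", "n_unknown"),
    names_to = "category", values_to = "n"
  )
  df$category <- sub("^n_", "", df$category)
  df$per_mbp <- df$n / (df$length_bp / 1e6)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, y = .data$per_mbp,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "insertions / Mbp",
                  title = "Chromosomal density of lineage-specific ERV copies") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.erv_age <- function(object, ...) {
  df <- tidy(object)
  df$idx <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$age_young_myr,
                                         ymax = .data$age_old_myr),
                            color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$age_young_myr),
                        color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$age_old_myr),
                        color = "firebrick") +
    ggplot2::labs(x = "element", y = "age (myr)",
                  title = "LTR-divergence age intervals (two rate calibrations)") +
    ggplot2::theme_minimal()
}

#' Deletion-size distribution of non-classical insertions
#'
#' @param events NCPI event tibble (needs `deletion_size_bp`).
#' @return A ggplot object.
#' @export
plot_ncpi_deletions <- function(events) {
  ggplot2::ggplot(events, ggplot2::aes(x = .data$deletion_size_bp)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue") +
    ggplot2::labs(x = "associated deletion (bp)", y = "events",
                  title = "Deletions associated with non-classical insertions") +
    ggplot2::theme_minimal()
}
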