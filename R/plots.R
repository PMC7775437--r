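#  ggplot2 views of the main result types

#' Heatmap of methylation-pattern frequencies
#'
#' One column per distinct binary pattern (most frequent first, width
#' proportional to nothing -- equal tiles), one row per CpG; tile fill
#' encodes methylated/unmethylated. The bar of frequencies is annotated
#' on the x axis.
#'
#' @param table Pattern table for one sample and amplicon.
#' @param max_patterns Show at most this many most-frequent patterns.
#' @return A ggplot object.
#' @export
plot_pattern_frequencies <- function(table, max_patterns = 30L) {
  table <- tibble::as_tibble(table) |>
    dplyr::arrange(dplyr::desc(.data$count)) |>
    head(max_patterns)
  m <- pattern_to_matrix(table$pattern)
  df <- tibble::tibble(
    pattern_rank = rep(seq_len(nrow(m)), each = ncol(m)),
    cpg_index = rep(seq_len(ncol(m)), times = nrow(m)),
    state = factor(t(m)[], levels = c(0L, 1L),
                   labels = c("unmethylated", "methylated")),
    frequency = rep(table$count / sum(table$count), each = ncol(m))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern_rank,
                                   y = .data$cpg_index,
                                   fill = .data$state)) +
    ggplot2::geom_tile(color = "grey90") +
    ggplot2::scale_fill_manual(values = c(unmethylated = "#3B6FB6",
                                          methylated = "#C0392B"),
                               na.value = "grey80", name = NULL) +
    ggplot2::scale_y_reverse(breaks = seq_len(ncol(m))) +
    ggplot2::labs(x = "pattern (by decreasing frequency)", y = "CpG",
                  title = unique(table$amplicon)) +
    ggplot2::theme_minimal()
}

#' Heatmap of neighbor-CpG methylation correlation
#'
#' @param corr Matrix from [neighbor_correlation()].
#' @return A ggplot object.
#' @export
plot_neighbor_correlation <- function(corr) {
  df <- tibble::as_tibble(as.table(corr), .name_repair = "minimal")
  names(df) <- c("cpg_i", "cpg_j", "r")
  df$cpg_i <- as.integer(as.character(df$cpg_i))
  df$cpg_j <- as.integer(as.character(df$cpg_j))
  ggplot2::ggplot(df, ggplot2::aes(.data$cpg_i, .data$cpg_j, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#3B6FB6", mid = "white",
                                  high = "#C0392B", limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "CpG", y = "CpG", fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Positional CpG-age correlation profile
#'
#' Pearson correlation of DNAm with age against CpG position within each
#' amplicon -- the bell-shaped profile plot.
#'
#' @param profile Tibble from [cpg_age_profile()].
#' @return A ggplot object.
#' @export
plot_age_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$cpg_index, .data$pearson_r)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~amplicon, scales = "free_x") +
    ggplot2::labs(x = "CpG position within amplicon",
                  y = "Pearson r (DNAm vs age)") +
    ggplot2::theme_minimal()
}

#' Heatmap of single-read predicted-age distributions
#'
#' One row per sample (ordered by chronological age when provided), one
#' column per grid age; fill is log10 of the read frequency offset by one
#' read -- the stored distributions stay linear, the log is presentation
#' only.
#'
#' @param dist Long distribution tibble (rows of [predict_sample_age()]
#'   distributions bound together).
#' @param ages Optional tibble `sample_id`, `age_weeks` used to order
#'   samples.
#' @return A ggplot object.
#' @export
plot_read_age_distribution <- function(dist, ages = NULL) {
  dist <- tibble::as_tibble(dist)
  if (!is.null(ages)) {
    ord <- ages$sample_id[order(ages$age_weeks)]
    dist$sample_id <- factor(dist$sample_id, levels = ord)
  }
  n_reads_guess <- 1 / max(dist$frequency[dist$frequency > 0], na.rm = TRUE)
  dist$log_freq <- log10(dist$frequency + 1 / max(n_reads_guess, 1))
  ggplot2::ggplot(dist, ggplot2::aes(.data$age, .data$sample_id,
                                     fill = .data$log_freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 frequency") +
    ggplot2::facet_wrap(~amplicon) +
    ggplot2::labs(x = "predicted age (weeks)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Predicted versus chronological age scatter
#'
#' @param object A `clock_evaluation` from [evaluate_clock()].
#' @param ... Unused.
#' @return A ggplot object annotated with R-squared and median error.
#' @method autoplot clock_evaluation
#' @export
autoplot.clock_evaluation <- function(object, ...) {
  g <- glance(object)
  lab <- sprintf("R² = %.2f\nmedian error = %.1f weeks",
                 g$r_squared, g$median_abs_error)
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$chronological, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.2,
                      label = lab) +
    ggplot2::labs(x = "chronological age (weeks)",
                  y = "predicted age (weeks)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
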