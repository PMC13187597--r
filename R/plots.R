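# ggplot2 visualizations for the main result types.

#' @export
autoplot.km_curve <- function(object, ...) {
  st <- object$steps
  df <- dplyr::bind_rows(tibble(time = 0, estimate = 1), st)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = filter(st, .data$n_censor > 0), shape = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pfs_ratio_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$delta, y = .data$survival)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$delta, linetype = "dashed") +
    ggplot2::labs(x = expression(delta), y = "S(PFS2/PFS1 > delta)",
                  title = sprintf("Benefit rate at delta = %.2f: %s",
                                  object$delta,
                                  ifelse(is.na(object$benefit_rate), "undefined",
                                         sprintf("%.2f", object$benefit_rate)))) +
    ggplot2::theme_minimal()
}

#' OncoPrint-style tile plot of an alteration matrix
#' @param mat An `alteration_matrix`.
#' @return A ggplot object.
#' @export
plot_alteration_matrix <- function(mat) {
  df <- as_tibble(as.table(unclass(mat)), .name_repair = "minimal")
  names(df) <- c("alteration", "sample", "altered")
  freq_order <- names(sort(rowSums(mat), decreasing = FALSE))
  df$alteration <- factor(df$alteration, levels = freq_order)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$alteration,
                                   fill = .data$altered > 0)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey92",
                                          `TRUE` = "#2c6e9e"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Stacked bar plot of signature exposure fractions
#' @param exposures A `signature_exposure` tibble.
#' @return A ggplot object.
#' @export
plot_exposures <- function(exposures) {
  df <- exposure_fractions(exposures)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$fraction,
                                   fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Exposure fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Bar plot of TOP-ART totals colored by positivity
#' @param assessment A `topart_assessment` tibble.
#' @return A ggplot object.
#' @export
plot_topart <- function(assessment) {
  df <- count(assessment, .data$total, .data$positive)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$total), y = .data$n,
                                   fill = .data$positive)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "TOP-ART score", y = "Patients", fill = "Positive") +
    ggplot2::theme_minimal()
}
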