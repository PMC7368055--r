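#' Heatmap of scaled parameter values
#'
#' Rows are parameter x time cells, columns the surface x condition cells of
#' the comparison set, filled with the 0--10 scaled value.
#'
#' @param scaled Scaled tibble (from [scale_parameters()]).
#' @return A ggplot object.
#' @export
plot_scaled_heatmap <- function(scaled) {
  d <- scaled |>
    mutate(
      row = paste0(.data$parameter, ifelse(is.na(.data$time), "",
                                           paste0(" t", .data$time))),
      col = paste0(.data$surface, ifelse(.data$tf > 0, " +TF", ""))
    ) |>
    summarise(scaled = mean(.data$scaled), .by = c("row", "col"))
  ggplot(d, aes(x = .data$col, y = .data$row, fill = .data$scaled)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 10), name = "scaled 0-10") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Subtraction / relevant-change heatmap
#'
#' Green encodes a relevant decrease, red a relevant increase; cells inside
#' the relevance band are blank (zero).
#'
#' @param diff Output of [subtraction_heatmap()] or [patient_changes()].
#' @param columns Column(s) to paste into the x axis label (default:
#'   whatever of `subject` and `surface` is present).
#' @return A ggplot object.
#' @export
plot_subtraction_heatmap <- function(diff, columns = NULL) {
  if (is.null(columns)) {
    columns <- intersect(c("subject", "surface", "tf"), names(diff))
  }
  d <- diff |>
    mutate(row = paste0(.data$parameter, ifelse(is.na(.data$time), "",
                                                paste0(" t", .data$time))))
  d$col <- do.call(paste, c(unclass(d[columns]), sep = " "))
  lim <- max(abs(d$value), 1e-9)
  ggplot(d, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient2(low = "darkgreen", mid = "white", high = "red",
                         limits = c(-lim, lim), name = "relevant change") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Bar chart of integrated group changes
#'
#' Cumulative relevant changes per subject and parameter group, split by TF
#' stratum — the integrative patient-versus-control summary.
#'
#' @param sums Output of [integrate_changes()].
#' @return A ggplot object.
#' @export
plot_integration <- function(sums) {
  ggplot(sums, aes(x = .data$subject, y = .data$change_sum,
                   fill = .data$tf_present)) +
    geom_col(position = "dodge") +
    facet_wrap(~param_group, ncol = 1) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    scale_fill_manual(values = c(`FALSE` = "grey80", `TRUE` = "steelblue"),
                      name = "TF present") +
    labs(x = NULL, y = "cumulative relevant change") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot a thrombin-generation curve with its characteristics
#'
#' @param curve Tibble `time`, `thrombin`.
#' @param characteristics Annotate lag and peak from
#'   [characterize_thrombin()].
#' @return A ggplot object.
#' @export
plot_thrombin_curve <- function(curve, characteristics = TRUE) {
  p <- ggplot(curve, aes(x = .data$time, y = .data$thrombin)) +
    geom_line(colour = "firebrick") +
    labs(x = "time (min)", y = "thrombin (nM)") +
    theme_minimal()
  if (characteristics) {
    ch <- characterize_thrombin(curve)
    if (!is.na(ch$lag)) {
      p <- p + geom_vline(xintercept = ch$lag, linetype = 2, colour = "grey40")
    }
    p <- p + geom_hline(yintercept = ch$peak, linetype = 3, colour = "grey40")
  }
  p
}

#' @export
autoplot.prediction_report <- function(object, ...) {
  ggplot(object$accuracies,
         aes(x = .data$surface, y = .data$accuracy, colour = .data$classifier)) +
    geom_point(position = position_jitter(width = 0.1, height = 0), size = 2) +
    geom_point(data = object$mean_accuracy,
               mapping = aes(x = .data$surface, y = .data$mean_accuracy),
               colour = "black", shape = 95, size = 10,
               inherit.aes = FALSE) +
    geom_hline(yintercept = 1 / 8, linetype = 2, colour = "grey50") +
    scale_y_continuous(limits = c(0, 1)) +
    labs(y = "LOOCV accuracy", x = NULL) +
    theme_minimal()
}
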