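# ggplot2 visualizations for the main result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @describeIn roe Tile heat map of Ro/e values with significance capped at 1.
#' @param object A `roe_table`.
#' @param ... Unused.
#' @method autoplot roe_table
#' @export
autoplot.roe_table <- function(object, ...) {
  nms <- names(object)[1:2]
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[nms[[2]]]], y = .data[[nms[[1]]]], fill = .data$roe)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$roe), "", sprintf("%.2f", .data$roe))),
      size = 3) +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "#2166AC",
                                  mid = "white", high = "#B2182B",
                                  na.value = "grey92") +
    ggplot2::labs(fill = "Ro/e") +
    ggplot2::theme_minimal()
}

#' @describeIn cooccurrence_modules Correlation heat map ordered by the
#'   module tree, with module assignments on the axis labels.
#' @param object A `cm_partition`.
#' @param ... Unused.
#' @method autoplot cm_partition
#' @export
autoplot.cm_partition <- function(object, ...) {
  ord <- object$tree$labels[object$tree$order]
  df <- tibble::as_tibble(as.data.frame(as.table(object$correlation),
                                        stringsAsFactors = FALSE))
  names(df) <- c("a", "b", "r")
  df$a <- factor(df$a, levels = ord)
  df$b <- factor(df$b, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @describeIn consensus_programs Consensus heat map for the selected k.
#' @param object A `consensus_programs` object.
#' @param ... Unused.
#' @method autoplot consensus_programs
#' @export
autoplot.consensus_programs <- function(object, ...) {
  ord <- object$programs$set[order(object$programs$program)]
  df <- tibble::as_tibble(as.data.frame(as.table(object$consensus),
                                        stringsAsFactors = FALSE))
  names(df) <- c("a", "b", "consensus")
  df$a <- factor(df$a, levels = ord)
  df$b <- factor(df$b, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#00441B",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Consensus matrix (k = %d)", object$k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @describeIn fit_risk_model Lollipop plot of the selected coefficients.
#' @param object A `risk_model`.
#' @method autoplot risk_model
#' @export
autoplot.risk_model <- function(object, ...) {
  df <- tidy.risk_model(object)
  df <- df[order(df$estimate), ]
  df$term <- factor(df$term, levels = df$term)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$estimate,
                                       yend = .data$term), color = "grey60") +
    ggplot2::geom_point(size = 3, color = "#B2182B") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "LASSO Cox coefficient", y = NULL) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by group
#'
#' @param records Survival tibble.
#' @param group Group label per patient (vector or column name).
#' @return A ggplot object of step survival curves.
#' @export
plot_km <- function(records, group) {
  records <- validate_survival(records)
  g <- if (is.character(group) && length(group) == 1 &&
           group %in% names(records)) records[[group]] else group
  df <- purrr::map_dfr(sort(unique(g)), function(lev) {
    km <- km_estimate(records[g == lev, , drop = FALSE])
    km$group <- lev
    km
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", color = NULL) +
    ggplot2::theme_minimal()
}

#' Time-dependent ROC AUC profile
#'
#' @param troc Tibble from [time_roc()].
#' @return A ggplot object.
#' @export
plot_time_roc <- function(troc) {
  ggplot2::ggplot(troc, ggplot2::aes(x = .data$horizon, y = .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Horizon", y = "AUC(t)") +
    ggplot2::theme_minimal()
}
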