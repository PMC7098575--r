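#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' @param x A `gx_cv` object.
#' @param ... Unused.
#' @return A plain tibble with one row per (repeat, fold).
#' @method tidy gx_cv
#' @export
tidy.gx_cv <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' Summarise a cross-validation result
#'
#' @param x A `gx_cv` object.
#' @param ... Unused.
#' @return One-row tibble with the record count and the mean of every
#'   metric across folds (the conventional way repeated-CV performance is
#'   reported).
#' @method glance gx_cv
#' @export
glance.gx_cv <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x),
    repeats = attr(x, "repeats"),
    folds = attr(x, "folds"),
    auc = mean(x$auc), sensitivity = mean(x$sensitivity),
    specificity = mean(x$specificity), f_measure = mean(x$f_measure),
    accuracy = mean(x$accuracy), mcc = mean(x$mcc)
  )
}

#' Box-plot of fold-wise AUC distributions
#'
#' @param object A `gx_cv` object, or a named list of them for side-by-side
#'   comparison.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gx_cv
#' @export
autoplot.gx_cv <- function(object, ...) {
  df <- tidy(object)
  df$model <- attr(object, "model") %||% "model"
  plot_cv_auc(stats::setNames(list(object), df$model[1]))
}

#' Compare AUC distributions of several CV results
#'
#' @param cv_list Named list of `gx_cv` objects.
#' @return A ggplot box-plot of fold-wise validation AUC per model.
#' @export
plot_cv_auc <- function(cv_list) {
  stopifnot(is.list(cv_list), !is.null(names(cv_list)))
  df <- purrr::imap(cv_list, function(cv, nm) {
    tibble::tibble(model = nm, auc = cv$auc)
  }) |> purrr::list_rbind()
  df$model <- factor(df$model, levels = names(cv_list))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$auc)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "validation AUC") +
    ggplot2::theme_minimal()
}

#' Plot a gene-expression image
#'
#' @param object A `gx_image`.
#' @param ... Unused.
#' @return A ggplot raster (lighter = higher expression).
#' @method autoplot gx_image
#' @export
autoplot.gx_image <- function(object, ...) {
  df <- expand.grid(row = seq_len(nrow(object)), col = seq_len(ncol(object)))
  df$value <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "expression",
                  title = attr(object, "sample_id")) +
    ggplot2::theme_void()
}

#' Plot the rectangles of a template layout
#'
#' @param template A `gx_template`.
#' @param level Which level to outline (`"leaf"`, `"hierarchy"`,
#'   `"category"`).
#' @return A ggplot of the treemap rectangles.
#' @export
plot_template <- function(template, level = c("hierarchy", "category", "leaf")) {
  stopifnot(inherits(template, "gx_template"))
  level <- match.arg(level)
  df <- template$rects[template$rects$level == level, ]
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                                    ymin = .data$y0, ymax = .data$y1),
                       fill = "grey90", colour = "grey20", linewidth = 0.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
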