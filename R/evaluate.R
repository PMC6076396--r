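#' Evaluate sequence classification results
#'
#' Computes the per-class accuracy (recall), their macro average, and the
#' L x L confusion matrix, formatted like the per-accession result tables of
#' phenotyping benchmarks (one column per class plus `Avg.`, in percent).
#'
#' @param predictions 0-based predicted classes.
#' @param truth 0-based true classes, same length.
#' @param class_names optional class labels (defaults to `class0..`).
#' @return a `phenoseq_eval` object; its `$summary` holds the per-class
#'   accuracies in percent, `$confusion` the confusion matrix (rows = truth).
#' @export
evaluate <- function(predictions, truth, class_names = NULL) {
  stopifnot(length(predictions) == length(truth))
  predictions <- as.integer(predictions); truth <- as.integer(truth)
  L <- max(truth) + 1L
  if (any(predictions < 0L | predictions >= L))
    stop("prediction outside the classes present in `truth`", call. = FALSE)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(L) - 1L)
  stopifnot(length(class_names) == L)
  conf <- matrix(0L, L, L, dimnames = list(truth = class_names, predicted = class_names))
  for (i in seq_along(truth)) conf[truth[i] + 1L, predictions[i] + 1L] <-
      conf[truth[i] + 1L, predictions[i] + 1L] + 1L
  per_class <- unname(ifelse(rowSums(conf) > 0, 100 * diag(conf) / rowSums(conf), NA_real_))
  macro <- mean(per_class, na.rm = TRUE)
  summary <- tibble::tibble(class = class_names, n = unname(rowSums(conf)),
                            accuracy = per_class)
  structure(list(summary = summary, confusion = conf, macro_accuracy = macro,
                 overall_accuracy = 100 * mean(predictions == truth),
                 n = length(truth)),
            class = "phenoseq_eval")
}

#' @export
print.phenoseq_eval <- function(x, ...) {
  vals <- c(x$summary$accuracy, x$macro_accuracy)
  hdr <- c(x$summary$class, "Avg.")
  w <- pmax(nchar(hdr), 5L)
  cat(paste(formatC(hdr, width = w), collapse = "  "), "\n")
  cat(paste(formatC(sprintf("%.1f", vals), width = w), collapse = "  "), "\n")
  invisible(x)
}

#' @rdname evaluate
#' @param x a `phenoseq_eval` object.
#' @param ... unused.
#' @export
tidy.phenoseq_eval <- function(x, ...) x$summary

#' @rdname evaluate
#' @export
glance.phenoseq_eval <- function(x, ...) {
  tibble::tibble(macro_accuracy = x$macro_accuracy,
                 overall_accuracy = x$overall_accuracy, n = x$n)
}

#' Confusion-matrix heat map of an evaluation
#'
#' @param object a `phenoseq_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.phenoseq_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$confusion))) +
    ggplot2::scale_fill_gradient(low = "grey20", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted accession", y = "true accession", fill = "plants") +
    ggplot2::theme_minimal()
}

#' Growth curves of a synthetic dataset
#'
#' Plots per-plant truth-mask area against day, coloured by accession; a quick
#' visual check of the dynamics the sequence models must exploit.
#'
#' @param sequences list of [plant_sequence()] objects with truth masks.
#' @return a ggplot object.
#' @export
plot_growth_curves <- function(sequences) {
  df <- dplyr::bind_rows(lapply(sequences, function(sq) {
    tibble::tibble(plant_id = sq$plant_id, genotype = factor(sq$genotype),
                   day = sq$day_index,
                   area = vapply(sq$truth_masks, sum, numeric(1)))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$area,
                                   group = .data$plant_id, colour = .data$genotype)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "day", y = "rosette area (px)", colour = "accession") +
    ggplot2::theme_minimal()
}
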