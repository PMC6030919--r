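#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training log of a fitted DDI model
#'
#' @param x a `ddi_model`.
#' @param ... unused.
#' @return the per-epoch log tibble (`epoch`, `train_loss`,
#'   `dev_micro_f`, `seconds`).
#' @export
tidy.ddi_model <- function(x, ...) x$log

#' One-row summary of a fitted DDI model
#'
#' @param x a `ddi_model`.
#' @param ... unused.
#' @return a one-row tibble: cell type, hidden sizes, vocabulary size,
#'   number of parameters, epochs trained, best epoch and best dev
#'   micro-F.
#' @export
glance.ddi_model <- function(x, ...) {
  count <- function(p) {
    if (is.numeric(p)) length(p)
    else if (is.list(p)) sum(vapply(p, count, numeric(1)))
    else 0
  }
  tibble(
    cell = x$config$model$cell,
    bottom_hidden = x$config$model$bottom_hidden,
    top_hidden = x$config$model$top_hidden,
    vocab_words = length(x$vocab$word),
    n_parameters = count(x$params),
    epochs = nrow(x$log),
    best_epoch = x$best_epoch,
    best_dev_micro_f = if (all(is.na(x$log$dev_micro_f))) NA_real_
                       else max(x$log$dev_micro_f, na.rm = TRUE)
  )
}

#' Tidy an evaluation report
#'
#' @param x a `ddi_eval`.
#' @param ... unused.
#' @return per-class rows plus a pooled `micro` row.
#' @export
tidy.ddi_eval <- function(x, ...) {
  bind_rows(x$per_class, bind_cols(tibble(class = "micro"), x$micro))
}

#' One-row summary of an evaluation report
#'
#' @param x a `ddi_eval`.
#' @param ... unused.
#' @return one-row tibble with micro precision/recall/F and instance
#'   count.
#' @export
glance.ddi_eval <- function(x, ...) {
  bind_cols(x$micro, tibble(n = x$n))
}

#' Training-curve plot for a fitted DDI model
#'
#' Training loss and, when available, held-out micro-F by epoch.
#'
#' @param object a `ddi_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ddi_model <- function(object, ...) {
  long <- object$log |>
    select("epoch", "train_loss", "dev_micro_f") |>
    tidyr::pivot_longer(-"epoch", names_to = "metric") |>
    filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Confusion-matrix heatmap for an evaluation report
#'
#' @param object a `ddi_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ddi_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("gold", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$gold,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "gold")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
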