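#' Harmonic mean of precision and recall
#'
#' `2 * precision * recall / (precision + recall)`, defined as 0 when both
#' arguments are 0.
#'
#' @param precision,recall values in `[0, 1]` (vectorised).
#' @return the F-score(s).
#' @export
#' @examples
#' f_score(0.741, 0.718)  # 0.729 at 3-decimal rounding
f_score <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Score predicted DDI labels against gold labels
#'
#' Per-class and micro-averaged precision/recall/F in the
#' DDIExtraction-2013 convention: a positive prediction counts as a true
#' positive only when the predicted type equals the gold type, and the
#' micro average pools tp/fp/fn over the four positive classes with
#' Negative excluded. Classes with an empty denominator report
#' precision (or recall) 0, so F is always defined.
#'
#' @param predictions predicted labels: a named character vector
#'   (names = pair ids) or a tibble with `pair_id` and `label` columns.
#' @param gold gold labels in the same form. The pair-id sets must match
#'   exactly.
#' @return an object of class `ddi_eval`: list with `per_class` (tibble:
#'   class, tp, fp, fn, precision, recall, f), `micro` (one-row tibble)
#'   and `confusion` (5 x 5 matrix, gold rows by predicted columns).
#' @export
ddi_score <- function(predictions, gold) {
  as_map <- function(x, what) {
    if (is.data.frame(x)) {
      stats::setNames(x$label, x$pair_id)
    } else if (!is.null(names(x))) {
      x
    } else {
      abort(paste0(what, " must be a named vector or a pair_id/label tibble"))
    }
  }
  p <- as_map(predictions, "predictions")
  g <- as_map(gold, "gold")
  only_p <- setdiff(names(p), names(g))
  only_g <- setdiff(names(g), names(p))
  if (length(only_p) || length(only_g)) {
    abort(paste0(
      "pair id sets differ; only in predictions: {",
      paste(utils::head(only_p, 5), collapse = ", "),
      "}, only in gold: {", paste(utils::head(only_g, 5), collapse = ", "), "}"
    ))
  }
  p <- p[names(g)]
  pf <- factor(unname(p), levels = DDI_CLASSES)
  gf <- factor(unname(g), levels = DDI_CLASSES)
  if (anyNA(pf) || anyNA(gf)) abort("labels outside the five DDI classes")
  confusion <- table(gold = gf, predicted = pf)

  per_class <- bind_rows(lapply(DDI_POSITIVE, function(cl) {
    tp <- sum(p == cl & g == cl)
    fp <- sum(p == cl & g != cl)
    fn <- sum(p != cl & g == cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    tibble(class = cl, tp = tp, fp = fp, fn = fn,
           precision = prec, recall = rec, f = f_score(prec, rec))
  }))
  tp <- sum(per_class$tp)
  fp <- sum(per_class$fp)
  fn <- sum(per_class$fn)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  micro <- tibble(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec,
                  f = f_score(prec, rec))
  structure(list(per_class = per_class, micro = micro,
                 confusion = unclass(confusion), n = length(g)),
            class = "ddi_eval")
}

#' @export
print.ddi_eval <- function(x, ...) {
  cat(sprintf("<ddi_eval> %d instances | micro P %.3f R %.3f F %.3f\n",
              x$n, x$micro$precision, x$micro$recall, x$micro$f))
  print(x$per_class)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report a `ddi_eval`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(
      micro = as.list(report$micro),
      per_class = report$per_class,
      confusion = list(classes = DDI_CLASSES,
                       counts = matrix(as.integer(report$confusion), 5L, 5L)),
      n = report$n
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
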