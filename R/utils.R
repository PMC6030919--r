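#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 map_int map_chr map_lgl
NULL

# The five DDI classes, in the fixed id order used throughout the package.
# Negative is class 1; the four positive interaction types follow.
DDI_CLASSES <- c("Negative", "Advice", "Effect", "Mechanism", "Int")

# Positive classes pooled by the micro-averaged evaluation.
DDI_POSITIVE <- DDI_CLASSES[-1]

# Placeholder surfaces introduced by entity anonymization.
PLACEHOLDER_E0 <- "drug0"
PLACEHOLDER_E1 <- "drug1"
PLACEHOLDER_OTHER <- "drugn"

ddi_class_id <- function(label) {
  id <- match(label, DDI_CLASSES)
  if (anyNA(id)) {
    abort(paste0(
      "unknown DDI label(s): ",
      paste(unique(label[is.na(id)]), collapse = ", ")
    ))
  }
  id
}

#' Normalise a DDI type attribute to a canonical class label
#'
#' The DDIExtraction-2013 dialect writes positive types in lower case and
#' uses the historical spelling "advise" for the Advice class; both are
#' accepted case-insensitively.
#'
#' @param type character vector of type attributes (e.g. "effect").
#' @return character vector of canonical labels (see [ddi_classes()]).
#' @keywords internal
normalize_ddi_type <- function(type) {
  lk <- c(
    advice = "Advice", advise = "Advice", effect = "Effect",
    mechanism = "Mechanism", int = "Int", negative = "Negative"
  )
  out <- unname(lk[tolower(type)])
  if (anyNA(out)) {
    abort(paste0("unknown DDI type attribute: ",
                 paste(unique(type[is.na(out)]), collapse = ", ")))
  }
  out
}

#' The DDI class labels
#'
#' @return character vector of the five class labels in id order:
#'   Negative, Advice, Effect, Mechanism, Int.
#' @export
#' @examples
#' ddi_classes()
ddi_classes <- function() DDI_CLASSES

# Stable, seed-driven RNG scope: evaluates `expr` with the given seed and
# restores the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
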