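#' Full run configuration with reference-default hyperparameters
#'
#' Nested configuration covering every stage. Defaults follow the
#' reference configuration for this architecture: 200/10/10 embedding dimensions, hidden size 100 for
#' both encoder levels, LSTM cells, RMSProp with learning rate 0.001,
#' mini-batches of 64, and dropout 0.7 / 0.5 on the embedding and output
#' layers. Unknown keys are rejected.
#'
#' Sections and keys:
#' \describe{
#'   \item{embedding}{`d_word` (200), `d_pos` (10), `d_dis` (10), `clip`
#'     (30), `min_count` (1), `noun_pos` ("NN"), `seed` (42),
#'     `attention_rescale` ("none" or "times_m"),
#'     `sdp_include_relations` (FALSE)}
#'   \item{model}{`bottom_hidden` (100), `top_hidden` (100), `cell`
#'     ("lstm", "gru" or "simple"), `n_classes` (5), `dropout_embed`
#'     (0.7), `dropout_output` (0.5),
#'     `share_bottom_across_subsequences` (TRUE), `entity_projection`
#'     (TRUE), `bottom_pooling` ("final" or "max")}
#'   \item{train}{`optimizer` ("rmsprop"), `learning_rate` (0.001),
#'     `batch_size` (64), `epochs` (30), `seed` (1), `rho` (0.9),
#'     `epsilon` (1e-8)}
#'   \item{corpus}{`anonymize_others` (TRUE)}
#'   \item{synth}{see [synthetic_spec()]}
#' }
#'
#' @param ... named overrides, either nested lists (`model =
#'   list(cell = "gru")`) or section-level lists from YAML.
#' @return an object of class `ddi_config`.
#' @export
#' @examples
#' cfg <- ddi_config(model = list(cell = "gru"), train = list(epochs = 5))
#' cfg$model$cell
ddi_config <- function(...) {
  defaults <- list(
    embedding = list(
      d_word = 200L, d_pos = 10L, d_dis = 10L, clip = 30L, min_count = 1L,
      noun_pos = "NN", seed = 42L, attention_rescale = "none",
      sdp_include_relations = FALSE
    ),
    model = list(
      bottom_hidden = 100L, top_hidden = 100L, cell = "lstm",
      n_classes = 5L, dropout_embed = 0.7, dropout_output = 0.5,
      share_bottom_across_subsequences = TRUE, entity_projection = TRUE,
      bottom_pooling = "final"
    ),
    train = list(
      optimizer = "rmsprop", learning_rate = 0.001, batch_size = 64L,
      epochs = 30L, seed = 1L, rho = 0.9, epsilon = 1e-8
    ),
    corpus = list(anonymize_others = TRUE),
    synth = unclass(synthetic_spec())
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  cfg <- merge_config(defaults, overrides, path = "")
  validate_config(cfg)
  structure(cfg, class = "ddi_config")
}

merge_config <- function(base, overrides, path) {
  if (length(overrides) == 0L) return(base)
  nm <- names(overrides)
  if (is.null(nm) || any(!nzchar(nm))) {
    abort(paste0("config overrides must be named (at '", path, "')"))
  }
  bad <- setdiff(nm, names(base))
  if (length(bad)) {
    abort(paste0("unknown config key(s): ",
                 paste0(sub("^\\.", "", paste0(path, ".", bad)),
                        collapse = ", ")))
  }
  for (k in nm) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], as.list(overrides[[k]]),
                                paste0(path, ".", k))
    } else {
      v <- overrides[[k]]
      if (is.numeric(base[[k]]) && is.numeric(v)) {
        storage.mode(v) <- storage.mode(base[[k]])
      }
      base[[k]] <- v
    }
  }
  base
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$embedding$d_word > 0L, cfg$embedding$d_pos > 0L,
    cfg$embedding$d_dis > 0L, cfg$embedding$clip > 0L,
    cfg$model$bottom_hidden > 0L, cfg$model$top_hidden > 0L,
    cfg$model$n_classes == 5L,
    cfg$model$dropout_embed >= 0, cfg$model$dropout_embed < 1,
    cfg$model$dropout_output >= 0, cfg$model$dropout_output < 1,
    cfg$train$learning_rate > 0, cfg$train$batch_size >= 1L
  )
  if (!cfg$model$cell %in% c("lstm", "gru", "simple")) {
    abort("model$cell must be one of lstm, gru, simple")
  }
  if (!cfg$model$bottom_pooling %in% c("final", "max")) {
    abort("model$bottom_pooling must be 'final' or 'max'")
  }
  if (!cfg$embedding$attention_rescale %in% c("none", "times_m")) {
    abort("embedding$attention_rescale must be 'none' or 'times_m'")
  }
  if (cfg$train$optimizer != "rmsprop") {
    abort("train$optimizer must be 'rmsprop'")
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Unknown keys anywhere in the file are rejected with the offending key
#' named.
#'
#' @param path YAML file.
#' @return a `ddi_config`.
#' @export
read_ddi_config <- function(path) {
  ddi_config(yaml::read_yaml(path))
}

#' @export
print.ddi_config <- function(x, ...) {
  cat("<ddi_config>\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
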