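#' Fit the hierarchical recurrent DDI model
#'
#' Trains the full architecture end to end: four-channel embeddings with
#' entity attention, bottom bidirectional encoders over the three context
#' subsequences and the SDP, a top bidirectional encoder over the six-slot
#' sequence, and a softmax head, minimising mean cross-entropy with
#' RMSProp. Dropout is applied at train time to the embedding outputs and
#' to the sentence representation before the head. When `dev` is given,
#' micro-averaged F over the four positive classes is logged per epoch and
#' the best-dev parameters are retained; otherwise the final parameters
#' are kept.
#'
#' All randomness (parameter init, shuffling, dropout) is driven by
#' `config$train$seed`; embedding-table initialisation by
#' `config$embedding$seed`. Identical seeds and data give identical
#' per-epoch loss sequences.
#'
#' @param train anonymized instance tibble with SDPs attached.
#' @param dev optional held-out instance tibble for per-epoch evaluation.
#' @param config a [ddi_config()].
#' @param vectors optional path to pretrained word vectors (word2vec text
#'   format).
#' @param quiet suppress per-epoch messages.
#' @return an object of class `ddi_model`: list with `params`, `config`,
#'   `vocab`, `log` (tibble: epoch, train_loss, dev_micro_f, seconds),
#'   `best_epoch`, and `coverage` (when `vectors` was given).
#' @seealso [predict.ddi_model()], [ddi_score()]
#' @export
ddi_fit <- function(train, dev = NULL, config = ddi_config(), vectors = NULL,
                    quiet = FALSE) {
  stopifnot(nrow(train) > 0L)
  ec <- config$embedding
  vocab <- build_vocab(train, ec$min_count, ec$noun_pos)
  emb <- init_embeddings(vocab, ec$d_word, ec$d_pos, ec$d_dis, ec$clip,
                         ec$seed, vectors)
  idx_train <- indexize_instances(train, vocab, config)
  idx_dev <- if (!is.null(dev)) indexize_instances(dev, vocab, config)
  dev_gold <- if (!is.null(dev)) stats::setNames(dev$label, dev$pair_id)

  tc <- config$train
  n <- length(idx_train)
  state <- with_seed(tc$seed, {
    params <- init_params(vocab, config, emb)
    cache <- NULL
    log <- vector("list", tc$epochs)
    best <- list(f = -Inf, params = params, epoch = 0L)
    for (epoch in seq_len(tc$epochs)) {
      t0 <- proc.time()[3]
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1L, n, by = tc$batch_size)) {
        ids <- ord[b0:min(b0 + tc$batch_size - 1L, n)]
        bt <- make_batch(idx_train[ids], config)
        fw <- forward_batch(params, bt, config, vocab, train = TRUE)
        if (!is.finite(fw$loss)) {
          abort(paste0("non-finite loss in epoch ", epoch,
                       ", batch starting at instance ", b0))
        }
        gr <- backward_batch(params, bt, config, fw)
        upd <- rmsprop_update(params, gr, cache, tc$learning_rate, tc$rho,
                              tc$epsilon)
        params <- upd$p
        cache <- upd$c
        losses <- c(losses, fw$loss)
      }
      dev_f <- NA_real_
      if (!is.null(idx_dev)) {
        pred <- predict_batched(params, idx_dev, config, vocab)
        rep <- ddi_score(
          stats::setNames(pred$label, pred$pair_id)[names(dev_gold)],
          dev_gold
        )
        dev_f <- rep$micro$f
        if (dev_f >= best$f + 1e-12) {
          best <- list(f = dev_f, params = params, epoch = epoch)
        }
      }
      secs <- proc.time()[3] - t0
      log[[epoch]] <- tibble(epoch = epoch, train_loss = mean(losses),
                             dev_micro_f = dev_f, seconds = secs)
      if (!quiet) {
        message(sprintf("epoch %3d  loss %.4f  dev micro-F %s  (%.1fs)",
                        epoch, mean(losses),
                        ifelse(is.na(dev_f), "-", sprintf("%.3f", dev_f)),
                        secs))
      }
    }
    if (is.null(idx_dev)) best <- list(f = NA_real_, params = params,
                                       epoch = tc$epochs)
    list(params = best$params, log = bind_rows(log), best_epoch = best$epoch)
  })
  structure(
    list(params = state$params, config = config, vocab = vocab,
         log = state$log, best_epoch = state$best_epoch,
         coverage = emb$coverage, classes = DDI_CLASSES),
    class = "ddi_model"
  )
}

predict_batched <- function(params, idx, config, vocab, batch_size = 256L,
                            ablate_sdp = FALSE) {
  out <- vector("list", 0L)
  n <- length(idx)
  for (b0 in seq(1L, n, by = batch_size)) {
    ids <- b0:min(b0 + batch_size - 1L, n)
    bt <- make_batch(idx[ids], config)
    fw <- forward_batch(params, bt, config, vocab, train = FALSE,
                        ablate_sdp = ablate_sdp)
    probs <- fw$probs
    colnames(probs) <- paste0("prob_", DDI_CLASSES)
    out[[length(out) + 1L]] <- bind_cols(
      tibble(pair_id = bt$pair_id,
             label = DDI_CLASSES[max.col(probs, ties.method = "first")]),
      as_tibble(probs)
    )
  }
  bind_rows(out)
}

#' Predict DDI labels and class probabilities
#'
#' Inference is deterministic: dropout is disabled.
#'
#' @param object a fitted `ddi_model`.
#' @param instances anonymized instance tibble with SDPs attached.
#' @param ablate_sdp zero the SDP slot of the top encoder before
#'   integration (diagnostic: measures how much signal the SDP pathway
#'   carries).
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return a tibble with `pair_id`, predicted `label`, and one
#'   `prob_<class>` column per class (rows sum to 1).
#' @export
predict.ddi_model <- function(object, instances, ablate_sdp = FALSE,
                              batch_size = 256L, ...) {
  idx <- indexize_instances(instances, object$vocab, object$config)
  predict_batched(object$params, idx, object$config, object$vocab,
                  batch_size = batch_size, ablate_sdp = ablate_sdp)
}

#' @export
print.ddi_model <- function(x, ...) {
  cat(sprintf(
    "<ddi_model> cell=%s bottom=%d top=%d | vocab %d words | %d epochs%s\n",
    x$config$model$cell, x$config$model$bottom_hidden,
    x$config$model$top_hidden, length(x$vocab$word), nrow(x$log),
    if (!is.na(x$log$dev_micro_f[nrow(x$log)])) {
      sprintf(" | best dev micro-F %.3f (epoch %d)",
              max(x$log$dev_micro_f, na.rm = TRUE), x$best_epoch)
    } else ""
  ))
  invisible(x)
}

#' Save / load a fitted model as a checkpoint directory
#'
#' Plain-text bundle: `params.json` (all parameter matrices),
#' `config.yaml`, `vocab.json`, `log.jsonl` (one epoch per line) and
#' `meta.json`.
#'
#' @param model a `ddi_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `write_ddi_model` returns `dir` invisibly; `read_ddi_model`
#'   the restored `ddi_model`.
#' @export
write_ddi_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(model$params, file.path(dir, "params.json"),
                       digits = NA, null = "null")
  yaml::write_yaml(unclass(model$config), file.path(dir, "config.yaml"))
  write_vocab(model$vocab, file.path(dir, "vocab.json"))
  writeLines(
    vapply(seq_len(nrow(model$log)), function(i) {
      as.character(jsonlite::toJSON(as.list(model$log[i, ]),
                                    auto_unbox = TRUE, na = "null",
                                    digits = NA))
    }, character(1)),
    file.path(dir, "log.jsonl")
  )
  jsonlite::write_json(
    list(best_epoch = model$best_epoch, classes = model$classes,
         coverage = model$coverage),
    file.path(dir, "meta.json"), auto_unbox = TRUE, null = "null"
  )
  invisible(dir)
}

#' @rdname write_ddi_model
#' @export
read_ddi_model <- function(dir) {
  restore <- function(x) {
    if (is.list(x) && is.null(names(x))) {
      # jsonlite may give a list of equal-length rows for a matrix
      do.call(rbind, lapply(x, unlist))
    } else if (is.list(x)) {
      lapply(x, restore)
    } else {
      x
    }
  }
  params <- jsonlite::fromJSON(file.path(dir, "params.json"),
                               simplifyVector = TRUE)
  params <- restore(params)
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"),
                             simplifyVector = TRUE)
  log_lines <- readLines(file.path(dir, "log.jsonl"))
  log <- bind_rows(lapply(log_lines, function(ln) {
    row <- jsonlite::fromJSON(ln)
    row[vapply(row, is.null, logical(1))] <- NA_real_
    as_tibble(row)
  }))
  structure(
    list(params = params, config = ddi_config(yaml::read_yaml(
      file.path(dir, "config.yaml"))),
      vocab = read_vocab(file.path(dir, "vocab.json")),
      log = log, best_epoch = meta$best_epoch,
      coverage = meta$coverage, classes = meta$classes),
    class = "ddi_model"
  )
}
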