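VOCAB_PAD <- "<pad>"
VOCAB_UNK <- "<unk>"

#' Build word and POS vocabularies from training instances
#'
#' Surfaces seen fewer than `min_count` times map to the unknown id. The
#' pad and unknown symbols occupy ids 1 and 2; the anonymization
#' placeholders `drug0`/`drug1`/`drugn` and the original entity surface
#' words are always in-vocabulary. Dependency-relation labels get their
#' own vocabulary (used only when SDP relation interleaving is enabled).
#'
#' @param instances anonymized training instances.
#' @param min_count minimum surface frequency to receive its own id.
#' @param noun_pos POS tag assigned to entity mentions; always added to
#'   the POS vocabulary.
#' @return an object of class `ddi_vocab`: list of character vectors
#'   `word`, `pos`, `rel` (position = id) plus `pad_id`, `unk_id`.
#' @export
build_vocab <- function(instances, min_count = 1L, noun_pos = "NN") {
  if (nrow(instances) == 0L) abort("empty training set")
  surfaces <- unlist(map(instances$tokens, "surface"))
  counts <- table(surfaces)
  keep <- names(counts)[counts >= min_count]
  always <- unique(c(
    PLACEHOLDER_E0, PLACEHOLDER_E1, PLACEHOLDER_OTHER,
    unlist(instances$e0_words), unlist(instances$e1_words)
  ))
  word <- c(VOCAB_PAD, VOCAB_UNK, sort(unique(c(keep, always))))
  pos <- c(VOCAB_PAD, VOCAB_UNK,
           sort(unique(c(noun_pos, unlist(map(instances$tokens, "pos"))))))
  rel <- c(VOCAB_PAD, VOCAB_UNK,
           sort(unique(unlist(map(instances$tokens, "deprel")))))
  structure(
    list(word = word, pos = pos, rel = rel, pad_id = 1L, unk_id = 2L),
    class = "ddi_vocab"
  )
}

#' @export
print.ddi_vocab <- function(x, ...) {
  cat(sprintf("<ddi_vocab> %d words, %d POS tags, %d relations\n",
              length(x$word), length(x$pos), length(x$rel)))
  invisible(x)
}

#' Map tokens to vocabulary ids
#'
#' @param vocab a `ddi_vocab`.
#' @param tokens character vector.
#' @param table which vocabulary: "word", "pos" or "rel".
#' @return integer ids; out-of-vocabulary tokens get the unknown id.
#' @export
vocab_id <- function(vocab, tokens, table = "word") {
  id <- match(tokens, vocab[[table]])
  id[is.na(id)] <- vocab$unk_id
  id
}

#' Serialize / deserialize a vocabulary
#'
#' @param vocab a `ddi_vocab`.
#' @param path JSON file path.
#' @return `write_vocab` returns `path` invisibly; `read_vocab` the
#'   restored `ddi_vocab`.
#' @export
write_vocab <- function(vocab, path) {
  jsonlite::write_json(unclass(vocab), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(
    list(word = x$word, pos = x$pos, rel = x$rel,
         pad_id = as.integer(x$pad_id), unk_id = as.integer(x$unk_id)),
    class = "ddi_vocab"
  )
}
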