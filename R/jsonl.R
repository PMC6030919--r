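#' Write prepared instances to JSON-lines
#'
#' One JSON object per instance, in a stable documented schema. All token
#' indices are 1-based; the root token's `head` is `null`. Fields:
#' `pair_id`, `sentence_id`, `label`, `e0`/`e1` (objects with `id`,
#' `type`, `text`, `tok` placeholder position, `words` original
#' surfaces), `tokens` (columnar object with `tid`, `surface`, `lemma`,
#' `pos`, `head`, `deprel`) and `sdp` (object with `nodes`, `rels`,
#' `dirs`).
#'
#' @param instances anonymized instances with SDPs attached
#'   (see [attach_sdp()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_instances_jsonl <- function(instances, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(instances))) {
    r <- instances[i, ]
    tok <- r$tokens[[1]]
    obj <- list(
      pair_id = r$pair_id, sentence_id = r$sentence_id, label = r$label,
      e0 = list(id = r$e0_id, type = r$e0_type, text = r$e0_text,
                tok = r$e0_tok, words = as.list(r$e0_words[[1]])),
      e1 = list(id = r$e1_id, type = r$e1_type, text = r$e1_text,
                tok = r$e1_tok, words = as.list(r$e1_words[[1]])),
      tokens = list(tid = tok$tid, surface = tok$surface, lemma = tok$lemma,
                    pos = tok$pos, head = tok$head, deprel = tok$deprel),
      sdp = list(nodes = r$sdp[[1]], rels = as.list(r$sdp_rels[[1]]),
                 dirs = as.list(r$sdp_dirs[[1]]))
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                                na = "null"), con)
  }
  invisible(path)
}

#' Read instances from JSON-lines
#'
#' Inverse of [write_instances_jsonl()].
#'
#' @param path JSON-lines file.
#' @return an instance tibble in the layout produced by
#'   [anonymize_instances()] + [attach_sdp()].
#' @export
read_instances_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    o <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    tok <- tibble(
      sentence_id = o$sentence_id,
      tid = as.integer(o$tokens$tid),
      surface = as.character(o$tokens$surface),
      lemma = as.character(o$tokens$lemma),
      pos = as.character(o$tokens$pos),
      head = as.integer(o$tokens$head),
      deprel = as.character(o$tokens$deprel),
      char_start = NA_integer_, char_end = NA_integer_
    )
    tibble(
      sentence_id = o$sentence_id, pair_id = o$pair_id, label = o$label,
      e0_id = o$e0$id, e0_type = o$e0$type, e0_text = o$e0$text,
      e1_id = o$e1$id, e1_type = o$e1$type, e1_text = o$e1$text,
      tokens = list(tok),
      e0_tok = as.integer(o$e0$tok), e1_tok = as.integer(o$e1$tok),
      e0_words = list(as.character(unlist(o$e0$words))),
      e1_words = list(as.character(unlist(o$e1$words))),
      sdp = list(as.integer(o$sdp$nodes)),
      sdp_rels = list(as.character(unlist(o$sdp$rels))),
      sdp_dirs = list(as.character(unlist(o$sdp$dirs)))
    )
  })
  bind_rows(rows)
}
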