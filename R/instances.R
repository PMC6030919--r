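#' Build labelled pair instances from a corpus and its parses
#'
#' Joins the XML annotations with the CoNLL-U parses: token character
#' offsets are recovered from the sentence text where missing, entity
#' character offsets are resolved to token spans, and one instance row is
#' produced per `pair` element. The pair's two entities are ordered so
#' that `e0` precedes `e1` in the sentence.
#'
#' @param corpus a `ddi_corpus` from [read_ddi_corpus()].
#' @param parses token tibble from [read_conllu()]; its sentence ids must
#'   cover every corpus sentence that carries a pair.
#' @return a tibble with one row per candidate pair: identifiers, `label`,
#'   entity token spans (`e0_from`/`e0_to`/`e1_from`/`e1_to`, 1-based
#'   inclusive), entity metadata, a `tokens` list-column, and an
#'   `others` list-column of non-target entity spans in the sentence.
#' @export
build_instances <- function(corpus, parses) {
  stopifnot(inherits(corpus, "ddi_corpus"))
  need <- unique(corpus$pairs$sentence_id)
  missing <- setdiff(need, unique(parses$sentence_id))
  if (length(missing)) {
    abort(paste0("no CoNLL-U parse for sentence id(s): ",
                 paste(missing, collapse = ", ")))
  }
  sent_text <- stats::setNames(corpus$sentences$text,
                               corpus$sentences$sentence_id)
  tok_split <- split(parses, factor(parses$sentence_id, levels = need))
  ent_split <- split(corpus$entities,
                     factor(corpus$entities$sentence_id, levels = need))
  pair_split <- split(corpus$pairs,
                      factor(corpus$pairs$sentence_id, levels = need))
  rows <- lapply(need, function(sid) {
    tok <- align_tokens_to_text(tok_split[[sid]], sent_text[[sid]])
    ents <- align_entity_offsets(ent_split[[sid]], tok, sid)
    prs <- pair_split[[sid]]
    lapply(seq_len(nrow(prs)), function(j) {
      ia <- match(prs$e0[j], ents$entity_id)
      ib <- match(prs$e1[j], ents$entity_id)
      if (is.na(ia) || is.na(ib)) {
        abort(paste0("pair ", prs$pair_id[j], " references unknown entity id"))
      }
      if (ents$from_tok[ia] > ents$from_tok[ib]) { tmp <- ia; ia <- ib; ib <- tmp }
      others <- ents[-c(ia, ib), c("entity_id", "from_tok", "to_tok")]
      list(
        sentence_id = sid, pair_id = prs$pair_id[j], label = prs$label[j],
        e0_id = ents$entity_id[ia], e0_from = ents$from_tok[ia],
        e0_to = ents$to_tok[ia], e0_text = ents$text[ia],
        e0_type = ents$type[ia],
        e1_id = ents$entity_id[ib], e1_from = ents$from_tok[ib],
        e1_to = ents$to_tok[ib], e1_text = ents$text[ib],
        e1_type = ents$type[ib],
        tokens = tok, others = others
      )
    })
  })
  rows <- unlist(rows, recursive = FALSE)
  tibble(
    sentence_id = map_chr(rows, "sentence_id"),
    pair_id = map_chr(rows, "pair_id"),
    label = map_chr(rows, "label"),
    e0_id = map_chr(rows, "e0_id"),
    e0_from = map_int(rows, "e0_from"), e0_to = map_int(rows, "e0_to"),
    e0_text = map_chr(rows, "e0_text"), e0_type = map_chr(rows, "e0_type"),
    e1_id = map_chr(rows, "e1_id"),
    e1_from = map_int(rows, "e1_from"), e1_to = map_int(rows, "e1_to"),
    e1_text = map_chr(rows, "e1_text"), e1_type = map_chr(rows, "e1_type"),
    tokens = map(rows, "tokens"), others = map(rows, "others")
  )
}

#' Anonymize target and non-target drug mentions
#'
#' Replaces the two target mentions by single placeholder tokens `drug0`
#' and `drug1` (a multi-token span is collapsed onto its internal
#' syntactic head; external heads pointing into the span are redirected to
#' the collapsed token, so the parse stays a tree) and, when
#' `anonymize_others` is `TRUE`, blinds every other drug mention with the
#' shared placeholder `drugn`. Character offsets are invalidated. The
#' original surface words of each target mention are retained for the
#' entity embedding average.
#'
#' @param instances tibble from [build_instances()].
#' @param anonymize_others blind non-target mentions with `drugn`?
#' @return the instance tibble with updated `tokens` plus columns
#'   `e0_tok`, `e1_tok` (placeholder token positions) and `e0_words`,
#'   `e1_words` (list-columns of original surfaces).
#' @export
anonymize_instances <- function(instances, anonymize_others = TRUE) {
  out <- lapply(seq_len(nrow(instances)), function(i) {
    anonymize_one(
      instances$tokens[[i]], instances$e0_from[i], instances$e0_to[i],
      instances$e1_from[i], instances$e1_to[i],
      instances$others[[i]], anonymize_others
    )
  })
  instances$tokens <- map(out, "tokens")
  instances$e0_tok <- map_int(out, "e0_tok")
  instances$e1_tok <- map_int(out, "e1_tok")
  instances$e0_words <- map(out, "e0_words")
  instances$e1_words <- map(out, "e1_words")
  instances
}

anonymize_one <- function(tokens, e0_from, e0_to, e1_from, e1_to,
                          others, anonymize_others) {
  e0_words <- tokens$surface[e0_from:e0_to]
  e1_words <- tokens$surface[e1_from:e1_to]
  if (anonymize_others && nrow(others)) {
    for (j in seq_len(nrow(others))) {
      sp <- others$from_tok[j]:others$to_tok[j]
      tokens$surface[sp] <- PLACEHOLDER_OTHER
      tokens$lemma[sp] <- PLACEHOLDER_OTHER
    }
  }
  # collapse the later span first so the earlier span's indices stay valid
  tokens <- collapse_span(tokens, e1_from, e1_to, PLACEHOLDER_E1)
  tokens <- collapse_span(tokens, e0_from, e0_to, PLACEHOLDER_E0)
  e1_tok <- e1_from - (e0_to - e0_from)
  tokens$tid <- seq_len(nrow(tokens))
  tokens$char_start <- NA_integer_
  tokens$char_end <- NA_integer_
  list(tokens = tokens, e0_tok = e0_from, e1_tok = e1_tok,
       e0_words = e0_words, e1_words = e1_words)
}

# Collapses tokens[from:to] onto the span's internal syntactic head and
# renames it `surface`; remaps all head indices onto the shrunk sentence.
collapse_span <- function(tokens, from, to, surface) {
  n <- nrow(tokens)
  span <- from:to
  if (length(span) == 1L) {
    tokens$surface[from] <- surface
    tokens$lemma[from] <- surface
    return(tokens)
  }
  inside <- tokens$head[span] %in% span  # NA head (root) counts as external
  inside[is.na(tokens$head[span])] <- FALSE
  h <- span[which(!inside)[1]]           # span token whose head is outside

  old2new <- integer(n)
  before <- seq_len(n) < from
  after <- seq_len(n) > to
  old2new[before] <- which(before)
  old2new[span] <- from
  old2new[after] <- which(after) - (to - from)

  kept <- c(which(before), h, which(after))
  new <- tokens[kept, ]
  new$head <- ifelse(is.na(new$head), NA_integer_, old2new[new$head])
  new$surface[from] <- surface
  new$lemma[from] <- surface
  new
}
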