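#' Read a corpus in the DDIExtraction-2013 XML dialect
#'
#' Reads one XML file, or every `*.xml` file in a directory, in the
#' DDIExtraction-2013 dialect (`document` > `sentence` > `entity`/`pair`).
#' Entity `charOffset` attributes are inclusive 0-based ranges `"a-b"`;
#' they are converted to half-open ranges internally. Discontinuous
#' offsets (`"a-b;c-d"`) keep only the first span, with a warning. A pair
#' with `ddi="false"` is labelled `Negative`; `ddi="true"` takes its label
#' from the `type` attribute ("advise" is accepted for Advice).
#'
#' @param path path to an XML file or a directory of XML files.
#' @return an object of class `ddi_corpus`: a list of three tibbles,
#'   `sentences` (`sentence_id`, `text`), `entities` (`sentence_id`,
#'   `entity_id`, `char_start`, `char_end` half-open 0-based, `type`,
#'   `text`, `discontinuous`), and `pairs` (`sentence_id`, `pair_id`,
#'   `e0`, `e1`, `label`).
#' @seealso [write_ddi_corpus()], [build_instances()]
#' @export
read_ddi_corpus <- function(path) {
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.xml$", full.names = TRUE))
  } else if (file.exists(path)) {
    path
  } else {
    abort(paste0("no XML files found under ", path))
  }
  if (length(files) == 0L) abort(paste0("no XML files found under ", path))
  parts <- lapply(files, read_ddi_xml_file)
  structure(
    list(
      sentences = bind_rows(lapply(parts, `[[`, "sentences")),
      entities  = bind_rows(lapply(parts, `[[`, "entities")),
      pairs     = bind_rows(lapply(parts, `[[`, "pairs"))
    ),
    class = "ddi_corpus"
  )
}

#' @export
print.ddi_corpus <- function(x, ...) {
  cat(sprintf(
    "<ddi_corpus> %d sentences, %d entities, %d pairs\n",
    nrow(x$sentences), nrow(x$entities), nrow(x$pairs)
  ))
  if (nrow(x$pairs)) print(table(x$pairs$label))
  invisible(x)
}

read_ddi_xml_file <- function(file) {
  doc <- tryCatch(
    xml2::read_xml(file),
    error = function(e) abort(paste0("malformed XML in ", file, ": ", conditionMessage(e)))
  )
  sent_nodes <- xml2::xml_find_all(doc, ".//sentence")
  sentences <- tibble(
    sentence_id = xml2::xml_attr(sent_nodes, "id"),
    text = xml2::xml_attr(sent_nodes, "text")
  )
  if (anyNA(sentences$sentence_id)) {
    abort(paste0("sentence element without id attribute in ", file))
  }

  en <- xml2::xml_find_all(doc, ".//sentence/entity")
  entities <- if (length(en)) {
    off <- xml2::xml_attr(en, "charOffset")
    parsed <- lapply(off, parse_char_offset)
    tibble(
      sentence_id = xml2::xml_attr(xml2::xml_find_first(en, "parent::sentence"), "id"),
      entity_id = xml2::xml_attr(en, "id"),
      char_start = map_int(parsed, "start"),
      char_end = map_int(parsed, "end"),
      type = xml2::xml_attr(en, "type"),
      text = xml2::xml_attr(en, "text"),
      discontinuous = map_lgl(parsed, "discontinuous")
    )
  } else {
    NULL
  }
  entities <- bind_rows(entities)
  if (nrow(entities)) {
    if (anyNA(entities$entity_id)) abort(paste0("entity without id in ", file))
    if (any(entities$discontinuous)) {
      warn(paste0(
        "discontinuous charOffset for entities ",
        paste(entities$entity_id[entities$discontinuous], collapse = ", "),
        "; keeping first span only"
      ))
    }
    # overlapping mentions in the same sentence are legal but worth flagging
    ov <- entities |>
      group_by(.data$sentence_id) |>
      filter(n() > 1) |>
      summarise(overlap = {
        o <- order(.data$char_start)
        any(.data$char_start[o][-1] < .data$char_end[o][-length(o)])
      }, .groups = "drop")
    if (any(ov$overlap)) {
      warn(paste0(
        "overlapping entity offsets in sentence(s): ",
        paste(ov$sentence_id[ov$overlap], collapse = ", "), "; keeping all"
      ))
    }
  }

  pn <- xml2::xml_find_all(doc, ".//sentence/pair")
  pairs <- if (length(pn)) {
    ddi <- tolower(xml2::xml_attr(pn, "ddi"))
    type <- xml2::xml_attr(pn, "type")
    label <- ifelse(ddi == "true", type, "negative")
    if (anyNA(label)) {
      abort(paste0("pair with ddi=\"true\" but no type in sentence ",
                   xml2::xml_attr(xml2::xml_find_first(pn, "parent::sentence"), "id")[is.na(label)][1]))
    }
    tibble(
      sentence_id = xml2::xml_attr(xml2::xml_find_first(pn, "parent::sentence"), "id"),
      pair_id = xml2::xml_attr(pn, "id"),
      e0 = xml2::xml_attr(pn, "e1"),
      e1 = xml2::xml_attr(pn, "e2"),
      label = normalize_ddi_type(label)
    )
  } else {
    NULL
  }
  pairs <- bind_rows(pairs)
  if (nrow(pairs)) {
    known <- entities$entity_id
    bad <- setdiff(c(pairs$e0, pairs$e1), known)
    if (length(bad)) {
      abort(paste0("pair references unknown entity id(s): ",
                   paste(bad, collapse = ", "), " in ", file))
    }
  }
  list(sentences = sentences, entities = entities, pairs = pairs)
}

parse_char_offset <- function(off) {
  if (is.na(off)) abort("entity without charOffset attribute")
  spans <- strsplit(off, ";", fixed = TRUE)[[1]]
  first <- strsplit(spans[[1]], "-", fixed = TRUE)[[1]]
  if (length(first) != 2L) abort(paste0("malformed charOffset: ", off))
  a <- suppressWarnings(as.integer(first[1]))
  b <- suppressWarnings(as.integer(first[2]))
  if (is.na(a) || is.na(b) || b < a) abort(paste0("malformed charOffset: ", off))
  # inclusive "a-b" -> half-open [a, b+1)
  list(start = a, end = b + 1L, discontinuous = length(spans) > 1L)
}

#' Write a corpus in the DDIExtraction-2013 XML dialect
#'
#' Inverse of [read_ddi_corpus()]: writes one `document` element holding
#' every sentence, converting half-open offsets back to the dialect's
#' inclusive `charOffset` form and labels back to lower-case `type`
#' attributes (`ddi="false"` for Negative pairs).
#'
#' @param corpus a `ddi_corpus` object.
#' @param path output file path.
#' @param document_id id attribute for the document element.
#' @return `path`, invisibly.
#' @export
write_ddi_corpus <- function(corpus, path, document_id = "d0") {
  stopifnot(inherits(corpus, "ddi_corpus"))
  doc <- xml2::xml_new_root("document", id = document_id)
  for (i in seq_len(nrow(corpus$sentences))) {
    sid <- corpus$sentences$sentence_id[i]
    sn <- xml2::xml_add_child(doc, "sentence",
                              id = sid, text = corpus$sentences$text[i])
    ents <- corpus$entities[corpus$entities$sentence_id == sid, ]
    for (j in seq_len(nrow(ents))) {
      xml2::xml_add_child(
        sn, "entity",
        id = ents$entity_id[j],
        charOffset = paste0(ents$char_start[j], "-", ents$char_end[j] - 1L),
        type = ents$type[j],
        text = ents$text[j]
      )
    }
    prs <- corpus$pairs[corpus$pairs$sentence_id == sid, ]
    for (j in seq_len(nrow(prs))) {
      lab <- prs$label[j]
      if (lab == "Negative") {
        xml2::xml_add_child(sn, "pair", id = prs$pair_id[j],
                            e1 = prs$e0[j], e2 = prs$e1[j], ddi = "false")
      } else {
        xml2::xml_add_child(sn, "pair", id = prs$pair_id[j],
                            e1 = prs$e0[j], e2 = prs$e1[j], ddi = "true",
                            type = tolower(lab))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read dependency parses from a CoNLL-U file
#'
#' Sentence ids are taken from `# sent_id = ...` comment lines and must
#' match the corpus sentence ids. Multiword-token range lines (`3-4`) and
#' empty nodes (`5.1`) are skipped. Heads are kept 1-based with the root
#' stored as `NA`. Character offsets are read from `start_char=`/
#' `end_char=` MISC annotations when present, `NA` otherwise (they can be
#' recovered later against the sentence text, see [align_tokens_to_text()]).
#'
#' @param path path to a CoNLL-U file.
#' @return a tibble with one row per token: `sentence_id`, `tid` (1-based),
#'   `surface`, `lemma`, `pos`, `head` (1-based, `NA` for the root),
#'   `deprel`, `char_start`, `char_end` (half-open 0-based or `NA`).
#' @export
read_conllu <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- startsWith(lines, "#")
  is_sid <- is_comment & grepl("^#\\s*sent_id\\s*=", lines)
  sids <- sub("^#\\s*sent_id\\s*=\\s*(\\S+).*$", "\\1", lines[is_sid])
  block <- cumsum(is_sid)
  is_tok <- !is_comment & nzchar(lines)
  if (any(is_tok & block == 0L)) {
    abort(paste0("CoNLL-U block without '# sent_id' comment in ", path))
  }
  tl <- lines[is_tok]
  fields <- strsplit(tl, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    abort(paste0("malformed CoNLL-U line: ", tl[which(nf < 8L)[1]]))
  }
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i]
                            else "_", character(1))
  id <- col(1L)
  plain <- grepl("^[0-9]+$", id)  # drop multiword ranges and empty nodes
  sid_of <- sids[block[is_tok]][plain]
  form <- col(2L)[plain]
  lemma <- col(3L)[plain]
  upos <- col(4L)[plain]
  xpos <- col(5L)[plain]
  head <- as.integer(col(7L)[plain])
  misc <- col(10L)[plain]
  cs <- misc_field(misc, "start_char")
  ce <- misc_field(misc, "end_char")
  out <- tibble(
    sentence_id = sid_of,
    tid = as.integer(id[plain]),
    surface = form,
    lemma = ifelse(lemma == "_", form, lemma),
    pos = ifelse(upos == "_", xpos, upos),
    head = ifelse(is.na(head) | head == 0L, NA_integer_, head),
    deprel = col(8L)[plain],
    char_start = cs,
    char_end = ce
  )
  heads_by_sent <- split(out$head, factor(out$sentence_id,
                                          levels = unique(out$sentence_id)))
  for (sid in names(heads_by_sent)) check_head_tree(heads_by_sent[[sid]], sid)
  out
}

misc_field <- function(misc, key) {
  pat <- paste0(".*", key, "=(\\d+).*")
  hit <- grepl(paste0(key, "="), misc, fixed = TRUE)
  val <- rep(NA_integer_, length(misc))
  val[hit] <- as.integer(sub(pat, "\\1", misc[hit]))
  val
}

# Validates that the 1-based head vector (NA = root) is a single tree:
# exactly one root, all heads in bounds, no cycles.
check_head_tree <- function(head, sid) {
  n <- length(head)
  if (sum(is.na(head)) != 1L) {
    abort(paste0("sentence ", sid, ": expected exactly one root, found ",
                 sum(is.na(head))))
  }
  if (any(!is.na(head) & (head < 1L | head > n))) {
    abort(paste0("sentence ", sid, ": head index out of bounds"))
  }
  if (any(!is.na(head) & head == seq_len(n))) {
    abort(paste0("sentence ", sid, ": token is its own head"))
  }
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (!is.na(head[j])) {
      if (seen[j]) abort(paste0("sentence ", sid, ": cyclic head structure"))
      seen[j] <- TRUE
      j <- head[j]
    }
  }
  invisible(TRUE)
}

#' Write tokens to a CoNLL-U file
#'
#' Companion writer used by the synthetic-corpus generator; stores
#' character offsets in the MISC column (`start_char=`/`end_char=`).
#'
#' @param tokens tibble in the layout returned by [read_conllu()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_conllu <- function(tokens, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (sid in unique(tokens$sentence_id)) {
    tok <- tokens[tokens$sentence_id == sid, ]
    writeLines(paste0("# sent_id = ", sid), con)
    misc <- ifelse(
      is.na(tok$char_start), "_",
      paste0("start_char=", tok$char_start, "|end_char=", tok$char_end)
    )
    writeLines(paste(
      tok$tid, tok$surface, tok$lemma, tok$pos, "_", "_",
      ifelse(is.na(tok$head), 0L, tok$head), tok$deprel, "_", misc,
      sep = "\t"
    ), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Recover token character offsets from the sentence text
#'
#' Fills missing `char_start`/`char_end` by matching each surface form
#' left-to-right in the sentence text; errors if a surface cannot be found
#' after the previous token.
#'
#' @param tokens token tibble for one sentence.
#' @param text the sentence text.
#' @return the token tibble with offsets filled in.
#' @export
align_tokens_to_text <- function(tokens, text) {
  if (!anyNA(tokens$char_start)) return(tokens)
  cur <- 0L
  for (i in seq_len(nrow(tokens))) {
    if (!is.na(tokens$char_start[i])) { cur <- tokens$char_end[i]; next }
    hit <- regexpr(tokens$surface[i], substr(text, cur + 1L, nchar(text)),
                   fixed = TRUE)
    if (hit < 0L) {
      abort(paste0("token surface '", tokens$surface[i],
                   "' not found in sentence text after offset ", cur))
    }
    tokens$char_start[i] <- cur + as.integer(hit) - 1L
    tokens$char_end[i] <- tokens$char_start[i] + nchar(tokens$surface[i])
    cur <- tokens$char_end[i]
  }
  tokens
}

#' Resolve entity character offsets to token spans
#'
#' Maps each entity's half-open character range to the minimal contiguous
#' token range overlapping it.
#'
#' @param entities entity tibble for one sentence (needs `char_start`,
#'   `char_end`).
#' @param tokens token tibble for the same sentence with character offsets.
#' @param sentence_id used in error messages.
#' @return `entities` with integer columns `from_tok` and `to_tok`
#'   (1-based, inclusive).
#' @export
align_entity_offsets <- function(entities, tokens, sentence_id = "?") {
  from <- integer(nrow(entities))
  to <- integer(nrow(entities))
  for (i in seq_len(nrow(entities))) {
    a <- entities$char_start[i]
    b <- entities$char_end[i]
    hit <- which(tokens$char_end > a & tokens$char_start < b)
    if (length(hit) == 0L) {
      abort(paste0("entity ", entities$entity_id[i], " offsets [", a, ",", b,
                   ") not covered by any token in sentence ", sentence_id))
    }
    from[i] <- min(hit)
    to[i] <- max(hit)
  }
  entities$from_tok <- from
  entities$to_tok <- to
  entities
}
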