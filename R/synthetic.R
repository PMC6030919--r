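#' Specification for the synthetic DDI corpus generator
#'
#' The generator emulates the shape of sentence-level DDI corpora at desk
#' scale: each sentence carries two drug mentions and one labelled pair,
#' with a Negative-dominant class distribution, and the class signal for
#' positive labels is a planted trigger lemma placed on the dependency
#' path between the two mentions (with probability `p_trigger_on_sdp`;
#' off-path otherwise). Negative sentences never carry a trigger on the
#' path.
#'
#' With `trigger_only_on_sdp = TRUE` every sentence contains exactly one
#' token of each of the four trigger lemmas, so the bag of words is
#' uninformative and only the structural position of the trigger (on or
#' off the entity-to-entity path) determines the label: the signal is
#' carried by the SDP pathway alone.
#'
#' @param n_sentences number of sentences (one labelled pair each).
#' @param vocab_size number of filler word types.
#' @param max_len maximum sentence length in tokens (>= 6, <= 40);
#'   lengths are uniform on `min(8, max_len)..max_len`.
#' @param class_priors probabilities of Negative, Advice, Effect,
#'   Mechanism, Int (must sum to 1).
#' @param trigger_map named character vector: trigger lemma per positive
#'   class (4 distinct lemmas).
#' @param p_trigger_on_sdp probability that a positive sentence's trigger
#'   lies on the entity-to-entity path.
#' @param trigger_only_on_sdp plant off-path decoy triggers so the signal
#'   is SDP-only (see above).
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return an object of class `ddi_synth_spec`.
#' @export
synthetic_spec <- function(n_sentences = 2000L, vocab_size = 120L,
                           max_len = 16L,
                           class_priors = c(Negative = 0.8, Advice = 0.05,
                                            Effect = 0.05, Mechanism = 0.05,
                                            Int = 0.05),
                           trigger_map = c(Advice = "recommend",
                                           Effect = "enhance",
                                           Mechanism = "inhibit",
                                           Int = "interact"),
                           p_trigger_on_sdp = 1.0,
                           trigger_only_on_sdp = FALSE,
                           seed = 7L) {
  class_priors <- unlist(class_priors)
  trigger_map <- unlist(trigger_map)
  stopifnot(
    max_len >= 6L, max_len <= 40L,
    abs(sum(class_priors) - 1) < 1e-9,
    length(class_priors) == 5L,
    length(trigger_map) == 4L,
    !anyDuplicated(trigger_map),
    p_trigger_on_sdp >= 0, p_trigger_on_sdp <= 1
  )
  names(class_priors) <- DDI_CLASSES
  names(trigger_map) <- DDI_POSITIVE
  structure(
    list(n_sentences = as.integer(n_sentences),
         vocab_size = as.integer(vocab_size), max_len = as.integer(max_len),
         class_priors = class_priors, trigger_map = trigger_map,
         p_trigger_on_sdp = p_trigger_on_sdp,
         trigger_only_on_sdp = isTRUE(trigger_only_on_sdp),
         seed = as.integer(seed)),
    class = "ddi_synth_spec"
  )
}

#' Generate a synthetic annotated corpus with parses
#'
#' Builds `n_sentences` sentences according to a [synthetic_spec()]: the
#' dependency tree is constructed around a three-to-five node chain
#' `e0 - (filler) - centre - (filler) - e1`, every remaining token is
#' attached as a dependent of an already-placed node (so the tree and the
#' entity-to-entity path are valid by construction), and token order is a
#' random permutation of the nodes. Drug mentions are occasionally
#' two-token names to exercise span collapsing.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir optional directory; when given, writes `corpus.xml`,
#'   `parses.conllu` and `gold.jsonl` (pair_id/label records).
#' @return list with `corpus` (a `ddi_corpus`), `parses` (token tibble as
#'   from [read_conllu()]) and `gold` (tibble: sentence_id, pair_id,
#'   label).
#' @export
generate_corpus <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "ddi_synth_spec"))
  fillers <- sprintf("w%03d", seq_len(spec$vocab_size))
  fillers <- setdiff(fillers, spec$trigger_map)
  drugnames <- sprintf("dg%02d", 1:40)
  pos_pool <- c("NN", "JJ", "RB", "IN", "DT")
  rel_pool <- c("amod", "advmod", "case", "det", "conj", "nmod")

  out <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_sentences), function(s) {
      sid <- sprintf("s%05d", s)
      label <- sample(DDI_CLASSES, 1L, prob = spec$class_priors)
      Lmin <- min(8L, spec$max_len)
      L <- sample(Lmin:spec$max_len, 1L)
      gen_sentence(sid, label, L, spec, fillers, drugnames, pos_pool,
                   rel_pool)
    })
  })

  sids <- vapply(out, `[[`, "", "sid")
  L <- vapply(out, function(x) length(x$surface), integer(1))
  cat2 <- function(field) unlist(map(out, field), use.names = FALSE)
  corpus <- structure(
    list(
      sentences = tibble(sentence_id = sids,
                         text = vapply(out, `[[`, "", "text")),
      entities = tibble(
        sentence_id = rep(sids, each = 2L),
        entity_id = cat2("ent_id"),
        char_start = cat2("ent_start"),
        char_end = cat2("ent_end"),
        type = "drug",
        text = cat2("ent_text"),
        discontinuous = FALSE
      ),
      pairs = tibble(
        sentence_id = sids, pair_id = paste0(sids, ".p0"),
        e0 = vapply(out, function(x) x$ent_id[1], ""),
        e1 = vapply(out, function(x) x$ent_id[2], ""),
        label = vapply(out, `[[`, "", "label")
      )
    ),
    class = "ddi_corpus"
  )
  parses <- tibble(
    sentence_id = rep(sids, L),
    tid = unlist(lapply(L, seq_len), use.names = FALSE),
    surface = cat2("surface"),
    lemma = cat2("surface"),
    pos = cat2("pos"),
    head = cat2("head"),
    deprel = cat2("deprel"),
    char_start = cat2("char_start"),
    char_end = cat2("char_end")
  )
  gold <- corpus$pairs[, c("sentence_id", "pair_id", "label")]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ddi_corpus(corpus, file.path(out_dir, "corpus.xml"))
    write_conllu(parses, file.path(out_dir, "parses.conllu"))
    con <- file(file.path(out_dir, "gold.jsonl"), "w")
    for (i in seq_len(nrow(gold))) {
      writeLines(as.character(jsonlite::toJSON(as.list(gold[i, ]),
                                               auto_unbox = TRUE)), con)
    }
    close(con)
  }
  invisible(list(corpus = corpus, parses = parses, gold = gold))
}

# One synthetic sentence: returns sentence/entity/pair rows and tokens.
gen_sentence <- function(sid, label, L, spec, fillers, drugnames, pos_pool,
                         rel_pool) {
  positive <- label != "Negative"
  on_sdp <- positive && stats::runif(1) < spec$p_trigger_on_sdp
  decoys <- if (spec$trigger_only_on_sdp) {
    if (on_sdp) setdiff(spec$trigger_map, spec$trigger_map[label])
    else unname(spec$trigger_map)
  } else if (positive && !on_sdp) {
    spec$trigger_map[label]
  } else {
    character(0)
  }

  # node budget: e0, e1, centre chain, decoys, then optional extras
  base_need <- 3L + length(decoys)
  if (base_need > L) {
    abort(paste0("max_len too small for sentence structure (need ",
                 base_need, " tokens, have ", L, ")"))
  }
  slack <- L - base_need
  ex0 <- if (slack >= 1L && stats::runif(1) < 0.5) 1L else 0L
  ex1 <- if (slack - ex0 >= 1L && stats::runif(1) < 0.5) 1L else 0L
  slack <- slack - ex0 - ex1
  e0_two <- slack >= 1L && stats::runif(1) < 0.15
  slack <- slack - e0_two
  e1_two <- slack >= 1L && stats::runif(1) < 0.15

  centre_surface <- if (on_sdp) unname(spec$trigger_map[label])
                    else sample(fillers, 1L)

  # abstract nodes: 1 = e0 head, 2 = centre, 3 = e1 head, then extras,
  # decoys, entity second tokens, fillers
  surf <- c(sample(drugnames, 1L), centre_surface, sample(drugnames, 1L))
  pos <- c("NN", if (on_sdp) "VB" else sample(pos_pool, 1L), "NN")
  head_of <- c(2L, NA_integer_, 2L)   # may be rewired through extras
  rel <- c("nsubj", "root", "obj")
  n_nodes <- 3L
  add_node <- function(surface, postag, head, deprel) {
    force(surface); force(postag); force(head); force(deprel)
    n_nodes <<- n_nodes + 1L
    surf[n_nodes] <<- surface
    pos[n_nodes] <<- postag
    head_of[n_nodes] <<- head
    rel[n_nodes] <<- deprel
    n_nodes
  }
  if (ex0) {
    x0 <- add_node(sample(fillers, 1L), sample(pos_pool, 1L), 2L, "nmod")
    head_of[1L] <- x0
  }
  if (ex1) {
    x1 <- add_node(sample(fillers, 1L), sample(pos_pool, 1L), 2L, "nmod")
    head_of[3L] <- x1
  }
  path_nodes <- c(1L, if (ex0) 4L, 2L, if (ex1) 3L + ex0 + 1L, 3L)

  # decoy triggers attach as leaves, which can never lie on the e0-e1 path
  for (d in decoys) {
    add_node(d, "VB", sample(seq_len(n_nodes), 1L), "conj")
  }
  e0_second <- if (e0_two) add_node(sample(drugnames, 1L), "NN", 1L,
                                    "compound") else NA_integer_
  e1_second <- if (e1_two) add_node(sample(drugnames, 1L), "NN", 3L,
                                    "compound") else NA_integer_
  while (n_nodes < L) {
    add_node(sample(fillers, 1L), sample(pos_pool, 1L),
             sample(seq_len(n_nodes), 1L), sample(rel_pool, 1L))
  }

  # token order: random permutation, but an entity's second token sits
  # immediately after its head token so the mention is contiguous
  units <- as.list(seq_len(n_nodes))
  drop <- c(e0_second, e1_second)
  drop <- drop[!is.na(drop)]
  units <- units[!vapply(units, function(u) u %in% drop, logical(1))]
  if (!is.na(e0_second)) units[[which(vapply(units, identical, logical(1), 1L))]] <- c(1L, e0_second)
  if (!is.na(e1_second)) units[[which(vapply(units, identical, logical(1), 3L))]] <- c(3L, e1_second)
  order_units <- sample(units)
  node_order <- unlist(order_units)
  node_pos <- match(seq_len(n_nodes), node_order)

  o_surf <- surf[node_order]
  o_pos <- pos[node_order]
  o_head <- ifelse(is.na(head_of[node_order]), NA_integer_,
                   node_pos[head_of[node_order]])
  o_rel <- rel[node_order]
  starts <- cumsum(c(0L, nchar(o_surf[-n_nodes]) + 1L))
  ends <- starts + nchar(o_surf)
  text <- paste(o_surf, collapse = " ")

  ent_span <- function(first, second) {
    a <- node_pos[first]
    b <- if (is.na(second)) a else node_pos[second]
    c(min(a, b), max(a, b))
  }
  sp0 <- ent_span(1L, e0_second)
  sp1 <- ent_span(3L, e1_second)
  list(
    sid = sid, label = label, text = text,
    surface = o_surf, pos = o_pos, head = as.integer(o_head), deprel = o_rel,
    char_start = starts, char_end = ends,
    ent_id = paste0(sid, ".e", 0:1),
    ent_start = c(starts[sp0[1]], starts[sp1[1]]),
    ent_end = c(ends[sp0[2]], ends[sp1[2]]),
    ent_text = c(substr(text, starts[sp0[1]] + 1L, ends[sp0[2]]),
                 substr(text, starts[sp1[1]] + 1L, ends[sp1[2]]))
  )
}

#' Write deterministic toy word vectors in word2vec text format
#'
#' Every word receives a deterministic random vector; the four trigger
#' lemmas receive mutually orthogonal coordinate directions (disjoint
#' support), making the planted class signal linearly separable at the
#' embedding level. Non-trigger vectors are zero on the trigger
#' coordinates.
#'
#' @param words character vector of words (or a `ddi_vocab`, whose word
#'   list minus pad/unknown is used).
#' @param path output file.
#' @param dim vector dimensionality (>= number of triggers).
#' @param seed RNG seed.
#' @param triggers trigger lemmas to orthogonalise.
#' @return `path`, invisibly.
#' @export
make_toy_vectors <- function(words, path, dim = 200L, seed = 7L,
                             triggers = synthetic_spec()$trigger_map) {
  if (inherits(words, "ddi_vocab")) {
    words <- setdiff(words$word, c(VOCAB_PAD, VOCAB_UNK))
  }
  words <- unique(words)
  triggers <- unname(triggers)
  stopifnot(dim >= length(triggers) + 1L)
  vecs <- with_seed(seed, {
    m <- matrix(stats::rnorm(length(words) * dim) * 0.1, length(words), dim)
    m[, seq_along(triggers)] <- 0
    for (k in seq_along(triggers)) {
      i <- match(triggers[k], words)
      if (!is.na(i)) {
        m[i, ] <- 0
        m[i, k] <- 2
      }
    }
    m
  })
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(length(words), dim), con)
  for (i in seq_along(words)) {
    writeLines(paste(words[i], paste(sprintf("%.8g", vecs[i, ]),
                                     collapse = " ")), con)
  }
  invisible(path)
}
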