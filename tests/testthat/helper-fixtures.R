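# Shared fixtures and independent oracles for the test suite.

# A tiny hand-written corpus: sentence text, two or three drug mentions,
# labelled pairs. Returns the path of a temporary XML file.
write_tiny_xml <- function(body, path = tempfile(fileext = ".xml")) {
  writeLines(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
               "<document id=\"d1\">", body, "</document>"), path)
  path
}

tiny_corpus_xml <- function() {
  write_tiny_xml(c(
    '<sentence id="s1" text="aspirin raises warfarin level">',
    '<entity id="s1.e0" charOffset="0-6" type="drug" text="aspirin"/>',
    '<entity id="s1.e1" charOffset="15-22" type="drug" text="warfarin"/>',
    '<pair id="s1.p0" e1="s1.e0" e2="s1.e1" ddi="false"/>',
    "</sentence>"
  ))
}

tiny_conllu <- function(lines, path = tempfile(fileext = ".conllu")) {
  writeLines(lines, path)
  path
}

# CoNLL-U block for "aspirin raises warfarin level": raises is the root,
# aspirin its subject, warfarin modified by level.
tiny_conllu_s1 <- function() {
  tiny_conllu(c(
    "# sent_id = s1",
    "1\taspirin\taspirin\tNN\t_\t_\t2\tnsubj\t_\t_",
    "2\traises\traise\tVB\t_\t_\t0\troot\t_\t_",
    "3\twarfarin\twarfarin\tNN\t_\t_\t2\tobj\t_\t_",
    "4\tlevel\tlevel\tNN\t_\t_\t3\tnmod\t_\t_",
    ""
  ))
}

# Token tibble constructor for unit fixtures (1-based heads, NA root).
tok_tbl <- function(surface, head, deprel = rep("dep", length(surface)),
                    pos = rep("NN", length(surface)), sid = "s") {
  tibble::tibble(
    sentence_id = sid, tid = seq_along(surface), surface = surface,
    lemma = surface, pos = pos, head = as.integer(head), deprel = deprel,
    char_start = NA_integer_, char_end = NA_integer_
  )
}

# Random dependency tree over n tokens: each node after the first attaches
# to a uniformly chosen earlier node, then labels are permuted.
random_tree_tokens <- function(n) {
  perm <- sample.int(n)
  head <- rep(NA_integer_, n)
  for (k in 2:n) head[perm[k]] <- perm[sample.int(k - 1L, 1L)]
  tok_tbl(sprintf("w%d", seq_len(n)), head,
          deprel = sprintf("r%d", seq_len(n)))
}

# Exhaustive enumeration of all simple paths between src and dst in the
# undirected view of the dependency graph; returns the shortest.
enumerate_shortest_path <- function(tokens, src, dst) {
  n <- nrow(tokens)
  adj <- lapply(seq_len(n), function(v) integer(0))
  for (i in seq_len(n)) {
    h <- tokens$head[i]
    if (!is.na(h)) {
      adj[[i]] <- c(adj[[i]], h)
      adj[[h]] <- c(adj[[h]], i)
    }
  }
  best <- NULL
  walk <- function(v, path) {
    if (v == dst) {
      if (is.null(best) || length(path) < length(best)) best <<- path
      return()
    }
    for (w in adj[[v]]) {
      if (!w %in% path) walk(w, c(path, w))
    }
  }
  walk(src, src)
  best
}

# Independently coded softmax attention oracle (plain loops, no reuse of
# package internals).
oracle_attention <- function(wv, e0, e1) {
  m <- nrow(wv)
  th <- function(ev) {
    logit <- numeric(m)
    for (i in seq_len(m)) logit[i] <- sum(wv[i, ] * ev)
    e <- exp(logit - max(logit))
    e / sum(e)
  }
  t0 <- th(e0)
  t1 <- th(e1)
  list(theta0 = t0, theta1 = t1, joint = (t0 + t1) / 2)
}

# Small prepared instance set from the synthetic generator, cached per
# session.
synth_instances <- local({
  cache <- new.env()
  function(n = 40, seed = 13, max_len = 12, ...) {
    key <- paste(n, seed, max_len, ...)
    if (is.null(cache[[key]])) {
      d <- tempfile("synth")
      dir.create(d)
      spec <- synthetic_spec(n_sentences = n, seed = seed, max_len = max_len,
                             ...)
      generate_corpus(spec, out_dir = d)
      cache[[key]] <- prepare_instances(file.path(d, "corpus.xml"),
                                        file.path(d, "parses.conllu"))
    }
    cache[[key]]
  }
})

# Checks that a head vector is a single tree (one root, acyclic).
expect_tree <- function(head) {
  expect_equal(sum(is.na(head)), 1L)
  n <- length(head)
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (!is.na(head[j])) {
      expect_false(seen[j])
      seen[j] <- TRUE
      j <- head[j]
    }
  }
}
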