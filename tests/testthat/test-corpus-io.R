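test_that("a pair with ddi='false' maps to one Negative instance", {
  corpus <- read_ddi_corpus(tiny_corpus_xml())
  expect_equal(nrow(corpus$sentences), 1L)
  expect_equal(nrow(corpus$entities), 2L)
  expect_equal(corpus$pairs$label, "Negative")
  inst <- build_instances(corpus, read_conllu(tiny_conllu_s1()))
  expect_equal(nrow(inst), 1L)
  expect_equal(inst$label, "Negative")
  expect_equal(inst$e0_from, 1L)
  expect_equal(inst$e1_from, 3L)
})

test_that("every pair element yields exactly one instance", {
  xml <- write_tiny_xml(c(
    '<sentence id="s2" text="aa bb cc">',
    '<entity id="s2.e0" charOffset="0-1" type="drug" text="aa"/>',
    '<entity id="s2.e1" charOffset="3-4" type="drug" text="bb"/>',
    '<entity id="s2.e2" charOffset="6-7" type="drug" text="cc"/>',
    '<pair id="s2.p0" e1="s2.e0" e2="s2.e1" ddi="true" type="effect"/>',
    '<pair id="s2.p1" e1="s2.e0" e2="s2.e2" ddi="true" type="advise"/>',
    '<pair id="s2.p2" e1="s2.e1" e2="s2.e2" ddi="false"/>',
    "</sentence>"
  ))
  corpus <- read_ddi_corpus(xml)
  expect_equal(nrow(corpus$pairs), 3L)
  expect_setequal(corpus$pairs$label, c("Effect", "Advice", "Negative"))
  conllu <- tiny_conllu(c(
    "# sent_id = s2",
    "1\taa\t_\tNN\t_\t_\t2\tnsubj\t_\t_",
    "2\tbb\t_\tNN\t_\t_\t0\troot\t_\t_",
    "3\tcc\t_\tNN\t_\t_\t2\tobj\t_\t_", ""
  ))
  inst <- build_instances(corpus, read_conllu(conllu))
  expect_equal(nrow(inst), 3L)
  expect_equal(sort(inst$pair_id), c("s2.p0", "s2.p1", "s2.p2"))
})

test_that("XML round-trip preserves entity and pair attribute sets", {
  spec <- synthetic_spec(n_sentences = 10, seed = 3)
  g <- generate_corpus(spec)
  path <- tempfile(fileext = ".xml")
  write_ddi_corpus(g$corpus, path)
  back <- read_ddi_corpus(path)
  canon <- function(corpus) {
    list(
      s = dplyr::arrange(corpus$sentences, sentence_id),
      e = dplyr::arrange(corpus$entities, entity_id),
      p = dplyr::arrange(corpus$pairs, pair_id)
    )
  }
  expect_equal(canon(back), canon(g$corpus))
  # and a second round trip is byte-identical
  path2 <- tempfile(fileext = ".xml")
  write_ddi_corpus(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("a directory of XML files is read as one corpus", {
  d <- tempfile("xmldir")
  dir.create(d)
  for (k in 1:2) {
    body <- c(
      sprintf('<sentence id="d%d.s1" text="aa bb">', k),
      sprintf('<entity id="d%d.s1.e0" charOffset="0-1" type="drug" text="aa"/>', k),
      sprintf('<entity id="d%d.s1.e1" charOffset="3-4" type="drug" text="bb"/>', k),
      sprintf('<pair id="d%d.s1.p0" e1="d%d.s1.e0" e2="d%d.s1.e1" ddi="false"/>', k, k, k),
      "</sentence>"
    )
    write_tiny_xml(body, file.path(d, sprintf("f%d.xml", k)))
  }
  corpus <- read_ddi_corpus(d)
  expect_equal(nrow(corpus$sentences), 2L)
  expect_equal(nrow(corpus$pairs), 2L)
  expect_error(read_ddi_corpus(tempfile("empty")), "no XML files")
})

test_that("malformed XML and dangling entity references are hard errors", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<document><sentence id=", bad)
  expect_error(read_ddi_corpus(bad), "malformed XML")
  dangling <- write_tiny_xml(c(
    '<sentence id="s1" text="aa bb">',
    '<entity id="s1.e0" charOffset="0-1" type="drug" text="aa"/>',
    '<pair id="s1.p0" e1="s1.e0" e2="s1.eX" ddi="false"/>',
    "</sentence>"
  ))
  expect_error(read_ddi_corpus(dangling), "unknown entity")
})

test_that("discontinuous charOffsets keep the first span with a warning", {
  xml <- write_tiny_xml(c(
    '<sentence id="s1" text="aa bb cc dd">',
    '<entity id="s1.e0" charOffset="0-1;6-7" type="drug" text="aa cc"/>',
    '<entity id="s1.e1" charOffset="3-4" type="drug" text="bb"/>',
    '<pair id="s1.p0" e1="s1.e0" e2="s1.e1" ddi="false"/>',
    "</sentence>"
  ))
  expect_warning(corpus <- read_ddi_corpus(xml), "discontinuous")
  e0 <- corpus$entities[corpus$entities$entity_id == "s1.e0", ]
  expect_equal(c(e0$char_start, e0$char_end), c(0L, 2L))
  expect_true(e0$discontinuous)
})

test_that("overlapping entity offsets warn but both are kept", {
  xml <- write_tiny_xml(c(
    '<sentence id="s1" text="aabb cc">',
    '<entity id="s1.e0" charOffset="0-3" type="drug" text="aabb"/>',
    '<entity id="s1.e1" charOffset="2-3" type="drug" text="bb"/>',
    "</sentence>"
  ))
  expect_warning(corpus <- read_ddi_corpus(xml), "overlapping")
  expect_equal(nrow(corpus$entities), 2L)
})

test_that("CoNLL-U heads shift to NA-rooted 1-based form", {
  p <- tiny_conllu(c(
    "# sent_id = x",
    "1\ta\t_\tNN\t_\t_\t2\tdep\t_\t_",
    "2\tb\t_\tVB\t_\t_\t0\troot\t_\t_",
    "3\tc\t_\tNN\t_\t_\t2\tdep\t_\t_", ""
  ))
  tok <- read_conllu(p)
  expect_equal(tok$head, c(2L, NA_integer_, 2L))
  expect_equal(tok$tid, 1:3)
})

test_that("multiword ranges and empty nodes are skipped", {
  p <- tiny_conllu(c(
    "# sent_id = x",
    "1\tdon't\t_\tNN\t_\t_\t3\tdep\t_\t_",
    "2-3\tcannot\t_\t_\t_\t_\t_\t_\t_\t_",
    "2\tcan\t_\tMD\t_\t_\t3\taux\t_\t_",
    "3\tnot\t_\tVB\t_\t_\t0\troot\t_\t_",
    "3.1\telided\t_\t_\t_\t_\t_\t_\t_\t_",
    ""
  ))
  tok <- read_conllu(p)
  expect_equal(nrow(tok), 3L)  # one row per plain integer id
  expect_false("cannot" %in% tok$surface)
  expect_false("elided" %in% tok$surface)
})

test_that("cyclic heads and missing parses are hard errors", {
  cyc <- tiny_conllu(c(
    "# sent_id = x",
    "1\ta\t_\tNN\t_\t_\t2\tdep\t_\t_",
    "2\tb\t_\tNN\t_\t_\t1\tdep\t_\t_",
    "3\tc\t_\tNN\t_\t_\t0\troot\t_\t_", ""
  ))
  expect_error(read_conllu(cyc), "cyclic")
  corpus <- read_ddi_corpus(tiny_corpus_xml())
  other <- read_conllu(tiny_conllu(c(
    "# sent_id = not_s1",
    "1\ta\t_\tNN\t_\t_\t0\troot\t_\t_", ""
  )))
  expect_error(build_instances(corpus, other), "s1")
})

test_that("entity offsets resolve to minimal covering token spans", {
  tok <- tok_tbl(c("aspirin", "based", "drugs"), c(3L, 3L, NA))
  tok$char_start <- c(0L, 8L, 14L)
  tok$char_end <- c(7L, 13L, 19L)
  one <- align_entity_offsets(
    tibble::tibble(entity_id = "e", char_start = 0L, char_end = 7L), tok)
  expect_equal(c(one$from_tok, one$to_tok), c(1L, 1L))
  two <- align_entity_offsets(
    tibble::tibble(entity_id = "e", char_start = 0L, char_end = 13L), tok)
  expect_equal(c(two$from_tok, two$to_tok), c(1L, 2L))
  expect_error(
    align_entity_offsets(
      tibble::tibble(entity_id = "e", char_start = 100L, char_end = 103L),
      tok),
    "not covered"
  )
})

test_that("resolved spans always contain the entity text (synthetic)", {
  spec <- synthetic_spec(n_sentences = 25, seed = 5)
  g <- generate_corpus(spec)
  for (sid in g$corpus$sentences$sentence_id) {
    text <- g$corpus$sentences$text[g$corpus$sentences$sentence_id == sid]
    tok <- g$parses[g$parses$sentence_id == sid, ]
    ents <- align_entity_offsets(
      g$corpus$entities[g$corpus$entities$sentence_id == sid, ], tok, sid)
    for (j in seq_len(nrow(ents))) {
      span_text <- substr(text, tok$char_start[ents$from_tok[j]] + 1L,
                          tok$char_end[ents$to_tok[j]])
      expect_true(grepl(ents$text[j], span_text, fixed = TRUE))
    }
  }
})

test_that("anonymization replaces targets and preserves token count for single-token spans", {
  corpus <- read_ddi_corpus(tiny_corpus_xml())
  inst <- build_instances(corpus, read_conllu(tiny_conllu_s1()))
  anon <- anonymize_instances(inst)
  tok <- anon$tokens[[1]]
  expect_equal(nrow(tok), 4L)
  expect_equal(tok$surface[anon$e0_tok], "drug0")
  expect_equal(tok$surface[anon$e1_tok], "drug1")
  expect_equal(anon$e0_words[[1]], "aspirin")
  expect_true(all(is.na(tok$char_start)))
})

test_that("multi-token spans collapse onto the internal head with valid heads", {
  # "acetyl salicylic acid raises warfarin": 3-token e0 headed by "acid"
  tok <- tok_tbl(c("acetyl", "salicylic", "acid", "raises", "warfarin"),
                 c(3L, 3L, 4L, NA, 4L),
                 deprel = c("amod", "amod", "nsubj", "root", "obj"))
  inst <- tibble::tibble(
    sentence_id = "s", pair_id = "p", label = "Mechanism",
    e0_id = "e0", e0_from = 1L, e0_to = 3L, e0_text = "acetyl salicylic acid",
    e0_type = "drug",
    e1_id = "e1", e1_from = 5L, e1_to = 5L, e1_text = "warfarin",
    e1_type = "drug",
    tokens = list(tok),
    others = list(tibble::tibble(entity_id = character(0),
                                 from_tok = integer(0), to_tok = integer(0)))
  )
  anon <- anonymize_instances(inst)
  tok2 <- anon$tokens[[1]]
  expect_equal(nrow(tok2), 3L)  # token count decreases by 2
  expect_equal(tok2$surface, c("drug0", "raises", "drug1"))
  expect_equal(tok2$head, c(2L, NA, 2L))
  expect_equal(anon$e0_words[[1]], c("acetyl", "salicylic", "acid"))
  expect_tree(tok2$head)
})

test_that("non-target drug mentions become drugn", {
  xml <- write_tiny_xml(c(
    '<sentence id="s3" text="aa bb cc dd">',
    '<entity id="s3.e0" charOffset="0-1" type="drug" text="aa"/>',
    '<entity id="s3.e1" charOffset="3-4" type="drug" text="bb"/>',
    '<entity id="s3.e2" charOffset="6-7" type="drug" text="cc"/>',
    '<pair id="s3.p0" e1="s3.e0" e2="s3.e1" ddi="false"/>',
    "</sentence>"
  ))
  conllu <- tiny_conllu(c(
    "# sent_id = s3",
    "1\taa\t_\tNN\t_\t_\t4\tdep\t_\t_",
    "2\tbb\t_\tNN\t_\t_\t4\tdep\t_\t_",
    "3\tcc\t_\tNN\t_\t_\t4\tdep\t_\t_",
    "4\tdd\t_\tVB\t_\t_\t0\troot\t_\t_", ""
  ))
  inst <- build_instances(read_ddi_corpus(xml), read_conllu(conllu))
  anon <- anonymize_instances(inst)
  expect_equal(anon$tokens[[1]]$surface, c("drug0", "drug1", "drugn", "dd"))
  keep <- anonymize_instances(inst, anonymize_others = FALSE)
  expect_equal(keep$tokens[[1]]$surface[3], "cc")
})

test_that("anonymization keeps the parse a tree on synthetic instances", {
  inst <- synth_instances(n = 60, seed = 21)
  for (i in seq_len(nrow(inst))) {
    expect_tree(inst$tokens[[i]]$head)
  }
  # instance count equals pair count by construction
  expect_equal(nrow(inst), 60L)
})

test_that("JSON-lines round-trip preserves instances", {
  inst <- synth_instances(n = 15, seed = 9)
  path <- tempfile(fileext = ".jsonl")
  write_instances_jsonl(inst, path)
  back <- read_instances_jsonl(path)
  expect_equal(nrow(back), nrow(inst))
  expect_equal(back$label, inst$label)
  expect_equal(back$e0_tok, inst$e0_tok)
  expect_equal(back$sdp, inst$sdp)
  for (i in seq_len(nrow(inst))) {
    expect_equal(back$tokens[[i]]$surface, inst$tokens[[i]]$surface)
    expect_equal(back$tokens[[i]]$head, inst$tokens[[i]]$head)
  }
})
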