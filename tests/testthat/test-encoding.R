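make_vocab_fixture <- function() {
  inst <- synth_instances(n = 20, seed = 31)
  build_vocab(inst)
}

test_that("vocabulary reserves pad/unk and always contains placeholders", {
  inst <- synth_instances(n = 20, seed = 31)
  v <- build_vocab(inst, min_count = 1L)
  expect_equal(v$word[v$pad_id], "<pad>")
  expect_equal(v$word[v$unk_id], "<unk>")
  expect_true(all(c("drug0", "drug1", "drugn") %in% v$word))
  # words under min_count map to unk
  v2 <- build_vocab(inst, min_count = 1000L)
  rare <- setdiff(unique(inst$tokens[[1]]$surface),
                  c(v2$word, unlist(inst$e0_words), unlist(inst$e1_words)))
  if (length(rare)) {
    expect_equal(vocab_id(v2, rare[1]), v2$unk_id)
  }
  expect_error(build_vocab(inst[0, ]), "empty")
})

test_that("min_count=1 vocabulary size is distinct words plus specials", {
  tok <- tok_tbl(c("u1", "u2", "u3", "u4", "u5"), c(2L, NA, 2L, 2L, 2L))
  inst <- tibble::tibble(
    tokens = list(tok), e0_words = list("u1"), e1_words = list("u3")
  )
  v <- build_vocab(inst)
  expect_equal(length(v$word), 5L + 2L + 3L)  # words + pad/unk + placeholders
})

test_that("vocabulary serialization round-trips id assignments", {
  v <- make_vocab_fixture()
  p <- tempfile(fileext = ".json")
  write_vocab(v, p)
  v2 <- read_vocab(p)
  expect_identical(v2$word, v$word)
  expect_identical(v2$pos, v$pos)
  words <- sample(v$word, 10)
  expect_identical(vocab_id(v, words), vocab_id(v2, words))
})

test_that("word vectors load exactly for file tokens and reproducibly otherwise", {
  v <- make_vocab_fixture()
  p <- tempfile(fileext = ".txt")
  target <- v$word[10]
  writeLines(c("1 4", paste(target, "0.25 -1 0.5 3")), p)
  e1 <- init_embeddings(v, d_word = 4L, d_pos = 2L, d_dis = 2L, clip = 3L,
                        seed = 5L, vectors = p)
  expect_equal(unname(e1$word[10, ]), c(0.25, -1, 0.5, 3))
  expect_equal(e1$coverage$n_hit, 1L)
  # absent tokens: same seed, same rows
  e2 <- init_embeddings(v, d_word = 4L, d_pos = 2L, d_dis = 2L, clip = 3L,
                        seed = 5L, vectors = p)
  expect_identical(e1$word, e2$word)
  # dim mismatch is a hard error
  e0 <- init_embeddings(v, d_word = 3L, d_pos = 2L, d_dis = 2L, clip = 3L,
                        seed = 5L)
  expect_error(load_word_vectors(p, v, e0), "does not match")
})

test_that("coverage counts the vocabulary/file intersection", {
  v <- make_vocab_fixture()
  p <- tempfile(fileext = ".txt")
  hits <- v$word[5:9]
  writeLines(c(
    paste(length(hits) + 1, 3),
    vapply(hits, function(w) paste(w, "1 2 3"), ""),
    "zzz_not_in_vocab 9 9 9"
  ), p)
  e <- init_embeddings(v, d_word = 3L, d_pos = 2L, d_dis = 2L, clip = 3L,
                       seed = 1L, vectors = p)
  expect_equal(e$coverage$n_hit, length(intersect(v$word, c(hits, "zzz_not_in_vocab"))))
})

test_that("position ids clip and are antisymmetric before clipping", {
  expect_equal(position_index(5L, 5L, 30L), 31L)       # distance 0
  expect_equal(position_index(50L, 5L, 30L), 61L)      # 45 clipped to 30
  expect_equal(position_index(1L, 40L, 30L), 1L)       # -39 clipped to -30
  set.seed(2)
  for (rep in 1:50) {
    i <- sample(100, 1); j <- sample(100, 1)
    d1 <- position_index(i, j, 30L) - 31L
    d2 <- position_index(j, i, 30L) - 31L
    expect_equal(d1, max(-30L, min(30L, i - j)))
    if (abs(i - j) <= 30L) expect_equal(d1, -d2)
  }
})

test_that("entity embedding averages the original word vectors", {
  v <- make_vocab_fixture()
  e <- init_embeddings(v, d_word = 6L, d_pos = 2L, d_dis = 2L, clip = 3L,
                       seed = 4L)
  w1 <- v$word[12]; w2 <- v$word[13]
  one <- embed_entity(w1, v, e, dist_to_other = 2L)
  expect_equal(one[1:6], unname(e$word[12, ]))
  two <- embed_entity(c(w1, w2), v, e, dist_to_other = 2L)
  expect_equal(two[1:6], unname((e$word[12, ] + e$word[13, ]) / 2))
  # POS channel is the noun row; position channels are 0 and the signed
  # distance to the other entity
  expect_equal(two[7:8], unname(e$pos[vocab_id(v, "NN", "pos"), ]))
  expect_equal(two[9:10], unname(e$dis[position_index(0L, 0L, 3L), ]))
  expect_equal(two[11:12], unname(e$dis[position_index(2L, 0L, 3L), ]))
})

test_that("out-of-vocabulary entity words average seeded unk rows", {
  v <- make_vocab_fixture()
  e <- init_embeddings(v, d_word = 5L, d_pos = 2L, d_dis = 2L, clip = 3L,
                       seed = 8L)
  oov <- c("qqq1", "qqq2", "qqq3")
  got <- embed_entity(oov, v, e, dist_to_other = 1L)[1:5]
  # all three map to the single unk row, so the mean equals that row
  expect_equal(got, unname(e$word[v$unk_id, ]))
  e2 <- init_embeddings(v, d_word = 5L, d_pos = 2L, d_dis = 2L, clip = 3L,
                        seed = 8L)
  expect_identical(got, embed_entity(oov, v, e2, dist_to_other = 1L)[1:5])
})

test_that("identical word vectors give uniform attention; m=1 gives weight 1", {
  wv <- matrix(1, 5, 3)
  a <- attention_weights(wv, c(1, 0, 0), c(0, 2, 0))
  expect_equal(a$theta0, rep(0.2, 5))
  expect_equal(a$theta1, rep(0.2, 5))
  expect_equal(a$joint, rep(0.2, 5))
  one <- attention_weights(matrix(rnorm(3), 1, 3), rnorm(3), rnorm(3))
  expect_equal(one$joint, 1)
})

test_that("attention matches the independent softmax oracle", {
  wv <- rbind(c(1, 0), c(0, 1), c(1, 1))
  a <- attention_weights(wv, c(1, 0), c(0, 1))
  o <- oracle_attention(wv, c(1, 0), c(0, 1))
  expect_equal(a$joint, o$joint, tolerance = 1e-10)
  expect_equal(a$theta0, o$theta0, tolerance = 1e-10)
  set.seed(14)
  for (rep in 1:20) {
    m <- sample(3:20, 1)
    wv <- matrix(rnorm(m * 4), m, 4)
    e0 <- rnorm(4); e1 <- rnorm(4)
    a <- attention_weights(wv, e0, e1)
    o <- oracle_attention(wv, e0, e1)
    expect_equal(a$joint, o$joint, tolerance = 1e-10)
    expect_equal(sum(a$theta0), 1, tolerance = 1e-6)
    expect_equal(sum(a$theta1), 1, tolerance = 1e-6)
    expect_equal(sum(a$joint), 1, tolerance = 1e-6)
  }
})

test_that("attention is invariant to a constant logit shift", {
  set.seed(6)
  wv <- matrix(rnorm(12), 4, 3)
  e0 <- rnorm(3); e1 <- rnorm(3)
  base <- attention_weights(wv, e0, e1)
  # adding 5 to every logit = appending a constant-dot direction; emulate
  # by extending vectors with a shared component
  wv2 <- cbind(wv, 1)
  shifted <- attention_weights(wv2, c(e0, 5), c(e1, 5))
  expect_equal(shifted$joint, base$joint, tolerance = 1e-12)
})

test_that("attend scales whole rows by the joint weight", {
  z <- matrix(rnorm(4 * 6), 4, 6)
  w <- structure(list(theta0 = rep(0.25, 4), theta1 = rep(0.25, 4),
                      joint = rep(0.25, 4)), class = "ddi_attention")
  expect_equal(attend(z, w), z / 4)
  w1 <- structure(list(theta0 = c(1, 0, 0, 0), theta1 = c(1, 0, 0, 0),
                       joint = c(1, 0, 0, 0)), class = "ddi_attention")
  expect_equal(attend(z, w1)[1, ], z[1, ])
  # column sums match a brute-force loop
  set.seed(5)
  wts <- runif(4); wts <- wts / sum(wts)
  wr <- structure(list(theta0 = wts, theta1 = wts, joint = wts),
                  class = "ddi_attention")
  got <- colSums(attend(z, wr))
  want <- numeric(6)
  for (i in 1:4) for (j in 1:6) want[j] <- want[j] + wts[i] * z[i, j]
  expect_equal(got, want)
  expect_error(attend(z[1:3, ], wr), "3 rows")
})

test_that("five-part segmentation partitions the sentence", {
  inst <- synth_instances(n = 50, seed = 23)
  v <- build_vocab(inst)
  e <- init_embeddings(v, d_word = 8L, d_pos = 3L, d_dis = 2L, clip = 10L,
                       seed = 2L)
  for (i in seq_len(nrow(inst))) {
    enc <- encode_instance(inst[i, ], v, e)
    m <- nrow(inst$tokens[[i]])
    expect_equal(nrow(enc$sub0) + nrow(enc$sub1) + nrow(enc$sub2) + 2L, m)
    expect_gte(nrow(enc$sdp), 2L)
    expect_equal(length(enc$ent0), 8L + 3L + 2L * 2L)
  }
})

test_that("entity-initial and adjacent-entity boundaries give empty segments", {
  tok <- tok_tbl(c("drug0", "drug1", "x"), c(2L, NA, 2L))
  inst <- tibble::tibble(
    sentence_id = "s", pair_id = "p", label = "Int",
    tokens = list(tok), e0_tok = 1L, e1_tok = 2L,
    e0_words = list("a"), e1_words = list("b"),
    sdp = list(c(1L, 2L)), sdp_rels = list("dep"), sdp_dirs = list("DH")
  )
  v <- build_vocab(inst)
  e <- init_embeddings(v, d_word = 4L, d_pos = 2L, d_dis = 2L, clip = 3L,
                       seed = 1L)
  enc <- encode_instance(inst[1, ], v, e)
  expect_equal(nrow(enc$sub0), 0L)
  expect_equal(nrow(enc$sub1), 0L)
  expect_equal(nrow(enc$sub2), 1L)
})

test_that("encoding a fixed instance is deterministic given seed and tables", {
  inst <- synth_instances(n = 10, seed = 41)
  v <- build_vocab(inst)
  e <- init_embeddings(v, d_word = 6L, d_pos = 2L, d_dis = 2L, clip = 5L,
                       seed = 9L)
  a <- encode_instance(inst[3, ], v, e)
  b <- encode_instance(inst[3, ], v, e)
  expect_identical(a$sub0, b$sub0)
  expect_identical(a$sdp, b$sdp)
  expect_identical(a$ent0, b$ent0)
})

test_that("SDP attention is normalised over the path only", {
  inst <- synth_instances(n = 10, seed = 41)
  v <- build_vocab(inst)
  e <- init_embeddings(v, d_word = 6L, d_pos = 2L, d_dis = 2L, clip = 5L,
                       seed = 9L)
  i <- which(lengths(inst$sdp) >= 3)[1]
  enc <- encode_instance(inst[i, ], v, e)
  expect_equal(sum(enc$att_sdp$joint), 1, tolerance = 1e-9)
  expect_equal(length(enc$att_sdp$joint), length(inst$sdp[[i]]))
})
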