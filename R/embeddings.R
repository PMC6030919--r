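#' Initialise embedding tables
#'
#' Creates the word, POS and position embedding tables. Word and POS rows
#' are drawn from a standard normal scaled by 0.1; position rows follow a
#' standard normal. The position table holds one row per clipped signed
#' distance in `-clip..clip` plus a dedicated pad row. All draws are
#' reproducible from `seed`. When `vectors` is given, in-vocabulary
#' tokens present in the word2vec text file keep their file vectors.
#'
#' @param vocab a `ddi_vocab`.
#' @param d_word,d_pos,d_dis channel dimensions (defaults 200, 10, 10).
#' @param clip maximum absolute signed distance (default 30).
#' @param seed RNG seed for random rows.
#' @param vectors optional path to word vectors in word2vec text format.
#' @param d_rel width of the optional dependency-relation table
#'   (full token-vector width, used only for SDP relation interleaving).
#' @return an object of class `ddi_embeddings`: list of matrices `word`,
#'   `pos`, `dis`, `rel`, the dimensions, `clip`, and (when `vectors` is
#'   given) a `coverage` list with `n_vocab`, `n_hit` and `hit_rate`.
#' @export
init_embeddings <- function(vocab, d_word = 200L, d_pos = 10L, d_dis = 10L,
                            clip = 30L, seed = 42L, vectors = NULL,
                            d_rel = d_word + d_pos + 2L * d_dis) {
  stopifnot(d_word > 0L, d_pos > 0L, d_dis > 0L, clip > 0L)
  tabs <- with_seed(seed, {
    word <- matrix(stats::rnorm(length(vocab$word) * d_word) * 0.1,
                   nrow = length(vocab$word))
    pos <- matrix(stats::rnorm(length(vocab$pos) * d_pos) * 0.1,
                  nrow = length(vocab$pos))
    dis <- matrix(stats::rnorm((2L * clip + 2L) * d_dis),
                  nrow = 2L * clip + 2L)
    rel <- matrix(stats::rnorm(length(vocab$rel) * d_rel) * 0.1,
                  nrow = length(vocab$rel))
    list(word = word, pos = pos, dis = dis, rel = rel)
  })
  rownames(tabs$word) <- vocab$word
  rownames(tabs$pos) <- vocab$pos
  rownames(tabs$rel) <- vocab$rel
  out <- structure(
    c(tabs, list(d_word = d_word, d_pos = d_pos, d_dis = d_dis, clip = clip,
                 coverage = NULL)),
    class = "ddi_embeddings"
  )
  if (!is.null(vectors)) out <- load_word_vectors(vectors, vocab, out)
  out
}

#' Load pretrained word vectors into the word table
#'
#' Reads a word2vec text file (`count dim` header, then one
#' `token v1 ... vdim` line per token). In-vocabulary tokens found in the
#' file receive their file vectors exactly; all other rows keep their
#' seeded random initialisation.
#'
#' @param path word2vec text file.
#' @param vocab a `ddi_vocab`.
#' @param embeddings a `ddi_embeddings` whose word table is updated.
#' @return `embeddings` with the word table overwritten at hit rows and a
#'   `coverage` report (`n_vocab`, `n_hit`, `hit_rate`).
#' @export
load_word_vectors <- function(path, vocab, embeddings) {
  stopifnot(inherits(embeddings, "ddi_embeddings"))
  lines <- readLines(path, encoding = "UTF-8")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  dim <- as.integer(header[2])
  if (is.na(dim) || dim != embeddings$d_word) {
    abort(paste0("word vector dimension ", dim,
                 " does not match configured d_word ", embeddings$d_word))
  }
  n_hit <- 0L
  for (ln in lines[-1]) {
    if (!nzchar(ln)) next
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    id <- match(f[1], vocab$word)
    if (is.na(id)) next
    v <- as.numeric(f[-1])
    if (length(v) != dim) abort(paste0("bad vector line for token ", f[1]))
    embeddings$word[id, ] <- v
    n_hit <- n_hit + 1L
  }
  embeddings$coverage <- list(
    n_vocab = length(vocab$word), n_hit = n_hit,
    hit_rate = n_hit / length(vocab$word)
  )
  embeddings
}

#' Signed clipped distance id for the position channel
#'
#' Encodes `i - ent_token` clipped to `-clip..clip` as a 1-based row id of
#' the position table (`id = clipped + clip + 1`); the table's last row
#' (`2 * clip + 2`) is reserved for padding.
#'
#' @param i token index (or vector of indices).
#' @param ent_token index of the entity token.
#' @param clip maximum absolute distance (default 30).
#' @return integer row id(s) into the position table.
#' @export
position_index <- function(i, ent_token, clip = 30L) {
  d <- pmax(-clip, pmin(clip, i - ent_token))
  as.integer(d + clip + 1L)
}

#' Four-channel embedding vector of a drug entity
#'
#' The word channel is the arithmetic mean of the original (pre-collapse)
#' surface word vectors; the POS channel is the configured noun tag's row;
#' the two position channels encode distance 0 to the entity itself and
#' the signed distance to the other entity's token.
#'
#' @param words original surface words of the mention.
#' @param vocab a `ddi_vocab`.
#' @param embeddings a `ddi_embeddings`.
#' @param dist_to_other signed token distance to the other entity.
#' @param noun_pos POS tag used for drug entities (default `"NN"`).
#' @return numeric vector of length `d_word + d_pos + 2 * d_dis`.
#' @export
embed_entity <- function(words, vocab, embeddings, dist_to_other,
                         noun_pos = "NN") {
  stopifnot(length(words) >= 1L)
  ids <- vocab_id(vocab, words)
  wvec <- colMeans(embeddings$word[ids, , drop = FALSE])
  c(
    wvec,
    embeddings$pos[vocab_id(vocab, noun_pos, "pos"), ],
    embeddings$dis[position_index(0L, 0L, embeddings$clip), ],
    embeddings$dis[position_index(dist_to_other, 0L, embeddings$clip), ]
  )
}
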