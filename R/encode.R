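#' Entity attention weights for a token sequence
#'
#' For every token the relevance to each target entity is the dot product
#' of its word-channel vector with the entity's averaged word vector,
#' softmax-normalised over the sequence (numerically stabilised by
#' subtracting the maximum logit). The joint weight is the simple average
#' of the two entity-specific weights, so it also sums to 1.
#'
#' @param word_vectors `m x d_word` matrix of word-channel vectors.
#' @param ent0_vec,ent1_vec entity word-channel vectors (length `d_word`).
#' @return an object of class `ddi_attention`: list of numeric vectors
#'   `theta0`, `theta1`, `joint`, each of length `m` and summing to 1.
#' @export
attention_weights <- function(word_vectors, ent0_vec, ent1_vec) {
  word_vectors <- rbind(word_vectors)
  if (nrow(word_vectors) == 0L) abort("empty token sequence")
  theta <- function(ev) {
    logits <- drop(word_vectors %*% ev)
    e <- exp(logits - max(logits))
    e / sum(e)
  }
  t0 <- theta(ent0_vec)
  t1 <- theta(ent1_vec)
  structure(list(theta0 = t0, theta1 = t1, joint = (t0 + t1) / 2),
            class = "ddi_attention")
}

#' Scale token vectors by their joint attention weights
#'
#' Row `i` of the result is `joint[i]` times the full concatenated token
#' vector (all four channels).
#'
#' @param z `m x k` matrix of concatenated token vectors.
#' @param weights a `ddi_attention` for the same sequence.
#' @return the attended `m x k` matrix.
#' @export
attend <- function(z, weights) {
  z <- rbind(z)
  if (nrow(z) != length(weights$joint)) {
    abort(paste0("attend: ", nrow(z), " rows but ",
                 length(weights$joint), " weights"))
  }
  z * weights$joint
}

#' Encode one instance into its attended five-part representation
#'
#' Reference single-instance encoder: builds the four-channel token
#' matrix, applies entity attention over the sentence sequence and
#' (independently normalised) over the SDP token sequence, and splits the
#' sentence into `sub0 | ent0 | sub1 | ent1 | sub2`. The entity slots use
#' the mean-of-original-words entity vectors scaled by the entity token's
#' own joint weight.
#'
#' @param instance one row of an instance tibble (anonymized, SDP
#'   attached).
#' @param vocab a `ddi_vocab`.
#' @param embeddings a `ddi_embeddings`.
#' @param noun_pos POS tag for entity slots.
#' @param attention_rescale `"none"` (literal attended vectors) or
#'   `"times_m"` (multiply by sequence length, undoing the softmax mean
#'   shrinkage).
#' @param sdp_include_relations interleave dependency-relation pseudo
#'   tokens (with learned label embeddings) into the SDP sequence.
#' @return an object of class `ddi_encoded`: matrices `sub0`, `sub1`,
#'   `sub2`, `sdp` (possibly zero-row except `sdp`), vectors `ent0`,
#'   `ent1`, the `label`, and the attention objects (`att_sent`,
#'   `att_sdp`).
#' @export
encode_instance <- function(instance, vocab, embeddings, noun_pos = "NN",
                            attention_rescale = c("none", "times_m"),
                            sdp_include_relations = FALSE) {
  attention_rescale <- match.arg(attention_rescale)
  tok <- instance$tokens[[1]]
  m <- nrow(tok)
  p0 <- instance$e0_tok
  p1 <- instance$e1_tok
  clip <- embeddings$clip

  wids <- vocab_id(vocab, tok$surface)
  posids <- vocab_id(vocab, tok$pos, "pos")
  d0 <- position_index(seq_len(m), p0, clip)
  d1 <- position_index(seq_len(m), p1, clip)
  W <- embeddings$word[wids, , drop = FALSE]
  Z <- cbind(W,
             embeddings$pos[posids, , drop = FALSE],
             embeddings$dis[d0, , drop = FALSE],
             embeddings$dis[d1, , drop = FALSE])

  e0v <- colMeans(embeddings$word[vocab_id(vocab, instance$e0_words[[1]]), ,
                                  drop = FALSE])
  e1v <- colMeans(embeddings$word[vocab_id(vocab, instance$e1_words[[1]]), ,
                                  drop = FALSE])

  att <- attention_weights(W, e0v, e1v)
  Zatt <- attend(Z, att)
  if (attention_rescale == "times_m") Zatt <- Zatt * m

  ze0 <- embed_entity(instance$e0_words[[1]], vocab, embeddings,
                      p0 - p1, noun_pos)
  ze1 <- embed_entity(instance$e1_words[[1]], vocab, embeddings,
                      p1 - p0, noun_pos)
  ent0 <- att$joint[p0] * ze0
  ent1 <- att$joint[p1] * ze1
  if (attention_rescale == "times_m") {
    ent0 <- ent0 * m
    ent1 <- ent1 * m
  }

  # SDP sequence: on-path tokens (entity endpoints included), with their
  # own softmax over the path; optional relation pseudo-tokens in between
  path <- instance$sdp[[1]]
  if (sdp_include_relations && length(path) > 1L) {
    rels <- instance$sdp_rels[[1]]
    rids <- vocab_id(vocab, rels, "rel")
    n <- length(path)
    kind <- c(rbind(rep("tok", n - 1L), rep("rel", n - 1L)), "tok")
    slot <- c(rbind(path[-n], rids), path[n])
    Zsdp_rows <- matrix(0, length(kind), ncol(Z))
    Wsdp <- matrix(0, length(kind), ncol(W))
    for (k in seq_along(kind)) {
      if (kind[k] == "tok") {
        Zsdp_rows[k, ] <- Z[slot[k], ]
        Wsdp[k, ] <- W[slot[k], ]
      } else {
        Zsdp_rows[k, ] <- embeddings$rel[slot[k], ]
        Wsdp[k, ] <- embeddings$rel[slot[k], seq_len(ncol(W))]
      }
    }
    att_sdp <- attention_weights(Wsdp, e0v, e1v)
    Zsdp <- attend(Zsdp_rows, att_sdp)
  } else {
    att_sdp <- attention_weights(W[path, , drop = FALSE], e0v, e1v)
    Zsdp <- attend(Z[path, , drop = FALSE], att_sdp)
  }
  if (attention_rescale == "times_m") Zsdp <- Zsdp * nrow(Zsdp)

  structure(
    list(
      sub0 = Zatt[seq_len(p0 - 1L), , drop = FALSE],
      ent0 = ent0,
      sub1 = if (p1 - p0 > 1L) Zatt[(p0 + 1L):(p1 - 1L), , drop = FALSE]
             else Zatt[0L, , drop = FALSE],
      ent1 = ent1,
      sub2 = if (p1 < m) Zatt[(p1 + 1L):m, , drop = FALSE]
             else Zatt[0L, , drop = FALSE],
      sdp = Zsdp,
      label = instance$label,
      att_sent = att, att_sdp = att_sdp
    ),
    class = "ddi_encoded"
  )
}

#' @export
print.ddi_encoded <- function(x, ...) {
  cat(sprintf(
    "<ddi_encoded> label=%s | sub0:%d ent0 sub1:%d ent1 sub2:%d | sdp:%d rows\n",
    x$label, nrow(x$sub0), nrow(x$sub1), nrow(x$sub2), nrow(x$sdp)
  ))
  invisible(x)
}
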