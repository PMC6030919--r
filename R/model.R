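# Hierarchical bidirectional recurrent model: batched forward/backward
# passes and the RMSProp training loop. Everything is plain R matrices;
# the heavy lifting is BLAS matrix products over padded step batches.

z_dim <- function(cfg) {
  with(cfg$embedding, d_word + d_pos + 2L * d_dis)
}

init_params <- function(vocab, cfg, embeddings) {
  mc <- cfg$model
  dz <- z_dim(cfg)
  H <- mc$bottom_hidden
  Ht <- mc$top_hidden
  type <- mc$cell
  enc <- list(sdp = list(fwd = cell_init(dz, H, type),
                         bwd = cell_init(dz, H, type)))
  if (mc$share_bottom_across_subsequences) {
    enc$sub <- list(fwd = cell_init(dz, H, type), bwd = cell_init(dz, H, type))
  } else {
    for (nm in c("sub0", "sub1", "sub2")) {
      enc[[nm]] <- list(fwd = cell_init(dz, H, type),
                        bwd = cell_init(dz, H, type))
    }
  }
  proj <- if (mc$entity_projection) {
    list(W = glorot(dz, 2L * H), b = numeric(2L * H))
  } else {
    if (dz != 2L * H) {
      abort(paste0("entity_projection = FALSE requires the token vector ",
                   "width (", dz, ") to equal 2 * bottom_hidden (", 2L * H, ")"))
    }
    NULL
  }
  list(
    emb = list(word = embeddings$word, pos = embeddings$pos,
               dis = embeddings$dis, rel = embeddings$rel),
    enc = enc,
    proj = proj,
    top = list(fwd = cell_init(2L * H, Ht, type),
               bwd = cell_init(2L * H, Ht, type)),
    head = list(W = glorot(2L * Ht, mc$n_classes), b = numeric(mc$n_classes))
  )
}

# ---- instance indexing -----------------------------------------------------

# Freezes an instance tibble into integer id structures; all embedding and
# attention quantities are recomputed from the current tables each batch.
indexize_instances <- function(instances, vocab, cfg) {
  clip <- cfg$embedding$clip
  lapply(seq_len(nrow(instances)), function(i) {
    r <- instances[i, ]
    tok <- r$tokens[[1]]
    m <- nrow(tok)
    p0 <- r$e0_tok
    p1 <- r$e1_tok
    path <- r$sdp[[1]]
    if (isTRUE(cfg$embedding$sdp_include_relations) && length(path) > 1L) {
      rids <- vocab_id(vocab, r$sdp_rels[[1]], "rel")
      n <- length(path)
      sdp_kind <- c(rbind(rep(1L, n - 1L), rep(2L, n - 1L)), 1L)
      sdp_loc <- c(rbind(path[-n], rids), path[n])
    } else {
      sdp_kind <- rep(1L, length(path))
      sdp_loc <- path
    }
    list(
      m = m, p0 = p0, p1 = p1,
      y = ddi_class_id(r$label),
      pair_id = r$pair_id,
      wids = vocab_id(vocab, tok$surface),
      posids = vocab_id(vocab, tok$pos, "pos"),
      d0 = position_index(seq_len(m), p0, clip),
      d1 = position_index(seq_len(m), p1, clip),
      e0ids = vocab_id(vocab, r$e0_words[[1]]),
      e1ids = vocab_id(vocab, r$e1_words[[1]]),
      ent0_d1 = position_index(p0 - p1, 0L, clip),
      ent1_d0 = position_index(p1 - p0, 0L, clip),
      sdp_kind = sdp_kind, sdp_loc = sdp_loc
    )
  })
}

make_batch <- function(idx, cfg) {
  B <- length(idx)
  m_vec <- map_int(idx, "m")
  off <- cumsum(c(0L, m_vec[-B]))
  plen <- map_int(idx, function(x) length(x$sdp_kind))
  poff <- cumsum(c(0L, plen[-B]))
  inst <- rep(seq_len(B), m_vec)
  sdp_inst <- rep(seq_len(B), plen)
  sdp_kind <- unlist(map(idx, "sdp_kind"))
  sdp_loc_local <- map(idx, "sdp_loc")
  # token entries point at global sentence rows; relation entries keep ids
  sdp_glob <- unlist(map2(sdp_loc_local, seq_len(B), function(loc, i) {
    k <- idx[[i]]$sdp_kind
    ifelse(k == 1L, loc + off[i], loc)
  }))
  list(
    B = B, m_vec = m_vec, off = off, inst = inst,
    N = sum(m_vec),
    wids = unlist(map(idx, "wids")),
    posids = unlist(map(idx, "posids")),
    d0 = unlist(map(idx, "d0")),
    d1 = unlist(map(idx, "d1")),
    p0 = map_int(idx, "p0"), p1 = map_int(idx, "p1"),
    p0g = off + map_int(idx, "p0"),
    p1g = off + map_int(idx, "p1"),
    e0ids = unlist(map(idx, "e0ids")),
    e0grp = rep(seq_len(B), map_int(idx, function(x) length(x$e0ids))),
    e0l = map_int(idx, function(x) length(x$e0ids)),
    e1ids = unlist(map(idx, "e1ids")),
    e1grp = rep(seq_len(B), map_int(idx, function(x) length(x$e1ids))),
    e1l = map_int(idx, function(x) length(x$e1ids)),
    ent0_d1 = map_int(idx, "ent0_d1"),
    ent1_d0 = map_int(idx, "ent1_d0"),
    P = sum(plen), plen = plen, poff = poff,
    sdp_inst = sdp_inst, sdp_kind = sdp_kind, sdp_glob = sdp_glob,
    y = map_int(idx, "y"),
    pair_id = map_chr(idx, "pair_id")
  )
}

group_softmax <- function(logits, group, B) {
  gmax <- rep(-Inf, B)
  gm <- tapply(logits, factor(group, levels = seq_len(B)), max)
  gmax[!is.na(gm)] <- gm[!is.na(gm)]
  e <- exp(logits - gmax[group])
  gs <- as.numeric(rowsum(e, group))
  e / gs[group]
}

group_softmax_back <- function(theta, dtheta, group) {
  s <- as.numeric(rowsum(theta * dtheta, group))
  theta * (dtheta - s[group])
}

group_rowsum <- function(x, group, B) {
  rs <- rowsum(x, group)
  out <- matrix(0, B, ncol(x))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# Scatter-add row contributions into a zero table of nrow n.
scatter_rows <- function(n, ncol, idx_list, mat_list) {
  idx <- unlist(idx_list)
  mat <- do.call(rbind, mat_list)
  out <- matrix(0, n, ncol)
  if (length(idx)) {
    rs <- rowsum(mat, idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

# ---- full forward / backward ----------------------------------------------

forward_batch <- function(params, bt, cfg, vocab, train = FALSE,
                          ablate_sdp = FALSE) {
  ec <- cfg$embedding
  mc <- cfg$model
  dw <- ec$d_word
  dz <- z_dim(cfg)
  H <- mc$bottom_hidden
  Ht <- mc$top_hidden
  type <- mc$cell
  B <- bt$B

  W <- params$emb$word
  Wtok <- W[bt$wids, , drop = FALSE]
  E0 <- group_rowsum(W[bt$e0ids, , drop = FALSE], bt$e0grp, B) / bt$e0l
  E1 <- group_rowsum(W[bt$e1ids, , drop = FALSE], bt$e1grp, B) / bt$e1l

  theta0 <- group_softmax(rowSums(Wtok * E0[bt$inst, , drop = FALSE]),
                          bt$inst, B)
  theta1 <- group_softmax(rowSums(Wtok * E1[bt$inst, , drop = FALSE]),
                          bt$inst, B)
  a_s <- (theta0 + theta1) / 2
  rs_s <- if (ec$attention_rescale == "times_m") bt$m_vec[bt$inst] else 1

  Z <- cbind(Wtok,
             params$emb$pos[bt$posids, , drop = FALSE],
             params$emb$dis[bt$d0, , drop = FALSE],
             params$emb$dis[bt$d1, , drop = FALSE])
  Zatt <- (rs_s * a_s) * Z

  noun_id <- vocab_id(vocab, ec$noun_pos, "pos")
  zero_did <- position_index(0L, 0L, ec$clip)
  pos_noun <- matrix(params$emb$pos[noun_id, ], B, ec$d_pos, byrow = TRUE)
  dis_zero <- matrix(params$emb$dis[zero_did, ], B, ec$d_dis, byrow = TRUE)
  ze0 <- cbind(E0, pos_noun, dis_zero,
               params$emb$dis[bt$ent0_d1, , drop = FALSE])
  ze1 <- cbind(E1, pos_noun,
               params$emb$dis[bt$ent1_d0, , drop = FALSE], dis_zero)
  rs_e <- if (ec$attention_rescale == "times_m") bt$m_vec else 1
  ae0 <- a_s[bt$p0g]
  ae1 <- a_s[bt$p1g]
  ent0 <- (rs_e * ae0) * ze0
  ent1 <- (rs_e * ae1) * ze1

  # SDP sequence with its own softmax over the path entries
  tok_sel <- bt$sdp_kind == 1L
  Wsdp <- matrix(0, bt$P, dw)
  Zsdp <- matrix(0, bt$P, dz)
  Wsdp[tok_sel, ] <- Wtok[bt$sdp_glob[tok_sel], , drop = FALSE]
  Zsdp[tok_sel, ] <- Z[bt$sdp_glob[tok_sel], , drop = FALSE]
  if (any(!tok_sel)) {
    Wsdp[!tok_sel, ] <- params$emb$rel[bt$sdp_glob[!tok_sel], seq_len(dw),
                                       drop = FALSE]
    Zsdp[!tok_sel, ] <- params$emb$rel[bt$sdp_glob[!tok_sel], , drop = FALSE]
  }
  theta0p <- group_softmax(rowSums(Wsdp * E0[bt$sdp_inst, , drop = FALSE]),
                           bt$sdp_inst, B)
  theta1p <- group_softmax(rowSums(Wsdp * E1[bt$sdp_inst, , drop = FALSE]),
                           bt$sdp_inst, B)
  a_p <- (theta0p + theta1p) / 2
  rs_p <- if (ec$attention_rescale == "times_m") bt$plen[bt$sdp_inst] else 1
  Zp_att <- (rs_p * a_p) * Zsdp

  # embedding-layer dropout (inverted)
  if (train && mc$dropout_embed > 0) {
    keep <- 1 - mc$dropout_embed
    Ms <- matrix(stats::rbinom(bt$N * dz, 1L, keep), bt$N, dz) / keep
    Mp <- matrix(stats::rbinom(bt$P * dz, 1L, keep), bt$P, dz) / keep
    Me0 <- matrix(stats::rbinom(B * dz, 1L, keep), B, dz) / keep
    Me1 <- matrix(stats::rbinom(B * dz, 1L, keep), B, dz) / keep
  } else {
    Ms <- Mp <- Me0 <- Me1 <- NULL
  }
  Zatt_d <- if (is.null(Ms)) Zatt else Zatt * Ms
  Zp_att_d <- if (is.null(Mp)) Zp_att else Zp_att * Mp
  ent0_d <- if (is.null(Me0)) ent0 else ent0 * Me0
  ent1_d <- if (is.null(Me1)) ent1 else ent1 * Me1

  # bottom encoders over the three subsequences and the SDP
  sub_rows <- function(which) {
    lapply(seq_len(B), function(i) {
      p0 <- bt$p0[i]; p1 <- bt$p1[i]; m <- bt$m_vec[i]; o <- bt$off[i]
      switch(which,
             s0 = if (p0 > 1L) o + seq_len(p0 - 1L) else integer(0),
             s1 = if (p1 - p0 > 1L) o + (p0 + 1L):(p1 - 1L) else integer(0),
             s2 = if (p1 < m) o + (p1 + 1L):m else integer(0))
    })
  }
  rows0 <- sub_rows("s0"); rows1 <- sub_rows("s1"); rows2 <- sub_rows("s2")
  shared <- mc$share_bottom_across_subsequences
  if (shared) {
    pk_sub <- pack_sequences(c(rows0, rows1, rows2), bt$N)
    st_sub <- bi_encoder_forward(params$enc$sub, Zatt_d, pk_sub, type, H,
                                 mc$bottom_pooling)
    v0 <- st_sub$out[seq_len(B), , drop = FALSE]
    v1 <- st_sub$out[B + seq_len(B), , drop = FALSE]
    v2 <- st_sub$out[2L * B + seq_len(B), , drop = FALSE]
    st_subs <- list(st_sub)
    pk_subs <- list(pk_sub)
  } else {
    pk_subs <- list(pack_sequences(rows0, bt$N), pack_sequences(rows1, bt$N),
                    pack_sequences(rows2, bt$N))
    st_subs <- list(
      bi_encoder_forward(params$enc$sub0, Zatt_d, pk_subs[[1]], type, H,
                         mc$bottom_pooling),
      bi_encoder_forward(params$enc$sub1, Zatt_d, pk_subs[[2]], type, H,
                         mc$bottom_pooling),
      bi_encoder_forward(params$enc$sub2, Zatt_d, pk_subs[[3]], type, H,
                         mc$bottom_pooling)
    )
    v0 <- st_subs[[1]]$out; v1 <- st_subs[[2]]$out; v2 <- st_subs[[3]]$out
  }
  sdp_rows <- lapply(seq_len(B), function(i) bt$poff[i] + seq_len(bt$plen[i]))
  pk_sdp <- pack_sequences(sdp_rows, bt$P)
  st_sdp <- bi_encoder_forward(params$enc$sdp, Zp_att_d, pk_sdp, type, H,
                               mc$bottom_pooling)
  vsdp <- st_sdp$out
  if (ablate_sdp) vsdp <- vsdp * 0

  if (mc$entity_projection) {
    pe0 <- sweep(ent0_d %*% params$proj$W, 2L, params$proj$b, "+")
    pe1 <- sweep(ent1_d %*% params$proj$W, 2L, params$proj$b, "+")
  } else {
    pe0 <- ent0_d
    pe1 <- ent1_d
  }

  # top encoder over the six-slot sequence
  Ztop <- rbind(v0, pe0, v1, pe1, v2, vsdp)
  top_rows <- lapply(seq_len(B), function(i) i + B * 0:5)
  pk_top <- pack_sequences(top_rows, nrow(Ztop))
  st_top <- bi_encoder_forward(params$top, Ztop, pk_top, type, Ht, "final")
  s <- st_top$out

  if (train && mc$dropout_output > 0) {
    keep_o <- 1 - mc$dropout_output
    Mo <- matrix(stats::rbinom(length(s), 1L, keep_o), nrow(s)) / keep_o
  } else {
    Mo <- NULL
  }
  s_d <- if (is.null(Mo)) s else s * Mo
  probs <- classify(s_d, params$head)
  loss <- -mean(log(pmax(probs[cbind(seq_len(B), bt$y)], 1e-300)))

  list(
    probs = probs, loss = loss,
    cache = list(
      Wtok = Wtok, E0 = E0, E1 = E1, theta0 = theta0, theta1 = theta1,
      a_s = a_s, rs_s = rs_s, Z = Z, Zatt = Zatt, ze0 = ze0, ze1 = ze1,
      ae0 = ae0, ae1 = ae1, rs_e = rs_e, ent0_d = ent0_d, ent1_d = ent1_d,
      Wsdp = Wsdp, Zsdp = Zsdp, theta0p = theta0p, theta1p = theta1p,
      a_p = a_p, rs_p = rs_p, tok_sel = tok_sel,
      Ms = Ms, Mp = Mp, Me0 = Me0, Me1 = Me1, Mo = Mo,
      pk_subs = pk_subs, st_subs = st_subs, shared = shared,
      pk_sdp = pk_sdp, st_sdp = st_sdp,
      pk_top = pk_top, st_top = st_top,
      s = s, s_d = s_d, noun_id = noun_id, zero_did = zero_did
    )
  )
}

backward_batch <- function(params, bt, cfg, fw) {
  ec <- cfg$embedding
  mc <- cfg$model
  dw <- ec$d_word
  dp <- ec$d_pos
  dd <- ec$d_dis
  dz <- z_dim(cfg)
  H <- mc$bottom_hidden
  Ht <- mc$top_hidden
  type <- mc$cell
  B <- bt$B
  ch <- fw$cache

  Y <- matrix(0, B, mc$n_classes)
  Y[cbind(seq_len(B), bt$y)] <- 1
  dlogits <- (fw$probs - Y) / B
  g_head <- list(W = crossprod(ch$s_d, dlogits), b = colSums(dlogits))
  ds <- dlogits %*% t(params$head$W)
  if (!is.null(ch$Mo)) ds <- ds * ch$Mo

  bk_top <- bi_encoder_backward(params$top, ch$st_top, ch$pk_top, type, Ht,
                                "final", ds)
  dZtop <- bk_top$dZ
  dv0 <- dZtop[seq_len(B), , drop = FALSE]
  dpe0 <- dZtop[B + seq_len(B), , drop = FALSE]
  dv1 <- dZtop[2L * B + seq_len(B), , drop = FALSE]
  dpe1 <- dZtop[3L * B + seq_len(B), , drop = FALSE]
  dv2 <- dZtop[4L * B + seq_len(B), , drop = FALSE]
  dvsdp <- dZtop[5L * B + seq_len(B), , drop = FALSE]

  if (mc$entity_projection) {
    g_proj <- list(
      W = crossprod(ch$ent0_d, dpe0) + crossprod(ch$ent1_d, dpe1),
      b = colSums(dpe0) + colSums(dpe1)
    )
    dent0_d <- dpe0 %*% t(params$proj$W)
    dent1_d <- dpe1 %*% t(params$proj$W)
  } else {
    g_proj <- NULL
    dent0_d <- dpe0
    dent1_d <- dpe1
  }

  if (ch$shared) {
    bk_sub <- bi_encoder_backward(params$enc$sub, ch$st_subs[[1]],
                                  ch$pk_subs[[1]], type, H, mc$bottom_pooling,
                                  rbind(dv0, dv1, dv2))
    dZatt_d <- bk_sub$dZ
    g_enc <- list(sub = bk_sub$grads)
  } else {
    bks <- list(
      bi_encoder_backward(params$enc$sub0, ch$st_subs[[1]], ch$pk_subs[[1]],
                          type, H, mc$bottom_pooling, dv0),
      bi_encoder_backward(params$enc$sub1, ch$st_subs[[2]], ch$pk_subs[[2]],
                          type, H, mc$bottom_pooling, dv1),
      bi_encoder_backward(params$enc$sub2, ch$st_subs[[3]], ch$pk_subs[[3]],
                          type, H, mc$bottom_pooling, dv2)
    )
    dZatt_d <- bks[[1]]$dZ + bks[[2]]$dZ + bks[[3]]$dZ
    g_enc <- list(sub0 = bks[[1]]$grads, sub1 = bks[[2]]$grads,
                  sub2 = bks[[3]]$grads)
  }
  bk_sdp <- bi_encoder_backward(params$enc$sdp, ch$st_sdp, ch$pk_sdp, type, H,
                                mc$bottom_pooling, dvsdp)
  g_enc$sdp <- bk_sdp$grads
  dZp_att_d <- bk_sdp$dZ

  # dropout backward
  dZatt <- if (is.null(ch$Ms)) dZatt_d else dZatt_d * ch$Ms
  dZp_att <- if (is.null(ch$Mp)) dZp_att_d else dZp_att_d * ch$Mp
  dent0 <- if (is.null(ch$Me0)) dent0_d else dent0_d * ch$Me0
  dent1 <- if (is.null(ch$Me1)) dent1_d else dent1_d * ch$Me1

  # attention / embedding stage backward
  dZ <- (ch$rs_s * ch$a_s) * dZatt
  da_s <- ch$rs_s * rowSums(dZatt * ch$Z)
  dze0 <- (ch$rs_e * ch$ae0) * dent0
  dze1 <- (ch$rs_e * ch$ae1) * dent1
  da_e0 <- ch$rs_e * rowSums(dent0 * ch$ze0)
  da_e1 <- ch$rs_e * rowSums(dent1 * ch$ze1)
  da_s[bt$p0g] <- da_s[bt$p0g] + da_e0
  da_s[bt$p1g] <- da_s[bt$p1g] + da_e1

  dZsdp <- (ch$rs_p * ch$a_p) * dZp_att
  da_p <- ch$rs_p * rowSums(dZp_att * ch$Zsdp)

  dlog0 <- group_softmax_back(ch$theta0, da_s / 2, bt$inst)
  dlog1 <- group_softmax_back(ch$theta1, da_s / 2, bt$inst)
  dlog0p <- group_softmax_back(ch$theta0p, da_p / 2, bt$sdp_inst)
  dlog1p <- group_softmax_back(ch$theta1p, da_p / 2, bt$sdp_inst)

  E0i <- ch$E0[bt$inst, , drop = FALSE]
  E1i <- ch$E1[bt$inst, , drop = FALSE]
  E0p <- ch$E0[bt$sdp_inst, , drop = FALSE]
  E1p <- ch$E1[bt$sdp_inst, , drop = FALSE]

  # gradients on the word-channel rows of sentence tokens
  dWtok <- dZ[, seq_len(dw), drop = FALSE] + dlog0 * E0i + dlog1 * E1i
  # SDP rows add to word channel of their sources
  dWsdp <- dlog0p * E0p + dlog1p * E1p
  dZsdp_tok <- dZsdp[ch$tok_sel, , drop = FALSE]
  tok_glob <- bt$sdp_glob[ch$tok_sel]

  # entity mean vectors: used in ze word channel and all four logit terms
  dE0 <- dze0[, seq_len(dw), drop = FALSE] +
    group_rowsum(dlog0 * ch$Wtok, bt$inst, B) +
    group_rowsum(dlog0p * ch$Wsdp, bt$sdp_inst, B)
  dE1 <- dze1[, seq_len(dw), drop = FALSE] +
    group_rowsum(dlog1 * ch$Wtok, bt$inst, B) +
    group_rowsum(dlog1p * ch$Wsdp, bt$sdp_inst, B)

  wcol <- seq_len(dw)
  pcol <- dw + seq_len(dp)
  c0 <- dw + dp + seq_len(dd)
  c1 <- dw + dp + dd + seq_len(dd)

  g_word <- scatter_rows(
    nrow(params$emb$word), dw,
    list(bt$wids, bt$wids[tok_glob], bt$wids[tok_glob],
         bt$e0ids, bt$e1ids),
    list(dWtok,
         dWsdp[ch$tok_sel, , drop = FALSE],
         dZsdp_tok[, wcol, drop = FALSE],
         (dE0 / bt$e0l)[bt$e0grp, , drop = FALSE],
         (dE1 / bt$e1l)[bt$e1grp, , drop = FALSE])
  )
  g_pos <- scatter_rows(
    nrow(params$emb$pos), dp,
    list(bt$posids, bt$posids[tok_glob],
         rep(ch$noun_id, 2L * B)),
    list(dZ[, pcol, drop = FALSE],
         dZsdp_tok[, pcol, drop = FALSE],
         rbind(dze0[, pcol, drop = FALSE], dze1[, pcol, drop = FALSE]))
  )
  g_dis <- scatter_rows(
    nrow(params$emb$dis), dd,
    list(bt$d0, bt$d1, bt$d0[tok_glob], bt$d1[tok_glob],
         rep(ch$zero_did, B), bt$ent0_d1,
         bt$ent1_d0, rep(ch$zero_did, B)),
    list(dZ[, c0, drop = FALSE], dZ[, c1, drop = FALSE],
         dZsdp_tok[, c0, drop = FALSE], dZsdp_tok[, c1, drop = FALSE],
         dze0[, c0, drop = FALSE], dze0[, c1, drop = FALSE],
         dze1[, c0, drop = FALSE], dze1[, c1, drop = FALSE])
  )
  g_rel <- matrix(0, nrow(params$emb$rel), ncol(params$emb$rel))
  if (any(!ch$tok_sel)) {
    rel_glob <- bt$sdp_glob[!ch$tok_sel]
    d_rel_rows <- dZsdp[!ch$tok_sel, , drop = FALSE]
    d_rel_rows[, wcol] <- d_rel_rows[, wcol] +
      dWsdp[!ch$tok_sel, , drop = FALSE]
    g_rel <- scatter_rows(nrow(params$emb$rel), ncol(params$emb$rel),
                          list(rel_glob), list(d_rel_rows))
  }

  list(
    emb = list(word = g_word, pos = g_pos, dis = g_dis, rel = g_rel),
    enc = g_enc,
    proj = g_proj,
    top = bk_top$grads,
    head = g_head
  )
}

#' Softmax output layer
#'
#' Maps sentence representations to class probabilities through the fully
#' connected output layer, `softmax(W %*% s + b)` per row, numerically
#' stabilised by subtracting the row maximum.
#'
#' @param s representation matrix (rows = instances) or a single vector.
#' @param head list with weight matrix `W` (`d_s` x `n_classes`) and bias
#'   `b`.
#' @return matrix of class probabilities; rows sum to 1.
#' @export
#' @examples
#' head <- list(W = matrix(0, 4, 5), b = rep(0, 5))
#' classify(rnorm(4), head)  # uniform 0.2
classify <- function(s, head) {
  s <- rbind(s)
  if (ncol(s) != nrow(head$W)) abort("representation/head shape mismatch")
  logits <- sweep(s %*% head$W, 2L, head$b, "+")
  lmax <- apply(logits, 1L, max)
  el <- exp(logits - lmax)
  el / rowSums(el)
}

# ---- optimiser -------------------------------------------------------------

rmsprop_update <- function(params, grads, cache, lr, rho, eps) {
  walk <- function(p, g, c) {
    if (is.numeric(p)) {
      if (is.null(g)) return(list(p = p, c = c))
      c <- if (is.null(c)) (1 - rho) * g^2 else rho * c + (1 - rho) * g^2
      list(p = p - lr * g / (sqrt(c) + eps), c = c)
    } else if (is.list(p)) {
      cc <- c %||% vector("list", length(p))
      names(cc) <- names(p)
      for (nm in names(p)) {
        if (is.null(p[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], cc[[nm]])
        p[[nm]] <- r$p
        cc[[nm]] <- r$c
      }
      list(p = p, c = cc)
    } else {
      list(p = p, c = c)
    }
  }
  walk(params, grads, cache)
}
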