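# Recurrent cell primitives: LSTM / GRU / simple cells with hand-written
# backpropagation over packed variable-length batches. The input-to-hidden
# projection (plus bias) is hoisted out of the time loop: each direction
# first computes XW = Z %*% Wx + b for every real token row, then the step
# loop only performs the recurrent H x ngH products. Gate pre-activation
# gradients are scattered back into a token-indexed matrix so that dWx,
# db and dZ are each a single BLAS call per direction.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

orthogonal <- function(n, m) {
  k <- max(n, m)
  q <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  q[seq_len(n), seq_len(m), drop = FALSE]
}

cell_init <- function(din, H, type) {
  ng <- switch(type, lstm = 4L, gru = 3L, simple = 1L)
  Wx <- glorot(din, ng * H)
  Wh <- do.call(cbind, lapply(seq_len(ng), function(i) orthogonal(H, H)))
  b <- numeric(ng * H)
  if (type == "lstm") b[(H + 1L):(2L * H)] <- 1  # forget-gate bias at 1
  list(Wx = Wx, Wh = Wh, b = b)
}

# xw: precomputed X %*% Wx + b for this step's rows (K x ngH)
cell_forward <- function(p, xw, h_prev, c_prev, type, H) {
  if (type == "lstm") {
    pre <- xw + h_prev %*% p$Wh
    i <- sigmoid(pre[, 1:H, drop = FALSE])
    f <- sigmoid(pre[, (H + 1L):(2L * H), drop = FALSE])
    g <- tanh(pre[, (2L * H + 1L):(3L * H), drop = FALSE])
    o <- sigmoid(pre[, (3L * H + 1L):(4L * H), drop = FALSE])
    c <- f * c_prev + i * g
    tc <- tanh(c)
    list(h = o * tc, c = c,
         cache = list(c_prev = c_prev, i = i, f = f, g = g, o = o, tc = tc))
  } else if (type == "gru") {
    zr <- 1:(2L * H)
    hcol <- (2L * H + 1L):(3L * H)
    pre <- xw[, zr, drop = FALSE] + h_prev %*% p$Wh[, zr, drop = FALSE]
    u <- sigmoid(pre[, 1:H, drop = FALSE])
    r <- sigmoid(pre[, H + 1:H, drop = FALSE])
    rh <- r * h_prev
    hh <- tanh(xw[, hcol, drop = FALSE] + rh %*% p$Wh[, hcol, drop = FALSE])
    list(h = (1 - u) * h_prev + u * hh, c = c_prev,
         cache = list(u = u, r = r, rh = rh, hh = hh))
  } else {
    h <- tanh(xw + h_prev %*% p$Wh)
    list(h = h, c = c_prev, cache = list(h = h))
  }
}

# Returns dh_prev, dc_prev and the gate pre-activation gradient dpre
# (K x ngH); tWh is t(p$Wh) cached by the caller. h_prev is the state the
# step consumed (needed for the GRU reset path).
cell_backward <- function(cache, dh, dc, type, H, tWh, h_prev) {
  if (type == "lstm") {
    i <- cache$i; f <- cache$f; g <- cache$g; o <- cache$o; tc <- cache$tc
    do <- dh * tc
    dct <- dc + dh * o * (1 - tc^2)
    dpre <- cbind(dct * g * i * (1 - i),
                  dct * cache$c_prev * f * (1 - f),
                  dct * i * (1 - g^2),
                  do * o * (1 - o))
    list(dh_prev = dpre %*% tWh, dc_prev = dct * f, dpre = dpre)
  } else if (type == "gru") {
    u <- cache$u; r <- cache$r; hh <- cache$hh
    zr <- 1:(2L * H)
    hcol <- (2L * H + 1L):(3L * H)
    du <- dh * (hh - h_prev)
    dpre_h <- (dh * u) * (1 - hh^2)
    drh <- dpre_h %*% tWh[hcol, , drop = FALSE]
    dr <- drh * h_prev
    dpre_ur <- cbind(du * u * (1 - u), dr * r * (1 - r))
    dh_prev <- dh * (1 - u) + drh * r +
      dpre_ur %*% tWh[zr, , drop = FALSE]
    list(dh_prev = dh_prev, dc_prev = dc, dpre = cbind(dpre_ur, dpre_h))
  } else {
    dpre <- dh * (1 - cache$h^2)
    list(dh_prev = dpre %*% tWh, dc_prev = dc, dpre = dpre)
  }
}

# ---- packed variable-length sequence batches -------------------------------

# Packs K variable-length sequences whose rows live in a single source
# matrix Z (n x d). `rows` is a list of K integer vectors of row indices
# into Z (possibly empty). Sequences are sorted by decreasing length so
# that at step t only the first Kt[t] rows are active: no masking is ever
# needed, and finished sequences simply stop being updated (their rows of
# the state matrix freeze at their final state).
pack_sequences <- function(rows, n) {
  K <- length(rows)
  L <- lengths(rows)
  T <- max(L, 0L)
  ord <- order(L, decreasing = TRUE)
  Ls <- L[ord]
  inv <- integer(K)
  inv[ord] <- seq_len(K)
  map <- matrix(0L, K, max(T, 1L))
  map_rev <- matrix(0L, K, max(T, 1L))
  for (k in seq_len(K)) {
    lk <- Ls[k]
    if (lk > 0L) {
      map[k, seq_len(lk)] <- rows[[ord[k]]]
      map_rev[k, seq_len(lk)] <- rev(rows[[ord[k]]])
    }
  }
  Kt <- if (T > 0L) vapply(seq_len(T), function(t) sum(Ls >= t), integer(1))
        else integer(0)
  list(map = map, map_rev = map_rev, K = K, T = T, L = Ls, Kt = Kt,
       ord = ord, inv = inv)
}

run_direction <- function(p, XWb, pk, use_map, type, H) {
  K <- pk$K
  h <- matrix(0, K, H)
  c <- matrix(0, K, H)
  caches <- vector("list", pk$T)
  hs <- vector("list", pk$T)
  for (t in seq_len(pk$T)) {
    Ka <- pk$Kt[t]
    act <- seq_len(Ka)
    st <- cell_forward(p, XWb[use_map[act, t], , drop = FALSE],
                       h[act, , drop = FALSE], c[act, , drop = FALSE],
                       type, H)
    h[act, ] <- st$h
    c[act, ] <- st$c
    caches[[t]] <- st$cache
    hs[[t]] <- st$h
  }
  list(h_final = h, hs = hs, caches = caches)
}

# Backward of run_direction. Accumulates gate gradients into a
# token-indexed matrix `dPre` so dWx/db/dZ reduce to one product each.
# dh_final is in sorted order; dhs (optional, max pooling) holds per-step
# gradients on the active rows.
run_direction_backward <- function(p, n, pk, use_map, type, H, fwd,
                                   dh_final, dhs = NULL) {
  ng <- ncol(p$Wx) / H
  dPre <- matrix(0, n, ng * H)
  tWh <- t(p$Wh)
  dh_full <- dh_final
  dc_full <- matrix(0, pk$K, H)
  h_prevs <- vector("list", pk$T)
  rh_list <- if (type == "gru") vector("list", pk$T)
  dpre_list <- vector("list", pk$T)
  for (t in rev(seq_len(pk$T))) {
    Ka <- pk$Kt[t]
    act <- seq_len(Ka)
    dh <- dh_full[act, , drop = FALSE]
    if (!is.null(dhs) && !is.null(dhs[[t]])) dh <- dh + dhs[[t]]
    h_prev <- if (t > 1L) fwd$hs[[t - 1L]][act, , drop = FALSE]
              else matrix(0, Ka, H)
    bk <- cell_backward(fwd$caches[[t]], dh, dc_full[act, , drop = FALSE],
                        type, H, tWh, h_prev)
    dPre[use_map[act, t], ] <- bk$dpre
    h_prevs[[t]] <- h_prev
    if (type == "gru") rh_list[[t]] <- fwd$caches[[t]]$rh
    dpre_list[[t]] <- bk$dpre
    dh_full[act, ] <- bk$dh_prev
    dc_full[act, ] <- bk$dc_prev
  }
  grads <- list(Wx = NULL, Wh = NULL, b = colSums(dPre))
  if (pk$T > 0L) {
    Hcat <- do.call(rbind, h_prevs)
    Pcat <- do.call(rbind, dpre_list)
    if (type == "gru") {
      hcol <- (2L * H + 1L):(3L * H)
      grads$Wh <- cbind(
        crossprod(Hcat, Pcat[, 1:(2L * H), drop = FALSE]),
        crossprod(do.call(rbind, rh_list), Pcat[, hcol, drop = FALSE])
      )
    } else {
      grads$Wh <- crossprod(Hcat, Pcat)
    }
  } else {
    grads$Wh <- matrix(0, H, ng * H)
  }
  list(dPre = dPre, grads = grads)
}

# Bidirectional encoder over a packed batch: concatenated forward/backward
# outputs, reduced by final state or elementwise max over valid steps.
bi_encoder_forward <- function(enc, Z, pk, type, H, pooling = "final") {
  XWf <- sweep(Z %*% enc$fwd$Wx, 2L, enc$fwd$b, "+")
  XWb <- sweep(Z %*% enc$bwd$Wx, 2L, enc$bwd$b, "+")
  fw <- run_direction(enc$fwd, XWf, pk, pk$map, type, H)
  bw <- run_direction(enc$bwd, XWb, pk, pk$map_rev, type, H)
  if (pooling == "final") {
    out <- cbind(fw$h_final, bw$h_final)
    argmax <- NULL
  } else {
    red <- function(run) {
      out <- matrix(-Inf, pk$K, H)
      arg <- matrix(0L, pk$K, H)
      for (t in seq_len(pk$T)) {
        act <- seq_len(pk$Kt[t])
        cand <- run$hs[[t]]
        cur <- out[act, , drop = FALSE]
        upd <- cand > cur
        cur[upd] <- cand[upd]
        out[act, ] <- cur
        a <- arg[act, , drop = FALSE]
        a[upd] <- t
        arg[act, ] <- a
      }
      out[arg == 0L] <- 0  # empty sequences reduce to the zero vector
      list(out = out, arg = arg)
    }
    rf <- red(fw); rb <- red(bw)
    out <- cbind(rf$out, rb$out)
    argmax <- list(f = rf$arg, b = rb$arg)
  }
  # states are in length-sorted order; restore caller order
  list(out = out[pk$inv, , drop = FALSE], fw = fw, bw = bw, Z = Z,
       argmax = argmax)
}

bi_encoder_backward <- function(enc, st, pk, type, H, pooling, dout) {
  n <- nrow(st$Z)
  dout <- dout[pk$ord, , drop = FALSE]  # to length-sorted order
  dhf <- dout[, seq_len(H), drop = FALSE]
  dhb <- dout[, H + seq_len(H), drop = FALSE]
  if (pooling == "final") {
    bf <- run_direction_backward(enc$fwd, n, pk, pk$map, type, H, st$fw, dhf)
    bb <- run_direction_backward(enc$bwd, n, pk, pk$map_rev, type, H, st$bw,
                                 dhb)
  } else {
    route <- function(arg, dh) {
      dhs <- vector("list", pk$T)
      for (t in seq_len(pk$T)) {
        act <- seq_len(pk$Kt[t])
        sel <- arg[act, , drop = FALSE] == t
        if (any(sel)) {
          d <- matrix(0, pk$Kt[t], H)
          d[sel] <- dh[act, , drop = FALSE][sel]
          dhs[[t]] <- d
        }
      }
      dhs
    }
    zero <- matrix(0, pk$K, H)
    bf <- run_direction_backward(enc$fwd, n, pk, pk$map, type, H, st$fw,
                                 zero, route(st$argmax$f, dhf))
    bb <- run_direction_backward(enc$bwd, n, pk, pk$map_rev, type, H, st$bw,
                                 zero, route(st$argmax$b, dhb))
  }
  list(
    dZ = bf$dPre %*% t(enc$fwd$Wx) + bb$dPre %*% t(enc$bwd$Wx),
    grads = list(
      fwd = list(Wx = crossprod(st$Z, bf$dPre), Wh = bf$grads$Wh,
                 b = bf$grads$b),
      bwd = list(Wx = crossprod(st$Z, bb$dPre), Wh = bb$grads$Wh,
                 b = bb$grads$b)
    )
  )
}
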