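# Neural network internals: small transformer and (bi)LSTM token encoders
# with a shared linear softmax head, trained by Adam on token-level
# cross-entropy. Gradients are derived by hand and verified against finite
# differences in the test suite. Everything is dense base-R linear algebra;
# model sizes are deliberately small (H ~ tens), so BLAS calls on tiny
# matrices dominate and batching is done over the concatenated tokens of a
# batch wherever the operation is position-wise.

.LN_EPS <- 1e-5
.N_CLASS <- 4L

# row-wise softmax with max-shift
.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# scale matrix rows (v length nrow) / columns (v length ncol)
.rowscale <- function(M, v) M * v
.colscale <- function(M, v) M * rep(v, each = nrow(M))

.ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + .LN_EPS)
  xhat <- .rowscale(xc, inv)
  list(Y = .colscale(xhat, g) + rep(b, each = nrow(X)), xhat = xhat, inv = inv)
}

.ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- .colscale(dY, g)
  dX <- .rowscale(dxhat - rowMeans(dxhat) - .rowscale(xhat, rowMeans(dxhat * xhat)),
                  cache$inv)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

.mat <- function(rng, nr, nc, sd) matrix(rng_norm(rng, nr * nc, sd = sd), nr, nc)

# ---- transformer -----------------------------------------------------------

nn_init_transformer <- function(vocab_size, cfg, rng) {
  H <- cfg$d_model; FF <- cfg$d_ff; sd <- cfg$init_sd
  p <- list(E = .mat(rng, vocab_size, H, sd), P = .mat(rng, cfg$max_len, H, sd))
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("L", l, "_")
    p[[paste0(pre, "Wq")]] <- .mat(rng, H, H, sd)
    p[[paste0(pre, "Wk")]] <- .mat(rng, H, H, sd)
    p[[paste0(pre, "Wv")]] <- .mat(rng, H, H, sd)
    p[[paste0(pre, "Wo")]] <- .mat(rng, H, H, sd)
    p[[paste0(pre, "g1")]] <- rep(1, H); p[[paste0(pre, "b1")]] <- rep(0, H)
    p[[paste0(pre, "W1")]] <- .mat(rng, H, FF, sd)
    p[[paste0(pre, "c1")]] <- rep(0, FF)
    p[[paste0(pre, "W2")]] <- .mat(rng, FF, H, sd)
    p[[paste0(pre, "c2")]] <- rep(0, H)
    p[[paste0(pre, "g2")]] <- rep(1, H); p[[paste0(pre, "b2")]] <- rep(0, H)
  }
  p$gf <- rep(1, H); p$bf <- rep(0, H)
  p$Wc <- .mat(rng, H, .N_CLASS, sd); p$bc <- rep(0, .N_CLASS)
  p
}

# batch: list of examples, each list(ids, heads, y) where ids are the real
# (non-padding) subword ids of one window, heads the 1-based positions of
# word-initial subwords and y the integer label ids at those positions (NULL
# at prediction time). Padding is excluded before the encoder, which is what
# makes it inert in both the loss and the attention.
nn_tf_apply <- function(params, batch, cfg, need_grads = TRUE) {
  H <- cfg$d_model
  lens <- vapply(batch, function(e) length(e$ids), integer(1))
  ids <- unlist(lapply(batch, `[[`, "ids"), use.names = FALSE)
  pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  ranges <- lapply(seq_along(batch), function(s) offs[s] + seq_len(lens[s]))
  N <- length(ids)
  scale <- 1 / sqrt(H)

  X <- params$E[ids, , drop = FALSE] + params$P[pos, , drop = FALSE]
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("L", l, "_")
    ln1 <- .ln_fwd(X, params[[paste0(pre, "g1")]], params[[paste0(pre, "b1")]])
    Q <- ln1$Y %*% params[[paste0(pre, "Wq")]]
    K <- ln1$Y %*% params[[paste0(pre, "Wk")]]
    V <- ln1$Y %*% params[[paste0(pre, "Wv")]]
    O <- matrix(0, N, H)
    As <- vector("list", length(ranges))
    for (s in seq_along(ranges)) {
      rs <- ranges[[s]]
      A <- .softmax_rows(Q[rs, , drop = FALSE] %*% t(K[rs, , drop = FALSE]) * scale)
      O[rs, ] <- A %*% V[rs, , drop = FALSE]
      As[[s]] <- A
    }
    X2 <- X + O %*% params[[paste0(pre, "Wo")]]
    ln2 <- .ln_fwd(X2, params[[paste0(pre, "g2")]], params[[paste0(pre, "b2")]])
    Hpre <- ln2$Y %*% params[[paste0(pre, "W1")]] +
      rep(params[[paste0(pre, "c1")]], each = N)
    Hh <- pmax(Hpre, 0)
    X3 <- X2 + Hh %*% params[[paste0(pre, "W2")]] +
      rep(params[[paste0(pre, "c2")]], each = N)
    caches[[l]] <- list(ln1 = ln1, Q = Q, K = K, V = V, O = O, As = As,
                        X = X, X2 = X2, ln2 = ln2, Hh = Hh)
    X <- X3
  }
  lnf <- .ln_fwd(X, params$gf, params$bf)
  Z <- lnf$Y %*% params$Wc + rep(params$bc, each = N)
  Pr <- .softmax_rows(Z)

  sup_rows <- integer(); sup_y <- integer()
  for (s in seq_along(batch)) {
    if (!is.null(batch[[s]]$y)) {
      sup_rows <- c(sup_rows, offs[s] + batch[[s]]$heads)
      sup_y <- c(sup_y, batch[[s]]$y)
    }
  }
  n_sup <- length(sup_rows)
  loss <- if (n_sup > 0L)
    -mean(log(pmax(Pr[cbind(sup_rows, sup_y)], 1e-12))) else NA_real_

  out <- list(loss = loss, n_sup = n_sup, probs = Pr, offsets = offs)
  if (!need_grads || n_sup == 0L) return(out)

  g <- list()
  dZ <- matrix(0, N, .N_CLASS)
  dZ[sup_rows, ] <- Pr[sup_rows, , drop = FALSE] / n_sup
  dZ[cbind(sup_rows, sup_y)] <- dZ[cbind(sup_rows, sup_y)] - 1 / n_sup
  g$Wc <- t(lnf$Y) %*% dZ; g$bc <- colSums(dZ)
  bk <- .ln_bwd(dZ %*% t(params$Wc), lnf, params$gf)
  g$gf <- bk$dg; g$bf <- bk$db
  dX <- bk$dX
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- paste0("L", l, "_"); ch <- caches[[l]]
    # FFN block: X3 = X2 + relu(ln2(X2) W1 + c1) W2 + c2
    g[[paste0(pre, "W2")]] <- t(ch$Hh) %*% dX
    g[[paste0(pre, "c2")]] <- colSums(dX)
    dHh <- dX %*% t(params[[paste0(pre, "W2")]])
    dHpre <- dHh * (ch$Hh > 0)
    g[[paste0(pre, "W1")]] <- t(ch$ln2$Y) %*% dHpre
    g[[paste0(pre, "c1")]] <- colSums(dHpre)
    bk2 <- .ln_bwd(dHpre %*% t(params[[paste0(pre, "W1")]]), ch$ln2,
                   params[[paste0(pre, "g2")]])
    g[[paste0(pre, "g2")]] <- bk2$dg; g[[paste0(pre, "b2")]] <- bk2$db
    dX2 <- dX + bk2$dX
    # attention block: X2 = X + attn(ln1(X)) Wo
    g[[paste0(pre, "Wo")]] <- t(ch$O) %*% dX2
    dO <- dX2 %*% t(params[[paste0(pre, "Wo")]])
    dQ <- matrix(0, N, H); dK <- matrix(0, N, H); dV <- matrix(0, N, H)
    for (s in seq_along(ranges)) {
      rs <- ranges[[s]]; A <- ch$As[[s]]
      dOs <- dO[rs, , drop = FALSE]
      dV[rs, ] <- t(A) %*% dOs
      dA <- dOs %*% t(ch$V[rs, , drop = FALSE])
      dS <- A * (dA - rowSums(dA * A))
      dQ[rs, ] <- dS %*% ch$K[rs, , drop = FALSE] * scale
      dK[rs, ] <- t(dS) %*% ch$Q[rs, , drop = FALSE] * scale
    }
    g[[paste0(pre, "Wq")]] <- t(ch$ln1$Y) %*% dQ
    g[[paste0(pre, "Wk")]] <- t(ch$ln1$Y) %*% dK
    g[[paste0(pre, "Wv")]] <- t(ch$ln1$Y) %*% dV
    dXn <- dQ %*% t(params[[paste0(pre, "Wq")]]) +
      dK %*% t(params[[paste0(pre, "Wk")]]) +
      dV %*% t(params[[paste0(pre, "Wv")]])
    bk1 <- .ln_bwd(dXn, ch$ln1, params[[paste0(pre, "g1")]])
    g[[paste0(pre, "g1")]] <- bk1$dg; g[[paste0(pre, "b1")]] <- bk1$db
    dX <- dX2 + bk1$dX
  }
  gE <- matrix(0, nrow(params$E), H)
  agg <- rowsum(dX, group = ids)
  gE[as.integer(rownames(agg)), ] <- agg
  g$E <- gE
  gP <- matrix(0, cfg$max_len, H)
  aggp <- rowsum(dX, group = pos)
  gP[as.integer(rownames(aggp)), ] <- aggp
  g$P <- gP
  out$grads <- g
  out
}

# ---- LSTM ------------------------------------------------------------------

nn_init_lstm <- function(vocab_size, cfg, rng) {
  H <- cfg$d_model; sd <- cfg$init_sd
  p <- list(E = .mat(rng, vocab_size, H, sd))
  dirs <- if (cfg$bidirectional) c("f", "b") else "f"
  for (d in dirs) {
    p[[paste0("Wx_", d)]] <- .mat(rng, H, 4L * H, sd)
    p[[paste0("Wh_", d)]] <- .mat(rng, H, 4L * H, sd)
    p[[paste0("bg_", d)]] <- rep(0, 4L * H)
  }
  out_dim <- H * length(dirs)
  p$Wc <- .mat(rng, out_dim, .N_CLASS, sd); p$bc <- rep(0, .N_CLASS)
  p
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# one directional pass over a single sequence; returns hidden states and
# caches for BPTT
.lstm_dir_fwd <- function(X, Wx, Wh, bg) {
  n <- nrow(X); H <- ncol(X)
  Hs <- matrix(0, n, H)
  cache <- vector("list", n)
  h <- numeric(H); cst <- numeric(H)
  XW <- X %*% Wx
  for (t in seq_len(n)) {
    G <- XW[t, ] + drop(h %*% Wh) + bg
    i <- .sigmoid(G[1:H]); f <- .sigmoid(G[(H + 1):(2 * H)])
    o <- .sigmoid(G[(2 * H + 1):(3 * H)]); gg <- tanh(G[(3 * H + 1):(4 * H)])
    c_prev <- cst
    cst <- f * c_prev + i * gg
    tc <- tanh(cst)
    h_prev <- h
    h <- o * tc
    Hs[t, ] <- h
    cache[[t]] <- list(i = i, f = f, o = o, g = gg, c = cst, tc = tc,
                       c_prev = c_prev, h_prev = h_prev)
  }
  list(Hs = Hs, cache = cache)
}

.lstm_dir_bwd <- function(dHs, X, fwd, Wx, Wh) {
  n <- nrow(X); H <- ncol(X)
  dWx <- matrix(0, H, 4L * H); dWh <- matrix(0, H, 4L * H); dbg <- numeric(4L * H)
  dX <- matrix(0, n, H)
  dh_next <- numeric(H); dc_next <- numeric(H)
  for (t in rev(seq_len(n))) {
    ch <- fwd$cache[[t]]
    dh <- dHs[t, ] + dh_next
    do <- dh * ch$tc
    dc <- dh * ch$o * (1 - ch$tc^2) + dc_next
    di <- dc * ch$g; df <- dc * ch$c_prev; dg <- dc * ch$i
    dG <- c(di * ch$i * (1 - ch$i), df * ch$f * (1 - ch$f),
            do * ch$o * (1 - ch$o), dg * (1 - ch$g^2))
    dWx <- dWx + outer(X[t, ], dG)
    dWh <- dWh + outer(ch$h_prev, dG)
    dbg <- dbg + dG
    dX[t, ] <- drop(Wx %*% dG)
    dh_next <- drop(Wh %*% dG)
    dc_next <- dc * ch$f
  }
  list(dWx = dWx, dWh = dWh, dbg = dbg, dX = dX)
}

nn_lstm_apply <- function(params, batch, cfg, need_grads = TRUE) {
  H <- cfg$d_model
  dirs <- if (cfg$bidirectional) c("f", "b") else "f"
  total_loss <- 0; n_sup_total <- 0L
  grads <- NULL
  probs_list <- vector("list", length(batch))
  for (s in seq_along(batch)) {
    e <- batch[[s]]
    n <- length(e$ids)
    X <- params$E[e$ids, , drop = FALSE]
    passes <- list()
    Hcat <- NULL
    for (d in dirs) {
      Xd <- if (d == "b") X[n:1, , drop = FALSE] else X
      fw <- .lstm_dir_fwd(Xd, params[[paste0("Wx_", d)]],
                          params[[paste0("Wh_", d)]], params[[paste0("bg_", d)]])
      Hd <- if (d == "b") fw$Hs[n:1, , drop = FALSE] else fw$Hs
      passes[[d]] <- list(fw = fw, Xd = Xd, Hd = Hd)
      Hcat <- if (is.null(Hcat)) Hd else cbind(Hcat, Hd)
    }
    Z <- Hcat %*% params$Wc + rep(params$bc, each = n)
    Pr <- .softmax_rows(Z)
    probs_list[[s]] <- Pr

    if (is.null(e$y)) next
    n_sup <- length(e$heads)
    total_loss <- total_loss -
      sum(log(pmax(Pr[cbind(e$heads, e$y)], 1e-12)))
    n_sup_total <- n_sup_total + n_sup
    if (!need_grads) next

    dZ <- matrix(0, n, .N_CLASS)
    dZ[e$heads, ] <- Pr[e$heads, , drop = FALSE]
    dZ[cbind(e$heads, e$y)] <- dZ[cbind(e$heads, e$y)] - 1
    g <- list(Wc = t(Hcat) %*% dZ, bc = colSums(dZ))
    dHcat <- dZ %*% t(params$Wc)
    dXtot <- matrix(0, n, H)
    for (k in seq_along(dirs)) {
      d <- dirs[k]
      dHd <- dHcat[, ((k - 1L) * H + 1L):(k * H), drop = FALSE]
      if (d == "b") dHd <- dHd[n:1, , drop = FALSE]
      bw <- .lstm_dir_bwd(dHd, passes[[d]]$Xd, passes[[d]]$fw,
                          params[[paste0("Wx_", d)]], params[[paste0("Wh_", d)]])
      g[[paste0("Wx_", d)]] <- bw$dWx
      g[[paste0("Wh_", d)]] <- bw$dWh
      g[[paste0("bg_", d)]] <- bw$dbg
      dXd <- if (d == "b") bw$dX[n:1, , drop = FALSE] else bw$dX
      dXtot <- dXtot + dXd
    }
    gE <- matrix(0, nrow(params$E), H)
    agg <- rowsum(dXtot, group = e$ids)
    gE[as.integer(rownames(agg)), ] <- agg
    g$E <- gE
    grads <- if (is.null(grads)) g else .acc_grads(grads, g)
  }
  loss <- if (n_sup_total > 0L) total_loss / n_sup_total else NA_real_
  out <- list(loss = loss, n_sup = n_sup_total, probs_list = probs_list)
  if (need_grads && !is.null(grads)) {
    out$grads <- lapply(grads, function(x) x / n_sup_total)
  }
  out
}

.acc_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

# ---- shared dispatch -------------------------------------------------------

nn_init <- function(backend, vocab_size, cfg, rng) {
  switch(backend,
         transformer = nn_init_transformer(vocab_size, cfg, rng),
         lstm = nn_init_lstm(vocab_size, cfg, rng),
         stop("unknown backend: ", backend))
}

nn_apply <- function(backend, params, batch, cfg, need_grads = TRUE) {
  switch(backend,
         transformer = nn_tf_apply(params, batch, cfg, need_grads),
         lstm = nn_lstm_apply(params, batch, cfg, need_grads),
         stop("unknown backend: ", backend))
}

# per-word class probabilities (words x 4) for one example
nn_head_probs <- function(backend, params, example, cfg) {
  out <- nn_apply(backend, params, list(example), cfg, need_grads = FALSE)
  if (backend == "transformer") {
    out$probs[example$heads, , drop = FALSE]
  } else {
    out$probs_list[[1]][example$heads, , drop = FALSE]
  }
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat * gmat
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
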