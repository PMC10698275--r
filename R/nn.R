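## From-scratch sequence-to-sequence network: convolutional stem with
## residual blocks, sinusoidal positional encoding, transformer encoder
## layers (multi-head self-attention + feed-forward, post-layer-norm), and a
## pointwise head squashed onto the target range.
##
## Batches of B equal-length sequences are processed as flat matrices of
## shape (T*B) x C, column-major with time fastest, so every pointwise layer
## is a single matrix product. Analytic gradients throughout; verified
## against finite differences in the test suite.

## out[t] = in[t - s], zero-filled at the boundary (per sequence)
shift_time <- function(M, T, B, s) {
  if (s == 0L) return(M)
  C <- ncol(M)
  A <- array(M, c(T, B, C))
  out <- array(0, c(T, B, C))
  if (s > 0L) out[(s + 1L):T, , ] <- A[1L:(T - s), , , drop = FALSE]
  else out[1L:(T + s), , ] <- A[(1L - s):T, , , drop = FALSE]
  matrix(out, T * B, C)
}

conv_offsets <- function(k) -(k %/% 2L):(k %/% 2L)

conv_fwd <- function(M, layer, T, B) {
  offs <- conv_offsets(length(layer$W))
  Y <- matrix(0, nrow(M), ncol(layer$W[[1L]]))
  for (j in seq_along(offs))
    Y <- Y + shift_time(M, T, B, -offs[j]) %*% layer$W[[j]]
  sweep(Y, 2L, layer$b, "+")
}

conv_bwd <- function(M, dY, layer, T, B) {
  offs <- conv_offsets(length(layer$W))
  dW <- vector("list", length(offs))
  dM <- matrix(0, nrow(M), ncol(M))
  for (j in seq_along(offs)) {
    dW[[j]] <- crossprod(shift_time(M, T, B, -offs[j]), dY)
    dM <- dM + shift_time(dY %*% t(layer$W[[j]]), T, B, offs[j])
  }
  list(grad = list(W = dW, b = colSums(dY)), dM = dM)
}

relu_fwd <- function(M) M * (M > 0)
relu_bwd <- function(dY, M) dY * (M > 0)

ln_fwd <- function(M, g, b, eps = 1e-5) {
  mu <- rowMeans(M)
  xc <- M - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xh <- xc * inv
  list(Y = sweep(xh * rep(1, nrow(M)) %o% g, 2L, b, "+"), xh = xh, inv = inv)
}

ln_bwd <- function(dY, cache, g) {
  d <- ncol(dY)
  dxh <- sweep(dY, 2L, g, "*")
  xh <- cache$xh
  t1 <- rowSums(dxh) / d
  t2 <- rowSums(dxh * xh) / d
  dM <- (dxh - t1 - xh * t2) * cache$inv
  list(dM = dM, dg = colSums(dY * xh), db = colSums(dY))
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

attn_fwd <- function(M, p, T, B, H) {
  d <- ncol(M)
  dh <- d %/% H
  Q <- sweep(M %*% p$Wq, 2L, p$bq, "+")
  K <- sweep(M %*% p$Wk, 2L, p$bk, "+")
  V <- sweep(M %*% p$Wv, 2L, p$bv, "+")
  O <- matrix(0, nrow(M), d)
  A_list <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    Ab <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[rows, cols, drop = FALSE],
                      K[rows, cols, drop = FALSE]) / sqrt(dh)
      A <- softmax_rows(S)
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      Ab[[h]] <- A
    }
    A_list[[b]] <- Ab
  }
  Y <- sweep(O %*% p$Wo, 2L, p$bo, "+")
  list(Y = Y, Q = Q, K = K, V = V, O = O, A = A_list)
}

attn_bwd <- function(M, dY, cache, p, T, B, H) {
  d <- ncol(M)
  dh <- d %/% H
  dWo <- crossprod(cache$O, dY)
  dbo <- colSums(dY)
  dO <- dY %*% t(p$Wo)
  dQ <- matrix(0, nrow(M), d); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A[[b]][[h]]
      dOh <- dO[rows, cols, drop = FALSE]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[rows, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] / sqrt(dh)
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) / sqrt(dh)
    }
  }
  dM <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(grad = list(Wq = crossprod(M, dQ), bq = colSums(dQ),
                   Wk = crossprod(M, dK), bk = colSums(dK),
                   Wv = crossprod(M, dV), bv = colSums(dV),
                   Wo = dWo, bo = dbo),
       dM = dM)
}

## sinusoidal positional encoding for the actual sequence length
pos_encoding <- function(T, d) {
  pos <- seq_len(T) - 1L
  i <- seq_len(d %/% 2L) - 1L
  rate <- 1 / 10000^(2 * i / d)
  ang <- outer(pos, rate)
  PE <- matrix(0, T, d)
  PE[, seq(1L, d, by = 2L)] <- sin(ang)
  PE[, seq(2L, d, by = 2L)] <- cos(ang)
  PE
}

net_fwd <- function(params, M0, T, B, cfg) {
  cc <- list(M0 = M0)
  z <- conv_fwd(M0, params$stem, T, B); cc$stem_pre <- z
  x <- relu_fwd(z)
  cc$res <- vector("list", length(params$res))
  for (i in seq_along(params$res)) {
    rp <- params$res[[i]]
    a1p <- conv_fwd(x, rp$c1, T, B)
    a1 <- relu_fwd(a1p)
    a2 <- conv_fwd(a1, rp$c2, T, B)
    pre <- x + a2
    cc$res[[i]] <- list(x_in = x, a1p = a1p, a1 = a1, pre = pre)
    x <- relu_fwd(pre)
  }
  PE <- pos_encoding(T, ncol(x))
  x <- x + PE[rep(seq_len(T), B), ]
  cc$enc <- vector("list", length(params$enc))
  for (l in seq_along(params$enc)) {
    ep <- params$enc[[l]]
    at <- attn_fwd(x, ep, T, B, cfg$heads)
    l1 <- ln_fwd(x + at$Y, ep$ln1_g, ep$ln1_b)
    f1p <- sweep(l1$Y %*% ep$W1, 2L, ep$b1, "+")
    f1 <- relu_fwd(f1p)
    f2 <- sweep(f1 %*% ep$W2, 2L, ep$b2, "+")
    l2 <- ln_fwd(l1$Y + f2, ep$ln2_g, ep$ln2_b)
    cc$enc[[l]] <- list(x_in = x, at = at, l1 = l1, f1p = f1p, f1 = f1, l2 = l2)
    x <- l2$Y
  }
  h1p <- sweep(x %*% params$head$W1, 2L, params$head$b1, "+")
  h1 <- relu_fwd(h1p)
  z <- as.numeric(h1 %*% params$head$W2 + params$head$b2)
  sig <- 1 / (1 + exp(-z))
  lo <- cfg$output_range[1]; hi <- cfg$output_range[2]
  y <- lo + (hi - lo) * sig
  cc$x_head <- x; cc$h1p <- h1p; cc$h1 <- h1; cc$sig <- sig
  list(y = matrix(y, T, B), cache = cc)
}

net_bwd <- function(params, cache, dy, T, B, cfg) {
  lo <- cfg$output_range[1]; hi <- cfg$output_range[2]
  sig <- cache$sig
  dz <- as.numeric(dy) * (hi - lo) * sig * (1 - sig)
  g <- list()
  g$head <- list(
    W2 = crossprod(cache$h1, dz), b2 = sum(dz),
    W1 = NULL, b1 = NULL)
  dh1 <- relu_bwd(dz %*% t(params$head$W2), cache$h1p)
  g$head$W1 <- crossprod(cache$x_head, dh1)
  g$head$b1 <- colSums(dh1)
  dx <- dh1 %*% t(params$head$W1)
  g$enc <- vector("list", length(params$enc))
  for (l in rev(seq_along(params$enc))) {
    ep <- params$enc[[l]]; cl <- cache$enc[[l]]
    b2b <- ln_bwd(dx, cl$l2, ep$ln2_g)
    df2 <- b2b$dM
    dW2 <- crossprod(cl$f1, df2); db2 <- colSums(df2)
    df1 <- relu_bwd(df2 %*% t(ep$W2), cl$f1p)
    dW1 <- crossprod(cl$l1$Y, df1); db1 <- colSums(df1)
    dl1 <- b2b$dM + df1 %*% t(ep$W1)
    b1b <- ln_bwd(dl1, cl$l1, ep$ln1_g)
    datt <- b1b$dM
    ab <- attn_bwd(cl$x_in, datt, cl$at, ep, T, B, cfg$heads)
    dx <- b1b$dM + ab$dM
    g$enc[[l]] <- c(ab$grad,
                    list(ln1_g = b1b$dg, ln1_b = b1b$db,
                         W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                         ln2_g = b2b$dg, ln2_b = b2b$db))
  }
  ## positional encoding is additive: gradient passes through unchanged
  g$res <- vector("list", length(params$res))
  for (i in rev(seq_along(params$res))) {
    rp <- params$res[[i]]; cr <- cache$res[[i]]
    dpre <- relu_bwd(dx, cr$pre)
    c2b <- conv_bwd(cr$a1, dpre, rp$c2, T, B)
    da1 <- relu_bwd(c2b$dM, cr$a1p)
    c1b <- conv_bwd(cr$x_in, da1, rp$c1, T, B)
    dx <- dpre + c1b$dM
    g$res[[i]] <- list(c1 = c1b$grad, c2 = c2b$grad)
  }
  dstem <- relu_bwd(dx, cache$stem_pre)
  sb <- conv_bwd(cache$M0, dstem, params$stem, T, B)
  g$stem <- sb$grad
  g
}

## -- parameter initialization ------------------------------------------------

rand_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

init_conv <- function(cin, cout, k) {
  sd <- sqrt(2 / (cin * k))
  list(W = lapply(seq_len(k), function(j) rand_mat(cin, cout, sd)),
       b = rep(0, cout))
}

init_params <- function(cfg) {
  d <- cfg$embed_dim
  ps <- list(stem = init_conv(cfg$n_features, d, cfg$kernel_size))
  ps$res <- lapply(seq_len(cfg$conv_blocks), function(i)
    list(c1 = init_conv(d, d, cfg$kernel_size),
         c2 = init_conv(d, d, cfg$kernel_size)))
  sa <- sqrt(1 / d)
  ps$enc <- lapply(seq_len(cfg$encoder_layers), function(l) list(
    Wq = rand_mat(d, d, sa), bq = rep(0, d),
    Wk = rand_mat(d, d, sa), bk = rep(0, d),
    Wv = rand_mat(d, d, sa), bv = rep(0, d),
    Wo = rand_mat(d, d, sa), bo = rep(0, d),
    ln1_g = rep(1, d), ln1_b = rep(0, d),
    W1 = rand_mat(d, cfg$ffn_dim, sqrt(2 / d)), b1 = rep(0, cfg$ffn_dim),
    W2 = rand_mat(cfg$ffn_dim, d, sqrt(1 / cfg$ffn_dim)), b2 = rep(0, d),
    ln2_g = rep(1, d), ln2_b = rep(0, d)))
  ps$head <- list(W1 = rand_mat(d, cfg$head_dim, sqrt(2 / d)),
                  b1 = rep(0, cfg$head_dim),
                  W2 = rand_mat(cfg$head_dim, 1L, 0.1),
                  b2 = 0)
  ps
}

## -- Adam on the nested parameter list --------------------------------------

adam_init <- function(params) rapply(params, function(x) x * 0, how = "replace")

adam_step <- function(params, grads, m, v, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, mm, vv) {
    if (is.list(p)) {
      if (!is.null(names(p))) {             # align gradient fields by name
        g <- g[names(p)]; mm <- mm[names(p)]; vv <- vv[names(p)]
      }
      out <- mapply(upd, p, g, mm, vv, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    mm <- beta1 * mm + (1 - beta1) * g
    vv <- beta2 * vv + (1 - beta2) * g * g
    mhat <- mm / (1 - beta1^t); vhat <- vv / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = mm, v = vv)
  }
  out <- upd(params, grads, m, v)
  list(params = out$p, m = out$m, v = out$v)
}
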