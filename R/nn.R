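# Small neural-network toolkit: 2D convolutions via im2col, dense layers,
# leaky ReLU, nearest-neighbour upsampling, and Adam. Forward passes cache
# what the hand-written backward passes need; gradients are verified against
# finite differences in the test suite. Feature maps are arrays (H, W, C).

# ---- im2col plan ------------------------------------------------------------

# Precomputed gather indices for one (H, W, k, stride, pad) geometry. Row r of
# $idx lists, for output position r (column-major over Ho x Wo), the k*k
# linear indices into the zero-padded single-channel image.
conv_plan <- function(H, W, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  pos <- seq_len(Ho * Wo) - 1L
  oi <- (pos %% Ho) * stride      # padded row of the window top-left
  oj <- (pos %/% Ho) * stride     # padded col
  tap <- seq_len(k * k) - 1L
  di <- tap %% k; dj <- tap %/% k
  idx <- outer(oj, dj, "+") * Hp + outer(oi, di, "+") + 1L
  list(H = H, W = W, k = k, stride = stride, pad = pad,
       Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, idx = idx)
}

pad_channel <- function(x, plan) {
  if (plan$pad == 0L) return(as.vector(x))
  p <- matrix(0, plan$Hp, plan$Wp)
  p[(plan$pad + 1L):(plan$pad + plan$H), (plan$pad + 1L):(plan$pad + plan$W)] <- x
  as.vector(p)
}

im2col <- function(x, plan) {
  cin <- dim(x)[3L]
  k2 <- plan$k^2
  X <- matrix(0, nrow(plan$idx), k2 * cin)
  for (c in seq_len(cin)) {
    xp <- pad_channel(x[, , c], plan)
    X[, ((c - 1L) * k2 + 1L):(c * k2)] <- xp[plan$idx]
  }
  X
}

# ---- parameter initialisation ----------------------------------------------

conv_par <- function(k, cin, cout) {
  sc <- sqrt(2 / (k * k * cin))
  list(W = matrix(stats::rnorm(k * k * cin * cout) * sc, k * k * cin, cout),
       b = numeric(cout))
}

dense_par <- function(nin, nout) {
  sc <- sqrt(2 / nin)
  list(W = matrix(stats::rnorm(nin * nout) * sc, nin, nout), b = numeric(nout))
}

# ---- forward / backward primitives -----------------------------------------

conv_fwd <- function(x, par, plan) {
  X <- im2col(x, plan)
  Y <- X %*% par$W
  Y <- sweep(Y, 2L, par$b, "+")
  list(y = array(Y, dim = c(plan$Ho, plan$Wo, ncol(par$W))),
       cache = list(X = X, plan = plan, cin = dim(x)[3L]))
}

conv_bwd <- function(dy, par, cache) {
  plan <- cache$plan
  k2 <- plan$k^2
  dY <- matrix(dy, plan$Ho * plan$Wo, ncol(par$W))
  dW <- crossprod(cache$X, dY)
  db <- colSums(dY)
  dX <- dY %*% t(par$W)
  cin <- cache$cin
  dx <- array(0, dim = c(plan$H, plan$W, cin))
  gidx <- as.vector(plan$idx)
  for (c in seq_len(cin)) {
    v <- as.vector(dX[, ((c - 1L) * k2 + 1L):(c * k2)])
    acc <- rowsum(v, gidx)
    dxp <- numeric(plan$Hp * plan$Wp)
    dxp[as.integer(rownames(acc))] <- acc
    dpm <- matrix(dxp, plan$Hp, plan$Wp)
    dx[, , c] <- dpm[(plan$pad + 1L):(plan$pad + plan$H),
                     (plan$pad + 1L):(plan$pad + plan$W)]
  }
  list(dx = dx, dW = dW, db = db)
}

dense_fwd <- function(x, par) {
  y <- as.vector(x %*% par$W) + par$b
  list(y = y, cache = x)
}

dense_bwd <- function(dy, par, x) {
  list(dx = as.vector(par$W %*% dy),
       dW = outer(as.vector(x), dy), db = dy)
}

lrelu_fwd <- function(x, a = 0.2) {
  y <- ifelse(x > 0, x, a * x)
  list(y = y, cache = x > 0)
}

lrelu_bwd <- function(dy, mask, a = 0.2) dy * ifelse(mask, 1, a)

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1L, d[1L], by = 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2L], by = 2L); j2 <- j1 + 1L
  dy[i1, j1, , drop = FALSE] + dy[i2, j1, , drop = FALSE] +
    dy[i1, j2, , drop = FALSE] + dy[i2, j2, , drop = FALSE]
}

# fixed (parameter-free) bilinear upsampling by an integer factor, with
# replicate edges; used as the base prediction of the super-resolution stage
bilinear_upsample <- function(x, factor) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]
  Hf <- H * factor; Wf <- W * factor
  # pixel-centre alignment, clamped to the source grid (replicate edges)
  src <- function(n, N) pmin(pmax((seq_len(N) - 0.5) / factor + 0.5, 1), n)
  yi <- src(H, Hf); xj <- src(W, Wf)
  xp <- rep(xj, each = Hf); yp <- rep(yi, times = Wf)
  out <- array(0, dim = c(Hf, Wf, d[3L]))
  for (c in seq_len(d[3L])) {
    v <- pracma::interp2(x = seq_len(W), y = seq_len(H), Z = x[, , c],
                         xp = xp, yp = yp, method = "linear")
    out[, , c] <- matrix(v, Hf, Wf)
  }
  out
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = grad_zero_like(params), v = grad_zero_like(params), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# params/grads are arbitrarily nested lists of numeric arrays with identical
# shape; returns list(params, state)
adam_update <- function(params, grads, state, lr = 1e-3,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  step <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else step(p, g, m, v)
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

# elementwise sum of two identically shaped nested gradient lists
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) Map(grad_add, a, b) else a + b
}

grad_scale <- function(a, s) {
  if (is.list(a)) lapply(a, grad_scale, s = s) else a * s
}

grad_zero_like <- function(p) {
  if (is.list(p)) lapply(p, grad_zero_like)
  else {
    z <- p
    z[] <- 0
    z
  }
}
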