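# Minimal dense-prediction network layers on base R matrices.
#
# A batch of N single- or multi-channel rasters of common size H x W is
# held as one matrix X of dim (N*H*W) x C: rows are image-major, pixels
# column-major within an image (R's native flatten). Convolutions are
# im2col + BLAS GEMM; every layer has a hand-written backward pass,
# verified by finite-difference tests.

nn_rows <- function(n, HW) ((n - 1L) * HW + 1L):(n * HW)

# Geometry cache: for each raster size, the linear indices of the interior
# of a zero-padded (H+2) x (W+2) plane and the 3x3 neighbourhood gather
# indices (9*H*W, offsets enumerated dj = -1..1 outer, di = -1..1 inner,
# so reversing the 9 offsets gives the flipped kernel).
.nn_geom <- new.env(parent = emptyenv())

nn_geom <- function(H, W) {
  key <- paste0(H, "x", W)
  g <- .nn_geom[[key]]
  if (!is.null(g)) return(g)
  Hp <- H + 2L
  inner <- as.vector(outer(2:(H + 1L), (2:(W + 1L) - 1L) * Hp, `+`))
  L <- vector("list", 9L)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    L[[k]] <- as.vector(outer((2:(H + 1L)) + di,
                              ((2:(W + 1L)) + dj - 1L) * Hp, `+`))
  }
  g <- list(inner = inner, gather = unlist(L), np = Hp * (W + 2L))
  .nn_geom[[key]] <- g
  g
}

# im2col via one indexed gather: input (H*W) x Cin -> (H*W) x (9*Cin),
# column j corresponds to offset k = (j-1) %% 9 + 1, channel
# cin = (j-1) %/% 9 + 1 (weight rows use the same layout)
nn_im2col <- function(Xn, H, W, g = nn_geom(H, W)) {
  Cin <- ncol(Xn)
  P <- matrix(0, g$np, Cin)
  P[g$inner, ] <- Xn
  M <- P[g$gather, , drop = FALSE]
  dim(M) <- c(H * W, 9L * Cin)
  M
}

nn_conv3_fwd <- function(X, H, W, N, Wt, b) {
  HW <- H * W
  Cin <- ncol(X)
  g <- nn_geom(H, W)
  Cout <- ncol(Wt)
  Y <- matrix(0, N * HW, Cout)
  Ms <- vector("list", N)
  for (n in seq_len(N)) {
    rows <- nn_rows(n, HW)
    Mn <- nn_im2col(X[rows, , drop = FALSE], H, W, g)
    Ms[[n]] <- Mn
    Y[rows, ] <- Mn %*% Wt
  }
  Y <- Y + rep(b, each = N * HW)
  list(Y = Y, M = Ms)
}

# kernel flipped and transposed for the input gradient: (9*Cout) x Cin
nn_flip_kernel <- function(Wt) {
  Cin <- nrow(Wt) %/% 9L
  Cout <- ncol(Wt)
  A <- Wt
  dim(A) <- c(9L, Cin, Cout)
  A <- A[9:1, , , drop = FALSE]
  B <- aperm(A, c(1, 3, 2))
  dim(B) <- c(9L * Cout, Cin)
  B
}

nn_conv3_bwd <- function(dY, Ms, Wt, H, W, N) {
  HW <- H * W
  Cin <- nrow(Wt) %/% 9L
  g <- nn_geom(H, W)
  B <- nn_flip_kernel(Wt)
  dW <- 0
  dX <- matrix(0, N * HW, Cin)
  for (n in seq_len(N)) {
    rows <- nn_rows(n, HW)
    dYn <- dY[rows, , drop = FALSE]
    dW <- dW + crossprod(Ms[[n]], dYn)
    dX[rows, ] <- nn_im2col(dYn, H, W, g) %*% B
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

nn_bn_fwd <- function(X, gamma, beta, rmean, rvar, train,
                      momentum = 0.1, eps = 1e-5) {
  R <- nrow(X)
  if (train) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = R)
    v <- colMeans(xc * xc)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean
    v <- rvar
    xc <- X - rep(mu, each = R)
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- xc * rep(ivar, each = R)
  Y <- xhat * rep(gamma, each = R) + rep(beta, each = R)
  list(Y = Y, xhat = xhat, ivar = ivar, rmean = rmean, rvar = rvar)
}

nn_bn_bwd <- function(dY, xhat, ivar, gamma) {
  R <- nrow(dY)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(gamma, each = R)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dX <- (dxhat - rep(s1 / R, each = R) - xhat * rep(s2 / R, each = R)) *
    rep(ivar, each = R)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# 2x2 max pooling; H and W must be even. Child indices are precomputed for
# the (H, W, N) geometry.
nn_pool_idx <- function(H, W, N) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  i <- rep(seq_len(H2), W2)            # pooled row (1-based)
  j <- rep(seq_len(W2), each = H2)     # pooled col
  base <- list(
    (2L * j - 2L) * H + (2L * i - 1L),
    (2L * j - 2L) * H + (2L * i),
    (2L * j - 1L) * H + (2L * i - 1L),
    (2L * j - 1L) * H + (2L * i))
  off <- (seq_len(N) - 1L) * (H * W)
  lapply(base, function(b) as.vector(outer(b, off, `+`)))
}

nn_maxpool_fwd <- function(X, H, W, N) {
  idx <- nn_pool_idx(H, W, N)
  x1 <- X[idx[[1]], , drop = FALSE]; x2 <- X[idx[[2]], , drop = FALSE]
  x3 <- X[idx[[3]], , drop = FALSE]; x4 <- X[idx[[4]], , drop = FALSE]
  Y <- pmax(x1, x2, x3, x4)
  list(Y = Y, idx = idx, parts = list(x1, x2, x3, x4))
}

nn_maxpool_bwd <- function(dY, cache, X_nrow, C) {
  dX <- matrix(0, X_nrow, C)
  taken <- matrix(FALSE, nrow(dY), ncol(dY))
  Y <- pmax(cache$parts[[1]], cache$parts[[2]],
            cache$parts[[3]], cache$parts[[4]])
  for (k in 1:4) {
    m <- (cache$parts[[k]] == Y) & !taken
    taken <- taken | m
    D <- dY; D[!m] <- 0
    dX[cache$idx[[k]], ] <- D
  }
  dX
}

# nearest-neighbour 2x upsampling
nn_up_idx <- function(H, W, N) {
  H2 <- 2L * H; W2 <- 2L * W
  i <- rep(seq_len(H2), W2)
  j <- rep(seq_len(W2), each = H2)
  base <- (ceiling(j / 2) - 1L) * H + ceiling(i / 2)
  off <- (seq_len(N) - 1L) * (H * W)
  as.vector(outer(as.integer(base), off, `+`))
}

nn_upsample_fwd <- function(X, H, W, N) {
  u <- nn_up_idx(H, W, N)
  list(Y = X[u, , drop = FALSE], u = u)
}

nn_upsample_bwd <- function(dY, u, X_nrow) {
  dX <- rowsum(dY, group = u)          # group ids 1..X_nrow all present
  dX
}

nn_relu_fwd <- function(X) {
  Y <- X
  Y[Y < 0] <- 0
  list(Y = Y, mask = X > 0)
}

# ---- network definition ------------------------------------------------

nn_he_init <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))

# Flat named parameter list for a U-shaped encoder-decoder. The head bias
# starts at the logit of a ~1% foreground prior: seed pixels are a tiny
# minority, and starting the output near the background rate keeps the
# early cross-entropy gradients focused on the seeds instead of first
# having to learn "mostly background".
unet_init_params <- function(depth, base, in_channels = 1L,
                             head_bias = stats::qlogis(0.01)) {
  p <- list()
  add_conv <- function(name, cin, cout) {
    p[[paste0(name, ".W")]] <<- matrix(nn_he_init(9 * cin, 9 * cin * cout),
                                       9 * cin, cout)
    p[[paste0(name, ".b")]] <<- numeric(cout)
  }
  add_bn <- function(name, c) {
    p[[paste0(name, ".gamma")]] <<- rep(1, c)
    p[[paste0(name, ".beta")]] <<- numeric(c)
    p[[paste0(name, ".rmean")]] <<- numeric(c)
    p[[paste0(name, ".rvar")]] <<- rep(1, c)
  }
  cin <- in_channels
  for (l in seq_len(depth)) {
    cl <- base * 2^(l - 1)
    add_conv(sprintf("enc%d.c1", l), cin, cl); add_bn(sprintf("enc%d.b1", l), cl)
    add_conv(sprintf("enc%d.c2", l), cl, cl);  add_bn(sprintf("enc%d.b2", l), cl)
    cin <- cl
  }
  cb <- base * 2^depth
  add_conv("bott.c1", cin, cb); add_bn("bott.b1", cb)
  add_conv("bott.c2", cb, cb);  add_bn("bott.b2", cb)
  below <- cb
  for (l in rev(seq_len(depth))) {
    cl <- base * 2^(l - 1)
    add_conv(sprintf("dec%d.c1", l), below + cl, cl)
    add_bn(sprintf("dec%d.b1", l), cl)
    add_conv(sprintf("dec%d.c2", l), cl, cl)
    add_bn(sprintf("dec%d.b2", l), cl)
    below <- cl
  }
  p[["head.W"]] <- matrix(nn_he_init(base, base), base, 1)
  p[["head.b"]] <- head_bias
  p
}

# forward through the whole network; returns logits plus a tape for
# backward. `train` toggles batch-norm statistics.
unet_forward <- function(p, X, H, W, N, depth, train = TRUE) {
  tape <- list()
  push <- function(rec) tape[[length(tape) + 1L]] <<- rec
  cbr_fwd <- function(prefix_c, prefix_b, X, H, W, N) {
    cv <- nn_conv3_fwd(X, H, W, N, p[[paste0(prefix_c, ".W")]],
                       p[[paste0(prefix_c, ".b")]])
    bn <- nn_bn_fwd(cv$Y, p[[paste0(prefix_b, ".gamma")]],
                    p[[paste0(prefix_b, ".beta")]],
                    p[[paste0(prefix_b, ".rmean")]],
                    p[[paste0(prefix_b, ".rvar")]], train)
    if (train) {
      p[[paste0(prefix_b, ".rmean")]] <<- bn$rmean
      p[[paste0(prefix_b, ".rvar")]] <<- bn$rvar
    }
    rl <- nn_relu_fwd(bn$Y)
    push(list(op = "cbr", c = prefix_c, b = prefix_b, M = cv$M,
              xhat = bn$xhat, ivar = bn$ivar, mask = rl$mask,
              H = H, W = W, N = N))
    rl$Y
  }
  cur <- X; curH <- H; curW <- W
  skips <- list()
  for (l in seq_len(depth)) {
    cur <- cbr_fwd(sprintf("enc%d.c1", l), sprintf("enc%d.b1", l),
                   cur, curH, curW, N)
    cur <- cbr_fwd(sprintf("enc%d.c2", l), sprintf("enc%d.b2", l),
                   cur, curH, curW, N)
    skips[[l]] <- list(Y = cur, H = curH, W = curW)
    mp <- nn_maxpool_fwd(cur, curH, curW, N)
    push(list(op = "pool", cache = mp, in_nrow = nrow(cur), C = ncol(cur)))
    cur <- mp$Y; curH <- curH %/% 2L; curW <- curW %/% 2L
  }
  cur <- cbr_fwd("bott.c1", "bott.b1", cur, curH, curW, N)
  cur <- cbr_fwd("bott.c2", "bott.b2", cur, curH, curW, N)
  for (l in rev(seq_len(depth))) {
    up <- nn_upsample_fwd(cur, curH, curW, N)
    push(list(op = "up", u = up$u, in_nrow = nrow(cur)))
    cur <- up$Y; curH <- 2L * curH; curW <- 2L * curW
    sk <- skips[[l]]
    push(list(op = "concat", c1 = ncol(cur), c2 = ncol(sk$Y)))
    cur <- cbind(cur, sk$Y)
    cur <- cbr_fwd(sprintf("dec%d.c1", l), sprintf("dec%d.b1", l),
                   cur, curH, curW, N)
    cur <- cbr_fwd(sprintf("dec%d.c2", l), sprintf("dec%d.b2", l),
                   cur, curH, curW, N)
  }
  logits <- cur %*% p[["head.W"]] + p[["head.b"]]
  push(list(op = "head", X = cur))
  list(logits = logits, tape = tape, p = p)
}

# backward pass over the tape; returns flat gradient list (same names as
# trainable params) and nothing else
unet_backward <- function(p, tape, dlogits, depth) {
  g <- list()
  i <- length(tape)
  rec <- tape[[i]]; i <- i - 1L          # head
  g[["head.W"]] <- crossprod(rec$X, dlogits)
  g[["head.b"]] <- sum(dlogits)
  dcur <- tcrossprod(dlogits, p[["head.W"]])
  skip_grads <- list()
  cbr_bwd <- function(rec, dY) {
    dY[!rec$mask] <- 0
    bn <- nn_bn_bwd(dY, rec$xhat, rec$ivar, p[[paste0(rec$b, ".gamma")]])
    g[[paste0(rec$b, ".gamma")]] <<- bn$dgamma
    g[[paste0(rec$b, ".beta")]] <<- bn$dbeta
    cv <- nn_conv3_bwd(bn$dX, rec$M, p[[paste0(rec$c, ".W")]],
                       rec$H, rec$W, rec$N)
    g[[paste0(rec$c, ".W")]] <<- cv$dW
    g[[paste0(rec$c, ".b")]] <<- cv$db
    cv$dX
  }
  # decoder: per level dec.c2, dec.c1, concat, up
  for (l in seq_len(depth)) {
    dcur <- cbr_bwd(tape[[i]], dcur); i <- i - 1L   # dec c2
    dcur <- cbr_bwd(tape[[i]], dcur); i <- i - 1L   # dec c1
    rec <- tape[[i]]; i <- i - 1L                   # concat
    dskip <- dcur[, (rec$c1 + 1L):(rec$c1 + rec$c2), drop = FALSE]
    dcur <- dcur[, seq_len(rec$c1), drop = FALSE]
    skip_grads[[length(skip_grads) + 1L]] <- dskip
    rec <- tape[[i]]; i <- i - 1L                   # up
    dcur <- nn_upsample_bwd(dcur, rec$u, rec$in_nrow)
  }
  dcur <- cbr_bwd(tape[[i]], dcur); i <- i - 1L     # bott c2
  dcur <- cbr_bwd(tape[[i]], dcur); i <- i - 1L     # bott c1
  # encoder in reverse; the decoder backward ran levels 1..depth, so
  # skip_grads[[l]] is the gradient flowing into encoder level l's skip
  for (l in rev(seq_len(depth))) {
    rec <- tape[[i]]; i <- i - 1L                   # pool
    dcur <- nn_maxpool_bwd(dcur, rec$cache, rec$in_nrow, rec$C)
    dcur <- dcur + skip_grads[[l]]
    dcur <- cbr_bwd(tape[[i]], dcur); i <- i - 1L   # enc c2
    dcur <- cbr_bwd(tape[[i]], dcur); i <- i - 1L   # enc c1
  }
  g
}

# names of trainable parameters (BN running stats are not optimized)
nn_trainable <- function(p)
  names(p)[!grepl("\\.(rmean|rvar)$", names(p))]

nn_adam_init <- function(p) {
  tr <- nn_trainable(p)
  list(m = lapply(p[tr], function(x) x * 0),
       v = lapply(p[tr], function(x) x * 0), t = 0L)
}

nn_adam_step <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(state$m)) {
    if (is.null(g[[nm]])) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, state = state)
}

# loss and gradient w.r.t. logits for BCE + Dice on a stacked batch
nn_loss_grad <- function(logits, target, smooth = 1, eps = 1e-7) {
  prob <- stats::plogis(logits)
  pc <- pmin(pmax(prob, eps), 1 - eps)
  R <- length(pc)
  bce <- -mean(target * log(pc) + (1 - target) * log(1 - pc))
  sp <- sum(prob); st <- sum(target); spt <- sum(prob * target)
  denom <- sp + st + smooth
  dice <- 1 - (2 * spt + smooth) / denom
  dldp <- -(2 * target * denom - (2 * spt + smooth)) / denom^2
  dz <- (prob - target) / R + dldp * prob * (1 - prob)
  list(loss = bce + dice, bce = bce, dice = dice, dlogits = dz)
}
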