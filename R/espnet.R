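# Small encoder-decoder segmentation network, written directly on matrix
# operations. Feature maps are (H*W) x C matrices in column-major pixel
# order; convolutions are im2col matrix products, so the whole model is
# plain BLAS and is deterministic for a fixed seed.
#
# Architecture (base width w, K classes):
#   esp1: 1x1 reduce (3 -> w/2) + parallel 3x3 convs at dilation 1 and 2
#         with hierarchical fusion, concat -> w channels, full resolution
#   down: 2x2 average pool of esp1 concatenated with a pooled copy of the
#         RGB input (input-aware encoding) -> w + 3 channels, half res
#   esp2: same block shape (reduce to w, branches w) -> 2w channels
#   dec:  upsample(esp2) ++ esp1 ++ input (dense skips) -> 3x3 conv -> w
#   head: class scores = 1x1(dec) + 1x1(esp1) + upsample(1x1(esp2)),
#         i.e. three decoding paths combined before the softmax

relu <- function(x) { x[x < 0] <- 0; x }

conv_index_map <- function(H, W, d) {
  N <- H * W
  ys <- rep.int(seq_len(H), W)
  xs <- rep(seq_len(W), each = H)
  idx <- matrix(0L, N, 9L)
  o <- 0L
  for (dx in c(-d, 0L, d)) for (dy in c(-d, 0L, d)) {
    o <- o + 1L
    ny <- ys + dy; nx <- xs + dx
    ok <- ny >= 1L & ny <= H & nx >= 1L & nx <= W
    idx[, o] <- ifelse(ok, ny + H * (nx - 1L), N + 1L)
  }
  idx
}

pool_index_map <- function(H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  y2 <- rep.int(seq_len(H2), W2); x2 <- rep(seq_len(W2), each = H2)
  by <- 2L * y2 - 1L; bx <- 2L * x2 - 1L
  lin <- function(y, x) y + H * (x - 1L)
  cbind(lin(by, bx), lin(by + 1L, bx), lin(by, bx + 1L), lin(by + 1L, bx + 1L))
}

up_index_map <- function(H2, W2) {
  H <- 2L * H2; W <- 2L * W2
  ys <- rep.int(seq_len(H), W)
  xs <- rep(seq_len(W), each = H)
  ((ys + 1L) %/% 2L) + H2 * (((xs + 1L) %/% 2L) - 1L)
}

conv3_fwd <- function(X, idx, Wt, b) {
  Cin <- ncol(X)
  Xp <- rbind(X, 0)
  P <- matrix(0, nrow(X), 9L * Cin)
  for (o in 1:9) P[, ((o - 1L) * Cin + 1L):(o * Cin)] <- Xp[idx[, o], , drop = FALSE]
  list(Y = sweep(P %*% Wt, 2L, b, "+"), P = P)
}

conv3_bwd <- function(dY, P, idx, Wt, Cin) {
  N <- nrow(dY)
  dP <- dY %*% t(Wt)
  dX <- matrix(0, N + 1L, Cin)
  for (o in 1:9) {
    cols <- ((o - 1L) * Cin + 1L):(o * Cin)
    dX[idx[, o], ] <- dX[idx[, o], ] + dP[, cols, drop = FALSE]
  }
  list(dX = dX[seq_len(N), , drop = FALSE],
       dW = crossprod(P, dY), db = colSums(dY))
}

avgpool_fwd <- function(X, pmap) {
  (X[pmap[, 1], , drop = FALSE] + X[pmap[, 2], , drop = FALSE] +
   X[pmap[, 3], , drop = FALSE] + X[pmap[, 4], , drop = FALSE]) / 4
}

avgpool_bwd <- function(dY, pmap, N) {
  dX <- matrix(0, N, ncol(dY))
  for (j in 1:4) dX[pmap[, j], ] <- dX[pmap[, j], ] + dY / 4
  dX
}

he_w <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
}

espnet_init <- function(width = 8, n_classes = 8, seed = 1) {
  w <- as.integer(width)
  b1 <- max(1L, w %/% 2L)
  set.seed(seed)
  list(
    r1W = he_w(3L, b1), r1b = numeric(b1),
    a1W = he_w(9L * b1, b1), a1b = numeric(b1),
    b1W = he_w(9L * b1, b1), b1b = numeric(b1),
    r2W = he_w(2L * b1 + 3L, w), r2b = numeric(w),
    a2W = he_w(9L * w, w), a2b = numeric(w),
    b2W = he_w(9L * w, w), b2b = numeric(w),
    dW = he_w(9L * (2L * w + 2L * b1 + 3L), w), db = numeric(w),
    hAW = he_w(w, n_classes), hAb = numeric(n_classes),
    hBW = he_w(2L * b1, n_classes), hBb = numeric(n_classes),
    hCW = he_w(2L * w, n_classes), hCb = numeric(n_classes),
    width = w, b1 = b1, n_classes = as.integer(n_classes))
}

# ESP-style unit: 1x1 reduction, two dilated 3x3 branches, hierarchical
# fusion (second branch adds the first), concatenation, ReLU
esp_fwd <- function(X, m1, m2, Wr, br, Wa, ba, Wb, bb) {
  R0 <- sweep(X %*% Wr, 2L, br, "+")
  R <- relu(R0)
  A <- conv3_fwd(R, m1, Wa, ba)
  B <- conv3_fwd(R, m2, Wb, bb)
  O0 <- cbind(A$Y, A$Y + B$Y)
  list(out = relu(O0), O0 = O0, A = A, B = B, R = R, R0 = R0, X = X)
}

esp_bwd <- function(dOut, cache, m1, m2, Wr, Wa, Wb) {
  b <- ncol(cache$A$Y)
  dO0 <- dOut * (cache$O0 > 0)
  d1 <- dO0[, seq_len(b), drop = FALSE]
  d2 <- dO0[, b + seq_len(b), drop = FALSE]
  bwA <- conv3_bwd(d1 + d2, cache$A$P, m1, Wa, ncol(cache$R))
  bwB <- conv3_bwd(d2, cache$B$P, m2, Wb, ncol(cache$R))
  dR <- (bwA$dX + bwB$dX) * (cache$R0 > 0)
  list(dX = dR %*% t(Wr),
       grads = list(rW = crossprod(cache$X, dR), rb = colSums(dR),
                    aW = bwA$dW, ab = bwA$db, bW = bwB$dW, bb = bwB$db))
}

espnet_fwd <- function(X0, H, W, p, maps = NULL) {
  if (is.null(maps)) maps <- espnet_maps(H, W)
  e1 <- esp_fwd(X0, maps$m1, maps$m2, p$r1W, p$r1b, p$a1W, p$a1b, p$b1W, p$b1b)
  z <- cbind(avgpool_fwd(e1$out, maps$pmap), avgpool_fwd(X0, maps$pmap))
  e2 <- esp_fwd(z, maps$m1h, maps$m2h, p$r2W, p$r2b, p$a2W, p$a2b,
                p$b2W, p$b2b)
  up <- e2$out[maps$umap, , drop = FALSE]
  dcat <- cbind(up, e1$out, X0)
  dc <- conv3_fwd(dcat, maps$m1, p$dW, p$db)
  dec <- relu(dc$Y)
  sA <- sweep(dec %*% p$hAW, 2L, p$hAb, "+")
  sB <- sweep(e1$out %*% p$hBW, 2L, p$hBb, "+")
  sC0 <- sweep(e2$out %*% p$hCW, 2L, p$hCb, "+")
  scores <- sA + sB + sC0[maps$umap, , drop = FALSE]
  list(scores = scores, e1 = e1, e2 = e2, z = z, up = up, dc = dc,
       dec = dec, X0 = X0, maps = maps)
}

espnet_maps <- function(H, W) {
  list(m1 = conv_index_map(H, W, 1L), m2 = conv_index_map(H, W, 2L),
       m1h = conv_index_map(H %/% 2L, W %/% 2L, 1L),
       m2h = conv_index_map(H %/% 2L, W %/% 2L, 2L),
       pmap = pool_index_map(H, W), umap = up_index_map(H %/% 2L, W %/% 2L))
}

espnet_bwd <- function(dS, fw, p) {
  maps <- fw$maps
  N <- nrow(fw$X0); N2 <- nrow(fw$e2$out)
  g <- list()
  # heads
  g$hAW <- crossprod(fw$dec, dS); g$hAb <- colSums(dS)
  g$hBW <- crossprod(fw$e1$out, dS); g$hBb <- colSums(dS)
  dSC <- rowsum(dS, maps$umap)            # gradient at half resolution
  g$hCW <- crossprod(fw$e2$out, dSC); g$hCb <- colSums(dSC)
  de1 <- dS %*% t(p$hBW)
  de2 <- dSC %*% t(p$hCW)
  # decoder conv
  ddec <- (dS %*% t(p$hAW)) * (fw$dc$Y > 0)
  bwD <- conv3_bwd(ddec, fw$dc$P, maps$m1, p$dW, ncol(fw$dc$P) / 9L)
  g$dW <- bwD$dW; g$db <- bwD$db
  cu <- ncol(fw$e2$out); c1 <- ncol(fw$e1$out)
  de2 <- de2 + rowsum(bwD$dX[, seq_len(cu), drop = FALSE], maps$umap)
  de1 <- de1 + bwD$dX[, cu + seq_len(c1), drop = FALSE]
  # encoder stage 2
  bw2 <- esp_bwd(de2, fw$e2, maps$m1h, maps$m2h, p$r2W, p$a2W, p$b2W)
  g$r2W <- bw2$grads$rW; g$r2b <- bw2$grads$rb
  g$a2W <- bw2$grads$aW; g$a2b <- bw2$grads$ab
  g$b2W <- bw2$grads$bW; g$b2b <- bw2$grads$bb
  dz1 <- bw2$dX[, seq_len(c1), drop = FALSE]     # pooled esp1 part
  de1 <- de1 + avgpool_bwd(dz1, maps$pmap, N)
  # encoder stage 1
  bw1 <- esp_bwd(de1, fw$e1, maps$m1, maps$m2, p$r1W, p$a1W, p$b1W)
  g$r1W <- bw1$grads$rW; g$r1b <- bw1$grads$rb
  g$a1W <- bw1$grads$aW; g$a1b <- bw1$grads$ab
  g$b1W <- bw1$grads$bW; g$b1b <- bw1$grads$bb
  g
}

softmax_rows <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

espnet_loss_grad <- function(scores, yidx) {
  p <- softmax_rows(scores)
  n <- length(yidx)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), yidx)], 1e-12)))
  dS <- p
  dS[cbind(seq_len(n), yidx)] <- dS[cbind(seq_len(n), yidx)] - 1
  list(loss = loss, dS = dS / n)
}

espnet_param_names <- function() {
  c("r1W", "r1b", "a1W", "a1b", "b1W", "b1b",
    "r2W", "r2b", "a2W", "a2b", "b2W", "b2b",
    "dW", "db", "hAW", "hAb", "hBW", "hBb", "hCW", "hCb")
}

espnet_train <- function(patches, model, epochs = 30, seed = 1,
                         lr = NULL) {
  p <- model$params
  if (is.null(lr)) lr <- model$config$learning_rate
  classes <- model$classes
  for (pt in patches) {
    d <- dim(as_pixel_array(pt$image))
    if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
      stop("patch dimensions must be divisible by 4")
  }
  nm <- espnet_param_names()
  mom <- stats::setNames(lapply(nm, function(n) p[[n]] * 0), nm)
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L
  set.seed(seed)
  loss_trace <- numeric(epochs)
  # precompute per-patch inputs and per-shape index maps
  inputs <- lapply(patches, function(pt) {
    px <- as_pixel_array(pt$image)
    list(X0 = matrix(as.numeric(px), ncol = 3L) / 255 - 0.5,
         H = dim(px)[1], W = dim(px)[2],
         yidx = match(as.vector(pt$labels), classes))
  })
  shapes <- unique(lapply(inputs, function(i) c(i$H, i$W)))
  mapcache <- lapply(shapes, function(s) espnet_maps(s[1], s[2]))
  shape_of <- vapply(inputs, function(i) {
    which(vapply(shapes, function(s) all(s == c(i$H, i$W)), logical(1)))
  }, integer(1))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(inputs))
    tot <- 0
    for (i in ord) {
      inp <- inputs[[i]]
      fw <- espnet_fwd(inp$X0, inp$H, inp$W, p, mapcache[[shape_of[i]]])
      lg <- espnet_loss_grad(fw$scores, inp$yidx)
      tot <- tot + lg$loss
      g <- espnet_bwd(lg$dS, fw, p)
      t <- t + 1L
      for (n in nm) {
        mom[[n]] <- beta1 * mom[[n]] + (1 - beta1) * g[[n]]
        vel[[n]] <- beta2 * vel[[n]] + (1 - beta2) * g[[n]]^2
        mhat <- mom[[n]] / (1 - beta1^t)
        vhat <- vel[[n]] / (1 - beta2^t)
        p[[n]] <- p[[n]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    loss_trace[ep] <- tot / length(inputs)
  }
  list(params = p, loss_trace = loss_trace)
}

reflect_pad <- function(px, target_h, target_w) {
  h <- dim(px)[1]; w <- dim(px)[2]
  ri <- seq_len(target_h); ci <- seq_len(target_w)
  refl <- function(i, n) {
    i <- (i - 1L) %% (2L * n)
    ifelse(i < n, i + 1L, 2L * n - i)
  }
  px[refl(ri, h), refl(ci, w), , drop = FALSE]
}

espnet_scores <- function(px, model) {
  p <- model$params
  X0 <- matrix(as.numeric(px), ncol = 3L) / 255 - 0.5
  fw <- espnet_fwd(X0, dim(px)[1], dim(px)[2], p)
  softmax_rows(fw$scores)
}

espnet_predict <- function(px, model) {
  ps <- model$config$patch_size
  h <- dim(px)[1]; w <- dim(px)[2]
  K <- length(model$classes)
  if (h < ps || w < ps) {
    th <- max(h, ps); tw <- max(w, ps)
    th <- ((th + 3L) %/% 4L) * 4L; tw <- ((tw + 3L) %/% 4L) * 4L
    padded <- reflect_pad(px, th, tw)
    pr <- espnet_scores(padded, model)
    probs <- array(pr, c(th, tw, K))[seq_len(h), seq_len(w), , drop = FALSE]
    lab <- apply(matrix(probs, ncol = K), 1L, which.max)
    return(matrix(model$classes[lab], h, w))
  }
  stride <- ps %/% 2L
  acc <- array(0, c(h, w, K))
  cnt <- matrix(0, h, w)
  for (y0 in window_starts(h, ps, stride)) {
    for (x0 in window_starts(w, ps, stride)) {
      tile <- px[(y0 + 1L):(y0 + ps), (x0 + 1L):(x0 + ps), , drop = FALSE]
      pr <- array(espnet_scores(tile, model), c(ps, ps, K))
      acc[(y0 + 1L):(y0 + ps), (x0 + 1L):(x0 + ps), ] <-
        acc[(y0 + 1L):(y0 + ps), (x0 + 1L):(x0 + ps), , drop = FALSE] + pr
      cnt[(y0 + 1L):(y0 + ps), (x0 + 1L):(x0 + ps)] <-
        cnt[(y0 + 1L):(y0 + ps), (x0 + 1L):(x0 + ps)] + 1
    }
  }
  lab <- apply(matrix(acc, ncol = K), 1L, which.max)
  matrix(model$classes[lab], h, w)
}
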