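# Internal minimal convolutional network machinery for the reference
# detector. Activations are stored as (positions * batch) x channels
# matrices with positions row-major (col fastest) and rows grouped by
# image; convolutions are BLAS matmuls over precomputed im2col index
# maps. Everything is 3x3 stride-2 pad-1 (each stage halves the map) so
# the feature pyramid lines up with the default-box grid.

hard_swish <- function(x) x * pmin(pmax(x + 3, 0), 6) / 6

hard_swish_grad <- function(x) {
  mid <- x > -3 & x < 3
  mid * (2 * x + 3) / 6 + (x >= 3)
}

# source-position map for a 3x3 stride-2 pad-1 conv: (npos_out x 9)
# matrix of input position indices, 0 where the tap falls on padding
conv_src_map <- function(h_in, w_in) {
  h_out <- ceiling(h_in / 2); w_out <- ceiling(w_in / 2)
  pos <- expand.grid(c_o = seq_len(w_out), r_o = seq_len(h_out))  # col fastest
  src <- matrix(0L, nrow(pos), 9)
  k <- 0
  for (dr in 0:2) for (dc in 0:2) {
    k <- k + 1
    in_r <- 2 * pos$r_o - 2 + dr
    in_c <- 2 * pos$c_o - 2 + dc
    ok <- in_r >= 1 & in_r <= h_in & in_c >= 1 & in_c <= w_in
    src[ok, k] <- (in_r[ok] - 1L) * w_in + in_c[ok]
  }
  attr(src, "out_size") <- c(h_out, w_out)
  src
}

# batch gather indices: src position 0 -> the appended zero row
batch_gather_ix <- function(src_col, npos_in, B) {
  zero_row <- npos_in * B + 1L
  off <- rep((seq_len(B) - 1L) * npos_in, each = length(src_col))
  gix <- rep(src_col, B) + off
  gix[rep(src_col == 0L, B)] <- zero_row
  gix
}

im2col <- function(X, src, B) {
  npos_in <- nrow(X) / B
  Xp <- rbind(X, 0)
  cols <- vector("list", 9)
  for (k in 1:9) {
    cols[[k]] <- Xp[batch_gather_ix(src[, k], npos_in, B), , drop = FALSE]
  }
  do.call(cbind, cols)   # (npos_out*B) x (9*C_in), kernel-tap-major blocks
}

# Inverse tap map: inv[i, k] is the output position whose k-th kernel
# tap reads input position i (0 if none). For a fixed tap the stride-2
# output -> input map is injective, so this is well defined and lets the
# backward col2im be 9 gathers instead of scatter-adds.
inv_src_map <- function(src, npos_in) {
  inv <- matrix(0L, npos_in, 9)
  for (k in 1:9) {
    live <- which(src[, k] != 0L)
    inv[src[live, k], k] <- live
  }
  inv
}

col2im <- function(dcol, inv, npos_out, npos_in, B, C_in) {
  dX <- matrix(0, npos_in * B, C_in)
  dcolp <- rbind(dcol, 0)
  zero_row <- npos_out * B + 1L
  off <- rep((seq_len(B) - 1L) * npos_out, each = npos_in)
  for (k in 1:9) {
    gix <- rep(inv[, k], B) + off
    gix[rep(inv[, k] == 0L, B)] <- zero_row
    dX <- dX + dcolp[gix, ((k - 1) * C_in + 1):(k * C_in), drop = FALSE]
  }
  dX
}

init_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# A standard 3x3 stride-2 conv layer; W is (9*C_in) x C_out
make_conv <- function(h_in, w_in, C_in, C_out) {
  src <- conv_src_map(h_in, w_in)
  list(type = "conv", src = src, inv = inv_src_map(src, h_in * w_in),
       C_in = C_in, C_out = C_out,
       npos_in = h_in * w_in, npos_out = nrow(src),
       out_size = attr(src, "out_size"),
       W = init_mat(9 * C_in, C_out, 9 * C_in), b = numeric(C_out))
}

# Depthwise-separable stage: per-channel 3x3 stride-2 (Wd is 9 x C_in)
# followed by a 1x1 pointwise conv (Wp is C_in x C_out)
make_dwsep <- function(h_in, w_in, C_in, C_out) {
  src <- conv_src_map(h_in, w_in)
  list(type = "dwsep", src = src, C_in = C_in, C_out = C_out,
       npos_in = h_in * w_in, out_size = attr(src, "out_size"),
       Wd = init_mat(9, C_in, 9), bd = numeric(C_in),
       Wp = init_mat(C_in, C_out, C_in), b = numeric(C_out))
}

conv_forward <- function(layer, X, B, Xcol = NULL) {
  if (layer$type == "conv") {
    if (is.null(Xcol)) Xcol <- im2col(X, layer$src, B)
    Z <- Xcol %*% layer$W + matrix(layer$b, nrow(Xcol), layer$C_out, byrow = TRUE)
    list(Z = Z, A = hard_swish(Z), cache = list(Xcol = Xcol))
  } else {
    npos_in <- nrow(X) / B
    Xp <- rbind(X, 0)
    Zd <- matrix(0, nrow(layer$src) * B, layer$C_in)
    gixs <- vector("list", 9)
    for (k in 1:9) {
      gixs[[k]] <- batch_gather_ix(layer$src[, k], npos_in, B)
      Zd <- Zd + Xp[gixs[[k]], , drop = FALSE] *
        matrix(layer$Wd[k, ], nrow(Zd), layer$C_in, byrow = TRUE)
    }
    Zd <- Zd + matrix(layer$bd, nrow(Zd), layer$C_in, byrow = TRUE)
    Ad <- hard_swish(Zd)
    Z <- Ad %*% layer$Wp + matrix(layer$b, nrow(Ad), layer$C_out, byrow = TRUE)
    list(Z = Z, A = hard_swish(Z),
         cache = list(Xp = Xp, gixs = gixs, Zd = Zd, Ad = Ad))
  }
}

conv_backward <- function(layer, dA, fwd, X, B, need_dx = TRUE) {
  dZ <- dA * hard_swish_grad(fwd$Z)
  if (layer$type == "conv") {
    dW <- crossprod(fwd$cache$Xcol, dZ)
    db <- colSums(dZ)
    dX <- NULL
    if (need_dx) {
      dcol <- tcrossprod(dZ, layer$W)
      dX <- col2im(dcol, layer$inv, layer$npos_out, layer$npos_in, B, layer$C_in)
    }
    list(grads = list(W = dW, b = db), dX = dX)
  } else {
    dAd <- tcrossprod(dZ, layer$Wp)
    dWp <- crossprod(fwd$cache$Ad, dZ)
    db <- colSums(dZ)
    dZd <- dAd * hard_swish_grad(fwd$cache$Zd)
    dbd <- colSums(dZd)
    dWd <- matrix(0, 9, layer$C_in)
    dXp <- matrix(0, nrow(fwd$cache$Xp), layer$C_in)
    B_loc <- (nrow(fwd$cache$Xp) - 1) / layer$npos_in
    for (k in 1:9) {
      gix <- fwd$cache$gixs[[k]]
      Xk <- fwd$cache$Xp[gix, , drop = FALSE]
      dWd[k, ] <- colSums(Xk * dZd)
      contrib <- dZd * matrix(layer$Wd[k, ], nrow(dZd), layer$C_in, byrow = TRUE)
      live <- layer$src[, k] != 0L
      if (!all(live)) {
        live_b <- rep(live, B_loc)
        gix <- gix[live_b]
        contrib <- contrib[live_b, , drop = FALSE]
      }
      dXp[gix, ] <- dXp[gix, , drop = FALSE] + contrib
    }
    list(grads = list(Wd = dWd, bd = dbd, Wp = dWp, b = db),
         dX = dXp[seq_len(layer$npos_in * B), , drop = FALSE])
  }
}

# 1x1 head: plain matmul. W is C_in x C_out.
make_head <- function(C_in, C_out) {
  list(W = init_mat(C_in, C_out, C_in), b = numeric(C_out))
}

head_forward <- function(head, X) {
  X %*% head$W + matrix(head$b, nrow(X), length(head$b), byrow = TRUE)
}

head_backward <- function(head, X, dY) {
  list(grads = list(W = crossprod(X, dY), b = colSums(dY)),
       dX = tcrossprod(dY, head$W))
}

# Reshape one image's head output (npos x (4*C_per)) into default-box
# rows ((npos*4) x C_per), defaults ordered position-major then slot --
# matching the default_box_grid ordering (row, col, slot).
head_to_defaults <- function(Y_i, C_per) {
  t(matrix(t(Y_i), nrow = C_per))
}

defaults_to_head <- function(D_i, C_per, npos) {
  # inverse of head_to_defaults
  t(matrix(t(D_i), ncol = npos))
}

flatten_image <- function(img) {
  # H x W x 3 array -> (H*W) x 3 with position index (y-1)*W + x
  matrix(aperm(img, c(2, 1, 3)), dim(img)[1] * dim(img)[2], dim(img)[3])
}
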