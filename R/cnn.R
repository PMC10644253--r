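# CNN-FC internals: 2x2 valid convolutions and 2x2/stride-2 max pooling,
# implemented with precomputed index maps so each sample is a handful of
# matrix operations. The second convolution is depthwise (one 2x2 kernel per
# feature map), the reading under which its parameter count is 2*2*32 + 32.

# index map: for a h x h grid, the 4 source linear indices of each 2x2 patch
conv_patch_idx <- function(h) {
  s <- h - 1L
  ij <- expand.grid(i = seq_len(s), j = seq_len(s))
  cbind((ij$j - 1L) * h + ij$i,          # (i,   j)
        (ij$j - 1L) * h + ij$i + 1L,     # (i+1, j)
        ij$j * h + ij$i,                 # (i,   j+1)
        ij$j * h + ij$i + 1L)            # (i+1, j+1)
}

# index map: 2x2 stride-2 pooling of a s x s grid down to p x p (p = s %/% 2)
pool_idx <- function(s) {
  p <- s %/% 2L
  ab <- expand.grid(a = seq_len(p), b = seq_len(p))
  cbind((2L * ab$b - 2L) * s + 2L * ab$a - 1L,
        (2L * ab$b - 2L) * s + 2L * ab$a,
        (2L * ab$b - 1L) * s + 2L * ab$a - 1L,
        (2L * ab$b - 1L) * s + 2L * ab$a)
}

cnn_maps <- function(dims) {
  list(P1 = conv_patch_idx(dims$side), I1 = pool_idx(dims$s1),
       P2 = conv_patch_idx(dims$p1),  I2 = pool_idx(dims$s2))
}

max_pool <- function(M, I) {
  out <- M[I[, 1], , drop = FALSE]
  which <- matrix(1L, nrow(out), ncol(out))
  for (o in 2:4) {
    V <- M[I[, o], , drop = FALSE]
    sel <- V > out
    out[sel] <- V[sel]
    which[sel] <- o
  }
  list(out = out, which = which)
}

max_pool_back <- function(dout, which, I, n_src, nmap) {
  dM <- matrix(0, n_src, nmap)
  for (o in 1:4) {
    tmp <- dout * (which == o)
    dM[I[, o], ] <- dM[I[, o], ] + tmp
  }
  dM
}

cnn_forward_one <- function(img, p, dims, maps) {
  v <- as.vector(img)
  patches <- matrix(v[maps$P1], nrow(maps$P1), 4)
  Z1c <- patches %*% p$K1 + rep(p$c1b, each = nrow(maps$P1))
  M1 <- relu(Z1c)
  pl1 <- max_pool(M1, maps$I1)
  Z2 <- matrix(rep(p$c2b, each = nrow(maps$P2)), nrow(maps$P2), dims$nmap)
  for (o in 1:4) {
    Z2 <- Z2 + pl1$out[maps$P2[, o], , drop = FALSE] *
      rep(p$K2[o, ], each = nrow(maps$P2))
  }
  M2 <- relu(Z2)
  pl2 <- max_pool(M2, maps$I2)
  f <- as.vector(pl2$out)
  logits <- drop(f %*% p$W) + p$b
  list(logits = logits, f = f, patches = patches, Z1c = Z1c, M1 = M1,
       pl1 = pl1, Z2 = Z2, M2 = M2, pl2 = pl2)
}

cnn_backward_one <- function(dlogits, cache, p, dims, maps, grads) {
  grads$W <- grads$W + outer(cache$f, dlogits)
  grads$b <- grads$b + dlogits
  dM2p <- matrix(p$W %*% dlogits, ncol = dims$nmap)
  dM2 <- max_pool_back(dM2p, cache$pl2$which, maps$I2,
                       nrow(maps$P2), dims$nmap)
  dZ2 <- dM2 * relu_grad(cache$Z2)
  for (o in 1:4) {
    grads$K2[o, ] <- grads$K2[o, ] +
      colSums(cache$pl1$out[maps$P2[, o], , drop = FALSE] * dZ2)
  }
  grads$c2b <- grads$c2b + colSums(dZ2)
  dM1p <- matrix(0, nrow(maps$I1), dims$nmap)
  for (o in 1:4) {
    dM1p[maps$P2[, o], ] <- dM1p[maps$P2[, o], ] +
      dZ2 * rep(p$K2[o, ], each = nrow(dZ2))
  }
  dM1 <- max_pool_back(dM1p, cache$pl1$which, maps$I1,
                       nrow(maps$P1), dims$nmap)
  dZ1 <- dM1 * relu_grad(cache$Z1c)
  grads$K1 <- grads$K1 + crossprod(cache$patches, dZ1)
  grads$c1b <- grads$c1b + colSums(dZ1)
  grads
}

#' Forward pass of the CNN baseline on one PLV image
#'
#' @param img square numeric matrix (the sparse PLV matrix as an image).
#' @param model a `vnfc_model` of kind cnn.
#' @return List with `prob` and `logits`.
#' @export
cnn_forward <- function(img, model) {
  stopifnot(inherits(model, "vnfc_model"), model$kind == "cnn")
  if (nrow(img) != model$dims$side) {
    rlang::abort(sprintf("image is %d x %d but model expects side %d",
                         nrow(img), ncol(img), model$dims$side))
  }
  maps <- cnn_maps(model$dims)
  fw <- cnn_forward_one(img, model$params, model$dims, maps)
  list(prob = drop(softmax_rows(matrix(fw$logits, 1))), logits = fw$logits)
}
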