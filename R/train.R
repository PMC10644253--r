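#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs passes over the training set (default 100).
#' @param batch_size mini-batch size (default 64).
#' @param seed RNG seed controlling batching; fixed and logged so training is
#'   bit-reproducible in single-threaded runs.
#' @param verbose print a line per 10 epochs.
#' @return A `vnfc_train_config` list.
#' @export
train_config <- function(lr = 1e-3, epochs = 100, batch_size = 64,
                         seed = 1, verbose = FALSE) {
  stopifnot(lr > 0, epochs >= 0, batch_size >= 1)
  structure(list(optimizer = "adam", lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss = "categorical_crossentropy", verbose = verbose),
            class = "vnfc_train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

# Mini-batches for the graph models: node activations of all samples are
# stacked row-wise, so everything except the operator product is one dense
# matrix operation per batch; the block-diagonal operator product is a short
# loop of small dense multiplies. Batch composition is fixed once per
# training run (order is shuffled each epoch).
prep_gcn_batches <- function(S_list, y_idx, m, batch_size, seed) {
  n <- length(S_list)
  set.seed(seed)
  ord <- sample.int(n)
  parts <- split(ord, ceiling(seq_along(ord) / batch_size))
  lapply(parts, function(idx) {
    list(S = S_list[idx],
         rs = unlist(lapply(S_list[idx], rowSums), use.names = FALSE),
         noderep = rep(seq_len(m), length(idx)),
         y = y_idx[idx], B = length(idx), idx = idx, m = m)
  })
}

# block-diagonal product: out[rows_b, ] = S_b %*% H[rows_b, ] per sample b
block_mult <- function(S_blocks, H, m) {
  out <- H
  off <- 0L
  for (S in S_blocks) {
    rows <- (off + 1L):(off + m)
    out[rows, ] <- S %*% H[rows, , drop = FALSE]
    off <- off + m
  }
  out
}

flatten_batch <- function(H, m, h, B) {
  # (B*m) x h stacked node activations -> B x (m*h) rows of as.vector(H_b)
  t(matrix(aperm(array(H, c(m, B, h)), c(1, 3, 2)), m * h, B))
}

unflatten_batch <- function(Fm, m, h, B) {
  matrix(aperm(array(t(Fm), c(m, h, B)), c(1, 3, 2)), B * m, h)
}

# With all-ones node features, S X is the degree vector replicated across
# feature columns, so layer 1 collapses to an outer product: (S X W)[i, f] =
# rs_i * sum_k W[k, f]. The corresponding weight gradient has identical rows.
gcn_batch_forward <- function(p, d, bt) {
  Z1 <- outer(bt$rs, colSums(p$W1)) + p$b1[bt$noderep, , drop = FALSE]
  H1 <- relu(Z1)
  SH1 <- block_mult(bt$S, H1, bt$m)
  Z2 <- SH1 %*% p$W2 + p$b2[bt$noderep, , drop = FALSE]
  H2 <- relu(Z2)
  Fm <- flatten_batch(H2, d$m, d$h2, bt$B)
  logits <- sweep(Fm %*% p$W3, 2, p$b3, "+")
  P <- softmax_rows(logits)
  list(P = P, Fm = Fm, Z1 = Z1, H1 = H1, SH1 = SH1, Z2 = Z2)
}

gcn_batch_backward <- function(p, d, bt, fw) {
  B <- bt$B
  Y <- matrix(0, B, ncol(fw$P))
  Y[cbind(seq_len(B), bt$y)] <- 1
  dZ3 <- (fw$P - Y) / B
  dW3 <- crossprod(fw$Fm, dZ3)
  db3 <- colSums(dZ3)
  dF <- tcrossprod(dZ3, p$W3)
  dH2 <- unflatten_batch(dF, d$m, d$h2, B)
  dZ2 <- dH2 * relu_grad(fw$Z2)
  dW2 <- crossprod(fw$SH1, dZ2)
  db2 <- rowsum(dZ2, bt$noderep)
  dH1 <- block_mult(bt$S, tcrossprod(dZ2, p$W2), bt$m)
  dZ1 <- dH1 * relu_grad(fw$Z1)
  dW1 <- matrix(drop(bt$rs %*% dZ1), nrow(p$W1), ncol(p$W1), byrow = TRUE)
  db1 <- rowsum(dZ1, bt$noderep)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

#' Train an identification model
#'
#' Minimizes categorical cross-entropy with Adam. For the graph models the
#' inputs are the per-window propagation operators (from
#' [renormalized_operator()] on the augmented or plain PLV graph); for the
#' CNN they are the per-window sparse PLV matrices as images. Training is
#' deterministic for a fixed `config$seed` in single-threaded runs.
#'
#' @param model a `vnfc_model`.
#' @param inputs list of per-window inputs (m x m operators, or side x side
#'   images for `cnn_fc`).
#' @param labels per-window subject labels (coercible to factor; at least 2
#'   distinct values).
#' @param config a [train_config()].
#' @return The fitted `vnfc_model`, with `$classes` set and a `$history`
#'   tibble (epoch, loss, accuracy on the training batches).
#' @export
train_model <- function(model, inputs, labels, config = train_config()) {
  stopifnot(inherits(model, "vnfc_model"), inherits(config, "vnfc_train_config"))
  labels <- factor(labels)
  if (nlevels(labels) < 2) rlang::abort("training needs at least 2 classes")
  if (nlevels(labels) != model$n_classes) {
    rlang::abort(sprintf("model was built for %d classes but data has %d",
                         model$n_classes, nlevels(labels)))
  }
  if (length(inputs) != length(labels)) {
    rlang::abort("inputs and labels differ in length")
  }
  model$classes <- levels(labels)
  model$config <- config
  if (config$epochs == 0L) {
    model$history <- tibble::tibble(epoch = integer(), loss = numeric(),
                                    accuracy = numeric())
    return(model)
  }
  y_idx <- as.integer(labels)
  p <- model$params
  st <- adam_init(p)
  hist <- vector("list", config$epochs)

  if (model$kind == "gcn") {
    bts <- prep_gcn_batches(inputs, y_idx, model$dims$m,
                            config$batch_size, config$seed)
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0; ep_hit <- 0; ntot <- 0
      for (bi in sample.int(length(bts))) {
        bt <- bts[[bi]]
        fw <- gcn_batch_forward(p, model$dims, bt)
        ll <- -sum(log(pmax(fw$P[cbind(seq_len(bt$B), bt$y)], 1e-12)))
        if (!is.finite(ll)) {
          rlang::abort(sprintf("non-finite loss at epoch %d (batch %d)", ep, bi))
        }
        ep_loss <- ep_loss + ll
        ep_hit <- ep_hit + sum(max.col(fw$P) == bt$y)
        ntot <- ntot + bt$B
        gr <- gcn_batch_backward(p, model$dims, bt, fw)
        upd <- adam_step(p, gr, st, config$lr)
        p <- upd$params; st <- upd$state
      }
      hist[[ep]] <- c(ep_loss / ntot, ep_hit / ntot)
      if (config$verbose && ep %% 10 == 0) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep,
                        ep_loss / ntot, ep_hit / ntot))
      }
    }
  } else {
    maps <- cnn_maps(model$dims)
    n <- length(inputs)
    set.seed(config$seed)
    parts <- split(sample.int(n), ceiling(seq_len(n) / config$batch_size))
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0; ep_hit <- 0
      for (bi in sample.int(length(parts))) {
        idx <- parts[[bi]]
        B <- length(idx)
        gr <- zero_like(p)
        bl <- 0
        for (s in idx) {
          fw <- cnn_forward_one(inputs[[s]], p, model$dims, maps)
          pr <- drop(softmax_rows(matrix(fw$logits, 1)))
          bl <- bl - log(max(pr[y_idx[s]], 1e-12))
          ep_hit <- ep_hit + (which.max(pr) == y_idx[s])
          dlog <- pr
          dlog[y_idx[s]] <- dlog[y_idx[s]] - 1
          gr <- cnn_backward_one(dlog / B, fw, p, model$dims, maps, gr)
        }
        if (!is.finite(bl)) rlang::abort(sprintf("non-finite loss at epoch %d", ep))
        ep_loss <- ep_loss + bl
        upd <- adam_step(p, gr, st, config$lr)
        p <- upd$params; st <- upd$state
      }
      hist[[ep]] <- c(ep_loss / n, ep_hit / n)
      if (config$verbose && ep %% 10 == 0) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep,
                        ep_loss / n, ep_hit / n))
      }
    }
  }
  model$params <- p
  hm <- do.call(rbind, hist)
  model$history <- tibble::tibble(epoch = seq_len(config$epochs),
                                  loss = hm[, 1], accuracy = hm[, 2])
  model
}

#' Predict subject identities
#'
#' @param object a fitted `vnfc_model`.
#' @param inputs list of per-window inputs (operators or images, matching the
#'   model kind).
#' @param ... unused.
#' @return A tibble with the predicted class per window (`pred`), its softmax
#'   probability (`prob`), and the full probability matrix as attribute
#'   `"prob_matrix"` (rows sum to 1).
#' @export
predict.vnfc_model <- function(object, inputs, ...) {
  if (is.null(object$classes)) rlang::abort("model has not been trained")
  probs <- if (object$kind == "gcn") {
    t(vapply(inputs, function(S) gcn_forward(S, object)$prob,
             numeric(object$n_classes)))
  } else {
    t(vapply(inputs, function(img) cnn_forward(img, object)$prob,
             numeric(object$n_classes)))
  }
  colnames(probs) <- object$classes
  out <- tibble::tibble(
    pred = factor(object$classes[max.col(probs, ties.method = "first")],
                  levels = object$classes),
    prob = probs[cbind(seq_len(nrow(probs)), max.col(probs, ties.method = "first"))]
  )
  attr(out, "prob_matrix") <- probs
  out
}

#' @describeIn train_model broom-style one-row training summary.
#' @param x a fitted `vnfc_model`.
#' @export
glance.vnfc_model <- function(x, ...) {
  tibble::tibble(
    model = x$name,
    n_params = count_parameters(x),
    n_classes = x$n_classes,
    trained = !is.null(x$classes),
    final_loss = if (!is.null(x$history) && nrow(x$history))
      x$history$loss[nrow(x$history)] else NA_real_,
    final_accuracy = if (!is.null(x$history) && nrow(x$history))
      x$history$accuracy[nrow(x$history)] else NA_real_
  )
}

#' @describeIn train_model broom-style per-layer tidy summary (parameter
#'   table).
#' @export
tidy.vnfc_model <- function(x, ...) parameter_table(x)
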