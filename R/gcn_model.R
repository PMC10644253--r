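# leaky ReLU: hidden units never die permanently, which matters here because
# every layer input is non-negative (PLV weights, degrees), so a unit whose
# weights turn negative would otherwise be dead for *all* samples at once
relu <- function(x) pmax(x, 0) + 0.01 * pmin(x, 0)

relu_grad <- function(z) (z > 0) + 0.01 * (z <= 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

glorot <- function(nin, nout, n_row = nin) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(n_row * nout, -lim, lim), n_row, nout)
}

#' Build an identification model
#'
#' Three architectures are available, sharing the head
#' `flatten -> dense -> softmax` trained with categorical cross-entropy:
#'
#' * `"vn_gcn"`: two graph convolutions (widths 32 then 8) on the
#'   virtual-node-augmented graph (73 nodes for the default montage), flatten
#'   to 584, dense to `n_classes`.
#' * `"tinas_gcn"`: the same two graph convolutions on the plain 64-node PLV
#'   graph (no virtual nodes), flatten to 512.
#' * `"cnn_fc"`: the PLV matrix consumed as an image: 2x2 convolution
#'   (1 -> 32 maps), 2x2 max-pool, 2x2 depthwise convolution (one 2x2 kernel
#'   per map), 2x2 max-pool, flatten (7,200 for a 64 x 64 input), dense.
#'
#' Graph-convolution layers follow `X' = sigma(S X W + b)` with the
#' renormalized operator `S` ([renormalized_operator()]) and a per-node,
#' per-feature bias matrix `b` (m x out); hidden activations are leaky ReLU
#' (slope 0.01 below zero).
#'
#' @param name one of `"vn_gcn"`, `"tinas_gcn"`, `"cnn_fc"`.
#' @param n_classes number of subjects to identify (default 109).
#' @param n_channels number of real electrode channels (default 64; for
#'   `cnn_fc` this is the input image side).
#' @param n_groups number of electrode groups / local virtual nodes used by
#'   `vn_gcn` (default 8).
#' @param feature_dim input node-feature dimension N (default 32).
#' @param hidden widths of the two graph convolutions (default `c(32, 8)`).
#' @param seed RNG seed for weight initialization (Glorot uniform; biases 0).
#' @return A `vnfc_model` with untrained parameters.
#' @examples
#' m <- build_model("vn_gcn", n_classes = 109)
#' count_parameters(m)  # 67965, reported as 68.0 k
#' @export
build_model <- function(name = c("vn_gcn", "tinas_gcn", "cnn_fc"),
                        n_classes = 109, n_channels = 64, n_groups = 8,
                        feature_dim = 32, hidden = c(32, 8), seed = 1) {
  name <- match.arg(name)
  if (n_classes < 2) rlang::abort("need at least 2 classes")
  set.seed(seed)
  if (name == "cnn_fc") {
    side <- n_channels
    nmap <- 32L
    s1 <- side - 1L; p1 <- s1 %/% 2L
    s2 <- p1 - 1L; p2 <- s2 %/% 2L
    if (s2 < 1) rlang::abort("input image too small for the CNN architecture")
    flat <- p2 * p2 * nmap
    params <- list(
      K1 = glorot(4, nmap), c1b = numeric(nmap),
      K2 = matrix(stats::runif(4 * nmap, -sqrt(6 / 5), sqrt(6 / 5)), 4, nmap),
      c2b = numeric(nmap),
      W = glorot(flat, n_classes), b = numeric(n_classes)
    )
    dims <- list(side = side, nmap = nmap, s1 = s1, p1 = p1, s2 = s2, p2 = p2,
                 flatten = flat)
  } else {
    m <- if (name == "vn_gcn") n_channels + n_groups + 1L else n_channels
    h1 <- hidden[1]; h2 <- hidden[2]
    params <- list(
      W1 = glorot(feature_dim, h1), b1 = matrix(0, m, h1),
      W2 = glorot(h1, h2), b2 = matrix(0, m, h2),
      W3 = glorot(m * h2, n_classes), b3 = numeric(n_classes)
    )
    dims <- list(m = m, feature_dim = feature_dim, h1 = h1, h2 = h2,
                 flatten = m * h2)
  }
  structure(list(name = name, kind = if (name == "cnn_fc") "cnn" else "gcn",
                 n_classes = n_classes, n_channels = n_channels,
                 n_groups = n_groups, dims = dims, params = params,
                 classes = NULL, seed = seed),
            class = "vnfc_model")
}

#' @export
print.vnfc_model <- function(x, ...) {
  cat(sprintf("<vnfc_model %s: %s params, %d classes%s>\n", x$name,
              format(count_parameters(x), big.mark = ","), x$n_classes,
              if (is.null(x$classes)) " (untrained)" else ""))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model a `vnfc_model`.
#' @return Integer: the exact number of trainable scalars.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "vnfc_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' Per-layer parameter table
#'
#' @param model a `vnfc_model`.
#' @return Tibble with layer name, output shape, exact parameter count and
#'   the count rounded to 0.1 k (the conventional reporting unit).
#' @export
parameter_table <- function(model) {
  stopifnot(inherits(model, "vnfc_model"))
  p <- model$params; d <- model$dims
  if (model$kind == "gcn") {
    tb <- tibble::tibble(
      layer = c("graph_conv_1", "graph_conv_2", "flatten", "dense", "softmax"),
      output = c(sprintf("%d x %d", d$m, d$h1), sprintf("%d x %d", d$m, d$h2),
                 sprintf("%d x 1", d$flatten),
                 sprintf("%d x 1", model$n_classes),
                 sprintf("%d x 1", model$n_classes)),
      n_params = c(length(p$W1) + length(p$b1), length(p$W2) + length(p$b2),
                   0L, length(p$W3) + length(p$b3), 0L)
    )
  } else {
    tb <- tibble::tibble(
      layer = c("conv_1", "pool_1", "conv_2_depthwise", "pool_2", "flatten",
                "dense", "softmax"),
      output = c(sprintf("%d x %d x %d", d$s1, d$s1, d$nmap),
                 sprintf("%d x %d x %d", d$p1, d$p1, d$nmap),
                 sprintf("%d x %d x %d", d$s2, d$s2, d$nmap),
                 sprintf("%d x %d x %d", d$p2, d$p2, d$nmap),
                 sprintf("%d x 1", d$flatten),
                 sprintf("%d x 1", model$n_classes),
                 sprintf("%d x 1", model$n_classes)),
      n_params = c(length(p$K1) + length(p$c1b), 0L,
                   length(p$K2) + length(p$c2b), 0L, 0L,
                   length(p$W) + length(p$b), 0L)
    )
  }
  tb$kilo <- round(tb$n_params / 1000, 1)
  tb
}

#' Forward pass of a graph-convolution model on one graph
#'
#' Applies the two layers `X' = relu(S X W + b)`, flattens the m x 8 output
#' column-major, applies the dense layer and a softmax.
#'
#' @param S propagation operator from [renormalized_operator()].
#' @param X node-feature matrix (defaults to all-ones of the right shape).
#' @param model a `vnfc_model` of kind gcn.
#' @return List with `prob` (softmax scores summing to 1), `logits`, and the
#'   hidden activations `H1`, `H2`.
#' @export
gcn_forward <- function(S, model, X = NULL) {
  stopifnot(inherits(model, "vnfc_model"), model$kind == "gcn")
  d <- model$dims; p <- model$params
  if (nrow(S) != d$m) {
    rlang::abort(sprintf("operator is %d x %d but model expects m = %d",
                         nrow(S), ncol(S), d$m))
  }
  if (is.null(X)) X <- make_node_features(d$m, d$feature_dim)
  H1 <- relu(S %*% X %*% p$W1 + p$b1)
  H2 <- relu(S %*% H1 %*% p$W2 + p$b2)
  logits <- drop(as.vector(H2) %*% p$W3) + p$b3
  prob <- drop(softmax_rows(matrix(logits, 1)))
  list(prob = prob, logits = logits, H1 = H1, H2 = H2)
}

#' Write a JSON architecture manifest for a model
#'
#' Records the model name, per-layer output shapes and parameter counts, the
#' exact total, and any deliberate shape conventions (the per-node bias, the
#' depthwise second convolution of the CNN, and the 73 x 32 first
#' graph-convolution output adopted over an inconsistent 63 x 32 variant).
#'
#' @param model a `vnfc_model`.
#' @param path output JSON file.
#' @return The manifest list, invisibly.
#' @export
model_manifest <- function(model, path) {
  stopifnot(inherits(model, "vnfc_model"))
  tb <- parameter_table(model)
  notes <- c(
    "graph-convolution bias is per-node, per-feature (m x out)",
    if (model$name == "vn_gcn")
      "graph convolution I output is 73 x 32; a 63 x 32 variant is inconsistent with the 73-node graph and the 584 flatten length",
    if (model$name == "cnn_fc")
      "convolution II is depthwise (one 2x2 kernel per map): 2*2*32 + 32 = 160 parameters"
  )
  man <- list(
    model = model$name,
    n_classes = model$n_classes,
    layers = lapply(seq_len(nrow(tb)), function(i) {
      list(layer = tb$layer[i], output = tb$output[i], n_params = tb$n_params[i])
    }),
    total_params = count_parameters(model),
    conventions = notes
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(man)
}
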