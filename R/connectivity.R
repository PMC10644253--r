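#' Instantaneous phase via the analytic signal
#'
#' Each channel's instantaneous phase is the angle of its analytic signal,
#' obtained by the discrete Hilbert transform (FFT one-sided spectrum
#' doubling). Channels are demeaned first so the DC offset does not bias the
#' phase; no band-pass is applied by default, matching a pipeline that works
#' on raw broadband signals.
#'
#' @param x channels x samples numeric matrix (or a single numeric vector),
#'   at least 8 samples.
#' @return Matrix of the same shape with phases wrapped to `(-pi, pi]`.
#' @export
instantaneous_phase <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) rlang::abort("signal contains non-finite values")
  n <- ncol(x)
  if (n < 8) rlang::abort("need at least 8 samples for phase estimation")
  power <- apply(x, 1, function(ch) sum((ch - mean(ch))^2))
  if (any(power == 0)) {
    rlang::abort(sprintf("phase undefined for constant channel(s): %s",
                         paste(which(power == 0), collapse = ", ")))
  }
  xc <- x - rowMeans(x)
  # analytic signal: zero negative frequencies, double positive ones
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- t(stats::mvfft(t(xc)))
  analytic <- t(stats::mvfft(t(X * rep(h, each = nrow(x))), inverse = TRUE)) / n
  ph <- Arg(analytic)
  ph[ph <= -pi] <- ph[ph <= -pi] + 2 * pi   # wrap to (-pi, pi]
  ph
}

#' Phase-locking value between two phase sequences
#'
#' PLV is the modulus of the time-averaged unit phasor of the phase
#' difference, `| mean_t exp(i (phi_x(t) - phi_y(t))) |`. It is 1 for strict
#' phase coupling (any constant phase lag) and tends to 0 for independent
#' phases as the window grows.
#'
#' @param phix,phiy equal-length numeric vectors of phases (radians).
#' @return A scalar in `[0, 1]`.
#' @export
plv_pair <- function(phix, phiy) {
  if (length(phix) != length(phiy)) rlang::abort("phase sequences differ in length")
  if (length(phix) < 1) rlang::abort("empty phase sequence")
  min(1, Mod(mean(exp(1i * (phix - phiy)))))
}

#' PLV functional-connectivity matrix
#'
#' Computes all `n(n-1)/2` pairwise phase-locking values of a window in one
#' complex matrix product and mirrors them into a symmetric matrix with unit
#' diagonal.
#'
#' @param x channels x samples numeric data matrix, or a phase matrix already
#'   produced by [instantaneous_phase()] (pass `is_phase = TRUE`).
#' @param is_phase set `TRUE` if `x` already holds phases in radians.
#' @return A `vnfc_plv`: symmetric n x n matrix, entries in `[0, 1]`,
#'   `diag == 1`.
#' @examples
#' x <- matrix(rnorm(4 * 256), 4)
#' P <- plv_matrix(x)
#' all(P >= 0 & P <= 1); isSymmetric(P)
#' @export
plv_matrix <- function(x, is_phase = FALSE) {
  ph <- if (is_phase) as.matrix(x) else instantaneous_phase(x)
  if (nrow(ph) < 2) rlang::abort("need at least 2 channels")
  Tn <- ncol(ph)
  Z <- exp(1i * ph)
  P <- Mod(Z %*% Conj(t(Z))) / Tn
  P <- (P + t(P)) / 2
  P[P > 1] <- 1
  diag(P) <- 1
  rownames(P) <- colnames(P) <- rownames(x)
  structure(P, class = c("vnfc_plv", "matrix", "array"))
}

#' Sparsify a PLV matrix
#'
#' Weak edges are pruned before graph construction, either by a fixed
#' threshold (entries strictly greater than `threshold` survive) or by a
#' density target (exactly the top `round(density * n(n-1)/2)` off-diagonal
#' pairs survive, ties broken by pair order). The default keeps the strongest
#' 20% of edges. The diagonal is excluded and set to zero: self-loops enter
#' the graph convolution only through the renormalization's `A + I`.
#'
#' @param plv a `vnfc_plv` (or plain symmetric matrix in `[0,1]`).
#' @param threshold fixed cutoff in `[0, 1]`, or `NULL` to use `density`.
#' @param density fraction of edges to keep, in `(0, 1]` (default 0.2).
#' @return A `vnfc_sparse_plv` matrix (zero diagonal) with attributes `rule`,
#'   `threshold`/`density`, and realized `edge_density`.
#' @export
sparsify <- function(plv, threshold = NULL, density = 0.2) {
  P <- unclass(plv)
  n <- nrow(P)
  out <- P
  diag(out) <- 0
  ut <- upper.tri(P)
  vals <- P[ut]
  npairs <- length(vals)
  if (!is.null(threshold)) {
    if (threshold < 0 || threshold > 1) rlang::abort("threshold must be in [0, 1]")
    keep <- vals > threshold
  } else {
    if (is.null(density) || density <= 0 || density > 1) {
      rlang::abort("density must be in (0, 1]")
    }
    nkeep <- as.integer(round(density * npairs))
    keep <- logical(npairs)
    if (nkeep > 0) keep[order(vals, decreasing = TRUE)[seq_len(nkeep)]] <- TRUE
  }
  vals[!keep] <- 0
  M <- matrix(0, n, n, dimnames = dimnames(P))
  M[ut] <- vals
  M <- M + t(M)
  structure(M, class = c("vnfc_sparse_plv", "matrix", "array"),
            rule = if (is.null(threshold)) "density" else "threshold",
            threshold = threshold, density = if (is.null(threshold)) density else NULL,
            edge_density = sum(keep) / npairs)
}

#' Heatmap of a PLV matrix
#'
#' @param object a `vnfc_plv` or `vnfc_sparse_plv`.
#' @param ... unused.
#' @return A ggplot tile plot of connection strengths.
#' @export
autoplot.vnfc_plv <- function(object, ...) {
  n <- nrow(object)
  labs_ <- rownames(object) %||% as.character(seq_len(n))
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$plv <- unclass(object)[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$plv)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "channel", y = "channel", fill = "PLV") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vnfc_sparse_plv <- autoplot.vnfc_plv

#' Export a PLV or adjacency matrix as an edge list
#'
#' @param mat square matrix with optional dimnames.
#' @return Tibble with columns `from`, `to`, `weight` (upper triangle,
#'   nonzero entries only).
#' @export
edge_list <- function(mat) {
  m <- unclass(mat)
  labs_ <- rownames(m) %||% as.character(seq_len(nrow(m)))
  ut <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  tibble::tibble(from = labs_[ut[, 1]], to = labs_[ut[, 2]],
                 weight = m[ut])
}
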