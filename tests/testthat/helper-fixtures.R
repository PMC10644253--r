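# Shared fixtures, memoised so expensive simulations run once per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Small separable cohort: 5 subjects, one 20-s run each at 160 Hz.
tiny_windows <- function() {
  memo("tiny_windows", {
    co <- simulate_cohort(n_subjects = 5, runs_per_subject = 1,
                          duration_s = 20, fs = 160, seed = 7)
    prepare_plv(sliding_windows(co$recordings))
  })
}

# A fixed deterministic sparse PLV + grouping for graph-structure tests.
tiny_graph_parts <- function() {
  memo("tiny_graph_parts", {
    mon <- load_montage("physionet64")
    set.seed(42)
    x <- matrix(rnorm(64 * 160), 64)
    sp <- sparsify(plv_matrix(x), density = 0.2)
    list(montage = mon, groups = assign_groups(mon, 8), sp = sp)
  })
}

# Naive O(n^2) DFT analytic-signal oracle, independent of stats::fft.
analytic_dft_oracle <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  k <- 0:(n - 1)
  X <- vapply(k, function(kk) sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n)),
              complex(1))
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[c(1, n / 2 + 1)] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  vapply(0:(n - 1), function(t) {
    sum(w * X * exp(2i * pi * k * t / n)) / n
  }, complex(1))
}

expect_symmetric <- function(M, tol = 1e-12) {
  expect_lt(max(abs(M - t(M))), tol)
}
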