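test_that("degree and Laplacian follow their defining identities", {
  A <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(degree_matrix(A), c(1, 1))
  expect_equal(degree_matrix(matrix(0, 3, 3)), rep(0, 3))
  expect_equal(laplacian(A), matrix(c(1, -1, -1, 1), 2))
  expect_error(degree_matrix(matrix(1, 2, 3)), "square")

  set.seed(4)
  R <- matrix(runif(100), 10); R <- (R + t(R)) / 2; diag(R) <- 0
  # per-row summation oracle
  expect_equal(degree_matrix(R),
               vapply(1:10, function(i) sum(R[i, ]), numeric(1)))
  L <- laplacian(R)
  expect_lt(max(abs(L %*% rep(1, 10))), 1e-12)
  expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
})

test_that("renormalized operator matches the elementwise formula and bounds", {
  expect_identical(renormalized_operator(matrix(c(0, 1, 1, 0), 2)),
                   matrix(0.5, 2, 2))
  expect_equal(renormalized_operator(matrix(0, 4, 4)), diag(4))
  expect_error(renormalized_operator(matrix(c(0, -1, -1, 0), 2)), "non-negative")

  set.seed(8)
  A <- matrix(runif(64), 8); A <- (A + t(A)) / 2; diag(A) <- 0
  S <- renormalized_operator(A)
  At <- A + diag(8)
  dt <- rowSums(At)
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) oracle[i, j] <- At[i, j] / sqrt(dt[i] * dt[j])
  expect_lt(max(abs(S - oracle)), 1e-12)
  expect_symmetric(S)
  expect_lte(max(abs(eigen(S, symmetric = TRUE, only.values = TRUE)$values)), 1 + 1e-12)
  # rows of D~^{-1} A~ sum to 1
  expect_equal(rowSums(At / dt), rep(1, 8))
})

test_that("a graph-convolution layer equals the triple-loop oracle", {
  set.seed(15)
  act <- function(z) if (z > 0) z else 0.01 * z  # scalar leaky ReLU
  for (n_ch in c(2, 3, 4)) {
    mdl <- build_model("vn_gcn", n_classes = 2, n_channels = n_ch,
                       n_groups = 1, feature_dim = 4, hidden = c(3, 2),
                       seed = n_ch)
    m <- mdl$dims$m  # n_ch + 2 <= 6 nodes
    A <- matrix(runif(m * m), m); A <- (A + t(A)) / 2; diag(A) <- 0
    S <- renormalized_operator(A)
    X <- matrix(rnorm(m * 4), m)
    mdl$params$b1 <- matrix(rnorm(m * 3), m)
    out <- gcn_forward(S, mdl, X)
    W <- mdl$params$W1; b <- mdl$params$b1
    oracle <- matrix(0, m, 3)
    for (i in 1:m) for (f in 1:3) {
      acc <- 0
      for (j in 1:m) for (k in 1:4) acc <- acc + S[i, j] * X[j, k] * W[k, f]
      oracle[i, f] <- act(acc + b[i, f])
    }
    expect_lt(max(abs(out$H1 - oracle)), 1e-10)
  }
})

test_that("model shapes match the three reference architectures", {
  vn <- build_model("vn_gcn", n_classes = 109)
  expect_equal(vn$dims$m, 73)
  expect_equal(vn$dims$flatten, 584)
  tg <- build_model("tinas_gcn", n_classes = 109)
  expect_equal(tg$dims$m, 64)
  expect_equal(tg$dims$flatten, 512)
  cn <- build_model("cnn_fc", n_classes = 109)
  expect_equal(unlist(cn$dims[c("s1", "p1", "s2", "p2")]),
               c(s1 = 63, p1 = 31, s2 = 30, p2 = 15))
  expect_equal(cn$dims$flatten, 7200)
  expect_equal(7200, 15 * 15 * 32)
  expect_error(build_model("mlp"))

  # the architecture manifest round-trips shapes, counts and conventions
  f <- withr::local_tempfile(fileext = ".json")
  model_manifest(vn, f)
  man <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(man$total_params, 67965)
  expect_equal(nrow(man$layers), 5)
  expect_true(any(grepl("73 x 32", man$conventions)))
})

test_that("parameter counts reproduce the closed-form identities", {
  # per-node-bias convention, feature dim 32:
  # GC-I = 32*32 + m*32 ; GC-II = 32*8 + m*8 ; dense = 8m*109 + 109
  for (spec in list(list(name = "vn_gcn", m = 73), list(name = "tinas_gcn", m = 64))) {
    mdl <- build_model(spec$name, n_classes = 109)
    tb <- parameter_table(mdl)
    m <- spec$m
    expect_equal(tb$n_params[tb$layer == "graph_conv_1"], 32 * 32 + m * 32)
    expect_equal(tb$n_params[tb$layer == "graph_conv_2"], 32 * 8 + m * 8)
    expect_equal(tb$n_params[tb$layer == "dense"], 8 * m * 109 + 109)
    expect_equal(count_parameters(mdl), sum(tb$n_params))
  }
  cn <- build_model("cnn_fc", n_classes = 109)
  tb <- parameter_table(cn)
  expect_equal(tb$n_params[tb$layer == "conv_1"], 2 * 2 * 32 + 32)          # 160
  expect_equal(tb$n_params[tb$layer == "conv_2_depthwise"], 2 * 2 * 32 + 32) # 160
  expect_equal(tb$n_params[tb$layer == "dense"], 7200 * 109 + 109)
})

test_that("gcn forward produces a proper softmax and catches shape errors", {
  mdl <- build_model("vn_gcn", n_classes = 5, n_channels = 12, n_groups = 3)
  m <- mdl$dims$m
  A <- matrix(runif(m * m), m); A <- (A + t(A)) / 2; diag(A) <- 0
  out <- gcn_forward(renormalized_operator(A), mdl)
  expect_equal(sum(out$prob), 1, tolerance = 1e-9)
  expect_length(out$prob, 5)
  # zero weights and biases -> exactly uniform class scores
  mdl0 <- mdl
  mdl0$params <- lapply(mdl0$params, function(p) p * 0)
  expect_equal(gcn_forward(renormalized_operator(A), mdl0)$prob, rep(0.2, 5))
  expect_error(gcn_forward(diag(3), mdl), "expects m")
})

test_that("analytic gradients match numerical differentiation (GCN)", {
  set.seed(33)
  m <- 5
  mdl <- build_model("vn_gcn", n_classes = 3, n_channels = 3, n_groups = 1,
                     seed = 2)
  stopifnot(mdl$dims$m == m)
  S_list <- lapply(1:4, function(i) {
    A <- matrix(runif(m * m), m); A <- (A + t(A)) / 2; diag(A) <- 0
    renormalized_operator(A)
  })
  y <- c(1L, 2L, 3L, 1L)
  bt <- vnfc:::prep_gcn_batches(S_list, y, m, batch_size = 4, seed = 1)[[1]]
  p <- mdl$params
  fw <- vnfc:::gcn_batch_forward(p, mdl$dims, bt)
  gr <- vnfc:::gcn_batch_backward(p, mdl$dims, bt, fw)
  loss_at <- function(p) {
    fw <- vnfc:::gcn_batch_forward(p, mdl$dims, bt)
    -mean(log(fw$P[cbind(seq_along(bt$y), bt$y)]))
  }
  eps <- 1e-6
  for (nm in names(p)) {
    for (ix in sample(seq_along(p[[nm]]), min(4, length(p[[nm]])))) {
      pp <- p; pp[[nm]][ix] <- pp[[nm]][ix] + eps
      pm <- p; pm[[nm]][ix] <- pm[[nm]][ix] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(gr[[nm]][ix], num, tolerance = 1e-4)
    }
  }
})

test_that("analytic gradients match numerical differentiation (CNN)", {
  set.seed(34)
  mdl <- build_model("cnn_fc", n_classes = 3, n_channels = 10, seed = 3)
  maps <- vnfc:::cnn_maps(mdl$dims)
  img <- matrix(runif(100), 10)
  p <- mdl$params
  fw <- vnfc:::cnn_forward_one(img, p, mdl$dims, maps)
  pr <- exp(fw$logits - max(fw$logits)); pr <- pr / sum(pr)
  dlog <- pr; dlog[2] <- dlog[2] - 1
  gr <- vnfc:::cnn_backward_one(dlog, fw, p, mdl$dims, maps, vnfc:::zero_like(p))
  loss_at <- function(p) {
    fw <- vnfc:::cnn_forward_one(img, p, mdl$dims, maps)
    -log(exp(fw$logits[2] - max(fw$logits)) / sum(exp(fw$logits - max(fw$logits))))
  }
  eps <- 1e-6
  for (nm in names(p)) {
    for (ix in sample(seq_along(p[[nm]]), min(3, length(p[[nm]])))) {
      pp <- p; pp[[nm]][ix] <- pp[[nm]][ix] + eps
      pm <- p; pm[[nm]][ix] <- pm[[nm]][ix] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(gr[[nm]][ix], num, tolerance = 1e-4)
    }
  }
})

test_that("training memorizes a separable two-subject problem; zero epochs is a no-op", {
  set.seed(55)
  # two subjects with disjoint strong coupling, windows of each
  co <- simulate_cohort(n_subjects = 2, runs_per_subject = 1, duration_s = 30,
                        fs = 160, seed = 11)
  w <- prepare_plv(sliding_windows(co$recordings))
  gr <- assign_groups(load_montage("physionet64"), 8)
  mi <- vnfc:::model_inputs(w, "vn_gcn", groups = gr)
  mdl <- build_model("vn_gcn", n_classes = 2, seed = 5)

  same <- train_model(mdl, mi$inputs, w$subject_id, train_config(epochs = 0))
  expect_identical(same$params, mdl$params)

  fit <- train_model(mdl, mi$inputs, w$subject_id,
                     train_config(epochs = 30, seed = 5))
  expect_equal(fit$history$accuracy[30], 1.0)
  # a training window is predicted as its training label
  pr <- predict(fit, mi$inputs[1:10])
  expect_true(all(as.character(pr$pred) == w$subject_id[1:10]))
  probs <- attr(pr, "prob_matrix")
  expect_equal(rowSums(probs), rep(1, 10), tolerance = 1e-6)
})

test_that("training is bit-reproducible for a fixed seed", {
  w <- tiny_windows()[1:40, ]
  gr <- assign_groups(load_montage("physionet64"), 8)
  mi <- vnfc:::model_inputs(w, "vn_gcn", groups = gr)
  mdl <- build_model("vn_gcn", n_classes = length(unique(w$subject_id)), seed = 9)
  f1 <- train_model(mdl, mi$inputs, w$subject_id, train_config(epochs = 3, seed = 4))
  f2 <- train_model(mdl, mi$inputs, w$subject_id, train_config(epochs = 3, seed = 4))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
})

test_that("prediction is invariant under a consistent channel permutation", {
  set.seed(66)
  w <- tiny_windows()
  w <- w[w$subject_id %in% c("S01", "S02"), ][c(1:15, 40:54), ]
  mon <- load_montage("physionet64")
  gr <- assign_groups(mon, 8)
  mi <- vnfc:::model_inputs(w, "vn_gcn", groups = gr)
  mdl <- build_model("vn_gcn", n_classes = 2, seed = 2)
  fit <- train_model(mdl, mi$inputs, w$subject_id, train_config(epochs = 5, seed = 3))

  # permute channels of the PLV and the grouping consistently: the augmented
  # graph is relabelled, and with node-aligned parameters the softmax output
  # must be unchanged up to the permutation of node order.
  sp <- w$sp[[1]]
  perm <- sample(64)
  gr_p <- structure(unclass(gr)[perm], g = 8L, class = "vnfc_groups")
  sp_p <- structure(unclass(sp)[perm, perm], class = class(sp))
  G <- build_augmented_graph(sp, gr)
  Gp <- build_augmented_graph(sp_p, gr_p)
  # the two adjacencies are equal up to the node permutation
  full_perm <- c(perm, 65:73)
  expect_equal(Gp$adjacency, G$adjacency[full_perm, full_perm],
               ignore_attr = TRUE)
  # with all-ones features and per-node bias permuted alike, probabilities match
  S <- renormalized_operator(G$adjacency)
  Sp <- renormalized_operator(Gp$adjacency)
  fit_p <- fit
  fit_p$params$b1 <- fit$params$b1[full_perm, ]
  fit_p$params$b2 <- fit$params$b2[full_perm, ]
  W3r <- array(fit$params$W3, c(73, 8, fit$n_classes))
  fit_p$params$W3 <- matrix(W3r[full_perm, , ], 73 * 8, fit$n_classes)
  expect_equal(gcn_forward(Sp, fit_p)$prob, gcn_forward(S, fit)$prob,
               tolerance = 1e-10)
})
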