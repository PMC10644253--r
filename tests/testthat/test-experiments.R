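cv_cfg <- function(epochs = 15) train_config(epochs = epochs, seed = 7)

test_that("cross-validation folds partition windows and stratify by subject", {
  w <- tiny_windows()
  fid <- vnfc:::assign_folds(w, 5, "window", seed = 1)
  expect_length(fid, nrow(w))
  expect_setequal(unique(fid), 1:5)
  # every subject appears in every fold
  tab <- table(w$subject_id, fid)
  expect_true(all(tab > 0))
  # exact partition: fold sizes sum to the window count
  expect_equal(sum(table(fid)), nrow(w))

  # block split keeps folds contiguous in time per subject
  fidb <- vnfc:::assign_folds(w, 5, "block", seed = 1)
  for (sid in unique(w$subject_id)) {
    idx <- which(w$subject_id == sid)
    ord <- order(w$condition[idx], w$offset[idx])
    expect_true(all(diff(fidb[idx][ord]) >= 0))
  }

  few <- w[1:3, ]
  expect_error(vnfc:::assign_folds(few, 5, "window", 1), "folds requested")
})

test_that("identification recovers subjects well above chance; label shuffling is at chance", {
  w <- tiny_windows()
  cv <- run_cv(w, "vn_gcn", folds = 5, config = cv_cfg(100))
  expect_gte(cv$mean, 0.9)
  expect_equal(nrow(tidy(cv)), 5)
  expect_true(all(tidy(cv)$accuracy >= 0 & tidy(cv)$accuracy <= 1))
  g <- glance(cv)
  expect_equal(g$mean, mean(tidy(cv)$accuracy))
  expect_equal(g$sd, sd(tidy(cv)$accuracy))

  cvp <- run_cv(w, "vn_gcn", folds = 5, config = cv_cfg(8), permute_labels = TRUE)
  # chance for 5 subjects is 0.2; binomial 3 sigma on ~700 windows ~ 0.045
  expect_lt(abs(cvp$mean - 0.2), 0.1)
})

test_that("the plain-graph baseline also learns the separable cohort", {
  w <- tiny_windows()
  cv <- run_cv(w, "tinas_gcn", folds = 3, config = cv_cfg(100))
  expect_gte(cv$mean, 0.7)
})

test_that("the CNN baseline trains end to end on a small cohort", {
  w <- tiny_windows()
  idx <- which(w$subject_id %in% c("S01", "S02"))
  cv <- run_cv(w[idx, ], "cnn_fc", folds = 2,
               config = train_config(epochs = 20, seed = 7))
  expect_gte(cv$mean, 0.8)
})

test_that("channel-reduction ablation has the right shape and baseline row", {
  w <- tiny_windows()
  tb <- run_channel_reduction(w, models = "vn_gcn", ks = c(64, 32),
                              folds = 3, config = cv_cfg(12))
  expect_equal(nrow(tb), 2)
  expect_setequal(tb$k, c(64, 32))
  # the k = 64 row equals the unablated CV result (same seeds, no slicing)
  cv64 <- run_cv(w, "vn_gcn", folds = 3, config = cv_cfg(12))
  expect_equal(tb$accuracy[tb$k == 64], cv64$mean)
})

test_that("region removal reports drops consistent with raw accuracies", {
  w <- tiny_windows()
  tb <- run_region_removal(w, models = "vn_gcn",
                           regions = c("occipital", "temporal"),
                           folds = 3, config = cv_cfg(12))
  expect_equal(nrow(tb), 2)
  # arithmetic identity: drop == baseline - accuracy
  expect_equal(tb$drop, tb$baseline - tb$accuracy, tolerance = 1e-12)
  cvs <- attr(tb, "cv")
  expect_equal(tb$accuracy[1], cvs[["occipital_vn_gcn"]]$mean)

  # an empty custom mask removes nothing and reproduces the baseline exactly
  tb0 <- run_region_removal(w, models = "vn_gcn",
                            regions = list(nothing = integer(0)),
                            folds = 3, config = cv_cfg(8))
  expect_equal(tb0$drop, 0, tolerance = 1e-12)
})

test_that("report writes csv, markdown percentages, and a manifest; empty results ok", {
  w <- tiny_windows()
  cv <- run_cv(w[w$subject_id %in% c("S01", "S02"), ], "vn_gcn", folds = 2,
               config = cv_cfg(5))
  dir <- withr::local_tempdir()
  cfg <- resolve_config(overrides = list(folds = 2L, epochs = 5L))
  paths <- report(cv, dir, config = cfg, name = "cv")
  expect_true(all(file.exists(unlist(paths))))
  md <- readLines(paths$md)
  expect_true(any(grepl("\\d+\\.\\d{2} \\+/- \\d+\\.\\d{2}", md)))
  man <- read_manifest(paths$manifest)
  expect_equal(man$config$folds, 2)
  expect_false(is.null(man$results_digest))

  paths0 <- report(NULL, dir, config = cfg, name = "empty")
  expect_equal(readLines(paths0$md), "no results")
})

test_that("identical config and seed give identical result digests across runs", {
  w <- tiny_windows()[seq(1, 195, by = 3), ]
  cfg <- resolve_config(overrides = list(folds = 2L, epochs = 4L, seed = 5L))
  run_once <- function() {
    cv <- run_cv(w, "vn_gcn", folds = cfg$folds,
                 config = train_config(epochs = cfg$epochs, seed = cfg$seed),
                 seed = cfg$seed)
    dir <- withr::local_tempdir()
    p <- report(cv, dir, config = cfg)
    read_manifest(p$manifest)
  }
  m1 <- run_once()
  m2 <- run_once()
  expect_identical(m1$results_digest, m2$results_digest)
  expect_identical(m1$config_hash, m2$config_hash)
  expect_identical(m1, m2)
})
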