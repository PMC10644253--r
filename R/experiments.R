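#' Attach sparse PLV matrices to a window table
#'
#' Computes the PLV functional-connectivity matrix of every window once and
#' sparsifies it, so several models/ablations can reuse the same
#' connectivity. Piped between [sliding_windows()] and [run_cv()].
#'
#' @param windows tibble from [sliding_windows()] (list-column `data`).
#' @param density,threshold sparsification rule passed to [sparsify()];
#'   default keeps the top 20% of edges.
#' @return The tibble with an added list-column `sp` of `vnfc_sparse_plv`.
#' @export
prepare_plv <- function(windows, density = 0.2, threshold = NULL) {
  stopifnot(is.data.frame(windows), "data" %in% names(windows))
  windows$sp <- lapply(windows$data, function(d) {
    sparsify(plv_matrix(d), threshold = threshold, density = density)
  })
  windows
}

# Per-window model inputs (propagation operators or images), optionally
# restricted to a channel layout. Returns list(inputs, n, g).
model_inputs <- function(windows, model, groups = NULL, layout = NULL,
                         w_virtual = 1.0) {
  stopifnot("sp" %in% names(windows))
  sp <- windows$sp
  n_full <- nrow(sp[[1]])
  kept <- if (is.null(layout)) seq_len(n_full) else layout$kept
  if (model == "vn_gcn") {
    if (is.null(groups)) rlang::abort("vn_gcn needs a group scheme")
    sub_groups <- structure(unclass(groups)[kept], g = attr(groups, "g"),
                            class = "vnfc_groups")
    g_active <- length(unique(unclass(sub_groups)))
    inputs <- lapply(sp, function(P) {
      gr <- build_augmented_graph(unclass(P)[kept, kept, drop = FALSE],
                                  sub_groups, w_virtual)
      renormalized_operator(gr$adjacency)
    })
    list(inputs = inputs, n = length(kept), g = g_active)
  } else if (model == "tinas_gcn") {
    inputs <- lapply(sp, function(P) {
      renormalized_operator(unclass(P)[kept, kept, drop = FALSE])
    })
    list(inputs = inputs, n = length(kept), g = 0L)
  } else if (model == "cnn_fc") {
    inputs <- lapply(sp, function(P) unclass(P)[kept, kept, drop = FALSE])
    list(inputs = inputs, n = length(kept), g = 0L)
  } else {
    rlang::abort(sprintf("unknown model '%s'", model))
  }
}

assign_folds <- function(windows, folds, split_by, seed) {
  fold_id <- integer(nrow(windows))
  set.seed(seed)
  for (sid in unique(windows$subject_id)) {
    idx <- which(windows$subject_id == sid)
    if (length(idx) < folds) {
      rlang::abort(sprintf("subject %s has %d windows but %d folds requested",
                           sid, length(idx), folds))
    }
    if (split_by == "window") {
      idx <- sample(idx)
    } else if (split_by == "block") {
      ord <- order(windows$condition[idx], windows$offset[idx])
      idx <- idx[ord]
    } else {
      rlang::abort("split_by must be 'window' or 'block'")
    }
    if (split_by == "block") {
      # contiguous time blocks per subject
      fold_id[idx] <- ceiling(seq_along(idx) / (length(idx) / folds))
    } else {
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  }
  pmin(fold_id, folds)
}

#' Cross-validated person identification
#'
#' Runs the identification protocol: every window becomes one classification
#' sample, folds are stratified by subject (each subject appears in every
#' test fold), one model is trained from scratch per fold, and per-fold test
#' accuracies are reported. The default split assigns windows to folds
#' independently; `split_by = "block"` holds out contiguous time blocks
#' instead (harder, no temporal leakage between train and test).
#'
#' @param windows window table from [sliding_windows()], ideally already
#'   piped through [prepare_plv()].
#' @param model `"vn_gcn"`, `"tinas_gcn"` or `"cnn_fc"`.
#' @param folds number of CV folds (default 5).
#' @param config a [train_config()].
#' @param montage montage used for grouping (default builtin 64-channel).
#' @param groups group scheme for `vn_gcn` (default 8 angular groups).
#' @param layout optional `vnfc_layout` restricting channels (ablations).
#' @param sparsify_density,sparsify_threshold connectivity sparsification if
#'   `windows` lacks a precomputed `sp` column.
#' @param w_virtual virtual edge weight.
#' @param split_by `"window"` (default) or `"block"`.
#' @param permute_labels if `TRUE`, subject labels are randomly permuted
#'   before folding — the chance-level control (expected accuracy
#'   `1/n_subjects`).
#' @param seed seed for folding/permutation; per-fold training seeds are
#'   derived from it. Defaults to `config$seed`.
#' @return A `vnfc_cv` object; see [tidy.vnfc_cv()] / [glance.vnfc_cv()].
#' @export
run_cv <- function(windows, model = "vn_gcn", folds = 5,
                   config = train_config(), montage = NULL, groups = NULL,
                   layout = NULL, sparsify_density = 0.2,
                   sparsify_threshold = NULL, w_virtual = 1.0,
                   split_by = "window", permute_labels = FALSE,
                   seed = config$seed) {
  stopifnot(is.data.frame(windows))
  if (!"sp" %in% names(windows)) {
    windows <- prepare_plv(windows, density = sparsify_density,
                           threshold = sparsify_threshold)
  }
  if (model == "vn_gcn" && is.null(groups)) {
    if (is.null(montage)) montage <- load_montage("physionet64")
    if (nrow(montage) != nrow(windows$sp[[1]])) {
      rlang::abort("supply a montage/groups matching the channel count")
    }
    groups <- assign_groups(montage, 8)
  }
  labels <- windows$subject_id
  if (permute_labels) {
    set.seed(derive_seed(seed, "permute"))
    labels <- sample(labels)
  }
  subjects <- sort(unique(labels))
  mi <- model_inputs(windows, model, groups = groups, layout = layout,
                     w_virtual = w_virtual)
  wtbl <- windows
  wtbl$subject_id <- labels
  fold_id <- assign_folds(wtbl, folds, split_by, derive_seed(seed, "folds"))

  fold_rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- which(fold_id == f)
    tr <- which(fold_id != f)
    mdl <- build_model(model, n_classes = length(subjects),
                       n_channels = mi$n, n_groups = mi$g,
                       seed = derive_seed(seed, paste0("init_fold", f)))
    cfg_f <- config
    cfg_f$seed <- derive_seed(seed, paste0("train_fold", f))
    mdl <- train_model(mdl, mi$inputs[tr], labels[tr], cfg_f)
    pred <- predict(mdl, mi$inputs[te])
    acc <- mean(as.character(pred$pred) == labels[te])
    fold_rows[[f]] <- tibble::tibble(fold = f, accuracy = acc,
                                     n_train = length(tr), n_test = length(te))
  }
  fold_tbl <- dplyr::bind_rows(fold_rows)
  structure(list(folds = fold_tbl,
                 mean = mean(fold_tbl$accuracy),
                 sd = stats::sd(fold_tbl$accuracy),
                 model = model, n_subjects = length(subjects),
                 n_windows = nrow(windows), n_channels = mi$n,
                 split_by = split_by, permuted = permute_labels,
                 seed = seed),
            class = "vnfc_cv")
}

#' @export
print.vnfc_cv <- function(x, ...) {
  cat(sprintf("<vnfc_cv %s: %d-fold accuracy %.2f%% +/- %.2f%% (%d subjects, %d windows)>\n",
              x$model, nrow(x$folds), 100 * x$mean, 100 * x$sd,
              x$n_subjects, x$n_windows))
  invisible(x)
}

#' @describeIn run_cv per-fold accuracies as a tibble.
#' @param x a `vnfc_cv`.
#' @param ... unused.
#' @export
tidy.vnfc_cv <- function(x, ...) x$folds

#' @describeIn run_cv one-row summary (mean, sd, acc_pct).
#' @export
glance.vnfc_cv <- function(x, ...) {
  tibble::tibble(model = x$model, folds = nrow(x$folds), mean = x$mean,
                 sd = x$sd, acc_pct = round(100 * x$mean, 2),
                 sd_pct = round(100 * x$sd, 2), n_subjects = x$n_subjects,
                 n_windows = x$n_windows, n_channels = x$n_channels)
}

#' @export
autoplot.vnfc_cv <- function(object, ...) {
  df <- object$folds
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = 100 * .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "fold", y = "accuracy (%)",
                  title = sprintf("%s: %.2f%% +/- %.2f%%", object$model,
                                  100 * object$mean, 100 * object$sd)) +
    ggplot2::theme_minimal()
}

#' Uniform channel-reduction ablation
#'
#' Re-runs the cross-validated identification with the montage uniformly
#' thinned to each requested channel count, for each model, reporting
#' accuracy per (k, model).
#'
#' @param windows window table (full montage).
#' @param models character vector of model names.
#' @param ks channel counts to retain (default `c(56, 48, 40, 32, 24, 16)`;
#'   include 64 for the unablated baseline row).
#' @param montage the montage (default builtin).
#' @param ... further arguments forwarded to [run_cv()].
#' @return A `vnfc_ablation` tibble with columns `k`, `model`, `accuracy`,
#'   `sd` and per-fold results in attribute `"cv"`.
#' @export
run_channel_reduction <- function(windows, models = "vn_gcn",
                                  ks = c(56, 48, 40, 32, 24, 16),
                                  montage = NULL, ...) {
  if (is.null(montage)) montage <- load_montage("physionet64")
  cvs <- list()
  rows <- list()
  for (k in ks) {
    layout <- reduce_channels(montage, k)
    for (mdl in models) {
      cv <- run_cv(windows, model = mdl, montage = montage,
                   layout = if (k == nrow(montage)) NULL else layout, ...)
      key <- sprintf("k%d_%s", k, mdl)
      cvs[[key]] <- cv
      rows[[key]] <- tibble::tibble(k = k, model = mdl, accuracy = cv$mean,
                                    sd = cv$sd)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "cv") <- cvs
  class(out) <- c("vnfc_ablation", class(out))
  out
}

#' Brain-region removal ablation
#'
#' For each of the five scalp regions, removes the region's channels and
#' re-runs the cross-validated identification; the accuracy drop is measured
#' against the same model's full-montage baseline.
#'
#' @param windows window table (full montage).
#' @param models character vector of model names.
#' @param regions regions to remove: either a character vector of builtin
#'   region names (default all five) or a named list of custom channel-index
#'   masks (an empty mask removes nothing and must reproduce the baseline).
#' @param montage the montage (default builtin).
#' @param ... further arguments forwarded to [run_cv()].
#' @return A `vnfc_ablation` tibble with columns `region`, `model`,
#'   `accuracy`, `sd`, `baseline`, `drop` (baseline - accuracy; same scale as
#'   accuracy).
#' @export
run_region_removal <- function(windows, models = "vn_gcn",
                               regions = c("frontal", "central", "parietal",
                                           "occipital", "temporal"),
                               montage = NULL, ...) {
  if (is.null(montage)) montage <- load_montage("physionet64")
  custom <- is.list(regions)
  if (custom && is.null(names(regions))) rlang::abort("custom masks must be named")
  cvs <- list()
  rows <- list()
  base <- list()
  for (mdl in models) {
    cv0 <- run_cv(windows, model = mdl, montage = montage, ...)
    base[[mdl]] <- cv0$mean
    cvs[[paste0("baseline_", mdl)]] <- cv0
  }
  for (reg in if (custom) names(regions) else regions) {
    layout <- if (custom) {
      new_layout(setdiff(seq_len(nrow(montage)), regions[[reg]]), montage)
    } else {
      remove_region(montage, reg)
    }
    for (mdl in models) {
      cv <- run_cv(windows, model = mdl, montage = montage, layout = layout, ...)
      key <- sprintf("%s_%s", reg, mdl)
      cvs[[key]] <- cv
      rows[[key]] <- tibble::tibble(region = reg, model = mdl,
                                    accuracy = cv$mean, sd = cv$sd,
                                    baseline = base[[mdl]],
                                    drop = base[[mdl]] - cv$mean)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "cv") <- cvs
  class(out) <- c("vnfc_ablation", class(out))
  out
}

#' @export
autoplot.vnfc_ablation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if ("k" %in% names(df)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = 100 * .data$accuracy,
                                     colour = .data$model)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "channels retained", y = "accuracy (%)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = 100 * .data$drop,
                                     fill = .data$model)) +
      ggplot2::geom_col(position = ggplot2::position_dodge()) +
      ggplot2::labs(x = "removed region", y = "accuracy drop (%)") +
      ggplot2::theme_minimal()
  }
}

fmt_pct <- function(x) sprintf("%.2f", 100 * x)

#' Write experiment results to disk
#'
#' Emits a CSV table, a markdown rendering (accuracies as percentages with
#' two decimals, mean +/- sd), and a JSON manifest tying the result to its
#' configuration (see [emit_manifest()]).
#'
#' @param results a `vnfc_cv` or `vnfc_ablation`, or `NULL`.
#' @param dir output directory (created if needed).
#' @param config optional `vnfc_config` recorded in the manifest.
#' @param name file stem (default `"results"`).
#' @return Named list of written file paths, invisibly.
#' @export
report <- function(results, dir, config = resolve_config(), name = "results") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  md <- file.path(dir, paste0(name, ".md"))
  man <- file.path(dir, paste0(name, "_manifest.json"))
  if (is.null(results) || (is.data.frame(results) && nrow(results) == 0)) {
    writeLines("no results", md)
    utils::write.csv(tibble::tibble(), csv, row.names = FALSE)
    emit_manifest(config, NULL, man, status = "ok")
    return(invisible(list(csv = csv, md = md, manifest = man)))
  }
  if (inherits(results, "vnfc_cv")) {
    tb <- tidy(results)
    utils::write.csv(tb, csv, row.names = FALSE)
    lines <- c(sprintf("| Model | ACC(%%) |"), "|---|---|",
               sprintf("| %s | %s +/- %s |", results$model,
                       fmt_pct(results$mean), fmt_pct(results$sd)))
  } else {
    tb <- tibble::as_tibble(results)
    utils::write.csv(tb, csv, row.names = FALSE)
    cols <- names(tb)[1:2]
    has_drop <- "drop" %in% names(tb)
    hdr <- if (has_drop) "| %s | %s | ACC(%%) | Drop(%%) |" else "| %s | %s | ACC(%%) |"
    lines <- c(sprintf(hdr, cols[1], cols[2]),
               if (has_drop) "|---|---|---|---|" else "|---|---|---|")
    for (i in seq_len(nrow(tb))) {
      lines <- c(lines, if (has_drop) {
        sprintf("| %s | %s | %s +/- %s | %s |", tb[[1]][i], tb[[2]][i],
                fmt_pct(tb$accuracy[i]), fmt_pct(tb$sd[i]), fmt_pct(tb$drop[i]))
      } else {
        sprintf("| %s | %s | %s +/- %s |", tb[[1]][i], tb[[2]][i],
                fmt_pct(tb$accuracy[i]), fmt_pct(tb$sd[i]))
      })
    }
  }
  writeLines(lines, md)
  emit_manifest(config, if (is.data.frame(results)) tibble::as_tibble(results)
                else results$folds, man)
  invisible(list(csv = csv, md = md, manifest = man))
}
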