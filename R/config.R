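#' Derive a stage seed from the global run seed
#'
#' One global seed fans out to per-stage seeds through a fixed documented
#' formula, `(seed * 1009 + polynomial hash of the stage key) mod (2^31 - 1)`,
#' so each pipeline stage (subject sampling, each simulated run, fold
#' splitting, weight initialization, batching) is independently reproducible.
#'
#' @param seed integer global seed.
#' @param key character stage identifier.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

#' Package-wide default run configuration
#'
#' @return Named list of every tunable pipeline setting with its default.
#' @export
default_config <- function() {
  list(
    montage = "physionet64",
    groups = 8L,
    window_s = 1.0,
    overlap = 0.5,
    sparsify_rule = "density",     # "density" or "threshold"
    sparsify_density = 0.2,
    sparsify_threshold = NA_real_,
    w_virtual = 1.0,
    feature_dim = 32L,
    model = "vn_gcn",
    folds = 5L,
    split_by = "window",           # "window" or "block"
    lr = 1e-3,
    epochs = 100L,
    batch_size = 64L,
    seed = 7L
  )
}

#' Resolve a run configuration from defaults, a file and overrides
#'
#' Precedence is overrides > file > defaults. Unknown keys and type
#' mismatches are rejected rather than silently carried along.
#'
#' @param file optional YAML file of settings.
#' @param overrides optional named list (e.g. parsed command-line flags).
#' @return A `vnfc_config` list in which every field has a value, plus a
#'   stable hash in attribute `"hash"`.
#' @export
resolve_config <- function(file = NULL, overrides = list()) {
  cfg <- default_config()
  apply_layer <- function(cfg, layer, origin) {
    bad <- setdiff(names(layer), names(cfg))
    if (length(bad)) {
      rlang::abort(sprintf("unknown config key(s) in %s: %s", origin,
                           paste(bad, collapse = ", ")))
    }
    for (k in names(layer)) {
      v <- layer[[k]]
      tmpl <- cfg[[k]]
      if (is.numeric(tmpl) && !is.numeric(v)) {
        rlang::abort(sprintf("config key '%s' must be numeric (%s)", k, origin))
      }
      if (is.character(tmpl) && !is.character(v)) {
        rlang::abort(sprintf("config key '%s' must be character (%s)", k, origin))
      }
      if (is.integer(tmpl) && is.numeric(v)) v <- as.integer(v)
      cfg[[k]] <- v
    }
    cfg
  }
  if (!is.null(file)) {
    if (!file.exists(file)) rlang::abort(sprintf("config file not found: %s", file))
    cfg <- apply_layer(cfg, yaml::read_yaml(file), file)
  }
  if (length(overrides)) cfg <- apply_layer(cfg, overrides, "overrides")
  structure(cfg, hash = rlang::hash(cfg), class = c("vnfc_config", "list"))
}

#' @export
print.vnfc_config <- function(x, ...) {
  cat("<vnfc_config>", sprintf("hash: %s", attr(x, "hash")), sep = "\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Write a run manifest
#'
#' Every experiment output is tied to the exact configuration that produced
#' it: the manifest records the resolved config, its hash, the package
#' version, and a digest of the results object. Two runs with the same config
#' and seed produce byte-identical manifests (no timestamps).
#'
#' @param config a `vnfc_config` (or plain named list).
#' @param results any result object, or `NULL` for an aborted run.
#' @param path output JSON path.
#' @param status `"ok"` or `"failed"`.
#' @param error optional error message for failed runs.
#' @return The manifest list, invisibly.
#' @export
emit_manifest <- function(config, results, path, status = "ok", error = NULL) {
  man <- list(
    package = "vnfc",
    version = as.character(utils::packageVersion("vnfc")),
    status = status,
    config = unclass(config),
    config_hash = attr(config, "hash") %||% rlang::hash(unclass(config)),
    results_digest = if (is.null(results)) NA_character_ else rlang::hash(results),
    error = error
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(man)
}

#' Read back a manifest
#'
#' @param path manifest JSON path.
#' @return The manifest list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
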