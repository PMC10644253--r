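#' Electrode montages
#'
#' A montage is the ordered set of EEG channel labels together with 2-D scalp
#' coordinates on a normalized head disc (vertex near the origin, +y anterior,
#' +x right; only relative positions matter). The shipped `"physionet64"`
#' montage is the 64-channel 10-10 layout used by the PhysioNet motor
#' movement/imagery recordings.
#'
#' @param source either the name of a builtin montage (currently
#'   `"physionet64"`) or the path to a delimited text file with columns
#'   `label,x,y` and a header row.
#' @return A `vnfc_montage`: a tibble with columns `label`, `x`, `y` and one
#'   row per channel, in channel order.
#' @examples
#' mon <- load_montage("physionet64")
#' nrow(mon)  # 64
#' @export
load_montage <- function(source = "physionet64") {
  stopifnot(is.character(source), length(source) == 1)
  path <- if (identical(source, "physionet64")) {
    system.file("extdata", "physionet64_montage.csv", package = "vnfc", mustWork = TRUE)
  } else {
    if (!file.exists(source)) {
      rlang::abort(sprintf("montage file not found: %s", source))
    }
    source
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("label", "x", "y")
  if (!all(req %in% names(df))) {
    rlang::abort("montage file must have columns label, x, y")
  }
  df <- df[, req]
  if (anyDuplicated(df$label)) {
    dup <- unique(df$label[duplicated(df$label)])
    rlang::abort(sprintf("duplicate channel label(s): %s", paste(dup, collapse = ", ")))
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    rlang::abort("montage positions must be finite")
  }
  if (nrow(df) < 1) rlang::abort("montage has no channels")
  out <- tibble::as_tibble(df)
  class(out) <- c("vnfc_montage", class(out))
  attr(out, "montage_name") <- if (identical(source, "physionet64")) "physionet64" else basename(path)
  out
}

#' @export
print.vnfc_montage <- function(x, ...) {
  cat(sprintf("<vnfc_montage: %d channels (%s)>\n", nrow(x),
              attr(x, "montage_name") %||% "custom"))
  NextMethod()
}

n_channels <- function(montage) nrow(montage)

is_builtin64 <- function(montage) {
  identical(attr(montage, "montage_name"), "physionet64") && nrow(montage) == 64
}

#' Partition a montage into spatial electrode groups
#'
#' Channels are divided into `g` spatially contiguous groups, each of which
#' will later be served by one local virtual node. The default `"angular"`
#' strategy sorts channels by their angle around the montage centroid and cuts
#' the circle into `g` consecutive arcs of (near-)equal size, so on the
#' 64-channel 10-10 montage with `g = 8` every group holds exactly 8 channels.
#'
#' @param montage a `vnfc_montage`.
#' @param g number of groups (default 8).
#' @param strategy partition rule; `"angular"` (default) or the path of a JSON
#'   file mapping channel label to group id (a user-supplied override).
#' @return A `vnfc_groups` object: an integer vector of group ids in
#'   `1..g`, one per channel in montage order, with attribute `g`.
#' @export
assign_groups <- function(montage, g = 8L, strategy = "angular") {
  stopifnot(inherits(montage, "vnfc_montage"))
  n <- n_channels(montage)
  g <- as.integer(g)
  if (g < 1L) rlang::abort("g must be >= 1")
  if (g > n) rlang::abort(sprintf("g = %d exceeds channel count %d", g, n))

  if (file.exists(strategy)) {
    map <- jsonlite::read_json(strategy, simplifyVector = TRUE)
    if (!all(montage$label %in% names(map))) {
      miss <- setdiff(montage$label, names(map))
      rlang::abort(sprintf("grouping file misses channel(s): %s",
                           paste(miss, collapse = ", ")))
    }
    ids <- as.integer(map[montage$label])
  } else if (identical(strategy, "angular")) {
    cx <- mean(montage$x); cy <- mean(montage$y)
    ang <- atan2(montage$y - cy, montage$x - cx)
    rad <- sqrt((montage$x - cx)^2 + (montage$y - cy)^2)
    ord <- order(ang, rad, montage$label)
    sizes <- rep(n %/% g, g)
    extra <- n %% g
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ids <- integer(n)
    ids[ord] <- rep(seq_len(g), times = sizes)
  } else {
    rlang::abort(sprintf("unknown grouping strategy: %s", strategy))
  }
  if (any(is.na(ids)) || any(ids < 1L) || any(ids > g)) {
    rlang::abort("group ids must lie in 1..g for every channel")
  }
  structure(ids, g = g, class = "vnfc_groups")
}

#' @export
print.vnfc_groups <- function(x, ...) {
  cat(sprintf("<vnfc_groups: %d channels in %d groups (sizes %s)>\n",
              length(x), attr(x, "g"),
              paste(tabulate(unclass(x), attr(x, "g")), collapse = ", ")))
  invisible(x)
}

region_prefix_map <- list(
  Fp = "frontal", Af = "frontal", F = "frontal",
  Fc = c("frontal", "central"), C = "central",
  Cp = c("central", "parietal"), P = "parietal",
  Po = c("parietal", "occipital"), O = "occipital", I = "occipital",
  T = "temporal", Ft = c("frontal", "temporal"), Tp = c("temporal", "parietal")
)

#' Brain-region channel masks
#'
#' The 10-10 labels are assigned to five overlapping scalp regions by their
#' alphabetic prefix: pure prefixes map to one region (`F`/`Fp`/`Af` frontal,
#' `C` central, `P` parietal, `O`/`I` occipital, `T` temporal) and boundary
#' prefixes to both of their neighbours (`Fc` frontal+central, `Cp`
#' central+parietal, `Po` parietal+occipital, `Ft` frontal+temporal, `Tp`
#' temporal+parietal), so the five masks overlap and their union covers every
#' channel.
#'
#' @param montage a `vnfc_montage`.
#' @return Named list of integer channel-index vectors, one per region
#'   (`frontal`, `central`, `parietal`, `occipital`, `temporal`).
#' @export
region_masks <- function(montage) {
  stopifnot(inherits(montage, "vnfc_montage"))
  prefix <- sub("z$", "", sub("[0-9]+$", "", montage$label), ignore.case = TRUE)
  prefix <- paste0(toupper(substr(prefix, 1, 1)), tolower(substring(prefix, 2)))
  regions <- c("frontal", "central", "parietal", "occipital", "temporal")
  masks <- stats::setNames(vector("list", 5), regions)
  for (r in regions) masks[[r]] <- integer(0)
  for (i in seq_along(prefix)) {
    rs <- region_prefix_map[[prefix[i]]]
    if (is.null(rs)) {
      rlang::abort(sprintf("channel %s: unrecognised 10-10 prefix '%s'",
                           montage$label[i], prefix[i]))
    }
    for (r in rs) masks[[r]] <- c(masks[[r]], i)
  }
  masks
}

new_layout <- function(kept, montage) {
  kept <- sort(unique(as.integer(kept)))
  structure(list(kept = kept, k = length(kept),
                 labels = montage$label[kept], n_total = nrow(montage)),
            class = "vnfc_layout")
}

#' @export
print.vnfc_layout <- function(x, ...) {
  cat(sprintf("<vnfc_layout: %d of %d channels kept>\n", x$k, x$n_total))
  invisible(x)
}

#' Uniform channel-reduction layouts
#'
#' Thins a montage to `k` channels while keeping spatial coverage as uniform
#' as possible, for channel-reduction ablations. The kept set is the first `k`
#' channels of a deterministic farthest-point ordering of the montage
#' coordinates (seeded at the channel nearest the centroid), which makes the
#' layouts nested: the 16-channel layout is a subset of the 24-channel layout,
#' and so on up to the full montage. For the builtin 64-channel montage the
#' layouts for k in 56, 48, 40, 32, 24, 16 are additionally frozen in a
#' shipped JSON file (`physionet64_reduction_layouts.json`), which this
#' function returns verbatim; they are a documented reconstruction of uniform
#' thinning, not a replica of any published electrode selection.
#'
#' @param montage a `vnfc_montage`.
#' @param k number of channels to retain, `1 <= k <= n_channels`.
#' @return A `vnfc_layout` with `k` kept channel indices (montage order).
#' @export
reduce_channels <- function(montage, k) {
  stopifnot(inherits(montage, "vnfc_montage"))
  n <- n_channels(montage)
  k <- as.integer(k)
  if (k < 1L || k > n) rlang::abort(sprintf("k must be in 1..%d, got %d", n, k))
  if (k == n) return(new_layout(seq_len(n), montage))

  if (is_builtin64(montage) && k %in% c(56L, 48L, 40L, 32L, 24L, 16L)) {
    path <- system.file("extdata", "physionet64_reduction_layouts.json",
                        package = "vnfc", mustWork = TRUE)
    layouts <- jsonlite::read_json(path, simplifyVector = TRUE)
    labs <- layouts[[as.character(k)]]
    return(new_layout(match(labs, montage$label), montage))
  }
  new_layout(farthest_point_order(montage)[seq_len(k)], montage)
}

# Deterministic farthest-point ordering: start nearest the centroid, then
# repeatedly add the channel with the largest minimum distance to those
# already chosen (ties -> lowest channel index).
farthest_point_order <- function(montage) {
  xy <- cbind(montage$x, montage$y)
  n <- nrow(xy)
  cx <- colMeans(xy)
  d0 <- sqrt(rowSums(sweep(xy, 2, cx)^2))
  ord <- which.min(d0)
  mind <- sqrt(rowSums(sweep(xy, 2, xy[ord, ])^2))
  for (i in 2:n) {
    mind[ord] <- -Inf
    nxt <- which.max(mind)
    ord <- c(ord, nxt)
    d <- sqrt(rowSums(sweep(xy, 2, xy[nxt, ])^2))
    mind <- pmin(mind, d)
  }
  ord
}

#' Remove a brain region's channels from a montage
#'
#' @param montage a `vnfc_montage`.
#' @param region one of `"frontal"`, `"central"`, `"parietal"`, `"occipital"`,
#'   `"temporal"`.
#' @return A `vnfc_layout` keeping every channel outside the region mask.
#' @seealso [region_masks()] for the mask definitions.
#' @export
remove_region <- function(montage, region) {
  masks <- region_masks(montage)
  if (!region %in% names(masks)) {
    rlang::abort(sprintf("unknown region '%s' (expected one of %s)",
                         region, paste(names(masks), collapse = ", ")))
  }
  kept <- setdiff(seq_len(n_channels(montage)), masks[[region]])
  if (length(kept) == 0) rlang::abort("removing this region would leave no channels")
  new_layout(kept, montage)
}

#' Restrict a montage to a reduction layout
#'
#' @param montage a `vnfc_montage`.
#' @param layout a `vnfc_layout` produced from the same montage.
#' @return A new `vnfc_montage` containing only the kept channels, in order.
#' @export
apply_layout <- function(montage, layout) {
  stopifnot(inherits(montage, "vnfc_montage"), inherits(layout, "vnfc_layout"))
  if (layout$n_total != nrow(montage)) {
    rlang::abort("layout was built for a montage of different size")
  }
  out <- montage[layout$kept, ]
  class(out) <- class(montage)
  attr(out, "montage_name") <- paste0(attr(montage, "montage_name") %||% "custom",
                                      "[", layout$k, "]")
  out
}

#' Plot a montage with optional group colouring
#'
#' @param object a `vnfc_montage`.
#' @param groups optional `vnfc_groups` for colouring.
#' @param ... unused.
#' @return A ggplot object showing electrode positions on the head disc.
#' @export
autoplot.vnfc_montage <- function(object, groups = NULL, ...) {
  df <- tibble::tibble(label = object$label, x = object$x, y = object$y)
  if (!is.null(groups)) df$group <- factor(unclass(groups))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p <- p + ggplot2::geom_point(size = 2)
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  }
  p + ggplot2::geom_text(ggplot2::aes(label = .data$label),
                         size = 2.2, vjust = -1)
}
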