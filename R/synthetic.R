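#' Sample a synthetic subject's ground-truth coupling model
#'
#' A subject is defined by a sparse symmetric phase-coupling matrix over the
#' channels: the subject's "connectome fingerprint". Coupled pairs are drawn
#' uniformly at random (optionally constrained to a channel subset, which the
#' ablation tests use to plant region-specific identity signal).
#'
#' @param n_channels number of channels (default 64).
#' @param coupling_density fraction of the `n(n-1)/2` pairs that are coupled,
#'   in `(0, 1]` (default 0.05).
#' @param coupling_strength strength in `[0, 1]` written into coupled entries
#'   (default 0.7). 0 gives an uncoupled (null) subject.
#' @param base_freq mean oscillator frequency in Hz (default 10, the alpha
#'   band).
#' @param freq_jitter per-channel frequency spread in Hz (default 1).
#' @param noise_sd sensor noise amplitude relative to signal sd (default 0.3).
#' @param phase_noise phase-diffusion strength in rad/sqrt(s) (default 2.5).
#' @param smoothing spatial mixing width on the unit head disc emulating
#'   volume conduction (default 0.08; 0 disables).
#' @param channels optional subset of channel indices within which coupled
#'   pairs are drawn (default all).
#' @param seed RNG seed; distinct seeds give distinct coupling patterns.
#' @return A `vnfc_subject` with the fields above plus `coupling`
#'   (n x n symmetric, zero diagonal).
#' @export
sample_subject <- function(n_channels = 64, coupling_density = 0.05,
                           coupling_strength = 0.7, base_freq = 10,
                           freq_jitter = 1, noise_sd = 0.3,
                           phase_noise = 2.5, smoothing = 0.08,
                           channels = NULL, seed = 1) {
  if (coupling_density <= 0 || coupling_density > 1) {
    rlang::abort("coupling_density must be in (0, 1]")
  }
  if (coupling_strength < 0 || coupling_strength > 1) {
    rlang::abort("coupling_strength must be in [0, 1]")
  }
  if (noise_sd < 0) rlang::abort("noise_sd must be >= 0")
  n <- as.integer(n_channels)
  channels <- if (is.null(channels)) seq_len(n) else as.integer(channels)
  stopifnot(all(channels >= 1), all(channels <= n))
  set.seed(seed)
  K <- matrix(0, n, n)
  nc <- length(channels)
  pairs <- which(upper.tri(matrix(0, nc, nc)), arr.ind = TRUE)
  npair_total <- n * (n - 1) / 2
  nkeep <- round(coupling_density * npair_total)
  nkeep <- min(nkeep, nrow(pairs))
  if (nkeep > 0 && coupling_strength > 0) {
    sel <- pairs[sample.int(nrow(pairs), nkeep), , drop = FALSE]
    i <- channels[sel[, 1]]; j <- channels[sel[, 2]]
    K[cbind(i, j)] <- coupling_strength
    K[cbind(j, i)] <- coupling_strength
  }
  structure(list(coupling = K, n_channels = n, base_freq = base_freq,
                 freq_jitter = freq_jitter, noise_sd = noise_sd,
                 phase_noise = phase_noise, smoothing = smoothing,
                 coupling_density = coupling_density,
                 coupling_strength = coupling_strength, seed = seed),
            class = "vnfc_subject")
}

#' @export
print.vnfc_subject <- function(x, ...) {
  cat(sprintf("<vnfc_subject: %d ch, %d coupled pairs @ strength %.2f>\n",
              x$n_channels, sum(x$coupling[upper.tri(x$coupling)] > 0),
              x$coupling_strength))
  invisible(x)
}

#' Simulate one EEG-like recording from a subject model
#'
#' Channels are Kuramoto-style phase oscillators: each phase advances at its
#' own frequency, is pulled toward coupled channels' phases
#' (`dtheta_i = 2 pi f_i dt + g sum_j K_ij sin(theta_j - theta_i) dt + noise`),
#' and the emitted signal is `sin(theta_i)` mixed with nearby channels (a
#' volume-conduction surrogate) plus white sensor noise. PLV is exactly the
#' order parameter of this process, so coupled pairs have high PLV and
#' independent channels decay to the finite-window null level.
#'
#' @param subject a `vnfc_subject`.
#' @param duration_s recording length in seconds (>= 1).
#' @param fs sampling rate in Hz (>= 32; default 160).
#' @param seed RNG seed; the recording is deterministic given
#'   (subject, duration, fs, seed).
#' @param montage optional `vnfc_montage` supplying positions for the spatial
#'   mixing; defaults to the builtin 64-channel montage when the channel
#'   counts match, otherwise mixing is skipped.
#' @param coupling_gain conversion from coupling strength to pull rate in
#'   rad/s (default 5, of the same order as the detuning spread: strong
#'   enough that full-strength pairs phase-lock visibly, weak enough that
#'   locking does not percolate into global synchrony).
#' @param freqs optional fixed per-channel frequency vector (Hz). By default
#'   frequencies are drawn per recording from
#'   `base_freq + freq_jitter * N(0,1)`; a fixed vector makes the frequency
#'   pattern common to several recordings (see `shared_freqs` in
#'   [simulate_cohort()]).
#' @return A `vnfc_recording` of `n_channels x duration_s * fs` samples.
#' @export
simulate_recording <- function(subject, duration_s = 60, fs = 160, seed = 1,
                               montage = NULL, coupling_gain = 5,
                               freqs = NULL) {
  stopifnot(inherits(subject, "vnfc_subject"))
  if (duration_s < 1) rlang::abort("duration must be at least 1 s")
  if (fs < 32) rlang::abort("fs must be at least 32 Hz")
  n <- subject$n_channels
  Tn <- as.integer(round(duration_s * fs))
  dt <- 1 / fs
  set.seed(seed)
  freq <- if (is.null(freqs)) {
    subject$base_freq + subject$freq_jitter * stats::rnorm(n)
  } else {
    stopifnot(length(freqs) == n)
    freqs
  }
  omega <- 2 * pi * freq
  K <- subject$coupling * coupling_gain
  coupled <- any(K > 0)
  theta <- matrix(0, n, Tn)
  theta[, 1] <- stats::runif(n, -pi, pi)
  pn <- subject$phase_noise * sqrt(dt)
  noise <- matrix(stats::rnorm(n * (Tn - 1)), n, Tn - 1) * pn
  for (t in seq_len(Tn - 1)) {
    th <- theta[, t]
    pull <- if (coupled) {
      z <- exp(1i * th)
      Im(Conj(z) * (K %*% z))
    } else 0
    theta[, t + 1] <- th + (omega + pull) * dt + noise[, t]
  }
  x <- sin(theta)
  if (subject$smoothing > 0) {
    if (is.null(montage) && n == 64) montage <- load_montage("physionet64")
    if (!is.null(montage) && nrow(montage) == n) {
      d2 <- as.matrix(stats::dist(cbind(montage$x, montage$y)))^2
      G <- exp(-d2 / (2 * subject$smoothing^2))
      G <- G / rowSums(G)
      x <- G %*% x
    }
  }
  if (subject$noise_sd > 0) {
    x <- x + subject$noise_sd * stats::sd(x) *
      matrix(stats::rnorm(n * Tn), n, Tn)
  }
  new_recording(x, fs = fs, subject_id = paste0("subject", subject$seed),
                condition = "synthetic")
}

#' Simulate a multi-subject cohort
#'
#' Draws `n_subjects` subject models with controllably distinct coupling
#' fingerprints and simulates `runs_per_subject` recordings each. With
#' `separation = 1` every subject's coupled pairs are drawn independently
#' (expected pattern overlap ~ `coupling_density`); lower values mix in a
#' pool of shared edges so subjects become harder to tell apart.
#'
#' @param n_subjects number of subjects (>= 2; default 10).
#' @param runs_per_subject recordings per subject (default 3).
#' @param duration_s length of each recording (default 60 s).
#' @param fs sampling rate (default 160 Hz).
#' @param n_channels channels (default 64).
#' @param separation in `[0, 1]`: fraction of each subject's coupled pairs
#'   that are subject-specific rather than drawn from a cohort-shared pool
#'   (default 1).
#' @param seed global seed; per-subject and per-run seeds are derived from it
#'   (see [derive_seed()]).
#' @param coupling_gain forwarded to [simulate_recording()].
#' @param shared_freqs if `TRUE`, one per-channel frequency vector is drawn
#'   from the global seed and shared by every recording in the cohort, so
#'   channel frequencies carry no subject information and only the coupling
#'   fingerprints distinguish subjects (used by planted-signal tests).
#' @param ... further arguments passed to [sample_subject()]
#'   (coupling density/strength, noise levels, planted `channels`, ...).
#' @return A `vnfc_cohort`: list with `subjects`, `recordings` (flat list of
#'   `vnfc_recording` with subject ids `S01`, `S02`, ...), and a `manifest`
#'   recording every parameter.
#' @export
simulate_cohort <- function(n_subjects = 10, runs_per_subject = 3,
                            duration_s = 60, fs = 160, n_channels = 64,
                            separation = 1, seed = 7, coupling_gain = 5,
                            shared_freqs = FALSE, ...) {
  if (n_subjects < 2) rlang::abort("need at least 2 subjects")
  if (separation < 0 || separation > 1) rlang::abort("separation must be in [0, 1]")
  dots <- list(...)
  density <- dots$coupling_density %||% formals(sample_subject)$coupling_density
  npair <- n_channels * (n_channels - 1) / 2
  n_edges <- round(density * npair)
  n_shared <- round((1 - separation) * n_edges)
  set.seed(derive_seed(seed, "shared_pool"))
  all_pairs <- which(upper.tri(matrix(0, n_channels, n_channels)), arr.ind = TRUE)
  shared_sel <- if (n_shared > 0) all_pairs[sample.int(npair, n_shared), , drop = FALSE]

  freqs <- if (shared_freqs) {
    set.seed(derive_seed(seed, "shared_freqs"))
    base <- dots$base_freq %||% formals(sample_subject)$base_freq
    jit <- dots$freq_jitter %||% formals(sample_subject)$freq_jitter
    base + jit * stats::rnorm(n_channels)
  }
  subjects <- vector("list", n_subjects)
  recordings <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    args <- c(list(n_channels = n_channels,
                   seed = derive_seed(seed, paste0("subject", s))), dots)
    sub <- do.call(sample_subject, args)
    if (n_shared > 0) {
      # overwrite part of the fingerprint with the cohort-shared edges
      ut <- which(upper.tri(sub$coupling) & sub$coupling > 0)
      set.seed(derive_seed(seed, paste0("blend", s)))
      drop_n <- min(n_shared, length(ut))
      drop_idx <- sample(ut, drop_n)
      M <- sub$coupling
      M[drop_idx] <- 0
      M[cbind(shared_sel[, 1], shared_sel[, 2])] <- sub$coupling_strength
      M[lower.tri(M)] <- 0
      M <- M + t(M)
      sub$coupling <- M
    }
    subjects[[s]] <- sub
    for (r in seq_len(runs_per_subject)) {
      rec <- simulate_recording(sub, duration_s = duration_s, fs = fs,
                                seed = derive_seed(seed, sprintf("run_%d_%d", s, r)),
                                coupling_gain = coupling_gain, freqs = freqs)
      rec$subject_id <- sid
      rec$condition <- sprintf("run%d", r)
      recordings[[length(recordings) + 1]] <- rec
    }
  }
  names(subjects) <- sprintf("S%02d", seq_len(n_subjects))
  manifest <- c(list(n_subjects = n_subjects, runs_per_subject = runs_per_subject,
                     duration_s = duration_s, fs = fs, n_channels = n_channels,
                     separation = separation, seed = seed,
                     coupling_gain = coupling_gain,
                     shared_freqs = shared_freqs), dots)
  structure(list(subjects = subjects, recordings = recordings,
                 manifest = manifest, seed = seed),
            class = "vnfc_cohort")
}

#' @export
print.vnfc_cohort <- function(x, ...) {
  cat(sprintf("<vnfc_cohort: %d subjects x %d runs (%g s @ %g Hz)>\n",
              x$manifest$n_subjects, x$manifest$runs_per_subject,
              x$manifest$duration_s, x$manifest$fs))
  invisible(x)
}

#' Save / load a cohort as a plain-text directory
#'
#' The container is a directory holding `manifest.json`, one
#' `coupling_S??.tsv` per subject, and one `rec_???.tsv` per recording
#' (channels in columns), so fixtures stay inspectable text.
#'
#' @param cohort a `vnfc_cohort`.
#' @param dir target directory (created if missing).
#' @return `dir` (for `save_cohort`) or the reloaded `vnfc_cohort`.
#' @export
save_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vnfc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (sid in names(cohort$subjects)) {
    utils::write.table(cohort$subjects[[sid]]$coupling,
                       file.path(dir, paste0("coupling_", sid, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  meta <- lapply(seq_along(cohort$recordings), function(i) {
    rec <- cohort$recordings[[i]]
    f <- sprintf("rec_%03d.tsv", i)
    utils::write.table(round(t(rec$data), 6), file.path(dir, f), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    list(file = f, subject_id = rec$subject_id, condition = rec$condition,
         fs = rec$fs)
  })
  jsonlite::write_json(meta, file.path(dir, "recordings.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "recordings.json"),
                              simplifyVector = FALSE)
  recs <- lapply(meta, function(m) {
    d <- t(as.matrix(utils::read.table(file.path(dir, m$file), sep = "\t")))
    new_recording(d, fs = m$fs, subject_id = m$subject_id,
                  condition = m$condition)
  })
  cfiles <- sort(list.files(dir, pattern = "^coupling_.*\\.tsv$"))
  subjects <- lapply(cfiles, function(f) {
    K <- as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))
    dimnames(K) <- NULL
    structure(list(coupling = K, n_channels = nrow(K)),
              class = "vnfc_subject")
  })
  names(subjects) <- sub("^coupling_(.*)\\.tsv$", "\\1", cfiles)
  structure(list(subjects = subjects, recordings = recs, manifest = manifest,
                 seed = manifest$seed),
            class = "vnfc_cohort")
}
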