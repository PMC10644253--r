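test_that("subject coupling matrices honour density, strength and symmetry", {
  s0 <- sample_subject(coupling_strength = 0, seed = 1)
  expect_true(all(s0$coupling == 0))

  s1 <- sample_subject(n_channels = 10, coupling_density = 1, seed = 2)
  expect_true(all(s1$coupling[upper.tri(s1$coupling)] > 0))

  # realized density within one edge of target, by exhaustive count
  s <- sample_subject(n_channels = 64, coupling_density = 0.05, seed = 3)
  n_edges <- sum(s$coupling[upper.tri(s$coupling)] > 0)
  expect_lte(abs(n_edges - 0.05 * 2016), 1)
  expect_symmetric(s$coupling)
  expect_equal(diag(s$coupling), rep(0, 64))

  # distinct seeds -> distinct fingerprints
  expect_false(identical(sample_subject(seed = 4)$coupling,
                         sample_subject(seed = 5)$coupling))
  expect_error(sample_subject(coupling_density = 0), "density")
  expect_error(sample_subject(coupling_strength = 2), "strength")
})

test_that("recordings are deterministic and phase-lock as designed", {
  sub <- sample_subject(n_channels = 4, coupling_density = 1e-9, seed = 1)
  # no coupling, no noise, identical frequencies and phases -> identical channels
  sub$coupling[] <- 0
  sub$noise_sd <- 0; sub$phase_noise <- 0; sub$freq_jitter <- 0
  sub$smoothing <- 0
  # initial phases differ per channel, but with zero detuning and zero noise
  # the phase differences are constant, so every pairwise PLV is 1
  rec <- simulate_recording(sub, duration_s = 4, fs = 160, seed = 1)
  P <- plv_matrix(rec$data)
  expect_true(all(P > 0.999))  # zero detuning, zero noise: perfect locking

  r1 <- simulate_recording(sample_subject(seed = 9), 2, 160, seed = 3)
  r2 <- simulate_recording(sample_subject(seed = 9), 2, 160, seed = 3)
  expect_identical(r1$data, r2$data)
  expect_error(simulate_recording(sample_subject(seed = 1), 0.5, 160), "duration")
})

test_that("uncoupled channels sit at the finite-window PLV null level", {
  sub <- sample_subject(n_channels = 8, coupling_strength = 0, seed = 2,
                        smoothing = 0, noise_sd = 0)
  plvs <- c()
  for (r in 1:6) {
    rec <- simulate_recording(sub, duration_s = 30, fs = 160, seed = 100 + r)
    P <- plv_matrix(rec$data)
    plvs <- c(plvs, P[upper.tri(P)])
  }
  # null expectation for T = 4800 independent-ish phases is sqrt(pi)/2/sqrt(T)
  # ~ 0.013; detuned oscillators decorrelate more slowly, so allow an order
  # of magnitude, still far below the coupled regime (~0.5+)
  expect_lt(mean(plvs), 0.15)
})

test_that("a strongly coupled pair beats an uncoupled pair in >= 95% of replicates", {
  hits <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    sub <- sample_subject(n_channels = 4, coupling_density = 1e-9,
                          seed = 1000 + r, smoothing = 0)
    sub$coupling[1, 2] <- sub$coupling[2, 1] <- 1  # planted strong pair
    rec <- simulate_recording(sub, duration_s = 10, fs = 160, seed = 2000 + r)
    P <- plv_matrix(rec$data)
    hits <- hits + (P[1, 2] > P[3, 4])
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("estimated PLV is monotone in coupling strength (Monte-Carlo averaged)", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(grid, function(k) {
    vals <- vapply(1:5, function(r) {
      sub <- sample_subject(n_channels = 2, coupling_density = 1e-9,
                            seed = r, smoothing = 0)
      sub$coupling[1, 2] <- sub$coupling[2, 1] <- k
      rec <- simulate_recording(sub, duration_s = 10, fs = 160, seed = 300 + r)
      plv_matrix(rec$data)[1, 2]
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) > -0.02))  # non-decreasing up to MC noise
  expect_gt(means[5], means[1] + 0.2)
})

test_that("cohorts are reproducible, separable and recover ground truth", {
  co <- simulate_cohort(n_subjects = 3, runs_per_subject = 2, duration_s = 10,
                        fs = 160, seed = 7)
  expect_length(co$recordings, 6)
  expect_equal(unique(vapply(co$recordings, function(r) r$subject_id, "")),
               c("S01", "S02", "S03"))

  co2 <- simulate_cohort(n_subjects = 3, runs_per_subject = 2, duration_s = 10,
                         fs = 160, seed = 7)
  expect_identical(co$recordings[[1]]$data, co2$recordings[[1]]$data)

  # max separation: pairwise coupling-pattern correlation stays low
  cors <- c()
  for (i in 1:2) for (j in (i + 1):3) {
    a <- co$subjects[[i]]$coupling[upper.tri(co$subjects[[i]]$coupling)]
    b <- co$subjects[[j]]$coupling[upper.tri(co$subjects[[j]]$coupling)]
    cors <- c(cors, cor(a, b))
  }
  expect_lt(max(abs(cors)), 0.25)

  # lower separation raises overlap
  cosh_ <- simulate_cohort(n_subjects = 3, runs_per_subject = 1, duration_s = 1,
                           fs = 160, seed = 7, separation = 0)
  a <- cosh_$subjects[[1]]$coupling; b <- cosh_$subjects[[2]]$coupling
  expect_gt(cor(a[upper.tri(a)], b[upper.tri(b)]), 0.9)

  expect_error(simulate_cohort(n_subjects = 1), "at least 2")
})

test_that("estimated PLV correlates with the subject's true coupling (r > 0.5)", {
  co <- simulate_cohort(n_subjects = 2, runs_per_subject = 1, duration_s = 60,
                        fs = 160, seed = 7)
  for (s in 1:2) {
    rec <- co$recordings[[s]]
    K <- co$subjects[[rec$subject_id]]$coupling
    P <- plv_matrix(rec$data)
    ut <- upper.tri(P)
    expect_gt(cor(P[ut], K[ut]), 0.5)
  }
})

test_that("cohort text container round-trips", {
  co <- simulate_cohort(n_subjects = 2, runs_per_subject = 1, duration_s = 2,
                        fs = 64, seed = 3)
  dir <- withr::local_tempdir()
  save_cohort(co, dir)
  back <- load_cohort(dir)
  expect_length(back$recordings, 2)
  expect_equal(back$recordings[[1]]$subject_id, co$recordings[[1]]$subject_id)
  expect_equal(back$recordings[[1]]$data, co$recordings[[1]]$data,
               tolerance = 1e-5)
  expect_equal(back$subjects$S01$coupling, co$subjects$S01$coupling)
  expect_equal(back$manifest$seed, 3)
})
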