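test_that("proximity ratio and stoichiometry follow their definitions", {
  tr <- make_trace(DD = c(60, 0, 50), DA = c(60, 100, 50),
                   AA = c(120, 100, 0))
  fs <- compute_fret_series(tr, background = "none")
  expect_equal(fs$E, c(0.5, 1.0, 0.5))
  expect_equal(fs$S, c(0.5, 0.5, 1.0))

  # nonpositive FRET denominator is masked, not dropped
  tr <- make_trace(DD = c(10, 0), DA = c(10, 0), AA = c(5, 5))
  fs <- compute_fret_series(tr, background = "none")
  expect_equal(fs$valid, c(TRUE, FALSE))
  expect_true(is.na(fs$E[2]))
})

test_that("E* and S are invariant under intensity rescaling", {
  set.seed(42)
  for (c_scale in c(0.5, 3, 17)) {
    DD <- runif(50, 50, 300); DA <- runif(50, 50, 300)
    AA <- runif(50, 50, 300)
    f1 <- compute_fret_series(make_trace(DD, DA, AA), background = "none")
    f2 <- compute_fret_series(make_trace(c_scale * DD, c_scale * DA,
                                         c_scale * AA), background = "none")
    expect_equal(f1$E, f2$E, tolerance = 1e-12)
    expect_equal(f1$S, f2$S, tolerance = 1e-12)
  }
})

test_that("histogram enforces the per-molecule frame budget", {
  # budget: min(250, available) earliest valid frames per molecule
  fs_long <- rep(0.45, 400)
  fs_short <- rep(0.2, 120)
  h <- build_fret_histogram(list(fs_long, fs_short))
  expect_equal(sum(h$counts), 250 + 120)

  # one molecule at constant E* occupies a single bin
  h1 <- build_fret_histogram(list(rep(0.45, 100)))
  expect_equal(sum(h1$counts > 0), 1L)

  # equal-frame molecules at two levels give two equal-mass modes
  h2 <- build_fret_histogram(list(rep(0.2, 250), rep(0.45, 250)))
  occupied <- which(h2$counts > 0)
  expect_length(occupied, 2L)
  expect_equal(h2$counts[occupied], c(250L, 250L))
  expect_error(build_fret_histogram(list()), "empty")
})

test_that("Gaussian mixture EM recovers known mixtures", {
  set.seed(7)
  # single component
  x <- rnorm(5000, 0.45, 0.07)
  f1 <- fit_fret_mixture(x, k = 1)
  expect_equal(f1$means, 0.45, tolerance = 3 * 0.07 / sqrt(5000) / 0.45)
  expect_equal(f1$sds, 0.07, tolerance = 0.05)

  # 75/25 at 0.45 / 0.2 (the canonical bubble histogram shape)
  x <- c(rnorm(15000, 0.45, 0.07), rnorm(5000, 0.2, 0.06))
  f2 <- fit_fret_mixture(x, k = 2)
  expect_equal(f2$weights, c(0.25, 0.75), tolerance = 0.03)
  expect_equal(f2$means, c(0.2, 0.45), tolerance = 0.05)

  # symmetric mixture
  x <- c(rnorm(8000, 0.2, 0.06), rnorm(8000, 0.45, 0.06))
  f3 <- fit_fret_mixture(x, k = 2)
  expect_equal(f3$weights, c(0.5, 0.5), tolerance = 0.03)
})

test_that("mixture EM agrees with an independent GMM implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(11)
  x <- c(rnorm(6000, 0.45, 0.07), rnorm(2000, 0.2, 0.06))
  ours <- fit_fret_mixture(x, k = 2)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  o <- order(mc$parameters$mean)
  expect_equal(ours$means, as.numeric(mc$parameters$mean[o]),
               tolerance = 0.01)
  expect_equal(ours$weights, as.numeric(mc$parameters$pro[o]),
               tolerance = 0.02)
})

test_that("distance-FRET conversion matches the Foerster relation", {
  expect_equal(distance_to_fret(7.06, 7.06), 0.5)
  expect_gt(distance_to_fret(0.1, 7.06), 0.999)
  expect_lt(distance_to_fret(100, 7.06), 1e-6)
  # 7.3 nm separation with R0 = 7.06 nm sits at the open-bubble E* ~ 0.45
  expect_equal(distance_to_fret(7.3, 7.06), 0.45, tolerance = 0.01)
  expect_error(distance_to_fret(-1, 5), "positive")
})

test_that("static free-DNA molecules read back their true E*", {
  cfg <- scenario_fixture("free_dna", n_molecules = 8, seed = 15)
  ds <- simulate_dataset(cfg)
  means <- vapply(seq_along(ds$traces), function(i) {
    fs <- compute_fret_series(ds$traces[[i]])
    end <- min(c(ds$truth[[i]]$donor_bleach_frame,
                 ds$truth[[i]]$acceptor_bleach_frame,
                 length(fs$E) + 1L), na.rm = TRUE) - 1L
    fs <- truncate_fret(fs, max(end, 20L))
    mean(fs$E[fs$valid])
  }, numeric(1))
  expect_true(all(abs(means - 0.17) < 0.02))
})
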