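test_that("a chain with no exit rates stays put for the whole record", {
  sc <- static_scheme(0.45, "open")
  ev <- simulate_state_path(sc, 12.5, seed = 4)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$entry_time, 0)
  expect_equal(ev$exit_time, 12.5)
})

test_that("symmetric two-state chain splits its time evenly", {
  sc <- two_state_scheme(5, 5)
  ev <- simulate_state_path(sc, 1000, seed = 7)
  frac1 <- sum((ev$exit_time - ev$entry_time)[ev$state == 1]) / 1000
  expect_equal(frac1, 0.5, tolerance = 0.03)
})

test_that("closed sojourns are exponential with the configured exit rate", {
  # closed-state exit rate 6.4 1/s -> mean sojourn 1/6.4 ~ 156 ms
  sc <- two_state_scheme(6.4, 8)
  ev <- simulate_state_path(sc, 3000, seed = 11)
  soj <- (ev$exit_time - ev$entry_time)[ev$state == 1]
  soj <- soj[-c(1, length(soj))]          # drop boundary-truncated sojourns
  expect_gt(length(soj), 5000)
  se <- (1 / 6.4) / sqrt(length(soj))
  expect_lt(abs(mean(soj) - 1 / 6.4), 3 * se)
  # distributional agreement (Kolmogorov-Smirnov at alpha = 0.01)
  ks <- suppressWarnings(ks.test(soj, "pexp", 6.4))
  expect_gt(ks$p.value, 0.01)
})

test_that("long-run state occupancy matches the stationary distribution", {
  sc <- dynamic_bubble_scheme()
  pi_true <- stationary_distribution(sc)
  ev <- simulate_state_path(sc, 2000, seed = 13)
  dur <- ev$exit_time - ev$entry_time
  occ <- vapply(1:3, function(s) sum(dur[ev$state == s]), numeric(1)) / 2000
  # batch-means standard error over 20 blocks
  blocks <- cut(ev$entry_time, breaks = seq(0, 2000, length.out = 21))
  for (s in 1:3) {
    bfrac <- tapply(dur * (ev$state == s), blocks, sum) / 100
    se <- sd(bfrac) / sqrt(20)
    expect_lt(abs(occ[s] - pi_true[s]), 3 * se)
  }
})

test_that("frame discretization averages FRET by occupancy", {
  sc <- two_state_scheme(0, 0, e1 = 0.2, e2 = 0.45)
  # one state for the whole trace
  ev <- manual_events(1L, c(0, 0.05), sc)
  d <- discretize_path(ev, 0.01, sc)
  expect_equal(d$fret, rep(0.2, 5))
  expect_equal(d$dominant_state, rep(1L, 5))
  # transition exactly at a frame boundary: pure values on either side
  ev <- manual_events(c(1L, 2L), c(0, 0.02, 0.04), sc)
  d <- discretize_path(ev, 0.01, sc)
  expect_equal(d$fret, c(0.2, 0.2, 0.45, 0.45))
  # mid-frame transition mixes proportionally: 0.5 * 0.2 + 0.5 * 0.45
  ev <- manual_events(c(1L, 2L), c(0, 0.015, 0.03), sc)
  d <- discretize_path(ev, 0.01, sc)
  expect_equal(d$fret[2], 0.325)
  expect_equal(d$fret[c(1, 3)], c(0.2, 0.45))
  expect_error(discretize_path(ev[0, ], 0.01, sc), "empty")
})

test_that("camera model reproduces its photon budget and gain", {
  pp <- photophysics_params(photons_per_frame_dex = 0,
                            background_per_channel = 0, read_noise_sd = 0,
                            donor_bleach_rate = 0, acceptor_bleach_rate = 0)
  sim <- simulate_alex_trace(rep(0.5, 200), pp, 0.01, seed = 1)
  expect_true(all(sim$trace$DD == 0) && all(sim$trace$DA == 0))

  # huge photon budget: DD and DA agree to < 0.2% at E = 0.5
  pp <- photophysics_params(photons_per_frame_dex = 1e6,
                            background_per_channel = 0, read_noise_sd = 0,
                            donor_bleach_rate = 0, acceptor_bleach_rate = 0)
  sim <- simulate_alex_trace(rep(0.5, 50), pp, 0.01, seed = 2)
  expect_lt(abs(mean(sim$trace$DD) / mean(sim$trace$DA) - 1), 0.002)

  # 100 photons/frame at gain 4.55 -> ~455 counts/frame
  pp <- photophysics_params(photons_per_frame_dex = 100,
                            background_per_channel = 0, read_noise_sd = 0,
                            donor_bleach_rate = 0, acceptor_bleach_rate = 0)
  sim <- simulate_alex_trace(rep(0.4, 3000), pp, 0.01, seed = 3)
  expect_equal(mean(sim$trace$DD + sim$trace$DA), 455, tolerance = 0.02)
})

test_that("bleaching silences the right channels", {
  pp <- photophysics_params(acceptor_bleach_rate = 2, donor_bleach_rate = 0,
                            background_per_channel = 0, read_noise_sd = 0)
  sim <- simulate_alex_trace(rep(0.45, 500), pp, 0.01, seed = 8)
  ab <- sim$truth$acceptor_bleach_frame
  expect_false(is.na(ab))
  post <- (ab + 1):500
  expect_equal(mean(sim$trace$AA[post]), 0, tolerance = 1e-9)
  expect_equal(mean(sim$trace$DA[post]), 0, tolerance = 1e-9)
  # donor-excitation photons all land in DD after acceptor loss
  expect_equal(mean(sim$trace$DD[post]), 455, tolerance = 0.05)
})

test_that("dataset allocation is exactly proportional and seeded", {
  cfg <- scenario_fixture("wt_dsDNA_22C", n_molecules = 100, seed = 3)
  ds <- simulate_dataset(cfg)
  tab <- table(vapply(ds$truth, `[[`, character(1), "subpopulation"))
  expect_equal(tab[["static_open"]], 50)
  expect_equal(tab[["static_closed"]], 20)
  expect_equal(tab[["static_mid"]], 5)
  expect_equal(tab[["dynamic"]], 25)

  sub <- scenario_config("tiny", list(
    list(proportion = 0.75, scheme = static_scheme(0.45, "open"), label = "a"),
    list(proportion = 0.25, scheme = static_scheme(0.2, "closed"), label = "b")),
    n_molecules = 4, max_duration_s = 1, seed = 5)
  ds <- simulate_dataset(sub)
  tab <- table(vapply(ds$truth, `[[`, character(1), "subpopulation"))
  expect_equal(as.integer(tab[c("a", "b")]), c(3L, 1L))

  expect_error(simulate_dataset(scenario_config("x", sub$subpopulations,
                                                n_molecules = 0)),
               "n_molecules")
})

test_that("identical seeds give bit-identical datasets, new seeds fresh noise", {
  cfg1 <- scenario_fixture("free_dna", n_molecules = 4, seed = 9,
                           max_duration_s = 2)
  cfg2 <- scenario_fixture("free_dna", n_molecules = 4, seed = 9,
                           max_duration_s = 2)
  ds1 <- simulate_dataset(cfg1)
  ds2 <- simulate_dataset(cfg2)
  expect_identical(ds1$traces, ds2$traces)
  cfg3 <- scenario_fixture("free_dna", n_molecules = 4, seed = 10,
                           max_duration_s = 2)
  ds3 <- simulate_dataset(cfg3)
  expect_false(identical(ds1$traces[[1]]$DD, ds3$traces[[1]]$DD))
})

test_that("without noise or bleaching E* equals the true frame FRET exactly", {
  sc <- dynamic_bubble_scheme()
  ev <- simulate_state_path(sc, 5, seed = 21)
  disc <- discretize_path(ev, 0.01, sc)
  sim <- simulate_alex_trace(disc$fret, noiseless_photophysics(), 0.01,
                             seed = 1)
  fs <- compute_fret_series(sim$trace, background = "none")
  expect_equal(fs$E, disc$fret, tolerance = 1e-12)
})

test_that("contact quenching suppresses donor-excitation emission", {
  cfg <- scenario_fixture("bubble_labels_22C", n_molecules = 2, seed = 2,
                          max_duration_s = 3)
  ds <- simulate_dataset(cfg)
  tr <- ds$traces[[1]]
  truth <- ds$truth[[1]]
  closed <- truth$scheme$state_category[truth$state_per_frame] == "closed"
  pre <- seq_len(min(c(truth$donor_bleach_frame, truth$acceptor_bleach_frame,
                       length(tr$DD)), na.rm = TRUE) - 1)
  tot <- (tr$DD + tr$DA - 40)[pre]
  expect_lt(mean(tot[closed[pre]]), 0.3 * mean(tot[!closed[pre]]))
})
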