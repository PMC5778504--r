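test_that("noise-free two-level series is recovered essentially exactly", {
  x <- rep(c(0.2, 0.2, 0.2, 0.45, 0.45), 30)
  m <- fit_vb_hmm(x, K = 2, seed = 1)
  expect_equal(sort(m$emission_mean), c(0.2, 0.45), tolerance = 1e-3)
  p <- decode_path(m, x)
  truth <- rep(c(1L, 1L, 1L, 2L, 2L), 30)
  lo_state <- which.min(m$emission_mean)
  decoded <- ifelse(p$states == lo_state, 1L, 2L)
  expect_equal(decoded, truth)
})

test_that("single-state fit recovers an i.i.d. Gaussian", {
  set.seed(2)
  x <- rnorm(400, 0.45, 0.07)
  m <- fit_vb_hmm(x, K = 1, seed = 1)
  expect_equal(m$emission_mean, mean(x), tolerance = 3 * 0.07 / sqrt(400))
  expect_equal(m$emission_sd, sd(x), tolerance = 0.01)
  expect_true(m$converged)
})

test_that("the variational evidence is non-decreasing over iterations", {
  set.seed(3)
  for (rep_i in 1:4) {
    sc <- two_state_scheme(4, 4)
    ev <- simulate_state_path(sc, 6, seed = 40 + rep_i)
    disc <- discretize_path(ev, 0.01, sc)
    x <- disc$fret + rnorm(length(disc$fret), 0, 0.07)
    for (K in 1:3) {
      m <- fit_vb_hmm(x, K, seed = rep_i)
      expect_true(all(diff(m$elbo_trace) > -1e-7),
                  info = sprintf("rep %d K %d", rep_i, K))
    }
  }
})

test_that("K=1 evidence equals the closed-form conjugate marginal", {
  set.seed(4)
  x <- rnorm(300, 0.35, 0.08)
  pri <- hmm_priors()
  m <- fit_vb_hmm(x, K = 1, priors = pri, seed = 1)
  oracle <- gaussian_log_marginal(x, m0 = mean(x), beta0 = pri$beta0,
                                  a0 = pri$a0, b0 = pri$b0)
  expect_equal(m$evidence, oracle, tolerance = 1e-6)
})

test_that("Viterbi decoding matches exhaustive enumeration on short series", {
  set.seed(5)
  for (rep_i in 1:5) {
    x <- runif(10, 0, 0.7)
    mu <- c(0.2, 0.45); sdv <- c(0.07, 0.07)
    pi0 <- c(0.6, 0.4)
    A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
    model <- structure(list(K = 2L, initial_probs = pi0,
                            transition_matrix = A, emission_mean = mu,
                            emission_sd = sdv), class = "hmm_model")
    got <- decode_path(model, x)$states
    want <- enumerate_map_path(x, pi0, A, mu, sdv)
    expect_equal(got, want, info = paste("replicate", rep_i))
  }
})

test_that("posterior state probabilities sum to one per frame", {
  set.seed(6)
  x <- c(rnorm(100, 0.2, 0.07), rnorm(100, 0.45, 0.07))
  m <- fit_vb_hmm(x, K = 2, seed = 2)
  p <- decode_path(m, x)
  expect_equal(rowSums(p$posterior), rep(1, 200), tolerance = 1e-9)
})

test_that("invalid-frame gaps split the series without breaking decoding", {
  set.seed(7)
  x <- c(rnorm(120, 0.2, 0.06), rep(NA_real_, 10), rnorm(120, 0.45, 0.06))
  m <- fit_vb_hmm(x, K = 2, seed = 3)
  expect_equal(sort(m$emission_mean), c(0.2, 0.45), tolerance = 0.03)
  p <- decode_path(m, x)
  expect_true(all(is.na(p$states[121:130])))
  expect_equal(length(unique(p$states[1:120])), 1L)
})

test_that("maximum evidence selects the true number of states", {
  set.seed(8)
  # constant plus noise -> one state
  x <- rnorm(400, 0.45, 0.07)
  expect_equal(select_model(x, seed = 1)$K, 1L)

  # well-separated two-state dynamics -> two states, in most replicates
  hits <- 0L
  for (r in 1:8) {
    sc <- two_state_scheme(4, 4)
    ev <- simulate_state_path(sc, 8, seed = 100 + r)
    disc <- discretize_path(ev, 0.01, sc)
    x <- disc$fret + rnorm(length(disc$fret), 0, 0.07)
    hits <- hits + (select_model(x, seed = r)$K == 2L)
  }
  expect_gte(hits, 7L)

  # three-state linear chain with ample dwell statistics -> three states
  sc3 <- kinetic_scheme(
    c("c", "i", "o"), c(0.2, 0.35, 0.45),
    c("closed", "intermediate", "open"),
    matrix(c(0, 4, 0,
             4, 0, 4,
             0, 4, 0), 3, 3, byrow = TRUE))
  ev <- simulate_state_path(sc3, 25, seed = 9)
  disc <- discretize_path(ev, 0.01, sc3)
  x <- disc$fret + rnorm(length(disc$fret), 0, 0.04)
  expect_equal(select_model(x, seed = 2)$K, 3L)
})

test_that("emission means are recovered on dynamic fixture traces", {
  sc <- dynamic_bubble_scheme()
  err <- c()
  for (r in 1:3) {
    ev <- simulate_state_path(sc, 10, seed = 200 + r)
    disc <- discretize_path(ev, 0.01, sc)
    sim <- simulate_alex_trace(disc$fret, photophysics_params(
      donor_bleach_rate = 0, acceptor_bleach_rate = 0), 0.01, seed = r)
    fs <- compute_fret_series(sim$trace, background = "none")
    m <- fit_vb_hmm(fs, K = 2, seed = r)
    err <- c(err, abs(sort(m$emission_mean) - c(0.2, 0.45)))
  }
  expect_lt(max(err), 0.03)
})

test_that("state categorization uses half-open boundary intervals", {
  mk <- function(mu) structure(list(K = length(mu), emission_mean = mu),
                               class = "hmm_model")
  expect_equal(categorize_states(mk(c(0.2, 0.45))), c("closed", "open"))
  expect_equal(categorize_states(mk(0.35)), "intermediate")
  expect_equal(categorize_states(mk(0.40)), "open")     # boundary is open
  expect_equal(categorize_states(mk(0.275)), "intermediate")
})

test_that("series shorter than the frame minimum are rejected from fitting", {
  expect_error(fit_vb_hmm(rnorm(30, 0.3, 0.05), K = 2), "valid frames")
})
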