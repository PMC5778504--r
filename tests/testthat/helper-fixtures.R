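# shared builders for the test suite (everything generated in code)

# symmetric two-state scheme
two_state_scheme <- function(k12 = 5, k21 = 5, e1 = 0.2, e2 = 0.45) {
  kinetic_scheme(c("lo", "hi"), c(e1, e2), c("closed", "open"),
                 matrix(c(0, k12, k21, 0), 2, 2, byrow = TRUE))
}

# manually built event path (entry/exit times in seconds)
manual_events <- function(states, times, scheme) {
  data.frame(state = states,
             label = scheme$state_labels[states],
             category = scheme$state_category[states],
             entry_time = head(times, -1),
             exit_time = tail(times, -1))
}

# synthetic intensity trace with a given AA / DD / DA shape
make_trace <- function(DD, DA, AA, dt = 0.01, id = "t",
                       background = c(DD = 0, DA = 0, AA = 0)) {
  alex_trace(DD, DA, AA, frame_period_s = dt, molecule_id = id,
             background = background)
}

# dwell data.frame from raw durations
make_dwells <- function(durations, category = "closed", t_min = 0.01,
                        molecule_id = NULL) {
  n <- length(durations)
  if (is.null(molecule_id))
    molecule_id <- paste0("m", rep(seq_len(max(1, n %/% 50)), length.out = n))
  d <- data.frame(molecule_id = molecule_id, category = category,
                  duration_s = durations,
                  left_censored = FALSE, right_censored = FALSE,
                  stringsAsFactors = FALSE)
  attr(d, "frame_period_s") <- t_min
  d
}

# closed-form log marginal likelihood of the conjugate Gaussian model
# (independent oracle for the K = 1 variational bound)
gaussian_log_marginal <- function(x, m0, beta0, a0, b0) {
  n <- length(x)
  xbar <- mean(x)
  S <- sum((x - xbar)^2)
  betan <- beta0 + n
  an <- a0 + n / 2
  bn <- b0 + 0.5 * (S + beta0 * n * (xbar - m0)^2 / betan)
  -n / 2 * log(2 * pi) + 0.5 * (log(beta0) - log(betan)) +
    lgamma(an) - lgamma(a0) + a0 * log(b0) - an * log(bn)
}

# brute-force most-probable path by enumeration (oracle for Viterbi)
enumerate_map_path <- function(x, pi0, A, mu, sdv) {
  K <- length(pi0); T <- length(x)
  grid <- expand.grid(rep(list(seq_len(K)), T))
  best <- -Inf; best_z <- NULL
  for (i in seq_len(nrow(grid))) {
    z <- as.integer(grid[i, ])
    lp <- log(pi0[z[1]]) + dnorm(x[1], mu[z[1]], sdv[z[1]], log = TRUE)
    if (T > 1) for (t in 2:T)
      lp <- lp + log(A[z[t - 1], z[t]]) +
        dnorm(x[t], mu[z[t]], sdv[z[t]], log = TRUE)
    if (lp > best) { best <- lp; best_z <- z }
  }
  best_z
}

# memoised expensive shared dataset runs (built once per test session)
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}
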