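#' @name vb_hmm
#' @title Variational-Bayes Gaussian hidden Markov modelling of E* traces
#'
#' @description
#' A single-molecule E* trajectory is modelled as a K-state hidden Markov
#' chain with Gaussian emissions.  Inference is conjugate variational Bayes
#' (coordinate ascent): Dirichlet priors on the initial distribution and on
#' each transition-matrix row, Normal-Gamma priors on each state's emission
#' mean and precision.  The converged variational lower bound ("evidence")
#' scores each K, and [select_model()] picks the number of states by
#' maximum evidence.  Invalid frames are handled by splitting the series at
#' gaps of 3 or more frames (segments share parameters and each restarts
#' from the initial distribution); shorter gaps are treated as missing
#' observations inside a segment.
NULL

#' Default conjugate prior hyperparameters
#'
#' Dirichlet concentration 1 (uniform) on initial and transition rows; the
#' emission mean prior is centred at the series mean (`m0 = NULL`) with
#' weak precision-scaling `beta0 = 0.1`; Gamma prior on the emission
#' precision with shape 1 and rate 0.01 (prior sd scale ~0.1 E* units).
#'
#' @param dirichlet,beta0,a0,b0,m0 hyperparameters; `m0 = NULL` means
#'   "centre at the observed series mean".
#' @export
hmm_priors <- function(dirichlet = 1, beta0 = 0.1, a0 = 1, b0 = 0.01,
                       m0 = NULL) {
  list(dirichlet = dirichlet, beta0 = beta0, a0 = a0, b0 = b0, m0 = m0)
}

# split a fret_series (or numeric vector) into contiguous segments,
# bridging invalid gaps shorter than `gap_break` as missing observations
build_segments <- function(x, gap_break = 3L) {
  if (inherits(x, "fret_series")) {
    E <- x$E; valid <- x$valid & is.finite(x$E)
  } else {
    E <- as.numeric(x); valid <- is.finite(E)
  }
  idx <- which(valid)
  if (!length(idx)) return(list())
  gaps <- diff(idx)
  brk <- which(gaps > gap_break)     # > allows bridging gaps of < gap_break
  starts <- c(idx[1], idx[brk + 1])
  ends <- c(idx[brk], idx[length(idx)])
  lapply(seq_along(starts), function(s) {
    fr <- starts[s]:ends[s]
    xx <- E[fr]
    xx[!valid[fr]] <- NA_real_
    list(frames = fr, x = xx)
  })
}

kl_dirichlet <- function(alpha, u) {
  sa <- sum(alpha)
  lgamma(sa) - sum(lgamma(alpha)) - lgamma(sum(u)) + sum(lgamma(u)) +
    sum((alpha - u) * (digamma(alpha) - digamma(sa)))
}

kl_normal_gamma <- function(m, beta, a, b, m0, beta0, a0, b0) {
  kl_gamma <- (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
    a0 * (log(b) - log(b0)) + a * (b0 - b) / b
  kl_norm <- 0.5 * (log(beta / beta0) + beta0 / beta - 1 +
                      beta0 * (a / b) * (m - m0)^2)
  kl_gamma + kl_norm
}

# expected log Gaussian density under the Normal-Gamma posterior
expected_log_emission <- function(x, m, beta, a, b) {
  # x: vector (NA -> 0 contribution, handled by caller)
  0.5 * (digamma(a) - log(b) - log(2 * pi) - 1 / beta -
           (a / b) * (x - m)^2)
}

#' Fit a K-state variational-Bayes Gaussian HMM
#'
#' Coordinate-ascent variational inference, iterated until the evidence
#' (variational lower bound) changes by less than `tol` or `max_iter`
#' iterations; `n_restarts` seeded jittered initializations are run and the
#' best-evidence fit returned.  The evidence trace is stored and is
#' non-decreasing within a restart.
#'
#' @param x a `fret_series` from [compute_fret_series()] or a numeric E*
#'   vector (NA = missing frame).
#' @param K number of states (1-3 in routine use; any K >= 1 accepted).
#' @param priors from [hmm_priors()].
#' @param seed integer seed for the restart initializations.
#' @param n_restarts number of jittered initializations (default 10).
#' @param max_iter,tol stopping rule on the evidence.
#' @param min_frames minimum number of valid frames required (default 50).
#' @return object of class `hmm_model`: `K`, `initial_probs`,
#'   `transition_matrix`, `emission_mean`, `emission_sd`, `evidence`,
#'   `converged`, `n_iterations`, `elbo_trace`, `posterior` (variational
#'   parameters), `priors`.
#' @export
fit_vb_hmm <- function(x, K, priors = hmm_priors(), seed = 1L,
                       n_restarts = 10L, max_iter = 500L, tol = 1e-6,
                       min_frames = 50L) {
  segs <- build_segments(x)
  obs <- unlist(lapply(segs, function(s) s$x[is.finite(s$x)]))
  n_obs <- length(obs)
  if (n_obs < min_frames)
    stop("series has fewer than ", min_frames, " valid frames")
  if (K < 1L) stop("K must be >= 1")
  m0 <- priors$m0 %||% mean(obs)
  sd_obs <- max(sd(obs), 1e-4)
  if (K == 1L) n_restarts <- 1L   # single-state fit is deterministic

  # short seeded burn-in for every restart, full convergence for the best
  burn_iter <- min(max_iter, 50L)
  burn_tol <- max(tol, 1e-4)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init_mu <- with_local_seed(substream_seed(seed, 31L, r), {
      q <- quantile(obs, probs = (seq_len(K) - 0.5) / K, names = FALSE)
      jit <- if (r == 1L) 0 else rnorm(K, 0, 0.3 * sd_obs)
      sort(q + jit)
    })
    fit <- vb_hmm_once(segs, K, init_mu, m0, sd_obs, priors,
                       max_iter = burn_iter, tol = burn_tol)
    if (is.null(best) || fit$evidence > best$evidence) best <- fit
  }
  if (!best$converged || burn_tol > tol) {
    refined <- vb_hmm_once(segs, K, NULL, m0, sd_obs, priors,
                           max_iter = max_iter, tol = tol,
                           init_post = best$posterior)
    refined$n_iterations <- refined$n_iterations + best$n_iterations
    best <- refined
  }
  best$n_valid_frames <- n_obs
  best$priors <- priors
  best$seed <- seed
  class(best) <- "hmm_model"
  best
}

# one VB run, from initial means (hard-assignment init) or a posterior
vb_hmm_once <- function(segs, K, init_mu, m0, sd_obs, priors,
                        max_iter = 500L, tol = 1e-6, init_post = NULL) {
  u_pi <- rep(priors$dirichlet, K)
  u_A <- matrix(priors$dirichlet, K, K)

  if (!is.null(init_post)) {
    post <- init_post
  } else {
    # hard-assignment initialization of the variational posteriors
    n_pi0 <- rep(0, K); n_A0 <- matrix(0, K, K)
    Nk <- rep(0, K); Sx <- rep(0, K); Sxx <- rep(0, K)
    for (s in segs) {
      z <- vapply(s$x, function(v)
        if (is.finite(v)) which.min(abs(init_mu - v)) else NA_integer_,
        integer(1))
      zf <- z[!is.na(z)]
      if (!length(zf)) next
      n_pi0[zf[1]] <- n_pi0[zf[1]] + 1
      if (length(zf) > 1L)
        for (t in 2:length(zf))
          n_A0[zf[t - 1], zf[t]] <- n_A0[zf[t - 1], zf[t]] + 1
      xs <- s$x[!is.na(z)]
      for (k in seq_len(K)) {
        sel <- zf == k
        Nk[k] <- Nk[k] + sum(sel)
        Sx[k] <- Sx[k] + sum(xs[sel])
        Sxx[k] <- Sxx[k] + sum(xs[sel]^2)
      }
    }
    post <- mstep_from_counts(n_pi0, n_A0, Nk, Sx, Sxx, u_pi, u_A, priors,
                              m0, init_mu, sd_obs)
  }

  elbo_trace <- numeric(0)
  elbo_old <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    # E-step with expected log parameters of the current posterior
    Elog_pi <- digamma(post$alpha_pi) - digamma(sum(post$alpha_pi))
    Elog_A <- digamma(post$alpha_A) - digamma(rowSums(post$alpha_A))
    Elog_A <- matrix(Elog_A, K, K)

    n_pi <- rep(0, K); n_A <- matrix(0, K, K)
    Nk <- rep(0, K); Sx <- rep(0, K); Sxx <- rep(0, K)
    logZ <- 0
    gammas <- vector("list", length(segs))
    for (si in seq_along(segs)) {
      s <- segs[[si]]
      Tn <- length(s$x)
      logb <- matrix(0, Tn, K)
      fin <- is.finite(s$x)
      for (k in seq_len(K))
        logb[fin, k] <- expected_log_emission(s$x[fin], post$m[k],
                                              post$beta[k], post$a[k],
                                              post$b[k])
      fb <- .fb_segment(logb, Elog_pi, Elog_A)
      gammas[[si]] <- fb$gamma
      logZ <- logZ + fb$logZ
      n_pi <- n_pi + fb$gamma[1, ]
      n_A <- n_A + fb$xi
      g <- fb$gamma[fin, , drop = FALSE]
      xv <- s$x[fin]
      Nk <- Nk + colSums(g)
      Sx <- Sx + colSums(g * xv)
      Sxx <- Sxx + colSums(g * xv^2)
    }

    elbo <- logZ - kl_dirichlet(post$alpha_pi, u_pi) -
      sum(vapply(seq_len(K), function(j)
        kl_dirichlet(post$alpha_A[j, ], u_A[j, ]), numeric(1))) -
      sum(kl_normal_gamma(post$m, post$beta, post$a, post$b,
                          m0, priors$beta0, priors$a0, priors$b0))
    elbo_trace <- c(elbo_trace, elbo)
    if (is.finite(elbo_old) && abs(elbo - elbo_old) < tol) {
      converged <- TRUE
      break
    }
    elbo_old <- elbo

    post <- mstep_from_counts(n_pi, n_A, Nk, Sx, Sxx, u_pi, u_A, priors, m0,
                              post$m, sd_obs)
  }

  A_hat <- post$alpha_A / rowSums(post$alpha_A)
  list(K = K,
       initial_probs = post$alpha_pi / sum(post$alpha_pi),
       transition_matrix = matrix(A_hat, K, K),
       emission_mean = post$m,
       emission_sd = sqrt(post$b / post$a),
       evidence = elbo_trace[length(elbo_trace)],
       converged = converged,
       n_iterations = it,
       elbo_trace = elbo_trace,
       posterior = post)
}

mstep_from_counts <- function(n_pi, n_A, Nk, Sx, Sxx, u_pi, u_A, priors, m0,
                              mu_fallback, sd_obs) {
  K <- length(Nk)
  beta <- priors$beta0 + Nk
  a <- priors$a0 + Nk / 2
  xbar <- ifelse(Nk > 1e-12, Sx / pmax(Nk, 1e-12), mu_fallback)
  S <- pmax(Sxx - Nk * xbar^2, 0)
  m <- (priors$beta0 * m0 + Nk * xbar) / beta
  b <- priors$b0 + 0.5 * (S + priors$beta0 * Nk * (xbar - m0)^2 / beta)
  b <- pmax(b, 1e-12)
  list(alpha_pi = u_pi + n_pi, alpha_A = u_A + n_A,
       m = m, beta = beta, a = a, b = b)
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> K=%d, evidence=%.4f, %sconverged in %d iter\n",
              x$K, x$evidence, if (x$converged) "" else "NOT ", x$n_iterations))
  cat("  means:", paste(sprintf("%.3f", x$emission_mean), collapse = ", "),
      " sds:", paste(sprintf("%.3f", x$emission_sd), collapse = ", "), "\n")
  invisible(x)
}

#' Select the number of HMM states by maximum evidence
#'
#' Fits K = 1 .. `K_max` with [fit_vb_hmm()] and returns the model with the
#' largest evidence; ties (within 1e-9) go to the smaller K.
#'
#' @inheritParams fit_vb_hmm
#' @param K_max largest number of states tried (default 3).
#' @return the winning `hmm_model`, with an `evidence_by_K` attribute-like
#'   list element giving the evidence of every fitted K.
#' @export
select_model <- function(x, K_max = 3L, priors = hmm_priors(), seed = 1L,
                         n_restarts = 10L, ...) {
  fits <- lapply(seq_len(K_max), function(K)
    fit_vb_hmm(x, K, priors = priors, seed = substream_seed(seed, 7L, K),
               n_restarts = n_restarts, ...))
  ev <- vapply(fits, `[[`, numeric(1), "evidence")
  best <- 1L
  for (K in seq_len(K_max))
    if (ev[K] > ev[best] + 1e-9) best <- K
  out <- fits[[best]]
  out$evidence_by_K <- ev
  out
}

#' Decode the most probable state path
#'
#' Dynamic-programming (Viterbi) decoding under the model's point
#' estimates, plus per-frame posterior state probabilities from
#' forward-backward.  Frames outside fitted segments get `NA`.
#'
#' @param model an `hmm_model`.
#' @param x the series it was fitted to (`fret_series` or numeric).
#' @return object of class `state_path`: list with `states` (integer per
#'   frame, NA outside segments), `posterior` (frames x K matrix) and
#'   `n_frames`.
#' @export
decode_path <- function(model, x) {
  segs <- build_segments(x)
  n <- if (inherits(x, "fret_series")) length(x$E) else length(x)
  K <- model$K
  states <- rep(NA_integer_, n)
  posterior <- matrix(NA_real_, n, K)
  log_pi <- log(pmax(model$initial_probs, 1e-300))
  log_A <- log(pmax(model$transition_matrix, 1e-300))
  for (s in segs) {
    Tn <- length(s$x)
    logb <- matrix(0, Tn, K)
    fin <- is.finite(s$x)
    for (k in seq_len(K))
      logb[fin, k] <- dnorm(s$x[fin], model$emission_mean[k],
                            model$emission_sd[k], log = TRUE)
    states[s$frames] <- .viterbi_segment(logb, log_pi, log_A)
    fb <- .fb_segment(logb, log_pi, log_A)
    posterior[s$frames, ] <- fb$gamma
  }
  structure(list(states = states, posterior = posterior, n_frames = n),
            class = "state_path")
}

#' Map HMM states to conformational categories
#'
#' States are categorized by their emission mean E*: closed below the lower
#' boundary, open at or above the upper boundary, intermediate in between
#' (half-open intervals; a mean exactly at the upper boundary is open).
#'
#' @param model an `hmm_model`.
#' @param boundaries two thresholds, default `c(0.275, 0.40)` (midpoints
#'   between the canonical state levels 0.2 / 0.35 / 0.45).
#' @return character vector of length K with values in
#'   `c("closed", "intermediate", "open")`.
#' @export
categorize_states <- function(model, boundaries = c(0.275, 0.40)) {
  mu <- model$emission_mean
  ifelse(mu < boundaries[1], "closed",
         ifelse(mu < boundaries[2], "intermediate", "open"))
}
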