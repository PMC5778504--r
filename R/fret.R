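#' Apparent FRET efficiency and stoichiometry of a trace
#'
#' Computes the proximity-ratio apparent FRET efficiency
#' `E* = DA / (DD + DA)` and the ALEX stoichiometry
#' `S = (DD + DA) / (DD + DA + AA)` per frame, after optional per-channel
#' constant background subtraction.  No gamma, leakage or direct-excitation
#' corrections are applied (apparent quantities throughout).  Frames whose
#' background-subtracted `DD + DA` (for E*) or `DD + DA + AA` (for S) is
#' non-positive are masked invalid rather than dropped.
#'
#' @param trace an [alex_trace()].
#' @param background `"auto"` (default: post-bleach median per channel when
#'   a bleach is detected on that channel's reporter series, else the
#'   trace's recorded background), `"none"`, or a named numeric vector
#'   `c(DD=, DA=, AA=)`.
#' @return an object of class `fret_series`: list with `E`, `S`, `valid`
#'   (logical mask), `frame_period_s`, `molecule_id`.
#' @export
compute_fret_series <- function(trace, background = "auto") {
  if (!inherits(trace, "alex_trace")) stop("not an alex_trace")
  bg <- resolve_background(trace, background)
  DD <- trace$DD - bg[["DD"]]
  DA <- trace$DA - bg[["DA"]]
  AA <- trace$AA - bg[["AA"]]
  den_e <- DD + DA
  den_s <- DD + DA + AA
  valid <- is.finite(den_e) & den_e > 0
  E <- ifelse(valid, DA / den_e, NA_real_)
  S <- ifelse(valid & den_s > 0, den_e / den_s, NA_real_)
  structure(list(E = E, S = S, valid = valid,
                 frame_period_s = trace$frame_period_s,
                 molecule_id = trace$molecule_id,
                 n_valid = sum(valid)),
            class = "fret_series")
}

# background resolution used by compute_fret_series
resolve_background <- function(trace, background) {
  if (is.numeric(background)) {
    stopifnot(all(c("DD", "DA", "AA") %in% names(background)))
    return(background[c("DD", "DA", "AA")])
  }
  if (identical(background, "none")) return(c(DD = 0, DA = 0, AA = 0))
  if (!identical(background, "auto")) stop("invalid background specification")
  estimate_background(trace)
}

#' Estimate per-channel constant background
#'
#' For each fluorophore reporter series (AA for the acceptor, DD + DA for
#' the donor) a photobleach step is searched with [detect_bleach_steps()];
#' if found, the post-bleach median of the affected channels is used as
#' their background.  Channels without an observed bleach fall back to the
#' trace's recorded background (or 0).
#'
#' @param trace an [alex_trace()].
#' @return named numeric vector `c(DD=, DA=, AA=)`.
#' @export
estimate_background <- function(trace) {
  fallback <- trace$background %||% c(DD = 0, DA = 0, AA = 0)
  bg <- fallback[c("DD", "DA", "AA")]
  n <- length(trace$AA)
  if (n >= 20L) {
    st_a <- detect_bleach_steps(trace$AA)
    if (nrow(st_a)) {
      post <- (max(st_a$frame) + 1L):n
      if (length(post) >= 5L) bg[["AA"]] <- median(trace$AA[post])
    }
    st_d <- detect_bleach_steps(trace$DD + trace$DA)
    if (nrow(st_d)) {
      post <- (max(st_d$frame) + 1L):n
      if (length(post) >= 5L) {
        bg[["DD"]] <- median(trace$DD[post])
        bg[["DA"]] <- median(trace$DA[post])
      }
    }
  }
  bg
}

#' Pooled E* histogram with equal per-molecule frame budgets
#'
#' Pools per-frame E* values across molecules, each contributing its
#' earliest `min(frames_per_molecule, available)` valid frames, and bins
#' them on a fixed range.  Values outside the range are clamped into the
#' edge bins so the total count always equals the pooled frame budget.
#'
#' @param fret_list list of `fret_series` (or plain numeric E* vectors).
#' @param frames_per_molecule per-molecule frame budget (default 250).
#' @param breaks histogram bin edges (default 0.02-wide bins on
#'   `[-0.2, 1.2]`).
#' @return object of class `fret_histogram`: list with `breaks`, `counts`,
#'   `n_molecules`, `frames_per_molecule`, `values` (the pooled E* used).
#' @export
build_fret_histogram <- function(fret_list, frames_per_molecule = 250,
                                 breaks = seq(-0.2, 1.2, by = 0.02)) {
  if (!length(fret_list)) stop("empty input")
  pooled <- lapply(fret_list, function(fs) {
    e <- if (inherits(fs, "fret_series")) fs$E[fs$valid] else fs[is.finite(fs)]
    head(e, frames_per_molecule)
  })
  values <- unlist(pooled, use.names = FALSE)
  if (!length(values)) stop("no valid frames to histogram")
  lo <- min(breaks); hi <- max(breaks)
  clamped <- pmin(pmax(values, lo + 1e-12), hi - 1e-12)
  counts <- tabulate(.bincode(clamped, breaks, include.lowest = TRUE),
                     nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, counts = counts,
                 n_molecules = length(fret_list),
                 frames_per_molecule = frames_per_molecule,
                 values = values),
            class = "fret_histogram")
}

#' Gaussian mixture fit of pooled E* values
#'
#' Maximum-likelihood 1-D Gaussian mixture by expectation-maximization on
#' the pooled per-frame E* values (not on binned counts), with a
#' deterministic initialization: component means start at `init_means`
#' (defaults to the conformational-state levels 0.2/0.35/0.45 subset for
#' small k, else equally spaced quantiles), equal weights and a common
#' starting sd.  Components are reported sorted by mean.
#'
#' @param x a `fret_histogram`, a `fret_series` list, or a numeric vector of
#'   pooled E* values.
#' @param k number of components (>= 1).
#' @param init_means optional numeric vector of starting means (length k).
#' @param init_sd starting standard deviation.
#' @param max_iter,tol EM stopping rule on the log-likelihood.
#' @return list with `means`, `sds`, `weights` (sorted by mean),
#'   `loglik`, `converged`, `n_iter`, `n`.
#' @export
fit_fret_mixture <- function(x, k, init_means = NULL, init_sd = 0.07,
                             max_iter = 500L, tol = 1e-8) {
  values <- if (inherits(x, "fret_histogram")) x$values
            else if (is.list(x)) unlist(lapply(x, function(fs) fs$E[fs$valid]))
            else as.numeric(x)
  values <- values[is.finite(values)]
  n <- length(values)
  if (k < 1L) stop("k must be >= 1")
  if (n <= 10L * k) stop("too few data points for a ", k, "-component fit")
  if (is.null(init_means)) {
    canonical <- c(0.2, 0.45, 0.35)
    init_means <- if (k <= 3L) sort(canonical[seq_len(k)])
                  else quantile(values, probs = (seq_len(k) - 0.5) / k,
                                names = FALSE)
  }
  if (length(init_means) != k) stop("init_means must have length k")
  mu <- as.numeric(init_means)
  sdv <- rep(init_sd, k)
  w <- rep(1 / k, k)
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * dnorm(values, mu[j], sdv[j]),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    rs <- rowSums(dens)
    rs[rs <= 0] <- .Machine$double.xmin
    ll <- sum(log(rs))
    r <- dens / rs
    nk <- colSums(r)
    nk[nk < 1e-12] <- 1e-12
    mu <- colSums(r * values) / nk
    sdv <- sqrt(pmax(colSums(r * (values - rep(mu, each = n))^2) / nk, 1e-8))
    w <- nk / n
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  o <- order(mu)
  list(means = mu[o], sds = sdv[o], weights = w[o] / sum(w),
       loglik = ll_old, converged = converged, n_iter = it, n = n)
}

#' FRET efficiency at a given donor-acceptor distance
#'
#' `E = 1 / (1 + (R / R0)^6)` with `R0` the Foerster radius (the distance
#' of half-maximal transfer).
#'
#' @param distance_nm donor-acceptor distance (nm), > 0.
#' @param forster_radius_nm Foerster radius (nm), > 0.
#' @return FRET efficiency in (0, 1).
#' @examples
#' distance_to_fret(7.3, 7.06)  # ~0.45
#' @export
distance_to_fret <- function(distance_nm, forster_radius_nm) {
  if (any(distance_nm <= 0) || any(forster_radius_nm <= 0))
    stop("distances must be positive")
  1 / (1 + (distance_nm / forster_radius_nm)^6)
}
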