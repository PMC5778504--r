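#' Extract category dwell times from a decoded state path
#'
#' Maximal runs of constant state category are converted to durations (run
#' length x frame period).  The first dwell of each contiguous segment is
#' left-censored (its start was not observed) and a dwell ending at a
#' segment end (trace end or bleach) is right-censored.  Single-frame runs
#' are retained.
#'
#' @param path a [decode_path()] result, or an integer state vector (NA =
#'   unanalysed frame).
#' @param category_map character vector mapping state index to category
#'   (from [categorize_states()]).
#' @param frame_period seconds per frame.
#' @param molecule_id identifier attached to every dwell.
#' @return data.frame of dwell records: `molecule_id`, `category`,
#'   `duration_s`, `left_censored`, `right_censored`, with the frame period
#'   stored in `attr(, "frame_period_s")`.
#' @export
extract_dwells <- function(path, category_map, frame_period,
                           molecule_id = "mol") {
  states <- if (inherits(path, "state_path")) path$states else as.integer(path)
  stop_if_not_scalar_pos(frame_period, "frame_period")
  out <- list()
  n <- length(states)
  if (n) {
    cat_series <- ifelse(is.na(states), NA_character_, category_map[states])
    seg_id <- cumsum(is.na(cat_series))
    for (sid in unique(seg_id[!is.na(cat_series)])) {
      idx <- which(seg_id == sid & !is.na(cat_series))
      if (!length(idx)) next
      r <- rle(cat_series[idx])
      k <- length(r$lengths)
      out[[length(out) + 1L]] <- data.frame(
        molecule_id = molecule_id,
        category = r$values,
        duration_s = r$lengths * frame_period,
        left_censored = seq_len(k) == 1L,
        right_censored = seq_len(k) == k,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(molecule_id = character(0), category = character(0),
                         duration_s = numeric(0), left_censored = logical(0),
                         right_censored = logical(0))
  attr(res, "frame_period_s") <- frame_period
  res
}

#' Build a dwell table from raw durations
#'
#' Convenience constructor for fitting dwell samples that did not come from
#' a decoded trace (e.g. simulated draws): all dwells uncensored, molecules
#' assigned in blocks of `per_molecule` so the molecule-level bootstrap
#' remains meaningful.
#'
#' @param durations numeric dwell durations (s).
#' @param t_min frame period / left-truncation point recorded on the table.
#' @param category dwell category label.
#' @param per_molecule dwells per synthetic molecule id.
#' @return dwell data.frame as produced by [extract_dwells()].
#' @export
make_dwell_frame <- function(durations, t_min, category = "open",
                             per_molecule = 50L) {
  n <- length(durations)
  d <- data.frame(
    molecule_id = paste0("m", rep(seq_len(max(1L, ceiling(n / per_molecule))),
                                  each = per_molecule, length.out = n)),
    category = category, duration_s = durations,
    left_censored = FALSE, right_censored = FALSE,
    stringsAsFactors = FALSE)
  attr(d, "frame_period_s") <- t_min
  d
}

# uncensored selection helper
.uncensored <- function(dwells) {
  dwells[!dwells$left_censored & !dwells$right_censored, , drop = FALSE]
}

#' Single-exponential dwell-time fit
#'
#' Maximum-likelihood mean of an exponential distribution left-truncated at
#' the minimum resolvable dwell `t_min` (one frame): for uncensored dwells
#' the shifted-exponential MLE is `tau = mean(duration) - t_min`.  With
#' `use_censored = TRUE` right-censored dwells contribute survival terms:
#' `tau = sum(all durations - t_min) / n_uncensored`.  A seeded bootstrap
#' (resampling molecules, to respect within-molecule correlation) gives the
#' percentile confidence interval.
#'
#' @param dwells dwell data.frame from [extract_dwells()] (one category).
#' @param t_min left-truncation point in seconds; defaults to the recorded
#'   frame period.
#' @param use_censored include right-censored dwells via survival terms.
#' @param n_boot bootstrap replicates (default 1000); 0 disables.
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @return object of class `exp_fit`: `n_components = 1`, `tau`, `rate`,
#'   `weights = 1`, `loglik`, `n`, `ci` (length-2), `insufficient_data` flag.
#' @export
fit_exponential <- function(dwells, t_min = NULL, use_censored = FALSE,
                            n_boot = 1000L, seed = 1L, conf = 0.95) {
  t_min <- t_min %||% attr(dwells, "frame_period_s") %||% min(dwells$duration_s)
  unc <- .uncensored(dwells)
  if (nrow(unc) < 10L)
    return(structure(list(n_components = 1L, tau = NA_real_, rate = NA_real_,
                          weights = 1, loglik = NA_real_, n = nrow(unc),
                          ci = c(NA_real_, NA_real_),
                          insufficient_data = TRUE), class = "exp_fit"))
  est <- function(d) {
    u <- .uncensored(d)
    excess <- sum(u$duration_s - t_min)
    if (use_censored) {
      rc <- d[d$right_censored & !d$left_censored, , drop = FALSE]
      excess <- excess + sum(pmax(rc$duration_s - t_min, 0))
    }
    max(excess / nrow(u), t_min * 1e-6)
  }
  tau <- est(dwells)
  ll <- sum(-log(tau) - (unc$duration_s - t_min) / tau)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    mols <- unique(dwells$molecule_id)
    reps <- with_local_seed(substream_seed(seed, 97L), {
      vapply(seq_len(n_boot), function(b) {
        pick <- sample(mols, length(mols), replace = TRUE)
        d <- do.call(rbind, lapply(pick, function(m)
          dwells[dwells$molecule_id == m, , drop = FALSE]))
        if (nrow(.uncensored(d)) < 2L) return(NA_real_)
        est(d)
      }, numeric(1))
    })
    ci <- quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                   na.rm = TRUE, names = FALSE)
  }
  structure(list(n_components = 1L, tau = tau, rate = 1 / tau, weights = 1,
                 loglik = ll, n = nrow(unc), t_min = t_min, ci = ci,
                 insufficient_data = FALSE), class = "exp_fit")
}

# core EM for a 2-component exponential mixture on excess times s >= 0
.biexp_em <- function(s, tau_init, w_init, max_iter = 1000L, tol = 1e-10) {
  n <- length(s)
  tau <- tau_init; w <- w_init
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] / tau[1] * exp(-s / tau[1])
    d2 <- w[2] / tau[2] * exp(-s / tau[2])
    tot <- d1 + d2
    tot[tot <= 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r1 <- d1 / tot
    n1 <- sum(r1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    tau <- c(sum(r1 * s) / n1, sum((1 - r1) * s) / n2)
    tau <- pmax(tau, 1e-12)
    w <- c(n1, n2) / n
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(tau = tau, w = w, loglik = ll, n_iter = it)
}

#' Bi-exponential dwell-time fit
#'
#' Two-component exponential mixture fitted by expectation-maximization to
#' the uncensored dwell durations, left-truncated at `t_min` (the excess
#' durations over `t_min` are exactly exponential-mixture distributed by
#' memorylessness; reported weights are corrected back to the untruncated
#' mixture).  Seeded multi-restart EM; components sorted `tau1 < tau2`.
#' If one component's weight collapses below 0.01 the single-exponential
#' fallback is reported with a `collapsed` flag.
#'
#' @inheritParams fit_exponential
#' @param n_restarts jittered EM restarts (default 20).
#' @return object of class `exp_fit` with `n_components = 2`: `tau`
#'   (ascending), `weights`, `rate`, `loglik`, `n`, `collapsed`.
#' @export
fit_biexponential <- function(dwells, t_min = NULL, seed = 1L,
                              n_restarts = 20L) {
  t_min <- t_min %||% attr(dwells, "frame_period_s") %||% min(dwells$duration_s)
  unc <- .uncensored(dwells)
  n <- nrow(unc)
  if (n < 100L)
    return(structure(list(n_components = 2L, tau = c(NA_real_, NA_real_),
                          rate = c(NA_real_, NA_real_), weights = c(NA, NA),
                          loglik = NA_real_, n = n, insufficient_data = TRUE,
                          collapsed = FALSE), class = "exp_fit"))
  s <- pmax(unc$duration_s - t_min, 0)
  mu <- mean(s)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- with_local_seed(substream_seed(seed, 53L, r), {
      if (r == 1L) list(tau = mu * c(0.4, 2.0), w = c(0.5, 0.5))
      else list(tau = mu * sort(exp(rnorm(2, 0, 1))),
                w = {p <- runif(1, 0.1, 0.9); c(p, 1 - p)})
    })
    fit <- .biexp_em(s, init$tau, init$w)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  o <- order(best$tau)
  tau <- best$tau[o]; w <- best$w[o]
  # undo the truncation thinning of the weights
  w_adj <- w * exp(t_min / tau)
  w_adj <- w_adj / sum(w_adj)
  collapsed <- min(w) < 0.01 || tau[2] / tau[1] < 1.001
  structure(list(n_components = 2L, tau = tau, rate = 1 / tau,
                 weights = w_adj, loglik = best$loglik, n = n, t_min = t_min,
                 insufficient_data = FALSE, collapsed = collapsed),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (isTRUE(x$insufficient_data)) {
    cat("<exp_fit> insufficient data (n =", x$n, ")\n")
    return(invisible(x))
  }
  cat(sprintf("<exp_fit> %d component(s), n=%d\n", x$n_components, x$n))
  for (j in seq_len(x$n_components))
    cat(sprintf("  tau=%.4g s (k=%.4g 1/s) weight=%.3f\n",
                x$tau[j], 1 / x$tau[j], x$weights[j]))
  invisible(x)
}

#' Choose between single- and bi-exponential dwell models
#'
#' Both models are fitted and compared by BIC on the uncensored,
#' left-truncated durations; fewer than 100 uncensored dwells defaults to
#' the single-exponential model (insufficient-data guard), as does a
#' collapsed two-component fit.  Ties go to one component.
#'
#' @inheritParams fit_biexponential
#' @return list with `n_components`, `bic` (named length-2), `fit1`, `fit2`.
#' @export
compare_exp_models <- function(dwells, t_min = NULL, seed = 1L) {
  fit1 <- fit_exponential(dwells, t_min = t_min, n_boot = 0L, seed = seed)
  fit2 <- fit_biexponential(dwells, t_min = t_min, seed = seed)
  n <- fit1$n
  if (isTRUE(fit2$insufficient_data) || isTRUE(fit2$collapsed) ||
      isTRUE(fit1$insufficient_data))
    return(list(n_components = 1L, bic = c(one = NA, two = NA),
                fit1 = fit1, fit2 = fit2))
  bic1 <- -2 * fit1$loglik + 1 * log(n)
  bic2 <- -2 * fit2$loglik + 3 * log(n)
  list(n_components = if (bic2 < bic1) 2L else 1L,
       bic = c(one = bic1, two = bic2), fit1 = fit1, fit2 = fit2)
}

#' Kinetics summary over pooled dwells of one condition
#'
#' Pools dwells across molecules, fits the closed and open categories
#' (single-exponential MLE plus BIC-selected single/bi-exponential), and
#' tabulates mean dwell times, rates and bootstrap CIs.  Intermediate
#' dwells are tabulated but excluded from opening/closing kinetics.
#'
#' @param dwells pooled dwell data.frame (from [extract_dwells()], rbind-ed
#'   across molecules).
#' @param condition condition label for the output rows.
#' @param seed bootstrap / EM seed.
#' @param n_boot bootstrap replicates.
#' @return data.frame with one row per category: `condition`, `category`,
#'   `n_dwells`, `tau_s`, `rate_per_s`, `ci_lo`, `ci_hi`,
#'   `n_components` (BIC choice), `tau1_s`, `tau2_s`, `weight1`.
#' @export
kinetics_report <- function(dwells, condition = "condition", seed = 1L,
                            n_boot = 1000L) {
  t_min <- attr(dwells, "frame_period_s")
  rows <- lapply(c("closed", "open", "intermediate"), function(cat) {
    d <- dwells[dwells$category == cat, , drop = FALSE]
    attr(d, "frame_period_s") <- t_min
    if (!nrow(d)) return(NULL)
    f1 <- fit_exponential(d, n_boot = n_boot, seed = substream_seed(seed, 3L))
    cmpv <- if (cat == "intermediate")
      list(n_components = 1L, fit2 = NULL)
    else compare_exp_models(d, seed = substream_seed(seed, 5L))
    f2 <- cmpv$fit2
    two <- !is.null(f2) && cmpv$n_components == 2L
    data.frame(condition = condition, category = cat,
               n_dwells = f1$n, tau_s = f1$tau,
               rate_per_s = f1$rate, ci_lo = f1$ci[1], ci_hi = f1$ci[2],
               n_components = cmpv$n_components,
               tau1_s = if (two) f2$tau[1] else f1$tau,
               tau2_s = if (two) f2$tau[2] else NA_real_,
               weight1 = if (two) f2$weights[1] else 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
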