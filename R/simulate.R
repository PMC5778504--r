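#' Sample a continuous-time Markov state path
#'
#' Exact (event-driven, Gillespie-style) sample of the scheme's
#' continuous-time Markov chain.  The sojourn in state i is exponential
#' with the state's exit rate; the next state j is chosen with probability
#' `k_ij / sum_j k_ij`.  A state with zero exit rate is absorbing and the
#' path ends with one sojourn spanning the remaining duration.
#'
#' @param scheme a [kinetic_scheme()].
#' @param duration trace length in seconds.
#' @param seed integer seed.
#' @return data.frame with columns `state` (index), `label`, `category`,
#'   `entry_time`, `exit_time` (seconds); sojourns tile `[0, duration]`.
#' @export
simulate_state_path <- function(scheme, duration, seed = 1L) {
  stop_if_not_scalar_pos(duration, "duration")
  exit <- scheme_exit_rates(scheme)
  Q <- scheme$rate_matrix
  with_local_seed(seed, {
    s <- sample.int(length(scheme$state_labels), 1L,
                    prob = scheme$initial_distribution)
    t <- 0
    cap <- 64L; n_ev <- 0L
    states <- integer(cap); t0 <- numeric(cap); t1 <- numeric(cap)
    repeat {
      dwell <- if (exit[s] > 0) rexp(1L, exit[s]) else Inf
      t_end <- min(t + dwell, duration)
      n_ev <- n_ev + 1L
      if (n_ev > cap) {          # grow by doubling
        cap <- cap * 2L
        length(states) <- cap; length(t0) <- cap; length(t1) <- cap
      }
      states[n_ev] <- s; t0[n_ev] <- t; t1[n_ev] <- t_end
      if (t_end >= duration) break
      p <- Q[s, ]; p[s] <- 0
      s <- sample.int(length(p), 1L, prob = p)
      t <- t_end
    }
    keep <- seq_len(n_ev)
    data.frame(state = states[keep],
               label = scheme$state_labels[states[keep]],
               category = scheme$state_category[states[keep]],
               entry_time = t0[keep], exit_time = t1[keep])
  })
}

#' Discretize a continuous state path onto camera frames
#'
#' Each frame's true FRET value is the occupancy-weighted average of the
#' state FRET efficiencies over the frame interval; the dominant state is
#' the one occupying the largest fraction of the frame, ties broken in
#' favour of the state entered earlier within the frame.
#'
#' @param events state path from [simulate_state_path()].
#' @param frame_period frame (alternation period) duration in seconds.
#' @param scheme the [kinetic_scheme()] that produced `events`.
#' @param n_frames number of frames; defaults to the full frames covered by
#'   the path.
#' @return list with `fret` (numeric per frame), `dominant_state` (integer
#'   per frame), `occupancy` (frames x states matrix of frame fractions) and
#'   `intensity_factor` (per-frame donor-excitation emission factor after
#'   contact quenching; all 1 unless quenching is configured downstream).
#' @export
discretize_path <- function(events, frame_period, scheme, n_frames = NULL) {
  stop_if_not_scalar_pos(frame_period, "frame_period")
  if (is.null(events) || nrow(events) == 0L) stop("empty event list")
  total <- max(events$exit_time)
  if (is.null(n_frames)) n_frames <- floor(total / frame_period + 1e-9)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("path shorter than one frame")
  K <- length(scheme$state_labels)
  occ <- matrix(0, n_frames, K)
  first_entry <- matrix(Inf, n_frames, K)
  for (r in seq_len(nrow(events))) {
    s <- events$state[r]
    a <- events$entry_time[r]; b <- events$exit_time[r]
    f0 <- max(1L, floor(a / frame_period + 1e-12) + 1L)
    f1 <- min(n_frames, ceiling(b / frame_period - 1e-12))
    if (f1 < f0) next
    for (f in f0:f1) {
      lo <- max(a, (f - 1L) * frame_period)
      hi <- min(b, f * frame_period)
      if (hi <= lo) next
      occ[f, s] <- occ[f, s] + (hi - lo) / frame_period
      first_entry[f, s] <- min(first_entry[f, s], lo)
    }
  }
  fret <- as.numeric(occ %*% scheme$state_fret)
  dominant <- vapply(seq_len(n_frames), function(f) {
    mx <- max(occ[f, ])
    cand <- which(occ[f, ] >= mx - 1e-12)
    cand[which.min(first_entry[f, cand])]
  }, integer(1))
  list(fret = fret, dominant_state = dominant, occupancy = occ,
       intensity_factor = rep(1, n_frames))
}

# per-frame emission factor given quenched state labels
quench_factor_series <- function(occ, scheme, quench_states, q) {
  if (is.null(quench_states) || !length(quench_states)) return(rep(1, nrow(occ)))
  fac <- ifelse(scheme$state_labels %in% quench_states, q, 1)
  as.numeric(occ %*% fac)
}

#' Construct an ALEX intensity trace object
#'
#' @param DD,DA,AA numeric intensity series (camera counts): donor-excitation
#'   donor emission, donor-excitation acceptor emission (FRET), and
#'   acceptor-excitation acceptor emission.
#' @param frame_period_s frame (alternation period) duration in seconds.
#' @param molecule_id identifier.
#' @param background optional named numeric vector `c(DD=, DA=, AA=)` of
#'   per-channel mean background counts.
#' @return an object of class `alex_trace`.
#' @export
alex_trace <- function(DD, DA, AA, frame_period_s, molecule_id = "mol",
                       background = NULL) {
  n <- length(DD)
  if (length(DA) != n || length(AA) != n)
    stop("DD, DA and AA must have equal length")
  if (any(!is.finite(c(DD, DA, AA)))) stop("intensities must be finite")
  stop_if_not_scalar_pos(frame_period_s, "frame_period_s")
  structure(list(frame_index = seq_len(n),
                 time_s = (seq_len(n) - 1) * frame_period_s,
                 DD = as.numeric(DD), DA = as.numeric(DA), AA = as.numeric(AA),
                 frame_period_s = frame_period_s,
                 molecule_id = as.character(molecule_id),
                 background = background),
            class = "alex_trace")
}

#' @export
print.alex_trace <- function(x, ...) {
  cat(sprintf("<alex_trace> %s: %d frames @ %.4g s\n",
              x$molecule_id, length(x$DD), x$frame_period_s))
  invisible(x)
}

# scaled-Poisson draw with variance inflation F (EM-register approximation)
.rpois_excess <- function(n, mean, F) {
  if (F <= 1) return(rpois(n, mean))
  F * rpois(n, mean / F)
}

#' Simulate camera counts for one molecule
#'
#' Turns a per-frame true-FRET series into a three-channel ALEX intensity
#' trace.  Donor-excitation photons split between DA (fraction E) and DD
#' (fraction 1 - E); acceptor-excitation photons populate AA.  Single-step
#' photobleaching of each dye is drawn from exponential waiting times;
#' after acceptor bleach DA and AA fall to background while DD rises to the
#' full photon budget, after donor bleach DD and DA fall to background.
#' Photon shot noise is Poisson with the variance inflated by the EMCCD
#' excess-noise factor; counts are gain x photons + background + Gaussian
#' read noise, clipped at zero.
#'
#' @param frame_fret numeric vector of true FRET per frame.
#' @param params a [photophysics_params()].
#' @param frame_period seconds per frame.
#' @param seed integer seed.
#' @param intensity_factor optional per-frame multiplier on the
#'   donor-excitation photon budget (contact quenching), default 1.
#' @param molecule_id identifier stored on the trace.
#' @return list with `trace` (an [alex_trace()]) and `truth` (list with
#'   `donor_bleach_frame`, `acceptor_bleach_frame`, possibly `NA`).
#' @export
simulate_alex_trace <- function(frame_fret, params, frame_period, seed = 1L,
                                intensity_factor = NULL,
                                molecule_id = "mol") {
  if (!length(frame_fret)) stop("frame_fret must be nonempty")
  if (!inherits(params, "photophysics_params")) stop("invalid params")
  n <- length(frame_fret)
  if (is.null(intensity_factor)) intensity_factor <- rep(1, n)
  dt <- frame_period
  with_local_seed(seed, {
    t_d <- if (params$donor_bleach_rate > 0)
      rexp(1L, params$donor_bleach_rate) else Inf
    t_a <- if (params$acceptor_bleach_rate > 0)
      rexp(1L, params$acceptor_bleach_rate) else Inf

    # alive fraction of each frame [ (f-1)dt, f dt ]
    alive_frac <- function(t_bleach) {
      fr <- pmin(pmax((t_bleach - (seq_len(n) - 1) * dt) / dt, 0), 1)
      fr
    }
    a_d <- alive_frac(t_d)
    a_a <- alive_frac(t_a)

    # acceptor blinking (dark fraction per frame), optional
    if (params$blink_on_rate > 0 && params$blink_off_rate > 0) {
      blink <- kinetic_scheme(c("on", "off"), c(0, 0), c("open", "open"),
                              matrix(c(0, params$blink_on_rate,
                                       params$blink_off_rate, 0),
                                     2, 2, byrow = TRUE),
                              initial_distribution = c(1, 0))
      ev <- simulate_state_path(blink, n * dt,
                                seed = substream_seed(seed, 77L))
      occ <- discretize_path(ev, dt, blink, n_frames = n)$occupancy
      a_a <- a_a * occ[, 1]
    }

    N_dex <- params$photons_per_frame_dex * intensity_factor * a_d
    acc_on <- a_a                       # acceptor able to accept/emit
    da_mean <- frame_fret * N_dex * acc_on
    dd_mean <- N_dex * (1 - frame_fret * acc_on)
    aa_mean <- params$photons_per_frame_aex * a_a

    g <- params$camera_gain
    bg <- params$background_per_channel
    if (params$shot_noise) {
      F <- params$excess_noise_factor
      draw <- function(m) {
        cnt <- g * .rpois_excess(n, m, F) + bg
        if (params$read_noise_sd > 0)
          cnt <- cnt + rnorm(n, 0, params$read_noise_sd)
        pmax(cnt, 0)
      }
      DD <- draw(dd_mean); DA <- draw(da_mean); AA <- draw(aa_mean)
    } else {
      DD <- g * dd_mean + bg; DA <- g * da_mean + bg; AA <- g * aa_mean + bg
    }
    bgv <- c(DD = bg, DA = bg, AA = bg)
    list(trace = alex_trace(DD, DA, AA, dt, molecule_id, background = bgv),
         truth = list(
           donor_bleach_frame = if (t_d < n * dt) floor(t_d / dt) + 1L else NA_integer_,
           acceptor_bleach_frame = if (t_a < n * dt) floor(t_a / dt) + 1L else NA_integer_))
  })
}

# category-level true dwells from a continuous event path
true_dwells_from_events <- function(events) {
  if (nrow(events) == 0L) return(NULL)
  cat_run <- rle(events$category)
  ends <- cumsum(cat_run$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  data.frame(category = cat_run$values,
             entry_time = events$entry_time[starts],
             exit_time = events$exit_time[ends],
             duration_s = events$exit_time[ends] - events$entry_time[starts])
}

#' Simulate a full ground-truthed scenario dataset
#'
#' Molecules are allocated to subpopulations by exact proportional
#' allocation (integer parts), remainders assigned by a seeded draw with
#' probabilities proportional to the fractional parts.  Each molecule then
#' receives its own derived random sub-stream, so the dataset is
#' bit-identical for a fixed scenario seed.
#'
#' @param config a [scenario_config()].
#' @return an object of class `alex_dataset`: list with `traces` (list of
#'   [alex_trace()]), `truth` (per-molecule ground-truth lists with the true
#'   state path, subpopulation, bleach frames and true dwells) and
#'   `manifest` (summary list).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "scenario_config")) stop("invalid scenario config")
  n <- config$n_molecules
  if (n <= 0L) stop("n_molecules must be positive")
  props <- vapply(config$subpopulations, `[[`, numeric(1), "proportion")
  base <- floor(props * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- props * n - base
    if (sum(frac) <= 0) frac <- props
    extra <- with_local_seed(substream_seed(config$seed, 11L),
                             sample.int(length(props), rem, replace = TRUE,
                                        prob = frac))
    base <- base + tabulate(extra, nbins = length(props))
  }
  assignment <- rep(seq_along(props), base)

  dt <- 1 / config$alternation_rate_hz
  n_frames <- floor(config$max_duration_s / dt + 1e-9)
  traces <- vector("list", n)
  truth <- vector("list", n)
  for (m in seq_len(n)) {
    sp <- assignment[m]
    scheme <- config$subpopulations[[sp]]$scheme
    id <- sprintf("%s_mol%03d", config$name, m)
    ev <- simulate_state_path(scheme, config$max_duration_s,
                              seed = substream_seed(config$seed, 1L, m))
    disc <- discretize_path(ev, dt, scheme, n_frames = n_frames)
    qf <- quench_factor_series(disc$occupancy, scheme,
                               config$photophysics$quench_states,
                               config$photophysics$quench_factor)
    sim <- simulate_alex_trace(disc$fret, config$photophysics, dt,
                               seed = substream_seed(config$seed, 2L, m),
                               intensity_factor = qf, molecule_id = id)
    traces[[m]] <- sim$trace
    truth[[m]] <- list(
      molecule_id = id,
      subpopulation = config$subpopulations[[sp]]$label,
      scheme = scheme,
      events = ev,
      state_per_frame = disc$dominant_state,
      fret_per_frame = disc$fret,
      donor_bleach_frame = sim$truth$donor_bleach_frame,
      acceptor_bleach_frame = sim$truth$acceptor_bleach_frame,
      true_dwells = true_dwells_from_events(ev))
  }
  manifest <- list(
    scenario = config$name, seed = config$seed,
    alternation_rate_hz = config$alternation_rate_hz,
    frame_period_s = dt, n_molecules = n,
    molecules = lapply(seq_len(n), function(m) list(
      molecule_id = truth[[m]]$molecule_id,
      subpopulation = truth[[m]]$subpopulation,
      donor_bleach_frame = truth[[m]]$donor_bleach_frame,
      acceptor_bleach_frame = truth[[m]]$acceptor_bleach_frame,
      n_frames = length(traces[[m]]$DD))))
  structure(list(traces = traces, truth = truth, manifest = manifest),
            class = "alex_dataset")
}

#' @export
print.alex_dataset <- function(x, ...) {
  cat(sprintf("<alex_dataset> scenario '%s': %d molecules, %.4g s frames\n",
              x$manifest$scenario, length(x$traces),
              x$manifest$frame_period_s))
  invisible(x)
}
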