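#' Single-state (static) kinetic scheme
#'
#' @param fret true FRET efficiency of the single state.
#' @param category state category (`"closed"`, `"intermediate"`, `"open"`).
#' @param label state label.
#' @export
static_scheme <- function(fret, category, label = category) {
  kinetic_scheme(state_labels = label, state_fret = fret,
                 state_category = category,
                 rate_matrix = matrix(0, 1, 1))
}

#' Two-category bubble scheme with bi-exponential open dwells
#'
#' Closed <-> open interconversion in which the open-state dwell-time
#' distribution is a two-component exponential mixture.  The mixture is
#' realized by two open substates sharing the same FRET efficiency but with
#' different exit rates; the closed state branches into them with the given
#' probabilities, so open sojourns (at the category level) are distributed
#' as `sum(branching * dexp(mean = open_dwell_means))`.
#'
#' @param fret_closed,fret_open FRET efficiencies of the closed state and of
#'   both open substates.
#' @param k_open closed-state exit rate (1/s); the bubble opening rate.
#' @param open_dwell_means mean dwell times (s) of the two open substates.
#'   A single value gives a plain two-state scheme.
#' @param branching entry probabilities of the open substates (sums to 1).
#' @param closed_category,open_category category labels for threshold-based
#'   classification downstream.
#' @export
dynamic_bubble_scheme <- function(fret_closed = 0.2, fret_open = 0.45,
                                  k_open = 6.4,
                                  open_dwell_means = c(0.22, 1.0),
                                  branching = NULL,
                                  closed_category = "closed",
                                  open_category = "open") {
  stop_if_not_scalar_pos(k_open, "k_open")
  m <- length(open_dwell_means)
  if (is.null(branching)) branching <- rep(1 / m, m)
  if (length(branching) != m || any(branching < 0))
    stop("branching must be a probability vector over open substates")
  branching <- branching / sum(branching)
  n <- m + 1L
  labels <- c("closed", if (m == 1L) "open" else paste0("open", seq_len(m)))
  Q <- matrix(0, n, n)
  Q[1, 1 + seq_len(m)] <- k_open * branching
  for (i in seq_len(m)) Q[1 + i, 1] <- 1 / open_dwell_means[i]
  kinetic_scheme(state_labels = labels,
                 state_fret = c(fret_closed, rep(fret_open, m)),
                 state_category = c(closed_category, rep(open_category, m)),
                 rate_matrix = Q)
}

#' Scale all rates of a scheme by a constant factor
#'
#' Used to derive mutant fixtures whose opening and closing rates are a
#' fixed multiple of the wild-type rates (dwell times divide by the factor,
#' state occupancies are unchanged).
#'
#' @param scheme a [kinetic_scheme()].
#' @param factor positive multiplier.
#' @export
scale_scheme_rates <- function(scheme, factor) {
  stop_if_not_scalar_pos(factor, "factor")
  kinetic_scheme(scheme$state_labels, scheme$state_fret,
                 scheme$state_category, scheme$rate_matrix * factor,
                 scheme$initial_distribution)
}

#' Scenario configuration for dataset simulation
#'
#' A named experimental condition: a mixture of molecular subpopulations
#' (each a proportion plus a kinetic scheme), shared photophysics, the laser
#' alternation rate and the dataset size.
#'
#' @param name scenario identifier.
#' @param subpopulations list of subpopulations, each a list with elements
#'   `proportion` (non-negative; normalized to sum 1), `scheme`
#'   (a [kinetic_scheme()]) and optional `label`.
#' @param photophysics a [photophysics_params()].
#' @param alternation_rate_hz laser alternation rate; one E* point is
#'   produced per full alternation period, so the frame period is
#'   `1 / alternation_rate_hz`.
#' @param n_molecules number of molecules to simulate.
#' @param max_duration_s record length per molecule (s).
#' @param seed integer seed; every random draw in the scenario derives from it.
#' @export
scenario_config <- function(name, subpopulations,
                            photophysics = photophysics_params(),
                            alternation_rate_hz = 100,
                            n_molecules = 100,
                            max_duration_s = 10,
                            seed = 1L) {
  stop_if_not_scalar_pos(alternation_rate_hz, "alternation_rate_hz")
  stop_if_not_scalar_pos(max_duration_s, "max_duration_s")
  if (!is.numeric(n_molecules) || n_molecules < 1)
    stop("n_molecules must be >= 1")
  if (!length(subpopulations)) stop("at least one subpopulation is required")
  props <- vapply(subpopulations, function(s) s$proportion, numeric(1))
  if (any(props < 0) || sum(props) <= 0)
    stop("subpopulation proportions must be >= 0 and not all zero")
  for (i in seq_along(subpopulations)) {
    if (!inherits(subpopulations[[i]]$scheme, "kinetic_scheme"))
      stop("each subpopulation needs a kinetic_scheme in $scheme")
    subpopulations[[i]]$proportion <- props[i] / sum(props)
    subpopulations[[i]]$label <-
      subpopulations[[i]]$label %||% paste0("subpop", i)
  }
  structure(list(name = name, subpopulations = subpopulations,
                 photophysics = photophysics,
                 alternation_rate_hz = alternation_rate_hz,
                 n_molecules = as.integer(n_molecules),
                 max_duration_s = max_duration_s,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# ---- bundled fixture library ------------------------------------------------

# composition helper: four behavioural subpopulations
.composition <- function(p_open, p_closed, p_mid, p_dyn,
                         e_closed, e_mid, e_open, dyn_scheme) {
  list(
    list(proportion = p_open,
         scheme = static_scheme(e_open, "open", "static_open"),
         label = "static_open"),
    list(proportion = p_closed,
         scheme = static_scheme(e_closed, "closed", "static_closed"),
         label = "static_closed"),
    list(proportion = p_mid,
         scheme = static_scheme(e_mid, "intermediate", "static_mid"),
         label = "static_mid"),
    list(proportion = p_dyn, scheme = dyn_scheme, label = "dynamic")
  )
}

#' Bundled scenario and kinetic-scheme fixtures
#'
#' `scenario_fixture()` returns one of the named experimental conditions the
#' package ships with; `scenario_fixture_names()` lists them.  The wild-type
#' double-stranded-DNA condition at 22 degrees C combines 50% static open
#' (E* 0.45), 20% static closed (E* 0.2), 5% static intermediate (E* 0.35)
#' and 25% dynamic molecules interconverting between the closed state
#' (exit rate 6.4 1/s) and an open state with bi-exponential dwells
#' (means 0.22 s and 1 s, equal branching).  Pre-melted (pmDNA) conditions
#' slow the closed-state exit to 1/0.24 1/s and shift the composition toward
#' dynamic molecules; the sigma3.2-deletion and jaw-deletion variants scale
#' all interconversion rates by 3 and 1.3 respectively.  37 degrees C
#' variants shift all FRET levels up by 0.05 and enlarge the intermediate
#' population.  `"bubble_labels_22C"` emulates intra-bubble labelling where
#' the closed state has high FRET (0.85) and is contact-quenched
#' (q = 0.1); `"free_dna"` is a single static state at E* 0.17.
#'
#' @param name fixture name, one of `scenario_fixture_names()`.
#' @param n_molecules,seed,... overrides forwarded to [scenario_config()].
#' @return a [scenario_config()].
#' @export
scenario_fixture <- function(name, n_molecules = 100, seed = 1L, ...) {
  wt_dyn  <- dynamic_bubble_scheme(0.2, 0.45, k_open = 6.4)
  wt_dyn37 <- dynamic_bubble_scheme(0.25, 0.50, k_open = 6.4)
  pm_dyn  <- dynamic_bubble_scheme(0.2, 0.45, k_open = 1 / 0.24)
  pm_dyn37 <- dynamic_bubble_scheme(0.25, 0.50, k_open = 1 / 0.24)
  pm_comp <- c(16, 21, 13, 56) / 106   # open/closed/mid/dynamic, normalized

  subpops <- switch(
    name,
    wt_dsDNA_22C = .composition(0.50, 0.20, 0.05, 0.25,
                                0.2, 0.35, 0.45, wt_dyn),
    wt_dsDNA_37C = .composition(0.44, 0.13, 0.20, 0.23,
                                0.25, 0.40, 0.50, wt_dyn37),
    wt_pmDNA_22C = .composition(pm_comp[1], pm_comp[2], pm_comp[3], pm_comp[4],
                                0.2, 0.35, 0.45, pm_dyn),
    wt_pmDNA_37C = .composition(pm_comp[1], pm_comp[2], pm_comp[3], pm_comp[4],
                                0.25, 0.40, 0.50, pm_dyn37),
    d32_dsDNA = .composition(0.50, 0.20, 0.05, 0.25, 0.2, 0.35, 0.45,
                             scale_scheme_rates(wt_dyn, 3)),
    d32_pmDNA = .composition(pm_comp[1], pm_comp[2], pm_comp[3], pm_comp[4],
                             0.2, 0.35, 0.45, scale_scheme_rates(pm_dyn, 3)),
    djaw_dsDNA = .composition(0.50, 0.20, 0.05, 0.25, 0.2, 0.35, 0.45,
                              scale_scheme_rates(wt_dyn, 1.3)),
    djaw_pmDNA = .composition(pm_comp[1], pm_comp[2], pm_comp[3], pm_comp[4],
                              0.2, 0.35, 0.45, scale_scheme_rates(pm_dyn, 1.3)),
    bubble_labels_22C = list(
      list(proportion = 1,
           scheme = dynamic_bubble_scheme(0.85, 0.60, k_open = 6.4,
                                          closed_category = "closed",
                                          open_category = "open"),
           label = "dynamic_quenched")),
    free_dna = list(
      list(proportion = 1,
           scheme = static_scheme(0.17, "closed", "free_dna"),
           label = "free_dna")),
    wt_dynamic_only = list(
      list(proportion = 1, scheme = wt_dyn, label = "dynamic")),
    pm_dynamic_only = list(
      list(proportion = 1, scheme = pm_dyn, label = "dynamic")),
    d32_dynamic_only = list(
      list(proportion = 1, scheme = scale_scheme_rates(wt_dyn, 3),
           label = "dynamic")),
    stop("unknown scenario fixture: ", name)
  )
  phys <- if (name == "bubble_labels_22C")
    photophysics_params(quench_states = "closed", quench_factor = 0.1)
  else photophysics_params()
  scenario_config(name = name, subpopulations = subpops,
                  photophysics = phys, n_molecules = n_molecules,
                  seed = seed, ...)
}

#' @rdname scenario_fixture
#' @export
scenario_fixture_names <- function() {
  c("wt_dsDNA_22C", "wt_dsDNA_37C", "wt_pmDNA_22C", "wt_pmDNA_37C",
    "d32_dsDNA", "d32_pmDNA", "djaw_dsDNA", "djaw_pmDNA",
    "bubble_labels_22C", "free_dna",
    "wt_dynamic_only", "pm_dynamic_only", "d32_dynamic_only")
}
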