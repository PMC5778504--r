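#' Define a labelled conformational kinetic scheme
#'
#' A `kinetic_scheme` couples a set of conformational states (each with a
#' true FRET efficiency and a closed/intermediate/open category) to a
#' continuous-time Markov rate matrix.  It is the ground truth that the
#' simulator realizes and that the analysis pipeline is asked to recover.
#'
#' @param state_labels character vector of state identifiers.
#' @param state_fret numeric vector of true FRET efficiencies, in `[0, 1]`.
#' @param state_category character vector, each one of `"closed"`,
#'   `"intermediate"`, `"open"`.
#' @param rate_matrix square numeric matrix of first-order rate constants
#'   (1/s).  Off-diagonal entries `k[i, j] >= 0` are the i -> j rates; the
#'   diagonal is overwritten with minus the off-diagonal row sums.
#' @param initial_distribution probability vector over states; defaults to
#'   the stationary distribution of `rate_matrix` (uniform if all rates are
#'   zero).
#' @return an object of class `kinetic_scheme`.
#' @examples
#' # two-state bubble: closed (E* 0.2) <-> open (E* 0.45)
#' sc <- kinetic_scheme(
#'   state_labels = c("closed", "open"),
#'   state_fret = c(0.2, 0.45),
#'   state_category = c("closed", "open"),
#'   rate_matrix = matrix(c(0, 6.4, 1.6, 0), 2, 2, byrow = TRUE)
#' )
#' stationary_distribution(sc)
#' @export
kinetic_scheme <- function(state_labels, state_fret, state_category,
                           rate_matrix, initial_distribution = NULL) {
  n <- length(state_labels)
  if (n < 1L) stop("at least one state is required")
  if (length(state_fret) != n || length(state_category) != n)
    stop("state_fret and state_category must match state_labels in length")
  if (any(!is.finite(state_fret)) || any(state_fret < 0) || any(state_fret > 1))
    stop("state_fret values must lie in [0, 1]")
  if (!all(state_category %in% c("closed", "intermediate", "open")))
    stop("state_category entries must be 'closed', 'intermediate' or 'open'")
  rate_matrix <- as.matrix(rate_matrix)
  if (!all(dim(rate_matrix) == c(n, n)))
    stop("rate_matrix must be ", n, " x ", n)
  off <- rate_matrix; diag(off) <- 0
  if (any(!is.finite(off)) || any(off < 0))
    stop("off-diagonal rates must be finite and >= 0")
  diag(rate_matrix) <- -rowSums(off)
  dimnames(rate_matrix) <- list(state_labels, state_labels)

  obj <- structure(
    list(state_labels = as.character(state_labels),
         state_fret = as.numeric(state_fret),
         state_category = as.character(state_category),
         rate_matrix = rate_matrix,
         initial_distribution = NULL),
    class = "kinetic_scheme")
  if (is.null(initial_distribution))
    initial_distribution <- stationary_distribution(obj)
  initial_distribution <- as.numeric(initial_distribution)
  if (length(initial_distribution) != n || any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-9)
    stop("initial_distribution must be a probability vector over the states")
  obj$initial_distribution <- initial_distribution
  obj
}

#' Stationary distribution of a kinetic scheme
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` by a linear solve.  For a reducible
#' chain with all-zero rates the uniform distribution is returned.
#'
#' @param scheme a [kinetic_scheme()].
#' @return numeric probability vector.
#' @export
stationary_distribution <- function(scheme) {
  Q <- scheme$rate_matrix
  n <- nrow(Q)
  if (n == 1L || all(Q == 0)) return(rep(1 / n, n))
  # solve t(Q) pi = 0 with normalization row appended
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_hat <- unname(qr.solve(A, b))
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  if (any(pi_hat < 0)) stop("rate matrix has no non-negative stationary solution")
  pi_hat / sum(pi_hat)
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> ", length(x$state_labels), " state(s)\n", sep = "")
  df <- data.frame(state = x$state_labels, E = x$state_fret,
                   category = x$state_category,
                   exit_rate = -diag(x$rate_matrix),
                   p0 = x$initial_distribution)
  print(df, row.names = FALSE)
  invisible(x)
}

# exit rate (1/s) of each state
scheme_exit_rates <- function(scheme) -diag(scheme$rate_matrix)
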