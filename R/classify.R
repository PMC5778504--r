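#' Behavioural classification of an accepted trace
#'
#' A trace is `dynamic` when its selected HMM has at least two states whose
#' emission means differ by at least `min_delta` E*, the decoded path
#' actually visits a transition between such a pair, and the DD/DA
#' intensity changes at those transition frames are anti-correlated
#' (Pearson r below `anticorr_max`; with a single qualifying transition the
#' sign of the DD/DA change product is used instead).  Otherwise the trace
#' is static, classified by its mean pre-bleach E*: below the lower class
#' boundary `static_closed`, above the upper one `static_open`,
#' `static_intermediate` in between.
#'
#' @param trace the [alex_trace()] (needed for the anti-correlation check).
#' @param fret the `fret_series` of the analysed (pre-bleach) region.
#' @param hmm an `hmm_model` for the same region (e.g. from
#'   [select_model()]), or `NULL` for mean-E*-only classification.
#' @param path optional pre-computed [decode_path()] result.
#' @param boundaries class boundaries on mean E*, default `c(0.275, 0.40)`.
#' @param min_delta minimum emission-mean separation for a dynamic pair.
#' @param anticorr_max Pearson-r threshold (default -0.5).
#' @return list of class `trace_class`: `class`, `mean_E`, `n_transitions`,
#'   `anticorrelation`.
#' @export
classify_trace <- function(trace, fret, hmm = NULL, path = NULL,
                           boundaries = c(0.275, 0.40), min_delta = 0.1,
                           anticorr_max = -0.5) {
  mean_E <- mean(fret$E[fret$valid])
  if (!is.finite(mean_E))
    return(structure(list(class = "unclassifiable", mean_E = NA_real_,
                          n_transitions = 0L, anticorrelation = NA_real_),
                     class = "trace_class"))
  n_trans <- 0L; r <- NA_real_
  dynamic <- FALSE
  if (!is.null(hmm) && hmm$K >= 2L) {
    if (is.null(path)) path <- decode_path(hmm, fret)
    z <- path$states
    sep <- abs(outer(hmm$emission_mean, hmm$emission_mean, "-")) >= min_delta
    # decoded-state runs; transitions are boundaries between adjacent runs
    ok <- !is.na(z)
    rz <- rle(ifelse(ok, z, -1L))
    ends <- cumsum(rz$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    dDD <- numeric(0); dDA <- numeric(0)
    n_trans <- 0L
    for (j in seq_len(length(rz$values) - 1L)) {
      a <- rz$values[j]; b <- rz$values[j + 1L]
      if (a < 0L || b < 0L || a == b || !sep[a, b]) next
      n_trans <- n_trans + 1L
      # dwell-averaged intensity change across the transition (up to 3
      # frames each side) suppresses shot noise on the step estimate
      pre <- max(starts[j], ends[j] - 2L):ends[j]
      post <- starts[j + 1L]:min(ends[j + 1L], starts[j + 1L] + 2L)
      dDD <- c(dDD, mean(trace$DD[post]) - mean(trace$DD[pre]))
      dDA <- c(dDA, mean(trace$DA[post]) - mean(trace$DA[pre]))
    }
    if (n_trans >= 1L) {
      if (n_trans >= 3L) {
        r <- suppressWarnings(cor(dDD, dDA))
        dynamic <- is.finite(r) && r < anticorr_max
      } else {
        # too few points for a meaningful correlation: require opposite signs
        dynamic <- all(dDD * dDA < 0)
        r <- if (dynamic) -1 else 1
      }
    }
  }
  cls <- if (dynamic) "dynamic"
         else if (mean_E < boundaries[1]) "static_closed"
         else if (mean_E < boundaries[2]) "static_intermediate"
         else "static_open"
  structure(list(class = cls, mean_E = mean_E, n_transitions = n_trans,
                 anticorrelation = r),
            class = "trace_class")
}

#' Population table over behavioural classes
#'
#' @param classes character vector (or list of `trace_class`) of per-molecule
#'   class labels.
#' @return data.frame with `class`, `n`, `fraction` (fractions sum to 1),
#'   covering all four behavioural classes.
#' @export
population_table <- function(classes) {
  if (is.list(classes))
    classes <- vapply(classes, function(c) c$class, character(1))
  classes <- classes[classes != "unclassifiable"]
  if (!length(classes)) stop("no classified molecules")
  lev <- c("static_open", "static_closed", "static_intermediate", "dynamic")
  tab <- table(factor(classes, levels = union(lev, unique(classes))))
  data.frame(class = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
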