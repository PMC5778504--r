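#' Change-point (bleach step) detection in an intensity series
#'
#' Recursive binary segmentation: within each segment the split maximizing
#' the two-sample step statistic (mean difference over pooled residual sd,
#' standardized by the split sizes) is accepted as a change-point if the
#' statistic exceeds `threshold` (default 6, well above the null maximum for
#' kilo-frame traces while real bleach steps score in the tens), then both
#' halves are searched
#' recursively.  The pooled sd guards against the noise-free limit (an
#' exact step gives an effectively infinite statistic).
#'
#' @param x numeric intensity series (length >= 20).
#' @param threshold step-statistic acceptance threshold.
#' @param min_segment smallest segment length considered (frames).
#' @return data.frame with columns `frame` (first frame of the new level)
#'   and `step_size` (new level minus old level), ordered by frame.
#' @export
detect_bleach_steps <- function(x, threshold = 6.0, min_segment = 5L) {
  n <- length(x)
  if (n < 20L) stop("series must have at least 20 frames")
  cps <- integer(0)

  find_split <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 2L * min_segment) return(NULL)
    seg <- x[lo:hi]
    cs <- cumsum(seg); cs2 <- cumsum(seg^2)
    i <- min_segment:(len - min_segment)     # split after position i
    n1 <- i; n2 <- len - i
    m1 <- cs[i] / n1
    m2 <- (cs[len] - cs[i]) / n2
    ss1 <- cs2[i] - n1 * m1^2
    ss2 <- (cs2[len] - cs2[i]) - n2 * m2^2
    pooled <- sqrt(pmax(ss1 + ss2, 0) / pmax(len - 2L, 1L))
    scale <- max(abs(seg)) + 1
    # two-sample t statistic of the split
    stat <- abs(m1 - m2) / (pmax(pooled, 1e-9 * scale) * sqrt(1 / n1 + 1 / n2))
    best <- which.max(stat)
    if (stat[best] < threshold) return(NULL)
    list(split = lo + i[best] - 1L, stat = stat[best])
  }

  recurse <- function(lo, hi) {
    sp <- find_split(lo, hi)
    if (is.null(sp)) return(invisible())
    cps <<- c(cps, sp$split)
    recurse(lo, sp$split)
    recurse(sp$split + 1L, hi)
  }
  recurse(1L, n)
  cps <- sort(cps)
  if (!length(cps))
    return(data.frame(frame = integer(0), step_size = numeric(0)))
  bounds <- c(0L, cps, n)
  level <- vapply(seq_len(length(bounds) - 1L), function(j)
    mean(x[(bounds[j] + 1L):bounds[j + 1L]]), numeric(1))
  data.frame(frame = cps + 1L, step_size = diff(level))
}

# first bleach frame on a reporter series: the first downward step after
# which the remaining level stays consistent with background
find_bleach_frame <- function(x, background = 0, threshold = 6.0) {
  steps <- detect_bleach_steps(x, threshold = threshold)
  down <- steps[steps$step_size < 0, , drop = FALSE]
  n_down <- nrow(down)
  bleach <- NA_integer_
  for (j in seq_len(n_down)) {
    post <- x[down$frame[j]:length(x)]
    if (mean(post) <= background + 2 * max(sd(post), 1e-9)) {
      bleach <- down$frame[j]
      break
    }
  }
  list(bleach_frame = bleach, n_down_steps = n_down, steps = steps)
}

# dark intervals of >= min_run frames followed by recovery, before `before`
has_blinking <- function(x, level, background, before = length(x),
                         min_run = 3L) {
  if (before <= 1L) return(FALSE)
  thr <- background + 0.3 * max(level - background, 0)
  dark <- x[seq_len(before - 1L)] < thr
  r <- rle(dark)
  if (length(r$lengths) < 2L) return(FALSE)
  ends <- cumsum(r$lengths)
  # a qualifying dark run must be followed by a bright run (recovery)
  any(r$values & r$lengths >= min_run & ends < (before - 1L))
}

#' Apply the trace-selection criteria to one molecule
#'
#' Algorithmic version of the manual single-molecule selection rules:
#' single-step photobleaching of each fluorophore (acceptor presence read
#' from AA, donor presence from DD + DA), with the earlier bleach occurring
#' no sooner than `min_frames`; no blinking (a dark interval of at least 3
#' frames followed by recovery; shorter fluctuations are permitted); and a
#' total pre-bleach intensity within a configurable band around the dataset
#' median.  At least one fluorophore must bleach within the record (the
#' single-step loss is what certifies a single molecule).
#'
#' @param trace an [alex_trace()].
#' @param dataset_median_intensity median over the dataset of the mean
#'   pre-bleach total intensity (DD + DA + AA); `NULL` skips the band check
#'   (it is applied by [qc_dataset()]).
#' @param min_frames minimum first-bleach frame (default 105).
#' @param intensity_band allowed multiplicative band around the dataset
#'   median (default `c(0.3, 3)`).
#' @param step_threshold change-point acceptance threshold.
#' @return one-row data.frame (a QC report): `molecule_id`, `accepted`,
#'   `reasons` (';'-joined), `donor_bleach_frame`, `acceptor_bleach_frame`,
#'   `first_bleach_frame`, `prebleach_mean_intensity`.
#' @export
apply_selection <- function(trace, dataset_median_intensity = NULL,
                            min_frames = 105L, intensity_band = c(0.3, 3),
                            step_threshold = 6.0) {
  bg <- trace$background %||% c(DD = 0, DA = 0, AA = 0)
  aa <- trace$AA
  dd_da <- trace$DD + trace$DA
  n <- length(aa)
  reasons <- character(0)

  acc <- find_bleach_frame(aa, background = bg[["AA"]],
                           threshold = step_threshold)
  don <- find_bleach_frame(dd_da, background = bg[["DD"]] + bg[["DA"]],
                           threshold = step_threshold)

  # more than one distinct downward level change on a reporter series that
  # does end at background = multi-step photobleaching
  if ((!is.na(acc$bleach_frame) && acc$n_down_steps > 1L) ||
      (!is.na(don$bleach_frame) && don$n_down_steps > 1L))
    reasons <- c(reasons, "multi_step_bleach")

  first_bleach <- suppressWarnings(
    min(c(acc$bleach_frame, don$bleach_frame), na.rm = TRUE))
  if (!is.finite(first_bleach)) {
    reasons <- c(reasons, "no_bleach_observed")
    first_bleach <- NA_integer_
  } else if (first_bleach < min_frames) {
    reasons <- c(reasons, "too_short")
  }

  pre_end <- if (is.na(first_bleach)) n else first_bleach - 1L
  if (pre_end >= 2L) {
    lvl_a <- median(aa[seq_len(pre_end)])
    lvl_d <- median(dd_da[seq_len(pre_end)])
    a_end <- if (is.na(acc$bleach_frame)) n else acc$bleach_frame
    d_end <- if (is.na(don$bleach_frame)) n else don$bleach_frame
    if (has_blinking(aa, lvl_a, bg[["AA"]], before = a_end))
      reasons <- c(reasons, "acceptor_blink")
    if (has_blinking(dd_da, lvl_d, bg[["DD"]] + bg[["DA"]], before = d_end))
      reasons <- c(reasons, "donor_blink")
  }

  pre_int <- mean((trace$DD + trace$DA + trace$AA)[seq_len(max(pre_end, 1L))])
  if (!is.null(dataset_median_intensity) &&
      (pre_int < intensity_band[1] * dataset_median_intensity ||
       pre_int > intensity_band[2] * dataset_median_intensity))
    reasons <- c(reasons, "intensity_out_of_range")

  data.frame(molecule_id = trace$molecule_id,
             accepted = length(reasons) == 0L,
             reasons = paste(reasons, collapse = ";"),
             donor_bleach_frame = don$bleach_frame,
             acceptor_bleach_frame = acc$bleach_frame,
             first_bleach_frame = if (is.na(first_bleach)) NA_integer_
                                  else as.integer(first_bleach),
             prebleach_mean_intensity = pre_int,
             stringsAsFactors = FALSE)
}

#' QC an entire dataset
#'
#' Runs [apply_selection()] on every trace, applying the intensity-band
#' criterion against the dataset-wide median pre-bleach intensity.
#'
#' @param traces list of [alex_trace()] (or an `alex_dataset`).
#' @param ... passed to [apply_selection()].
#' @return data.frame with one QC report row per molecule.
#' @export
qc_dataset <- function(traces, ...) {
  if (inherits(traces, "alex_dataset")) traces <- traces$traces
  rep0 <- do.call(rbind, lapply(traces, apply_selection, ...))
  med <- median(rep0$prebleach_mean_intensity)
  out <- do.call(rbind, lapply(traces, apply_selection,
                               dataset_median_intensity = med, ...))
  out
}
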