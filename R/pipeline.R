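#' Truncate a FRET series to its pre-bleach region
#'
#' @param fret a `fret_series`.
#' @param end last frame to keep (e.g. first bleach frame minus one); `NA`
#'   keeps everything.
#' @return a `fret_series` restricted to frames `1..end`.
#' @export
truncate_fret <- function(fret, end) {
  if (is.na(end)) return(fret)
  end <- max(1L, min(end, length(fret$E)))
  keep <- seq_len(end)
  structure(list(E = fret$E[keep], S = fret$S[keep],
                 valid = fret$valid[keep],
                 frame_period_s = fret$frame_period_s,
                 molecule_id = fret$molecule_id,
                 n_valid = sum(fret$valid[keep])),
            class = "fret_series")
}

#' Analyse one accepted molecule
#'
#' Computes the pre-bleach E* series, fits and selects the HMM, decodes the
#' state path, classifies the behaviour and (for dynamic traces) extracts
#' category dwell times.
#'
#' @param trace an [alex_trace()].
#' @param qc_row the molecule's QC report row (from [apply_selection()]).
#' @param seed integer seed for the HMM restarts.
#' @param boundaries class/category boundaries on E*.
#' @param priors HMM priors from [hmm_priors()].
#' @param K_max maximum number of HMM states.
#' @param n_restarts HMM restarts per K.
#' @return list with `fret`, `model` (or NULL), `path`, `class`
#'   (a `trace_class`), `dwells` (data.frame or NULL).
#' @export
analyze_molecule <- function(trace, qc_row, seed = 1L,
                             boundaries = c(0.275, 0.40),
                             priors = hmm_priors(), K_max = 3L,
                             n_restarts = 10L) {
  fs <- compute_fret_series(trace, background = "auto")
  pre_end <- if (is.na(qc_row$first_bleach_frame)) NA_integer_
             else qc_row$first_bleach_frame - 1L
  fs_pre <- truncate_fret(fs, pre_end)
  model <- NULL; path <- NULL
  if (fs_pre$n_valid >= 50L) {
    model <- select_model(fs_pre, K_max = K_max, priors = priors,
                          seed = seed, n_restarts = n_restarts)
    path <- decode_path(model, fs_pre)
  }
  cls <- classify_trace(trace, fs_pre, model, path, boundaries = boundaries)
  dwells <- NULL
  if (cls$class == "dynamic") {
    cmap <- categorize_states(model, boundaries)
    dwells <- extract_dwells(path, cmap, fs_pre$frame_period_s,
                             molecule_id = trace$molecule_id)
  }
  list(fret = fs_pre, model = model, path = path, class = cls,
       dwells = dwells)
}

#' Run the full analysis pipeline on one scenario
#'
#' simulate (or load) -> E*/S -> QC -> HMM segmentation -> classification
#' -> dwell kinetics, returning a machine-readable report.  Fully
#' deterministic for a fixed configuration (every random draw derives from
#' the scenario seed).
#'
#' @param config a [scenario_config()] to simulate, or an `alex_dataset`.
#' @param out_dir optional output directory; when given, the dataset,
#'   per-stage CSVs and the report JSON are written there.
#' @param frames_per_molecule per-molecule frame budget for the pooled
#'   histogram (default 250).
#' @param mixture_k components of the E* Gaussian mixture summary.
#' @param boundaries class/category boundaries on E*.
#' @param K_max,n_restarts HMM settings.
#' @param n_boot bootstrap replicates for dwell CIs.
#' @param progress print per-stage progress messages.
#' @return object of class `run_report`: list with `scenario`, `seed`,
#'   `n_molecules`, `n_accepted`, `qc`, `populations`, `histogram`,
#'   `mixture`, `kinetics`, `classes`, `dwells`, `analyses`.
#' @export
run_pipeline <- function(config, out_dir = NULL, frames_per_molecule = 250,
                         mixture_k = 2L, boundaries = c(0.275, 0.40),
                         K_max = 3L, n_restarts = 10L, n_boot = 1000L,
                         progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  if (inherits(config, "scenario_config")) {
    say("simulating scenario '%s' (%d molecules)", config$name,
        config$n_molecules)
    dataset <- simulate_dataset(config)
    seed <- config$seed
    name <- config$name
  } else if (inherits(config, "alex_dataset")) {
    dataset <- config
    seed <- dataset$manifest$seed %||% 1L
    name <- dataset$manifest$scenario %||% "dataset"
  } else stop("config must be a scenario_config or alex_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset(dataset, file.path(out_dir, "dataset"))
  }

  say("QC on %d traces", length(dataset$traces))
  qc <- qc_dataset(dataset$traces)
  accepted <- which(qc$accepted)
  if (!length(accepted)) stop("no molecules passed selection")

  say("HMM + classification on %d accepted traces", length(accepted))
  analyses <- vector("list", length(accepted))
  for (i in seq_along(accepted)) {
    m <- accepted[i]
    analyses[[i]] <- analyze_molecule(
      dataset$traces[[m]], qc[m, ], seed = substream_seed(seed, 100L, m),
      boundaries = boundaries, K_max = K_max, n_restarts = n_restarts)
  }
  names(analyses) <- qc$molecule_id[accepted]

  classes <- data.frame(
    molecule_id = qc$molecule_id[accepted],
    class = vapply(analyses, function(a) a$class$class, character(1)),
    mean_E = vapply(analyses, function(a) a$class$mean_E, numeric(1)),
    n_transitions = vapply(analyses, function(a)
      a$class$n_transitions, integer(1)),
    stringsAsFactors = FALSE)
  populations <- population_table(classes$class)

  histogram <- build_fret_histogram(lapply(analyses, `[[`, "fret"),
                                    frames_per_molecule = frames_per_molecule)
  mixture <- fit_fret_mixture(histogram, k = mixture_k)

  dwell_list <- Filter(Negate(is.null), lapply(analyses, `[[`, "dwells"))
  dwells <- if (length(dwell_list)) {
    d <- do.call(rbind, dwell_list)
    attr(d, "frame_period_s") <- dataset$manifest$frame_period_s %||%
      dataset$traces[[1]]$frame_period_s
    rownames(d) <- NULL
    d
  } else NULL
  kinetics <- if (!is.null(dwells))
    kinetics_report(dwells, condition = name,
                    seed = substream_seed(seed, 200L), n_boot = n_boot)
  else NULL

  report <- structure(list(
    scenario = name, seed = seed,
    n_molecules = length(dataset$traces),
    n_accepted = length(accepted),
    qc = qc, populations = populations,
    histogram = histogram, mixture = mixture,
    kinetics = kinetics, classes = classes, dwells = dwells,
    analyses = analyses), class = "run_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> scenario '%s': %d/%d molecules accepted\n",
              x$scenario, x$n_accepted, x$n_molecules))
  print(x$populations)
  cat("mixture components (mean / sd / weight):\n")
  for (j in seq_along(x$mixture$means))
    cat(sprintf("  %.3f / %.3f / %.3f\n", x$mixture$means[j],
                x$mixture$sds[j], x$mixture$weights[j]))
  if (!is.null(x$kinetics)) {
    cat("kinetics:\n")
    print(x$kinetics[, c("category", "n_dwells", "tau_s", "rate_per_s",
                         "ci_lo", "ci_hi", "n_components")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write the machine-readable outputs of a pipeline run
#'
#' @param report a `run_report`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$qc, file.path(out_dir, "qc_report.csv"),
                   row.names = FALSE)
  utils::write.csv(report$classes, file.path(out_dir, "classes.csv"),
                   row.names = FALSE)
  utils::write.csv(report$populations, file.path(out_dir, "populations.csv"),
                   row.names = FALSE)
  hb <- report$histogram
  utils::write.csv(
    data.frame(bin_left = head(hb$breaks, -1), bin_right = tail(hb$breaks, -1),
               count = hb$counts),
    file.path(out_dir, "histogram.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(means = report$mixture$means, sds = report$mixture$sds,
         weights = report$mixture$weights, n = report$mixture$n),
    file.path(out_dir, "mixture.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(report$dwells))
    utils::write.csv(report$dwells, file.path(out_dir, "dwells.csv"),
                     row.names = FALSE)
  if (!is.null(report$kinetics))
    utils::write.csv(report$kinetics, file.path(out_dir, "kinetics.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(scenario = report$scenario, seed = report$seed,
         n_molecules = report$n_molecules, n_accepted = report$n_accepted,
         populations = report$populations),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Compare pipeline reports across conditions
#'
#' Per-class population deltas and opening/closing rate fold-changes of
#' each report against a reference condition.  Rate-ratio intervals combine
#' the two bootstrap CIs conservatively (lo/hi against hi/lo).
#'
#' @param reports named list of `run_report`s (names = condition labels).
#' @param reference name of the reference condition.
#' @return list with `populations` (long data.frame of fractions and deltas)
#'   and `rates` (data.frame of rate ratios per category).
#' @export
compare_conditions <- function(reports, reference) {
  if (length(reports) < 2L && !(reference %in% names(reports)))
    stop("need at least the reference plus one other report")
  if (!reference %in% names(reports))
    stop("reference condition not among the reports")
  ref <- reports[[reference]]
  pop_rows <- list(); rate_rows <- list()
  for (nm in names(reports)) {
    rp <- reports[[nm]]
    if (!identical(rp$populations$class, ref$populations$class))
      stop("population schema mismatch between '", nm, "' and reference")
    pop_rows[[nm]] <- data.frame(
      condition = nm, class = rp$populations$class,
      fraction = rp$populations$fraction,
      delta_vs_ref = rp$populations$fraction - ref$populations$fraction,
      stringsAsFactors = FALSE)
    if (!is.null(rp$kinetics) && !is.null(ref$kinetics)) {
      for (cat in c("closed", "open")) {
        a <- rp$kinetics[rp$kinetics$category == cat, ]
        b <- ref$kinetics[ref$kinetics$category == cat, ]
        if (nrow(a) && nrow(b) && is.finite(a$rate_per_s) &&
            is.finite(b$rate_per_s)) {
          rate_rows[[paste(nm, cat)]] <- data.frame(
            condition = nm, category = cat,
            rate_per_s = a$rate_per_s,
            ratio_vs_ref = a$rate_per_s / b$rate_per_s,
            ratio_lo = (1 / a$ci_hi) / (1 / b$ci_lo),
            ratio_hi = (1 / a$ci_lo) / (1 / b$ci_hi),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(populations = do.call(rbind, c(pop_rows, make.row.names = FALSE)),
       rates = if (length(rate_rows))
         do.call(rbind, c(rate_rows, make.row.names = FALSE)) else NULL)
}
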