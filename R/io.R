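#' Write a simulated dataset to disk
#'
#' One tab-delimited file per molecule with '#'-prefixed metadata header
#' lines (`frame_period_s`, `molecule_id`) and columns `frame_index`,
#' `time_s`, `DD`, `DA`, `AA`, plus a `manifest.json` recording the
#' scenario, seed and per-molecule ground-truth summary.
#'
#' @param dataset an `alex_dataset` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "alex_dataset")) stop("not an alex_dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(dataset$traces))
  for (i in seq_along(dataset$traces)) {
    tr <- dataset$traces[[i]]
    f <- file.path(dir, paste0(tr$molecule_id, ".tsv"))
    paths[i] <- basename(f)
    con <- file(f, "w", encoding = "UTF-8")
    writeLines(c(sprintf("# frame_period_s\t%.10g", tr$frame_period_s),
                 sprintf("# molecule_id\t%s", tr$molecule_id),
                 if (!is.null(tr$background))
                   sprintf("# background\t%.10g\t%.10g\t%.10g",
                           tr$background[["DD"]], tr$background[["DA"]],
                           tr$background[["AA"]])), con)
    df <- data.frame(frame_index = tr$frame_index, time_s = tr$time_s,
                     DD = tr$DD, DA = tr$DA, AA = tr$AA)
    write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  man <- dataset$manifest
  man$files <- paths
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a single ALEX trace TSV
#'
#' @param path path to a per-molecule TSV written by [write_dataset()] (or
#'   by any extraction tool following the same layout).
#' @return an [alex_trace()].
#' @export
read_alex_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    parts <- strsplit(sub("^#\\s*", "", h), "\t")[[1]]
    meta[[parts[1]]] <- parts[-1]
  }
  body <- lines[!grepl("^#", lines)]
  df <- read.table(text = body, header = TRUE, sep = "\t")
  bg <- NULL
  if (!is.null(meta$background)) {
    bg <- as.numeric(meta$background)
    names(bg) <- c("DD", "DA", "AA")
  }
  alex_trace(df$DD, df$DA, df$AA,
             frame_period_s = as.numeric(meta$frame_period_s[1]),
             molecule_id = meta$molecule_id[1] %||%
               sub("\\.tsv$", "", basename(path)),
             background = bg)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.json` and per-molecule
#'   TSV files.
#' @return an `alex_dataset` (without simulation-only ground-truth fields
#'   beyond those recorded in the manifest).
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  files <- unlist(man$files)
  traces <- lapply(file.path(dir, files), read_alex_trace)
  truth <- lapply(man$molecules, function(m) list(
    molecule_id = m$molecule_id,
    subpopulation = m$subpopulation,
    donor_bleach_frame = m$donor_bleach_frame %||% NA_integer_,
    acceptor_bleach_frame = m$acceptor_bleach_frame %||% NA_integer_))
  structure(list(traces = traces, truth = truth, manifest = man),
            class = "alex_dataset")
}

# ---- scenario YAML ----------------------------------------------------------

scheme_to_list <- function(s) {
  list(state_labels = s$state_labels, state_fret = s$state_fret,
       state_category = s$state_category,
       rate_matrix = apply(s$rate_matrix, 1, as.numeric, simplify = FALSE),
       initial_distribution = s$initial_distribution)
}

scheme_from_list <- function(l) {
  K <- length(l$state_labels)
  Q <- do.call(rbind, lapply(l$rate_matrix, as.numeric))
  kinetic_scheme(unlist(l$state_labels), as.numeric(unlist(l$state_fret)),
                 unlist(l$state_category), Q,
                 as.numeric(unlist(l$initial_distribution)))
}

#' Write / read a scenario configuration as YAML
#'
#' The YAML schema mirrors [scenario_config()]: top-level `name`,
#' `alternation_rate_hz`, `n_molecules`, `max_duration_s`, `seed`, a
#' `photophysics` mapping and a `subpopulations` sequence whose entries
#' hold `proportion`, `label` and a `scheme` mapping (`state_labels`,
#' `state_fret`, `state_category`, `rate_matrix` as a list of rows,
#' `initial_distribution`).
#'
#' @param config a [scenario_config()].
#' @param path YAML file path.
#' @return `write_scenario_yaml()` returns `path` invisibly;
#'   `read_scenario_yaml()` returns a [scenario_config()].
#' @export
write_scenario_yaml <- function(config, path) {
  ph <- unclass(config$photophysics)
  ph$quench_states <- as.list(ph$quench_states %||% character(0))
  out <- list(
    name = config$name,
    alternation_rate_hz = config$alternation_rate_hz,
    n_molecules = config$n_molecules,
    max_duration_s = config$max_duration_s,
    seed = config$seed,
    photophysics = ph,
    subpopulations = lapply(config$subpopulations, function(sp)
      list(proportion = sp$proportion, label = sp$label,
           scheme = scheme_to_list(sp$scheme))))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  l <- yaml::read_yaml(path)
  ph_args <- l$photophysics %||% list()
  qs <- unlist(ph_args$quench_states)
  ph_args$quench_states <- if (length(qs)) as.character(qs) else NULL
  ph <- do.call(photophysics_params, ph_args)
  subpops <- lapply(l$subpopulations, function(sp)
    list(proportion = as.numeric(sp$proportion), label = sp$label,
         scheme = scheme_from_list(sp$scheme)))
  scenario_config(name = l$name, subpopulations = subpops, photophysics = ph,
                  alternation_rate_hz = l$alternation_rate_hz %||% 100,
                  n_molecules = l$n_molecules %||% 100,
                  max_duration_s = l$max_duration_s %||% 10,
                  seed = l$seed %||% 1L)
}
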