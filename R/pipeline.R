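#' Pipeline run configuration
#'
#' Collects every input, parameter and seed of an end-to-end run:
#' filter -> phase -> microstates -> msPLI -> ROI aggregation -> graph
#' measures -> statistics. All referenced files must exist when the config
#' is built (fail-fast), and every seed is recorded in the output manifest
#' so a run can be reproduced bit-identically.
#'
#' @param eeg_paths Character vector of per-subject EEG files (TSV matrix
#'   dialect), in the row order of `cohort`.
#' @param cohort Covariate data frame or path to its CSV.
#' @param roi_map ROI map data frame or path to its TSV (default the
#'   packaged 22-ROI layout).
#' @param out_dir Output directory (created if missing).
#' @param bands Analysis bands (default [analysis_bands()]).
#' @param k Microstate count, or `NULL` to select it per subject with
#'   [select_k()] over `k_range`.
#' @param k_range Candidate k values when `k` is `NULL`.
#' @param ms_fit_band Length-2 numeric: broadband filter (Hz) applied
#'   before microstate fitting (default 2-20 Hz).
#' @param epoch_len,n_epochs msPLI epoch geometry (defaults 4000 and 4).
#' @param n_surrogates Surrogates for `Gamma`/`Lambda` (default 50).
#' @param n_perm Permutations for the corrected p-values (default 10000).
#' @param outcome,confounds Statistics columns, see [correlate_edges()].
#' @param seed Master seed; per-stage seeds derive from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(eeg_paths, cohort, roi_map = default_roi_map(),
                       out_dir = tempfile("mspli_run_"),
                       bands = analysis_bands(),
                       k = 4L, k_range = 2:6, ms_fit_band = c(2, 20),
                       epoch_len = 4000L, n_epochs = 4L,
                       n_surrogates = 50L, n_perm = 10000L,
                       outcome = "aes",
                       confounds = c("age", "sex", "education", "mms",
                                     "led"),
                       seed = 1L) {
  missing_files <- eeg_paths[!file.exists(eeg_paths)]
  if (length(missing_files) > 0L)
    stop("missing EEG file(s): ", paste(missing_files, collapse = ", "),
         call. = FALSE)
  if (is.character(cohort)) {
    if (!file.exists(cohort)) stop("missing cohort CSV: ", cohort,
                                   call. = FALSE)
    cohort <- utils::read.csv(cohort, stringsAsFactors = FALSE)
  }
  if (is.character(roi_map)) {
    if (!file.exists(roi_map)) stop("missing ROI map: ", roi_map,
                                    call. = FALSE)
    roi_map <- read_roi_map(roi_map)
  }
  if (nrow(cohort) != length(eeg_paths))
    stop("cohort rows and EEG files disagree", call. = FALSE)
  if (anyDuplicated(cohort$id))
    stop("duplicate subject ids", call. = FALSE)
  structure(list(eeg_paths = eeg_paths, cohort = cohort, roi_map = roi_map,
                 out_dir = out_dir, bands = bands, k = k, k_range = k_range,
                 ms_fit_band = ms_fit_band,
                 epoch_len = as.integer(epoch_len),
                 n_epochs = as.integer(n_epochs),
                 n_surrogates = as.integer(n_surrogates),
                 n_perm = as.integer(n_perm),
                 outcome = outcome, confounds = confounds,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- config
  plain$out_dir <- NULL   # the hash identifies the analysis, not its sink
  plain$cohort <- as.list(plain$cohort)
  plain$roi_map <- as.list(plain$roi_map)
  jsonlite::write_json(plain, tmp, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full msPLI analysis pipeline
#'
#' For every subject: read the EEG, fit (or reuse) the microstate model on
#' the broadband-filtered recording, backfit labels, compute the msPLI
#' matrix per band, aggregate to ROIs, and compute the graph measures.
#' Across subjects: residualised Spearman statistics of every ROI edge
#' against the outcome, permutation-corrected per band. Writes per-stage
#' CSV outputs, a coverage log (epochs found per microstate class), and a
#' JSON manifest carrying every seed and the config hash.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress (default TRUE).
#' @return (Invisibly) a list with `roi_matrices` (subject x band),
#'   `graph` (per-subject metrics data frame), `stats` (per-band
#'   correlation results), `coverage`, and `manifest`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  n_sub <- length(config$eeg_paths)
  band_names <- vapply(config$bands, `[[`, "", "name")
  roi_matrices <- vector("list", n_sub)
  graph_rows <- list()
  coverage_rows <- list()

  for (s in seq_len(n_sub)) {
    id <- config$cohort$id[s]
    rec <- tryCatch(read_eeg(config$eeg_paths[s]), error = function(e)
      stop("stage read_eeg failed for subject ", id, ": ",
           conditionMessage(e), call. = FALSE))
    broad <- eeg_bandpass(rec, band_definition("broad",
                                               config$ms_fit_band[1],
                                               config$ms_fit_band[2]))
    k_use <- config$k
    if (is.null(k_use))
      k_use <- as.integer(select_k(broad, config$k_range,
                                   seed = config$seed + s))
    model <- fit_microstates(broad, k_use, seed = config$seed + s)
    labels <- backfit(broad, model)
    say("subject %s: k = %d, GEV = %.2f", id, k_use, model$gev)
    mats <- list()
    for (b in config$bands) {
      W <- tryCatch(
        ms_pli(rec, labels, b, config$epoch_len, config$n_epochs),
        error = function(e)
          stop("stage ms_pli (", b$name, ") failed for subject ", id, ": ",
               conditionMessage(e), call. = FALSE))
      R <- roi_aggregate(W, config$roi_map)
      mats[[b$name]] <- R
      cov <- attr(W, "coverage")
      coverage_rows[[length(coverage_rows) + 1L]] <-
        cbind(id = id, band = b$name, cov,
              n_matrices = attr(W, "n_matrices"))
      gm <- graph_metrics(R, config$n_surrogates, seed = config$seed + s)
      graph_rows[[length(graph_rows) + 1L]] <-
        cbind(id = id, band = b$name, gm)
      write_connectivity_csv(R, file.path(config$out_dir,
                                          sprintf("roi_%s_%s.csv", id,
                                                  b$name)))
    }
    roi_matrices[[s]] <- mats
  }
  names(roi_matrices) <- config$cohort$id

  graph <- do.call(rbind, graph_rows)
  coverage <- do.call(rbind, coverage_rows)
  utils::write.csv(graph, file.path(config$out_dir, "graph_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(coverage, file.path(config$out_dir, "coverage.csv"),
                   row.names = FALSE)

  stats_res <- list()
  for (bn in band_names) {
    edges <- t(vapply(roi_matrices, function(m) {
      W <- m[[bn]]
      W[upper.tri(W)]
    }, numeric(sum(upper.tri(roi_matrices[[1L]][[bn]])))))
    W1 <- roi_matrices[[1L]][[bn]]
    ut <- which(upper.tri(W1), arr.ind = TRUE)
    colnames(edges) <- paste(rownames(W1)[ut[, 1L]],
                             rownames(W1)[ut[, 2L]], sep = "--")
    stats_res[[bn]] <- correlate_edges(edges, config$cohort,
                                       outcome = config$outcome,
                                       confounds = config$confounds,
                                       n_perm = config$n_perm,
                                       seed = config$seed + 7L)
    utils::write.csv(stats_res[[bn]],
                     file.path(config$out_dir,
                               sprintf("stats_%s.csv", bn)),
                     row.names = FALSE)
  }

  manifest <- list(config_hash = config_hash(config),
                   seed = config$seed, n_perm = config$n_perm,
                   n_surrogates = config$n_surrogates,
                   epoch_len = config$epoch_len,
                   n_epochs = config$n_epochs,
                   bands = band_names,
                   outcome = config$outcome, confounds = config$confounds,
                   n_subjects = n_sub,
                   transforms = c("log(msPLI)", "sqrt(AES)"),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  say("pipeline complete: %s", config$out_dir)
  invisible(list(roi_matrices = roi_matrices, graph = graph,
                 stats = stats_res, coverage = coverage,
                 manifest = manifest))
}
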