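#' EEG recording container
#'
#' A multichannel EEG recording: a channel x time voltage matrix in microvolt
#' together with the sampling rate, unique channel labels, and optional 2-D
#' sensor positions.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param rate Sampling rate in Hz.
#' @param labels Character vector of unique channel names, one per row.
#' @param positions Optional numeric matrix (channels x 2 or x 3) of sensor
#'   coordinates.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, labels, positions = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric", call. = FALSE)
  if (any(!is.finite(data)))
    stop("recording contains non-finite samples", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop("length(labels) must equal the number of channels (rows)",
         call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    stopifnot(nrow(positions) == nrow(data))
  }
  rownames(data) <- labels
  structure(list(data = data, rate = rate, labels = labels,
                 positions = positions),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Write an EEG recording as a plain TSV matrix
#'
#' The dialect is two comment header lines (`# rate: <Hz>` and
#' `# labels: <tab-separated names>`) followed by one tab-separated row of
#' samples per channel.
#'
#' @param rec An [eeg_recording].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_tsv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate: %.10g", rec$rate),
               paste0("# labels: ", paste(rec$labels, collapse = "\t"))), con)
  write.table(format(rec$data, digits = 10, trim = TRUE, scientific = TRUE),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read an EEG recording from the plain TSV matrix dialect
#'
#' @param path File written by [write_eeg_tsv()].
#' @return An [eeg_recording].
#' @export
read_eeg_tsv <- function(path) {
  header <- readLines(path, n = 2L)
  rate_line <- grep("^# rate:", header, value = TRUE)
  if (length(rate_line) != 1L)
    stop("TSV header is missing the 'rate' key", call. = FALSE)
  label_line <- grep("^# labels:", header, value = TRUE)
  if (length(label_line) != 1L)
    stop("TSV header is missing the 'labels' key", call. = FALSE)
  rate <- as.numeric(sub("^# rate:\\s*", "", rate_line))
  labels <- strsplit(sub("^# labels:\\s*", "", label_line), "\t",
                     fixed = TRUE)[[1]]
  data <- as.matrix(read.table(path, sep = "\t", skip = 2L,
                               colClasses = "numeric"))
  dimnames(data) <- NULL
  if (nrow(data) != length(labels))
    stop("TSV data rows do not match the number of labels", call. = FALSE)
  eeg_recording(data, rate, labels)
}

#' Read an EEG recording, dispatching on file extension
#'
#' Supports the package's documented TSV matrix dialect (`.tsv`, `.txt`).
#' EDF files are recognised but not supported in this build; a distinct error
#' is raised rather than a silent misread.
#'
#' @param path Input file.
#' @return An [eeg_recording].
#' @export
read_eeg <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tsv = ,
         txt = read_eeg_tsv(path),
         edf = stop("EDF input is not supported by this build; ",
                    "convert to the TSV matrix dialect (see write_eeg_tsv)",
                    call. = FALSE),
         stop("unknown EEG format: .", ext, call. = FALSE))
}

# Schematic 32-channel montage: 22 lateral channels mapped to the 22 ROIs
# (11 per hemisphere) plus 10 unmapped midline channels. Positions are
# schematic head coordinates (x: left -1 .. right 1, y: posterior -1 ..
# anterior 1), sufficient for map visualisation and template construction.
montage_table <- function() {
  t <- read.table(text = "
label   x      y      roi
Fp1   -0.30   0.95  frontopolar_L
Fp2    0.30   0.95  frontopolar_R
F3    -0.40   0.55  frontal_L
F4     0.40   0.55  frontal_R
F7    -0.80   0.55  frontal_lateral_L
F8     0.80   0.55  frontal_lateral_R
C3    -0.40   0.00  central_L
C4     0.40   0.00  central_R
C5    -0.75   0.00  central_lateral_L
C6     0.75   0.00  central_lateral_R
T7    -0.95   0.00  temporal_anterior_L
T8     0.95   0.00  temporal_anterior_R
TP7   -0.90  -0.35  temporal_posterior_L
TP8    0.90  -0.35  temporal_posterior_R
P3    -0.40  -0.55  parietal_L
P4     0.40  -0.55  parietal_R
P7    -0.80  -0.55  parietal_lateral_L
P8     0.80  -0.55  parietal_lateral_R
O1    -0.30  -0.95  occipital_L
O2     0.30  -0.95  occipital_R
PO7   -0.60  -0.80  occipital_lateral_L
PO8    0.60  -0.80  occipital_lateral_R
Fpz    0.00   1.00  NA
AFz    0.00   0.80  NA
Fz     0.00   0.55  NA
FCz    0.00   0.30  NA
Cz     0.00   0.00  NA
CPz    0.00  -0.30  NA
Pz     0.00  -0.55  NA
POz    0.00  -0.80  NA
Oz     0.00  -1.00  NA
Iz     0.00  -1.10  NA
", header = TRUE, stringsAsFactors = FALSE)
  t
}

#' Default scaled-down montage
#'
#' A schematic 32-channel montage used by the synthetic-data generator: 22
#' lateral channels (11 per hemisphere) that carry the region-of-interest
#' map, plus 10 midline channels that are recorded but excluded from ROI
#' aggregation, mirroring the exclusion of midline/neck/face electrodes.
#'
#' @return List with `labels` (character 32) and `positions` (32 x 2 matrix).
#' @export
default_montage <- function() {
  t <- montage_table()
  list(labels = t$label,
       positions = as.matrix(t[, c("x", "y")]))
}

#' Default channel-to-ROI map for the scaled-down montage
#'
#' Maps the 22 lateral channels of [default_montage()] onto 22 regions of
#' interest, 11 per hemisphere; midline channels are intentionally absent
#' from the map.
#'
#' @return Data frame with columns `channel` and `roi`.
#' @export
default_roi_map <- function() {
  t <- montage_table()
  t <- t[!is.na(t$roi) & t$roi != "NA", c("label", "roi")]
  names(t) <- c("channel", "roi")
  rownames(t) <- NULL
  t
}

#' Read / write a channel-to-ROI map as two-column TSV
#'
#' @param path File path.
#' @return For `read_roi_map`, a data frame with columns `channel`, `roi`.
#' @export
read_roi_map <- function(path) {
  m <- read.table(path, sep = "\t", header = TRUE,
                  colClasses = "character")
  if (!all(c("channel", "roi") %in% names(m)))
    stop("ROI map must have columns 'channel' and 'roi'", call. = FALSE)
  if (anyDuplicated(m$channel))
    stop("ROI map assigns a channel more than once", call. = FALSE)
  m[, c("channel", "roi")]
}

#' @rdname read_roi_map
#' @param roi_map Data frame with columns `channel`, `roi`.
#' @export
write_roi_map <- function(roi_map, path) {
  write.table(roi_map[, c("channel", "roi")], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
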