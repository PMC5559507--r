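#' Phase lag index of a phase-difference series
#'
#' `PLI = |mean_t sign(wrap(delta_phi_t))|`, the absolute time-average of
#' the sign of the wrapped phase difference. A consistent non-zero lag gives
#' 1, a sign-balanced series 0; zero-lag (volume-conduction) coupling does
#' not contribute because `sign(0) = 0`.
#'
#' @param dphi Numeric vector of phase differences in radians (any wrap).
#' @return PLI value in `[0, 1]`.
#' @export
#' @examples
#' pli(rep(pi / 4, 100))                       # 1
#' pli(rep(c(0.1, -0.1), 50))                  # 0
pli <- function(dphi) {
  if (length(dphi) == 0L) stop("empty phase-difference series", call. = FALSE)
  if (any(!is.finite(dphi))) stop("non-finite phase differences", call. = FALSE)
  abs(mean(sign(wrap_phase(dphi))))
}

#' Extract stitched microstate epochs
#'
#' For every microstate class, the valid samples carrying that label are
#' concatenated in temporal order and cut into up to `n_epochs` consecutive
#' stretches of `epoch_len` samples. Classes with fewer than
#' `n_epochs * epoch_len` labelled samples yield as many full epochs as
#' available (possibly zero); the shortfall is recorded.
#'
#' @param phases A `phase_tensor` from [hilbert_phase()].
#' @param labels A `label_vector` from [backfit()] aligned to the samples.
#' @param epoch_len Samples per epoch (default 4000).
#' @param n_epochs Target number of epochs per class (default 4).
#' @return Object of class `ms_epochs`: per class a list of sample-index
#'   vectors (each of length `epoch_len`), plus a coverage table with the
#'   available labelled-sample and epoch counts per class.
#' @export
extract_ms_epochs <- function(phases, labels, epoch_len = 4000L,
                              n_epochs = 4L) {
  stopifnot(inherits(phases, "phase_tensor"), inherits(labels, "label_vector"))
  if (epoch_len <= 0L) stop("epoch_len must be positive", call. = FALSE)
  if (length(labels$labels) != ncol(phases$phase))
    stop("label vector not aligned to phase samples", call. = FALSE)
  valid <- apply(phases$valid, 2L, all)
  classes <- seq_len(labels$k)
  epochs <- vector("list", labels$k)
  n_labelled <- integer(labels$k)
  for (c in classes) {
    idx <- which(valid & !is.na(labels$labels) & labels$labels == c)
    n_labelled[c] <- length(idx)
    n_full <- min(n_epochs, length(idx) %/% epoch_len)
    epochs[[c]] <- lapply(seq_len(n_full), function(e)
      idx[((e - 1L) * epoch_len + 1L):(e * epoch_len)])
  }
  coverage <- data.frame(class = classes, n_labelled = n_labelled,
                         n_epochs = vapply(epochs, length, 0L),
                         target = n_epochs)
  structure(list(epochs = epochs, coverage = coverage,
                 epoch_len = as.integer(epoch_len),
                 n_epochs = as.integer(n_epochs)),
            class = "ms_epochs")
}

#' @export
print.ms_epochs <- function(x, ...) {
  cat("<ms_epochs>\n")
  print(x$coverage, row.names = FALSE)
  invisible(x)
}

# PLI matrix over one epoch (index set) of a phase tensor; channels x
# channels, symmetric, zero diagonal. Z is exp(1i * phase) for the epoch.
epoch_pli_matrix <- function(Z) {
  m <- nrow(Z)
  W <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) {
    zi <- Z[i, ]
    for (j in (i + 1L):m) {
      s <- sign(Im(zi * Conj(Z[j, ])))
      W[i, j] <- W[j, i] <- abs(mean(s))
    }
  }
  W
}

#' PLI matrices from a phase tensor and stitched epochs
#'
#' Computes one PLI matrix per (class, epoch) and their element-wise
#' average. This is the computational core of [ms_pli()], exposed so phase
#' tensors constructed directly (e.g. i.i.d. null phases) can be run through
#' the identical code path.
#'
#' @param phases A `phase_tensor`.
#' @param epochs An `ms_epochs` object.
#' @return List with `mean` (averaged matrix), `n_matrices`, and `coverage`.
#' @export
pli_over_epochs <- function(phases, epochs) {
  stopifnot(inherits(phases, "phase_tensor"), inherits(epochs, "ms_epochs"))
  E <- exp(1i * phases$phase)
  m <- nrow(phases$phase)
  acc <- matrix(0, m, m)
  n_mat <- 0L
  for (c in seq_along(epochs$epochs)) {
    for (idx in epochs$epochs[[c]]) {
      acc <- acc + epoch_pli_matrix(E[, idx, drop = FALSE])
      n_mat <- n_mat + 1L
    }
  }
  if (n_mat == 0L)
    stop("no complete epochs for any microstate class (labelled samples: ",
         paste(epochs$coverage$n_labelled, collapse = ", "), ")",
         call. = FALSE)
  list(mean = acc / n_mat, n_matrices = n_mat, coverage = epochs$coverage)
}

#' Microstate-segmented phase lag index (msPLI)
#'
#' Band-pass filters the recording, extracts instantaneous phase with the
#' sliding-window Hilbert transform, stitches the labelled samples of each
#' microstate class into epochs (target 4 epochs x 4000 samples per class),
#' computes one PLI matrix per epoch, and averages all available matrices
#' (target `n_epochs * k`, e.g. 16 for k = 4) into one symmetric
#' connectivity matrix per subject and band.
#'
#' @param rec An [eeg_recording] (unfiltered).
#' @param labels A `label_vector` aligned to the recording.
#' @param band A [band_definition].
#' @param epoch_len,n_epochs Epoch geometry, see [extract_ms_epochs()].
#' @param window_s Hilbert window length in seconds.
#' @param filter_order Butterworth order for the band-pass.
#' @return A `connectivity_matrix` (see [connectivity_matrix()]) with
#'   attributes `n_matrices` and `coverage`.
#' @export
ms_pli <- function(rec, labels, band, epoch_len = 4000L, n_epochs = 4L,
                   window_s = 4, filter_order = 4L) {
  ph <- hilbert_phase(eeg_bandpass(rec, band, filter_order), window_s)
  ep <- extract_ms_epochs(ph, labels, epoch_len, n_epochs)
  res <- pli_over_epochs(ph, ep)
  W <- connectivity_matrix(res$mean, rec$labels, band)
  attr(W, "n_matrices") <- res$n_matrices
  attr(W, "coverage") <- res$coverage
  W
}

#' Connectivity matrix container
#'
#' Validates and wraps a symmetric node x node PLI matrix with values in
#' `[0, 1]` and zero diagonal.
#'
#' @param W Numeric symmetric matrix.
#' @param nodes Node (electrode or ROI) labels.
#' @param band Optional [band_definition].
#' @return Object of class `connectivity_matrix` (a matrix with attributes).
#' @export
connectivity_matrix <- function(W, nodes, band = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("matrix must be square", call. = FALSE)
  if (length(nodes) != nrow(W))
    stop("node labels must match matrix size", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-12)
    stop("connectivity matrix must be symmetric", call. = FALSE)
  if (any(W < -1e-12) || any(W > 1 + 1e-12))
    stop("PLI values must lie in [0, 1]", call. = FALSE)
  if (any(diag(W) != 0)) stop("diagonal must be zero", call. = FALSE)
  W <- (W + t(W)) / 2
  dimnames(W) <- list(nodes, nodes)
  structure(W, class = c("connectivity_matrix", "matrix", "array"),
            band = band)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  b <- attr(x, "band")
  cat(sprintf("<connectivity_matrix> %d nodes (%s); mean off-diagonal %.4f\n",
              nrow(x), if (is.null(b)) "no band" else b$name,
              mean(x[upper.tri(x)])))
  invisible(x)
}

#' Aggregate an electrode-level matrix into regions of interest
#'
#' Each ROI-pair value is the mean PLI over all electrode pairs spanning the
#' two regions; within-ROI pairs do not enter off-diagonal entries and the
#' diagonal stays zero. Channels absent from the map (midline/neck/face in
#' the study layout) are dropped with a message.
#'
#' @param W A `connectivity_matrix` at electrode level.
#' @param roi_map Data frame with columns `channel`, `roi`.
#' @param stat Aggregation statistic, `"mean"` (default) or `"median"`.
#' @return A `connectivity_matrix` over the ROIs (alphabetical order).
#' @export
roi_aggregate <- function(W, roi_map, stat = c("mean", "median")) {
  stopifnot(inherits(W, "connectivity_matrix"))
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else median
  nodes <- rownames(W)
  unmapped <- setdiff(nodes, roi_map$channel)
  if (length(unmapped) > 0L)
    message("roi_aggregate: ignoring unmapped channels: ",
            paste(unmapped, collapse = ", "))
  rois <- sort(unique(roi_map$roi))
  members <- lapply(rois, function(r)
    which(nodes %in% roi_map$channel[roi_map$roi == r]))
  empty <- vapply(members, length, 0L) == 0L
  if (any(empty))
    stop("ROI(s) without any channel present in the matrix: ",
         paste(rois[empty], collapse = ", "), call. = FALSE)
  n <- length(rois)
  R <- matrix(0, n, n)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      R[a, b] <- R[b, a] <- f(W[members[[a]], members[[b]]])
    }
  }
  connectivity_matrix(R, rois, attr(W, "band"))
}

#' Write / read a connectivity matrix as labelled CSV
#' @param W A `connectivity_matrix`.
#' @param path File path.
#' @export
write_connectivity_csv <- function(W, path) {
  write.csv(as.data.frame(unclass(W)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @export
read_connectivity_csv <- function(path) {
  d <- read.csv(path, row.names = 1L, check.names = FALSE)
  connectivity_matrix(as.matrix(d), rownames(d))
}

#' Flatten a connectivity matrix to an edge list
#'
#' @param W A `connectivity_matrix`.
#' @return Data frame with columns `node_i`, `node_j`, `value` (upper
#'   triangle, `i < j`).
#' @export
edge_list <- function(W) {
  stopifnot(inherits(W, "connectivity_matrix"))
  ut <- which(upper.tri(W), arr.ind = TRUE)
  data.frame(node_i = rownames(W)[ut[, 1L]],
             node_j = rownames(W)[ut[, 2L]],
             value = W[ut], stringsAsFactors = FALSE)
}
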