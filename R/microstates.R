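#' Global field power
#'
#' The spatial standard deviation of the scalp map at each sample. GFP peaks
#' mark moments of high signal-to-noise topography and are the samples used
#' for microstate clustering.
#'
#' @param rec An [eeg_recording] with at least two channels.
#' @return Numeric vector, one value (microvolt) per sample.
#' @export
gfp <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L)
    stop("GFP requires at least 2 channels", call. = FALSE)
  m <- nrow(rec$data)
  mu <- colMeans(rec$data)
  sqrt(colSums((rec$data - matrix(mu, m, length(mu), byrow = TRUE))^2) /
         (m - 1L))
}

# Indices of strict local maxima of a series.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
}

# Polarity-invariant (modified) k-means on unit-norm maps.
# maps: channels x n matrix of unit-norm columns. Returns templates
# (channels x k, unit norm), assignment, and explained variance.
modified_kmeans <- function(maps, k, max_iter = 100L, tol = 1e-8) {
  m <- nrow(maps); n <- ncol(maps)
  init <- sample.int(n, k)
  templates <- maps[, init, drop = FALSE]
  ev_old <- -Inf
  assign <- rep(1L, n)
  for (iter in seq_len(max_iter)) {
    proj <- crossprod(templates, maps)        # k x n, t_c . x_i
    assign <- max.col(t(proj^2), ties.method = "first")
    for (c in seq_len(k)) {
      sel <- assign == c
      if (!any(sel)) {  # empty cluster: reseed at worst-fitted map
        fit <- proj[cbind(assign, seq_len(n))]^2
        templates[, c] <- maps[, which.min(fit)]
        next
      }
      M <- maps[, sel, drop = FALSE]
      # dominant eigenvector of M M^T: polarity-invariant mean map
      S <- tcrossprod(M)
      e <- eigen(S, symmetric = TRUE)
      v <- e$vectors[, 1L]
      templates[, c] <- v / sqrt(sum(v^2))
    }
    proj <- crossprod(templates, maps)
    ev <- sum(proj[cbind(assign, seq_len(n))]^2) / n
    if (ev - ev_old < tol) break
    ev_old <- ev
  }
  list(templates = templates, assignment = assign, ev = ev)
}

# Fit k-means at GFP peaks for any k >= 1; internal (select_k needs k = 1).
fit_kmeans_at_peaks <- function(rec, k, n_restarts, seed) {
  g <- gfp(rec)
  pk <- local_maxima(g)
  pk <- pk[g[pk] > 0]
  if (length(pk) < 10L * k)
    stop(sprintf("only %d GFP peaks for k = %d (need >= %d)",
                 length(pk), k, 10L * k), call. = FALSE)
  maps <- rec$data[, pk, drop = FALSE]
  nrm <- sqrt(colSums(maps^2))
  maps <- maps / matrix(nrm, nrow(maps), ncol(maps), byrow = TRUE)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- modified_kmeans(maps, k)
    if (is.null(best) || fit$ev > best$ev) best <- fit
  }
  best$maps <- maps
  best$peaks <- pk
  best
}

#' Fit microstate templates by polarity-invariant k-means
#'
#' Scalp maps at local GFP maxima are normalised to unit norm and clustered
#' with a modified k-means whose assignment uses squared spatial projection
#' (so a map and its polarity reversal are equivalent) and whose cluster
#' update is the dominant eigenvector of the within-cluster scatter. The
#' best of `n_restarts` seeded restarts by explained variance is kept.
#'
#' @param rec An [eeg_recording].
#' @param k Number of microstate classes, `>= 2`.
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed; the fit is deterministic given it.
#' @return Object of class `microstate_model`: `templates` (channels x k,
#'   unit norm), `k`, `gev` (global explained variance at GFP peaks in
#'   `[0, 1]`), `labels` (channel labels).
#' @export
fit_microstates <- function(rec, k, n_restarts = 10L, seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(k) || k < 2L) stop("k must be >= 2", call. = FALSE)
  k <- as.integer(k)
  best <- fit_kmeans_at_peaks(rec, k, n_restarts, seed)
  structure(list(templates = best$templates, k = k, gev = best$ev,
                 labels = rec$labels),
            class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> k = %d, GEV = %.3f, %d channels\n",
              x$k, x$gev, nrow(x$templates)))
  invisible(x)
}

#' Select the number of microstates by the Krzanowski-Lai criterion
#'
#' For each candidate `k` the within-cluster dispersion `W_k` (residual map
#' variance at GFP peaks under the polarity-invariant fit) is computed and
#' the Krzanowski-Lai index
#' `KL(k) = |DIFF(k)| / |DIFF(k+1)|` with
#' `DIFF(k) = (k-1)^(2/m) W_(k-1) - k^(2/m) W_k` (`m` = number of channels)
#' is maximised over `k_range`. If the KL curve is degenerate (no finite
#' interior maximum, as for single-template data), the smallest candidate is
#' returned -- the documented fallback.
#'
#' @param rec An [eeg_recording].
#' @param k_range Integer vector of candidate `k` (>= 3 values, min >= 2).
#' @param seed Integer seed.
#' @param n_restarts Restarts per candidate fit (default 5).
#' @return The selected `k` (integer), with the KL curve as attribute `"kl"`.
#' @export
select_k <- function(rec, k_range, seed = 1L, n_restarts = 5L) {
  stopifnot(inherits(rec, "eeg_recording"))
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3L)
    stop("k_range must contain at least 3 values", call. = FALSE)
  if (min(k_range) < 2L) stop("candidate k must be >= 2", call. = FALSE)
  m <- nrow(rec$data)
  ks <- (min(k_range) - 1L):(max(k_range) + 1L)
  W <- vapply(ks, function(k) {
    fit <- fit_kmeans_at_peaks(rec, k, n_restarts, seed + k)
    # residual dispersion of unit-norm maps under polarity-invariant fit
    proj <- crossprod(fit$templates, fit$maps)
    sum(1 - proj[cbind(fit$assignment, seq_len(ncol(fit$maps)))]^2)
  }, numeric(1))
  names(W) <- ks
  diffk <- function(k) {
    (k - 1)^(2 / m) * W[as.character(k - 1)] - k^(2 / m) * W[as.character(k)]
  }
  kl <- vapply(k_range, function(k) {
    d1 <- abs(diffk(k)); d2 <- abs(diffk(k + 1L))
    if (!is.finite(d1) || !is.finite(d2) || d2 == 0) NA_real_ else d1 / d2
  }, numeric(1))
  names(kl) <- k_range
  out <- if (all(!is.finite(kl))) min(k_range) else
    k_range[which.max(kl)]
  attr(out, "kl") <- kl
  out
}

#' Assign every sample to its best-matching microstate template
#'
#' Each sample's map is labelled by the template with the largest absolute
#' spatial (Pearson) correlation -- polarity-invariant, so negating the
#' recording leaves the labels unchanged. Samples with an all-constant map
#' (zero spatial variance) are unassigned (`NA`). Segments shorter than
#' `min_dur_s` are then merged into the preceding segment to avoid
#' single-sample label flicker.
#'
#' @param rec An [eeg_recording] whose channels match the model.
#' @param model A [fit_microstates()] model.
#' @param min_dur_s Minimum segment duration in seconds (default 0.03);
#'   set to 0 to disable smoothing.
#' @return Object of class `label_vector`: integer labels in `1..k` (or
#'   `NA`), plus `k` and the sampling rate.
#' @export
backfit <- function(rec, model, min_dur_s = 0.03) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(model, "microstate_model"))
  if (nrow(rec$data) != nrow(model$templates) ||
      !identical(rec$labels, model$labels))
    stop("recording channels do not match the microstate model",
         call. = FALSE)
  X <- rec$data
  m <- nrow(X)
  Xc <- X - matrix(colMeans(X), m, ncol(X), byrow = TRUE)
  sdx <- sqrt(colSums(Xc^2))
  Tc <- model$templates -
    matrix(colMeans(model$templates), m, model$k, byrow = TRUE)
  Tc <- Tc / matrix(sqrt(colSums(Tc^2)), m, model$k, byrow = TRUE)
  corr <- crossprod(Tc, Xc)                   # k x T, unnormalised by sdx
  labels <- max.col(t(abs(corr)), ties.method = "first")
  labels[sdx <= 1e-12] <- NA_integer_
  min_len <- floor(min_dur_s * rec$rate)
  if (min_len > 1L) labels <- merge_short_runs(labels, min_len)
  structure(list(labels = as.integer(labels), k = model$k, rate = rec$rate),
            class = "label_vector")
}

# Merge runs shorter than min_len into the previous run (the first run, if
# short, joins the following one). Iterates until stable. NA runs are kept.
merge_short_runs <- function(labels, min_len, max_pass = 10L) {
  for (pass in seq_len(max_pass)) {
    r <- rle(labels)
    short <- which(r$lengths < min_len & !is.na(r$values))
    if (length(short) == 0L || length(r$lengths) == 1L) break
    for (i in short) {
      r$values[i] <- if (i > 1L) r$values[i - 1L] else r$values[i + 1L]
    }
    labels <- inverse.rle(r)
  }
  labels
}

#' Construct a label vector directly
#'
#' Wraps an integer per-sample class sequence (e.g. a simulated ground-truth
#' sequence) as a `label_vector` so it can gate [ms_pli()] epoch extraction.
#'
#' @param labels Integer vector of classes in `1..k`, `NA` for unassigned.
#' @param k Number of classes.
#' @param rate Sampling rate in Hz.
#' @return A `label_vector`.
#' @export
label_vector <- function(labels, k, rate) {
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > k, na.rm = TRUE))
    stop("labels must lie in 1..k or be NA", call. = FALSE)
  structure(list(labels = labels, k = as.integer(k), rate = rate),
            class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  tab <- table(factor(x$labels, levels = seq_len(x$k)), useNA = "ifany")
  cat(sprintf("<label_vector> %d samples, k = %d; coverage: %s\n",
              length(x$labels), x$k,
              paste(sprintf("%s:%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Write / read a microstate model as JSON
#' @param model A `microstate_model`.
#' @param path File path.
#' @export
write_microstate_model <- function(model, path) {
  jsonlite::write_json(list(templates = model$templates, k = model$k,
                            gev = model$gev, labels = model$labels),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_microstate_model
#' @export
read_microstate_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(templates = x$templates, k = as.integer(x$k),
                 gev = x$gev, labels = x$labels),
            class = "microstate_model")
}
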