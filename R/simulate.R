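#' Simulation configuration for synthetic EEG cohorts
#'
#' Defines a seeded, desk-scale synthetic cohort: band-limited oscillatory
#' signals with controllable cross-channel phase-lag coupling, switching
#' spatial topographies (microstate structure), and a covariate table in
#' which a planted monotone association links the apathy score to coupling
#' strength at chosen edges, with confounds correlated to both. Defaults
#' (32 channels, 250 Hz, 180 s) are scaled down from the study recordings
#' (256 channels, 1000 Hz, 12 min), which remain configurable.
#'
#' @param n_subjects Number of subjects (cohort generation requires >= 4).
#' @param n_channels Number of channels; if 32 (default) the packaged
#'   montage supplies labels and positions.
#' @param rate Sampling rate in Hz (default 250).
#' @param duration Recording length in seconds (default 180).
#' @param bands Analysis bands, default [analysis_bands()].
#' @param k Number of microstate classes (default 4).
#' @param templates Channels x k matrix of unit-norm topographies; default
#'   smooth orthonormal maps over the montage positions.
#' @param markov_transition k x k row-stochastic matrix giving the
#'   conditional distribution of the next class at a switch (diagonal 0 by
#'   default: uniform over the other classes).
#' @param mean_dwell Mean microstate dwell time in seconds (default 0.08,
#'   the conventional 50-100 ms microstate timescale).
#' @param min_dwell Minimum dwell time in seconds (default 0.03): dwell
#'   times are `min_dwell` plus a geometric tail with overall mean
#'   `mean_dwell`, mirroring the refractory character of empirical
#'   microstate duration distributions.
#' @param coupling_spec Data frame with columns `ch_i`, `ch_j` (labels),
#'   `band` (name in `bands`), `lag` (radians), `strength` in `[0, 1]`.
#' @param effect_spec Data frame with columns `ch_i`, `ch_j`, `band`,
#'   `slope`: coupling strength at that edge becomes
#'   `strength + slope * z(AES)`, clipped to `[0, 1]` (negative slope
#'   plants the "higher apathy, lower connectivity" direction).
#' @param confound_spec Named numeric vector of latent correlations of the
#'   confounds (`age`, `sex`, `education`, `mms`, `led`) with the apathy
#'   score.
#' @param ms_amp Amplitude (microvolt) of the microstate topography
#'   component.
#' @param ms_band Length-2 numeric, carrier band of the microstate
#'   component in Hz (default 8-10).
#' @param couple_amp Amplitude of coupled-pair oscillations.
#' @param bg_amp Amplitude of per-channel independent background
#'   oscillations (one per analysis band).
#' @param noise_sd White-noise standard deviation in microvolt.
#' @param carrier `"noise"` (band-pass filtered Gaussian noise, realistic
#'   phase diffusion) or `"tone"` (constant frequency at band centre,
#'   analytically exact lags).
#' @param aes_range Integer range of the apathy score (default 18-39, the
#'   study's observed range).
#' @param aes_mean,aes_sd Population mean and SD used to standardise the
#'   apathy score inside the strength-effect map (defaults 26.2 and 6.2).
#' @param seed Integer master seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 8L,
                       n_channels = 32L,
                       rate = 250,
                       duration = 180,
                       bands = analysis_bands(),
                       k = 4L,
                       templates = NULL,
                       markov_transition = NULL,
                       mean_dwell = 0.08,
                       min_dwell = 0.03,
                       coupling_spec = NULL,
                       effect_spec = NULL,
                       confound_spec = c(age = 0.25, sex = 0.10,
                                         education = -0.20, mms = -0.25,
                                         led = 0.20),
                       ms_amp = 20,
                       ms_band = c(8, 10),
                       couple_amp = 5,
                       bg_amp = 1.5,
                       noise_sd = 1.5,
                       carrier = c("noise", "tone"),
                       aes_range = c(18L, 39L),
                       aes_mean = 26.2,
                       aes_sd = 6.2,
                       seed = 1L) {
  carrier <- match.arg(carrier)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (min_dwell < 0 || min_dwell >= mean_dwell)
    stop("need 0 <= min_dwell < mean_dwell", call. = FALSE)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (n_channels == 32L) {
    mon <- default_montage()
  } else {
    mon <- list(labels = sprintf("ch%02d", seq_len(n_channels)),
                positions = cbind(cos(seq_len(n_channels)),
                                  sin(seq_len(n_channels))))
  }
  if (is.null(templates))
    templates <- default_templates(k, mon$positions)
  templates <- as.matrix(templates)
  if (nrow(templates) != n_channels || ncol(templates) != k)
    stop("templates must be n_channels x k", call. = FALSE)
  nrm <- sqrt(colSums(templates^2))
  if (any(abs(nrm - 1) > 1e-8))
    stop("template vectors must be unit norm", call. = FALSE)
  if (is.null(markov_transition)) {
    markov_transition <- matrix(1 / (k - 1), k, k)
    diag(markov_transition) <- 0
  }
  markov_transition <- as.matrix(markov_transition)
  if (nrow(markov_transition) != k || ncol(markov_transition) != k ||
      any(markov_transition < 0) ||
      any(abs(rowSums(markov_transition) - 1) > 1e-8))
    stop("markov_transition must be a k x k row-stochastic matrix",
         call. = FALSE)
  band_names <- vapply(bands, `[[`, "", "name")
  check_edge_spec <- function(spec, need) {
    if (is.null(spec)) return(NULL)
    spec <- as.data.frame(spec)
    if (!all(need %in% names(spec)))
      stop("edge spec needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    bad <- setdiff(c(spec$ch_i, spec$ch_j), mon$labels)
    if (length(bad) > 0L)
      stop("edge spec references nonexistent channel(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    if (!all(spec$band %in% band_names))
      stop("edge spec references unknown band(s)", call. = FALSE)
    spec
  }
  coupling_spec <- check_edge_spec(coupling_spec,
                                   c("ch_i", "ch_j", "band", "lag",
                                     "strength"))
  if (!is.null(coupling_spec) &&
      (any(coupling_spec$strength < 0) || any(coupling_spec$strength > 1)))
    stop("coupling strengths must lie in [0, 1]", call. = FALSE)
  effect_spec <- check_edge_spec(effect_spec,
                                 c("ch_i", "ch_j", "band", "slope"))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_channels = as.integer(n_channels),
                 rate = rate, duration = duration, bands = bands,
                 k = as.integer(k), templates = templates,
                 markov_transition = markov_transition,
                 mean_dwell = mean_dwell, min_dwell = min_dwell,
                 coupling_spec = coupling_spec, effect_spec = effect_spec,
                 confound_spec = confound_spec,
                 ms_amp = ms_amp, ms_band = ms_band,
                 couple_amp = couple_amp, bg_amp = bg_amp,
                 noise_sd = noise_sd, carrier = carrier,
                 aes_range = as.integer(aes_range),
                 aes_mean = aes_mean, aes_sd = aes_sd,
                 labels = mon$labels, positions = mon$positions,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Smooth orthonormal topographies from low-order spatial polynomials of the
# sensor positions (anterior-posterior and left-right gradients first), via
# QR orthonormalisation. Deterministic.
default_templates <- function(k, positions) {
  x <- positions[, 1L]; y <- positions[, 2L]
  basis <- cbind(y, x, x * y, x^2 - y^2, rep(1, length(x)), x^2 + y^2,
                 x^3, y^3)
  if (k > ncol(basis)) stop("too many templates requested", call. = FALSE)
  q <- qr.Q(qr(basis))[, seq_len(k), drop = FALSE]
  q / matrix(sqrt(colSums(q^2)), nrow(q), k, byrow = TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d subjects, %d channels @ %g Hz, %g s, ",
                     "k = %d, carrier = %s, seed = %d\n"),
              x$n_subjects, x$n_channels, x$rate, x$duration, x$k,
              x$carrier, x$seed))
  invisible(x)
}

# Microstate label sequence: geometric dwell times (mean mean_dwell*rate)
# with class switches drawn from the transition matrix.
sim_label_sequence <- function(config, n_samples) {
  min_samp <- round(config$min_dwell * config$rate)
  # dwell = min_samp + 1 + geometric tail; expectation mean_dwell * rate
  p_tail <- 1 / ((config$mean_dwell - config$min_dwell) * config$rate)
  k <- config$k
  labels <- integer(n_samples)
  state <- sample.int(k, 1L)
  t <- 1L
  while (t <= n_samples) {
    dwell <- min_samp + rgeom(1L, p_tail) + 1L
    end <- min(t + dwell - 1L, n_samples)
    labels[t:end] <- state
    state <- sample.int(k, 1L, prob = config$markov_transition[state, ])
    t <- end + 1L
  }
  labels
}

# Complex narrowband unit-amplitude carrier in `band` (length-2 Hz).
# "noise": analytic signal of band-pass filtered white noise, amplitude
# normalised away (pure phase process with realistic diffusion).
# "tone": constant frequency at the band centre, random initial phase.
sim_carrier <- function(n_samples, rate, band, carrier) {
  if (carrier == "tone") {
    f0 <- mean(band)
    phi0 <- runif(1L, -pi, pi)
    return(exp(1i * (2 * pi * f0 * seq_len(n_samples) / rate + phi0)))
  }
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n_samples + 2L * rate))
  x <- x[(rate + 1L):(rate + n_samples)]        # drop filter transients
  a <- analytic_signal(x)
  a / pmax(Mod(a), 1e-12)
}

#' Generate one subject's synthetic EEG
#'
#' The recording is assembled as (i) the active microstate template scaled
#' by a band-limited carrier, (ii) per-channel independent background
#' oscillations in each analysis band, (iii) coupled channel pairs sharing
#' a narrowband carrier with a fixed phase lag, mixed in proportion to the
#' coupling strength (`s` parts lagged shared carrier, `1 - s` parts
#' independent carrier), and (iv) white sensor noise. Effect edges have
#' `s = strength + slope * z(AES)`, clipped to `[0, 1]`. Deterministic
#' given the config seed and subject index.
#'
#' @param config A [sim_config()].
#' @param subject_index Positive integer, decorrelates per-subject seeds.
#' @param apathy_score AES value used by the effect edges.
#' @return List with `recording` (an [eeg_recording]) and `truth`
#'   (microstate label sequence, per-edge realised coupling strengths).
#' @export
generate_subject_eeg <- function(config, subject_index, apathy_score) {
  stopifnot(inherits(config, "sim_config"))
  set.seed((config$seed + 104729L * as.integer(subject_index)) %%
             .Machine$integer.max)
  n <- round(config$duration * config$rate)
  m <- config$n_channels
  labels_seq <- sim_label_sequence(config, n)
  data <- matrix(0, m, n)

  if (config$ms_amp > 0) {
    a <- Re(sim_carrier(n, config$rate, config$ms_band, config$carrier))
    data <- data + config$ms_amp *
      config$templates[, labels_seq, drop = FALSE] *
      matrix(a, m, n, byrow = TRUE)
  }

  if (config$bg_amp > 0) {
    for (b in config$bands) {
      for (ch in seq_len(m)) {
        data[ch, ] <- data[ch, ] + config$bg_amp *
          Re(sim_carrier(n, config$rate, c(b$low, b$high), config$carrier))
      }
    }
  }

  spec <- config$coupling_spec
  realised <- NULL
  if (!is.null(spec) && nrow(spec) > 0L) {
    z_aes <- (apathy_score - config$aes_mean) / config$aes_sd
    strength <- spec$strength
    if (!is.null(config$effect_spec) && nrow(config$effect_spec) > 0L) {
      for (r in seq_len(nrow(config$effect_spec))) {
        ef <- config$effect_spec[r, ]
        hit <- which(spec$ch_i == ef$ch_i & spec$ch_j == ef$ch_j &
                       spec$band == ef$band)
        if (length(hit) == 0L)
          stop("effect edge not present in coupling_spec: ",
               ef$ch_i, "-", ef$ch_j, " ", ef$band, call. = FALSE)
        strength[hit] <- strength[hit] + ef$slope * z_aes
      }
    }
    strength <- pmin(1, pmax(0, strength))
    band_lu <- lapply(config$bands, function(b) c(b$low, b$high))
    names(band_lu) <- vapply(config$bands, `[[`, "", "name")
    for (r in seq_len(nrow(spec))) {
      i <- match(spec$ch_i[r], config$labels)
      j <- match(spec$ch_j[r], config$labels)
      z <- sim_carrier(n, config$rate, band_lu[[spec$band[r]]],
                       config$carrier)
      z_ind <- sim_carrier(n, config$rate, band_lu[[spec$band[r]]],
                           config$carrier)
      s <- strength[r]
      data[i, ] <- data[i, ] + config$couple_amp * Re(z)
      data[j, ] <- data[j, ] + config$couple_amp *
        (s * Re(z * exp(-1i * spec$lag[r])) + (1 - s) * Re(z_ind))
    }
    realised <- data.frame(spec[, c("ch_i", "ch_j", "band", "lag")],
                           strength = strength)
  }

  if (config$noise_sd > 0)
    data <- data + matrix(rnorm(m * n, sd = config$noise_sd), m, n)

  list(recording = eeg_recording(data, config$rate, config$labels,
                                 config$positions),
       truth = list(labels = labels_seq, coupling = realised,
                    apathy_score = apathy_score))
}

# Latent Gaussian copula draw: AES plus confounds with the configured
# correlations to the AES latent (confounds mutually correlated only
# through it). Returns the n x (1 + n_conf) latent matrix.
copula_latents <- function(n, confound_spec) {
  r <- confound_spec
  p <- length(r) + 1L
  R <- diag(p)
  R[1L, -1L] <- r
  R[-1L, 1L] <- r
  for (a in seq_along(r))
    for (b in seq_along(r))
      if (a != b) R[a + 1L, b + 1L] <- r[a] * r[b]
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-10)
    stop("confound_spec correlations are not jointly feasible",
         call. = FALSE)
  L <- ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors)
  Z <- matrix(rnorm(n * p), n, p) %*% L
  colnames(Z) <- c("aes", names(r))
  Z
}

# Marginal transforms producing the demographic covariate table from the
# latents. AES is right-skewed over aes_range (beta quantile transform);
# the remaining marginals follow the study cohort's summary statistics.
covariates_from_latents <- function(Z, aes_range) {
  u <- pnorm(Z[, "aes"])
  aes <- as.integer(round(aes_range[1L] +
                            diff(aes_range) * qbeta(u, 1.15, 1.8)))
  n <- nrow(Z)
  data.frame(
    id = sprintf("S%03d", seq_len(n)),
    aes = aes,
    age = round(68.0 + 7.7 * Z[, "age"]),
    sex = as.integer(pnorm(Z[, "sex"]) < 0.35),      # 1 = female, 35%
    education = pmax(8, round(14.6 + 3.0 * Z[, "education"])),
    mms = pmin(30L, as.integer(round(28.8 + 1.0 * Z[, "mms"]))),
    led = round(exp(log(569) + 0.55 * Z[, "led"]), 1),
    bdi = pmax(0, round(7.4 + 4.3 * rnorm(n))),
    updrs_iii = pmax(0, round(15.4 + 11.2 * rnorm(n))),
    stringsAsFactors = FALSE)
}

# Five initiation-test z-scores: fluency-type tests load negatively on the
# apathy latent (higher apathy, worse initiation), timed tests (TMT-A,
# Stroop naming) positively (higher = slower = worse). The default loading
# puts the composite's Cronbach alpha near the 0.70 acceptability bound.
initiation_scores <- function(z_aes, loading = 0.65) {
  n <- length(z_aes)
  res <- sqrt(1 - loading^2)
  data.frame(
    phonemic_fluency = -loading * z_aes + res * rnorm(n),
    semantic_fluency = -loading * z_aes + res * rnorm(n),
    five_point       = -loading * z_aes + res * rnorm(n),
    tmt_a            =  loading * z_aes + res * rnorm(n),
    stroop_naming    =  loading * z_aes + res * rnorm(n))
}

#' Generate a synthetic cohort of EEG recordings with covariates
#'
#' Apathy scores are drawn from a right-skewed distribution over the
#' configured range; the confounds (age, sex, education, MMS, LED) are
#' correlated with the apathy latent through a Gaussian copula; five
#' initiation-test z-scores load on the same latent. Every subject's EEG is
#' generated by [generate_subject_eeg()], so planted effect edges couple
#' the cohort's apathy scores to connectivity.
#'
#' @param config A [sim_config()] with `n_subjects >= 4`.
#' @return List with `recordings` (list of [eeg_recording]), `cohort`
#'   (covariate data frame), and `truth` (per-subject ground truth,
#'   including the planted slopes).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_subjects < 4L)
    stop("n_subjects must be >= 4 (residualisation on 5 confounds)",
         call. = FALSE)
  set.seed(config$seed)
  Z <- copula_latents(config$n_subjects, config$confound_spec)
  cohort <- covariates_from_latents(Z, config$aes_range)
  cohort <- cbind(cohort, initiation_scores(Z[, "aes"]))
  recs <- vector("list", config$n_subjects)
  truths <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    out <- generate_subject_eeg(config, s, cohort$aes[s])
    recs[[s]] <- out$recording
    truths[[s]] <- out$truth
  }
  list(recordings = recs, cohort = cohort,
       truth = list(subjects = truths, effect_spec = config$effect_spec,
                    confound_spec = config$confound_spec))
}

#' Generate a statistics-level cohort of connectivity values
#'
#' A fast generator that emits per-subject msPLI edge values directly (no
#' EEG synthesis), for calibration studies of the statistical layer at
#' realistic cohort and family sizes. Log-connectivity at every edge is
#' Gaussian around an edge-specific baseline with loadings on the confound
#' latents; planted edges additionally correlate with the apathy latent at
#' `effect_r` (negative plants the "higher apathy, lower connectivity"
#' direction).
#'
#' @param n_subjects Cohort size (>= 4).
#' @param rois Character vector of node names (default the packaged 22-ROI
#'   layout).
#' @param effect_edges Character vector of planted edge names, formatted
#'   `"roiA--roiB"` with the two ROIs in sorted order; `NULL` for a global
#'   null cohort.
#' @param effect_r Latent correlation between apathy and log-connectivity
#'   at planted edges (default -0.9, a strong planted effect: confound
#'   correlations with both sides attenuate the recoverable partial
#'   association).
#' @param confound_spec As in [sim_config()].
#' @param confound_loading Loading of each confound latent on every edge's
#'   log-connectivity (default 0.1).
#' @param log_mu,log_sd Baseline mean and SD of log-connectivity (defaults
#'   -2 and 0.3, i.e. msPLI around 0.14).
#' @param seed Integer seed.
#' @return List with `cohort` (covariate data frame), `edges` (subjects x
#'   edges matrix of msPLI values, columns named `"roiA--roiB"`), and
#'   `truth` (planted edge names and `effect_r`).
#' @export
generate_connectivity_cohort <- function(n_subjects = 40L,
                                         rois = sort(unique(default_roi_map()$roi)),
                                         effect_edges = NULL,
                                         effect_r = -0.9,
                                         confound_spec = c(age = 0.25,
                                                           sex = 0.10,
                                                           education = -0.20,
                                                           mms = -0.25,
                                                           led = 0.20),
                                         confound_loading = 0.1,
                                         log_mu = -2, log_sd = 0.3,
                                         seed = 1L) {
  if (n_subjects < 4L) stop("n_subjects must be >= 4", call. = FALSE)
  set.seed(as.integer(seed))
  Z <- copula_latents(n_subjects, confound_spec)
  cohort <- covariates_from_latents(Z, c(18L, 39L))
  cohort <- cbind(cohort, initiation_scores(Z[, "aes"]))
  pairs <- utils::combn(sort(rois), 2L)
  edge_names <- paste(pairs[1L, ], pairs[2L, ], sep = "--")
  if (!is.null(effect_edges)) {
    missing <- setdiff(effect_edges, edge_names)
    if (length(missing) > 0L)
      stop("unknown effect edge(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  n_edges <- length(edge_names)
  conf_part <- rowSums(Z[, -1L, drop = FALSE]) * confound_loading
  logv <- matrix(0, n_subjects, n_edges, dimnames = list(cohort$id,
                                                         edge_names))
  for (e in seq_len(n_edges)) {
    planted <- !is.null(effect_edges) && edge_names[e] %in% effect_edges
    r <- if (planted) effect_r else 0
    eps <- rnorm(n_subjects)
    logv[, e] <- log_mu + conf_part +
      log_sd * (r * Z[, "aes"] + sqrt(1 - r^2) * eps)
  }
  edges <- exp(logv)
  edges[edges >= 1] <- 0.999
  list(cohort = cohort, edges = edges,
       truth = list(effect_edges = effect_edges, effect_r = effect_r))
}
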