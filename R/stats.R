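#' Square-root transform of apathy scores
#'
#' The apathy total score is right-skewed; the square root is the variance
#' stabilising transform applied before normality checking. Being monotone,
#' it leaves every rank-based (Spearman) result unchanged.
#'
#' @param aes Numeric vector of non-negative scores.
#' @return Element-wise square roots.
#' @export
sqrt_transform_aes <- function(aes) {
  if (any(!is.finite(aes)) || any(aes < 0))
    stop("apathy scores must be non-negative and finite", call. = FALSE)
  sqrt(aes)
}

#' Lilliefors (Kolmogorov-Smirnov) normality test
#'
#' KS test against a normal with estimated mean and SD, with the Lilliefors
#' correction for the estimation (via `nortest::lillie.test`).
#'
#' @param x Numeric sample, `n >= 5`, non-constant.
#' @return List with `statistic` and `p.value`.
#' @export
lilliefors_test <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5L) stop("need at least 5 observations", call. = FALSE)
  if (sd(x) == 0) stop("constant sample: normality undefined", call. = FALSE)
  t <- nortest::lillie.test(x)
  list(statistic = unname(t$statistic), p.value = unname(t$p.value))
}

# Cronbach's alpha of an items matrix (subjects x items).
cronbach_alpha <- function(X) {
  k <- ncol(X)
  (k / (k - 1)) * (1 - sum(apply(X, 2L, var)) / var(rowSums(X)))
}

#' Composite initiation score with internal consistency
#'
#' Each test variable is z-transformed across subjects; variables for which
#' smaller raw values indicate good performance are sign-reversed; the
#' oriented z-scores are averaged into the composite. Cronbach's alpha of
#' the oriented z-matrix is reported and the composite is flagged when
#' alpha falls below 0.70 (the conventional acceptability bound).
#'
#' @param cohort Data frame containing the test columns.
#' @param tests Character vector of test column names (>= 2).
#' @param reverse Logical vector along `tests`: `TRUE` for
#'   smaller-is-better variables (e.g. timed tests).
#' @return List with `score` (per subject), `alpha`, and `acceptable`
#'   (`alpha >= 0.70`).
#' @export
build_initiation_score <- function(cohort,
                                   tests = c("phonemic_fluency",
                                             "semantic_fluency",
                                             "five_point", "tmt_a",
                                             "stroop_naming"),
                                   reverse = c(FALSE, FALSE, FALSE,
                                               TRUE, TRUE)) {
  stopifnot(length(tests) >= 2L, length(reverse) == length(tests))
  if (!all(tests %in% names(cohort)))
    stop("missing test column(s): ",
         paste(setdiff(tests, names(cohort)), collapse = ", "),
         call. = FALSE)
  X <- as.matrix(cohort[, tests])
  if (nrow(X) < 3L) stop("need at least 3 subjects", call. = FALSE)
  sds <- apply(X, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance test variable(s): ",
         paste(tests[sds == 0], collapse = ", "), call. = FALSE)
  Z <- scale(X)
  Z[, reverse] <- -Z[, reverse, drop = FALSE]
  alpha <- cronbach_alpha(Z)
  list(score = rowMeans(Z), alpha = alpha, acceptable = alpha >= 0.70)
}

#' Residualise connectivity values on confounds
#'
#' For every edge, an ordinary least-squares regression of the
#' (log-transformed) connectivity value on the confounds plus an intercept
#' is fitted; the residuals carry the connectivity variation unexplained by
#' the confounds and are what enters the correlation analysis.
#'
#' @param values Numeric matrix, subjects x edges (already transformed).
#' @param confounds Data frame of confound columns (one row per subject);
#'   sex may be a 0/1 numeric.
#' @return Matrix of residuals with the dimensions of `values`.
#' @export
residualize <- function(values, confounds) {
  values <- as.matrix(values)
  confounds <- as.data.frame(confounds)
  n <- nrow(values)
  if (nrow(confounds) != n)
    stop("confounds and values disagree on subject count", call. = FALSE)
  if (n <= ncol(confounds) + 1L)
    stop("need more subjects than confounds + 1", call. = FALSE)
  X <- cbind(`(intercept)` = 1, as.matrix(confounds))
  if (any(!is.finite(X))) stop("non-finite confound values", call. = FALSE)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("collinear confound column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  res <- qr.resid(q, values)
  dimnames(res) <- dimnames(values)
  res
}

# Column-wise mid-ranks, scaled to zero mean / unit norm (so Spearman rho
# is a plain cross-product).
scaled_ranks <- function(X) {
  R <- apply(as.matrix(X), 2L, rank)
  R <- scale(R, center = TRUE, scale = FALSE)
  nrm <- sqrt(colSums(R^2))
  nrm[nrm == 0] <- 1
  sweep(R, 2L, nrm, "/")
}

#' Edge-wise Spearman correlation with an outcome
#'
#' Spearman rank correlation of each edge's (residualised) connectivity
#' with the outcome, ties mid-ranked, with the two-sided t-approximation
#' p-value (the same approximation `stats::cor.test` uses for tied data).
#'
#' @param values Numeric matrix, subjects x edges.
#' @param outcome Numeric outcome (e.g. square-root AES or the initiation
#'   composite), `n >= 5`, non-constant.
#' @return Data frame with columns `edge`, `rho`, `p_uncorrected`, `n`.
#' @export
edge_spearman <- function(values, outcome) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 5L) stop("need at least 5 subjects", call. = FALSE)
  if (length(outcome) != n)
    stop("outcome length must match subject count", call. = FALSE)
  if (sd(outcome) == 0) stop("constant outcome", call. = FALSE)
  rho <- drop(crossprod(scaled_ranks(values), scaled_ranks(outcome)))
  rho <- pmin(1, pmax(-1, rho))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * pt(-abs(tstat), n - 2)
  data.frame(edge = colnames(values) %||% as.character(seq_along(rho)),
             rho = rho, p_uncorrected = p, n = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Max-statistic permutation correction for edge-wise correlations
#'
#' The outcome is shuffled across subjects `n_perm` times; for each
#' permutation the per-edge `|rho|` is recomputed and its maximum over the
#' edge family stored. The corrected p-value of an edge is
#' `(1 + #\{permutation maxima >= observed |rho|\}) / (n_perm + 1)`, which
#' controls the family-wise error rate and never returns a zero p-value.
#'
#' @inheritParams edge_spearman
#' @param n_perm Number of permutations (>= 100; the study-scale default
#'   is 10000).
#' @param seed Integer seed for the permutation stream.
#' @return Numeric vector of corrected p-values, one per edge, with the
#'   permutation maxima as attribute `"max_null"`.
#' @export
permutation_correct <- function(values, outcome, n_perm = 10000L,
                                seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  values <- as.matrix(values)
  n <- nrow(values)
  Rv <- scaled_ranks(values)
  ro <- drop(scaled_ranks(outcome))
  obs <- abs(drop(crossprod(Rv, ro)))
  set.seed(as.integer(seed))
  maxima <- numeric(n_perm)
  chunk <- 500L
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    P <- vapply(seq_len(b), function(i) ro[sample.int(n)], numeric(n))
    maxima[done + seq_len(b)] <- apply(abs(crossprod(Rv, P)), 2L, max)
    done <- done + b
  }
  p <- vapply(obs, function(o) (1 + sum(maxima >= o)) / (n_perm + 1),
              numeric(1))
  attr(p, "max_null") <- maxima
  p
}

#' Residualised Spearman analysis of connectivity against an outcome
#'
#' The full inferential chain for one band: log-transform the msPLI edge
#' values, residualise on the confounds, square-root transform the apathy
#' outcome (ranks, and hence every rho, are unchanged by both monotone
#' transforms -- they matter only for the normality checks), then edge-wise
#' Spearman correlation with max-statistic permutation correction.
#'
#' @param edges Numeric matrix, subjects x edges, of msPLI values in
#'   `(0, 1)`; column names identify the edges.
#' @param cohort Covariate data frame (needs the outcome and confound
#'   columns).
#' @param outcome Column name of the outcome, default `"aes"`; the
#'   square-root transform is applied only to `"aes"`.
#' @param confounds Confound column names (default age, sex, education,
#'   MMS, LED).
#' @param n_perm,seed Passed to [permutation_correct()].
#' @param log_transform Log-transform the edge values first (default TRUE).
#' @return Data frame with `edge`, `rho`, `p_uncorrected`, `p_corrected`,
#'   `n`, sorted as the input columns.
#' @export
correlate_edges <- function(edges, cohort, outcome = "aes",
                            confounds = c("age", "sex", "education",
                                          "mms", "led"),
                            n_perm = 10000L, seed = 1L,
                            log_transform = TRUE) {
  edges <- as.matrix(edges)
  if (!outcome %in% names(cohort))
    stop("outcome column not in cohort: ", outcome, call. = FALSE)
  missing <- setdiff(confounds, names(cohort))
  if (length(missing) > 0L)
    stop("missing confound column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (log_transform) {
    if (any(edges <= 0))
      stop("msPLI values must be positive for the log transform",
           call. = FALSE)
    edges <- log(edges)
  }
  y <- cohort[[outcome]]
  if (identical(outcome, "aes")) y <- sqrt_transform_aes(y)
  res <- residualize(edges, cohort[, confounds, drop = FALSE])
  out <- edge_spearman(res, y)
  out$p_corrected <- as.numeric(permutation_correct(res, y, n_perm, seed))
  out[, c("edge", "rho", "p_uncorrected", "p_corrected", "n")]
}

#' Median-split ROC classification from a single connectivity value
#'
#' Subjects are split into low (`AES <= threshold`) and mildly apathetic
#' (`AES > threshold`) classes; the ROC over all thresholds of the
#' connectivity value is computed with `pROC` (trapezoidal AUC) and the
#' operating point maximising Youden's index is reported.
#'
#' @param values Numeric vector: one connectivity value per subject.
#' @param aes Apathy scores.
#' @param threshold Class boundary on the raw AES (default 24.5, a median
#'   split of the study cohort: low `<= 24`, mild `>= 25`).
#' @param direction `"higher"` if larger connectivity values indicate the
#'   mildly apathetic class, `"lower"` for the opposite orientation (the
#'   direction reported for the fronto-polar finding), `"auto"` to choose
#'   the orientation with AUC >= 0.5.
#' @return List with `auc`, `sensitivity`, `specificity`,
#'   `best_threshold`, `direction`, and `curve` (data frame of sensitivity
#'   and specificity over all cutpoints).
#' @export
median_split_roc <- function(values, aes, threshold = 24.5,
                             direction = c("higher", "lower", "auto")) {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(aes))
  cls <- factor(ifelse(aes > threshold, "mild", "low"),
                levels = c("low", "mild"))
  if (nlevels(droplevels(cls)) < 2L)
    stop("median split produced a single class", call. = FALSE)
  dir_proc <- switch(direction, higher = "<", lower = ">", auto = "auto")
  r <- pROC::roc(response = cls, predictor = values,
                 levels = c("low", "mild"), direction = dir_proc,
                 quiet = TRUE)
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1L, ]
  curve <- pROC::coords(r, "all",
                        ret = c("threshold", "sensitivity", "specificity"),
                        transpose = FALSE)
  list(auc = as.numeric(pROC::auc(r)),
       sensitivity = as.numeric(best$sensitivity),
       specificity = as.numeric(best$specificity),
       best_threshold = as.numeric(best$threshold),
       direction = r$direction,
       curve = curve)
}
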