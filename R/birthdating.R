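#' Label excess after k divisions
#'
#' The label-dilution law: a dividing cell loses 50% of its nuclear 15N label
#' at each division, so after `k` divisions an initial excess atom fraction
#' `e0` becomes `e0 * 0.5^k`. Integer `k` describes forward simulation; real
#' `k` is allowed for model curves.
#'
#' @param e0 Initial excess atom fraction, > 0.
#' @param k Number of divisions, >= 0 (vectorised).
#' @return Excess atom fraction(s) after `k` divisions.
#' @examples
#' label_after_divisions(0.96, 0:3)   # 0.96 0.48 0.24 0.12
#' @export
label_after_divisions <- function(e0, k) {
  stopifnot(is.numeric(e0), is.numeric(k))
  if (any(e0 <= 0)) stop("e0 must be > 0")
  if (any(k < 0)) stop("k must be >= 0")
  e0 * 0.5^k
}

#' Estimate division count from diluted label
#'
#' Inverts the label-dilution law: `k_est = log2(e_ref / excess)`, clipped
#' below at zero. Excess values that are zero or negative (noise-dominated
#' nuclei in which the measured atom fraction fell below natural abundance)
#' cannot be inverted; they return `NA` with a warning and should be treated
#' as maximally diluted downstream.
#'
#' @param excess Measured excess atom fraction(s).
#' @param e_ref Reference (undiluted) excess, > 0; typically the excess of
#'   post-mitotic reference cells such as cortical neurons.
#' @return Continuous division-count estimate(s), >= 0; `NA` where
#'   `excess <= 0`.
#' @examples
#' estimate_divisions(0.05, e_ref = 0.4)  # 3
#' @export
estimate_divisions <- function(excess, e_ref) {
  stopifnot(is.numeric(excess), is.numeric(e_ref), length(e_ref) == 1L)
  if (e_ref <= 0) stop("e_ref must be > 0")
  k <- rep(NA_real_, length(excess))
  ok <- is.finite(excess) & excess > 0
  if (any(!ok))
    warning(sum(!ok), " nucleus/nuclei with excess <= 0: ",
            "division count indeterminate (noise-dominated)")
  k[ok] <- pmax(0, log2(e_ref / excess[ok]))
  k
}

#' Reference thresholds from post-mitotic cells
#'
#' Computes the mean and the lowest 15N/14N ratio over a set of reference
#' post-mitotic cells (cortical neurons in the motivating study). Either of
#' these defines the cutoff separating long-lived cells (LLC) from younger,
#' divided cells.
#'
#' @param reference Either a numeric vector of 15N/14N ratios or a data frame
#'   with a `ratio` column (e.g. output of [measure_nuclei()]).
#' @return An object of class `reference_thresholds` with fields
#'   `ref_mean_ratio` and `ref_min_ratio`.
#' @export
reference_thresholds <- function(reference) {
  ratios <- if (is.data.frame(reference)) reference$ratio else reference
  stopifnot(is.numeric(ratios))
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 2L) stop("need at least 2 reference cells")
  if (any(ratios <= 0)) stop("reference ratios must be > 0")
  structure(list(ref_mean_ratio = mean(ratios),
                 ref_min_ratio = min(ratios),
                 n_reference = length(ratios)),
            class = "reference_thresholds")
}

#' @export
print.reference_thresholds <- function(x, ...) {
  cat("Reference thresholds (n = ", x$n_reference, "): mean ratio ",
      signif(x$ref_mean_ratio, 4), ", min ratio ",
      signif(x$ref_min_ratio, 4), "\n", sep = "")
  invisible(x)
}

#' Classify cells as long-lived or young
#'
#' Applies the neuron-referenced classification rule to per-nucleus
#' measurements: under the default `"min"` rule a cell is called a long-lived
#' cell (LLC) when its 15N/14N ratio is at or above the lowest reference
#' ratio (inclusive); the `"mean"` rule uses the reference mean instead. When
#' a reference excess `e_ref` is supplied, continuous and integer division
#' counts are estimated for each cell; nuclei with non-positive excess get
#' `NA` division counts and are classified as young.
#'
#' @param measurements Data frame with columns `label_id`, `ratio`, `excess`
#'   (e.g. from [measure_nuclei()] or [simulate_nucleus_counts()]).
#' @param thresholds A [reference_thresholds()] object.
#' @param rule `"min"` (default) or `"mean"`.
#' @param e_ref Optional reference excess for division-count estimation.
#' @return A data frame of cell-age calls with columns `cell_id`, `ratio`,
#'   `excess`, `k_est`, `k_int`, `is_llc`.
#' @export
classify_cells <- function(measurements, thresholds,
                           rule = c("min", "mean"), e_ref = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(thresholds, "reference_thresholds"),
            is.data.frame(measurements),
            all(c("ratio", "excess") %in% names(measurements)))
  cutoff <- switch(rule, min = thresholds$ref_min_ratio,
                   mean = thresholds$ref_mean_ratio)
  id <- if ("label_id" %in% names(measurements)) measurements$label_id
        else if ("cell_id" %in% names(measurements)) measurements$cell_id
        else seq_len(nrow(measurements))
  k_est <- if (is.null(e_ref)) rep(NA_real_, nrow(measurements))
           else suppressWarnings(estimate_divisions(measurements$excess, e_ref))
  data.frame(cell_id = id,
             ratio = measurements$ratio,
             excess = measurements$excess,
             k_est = k_est,
             k_int = as.integer(round(k_est)),
             is_llc = measurements$ratio >= cutoff,
             stringsAsFactors = FALSE)
}

#' Cohort LLC fraction with bootstrap confidence interval
#'
#' Summarises a cohort of cell-age calls: the fraction of cells classified as
#' long-lived, a percentile bootstrap confidence interval from cell-level
#' resampling, and the mean continuous division-count estimate.
#'
#' @param calls Data frame from [classify_cells()] (needs column `is_llc`).
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional RNG seed for reproducible intervals.
#' @param group Optional group label carried into the summary.
#' @return A one-row data frame with `group`, `n_cells`, `llc_fraction`,
#'   `ci_low`, `ci_high`, `mean_k_est`.
#' @export
cohort_llc_fraction <- function(calls, n_boot = 2000, conf = 0.95,
                                seed = NULL, group = NA_character_) {
  stopifnot(is.data.frame(calls), "is_llc" %in% names(calls),
            nrow(calls) >= 1L, n_boot >= 1L)
  x <- as.logical(calls$is_llc)
  frac <- mean(x)
  boot_one <- function() mean(sample(x, length(x), replace = TRUE))
  boots <- maybe_with_seed(seed, replicate(n_boot, boot_one()))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  data.frame(group = group,
             n_cells = length(x),
             llc_fraction = frac,
             ci_low = ci[1], ci_high = ci[2],
             mean_k_est = mean(calls$k_est, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' Mixture deconvolution of division counts
#'
#' Fits, by expectation-maximisation, a finite mixture over integer division
#' counts k = 0..K_max to measured log2 excess values. The model is
#' `log2(e_i) ~ Normal(log2(e_ref) - k, sigma^2)` mixed with weights `w_k`:
#' each division shifts the log2 excess down by exactly one, and `sigma`
#' absorbs measurement noise. Component means are fixed by the dilution law;
#' only the weights and the common `sigma` are estimated, so the
#' log-likelihood is monotone non-decreasing across EM iterations.
#'
#' @param excess_values Positive excess atom fractions (indeterminate,
#'   non-positive values must be excluded upstream).
#' @param e_ref Reference (undiluted) excess, > 0.
#' @param K_max Largest division count in the mixture (>= 1).
#' @param init Optional list with starting `weights` and `sigma`; defaults to
#'   uniform weights and the sample SD of log2 excess.
#' @param tol Convergence tolerance on the log-likelihood gain (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return An object of class `division_mixture_fit` with fields `weights`
#'   (named w0..wK), `sigma`, `loglik`, `loglik_trace`, `n_iter`, `converged`,
#'   and the posterior `responsibilities` matrix.
#' @export
fit_division_mixture <- function(excess_values, e_ref, K_max = 6,
                                 init = NULL, tol = 1e-8, max_iter = 1000) {
  stopifnot(is.numeric(excess_values), length(excess_values) >= 1L,
            is.numeric(e_ref), length(e_ref) == 1L)
  if (e_ref <= 0) stop("e_ref must be > 0")
  if (any(!is.finite(excess_values)) || any(excess_values <= 0))
    stop("all excess_values must be finite and > 0")
  if (K_max < 1) stop("K_max must be >= 1")

  x <- log2(excess_values)
  n <- length(x)
  ks <- 0:K_max
  mu <- log2(e_ref) - ks

  w <- if (!is.null(init$weights)) {
    stopifnot(length(init$weights) == K_max + 1L, all(init$weights >= 0))
    init$weights / sum(init$weights)
  } else rep(1 / (K_max + 1), K_max + 1)
  sigma <- if (!is.null(init$sigma)) init$sigma
           else max(stats::sd(x), 1e-3)
  if (is.na(sigma) || sigma <= 0) sigma <- 1e-3

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  resp <- NULL
  for (iter in seq_len(max_iter)) {
    # E-step
    dens <- vapply(seq_along(ks),
                   function(j) w[j] * stats::dnorm(x, mu[j], sigma),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- pmax(rowSums(dens), 1e-300)
    resp <- dens / tot
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M-step
    w <- colMeans(resp)
    dev2 <- (matrix(x, n, length(ks)) - matrix(mu, n, length(ks), byrow = TRUE))^2
    sigma <- sqrt(sum(resp * dev2) / n)
    sigma <- max(sigma, 1e-6)  # guard against degenerate collapse
  }

  structure(list(weights = stats::setNames(w, paste0("w", ks)),
                 sigma = sigma,
                 loglik = trace[length(trace)],
                 loglik_trace = trace,
                 n_iter = length(trace),
                 converged = converged,
                 K_max = K_max,
                 e_ref = e_ref,
                 responsibilities = resp),
            class = "division_mixture_fit")
}

#' @export
print.division_mixture_fit <- function(x, ...) {
  cat("Division-count mixture fit (K_max = ", x$K_max, "):\n", sep = "")
  print(round(x$weights, 4))
  cat("sigma = ", signif(x$sigma, 4), ", loglik = ", signif(x$loglik, 8),
      ", iterations = ", x$n_iter,
      if (x$converged) " (converged)\n" else " (not converged)\n", sep = "")
  invisible(x)
}
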