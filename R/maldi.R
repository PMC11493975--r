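#' Rank-based ROC AUC between two pixel classes
#'
#' The probability that a randomly chosen class-b pixel has higher intensity
#' than a randomly chosen class-a pixel, counting ties as one half:
#' `AUC = (P(b > a) + 0.5 P(b = a))`, computed through the rank-sum
#' (Mann-Whitney U) identity `AUC = U / (n_a n_b)` with midranks for ties.
#'
#' @param a Intensities of class-a pixels (e.g. AL islet pixels).
#' @param b Intensities of class-b pixels.
#' @return AUC in [0, 1]; 0.5 means no enrichment, values above 0.5 mean
#'   class b is enriched.
#' @examples
#' ion_auc(c(1, 2, 3), c(2, 3, 4))  # 7/9
#' @export
ion_auc <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) == 0L || length(b) == 0L) stop("both classes must be non-empty")
  r <- rank(c(a, b))
  nb <- length(b)
  U <- sum(r[(length(a) + 1):(length(a) + nb)]) - nb * (nb + 1) / 2
  U / (length(a) * nb)
}

#' Retention filter for ROC enrichment screening
#'
#' Retains an ion when its AUC deviates from 0.5 by at least `deviation`
#' (inclusive boundaries): `auc >= 0.5 + deviation` flags class-b
#' enrichment, `auc <= 0.5 - deviation` flags class-a enrichment. A
#' one-sided variant restricts to one direction.
#'
#' @param aucs Numeric AUC values, or a data frame with columns `mz` and
#'   `auc`.
#' @param deviation Retention half-width around 0.5 (default 0.1).
#' @param sided `"two"` (default), `"a"` or `"b"`.
#' @return Data frame with columns `mz` (if supplied), `auc`, `direction`
#'   (`"a"`, `"b"` or `NA`), `retained`.
#' @export
enrichment_filter <- function(aucs, deviation = 0.1,
                              sided = c("two", "a", "b")) {
  sided <- match.arg(sided)
  stopifnot(deviation > 0, deviation <= 0.5)
  df <- if (is.data.frame(aucs)) aucs else data.frame(auc = aucs)
  stopifnot("auc" %in% names(df), all(df$auc >= 0 & df$auc <= 1))
  up <- .geq(df$auc, 0.5 + deviation)
  dn <- .leq(df$auc, 0.5 - deviation)
  if (sided == "a") up[] <- FALSE
  if (sided == "b") dn[] <- FALSE
  df$direction <- ifelse(up, "b", ifelse(dn, "a", NA_character_))
  df$retained <- up | dn
  df
}

#' Accurate-mass metabolite matching
#'
#' Matches an observed m/z against a reference list using a hard mass
#' tolerance in daltons; the parts-per-million error is reported
#' diagnostically for each candidate. Matches are returned sorted by
#' absolute mass error.
#'
#' @param observed_mz Observed mass-to-charge (Da), > 0.
#' @param refs Data frame with columns `name` and `mz` (theoretical Da).
#' @param da_tol Tolerance in Da (default 0.00565, the instrument's ion
#'   mass resolution).
#' @return Data frame with columns `observed_mz`, `name`, `theoretical_mz`,
#'   `delta_da` (signed), `delta_ppm` (absolute), `matched`; zero rows when
#'   nothing is within tolerance.
#' @examples
#' refs <- data.frame(name = "cholesterol sulfate", mz = 465.30443)
#' match_metabolite(465.304, refs)
#' @export
match_metabolite <- function(observed_mz, refs, da_tol = 0.00565) {
  stopifnot(is.numeric(observed_mz), length(observed_mz) == 1L,
            observed_mz > 0, is.data.frame(refs),
            all(c("name", "mz") %in% names(refs)), all(refs$mz > 0))
  delta <- observed_mz - refs$mz
  out <- data.frame(observed_mz = observed_mz,
                    name = refs$name,
                    theoretical_mz = refs$mz,
                    delta_da = delta,
                    delta_ppm = abs(delta) / refs$mz * 1e6,
                    matched = .leq(abs(delta), da_tol),
                    stringsAsFactors = FALSE)
  out <- out[out$matched, , drop = FALSE]
  out <- out[order(abs(out$delta_da)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen a set of ion images for regional enrichment
#'
#' Runs [ion_auc()] on every ion image of a list (as produced by
#' [synthesize_ion_images()]) and applies [enrichment_filter()].
#'
#' @param ions List of `ion_image` objects.
#' @param deviation Retention half-width (default 0.1).
#' @param sided Passed to [enrichment_filter()].
#' @return Screen data frame with columns `mz`, `auc`, `direction`,
#'   `retained`.
#' @export
roc_screen <- function(ions, deviation = 0.1, sided = "two") {
  stopifnot(is.list(ions), length(ions) >= 1L)
  res <- data.frame(
    mz = vapply(ions, function(i) i$mz, numeric(1)),
    auc = vapply(ions, function(i)
      ion_auc(i$intensity[i$region_a], i$intensity[i$region_b]), numeric(1)))
  enrichment_filter(res, deviation = deviation, sided = sided)
}
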