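#' Simulate per-ion intensity images over two labelled regions
#'
#' Each ion's pixel intensities are lognormal with a region-specific
#' location: class-a pixels draw from `meanlog`, class-b pixels from
#' `meanlog + log_effect`. A zero `log_effect` makes the two regions
#' exchangeable (null ion); a large effect separates their supports.
#'
#' @param region_a,region_b Disjoint integer vectors of pixel indices into
#'   the raster (both non-empty).
#' @param ion_specs Data frame with columns `mz`, `log_effect`, and
#'   optionally `meanlog` (default 0) and `sdlog` (default 0.5).
#' @param raster_dim Raster dimensions.
#' @param seed Optional RNG seed.
#' @return List of `ion_image` objects: `mz`, `intensity` (matrix),
#'   `region_a`, `region_b`, `log_effect`.
#' @export
synthesize_ion_images <- function(region_a, region_b, ion_specs,
                                  raster_dim = c(64, 64), seed = NULL) {
  stopifnot(is.data.frame(ion_specs),
            all(c("mz", "log_effect") %in% names(ion_specs)),
            length(region_a) >= 1L, length(region_b) >= 1L)
  if (length(intersect(region_a, region_b)))
    stop("region masks must be disjoint")
  npx <- prod(raster_dim)
  stopifnot(all(c(region_a, region_b) >= 1),
            all(c(region_a, region_b) <= npx))
  meanlog <- if ("meanlog" %in% names(ion_specs)) ion_specs$meanlog
             else rep(0, nrow(ion_specs))
  sdlog <- if ("sdlog" %in% names(ion_specs)) ion_specs$sdlog
           else rep(0.5, nrow(ion_specs))
  maybe_with_seed(seed, {
    lapply(seq_len(nrow(ion_specs)), function(j) {
      img <- matrix(0, raster_dim[1], raster_dim[2])
      img[region_a] <- stats::rlnorm(length(region_a), meanlog[j], sdlog[j])
      img[region_b] <- stats::rlnorm(length(region_b),
                                     meanlog[j] + ion_specs$log_effect[j],
                                     sdlog[j])
      structure(list(mz = ion_specs$mz[j], intensity = img,
                     region_a = region_a, region_b = region_b,
                     log_effect = ion_specs$log_effect[j]),
                class = "ion_image")
    })
  })
}

#' Construct a tolerance curve
#'
#' Timed glucose (and optionally insulin) measurements from a tolerance
#' test. The baseline sample is the pre-bolus measurement (time < 0 when
#' present, otherwise the first sample).
#'
#' @param time_min Timepoints in minutes, strictly increasing.
#' @param glucose_mgdl Glucose in mg/dL, > 0.
#' @param insulin_ngml Optional insulin in ng/mL.
#' @param baseline_index Index of the pre-bolus sample.
#' @return Object of class `tolerance_curve`.
#' @export
tolerance_curve <- function(time_min, glucose_mgdl, insulin_ngml = NULL,
                            baseline_index = NULL) {
  stopifnot(is.numeric(time_min), is.numeric(glucose_mgdl),
            length(time_min) == length(glucose_mgdl))
  if (any(diff(time_min) <= 0)) stop("timepoints must be strictly increasing")
  if (any(glucose_mgdl <= 0)) stop("glucose values must be > 0")
  if (is.null(baseline_index)) {
    pre <- which(time_min < 0)
    baseline_index <- if (length(pre)) pre[length(pre)] else 1L
  }
  stopifnot(baseline_index >= 1L, baseline_index <= length(time_min))
  structure(list(time_min = time_min, glucose_mgdl = glucose_mgdl,
                 insulin_ngml = insulin_ngml,
                 baseline_index = as.integer(baseline_index)),
            class = "tolerance_curve")
}

#' Standard assay timepoints
#'
#' Sampling schedules of the modelled assays: the meal tolerance test (MTT,
#' pre-bolus at -10 min) and the intraperitoneal insulin tolerance test
#' (ipITT).
#'
#' @param assay `"mtt"` or `"ipitt"`.
#' @return Numeric vector of minutes.
#' @export
assay_timepoints <- function(assay = c("mtt", "ipitt")) {
  switch(match.arg(assay),
         mtt = c(-10, 5, 10, 15, 20, 30, 45, 60, 90, 120),
         ipitt = c(0, 10, 15, 20, 25, 30, 40, 60))
}

#' Simulate a glucose tolerance curve with known decay rate
#'
#' Generates `glucose(t) = baseline * exp(-decay_rate * t)` with
#' multiplicative lognormal noise, retaining the generating rate so the
#' Kitt estimator has a recovery target.
#'
#' @param decay_rate Exponential decay rate per minute (>= 0).
#' @param baseline Glucose at t = 0 in mg/dL (> 0).
#' @param timepoints Minutes, sorted ascending (default ipITT schedule).
#' @param noise_sd SD of the multiplicative log-scale noise.
#' @param seed Optional RNG seed.
#' @return A `tolerance_curve` with attribute `true_decay_rate`.
#' @export
synthesize_tolerance_curve <- function(decay_rate, baseline = 150,
                                       timepoints = assay_timepoints("ipitt"),
                                       noise_sd = 0, seed = NULL) {
  stopifnot(decay_rate >= 0, noise_sd >= 0)
  if (baseline <= 0) stop("baseline must be > 0")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be sorted ascending")
  g <- maybe_with_seed(seed, {
    mean_curve <- baseline * exp(-decay_rate * pmax(timepoints, 0))
    if (timepoints[1] < 0)  # pre-bolus samples sit at baseline
      mean_curve[timepoints < 0] <- baseline
    mean_curve * exp(stats::rnorm(length(timepoints), 0, noise_sd))
  })
  curve <- tolerance_curve(timepoints, g)
  attr(curve, "true_decay_rate") <- decay_rate
  curve
}
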