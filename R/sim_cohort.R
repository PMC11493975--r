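#' Simulate a labelled cell cohort under diet-dependent turnover
#'
#' Draws a cohort of cells whose latent division counts follow the
#' two-component turnover model: with probability `p_quiescent` a cell never
#' divides during the chase (k = 0); otherwise its division count is Poisson
#' with mean `division_rate * chase_months`. Each cell's true nuclear label
#' excess is the initial excess diluted by 50% per division,
#' `e = e0 * 0.5^k` (via [label_after_divisions()]). Reference neurons are
#' post-mitotic and always get k = 0.
#'
#' @param protocol A [labeling_protocol()].
#' @param params A [turnover_params()] (ignored for `cell_type = "neuron"`).
#' @param n_cells Number of cells to simulate (>= 1).
#' @param cell_type One of `"beta"`, `"alpha"`, `"delta"`, `"acinar"`,
#'   `"neuron"`.
#' @param seed Optional RNG seed; fixed seed gives identical cohorts.
#' @return Data frame with columns `cell_id`, `cell_type`, `group`,
#'   `true_divisions`, `true_excess`.
#' @examples
#' simulate_cohort(labeling_protocol(), default_turnover("CR"), 5, seed = 1)
#' @export
simulate_cohort <- function(protocol, params, n_cells,
                            cell_type = c("beta", "alpha", "delta",
                                          "acinar", "neuron"),
                            seed = NULL) {
  stopifnot(inherits(protocol, "labeling_protocol"),
            inherits(params, "turnover_params"))
  cell_type <- match.arg(cell_type)
  if (n_cells < 1) stop("n_cells must be >= 1")
  lambda_total <- params$division_rate * protocol$chase_months
  k <- maybe_with_seed(seed, {
    if (cell_type == "neuron") {
      integer(n_cells)
    } else {
      quiescent <- stats::runif(n_cells) < params$p_quiescent
      draws <- stats::rpois(n_cells, lambda_total)
      ifelse(quiescent, 0L, draws)
    }
  })
  data.frame(cell_id = sprintf("%s_%s_%04d", params$group, cell_type,
                               seq_len(n_cells)),
             cell_type = cell_type,
             group = params$group,
             true_divisions = as.integer(k),
             true_excess = label_after_divisions(protocol$initial_excess, k),
             stringsAsFactors = FALSE)
}

#' Simulate per-nucleus ion counts for a cohort
#'
#' A fast per-nucleus counting model used for end-to-end simulations that do
#' not need full rasters: for a cell with atom fraction
#' `f = f_nat + true_excess`, the summed nuclear counts are
#' `sum15 ~ Poisson(dose * f)` and `sum14 ~ Poisson(dose * (1 - f))`, the
#' same ion statistics the raster synthesiser applies per pixel.
#'
#' @param cohort Data frame from [simulate_cohort()].
#' @param dose Expected total ion counts per nucleus (default 2e5).
#' @param f_nat Natural 15N abundance.
#' @param seed Optional RNG seed.
#' @return Data frame of per-nucleus measurements with columns `label_id`,
#'   `area_px` (NA), `sum15`, `sum14`, `ratio`, `atom_fraction`, `excess`.
#' @export
simulate_nucleus_counts <- function(cohort, dose = 2e5,
                                    f_nat = NATURAL_15N_ABUNDANCE,
                                    seed = NULL) {
  stopifnot(is.data.frame(cohort), "true_excess" %in% names(cohort),
            dose > 0)
  f <- f_nat + cohort$true_excess
  stopifnot(all(f > 0), all(f < 1))
  counts <- maybe_with_seed(seed, {
    list(s15 = stats::rpois(nrow(cohort), dose * f),
         s14 = stats::rpois(nrow(cohort), dose * (1 - f)))
  })
  nucleus_measurement(label_id = cohort$cell_id,
                      sum15 = counts$s15, sum14 = counts$s14,
                      f_nat = f_nat, area_px = NA_integer_)
}
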