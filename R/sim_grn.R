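#' Ground-truth regulatory network for simulations
#'
#' Draws a random TF -> target network with positive importance weights.
#' TFs and targets live in disjoint namespaces, so no self-edges can arise.
#'
#' @param n_tfs Number of transcription factors.
#' @param n_targets Number of target genes.
#' @param n_edges Number of true edges.
#' @param p_tf_target Fraction of edges whose target is another TF
#'   (regulatory cascades; needed for non-trivial betweenness). Self-edges
#'   are never produced.
#' @param seed Optional RNG seed.
#' @return Object of class `grn_truth`: data frame `true_edges` (tf, target,
#'   importance) plus `n_tfs`, `n_targets`.
#' @export
grn_truth <- function(n_tfs = 10, n_targets = 50, n_edges = 50,
                      p_tf_target = 0.2, seed = NULL) {
  stopifnot(n_tfs >= 1, n_targets >= 1,
            n_edges >= 1, n_edges <= n_tfs * n_targets,
            p_tf_target >= 0, p_tf_target <= 1)
  maybe_with_seed(seed, {
    pool <- sample(n_tfs * n_targets, n_edges)
    tf_i <- (pool - 1L) %% n_tfs + 1L
    tg_i <- (pool - 1L) %/% n_tfs + 1L
    target <- sprintf("G%03d", tg_i)
    if (n_tfs >= 2 && p_tf_target > 0) {
      casc <- which(stats::runif(n_edges) < p_tf_target)
      for (i in casc) {
        other <- sample(setdiff(seq_len(n_tfs), tf_i[i]), 1L)
        target[i] <- sprintf("TF%02d", other)
      }
    }
    edges <- data.frame(tf = sprintf("TF%02d", tf_i),
                        target = target,
                        importance = stats::rlnorm(n_edges, log(5), 0.5),
                        stringsAsFactors = FALSE)
    edges <- edges[!duplicated(paste(edges$tf, edges$target)), ]
    rownames(edges) <- NULL
    structure(list(true_edges = edges, n_tfs = n_tfs,
                   n_targets = n_targets),
              class = "grn_truth")
  })
}

#' Simulate repeated stochastic network-inference runs
#'
#' Emulates the run-to-run variability of stochastic co-expression
#' inference: each run contains each true edge independently with
#' probability `p_true` (its importance multiplied by lognormal noise) and
#' each possible false edge with probability `p_false`.
#'
#' @param truth A [grn_truth()].
#' @param n_runs Number of runs (the motivating workflow uses 100).
#' @param p_true Per-run retention probability of a true edge.
#' @param p_false Per-run inclusion probability of a non-edge.
#' @param importance_noise_sd SD of the lognormal importance noise.
#' @param seed Optional RNG seed.
#' @return Object of class `run_set`: list `runs` of edge data frames
#'   (tf, target, importance) and `n_runs`.
#' @export
synthesize_grn_runs <- function(truth, n_runs = 100, p_true = 0.9,
                                p_false = 0.001, importance_noise_sd = 0.1,
                                seed = NULL) {
  stopifnot(inherits(truth, "grn_truth"), n_runs >= 1)
  if (p_false < 0 || p_true > 1 || p_false >= p_true)
    stop("need 0 <= p_false < p_true <= 1")
  te <- truth$true_edges
  all_tf <- sprintf("TF%02d", seq_len(truth$n_tfs))
  all_tg <- sprintf("G%03d", seq_len(truth$n_targets))
  true_key <- paste(te$tf, te$target)
  maybe_with_seed(seed, {
    runs <- lapply(seq_len(n_runs), function(r) {
      keep <- stats::runif(nrow(te)) < p_true
      ed <- te[keep, , drop = FALSE]
      if (nrow(ed))
        ed$importance <- ed$importance *
          stats::rlnorm(nrow(ed), 0, importance_noise_sd)
      if (p_false > 0) {
        n_pairs <- truth$n_tfs * truth$n_targets
        n_false_draw <- stats::rbinom(1, n_pairs - nrow(te), p_false)
        if (n_false_draw > 0) {
          # sample from the non-edge universe
          cand <- sample(n_pairs, min(n_pairs, n_false_draw + nrow(te)))
          tf_i <- (cand - 1L) %% truth$n_tfs + 1L
          tg_i <- (cand - 1L) %/% truth$n_tfs + 1L
          key <- paste(all_tf[tf_i], all_tg[tg_i])
          new <- which(!(key %in% true_key))[seq_len(min(n_false_draw,
                         sum(!(key %in% true_key))))]
          if (length(new))
            ed <- rbind(ed, data.frame(
              tf = all_tf[tf_i[new]], target = all_tg[tg_i[new]],
              importance = stats::rlnorm(length(new), log(0.5), 0.5),
              stringsAsFactors = FALSE))
        }
      }
      rownames(ed) <- NULL
      ed
    })
    structure(list(runs = runs, n_runs = n_runs), class = "run_set")
  })
}

#' Build a run set from explicit edge lists
#'
#' @param runs List of data frames with columns `tf`, `target`,
#'   `importance`; no duplicate (tf, target) within a run.
#' @return A `run_set`.
#' @export
run_set <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  for (ed in runs) {
    stopifnot(is.data.frame(ed),
              all(c("tf", "target", "importance") %in% names(ed)))
    if (anyDuplicated(paste(ed$tf, ed$target)))
      stop("duplicate (tf, target) within a run")
    if (any(ed$importance < 0)) stop("importances must be >= 0")
  }
  structure(list(runs = runs, n_runs = length(runs)), class = "run_set")
}

#' Simulate a cells x regulons activity matrix with bimodal scores
#'
#' Each regulon's per-cell activity is a two-component mixture: a cell is ON
#' with the spec's `on_fraction` and draws from the ON mode, otherwise from
#' the OFF mode. Draws are clipped to [0, 1], matching rank-based activity
#' scores. Ground-truth ON labels are returned for recovery experiments.
#'
#' @param n_cells Number of cells (rows).
#' @param regulon_specs Data frame with columns `name`, `on_fraction`,
#'   `on_mean`, `on_sd`, `off_mean`, `off_sd`; modes must lie in [0, 1].
#' @param seed Optional RNG seed.
#' @return List with `activity` (matrix, cells x regulons) and `truth`
#'   (logical ON matrix of the same shape).
#' @export
synthesize_activity_matrix <- function(n_cells, regulon_specs, seed = NULL) {
  stopifnot(n_cells >= 1, is.data.frame(regulon_specs),
            all(c("name", "on_fraction", "on_mean", "on_sd",
                  "off_mean", "off_sd") %in% names(regulon_specs)))
  with(regulon_specs, {
    if (any(on_fraction < 0 | on_fraction > 1))
      stop("on_fraction must be in [0, 1]")
    if (any(c(on_mean, off_mean) < 0 | c(on_mean, off_mean) > 1))
      stop("mode means must be in [0, 1]")
  })
  maybe_with_seed(seed, {
    k <- nrow(regulon_specs)
    act <- matrix(NA_real_, n_cells, k,
                  dimnames = list(sprintf("cell_%04d", seq_len(n_cells)),
                                  regulon_specs$name))
    truth <- matrix(FALSE, n_cells, k, dimnames = dimnames(act))
    for (j in seq_len(k)) {
      sp <- regulon_specs[j, ]
      on <- stats::runif(n_cells) < sp$on_fraction
      vals <- ifelse(on,
                     stats::rnorm(n_cells, sp$on_mean, sp$on_sd),
                     stats::rnorm(n_cells, sp$off_mean, sp$off_sd))
      act[, j] <- pmin(1, pmax(0, vals))
      truth[, j] <- on
    }
    list(activity = act, truth = truth)
  })
}
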