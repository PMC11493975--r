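#' Consensus filter across stochastic network-inference runs
#'
#' Retains a TF -> target association when it appears in at least
#' `min_support` of the runs (inclusive; the motivating workflow ran
#' inference 100 times and kept edges present at least 80% of the time).
#' Appearance counts are integer; support is the exact rational
#' `appearances / n_runs`. The importance of a retained edge is, by default,
#' averaged over the runs in which it appears; `absent_as_zero = TRUE`
#' averages over all runs instead (absent runs contributing zero).
#'
#' @param runs A `run_set` (from [synthesize_grn_runs()], [run_set()] or
#'   [read_run_tsvs()]).
#' @param min_support Retention threshold in (0, 1] (default 0.80).
#' @param absent_as_zero Importance-averaging convention (default FALSE).
#' @return Object of class `consensus_network`: data frame `edges` with
#'   columns `tf`, `target`, `support`, `n_runs_present`, `mean_importance`,
#'   plus `n_runs` and `min_support`.
#' @export
consensus_filter <- function(runs, min_support = 0.80,
                             absent_as_zero = FALSE) {
  stopifnot(inherits(runs, "run_set"))
  if (min_support <= 0 || min_support > 1)
    stop("min_support must be in (0, 1]")
  n_runs <- runs$n_runs
  all_edges <- do.call(rbind, runs$runs)
  if (is.null(all_edges) || nrow(all_edges) == 0L) {
    edges <- data.frame(tf = character(0), target = character(0),
                        support = numeric(0), n_runs_present = integer(0),
                        mean_importance = numeric(0))
  } else {
    key <- paste(all_edges$tf, all_edges$target, sep = "\r")
    counts <- tapply(all_edges$importance, key, length)
    sums <- tapply(all_edges$importance, key, sum)
    keys <- names(counts)
    n_present <- as.integer(counts)
    retained <- .geq(n_present / n_runs, min_support)
    parts <- strsplit(keys[retained], "\r", fixed = TRUE)
    denom <- if (absent_as_zero) n_runs else n_present[retained]
    edges <- data.frame(
      tf = vapply(parts, `[`, "", 1L),
      target = vapply(parts, `[`, "", 2L),
      support = n_present[retained] / n_runs,
      n_runs_present = n_present[retained],
      mean_importance = as.numeric(sums[retained]) / denom,
      stringsAsFactors = FALSE)
    edges <- edges[order(-edges$support, edges$tf, edges$target), ]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, n_runs = n_runs,
                 min_support = min_support),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat("Consensus network: ", nrow(x$edges), " edges retained at support >= ",
      x$min_support, " over ", x$n_runs, " runs\n", sep = "")
  invisible(x)
}

#' Directed igraph view of a consensus network
#'
#' @param net A `consensus_network`.
#' @return An igraph directed graph with edge attributes `support` and
#'   `mean_importance`.
#' @export
consensus_graph <- function(net) {
  stopifnot(inherits(net, "consensus_network"))
  if (nrow(net$edges) == 0L) stop("consensus network has no edges")
  igraph::graph_from_data_frame(net$edges, directed = TRUE)
}

#' Binarize regulon activity per regulon
#'
#' Assigns each (cell, regulon) an ON/OFF state by a per-regulon threshold.
#' Activities are clipped into (0, 1), logit-transformed, and a one- versus
#' two-component Gaussian mixture is compared by BIC (via mclust). For a
#' bimodal column the threshold is the crossing point of the two component
#' posteriors between the mode means; a cell is ON when its activity is at
#' or above the threshold. Columns judged unimodal (or with no variance)
#' conservatively fall back to all-OFF and are flagged.
#'
#' @param activity Numeric matrix, cells x regulons, values in [0, 1].
#' @return Object of class `binarized_activity`: `states` (0/1 integer
#'   matrix), `thresholds` (per-regulon, `Inf` where all-OFF), `bimodal`
#'   (logical per regulon).
#' @export
binarize_activity <- function(activity) {
  stopifnot(is.matrix(activity), nrow(activity) >= 2L)
  if (any(!is.finite(activity))) stop("activities must be finite")
  if (any(activity < 0 | activity > 1)) stop("activities must be in [0, 1]")
  k <- ncol(activity)
  states <- matrix(0L, nrow(activity), k, dimnames = dimnames(activity))
  thresholds <- rep(Inf, k)
  bimodal <- logical(k)
  for (j in seq_len(k)) {
    x <- activity[, j]
    if (stats::sd(x) < 1e-12) next
    z <- logit(pmin(1 - 1e-4, pmax(1e-4, x)))
    fit <- tryCatch(
      Mclust(z, G = 1:2, modelNames = c("E", "V"), verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit) || fit$G < 2) next
    mu <- fit$parameters$mean
    var <- fit$parameters$variance$sigmasq
    if (length(var) == 1L) var <- rep(var, 2)
    pro <- fit$parameters$pro
    lo <- which.min(mu); hi <- which.max(mu)
    post_diff <- function(t)
      log(pro[hi]) + stats::dnorm(t, mu[hi], sqrt(var[hi]), log = TRUE) -
      log(pro[lo]) - stats::dnorm(t, mu[lo], sqrt(var[lo]), log = TRUE)
    thr_z <- tryCatch(
      stats::uniroot(post_diff, lower = mu[lo], upper = mu[hi])$root,
      error = function(e) (mu[lo] + mu[hi]) / 2)
    thresholds[j] <- inv_logit(thr_z)
    bimodal[j] <- TRUE
    states[, j] <- as.integer(x >= thresholds[j])
  }
  structure(list(states = states, thresholds = thresholds,
                 bimodal = bimodal),
            class = "binarized_activity")
}

#' TF co-activity correlation and module detection
#'
#' Computes the Pearson correlation of regulon activities across cells and
#' groups co-regulated TFs by average-linkage hierarchical clustering on the
#' distance `1 - r`. Zero-variance columns are excluded with a warning.
#'
#' @param activity Numeric matrix, cells x regulons (>= 3 cells).
#' @param k Number of modules to cut the tree into (exclusive with `h`).
#' @param h Tree height to cut at (distance `1 - r`).
#' @return List with `correlation` (matrix), `tree` (hclust), `modules`
#'   (named integer vector), `excluded` (names of zero-variance columns).
#' @export
tf_correlation_modules <- function(activity, k = NULL, h = NULL) {
  stopifnot(is.matrix(activity), nrow(activity) >= 3L)
  sds <- apply(activity, 2, stats::sd)
  excluded <- colnames(activity)[sds < 1e-12]
  if (length(excluded))
    warning("excluding zero-variance regulons: ",
            paste(excluded, collapse = ", "))
  act <- activity[, sds >= 1e-12, drop = FALSE]
  if (ncol(act) < 2L) stop("fewer than 2 usable regulon columns")
  r <- stats::cor(act, use = "pairwise.complete.obs")
  tree <- stats::hclust(stats::as.dist(1 - r), method = "average")
  modules <- if (!is.null(k)) stats::cutree(tree, k = k)
             else if (!is.null(h)) stats::cutree(tree, h = h)
             else stats::cutree(tree, h = 0.5)
  list(correlation = r, tree = tree, modules = modules, excluded = excluded)
}

#' Betweenness influence of TFs in the consensus network
#'
#' Betweenness centrality over shortest paths on the directed consensus
#' graph; by default paths are unweighted. The importance-weighted variant
#' uses `1 / mean_importance` as edge length so that stronger edges are
#' shorter.
#'
#' @param net A `consensus_network`.
#' @param normalized Divide by the number of ordered node pairs excluding
#'   the node itself (default FALSE).
#' @param weighted Use importance-derived edge lengths (default FALSE).
#' @return Named numeric vector of betweenness scores.
#' @export
tf_betweenness <- function(net, normalized = FALSE, weighted = FALSE) {
  g <- consensus_graph(net)
  w <- if (weighted) 1 / igraph::E(g)$mean_importance else NA
  igraph::betweenness(g, directed = TRUE, weights = w,
                      normalized = normalized)
}
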