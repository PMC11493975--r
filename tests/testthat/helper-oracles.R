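# Independent brute-force oracles used to cross-check package results.

# ROC AUC by exhaustive pair enumeration (ties count one half).
bf_auc <- function(a, b) {
  cmp <- outer(b, a, ">") + 0.5 * outer(b, a, "==")
  mean(cmp)
}

# Betweenness by exhaustive simple-path enumeration on a directed adjacency
# matrix (feasible for <= 8 nodes). For every ordered pair (s, t) all simple
# paths are enumerated recursively; shortest ones are kept and interior
# vertices credited with sigma_st(v) / sigma_st.
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  score <- numeric(n)
  all_paths <- function(s, t) {
    found <- list()
    recur <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        found[[length(found) + 1L]] <<- path
        return()
      }
      for (v in which(adj[last, ] > 0))
        if (!(v %in% path)) recur(c(path, v))
    }
    recur(s)
    found
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- all_paths(s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    sigma <- length(shortest)
    for (p in shortest) {
      interior <- setdiff(p, c(s, t))
      score[interior] <- score[interior] + 1 / sigma
    }
  }
  score
}

# Random directed graph as an adjacency matrix (no self-loops).
random_digraph <- function(n, p = 0.3) {
  adj <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  diag(adj) <- 0L
  adj
}

# Convert an adjacency matrix into a consensus_network so the package path
# can run on it (every edge present in the single "run").
adj_to_consensus <- function(adj) {
  idx <- which(adj > 0, arr.ind = TRUE)
  ed <- data.frame(tf = paste0("n", idx[, 1]),
                   target = paste0("n", idx[, 2]),
                   importance = 1)
  consensus_filter(run_set(list(ed)), min_support = 1)
}

# Betweenness of all n nodes through the package, aligned to node order 1..n
# (nodes absent from the edge list get zero).
pkg_betweenness_all <- function(adj) {
  n <- nrow(adj)
  bt <- tf_betweenness(adj_to_consensus(adj))
  out <- numeric(n)
  out[as.integer(sub("n", "", names(bt)))] <- bt
  out
}

# Log-likelihood of the division-count mixture, written independently of the
# EM implementation.
bf_mixture_loglik <- function(excess, e_ref, w, sigma) {
  x <- log2(excess)
  mu <- log2(e_ref) - (seq_along(w) - 1)
  dens <- sapply(seq_along(w), function(j) w[j] * dnorm(x, mu[j], sigma))
  sum(log(rowSums(matrix(dens, nrow = length(x)))))
}

# Grid maximizer of the same likelihood over the weight simplex and sigma.
bf_mixture_grid_max <- function(excess, e_ref, K_max = 2,
                                w_step = 0.05, sigmas = seq(0.05, 0.5, 0.025)) {
  stopifnot(K_max == 2)
  best <- -Inf
  ws <- seq(0, 1, w_step)
  for (w0 in ws) for (w1 in ws) {
    w2 <- 1 - w0 - w1
    if (w2 < -1e-9) next
    w <- pmax(c(w0, w1, w2), 1e-12)
    for (s in sigmas) {
      ll <- bf_mixture_loglik(excess, e_ref, w, s)
      if (ll > best) best <- ll
    }
  }
  best
}
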