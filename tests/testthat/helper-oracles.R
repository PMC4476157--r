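# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own fast paths.

# Quick edge-list network without modes.
toy_net <- function(from, to, ...) {
  reg_network(tibble::tibble(regulator = from, target = to), ...)
}

# Dense adjacency of a network (self-loops dropped).
adj_matrix <- function(net) {
  ids <- net$genes$id
  n <- length(ids)
  a <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  e <- net$edges[net$edges$regulator != net$edges$target, ]
  a[cbind(match(e$regulator, ids), match(e$target, ids))] <- TRUE
  a
}

# Exhaustive all-triples triad census via classify_triad().
oracle_census <- function(net) {
  a <- adj_matrix(net)
  n <- nrow(a)
  counts <- integer(13)
  if (n >= 3) {
    for (tr in utils::combn(n, 3, simplify = FALSE)) {
      cls <- classify_triad(a[tr, tr])
      if (!is.null(cls)) counts[cls$class_id] <- counts[cls$class_id] + 1L
    }
  }
  counts
}

# Floyd-Warshall characteristic path length + triplet-count transitivity.
oracle_topology <- function(net) {
  a <- adj_matrix(net)
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  diag(d) <- Inf
  finite <- d[is.finite(d)]
  u <- a | t(a)
  diag(u) <- FALSE
  deg <- rowSums(u)
  triples <- sum(choose(deg, 2))
  triangles <- sum(diag(u %*% u %*% u)) / 6
  list(
    cpl = if (length(finite) > 0) mean(finite) else NA_real_,
    transitivity = if (triples > 0) 3 * triangles / triples else 0
  )
}

# Random simple digraph as a reg_network.
rand_digraph <- function(n, p, seed) {
  set.seed(seed)
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < p
  toy_net(paste0("n", sprintf("%02d", pairs$from[keep])),
          paste0("n", sprintf("%02d", pairs$to[keep])))
}

# Exact rank-sum p by enumeration of all group assignments (no ties).
enumerate_ranksum_p <- function(x, y, alternative) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(pooled), nx)
  u_all <- apply(combs, 2, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  if (alternative == "greater") mean(u_all >= u_obs) else mean(u_all <= u_obs)
}
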