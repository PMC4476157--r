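#' Global topological parameters of a regulatory network
#'
#' The four parameters contrasted between developmental and stress-response
#' subnetworks:
#' * `targets_per_tf` — mean out-degree over nodes with out-degree >= 1;
#' * `regulators_per_target` — mean in-degree over nodes with in-degree >= 1;
#' * `char_path_length` — mean directed shortest-path length over ordered
#'   pairs with a finite path (self-pairs excluded; unreachable pairs are
#'   dropped, not imputed);
#' * `clustering_coefficient` — global transitivity (closed / connected
#'   triplets) of the undirected simple projection.
#'
#' @param net A `reg_network`.
#' @return A one-row tibble with the four metrics plus `n_nodes`, `n_edges`.
#' @export
topology_summary <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  if (nrow(net$genes) == 0) abort("Network is empty.")
  topology_metrics(net$edges$regulator, net$edges$target, net$genes$id)
}

# Core metric computation on bare vectors, reused by the subsampler.
topology_metrics <- function(from, to, ids) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to), directed = TRUE,
    vertices = data.frame(name = ids)
  )
  outd <- igraph::degree(g, mode = "out", loops = TRUE)
  ind <- igraph::degree(g, mode = "in", loops = TRUE)
  d <- igraph::distances(g, mode = "out")
  diag(d) <- Inf
  finite <- d[is.finite(d)]
  cpl <- if (length(finite) > 0) mean(finite) else NA_real_
  gu <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
  cc <- igraph::transitivity(gu, type = "global")
  if (is.nan(cc)) cc <- 0
  tibble::tibble(
    targets_per_tf = if (any(outd > 0)) mean(outd[outd > 0]) else NA_real_,
    regulators_per_target = if (any(ind > 0)) mean(ind[ind > 0]) else NA_real_,
    char_path_length = cpl,
    clustering_coefficient = cc,
    n_nodes = length(ids),
    n_edges = length(from)
  )
}

#' Robustness of topology under edge subsampling
#'
#' For each fraction `f`, keeps `round(f * |E|)` regulations chosen
#' uniformly without replacement (all nodes retained), recomputes
#' [topology_summary()], and reports the per-fraction mean and standard
#' deviation of every metric over the replicates. Deterministic for a
#' given seed.
#'
#' @param net A `reg_network`.
#' @param fractions Fractions in (0, 1] (default `seq(0.5, 0.9, 0.1)`).
#' @param replicates Replicates per fraction (default 1000).
#' @param seed Integer RNG seed.
#' @return A tibble of class `reg_subsample` with columns `fraction`,
#'   `metric`, `mean`, `sd`, `replicates`, `n_edges_kept`.
#' @export
subsample_robustness <- function(net, fractions = seq(0.5, 0.9, by = 0.1),
                                 replicates = 1000, seed = 1) {
  stopifnot(inherits(net, "reg_network"))
  if (any(fractions <= 0 | fractions > 1)) {
    abort("`fractions` must lie in (0, 1].")
  }
  if (replicates < 1) abort("`replicates` must be >= 1.")
  m <- nrow(net$edges)
  keep_n <- round(fractions * m)
  if (any(keep_n == 0)) {
    abort("A fraction keeps 0 edges; increase the fraction or the network.")
  }
  metric_names <- c("targets_per_tf", "regulators_per_target",
                    "char_path_length", "clustering_coefficient")
  set.seed(seed)
  res <- purrr::map2_dfr(fractions, keep_n, function(f, k) {
    vals <- matrix(NA_real_, replicates, length(metric_names))
    for (r in seq_len(replicates)) {
      idx <- if (k == m) seq_len(m) else sample.int(m, k)
      ts <- topology_metrics(net$edges$regulator[idx],
                             net$edges$target[idx], net$genes$id)
      vals[r, ] <- unlist(ts[1, metric_names])
    }
    tibble::tibble(
      fraction = f,
      metric = metric_names,
      mean = colMeans(vals, na.rm = TRUE),
      sd = apply(vals, 2, sd, na.rm = TRUE),
      replicates = replicates,
      n_edges_kept = k
    )
  })
  class(res) <- c("reg_subsample", class(res))
  res
}

#' @rdname subsample_robustness
#' @param object A `reg_subsample` tibble.
#' @param ... Unused.
#' @export
autoplot.reg_subsample <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$fraction, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fraction of regulations kept",
                  y = "metric (mean ± SD)")
}
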