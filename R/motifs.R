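.regnet_env <- new.env(parent = emptyenv())

# Lazily built lookup tables for the 64 possible off-diagonal adjacency
# codes of a 3-node digraph. Bit layout (MSB..LSB): (1,2) (1,3) (2,1)
# (2,3) (3,1) (3,2). The canonical code of a triad is the minimum code over
# the 6 node permutations; exactly 13 codes are weakly connected.
triad_tables <- function() {
  if (!is.null(.regnet_env$triad)) return(.regnet_env$triad)
  cells <- cbind(c(1, 1, 2, 2, 3, 3), c(2, 3, 1, 3, 1, 2))
  weights <- c(32, 16, 8, 4, 2, 1)
  code_to_adj <- function(code) {
    a <- matrix(FALSE, 3, 3)
    bits <- bitwAnd(code %/% weights, 1) == 1
    a[cells] <- bits
    a
  }
  adj_to_code <- function(a) sum(weights[a[cells]])
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  canonical <- integer(64)
  connected <- logical(64)
  for (code in 0:63) {
    a <- code_to_adj(code)
    canonical[code + 1] <- min(apply(perms, 1, function(p) {
      adj_to_code(a[p, p, drop = FALSE])
    }))
    links <- c(a[1, 2] || a[2, 1], a[1, 3] || a[3, 1], a[2, 3] || a[3, 2])
    connected[code + 1] <- sum(links) >= 2
  }
  codes <- sort(unique(canonical[connected]))
  stopifnot(length(codes) == 13)
  class_of_code <- rep(NA_integer_, 64)
  class_of_code[connected] <- match(canonical[connected], codes)
  exemplar <- function(edges) {
    a <- matrix(FALSE, 3, 3)
    a[edges] <- TRUE
    canonical[adj_to_code(a) + 1]
  }
  names <- rep(NA_character_, 13)
  name_code <- function(code, nm) names[match(code, codes)] <<- nm
  name_code(exemplar(cbind(c(1, 1), c(2, 3))), "fan-out")
  name_code(exemplar(cbind(c(2, 3), c(1, 1))), "fan-in")
  name_code(exemplar(cbind(c(1, 2), c(2, 3))), "cascade")
  name_code(exemplar(cbind(c(1, 1, 2), c(2, 3, 3))), "feed-forward loop")
  name_code(exemplar(cbind(c(1, 2, 3), c(2, 3, 1))), "three-node cycle")
  name_code(exemplar(cbind(c(1, 2, 1, 3, 2, 3), c(2, 1, 3, 1, 3, 2))),
            "fully mutual")
  .regnet_env$triad <- list(canonical = canonical, connected = connected,
                            codes = codes, class_of_code = class_of_code,
                            names = names)
  .regnet_env$triad
}

#' The 13 weakly connected three-node triad classes
#'
#' @return A tibble with columns `class_id` (1..13, in ascending canonical
#'   code order), `code` (canonical 6-bit adjacency code) and `name`
#'   (display name where one is standard, otherwise `NA`).
#' @export
triad_classes <- function() {
  tt <- triad_tables()
  tibble::tibble(class_id = seq_along(tt$codes), code = tt$codes,
                 name = tt$names)
}

#' Classify a single 3-node adjacency matrix
#'
#' @param adjacency 3x3 logical (or 0/1) matrix; entry \[i, j\] is the edge
#'   i -> j.
#' @param ignore_self_loops Zero the diagonal before classifying
#'   (default TRUE).
#' @return A one-row tibble (`class_id`, `code`, `name`) or `NULL` if the
#'   triad is not weakly connected.
#' @export
classify_triad <- function(adjacency, ignore_self_loops = TRUE) {
  a <- matrix(as.logical(adjacency), 3, 3)
  if (ignore_self_loops) diag(a) <- FALSE
  weights <- c(32, 16, 8, 4, 2, 1)
  cells <- cbind(c(1, 1, 2, 2, 3, 3), c(2, 3, 1, 3, 1, 2))
  code <- sum(weights[a[cells]])
  tt <- triad_tables()
  cls <- tt$class_of_code[code + 1]
  if (is.na(cls)) return(NULL)
  tibble::tibble(class_id = cls, code = tt$codes[cls], name = tt$names[cls])
}

# Integer edge representation (self-loops dropped) shared by the census and
# the randomizer.
edge_ints <- function(net) {
  ids <- net$genes$id
  from <- match(net$edges$regulator, ids)
  to <- match(net$edges$target, ids)
  keep <- from != to
  list(n = length(ids), from = from[keep], to = to[keep], ids = ids)
}

# All weakly connected triples with their triad class.
triad_instances <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  e <- edge_ints(net)
  tt <- triad_tables()
  if (length(e$from) == 0) {
    return(tibble::tibble(i = character(), j = character(), k = character(),
                          class_id = integer()))
  }
  tri <- connected_triples_cpp(e$n, e$from - 1L, e$to - 1L)
  tibble::tibble(i = e$ids[tri[, 1]], j = e$ids[tri[, 2]],
                 k = e$ids[tri[, 3]],
                 class_id = tt$class_of_code[tri[, 4] + 1])
}

#' Three-node triad census
#'
#' Counts every unordered, weakly connected node triple exactly once in
#' exactly one of the 13 triad classes. Triples are enumerated by expanding
#' the neighbourhoods of adjacent node pairs (not by scanning all C(n, 3)
#' triples), so the census scales with the edge structure. Self-loops are
#' ignored for triad typing; edge modes are ignored (the census is
#' unsigned).
#'
#' @param net A `reg_network`.
#' @return A tibble of class `reg_triad_census` with columns `class_id`,
#'   `code`, `name`, `count`; attribute `n_triples_scanned` holds the number
#'   of connected triples.
#' @export
triad_census <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  e <- edge_ints(net)
  tt <- triad_tables()
  counts <- integer(13)
  n_scanned <- 0L
  if (length(e$from) > 0) {
    tri <- connected_triples_cpp(e$n, e$from - 1L, e$to - 1L)
    cls <- tt$class_of_code[tri[, 4] + 1]
    counts <- tabulate(cls, nbins = 13)
    n_scanned <- nrow(tri)
  }
  out <- tibble::tibble(class_id = 1:13, code = tt$codes, name = tt$names,
                        count = counts)
  attr(out, "n_triples_scanned") <- n_scanned
  class(out) <- c("reg_triad_census", class(out))
  out
}

#' Degree-preserving network randomization
#'
#' Repeated double edge swaps: two edges (a, b), (c, d) are rewired to
#' (a, d), (c, b) unless that would create a self-loop or duplicate an
#' existing edge. Every node keeps its exact in- and out-degree. The number
#' of attempted swaps is `swaps_per_edge * |E|`; failed attempts are
#' skipped. Deterministic given `seed`.
#'
#' @param net A `reg_network`.
#' @param swaps_per_edge Attempted swaps per edge (default 100).
#' @param seed Optional integer seed (`set.seed` is called when supplied;
#'   otherwise the current RNG stream is used).
#' @return A `reg_network` with the same gene table; rewired edges carry
#'   mode `"unknown"` and empty evidence.
#' @export
randomize_network <- function(net, swaps_per_edge = 100, seed = NULL) {
  stopifnot(inherits(net, "reg_network"))
  if (swaps_per_edge < 1) abort("`swaps_per_edge` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  ids <- net$genes$id
  from <- match(net$edges$regulator, ids)
  to <- match(net$edges$target, ids)
  if (length(from) >= 2) {
    rw <- rewire_edges_cpp(length(ids), from - 1L, to - 1L,
                           as.integer(swaps_per_edge * length(from)))
    new_from <- rw$from + 1L
    new_to <- rw$to + 1L
    # the swap moves preserve both degree sequences; guard against drift
    stopifnot(identical(tabulate(new_from, length(ids)),
                        tabulate(from, length(ids))),
              identical(tabulate(new_to, length(ids)),
                        tabulate(to, length(ids))))
    from <- new_from
    to <- new_to
  }
  m <- length(from)
  edges <- tibble::tibble(regulator = ids[from], target = ids[to],
                          mode = rep("unknown", m),
                          evidence = rep(list(character()), m),
                          assay = rep(list(character()), m))
  edges <- edges[order(edges$regulator, edges$target), ]
  structure(list(genes = net$genes, edges = edges,
                 name = paste0(net$name, " (randomized)")),
            class = "reg_network")
}

#' Motif enrichment against degree-preserving nulls
#'
#' Compares the observed triad census with the censuses of `n_random`
#' degree-preserving randomizations. For each of the 13 classes the
#' z-score is `(observed - null mean) / null sd` (0 when the sd is 0 and
#' the observed count equals the mean; `Inf` when the sd is 0 and the
#' observed count exceeds it) and the empirical p-value is
#' `(1 + #{null >= observed}) / (1 + n_random)`. A class is flagged as a
#' motif when `p <= p_max`, `z >= z_min` and `observed >= min_count`.
#'
#' @param net A `reg_network`.
#' @param n_random Number of null networks (default 1000).
#' @param swaps_per_edge Attempted swaps per edge per null (default 100).
#' @param seed Integer seed for the null ensemble.
#' @param p_max,z_min,min_count Motif criteria (defaults 0.01, 2, 4).
#' @return A tibble of class `reg_motif_enrichment` with columns
#'   `class_id`, `code`, `name`, `observed`, `null_mean`, `null_sd`,
#'   `z_score`, `empirical_p`, `is_motif`.
#' @export
motif_enrichment <- function(net, n_random = 1000, swaps_per_edge = 100,
                             seed = 1, p_max = 0.01, z_min = 2,
                             min_count = 4) {
  stopifnot(inherits(net, "reg_network"))
  if (n_random < 1) abort("`n_random` must be >= 1.")
  tt <- triad_tables()
  e <- edge_ints(net)
  census_of <- function(from, to) {
    if (length(from) == 0) return(integer(13))
    tri <- connected_triples_cpp(e$n, from - 1L, to - 1L)
    tabulate(tt$class_of_code[tri[, 4] + 1], nbins = 13)
  }
  obs <- census_of(e$from, e$to)
  null_counts <- matrix(0L, n_random, 13)
  set.seed(seed)
  attempts <- as.integer(swaps_per_edge * length(e$from))
  for (b in seq_len(n_random)) {
    if (length(e$from) >= 2) {
      rw <- rewire_edges_cpp(e$n, e$from - 1L, e$to - 1L, attempts)
      null_counts[b, ] <- census_of(rw$from + 1L, rw$to + 1L)
    }
  }
  null_mean <- colMeans(null_counts)
  null_sd <- apply(null_counts, 2, sd)
  z <- ifelse(null_sd > 0, (obs - null_mean) / null_sd,
              ifelse(obs == null_mean, 0,
                     ifelse(obs > null_mean, Inf, -Inf)))
  emp_p <- vapply(1:13, function(i) {
    (1 + sum(null_counts[, i] >= obs[i])) / (1 + n_random)
  }, numeric(1))
  out <- tibble::tibble(
    class_id = 1:13, code = tt$codes, name = tt$names,
    observed = obs, null_mean = null_mean, null_sd = null_sd,
    z_score = z, empirical_p = emp_p,
    is_motif = emp_p <= p_max & z >= z_min & obs >= min_count
  )
  attr(out, "params") <- list(n_random = n_random,
                              swaps_per_edge = swaps_per_edge, seed = seed,
                              p_max = p_max, z_min = z_min,
                              min_count = min_count)
  class(out) <- c("reg_motif_enrichment", class(out))
  out
}

#' @rdname motif_enrichment
#' @param object A `reg_motif_enrichment` tibble.
#' @param ... Unused.
#' @export
autoplot.reg_motif_enrichment <- function(object, ...) {
  df <- dplyr::mutate(object,
                      z_plot = ifelse(is.finite(.data$z_score),
                                      .data$z_score, NA_real_))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$class_id),
                                   y = .data$z_plot,
                                   fill = .data$is_motif)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "triad class", y = "z score vs degree-preserving null",
                  fill = "motif")
}

#' Per-gene motif membership and its process distribution
#'
#' `motif_membership()` counts, for each gene and each requested triad
#' class, the motif instances the gene takes part in (genes in no instance
#' get 0). `motif_process_distribution()` sums those node-level counts by
#' high-level process class.
#'
#' @param net A `reg_network`.
#' @param class_ids Triad class ids (subset of 1..13).
#' @return `motif_membership()`: a tibble `id`, `class_id`, `n_instances`.
#' @export
motif_membership <- function(net, class_ids) {
  class_ids <- as.integer(class_ids)
  if (length(class_ids) == 0 || !all(class_ids %in% 1:13)) {
    abort("`class_ids` must be a non-empty subset of 1..13.")
  }
  inst <- triad_instances(net)
  inst <- inst[inst$class_id %in% class_ids, ]
  long <- tibble::tibble(
    id = c(inst$i, inst$j, inst$k),
    class_id = rep(inst$class_id, 3)
  )
  grid <- tidyr::expand_grid(id = net$genes$id, class_id = class_ids)
  counts <- long |>
    dplyr::count(.data$id, .data$class_id, name = "n_instances")
  dplyr::left_join(grid, counts, by = c("id", "class_id")) |>
    dplyr::mutate(n_instances = dplyr::coalesce(.data$n_instances, 0L))
}

#' @rdname motif_membership
#' @param membership Output of `motif_membership()`.
#' @param gene_classes Output of [classify_genes()] (columns `id`,
#'   `process`).
#' @return `motif_process_distribution()`: a tibble `class_id`, `process`,
#'   `n_instances` (node-level instance counts summed per process).
#' @export
motif_process_distribution <- function(membership, gene_classes) {
  dplyr::inner_join(membership, gene_classes, by = "id") |>
    dplyr::group_by(.data$class_id, .data$process) |>
    dplyr::summarise(n_instances = sum(.data$n_instances), .groups = "drop")
}

#' Mapping between internal triad classes and published motif numbers
#'
#' Published three-node motif figures typically number subgraphs by the
#' Mfinder dictionary; only the feed-forward loop (motif 5 in that
#' numbering) can be identified from its structure alone here, so the other
#' entries ship as `NA` placeholders. Replace them when the structures of
#' the remaining motifs are known for the dataset at hand.
#'
#' @return A tibble `paper_motif`, `class_id`.
#' @export
motif_id_map <- function() {
  ffl <- classify_triad(matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0), 3, 3))$class_id
  tibble::tibble(paper_motif = c(5L, 6L, 10L, 11L, 12L),
                 class_id = c(ffl, NA, NA, NA, NA))
}
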