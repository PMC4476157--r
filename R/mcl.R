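#' Markov clustering of a regulatory network
#'
#' Runs the Markov cluster algorithm on the symmetrized adjacency matrix
#' with unit self-loops: columns are normalized to stochastic, then the
#' process alternates expansion (matrix power) and inflation (entrywise
#' power followed by column renormalization), zeroing entries below
#' `prune_threshold`, until the largest entry change drops below `tol` or
#' `max_iters` is reached. Clusters are read off as the weakly connected
#' components of the non-zero pattern of the limit matrix. The procedure is
#' deterministic.
#'
#' @param net A `reg_network`.
#' @param inflation Inflation exponent, > 1 (default 2).
#' @param expansion Expansion power, >= 2 (default 2).
#' @param prune_threshold Entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param max_iters Iteration cap (default 200).
#' @param tol Convergence threshold on the max entry change (default 1e-6).
#' @return An object of class `reg_clustering`: list with `clusters` (list
#'   of gene-id vectors, largest first), `membership` (tibble `id`,
#'   `cluster`), `inflation`, `iterations_used`, `converged`.
#' @export
mcl <- function(net, inflation = 2, expansion = 2, prune_threshold = 1e-5,
                max_iters = 200, tol = 1e-6) {
  stopifnot(inherits(net, "reg_network"))
  if (inflation <= 1) abort("`inflation` must be > 1.")
  if (expansion < 2) abort("`expansion` must be >= 2.")
  ids <- net$genes$id
  n <- length(ids)
  if (n == 0) abort("Network is empty.")
  from <- match(net$edges$regulator, ids)
  to <- match(net$edges$target, ids)
  a <- Matrix::sparseMatrix(i = c(from, to, seq_len(n)),
                            j = c(to, from, seq_len(n)),
                            x = 1, dims = c(n, n))
  a@x[a@x > 0] <- 1  # simple symmetric adjacency + self-loops
  m <- normalize_cols(a)
  converged <- FALSE
  iters <- 0
  for (it in seq_len(max_iters)) {
    iters <- it
    m_new <- m
    for (e in seq_len(expansion - 1)) m_new <- m_new %*% m
    m_new@x <- m_new@x^inflation
    m_new <- Matrix::drop0(m_new)
    m_new@x[m_new@x < prune_threshold] <- 0
    m_new <- Matrix::drop0(m_new)
    m_new <- normalize_cols(m_new)
    delta <- max(abs(m_new - m))
    m <- m_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn("MCL did not converge; returning best-effort clusters.")
  }
  mt <- methods::as(Matrix::drop0(m), "TsparseMatrix")
  g <- igraph::graph_from_data_frame(
    data.frame(from = mt@i + 1L, to = mt@j + 1L), directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  comp <- igraph::components(g, mode = "weak")$membership
  clusters <- split(ids, comp)
  clusters <- clusters[order(-lengths(clusters),
                             vapply(clusters, min, character(1)))]
  names(clusters) <- NULL
  membership <- tibble::tibble(
    id = unlist(clusters),
    cluster = rep(seq_along(clusters), lengths(clusters))
  )
  structure(list(clusters = clusters, membership = membership,
                 inflation = inflation, iterations_used = iters,
                 converged = converged),
            class = "reg_clustering")
}

normalize_cols <- function(m) {
  cs <- Matrix::colSums(m)
  cs[cs == 0] <- 1
  m %*% Matrix::Diagonal(x = 1 / cs)
}

#' @export
print.reg_clustering <- function(x, ...) {
  cat("<reg_clustering> ", length(x$clusters), " clusters (inflation ",
      x$inflation, ", ", x$iterations_used, " iterations",
      if (!x$converged) ", NOT converged", ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.reg_clustering <- function(x, ...) x$membership

#' @export
glance.reg_clustering <- function(x, ...) {
  tibble::tibble(n_clusters = length(x$clusters),
                 n_genes = nrow(x$membership),
                 largest = max(lengths(x$clusters)),
                 inflation = x$inflation,
                 iterations_used = x$iterations_used,
                 converged = x$converged)
}

#' Label communities by their dominant biological process
#'
#' Communities of at least `min_size` members are labeled with the most
#' frequent specific process term among their annotated members (ties break
#' to the lexicographically smallest term); `coverage` is the fraction of
#' annotated members carrying that term, and a community "corresponds" to a
#' specific process when coverage reaches `coverage_threshold`.
#'
#' @param clustering A [mcl()] result.
#' @param ann A [process_annotation()].
#' @param min_size Smallest community size to report (default 5).
#' @param coverage_threshold Coverage needed to call a correspondence
#'   (default 0.5).
#' @return A tibble `cluster`, `size`, `n_annotated`, `label_term`,
#'   `coverage`, `corresponds`.
#' @export
label_communities <- function(clustering, ann, min_size = 5,
                              coverage_threshold = 0.5) {
  stopifnot(inherits(clustering, "reg_clustering"),
            inherits(ann, "process_annotation"))
  if (min_size < 1) abort("`min_size` must be >= 1.")
  terms <- split(ann$annotations$term, ann$annotations$gene)
  rows <- purrr::imap(clustering$clusters, function(members, ci) {
    if (length(members) < min_size) return(NULL)
    tl <- terms[members]
    annotated <- sum(lengths(tl) > 0)
    if (annotated == 0) {
      return(tibble::tibble(cluster = ci, size = length(members),
                            n_annotated = 0L, label_term = NA_character_,
                            coverage = 0, corresponds = FALSE))
    }
    # per-term number of members carrying it (member counted once per term)
    tab <- table(unlist(lapply(tl, unique)))
    best <- sort(names(tab)[tab == max(tab)])[1]
    cov <- as.integer(tab[best]) / annotated
    tibble::tibble(cluster = ci, size = length(members),
                   n_annotated = as.integer(annotated), label_term = best,
                   coverage = cov,
                   corresponds = cov >= coverage_threshold)
  })
  dplyr::bind_rows(rows)
}
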