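#' Classify genes into high-level process categories
#'
#' A gene is `development` if it carries at least one development-class term
#' and no stress-class term (an "unambiguous" developmental gene),
#' `stress_response` symmetrically, `both` if it carries at least one of
#' each, and `other` otherwise (including unannotated genes).
#'
#' @param ann A [process_annotation()].
#' @param genes Character vector of gene ids to classify.
#' @return A tibble with columns `id` and `process`.
#' @export
classify_genes <- function(ann, genes) {
  stopifnot(inherits(ann, "process_annotation"))
  genes <- as.character(genes)
  cls <- setNames(ann$classes$class, ann$classes$term)
  per_gene <- ann$annotations |>
    dplyr::filter(.data$gene %in% genes) |>
    dplyr::mutate(class = unname(cls[.data$term])) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(dev = any(.data$class == "development"),
                     stress = any(.data$class == "stress_response"))
  out <- tibble::tibble(id = genes) |>
    dplyr::left_join(per_gene, by = c(id = "gene")) |>
    dplyr::mutate(
      dev = dplyr::coalesce(.data$dev, FALSE),
      stress = dplyr::coalesce(.data$stress, FALSE),
      process = dplyr::case_when(
        .data$dev & .data$stress ~ "both",
        .data$dev ~ "development",
        .data$stress ~ "stress_response",
        TRUE ~ "other"
      )
    )
  out[, c("id", "process")]
}

#' Co-annotation quality of a regulatory network
#'
#' The fraction of regulator-target pairs sharing at least one biological
#' process term is a standard proxy for the quality of a curated regulatory
#' map: true regulatory pairs tend to act in the same processes. Only pairs
#' where both genes carry at least one term enter the denominator — absence
#' of annotation is not evidence of a process mismatch. When a baseline
#' `(k, n)` from a comparison network is supplied, the proportion is tested
#' against it with a one-tailed exact binomial test (null proportion
#' `k / n`, alternative greater).
#'
#' @param net A `reg_network`.
#' @param ann A [process_annotation()].
#' @param baseline Optional length-2 numeric `c(k, n)`: co-annotated and
#'   eligible pair counts of the comparison network.
#' @return An object of class `reg_quality`: list with `n_pairs`,
#'   `n_coannotated`, `proportion` and (optionally) `comparison`
#'   (a [reg_test()]) and `baseline_proportion`.
#' @export
coannotation_quality <- function(net, ann, baseline = NULL) {
  stopifnot(inherits(net, "reg_network"), inherits(ann, "process_annotation"))
  if (nrow(net$edges) == 0) abort("Network has no regulations.")
  terms <- split(ann$annotations$term, ann$annotations$gene)
  reg_terms <- terms[net$edges$regulator]
  tgt_terms <- terms[net$edges$target]
  eligible <- lengths(reg_terms) > 0 & lengths(tgt_terms) > 0
  n_pairs <- sum(eligible)
  if (n_pairs == 0) abort("No regulation has both endpoints annotated.")
  shared <- mapply(function(a, b) length(intersect(a, b)) > 0,
                   reg_terms[eligible], tgt_terms[eligible])
  n_co <- sum(shared)
  comparison <- NULL
  baseline_prop <- NULL
  if (!is.null(baseline)) {
    stopifnot(length(baseline) == 2)
    baseline_prop <- baseline[1] / baseline[2]
    comparison <- binom_test(n_co, n_pairs, baseline_prop, "greater")
  }
  structure(list(n_pairs = n_pairs, n_coannotated = n_co,
                 proportion = n_co / n_pairs,
                 baseline_proportion = baseline_prop,
                 comparison = comparison),
            class = "reg_quality")
}

#' @export
print.reg_quality <- function(x, ...) {
  cat("<reg_quality> ", x$n_coannotated, "/", x$n_pairs,
      " co-annotated pairs (", format(100 * x$proportion, digits = 3),
      "%)\n", sep = "")
  if (!is.null(x$comparison)) {
    cat("  vs baseline ", format(100 * x$baseline_proportion, digits = 3),
        "%: p = ", format(x$comparison$p_value, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' @export
glance.reg_quality <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, n_coannotated = x$n_coannotated,
                 proportion = x$proportion,
                 baseline_proportion = x$baseline_proportion %||% NA_real_,
                 p_value = if (is.null(x$comparison)) NA_real_ else
                   x$comparison$p_value)
}

#' Per-term over-representation of a gene set
#'
#' Hypergeometric enrichment of every annotated term with at least one hit
#' in the gene set, against a background universe, with optional
#' Benjamini-Hochberg adjustment across the tested terms.
#'
#' @param gene_set Character vector of gene ids, a subset of `background`.
#' @param background Character vector of gene ids (the universe).
#' @param ann A [process_annotation()].
#' @param correction `"bh"` (default) or `"none"`.
#' @return A tibble with columns `term`, `k`, `K`, `n`, `N`, `p_value`,
#'   `p_adjusted`, sorted by `p_value`.
#' @export
go_enrichment <- function(gene_set, background, ann,
                          correction = c("bh", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(ann, "process_annotation"))
  background <- unique(as.character(background))
  gene_set <- unique(as.character(gene_set))
  if (length(background) == 0) abort("`background` is empty.")
  if (!all(gene_set %in% background)) {
    abort("`gene_set` must be a subset of `background`.")
  }
  anno <- ann$annotations[ann$annotations$gene %in% background, ]
  N <- length(background)
  n <- length(gene_set)
  res <- anno |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(K = dplyr::n_distinct(.data$gene),
                     k = dplyr::n_distinct(.data$gene[.data$gene %in% gene_set])) |>
    dplyr::filter(.data$k > 0) |>
    dplyr::mutate(n = n, N = N)
  res$p_value <- purrr::pmap_dbl(res[, c("k", "K", "n", "N")],
                                 function(k, K, n, N) {
                                   hypergeom_enrichment(k, K, n, N)$p_value
                                 })
  res$p_adjusted <- if (correction == "bh") {
    p.adjust(res$p_value, method = "BH")
  } else {
    res$p_value
  }
  dplyr::arrange(res[, c("term", "k", "K", "n", "N", "p_value", "p_adjusted")],
                 .data$p_value)
}

#' Recall of a reference pathway
#'
#' Compares the network against a reference set of directed edges (for
#' example a pathway summarized in a review): `recovered` are reference
#' edges present in the network (direction-sensitive, mode-insensitive),
#' `novel` are network edges among the reference-pathway genes that the
#' reference does not list.
#'
#' @param net A `reg_network`.
#' @param reference_edges Data frame with columns `regulator`, `target`.
#' @return An object of class `reg_recall`: list with tibbles
#'   `reference_edges`, `recovered`, `novel` and the scalar `recall`.
#' @export
pathway_recall <- function(net, reference_edges) {
  stopifnot(inherits(net, "reg_network"))
  ref <- dplyr::distinct(
    tibble::as_tibble(reference_edges)[, c("regulator", "target")]
  )
  ref$regulator <- as.character(ref$regulator)
  ref$target <- as.character(ref$target)
  net_keys <- paste(net$edges$regulator, net$edges$target, sep = "\r")
  ref_keys <- paste(ref$regulator, ref$target, sep = "\r")
  recovered <- ref[ref_keys %in% net_keys, ]
  path_genes <- unique(c(ref$regulator, ref$target))
  among <- net$edges$regulator %in% path_genes &
    net$edges$target %in% path_genes
  novel <- net$edges[among & !(net_keys %in% ref_keys),
                     c("regulator", "target")]
  structure(list(reference_edges = ref, recovered = recovered,
                 novel = novel,
                 recall = nrow(recovered) / nrow(ref)),
            class = "reg_recall")
}

#' @export
print.reg_recall <- function(x, ...) {
  cat("<reg_recall> ", nrow(x$recovered), "/", nrow(x$reference_edges),
      " reference edges recovered (recall ",
      format(x$recall, digits = 3), "); ", nrow(x$novel),
      " novel edges\n", sep = "")
  invisible(x)
}

#' @export
glance.reg_recall <- function(x, ...) {
  tibble::tibble(n_reference = nrow(x$reference_edges),
                 n_recovered = nrow(x$recovered),
                 n_novel = nrow(x$novel),
                 recall = x$recall)
}
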