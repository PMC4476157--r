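#' Build a regulatory network from an edge table
#'
#' A regulatory network couples a gene table (locus id, optional symbol,
#' TF flag, TF family) with a directed, signed edge table of regulations.
#' Duplicate (regulator, target) rows are merged: evidence sets are unioned
#' and conflicting modes are promoted to `"dual"` (`"unknown"` yields to any
#' informative mode). Self-regulations are allowed.
#'
#' Transcription factors are identified from the regulator role unless an
#' explicit TF list is supplied (targets can be TFs without outgoing edges
#' in a curated map, so a sidecar list is more faithful when available).
#'
#' @param edges Data frame with columns `regulator` and `target`, and
#'   optionally `mode` (one of activation/repression/dual/unknown),
#'   `evidence` (character, `;`-separated, or a list column of character
#'   vectors) and `assay` (subset of in_vitro/in_vivo, `;`-separated).
#' @param genes Optional data frame with column `id` and optionally
#'   `symbol` and `family`; lists additional genes and TF family labels.
#' @param tf_ids Optional character vector of TF ids. When supplied, every
#'   regulator must be listed in it and `is_tf` is taken from it.
#' @param name Label for the network.
#' @return An object of class `reg_network`: a list with tibbles `genes`
#'   (`id`, `symbol`, `is_tf`, `family`) and `edges` (`regulator`, `target`,
#'   `mode`, list columns `evidence`, `assay`), plus `name`.
#' @examples
#' net <- reg_network(tibble::tibble(
#'   regulator = c("A", "A", "B"),
#'   target    = c("B", "C", "C"),
#'   mode      = c("activation", "repression", "activation")
#' ))
#' glance(net)
#' @export
reg_network <- function(edges, genes = NULL, tf_ids = NULL, name = "network") {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0 &&
      !all(c("regulator", "target") %in% names(edges))) {
    abort("`edges` must have columns `regulator` and `target`.")
  }
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(regulator = character(), target = character(),
                            mode = character(), evidence = list(),
                            assay = list())
  }
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  if (any(edges$regulator == "" | edges$target == "")) {
    abort("Gene ids must be non-empty.")
  }
  if (!"mode" %in% names(edges)) edges$mode <- "unknown"
  edges$mode[is.na(edges$mode) | edges$mode == ""] <- "unknown"
  bad <- setdiff(unique(edges$mode),
                 c("activation", "repression", "dual", "unknown"))
  if (length(bad) > 0) {
    abort(paste0("Unknown regulation mode(s): ", paste(bad, collapse = ", ")))
  }
  edges$evidence <- canon_setcol(edges[["evidence"]], nrow(edges))
  edges$assay <- canon_setcol(edges[["assay"]], nrow(edges))
  bad_assay <- setdiff(unlist(edges$assay), c("in_vitro", "in_vivo"))
  if (length(bad_assay) > 0) {
    abort(paste0("Unknown assay value(s): ", paste(bad_assay, collapse = ", ")))
  }

  edges <- merge_edges(edges)

  ids <- sort(unique(c(edges$regulator, edges$target,
                       if (!is.null(genes)) as.character(genes$id))))
  gene_tbl <- tibble::tibble(id = ids, symbol = NA_character_,
                             is_tf = FALSE, family = NA_character_)
  if (!is.null(genes)) {
    genes <- tibble::as_tibble(genes)
    if (anyDuplicated(genes$id)) abort("Duplicate ids in `genes`.")
    idx <- match(genes$id, gene_tbl$id)
    if ("symbol" %in% names(genes)) {
      gene_tbl$symbol[idx] <- as.character(genes$symbol)
    }
    if ("family" %in% names(genes)) {
      gene_tbl$family[idx] <- as.character(genes$family)
    }
  }
  if (!is.null(tf_ids)) {
    tf_ids <- as.character(tf_ids)
    missing_tf <- setdiff(unique(edges$regulator), tf_ids)
    if (length(missing_tf) > 0) {
      abort(paste0("Regulator(s) absent from the TF table: ",
                   paste(head(missing_tf, 5), collapse = ", ")))
    }
    gene_tbl$is_tf <- gene_tbl$id %in% tf_ids
  } else {
    gene_tbl$is_tf <- gene_tbl$id %in% edges$regulator
  }
  # family labels only make sense for TFs
  gene_tbl$family[!gene_tbl$is_tf] <- NA_character_

  structure(list(genes = gene_tbl, edges = edges, name = name),
            class = "reg_network")
}

# Normalize an evidence/assay column to a list of sorted unique character
# vectors (accepts missing, ';'-separated strings, or list columns).
canon_setcol <- function(x, n) {
  if (is.null(x)) return(rep(list(character()), n))
  if (!is.list(x)) {
    x <- lapply(as.character(x), function(s) {
      if (is.na(s) || s == "") character() else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  }
  lapply(x, function(v) sort(unique(as.character(v[!is.na(v) & v != ""]))))
}

merge_edges <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  key <- paste(edges$regulator, edges$target, sep = "\r")
  ord <- order(edges$regulator, edges$target)
  edges <- edges[ord, ]
  key <- key[ord]
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  out <- edges[first, ]
  if (anyDuplicated(grp)) {
    out$mode <- unname(vapply(split(edges$mode, grp), merge_modes,
                              character(1)))
    out$evidence <- unname(lapply(split(edges$evidence, grp),
                                  function(e) sort(unique(unlist(e)))))
    out$assay <- unname(lapply(split(edges$assay, grp),
                               function(e) sort(unique(unlist(e)))))
  }
  out
}

merge_modes <- function(modes) {
  m <- setdiff(unique(modes), "unknown")
  if (length(m) == 0) return("unknown")
  if (length(m) == 1) return(m)
  "dual"
}

#' @export
print.reg_network <- function(x, ...) {
  cat("<reg_network> ", x$name, "\n", sep = "")
  cat("  genes: ", nrow(x$genes), " (", sum(x$genes$is_tf), " TFs)\n", sep = "")
  cat("  regulations: ", nrow(x$edges), "\n", sep = "")
  invisible(x)
}

#' Convert a regulatory network to an igraph graph
#'
#' @param net A `reg_network`.
#' @return An igraph directed graph whose vertices carry `is_tf` and `family`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  igraph::graph_from_data_frame(
    d = as.data.frame(net$edges[, c("regulator", "target")]),
    directed = TRUE,
    vertices = as.data.frame(net$genes[, c("id", "is_tf", "family")])
  )
}

#' Summary counts for a regulatory network
#'
#' Reports the counts a curation effort is described by: genes, TFs, TF
#' families, regulations, distinct supporting publications, and the edge
#' count per regulatory mode.
#'
#' @param net A `reg_network`.
#' @return A one-row tibble with columns `genes`, `tfs`, `families`,
#'   `regulations`, `evidence_ids`, `activation`, `repression`, `dual`,
#'   `unknown`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  tibble::tibble(
    genes = nrow(net$genes),
    tfs = sum(net$genes$is_tf),
    families = length(unique(net$genes$family[net$genes$is_tf &
                                                !is.na(net$genes$family)])),
    regulations = nrow(net$edges),
    evidence_ids = length(unique(unlist(net$edges$evidence))),
    activation = sum(net$edges$mode == "activation"),
    repression = sum(net$edges$mode == "repression"),
    dual = sum(net$edges$mode == "dual"),
    unknown = sum(net$edges$mode == "unknown")
  )
}

#' @rdname network_summary
#' @param x A `reg_network`.
#' @param ... Unused.
#' @export
glance.reg_network <- function(x, ...) network_summary(x)

#' @export
tidy.reg_network <- function(x, ...) {
  dplyr::mutate(
    x$edges,
    evidence = vapply(.data$evidence, paste, character(1), collapse = ";"),
    assay = vapply(.data$assay, paste, character(1), collapse = ";")
  )
}

#' Largest weakly connected component
#'
#' Returns the subnetwork induced by the largest weakly connected component;
#' ties are broken in favour of the component containing the
#' lexicographically smallest gene id.
#'
#' @param net A `reg_network`.
#' @return A `reg_network`.
#' @export
largest_connected_component <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  if (nrow(net$genes) == 0) return(net)
  comp <- igraph::components(as_igraph(net), mode = "weak")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # smallest lexicographic member decides
    firsts <- vapply(best, function(ci) {
      min(net$genes$id[comp$membership == ci])
    }, character(1))
    best <- best[order(firsts)][1]
  }
  keep <- net$genes$id[comp$membership == best]
  extract_subnetwork(net, keep)
}

#' Induced subnetwork on a gene set
#'
#' Keeps the given genes and the regulations with both endpoints inside the
#' set (used e.g. to extract interregulations among unambiguous
#' developmental or stress-response genes).
#'
#' @param net A `reg_network`.
#' @param gene_set Character vector of gene ids, all present in `net`.
#' @return A `reg_network`.
#' @export
extract_subnetwork <- function(net, gene_set) {
  stopifnot(inherits(net, "reg_network"))
  gene_set <- unique(as.character(gene_set))
  missing <- setdiff(gene_set, net$genes$id)
  if (length(missing) > 0) {
    abort(paste0("Unknown gene id(s): ", paste(head(missing, 5), collapse = ", ")))
  }
  genes <- net$genes[net$genes$id %in% gene_set, ]
  edges <- net$edges[net$edges$regulator %in% gene_set &
                       net$edges$target %in% gene_set, ]
  structure(list(genes = genes, edges = edges, name = net$name),
            class = "reg_network")
}
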