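#' Read a regulatory network from TSV or SIF
#'
#' The canonical edge-list dialect is UTF-8, tab-separated, `#`-prefixed
#' comment lines, and a required header with columns `regulator`, `target`
#' and optionally `mode`, `evidence` (`;`-separated publication ids) and
#' `assay` (`;`-separated subset of `in_vitro`, `in_vivo`). SIF input is
#' headerless `regulator<TAB>relation<TAB>target`; the relation token is
#' mapped onto a regulatory mode (`activates`/`activation`/`+` ->
#' activation, `represses`/`repression`/`-` -> repression, `dual` -> dual,
#' anything else -> unknown).
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"sif"`.
#' @param tf_ids Optional character vector (or path to a one-column file) of
#'   TF ids; see [reg_network()].
#' @param name Network label; defaults to the file name.
#' @return A [reg_network()].
#' @export
read_network <- function(path, format = c("tsv", "sif"), tf_ids = NULL,
                         name = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (is.character(tf_ids) && length(tf_ids) == 1 && file.exists(tf_ids)) {
    tf_ids <- read_id_column(tf_ids)
  }
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(reg_network(tibble::tibble(regulator = character(),
                                      target = character()),
                       tf_ids = tf_ids, name = name))
  }
  # sentinel keeps trailing empty fields from being dropped by strsplit
  fields <- lapply(strsplit(paste0(lines, "\t\x01"), "\t", fixed = TRUE),
                   function(f) f[-length(f)])
  if (format == "tsv") {
    header <- fields[[1]]
    if (!all(c("regulator", "target") %in% header)) {
      abort("TSV header must contain `regulator` and `target` columns.")
    }
    fields <- fields[-1]
    lineno <- lineno[-1]
    nf <- lengths(fields)
    bad <- which(nf != length(header))
    if (length(bad) > 0) {
      abort(paste0("Malformed row at line ", lineno[bad[1]], ": expected ",
                   length(header), " fields, found ", nf[bad[1]], "."))
    }
    if (length(fields) == 0) {
      edges <- tibble::tibble(regulator = character(), target = character())
    } else {
      mat <- do.call(rbind, fields)
      colnames(mat) <- header
      edges <- tibble::as_tibble(mat)
    }
  } else {
    nf <- lengths(fields)
    bad <- which(nf != 3)
    if (length(bad) > 0) {
      abort(paste0("Malformed SIF row at line ", lineno[bad[1]],
                   ": expected 3 fields, found ", nf[bad[1]], "."))
    }
    mat <- do.call(rbind, fields)
    edges <- tibble::tibble(regulator = mat[, 1],
                            mode = sif_relation_to_mode(mat[, 2]),
                            target = mat[, 3])
  }
  reg_network(edges, tf_ids = tf_ids, name = name)
}

sif_relation_to_mode <- function(rel) {
  rel <- tolower(rel)
  dplyr::case_when(
    rel %in% c("activates", "activation", "+") ~ "activation",
    rel %in% c("represses", "repression", "-") ~ "repression",
    rel == "dual" ~ "dual",
    TRUE ~ "unknown"
  )
}

read_id_column <- function(path) {
  x <- readLines(path, encoding = "UTF-8")
  x <- trimws(x[!grepl("^\\s*#", x)])
  x[nzchar(x)]
}

#' Write a regulatory network in the canonical TSV dialect
#'
#' Rows are sorted by (regulator, target) and set-valued columns are
#' `;`-joined in sorted order, so `read_network()` followed by
#' `write_network()` round-trips bit-identically.
#'
#' @param net A `reg_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "reg_network"))
  e <- net$edges[order(net$edges$regulator, net$edges$target), ]
  rows <- paste(e$regulator, e$target, e$mode,
                vapply(e$evidence, paste, character(1), collapse = ";"),
                vapply(e$assay, paste, character(1), collapse = ";"),
                sep = "\t")
  writeLines(c("regulator\ttarget\tmode\tevidence\tassay", rows),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read gene-to-process annotations
#'
#' Builds a [process_annotation()] from either a two-column TSV
#' (`gene<TAB>term`) or a GAF 2.x subset. For GAF input only biological
#' process rows (aspect `P`) with experimental evidence codes
#' (EXP/IDA/IPI/IMP/IGI/IEP) are kept; other rows are skipped with a
#' message. Term classes (development / stress_response / other) come from
#' an optional two-column file `term<TAB>class`; unlisted terms default to
#' `other`.
#'
#' @param path Annotation file path.
#' @param format `"two_col_tsv"` or `"gaf_subset"`.
#' @param class_path Optional path of the `term<TAB>class` table, or a data
#'   frame with columns `term`, `class`.
#' @return A [process_annotation()].
#' @export
read_annotation <- function(path, format = c("two_col_tsv", "gaf_subset"),
                            class_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*[#!]", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "two_col_tsv") {
    bad <- which(lengths(fields) < 2)
    if (length(bad) > 0) abort(paste0("Malformed annotation row ", bad[1], "."))
    ann <- tibble::tibble(gene = vapply(fields, `[[`, "", 1),
                          term = vapply(fields, `[[`, "", 2))
  } else {
    exp_codes <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")
    ok <- vapply(fields, function(f) {
      length(f) >= 9 && f[9] == "P" && f[7] %in% exp_codes
    }, logical(1))
    if (any(!ok)) {
      message(sum(!ok), " GAF row(s) skipped (non-BP aspect or ",
              "non-experimental evidence).")
    }
    fields <- fields[ok]
    ann <- tibble::tibble(gene = vapply(fields, `[[`, "", 2),
                          term = vapply(fields, `[[`, "", 5))
  }
  classes <- NULL
  if (!is.null(class_path)) {
    if (is.data.frame(class_path)) {
      classes <- tibble::as_tibble(class_path)
    } else {
      cl <- readLines(class_path, encoding = "UTF-8")
      cl <- cl[!grepl("^\\s*#", cl) & nzchar(trimws(cl))]
      cf <- strsplit(cl, "\t", fixed = TRUE)
      classes <- tibble::tibble(term = vapply(cf, `[[`, "", 1),
                                class = vapply(cf, `[[`, "", 2))
    }
  }
  process_annotation(ann, classes)
}

#' Gene-to-process annotation container
#'
#' @param annotations Data frame with columns `gene`, `term`.
#' @param classes Optional data frame with columns `term`, `class`, class
#'   one of `development`, `stress_response`, `other`. Terms without an
#'   entry are classed `other`.
#' @return An object of class `process_annotation` with tibbles
#'   `annotations` (distinct gene-term pairs) and `classes` (one row per
#'   term seen).
#' @export
process_annotation <- function(annotations, classes = NULL) {
  annotations <- dplyr::distinct(
    tibble::as_tibble(annotations)[, c("gene", "term")]
  )
  annotations$gene <- as.character(annotations$gene)
  annotations$term <- as.character(annotations$term)
  terms <- sort(unique(annotations$term))
  cls <- tibble::tibble(term = terms, class = "other")
  if (!is.null(classes)) {
    classes <- tibble::as_tibble(classes)
    bad <- setdiff(unique(classes$class),
                   c("development", "stress_response", "other"))
    if (length(bad) > 0) {
      abort(paste0("Unknown term class(es): ", paste(bad, collapse = ", ")))
    }
    extra <- setdiff(classes$term, terms)
    if (length(extra) > 0) {
      cls <- dplyr::bind_rows(cls, tibble::tibble(term = extra, class = "other"))
    }
    idx <- match(classes$term, cls$term)
    cls$class[idx] <- classes$class
  }
  structure(list(annotations = annotations, classes = cls),
            class = "process_annotation")
}

#' @export
print.process_annotation <- function(x, ...) {
  cat("<process_annotation> ", length(unique(x$annotations$gene)),
      " genes, ", nrow(x$classes), " terms\n", sep = "")
  invisible(x)
}

#' Read TF binding matrices
#'
#' Supports JASPAR-style count matrices (`>ID name` header, then four rows
#' `A [ ... ]` .. `T [ ... ]`) and a plain probability TSV (`tf_id`, `base`,
#' then one column per position). Counts are converted to probabilities as
#' `(count + pseudocount) / (column_total + 4 * pseudocount)`.
#'
#' @param path File path.
#' @param format `"jaspar_counts"` or `"probs_tsv"`.
#' @param pseudocount Nonnegative pseudocount for count input (default 0).
#' @return A named list of [binding_matrix()] objects.
#' @export
read_binding_matrices <- function(path, format = c("jaspar_counts", "probs_tsv"),
                                  pseudocount = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (pseudocount < 0) abort("`pseudocount` must be >= 0.")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  if (format == "jaspar_counts") {
    starts <- grep("^>", lines)
    if (length(starts) == 0) abort("No JASPAR records found.")
    ends <- c(starts[-1] - 1, length(lines))
    for (r in seq_along(starts)) {
      hdr <- sub("^>\\s*", "", lines[starts[r]])
      tf_id <- strsplit(hdr, "\\s+")[[1]][1]
      body <- lines[(starts[r] + 1):ends[r]]
      if (length(body) < 4) abort(paste0("Record ", tf_id, ": expected 4 base rows."))
      counts <- matrix(0, 4, 0)
      rows <- list()
      for (b in body[1:4]) {
        base <- sub("^\\s*([ACGTacgt]).*", "\\1", b)
        nums <- gsub("^[^\\[]*\\[|\\]\\s*$", "", b)
        vals <- as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
        rows[[toupper(base)]] <- vals
      }
      if (!setequal(names(rows), c("A", "C", "G", "T"))) {
        abort(paste0("Record ", tf_id, ": rows must be A, C, G, T."))
      }
      if (length(unique(lengths(rows))) != 1) {
        abort(paste0("Record ", tf_id, ": width mismatch across base rows."))
      }
      counts <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
      out[[tf_id]] <- binding_matrix(tf_id, counts = counts,
                                     pseudocount = pseudocount)
    }
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- fields[[1]]
    if (!all(c("tf_id", "base") %in% header[1:2])) {
      abort("Probability TSV must start with columns `tf_id`, `base`.")
    }
    fields <- fields[-1]
    mat <- do.call(rbind, fields)
    ids <- unique(mat[, 1])
    for (tf_id in ids) {
      block <- mat[mat[, 1] == tf_id, , drop = FALSE]
      ord <- match(c("A", "C", "G", "T"), block[, 2])
      if (anyNA(ord)) abort(paste0("Record ", tf_id, ": rows must be A, C, G, T."))
      probs <- apply(block[ord, -(1:2), drop = FALSE], 2, as.numeric)
      probs <- matrix(probs, nrow = 4,
                      dimnames = list(c("A", "C", "G", "T"), NULL))
      out[[tf_id]] <- binding_matrix(tf_id, probs = probs)
    }
  }
  out
}

#' Binding matrix (position weight matrix) container
#'
#' @param tf_id TF gene id.
#' @param probs Optional 4 x W probability matrix (rows A, C, G, T); every
#'   column must sum to 1 within 1e-9.
#' @param counts Optional 4 x W nonnegative count matrix; converted to
#'   probabilities with `pseudocount`.
#' @param pseudocount Pseudocount used for count input.
#' @return An object of class `binding_matrix` with fields `tf_id`, `width`,
#'   `probs` and (if given) `counts`.
#' @export
binding_matrix <- function(tf_id, probs = NULL, counts = NULL,
                           pseudocount = 0) {
  if (is.null(probs) && is.null(counts)) {
    abort("Supply `probs` or `counts`.")
  }
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (nrow(counts) != 4 || any(counts < 0)) {
      abort("`counts` must be a nonnegative 4 x W matrix.")
    }
    tot <- colSums(counts) + 4 * pseudocount
    if (any(tot == 0)) {
      abort("All-zero count column with pseudocount 0.")
    }
    probs <- sweep(counts + pseudocount, 2, tot, "/")
  }
  probs <- as.matrix(probs)
  if (nrow(probs) != 4 || any(probs < 0)) {
    abort("`probs` must be a nonnegative 4 x W matrix.")
  }
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    abort("Each probability column must sum to 1 (within 1e-9).")
  }
  rownames(probs) <- c("A", "C", "G", "T")
  structure(list(tf_id = as.character(tf_id), width = ncol(probs),
                 probs = probs, counts = counts),
            class = "binding_matrix")
}

#' @export
print.binding_matrix <- function(x, ...) {
  cat("<binding_matrix> ", x$tf_id, ": width ", x$width, ", ",
      format(information_content(x), digits = 4), " bits\n", sep = "")
  invisible(x)
}

#' Read a TF-family presence/absence matrix
#'
#' The TSV has a `family` column followed by one column per species whose
#' header encodes the species id, clade and divergence-order rank as
#' `id:clade:rank` with clade one of `green_alga`, `land_plant` (rank 1 is
#' the earliest-diverging lineage). Cells are 0/1.
#'
#' @param path File path.
#' @return A [presence_matrix()].
#' @export
read_presence_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]][-1]
  sp <- strsplit(header, ":", fixed = TRUE)
  bad <- which(lengths(sp) != 3)
  if (length(bad) > 0) {
    abort(paste0("Species header must be id:clade:rank, got `",
                 header[bad[1]], "`."))
  }
  species <- tibble::tibble(
    species = vapply(sp, `[[`, "", 1),
    clade = vapply(sp, `[[`, "", 2),
    rank = as.numeric(vapply(sp, `[[`, "", 3))
  )
  body <- fields[-1]
  fam <- vapply(body, `[[`, "", 1)
  pres <- do.call(rbind, lapply(body, function(f) as.integer(f[-1]) != 0L))
  rownames(pres) <- fam
  colnames(pres) <- species$species
  presence_matrix(fam, species, pres)
}

#' TF-family presence/absence container
#'
#' @param families Character vector of family names.
#' @param species Data frame with columns `species`, `clade` (one of
#'   `green_alga`, `land_plant`) and numeric `rank` (divergence order,
#'   1 = earliest).
#' @param present Logical families x species matrix.
#' @return An object of class `presence_matrix`.
#' @export
presence_matrix <- function(families, species, present) {
  species <- tibble::as_tibble(species)
  bad <- setdiff(unique(species$clade), c("green_alga", "land_plant"))
  if (length(bad) > 0) {
    abort(paste0("Unknown clade label(s): ", paste(bad, collapse = ", ")))
  }
  if (!all(c("green_alga", "land_plant") %in% species$clade)) {
    abort("Need at least one species per clade (green_alga and land_plant).")
  }
  present <- as.matrix(present) != 0
  if (nrow(present) != length(families) || ncol(present) != nrow(species)) {
    abort("`present` must be families x species.")
  }
  if (any(rowSums(present) == 0)) {
    abort("Every family must be present in at least one species.")
  }
  dimnames(present) <- list(families, species$species)
  structure(list(families = as.character(families), species = species,
                 present = present),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("<presence_matrix> ", length(x$families), " families x ",
      nrow(x$species), " species\n", sep = "")
  invisible(x)
}
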