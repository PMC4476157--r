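#' Run the full regulatory-map analysis
#'
#' Orchestrates every stage of the analysis on a compatible dataset, in
#' order: network summary, co-annotation quality (plus optional
#' reference-pathway recall), process classification and subnetwork
#' extraction, subnetwork topology with subsampling, motif enrichment with
#' membership and process distribution, Markov clustering with community
#' labels, binding-specificity analysis with the IC-wiring correlation, and
#' family dating with the wiring-preference battery. Stages whose inputs
#' are missing are skipped and recorded; a failing stage is recorded and
#' its dependents are skipped. The JSON report has stable key ordering and
#' contains no timestamps, so identical inputs and seeds reproduce it
#' byte-identically.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognized entries: `network` (path or `reg_network`), `tf_ids`,
#'   `annotation` (path or `process_annotation`), `annotation_classes`,
#'   `matrices` (path or list of [binding_matrix()]), `matrices_format`,
#'   `pseudocount`, `presence` (path or `presence_matrix`),
#'   `reference_pathway` (path or data frame), `baseline` (`c(k, n)`),
#'   `out_dir`, `seed`, and the parameter block `params` with any of
#'   `fractions`, `replicates`, `n_random`, `swaps_per_edge`, `p_max`,
#'   `z_min`, `min_count`, `inflation`, `min_size`, `coverage_threshold`,
#'   `novel_classes`, `ancient_classes`.
#' @return An object of class `reg_report` (a named list of stage results,
#'   plus `provenance`), invisibly written to `out_dir/report.json` and
#'   per-stage TSVs when `out_dir` is set.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1
  params <- config$params %||% list()
  p <- function(name, default) params[[name]] %||% default
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  stages <- list()
  status <- list()
  run_stage <- function(name, needs_ok = character(), fn) {
    blocked <- needs_ok[!vapply(needs_ok, function(s) {
      identical(status[[s]], "ok")
    }, logical(1))]
    if (length(blocked) > 0) {
      status[[name]] <<- "skipped"
      stages[[name]] <<- list(skipped = paste0("requires: ",
                                               paste(blocked, collapse = ", ")))
      return(invisible(NULL))
    }
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      status[[name]] <<- "failed"
      stages[[name]] <<- list(error = conditionMessage(res))
    } else if (is.null(res)) {
      status[[name]] <<- "skipped"
      stages[[name]] <<- list(skipped = "missing input")
    } else {
      status[[name]] <<- "ok"
      stages[[name]] <<- res
    }
    invisible(NULL)
  }

  # ---- inputs ------------------------------------------------------------
  net <- NULL
  if (!is.null(config$network)) {
    net <- if (inherits(config$network, "reg_network")) config$network else
      read_network(config$network, tf_ids = config$tf_ids)
  }
  ann <- NULL
  if (!is.null(config$annotation)) {
    ann <- if (inherits(config$annotation, "process_annotation")) {
      config$annotation
    } else {
      read_annotation(config$annotation,
                      class_path = config$annotation_classes)
    }
  }
  matrices <- NULL
  if (!is.null(config$matrices)) {
    matrices <- if (is.list(config$matrices) &&
                      !is.character(config$matrices)) {
      config$matrices
    } else {
      read_binding_matrices(config$matrices,
                            format = config$matrices_format %||%
                              "jaspar_counts",
                            pseudocount = config$pseudocount %||% 0)
    }
  }
  presence <- NULL
  if (!is.null(config$presence)) {
    presence <- if (inherits(config$presence, "presence_matrix")) {
      config$presence
    } else {
      read_presence_matrix(config$presence)
    }
  }
  reference <- config$reference_pathway
  if (is.character(reference)) {
    ref_lines <- readLines(reference)
    ref_lines <- ref_lines[!grepl("^\\s*#", ref_lines) & nzchar(ref_lines)]
    rf <- strsplit(ref_lines, "\t", fixed = TRUE)
    reference <- tibble::tibble(regulator = vapply(rf, `[[`, "", 1),
                                target = vapply(rf, `[[`, "", 2))
    if (reference$regulator[1] == "regulator") reference <- reference[-1, ]
  }

  if (is.null(net)) abort("`config$network` is required.")

  # ---- stages ------------------------------------------------------------
  run_stage("summary", fn = function() network_summary(net))

  run_stage("quality", fn = function() {
    if (is.null(ann)) return(NULL)
    glance(coannotation_quality(net, ann, baseline = config$baseline))
  })

  run_stage("recall", fn = function() {
    if (is.null(reference)) return(NULL)
    glance(pathway_recall(net, reference))
  })

  gene_classes <- NULL
  subnets <- NULL
  run_stage("subnetworks", fn = function() {
    if (is.null(ann)) return(NULL)
    gene_classes <<- classify_genes(ann, net$genes$id)
    subnets <<- list(
      development = extract_subnetwork(
        net, gene_classes$id[gene_classes$process == "development"]),
      stress_response = extract_subnetwork(
        net, gene_classes$id[gene_classes$process == "stress_response"])
    )
    lapply(subnets, function(s) as.list(network_summary(s)))
  })

  run_stage("topology", needs_ok = "subnetworks", fn = function() {
    lapply(subnets, function(s) {
      if (nrow(s$edges) == 0) return(list(skipped = "no edges"))
      as.list(topology_summary(s))
    })
  })

  run_stage("subsampling", needs_ok = "subnetworks", fn = function() {
    lapply(subnets, function(s) {
      if (nrow(s$edges) < 10) return(list(skipped = "too few edges"))
      subsample_robustness(s, fractions = p("fractions",
                                            seq(0.5, 0.9, by = 0.1)),
                           replicates = p("replicates", 1000),
                           seed = seed)
    })
  })

  enrich <- NULL
  run_stage("motifs", fn = function() {
    enrich <<- motif_enrichment(net, n_random = p("n_random", 1000),
                                swaps_per_edge = p("swaps_per_edge", 100),
                                seed = seed, p_max = p("p_max", 0.01),
                                z_min = p("z_min", 2),
                                min_count = p("min_count", 4))
    enrich
  })

  run_stage("motif_distribution", needs_ok = c("motifs", "subnetworks"),
            fn = function() {
    motif_classes <- enrich$class_id[enrich$is_motif]
    if (length(motif_classes) == 0) return(list(skipped = "no motifs"))
    mem <- motif_membership(net, motif_classes)
    motif_process_distribution(mem, gene_classes)
  })

  run_stage("communities", fn = function() {
    clu <- mcl(net, inflation = p("inflation", 2))
    res <- list(glance = as.list(glance(clu)), membership = tidy(clu))
    if (!is.null(ann)) {
      res$labels <- label_communities(clu, ann,
                                      min_size = p("min_size", 5),
                                      coverage_threshold =
                                        p("coverage_threshold", 0.5))
      res$glance$labeled_fraction <- mean(res$labels$corresponds)
    }
    res
  })

  run_stage("specificity", fn = function() {
    if (is.null(matrices)) return(NULL)
    tab <- specificity_table(matrices, net)
    corr <- tryCatch(ic_wiring_correlation(net, matrices),
                     error = function(e) NULL)
    list(table = tab,
         ic_wiring = if (is.null(corr)) NULL else as.list(tidy(corr)))
  })

  ages <- NULL
  run_stage("family_dating", fn = function() {
    if (is.null(presence)) return(NULL)
    ages <<- date_families(presence)
    c(as.list(table(ages$epoch)), list(ages = ages))
  })

  run_stage("wiring_preference", needs_ok = c("family_dating", "motifs"),
            fn = function() {
    novel_classes <- p("novel_classes", NULL)
    ancient_classes <- p("ancient_classes", NULL)
    if (is.null(novel_classes) || is.null(ancient_classes)) {
      return(list(skipped = "novel/ancient motif classes not configured"))
    }
    res <- list(
      wiring = wiring_preference_tests(net, ages, novel_classes,
                                       ancient_classes)
    )
    if (!is.null(ann)) {
      res$member_level <- tryCatch(
        as.list(tidy(member_level_process_test(net, ann, ages))),
        error = function(e) list(error = conditionMessage(e)))
      res$family_level <- tryCatch(
        as.list(tidy(family_level_process_test(net, ann, ages))),
        error = function(e) list(error = conditionMessage(e)))
    }
    res
  })

  report <- list(
    provenance = list(
      package = "regnet",
      version = as.character(utils::packageVersion("regnet")),
      seed = seed,
      params = params[order(names(params))],
      inputs = list(
        network = if (is.character(config$network)) config$network else
          net$name,
        annotation = is.null(ann) == FALSE,
        matrices = is.null(matrices) == FALSE,
        presence = is.null(presence) == FALSE,
        reference_pathway = is.null(reference) == FALSE
      )
    ),
    status = status,
    stages = stages
  )
  class(report) <- "reg_report"

  if (!is.null(out_dir)) {
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_stage_tsvs(report, out_dir)
  }
  invisible(report)
}

# Tibbles inside the report become plain data frames for serialization.
report_to_json <- function(x) {
  if (inherits(x, "reg_network")) return(list(name = x$name))
  if (is.data.frame(x)) {
    x <- as.data.frame(x)
    for (cn in names(x)) if (is.list(x[[cn]])) {
      x[[cn]] <- vapply(x[[cn]], paste, character(1), collapse = ";")
    }
    return(x)
  }
  if (is.list(x)) {
    attrs_stripped <- lapply(unclass(x), report_to_json)
    return(attrs_stripped)
  }
  x
}

write_stage_tsvs <- function(report, out_dir) {
  flat <- function(x, prefix) {
    if (is.data.frame(x)) {
      df <- report_to_json(x)
      utils::write.table(df, file.path(out_dir, paste0(prefix, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (is.list(x)) {
      for (nm in names(x)) flat(x[[nm]], paste(prefix, nm, sep = "_"))
    }
  }
  for (nm in names(report$stages)) flat(report$stages[[nm]], nm)
  invisible(NULL)
}

#' @export
print.reg_report <- function(x, ...) {
  cat("<reg_report> seed ", x$provenance$seed, "\n", sep = "")
  for (nm in names(x$status)) {
    cat("  ", format(nm, width = 20), x$status[[nm]], "\n", sep = "")
  }
  invisible(x)
}
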