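#' Date TF families from a phylogenetic presence profile
#'
#' Dollo-style dating: a family is taken to have emerged in the
#' earliest-diverging lineage that contains any member. Families present in
#' at least one green alga are `ancient`; families absent from algae whose
#' earliest land-plant occurrence is no later than `novel_max_rank` are
#' `novel` (they emerged around plant terrestrialization, roughly 1 Gya to
#' 450 Mya); families appearing only in later-diverging land plants are
#' `recent_other`.
#'
#' @param presence A [presence_matrix()].
#' @param novel_max_rank Largest divergence-order rank still counted as the
#'   landing window; defaults to the rank of the earliest-diverging land
#'   plant in the profile.
#' @return A tibble `family`, `epoch`, `earliest_clade`, `earliest_rank`.
#' @export
date_families <- function(presence, novel_max_rank = NULL) {
  stopifnot(inherits(presence, "presence_matrix"))
  sp <- presence$species
  if (is.null(novel_max_rank)) {
    novel_max_rank <- min(sp$rank[sp$clade == "land_plant"])
  }
  alga_cols <- sp$clade == "green_alga"
  purrr::map_dfr(seq_along(presence$families), function(i) {
    pres <- presence$present[i, ]
    if (!any(pres)) abort("Family absent from every species.")
    earliest <- which.min(ifelse(pres, sp$rank, Inf))
    in_alga <- any(pres[alga_cols])
    epoch <- if (in_alga) {
      "ancient"
    } else if (sp$rank[earliest] <= novel_max_rank) {
      "novel"
    } else {
      "recent_other"
    }
    tibble::tibble(family = presence$families[i], epoch = epoch,
                   earliest_clade = sp$clade[earliest],
                   earliest_rank = sp$rank[earliest])
  })
}

# Epoch per TF id; recent_other families and unclassified TFs drop out.
tf_epochs <- function(net, ages) {
  tfs <- net$genes[net$genes$is_tf & !is.na(net$genes$family), ]
  out <- dplyr::inner_join(tfs[, c("id", "family")],
                           ages[, c("family", "epoch")], by = "family")
  out[out$epoch %in% c("ancient", "novel"), ]
}

#' Member-level process preference of novel-family TFs
#'
#' 2x2 Fisher test of TF epoch (novel vs ancient family) against process
#' class (development vs stress_response). TFs classified `both` or `other`
#' are excluded, as are TFs of `recent_other` families. The one-tailed
#' alternative is that novel-family TFs are enriched among developmental
#' TFs.
#'
#' @param net A `reg_network` with family labels on TFs.
#' @param ann A [process_annotation()].
#' @param ages Output of [date_families()].
#' @return A [reg_test()]; attribute `table` holds the 2x2 table
#'   (rows novel/ancient, columns development/stress_response).
#' @export
member_level_process_test <- function(net, ann, ages) {
  eps <- tf_epochs(net, ages)
  if (length(unique(eps$epoch)) < 2) {
    abort("Need TFs from both ancient and novel families.")
  }
  proc <- classify_genes(ann, eps$id)
  df <- dplyr::inner_join(eps, proc, by = "id")
  df <- df[df$process %in% c("development", "stress_response"), ]
  tab <- table(factor(df$epoch, c("novel", "ancient")),
               factor(df$process, c("development", "stress_response")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Degenerate 2x2 table: a margin is zero.")
  }
  res <- fisher_exact(tab, "greater")
  res$method <- paste0(res$method, ", novel-family TFs vs development")
  attr(res, "table") <- tab
  res
}

#' Family-level process preference of novel families
#'
#' For each family with at least one process-classified member (classified
#' = unambiguous development or stress_response), the fraction of its
#' classified TFs that are developmental; novel vs ancient families are
#' compared with a one-tailed Wilcoxon rank-sum test (alternative: novel
#' greater).
#'
#' @inheritParams member_level_process_test
#' @return A [reg_test()]; attribute `data` holds the per-family fractions.
#' @export
family_level_process_test <- function(net, ann, ages) {
  eps <- tf_epochs(net, ages)
  proc <- classify_genes(ann, eps$id)
  df <- dplyr::inner_join(eps, proc, by = "id")
  df <- df[df$process %in% c("development", "stress_response"), ]
  fam <- df |>
    dplyr::group_by(.data$family, .data$epoch) |>
    dplyr::summarise(dev_fraction = mean(.data$process == "development"),
                     n_classified = dplyr::n(), .groups = "drop")
  if (sum(fam$epoch == "novel") < 2 || sum(fam$epoch == "ancient") < 2) {
    abort("Need >= 2 families per epoch with classified members.")
  }
  res <- wilcoxon_rank_sum(fam$dev_fraction[fam$epoch == "novel"],
                           fam$dev_fraction[fam$epoch == "ancient"],
                           "greater")
  res$method <- paste0(res$method,
                       ", novel vs ancient family developmental fraction")
  attr(res, "data") <- fam
  res
}

#' Wiring-preference tests for novel- vs ancient-family TFs
#'
#' Scores each classified TF on three wiring aspects — the fraction of its
#' targets that are TFs, its membership count in the designated "novel"
#' motif classes, and its membership count in the designated "ancient"
#' motif classes — then dichotomizes each score at the mean over all scored
#' TFs (values equal to the mean count as "not above average") and tests
#' the resulting 2x2 epoch-by-side tables with one-tailed Fisher tests. For
#' `regulates_tfs` and `novel_motif_membership` the alternative is that
#' novel-family TFs are enriched above the mean; for
#' `ancient_motif_membership` it is that ancient-family TFs are. An aspect
#' whose scores are all identical (so the mean dichotomy is degenerate) is
#' reported with `NA` entries and a warning rather than failing the whole
#' battery.
#'
#' @param net A `reg_network` with family labels on TFs.
#' @param ages Output of [date_families()].
#' @param novel_classes,ancient_classes Triad class ids treated as novel /
#'   ancient motifs (see [motif_id_map()] for the published numbering).
#' @param membership_novel,membership_ancient Optional precomputed
#'   [motif_membership()] outputs for those class sets.
#' @return An object of class `reg_wiring_report`: a tibble with one row
#'   per aspect (`aspect`, cell counts `novel_above`, `novel_below`,
#'   `ancient_above`, `ancient_below`, `alternative`, `p_value`);
#'   attribute `tests` holds the [reg_test()] objects.
#' @export
wiring_preference_tests <- function(net, ages, novel_classes,
                                    ancient_classes,
                                    membership_novel = NULL,
                                    membership_ancient = NULL) {
  eps <- tf_epochs(net, ages)
  if (sum(eps$epoch == "novel") == 0 || sum(eps$epoch == "ancient") == 0) {
    abort("Need TFs from both ancient and novel families.")
  }
  if (is.null(membership_novel)) {
    membership_novel <- motif_membership(net, novel_classes)
  }
  if (is.null(membership_ancient)) {
    membership_ancient <- motif_membership(net, ancient_classes)
  }
  agg <- function(mem) {
    mem |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(value = sum(.data$n_instances))
  }
  frac <- vapply(eps$id, function(tf) {
    tryCatch(tf_target_fraction(net, tf), error = function(e) NA_real_)
  }, numeric(1))
  aspects <- list(
    regulates_tfs = tibble::tibble(id = eps$id, value = frac),
    novel_motif_membership = agg(membership_novel),
    ancient_motif_membership = agg(membership_ancient)
  )
  favoured <- c(regulates_tfs = "novel", novel_motif_membership = "novel",
                ancient_motif_membership = "ancient")
  tests <- list()
  rows <- purrr::imap(aspects, function(vals, aspect) {
    df <- dplyr::inner_join(eps, vals, by = "id")
    df <- df[!is.na(df$value), ]
    if (nrow(df) == 0 || length(unique(df$value)) == 1) {
      # degenerate mean dichotomy: this aspect cannot be tested
      warn(paste0("Aspect `", aspect,
                  "`: all scores identical, mean dichotomy is degenerate."))
      return(tibble::tibble(aspect = aspect, novel_above = NA_integer_,
                            novel_below = NA_integer_,
                            ancient_above = NA_integer_,
                            ancient_below = NA_integer_,
                            alternative = NA_character_,
                            p_value = NA_real_))
    }
    above <- df$value > mean(df$value)
    top <- favoured[[aspect]]
    bottom <- setdiff(c("novel", "ancient"), top)
    tab <- rbind(c(sum(df$epoch == top & above), sum(df$epoch == top & !above)),
                 c(sum(df$epoch == bottom & above),
                   sum(df$epoch == bottom & !above)))
    res <- fisher_exact(tab, "greater")
    res$method <- paste0(res$method, ", ", aspect, " (", top,
                         "-family TFs above average)")
    tests[[aspect]] <<- res
    tibble::tibble(
      aspect = aspect,
      novel_above = sum(df$epoch == "novel" & above),
      novel_below = sum(df$epoch == "novel" & !above),
      ancient_above = sum(df$epoch == "ancient" & above),
      ancient_below = sum(df$epoch == "ancient" & !above),
      alternative = paste0(top, " above average"),
      p_value = res$p_value
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "tests") <- tests
  class(out) <- c("reg_wiring_report", class(out))
  out
}
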