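#' Information content of a binding matrix
#'
#' Binding specificity in bits under a uniform background:
#' `IC = sum_j (2 + sum_b p_bj * log2(p_bj))` with `0 * log2(0) == 0`.
#' Ranges from 0 (all columns uniform) to 2 per column (deterministic
#' columns). No small-sample correction is applied.
#'
#' @param pwm A [binding_matrix()].
#' @return Information content in bits.
#' @examples
#' unif <- binding_matrix("tf", probs = matrix(0.25, 4, 10))
#' information_content(unif)  # 0 bits
#' @export
information_content <- function(pwm) {
  stopifnot(inherits(pwm, "binding_matrix"))
  p <- pwm$probs
  if (any(abs(colSums(p) - 1) > 1e-9)) abort("Invalid column sums.")
  plogp <- ifelse(p > 0, p * log2(p), 0)
  sum(2 + colSums(plogp))
}

# One IC value per TF: matrices of the same TF are averaged.
per_tf_ic <- function(matrices) {
  stopifnot(length(matrices) > 0)
  ids <- vapply(matrices, function(m) m$tf_id, character(1))
  ics <- vapply(matrices, information_content, numeric(1))
  vapply(split(ics, ids), mean, numeric(1))
}

#' Per-TF binding specificity table
#'
#' One row per TF with its (averaged) information content and, when a
#' network is supplied, the fraction of its targets that are themselves
#' TFs.
#'
#' @param matrices List of [binding_matrix()] objects (multiple matrices
#'   per TF are averaged).
#' @param net Optional `reg_network` used to add `tf_target_fraction`
#'   (`NA` for TFs without outgoing edges).
#' @return A tibble `tf_id`, `ic_bits`, `tf_target_fraction`.
#' @export
specificity_table <- function(matrices, net = NULL) {
  ic <- per_tf_ic(matrices)
  out <- tibble::tibble(tf_id = names(ic), ic_bits = unname(ic))
  if (!is.null(net)) {
    out$tf_target_fraction <- vapply(out$tf_id, function(tf) {
      tryCatch(tf_target_fraction(net, tf), error = function(e) NA_real_)
    }, numeric(1))
  }
  out
}

#' Compare binding specificity between two TF groups
#'
#' Wilcoxon rank-sum test on per-TF information content (one value per TF;
#' multiple matrices per TF are averaged). `alternative = "greater"` tests
#' whether group A binds more specifically than group B.
#'
#' @param group_a,group_b Lists of [binding_matrix()] objects.
#' @param alternative `"greater"` or `"less"`.
#' @return A [reg_test()].
#' @export
compare_group_specificity <- function(group_a, group_b,
                                      alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("Both groups must be non-empty.")
  }
  wilcoxon_rank_sum(per_tf_ic(group_a), per_tf_ic(group_b), alternative)
}

#' Fraction of a TF's targets that are TFs
#'
#' @param net A `reg_network`.
#' @param tf Gene id of a TF with out-degree >= 1.
#' @return A number in \[0, 1\].
#' @export
tf_target_fraction <- function(net, tf) {
  stopifnot(inherits(net, "reg_network"))
  targets <- net$edges$target[net$edges$regulator == tf]
  if (length(targets) == 0) {
    abort(paste0("`", tf, "` has no targets; fraction undefined."))
  }
  is_tf <- setNames(net$genes$is_tf, net$genes$id)
  mean(is_tf[targets])
}

#' Correlation between binding specificity and TF-target wiring
#'
#' Spearman correlation, over TFs that have both a binding matrix and at
#' least one target, between information content and the fraction of
#' targets that are TFs. A positive correlation means more specific
#' binders sit higher in the regulatory hierarchy.
#'
#' @param net A `reg_network`.
#' @param matrices List of [binding_matrix()] objects.
#' @param alternative Passed to [spearman_cor()] (default `"greater"`:
#'   specificity increases the TF-target fraction).
#' @return A [reg_test()] with `estimate` = rho; attribute `data` holds the
#'   per-TF table used.
#' @export
ic_wiring_correlation <- function(net, matrices,
                                  alternative = c("greater", "two.sided",
                                                  "less")) {
  alternative <- match.arg(alternative)
  tab <- specificity_table(matrices, net)
  tab <- tab[!is.na(tab$tf_target_fraction), ]
  if (nrow(tab) < 3) {
    abort("Need at least 3 TFs with a binding matrix and >= 1 target.")
  }
  res <- spearman_cor(tab$ic_bits, tab$tf_target_fraction,
                      alternative = alternative)
  attr(res, "data") <- tab
  res
}

#' Distribution of binding specificity by group
#'
#' @param table A data frame with columns `ic_bits` and a grouping column.
#' @param group Name of the grouping column (default `"group"`).
#' @return A ggplot (boxplot plus points).
#' @export
plot_specificity <- function(table, group = "group") {
  ggplot2::ggplot(table, ggplot2::aes(x = .data[[group]],
                                      y = .data$ic_bits)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "information content (bits)")
}
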