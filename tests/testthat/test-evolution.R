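simple_presence <- function() {
  species <- tibble::tibble(
    species = c("alga1", "moss", "fern", "flower"),
    clade = c("green_alga", rep("land_plant", 3)),
    rank = 1:4
  )
  pres <- rbind(
    FAMa = c(TRUE, TRUE, TRUE, TRUE),   # in an alga -> ancient
    FAMn = c(FALSE, TRUE, TRUE, TRUE),  # from mosses onward -> novel
    FAMr = c(FALSE, FALSE, FALSE, TRUE) # single flowering plant -> recent
  )
  presence_matrix(rownames(pres), species, pres)
}

test_that("family dating follows the clade-emergence rule", {
  ages <- date_families(simple_presence())
  expect_equal(setNames(ages$epoch, ages$family),
               c(FAMa = "ancient", FAMn = "novel", FAMr = "recent_other"))
  expect_equal(ages$earliest_clade,
               c("green_alga", "land_plant", "land_plant"))
})

test_that("family dating is invariant to species column order", {
  pm <- simple_presence()
  perm <- c(3, 1, 4, 2)
  shuffled <- presence_matrix(pm$families, pm$species[perm, ],
                              pm$present[, perm])
  expect_equal(date_families(shuffled), date_families(pm))
})

test_that("generated presence profiles recover their planted epochs exactly", {
  for (seed in 1:5) {
    pm <- gen_presence(n_families = 40, seed = seed)
    ages <- date_families(pm)
    expect_equal(setNames(ages$epoch, ages$family), attr(pm, "epochs"))
  }
})

# A network whose novel-family TFs are developmental and target TFs.
epoch_fixture <- function(n_dev_novel = 5, n_str_ancient = 5) {
  tfs <- c(paste0("N", seq_len(n_dev_novel)),
           paste0("A", seq_len(n_str_ancient)))
  fams <- c(paste0("FN", seq_len(n_dev_novel)),
            paste0("FA", seq_len(n_str_ancient)))
  net <- reg_network(
    tibble::tibble(regulator = tfs, target = paste0("t", seq_along(tfs))),
    genes = tibble::tibble(id = tfs, family = fams),
    tf_ids = tfs
  )
  ann <- process_annotation(
    tibble::tibble(gene = tfs,
                   term = rep(c("dev", "str"),
                              c(n_dev_novel, n_str_ancient))),
    tibble::tibble(term = c("dev", "str"),
                   class = c("development", "stress_response"))
  )
  ages <- tibble::tibble(family = fams,
                         epoch = rep(c("novel", "ancient"),
                                     c(n_dev_novel, n_str_ancient)))
  list(net = net, ann = ann, ages = ages)
}

test_that("the member-level process test builds the exclusive 2x2 table", {
  fx <- epoch_fixture()
  res <- member_level_process_test(fx$net, fx$ann, fx$ages)
  expect_equal(res$p_value, 1 / 252)
  expect_equal(as.vector(attr(res, "table")), c(5, 0, 0, 5))

  # a TF annotated to both classes drops out of the table
  ann_both <- process_annotation(
    dplyr::bind_rows(fx$ann$annotations,
                     tibble::tibble(gene = "N1", term = "str")),
    fx$ann$classes
  )
  res2 <- member_level_process_test(fx$net, ann_both, fx$ages)
  expect_equal(sum(attr(res2, "table")), 9)

  # identical distributions are not significant
  mixed <- epoch_fixture()
  ann_mixed <- process_annotation(
    tibble::tibble(gene = c(paste0("N", 1:4), paste0("A", 1:4)),
                   term = rep(c("dev", "str"), 4)),
    fx$ann$classes
  )
  res3 <- member_level_process_test(mixed$net, ann_mixed, mixed$ages)
  expect_gte(res3$p_value, 0.5)
})

test_that("the family-level test ranks developmental fractions across families", {
  fx <- epoch_fixture(3, 3)
  res <- family_level_process_test(fx$net, fx$ann, fx$ages)
  expect_equal(res$p_value, 0.05)

  # families without classified members are excluded
  fx2 <- epoch_fixture(3, 3)
  ann_partial <- process_annotation(
    fx2$ann$annotations[fx2$ann$annotations$gene != "N3", ],
    fx2$ann$classes
  )
  res2 <- family_level_process_test(fx2$net, ann_partial, fx2$ages)
  expect_equal(length(attr(res2, "data")$family), 5)

  expect_error(
    family_level_process_test(epoch_fixture(1, 5)$net,
                              epoch_fixture(1, 5)$ann,
                              epoch_fixture(1, 5)$ages),
    ">= 2 families"
  )
})

test_that("wiring preference dichotomizes at the mean with ties below", {
  # novel TFs target TFs, ancient TFs target non-TFs
  tfs <- c("N1", "N2", "N3", "A1", "A2", "A3")
  fams <- paste0("F", tfs)
  edges <- tibble::tibble(
    regulator = rep(tfs, each = 2),
    target = c("N2", "N3", "N1", "N3", "N1", "N2",
               "x1", "x2", "x3", "x4", "x5", "x6")
  )
  net <- reg_network(edges, genes = tibble::tibble(id = tfs, family = fams),
                     tf_ids = tfs)
  ages <- tibble::tibble(family = fams,
                         epoch = rep(c("novel", "ancient"), each = 3))
  rep_out <- suppressWarnings(
    wiring_preference_tests(net, ages, novel_classes = 9,
                            ancient_classes = 5)
  )
  row <- rep_out[rep_out$aspect == "regulates_tfs", ]
  expect_equal(row$p_value, 1 / 20)
  expect_equal(row$novel_above, 3)
  expect_equal(row$ancient_below, 3)
  expect_match(row$alternative, "novel")
})

test_that("motif-membership aspects with identical scores degrade gracefully", {
  tfs <- c("N1", "A1")
  net <- reg_network(tibble::tibble(regulator = tfs, target = c("A1", "x1")),
                     genes = tibble::tibble(id = tfs,
                                            family = paste0("F", tfs)),
                     tf_ids = tfs)
  ages <- tibble::tibble(family = paste0("F", tfs),
                         epoch = c("novel", "ancient"))
  warns <- testthat::capture_warnings(
    rep_out <- wiring_preference_tests(net, ages, novel_classes = 9,
                                       ancient_classes = 5)
  )
  expect_true(any(grepl("degenerate", warns)))
  expect_true(is.na(
    rep_out$p_value[rep_out$aspect == "novel_motif_membership"]))
  # the informative aspect still reports
  expect_false(is.na(rep_out$p_value[rep_out$aspect == "regulates_tfs"]))
})

test_that("values equal to the mean count as not-above-average", {
  # fractions: N1 -> 1, N2 -> 0.5, A1 -> 0.5, A2 -> 0; mean = 0.5, so the
  # two TFs sitting exactly at the mean fall on the not-above side
  tfs <- c("N1", "N2", "A1", "A2")
  fams <- paste0("F", tfs)
  edges <- tibble::tibble(
    regulator = c("N1", "N2", "N2", "A1", "A1", "A2"),
    target = c("N2", "A1", "x1", "N1", "x2", "x3")
  )
  net <- reg_network(edges, genes = tibble::tibble(id = tfs, family = fams),
                     tf_ids = tfs)
  ages <- tibble::tibble(family = fams,
                         epoch = c("novel", "novel", "ancient", "ancient"))
  rep_out <- suppressWarnings(
    wiring_preference_tests(net, ages, novel_classes = 9,
                            ancient_classes = 5)
  )
  row <- rep_out[rep_out$aspect == "regulates_tfs", ]
  expect_equal(row$novel_above, 1)
  expect_equal(row$novel_below, 1)
  expect_equal(row$ancient_above, 0)
  expect_equal(row$ancient_below, 2)
})

test_that("planted epoch-dependent TF-targeting is flagged reliably", {
  gen_epoch_net <- function(seed, n_per_group = 30) {
    set.seed(seed)
    novel <- paste0("N", seq_len(n_per_group))
    ancient <- paste0("A", seq_len(n_per_group))
    tfs <- c(novel, ancient)
    nontf <- paste0("x", 1:100)
    p_tf <- rep(c(0.7, 0.3), each = n_per_group)
    from <- character(0); to <- character(0)
    for (i in seq_along(tfs)) {
      k <- 5
      tf_hits <- runif(k) < p_tf[i]
      tgt <- c(sample(setdiff(tfs, tfs[i]), sum(tf_hits)),
               sample(nontf, k - sum(tf_hits)))
      from <- c(from, rep(tfs[i], length(tgt)))
      to <- c(to, tgt)
    }
    net <- reg_network(tibble::tibble(regulator = from, target = to),
                       genes = tibble::tibble(id = tfs,
                                              family = paste0("F", tfs)),
                       tf_ids = tfs)
    ages <- tibble::tibble(family = paste0("F", tfs),
                           epoch = rep(c("novel", "ancient"),
                                       each = n_per_group))
    list(net = net, ages = ages)
  }
  hits <- vapply(1:100, function(seed) {
    fx <- gen_epoch_net(seed)
    rep_out <- suppressWarnings(
      wiring_preference_tests(fx$net, fx$ages, novel_classes = 9,
                              ancient_classes = 5)
    )
    rep_out$p_value[rep_out$aspect == "regulates_tfs"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
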