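test_that("triad classification is canonical and permutation-invariant", {
  ffl <- matrix(FALSE, 3, 3)
  ffl[1, 2] <- ffl[1, 3] <- ffl[2, 3] <- TRUE
  cls <- classify_triad(ffl)
  expect_equal(cls$name, "feed-forward loop")

  single <- matrix(FALSE, 3, 3)
  single[1, 2] <- TRUE
  expect_null(classify_triad(single))

  # class id is invariant under all node permutations
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  set.seed(21)
  for (i in 1:20) {
    a <- matrix(runif(9) < 0.5, 3, 3)
    diag(a) <- FALSE
    base <- classify_triad(a)
    for (p in perms) {
      expect_equal(classify_triad(a[p, p])$class_id, base$class_id)
    }
  }

  # self-loops are ignored for typing
  with_loop <- ffl
  diag(with_loop) <- TRUE
  expect_equal(classify_triad(with_loop)$class_id, cls$class_id)
})

test_that("there are exactly 13 connected triad classes", {
  tc <- triad_classes()
  expect_equal(tc$class_id, 1:13)
  expect_equal(tc$code, sort(tc$code))
  expect_equal(sum(!is.na(tc$name)), 6)
})

test_that("the census matches the exhaustive all-triples oracle", {
  cyc <- toy_net(c("A", "B", "C"), c("B", "C", "A"))
  cen <- triad_census(cyc)
  expect_equal(sum(cen$count), 1)
  expect_equal(cen$count[which(cen$name == "three-node cycle")], 1)

  ffl_plus <- reg_network(
    tibble::tibble(regulator = c("A", "A", "B"), target = c("B", "C", "C")),
    genes = tibble::tibble(id = c("A", "B", "C", "Isolated"))
  )
  cen <- triad_census(ffl_plus)
  expect_equal(sum(cen$count), 1)
  expect_equal(cen$count[which(cen$name == "feed-forward loop")], 1)

  for (seed in 1:10) {
    net <- rand_digraph(sample(8:30, 1), 0.1, seed + 500)
    expect_equal(triad_census(net)$count, oracle_census(net))
  }
})

test_that("the census agrees with igraph's Davis-Leinhardt triad census", {
  # derive the mapping between canonical classes and D-L positions from
  # single-triad exemplar graphs, then compare full census vectors
  dl_of_class <- integer(13)
  for (cls in 1:13) {
    net3 <- plant_motifs(toy_net(character(), character(),
                                 genes = tibble::tibble(id = c("a", "b", "c"))),
                         class_id = cls, count = 1, seed = 1)
    ig <- igraph::triad_census(as_igraph(net3))
    expect_equal(sum(ig[-(1:3)]), 1)
    dl_of_class[cls] <- which(ig == 1)
  }
  expect_equal(sort(dl_of_class), 4:16)
  for (seed in 1:5) {
    net <- rand_digraph(20, 0.12, seed + 900)
    ours <- triad_census(net)$count
    igs <- igraph::triad_census(as_igraph(net))
    expect_equal(ours, igs[dl_of_class])
  }
})

test_that("census is invariant under node relabeling", {
  net <- rand_digraph(15, 0.15, 77)
  perm <- setNames(paste0("z", sample(15)), net$genes$id)
  relab <- toy_net(unname(perm[net$edges$regulator]),
                   unname(perm[net$edges$target]))
  expect_equal(triad_census(relab)$count, triad_census(net)$count)
})

test_that("randomization preserves degree sequences and perturbs edges", {
  net <- gen_network(40, 40, "erdos_renyi", n_edges = 200, seed = 31)
  outdeg <- function(n) table(factor(n$edges$regulator, n$genes$id))
  indeg <- function(n) table(factor(n$edges$target, n$genes$id))
  for (seed in 1:20) {
    r <- randomize_network(net, swaps_per_edge = 10, seed = seed)
    expect_equal(outdeg(r), outdeg(net))
    expect_equal(indeg(r), indeg(net))
    expect_equal(nrow(r$edges), nrow(net$edges))
    expect_false(anyDuplicated(paste(r$edges$regulator, r$edges$target)) > 0)
  }

  # deterministic given seed
  expect_equal(randomize_network(net, 20, seed = 5),
               randomize_network(net, 20, seed = 5))

  # a single edge admits no legal swap
  one <- toy_net("A", "B")
  expect_equal(randomize_network(one, 100, seed = 1)$edges[, 1:2],
               one$edges[, 1:2])

  # an 8-node directed cycle is 1-regular and must move within 100 swaps/edge
  cyc8 <- toy_net(paste0("n", 1:8), paste0("n", c(2:8, 1)))
  r8 <- randomize_network(cyc8, swaps_per_edge = 100, seed = 3)
  expect_gt(length(setdiff(paste(r8$edges$regulator, r8$edges$target),
                           paste(cyc8$edges$regulator, cyc8$edges$target))),
            0)
})

test_that("a network that is a single FFL is its own null", {
  ffl <- toy_net(c("A", "A", "B"), c("B", "C", "C"))
  res <- motif_enrichment(ffl, n_random = 50, seed = 2)
  row <- res[which(res$name == "feed-forward loop"), ]
  expect_equal(row$observed, 1)
  expect_equal(row$empirical_p, 1)
  expect_false(row$is_motif)
  expect_equal(row$z_score, 0)
  expect_equal(sum(res$is_motif), 0)
})

test_that("planted FFLs are detected as motifs", {
  base <- gen_network(200, 0, "erdos_renyi", p = 0.005, seed = 10)
  ffl_class <- classify_triad(matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0), 3, 3))$class_id
  planted <- plant_motifs(base, ffl_class, 40, seed = 11)
  expect_gte(triad_census(planted)$count[ffl_class], 40)
  res <- motif_enrichment(planted, n_random = 100, seed = 12)
  expect_true(res$is_motif[res$class_id == ffl_class])
})

test_that("motif membership counts instances per gene and rolls up by process", {
  ffl_class <- classify_triad(matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0), 3, 3))$class_id
  # two FFLs sharing the apex A
  net <- toy_net(c("A", "A", "B", "A", "A", "D"),
                 c("B", "C", "C", "D", "E", "E"))
  mem <- motif_membership(net, ffl_class)
  counts <- setNames(mem$n_instances, mem$id)
  expect_equal(unname(counts["A"]), 2)
  expect_equal(unname(counts["B"]), 1)

  lone <- reg_network(tibble::tibble(regulator = "A", target = "B"),
                      genes = tibble::tibble(id = c("A", "B", "Z")))
  mem0 <- motif_membership(lone, ffl_class)
  expect_true(all(mem0$n_instances == 0))

  cls <- tibble::tibble(id = c("A", "B", "C", "D", "E"),
                        process = c("development", "development",
                                    "stress_response", "other", "other"))
  dist <- motif_process_distribution(mem, cls)
  expect_equal(dist$n_instances[dist$process == "development"], 3)
  expect_error(motif_membership(net, 14), "1..13")
})

test_that("the motif decision is monotone in the observed count", {
  # holding the null fixed, a larger observed count can only strengthen
  # the call
  tt <- motif_enrichment(toy_net(c("A", "A", "B"), c("B", "C", "C")),
                         n_random = 20, seed = 1)
  expect_s3_class(tt, "reg_motif_enrichment")
  null_counts <- c(2, 3, 4, 3, 2)
  decide <- function(obs) {
    z <- (obs - mean(null_counts)) / sd(null_counts)
    p <- (1 + sum(null_counts >= obs)) / (1 + length(null_counts))
    p <= 0.25 && z >= 1 && obs >= 4
  }
  flags <- vapply(1:10, decide, logical(1))
  expect_true(all(diff(flags) >= 0))
})
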