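#' Generate a synthetic regulatory network
#'
#' TFs are the only edge sources. Two edge models are available:
#' `erdos_renyi` includes each possible TF -> gene edge independently with
#' probability `p` (or samples exactly `n_edges` of them), and
#' `out_degree_powerlaw` draws per-TF out-degrees from a discrete power law
#' (exponent `gamma`) and picks targets uniformly, giving the heavy-tailed
#' fan-out typical of curated regulatory maps. Families are assigned to
#' TFs at random from `n_families` labels. Deterministic given `seed`.
#'
#' @param n_tf Number of TFs.
#' @param n_nontf Number of non-TF genes.
#' @param edge_model `"erdos_renyi"` or `"out_degree_powerlaw"`.
#' @param p Edge probability (ER model; ignored when `n_edges` is given).
#' @param n_edges Target edge count (both models; approximate under the
#'   power-law model only in that degrees are capped by the gene count).
#' @param gamma Power-law exponent for out-degrees (default 2).
#' @param n_families Number of TF family labels (default
#'   `max(1, n_tf %/% 8)`).
#' @param p_activation Probability that an edge is an activation (default
#'   0.6; the rest are repressions).
#' @param seed Integer seed.
#' @param name Network label.
#' @return A [reg_network()]; synthetic edges carry evidence ids of the
#'   form `SYN<k>`.
#' @export
gen_network <- function(n_tf, n_nontf, edge_model = c("erdos_renyi",
                                                      "out_degree_powerlaw"),
                        p = NULL, n_edges = NULL, gamma = 2,
                        n_families = max(1, n_tf %/% 8),
                        p_activation = 0.6, seed = 1,
                        name = "synthetic") {
  edge_model <- match.arg(edge_model)
  if (n_tf < 1) abort("Need at least one TF.")
  set.seed(seed)
  tf_ids <- sprintf("TF%04d", seq_len(n_tf))
  gene_ids <- c(tf_ids,
                if (n_nontf > 0) sprintf("G%04d", seq_len(n_nontf)))
  n_genes <- length(gene_ids)
  if (edge_model == "erdos_renyi") {
    possible <- n_tf * (n_genes - 1)  # no self-loops
    if (!is.null(n_edges)) {
      if (n_edges > possible) abort("`n_edges` exceeds the possible edges.")
      pick <- sample.int(possible, n_edges)
    } else {
      if (is.null(p)) abort("Supply `p` or `n_edges`.")
      pick <- which(runif(possible) < p)
    }
    # linear index over (tf, target != tf)
    tf_idx <- (pick - 1) %/% (n_genes - 1) + 1
    tgt_off <- (pick - 1) %% (n_genes - 1) + 1
    tgt_idx <- ifelse(tgt_off >= tf_idx, tgt_off + 1, tgt_off)
    from <- tf_ids[tf_idx]
    to <- gene_ids[tgt_idx]
  } else {
    if (is.null(n_edges)) abort("The power-law model needs `n_edges`.")
    w <- (seq_len(n_genes - 1))^(-gamma)
    deg <- sample(seq_len(n_genes - 1), n_tf, replace = TRUE,
                  prob = w / sum(w))
    # rescale to the requested total edge count
    deg <- pmax(0, round(deg * n_edges / sum(deg)))
    from <- character(0)
    to <- character(0)
    for (i in seq_len(n_tf)) {
      if (deg[i] == 0) next
      pool <- setdiff(gene_ids, tf_ids[i])
      k <- min(deg[i], length(pool))
      from <- c(from, rep(tf_ids[i], k))
      to <- c(to, sample(pool, k))
    }
  }
  m <- length(from)
  edges <- tibble::tibble(
    regulator = from, target = to,
    mode = ifelse(runif(m) < p_activation, "activation", "repression"),
    evidence = as.list(sprintf("SYN%05d", seq_len(m)))
  )
  families <- sprintf("FAM%02d", seq_len(n_families))
  genes <- tibble::tibble(
    id = gene_ids,
    family = c(sample(families, n_tf, replace = TRUE),
               rep(NA_character_, n_genes - n_tf))
  )
  reg_network(edges, genes = genes, tf_ids = tf_ids, name = name)
}

#' Preset generator emulating a curated plant regulatory map
#'
#' 388 TFs from 47 families, 400 non-TF targets and about 1,400
#' regulations with power-law fan-out — the scale of the curated map the
#' package's analyses were designed around (the edge count is an artifact
#' estimate, not a published figure).
#'
#' @param seed Integer seed.
#' @return A [reg_network()].
#' @export
gen_atrm_like <- function(seed = 1) {
  gen_network(n_tf = 388, n_nontf = 400,
              edge_model = "out_degree_powerlaw", n_edges = 1400,
              gamma = 1.6, n_families = 47, seed = seed,
              name = "atrm_like")
}

#' Plant motif instances into a network
#'
#' Adds `count` fresh instances of a triad class on vertex-disjoint node
#' triples whose induced subgraph is empty, so the census count of that
#' class is guaranteed to grow by at least `count`.
#'
#' @param net A `reg_network`.
#' @param class_id Triad class (1..13).
#' @param count Number of instances to plant.
#' @param seed Integer seed.
#' @return A `reg_network` with the planted edges added (mode
#'   `"activation"`).
#' @export
plant_motifs <- function(net, class_id, count, seed = 1) {
  stopifnot(inherits(net, "reg_network"))
  if (count == 0) return(net)
  tt <- triad_tables()
  if (!class_id %in% 1:13) abort("`class_id` must be in 1..13.")
  code <- tt$codes[class_id]
  cells <- cbind(c(1, 1, 2, 2, 3, 3), c(2, 3, 1, 3, 1, 2))
  weights <- c(32, 16, 8, 4, 2, 1)
  motif_edges <- cells[bitwAnd(code %/% weights, 1) == 1, , drop = FALSE]
  ids <- net$genes$id
  if (length(ids) < 3 * count) {
    abort("Not enough genes for vertex-disjoint planted triples.")
  }
  set.seed(seed)
  existing <- paste(net$edges$regulator, net$edges$target, sep = "\r")
  pick_disjoint <- function() {
    for (attempt in 1:200) {
      chosen <- sample(ids, 3 * count)
      triples <- matrix(chosen, ncol = 3, byrow = TRUE)
      internal <- apply(triples, 1, function(tr) {
        pairs <- expand.grid(a = tr, b = tr, stringsAsFactors = FALSE)
        pairs <- pairs[pairs$a != pairs$b, ]
        any(paste(pairs$a, pairs$b, sep = "\r") %in% existing)
      })
      if (!any(internal)) return(triples)
    }
    abort("Could not find enough edge-free disjoint triples.")
  }
  triples <- pick_disjoint()
  new_edges <- purrr::map_dfr(seq_len(count), function(r) {
    tr <- triples[r, ]
    tibble::tibble(regulator = tr[motif_edges[, 1]],
                   target = tr[motif_edges[, 2]],
                   mode = "activation")
  })
  all_edges <- dplyr::bind_rows(
    tidy_edges_for_rebuild(net$edges), new_edges
  )
  reg_network(all_edges, genes = net$genes[, c("id", "symbol", "family")],
              tf_ids = net$genes$id[net$genes$is_tf |
                                      net$genes$id %in% new_edges$regulator],
              name = net$name)
}

tidy_edges_for_rebuild <- function(edges) {
  tibble::tibble(regulator = edges$regulator, target = edges$target,
                 mode = edges$mode, evidence = edges$evidence,
                 assay = edges$assay)
}

#' Generate annotations with planted edge co-annotation
#'
#' Every gene receives one base process term drawn uniformly from
#' `n_terms` terms (so two random genes share a term at rate about
#' `q0 = 1 / n_terms`); then, with probability `(q - q0) / (1 - q0)` per
#' regulation, both endpoints receive a fresh term private to that edge.
#' Edge-private terms cannot leak sharing into other pairs, so
#' regulator-target pairs are co-annotated at rate `q` in expectation while
#' unrelated pairs stay at the background rate. Terms are assigned
#' high-level classes by the given fractions.
#'
#' @param net A `reg_network`.
#' @param q Co-annotation rate on edges.
#' @param q0 Background co-annotation rate (default `1 / n_terms`).
#' @param n_terms Number of process terms (default `round(1 / q0)` when
#'   `q0` is given, else 20).
#' @param class_fractions Named fractions for `development`,
#'   `stress_response`, `other` (must sum to 1).
#' @param seed Integer seed.
#' @return A [process_annotation()].
#' @export
gen_annotations <- function(net, q = 0.6, q0 = NULL, n_terms = NULL,
                            class_fractions = c(development = 0.3,
                                                stress_response = 0.3,
                                                other = 0.4),
                            seed = 1) {
  stopifnot(inherits(net, "reg_network"))
  if (is.null(n_terms)) {
    n_terms <- if (is.null(q0)) 20 else max(2, round(1 / q0))
  }
  q0 <- 1 / n_terms
  if (q < q0) abort("`q` must be >= the background rate 1 / n_terms.")
  set.seed(seed)
  terms <- sprintf("T%03d", seq_len(n_terms))
  genes <- net$genes$id
  base <- sample(terms, length(genes), replace = TRUE)
  ann <- tibble::tibble(gene = genes, term = base)
  q_extra <- if (q >= 1) 1 else (q - q0) / (1 - q0)
  force_share <- runif(nrow(net$edges)) < q_extra
  if (any(force_share)) {
    idx <- which(force_share)
    fresh <- sprintf("TE%05d", seq_along(idx))
    ann <- dplyr::bind_rows(
      ann,
      tibble::tibble(gene = net$edges$regulator[idx], term = fresh),
      tibble::tibble(gene = net$edges$target[idx], term = fresh)
    )
    terms <- c(terms, fresh)
  }
  cls <- sample(names(class_fractions), length(terms), replace = TRUE,
                prob = class_fractions)
  process_annotation(ann, tibble::tibble(term = terms, class = cls))
}

#' Generate binding matrices with a target information content
#'
#' Columns are drawn from a symmetric Dirichlet whose concentration is
#' found by bisection on the closed-form expected per-column information
#' content, `2 + (digamma(a + 1) - digamma(4a + 1)) / ln 2` bits, so the
#' realized mean IC lands near `target_ic`. The boundaries are exact:
#' `target_ic = 0` yields uniform columns and `target_ic = 2 * width`
#' deterministic ones.
#'
#' @param n Number of matrices.
#' @param width Matrix width W.
#' @param target_ic Desired total IC in bits, in `[0, 2 * width]`.
#' @param seed Integer seed.
#' @param ids TF ids (default `PWM<k>`).
#' @return A named list of [binding_matrix()] objects.
#' @export
gen_pwms <- function(n, width = 10, target_ic = width, seed = 1,
                     ids = sprintf("PWM%03d", seq_len(n))) {
  if (target_ic < 0 || target_ic > 2 * width) {
    abort("`target_ic` must be in [0, 2 * width].")
  }
  set.seed(seed)
  per_col <- target_ic / width
  make <- function(id) {
    if (per_col <= 1e-9) {
      probs <- matrix(0.25, 4, width)
    } else if (per_col >= 2 - 1e-9) {
      probs <- vapply(sample.int(4, width, replace = TRUE), function(b) {
        v <- numeric(4); v[b] <- 1; v
      }, numeric(4))
    } else {
      a <- dirichlet_conc_for_ic(per_col)
      probs <- vapply(seq_len(width), function(j) {
        g <- rgamma(4, shape = a)
        g / sum(g)
      }, numeric(4))
    }
    binding_matrix(id, probs = probs)
  }
  setNames(lapply(ids, make), ids)
}

# Expected per-column IC (bits) of a symmetric Dirichlet(a) column.
dirichlet_expected_ic <- function(a) {
  2 + (digamma(a + 1) - digamma(4 * a + 1)) / log(2)
}

dirichlet_conc_for_ic <- function(ic_per_col) {
  lo <- 1e-4; hi <- 1e4
  for (i in 1:80) {
    mid <- sqrt(lo * hi)
    if (dirichlet_expected_ic(mid) > ic_per_col) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Generate a TF-family presence profile with known epochs
#'
#' Ancient families are present in at least one green alga; novel families
#' first appear in the most basal land plant; recent families appear only
#' in the latest-diverging land plant. [date_families()] recovers the
#' planted epochs exactly.
#'
#' @param n_families Number of families.
#' @param ancient_fraction,recent_fraction Fractions of ancient and
#'   recent_other families (the rest are novel).
#' @param n_algae,n_land Species counts per clade (ranks 1..n_algae are
#'   algae, the rest land plants in divergence order).
#' @param seed Integer seed.
#' @param families Family names (default `FAM<k>`).
#' @return A [presence_matrix()]; attribute `epochs` holds the planted
#'   labels.
#' @export
gen_presence <- function(n_families = 47, ancient_fraction = 0.45,
                         recent_fraction = 0.1, n_algae = 3, n_land = 25,
                         seed = 1,
                         families = sprintf("FAM%02d", seq_len(n_families))) {
  n_families <- length(families)
  set.seed(seed)
  n_anc <- round(ancient_fraction * n_families)
  n_rec <- round(recent_fraction * n_families)
  n_nov <- n_families - n_anc - n_rec
  if (min(n_anc, n_nov) < 1) abort("Need at least one ancient and one novel family.")
  species <- tibble::tibble(
    species = c(sprintf("alga%02d", seq_len(n_algae)),
                sprintf("plant%02d", seq_len(n_land))),
    clade = c(rep("green_alga", n_algae), rep("land_plant", n_land)),
    rank = seq_len(n_algae + n_land)
  )
  epochs <- sample(c(rep("ancient", n_anc), rep("novel", n_nov),
                     rep("recent_other", n_rec)))
  pres <- matrix(FALSE, n_families, nrow(species))
  land_cols <- which(species$clade == "land_plant")
  basal_land <- land_cols[which.min(species$rank[land_cols])]
  last_land <- land_cols[which.max(species$rank[land_cols])]
  for (i in seq_len(n_families)) {
    if (epochs[i] == "ancient") {
      pres[i, sample(which(species$clade == "green_alga"), 1)] <- TRUE
      pres[i, land_cols] <- runif(length(land_cols)) < 0.8
      pres[i, last_land] <- TRUE  # retained in the focal species
    } else if (epochs[i] == "novel") {
      pres[i, basal_land] <- TRUE
      later <- land_cols[land_cols != basal_land]
      pres[i, later] <- runif(length(later)) < 0.8
    } else {
      pres[i, last_land] <- TRUE
    }
  }
  out <- presence_matrix(families, species, pres)
  attr(out, "epochs") <- setNames(epochs, families)
  out
}

#' Generate a network whose wiring follows binding specificity
#'
#' Draws a per-TF information content uniformly over `ic_range`, builds a
#' binding matrix at that IC, and wires each TF to `targets_per_tf`
#' targets on average, choosing a TF target with probability
#' `plogis(slope * (IC - mean IC))` — a planted positive link between
#' specificity and the fraction of TF targets when `slope > 0`.
#'
#' @param n_tf Number of TFs.
#' @param slope Logistic slope of the planted IC-wiring link (per bit).
#' @param n_nontf Size of the non-TF target pool (default 200).
#' @param targets_per_tf Mean out-degree (default 10).
#' @param ic_range IC range in bits (default `c(2, 12)`).
#' @param width PWM width (default 8).
#' @param seed Integer seed.
#' @return A list with elements `network` and `matrices`.
#' @export
gen_ic_wired_network <- function(n_tf = 60, slope = 0.6, n_nontf = 200,
                                 targets_per_tf = 10,
                                 ic_range = c(2, 12), width = 8, seed = 1) {
  set.seed(seed)
  tf_ids <- sprintf("TF%04d", seq_len(n_tf))
  nontf_ids <- sprintf("G%04d", seq_len(n_nontf))
  ic <- runif(n_tf, ic_range[1], ic_range[2])
  p_tf <- plogis(slope * (ic - mean(ic)))
  from <- character(0); to <- character(0)
  for (i in seq_len(n_tf)) {
    k <- max(1, rpois(1, targets_per_tf))
    n_tf_targets <- sum(runif(k) < p_tf[i])
    tf_pool <- setdiff(tf_ids, tf_ids[i])
    tgt <- c(sample(tf_pool, min(n_tf_targets, length(tf_pool))),
             sample(nontf_ids, min(k - n_tf_targets, n_nontf)))
    from <- c(from, rep(tf_ids[i], length(tgt)))
    to <- c(to, tgt)
  }
  net <- reg_network(tibble::tibble(regulator = from, target = to,
                                    mode = "unknown"),
                     tf_ids = tf_ids, name = "ic_wired")
  pwm_seeds <- sample.int(1e6, n_tf)
  matrices <- purrr::map2(seq_len(n_tf), tf_ids, function(i, id) {
    gen_pwms(1, width = width, target_ic = ic[i], seed = pwm_seeds[i],
             ids = id)[[1]]
  })
  names(matrices) <- tf_ids
  list(network = net, matrices = matrices)
}
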