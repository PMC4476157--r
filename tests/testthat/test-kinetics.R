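toggle_model <- function(beta = 4, hill = 2, basal = 0.01) {
  kinetic_model(tibble::tibble(from = c("x1", "x2"), to = c("x2", "x1"),
                               sign = c("-", "-")),
                beta = beta, alpha = 1, basal = basal, K = 1, hill = hill)
}

test_that("input-free nodes follow linear production-decay dynamics", {
  decay <- kinetic_model(tibble::tibble(from = character(),
                                        to = character()),
                         basal = 0, nodes = "x")
  sim <- simulate_model(decay, x0 = 1, t_end = 5, rel_tol = 1e-8)
  expect_equal(unname(sim$terminal), exp(-5), tolerance = 1e-6)
  # the whole trajectory matches the closed form
  expect_equal(sim$trajectory$x, exp(-sim$trajectory$time),
               tolerance = 1e-6)

  prod <- kinetic_model(tibble::tibble(from = character(),
                                       to = character()),
                        basal = 2, nodes = "x")
  sim2 <- simulate_model(prod, x0 = 0, t_end = 30)
  expect_true(sim2$steady)
  expect_equal(unname(sim2$terminal), 2, tolerance = 1e-5)
})

test_that("Hill terms half-saturate at K and vanish/saturate in the limits", {
  m <- kinetic_model(tibble::tibble(from = "a", to = "b", sign = "+"),
                     beta = 4, alpha = 1, basal = 0, K = 1, hill = 2)
  rhs <- regnet:::model_rhs(m)
  # activator at x_a = K contributes beta/2
  dx <- unlist(rhs(0, c(a = 1, b = 0), NULL))
  expect_equal(dx[2], 2)
  rep_m <- kinetic_model(tibble::tibble(from = "a", to = "b", sign = "-"),
                         beta = 4, alpha = 1, basal = 0, K = 1, hill = 2)
  rhs_r <- regnet:::model_rhs(rep_m)
  dx0 <- unlist(rhs_r(0, c(a = 0, b = 0), NULL))
  expect_equal(dx0[2], 4)  # repressor at 0 leaves full production
  dxinf <- unlist(rhs_r(0, c(a = 1e6, b = 0), NULL))
  expect_lt(dxinf[2], 1e-6)
})

test_that("trajectories from nonnegative states stay nonnegative", {
  set.seed(9)
  for (i in 1:5) {
    edges <- tibble::tibble(from = sample(c("a", "b", "c"), 4, TRUE),
                            to = sample(c("a", "b", "c"), 4, TRUE),
                            sign = sample(c("+", "-"), 4, TRUE))
    edges <- dplyr::distinct(edges, from, to, .keep_all = TRUE)
    m <- kinetic_model(edges, nodes = c("a", "b", "c"))
    sim <- simulate_model(m, x0 = runif(3, 0, 5), t_end = 50,
                          abs_tol = 1e-8)
    expect_true(all(as.matrix(sim$trajectory[, -1]) >= -1e-8))
  }
  expect_error(simulate_model(toggle_model(), x0 = c(-1, 1)), "nonnegative")
})

test_that("the symmetric toggle switch is bistable and settles by basin", {
  m <- toggle_model()
  sim <- simulate_model(m, x0 = c(3, 0.1), t_end = 100)
  expect_true(sim$steady)
  expect_gt(sim$terminal["x1"], 10 * sim$terminal["x2"])

  stab <- find_stable_states(m, grid_points_per_axis = 6, x_max = 5)
  expect_equal(stab$n_stable, 2)
  x1_levels <- vapply(stab$stable_states, `[[`, numeric(1), "x1")
  s_hi <- stab$stable_states[[which.max(x1_levels)]]
  s_lo <- stab$stable_states[[which.min(x1_levels)]]
  # mirror-image attractors: x1 high implies x2 low and vice versa
  expect_gt(s_hi[["x1"]], 10 * s_hi[["x2"]])
  expect_gt(s_lo[["x2"]], 10 * s_lo[["x1"]])
})

test_that("weak, non-cooperative mutual repression is monostable", {
  m <- toggle_model(beta = 0.5, hill = 1)
  stab <- find_stable_states(m, grid_points_per_axis = 5, x_max = 3)
  expect_equal(stab$n_stable, 1)
  # independent 1-D fixed-point oracle: by symmetry search x = f(x)
  f <- function(x) 0.01 + 0.5 / (1 + x) - x
  root <- uniroot(f, c(0, 3))$root
  expect_equal(unname(stab$stable_states[[1]]["x1"]), root,
               tolerance = 1e-3)
})

test_that("degradation-only circuits have exactly one stable state at b/alpha", {
  m <- kinetic_model(tibble::tibble(from = character(), to = character()),
                     basal = 2, alpha = 2, nodes = c("u", "v"))
  stab <- find_stable_states(m, grid_points_per_axis = 3, x_max = 4)
  expect_equal(stab$n_stable, 1)
  expect_equal(unname(stab$stable_states[[1]]), c(1, 1), tolerance = 1e-4)
})

test_that("pulses flip the toggle only when strong and long enough", {
  m <- toggle_model()
  stab <- find_stable_states(m, grid_points_per_axis = 6, x_max = 5)
  x1_levels <- vapply(stab$stable_states, `[[`, numeric(1), "x1")
  lo_state <- stab$stable_states[[which.min(x1_levels)]]  # x1 low, x2 high

  none <- pulse_transition(m, lo_state,
                           list(node = "x1", amplitude = 0, duration = 5),
                           stability = stab)
  expect_false(none$switched)

  flip <- pulse_transition(m, lo_state,
                           list(node = "x1", amplitude = 10, duration = 10),
                           stability = stab)
  expect_true(flip$switched)

  blip <- pulse_transition(m, lo_state,
                           list(node = "x1", amplitude = 10,
                                duration = 0.01),
                           stability = stab)
  expect_false(blip$switched)

  expect_error(
    pulse_transition(m, lo_state,
                     list(node = "zz", amplitude = 1, duration = 1),
                     stability = stab),
    "Unknown signal node"
  )
})

test_that("an external signal node gates its target through the Hill term", {
  m <- kinetic_model(tibble::tibble(from = "S", to = "x", sign = "+"),
                     beta = 4, alpha = 1, basal = 0.05, K = 1, hill = 2,
                     signal = "S")
  expect_equal(m$nodes, "x")
  off <- simulate_model(m, x0 = 0, t_end = 60, signal_level = 0)
  on <- simulate_model(m, x0 = 0, t_end = 60, signal_level = 5)
  expect_lt(unname(off$terminal), 0.1)
  expect_gt(unname(on$terminal), 2)
})

test_that("halving tolerances leaves terminal states essentially unchanged", {
  m <- toggle_model()
  a <- simulate_model(m, c(3, 0.1), t_end = 80, rel_tol = 1e-6,
                      abs_tol = 1e-8)
  b <- simulate_model(m, c(3, 0.1), t_end = 80, rel_tol = 5e-7,
                      abs_tol = 5e-9)
  expect_lt(sqrt(sum((a$terminal - b$terminal)^2)), 0.05)
})

test_that("every all-activation triad relaxes to at least one stable state", {
  tc <- triad_classes()
  cells <- cbind(c(1, 1, 2, 2, 3, 3), c(2, 3, 1, 3, 1, 2))
  weights <- c(32, 16, 8, 4, 2, 1)
  for (cls in 1:13) {
    on <- bitwAnd(tc$code[cls] %/% weights, 1) == 1
    nodes <- c("a", "b", "c")
    edges <- tibble::tibble(from = nodes[cells[on, 1]],
                            to = nodes[cells[on, 2]], sign = "+")
    m <- kinetic_model(edges, nodes = nodes)
    stab <- find_stable_states(m, grid_points_per_axis = 3, x_max = 5,
                               t_end = 300)
    expect_gte(stab$n_stable, 1)
  }
})
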