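#' Build a Hill-kinetics model of a small regulatory circuit
#'
#' Each regulatory node follows
#' `dx_i/dt = b_i + beta_i * prod(act) * prod(rep) - alpha_i * x_i`,
#' where the product runs over the node's activating inputs
#' (`x_j^n / (K^n + x_j^n)`) and repressing inputs (`K^n / (K^n + x_j^n)`) —
#' multiplicative (AND) input integration. A node with no inputs has no
#' regulated production term and follows `dx/dt = b - alpha * x`. One
#' optional external signal node may appear as an edge source; its level is
#' an input to the system (0 unless set), not a state.
#'
#' @param edges Data frame with columns `from`, `to`, `sign` (`"+"` or
#'   `"-"`, `"activation"`/`"repression"` also accepted).
#' @param beta Maximum regulated production rate (scalar or named per-node
#'   vector; concentration/time). Default 4.
#' @param alpha First-order decay rate (scalar or named; 1/time, > 0).
#'   Default 1.
#' @param basal Basal production `b` (scalar or named; concentration/time).
#'   Default 0.01.
#' @param K Hill threshold shared by all edges (concentration, > 0).
#'   Default 1.
#' @param hill Hill coefficient `n >= 1`. Default 2.
#' @param signal Optional name of the external signal node.
#' @param nodes Optional explicit node order.
#' @return An object of class `kinetic_model`.
#' @examples
#' toggle <- kinetic_model(tibble::tibble(
#'   from = c("x1", "x2"), to = c("x2", "x1"), sign = c("-", "-")
#' ))
#' @export
kinetic_model <- function(edges, beta = 4, alpha = 1, basal = 0.01,
                          K = 1, hill = 2, signal = NULL, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (!"sign" %in% names(edges)) edges$sign <- "+"
  edges$sign <- dplyr::case_when(
    edges$sign %in% c("+", "activation") ~ "+",
    edges$sign %in% c("-", "repression") ~ "-",
    TRUE ~ NA_character_
  )
  if (anyNA(edges$sign)) abort("Edge signs must be `+` or `-`.")
  all_names <- unique(c(edges$from, edges$to, nodes))
  state_nodes <- setdiff(all_names, signal)
  if (!is.null(signal) && signal %in% edges$to) {
    abort("The signal node cannot be a target.")
  }
  if (!is.null(nodes)) {
    if (!setequal(setdiff(nodes, signal), state_nodes)) {
      abort("Unknown node in the edge list.")
    }
    state_nodes <- setdiff(nodes, signal)
  }
  if (length(state_nodes) > 3) {
    abort("At most 3 regulatory nodes (plus an optional signal).")
  }
  expand <- function(x, default) {
    out <- rep(default, length(state_nodes))
    names(out) <- state_nodes
    if (length(x) == 1 && is.null(names(x))) {
      out[] <- x
    } else {
      out[names(x)] <- x
    }
    out
  }
  alpha <- expand(alpha, 1)
  if (any(alpha <= 0)) abort("`alpha` must be > 0.")
  if (K <= 0) abort("`K` must be > 0.")
  if (hill < 1) abort("`hill` must be >= 1.")
  structure(list(nodes = state_nodes, signal = signal, edges = edges,
                 beta = expand(beta, 4), alpha = alpha,
                 basal = expand(basal, 0.01), K = K, hill = hill),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("<kinetic_model> ", length(x$nodes), " nodes",
      if (!is.null(x$signal)) paste0(" + signal ", x$signal),
      ", ", nrow(x$edges), " edges (K = ", x$K, ", n = ", x$hill, ")\n",
      sep = "")
  invisible(x)
}

# Right-hand side; `signal_level` is the external input level, `inflow` an
# optional named vector of constant extra production (used for pulses).
model_rhs <- function(model, signal_level = 0, inflow = NULL) {
  nodes <- model$nodes
  Kn <- model$K^model$hill
  n <- model$hill
  inputs <- split(model$edges[, c("from", "sign")], model$edges$to)
  extra <- setNames(numeric(length(nodes)), nodes)
  if (!is.null(inflow)) extra[names(inflow)] <- inflow
  function(t, x, parms) {
    lev <- setNames(as.numeric(x), nodes)
    if (!is.null(model$signal)) lev[model$signal] <- signal_level
    dx <- numeric(length(nodes))
    for (i in seq_along(nodes)) {
      nd <- nodes[i]
      prod_term <- NULL
      inp <- inputs[[nd]]
      if (!is.null(inp) && nrow(inp) > 0) {
        xs <- lev[inp$from]^n
        h <- ifelse(inp$sign == "+", xs / (Kn + xs), Kn / (Kn + xs))
        prod_term <- model$beta[nd] * prod(h)
      }
      dx[i] <- model$basal[nd] + (prod_term %||% 0) + extra[nd] -
        model$alpha[nd] * x[i]
    }
    list(dx)
  }
}

#' Integrate a kinetic model
#'
#' Adaptive Runge-Kutta 4(5) integration of the circuit from a nonnegative
#' initial state. The run is flagged steady when `max |dx/dt| < 1e-6` at
#' `t_end`.
#'
#' @param model A [kinetic_model()].
#' @param x0 Named or positional nonnegative initial state (one value per
#'   regulatory node).
#' @param t_end End time.
#' @param rel_tol,abs_tol Integration tolerances.
#' @param n_steps Number of output time points (default 201).
#' @param signal_level Constant level of the external signal node
#'   (default 0).
#' @param inflow Optional named vector of constant extra production.
#' @return An object of class `reg_simulation`: list with `trajectory`
#'   (tibble `time` + one column per node), `terminal` (named state),
#'   `steady` (logical) and the model.
#' @export
simulate_model <- function(model, x0, t_end = 100, rel_tol = 1e-6,
                           abs_tol = 1e-8, n_steps = 201,
                           signal_level = 0, inflow = NULL) {
  stopifnot(inherits(model, "kinetic_model"))
  if (rel_tol <= 0 || abs_tol <= 0) abort("Tolerances must be > 0.")
  if (length(x0) != length(model$nodes)) {
    abort("`x0` must have one value per regulatory node.")
  }
  if (!is.null(names(x0))) x0 <- x0[model$nodes]
  x0 <- setNames(as.numeric(x0), model$nodes)
  if (any(x0 < 0)) abort("`x0` must be componentwise nonnegative.")
  rhs <- model_rhs(model, signal_level = signal_level, inflow = inflow)
  times <- seq(0, t_end, length.out = n_steps)
  sol <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                      method = "ode45", rtol = rel_tol, atol = abs_tol)
  traj <- tibble::as_tibble(as.data.frame(unclass(sol)))
  terminal <- setNames(as.numeric(sol[nrow(sol), -1]), model$nodes)
  dxdt <- unlist(rhs(t_end, terminal, NULL))
  structure(list(trajectory = traj, terminal = terminal,
                 steady = max(abs(dxdt)) < 1e-6, model = model),
            class = "reg_simulation")
}

#' @export
print.reg_simulation <- function(x, ...) {
  cat("<reg_simulation> t in [0, ",
      max(x$trajectory$time), "], terminal: ",
      paste(names(x$terminal), "=", format(x$terminal, digits = 3),
            collapse = ", "),
      if (x$steady) " (steady)" else " (not steady)", "\n", sep = "")
  invisible(x)
}

#' @rdname simulate_model
#' @param object A `reg_simulation`.
#' @param ... Unused.
#' @export
autoplot.reg_simulation <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trajectory, -"time",
                              names_to = "node", values_to = "level")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$level,
                                     colour = .data$node)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "concentration")
}

#' Locate the stable states of a circuit
#'
#' Integrates the model from a regular grid of initial conditions to
#' steadiness and merges terminal states closer than `merge_tol`
#' (Euclidean). Runs that fail to reach steadiness by `t_end` are excluded
#' with a warning.
#'
#' @param model A [kinetic_model()].
#' @param grid_points_per_axis Grid resolution per node (default 6).
#' @param x_max Upper bound of the initial-condition grid (default 5).
#' @param merge_tol Distance below which two terminal states are the same
#'   attractor (default 0.05).
#' @param t_end Integration horizon per run (default 200).
#' @param ... Passed on to [simulate_model()].
#' @return An object of class `reg_stability`: list with `stable_states`
#'   (list of named vectors), `n_stable`, `basins` (tibble: grid start,
#'   attractor index) and `model`.
#' @export
find_stable_states <- function(model, grid_points_per_axis = 6, x_max = 5,
                               merge_tol = 0.05, t_end = 200, ...) {
  stopifnot(inherits(model, "kinetic_model"))
  if (grid_points_per_axis < 2) abort("Need >= 2 grid points per axis.")
  axes <- rep(list(seq(0, x_max, length.out = grid_points_per_axis)),
              length(model$nodes))
  names(axes) <- model$nodes
  grid <- as.matrix(expand.grid(axes))
  states <- list()
  idx <- integer(nrow(grid))
  dropped <- 0
  for (r in seq_len(nrow(grid))) {
    sim <- simulate_model(model, grid[r, ], t_end = t_end, ...)
    if (!sim$steady) {
      dropped <- dropped + 1
      idx[r] <- NA_integer_
      next
    }
    hit <- which(vapply(states, function(s) {
      sqrt(sum((s - sim$terminal)^2)) <= merge_tol
    }, logical(1)))
    if (length(hit) == 0) {
      states[[length(states) + 1]] <- sim$terminal
      idx[r] <- length(states)
    } else {
      idx[r] <- hit[1]
    }
  }
  if (dropped > 0) {
    warn(paste0(dropped, " grid run(s) did not reach steadiness by t_end ",
                "and were excluded."))
  }
  # Symmetric grid starts can ride a separatrix into a saddle point, which
  # then looks steady; keep only states that attract back a small
  # asymmetric perturbation from both sides.
  is_attracting <- vapply(states, function(s) {
    dir <- (-1)^(seq_along(s) + 1) * merge_tol
    for (sgn in c(1, -1)) {
      x0 <- pmax(s + sgn * dir, 0)
      sim <- simulate_model(model, x0, t_end = t_end, ...)
      if (sqrt(sum((sim$terminal - s)^2)) > merge_tol) return(FALSE)
    }
    TRUE
  }, logical(1))
  states <- states[is_attracting]
  if (length(states) == 0) {
    warn("No attracting steady state found on the grid.")
  }
  old_ids <- which(is_attracting)
  idx <- match(idx, old_ids)
  ord <- order(vapply(states, sum, numeric(1)))
  relabel <- match(seq_along(states), ord)
  basins <- tibble::as_tibble(as.data.frame(grid))
  basins$attractor <- ifelse(is.na(idx), NA_integer_, relabel[idx])
  structure(list(stable_states = states[ord], n_stable = length(states),
                 basins = basins, merge_tol = merge_tol, model = model),
            class = "reg_stability")
}

#' @export
print.reg_stability <- function(x, ...) {
  cat("<reg_stability> ", x$n_stable, " stable state(s):\n", sep = "")
  for (s in x$stable_states) {
    cat("  ", paste(names(s), "=", format(s, digits = 3), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Pulse-driven transitions between stable states
#'
#' Starting from a stable state, applies a constant input to the named
#' node for the pulse duration (extra production for a regulatory node, or
#' the level of the external signal node), then lets the system relax and
#' reports whether it settled into a different stable state.
#'
#' @param model A [kinetic_model()].
#' @param state A stable state (named vector) or its index in `stability`.
#' @param pulse List with elements `node`, `amplitude`, `duration`.
#' @param t_relax Relaxation time after the pulse (default 200).
#' @param stability Optional precomputed [find_stable_states()] report
#'   (computed if missing).
#' @param ... Passed on to [simulate_model()].
#' @return A list: `switched` (logical), `from`, `to` (attractor indices),
#'   `final` (named state).
#' @export
pulse_transition <- function(model, state, pulse, t_relax = 200,
                             stability = NULL, ...) {
  stopifnot(inherits(model, "kinetic_model"))
  if (is.null(stability)) stability <- find_stable_states(model, ...)
  if (length(state) == 1 && is.numeric(state) &&
      state <= stability$n_stable) {
    state <- stability$stable_states[[state]]
  }
  nearest <- function(x) {
    d <- vapply(stability$stable_states,
                function(s) sqrt(sum((s - x)^2)), numeric(1))
    which.min(d)
  }
  from <- nearest(state)
  if (sqrt(sum((stability$stable_states[[from]] - state)^2)) >
      stability$merge_tol) {
    abort("`state` is not one of the model's stable states.")
  }
  node <- pulse$node
  known <- c(model$nodes, model$signal)
  if (!node %in% known) abort(paste0("Unknown signal node `", node, "`."))
  if (pulse$duration > 0 && pulse$amplitude != 0) {
    if (!is.null(model$signal) && node == model$signal) {
      during <- simulate_model(model, state, t_end = pulse$duration,
                               signal_level = pulse$amplitude, ...)
    } else {
      during <- simulate_model(model, state, t_end = pulse$duration,
                               inflow = setNames(pulse$amplitude, node), ...)
    }
    state <- during$terminal
  }
  relaxed <- simulate_model(model, state, t_end = t_relax, ...)
  to <- nearest(relaxed$terminal)
  list(switched = to != from, from = from, to = to,
       final = relaxed$terminal)
}
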