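#' Dynamics parameters
#'
#' Parameters of the continuous-logic update rule. Each unclamped node moves
#' by explicit Euler toward a sigmoid target of its aggregated regulatory
#' input \eqn{\omega} (see [input_strength()]):
#' \deqn{x_{t+1} = x_t + \Delta t\,(f(\omega) - \gamma x_t)}
#' where \eqn{f} is a logistic of gain `gain` rescaled so that
#' \eqn{f(0)=0}, \eqn{f(0.5)=0.5} and \eqn{f(1)=1} (half-activation input
#' maps to half-activation target, matching the 0/0.5/1 clamp semantics of
#' the condition presets).
#'
#' @param gain sigmoid steepness `h` (> 0). Default 10.
#' @param decay linear decay rate `gamma` (> 0). Default 1.
#' @param step explicit Euler step size (> 0). Default 0.1.
#' @param tol convergence tolerance on the maximum node-wise rate of change
#'   per step (`|dx| / step`, so the criterion is invariant to the Euler
#'   step size). Default 1e-6.
#' @param max_iter maximum number of iterations (>= 1). Default 10000.
#' @return an object of class `rnm_params`.
#' @export
dynamics_params <- function(gain = 10, decay = 1, step = 0.1,
                            tol = 1e-6, max_iter = 10000) {
  stopifnot(gain > 0, decay > 0, step > 0, tol > 0, max_iter >= 1)
  structure(list(gain = gain, decay = decay, step = step,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "rnm_params")
}

# rescaled logistic: f(0) = 0, f(1/2) = 1/2, f(1) = 1
sigmoid_target <- function(omega, gain) {
  lo <- stats::plogis(-gain / 2)
  hi <- stats::plogis(gain / 2)
  (stats::plogis(gain * (omega - 0.5)) - lo) / (hi - lo)
}

# precompute row-normalized activator/inhibitor weight matrices
compile_dynamics <- function(network) {
  nn <- network$nodes$node
  n <- length(nn)
  Wa <- matrix(0, n, n, dimnames = list(nn, nn))
  Wi <- matrix(0, n, n, dimnames = list(nn, nn))
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    if (e$sign[i] > 0) {
      Wa[e$target[i], e$source[i]] <- Wa[e$target[i], e$source[i]] + e$weight[i]
    } else {
      Wi[e$target[i], e$source[i]] <- Wi[e$target[i], e$source[i]] + e$weight[i]
    }
  }
  sa <- rowSums(Wa)
  si <- rowSums(Wi)
  has_act <- sa > 0
  has_inh <- si > 0
  An <- Wa / ifelse(has_act, sa, 1)
  In <- Wi / ifelse(has_inh, si, 1)
  no_reg <- !has_act & !has_inh
  pure_input <- no_reg &
    network$nodes$role %in% c("cytokine", "mechanoreceptor")
  list(nodes = nn, An = An, In = In, has_act = has_act, has_inh = has_inh,
       no_reg = no_reg, pure_input = pure_input)
}

# omega for a node x state matrix (nodes in rows, runs in columns)
omega_batch <- function(cd, X) {
  A <- cd$An %*% X
  A[!cd$has_act & cd$has_inh, ] <- 1
  I <- cd$In %*% X
  W <- A * (1 - I)
  if (any(cd$no_reg)) W[cd$no_reg, ] <- X[cd$no_reg, , drop = FALSE]
  if (any(cd$pure_input)) W[cd$pure_input, ] <- 0
  W
}

as_state_matrix <- function(state, nodes) {
  if (is.matrix(state)) {
    if (!setequal(rownames(state), nodes)) {
      stop("state rows must match network nodes")
    }
    return(state[nodes, , drop = FALSE])
  }
  if (is.null(names(state)) || !setequal(names(state), nodes)) {
    stop("state must be a named vector covering every network node")
  }
  matrix(state[nodes], ncol = 1, dimnames = list(nodes, NULL))
}

check_clamps <- function(clamps, nodes) {
  if (is.null(clamps) || length(clamps) == 0) return(numeric(0))
  clamps <- unlist(clamps)
  missing <- setdiff(names(clamps), nodes)
  if (length(missing)) {
    stop("clamped node(s) not in network: ", paste(missing, collapse = ", "))
  }
  if (any(clamps < 0 | clamps > 1)) stop("clamp values must lie in [0, 1]")
  clamps
}

apply_clamps <- function(X, clamps) {
  if (length(clamps)) X[names(clamps), ] <- clamps
  X
}

step_batch <- function(cd, X, clamps, params) {
  W <- omega_batch(cd, X)
  X1 <- X + params$step * (sigmoid_target(W, params$gain) - params$decay * X)
  if (!all(is.finite(X1))) {
    bad <- cd$nodes[which(!apply(is.finite(X1), 1, all))[1]]
    stop("non-finite update at node '", bad, "'")
  }
  X1 <- pmin(pmax(X1, 0), 1)
  apply_clamps(X1, clamps)
}

#' Aggregated regulatory input of a node
#'
#' The normalized influence \eqn{\omega \in [0,1]} of a node's regulators:
#' \deqn{\omega = A\,(1 - I)} with
#' \eqn{A = \sum w_a x_a / \sum w_a} over activators (taken as 1 when the
#' node has inhibitors but no activators) and
#' \eqn{I = \sum w_i x_i / \sum w_i} over inhibitors (0 when none).
#' A node with no regulators at all returns its own activation
#' (self-sustaining), except pure input nodes (role `cytokine` or
#' `mechanoreceptor`) which return 0 and therefore decay unless clamped.
#'
#' @param network an `rnm_network`.
#' @param node node name.
#' @param state named numeric state vector (all nodes, values in \[0,1\]).
#' @return scalar \eqn{\omega} in \[0,1\].
#' @export
input_strength <- function(network, node, state) {
  cd <- compile_dynamics(network)
  if (!node %in% cd$nodes) stop("unknown node: ", node)
  X <- as_state_matrix(state, cd$nodes)
  unname(omega_batch(cd, X)[node, 1])
}

#' One explicit-Euler step of the network dynamics
#'
#' Moves every unclamped node toward the sigmoid target implied by its
#' aggregated input (see [dynamics_params()] for the update rule); clamped
#' nodes are returned at their clamp value. All outputs lie in \[0,1\].
#'
#' @param network an `rnm_network`.
#' @param state named numeric vector over all nodes.
#' @param clamps named numeric vector of sustained clamps in \[0,1\]
#'   (0 = full knock-down, 1 = full activation), or `NULL`.
#' @param params an `rnm_params` object.
#' @return named numeric state vector after one step.
#' @export
step_dynamics <- function(network, state, clamps = NULL,
                          params = dynamics_params()) {
  cd <- compile_dynamics(network)
  cl <- check_clamps(clamps, cd$nodes)
  X <- apply_clamps(as_state_matrix(state, cd$nodes), cl)
  X1 <- step_batch(cd, X, cl, params)
  stats::setNames(X1[, 1], cd$nodes)
}

# iterate a state matrix to steady state; returns list(X, converged, iterations)
solve_batch <- function(cd, X0, clamps, params) {
  X <- apply_clamps(X0, clamps)
  m <- ncol(X)
  converged <- rep(FALSE, m)
  iterations <- rep(params$max_iter, m)
  for (it in seq_len(params$max_iter)) {
    X1 <- step_batch(cd, X, clamps, params)
    D <- abs(X1 - X)
    delta <- D[1, ]
    for (r in seq_len(nrow(D))[-1]) delta <- pmax(delta, D[r, ])
    delta <- delta / params$step
    newly <- !converged & delta < params$tol
    iterations[newly] <- it
    converged <- converged | newly
    X <- X1
    if (all(converged)) break
  }
  list(X = X, converged = converged, iterations = iterations)
}

#' Iterate the dynamics to a steady state
#'
#' Repeats [step_dynamics()] until the maximum node-wise rate of change in
#' one step (`|dx| / step`) falls below `params$tol`, or `params$max_iter`
#' is reached. Each solve is
#' one attractor search from one initial condition; non-convergence (e.g. an
#' oscillatory attractor) is a flagged outcome, not an error.
#'
#' @inheritParams step_dynamics
#' @param initial named numeric initial state over all nodes.
#' @return list with elements `state` (named vector; clamped nodes exactly at
#'   their clamp values), `converged` (logical) and `iterations` (integer).
#' @export
solve_steady_state <- function(network, initial, clamps = NULL,
                               params = dynamics_params()) {
  cd <- compile_dynamics(network)
  cl <- check_clamps(clamps, cd$nodes)
  res <- solve_batch(cd, as_state_matrix(initial, cd$nodes), cl, params)
  list(state = stats::setNames(res$X[, 1], cd$nodes),
       converged = res$converged[1],
       iterations = res$iterations[1])
}

#' Sample random initial conditions
#'
#' Unclamped nodes are drawn independently uniform on \[0,1\]; clamped nodes
#' are set to their clamp values. The seed fully determines the sample.
#'
#' @inheritParams step_dynamics
#' @param n number of initial states (>= 1).
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return numeric matrix, nodes in rows and samples in columns.
#' @export
sample_initial_states <- function(network, clamps = NULL, n, seed = NULL) {
  stopifnot(n >= 1)
  nodes <- network$nodes$node
  cl <- check_clamps(clamps, nodes)
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(stats::runif(length(nodes) * n), nrow = length(nodes),
              dimnames = list(nodes, NULL))
  apply_clamps(X, cl)
}
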