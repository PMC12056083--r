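# shared fixtures and independent oracles for the dynamics tests

fake_table <- function(x, y, condition = "TNF_unloaded",
                       protein = sprintf("P%02d", seq_along(x))) {
  structure(data.frame(condition = condition, protein = protein,
                       x = x, y = y, stringsAsFactors = FALSE),
            class = c("comparison_table", "data.frame"))
}

edge_df <- function(source, target, sign, weight = 1) {
  data.frame(source = source, target = target, sign = sign, weight = weight,
             stringsAsFactors = FALSE)
}

# independent re-implementation of the aggregation rule and sigmoid target,
# built from the edge list (never via the package's compiled matrices);
# returns the continuous-time residual f(omega(x)) - gamma * x
oracle_residual <- function(network, state, params) {
  nodes <- network$nodes$node
  roles <- stats::setNames(network$nodes$role, nodes)
  e <- network$edges
  lo <- stats::plogis(-params$gain / 2)
  hi <- stats::plogis(params$gain / 2)
  f <- function(w) (stats::plogis(params$gain * (w - 0.5)) - lo) / (hi - lo)
  res <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[i]
    act <- e[e$target == nd & e$sign > 0, ]
    inh <- e[e$target == nd & e$sign < 0, ]
    if (nrow(act) == 0 && nrow(inh) == 0) {
      w <- if (roles[[nd]] %in% c("cytokine", "mechanoreceptor")) 0 else
        state[[nd]]
    } else {
      A <- if (nrow(act)) sum(act$weight * state[act$source]) /
        sum(act$weight) else 1
      I <- if (nrow(inh)) sum(inh$weight * state[inh$source]) /
        sum(inh$weight) else 0
      w <- A * (1 - I)
    }
    res[i] <- f(w) - params$decay * state[[nd]]
  }
  stats::setNames(res, nodes)
}

# independently built weight matrices for the vectorized oracle
oracle_matrices <- function(network) {
  nodes <- network$nodes$node
  e <- network$edges
  n <- length(nodes)
  Wa <- Wi <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(e))) {
    if (e$sign[i] > 0) {
      Wa[e$target[i], e$source[i]] <- Wa[e$target[i], e$source[i]] +
        e$weight[i]
    } else {
      Wi[e$target[i], e$source[i]] <- Wi[e$target[i], e$source[i]] +
        e$weight[i]
    }
  }
  sa <- rowSums(Wa)
  si <- rowSums(Wi)
  none <- sa == 0 & si == 0
  list(Wa = Wa, Wi = Wi, sa = sa, si = si, none = none,
       pure = none & network$nodes$role %in% c("cytokine",
                                               "mechanoreceptor"))
}

# vectorized oracle residual for a points-in-rows matrix
oracle_residual_grid <- function(network, X, params, om = NULL) {
  if (is.null(om)) om <- oracle_matrices(network)
  S <- t(X)   # nodes x points
  A <- (om$Wa %*% S) / ifelse(om$sa > 0, om$sa, 1)
  A[om$sa == 0 & om$si > 0, ] <- 1
  I <- (om$Wi %*% S) / ifelse(om$si > 0, om$si, 1)
  W <- A * (1 - I)
  W[om$none, ] <- S[om$none, , drop = FALSE]
  W[om$pure, ] <- 0
  lo <- stats::plogis(-params$gain / 2)
  hi <- stats::plogis(params$gain / 2)
  F <- (stats::plogis(params$gain * (W - 0.5)) - lo) / (hi - lo)
  F - params$decay * S
}

# exhaustive root scan of the update map: coarse grid filter, candidate
# thinning, Newton refinement (pracma); finds stable and unstable roots
scan_fixed_points <- function(network, params, grid = 0.02) {
  nodes <- network$nodes$node
  d <- length(nodes)
  g <- seq(0, 1, by = grid)
  X <- as.matrix(expand.grid(rep(list(g), d)))
  colnames(X) <- nodes
  om <- oracle_matrices(network)
  R <- abs(oracle_residual_grid(network, X, params, om))
  rn <- R[1, ]
  for (r in seq_len(nrow(R))[-1]) rn <- pmax(rn, R[r, ])
  keep <- rn < 0.3
  cand <- X[keep, , drop = FALSE]
  cand <- cand[order(rn[keep]), , drop = FALSE]
  # thin candidates: one Newton start per 0.08-ball, best residual first
  starts <- list()
  for (i in seq_len(nrow(cand))) {
    if (!any(vapply(starts, function(z) max(abs(z - cand[i, ])) < 0.08,
                    TRUE))) {
      starts[[length(starts) + 1]] <- cand[i, ]
    }
  }
  fres <- function(x) {
    as.numeric(oracle_residual_grid(network, matrix(x, nrow = 1),
                                    params, om))
  }
  roots <- list()
  for (x0 in starts) {
    r <- try(suppressWarnings(pracma::newtonsys(fres, as.numeric(x0))),
             silent = TRUE)
    if (inherits(r, "try-error")) next
    x <- r$zero
    if (any(!is.finite(x)) || any(x < -1e-6 | x > 1 + 1e-6)) next
    if (max(abs(fres(x))) > 1e-8) next
    x <- pmin(pmax(x, 0), 1)
    if (!any(vapply(roots, function(z) max(abs(z - x)) < 1e-4, TRUE))) {
      roots[[length(roots) + 1]] <- stats::setNames(x, nodes)
    }
  }
  roots
}

# catalog of small toy networks used by the fixed-point oracle suite
toy_catalog <- function() {
  list(
    self_activator = make_toy_network("self_activator")$network,
    toggle = make_toy_network("toggle")$network,
    cascade2 = rnm_network(edge_df("X", "ACAN", 1),
                           nodes = data.frame(node = c("X", "ACAN"),
                                              role = c("cytokine",
                                                       "readout"))),
    mutual_activation = rnm_network(rbind(edge_df("ACAN", "B", 1),
                                          edge_df("B", "ACAN", 1))),
    cascade3 = make_toy_network("cascade")$network,
    feedforward = rnm_network(rbind(edge_df("X", "M", 1),
                                    edge_df("X", "ACAN", 1),
                                    edge_df("M", "ACAN", -1)),
                              nodes = data.frame(node = c("X", "M", "ACAN"),
                                                 role = c("cytokine",
                                                          "generic",
                                                          "readout"))),
    mixed3 = rnm_network(rbind(edge_df("ACAN", "ACAN", 1),
                               edge_df("ACAN", "B", 1),
                               edge_df("B", "C", -1)))
  )
}

# steady states reached from a regular grid of initial conditions; with
# jitter = TRUE each node's grid is shifted slightly so no initial state
# sits on a symmetric (equal-coordinate) manifold
grid_steady_states <- function(network, params, grid = 0.05, clamps = NULL,
                               jitter = FALSE) {
  nodes <- network$nodes$node
  g <- seq(0, 1, by = grid)
  gl <- lapply(seq_along(nodes), function(i) {
    if (jitter) (g + 0.013 * (i - 1)) %% 1 else g
  })
  X0 <- t(as.matrix(expand.grid(gl)))
  rownames(X0) <- nodes
  cd <- rnmconcord:::compile_dynamics(network)
  cl <- rnmconcord:::check_clamps(clamps, nodes)
  res <- rnmconcord:::solve_batch(cd, rnmconcord:::apply_clamps(X0, cl),
                                  cl, params)
  list(states = res$X[, res$converged, drop = FALSE],
       n_nonconverged = sum(!res$converged))
}
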