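#' Run an attractor ensemble for a condition
#'
#' Draws `n` random initial conditions (see [sample_initial_states()]),
#' iterates each to steady state under the preset's sustained clamps, labels
#' every converged steady state pro-anabolic or pro-catabolic, and summarizes
#' mean activations, label fractions and the number of distinct attractors.
#'
#' @param network an `rnm_network`.
#' @param preset a [condition_preset()], or a named numeric clamp vector.
#' @param rule a [classification_rule()].
#' @param n ensemble size. Default 100.
#' @param seed integer RNG seed (fully determines the ensemble).
#' @param params an [dynamics_params()] object.
#' @param dedup_tol two steady states belong to the same attractor when
#'   their max node-wise difference is below this. Default 1e-3.
#' @return An object of class `rnm_ensemble`: list with `states` (node x run
#'   matrix), `converged`, `labels`, `mean_activation` (over converged runs),
#'   `frac_anabolic`/`frac_catabolic` (percent of converged runs),
#'   `n_converged`, `attractors` (deduplicated representative states),
#'   `n_attractors`, plus the preset, rule, seed and params used.
#' @export
run_ensemble <- function(network, preset, rule = classification_rule(),
                         n = 100, seed = NULL, params = dynamics_params(),
                         dedup_tol = 1e-3) {
  if (inherits(preset, "condition_preset")) {
    clamps <- preset$clamps
    preset_name <- preset$name
  } else {
    clamps <- unlist(preset)
    preset_name <- "custom"
    preset <- condition_preset(preset_name, "literature", "control",
                               "unloaded", clamps)
  }
  nodes <- network$nodes$node
  missing <- setdiff(names(clamps), nodes)
  if (length(missing)) {
    stop("preset '", preset_name, "' clamps node(s) absent from the network: ",
         paste(missing, collapse = ", "))
  }
  if (!rule$readout %in% nodes) {
    stop("readout node '", rule$readout, "' absent from the network")
  }

  cd <- compile_dynamics(network)
  cl <- check_clamps(clamps, nodes)
  X0 <- sample_initial_states(network, clamps, n, seed)
  res <- solve_batch(cd, X0, cl, params)

  labels <- ifelse(res$X[rule$readout, ] >= rule$threshold,
                   "pro-anabolic", "pro-catabolic")
  labels[!res$converged] <- NA_character_
  conv <- res$converged
  n_conv <- sum(conv)

  mean_act <- if (n_conv) rowMeans(res$X[, conv, drop = FALSE]) else
    stats::setNames(rep(NA_real_, length(nodes)), nodes)

  attractors <- dedup_states(res$X[, conv, drop = FALSE], dedup_tol)

  structure(list(
    preset = preset, rule = rule, n = n, seed = seed, params = params,
    states = res$X, converged = conv, iterations = res$iterations,
    labels = labels, n_converged = n_conv,
    mean_activation = mean_act,
    frac_anabolic = if (n_conv) 100 * sum(labels == "pro-anabolic",
                                          na.rm = TRUE) / n_conv else NA_real_,
    frac_catabolic = if (n_conv) 100 * sum(labels == "pro-catabolic",
                                           na.rm = TRUE) / n_conv else NA_real_,
    attractors = attractors, n_attractors = ncol(attractors),
    dedup_tol = dedup_tol), class = "rnm_ensemble")
}

# greedy dedup of state columns by max node-wise difference
dedup_states <- function(X, tol) {
  if (ncol(X) == 0) return(X)
  reps <- X[, 1, drop = FALSE]
  for (j in seq_len(ncol(X))[-1]) {
    d <- apply(abs(reps - X[, j]), 2, max)
    if (all(d >= tol)) reps <- cbind(reps, X[, j])
  }
  colnames(reps) <- NULL
  reps
}

#' @export
print.rnm_ensemble <- function(x, ...) {
  cat(sprintf("rnm_ensemble '%s': %d runs (%d converged), seed %s\n",
              x$preset$name, x$n, x$n_converged,
              if (is.null(x$seed)) "none" else x$seed))
  cat(sprintf("  %.1f%% pro-anabolic / %.1f%% pro-catabolic (readout %s >= %g)\n",
              x$frac_anabolic, x$frac_catabolic, x$rule$readout,
              x$rule$threshold))
  cat(sprintf("  %d distinct attractor(s) at dedup tolerance %g\n",
              x$n_attractors, x$dedup_tol))
  invisible(x)
}

#' @export
summary.rnm_ensemble <- function(object, ...) {
  print(object)
  cat("mean activation over converged runs:\n")
  print(round(object$mean_activation, 4))
  invisible(object)
}

#' Predicted per-node change between two conditions
#'
#' Compares ensemble-mean activations of two conditions node by node:
#' `delta = meanB - meanA` and the relative change in percent
#' (`100 * delta / meanA`, `NA` where `meanA` is 0).
#'
#' @param ensembleA,ensembleB `rnm_ensemble` objects over the same network.
#' @param nodes nodes to compare; default all nodes shared by both.
#'   Requested nodes absent from the ensembles are skipped with a warning.
#' @return data.frame with columns `node`, `meanA`, `meanB`, `delta`,
#'   `rel_change_pct`.
#' @export
predict_condition_deltas <- function(ensembleA, ensembleB, nodes = NULL) {
  a <- ensembleA$mean_activation
  b <- ensembleB$mean_activation
  shared <- intersect(names(a), names(b))
  if (is.null(nodes)) nodes <- shared
  skipped <- setdiff(nodes, shared)
  if (length(skipped)) {
    warning("skipping node(s) absent from the ensembles: ",
            paste(skipped, collapse = ", "))
    nodes <- intersect(nodes, shared)
  }
  delta <- b[nodes] - a[nodes]
  data.frame(node = nodes, meanA = unname(a[nodes]), meanB = unname(b[nodes]),
             delta = unname(delta),
             rel_change_pct = ifelse(a[nodes] == 0, NA_real_,
                                     unname(100 * delta / a[nodes])),
             stringsAsFactors = FALSE)
}

#' Locate the critical clamp level of a node by bisection
#'
#' Scans the sustained clamp value of `node` on `interval` for the level at
#' which the majority steady-state label of an ensemble flips (e.g. the
#' critical IL-4 activation separating pro-catabolic from pro-anabolic
#' outcomes). Each bisection probe runs an `n_probe`-run ensemble under
#' `base_clamps` plus the probed clamp and is decided by majority label over
#' converged runs.
#'
#' @param network an `rnm_network`.
#' @param node name of the clamped node to scan.
#' @param base_clamps named clamp vector applied at every probe.
#' @param rule a [classification_rule()].
#' @param interval numeric length-2 search interval within \[0,1\].
#' @param tol interval width at which bisection stops; the midpoint is
#'   returned. Default 1e-4.
#' @param n_probe ensemble size per probe. Default 25.
#' @param seed integer seed (reused for every probe, so repeated calls with
#'   the same seed agree).
#' @param params an [dynamics_params()] object.
#' @return the critical clamp value (numeric scalar), with attributes
#'   `label_low`/`label_high` giving the majority labels at the endpoints.
#' @export
find_critical_clamp <- function(network, node, base_clamps = NULL,
                                rule = classification_rule(),
                                interval = c(0, 1), tol = 1e-4,
                                n_probe = 25, seed = NULL,
                                params = dynamics_params()) {
  if (!node %in% network$nodes$node) stop("unknown node: ", node)
  probe <- function(v) {
    cl <- c(base_clamps[setdiff(names(base_clamps), node)],
            stats::setNames(v, node))
    ens <- run_ensemble(network, cl, rule = rule, n = n_probe, seed = seed,
                        params = params)
    if (ens$n_converged == 0) stop("no converged runs at probe value ", v)
    if (ens$frac_anabolic >= 50) "pro-anabolic" else "pro-catabolic"
  }
  lo <- interval[1]
  hi <- interval[2]
  lab_lo <- probe(lo)
  lab_hi <- probe(hi)
  if (lab_lo == lab_hi) {
    stop("no crossing: majority label is '", lab_lo,
         "' at both ends of the interval")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (probe(mid) == lab_lo) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, label_low = lab_lo, label_high = lab_hi)
}

#' Ensemble summaries as CSV / JSON
#'
#' `write_ensemble_csv()` writes the per-node mean activations (node,value
#' rows); `ensemble_to_list()` returns a JSON-ready summary used by
#' [concordance_report()].
#'
#' @param ensemble an `rnm_ensemble`.
#' @param path output CSV path.
#' @return `write_ensemble_csv()` returns `invisible(ensemble)`;
#'   `ensemble_to_list()` a plain list.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  utils::write.csv(data.frame(node = names(ensemble$mean_activation),
                              value = unname(ensemble$mean_activation)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(ensemble)
}

#' @rdname write_ensemble_csv
#' @export
ensemble_to_list <- function(ensemble) {
  list(preset = ensemble$preset$name,
       condition = preset_condition(ensemble$preset),
       n = ensemble$n, seed = ensemble$seed,
       n_converged = ensemble$n_converged,
       frac_anabolic = ensemble$frac_anabolic,
       frac_catabolic = ensemble$frac_catabolic,
       n_attractors = ensemble$n_attractors,
       mean_activation = as.list(ensemble$mean_activation))
}
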