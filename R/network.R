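#' @keywords internal
node_roles <- function() c("generic", "mechanoreceptor", "cytokine", "readout", "ecm")

#' Construct a signed, weighted regulatory network
#'
#' A regulatory network model (RNM) is a signed, weighted directed graph whose
#' node activations evolve in \[0,1\] under continuous-logic dynamics (see
#' [step_dynamics()]). Edges carry a sign (+1 activation, -1 inhibition) and a
#' strictly positive weight; inhibition is encoded entirely by the sign.
#'
#' Node roles steer the dynamics and downstream bookkeeping:
#' \describe{
#'   \item{`readout`}{phenotype node used for pro-anabolic/pro-catabolic
#'     classification (by convention `ACAN`, aggrecan);}
#'   \item{`cytokine` / `mechanoreceptor`}{pure input nodes: with no incoming
#'     edges they are held only by a clamp, otherwise they decay to 0;}
#'   \item{`ecm`, `generic`}{ordinary nodes; an unregulated `generic`/`ecm`
#'     node is self-sustaining (its input equals its own activation).}
#' }
#'
#' @param edges data.frame with columns `source`, `target`, `sign` (+1/-1)
#'   and `weight` (> 0).
#' @param nodes optional data.frame with columns `node` and `role`. When
#'   supplied it is the authoritative node list: every edge endpoint must
#'   appear in it (an edge naming an undeclared node is an error), and
#'   isolated nodes are allowed. When `NULL`, nodes are inferred from the
#'   edge list with role `"generic"`.
#' @param default_readout node tagged `readout` when no node carries that
#'   role explicitly. Default `"ACAN"`.
#' @return An object of class `rnm_network`: a list with data.frames
#'   `nodes` (`node`, `role`) and `edges` (`source`, `target`, `sign`,
#'   `weight`).
#' @examples
#' net <- rnm_network(data.frame(
#'   source = c("TNF", "IL6"), target = c("IL6", "ACAN"),
#'   sign = c(1, -1), weight = c(1, 1)))
#' print(net)
#' @seealso [read_network()], [solve_steady_state()], [run_ensemble()]
#' @export
rnm_network <- function(edges, nodes = NULL, default_readout = "ACAN") {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  req <- c("source", "target", "sign", "weight")
  if (!all(req %in% names(edges))) {
    stop("edge table must have columns: ", paste(req, collapse = ", "))
  }
  edges$source <- trimws(as.character(edges$source))
  edges$target <- trimws(as.character(edges$target))
  edges$sign <- as.numeric(edges$sign)
  edges$weight <- as.numeric(edges$weight)

  if (!all(edges$sign %in% c(-1, 1))) {
    stop("edge sign must be +1 or -1")
  }
  bad_w <- which(!is.finite(edges$weight) | edges$weight <= 0)
  if (length(bad_w)) {
    stop(sprintf("edge %s -> %s has non-positive weight %s",
                 edges$source[bad_w[1]], edges$target[bad_w[1]],
                 format(edges$weight[bad_w[1]])))
  }

  if (is.null(nodes)) {
    nodes <- data.frame(node = unique(c(edges$source, edges$target)),
                        role = "generic", stringsAsFactors = FALSE)
  } else {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    if (!all(c("node", "role") %in% names(nodes))) {
      stop("node table must have columns: node, role")
    }
    nodes$node <- trimws(as.character(nodes$node))
    nodes$role <- trimws(as.character(nodes$role))
    if (anyDuplicated(nodes$node)) {
      stop("duplicate node name: ", nodes$node[duplicated(nodes$node)][1])
    }
    bad_role <- setdiff(nodes$role, node_roles())
    if (length(bad_role)) {
      stop("unknown node role: ", bad_role[1])
    }
  }

  missing_ep <- !(edges$source %in% nodes$node & edges$target %in% nodes$node)
  if (any(missing_ep)) {
    i <- which(missing_ep)[1]
    bad <- setdiff(c(edges$source[i], edges$target[i]), nodes$node)
    stop(sprintf("edge %s -> %s references undeclared node '%s'",
                 edges$source[i], edges$target[i], bad[1]))
  }

  if (!any(nodes$role == "readout")) {
    if (default_readout %in% nodes$node) {
      nodes$role[nodes$node == default_readout] <- "readout"
    } else {
      stop("network has no readout node (and no node named '",
           default_readout, "' to tag as readout)")
    }
  }

  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "rnm_network")
}

#' @export
print.rnm_network <- function(x, ...) {
  cat(sprintf("rnm_network: %d nodes, %d edges (%d activating, %d inhibiting)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  cat("readout:", paste(x$nodes$node[x$nodes$role == "readout"],
                        collapse = ", "), "\n")
  inputs <- x$nodes$node[x$nodes$role %in% c("cytokine", "mechanoreceptor")]
  if (length(inputs)) cat("inputs: ", paste(inputs, collapse = ", "), "\n")
  invisible(x)
}

#' Network node names
#' @param network an `rnm_network`.
#' @return character vector of node names.
#' @export
network_nodes <- function(network) network$nodes$node

#' Readout node of a network
#' @param network an `rnm_network`.
#' @return name of the first node tagged `readout`.
#' @export
readout_node <- function(network) {
  network$nodes$node[network$nodes$role == "readout"][1]
}

#' Read a regulatory network from a CSV edge list
#'
#' The edge-list dialect is a CSV with header `source,target,sign,weight`;
#' node roles may be supplied in a second CSV with header `node,role`.
#' Names are trimmed of surrounding whitespace but otherwise case-sensitive.
#'
#' @param path path to the edge-list CSV.
#' @param nodes_path optional path to the node-metadata CSV.
#' @inheritParams rnm_network
#' @return an `rnm_network`.
#' @export
read_network <- function(path, nodes_path = NULL, default_readout = "ACAN") {
  if (!file.exists(path)) stop("network file not found: ", path)
  edges <- utils::read.csv(path, stringsAsFactors = FALSE)
  nodes <- NULL
  if (!is.null(nodes_path)) {
    if (!file.exists(nodes_path)) stop("node file not found: ", nodes_path)
    nodes <- utils::read.csv(nodes_path, stringsAsFactors = FALSE)
  }
  rnm_network(edges, nodes, default_readout = default_readout)
}

#' Read a network in SIF format
#'
#' Simple interaction format: one edge per line,
#' `source<TAB>relation<TAB>target` with relation `activates` or `inhibits`.
#' All weights are set to 1.
#'
#' @inheritParams read_network
#' @return an `rnm_network`.
#' @export
read_network_sif <- function(path, nodes_path = NULL,
                             default_readout = "ACAN") {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) != 3)) {
    stop("SIF line must have 3 tab-separated fields: ",
         lines[which(lengths(parts) != 3)[1]])
  }
  rel <- vapply(parts, `[[`, "", 2)
  if (!all(rel %in% c("activates", "inhibits"))) {
    stop("unknown SIF relation: ", setdiff(rel, c("activates", "inhibits"))[1])
  }
  edges <- data.frame(source = vapply(parts, `[[`, "", 1),
                      target = vapply(parts, `[[`, "", 3),
                      sign = ifelse(rel == "activates", 1, -1),
                      weight = 1, stringsAsFactors = FALSE)
  nodes <- NULL
  if (!is.null(nodes_path)) nodes <- utils::read.csv(nodes_path,
                                                     stringsAsFactors = FALSE)
  rnm_network(edges, nodes, default_readout = default_readout)
}

#' Write a network to CSV files
#'
#' Inverse of [read_network()]: writes the edge list and (optionally)
#' node metadata in the documented CSV dialect.
#'
#' @param network an `rnm_network`.
#' @param path edge-list CSV path.
#' @param nodes_path optional node-metadata CSV path.
#' @return `invisible(network)`.
#' @export
write_network <- function(network, path, nodes_path = NULL) {
  utils::write.csv(network$edges, path, row.names = FALSE, quote = FALSE)
  if (!is.null(nodes_path)) {
    utils::write.csv(network$nodes, nodes_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(network)
}
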