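#' Degree metrics of a significant causal graph
#'
#' Counts, per node, the number of outgoing and incoming edges in the
#' binarized significant graph, and the net causal outflow
#' (out-degree minus in-degree). Net outflow sums to zero over nodes.
#'
#' @param g a `causal_graph` (its `significant` mask is used) or a logical /
#'   0-1 adjacency matrix in the package's (target, source) orientation
#' @return a data.frame: node, out_degree, in_degree, net_outflow
#' @export
degree_metrics <- function(g) {
  A <- graph_adjacency(g)
  out_deg <- colSums(A)   # column n: edges with source n
  in_deg <- rowSums(A)    # row m: edges with target m
  data.frame(node = colnames(A), out_degree = unname(out_deg),
             in_degree = unname(in_deg),
             net_outflow = unname(out_deg - in_deg))
}

# adjacency (target, source) from graph-ish inputs
graph_adjacency <- function(g) {
  A <- if (inherits(g, "causal_graph")) g$significant else as.matrix(g)
  A <- (A != 0) * 1
  diag(A) <- 0
  if (is.null(colnames(A))) {
    dimnames(A) <- list(paste0("R", seq_len(nrow(A))),
                        paste0("R", seq_len(ncol(A))))
  }
  A
}

#' Normalized shortest directed path length per node
#'
#' For each node, the mean over all other nodes of the shortest directed
#' path length (unit edge weights) from the node to the target, divided by
#' `M - 1`. Unreachable targets contribute a finite penalty of `M` steps
#' (longer than any realizable path) so that means stay defined on sparse
#' graphs; set `unreachable = "exclude"` to average over reachable targets
#' only. Shorter values indicate hub-like nodes.
#'
#' @param g a `causal_graph` or adjacency matrix (target, source)
#' @param unreachable `"penalty"` (default) or `"exclude"`
#' @return named numeric vector of normalized path lengths (NA for a node
#'   with no reachable targets under `"exclude"`)
#' @export
node_path_length <- function(g, unreachable = c("penalty", "exclude")) {
  unreachable <- match.arg(unreachable)
  A <- graph_adjacency(g)
  M <- nrow(A)
  # igraph wants (from, to): transpose the (target, source) adjacency
  ig <- igraph::graph_from_adjacency_matrix(t(A), mode = "directed")
  D <- igraph::distances(ig, mode = "out")
  diag(D) <- NA
  if (unreachable == "penalty") {
    D[is.infinite(D)] <- M
    res <- rowSums(D, na.rm = TRUE) / (M - 1)
  } else {
    D[is.infinite(D)] <- NA
    res <- rowMeans(D, na.rm = TRUE)
  }
  setNames(as.numeric(res), colnames(A))
}

#' Node-level hub test on per-subject metrics
#'
#' Tests, for each node, whether its per-subject metric values (net causal
#' outflow or normalized path length) differ from the pooled values of all
#' other nodes, using a two-sample t-test with BH-FDR across nodes.
#'
#' @param metrics numeric matrix, subjects x nodes, of a per-subject graph
#'   metric
#' @param alpha FDR threshold
#' @return data.frame: node, mean, mean_others, t, p, q, significant
#' @export
hub_test <- function(metrics, alpha = 0.05) {
  check_alpha(alpha)
  metrics <- as.matrix(metrics)
  if (nrow(metrics) < 3) stopf("need >= 3 subjects for the hub test")
  if (ncol(metrics) < 2) stopf("need >= 2 nodes to compare against")
  nodes <- colnames(metrics) %||% paste0("R", seq_len(ncol(metrics)))
  rows <- lapply(seq_len(ncol(metrics)), function(j) {
    a <- metrics[, j]
    b <- as.vector(metrics[, -j, drop = FALSE])
    if (sd(a) < 1e-12 && sd(b) < 1e-12) {
      # degenerate but common on small binarized graphs: identical values
      same <- abs(mean(a) - mean(b)) < 1e-12
      tt <- list(statistic = if (same) 0 else Inf * sign(mean(a) - mean(b)),
                 p.value = if (same) 1 else 0)
    } else {
      tt <- t.test(a, b)
    }
    data.frame(node = nodes[j], mean = mean(a), mean_others = mean(b),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  out
}

#' Per-subject graph metrics from subject-wise statistic matrices
#'
#' Builds, for each subject, a directed graph restricted to the
#' group-significant edge set (an edge is present for a subject when the
#' subject's statistic on that edge is positive), then computes net
#' outflow and normalized path length per node.
#'
#' @param subject_stats list of per-subject M x M statistic matrices in the
#'   (target, source) orientation (e.g. transposed doi, or per-subject
#'   coupling estimates)
#' @param mask logical M x M group-significance mask (target, source)
#' @return list with `net_outflow` and `path_length`, each a subjects x
#'   nodes matrix
#' @export
per_subject_graph_metrics <- function(subject_stats, mask) {
  mask <- (as.matrix(mask) != 0)
  diag(mask) <- FALSE
  net <- pl <- NULL
  for (s in seq_along(subject_stats)) {
    A <- (as.matrix(subject_stats[[s]]) > 0) & mask
    dm <- degree_metrics(A * 1)
    net <- rbind(net, dm$net_outflow)
    pl <- rbind(pl, node_path_length(A * 1))
  }
  nodes <- colnames(mask) %||% paste0("R", seq_len(ncol(mask)))
  colnames(net) <- nodes
  list(net_outflow = net, path_length = pl)
}
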