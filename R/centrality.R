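# Five centrality measures on weighted undirected contact networks.
#
# Geodesic measures (betweenness, closeness) convert tie weights to costs
# via d = 1/w: weights are interaction rates, so frequent partners are
# "close". Betweenness is unnormalized, endpoints excluded, unordered pairs
# counted once, equal-length geodesics credited fractionally. Closeness is
# the inverse sum of geodesic distances to all reachable nodes within the
# node's component (isolates score 0). Camp z-standardization downstream
# makes affine normalizations irrelevant.

.check_network <- function(network) {
  stopifnot(is.list(network), !is.null(network$W), !is.null(network$ids))
  W <- network$W
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-12)))
    stop("adjacency matrix must be symmetric")
  if (any(W < 0)) stop("edge weights must be nonnegative")
  invisible(W)
}

.node_index <- function(network, node) {
  i <- match(node, network$ids)
  if (anyNA(i)) stop("unknown node(s): ", paste(node[is.na(i)], collapse = ", "))
  i
}

# connected components of the positive-weight graph, by BFS
.components <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(W[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Degree: number of ties in the thresholded network
#'
#' @param network a `proximity_network`, normally after
#'   [threshold_for_degree()].
#' @param node optional node id(s); default all nodes.
#' @return named integer vector of tie counts.
#' @export
net_degree <- function(network, node = NULL) {
  W <- .check_network(network)
  d <- setNames(as.integer(rowSums(W > 0)), network$ids)
  if (is.null(node)) d else d[.node_index(network, node)]
}

#' Strength: sum of incident tie weights
#'
#' @inheritParams net_degree
#' @return named numeric vector; isolates score 0.
#' @export
net_strength <- function(network, node = NULL) {
  W <- .check_network(network)
  s <- setNames(rowSums(W), network$ids)
  if (is.null(node)) s else s[.node_index(network, node)]
}

#' Eigenvector centrality by power iteration
#'
#' Leading eigenvector of the weighted adjacency matrix, computed by power
#' iteration on the largest connected component (nodes outside it score 0),
#' normalized so the maximum score is 1. A small diagonal shift breaks the
#' period-2 oscillation of bipartite graphs without changing the
#' eigenvector.
#'
#' @param network a `proximity_network` with at least one edge.
#' @param tol convergence tolerance (max-norm change between normalized
#'   iterates).
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return named numeric vector in `[0, 1]`.
#' @export
eigenvector_centrality <- function(network, tol = 1e-10, max_iter = 1000) {
  W <- .check_network(network)
  n <- nrow(W)
  if (n == 0) return(setNames(numeric(0), network$ids))
  if (all(W == 0)) stop("eigenvector centrality needs at least one edge")
  comp <- .components(W)
  sizes <- tabulate(comp)
  main <- which.max(sizes)
  sel <- comp == main
  M <- W[sel, sel, drop = FALSE]
  shift <- 0.01 * max(rowSums(M))
  v <- rep(1, nrow(M))
  converged <- FALSE
  resid <- NA_real_
  for (it in seq_len(max_iter)) {
    v_new <- as.vector(M %*% v) + shift * v
    v_new <- v_new / max(v_new)
    resid <- max(abs(v_new - v))
    v <- v_new
    if (resid < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf("power iteration did not converge in %d iterations (residual %.3e)",
                 max_iter, resid))
  }
  out <- setNames(numeric(n), network$ids)
  out[sel] <- v
  out
}

#' Weighted betweenness centrality
#'
#' Fractional count of geodesic (shortest) paths between all other node
#' pairs that pass through each node, with edge distances `1/weight`.
#' Unordered pairs are counted once, endpoints are excluded, multiple
#' equal-length geodesics are credited fractionally, and no normalization
#' is applied. Disconnected pairs contribute nothing.
#'
#' @param network a `proximity_network` (positive edge weights).
#' @return named numeric vector of betweenness scores.
#' @export
betweenness_centrality <- function(network) {
  W <- .check_network(network)
  if (nrow(W) == 0) return(setNames(numeric(0), network$ids))
  res <- .graph_geodesics(W)
  setNames(res$betweenness, network$ids)
}

#' Weighted closeness centrality
#'
#' Inverse sum of geodesic distances (edge distance `1/weight`) from each
#' node to every other node it can reach within its component. Isolates
#' score 0. On disconnected networks this is a within-component quantity;
#' camps are near-complete so this rarely binds, but it is the documented
#' convention here.
#'
#' @inheritParams betweenness_centrality
#' @return named numeric vector of closeness scores.
#' @export
closeness_centrality <- function(network) {
  W <- .check_network(network)
  n <- nrow(W)
  if (n == 0) return(setNames(numeric(0), network$ids))
  D <- .graph_geodesics(W)$dist
  out <- numeric(n)
  for (v in seq_len(n)) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    out[v] <- if (length(d) && sum(d) > 0) 1 / sum(d) else 0
  }
  setNames(out, network$ids)
}

#' Standardize values within camps
#'
#' `z = (x - camp mean) / camp sample SD` (divisor `n - 1`). Centrality
#' scores are standardized within camp so a score expresses whether an
#' individual is central *relative to their own camp*; camps differ in size
#' and density, so raw scores are not comparable across camps.
#'
#' @param values numeric vector.
#' @param camp camp assignment, same length.
#' @return numeric vector of z-scores.
#' @section Errors: a singleton camp or a camp with zero variance is an
#'   error naming the camp, since its z-scores are undefined.
#' @export
standardize_by_camp <- function(values, camp) {
  stopifnot(length(values) == length(camp))
  out <- numeric(length(values))
  for (g in unique(camp)) {
    sel <- camp == g
    if (sum(sel) < 2) stop("cannot standardize singleton camp: ", g)
    s <- sd(values[sel])
    if (!is.finite(s) || s == 0)
      stop("zero variance in camp ", g, "; z-scores undefined")
    out[sel] <- (values[sel] - mean(values[sel])) / s
  }
  out
}

#' Per-individual centrality table with camp z-scores
#'
#' Computes the five measures for every camp network and standardizes each
#' within camp. Degree uses the thresholded network; strength, eigenvector,
#' betweenness and closeness use the full weighted network.
#'
#' @param networks list of `proximity_network`s (one per camp).
#' @param thresholded matching list of degree-thresholded networks
#'   ([threshold_for_degree()]); defaults to thresholding `networks` at 1%.
#' @return data frame `individual, camp, degree, strength, ec, betweenness,
#'   closeness, z_degree, ..., z_closeness`.
#' @export
centrality_table <- function(networks, thresholded = NULL) {
  if (inherits(networks, "proximity_network")) networks <- list(networks)
  if (is.null(thresholded)) thresholded <- lapply(networks, threshold_for_degree)
  if (inherits(thresholded, "proximity_network")) thresholded <- list(thresholded)
  stopifnot(length(networks) == length(thresholded))
  rows <- vector("list", length(networks))
  for (k in seq_along(networks)) {
    net <- networks[[k]]
    thr <- thresholded[[k]]
    stopifnot(identical(net$ids, thr$ids))
    rows[[k]] <- data.frame(
      individual = net$ids,
      camp = net$camp_id,
      degree = as.numeric(net_degree(thr)),
      strength = as.numeric(net_strength(net)),
      ec = as.numeric(eigenvector_centrality(net)),
      betweenness = as.numeric(betweenness_centrality(net)),
      closeness = as.numeric(closeness_centrality(net)),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  for (m in c("degree", "strength", "ec", "betweenness", "closeness")) {
    tab[[paste0("z_", m)]] <- standardize_by_camp(tab[[m]], tab$camp)
  }
  tab
}

#' Write the tidy centrality CSV (`individual,camp,measure,raw,z`)
#'
#' @param tab a [centrality_table()].
#' @param path output path.
#' @export
write_centrality <- function(tab, path) {
  measures <- c("degree", "strength", "ec", "betweenness", "closeness")
  long <- do.call(rbind, lapply(measures, function(m) {
    data.frame(individual = tab$individual, camp = tab$camp, measure = m,
               raw = tab[[m]], z = tab[[paste0("z_", m)]],
               stringsAsFactors = FALSE)
  }))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
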