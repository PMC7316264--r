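# accept a mixed_matrix, functional_matrix or plain symmetric matrix
as_weight_matrix <- function(x) {
  if (inherits(x, "mixed_matrix")) return(x$z_masked)
  if (inherits(x, "functional_matrix")) return(x$z)
  x <- as.matrix(x)
  check_square_symmetric(x, "weight matrix", tol = 1e-8)
  x
}

member_submatrix <- function(w, net) {
  if (inherits(net, "network_definition")) net <- net$members
  if (length(net) < 2)
    stop2("network must have at least 2 members")
  missing <- setdiff(net, rownames(w))
  if (length(missing))
    stop2("network members not in matrix: %s", paste(missing, collapse = ", "))
  w[net, net, drop = FALSE]
}

#' Within-network connectivity strength
#'
#' Mean of the off-diagonal upper-triangle Fisher-z entries of the
#' member-induced submatrix of the full functional matrix. Connections to
#' nodes outside the network have no influence. Negative z values are
#' retained: strength averages signed correlations.
#'
#' @param func a [functional_matrix()] (not a mixed matrix).
#' @param net a [network_definition()] or character vector of members.
#' @return scalar mean Fisher-z.
#' @export
network_strength <- function(func, net) {
  w <- member_submatrix(as_weight_matrix(func), net)
  mean(w[upper.tri(w)])
}

#' Edge lengths from connection weights
#'
#' Maps each positive weight to a travel cost `1/w` (stronger connections
#' are shorter); zero, masked and negative cells map to `+Inf` and carry no
#' path, since path lengths require positive weights.
#'
#' @param w symmetric weight matrix (or mixed/functional matrix object).
#' @return matrix of edge lengths with `+Inf` for absent edges and 0 diagonal.
#' @export
to_lengths <- function(w) {
  w <- as_weight_matrix(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  len
}

#' All-pairs shortest path lengths
#'
#' Dijkstra over the weighted graph defined by a finite-entry edge-length
#' matrix; unreachable pairs get `+Inf`.
#'
#' @param lengths symmetric matrix of nonnegative edge lengths (`+Inf` =
#'   no edge), as produced by [to_lengths()].
#' @return symmetric matrix of shortest-path distances (0 diagonal).
#' @export
shortest_path_lengths <- function(lengths) {
  n <- nrow(lengths)
  adj <- ifelse(is.finite(lengths), lengths, 0)
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- dimnames(lengths)
  d
}

#' Weighted global efficiency of a network
#'
#' On the member-induced subgraph: the average inverse shortest-path length
#' over ordered node pairs, `E_glob = (1/(n(n-1))) * sum_{i != j} 1/d_ij`,
#' with `1/Inf = 0`. Indexes functional integration; equals 1 on a
#' unit-weight clique.
#'
#' @param mixed a [mixed_matrix()] (or any symmetric weight matrix).
#' @param net a [network_definition()] or character vector; defaults to all
#'   nodes.
#' @return scalar in `[0, ...)`.
#' @export
global_efficiency <- function(mixed, net = NULL) {
  w <- as_weight_matrix(mixed)
  if (!is.null(net)) w <- member_submatrix(w, net)
  n <- nrow(w)
  if (n < 2) stop2("global efficiency needs at least 2 nodes")
  d <- shortest_path_lengths(to_lengths(w))
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted local efficiency of a network
#'
#' Per node `i` with neighbors `N(i)` (positive-weight connections), the
#' nodal value combines, with a cube root, the two attachment weights and
#' the inverse shortest interneighbor path computed on the
#' neighborhood-induced subgraph:
#' `E_loc(i) = sum_{j != h in N(i)} (w_ij * w_ih / d_jh(N_i))^(1/3) /
#' (k_i (k_i - 1))`. Nodes with fewer than two neighbors contribute 0; the
#' network value is the unweighted mean over member nodes. Indexes
#' functional segregation; equals 1 on a unit-weight clique and 0 on a star.
#'
#' @inheritParams global_efficiency
#' @return scalar in `[0, ...)`.
#' @export
local_efficiency <- function(mixed, net = NULL) {
  w <- as_weight_matrix(mixed)
  if (!is.null(net)) w <- member_submatrix(w, net)
  n <- nrow(w)
  if (n < 2) stop2("local efficiency needs at least 2 nodes")
  nodal <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    nb <- setdiff(nb, i)
    k <- length(nb)
    if (k < 2) return(0)
    sub <- w[nb, nb, drop = FALSE]
    d <- shortest_path_lengths(to_lengths(sub))
    invd <- 1 / d
    invd[!is.finite(invd)] <- 0
    diag(invd) <- 0
    wi <- w[i, nb]
    terms <- (outer(wi, wi) * invd)^(1 / 3)
    diag(terms) <- 0
    sum(terms) / (k * (k - 1))
  }, numeric(1))
  mean(nodal)
}

#' Per-subject network metric table
#'
#' For every subject, timepoint and network: connectivity strength from the
#' full functional matrix, and weighted global and local efficiency from the
#' backbone-masked mixed matrix.
#'
#' @param fmats named list (per subject) of lists with `tp1`/`tp2`
#'   [functional_matrix()] entries.
#' @param mixed same layout with [apply_mask()] results.
#' @param subjects data.frame with columns `subject`, `group`.
#' @param networks named list of [network_definition()]s.
#' @return data.frame: subject, group, timepoint, network, strength,
#'   e_glob, e_loc.
#' @export
compute_metric_table <- function(fmats, mixed, subjects, networks) {
  rows <- list()
  for (s in subjects$subject) {
    if (is.null(fmats[[s]]) || is.null(mixed[[s]]))
      stop2("missing matrices for subject %s", s)
    for (tp in c("tp1", "tp2")) {
      if (is.null(fmats[[s]][[tp]]) || is.null(mixed[[s]][[tp]]))
        stop2("subject %s is missing timepoint %s", s, tp)
      for (net in networks) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s,
          group = subjects$group[subjects$subject == s],
          timepoint = tp,
          network = net$name,
          strength = network_strength(fmats[[s]][[tp]], net),
          e_glob = global_efficiency(mixed[[s]][[tp]], net),
          e_loc = local_efficiency(mixed[[s]][[tp]], net),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
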