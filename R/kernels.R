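#' Shared-partner kernel from an interaction network
#'
#' Converts a binary drug x protein interaction matrix into two similarity
#' kernels over the bipartite network: `K_d[i, j]` counts the proteins
#' targeted by both drug i and drug j (`K_d = Y %*% t(Y)`), and `K_p[i, j]`
#' counts the drugs shared by proteins i and j (`K_p = t(Y) %*% Y`). The
#' assumption is that drugs sharing many targets are pharmacologically
#' similar, and likewise for proteins sharing many ligands. Diagonals hold
#' each node's own interaction count.
#'
#' @param Y binary matrix, drugs x proteins.
#' @return list with integer-valued symmetric matrices `K_d` (drugs) and
#'   `K_p` (proteins).
#' @examples
#' Y <- matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0, 1, 0, 0), nrow = 3, byrow = TRUE)
#' network_kernel(Y)$K_d  # drug 1 shares 3 targets with drug 2, 1 with drug 3
#' @export
network_kernel <- function(Y) {
  Y <- as.matrix(Y)
  check_binary(Y, "Y")
  list(K_d = Y %*% t(Y), K_p = t(Y) %*% Y)
}

#' Fuse an intrinsic similarity with a network kernel
#'
#' Convex-style combination `W = (gamma1 * S + gamma2 * K) / (gamma1 + gamma2)`
#' of an intrinsic similarity matrix (chemical or sequence) with the
#' shared-partner network kernel. `gamma2 = 0` recovers the intrinsic
#' similarity unchanged; scaling both weights by the same constant leaves
#' the result unchanged. The kernel is used as raw counts: the default
#' network weight 0.01 is calibrated against counts, not against a
#' rescaled kernel.
#'
#' @param S symmetric similarity matrix.
#' @param K network kernel of the same dimension.
#' @param gamma1 weight of the intrinsic similarity (nonnegative).
#' @param gamma2 weight of the network kernel (nonnegative).
#' @return Fused symmetric nonnegative matrix `W`.
#' @export
fuse_similarity <- function(S, K, gamma1, gamma2) {
  S <- as.matrix(S)
  K <- as.matrix(K)
  if (!all(dim(S) == dim(K))) {
    abort_validation("S and K must have identical dimensions")
  }
  if (gamma1 < 0 || gamma2 < 0 || gamma1 + gamma2 <= 0) {
    abort_validation("need gamma1, gamma2 >= 0 with gamma1 + gamma2 > 0")
  }
  (gamma1 * S + gamma2 * K) / (gamma1 + gamma2)
}

#' Normalized graph Laplacian of a similarity graph
#'
#' Treats `W` as the weighted adjacency matrix of an undirected graph and
#' returns the graph together with its degree vector `D` (row sums of `W`)
#' and normalized Laplacian `L = I - D^{-1/2} W D^{-1/2}`. Eigenvalues of
#' `L` lie in \[0, 2\]; the quadratic form `Trace(t(F) %*% L %*% F)` is the
#' smoothness penalty used by the graph-regularized solver.
#'
#' Zero-degree (isolated) nodes use the pseudo-inverse convention
#' `(D^{-1/2})_k = 0`, so their Laplacian row is the identity row and they
#' receive no smoothing. `L` is explicitly re-symmetrized to remove
#' floating-point drift.
#'
#' @param W symmetric nonnegative weight matrix.
#' @param zero_diagonal drop self-similarity from the graph before
#'   computing degrees (default keeps the diagonal, the literal reading of
#'   degrees as plain row sums).
#' @return An object of class `domain_graph`: list with `W`, `D` (degree
#'   vector), `L`.
#' @export
normalized_laplacian <- function(W, zero_diagonal = FALSE) {
  W <- as.matrix(W)
  if (any(W < 0)) {
    ij <- arrayInd(which(W < 0)[1], dim(W))
    abort_validation(sprintf(
      "graph weights must be nonnegative; W[%d, %d] = %g",
      ij[1], ij[2], W[ij[1], ij[2]]
    ))
  }
  if (max(abs(W - t(W))) > 1e-9) {
    abort_validation("graph weight matrix must be symmetric")
  }
  if (zero_diagonal) diag(W) <- 0
  D <- rowSums(W)
  d_inv_sqrt <- ifelse(D > 0, 1 / sqrt(D), 0)
  L <- diag(nrow(W)) - d_inv_sqrt * sweep(W, 2, d_inv_sqrt, `*`)
  L <- (L + t(L)) / 2
  structure(list(W = W, D = D, L = L), class = "domain_graph")
}

#' @export
print.domain_graph <- function(x, ...) {
  cat(sprintf("<domain_graph> %d nodes, total edge weight %.3f\n",
              nrow(x$W), sum(x$W) / 2))
  invisible(x)
}

# Builds the drug- and protein-domain graphs for a training interaction
# matrix: network kernel from Y_train, fusion, normalized Laplacians.
# use_network = FALSE skips kernel construction entirely (plain LapRLS).
build_domain_graphs <- function(S_d, S_p, Y_train, fusion, use_network = TRUE) {
  if (use_network && (fusion$gamma_d2 > 0 || fusion$gamma_p2 > 0)) {
    K <- network_kernel(Y_train)
    W_d <- fuse_similarity(S_d, K$K_d, fusion$gamma_d1, fusion$gamma_d2)
    W_p <- fuse_similarity(S_p, K$K_p, fusion$gamma_p1, fusion$gamma_p2)
  } else {
    W_d <- S_d
    W_p <- S_p
  }
  list(drug = normalized_laplacian(W_d), protein = normalized_laplacian(W_p))
}
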