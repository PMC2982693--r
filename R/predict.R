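#' Weighted-profile scores in a single domain
#'
#' The simplest similarity-based predictor: the score of sample i for
#' label column j is the similarity-weighted average of the known labels,
#' `f(i, j) = sum_k S[i, k] * Y_view[k, j] / sum_k S[i, k]`. Called with
#' the drug similarity and `Y` it predicts from chemical space; called
#' with the protein similarity and `t(Y)` it predicts from genomic space.
#' A row whose similarity sums to zero has no evidence and scores 0.
#'
#' @param S symmetric nonnegative similarity matrix, n x n.
#' @param Y_view binary label matrix, n x m.
#' @return numeric n x m score matrix.
#' @export
weighted_profile_domain <- function(S, Y_view) {
  S <- as.matrix(S)
  Y_view <- as.matrix(Y_view)
  if (ncol(S) != nrow(Y_view)) {
    abort_validation("similarity and label matrix dimensions do not agree")
  }
  norm <- rowSums(S)
  scores <- S %*% Y_view
  scale <- ifelse(norm > 0, 1 / norm, 0)
  scores * scale
}

#' Combine drug- and protein-domain weighted profiles
#'
#' Averages the chemical-space prediction (drugs x proteins) with the
#' genomic-space prediction (proteins x drugs, transposed) for each pair.
#'
#' @param F_drug drug-domain scores, n_d x n_p.
#' @param F_protein protein-domain scores, n_p x n_d.
#' @return numeric n_d x n_p matrix of combined scores.
#' @export
combine_weighted_profile <- function(F_drug, F_protein) {
  F_drug <- as.matrix(F_drug)
  F_protein <- as.matrix(F_protein)
  if (!all(dim(F_drug) == rev(dim(F_protein)))) {
    abort_validation("domain score matrices are not transpose-compatible")
  }
  (F_drug + t(F_protein)) / 2
}

#' Closed-form graph-regularized least-squares solve in one domain
#'
#' Minimizes `||Y_view - F||_F^2 + beta * Trace(t(F) L F)` over score
#' matrices of the form `F = W alpha` (representer form). The unique
#' minimizer is `F* = W (W + beta L W)^{-1} Y_view`; a small ridge jitter
#' `ridge_eps * I` is added to the system matrix because similarity
#' matrices with duplicate rows make `W` rank-deficient. The system is
#' solved as a general linear system (it is not symmetric), never by
#' forming an explicit inverse.
#'
#' @param W fused similarity matrix of the domain graph.
#' @param L its normalized Laplacian (from [normalized_laplacian()]).
#' @param Y_view label matrix, n x m.
#' @param beta nonnegative smoothness weight.
#' @param ridge_eps nonnegative jitter (default `1e-8`).
#' @return numeric n x m matrix of domain scores.
#' @export
laprls_domain_solve <- function(W, L, Y_view, beta, ridge_eps = 1e-8) {
  W <- as.matrix(W)
  L <- as.matrix(L)
  Y_view <- as.matrix(Y_view)
  if (beta < 0 || ridge_eps < 0) {
    abort_validation("beta and ridge_eps must be nonnegative")
  }
  n <- nrow(W)
  A <- W + beta * (L %*% W) + diag(ridge_eps, n)
  alpha <- tryCatch(
    solve(A, Y_view),
    error = function(e) {
      rlang::abort(sprintf(
        "domain system is numerically singular (rcond = %.3g) even with ridge_eps = %g",
        rcond(A), ridge_eps
      ), parent = e)
    }
  )
  W %*% alpha
}

#' Predict drug-protein interactions
#'
#' Fits one of three predictors to a gold-standard dataset and returns a
#' fitted object holding the combined drug x protein score matrix along
#' with both per-domain score matrices:
#'
#' * `"netlaprls"` -- graph-regularized least squares on similarity graphs
#'   that fuse the intrinsic similarities with the shared-partner network
#'   kernel built from the *training* interactions.
#' * `"laprls"` -- the same solver on the intrinsic similarities alone
#'   (no network kernel is ever constructed).
#' * `"weighted_profile"` -- the combined weighted-profile baseline;
#'   `"weighted_profile_drug"` and `"weighted_profile_protein"` expose the
#'   single-space baselines.
#'
#' The network kernel and all label information come from `Y_train` only,
#' so held-out interactions can never leak into the fit; the full
#' `dataset$Y` is merely carried along to flag known pairs when ranking.
#'
#' @param dataset a [dti_dataset()].
#' @param method one of `"netlaprls"`, `"laprls"`, `"weighted_profile"`,
#'   `"weighted_profile_drug"`, `"weighted_profile_protein"`.
#' @param params a [dti_params()].
#' @param Y_train binary training interaction matrix, same shape as
#'   `dataset$Y`, with training positives only (defaults to the full `Y`).
#' @return An object of class `dti_fit` with elements `scores` (combined
#'   matrix), `F_drug`, `F_protein` (per-domain, both stored as drugs x
#'   proteins), `method`, `params`, `dataset_dim`, plus the id vectors.
#' @examples
#' ds <- simulate_dti_dataset(n_d = 20, n_p = 12, seed = 1)
#' fit <- dti_predict(ds, "netlaprls")
#' tidy(fit)
#' @export
dti_predict <- function(dataset,
                        method = c("netlaprls", "laprls", "weighted_profile",
                                   "weighted_profile_drug",
                                   "weighted_profile_protein"),
                        params = dti_params(),
                        Y_train = dataset$Y) {
  stopifnot(inherits(dataset, "dti_dataset"))
  method <- match.arg(method)
  if (!inherits(params, "dti_params")) {
    abort_validation("params must be created with dti_params()")
  }
  Y_train <- as.matrix(Y_train)
  if (!all(dim(Y_train) == dim(dataset$Y))) {
    abort_validation("Y_train must have the same shape as dataset$Y")
  }
  check_binary(Y_train, "Y_train")
  if (any(Y_train == 1 & dataset$Y == 0)) {
    abort_validation("Y_train may only contain positives present in dataset$Y")
  }

  if (method %in% c("weighted_profile", "weighted_profile_drug",
                    "weighted_profile_protein")) {
    F_d <- weighted_profile_domain(dataset$S_d, Y_train)
    F_p <- weighted_profile_domain(dataset$S_p, t(Y_train))
    scores <- switch(method,
      weighted_profile = combine_weighted_profile(F_d, F_p),
      weighted_profile_drug = F_d,
      weighted_profile_protein = t(F_p)
    )
  } else {
    graphs <- build_domain_graphs(
      dataset$S_d, dataset$S_p, Y_train, params,
      use_network = method == "netlaprls"
    )
    F_d <- laprls_domain_solve(graphs$drug$W, graphs$drug$L, Y_train,
                               params$beta_d, params$ridge_eps)
    F_p <- laprls_domain_solve(graphs$protein$W, graphs$protein$L,
                               t(Y_train), params$beta_p, params$ridge_eps)
    scores <- (F_d + t(F_p)) / 2
  }

  dimnames(scores) <- dimnames(dataset$Y)
  structure(
    list(scores = scores, F_drug = F_d, F_protein = t(F_p),
         method = method, params = params,
         Y_train = Y_train, Y_known = dataset$Y,
         drug_ids = dataset$drug_ids, protein_ids = dataset$protein_ids),
    class = "dti_fit"
  )
}

#' @export
print.dti_fit <- function(x, ...) {
  cat(sprintf(
    "<dti_fit> method = %s, %d drugs x %d proteins, %d training interactions\n",
    x$method, nrow(x$scores), ncol(x$scores), sum(x$Y_train)
  ))
  invisible(x)
}

#' Tidy a fitted interaction predictor into an edge list
#'
#' @param x a `dti_fit`.
#' @param top_k keep only the `top_k` highest-scoring novel pairs.
#' @param ... unused.
#' @return tibble with `drug_id`, `protein_id`, `score`, `known`, sorted by
#'   score descending (ties by drug then protein index).
#' @export
tidy.dti_fit <- function(x, top_k = NULL, ...) {
  ds <- structure(
    list(drug_ids = x$drug_ids, protein_ids = x$protein_ids, Y = x$Y_known),
    class = "dti_dataset"
  )
  rank_edges(x$scores, ds, top_k = top_k)
}

#' One-row summary of a fitted interaction predictor
#'
#' @param x a `dti_fit`.
#' @param ... unused.
#' @export
glance.dti_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_drugs = nrow(x$scores),
    n_proteins = ncol(x$scores),
    n_train_pos = sum(x$Y_train),
    beta_d = x$params$beta_d,
    beta_p = x$params$beta_p,
    gamma_d2 = x$params$gamma_d2,
    gamma_p2 = x$params$gamma_p2
  )
}
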