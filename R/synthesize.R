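#' Simulate a gold-standard drug-target dataset
#'
#' Generates a seeded synthetic dataset with the statistical structure the
#' predictors assume: drugs and proteins fall into latent clusters;
#' within-cluster similarity is high and between-cluster similarity low
#' (plus Gaussian noise, symmetrized, clipped to \[0, 1\], unit diagonal);
#' each drug cluster is compatible with one uniformly drawn protein
#' cluster, and interactions are Bernoulli draws with a high rate inside
#' compatible cluster pairs and a low background rate elsewhere. The
#' defaults give a sparse `Y` (several percent density) comparable to
#' curated interaction collections. Any all-zero row or column of `Y` is
#' redrawn once, then accepted as-is.
#'
#' All draws come from a single seeded stream in a fixed order (drug
#' clusters, protein clusters, S_d noise, S_p noise, compatibility map, Y,
#' redraws), so a seed fully determines the dataset on any platform.
#'
#' @param n_d,n_p number of drugs and proteins.
#' @param n_clusters_d,n_clusters_p number of latent clusters per side.
#' @param within_sim,between_sim similarity level for pairs in the same /
#'   different clusters; `within_sim > between_sim` required.
#' @param sim_noise_sd standard deviation of the Gaussian similarity noise.
#' @param p_interact_on,p_interact_off interaction probability for
#'   compatible / incompatible cluster pairs; `p_interact_on >
#'   p_interact_off` required.
#' @param seed integer seed.
#' @return A [dti_dataset()] with attributes `drug_clusters`,
#'   `protein_clusters` and `compatible` (drug-cluster x protein-cluster
#'   logical matrix) recording the ground truth.
#' @examples
#' ds <- simulate_dti_dataset(seed = 42)
#' mean(ds$Y)  # interaction density
#' @export
simulate_dti_dataset <- function(n_d = 60, n_p = 40,
                                 n_clusters_d = 4, n_clusters_p = 3,
                                 within_sim = 0.8, between_sim = 0.2,
                                 sim_noise_sd = 0.05,
                                 p_interact_on = 0.3,
                                 p_interact_off = 0.005,
                                 seed = 0) {
  if (n_clusters_d > n_d || n_clusters_p > n_p) {
    abort_validation("cannot have more clusters than items")
  }
  probs <- c(within_sim, between_sim, p_interact_on, p_interact_off)
  if (any(probs < 0) || any(probs > 1)) {
    abort_validation("similarity levels and probabilities must lie in [0, 1]")
  }
  if (within_sim <= between_sim) {
    abort_validation("within_sim must exceed between_sim")
  }
  if (p_interact_on <= p_interact_off) {
    abort_validation("p_interact_on must exceed p_interact_off")
  }
  if (sim_noise_sd < 0) abort_validation("sim_noise_sd must be nonnegative")

  with_seed(seed, {
    cl_d <- sample(rep_len(seq_len(n_clusters_d), n_d))
    cl_p <- sample(rep_len(seq_len(n_clusters_p), n_p))
    S_d <- cluster_similarity(cl_d, within_sim, between_sim, sim_noise_sd)
    S_p <- cluster_similarity(cl_p, within_sim, between_sim, sim_noise_sd)
    compatible <- matrix(FALSE, n_clusters_d, n_clusters_p)
    compatible[cbind(seq_len(n_clusters_d),
                     sample.int(n_clusters_p, n_clusters_d, replace = TRUE))] <- TRUE
    p_mat <- ifelse(compatible[cbind(rep(cl_d, times = n_p),
                                     rep(cl_p, each = n_d))],
                    p_interact_on, p_interact_off)
    Y <- matrix(stats::rbinom(n_d * n_p, 1, p_mat), n_d, n_p)
    # one redraw pass for empty rows/columns, then accept
    for (i in which(rowSums(Y) == 0)) {
      Y[i, ] <- stats::rbinom(n_p, 1, p_mat[i + (seq_len(n_p) - 1) * n_d])
    }
    for (j in which(colSums(Y) == 0)) {
      Y[, j] <- stats::rbinom(n_d, 1, p_mat[(j - 1) * n_d + seq_len(n_d)])
    }
    ds <- dti_dataset(Y, S_d, S_p,
                      drug_ids = sprintf("d%03d", seq_len(n_d)),
                      protein_ids = sprintf("p%03d", seq_len(n_p)))
    attr(ds, "drug_clusters") <- cl_d
    attr(ds, "protein_clusters") <- cl_p
    attr(ds, "compatible") <- compatible
    ds
  })
}

cluster_similarity <- function(clusters, within, between, noise_sd) {
  n <- length(clusters)
  S <- matrix(between, n, n)
  S[outer(clusters, clusters, `==`)] <- within
  if (noise_sd > 0) {
    noise <- matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
    S <- S + (noise + t(noise)) / 2
  }
  S <- pmin(pmax(S, 0), 1)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}
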