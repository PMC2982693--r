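#' Model hyperparameters
#'
#' Collects the hyperparameters of the graph-regularized least-squares
#' models. Defaults are the values used for the gold-standard benchmark
#' runs: smoothness weights `beta_d = beta_p = 0.3` and fusion weights
#' `gamma_d1 = gamma_p1 = 1`, `gamma_d2 = gamma_p2 = 0.01` (intrinsic
#' similarity dominates; the shared-partner kernel, in raw counts, enters
#' with a small weight). Setting `gamma_d2 = gamma_p2 = 0` turns NetLapRLS
#' into plain LapRLS.
#'
#' @param beta_d,beta_p nonnegative graph-smoothness weights for the drug
#'   and protein domains. `beta = 0` removes regularization: with a
#'   nonsingular graph the solver then reproduces the training labels.
#' @param gamma_d1,gamma_d2 fusion weights for the drug domain (chemical
#'   similarity vs network kernel).
#' @param gamma_p1,gamma_p2 fusion weights for the protein domain
#'   (sequence similarity vs network kernel).
#' @param ridge_eps small jitter added to the solver's system matrix;
#'   guards against rank-deficient similarity matrices (duplicate rows are
#'   common in real similarity data).
#' @return list of class `dti_params`.
#' @export
dti_params <- function(beta_d = 0.3, beta_p = 0.3,
                       gamma_d1 = 1, gamma_d2 = 0.01,
                       gamma_p1 = 1, gamma_p2 = 0.01,
                       ridge_eps = 1e-8) {
  vals <- c(beta_d = beta_d, beta_p = beta_p,
            gamma_d1 = gamma_d1, gamma_d2 = gamma_d2,
            gamma_p1 = gamma_p1, gamma_p2 = gamma_p2,
            ridge_eps = ridge_eps)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort_validation("all hyperparameters must be finite and nonnegative")
  }
  if (gamma_d1 + gamma_d2 <= 0 || gamma_p1 + gamma_p2 <= 0) {
    abort_validation("gamma_d1 + gamma_d2 and gamma_p1 + gamma_p2 must be > 0")
  }
  structure(as.list(vals), class = "dti_params")
}

#' @export
print.dti_params <- function(x, ...) {
  cat(sprintf(
    "<dti_params> beta = (%g, %g), gamma_d = (%g, %g), gamma_p = (%g, %g), ridge_eps = %g\n",
    x$beta_d, x$beta_p, x$gamma_d1, x$gamma_d2, x$gamma_p1, x$gamma_p2,
    x$ridge_eps
  ))
  invisible(x)
}
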