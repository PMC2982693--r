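#' Build a cross-validation plan
#'
#' Two protocols are supported:
#'
#' * `"pairwise"` -- the known interactions (positive drug-protein pairs)
#'   are shuffled and split into `n_folds` subsets of near-equal size. In
#'   each fold the held-out positives are relabeled 0 in the training
#'   matrix, and the test set is *every* pair that is not a training
#'   positive -- the held-out positives plus all unknown pairs. This is
#'   the regime where labeled data are tiny relative to the test set and
#'   the semi-supervised smoothing pays off.
#' * `"blm_drug"` / `"blm_protein"` -- local-model style domain CV: the
#'   drugs (or proteins) themselves are partitioned; all pairs touching a
#'   held-out drug (protein) are zeroed for training and form the test set.
#'
#' @param dataset a [dti_dataset()].
#' @param scheme `"pairwise"`, `"blm_drug"` or `"blm_protein"`.
#' @param n_folds number of folds (>= 2); fold sizes differ by at most one.
#' @param seed integer seed for the shuffle.
#' @return An object of class `cv_plan`: list with `scheme`, `n_folds`,
#'   `seed` and `folds`, where each fold holds the held-out pair indices
#'   (pairwise; linear indices into `Y`) or held-out drug/protein indices.
#' @export
make_cv_plan <- function(dataset,
                         scheme = c("pairwise", "blm_drug", "blm_protein"),
                         n_folds = 10, seed = 0) {
  stopifnot(inherits(dataset, "dti_dataset"))
  scheme <- match.arg(scheme)
  if (n_folds < 2) abort_validation("n_folds must be at least 2")

  units <- switch(scheme,
    pairwise = which(dataset$Y == 1),
    blm_drug = seq_along(dataset$drug_ids),
    blm_protein = seq_along(dataset$protein_ids)
  )
  if (length(units) < n_folds) {
    abort_validation(sprintf(
      "cannot split %d %s units into %d folds", length(units),
      scheme, n_folds
    ))
  }
  shuffled <- with_seed(seed, sample(units))
  # cycling 1..n_folds across the shuffled units keeps sizes within 1
  assignment <- rep_len(seq_len(n_folds), length(shuffled))
  folds <- lapply(seq_len(n_folds), function(f) {
    sort(shuffled[assignment == f])
  })
  structure(
    list(scheme = scheme, n_folds = n_folds, seed = seed, folds = folds),
    class = "cv_plan"
  )
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> scheme = %s, %d folds (sizes %s), seed = %d\n",
              x$scheme, x$n_folds,
              paste(lengths(x$folds), collapse = "/"), x$seed))
  invisible(x)
}

# Runs expr with a locally seeded RNG, restoring global RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Training matrix and test pair indices for one fold of a plan.
fold_split <- function(dataset, plan, fold) {
  held <- plan$folds[[fold]]
  Y <- dataset$Y
  Y_train <- Y
  if (plan$scheme == "pairwise") {
    Y_train[held] <- 0
    test_idx <- which(Y_train == 0)   # held-out positives + all unknown pairs
  } else if (plan$scheme == "blm_drug") {
    Y_train[held, ] <- 0
    test_idx <- which(row(Y) %in% held)
  } else {
    Y_train[, held] <- 0
    test_idx <- which(col(Y) %in% held)
  }
  list(Y_train = Y_train, test_idx = test_idx)
}

#' Run cross-validation for an interaction predictor
#'
#' Executes a [make_cv_plan()] fold by fold: refits the model on the
#' fold's training matrix (the network kernel, when used, is rebuilt from
#' training positives only), scores the fold's test pairs, and evaluates.
#' Test-pair scores are pooled across folds for the headline metrics; a
#' per-fold table is returned alongside, since published comparisons
#' report both styles. Under the local-model schemes the score for a
#' held-out drug comes from the protein-domain classifier (and vice
#' versa), mirroring how local models handle nodes with no training
#' labels of their own.
#'
#' @param dataset a [dti_dataset()].
#' @param method prediction method, see [dti_predict()]; alternatively a
#'   function `(dataset, Y_train) -> score matrix` for custom scorers
#'   (useful for oracle checks and method prototyping).
#' @param params a [dti_params()].
#' @param plan a `cv_plan` from [make_cv_plan()].
#' @param cutoff_rule,percentile cutoff for
#'   sensitivity/specificity/PPV, see [threshold_metrics()].
#' @return An object of class `dti_cv` with `pooled` (one-row metrics
#'   tibble), `per_fold` (one row per fold), and the pooled
#'   `scores`/`labels` vectors for plotting.
#' @examples
#' ds <- simulate_dti_dataset(n_d = 20, n_p = 12, seed = 1)
#' cv <- run_cv(ds, "netlaprls", plan = make_cv_plan(ds, "pairwise", 5, seed = 1))
#' glance(cv)
#' @export
run_cv <- function(dataset, method = "netlaprls", params = dti_params(),
                   plan = make_cv_plan(dataset),
                   cutoff_rule = c("test_size", "top_percentile"),
                   percentile = 1) {
  stopifnot(inherits(plan, "cv_plan"))
  cutoff_rule <- match.arg(cutoff_rule)

  fold_results <- purrr::map(seq_len(plan$n_folds), function(f) {
    split <- fold_split(dataset, plan, f)
    if (is.function(method)) {
      scores <- method(dataset, split$Y_train)
    } else {
      fit <- dti_predict(dataset, method, params, Y_train = split$Y_train)
      scores <- switch(plan$scheme,
        pairwise = fit$scores,
        blm_drug = fit$F_protein,  # held-out drugs scored from protein domain
        blm_protein = fit$F_drug
      )
    }
    list(
      scores = scores[split$test_idx],
      labels = dataset$Y[split$test_idx],
      fold = f
    )
  })

  per_fold <- purrr::map_dfr(fold_results, function(r) {
    dplyr::bind_cols(
      tibble::tibble(fold = r$fold),
      metrics_row(r$scores, r$labels, cutoff_rule, percentile)
    )
  })
  pooled_scores <- unlist(purrr::map(fold_results, "scores"))
  pooled_labels <- unlist(purrr::map(fold_results, "labels"))
  pooled <- metrics_row(pooled_scores, pooled_labels, cutoff_rule, percentile)

  structure(
    list(method = if (is.function(method)) "custom" else method,
         scheme = plan$scheme, seed = plan$seed,
         params = params, pooled = pooled, per_fold = per_fold,
         scores = pooled_scores, labels = pooled_labels),
    class = "dti_cv"
  )
}

#' @export
print.dti_cv <- function(x, ...) {
  cat(sprintf(
    "<dti_cv> %s, %s CV: pooled AUC %.3f, AUPR %.3f, sens %.3f, spec %.3f\n",
    x$method, x$scheme, x$pooled$auc, x$pooled$aupr,
    x$pooled$sensitivity, x$pooled$specificity
  ))
  invisible(x)
}

#' Per-fold cross-validation metrics
#' @param x a `dti_cv`.
#' @param ... unused.
#' @return tibble with one row per fold.
#' @export
tidy.dti_cv <- function(x, ...) x$per_fold

#' Pooled cross-validation metrics
#' @param x a `dti_cv`.
#' @param ... unused.
#' @return one-row tibble: method, scheme, AUC, AUPR, sensitivity,
#'   specificity, PPV, cutoff bookkeeping.
#' @export
glance.dti_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(method = x$method, scheme = x$scheme, seed = x$seed),
    x$pooled
  )
}

#' Repeated cross-validation with mean(sd) summaries
#'
#' Reruns CV `repeats` times with seeds `seed, seed + 1, ...` and reports
#' the mean and standard deviation of each pooled metric across repeats --
#' the "96.8(0.1)" presentation style of benchmark tables.
#'
#' @inheritParams run_cv
#' @param scheme,n_folds,seed passed to [make_cv_plan()].
#' @param repeats number of repeated CV runs.
#' @return list with `summary` (tibble of mean/sd per metric) and `runs`
#'   (list of `dti_cv` objects).
#' @export
cross_validate <- function(dataset, method = "netlaprls",
                           params = dti_params(),
                           scheme = "pairwise", n_folds = 10, seed = 0,
                           repeats = 1,
                           cutoff_rule = "test_size", percentile = 1) {
  runs <- purrr::map(seq_len(repeats), function(r) {
    plan <- make_cv_plan(dataset, scheme, n_folds, seed = seed + r - 1)
    run_cv(dataset, method, params, plan, cutoff_rule, percentile)
  })
  pooled <- purrr::map_dfr(runs, ~ .x$pooled)
  num <- c("auc", "aupr", "sensitivity", "specificity", "ppv")
  summary <- tibble::tibble(
    metric = num,
    mean = purrr::map_dbl(num, ~ mean(pooled[[.x]])),
    sd = purrr::map_dbl(num, ~ stats::sd(pooled[[.x]]))
  )
  list(summary = summary, runs = runs)
}
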