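# Shared fixtures, built in code at test time.

# 2x2 toy with identity similarities.
toy_dataset <- function() {
  dti_dataset(
    Y = matrix(c(1, 0, 0, 1), 2, 2),
    S_d = diag(2), S_p = diag(2),
    drug_ids = c("d1", "d2"), protein_ids = c("p1", "p2")
  )
}

# Random valid similarity matrix with unit diagonal.
random_similarity <- function(n) {
  S <- matrix(stats::runif(n * n), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

# Random valid dataset of the requested shape; positives guaranteed.
random_dataset <- function(n_d, n_p, density = 0.3) {
  Y <- matrix(stats::rbinom(n_d * n_p, 1, density), n_d, n_p)
  if (sum(Y) == 0) Y[1, 1] <- 1
  dti_dataset(Y, random_similarity(n_d), random_similarity(n_p))
}

# Shared-partner counts by brute-force double loop (independent of the
# matrix-product implementation).
brute_force_kernel <- function(Y) {
  n_d <- nrow(Y); n_p <- ncol(Y)
  K_d <- matrix(0, n_d, n_d)
  for (i in seq_len(n_d)) for (j in seq_len(n_d)) {
    K_d[i, j] <- sum(Y[i, ] == 1 & Y[j, ] == 1)
  }
  K_p <- matrix(0, n_p, n_p)
  for (i in seq_len(n_p)) for (j in seq_len(n_p)) {
    K_p[i, j] <- sum(Y[, i] == 1 & Y[, j] == 1)
  }
  list(K_d = K_d, K_p = K_p)
}

# AUC by brute-force comparison of every positive-negative pair.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# AUPR by explicit sweep over every distinct threshold.
brute_force_aupr <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  for (t in thresholds) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    recall <- tp / sum(labels == 1)
    precision <- tp / sum(sel)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Confusion-matrix rates marking the top-k scores positive (stable order).
brute_force_threshold <- function(scores, labels, k) {
  ord <- order(-scores, seq_along(scores))
  pred <- rep(FALSE, length(scores))
  pred[ord[seq_len(k)]] <- TRUE
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = tp / (tp + fp))
}

# Solve the representer-form objective with a generic optimizer (BFGS with
# analytic gradient) -- the independent oracle for the closed-form solver.
optimizer_domain_solve <- function(W, L, Y_view, beta) {
  n <- nrow(W); m <- ncol(Y_view)
  obj <- function(a) {
    A <- matrix(a, n, m)
    sum((Y_view - W %*% A)^2) +
      beta * sum(diag(t(A) %*% W %*% L %*% W %*% A))
  }
  grad <- function(a) {
    A <- matrix(a, n, m)
    as.vector(-2 * W %*% (Y_view - W %*% A) +
                2 * beta * W %*% L %*% W %*% A)
  }
  opt <- stats::optim(rep(0, n * m), obj, grad, method = "BFGS",
                      control = list(maxit = 10000, reltol = 1e-15))
  W %*% matrix(opt$par, n, m)
}

# Write a dataset's three matrices into a temp dir; returns the paths.
write_fixture_files <- function(ds, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- list(
    Y = file.path(dir, "Y.tsv"),
    Sd = file.path(dir, "Sd.tsv"),
    Sp = file.path(dir, "Sp.tsv")
  )
  write_dti_dataset(ds, paths$Y, paths$Sd, paths$Sp)
  paths
}
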