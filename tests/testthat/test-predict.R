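test_that("weighted profile reduces to the labels under identity similarity", {
  set.seed(31)
  Y <- matrix(rbinom(24, 1, 0.4), 6, 4)
  expect_equal(weighted_profile_domain(diag(6), Y), Y)
})

test_that("weighted profile under uniform similarity gives column means", {
  set.seed(32)
  Y <- matrix(rbinom(20, 1, 0.5), 5, 4)
  out <- weighted_profile_domain(matrix(1, 5, 5), Y)
  for (i in 1:5) expect_equal(out[i, ], colMeans(Y))
})

test_that("weighted profile matches direct summation on the worked 2x2 case", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  Y <- diag(2)
  # row 1: (1*Y[1,] + 0.5*Y[2,]) / 1.5 = (2/3, 1/3)
  expect_equal(weighted_profile_domain(S, Y),
               matrix(c(2, 1, 1, 2) / 3, 2, 2))
})

test_that("an all-zero similarity row yields zero scores, not NaN", {
  S <- matrix(c(0, 0, 0, 1), 2, 2)
  out <- weighted_profile_domain(S, matrix(c(1, 1, 0, 1), 2, 2))
  expect_equal(out[1, ], c(0, 0))
  expect_true(all(is.finite(out)))
})

test_that("domain combination averages the drug view with the transposed protein view", {
  set.seed(33)
  A <- matrix(runif(12), 3, 4)
  B <- matrix(runif(12), 4, 3)
  expect_equal(combine_weighted_profile(A, B), (A + t(B)) / 2)
  expect_equal(combine_weighted_profile(A, t(A)), A)
  expect_equal(combine_weighted_profile(matrix(0, 3, 4), B), t(B) / 2)
  expect_error(combine_weighted_profile(A, matrix(0, 3, 4)),
               class = "dti_validation_error")
})

test_that("closed-form solve returns the labels when beta is zero and W is nonsingular", {
  set.seed(34)
  W <- diag(7) + 0.1
  g <- normalized_laplacian(W)
  Y <- matrix(rbinom(21, 1, 0.4), 7, 3)
  expect_equal(laprls_domain_solve(g$W, g$L, Y, beta = 0, ridge_eps = 0), Y,
               tolerance = 1e-8)
})

test_that("closed-form solve agrees with a generic numerical optimizer", {
  set.seed(35)
  for (beta in c(0.01, 0.3, 1, 10)) {
    n <- sample(4:8, 1); m <- sample(2:5, 1)
    W <- random_similarity(n)
    g <- normalized_laplacian(W)
    Y <- matrix(rbinom(n * m, 1, 0.4), n, m)
    F_closed <- laprls_domain_solve(g$W, g$L, Y, beta, ridge_eps = 0)
    F_opt <- optimizer_domain_solve(g$W, g$L, Y, beta)
    expect_equal(F_closed, F_opt, tolerance = 1e-6)
  }
})

test_that("graph smoothness of the solution decreases monotonically in beta", {
  set.seed(36)
  W <- random_similarity(9)
  g <- normalized_laplacian(W)
  Y <- matrix(rbinom(9 * 4, 1, 0.4), 9, 4)
  smoothness <- sapply(c(1, 10, 1e3, 1e6), function(b) {
    FF <- laprls_domain_solve(g$W, g$L, Y, b)
    sum(diag(t(FF) %*% g$L %*% FF))
  })
  expect_true(all(diff(smoothness) < 0))
})

test_that("NetLapRLS with zero network weights is elementwise identical to LapRLS", {
  ds <- simulate_dti_dataset(n_d = 15, n_p = 10, seed = 5)
  p0 <- dti_params(gamma_d2 = 0, gamma_p2 = 0)
  f_net <- dti_predict(ds, "netlaprls", p0)
  f_lap <- dti_predict(ds, "laprls", p0)
  expect_lt(max(abs(f_net$scores - f_lap$scores)), 1e-10)
})

test_that("identity similarities with beta = 0 reproduce the training labels", {
  set.seed(37)
  Y <- matrix(rbinom(30, 1, 0.4), 6, 5)
  ds <- dti_dataset(Y, diag(6), diag(5))
  fit <- dti_predict(ds, "laprls", dti_params(beta_d = 0, beta_p = 0))
  expect_equal(unname(fit$scores), Y, tolerance = 1e-6)
})

test_that("prediction is deterministic across repeated runs", {
  ds <- simulate_dti_dataset(n_d = 10, n_p = 8, seed = 6)
  f1 <- dti_predict(ds, "netlaprls")
  f2 <- dti_predict(ds, "netlaprls")
  expect_identical(f1$scores, f2$scores)
})

test_that("held-out labels cannot leak into the fit", {
  ds <- simulate_dti_dataset(n_d = 12, n_p = 9, seed = 7)
  Y_train <- ds$Y
  held <- which(Y_train == 1)[1:3]
  Y_train[held] <- 0
  fit1 <- dti_predict(ds, "netlaprls", Y_train = Y_train)
  # perturb the held-out labels in the dataset copy; scores must not move
  ds2 <- ds
  ds2$Y[held] <- 0
  fit2 <- dti_predict(ds2, "netlaprls", Y_train = Y_train)
  expect_identical(fit1$scores, fit2$scores)
})

test_that("prediction is equivariant under drug-protein exchange", {
  ds <- simulate_dti_dataset(n_d = 11, n_p = 7, seed = 8)
  params <- dti_params(beta_d = 0.3, beta_p = 0.7,
                       gamma_d2 = 0.02, gamma_p2 = 0.005)
  swapped <- dti_dataset(t(ds$Y), ds$S_p, ds$S_d,
                         drug_ids = ds$protein_ids,
                         protein_ids = ds$drug_ids)
  params_swapped <- dti_params(beta_d = 0.7, beta_p = 0.3,
                               gamma_d1 = params$gamma_p1,
                               gamma_d2 = params$gamma_p2,
                               gamma_p1 = params$gamma_d1,
                               gamma_p2 = params$gamma_d2)
  f <- dti_predict(ds, "netlaprls", params)
  f_swapped <- dti_predict(swapped, "netlaprls", params_swapped)
  expect_equal(unname(f$scores), unname(t(f_swapped$scores)),
               tolerance = 1e-10)
})

test_that("training matrices outside the dataset's positives are rejected", {
  ds <- toy_dataset()
  bad <- matrix(1, 2, 2)   # claims positives the dataset does not have
  expect_error(dti_predict(ds, "laprls", Y_train = bad),
               class = "dti_validation_error")
})

test_that("tidy and glance summarize a fit", {
  ds <- simulate_dti_dataset(n_d = 8, n_p = 6, seed = 9)
  fit <- dti_predict(ds, "weighted_profile")
  edges <- tidy(fit)
  expect_s3_class(edges, "tbl_df")
  expect_equal(nrow(edges), 48)
  expect_true(!is.unsorted(rev(edges$score)))
  g <- glance(fit)
  expect_equal(g$method, "weighted_profile")
  expect_equal(g$n_drugs, 8)
})
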