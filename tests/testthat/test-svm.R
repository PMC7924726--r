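test_that("the 1-D toy problem is solved exactly", {
  toy <- toy_linear_problem()
  m <- train_svm(toy$K, toy$y, svm_params(C = 10, epsilon = 1e-8))
  expect_equal(m$alpha, c(0, 0.5, 0.5, 0), tolerance = 1e-4)
  expect_equal(m$bias, 0, tolerance = 1e-4)
  # decision function is f(x) = x
  Kc <- rbind(3 * toy$x, 0 * toy$x)
  colnames(Kc) <- paste0("g", 1:4)
  expect_equal(unname(decision_scores(m, Kc)), c(3, 0), tolerance = 1e-4)
  # scoring the training points reproduces training-side decision values
  Kt <- toy$K
  expect_equal(unname(decision_scores(m, Kt)), m$f0 + m$bias, tolerance = 1e-8)

  # box constraint respected at small C
  m2 <- train_svm(toy$K, toy$y, svm_params(C = 0.1))
  expect_true(all(m2$alpha <= 0.1 + 1e-8))

  # flipping labels negates scores and bias
  m3 <- train_svm(toy$K, -toy$y, svm_params(C = 10, epsilon = 1e-8))
  expect_equal(unname(decision_scores(m3, Kc)), c(-3, 0), tolerance = 1e-4)
  expect_equal(m3$bias, -m$bias, tolerance = 1e-6)
})

test_that("degenerate and malformed training inputs are rejected", {
  toy <- toy_linear_problem()
  expect_error(train_svm(toy$K, c(1, 1, 1, 1)), "degenerate")
  expect_error(train_svm(toy$K, c(1, -1, 1, 0.5)), "labels")
  bad <- matrix(c(1, 2, 2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(train_svm(bad, c(-1, 1)), "PSD")
  m <- train_svm(toy$K, toy$y)
  expect_error(decision_scores(m, toy$K[, 1:2]), "column")
})

test_that("SMO agrees with an interior-point QP oracle on random instances", {
  skip_if_not_installed("kernlab")
  for (s in 1:50) {
    inst <- random_svm_instance(n = 10 + s %% 8, seed = s)
    C <- c(0.5, 1, 5)[1 + s %% 3]
    Cvec <- rep(C, length(inst$y))
    m <- train_svm(inst$K, inst$y, svm_params(C = C, epsilon = 1e-7,
                                              class_weight = FALSE))
    # KKT contract of the returned model
    res <- kkt_residuals(m, inst$K)
    expect_lt(res$box, 1e-10)
    expect_lt(res$equality, 1e-10)
    expect_lt(res$kkt_violation, 1e-5)
    # same optimum as the oracle (strictly convex: RBF kernel is PD)
    a_star <- qp_svm_oracle(inst$K, inst$y, Cvec)
    expect_equal(m$alpha, a_star, tolerance = 1e-4)
  }
})

test_that("per-class penalty rebalances the box for imbalanced labels", {
  inst <- random_svm_instance(n = 16, seed = 99)
  y <- rep(-1, 16); y[1:2] <- 1  # 2 positives vs 14 negatives
  m <- train_svm(inst$K, y, svm_params(C = 1, class_weight = TRUE))
  expect_equal(unique(m$Cvec[y == 1]), 1 * 14 / 2)
  expect_equal(unique(m$Cvec[y == -1]), 1)
  m0 <- train_svm(inst$K, y, svm_params(C = 1, class_weight = FALSE))
  expect_true(all(m0$Cvec == 1))
})

test_that("uniform multi-kernel training equals training on the pre-summed kernel", {
  ids <- sprintf("g%02d", 1:15)
  ks <- lapply(1:3, function(s) {
    X <- withr::with_seed(s, matrix(rnorm(45), 15, 3, dimnames = list(ids, NULL)))
    rbf_kernel(X, gamma = 1)
  })
  y <- withr::with_seed(7, sample(c(-1, 1), 15, replace = TRUE))
  Ksum <- Reduce(`+`, lapply(ks, unclass))
  dimnames(Ksum) <- list(ids, ids)
  p <- svm_params(C = 2, epsilon = 1e-8)
  m_mkl <- train_mkl(ks, y, p)
  m_sum <- train_svm(Ksum, y, p)
  expect_equal(m_mkl$alpha, m_sum$alpha, tolerance = 1e-8)
  expect_equal(decision_scores(m_mkl, Ksum), decision_scores(m_sum, Ksum),
               tolerance = 1e-8)
  expect_equal(m_mkl$mu, c(1, 1, 1))
})

test_that("duplicating a training point never hurts its own class side", {
  skip_if_not_installed("kernlab")
  for (s in 1:5) {
    inst <- random_svm_instance(n = 10, seed = 200 + s)
    p <- svm_params(C = 1, epsilon = 1e-8, class_weight = FALSE)
    m <- train_svm(inst$K, inst$y, p)
    i <- which.max(inst$y)  # a positive point
    K2 <- inst$K[c(seq_len(10), i), c(seq_len(10), i)]
    rownames(K2) <- colnames(K2) <- c(rownames(inst$K), "dup")
    y2 <- c(inst$y, inst$y[i])
    m2 <- train_svm(K2, y2, p)
    f1 <- decision_scores(m, inst$K[i, , drop = FALSE])
    f2 <- decision_scores(m2, K2[i, , drop = FALSE])
    expect_gte(f2 + 1e-6, f1)
  }
})

test_that("p-norm weight learning favours informative kernels", {
  ids <- sprintf("g%02d", 1:24)
  # identical kernels -> symmetric weights with unit p-norm
  X <- withr::with_seed(3, matrix(rnorm(72), 24, 3, dimnames = list(ids, NULL)))
  k <- rbf_kernel(X, gamma = 1)
  y <- withr::with_seed(4, sample(c(-1, 1), 24, replace = TRUE))
  mu <- suppressWarnings(
    learn_kernel_weights(list(k, k), y, svm_params(norm = 2))
  )
  expect_equal(as.numeric(mu), rep(1 / sqrt(2), 2), tolerance = 1e-6)
  expect_equal(sum(mu^2), 1, tolerance = 1e-10)

  expect_error(learn_kernel_weights(list(k), y), ">= 2")

  # informative vs pure-noise kernel on separable labels
  wins <- 0
  for (s in 1:10) {
    sep <- withr::with_seed(s, {
      yy <- rep(c(-1, 1), each = 12)
      Xs <- matrix(rnorm(72), 24, 3) + 2 * yy  # class-shifted features
      dimnames(Xs) <- list(ids, NULL)
      Xn <- matrix(rnorm(72), 24, 3, dimnames = list(ids, NULL))
      list(y = yy, informative = rbf_kernel(Xs, gamma = 0.2),
           noise = rbf_kernel(Xn, gamma = 0.2))
    })
    mu_s <- suppressWarnings(
      learn_kernel_weights(list(sep$informative, sep$noise), sep$y,
                           svm_params(norm = 2))
    )
    wins <- wins + (mu_s[1] > mu_s[2])
  }
  expect_gte(wins, 9)
})
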