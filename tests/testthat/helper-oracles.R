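# Independent oracles and small fixture builders shared across test files.

# Generic QP oracle for the SVM dual via kernlab::ipop (interior point),
# independent of the package's SMO solver:
#   min -e'a + 0.5 a'Qa  s.t. y'a = 0, 0 <= a <= C
qp_svm_oracle <- function(K, y, Cvec) {
  skip_if_not_installed("kernlab")
  n <- length(y)
  # escalate ridge and relax precision when the interior-point system is
  # ill-conditioned (e.g. fully saturated solutions)
  settings <- list(c(1e-10, 9), c(1e-8, 8), c(1e-6, 7))
  for (st in settings) {
    Q <- (y %o% y) * K + diag(st[1], n)
    a <- tryCatch({
      fit <- kernlab::ipop(c = rep(-1, n), H = Q, A = matrix(y, 1), b = 0,
                           l = rep(0, n), u = Cvec, r = 0, sigf = st[2],
                           maxiter = 400, margin = 0.1)
      kernlab::primal(fit)
    }, error = function(e) NULL)
    if (!is.null(a)) return(a)
  }
  stop("QP oracle failed to converge")
}

# Brute-force AUC: explicit loop over all positive-negative pairs, ties 1/2.
brute_auc <- function(scores, labels) {
  p <- scores[labels == 1]
  q <- scores[labels == -1]
  acc <- 0
  for (a in p) for (b in q) acc <- acc + (a > b) + 0.5 * (a == b)
  acc / (length(p) * length(q))
}

# Brute-force AUPR: naive sweep over descending unique thresholds with
# rectangular integration.
brute_aupr <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0
  area <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == -1)
    prec <- tp / (tp + fp)
    rec <- tp / sum(labels == 1)
    area <- area + (rec - prev_r) * prec
    prev_r <- rec
  }
  area
}

# Random strictly-PD kernel (RBF over random points) with labels that keep
# both classes non-empty.
random_svm_instance <- function(n = 12, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * 3), n, 3)
    rownames(X) <- sprintf("g%02d", seq_len(n))
    K <- rbf_kernel(X, gamma = 0.5)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (all(y == y[1])) y[1] <- -y[1]
    list(K = unclass(K), y = y)
  })
}

# Toy 1-D linearly separable problem whose exact solution is known:
# alpha = (0, 0.5, 0.5, 0), bias = 0, f(x) = x.
toy_linear_problem <- function() {
  x <- c(-2, -1, 1, 2)
  K <- outer(x, x)
  rownames(K) <- colnames(K) <- paste0("g", 1:4)
  list(x = x, K = K, y = c(-1, -1, 1, 1))
}

# Small aligned kernel + regulation fixture for inference tests.
small_inference_fixture <- function(n_genes = 60, n_tfs = 3, seed = 5) {
  cfg <- synthetic_config(n_genes = n_genes, n_samples = 40, n_tfs = n_tfs,
                          targets_per_tf = 8, seed = seed)
  sim <- generate_synthetic(cfg)
  K <- combine_kernels(list(normalize_kernel(rbf_kernel(sim$expression)),
                            normalize_kernel(diffusion_kernel(sim$ppi))))
  list(K = K, R = sim$regulations, sim = sim)
}
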