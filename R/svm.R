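#' SVM / MKL training parameters
#'
#' @param C Positive soft-margin penalty (default 1).
#' @param epsilon Positive solver termination tolerance on the maximal KKT
#'   violation (default 1e-5).
#' @param norm Kernel-weight norm `p >= 1` used by the optional multiple
#'   kernel weight learner (default 1, matching the 1-norm soft-margin
#'   formulation of the classifier itself).
#' @param class_weight If `TRUE` (default) the penalty is rebalanced per
#'   class: `C_+ = C * n_- / n_+`, `C_- = C`. With few known targets per TF
#'   the positives are heavily outnumbered and an unweighted SVM collapses to
#'   the all-negative solution.
#' @param max_iter Iteration cap for the SMO solver.
#' @return An object of class `svm_params`.
#' @export
svm_params <- function(C = 1, epsilon = 1e-5, norm = 1, class_weight = TRUE,
                       max_iter = 200000L) {
  if (!is.numeric(C) || C <= 0) abort("C must be > 0")
  if (!is.numeric(epsilon) || epsilon <= 0) abort("epsilon must be > 0")
  if (!is.numeric(norm) || norm < 1) abort("norm must be >= 1")
  structure(list(C = C, epsilon = epsilon, norm = norm,
                 class_weight = isTRUE(class_weight),
                 max_iter = as.integer(max_iter)),
            class = "svm_params")
}

as_svm_params <- function(p) {
  if (inherits(p, "svm_params")) return(p)
  do.call(svm_params, as.list(p))
}

#' Train a 1-norm soft-margin SVM on a precomputed kernel
#'
#' Solves the dual quadratic program
#' `max sum(alpha) - 0.5 * sum_ij alpha_i alpha_j y_i y_j K_ij` subject to
#' `0 <= alpha_i <= C_i` and `sum(alpha_i y_i) = 0`, by sequential minimal
#' optimization with second-order working-set selection. The bias is the
#' average of `y_i - f0_i` over free support vectors (`0 < alpha_i < C_i`);
#' when no free support vector exists it falls back to the midpoint of the
#' KKT-feasible interval.
#'
#' @param K Training-block kernel matrix (square, rows/cols = training genes).
#' @param y Labels in \{-1, +1\}, one per training gene.
#' @param params An [svm_params()] object (or list coercible to one).
#' @param check_psd Verify positive semi-definiteness of `K` before solving
#'   (an O(n^3) eigendecomposition; disable for repeated fold-level training
#'   on an already-validated kernel).
#' @return An object of class `tf_svm`: list with `alpha`, `y`, `bias`,
#'   `support_ids`, `Cvec`, `params`, `mu`, `iterations`, `converged`, `f0`
#'   (training decision values without bias).
#' @examples
#' x <- c(-2, -1, 1, 2)
#' K <- outer(x, x)                      # linear kernel
#' rownames(K) <- colnames(K) <- paste0("g", 1:4)
#' m <- train_svm(K, c(-1, -1, 1, 1), svm_params(C = 10))
#' round(m$alpha, 4); m$bias
#' @export
train_svm <- function(K, y, params = svm_params(), check_psd = TRUE) {
  params <- as_svm_params(params)
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) abort("training kernel must be square")
  y <- as.numeric(y)
  if (length(y) != nrow(K)) abort("one label per training gene required")
  if (!all(y %in% c(-1, 1))) abort("labels must be +1/-1")
  n_pos <- sum(y > 0)
  n_neg <- sum(y < 0)
  if (n_pos == 0L || n_neg == 0L) abort("degenerate labels: both classes required")
  if (check_psd) {
    v <- validate_psd(unclass(K), tol = 1e-6)
    if (!v$ok) abort("training kernel is not PSD (lambda_min = ",
                     format(v$lambda_min), ")")
  }
  Cvec <- rep(params$C, length(y))
  if (params$class_weight) Cvec[y > 0] <- params$C * n_neg / n_pos

  fit <- smo_solve(unclass(K), y, Cvec, params$epsilon, params$max_iter)
  alpha <- fit$alpha
  f0 <- fit$f0

  tol_a <- 1e-8 * max(Cvec)
  free <- alpha > tol_a & alpha < Cvec - tol_a
  if (any(free)) {
    bias <- mean(y[free] - f0[free])
  } else {
    # midpoint of [M, m]: m over I_up, M over I_low of (y_t - f0_t)
    up <- (y > 0 & alpha < Cvec - tol_a) | (y < 0 & alpha > tol_a)
    lo <- (y > 0 & alpha > tol_a) | (y < 0 & alpha < Cvec - tol_a)
    hi_b <- if (any(up)) max(y[up] - f0[up]) else 0
    lo_b <- if (any(lo)) min(y[lo] - f0[lo]) else 0
    bias <- (hi_b + lo_b) / 2
  }

  structure(list(alpha = alpha, y = y, bias = bias,
                 support_ids = rownames(K), Cvec = Cvec, params = params,
                 mu = NULL, iterations = fit$iterations,
                 converged = fit$converged, f0 = f0),
            class = "tf_svm")
}

#' Decision scores for query genes
#'
#' `f(g) = sum_i alpha_i y_i K(g, i) + bias`; higher scores mean a gene is
#' more likely regulated by the model's TF.
#'
#' @param model A `tf_svm`.
#' @param K_cross Kernel block with query genes as rows and the model's
#'   training genes as columns (same order as at training).
#' @return Named numeric vector of scores, one per query gene.
#' @export
decision_scores <- function(model, K_cross) {
  K_cross <- as.matrix(K_cross)
  if (ncol(K_cross) != length(model$alpha)) {
    abort("K_cross must have one column per training gene")
  }
  if (!is.null(model$support_ids) && !is.null(colnames(K_cross)) &&
      !identical(colnames(K_cross), model$support_ids)) {
    abort("K_cross column order does not match the model's training genes")
  }
  drop(unclass(K_cross) %*% (model$alpha * model$y)) + model$bias
}

#' Karush-Kuhn-Tucker residuals of a trained model
#'
#' Diagnostic for solver correctness: box-constraint violation, the equality
#' constraint `sum(alpha_i y_i)`, the maximal gradient-based KKT violation
#' (the SMO stopping quantity) and the complementary-slackness residual.
#'
#' @param model A `tf_svm`.
#' @param K The training kernel it was fitted on.
#' @return Named list of residuals (all should be at or below the solver
#'   tolerance for a converged model).
#' @export
kkt_residuals <- function(model, K) {
  a <- model$alpha
  y <- model$y
  Cv <- model$Cvec
  f0 <- drop(unclass(as.matrix(K)) %*% (a * y))
  g <- y * f0 - 1          # gradient of the dual (minimization form)
  v <- -y * g              # = y_t - f0_t
  up <- (y > 0 & a < Cv - 1e-12) | (y < 0 & a > 1e-12)
  lo <- (y > 0 & a > 1e-12) | (y < 0 & a < Cv - 1e-12)
  m_up <- if (any(up)) max(v[up]) else -Inf
  m_lo <- if (any(lo)) min(v[lo]) else Inf
  margins <- y * (f0 + model$bias)
  slack <- pmax(0, 1 - margins)
  comp <- max(abs(a * pmax(0, margins - 1)),      # alpha > 0 needs margin <= 1
              abs((Cv - a) * slack))              # alpha < C needs slack = 0
  list(box = max(0, max(-a), max(a - Cv)),
       equality = abs(sum(a * y)),
       kkt_violation = max(0, m_up - m_lo),
       complementarity = comp)
}

#' Train on multiple kernels with fixed fusion weights
#'
#' Fuses the training-block kernels with [combine_kernels()] (uniform weights
#' by default, i.e. plain kernel addition) and trains a single SVM on the
#' result; by construction this is identical to training on the pre-summed
#' kernel.
#'
#' @param ks List of training-block `kernel_matrix` objects.
#' @param y Labels in \{-1, +1\}.
#' @param params An [svm_params()].
#' @param weights Non-negative fusion weights (default uniform).
#' @inheritParams train_svm
#' @return A `tf_svm` whose `mu` field records the weights used.
#' @export
train_mkl <- function(ks, y, params = svm_params(), weights = NULL,
                      check_psd = TRUE) {
  K <- combine_kernels(ks, weights)
  m <- train_svm(K, y, params, check_psd = check_psd)
  m$mu <- attr(K, "params")$weights
  m
}

#' Learn fusion weights by alternating p-norm multiple kernel learning
#'
#' Optional extension to the fixed-weight fusion: alternates between (a)
#' training an SVM on `sum_m mu_m k_m` with `mu` fixed and (b) the closed-form
#' p-norm update `mu_m proportional to (||w_m||^2)^(1/(p+1))`, where
#' `||w_m||^2 = mu_m^2 * (alpha y)' K_m (alpha y)`, renormalized to unit
#' p-norm. Iterates until the relative change of the dual objective falls
#' below `params$epsilon` or `max_iter` sweeps.
#'
#' @param ks List of >= 2 training-block `kernel_matrix` objects.
#' @param y Labels in \{-1, +1\}.
#' @param params An [svm_params()]; `params$norm` is the p-norm (p >= 1).
#' @param max_iter Maximum alternating sweeps (default 50).
#' @return Numeric weight vector `mu` with `||mu||_p = 1`, carrying attributes
#'   `converged`, `iterations` and `model` (the final `tf_svm`). Warns when
#'   the sweep cap is reached.
#' @export
learn_kernel_weights <- function(ks, y, params = svm_params(norm = 2),
                                 max_iter = 50L) {
  params <- as_svm_params(params)
  if (length(ks) < 2L) abort("weight learning needs >= 2 kernels")
  p <- params$norm
  m <- length(ks)
  mu <- rep((1 / m)^(1 / p), m)   # uniform with unit p-norm
  obj_old <- Inf
  converged <- FALSE
  model <- NULL
  it <- 0L
  for (it in seq_len(max_iter)) {
    K <- combine_kernels(ks, mu)
    model <- train_svm(K, y, params, check_psd = FALSE)
    ay <- model$alpha * model$y
    obj <- sum(model$alpha) - 0.5 * drop(crossprod(ay, unclass(K) %*% ay))
    wsq <- vapply(ks, function(k) {
      drop(crossprod(ay, unclass(k) %*% ay))
    }, numeric(1))
    wsq <- pmax(wsq, 0) * mu^2
    if (sum(wsq) <= 0) break
    mu_new <- wsq^(1 / (p + 1))
    mu_new <- mu_new / sum(mu_new^p)^(1 / p)
    if (is.finite(obj_old) &&
        abs(obj - obj_old) <= params$epsilon * max(1, abs(obj_old))) {
      mu <- mu_new
      converged <- TRUE
      break
    }
    obj_old <- obj
    mu <- mu_new
  }
  if (!converged) {
    warning("kernel-weight learning did not converge in ", max_iter,
            " sweeps; returning best iterate", call. = FALSE)
  }
  structure(mu, converged = converged, iterations = it, model = model)
}
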