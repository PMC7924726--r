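#' Kernel matrices over genes
#'
#' A `kernel_matrix` is a symmetric positive semi-definite gene x gene
#' similarity matrix with aligned gene identifiers on both dimensions, plus
#' `kind` ("rbf", "diffusion", "linear", "combined") and `params` attributes
#' recording how it was built.
#'
#' @param values Symmetric numeric matrix with identical row/col gene names.
#' @param kind Construction kind.
#' @param params Named list of construction parameters.
#' @return A `kernel_matrix`.
#' @export
kernel_matrix <- function(values, kind = "linear", params = list()) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort("kernel matrix must be square")
  if (is.null(rownames(values))) abort("kernel matrix needs gene names")
  if (is.null(colnames(values))) colnames(values) <- rownames(values)
  if (!identical(rownames(values), colnames(values))) {
    abort("kernel row/column gene ids must match")
  }
  asym <- max(abs(values - t(values)))
  if (asym > 1e-10 * max(1, max(abs(values)))) {
    abort("kernel matrix asymmetric beyond tolerance")
  }
  if (any(!is.finite(diag(values)))) abort("kernel diagonal must be finite")
  structure((values + t(values)) / 2, kind = kind, params = params,
            class = c("kernel_matrix", "matrix", "array"))
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix (%s): %d genes\n", attr(x, "kind"), nrow(x)))
  invisible(x)
}

#' Gaussian radial basis function kernel over gene profiles
#'
#' `K_ij = exp(-gamma * ||x_i - x_j||^2)` computed over the rows (genes) of a
#' feature matrix. With `gamma = "median"` the bandwidth is set by the median
#' heuristic, `gamma = 1 / (2 m^2)` where `m` is the median pairwise Euclidean
#' distance over a deterministic subsample of at most `subsample_cap` genes.
#'
#' @param X genes x samples numeric matrix.
#' @param gamma Positive bandwidth, or `"median"` (default).
#' @param subsample_cap Genes used for the median heuristic (seeded,
#'   deterministic subsample when the matrix is larger).
#' @param heuristic_seed Seed for that subsample.
#' @return A `kernel_matrix` of kind `"rbf"` with unit diagonal and entries in
#'   (0, 1].
#' @examples
#' X <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("g", 1:5), NULL))
#' rbf_kernel(X, gamma = 0.5)
#' @export
rbf_kernel <- function(X, gamma = "median", subsample_cap = 1000L,
                       heuristic_seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) abort("need at least one sample column")
  if (is.null(rownames(X))) abort("feature matrix needs gene rownames")
  if (identical(gamma, "median")) {
    idx <- seq_len(nrow(X))
    if (nrow(X) > subsample_cap) {
      idx <- withr::with_seed(heuristic_seed,
                              sort(sample.int(nrow(X), subsample_cap)))
    }
    m <- median(stats::dist(X[idx, , drop = FALSE]))
    if (!is.finite(m) || m <= 0) {
      abort("median pairwise distance is 0; supply an explicit gamma")
    }
    gamma <- 1 / (2 * m^2)
    gamma_spec <- "median"
  } else {
    if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
      abort("gamma must be a positive number or \"median\"")
    }
    gamma_spec <- "fixed"
  }
  d2 <- as.matrix(stats::dist(X))^2
  K <- exp(-gamma * d2)
  diag(K) <- 1
  dimnames(K) <- list(rownames(X), rownames(X))
  kernel_matrix(K, kind = "rbf",
                params = list(gamma = gamma, gamma_spec = gamma_spec))
}

#' Graph diffusion kernel
#'
#' `K = expm(beta * H)` with `H = A - D`, where `A` is the (weighted)
#' adjacency matrix of the undirected gene graph and `D` the diagonal degree
#' matrix; `H` is the negative graph Laplacian. The matrix exponential is
#' computed exactly by symmetric eigendecomposition, which also guarantees a
#' PSD result. Because `H` has zero row sums, every row of `K` sums to 1:
#' diffusion redistributes similarity mass along edges.
#'
#' @param g A `gene_graph`.
#' @param beta Positive diffusion time (default 1).
#' @return A `kernel_matrix` of kind `"diffusion"` over `g$nodes`.
#' @examples
#' g <- gene_graph(data.frame(from = "g1", to = "g2"), nodes = c("g1", "g2"))
#' diffusion_kernel(g, beta = 1)
#' @export
diffusion_kernel <- function(g, beta = 1) {
  if (!inherits(g, "gene_graph")) abort("g must be a gene_graph")
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0) {
    abort("beta must be a non-negative number")
  }
  n <- length(g$nodes)
  A <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) {
    i <- match(g$edges$from, g$nodes)
    j <- match(g$edges$to, g$nodes)
    A[cbind(i, j)] <- g$edges$weight
    A[cbind(j, i)] <- g$edges$weight
  }
  H <- A - diag(rowSums(A), n)
  eig <- eigen(H, symmetric = TRUE)
  K <- eig$vectors %*% (exp(beta * eig$values) * t(eig$vectors))
  dimnames(K) <- list(g$nodes, g$nodes)
  kernel_matrix(K, kind = "diffusion", params = list(beta = beta))
}

#' Cosine (unit-diagonal) normalization of a kernel
#'
#' `K'_ij = K_ij / sqrt(K_ii K_jj)`. Preserves positive semi-definiteness and
#' is idempotent. Applied before fusion so that no single data type dominates
#' the combined kernel purely by scale.
#'
#' @param K A `kernel_matrix` with strictly positive diagonal.
#' @return A `kernel_matrix` with unit diagonal.
#' @export
normalize_kernel <- function(K) {
  d <- diag(K)
  bad <- which(d <= 0)
  if (length(bad)) {
    abort("non-positive kernel diagonal for gene(s): ",
          paste(rownames(K)[bad], collapse = ", "))
  }
  s <- 1 / sqrt(d)
  out <- unclass(K) * tcrossprod(s)
  diag(out) <- 1
  kernel_matrix(out, kind = attr(K, "kind"),
                params = c(attr(K, "params"), list(normalized = TRUE)))
}

#' Fuse kernels into a combined kernel
#'
#' Elementwise non-negative weighted sum `K = sum_i mu_i k_i`. A non-negative
#' combination of PSD matrices is PSD, so fusion preserves validity. The
#' default weights are uniform (all 1), i.e. plain kernel addition.
#'
#' @param ks List of `kernel_matrix` objects over the identical gene order.
#' @param weights Numeric vector of non-negative weights, one per kernel
#'   (default all 1).
#' @return A `kernel_matrix` of kind `"combined"`; `params$weights` records
#'   the weights used and `params$components` the input kinds.
#' @export
combine_kernels <- function(ks, weights = NULL) {
  if (!length(ks)) abort("need at least one kernel")
  if (is.null(weights)) weights <- rep(1, length(ks))
  if (length(weights) != length(ks)) abort("one weight per kernel required")
  if (any(!is.finite(weights)) || any(weights < 0)) {
    abort("kernel weights must be non-negative")
  }
  ids <- rownames(ks[[1]])
  for (k in ks[-1]) {
    if (!identical(rownames(k), ids)) abort("kernels have mismatched gene orders")
  }
  out <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ks)) out <- out + weights[i] * unclass(ks[[i]])
  kernel_matrix(out, kind = "combined",
                params = list(weights = weights,
                              components = vapply(ks, attr, "", "kind")))
}

#' Check numerical positive semi-definiteness
#'
#' A kernel passes when its smallest eigenvalue satisfies
#' `lambda_min >= -tol * max(1, lambda_max)`.
#'
#' @param K Square symmetric matrix (asymmetry beyond 1e-8 errors).
#' @param tol Relative tolerance (default 1e-8).
#' @return List with `ok` (logical), `lambda_min` and `lambda_max`.
#' @export
validate_psd <- function(K, tol = 1e-8) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) abort("matrix is not square")
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
    abort("matrix asymmetric beyond tolerance")
  }
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lmin <- min(ev)
  lmax <- max(ev)
  list(ok = lmin >= -tol * max(1, lmax), lambda_min = lmin, lambda_max = lmax)
}
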