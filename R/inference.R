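#' Seeded cross-validation plan over genes
#'
#' Uniform random partition of the gene universe into `n_folds` folds whose
#' sizes differ by at most one, deterministic given the gene order, fold
#' count and seed. One plan is shared by every TF of a run so that decision
#' scores are comparable across columns.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param n_folds Integer >= 2 (default 10).
#' @param seed Integer seed.
#' @return An object of class `cv_plan`: list with `n_folds`, `seed` and
#'   `fold` (named integer vector, gene -> fold index).
#' @export
make_cv_plan <- function(gene_ids, n_folds = 10L, seed = 1L) {
  n <- length(gene_ids)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) abort("n_folds must be >= 2")
  if (n_folds > n) abort("n_folds (", n_folds, ") exceeds number of genes (", n, ")")
  if (anyDuplicated(gene_ids)) abort("duplicate gene ids")
  fold <- withr::with_seed(as.integer(seed),
                           sample(rep_len(seq_len(n_folds), n)))
  names(fold) <- gene_ids
  structure(list(n_folds = n_folds, seed = as.integer(seed), fold = fold),
            class = "cv_plan")
}

#' Partition TFs into contiguous worker chunks
#'
#' Static equal-split scheduling: the canonical TF order is cut into at most
#' `n_workers` contiguous chunks whose sizes differ by at most one, so every
#' worker receives (nearly) the same number of classification subproblems.
#'
#' @param tf_ids Character vector of TF identifiers (canonical order).
#' @param n_workers Integer >= 1.
#' @return List of character vectors (the chunks), of class `parallel_plan`.
#' @examples
#' plan_partition(paste0("TF", 1:10), 4)  # sizes 3, 3, 2, 2
#' @export
plan_partition <- function(tf_ids, n_workers = 1L) {
  if (!length(tf_ids)) abort("empty TF list")
  n_workers <- as.integer(n_workers)
  if (n_workers < 1L) abort("n_workers must be >= 1")
  n <- length(tf_ids)
  k <- min(n_workers, n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  chunks <- Map(function(s, e) tf_ids[s:e], starts, ends)
  structure(unname(chunks), class = "parallel_plan")
}

#' Out-of-fold decision scores for a single TF
#'
#' The TF's regulation column supplies the labels (+1 known target, -1
#' otherwise; unlisted genes are accepted as presumed negatives even though
#' some are false negatives). For each fold, an SVM is trained on all genes
#' outside the fold and scores the genes inside it, so every gene receives
#' exactly one score from a model that never saw its label.
#'
#' @param tf_id TF column to score.
#' @param K Combined `kernel_matrix` over the gene universe.
#' @param R `regulation_matrix` aligned with `K`.
#' @param cv A [make_cv_plan()] over the same genes.
#' @param params An [svm_params()].
#' @param min_pos Minimum positives (spread over >= 2 folds) required to run
#'   cross-validated scoring (default 2).
#' @param skip_policy What to do below `min_pos`: `"skip"` (NA column,
#'   flagged) or `"all-data"` (single in-sample model over all genes,
#'   flagged).
#' @param check_psd Validate `K` before training (disable when the caller
#'   already did).
#' @return List with `tf_id`, `scores` (named vector over all genes),
#'   `status` (`"ok"`, `"skipped"`, `"all-data"`), `events` (per-fold notes,
#'   e.g. single-class folds that borrowed a neighbouring model), `n_pos`,
#'   `ops` (operation count: sum over trainings of training-set size squared)
#'   and `elapsed` (seconds).
#' @export
score_tf <- function(tf_id, K, R, cv, params = svm_params(), min_pos = 2L,
                     skip_policy = c("skip", "all-data"), check_psd = FALSE) {
  skip_policy <- match.arg(skip_policy)
  params <- as_svm_params(params)
  t0 <- proc.time()[["elapsed"]]
  genes <- rownames(K)
  if (!identical(genes, rownames(R))) abort("kernel and regulations misaligned")
  if (!tf_id %in% colnames(R)) abort("unknown TF: ", tf_id)
  if (!identical(names(cv$fold), genes)) abort("cv plan covers different genes")
  y <- unclass(R)[, tf_id]
  pos <- which(y == 1)
  events <- character()
  ops <- 0

  enough <- length(pos) >= min_pos && length(unique(cv$fold[pos])) >= 2L
  if (!enough) {
    if (skip_policy == "skip") {
      return(list(tf_id = tf_id,
                  scores = setNames(rep(NA_real_, length(genes)), genes),
                  status = "skipped",
                  events = sprintf("skipped: %d positive(s) in %d fold(s)",
                                   length(pos),
                                   length(unique(cv$fold[pos]))),
                  n_pos = length(pos), ops = 0,
                  elapsed = proc.time()[["elapsed"]] - t0))
    }
    if (length(pos) == 0L || length(pos) == length(y)) {
      return(list(tf_id = tf_id,
                  scores = setNames(rep(NA_real_, length(genes)), genes),
                  status = "skipped",
                  events = "skipped: single-class labels, all-data fallback impossible",
                  n_pos = length(pos), ops = 0,
                  elapsed = proc.time()[["elapsed"]] - t0))
    }
    m <- train_svm(K, y, params, check_psd = check_psd)
    ops <- length(y)^2
    sc <- decision_scores(m, unclass(K))
    return(list(tf_id = tf_id, scores = setNames(sc, genes),
                status = "all-data",
                events = "all-data fallback: too few positives for CV",
                n_pos = length(pos), ops = ops,
                elapsed = proc.time()[["elapsed"]] - t0))
  }

  models <- vector("list", cv$n_folds)
  train_idx <- vector("list", cv$n_folds)
  for (f in seq_len(cv$n_folds)) {
    idx <- which(cv$fold != f)
    yf <- y[idx]
    if (length(unique(yf)) < 2L) {
      events <- c(events, sprintf("fold %d: single-class training split", f))
      next
    }
    train_idx[[f]] <- idx
    models[[f]] <- train_svm(unclass(K)[idx, idx, drop = FALSE], yf, params,
                             check_psd = check_psd)
    ops <- ops + length(idx)^2
  }
  valid <- which(!vapply(models, is.null, logical(1)))
  if (!length(valid)) abort("no fold produced a valid training split for ", tf_id)

  scores <- setNames(rep(NA_real_, length(genes)), genes)
  for (f in seq_len(cv$n_folds)) {
    use <- f
    if (is.null(models[[f]])) {
      # nearest previous valid split, falling forward when none precedes
      prev <- valid[valid < f]
      use <- if (length(prev)) max(prev) else min(valid[valid > f])
      events <- c(events, sprintf("fold %d scored with fold-%d model", f, use))
    }
    test <- which(cv$fold == f)
    Kc <- unclass(K)[test, train_idx[[use]], drop = FALSE]
    scores[test] <- decision_scores(models[[use]], Kc)
  }
  list(tf_id = tf_id, scores = scores, status = "ok", events = events,
       n_pos = length(pos), ops = ops,
       elapsed = proc.time()[["elapsed"]] - t0)
}

#' Inference run configuration
#'
#' @param svm An [svm_params()] (or coercible list).
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Seed for the fold plan.
#' @param n_workers Parallel workers for the per-TF subproblems (default 1).
#' @param min_pos,skip_policy See [score_tf()].
#' @return List of class `inference_config`.
#' @export
inference_config <- function(svm = svm_params(), n_folds = 10L, seed = 1L,
                             n_workers = 1L, min_pos = 2L,
                             skip_policy = c("skip", "all-data")) {
  structure(list(svm = as_svm_params(svm), n_folds = as.integer(n_folds),
                 seed = as.integer(seed), n_workers = as.integer(n_workers),
                 min_pos = as.integer(min_pos),
                 skip_policy = match.arg(skip_policy)),
            class = "inference_config")
}

#' Infer a genome-wide TF-gene score matrix
#'
#' Decomposes network inference into one binary classification subproblem per
#' TF, runs the subproblems over a static partition of the TF list (forked
#' workers via [parallel::mclapply()] when `cfg$n_workers > 1`), and collects
#' the per-TF out-of-fold score vectors into a genes x TFs decision-score
#' matrix. Workers are stateless and share nothing but the result store, so
#' the output is identical for any worker count given the same seed.
#'
#' @param kernel Combined `kernel_matrix` over the gene universe.
#' @param R `regulation_matrix` aligned with `kernel` (same gene order).
#' @param cfg An [inference_config()].
#' @return A [score_matrix()] whose `provenance` records the fold plan seed,
#'   SVM parameters, worker count, per-TF timings and operation counts.
#'   Columns of skipped or failed TFs are `NA` and flagged in `status`.
#' @export
infer_network <- function(kernel, R, cfg = inference_config()) {
  if (!identical(rownames(kernel), rownames(R))) {
    abort("kernel and regulation matrix are not aligned; run align_universe()")
  }
  v <- validate_psd(unclass(kernel), tol = 1e-6)
  if (!v$ok) abort("combined kernel is not PSD (lambda_min = ",
                   format(v$lambda_min), ")")
  t0 <- proc.time()[["elapsed"]]
  tf_ids <- colnames(R)
  cv <- make_cv_plan(rownames(kernel), cfg$n_folds, cfg$seed)
  chunks <- plan_partition(tf_ids, cfg$n_workers)

  run_chunk <- function(chunk) {
    lapply(chunk, function(tf) {
      tryCatch(
        score_tf(tf, kernel, R, cv, cfg$svm, cfg$min_pos, cfg$skip_policy,
                 check_psd = FALSE),
        error = function(e) list(tf_id = tf, scores = NULL, status = "failed",
                                 events = conditionMessage(e), n_pos = NA,
                                 ops = 0, elapsed = NA_real_)
      )
    })
  }
  results <- if (cfg$n_workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(chunks, run_chunk, mc.cores = cfg$n_workers)
  } else {
    lapply(chunks, run_chunk)
  }
  # order-independent collection keyed by tf_id
  store <- new.env(parent = emptyenv())
  for (chunk_res in results) {
    for (r in chunk_res) assign(r$tf_id, r, envir = store)
  }
  scores <- matrix(NA_real_, nrow(kernel), length(tf_ids),
                   dimnames = list(rownames(kernel), tf_ids))
  status <- setNames(character(length(tf_ids)), tf_ids)
  events <- timings <- ops <- setNames(vector("list", length(tf_ids)), tf_ids)
  for (tf in tf_ids) {
    r <- get(tf, envir = store)
    status[tf] <- r$status
    events[[tf]] <- r$events
    timings[[tf]] <- r$elapsed
    ops[[tf]] <- r$ops
    if (!is.null(r$scores)) scores[, tf] <- r$scores
  }
  if (any(status == "failed")) {
    warning("TF column(s) failed: ",
            paste(tf_ids[status == "failed"], collapse = ", "), call. = FALSE)
  }
  score_matrix(scores, status = status,
               provenance = list(seed = cfg$seed, n_folds = cfg$n_folds,
                                 svm = unclass(cfg$svm),
                                 n_workers = cfg$n_workers,
                                 kernel_kind = attr(kernel, "kind"),
                                 kernel_params = attr(kernel, "params"),
                                 per_tf_elapsed = timings,
                                 per_tf_ops = ops,
                                 wall_elapsed = proc.time()[["elapsed"]] - t0,
                                 events = events))
}
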