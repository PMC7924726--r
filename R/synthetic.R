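#' Configuration for the synthetic-genome generator
#'
#' Defaults describe a desk-scale genome with planted regulatory structure:
#' 300 genes by 100 samples, 10 TFs with 20 targets each, regulatory effect
#' magnitudes uniform in \[0.5, 1.5\] with balanced signs, residual noise SD
#' 0.5 against unit-variance background genes, a PPI graph enriched for
#' co-regulated pairs (edge probability 0.3 within, 0.01 background), and 60%
#' of true edges revealed to training.
#'
#' @param n_genes,n_samples,n_tfs,targets_per_tf Dimensions of the genome.
#' @param effect_low,effect_high Range of absolute regulatory weights.
#' @param noise_sd Residual SD of target-gene expression.
#' @param p_in Edge probability between genes sharing >= 1 regulator.
#' @param p_out Background edge probability.
#' @param frac_known Fraction of true edges revealed in the regulation
#'   matrix (per TF, rounded to the nearest count).
#' @param with_methylation Also generate a methylation-like feature matrix.
#' @param seed Integer seed; all outputs are bit-reproducible given the
#'   config.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 300L, n_samples = 100L, n_tfs = 10L,
                             targets_per_tf = 20L, effect_low = 0.5,
                             effect_high = 1.5, noise_sd = 0.5, p_in = 0.3,
                             p_out = 0.01, frac_known = 0.6,
                             with_methylation = FALSE, seed = 7L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              n_tfs = as.integer(n_tfs),
              targets_per_tf = as.integer(targets_per_tf),
              effect_low = effect_low, effect_high = effect_high,
              noise_sd = noise_sd, p_in = p_in, p_out = p_out,
              frac_known = frac_known,
              with_methylation = isTRUE(with_methylation),
              seed = as.integer(seed))
  if (cfg$n_genes < 2L || cfg$n_samples < 1L || cfg$n_tfs < 1L) {
    abort("infeasible dimensions")
  }
  if (cfg$targets_per_tf > cfg$n_genes) abort("targets_per_tf exceeds n_genes")
  if (cfg$effect_low <= 0 || cfg$effect_high < cfg$effect_low) {
    abort("need 0 < effect_low <= effect_high")
  }
  if (cfg$noise_sd < 0) abort("noise_sd must be >= 0")
  if (cfg$p_out < 0 || cfg$p_in < cfg$p_out || cfg$p_in > 1) {
    abort("need 0 <= p_out <= p_in <= 1")
  }
  if (cfg$frac_known <= 0 || cfg$frac_known > 1) {
    abort("need 0 < frac_known <= 1")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a seeded synthetic genome with planted regulation
#'
#' Each TF carries a latent activity vector (standard normal across samples)
#' and a seeded uniform draw of target genes. Target expression is the
#' weighted sum of its regulators' activities plus Gaussian noise
#' (`noise_sd`); regulatory weights have magnitude uniform in
#' `[effect_low, effect_high]` and equiprobable sign, reflecting that the
#' classifier is agnostic to activation versus repression. Non-target genes
#' are unit-variance Gaussian noise. The PPI graph links two genes with
#' probability `p_in` when they share a regulator and `p_out` otherwise.
#' Methylation (optional) is `-0.5 * expression` plus unit noise for targets,
#' pure noise otherwise. The regulation matrix reveals a per-TF rounded
#' `frac_known` share of true edges as +1 (with `known_mask` set) and labels
#' everything else -1.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `expression`, `methylation` (or `NULL`), `ppi`
#'   (`gene_graph`), `regulations` (`regulation_matrix`) and `truth` (list:
#'   `true_edges` and `revealed_edges` data frames with columns `tf`, `gene`;
#'   `config`).
#' @export
generate_synthetic <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    gene_ids <- sprintf("g%0*d", nchar(cfg$n_genes), seq_len(cfg$n_genes))
    tf_ids <- sprintf("TF%0*d", nchar(cfg$n_tfs), seq_len(cfg$n_tfs))

    activities <- matrix(rnorm(cfg$n_tfs * cfg$n_samples),
                         cfg$n_tfs, cfg$n_samples,
                         dimnames = list(tf_ids, NULL))
    W <- matrix(0, cfg$n_genes, cfg$n_tfs, dimnames = list(gene_ids, tf_ids))
    for (tf in tf_ids) {
      tg <- sample.int(cfg$n_genes, cfg$targets_per_tf)
      w <- runif(cfg$targets_per_tf, cfg$effect_low, cfg$effect_high) *
        sample(c(-1, 1), cfg$targets_per_tf, replace = TRUE)
      W[tg, tf] <- w
    }
    is_target <- rowSums(W != 0) > 0

    expr <- matrix(rnorm(cfg$n_genes * cfg$n_samples), cfg$n_genes,
                   cfg$n_samples,
                   dimnames = list(gene_ids,
                                   sprintf("s%0*d", nchar(cfg$n_samples),
                                           seq_len(cfg$n_samples))))
    if (any(is_target)) {
      expr[is_target, ] <- W[is_target, , drop = FALSE] %*% activities +
        matrix(rnorm(sum(is_target) * cfg$n_samples, sd = cfg$noise_sd),
               sum(is_target), cfg$n_samples)
    }
    expr <- structure(expr, class = c("feature_matrix", class(expr)))

    # PPI enriched for co-regulated pairs
    share <- tcrossprod(W != 0) > 0
    pair_idx <- which(upper.tri(share), arr.ind = TRUE)
    p <- ifelse(share[pair_idx], cfg$p_in, cfg$p_out)
    hit <- runif(nrow(pair_idx)) < p
    ppi <- gene_graph(data.frame(from = gene_ids[pair_idx[hit, 1]],
                                 to = gene_ids[pair_idx[hit, 2]],
                                 weight = 1, stringsAsFactors = FALSE),
                      nodes = gene_ids)

    meth <- NULL
    if (cfg$with_methylation) {
      meth <- matrix(rnorm(cfg$n_genes * cfg$n_samples), cfg$n_genes,
                     cfg$n_samples, dimnames = dimnames(expr))
      meth[is_target, ] <- -0.5 * expr[is_target, ] +
        matrix(rnorm(sum(is_target) * cfg$n_samples), sum(is_target),
               cfg$n_samples)
      meth <- structure(meth, class = c("feature_matrix", class(meth)))
    }

    true_edges <- do.call(rbind, lapply(tf_ids, function(tf) {
      data.frame(tf = tf, gene = gene_ids[W[, tf] != 0],
                 stringsAsFactors = FALSE)
    }))
    revealed <- do.call(rbind, lapply(tf_ids, function(tf) {
      tg <- gene_ids[W[, tf] != 0]
      n_rev <- round(cfg$frac_known * length(tg))
      data.frame(tf = tf, gene = sort(sample(tg, n_rev)),
                 stringsAsFactors = FALSE)
    }))

    labels <- matrix(-1, cfg$n_genes, cfg$n_tfs,
                     dimnames = list(gene_ids, tf_ids))
    mask <- matrix(FALSE, cfg$n_genes, cfg$n_tfs,
                   dimnames = list(gene_ids, tf_ids))
    idx <- cbind(match(revealed$gene, gene_ids), match(revealed$tf, tf_ids))
    labels[idx] <- 1
    mask[idx] <- TRUE
    R <- regulation_matrix(labels, known_mask = mask)

    list(expression = expr, methylation = meth, ppi = ppi, regulations = R,
         truth = list(true_edges = true_edges, revealed_edges = revealed,
                      config = cfg))
  })
}

#' Regulation matrix encoding the full synthetic truth
#'
#' Labels every true edge +1 and everything else -1; the `known_mask` marks
#' the revealed (training) edges, so [cv_report()] with
#' `exclude_training_positives = TRUE` evaluates recovery of hidden edges
#' only.
#'
#' @param truth The `truth` element returned by [generate_synthetic()].
#' @return A `regulation_matrix`.
#' @export
truth_regulations <- function(truth) {
  cfg <- truth$config
  gene_ids <- sprintf("g%0*d", nchar(cfg$n_genes), seq_len(cfg$n_genes))
  tf_ids <- sprintf("TF%0*d", nchar(cfg$n_tfs), seq_len(cfg$n_tfs))
  labels <- matrix(-1, length(gene_ids), length(tf_ids),
                   dimnames = list(gene_ids, tf_ids))
  labels[cbind(match(truth$true_edges$gene, gene_ids),
               match(truth$true_edges$tf, tf_ids))] <- 1
  mask <- matrix(FALSE, length(gene_ids), length(tf_ids),
                 dimnames = list(gene_ids, tf_ids))
  mask[cbind(match(truth$revealed_edges$gene, gene_ids),
             match(truth$revealed_edges$tf, tf_ids))] <- TRUE
  regulation_matrix(labels, known_mask = mask)
}

#' Full-pipeline recovery experiment on synthetic data
#'
#' Generates a synthetic genome, builds the configured kernels (RBF over
#' expression/methylation, diffusion over PPI), fuses them with uniform
#' weights, infers the decision-score matrix, and evaluates it against the
#' *hidden* true edges (revealed training edges are excluded).
#'
#' @param cfg A [synthetic_config()] (`frac_known < 1` so hidden edges exist).
#' @param inf_cfg An [inference_config()].
#' @param kernels Character subset of `c("expression", "methylation", "ppi")`
#'   selecting the data types to fuse.
#' @param normalize Unit-diagonal normalize each kernel before fusion
#'   (default `TRUE`).
#' @param beta Diffusion time for the PPI kernel.
#' @return List with `mean_auc`, `mean_aupr` (means over TFs of hidden-edge
#'   AUC/AUPR), `report` (the full `eval_report`), `ds` (the score matrix)
#'   and `truth`.
#' @export
recovery_experiment <- function(cfg = synthetic_config(),
                                inf_cfg = inference_config(),
                                kernels = c("expression", "ppi"),
                                normalize = TRUE, beta = 1) {
  if (cfg$frac_known >= 1) abort("frac_known must be < 1: no hidden edges")
  kernels <- match.arg(kernels, c("expression", "methylation", "ppi"),
                       several.ok = TRUE)
  if ("methylation" %in% kernels && !cfg$with_methylation) {
    abort("config has with_methylation = FALSE")
  }
  sim <- generate_synthetic(cfg)
  ks <- list()
  if ("expression" %in% kernels) ks$expression <- rbf_kernel(sim$expression)
  if ("methylation" %in% kernels) ks$methylation <- rbf_kernel(sim$methylation)
  if ("ppi" %in% kernels) ks$ppi <- diffusion_kernel(sim$ppi, beta = beta)
  if (normalize) ks <- lapply(ks, normalize_kernel)
  K <- if (length(ks) > 1L) combine_kernels(ks) else ks[[1]]
  ds <- infer_network(K, sim$regulations, inf_cfg)
  truth_R <- truth_regulations(sim$truth)
  rep <- cv_report(ds, truth_R, threshold = 0,
                   exclude_training_positives = TRUE)
  list(mean_auc = rep$average[["auc"]], mean_aupr = rep$average[["aupr"]],
       report = rep, ds = ds, truth = sim$truth)
}
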