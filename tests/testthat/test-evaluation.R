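test_that("precision/recall/F1 worked examples", {
  expect_equal(unname(pr_f1(c(2, 1, -1, -2), c(1, 1, -1, -1), 0)),
               c(1, 1, 1), ignore_attr = TRUE)
  # TP = 2, FP = 2, FN = 0
  expect_equal(unname(pr_f1(c(1, 1, 1, 1), c(1, 1, -1, -1), 0)),
               c(0.5, 1, 2 / 3), ignore_attr = TRUE)
  # threshold above every score: vacuous precision, recall 0, F1 0
  r <- pr_f1(c(0.2, 0.1), c(1, -1), threshold = 5)
  expect_equal(unname(r), c(1, 0, 0), ignore_attr = TRUE)
  expect_true(attr(r, "vacuous"))
  expect_error(pr_f1(c(1, 2), c(-1, -1), 0), "positive")
})

test_that("pr_f1 is invariant under strictly monotone score transforms", {
  for (s in 1:10) {
    scores <- withr::with_seed(s, rnorm(40))
    labels <- withr::with_seed(s + 50, sample(c(-1, 1), 40, replace = TRUE,
                                              prob = c(0.7, 0.3)))
    if (!any(labels == 1)) labels[1] <- 1
    th <- withr::with_seed(s + 99, rnorm(1))
    f <- function(x) exp(2 * x) + x  # strictly increasing
    expect_equal(pr_f1(scores, labels, th), pr_f1(f(scores), labels, f(th)),
                 ignore_attr = TRUE)
  }
})

test_that("AUC equals brute-force pairwise concordance, including ties", {
  expect_equal(auc(c(3, 2, 1), c(1, 1, -1)), 1.0)
  expect_equal(auc(c(0.9, 0.8, 0.3), c(1, -1, 1)), 0.5)
  expect_equal(auc(rep(1, 6), c(1, 1, -1, -1, -1, 1)), 0.5)
  expect_error(auc(c(1, 2), c(1, 1)), "both classes")
  for (s in 1:100) {
    n <- withr::with_seed(s, sample(5:200, 1))
    scores <- withr::with_seed(s + 1000, round(rnorm(n), 1))  # force ties
    labels <- withr::with_seed(s + 2000, sample(c(-1, 1), n, replace = TRUE))
    if (length(unique(labels)) < 2) labels[1:2] <- c(-1, 1)
    expect_equal(auc(scores, labels), brute_auc(scores, labels))
  }
})

test_that("AUPR equals a brute-force threshold sweep", {
  expect_equal(aupr(c(3, 2, 1), c(1, 1, -1)), 1.0)
  expect_equal(aupr(c(0.9, 0.8, 0.3), c(1, -1, 1)), 1 * 0.5 + (2 / 3) * 0.5)
  for (s in 1:100) {
    n <- withr::with_seed(s, sample(5:120, 1))
    scores <- withr::with_seed(s + 1000, round(rnorm(n), 1))
    labels <- withr::with_seed(s + 2000, sample(c(-1, 1), n, replace = TRUE))
    if (length(unique(labels)) < 2) labels[1:2] <- c(-1, 1)
    expect_equal(aupr(scores, labels), brute_aupr(scores, labels),
                 tolerance = 1e-12)
  }
  # random scores: AUPR converges to the positive fraction
  big <- withr::with_seed(77, list(s = rnorm(20000),
                                   y = sample(c(-1, 1), 20000, replace = TRUE,
                                              prob = c(0.8, 0.2))))
  expect_lt(abs(aupr(big$s, big$y) - mean(big$y == 1)), 0.02)
})

test_that("cv_report averages per-TF metrics over evaluable columns", {
  genes <- paste0("g", 1:4)
  R <- regulation_matrix(matrix(c(1, 1, -1, -1, 1, -1, -1, -1), 4, 2,
                                dimnames = list(genes, c("TF1", "TF2"))))
  # DS equal to the labels -> perfect everything
  ds <- score_matrix(unclass(R))
  rep <- cv_report(ds, R)
  expect_equal(unname(rep$average[c("precision", "recall", "f1", "auc")]),
               rep(1, 4))

  # two TFs with F1 = 1 and 1/3 average to 2/3
  s2 <- unclass(R)
  s2[, 2] <- c(-1, 1, 1, 1)  # TP=1, FP=3 at threshold 0 -> P=0.25, R=1, F1=0.4
  pr <- pr_f1(s2[, 2], unclass(R)[, 2])
  ds2 <- score_matrix(s2)
  rep2 <- cv_report(ds2, R)
  expect_equal(rep2$average[["f1"]], mean(c(1, pr[["f1"]])))

  # single evaluable column reduces to that column's metrics
  ds3 <- score_matrix(s2, status = c(TF1 = "skipped", TF2 = "ok"))
  rep3 <- cv_report(ds3, R)
  expect_equal(rep3$n_evaluated, 1L)
  expect_equal(rep3$average[["f1"]], pr[["f1"]])
  expect_equal(rep3$n_excluded, 1L)

  ds4 <- score_matrix(s2, status = c(TF1 = "skipped", TF2 = "failed"))
  expect_error(cv_report(ds4, R), "evaluable")
})

test_that("excluding revealed positives evaluates hidden-edge recovery only", {
  genes <- paste0("g", 1:6)
  labels <- matrix(c(1, 1, 1, -1, -1, -1), 6, 1,
                   dimnames = list(genes, "TF1"))
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE), 6, 1,
                 dimnames = list(genes, "TF1"))
  R <- regulation_matrix(labels, known_mask = mask)
  scores <- matrix(c(10, 5, -2, 1, -1, -3), 6, 1,
                   dimnames = list(genes, "TF1"))
  ds <- score_matrix(scores)
  full <- cv_report(ds, R)
  hidden <- cv_report(ds, R, exclude_training_positives = TRUE)
  # g1 (revealed, top score) inflates the full AUC; hidden drops it
  expect_equal(full$average[["auc"]], auc(scores[, 1], labels[, 1]))
  expect_equal(hidden$average[["auc"]], auc(scores[-1, 1], labels[-1, 1]))
  expect_lt(hidden$average[["auc"]], full$average[["auc"]])
})

test_that("speedup/efficiency/redundancy/quality satisfy their identities", {
  pm <- perf_metrics(T1 = 80, Tj = 10, j = 8)
  expect_equal(pm, list(S = 8, E = 1, R = 1, Q = 8))
  pm2 <- perf_metrics(T1 = 100, Tj = 25, j = 8, O1 = 1, Oj = 1.2)
  expect_equal(pm2$S, 4)
  expect_equal(pm2$E, 0.5)
  expect_equal(pm2$R, 1.2)
  expect_equal(pm2$Q, 5 / 3)
  pm3 <- perf_metrics(T1 = 7, Tj = 7, j = 1)
  expect_equal(unlist(pm3), c(S = 1, E = 1, R = 1, Q = 1))
  expect_error(perf_metrics(T1 = -1, Tj = 1, j = 1), "positive")

  for (s in 1:25) {
    v <- withr::with_seed(s, runif(5, 0.1, 100))
    pm <- perf_metrics(v[1], v[2], ceiling(v[3]), v[4], v[5])
    expect_equal(pm$E, pm$S / ceiling(v[3]))
    expect_equal(pm$Q * pm$R, pm$S * pm$E)
  }
})
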