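test_that("feature matrices survive a write/read round trip", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t0.5\t1.25", "g2\t-1\t0", "g3\t2\t3"), tf)
  m <- read_feature_matrix(tf)
  expect_equal(dim(m), c(3L, 2L))
  expect_identical(rownames(m), c("g1", "g2", "g3"))
  expect_identical(colnames(m), c("s1", "s2"))
  expect_equal(m["g1", "s2"], 1.25)

  x <- withr::with_seed(42, matrix(rnorm(50), 10, 5,
                                   dimnames = list(sprintf("g%02d", 1:10),
                                                   sprintf("s%d", 1:5))))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(x, out)
  back <- read_feature_matrix(out)
  expect_identical(rownames(back), rownames(x))
  expect_lt(max(abs(back - x)), 1e-12)
})

test_that("malformed feature matrices are rejected with informative errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1", "g1\t1", "g1\t2"), tf)
  expect_error(read_feature_matrix(tf), "g1")

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\tfoo"), tf2)
  expect_error(read_feature_matrix(tf2), "g1.*s2")
})

test_that("missing values follow the configured policy", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\tNA", "g2\t2\t3"), tf)
  expect_warning(m <- read_feature_matrix(tf), "g1")
  expect_identical(rownames(m), "g2")
  expect_error(read_feature_matrix(tf, na_action = "error"), "g1")
  m2 <- suppressWarnings(read_feature_matrix(tf, na_action = "impute"))
  expect_equal(m2["g1", "s2"], 1)  # row mean
})

test_that("edge-list regulations expand to +1/-1 over the declared universe", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("TF1\tg2\t1", "TF1\tg3\t1"), tf)
  R <- read_regulations(tf, gene_ids = paste0("g", 1:4))
  expect_equal(unname(unclass(R)[, "TF1"]), c(-1, 1, 1, -1))
  expect_equal(unname(attr(R, "known_mask")[, "TF1"]), c(FALSE, TRUE, TRUE, FALSE))

  # declared TF absent from file -> all -1 column, flagged zero-positive
  R2 <- read_regulations(tf, gene_ids = paste0("g", 1:4),
                         tf_ids = c("TF1", "TF2"))
  expect_true(all(unclass(R2)[, "TF2"] == -1))
  expect_true(attr(R2, "zero_positive")[["TF2"]])
  expect_false(attr(R2, "zero_positive")[["TF1"]])

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("TF1\tg1\t2", bad)
  expect_error(read_regulations(bad, gene_ids = "g1"), "indicator")
})

test_that("matrix-format regulations agree with the equivalent edge list", {
  genes <- paste0("g", 1:5)
  el <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("TF1\tg1\t1", "TF2\tg4\t1", "TF2\tg5\t1"), el)
  R_el <- read_regulations(el, gene_ids = genes)

  mat <- withr::local_tempfile(fileext = ".tsv")
  lab <- unclass(R_el)
  write_feature_matrix(lab, mat)
  R_m <- read_regulations(mat, format = "matrix")
  expect_equal(unclass(R_m), lab, ignore_attr = TRUE)
  expect_identical(dimnames(R_m), dimnames(R_el))

  # a 0 entry is invalid unless unknown mode is on
  lab0 <- lab; lab0[1, 1] <- 0
  write_feature_matrix(lab0, mat)
  expect_error(read_regulations(mat, format = "matrix"), "unknown")
  R_u <- read_regulations(mat, format = "matrix", allow_unknown = TRUE)
  expect_equal(unclass(R_u)[1, 1], -1, ignore_attr = TRUE)
  expect_false(attr(R_u, "known_mask")[1, 1])
})

test_that("align_universe intersects gene sets in canonical order and reports drops", {
  expr <- matrix(rnorm(6), 3, 2,
                 dimnames = list(c("g3", "g1", "g2"), c("s1", "s2")))
  class(expr) <- c("feature_matrix", class(expr))
  ppi <- gene_graph(data.frame(from = "g2", to = "g3"),
                    nodes = c("g2", "g3", "g4"))
  al <- align_universe(list(expression = expr, ppi = ppi))
  expect_identical(al$universe, c("g2", "g3"))
  expect_identical(al$dropped$expression, "g1")
  expect_identical(al$dropped$ppi, "g4")
  expect_identical(rownames(al$aligned$expression), c("g2", "g3"))
  expect_identical(al$aligned$ppi$nodes, c("g2", "g3"))

  # idempotence and single-input identity
  al2 <- align_universe(al$aligned)
  expect_identical(al2$aligned, al$aligned)
  single <- align_universe(list(expression = expr))
  expect_equal(sort(rownames(single$aligned$expression)),
               sort(rownames(expr)))

  disjoint <- matrix(1, 1, 1, dimnames = list("zz", "s1"))
  expect_error(align_universe(list(a = expr, b = disjoint)), "intersection")
})

test_that("ranked network output sorts by score with lexicographic tie-breaks", {
  ds <- score_matrix(matrix(c(0.5, 0.9, 0.5), 3, 1,
                            dimnames = list(c("a", "b", "c"), "TF1")))
  out <- withr::local_tempfile(fileext = ".tsv")
  df <- write_network(ds, out)
  expect_identical(df$gene, c("b", "a", "c"))

  df1 <- write_network(ds, out, top_k = 1)
  expect_identical(df1$gene, "b")
  expect_error(write_network(ds, out, top_k = 0), "top_k")

  # round trip preserves ordering
  back <- read_network(out)
  expect_identical(back$gene, df1$gene)

  # known training positives can be excluded
  R <- regulation_matrix(matrix(c(1, -1, -1), 3, 1,
                                dimnames = list(c("a", "b", "c"), "TF1")))
  df_ex <- write_network(ds, out, regulations = R, known_positives = "exclude")
  expect_false("a" %in% df_ex$gene)
})

test_that("score matrices round-trip through TSV including skipped columns", {
  m <- matrix(rnorm(8), 4, 2,
              dimnames = list(paste0("g", 1:4), c("TF1", "TF2")))
  m[, 2] <- NA
  ds <- score_matrix(m, status = c(TF1 = "ok", TF2 = "skipped"))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_score_matrix(ds, out)
  back <- read_score_matrix(out)
  expect_lt(max(abs(back[, 1] - m[, 1])), 1e-12)
  expect_identical(unname(attr(back, "status")), c("ok", "skipped"))
})
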