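#' Read a genes-by-samples feature matrix
#'
#' Reads an expression (or methylation) matrix from delimited text. The first
#' column holds gene identifiers and the header row holds sample identifiers;
#' all remaining cells must be numeric.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param na_action What to do with rows containing missing values:
#'   `"drop"` (default) removes them with a warning, `"impute"` replaces each
#'   missing entry by the row mean, `"error"` refuses the file.
#' @return A numeric matrix with gene identifiers as `rownames` and sample
#'   identifiers as `colnames`, of class `feature_matrix`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t0.5\t1.2", "g2\t-1\t0"), tf)
#' read_feature_matrix(tf)
#' @export
read_feature_matrix <- function(path, dialect = c("tsv", "csv"),
                                na_action = c("drop", "impute", "error")) {
  dialect <- match.arg(dialect)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) abort("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) abort("feature matrix needs >= 1 sample column")
  gene_ids <- raw[[1]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) abort("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids in header")

  vals <- matrix(NA_real_, nrow(raw), length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  na_strings <- c("", "NA", "na", "NaN", "nan", "NULL")
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & !(trimws(col) %in% na_strings))
    if (length(bad)) {
      abort(sprintf("non-numeric value %s at gene '%s', sample '%s'",
                    dQuote(col[bad[1]]), gene_ids[bad[1]], sample_ids[j]))
    }
    vals[, j] <- num
  }

  incomplete <- which(rowSums(is.na(vals)) > 0L)
  if (length(incomplete)) {
    if (na_action == "error") {
      abort("missing values in rows: ", paste(gene_ids[incomplete], collapse = ", "))
    } else if (na_action == "drop") {
      warning("dropping ", length(incomplete), " row(s) with missing values: ",
              paste(gene_ids[incomplete], collapse = ", "), call. = FALSE)
      vals <- vals[-incomplete, , drop = FALSE]
    } else {
      for (i in incomplete) {
        m <- mean(vals[i, ], na.rm = TRUE)
        if (is.nan(m)) abort("row '", gene_ids[i], "' is entirely missing")
        vals[i, is.na(vals[i, ])] <- m
      }
    }
  }
  if (nrow(vals) == 0L) abort("no complete rows left in ", path)
  structure(vals, class = c("feature_matrix", class(vals)))
}

#' Write a feature matrix to delimited text
#'
#' Inverse of [read_feature_matrix()]; values survive a round trip to full
#' double precision.
#'
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_feature_matrix <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  fmt <- apply(unclass(x), 2, function(col) formatC(col, digits = 17, format = "g"))
  fmt[is.na(unclass(x))] <- "NA"
  df <- data.frame(gene = rownames(x), fmt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(x))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an undirected gene graph from an edge list
#'
#' @param edges Data frame with columns `from`, `to` and optionally `weight`
#'   (default 1). Self-loops are rejected; duplicate undirected edges are
#'   collapsed by keeping the first weight.
#' @param nodes Optional full node set (isolated nodes allowed); defaults to
#'   the genes present in `edges`.
#' @return An object of class `gene_graph`: a list with `nodes` (character)
#'   and `edges` (data frame `from`, `to`, `weight`).
#' @export
gene_graph <- function(edges, nodes = NULL) {
  if (is.null(edges)) edges <- data.frame(from = character(), to = character())
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) == 2L) edges$weight <- rep(1, nrow(edges))
  if (ncol(edges) != 3L) abort("edge list needs 2 or 3 columns")
  names(edges) <- c("from", "to", "weight")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (any(edges$from == edges$to)) abort("self-loops are not allowed")
  if (any(is.na(edges$weight)) || any(edges$weight < 0)) {
    abort("edge weights must be non-negative numbers")
  }
  # canonicalize undirected pairs, drop duplicates
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  edges <- data.frame(from = a[keep], to = b[keep], weight = edges$weight[keep],
                      stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- canonical_order(unique(c(edges$from, edges$to)))
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("duplicate node ids")
  missing <- setdiff(unique(c(edges$from, edges$to)), nodes)
  if (length(missing)) abort("edges reference unknown nodes: ",
                             paste(missing, collapse = ", "))
  structure(list(nodes = nodes, edges = edges), class = "gene_graph")
}

#' Read a protein-protein interaction graph from a 2/3-column edge list
#'
#' @param path Path to a whitespace/tab-delimited file with columns
#'   `gene_a gene_b [weight]` and no header (a header line is auto-detected
#'   and skipped when its third field is non-numeric).
#' @param nodes Optional node universe; see [gene_graph()].
#' @return A `gene_graph`.
#' @export
read_ppi <- function(path, nodes = NULL) {
  if (!file.exists(path)) abort("file not found: ", path)
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", comment.char = "#")
  if (!ncol(df) %in% c(2L, 3L)) abort("PPI edge list needs 2 or 3 columns")
  if (ncol(df) == 3L && nrow(df) > 0 &&
      is.na(suppressWarnings(as.numeric(df[1, 3])))) {
    df <- df[-1, , drop = FALSE]  # header row
  }
  if (ncol(df) == 3L) df[[3]] <- as.numeric(df[[3]])
  gene_graph(df, nodes = nodes)
}

#' Write a gene graph as a 3-column edge list
#' @param g A `gene_graph`.
#' @param path Output path.
#' @export
write_ppi <- function(g, path) {
  write.table(g$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a regulation label matrix
#'
#' @param labels genes x TFs matrix over \{+1, -1\} with gene rownames and TF
#'   colnames (0 allowed only when it denotes "unknown", see `allow_unknown`).
#' @param known_mask Optional logical matrix of the same shape marking entries
#'   backed by prior knowledge.
#' @param allow_unknown If `TRUE`, 0 entries are recoded to -1 with
#'   `known_mask` set to `FALSE` there (evaluation can then ignore them).
#' @return A `regulation_matrix`: the label matrix with a `known_mask`
#'   attribute.
#' @export
regulation_matrix <- function(labels, known_mask = NULL, allow_unknown = FALSE) {
  labels <- as.matrix(labels)
  if (is.null(rownames(labels)) || is.null(colnames(labels))) {
    abort("regulation matrix needs gene rownames and TF colnames")
  }
  storage.mode(labels) <- "double"
  if (is.null(known_mask)) known_mask <- matrix(TRUE, nrow(labels), ncol(labels))
  zeros <- labels == 0
  if (any(zeros)) {
    if (!allow_unknown) abort("regulation labels must be +1/-1 (found 0); ",
                              "set allow_unknown = TRUE to treat 0 as unknown")
    labels[zeros] <- -1
    known_mask[zeros] <- FALSE
  }
  if (!all(labels %in% c(-1, 1))) abort("regulation labels must be +1/-1")
  dimnames(known_mask) <- dimnames(labels)
  zero_pos <- colSums(labels == 1) == 0L
  structure(labels, known_mask = known_mask, zero_positive = zero_pos,
            class = c("regulation_matrix", class(labels)))
}

#' Read known TF-gene regulations
#'
#' Two on-disk forms are supported. `format = "edge_list"` expects the
#' 3-column gold-standard layout `TF  target_gene  1`; listed pairs become +1
#' over the declared gene universe and everything else -1 (the label scheme
#' used for per-TF classification). `format = "matrix"` expects a genes x TFs
#' matrix of +1/-1 with a header of TF ids and gene ids in the first column.
#'
#' @param path Path to the file (tab-delimited).
#' @param format `"edge_list"` or `"matrix"`.
#' @param gene_ids Declared gene universe (required for `edge_list`).
#' @param tf_ids Optional declared TF list; defaults to the TFs present in
#'   the file. TFs declared but absent from the file yield all -1 columns,
#'   flagged zero-positive.
#' @param allow_unknown Matrix format only: treat 0 entries as unknown rather
#'   than erroring (see [regulation_matrix()]).
#' @return A `regulation_matrix`. The `known_mask` attribute is `TRUE` at
#'   listed pairs for edge lists, all `TRUE` for matrix input (minus unknowns).
#' @export
read_regulations <- function(path, format = c("edge_list", "matrix"),
                             gene_ids = NULL, tf_ids = NULL,
                             allow_unknown = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort("file not found: ", path)
  if (format == "matrix") {
    m <- read_feature_matrix(path, dialect = "tsv", na_action = "error")
    return(regulation_matrix(unclass(m), allow_unknown = allow_unknown))
  }
  if (is.null(gene_ids)) abort("edge_list format needs a declared gene universe")
  df <- tryCatch(
    read.table(path, header = FALSE, stringsAsFactors = FALSE,
               colClasses = c("character", "character", "numeric")),
    error = function(e) data.frame(V1 = character(), V2 = character(),
                                   V3 = numeric())
  )
  if (nrow(df) && ncol(df) != 3L) abort("gold-standard edge list needs 3 columns")
  edge_list_to_regulations(df, gene_ids = gene_ids, tf_ids = tf_ids)
}

# shared core: 3-column (tf, gene, indicator) data frame -> regulation_matrix
edge_list_to_regulations <- function(df, gene_ids, tf_ids = NULL) {
  if (nrow(df)) {
    names(df) <- c("tf", "gene", "ind")
    if (any(df$ind != 1)) abort("edge-list indicator must be 1")
    unknown <- setdiff(df$gene, gene_ids)
    if (length(unknown)) abort("edge list targets outside the gene universe: ",
                               paste(unknown, collapse = ", "))
  } else {
    df <- data.frame(tf = character(), gene = character(), ind = numeric())
  }
  if (is.null(tf_ids)) tf_ids <- canonical_order(unique(df$tf))
  if (!length(tf_ids)) abort("no TFs declared or present in the edge list")
  extra <- setdiff(df$tf, tf_ids)
  if (length(extra)) abort("edge list TFs outside the declared TF list: ",
                           paste(extra, collapse = ", "))
  labels <- matrix(-1, length(gene_ids), length(tf_ids),
                   dimnames = list(gene_ids, tf_ids))
  mask <- matrix(FALSE, length(gene_ids), length(tf_ids),
                 dimnames = list(gene_ids, tf_ids))
  if (nrow(df)) {
    idx <- cbind(match(df$gene, gene_ids), match(df$tf, tf_ids))
    labels[idx] <- 1
    mask[idx] <- TRUE
    solo <- vapply(tf_ids, function(tf) {
      tg <- df$gene[df$tf == tf]
      length(tg) == 1L && tg == tf
    }, logical(1))
    if (any(solo)) warning("TF(s) whose only listed target is itself: ",
                           paste(tf_ids[solo], collapse = ", "), call. = FALSE)
  }
  regulation_matrix(labels, known_mask = mask)
}

#' Align heterogeneous inputs onto a common gene universe
#'
#' Restricts every input (feature matrices, gene graphs, regulation matrices,
#' kernel matrices) to the intersection of their gene identifier sets, in one
#' canonical (lexicographic, C collation) order. Matching is exact-string and
#' case-sensitive.
#'
#' @param inputs Named list of `feature_matrix` / `gene_graph` /
#'   `regulation_matrix` / `kernel_matrix` objects (plain matrices with gene
#'   rownames also work).
#' @return A list with `aligned` (the restricted inputs, same names),
#'   `universe` (the shared gene order) and `dropped` (per-input character
#'   vectors of removed gene ids).
#' @export
align_universe <- function(inputs) {
  if (!length(inputs)) abort("need at least one input")
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    names(inputs) <- paste0("input", seq_along(inputs))
  }
  ids_of <- function(x) {
    if (inherits(x, "gene_graph")) x$nodes else rownames(x)
  }
  all_ids <- lapply(inputs, ids_of)
  universe <- Reduce(intersect, all_ids)
  if (!length(universe)) abort("gene universes have an empty intersection")
  universe <- canonical_order(universe)
  restrict <- function(x) {
    if (inherits(x, "gene_graph")) {
      keep <- x$edges$from %in% universe & x$edges$to %in% universe
      g <- gene_graph(x$edges[keep, , drop = FALSE], nodes = universe)
      return(g)
    }
    if (inherits(x, "kernel_matrix")) {
      idx <- match(universe, rownames(x))
      out <- x[idx, idx, drop = FALSE]
      attributes(out) <- c(attributes(out),
                           attributes(x)[c("kind", "params")])
      class(out) <- class(x)
      return(out)
    }
    out <- x[match(universe, rownames(x)), , drop = FALSE]
    class(out) <- class(x)
    if (inherits(x, "regulation_matrix")) {
      km <- attr(x, "known_mask")[match(universe, rownames(x)), , drop = FALSE]
      out <- regulation_matrix(unclass(out), known_mask = km)
    }
    out
  }
  aligned <- lapply(inputs, restrict)
  dropped <- lapply(all_ids, function(ids) setdiff(ids, universe))
  list(aligned = aligned, universe = universe, dropped = dropped)
}

#' Assemble a decision-score matrix
#'
#' @param scores genes x TFs numeric matrix of SVM decision scores (gene
#'   rownames, TF colnames). Columns for skipped/failed TFs hold `NA`.
#' @param status Named character vector per TF: `"ok"`, `"skipped"`,
#'   `"all-data"` or `"failed"`.
#' @param provenance List recording how the scores were produced (seed, fold
#'   plan, SVM parameters, timings).
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(scores, status = NULL, provenance = list()) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    abort("score matrix needs gene rownames and TF colnames")
  }
  if (is.null(status)) {
    status <- setNames(rep("ok", ncol(scores)), colnames(scores))
  }
  if (!all(colnames(scores) %in% names(status))) {
    abort("status must cover every TF column")
  }
  structure(scores, status = status[colnames(scores)], provenance = provenance,
            class = c("score_matrix", class(scores)))
}

#' @export
print.score_matrix <- function(x, ...) {
  st <- attr(x, "status")
  cat(sprintf("score_matrix: %d genes x %d TFs (%d ok, %d skipped/failed)\n",
              nrow(x), ncol(x), sum(st == "ok"), sum(st != "ok")))
  invisible(x)
}

#' Write the full decision-score matrix as TSV
#' @param ds A `score_matrix`.
#' @param path Output path.
#' @export
write_score_matrix <- function(ds, path) {
  write_feature_matrix(ds, path)
}

#' Read a decision-score matrix written by [write_score_matrix()]
#' @param path Path to the TSV file.
#' @return A `score_matrix` (columns that are entirely `NA` are flagged
#'   `"skipped"`).
#' @export
read_score_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  st <- ifelse(colSums(is.na(m)) == nrow(m), "skipped", "ok")
  score_matrix(m, status = setNames(st, colnames(m)))
}

#' Write the inferred network as a ranked edge list
#'
#' Rows `(tf, gene, score)` are sorted by descending score with ties broken
#' lexicographically by `(tf, gene)`. Genes that are known training positives
#' of a TF (per the regulation matrix's `known_mask`) can be excluded or
#' marked.
#'
#' @param ds A `score_matrix`.
#' @param path Output path (TSV with header).
#' @param top_k Optional positive integer: keep only the `top_k` best edges.
#' @param regulations Optional `regulation_matrix` identifying known positives.
#' @param known_positives `"keep"`, `"exclude"` or `"mark"` (adds an
#'   `is_known` column). Only used when `regulations` is supplied.
#' @return Invisibly, the written data frame.
#' @export
write_network <- function(ds, path, top_k = NULL, regulations = NULL,
                          known_positives = c("keep", "exclude", "mark")) {
  known_positives <- match.arg(known_positives)
  if (!is.null(top_k) && (!is.numeric(top_k) || top_k <= 0)) {
    abort("top_k must be a positive integer")
  }
  st <- attr(ds, "status")
  keep_tf <- names(st)[st %in% c("ok", "all-data")]
  df <- data.frame(
    tf = rep(keep_tf, each = nrow(ds)),
    gene = rep(rownames(ds), times = length(keep_tf)),
    score = as.vector(ds[, keep_tf, drop = FALSE]),
    stringsAsFactors = FALSE
  )
  if (!is.null(regulations) && known_positives != "keep") {
    km <- attr(regulations, "known_mask")
    pos <- unclass(regulations) == 1 & km
    is_known <- mapply(function(tf, g) {
      tf %in% colnames(pos) && g %in% rownames(pos) && pos[g, tf]
    }, df$tf, df$gene)
    if (known_positives == "exclude") df <- df[!is_known, , drop = FALSE]
    else df$is_known <- as.logical(is_known)
  }
  ord <- order(-df$score, df$tf, df$gene, method = "radix")
  df <- df[ord, , drop = FALSE]
  if (!is.null(top_k)) df <- utils::head(df, as.integer(top_k))
  out <- df
  out$score <- formatC(out$score, digits = 17, format = "g")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a ranked edge list written by [write_network()]
#' @param path Path to the TSV file.
#' @return Data frame with columns `tf`, `gene`, `score` (and `is_known` if
#'   present), in file order.
#' @export
read_network <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
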