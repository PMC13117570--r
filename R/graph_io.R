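#' Gene interaction graphs
#'
#' A `gene_graph` holds the undirected gene–gene interaction network as an
#' ordered symbol vector, a 0-diagonal symmetric sparse 0/1 adjacency matrix
#' `A`, and (after [normalize_adjacency()]) the self-looped symmetrically
#' normalized propagation operator \eqn{\hat D^{-1/2}(A+I)\hat D^{-1/2}}
#' used by every graph-convolution layer.
#'
#' @param symbols character vector of unique gene identifiers.
#' @param edges two-column integer matrix of 1-based node index pairs;
#'   duplicates and self-pairs are removed.
#' @return An object of class `gene_graph` with fields `symbols`, `edges`
#'   (canonical i < j), `adjacency` and (once computed) `norm_adjacency`.
#' @export
gene_graph <- function(symbols, edges) {
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) stop("gene symbols must be unique")
  n <- length(symbols)
  if (n == 0L) stop("empty graph: no nodes")
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0) {
    if (any(edges < 1L | edges > n)) stop("edge endpoint outside symbol table")
    edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  if (nrow(edges) > 0) {
    A <- Matrix::sparseMatrix(i = c(edges[, 1L], edges[, 2L]),
                              j = c(edges[, 2L], edges[, 1L]),
                              x = 1, dims = c(n, n))
  } else {
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  }
  structure(list(symbols = symbols, edges = edges, adjacency = A,
                 norm_adjacency = NULL),
            class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("gene_graph: %d nodes, %d edges%s\n",
              length(x$symbols), nrow(x$edges),
              if (is.null(x$norm_adjacency)) "" else " (normalized)"))
  invisible(x)
}

clean_symbol <- function(x) toupper(trimws(x))

#' Read an undirected edge list
#'
#' Parses a whitespace/tab-delimited edge list of gene symbols with an
#' optional third numeric confidence column (`#` comment lines skipped).
#' Symbols are upper-cased and whitespace-stripped; duplicate edges and
#' self-edges are dropped.
#'
#' @param path file path.
#' @param min_confidence optional score threshold; rows with a confidence
#'   below it are excluded (nodes appearing only in excluded rows are
#'   dropped too).
#' @return A [gene_graph()] with the normalized adjacency already attached.
#' @export
read_edge_list <- function(path, min_confidence = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("empty edge list: ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  bad <- which(nf < 2L)
  if (length(bad)) {
    stop(sprintf("malformed edge-list row at line %d: need two symbols",
                 lineno[bad[1L]]))
  }
  a <- clean_symbol(vapply(parts, `[[`, "", 1L))
  b <- clean_symbol(vapply(parts, `[[`, "", 2L))
  if (any(!nzchar(a) | !nzchar(b))) {
    stop("malformed edge-list row: empty symbol field")
  }
  if (!is.null(min_confidence)) {
    sc <- rep(NA_real_, length(a))
    has3 <- nf >= 3L
    sc[has3] <- suppressWarnings(
      as.numeric(vapply(parts[has3], `[[`, "", 3L)))
    keep_row <- !is.na(sc) & sc >= min_confidence
    a <- a[keep_row]; b <- b[keep_row]
    if (length(a) == 0L) stop("empty graph after confidence filtering")
  }
  symbols <- sort(unique(c(a, b)))
  idx <- stats::setNames(seq_along(symbols), symbols)
  g <- gene_graph(symbols, cbind(idx[a], idx[b]))
  normalize_adjacency(g)
}

#' Write a gene graph back to an edge-list TSV
#' @param graph a [gene_graph()].
#' @param path output file.
#' @export
write_edge_list <- function(graph, path) {
  e <- graph$edges
  writeLines(paste(graph$symbols[e[, 1L]], graph$symbols[e[, 2L]], sep = "\t"),
             path)
  invisible(path)
}

#' Attach the symmetrically normalized self-looped adjacency operator
#'
#' Computes \eqn{\hat A = A + I}, \eqn{\hat D_{ii} = \sum_j \hat A_{ij}} and
#' stores \eqn{\hat D^{-1/2}\hat A\hat D^{-1/2}} sparsely. Isolated nodes
#' get the single entry 1 (their self-loop).
#'
#' @param graph a [gene_graph()].
#' @return The graph with `norm_adjacency` set.
#' @export
normalize_adjacency <- function(graph) {
  A <- graph$adjacency
  v <- A@x
  if (length(v) && (any(v < 0) || any(v != 1))) {
    stop("adjacency must be binary 0/1")
  }
  graph$norm_adjacency <- normalize_operator(A)
  graph
}

# D^-1/2 (A+I) D^-1/2 for an arbitrary symmetric 0/1 sparse A
normalize_operator <- function(A) {
  n <- nrow(A)
  Ahat <- A + Matrix::Diagonal(n)
  dhat <- Matrix::rowSums(Ahat)
  dinv <- 1 / sqrt(dhat)
  D <- Matrix::Diagonal(n, dinv)
  methods::as(D %*% Ahat %*% D, "generalMatrix")
}

#' Omics feature matrices
#'
#' An N x 64 per-gene feature matrix partitioned into four contiguous
#' 16-column blocks in fixed order: mutation, expression, methylation,
#' copy-number alteration. Rows follow the graph's symbol order.
#'
#' @param values numeric matrix with 64 columns.
#' @param standardized logical flag.
#' @return An `omics_matrix` object.
#' @export
omics_matrix <- function(values, standardized = FALSE) {
  values <- as.matrix(values)
  if (ncol(values) != 64L) stop("omics matrix must have 4 x 16 = 64 columns")
  storage.mode(values) <- "double"
  structure(list(values = values,
                 block_slices = omics_block_slices(),
                 standardized = standardized),
            class = "omics_matrix")
}

#' Column ranges of the four omics blocks
#' @return Named list of integer column index vectors.
#' @export
omics_block_slices <- function() {
  list(mutation    = 1:16,
       expression  = 17:32,
       methylation = 33:48,
       cnv         = 49:64)
}

#' Read a per-gene feature table (TSV/CSV)
#'
#' First column `gene`, then 64 numeric columns ordered mutation,
#' expression, methylation, CNV (16 each).
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.csv` vs tab-delimited otherwise).
#' @return data.frame with cleaned `gene` symbols and numeric columns.
#' @export
read_feature_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tb <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tb) != 65L) {
    stop("feature table must have a gene column plus 64 numeric columns; got ",
         ncol(tb))
  }
  tb[[1L]] <- clean_symbol(tb[[1L]])
  names(tb)[1L] <- "gene"
  tb
}

#' Align a feature table to a graph's node order
#'
#' Rows are reordered to the graph's symbol order. Genes absent from the
#' table are either zero-filled (`missing_policy = "zero"`) or removed from
#' the graph together with their incident edges (`"drop"`).
#'
#' @param graph a [gene_graph()].
#' @param table data.frame from [read_feature_table()].
#' @param missing_policy `"zero"` (default) or `"drop"`.
#' @return list with elements `graph` (possibly reduced) and `omics`
#'   (an [omics_matrix()]).
#' @export
align_features <- function(graph, table, missing_policy = c("zero", "drop")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(ncol(table) == 65L)
  tab_sym <- clean_symbol(table[[1L]])
  feat <- as.matrix(table[, -1L, drop = FALSE])
  storage.mode(feat) <- "double"
  hit <- match(graph$symbols, tab_sym)
  n_match <- sum(!is.na(hit))
  if (n_match < 0.5 * length(graph$symbols)) {
    stop(sprintf(paste0("only %d of %d graph symbols found in the feature ",
                        "table; likely an identifier-scheme mismatch"),
                 n_match, length(graph$symbols)))
  }
  message(sprintf("align_features: matched %d/%d symbols (%d missing)",
                  n_match, length(graph$symbols),
                  length(graph$symbols) - n_match))
  if (missing_policy == "drop" && n_match < length(graph$symbols)) {
    keep <- which(!is.na(hit))
    graph <- induced_gene_graph(graph, keep)
    hit <- hit[keep]
  }
  X <- matrix(0, length(graph$symbols), 64L)
  ok <- !is.na(hit)
  X[ok, ] <- feat[hit[ok], , drop = FALSE]
  list(graph = normalize_adjacency(graph), omics = omics_matrix(X))
}

# Subgraph induced by node indices `keep` (renumbered in order of `keep`).
induced_gene_graph <- function(graph, keep) {
  map <- integer(length(graph$symbols))
  map[keep] <- seq_along(keep)
  e <- graph$edges
  inside <- map[e[, 1L]] > 0L & map[e[, 2L]] > 0L
  gene_graph(graph$symbols[keep],
             cbind(map[e[inside, 1L]], map[e[inside, 2L]]))
}

#' Label sets for transductive node classification
#'
#' @param n_nodes node count.
#' @param positives,negatives disjoint 1-based index sets; remaining nodes
#'   are unlabeled.
#' @return A `label_set` with fields `positives`, `negatives`, `unlabeled`.
#' @export
label_set <- function(n_nodes, positives, negatives) {
  positives <- sort(unique(as.integer(positives)))
  negatives <- sort(unique(as.integer(negatives)))
  if (length(intersect(positives, negatives))) {
    stop("positive and negative label sets overlap")
  }
  all_idx <- seq_len(n_nodes)
  if (length(setdiff(c(positives, negatives), all_idx))) {
    stop("label index outside node range")
  }
  structure(list(positives = positives, negatives = negatives,
                 unlabeled = setdiff(all_idx, c(positives, negatives)),
                 n_nodes = as.integer(n_nodes)),
            class = "label_set")
}

#' Read positive/negative gene lists (one symbol per line)
#'
#' Symbols absent from the graph are ignored with a message.
#'
#' @param graph a [gene_graph()].
#' @param positives_path,negatives_path label files.
#' @return A [label_set()].
#' @export
read_labels <- function(graph, positives_path, negatives_path) {
  rd <- function(p) {
    s <- clean_symbol(readLines(p, warn = FALSE))
    s[nzchar(s) & !startsWith(s, "#")]
  }
  pos <- match(rd(positives_path), graph$symbols)
  neg <- match(rd(negatives_path), graph$symbols)
  n_miss <- sum(is.na(pos)) + sum(is.na(neg))
  if (n_miss > 0) message(sprintf("read_labels: %d label symbols not in graph",
                                  n_miss))
  label_set(length(graph$symbols), pos[!is.na(pos)], neg[!is.na(neg)])
}

#' 0/1 label vector over all nodes (NA for unlabeled)
#' @param labels a [label_set()].
#' @return numeric vector of length `n_nodes`.
#' @export
label_vector <- function(labels) {
  y <- rep(NA_real_, labels$n_nodes)
  y[labels$positives] <- 1
  y[labels$negatives] <- 0
  y
}

#' Fit fold-aware Z-score standardization statistics
#'
#' Per-column mean and population (ddof = 0) standard deviation computed
#' over `rows` only; constant columns get a standard deviation of 1 so the
#' transform maps them to exactly zero.
#'
#' @param matrix numeric matrix or [omics_matrix()].
#' @param rows row index set the statistics are fitted on (the training
#'   fold); recorded in the result for leakage audits.
#' @return A `standardization_stats` with `means`, `stds`, `source_rows`.
#' @export
fit_standardizer <- function(matrix, rows) {
  X <- if (inherits(matrix, "omics_matrix")) matrix$values else as.matrix(matrix)
  rows <- as.integer(rows)
  if (length(rows) == 0L) stop("cannot fit standardizer on an empty row set")
  Xr <- X[rows, , drop = FALSE]
  mu <- colMeans(Xr)
  sd0 <- sqrt(colMeans(sweep(Xr, 2L, mu, "-")^2))
  sd0[sd0 < 1e-12] <- 1
  structure(list(means = mu, stds = sd0, source_rows = rows),
            class = "standardization_stats")
}

#' Apply fitted standardization statistics to all rows
#'
#' @param matrix numeric matrix or [omics_matrix()]; an already-standardized
#'   `omics_matrix` is refused.
#' @param stats a [fit_standardizer()] result.
#' @return Same shape as the input; an `omics_matrix` keeps its class with
#'   the `standardized` flag set.
#' @export
apply_standardizer <- function(matrix, stats) {
  is_om <- inherits(matrix, "omics_matrix")
  if (is_om && isTRUE(matrix$standardized)) {
    stop("matrix is already standardized")
  }
  X <- if (is_om) matrix$values else as.matrix(matrix)
  if (ncol(X) != length(stats$means)) stop("standardizer width mismatch")
  Z <- sweep(sweep(X, 2L, stats$means, "-"), 2L, stats$stds, "/")
  if (is_om) omics_matrix(Z, standardized = TRUE) else Z
}
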