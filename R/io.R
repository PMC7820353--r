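#' Construct a weighted network container
#'
#' A light wrapper around a dense symmetric non-negative weight matrix
#' with optional node labels and coordinates, used by the surface
#' inversion routines. Matrices asymmetric beyond `tol` are rejected;
#' asymmetry within `tol` is symmetrised by averaging with a warning.
#'
#' @param weights Square numeric matrix, non-negative, zero diagonal.
#' @param labels Optional character vector of node names.
#' @param coords Optional `n x d` coordinate matrix.
#' @param tol Symmetry tolerance (default 1e-9).
#' @return An object of class `weighted_network`.
#' @export
weighted_network <- function(weights, labels = NULL, coords = NULL, tol = 1e-9) {
  w <- as.matrix(weights)
  if (nrow(w) != ncol(w)) stop_invalid("weight matrix must be square")
  if (any(w < 0)) stop_invalid("weights must be non-negative")
  asym <- max(abs(w - t(w)))
  if (asym > tol)
    stop_invalid("matrix is asymmetric beyond tolerance (max |W - W'| = ", asym, ")")
  if (asym > 0) {
    warning("symmetrising weight matrix by averaging (max asymmetry ", asym, ")")
    w <- (w + t(w)) / 2
  }
  if (any(diag(w) != 0)) stop_invalid("self-loops (nonzero diagonal) are not allowed")
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(w))
    rownames(w) <- colnames(w) <- labels
  }
  n <- nrow(w)
  structure(list(weights = w, labels = labels, coords = coords,
                 density = sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2)),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("Weighted network: n =", nrow(x$weights),
      " link density =", format(x$density, digits = 4), "\n")
  invisible(x)
}

# Accept a weighted_network, an sd_pairweights, or a plain matrix;
# always hand back a bare numeric matrix.
weight_matrix <- function(x) {
  m <- if (inherits(x, "weighted_network")) x$weights else as.matrix(unclass(x))
  if (nrow(m) != ncol(m)) stop_invalid("expected a square weight matrix")
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

#' Read a network from disk
#'
#' Supported formats: 3-column (or 2-column, weight defaulting to 1)
#' undirected edge-list TSV with arbitrary string node ids; headerless
#' dense numeric TSV/CSV adjacency; and MatrixMarket coordinate format
#' (`.mtx`). Edges listed in both orientations with equal weight collapse
#' to one undirected edge; self-loops are rejected with the offending
#' line. `format = "auto"` sniffs from the extension and content.
#'
#' @param path Input file.
#' @param format `"auto"`, `"edgelist"`, `"dense"` or `"matrixmarket"`.
#' @param as `"auto"` returns an `igraph` graph when every weight is 1
#'   and a [weighted_network()] otherwise; `"binary"`/`"weighted"` force
#'   the type (binarising positive weights, resp. keeping them).
#' @return An `igraph` graph (with a `name` vertex attribute when labels
#'   are present) or a `weighted_network`.
#' @export
read_network <- function(path, format = c("auto", "edgelist", "dense", "matrixmarket"),
                         as = c("auto", "binary", "weighted")) {
  format <- match.arg(format)
  as <- match.arg(as)
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mtx") "matrixmarket" else {
      first <- readLines(path, n = 1)
      nf <- length(strsplit(trimws(first), "[\t, ]+")[[1]])
      if (nf <= 3) "edgelist" else "dense"
    }
  }
  switch(format,
    edgelist = read_edgelist(path, as),
    dense = {
      w <- as.matrix(utils::read.table(path, header = FALSE,
                                       sep = if (grepl("\\.csv$", path)) "," else ""))
      dimnames(w) <- NULL
      finish_matrix(w, labels = NULL, as = as)
    },
    matrixmarket = {
      w <- as.matrix(Matrix::readMM(path))
      finish_matrix(w, labels = NULL, as = as)
    })
}

read_edgelist <- function(path, as) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = c("character", "character", NA)[
                            seq_len(length(strsplit(readLines(path, n = 1), "\t")[[1]]))],
                          stringsAsFactors = FALSE)
  if (ncol(df) == 2) df$V3 <- 1
  if (ncol(df) != 3) stop_invalid("edge list must have 2 or 3 columns")
  wts <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(wts)) stop_invalid("non-numeric weight at line ", which(is.na(wts))[1])
  if (any(wts < 0)) stop_invalid("negative weight at line ", which(wts < 0)[1])
  loops <- df[[1]] == df[[2]]
  if (any(loops)) stop_invalid("self-loop at line ", which(loops)[1])
  labels <- sort(unique(c(df[[1]], df[[2]])))
  n <- length(labels)
  i <- match(df[[1]], labels)
  j <- match(df[[2]], labels)
  a <- pmin(i, j); b <- pmax(i, j)
  key <- (a - 1) * n + b
  agg_w <- tapply(wts, key, function(v) {
    if (length(unique(v)) > 1)
      warning("edge listed with differing weights; averaging")
    mean(v)
  })
  ku <- as.numeric(names(agg_w))
  w <- matrix(0, n, n)
  ai <- (ku - 1) %/% n + 1
  bj <- (ku - 1) %% n + 1
  w[cbind(ai, bj)] <- agg_w
  w[cbind(bj, ai)] <- agg_w
  finish_matrix(w, labels = labels, as = as)
}

finish_matrix <- function(w, labels, as) {
  wn <- weighted_network(w, labels = labels)
  binary <- all(wn$weights[wn$weights != 0] == 1)
  if (as == "weighted" || (as == "auto" && !binary)) return(wn)
  g <- igraph::graph_from_adjacency_matrix((wn$weights > 0) * 1,
                                           mode = "undirected", diag = FALSE)
  if (!is.null(labels)) igraph::V(g)$name <- labels
  g
}

#' Write a network to disk
#'
#' Inverse of [read_network()]: edge-list TSV (3 columns, unit weights
#' for binary graphs), headerless dense TSV, or MatrixMarket.
#'
#' @param x An `igraph` graph, `weighted_network`, or square matrix.
#' @param path Output file.
#' @param format `"edgelist"`, `"dense"` or `"matrixmarket"` (default
#'   from extension: `.mtx` is MatrixMarket, otherwise edge list).
#' @return `path`, invisibly.
#' @export
write_network <- function(x, path, format = NULL) {
  if (is.null(format))
    format <- if (tolower(tools::file_ext(path)) == "mtx") "matrixmarket" else "edgelist"
  w <- if (igraph::is_igraph(x)) {
    a <- as.matrix(igraph::as_adjacency_matrix(x))
    dimnames(a) <- if (!is.null(igraph::V(x)$name))
      list(igraph::V(x)$name, igraph::V(x)$name) else NULL
    a
  } else weight_matrix(x)
  labels <- rownames(w)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(w)))
  switch(format,
    edgelist = {
      ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
      ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
      df <- data.frame(u = labels[ut[, 1]], v = labels[ut[, 2]],
                       w = format(w[ut], digits = 15, trim = TRUE, scientific = FALSE))
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    },
    dense = utils::write.table(w, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE),
    matrixmarket = Matrix::writeMM(methods::as(Matrix::Matrix(w, sparse = TRUE),
                                               "generalMatrix"), path),
    stop_invalid("unknown format: ", format))
  invisible(path)
}

#' Read node coordinates from CSV
#'
#' Expects columns `id, x, y[, z, ...]`; rows are returned in `id` order
#' matched against `labels` when given, else in file order.
#'
#' @param path CSV file.
#' @param labels Optional node labels defining the row order.
#' @return Numeric coordinate matrix with ids as rownames.
#' @export
read_coords <- function(path, labels = NULL) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!is.null(labels)) {
    ix <- match(labels, rownames(m))
    if (anyNA(ix)) stop_invalid("coordinates missing for node(s): ",
                                paste(labels[is.na(ix)], collapse = ", "))
    m <- m[ix, , drop = FALSE]
  }
  m
}

#' Read homologous node pairs from a two-column CSV
#'
#' @param path CSV file with two columns of node ids.
#' @param labels Optional labels used to translate ids to indices.
#' @return Two-column integer matrix of node indices.
#' @export
read_pairs <- function(path, labels = NULL) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_invalid("pair file must have two columns")
  if (!is.null(labels)) {
    a <- match(as.character(df[[1]]), labels)
    b <- match(as.character(df[[2]]), labels)
    if (anyNA(a) || anyNA(b)) stop_invalid("pair file names unknown nodes")
    cbind(a, b)
  } else cbind(as.integer(df[[1]]), as.integer(df[[2]]))
}

#' Build a planted ground-truth fixture for inversion experiments
#'
#' Generates latent coordinates, a depth factor, log-normal fitness, and
#' the combined weights `W_ij = d_ij (s_i + s_j)`, keeping every piece of
#' ground truth. With `sparsity < 1` only the top fraction of weights is
#' kept (rank thresholding) and the rest zeroed, emulating sparse
#' observed weighted networks.
#'
#' @param n Nodes.
#' @param q Latent dimension.
#' @param sigma True log-normal shape.
#' @param sparsity Fraction of pairs kept, in (0, 1] (default 1).
#' @param seed Integer master seed.
#' @return A list of class `planted_fixture`: `W` (a
#'   [weighted_network()]), `true_depth`, `true_fitness`, `true_params`,
#'   `coords`.
#' @export
make_planted_fixture <- function(n, q, sigma, sparsity = 1, seed = 1) {
  if (sparsity <= 0 || sparsity > 1) stop_invalid("sparsity must be in (0, 1]")
  coords <- sample_hypercube_coords(n, q, derive_seed(seed, 21))
  depth <- euclidean_depth(coords)
  fitness <- sample_lognormal_fitness(n, sigma = sigma, seed = derive_seed(seed, 22))
  w <- weight_matrix(combine_factors(depth, surface_pair_matrix(fitness)))
  if (sparsity < 1) {
    ut <- which(upper.tri(w))
    keep_n <- max(1, round(sparsity * length(ut)))
    drop <- ut[order(w[ut], decreasing = TRUE)][-seq_len(keep_n)]
    w[drop] <- 0
    w[cbind((col(w))[drop], (row(w))[drop])] <- 0
    w <- pmin(w, t(w)) # enforce exact symmetry of the zero pattern
  }
  structure(list(
    W = weighted_network(w),
    true_depth = unclass(depth),
    true_fitness = fitness,
    true_params = list(q = q, sigma = sigma),
    coords = coords,
    seed = seed
  ), class = "planted_fixture")
}
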