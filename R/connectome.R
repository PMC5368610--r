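# Partial-correlation connectome construction and edge vectorization.

#' Canonical edge index map
#'
#' Upper-triangle node pairs (i < j) in lexicographic order. This ordering
#' is fixed package-wide: every edge vector, selection profile and feature
#' matrix indexes edges this way, so feature indices are stable across
#' modules and runs. A 246-node network has 30,135 unique edges.
#'
#' @param n_nodes number of nodes (>= 2).
#' @return data frame with columns `edge` (1-based index), `i`, `j`.
#' @export
edge_index_map <- function(n_nodes) {
  if (n_nodes < 2) stop("need at least 2 nodes")
  i <- rep(seq_len(n_nodes - 1), times = (n_nodes - 1):1)
  j <- sequence((n_nodes - 1):1) + i
  data.frame(edge = seq_along(i), i = i, j = j)
}

#' @rdname edge_index_map
#' @param i,j node pair with `i < j`.
#' @export
pair_to_edge <- function(i, j, n_nodes) {
  stopifnot(all(i < j), all(j <= n_nodes))
  as.integer((i - 1) * (2 * n_nodes - i) / 2 + (j - i))
}

#' @rdname edge_index_map
#' @param edge 1-based edge index.
#' @export
edge_to_pair <- function(edge, n_nodes) {
  map <- edge_index_map(n_nodes)
  stopifnot(all(edge >= 1), all(edge <= nrow(map)))
  map[edge, c("i", "j")]
}

#' Partial correlation of two series given nuisance covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' regression on the covariates plus an intercept. With no covariates this
#' is the plain Pearson correlation. Note the conditioning set is the
#' supplied nuisance covariates only, not other network nodes: estimating a
#' full joint precision over hundreds of nodes from a few hundred frames
#' would be ill-posed without regularization.
#'
#' @param x,y numeric series of equal length.
#' @param covariates optional k x frames (or frames x k) matrix.
#' @return partial correlation in `[-1, 1]`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) {
    design <- matrix(1, n, 1)
  } else {
    design <- covariate_design(covariates, n)
  }
  k <- ncol(design) - 1
  if (n <= k + 3) stop("need more than k + 3 frames (k = ", k, ")")
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) {
    warning("rank-deficient covariate matrix: dropping dependent columns")
    design <- design[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
    qr_x <- qr(design)
  }
  rx <- qr.resid(qr_x, x)
  ry <- qr.resid(qr_x, y)
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12)
    stop("zero residual variance: partial correlation undefined")
  cor(rx, ry)
}

#' Build a subject's partial-correlation connectome
#'
#' Every edge is the partial correlation of the two node eigenvariates
#' given the same nuisance covariate set (by default 10 aCompCor components
#' plus 6 motion parameters, 16 covariates). The diagonal is stored as 0:
#' self-edges are never features.
#'
#' @param eigenvariates nodes x frames matrix of node summary time courses.
#' @param nuisance a `nuisance_components` object (or matrix of nuisance
#'   series).
#' @param motion_params frames x 6 motion table (or NULL to omit).
#' @param node_labels optional node names.
#' @return object of class `connectome`: list with `matrix` (symmetric,
#'   zero diagonal), `node_labels`, `covariate_count`, and `degenerate`
#'   (indices of nodes whose residual variance vanished; their edges are
#'   set to 0 and flagged rather than propagating NaN).
#' @export
build_connectome <- function(eigenvariates, nuisance = NULL,
                             motion_params = NULL, node_labels = NULL) {
  n_nodes <- nrow(eigenvariates)
  n_frames <- ncol(eigenvariates)
  pieces <- c(if (!is.null(nuisance)) list(nuisance),
              if (!is.null(motion_params)) list(motion_params))
  design <- if (length(pieces) > 0) covariate_design(pieces, n_frames)
            else matrix(1, n_frames, 1)
  k <- ncol(design) - 1
  if (n_frames <= k + 3)
    stop("need more than k + 3 frames (k = ", k, " covariates)")
  resid <- qr.resid(qr(design), t(eigenvariates)) # frames x nodes
  rsd <- apply(resid, 2, sd)
  degenerate <- which(rsd < 1e-10)
  if (length(degenerate) > 0) {
    warning("node(s) ", paste(degenerate, collapse = ", "),
            " have ~zero residual variance; their edges are set to 0")
    resid[, degenerate] <- rnorm(n_frames * length(degenerate)) * 0
  }
  m <- suppressWarnings(cor(resid))
  m[!is.finite(m)] <- 0
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n_nodes))
  dimnames(m) <- list(node_labels, node_labels)
  structure(list(matrix = m, node_labels = node_labels,
                 covariate_count = k, degenerate = degenerate),
            class = "connectome")
}

#' Vectorize a connectome along the canonical edge order
#'
#' @param conn a `connectome` or a symmetric matrix.
#' @return numeric vector of length n(n-1)/2, ordered as in
#'   [edge_index_map()].
#' @export
edge_vector <- function(conn) {
  m <- if (inherits(conn, "connectome")) conn$matrix else as.matrix(conn)
  map <- edge_index_map(nrow(m))
  v <- m[cbind(map$i, map$j)]
  names(v) <- paste0("e", map$edge)
  v
}

#' Stack per-subject connectomes into a subjects x edges feature table
#'
#' @param connectomes list of `connectome` objects (or symmetric matrices).
#' @return matrix, one row per subject, columns in canonical edge order.
#' @export
edge_table <- function(connectomes) {
  t(vapply(connectomes, edge_vector,
           numeric(length(edge_vector(connectomes[[1]])))))
}

#' Mean connectivity strength
#'
#' Arithmetic mean of raw correlation coefficients (no Fisher transform)
#' over all edges or an edge subset, as used for whole-connectome strength
#' and for feature-edge composites.
#'
#' @param conn a `connectome`, symmetric matrix, or edge vector.
#' @param subset optional vector of canonical edge indices.
#' @return scalar mean strength.
#' @export
mean_strength <- function(conn, subset = NULL) {
  v <- if (inherits(conn, "connectome") || is.matrix(conn)) edge_vector(conn)
       else as.numeric(conn)
  if (!is.null(subset)) {
    if (length(subset) == 0) stop("empty edge subset")
    if (any(subset < 1 | subset > length(v))) stop("edge subset out of range")
    v <- v[subset]
  }
  mean(v)
}
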