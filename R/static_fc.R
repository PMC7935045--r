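#' Static functional connectivity matrix
#'
#' Pearson correlation between every pair of node signals over the whole
#' (typically session-concatenated) time series: the "static" connectivity
#' summary that averages over moment-to-moment fluctuations.
#'
#' @param x Timepoints x nodes matrix, a [node_timeseries()], or rows of a
#'   `concat_timeseries` belonging to one subject-session.
#' @return An `fc_matrix`: symmetric nodes x nodes correlation matrix with
#'   unit diagonal.
#' @export
correlation_matrix <- function(x) {
  m <- if (inherits(x, "node_timeseries")) x$data else as.matrix(x)
  stop_if(nrow(m) < 3, "need at least 3 timepoints")
  check_finite(m, "time series")
  sdv <- apply(m, 2, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance node(s): ", paste(which(sdv == 0), collapse = ", "),
         call. = FALSE)
  r <- stats::cor(m)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(r, class = c("fc_matrix", "matrix"))
}

#' Vectorize the unique edges of a connectivity matrix
#'
#' Extracts the strictly upper triangle in row-major order, i.e. edges
#' (1,2), (1,3), ..., (1,p), (2,3), ..., (p-1,p). This ordering is stable
#' and documented so that loadings on edge features can be mapped back to
#' node pairs; [edge_index()] returns the pair for each position. Nodes are
#' indexed from 1 in all reports.
#'
#' @param m Symmetric nodes x nodes matrix (e.g. an `fc_matrix`).
#' @param tol Maximum allowed asymmetry.
#' @return Numeric vector of length `p (p - 1) / 2`.
#' @export
vectorize_edges <- function(m, tol = 1e-8) {
  m <- unclass(as.matrix(m))
  stop_if(nrow(m) != ncol(m), "matrix must be square")
  stop_if(max(abs(m - t(m))) > tol, "matrix is asymmetric beyond tolerance")
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' Edge ordering of [vectorize_edges()]
#'
#' @param p Number of nodes.
#' @return data.frame with 1-based `node_i`, `node_j` per edge position.
#' @export
edge_index <- function(p) {
  i <- rep(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(k) (k + 1L):p))
  data.frame(node_i = i, node_j = j)
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_edges()]; the diagonal is set to `diag_value`.
#'
#' @param v Edge vector of length `p (p - 1) / 2`.
#' @param diag_value Diagonal fill (1 for correlation matrices).
#' @return Symmetric p x p matrix.
#' @export
devectorize_edges <- function(v, diag_value = 1) {
  p <- (1 + sqrt(1 + 8 * length(v))) / 2
  stop_if(p != round(p), "edge vector length is not p(p-1)/2 for integer p")
  p <- as.integer(p)
  m <- matrix(0, p, p)
  m[lower.tri(m)] <- v            # row-major upper = column-major lower of t
  m <- t(m)
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Principal component reduction
#'
#' Column-centered (not re-scaled) PCA retaining the leading `k`
#' components, ordered by nonincreasing explained variance.
#'
#' @param X rows x features matrix.
#' @param k Number of components, `k <= min(rows - 1, features)`.
#' @return List with `scores` (rows x k), `basis` (features x k loadings),
#'   `explained_variance` (length k), `center`.
#' @export
pca_reduce <- function(X, k) {
  X <- as.matrix(X)
  stop_if(k < 1 || k > min(nrow(X) - 1L, ncol(X)),
          sprintf("k must lie in [1, min(rows - 1, features)] = [1, %d]",
                  min(nrow(X) - 1L, ncol(X))))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       basis = pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance = pc$sdev[seq_len(k)]^2,
       center = pc$center)
}

#' Per subject-session static FC edge features
#'
#' Computes a correlation matrix for every subject-session block of a
#' `concat_timeseries` and stacks the vectorized edges into the rows x
#' edges feature matrix used as the static-arm input.
#'
#' @param concat A `concat_timeseries` from [standardize_concat()].
#' @return List with `edges` (subject-sessions x p(p-1)/2 matrix, rownames
#'   = block labels), `blocks` (subject/session per row), `edge_index`.
#' @export
static_edge_features <- function(concat) {
  stopifnot(inherits(concat, "concat_timeseries"))
  labs <- levels(concat$block)
  rows <- lapply(labs, function(b) {
    vectorize_edges(correlation_matrix(concat$data[concat$block == b, ,
                                                   drop = FALSE]))
  })
  edges <- do.call(rbind, rows)
  rownames(edges) <- labs
  first <- match(labs, as.character(concat$block))
  list(edges = edges,
       blocks = data.frame(subject = concat$subject[first],
                           session = concat$session[first]),
       edge_index = edge_index(ncol(concat$data)))
}
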