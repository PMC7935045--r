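#' Fractional occupancy per subject-session
#'
#' The proportion of a block's timepoints attributed to each state: the
#' mean over the block's rows of the posterior `P(s_t = k)`.
#'
#' @param stc A [state_timecourse()].
#' @return Subject-sessions x K matrix; each row sums to 1. Rownames are
#'   the block labels.
#' @export
fractional_occupancy <- function(stc) {
  stopifnot(inherits(stc, "state_timecourse"))
  labs <- levels(stc$block)
  fo <- t(vapply(labs, function(b) {
    rows <- stc$block == b
    stop_if(!any(rows), "empty block: ", b)
    colMeans(stc$probs[rows, , drop = FALSE])
  }, numeric(ncol(stc$probs))))
  rownames(fo) <- labs
  colnames(fo) <- colnames(stc$probs)
  fo
}

#' Switching rate per subject-session
#'
#' Mean absolute change of the state-probability vector between consecutive
#' timepoints, summed over states: `SR(b) = (1/T) sum_t sum_k
#' |P(s_{t+1} = k) - P(s_t = k)|` over the block's consecutive pairs. The
#' absolute value is essential (the signed sum is identically zero), and
#' the denominator is the number of timepoints `T` by default
#' (`denominator = "T-1"` divides by the number of transitions instead).
#' The rate is bounded by 2 for probability vectors.
#'
#' @param stc A [state_timecourse()].
#' @param denominator `"T"` (default) or `"T-1"`.
#' @return Named numeric vector, one switching rate per subject-session.
#' @export
switching_rate <- function(stc, denominator = c("T", "T-1")) {
  stopifnot(inherits(stc, "state_timecourse"))
  denominator <- match.arg(denominator)
  labs <- levels(stc$block)
  sr <- vapply(labs, function(b) {
    P <- stc$probs[stc$block == b, , drop = FALSE]
    stop_if(nrow(P) < 2, "block ", b, " has fewer than 2 timepoints")
    tot <- sum(abs(diff(P)))
    tot / if (denominator == "T") nrow(P) else (nrow(P) - 1)
  }, 0)
  names(sr) <- labs
  sr
}

#' Metastate partition of the transition matrix
#'
#' Agglomerative single-linkage clustering of the rows of the transition
#' matrix under Euclidean distance, cut to `n_clusters`. States that
#' preferentially transition among themselves have similar outgoing
#' transition profiles and merge early; each resulting cluster is one
#' metastate.
#'
#' @param Theta Row-stochastic K x K transition matrix.
#' @param n_clusters Number of metastates to cut the tree at.
#' @return Object of class `metastate_partition`: `labels` (state ->
#'   cluster, length K), `tree` (the `hclust` object), `n_clusters`.
#' @export
cluster_metastates <- function(Theta, n_clusters = 3) {
  Theta <- as.matrix(Theta)
  K <- nrow(Theta)
  stop_if(ncol(Theta) != K, "Theta must be square")
  stop_if(max(abs(rowSums(Theta) - 1)) > 1e-6, "Theta rows must sum to 1")
  stop_if(n_clusters < 1 || n_clusters > K,
          "n_clusters must lie in [1, K]")
  tree <- stats::hclust(stats::dist(Theta, method = "euclidean"),
                        method = "single")
  labels <- stats::cutree(tree, k = n_clusters)
  structure(list(labels = labels, tree = tree, n_clusters = n_clusters),
            class = "metastate_partition")
}

#' @export
print.metastate_partition <- function(x, ...) {
  cat(sprintf("metastate_partition: %d states -> %d metastates {%s}\n",
              length(x$labels), x$n_clusters,
              paste(tabulate(x$labels, x$n_clusters), collapse = "/")))
  invisible(x)
}

#' Metastate time courses by pooling member states
#'
#' The metastate time course is the sum of the time courses of its member
#' states, so rows remain probability vectors over metastates; fractional
#' occupancy and switching rate of metastates are then computed exactly as
#' for single states.
#'
#' @param stc A [state_timecourse()] over K states.
#' @param partition A [cluster_metastates()] result (or an integer vector
#'   of length K mapping each state to a metastate).
#' @return A [state_timecourse()] over the metastates.
#' @export
metastate_timecourse <- function(stc, partition) {
  stopifnot(inherits(stc, "state_timecourse"))
  labels <- if (inherits(partition, "metastate_partition")) partition$labels
            else as.integer(partition)
  K <- ncol(stc$probs)
  stop_if(length(labels) != K, "partition must cover all ", K, " states")
  m <- max(labels)
  stop_if(!setequal(unique(labels), seq_len(m)),
          "metastate labels must be 1..n_clusters with none empty")
  pooled <- vapply(seq_len(m), function(g) {
    rowSums(stc$probs[, labels == g, drop = FALSE])
  }, numeric(nrow(stc$probs)))
  colnames(pooled) <- paste0("metastate", seq_len(m))
  state_timecourse(pooled, stc$block)
}

#' Assemble the time-varying connectivity feature matrix
#'
#' One row per subject-session: fractional occupancy of each state (K
#' columns), fractional occupancy of each metastate, the mean switching
#' rate across states (1 column) and across metastates (1 column). At the
#' defaults (K = 12 states, 3 metastates) this is the 17-column feature
#' matrix used as the dynamic-arm input to the behavioral analysis.
#'
#' @param stc A [state_timecourse()].
#' @param partition Metastate partition (from [cluster_metastates()] of the
#'   fitted transition matrix); `NULL` derives no metastate columns.
#' @param denominator Passed to [switching_rate()].
#' @return Subject-sessions x features numeric matrix with descriptive
#'   column names and block-label rownames.
#' @export
state_features <- function(stc, partition = NULL,
                           denominator = c("T", "T-1")) {
  denominator <- match.arg(denominator)
  fo <- fractional_occupancy(stc)
  colnames(fo) <- paste0("fo_state", seq_len(ncol(fo)))
  out <- cbind(fo, sr_states = switching_rate(stc, denominator))
  if (!is.null(partition)) {
    mstc <- metastate_timecourse(stc, partition)
    mfo <- fractional_occupancy(mstc)
    colnames(mfo) <- paste0("fo_", colnames(mstc$probs))
    out <- cbind(fo, mfo,
                 sr_states = switching_rate(stc, denominator),
                 sr_metastates = switching_rate(mstc, denominator))
  }
  out
}

#' Spatial overlap index between a state map and a network
#'
#' Thresholds a per-node state activation map to keep the top
#' `threshold_frac` of positive-valued nodes (by value) and the top
#' `threshold_frac` of negative-valued nodes (by magnitude), then reports
#' the fraction of the network's nodes contained in the thresholded
#' selection -- normalizing by network size to remove size bias. The index
#' is invariant to positive rescaling of the map. Ties are broken by node
#' index.
#'
#' @param state_map Numeric per-node activation vector.
#' @param network Integer indices (1-based) of the network's nodes.
#' @param threshold_frac Fraction of each signed subset to keep.
#' @return Overlap index in \[0, 1\].
#' @export
overlap_index <- function(state_map, network, threshold_frac = 0.40) {
  check_finite(state_map, "state map")
  network <- as.integer(network)
  stop_if(length(network) == 0, "network must contain at least one node")
  stop_if(any(network < 1 | network > length(state_map)),
          "network indices outside the node universe")
  stop_if(threshold_frac < 0 || threshold_frac > 1,
          "threshold_frac must lie in [0, 1]")
  pos <- which(state_map > 0)
  neg <- which(state_map < 0)
  top <- function(idx, val) {
    k <- floor(threshold_frac * length(idx))
    if (k == 0) return(integer(0))
    idx[order(-val, idx)][seq_len(k)]
  }
  sel <- c(top(pos, state_map[pos]), top(neg, -state_map[neg]))
  length(intersect(sel, network)) / length(network)
}

#' Association between state features and head motion
#'
#' Correlates each time-varying connectivity feature with session-specific
#' mean framewise displacement, separately per session, and applies
#' Benjamini-Hochberg false-discovery-rate correction jointly across all
#' feature x session tests (17 x 3 = 51 at the study defaults).
#'
#' @param features Subject-sessions x features matrix (e.g. from
#'   [state_features()]).
#' @param mean_fd Per subject-session mean FD, aligned with the rows of
#'   `features`.
#' @param session Per-row session identifier.
#' @return data.frame with columns `feature`, `session`, `r`, `p`,
#'   `p_adjusted` (one row per test; `r` is `NA` for constant features).
#' @export
qc_confound_association <- function(features, mean_fd, session) {
  features <- as.matrix(features)
  stop_if(length(mean_fd) != nrow(features),
          "mean_fd must align with feature rows")
  stop_if(length(session) != nrow(features),
          "session must align with feature rows")
  nm <- colnames(features)
  if (is.null(nm)) nm <- paste0("feature", seq_len(ncol(features)))
  out <- list()
  for (s in unique(session)) {
    rows <- session == s
    for (j in seq_len(ncol(features))) {
      x <- features[rows, j]
      y <- mean_fd[rows]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(x, y)
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        feature = nm[j], session = s, r = r, p = p)
    }
  }
  out <- do.call(rbind, out)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out
}
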