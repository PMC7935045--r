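#' Canonical correlation analysis
#'
#' Finds weight matrices `A`, `B` such that the variates `U = Xc A` and
#' `V = Yc B` (columns of both sides centered internally) are maximally
#' correlated, mode by mode: correlations are nonincreasing, and successive
#' variates are mutually uncorrelated within each side. Computed by
#' eigenvalue whitening of each side's covariance followed by a singular
#' value decomposition of the whitened cross-covariance; rank-deficient
#' sides are reduced to their numerical rank with a message.
#'
#' @param X,Y rows x d1 and rows x d2 numeric matrices (same rows).
#' @param rank_tol Relative eigenvalue tolerance defining numerical rank.
#' @return Object of class `cca_result`: `xweights` (d1 x m), `yweights`
#'   (d2 x m), `correlations` (length m = min(rank X, rank Y)),
#'   `xvariates`, `yvariates` (rows x m), `xcenter`, `ycenter`, `n`.
#' @export
cca <- function(X, Y, rank_tol = 1e-10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stop_if(nrow(X) != nrow(Y), "X and Y must have the same rows")
  n <- nrow(X)
  stop_if(n < 3, "need at least 3 rows")
  check_finite(X, "X"); check_finite(Y, "Y")
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  whiten <- function(M, side) {
    S <- crossprod(M) / (n - 1)
    e <- eigen(S, symmetric = TRUE)
    keep <- e$values > max(e$values) * rank_tol & e$values > 0
    if (sum(keep) < ncol(M))
      message(side, " is rank deficient: reducing ", ncol(M), " columns to rank ",
              sum(keep))
    e$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(e$values[keep]), sum(keep))
  }
  Wx <- whiten(Xc, "X"); Wy <- whiten(Yc, "Y")
  sv <- svd(crossprod(Xc %*% Wx, Yc %*% Wy) / (n - 1))
  m <- min(ncol(Wx), ncol(Wy))
  A <- Wx %*% sv$u[, seq_len(m), drop = FALSE]
  B <- Wy %*% sv$v[, seq_len(m), drop = FALSE]
  structure(list(
    xweights = A, yweights = B,
    correlations = pmin(1, pmax(0, sv$d[seq_len(m)])),
    xvariates = Xc %*% A, yvariates = Yc %*% B,
    xcenter = attr(Xc, "scaled:center"), ycenter = attr(Yc, "scaled:center"),
    n = n), class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("cca_result: %d modes on n = %d rows\n",
              length(x$correlations), x$n))
  cat("  canonical correlations:",
      paste(sprintf("%.3f", x$correlations), collapse = " "), "\n")
  invisible(x)
}

# Orthonormal column basis of a centered matrix (numerical rank columns).
orthobasis <- function(M) {
  qx <- qr(M)
  qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
}

# --- grouped permutation machinery ---------------------------------------

# Subjects form exchangeability blocks (all sessions of a subject move as a
# unit); blocks may only swap with blocks holding the same number of rows,
# so the permuted design keeps every row aligned with a row of the same
# session position. With `session_exchange`, sessions are additionally
# treated as exchangeable within each subject, enlarging the permutation
# group (valid when session order carries no information). Returns block
# bookkeeping used by the samplers.
exchange_structure <- function(groups, n, session_exchange = FALSE) {
  g <- factor(groups, levels = unique(groups))
  stop_if(length(g) != n, "groups must have one entry per row")
  rows_by_block <- split(seq_len(n), g)
  sizes <- lengths(rows_by_block)
  classes <- split(seq_along(sizes), sizes)
  if (!any(lengths(classes) > 1) &&
      !(session_exchange && any(sizes > 1)))
    stop("no two subject blocks share a session count: ",
         "grouped permutation has nothing to exchange", call. = FALSE)
  n_distinct <- prod(factorial(lengths(classes)))
  if (session_exchange) n_distinct <- n_distinct * prod(factorial(sizes))
  list(rows_by_block = rows_by_block, classes = classes,
       n_distinct = n_distinct, session_exchange = session_exchange)
}

# Row index realizing one block-level assignment: block b takes the rows of
# block assign[b] (same size), preserving within-block (session) order.
assignment_to_rows <- function(ex, assign) {
  idx <- integer(sum(lengths(ex$rows_by_block)))
  for (b in seq_along(ex$rows_by_block))
    idx[ex$rows_by_block[[b]]] <- ex$rows_by_block[[assign[b]]]
  idx
}

random_assignment <- function(ex) {
  assign <- seq_along(ex$rows_by_block)
  for (cl in ex$classes)
    if (length(cl) > 1) assign[cl] <- cl[sample.int(length(cl))]
  assign
}

# Random element of the full exchange group as a row index: block exchange
# plus, if enabled, a session shuffle within every (reassigned) block.
random_exchange_rows <- function(ex) {
  idx <- assignment_to_rows(ex, random_assignment(ex))
  if (isTRUE(ex$session_exchange)) {
    for (rows in ex$rows_by_block) {
      if (length(rows) > 1)
        idx[rows] <- idx[rows][sample.int(length(rows))]
    }
  }
  idx
}

# All distinct block assignments (rows of the returned matrix), including
# the identity; callers enumerate only when n_distinct is small.
enumerate_assignments <- function(ex) {
  per_class <- lapply(ex$classes, function(cl) {
    if (length(cl) == 1) matrix(cl, 1, 1)
    else matrix(cl[all_permutations(length(cl))], ncol = length(cl))
  })
  combo <- expand.grid(lapply(per_class, function(m) seq_len(nrow(m))))
  n_blocks <- sum(lengths(ex$classes))
  out <- matrix(0L, nrow(combo), n_blocks)
  for (i in seq_along(per_class))
    out[, ex$classes[[i]]] <- per_class[[i]][combo[[i]], , drop = FALSE]
  out
}

#' Permute rows under the subject-grouped exchangeability structure
#'
#' Returns a row index that reassigns whole subject blocks among blocks
#' with equal row counts, preserving within-subject row order. With all
#' singleton blocks this reduces exactly to an ordinary row permutation.
#'
#' @param groups Per-row subject labels.
#' @param session_exchange Additionally permute rows within each subject
#'   block (sessions exchangeable within subject).
#' @return Integer row index of the same length as `groups`.
#' @export
permute_rows_grouped <- function(groups, session_exchange = FALSE) {
  ex <- exchange_structure(groups, length(groups), session_exchange)
  random_exchange_rows(ex)
}

# All-mode canonical correlations from precomputed orthonormal bases;
# identical for any row reordering applied to Qx's rows.
basis_correlations <- function(Qx, Qy) {
  svd(crossprod(Qx, Qy), nu = 0, nv = 0)$d
}

#' Subject-grouped permutation test for CCA modes
#'
#' Builds the permutation null of the canonical correlations by reassigning
#' whole subject blocks of `X` relative to `Y` (blocks exchange only among
#' blocks with the same number of rows, so sessions stay aligned) and
#' recomputing the CCA for each permutation. When the whole permutation
#' group is no larger than `n_perm` it is enumerated and p-values are exact
#' (`p = #\{permutations with corr >= observed\} / #permutations`,
#' identity included, so the smallest attainable p is 1/#permutations);
#' otherwise `n_perm` random permutations are drawn and
#' `p = (1 + #\{perm >= obs\}) / (1 + n_perm)`, which can never be 0.
#'
#' @param X,Y rows x d1 / d2 matrices.
#' @param groups Per-row subject labels (all sessions of a subject form one
#'   exchangeability block).
#' @param n_perm Number of permutations (10,000 at the study default).
#' @param seed Optional seed.
#' @param statistic `"per_mode"` compares the k-th observed correlation to
#'   the permutation distribution of the k-th correlation; `"max"`
#'   compares every observed correlation to the distribution of the
#'   largest (family-wise control).
#' @param session_exchange Enlarge the permutation group by treating
#'   sessions as exchangeable within each subject (rows permute within
#'   blocks as well); always Monte Carlo sampled.
#' @return List: `p` (per mode), `observed` correlations, `method`
#'   (`"exact"` or `"sampled"`), `n_perm_used`, `statistic`.
#' @export
cca_permutation_test <- function(X, Y, groups, n_perm = 10000, seed = NULL,
                                 statistic = c("per_mode", "max"),
                                 session_exchange = FALSE) {
  statistic <- match.arg(statistic)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stop_if(nrow(Y) != n, "X and Y must have the same rows")
  stop_if(n_perm < 1, "n_perm must be >= 1")
  ex <- exchange_structure(groups, n, session_exchange)
  Qx <- orthobasis(scale(X, scale = FALSE))
  Qy <- orthobasis(scale(Y, scale = FALSE))
  obs <- basis_correlations(Qx, Qy)
  m <- length(obs)
  with_seed(seed, {
    if (!session_exchange && ex$n_distinct <= n_perm) {
      assigns <- enumerate_assignments(ex)
      perm_d <- t(apply(assigns, 1, function(a) {
        basis_correlations(Qx[assignment_to_rows(ex, a), , drop = FALSE], Qy)
      }))
      perm_d <- matrix(perm_d, nrow(assigns), m)
      denom <- nrow(assigns)
      count <- function(k, ref) sum(perm_d[, ref] >= obs[k] - 1e-12)
      p <- vapply(seq_len(m), function(k) {
        count(k, if (statistic == "max") 1L else k) / denom
      }, 0)
      method <- "exact"
      used <- denom
    } else {
      exceed <- numeric(m)
      for (i in seq_len(n_perm)) {
        idx <- random_exchange_rows(ex)
        d <- basis_correlations(Qx[idx, , drop = FALSE], Qy)
        ref <- if (statistic == "max") rep(d[1], m) else d
        exceed <- exceed + (ref >= obs - 1e-12)
      }
      p <- (1 + exceed) / (1 + n_perm)
      method <- "sampled"
      used <- n_perm
    }
    list(p = p, observed = obs, method = method, n_perm_used = used,
         statistic = statistic)
  })
}

#' Subject-grouped cross-validation of the first CCA mode
#'
#' Repeatedly splits subjects (never rows) into train and test sets, fits
#' the CCA on the training rows, projects the held-out rows with the
#' training weights and centers, and tests the held-out first-mode
#' correlation with a subject-grouped permutation test applied within the
#' test set. Splits are stratified by session count by default, so every
#' test set has the same block composition. Because a 20% test set holds
#' only a handful of subject blocks, pure block exchange offers very few
#' distinct rearrangements there; by default the fold test therefore uses
#' the full exchangeability group -- block exchange plus session
#' relabelling within subjects (`session_exchange = TRUE`), valid whenever
#' session order is uninformative.
#'
#' @param X,Y rows x d1 / d2 matrices.
#' @param groups Per-row subject labels.
#' @param n_folds Number of random train/test splits.
#' @param train_frac Fraction of subjects assigned to training.
#' @param n_perm Permutations for each held-out test.
#' @param alpha Significance level for the fold summary.
#' @param stratify Stratify the subject split by session count.
#' @param session_exchange Use within-subject session relabelling in the
#'   fold permutation test (see Details).
#' @param seed Optional seed.
#' @return List: `folds` (data.frame with `r_test`, `p` and the held-out
#'   `test_subjects` per fold), `prop_significant` (fraction of folds with
#'   `p <= alpha`), `alpha`, `n_folds`.
#' @export
cca_cross_validate <- function(X, Y, groups, n_folds = 1000,
                               train_frac = 0.8, n_perm = 1000,
                               alpha = 0.05, stratify = TRUE,
                               session_exchange = TRUE, seed = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  g <- factor(groups, levels = unique(groups))
  stop_if(length(g) != n, "groups must have one entry per row")
  blocks <- levels(g)
  sizes <- as.vector(table(g)[blocks])
  n_test_total <- if (stratify) {
    sum(vapply(split(seq_along(blocks), sizes), function(cl) {
      max(1L, as.integer(round((1 - train_frac) * length(cl))))
    }, 1L))
  } else max(1L, as.integer(round((1 - train_frac) * length(blocks))))
  stop_if(n_test_total < 3,
          "test sets would hold fewer than 3 subject blocks")
  with_seed(seed, {
    folds <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      test_blocks <- if (stratify) {
        unlist(lapply(split(seq_along(blocks), sizes), function(cl) {
          cl[sample.int(length(cl), max(1L, round((1 - train_frac) * length(cl))))]
        }), use.names = FALSE)
      } else {
        sample.int(length(blocks), n_test_total)
      }
      in_test <- as.integer(g) %in% test_blocks
      fit <- cca(X[!in_test, , drop = FALSE], Y[!in_test, , drop = FALSE])
      u <- (sweep(X[in_test, , drop = FALSE], 2, fit$xcenter) %*%
              fit$xweights)[, 1]
      v <- (sweep(Y[in_test, , drop = FALSE], 2, fit$ycenter) %*%
              fit$yweights)[, 1]
      r_obs <- stats::cor(u, v)
      ex <- exchange_structure(g[in_test], sum(in_test), session_exchange)
      if (!session_exchange && ex$n_distinct <= n_perm) {
        assigns <- enumerate_assignments(ex)
        rs <- apply(assigns, 1, function(a) {
          stats::cor(u[assignment_to_rows(ex, a)], v)
        })
        p <- sum(rs >= r_obs - 1e-12) / nrow(assigns)
      } else {
        exceed <- 0L
        for (i in seq_len(n_perm)) {
          rp <- stats::cor(u[random_exchange_rows(ex)], v)
          exceed <- exceed + (rp >= r_obs - 1e-12)
        }
        p <- (1 + exceed) / (1 + n_perm)
      }
      folds[[f]] <- data.frame(
        fold = f, r_test = r_obs, p = p,
        test_subjects = paste(blocks[test_blocks], collapse = ";"))
    }
    folds <- do.call(rbind, folds)
    list(folds = folds,
         prop_significant = mean(folds$p <= alpha),
         alpha = alpha, n_folds = n_folds)
  })
}

#' Post hoc loadings of original variables on the canonical variates
#'
#' Pearson correlation of every original `X` variable with the `U` variates
#' and every `Y` variable with the `V` variates, per mode: the quantity
#' used to interpret which variables define a mode.
#'
#' @param result A [cca()] result.
#' @param X,Y The matrices the result was fitted on (or any aligned
#'   variables to correlate with the variates).
#' @param modes Which modes to report (default all).
#' @return List with matrices `x` (d1 x modes) and `y` (d2 x modes);
#'   constant variables give `NA` with a warning.
#' @export
posthoc_loadings <- function(result, X, Y, modes = NULL) {
  stopifnot(inherits(result, "cca_result"))
  if (is.null(modes)) modes <- seq_along(result$correlations)
  lo <- function(M, variates, side) {
    M <- as.matrix(M)
    sds <- apply(M, 2, stats::sd)
    if (any(sds == 0))
      warning("constant ", side, " variable(s) give undefined loadings: ",
              paste(which(sds == 0), collapse = ", "), call. = FALSE)
    out <- suppressWarnings(
      stats::cor(M, variates[, modes, drop = FALSE]))
    out[sds == 0, ] <- NA_real_
    colnames(out) <- paste0("mode", modes)
    out
  }
  list(x = lo(X, result$xvariates, "X"), y = lo(Y, result$yvariates, "Y"))
}

#' Stability of the first CCA mode across analysis configurations
#'
#' Re-runs the factor-analysis + PCA + CCA pipeline over a grid of
#' (number of behavioral factors) x (number of feature principal
#' components), stores the post hoc loadings of every behavioral measure on
#' the first behavioral variate for each configuration, and reports the
#' Pearson similarity of these loading vectors across all configurations.
#' Because canonical variates have arbitrary sign, similarities come in
#' +/- pairs; a stable mode shows |similarity| near 1 across the grid.
#'
#' @param behavior Behavioral table (measure columns; `subject`/`session`
#'   columns are ignored).
#' @param features rows x features brain feature matrix (aligned rows).
#' @param factor_range Numbers of behavioral factors to sweep.
#' @param pc_range Numbers of feature principal components to sweep.
#' @param fit If `FALSE`, only enumerate the configuration grid (no models
#'   are fitted; loadings and similarities are `NA`).
#' @return Object of class `mode_stability`: `grid` (configurations, with
#'   `failed` flag), `loadings` (measures x configurations), `similarity`
#'   (configurations x configurations Pearson matrix, `NA` for failed
#'   fits).
#' @export
mode_stability_sweep <- function(behavior, features, factor_range = 1:9,
                                 pc_range = 1:20, fit = TRUE) {
  features <- as.matrix(features)
  stop_if(any(factor_range < 1), "factor_range must be positive")
  stop_if(any(pc_range < 1) ||
            any(pc_range > min(nrow(features) - 1L, ncol(features))),
          "pc_range outside the feasible component range")
  M <- behavior
  if (is.data.frame(M))
    M <- as.matrix(M[, !(names(M) %in% c("subject", "session")) &
                       vapply(M, is.numeric, TRUE), drop = FALSE])
  grid <- expand.grid(n_factors = factor_range, n_pcs = pc_range)
  loadings <- matrix(NA_real_, ncol(M), nrow(grid))
  rownames(loadings) <- colnames(M)
  failed <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (!fit) next
    res <- tryCatch({
      sol <- suppressMessages(fit_factors(behavior, grid$n_factors[i]))
      Xp <- pca_reduce(features, grid$n_pcs[i])$scores
      cfit <- suppressMessages(cca(Xp, sol$scores))
      as.vector(stats::cor(M, cfit$yvariates[, 1]))
    }, error = function(e) NULL)
    if (is.null(res)) failed[i] <- TRUE else loadings[, i] <- res
  }
  grid$failed <- failed
  sim <- suppressWarnings(stats::cor(loadings,
                                     use = "pairwise.complete.obs"))
  structure(list(grid = grid, loadings = loadings, similarity = sim),
            class = "mode_stability")
}

#' @export
print.mode_stability <- function(x, ...) {
  ok <- !x$grid$failed
  off <- x$similarity[lower.tri(x$similarity)]
  cat(sprintf("mode_stability: %d configurations (%d failed)\n",
              nrow(x$grid), sum(!ok)))
  if (any(is.finite(off)))
    cat(sprintf("  |similarity|: median %.3f, min %.3f\n",
                stats::median(abs(off), na.rm = TRUE),
                min(abs(off), na.rm = TRUE)))
  invisible(x)
}
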