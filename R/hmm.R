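#' Gaussian-observation hidden Markov model
#'
#' Container for a K-state HMM with multivariate Gaussian emissions:
#' state means `mu_k`, covariances `Sigma_k`, row-stochastic transition
#' matrix `Theta` (entry `[l, k]` = probability of moving from state `l`
#' to state `k`), and initial distribution `pi`.
#'
#' @param means K x d matrix of state means.
#' @param covariances List of K symmetric positive-definite d x d matrices.
#' @param transition K x K row-stochastic matrix.
#' @param initial Length-K probability vector.
#' @return Object of class `hmm_model`.
#' @export
hmm_model <- function(means, covariances, transition, initial) {
  means <- as.matrix(means)
  K <- nrow(means)
  stopifnot(length(covariances) == K, nrow(transition) == K,
            ncol(transition) == K, length(initial) == K)
  stop_if(max(abs(rowSums(transition) - 1)) > 1e-8,
          "transition rows must sum to 1")
  stop_if(abs(sum(initial) - 1) > 1e-8, "initial distribution must sum to 1")
  structure(list(n_states = K, means = means, covariances = covariances,
                 transition = transition, initial = as.numeric(initial)),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("hmm_model: %d states, %d features\n",
              x$n_states, ncol(x$means)))
  cat("  self-transition probabilities:",
      paste(sprintf("%.2f", diag(x$transition)), collapse = " "), "\n")
  invisible(x)
}

#' State time course (per-timepoint state posteriors)
#'
#' @param probs Timepoints x K matrix of posterior probabilities
#'   `P(s_t = k)`; rows sum to 1.
#' @param block Per-row subject-session labels (contiguous blocks).
#' @return Object of class `state_timecourse`.
#' @export
state_timecourse <- function(probs, block) {
  probs <- as.matrix(probs)
  stop_if(any(probs < -1e-8) || any(probs > 1 + 1e-8),
          "posterior probabilities must lie in [0, 1]")
  stop_if(max(abs(rowSums(probs) - 1)) > 1e-6, "posterior rows must sum to 1")
  structure(list(probs = probs,
                 block = as_blocks(block, nrow(probs), contiguous = TRUE)),
            class = "state_timecourse")
}

#' @export
print.state_timecourse <- function(x, ...) {
  cat(sprintf("state_timecourse: %d timepoints x %d states, %d blocks\n",
              nrow(x$probs), ncol(x$probs), nlevels(x$block)))
  invisible(x)
}

# Log density of rows of X under N(mu, Sigma), via Cholesky.
log_gauss_rows <- function(X, mu, Sigma) {
  d <- ncol(X)
  R <- tryCatch(chol(Sigma), error = function(e) {
    chol(Sigma + diag(1e-6 * sum(diag(Sigma)) / d, d))
  })
  Z <- backsolve(R, t(X) - mu, transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(Z^2))
}

# Scaled forward-backward over one contiguous block.
# logB: T x K log emission densities; returns smoothed marginals, summed
# two-slice statistics, first-frame marginal and the block log-likelihood.
forward_backward_block <- function(logB, Theta, pi0) {
  Tn <- nrow(logB)
  K <- ncol(logB)
  mx <- apply(logB, 1, max)
  W <- exp(logB - mx)
  alpha <- matrix(0, Tn, K)
  cs <- numeric(Tn)
  a <- pi0 * W[1, ]
  cs[1] <- sum(a)
  alpha[1, ] <- a / cs[1]
  if (Tn > 1) for (t in 2:Tn) {
    a <- as.vector(alpha[t - 1, ] %*% Theta) * W[t, ]
    cs[t] <- sum(a)
    alpha[t, ] <- a / cs[t]
  }
  beta <- matrix(0, Tn, K)
  beta[Tn, ] <- 1
  xi <- matrix(0, K, K)
  if (Tn > 1) for (t in (Tn - 1):1) {
    wb <- W[t + 1, ] * beta[t + 1, ]
    xi <- xi + (outer(alpha[t, ], wb) * Theta) / cs[t + 1]
    beta[t, ] <- as.vector(Theta %*% wb) / cs[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xi = xi, first = gamma[1, ],
       loglik = sum(log(cs) + mx))
}

# One E-step over all blocks; returns posteriors, sufficient statistics and
# the data log-likelihood under `model`.
hmm_estep <- function(X, block_rows, model) {
  K <- model$n_states
  n <- nrow(X)
  logB <- vapply(seq_len(K), function(k) {
    log_gauss_rows(X, model$means[k, ], model$covariances[[k]])
  }, numeric(n))
  gamma <- matrix(0, n, K)
  xi <- matrix(0, K, K)
  first <- numeric(K)
  ll <- 0
  for (rows in block_rows) {
    fb <- forward_backward_block(logB[rows, , drop = FALSE],
                                 model$transition, model$initial)
    gamma[rows, ] <- fb$gamma
    xi <- xi + fb$xi
    first <- first + fb$first
    ll <- ll + fb$loglik
  }
  list(gamma = gamma, xi = xi, first = first, loglik = ll)
}

# Log prior density of the model parameters under the conjugate priors used
# by the MAP M-step: symmetric Dirichlet(1 + 1/K) on each transition row and
# on pi, inverse-Wishart(psi_scale * I, d + 2) on each state covariance.
hmm_log_prior <- function(model, psi_scale) {
  K <- model$n_states
  d <- ncol(model$means)
  a <- 1 + 1 / K
  ldir <- function(p) lgamma(K * a) - K * lgamma(a) + sum((a - 1) * log(p))
  nu0 <- d + 2
  liw <- vapply(model$covariances, function(S) {
    R <- chol(S)
    logdetS <- 2 * sum(log(diag(R)))
    trinv <- psi_scale * sum(diag(chol2inv(R)))
    (nu0 / 2) * d * log(psi_scale) - (nu0 * d / 2) * log(2) -
      lmvgamma(d, nu0 / 2) - ((nu0 + d + 1) / 2) * logdetS - 0.5 * trinv
  }, 0)
  sum(vapply(seq_len(K), function(l) ldir(model$transition[l, ]), 0)) +
    ldir(model$initial) + sum(liw)
}

# MAP M-step given E-step statistics.
hmm_mstep <- function(X, est, model, psi_scale) {
  K <- model$n_states
  d <- ncol(X)
  a1 <- 1 / K                                 # Dirichlet pseudo-counts
  Theta <- est$xi + a1
  Theta <- Theta / rowSums(Theta)
  pi0 <- est$first + a1
  pi0 <- pi0 / sum(pi0)
  Nk <- colSums(est$gamma)
  means <- model$means
  covs <- model$covariances
  nu0 <- d + 2
  empty <- Nk < 1e-10
  for (k in seq_len(K)) {
    if (empty[k]) next                        # keep previous parameters
    mu <- as.vector(crossprod(est$gamma[, k], X)) / Nk[k]
    Xc <- sweep(X, 2, mu)
    Sk <- crossprod(Xc * sqrt(est$gamma[, k]))
    means[k, ] <- mu
    covs[[k]] <- (diag(psi_scale, d) + Sk) / (nu0 + Nk[k] + d + 1)
  }
  list(model = hmm_model(means, covs, Theta, pi0), empty = any(empty))
}

hmm_init <- function(X, K, block_rows, subsample = 2000L) {
  n <- nrow(X)
  idx <- if (n > subsample) sample.int(n, subsample) else seq_len(n)
  km <- tryCatch(
    stats::kmeans(X[idx, , drop = FALSE], centers = K,
                  nstart = 3, iter.max = 50),
    error = function(e) NULL)
  means <- if (is.null(km)) {
    X[sample.int(n, K), , drop = FALSE]
  } else km$centers
  d <- ncol(X)
  S0 <- stats::cov(X) + diag(1e-3 * mean(apply(X, 2, stats::var)), d)
  Theta <- matrix((1 - 0.8) / max(1, K - 1), K, K)
  diag(Theta) <- if (K > 1) 0.8 else 1
  pi0 <- rep(1 / K, K)
  hmm_model(means, replicate(K, S0, simplify = FALSE), Theta, pi0)
}

split_block_rows <- function(block) {
  lapply(levels(block), function(b) which(block == b))
}

#' Fit a Gaussian HMM by MAP expectation-maximization
#'
#' Infers state means, covariances, transition matrix and per-timepoint
#' state posteriors from (typically PCA-reduced) concatenated data. The
#' Markov chain restarts at every subject-session boundary: no transition
#' is counted across blocks. Inference is expectation-maximization on the
#' posterior density under weak conjugate priors (symmetric Dirichlet on
#' transition rows and the initial distribution, inverse-Wishart on state
#' covariances), so the reported objective -- log-likelihood plus log
#' prior -- is nondecreasing across iterations and the covariance updates
#' are always positive definite. The best of `n_restarts` k-means-seeded
#' restarts is returned.
#'
#' @param X rows x features matrix, or a `concat_timeseries` (its `data`
#'   and `block` are used).
#' @param blocks Per-row subject-session labels (ignored when `X` is a
#'   `concat_timeseries`); rows of a block must be contiguous.
#' @param K Number of states.
#' @param max_iter,tol EM stopping rule: stop when the relative objective
#'   change falls below `tol` or after `max_iter` iterations.
#' @param n_restarts Number of random restarts; the fit with the highest
#'   final objective is kept.
#' @param seed Integer seed; fixing it makes the fit bit-reproducible.
#' @param verbose Print per-restart progress.
#' @return Object of class `hmm_fit`: `model` ([hmm_model()]), `stc`
#'   ([state_timecourse()] of smoothed posteriors), `trace` (objective per
#'   iteration of the winning restart), `objective`, `converged`,
#'   `empty_states` (whether any state lost all occupancy during fitting).
#' @export
fit_hmm <- function(X, blocks = NULL, K = 12, max_iter = 500, tol = 1e-5,
                    n_restarts = 5, seed = 1, verbose = FALSE) {
  if (inherits(X, "concat_timeseries")) {
    blocks <- X$block
    X <- X$data
  }
  X <- as.matrix(X)
  stop_if(is.null(blocks), "blocks must be supplied for matrix input")
  block <- as_blocks(blocks, nrow(X), contiguous = TRUE)
  stop_if(K < 1, "K must be >= 1")
  stop_if(nrow(X) <= K, "need more rows than states")
  check_finite(X, "data")
  block_rows <- split_block_rows(block)
  psi_scale <- mean(apply(X, 2, stats::var))
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      model <- hmm_init(X, K, block_rows)
      trace <- numeric(0)
      prev <- -Inf
      converged <- FALSE
      empty <- FALSE
      est <- NULL
      for (it in seq_len(max_iter)) {
        est <- hmm_estep(X, block_rows, model)
        obj <- est$loglik + hmm_log_prior(model, psi_scale)
        trace <- c(trace, obj)
        if (it > 1 && abs(obj - prev) < tol * (abs(prev) + 1e-10)) {
          converged <- TRUE
          break
        }
        prev <- obj
        ms <- hmm_mstep(X, est, model, psi_scale)
        model <- ms$model
        empty <- empty || ms$empty
      }
      if (verbose)
        message(sprintf("restart %d: objective %.4f after %d iterations%s",
                        r, trace[length(trace)], length(trace),
                        if (converged) "" else " (not converged)"))
      if (is.null(best) || trace[length(trace)] > best$objective) {
        best <- list(model = model,
                     stc = state_timecourse(est$gamma, block),
                     trace = trace,
                     objective = trace[length(trace)],
                     converged = converged,
                     empty_states = empty)
      }
    }
  })
  if (!best$converged)
    warning("EM did not converge within max_iter; returning best iterate",
            call. = FALSE)
  if (best$empty_states)
    warning("one or more states had (near-)zero occupancy during fitting",
            call. = FALSE)
  class(best) <- "hmm_fit"
  best
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("hmm_fit: %d states, objective %.2f (%d iterations%s)\n",
              x$model$n_states, x$objective, length(x$trace),
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Posterior state probabilities under a fitted model
#'
#' Forward-backward smoothed marginals `P(s_t = k)` per subject-session
#' block, with the chain restarting at each block boundary.
#'
#' @param model An [hmm_model()].
#' @param X rows x features matrix (feature dimension must match the
#'   model), or a `concat_timeseries`.
#' @param blocks Per-row block labels (ignored for `concat_timeseries`).
#' @return A [state_timecourse()].
#' @export
posterior_decode <- function(model, X, blocks = NULL) {
  stopifnot(inherits(model, "hmm_model"))
  if (inherits(X, "concat_timeseries")) {
    blocks <- X$block
    X <- X$data
  }
  X <- as.matrix(X)
  stop_if(ncol(X) != ncol(model$means),
          sprintf("feature dimension %d does not match the model (%d)",
                  ncol(X), ncol(model$means)))
  block <- as_blocks(blocks, nrow(X), contiguous = TRUE)
  est <- hmm_estep(X, split_block_rows(block), model)
  state_timecourse(est$gamma, block)
}

#' Align estimated state labels to a reference labelling
#'
#' Finds the permutation of estimated state labels that maximizes
#' frame-wise agreement with a reference path (exhaustively for K <= 8,
#' greedily on the confusion matrix otherwise). Used for evaluating
#' recovery against ground truth; label identity in an HMM is arbitrary.
#'
#' @param reference,estimate Integer state sequences of equal length.
#' @param K Number of states.
#' @return List with `perm` (such that `perm[estimate]` best matches
#'   `reference`) and `accuracy` (agreement fraction after alignment).
#' @export
align_states <- function(reference, estimate, K) {
  stopifnot(length(reference) == length(estimate))
  conf <- matrix(0, K, K)   # conf[e, r] = frames with estimate e, reference r
  for (t in seq_along(reference))
    conf[estimate[t], reference[t]] <- conf[estimate[t], reference[t]] + 1
  if (K <= 8) {
    perms <- all_permutations(K)
    scores <- apply(perms, 1, function(p) sum(conf[cbind(seq_len(K), p)]))
    perm <- perms[which.max(scores), ]
  } else {
    perm <- integer(K)
    cf <- conf
    for (i in seq_len(K)) {
      j <- arrayInd(which.max(cf), dim(cf))
      perm[j[1]] <- j[2]
      cf[j[1], ] <- -1
      cf[, j[2]] <- -1
    }
  }
  list(perm = perm, accuracy = mean(perm[estimate] == reference))
}

#' Apply a state relabelling to a fitted model
#'
#' @param model An [hmm_model()].
#' @param perm Permutation from [align_states()]: state `k` of `model`
#'   becomes state `perm[k]`.
#' @return Relabelled [hmm_model()].
#' @export
permute_states <- function(model, perm) {
  inv <- order(perm)
  hmm_model(model$means[inv, , drop = FALSE],
            model$covariances[inv],
            model$transition[inv, inv, drop = FALSE],
            model$initial[inv])
}
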