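#' Oblique factor analysis of a behavioral battery
#'
#' Reduces the behavioral measures to `n_factors` correlated latent
#' factors: maximum-likelihood extraction on the correlation matrix
#' (measures are standardized internally, so results are invariant to
#' affine rescaling of any measure), promax oblique rotation (power 4),
#' and regression-method (Thurstone) factor scores.
#'
#' @param behavior data.frame or matrix of behavioral measures; non-numeric
#'   columns and columns named `subject`/`session` are dropped with a
#'   message.
#' @param n_factors Number of factors to extract (8 at the study default).
#' @param rotation `"promax"` (default) or `"none"`.
#' @param promax_power Promax power parameter.
#' @return Object of class `factor_solution`:
#'   \describe{
#'     \item{loadings}{measures x factors pattern matrix.}
#'     \item{Phi}{factor correlation matrix (identity when unrotated).}
#'     \item{scores}{rows x factors regression-method factor scores.}
#'     \item{uniquenesses, communalities}{per-measure variance split.}
#'     \item{labels}{factor labels (`NULL` until [label_factors()]).}
#'   }
#' @export
fit_factors <- function(behavior, n_factors = 8, rotation = c("promax", "none"),
                        promax_power = 4) {
  rotation <- match.arg(rotation)
  B <- behavior
  if (is.data.frame(B)) {
    drop <- names(B) %in% c("subject", "session") |
      !vapply(B, is.numeric, TRUE)
    if (any(drop))
      message("dropping non-measure column(s): ",
              paste(names(B)[drop], collapse = ", "))
    B <- as.matrix(B[, !drop, drop = FALSE])
  }
  B <- as.matrix(B)
  check_finite(B, "behavior measures")
  n <- nrow(B)
  stop_if(n <= n_factors, "need more rows than factors")
  stop_if(n <= ncol(B),
          "maximum-likelihood factor analysis needs more rows than measures")
  stop_if(any(apply(B, 2, stats::sd) == 0),
          "constant measure column(s) cannot be factor-analysed")
  Z <- scale(B)
  R <- stats::cor(B)
  fa <- tryCatch(
    stats::factanal(covmat = R, factors = n_factors, n.obs = n,
                    rotation = "none"),
    error = function(e) stop("factor extraction failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  L <- unclass(fa$loadings)
  if (rotation == "promax" && n_factors > 1) {
    pm <- stats::promax(L, m = promax_power)
    P <- unclass(pm$loadings)
    Phi <- solve(crossprod(pm$rotmat))
    Phi <- (Phi + t(Phi)) / 2
  } else {
    P <- L
    Phi <- diag(n_factors)
  }
  dimnames(Phi) <- list(paste0("factor", seq_len(n_factors)),
                        paste0("factor", seq_len(n_factors)))
  colnames(P) <- paste0("factor", seq_len(n_factors))
  rownames(P) <- colnames(B)
  # communality_i = (P Phi P')_ii; warn on Heywood cases and clip
  comm <- rowSums((P %*% Phi) * P)
  if (any(comm > 1 + 1e-6)) {
    warning("Heywood case: communality > 1 for ",
            paste(rownames(P)[comm > 1 + 1e-6], collapse = ", "),
            "; clipping", call. = FALSE)
    comm <- pmin(comm, 1)
  }
  # regression-method scores: Z R^{-1} S with structure matrix S = P Phi
  S <- P %*% Phi
  scores <- Z %*% solve(R, S)
  colnames(scores) <- colnames(P)
  rownames(scores) <- rownames(behavior)
  structure(list(loadings = P, Phi = Phi, scores = scores,
                 uniquenesses = pmax(0, 1 - comm), communalities = comm,
                 labels = NULL, n_factors = n_factors, n_obs = n,
                 rotation = rotation),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("factor_solution: %d measures -> %d factors (%s), n = %d\n",
              nrow(x$loadings), x$n_factors, x$rotation, x$n_obs))
  if (!is.null(x$labels))
    cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Label the factors of a solution
#'
#' Attaches qualitative factor labels, either user-supplied (in factor
#' order) or automatically from the measure with the largest absolute
#' loading on each factor.
#'
#' @param solution A [fit_factors()] result.
#' @param labels Character vector of length `n_factors`, or `NULL` for
#'   automatic naming. Duplicate labels are rejected.
#' @return The solution with `labels` set (and loading/score columns
#'   renamed accordingly).
#' @export
label_factors <- function(solution, labels = NULL) {
  stopifnot(inherits(solution, "factor_solution"))
  k <- solution$n_factors
  if (is.null(labels)) {
    labels <- vapply(seq_len(k), function(j) {
      rownames(solution$loadings)[which.max(abs(solution$loadings[, j]))]
    }, "")
    if (anyDuplicated(labels))
      labels <- make.unique(labels, sep = ".")
  }
  stop_if(length(labels) != k,
          sprintf("need exactly %d labels, got %d", k, length(labels)))
  stop_if(anyDuplicated(labels) > 0, "factor labels must be unique")
  solution$labels <- labels
  colnames(solution$loadings) <- labels
  colnames(solution$scores) <- labels
  dimnames(solution$Phi) <- list(labels, labels)
  solution
}

#' The study's eight behavioral factor labels
#'
#' Convenience constant with the qualitative names used for the
#' eight-factor solution of the 31-measure battery.
#'
#' @return Character vector of length 8.
#' @export
behavior_factor_labels <- function() {
  c("Processing Reaction Time", "Task General",
    "Working Memory Reaction Time", "Working Memory Precision Reaction Time",
    "Affect", "Processing Accuracy", "Arousal", "Impulsivity")
}
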